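#' Read a quantitative lipidomics CSV into a dataset
#'
#' The expected layout is the common lipidomics export: a header row of
#' sample names, a first column of lipid species names in any accepted
#' shorthand dialect, and numeric abundances (relative or molar) in the
#' remaining columns. Empty cells and \code{NA} are treated as missing, not
#' zero. Non-numeric abundance cells raise an error naming the offending
#' row. Duplicate species (same canonical label) are summed with a warning
#' before matching.
#'
#' @param path path to a CSV file.
#' @param db a \code{reaction_db} supplying the subclass registry.
#' @return an object of class \code{lipid_dataset}: list with
#'   \code{input} (one row per CSV row: raw name, parse result, canonical
#'   label), \code{species} (one row per distinct parsed species),
#'   \code{abundance} (species x samples matrix, rownames are canonical
#'   labels) and \code{samples}.
#' @export
read_dataset <- function(path, db = load_reaction_db()) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!nrow(raw) || ncol(raw) < 2L) {
    stop("configuration error: input must have a lipid-name column and at ",
         "least one sample column, with one row per species")
  }
  dataset_from_frame(raw, db = db)
}

# shared constructor for read_dataset() and simulate_dataset()
dataset_from_frame <- function(raw, db = load_reaction_db()) {
  names <- trimws(raw[[1L]])
  samples <- colnames(raw)[-1L]
  num <- matrix(NA_real_, nrow = nrow(raw), ncol = length(samples),
                dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    cell <- trimws(raw[[j + 1L]])
    blank <- is.na(cell) | !nzchar(cell) | toupper(cell) %in% c("NA", "NAN")
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!blank & is.na(val))
    if (length(bad)) {
      stop(sprintf("non-numeric abundance '%s' in row %d, sample '%s'",
                   cell[bad[1L]], bad[1L], samples[j]))
    }
    num[, j] <- val
  }
  parsed <- parse_lipids(names, registry = db$subclasses$code)
  ok <- parsed$status == "parsed"
  if (any(duplicated(parsed$label[ok]))) {
    dups <- unique(parsed$label[ok][duplicated(parsed$label[ok])])
    warning("duplicate species summed before matching: ",
            paste(dups, collapse = ", "))
  }
  labels <- sort(unique(parsed$label[ok]))
  ab <- matrix(NA_real_, nrow = length(labels), ncol = length(samples),
               dimnames = list(labels, samples))
  for (lab in labels) {
    rows <- which(ok & parsed$label == lab)
    if (length(rows) == 1L) {
      ab[lab, ] <- num[rows, ]
    } else {
      block <- num[rows, , drop = FALSE]
      all_na <- apply(block, 2L, function(x) all(is.na(x)))
      ab[lab, ] <- colSums(block, na.rm = TRUE)
      ab[lab, all_na] <- NA_real_
    }
  }
  species <- parsed[ok & !duplicated(parsed$label),
                    c("label", "subclass", "carbons", "double_bonds"),
                    drop = FALSE]
  species <- species[order(species$label), , drop = FALSE]
  rownames(species) <- NULL
  structure(list(input = parsed, species = species, abundance = ab,
                 samples = samples),
            class = "lipid_dataset")
}

#' @export
print.lipid_dataset <- function(x, ...) {
  cat(sprintf("<lipid_dataset> %d input rows, %d distinct species, %d samples\n",
              nrow(x$input), nrow(x$species), length(x$samples)))
  if (!is.null(x$classification)) {
    cat(sprintf("  processed %d / unprocessed %d / unrecognised %d\n",
                x$classification[["processed"]],
                x$classification[["unprocessed"]],
                x$classification[["unrecognised"]]))
  }
  invisible(x)
}

#' Describe the two-condition design of an experiment
#'
#' @param interest label of the condition of interest (e.g. treated, aged).
#' @param control label of the control condition.
#' @param assignment named character vector mapping each sample name to a
#'   condition label. Each condition needs at least two replicates (three
#'   or more are recommended).
#' @param paired logical; were replicates generated as matched pairs? When
#'   \code{TRUE} and \code{pairs} is omitted, samples are paired in the
#'   order they appear in \code{assignment}.
#' @param pairs optional data.frame with columns \code{interest} and
#'   \code{control} giving the matched sample names.
#' @return an object of class \code{condition_design}.
#' @export
condition_design <- function(interest, control, assignment, paired = FALSE,
                             pairs = NULL) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("assignment must be a named vector: sample name -> condition label")
  }
  n_i <- sum(assignment == interest)
  n_c <- sum(assignment == control)
  if (n_i < 2L || n_c < 2L) {
    stop("configuration error: minimum of two replicates per condition ",
         sprintf("(got %d '%s', %d '%s')", n_i, interest, n_c, control))
  }
  if (paired) {
    if (n_i != n_c) {
      stop("paired design needs equally many samples in both conditions")
    }
    if (is.null(pairs)) {
      pairs <- data.frame(
        interest = names(assignment)[assignment == interest],
        control = names(assignment)[assignment == control],
        stringsAsFactors = FALSE)
    }
    stopifnot(all(c("interest", "control") %in% names(pairs)))
    if (nrow(pairs) != n_i ||
        !setequal(pairs$interest, names(assignment)[assignment == interest]) ||
        !setequal(pairs$control, names(assignment)[assignment == control])) {
      stop("pairs must cover every sample of both conditions exactly once")
    }
  }
  structure(list(interest = interest, control = control,
                 assignment = assignment, paired = paired, pairs = pairs),
            class = "condition_design")
}

round3 <- function(x) sprintf("%.3f", x)

#' Export a scored network as a node-link JSON or TXT edge list
#'
#' JSON documents carry a \code{nodes} array (label, subclass, status) and
#' an \code{edges} array (reaction, substrate, product, z, p, status and
#' the instantiating species pairs). The TXT format is the human-readable
#' edge list \code{"substrate -> product\tz\tstatus"}. Both outputs are
#' byte-stable for a fixed input and configuration: nodes and edges are
#' emitted in lexicographic order and z is fixed to three decimals.
#'
#' Node status summarises the strongest incident edge call (active edges
#' win over suppressed, which win over none).
#'
#' @param network a scored \code{reaction_network}.
#' @param path output file path.
#' @param format \code{"json"} or \code{"txt"}.
#' @return \code{path}, invisibly.
#' @seealso [import_graph()] for the JSON round trip.
#' @export
export_graph <- function(network, path, format = c("json", "txt")) {
  format <- match.arg(format)
  stopifnot(isTRUE(network$scored))
  e <- network$edges[order(network$edges$substrate_node,
                           network$edges$product_node), , drop = FALSE]
  if (format == "txt") {
    lines <- sprintf("%s -> %s\t%s\t%s", e$substrate_node, e$product_node,
                     round3(e$z), e$status)
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(lines, con)
    return(invisible(path))
  }
  node_status <- vapply(network$nodes$label, function(l) {
    st <- e$status[e$substrate_node == l | e$product_node == l]
    if ("active" %in% st) "active"
    else if ("suppressed" %in% st) "suppressed"
    else "none"
  }, character(1))
  nodes <- lapply(seq_len(nrow(network$nodes)), function(i) {
    list(label = network$nodes$label[i],
         subclass = network$nodes$subclass[i],
         status = unname(node_status[i]))
  })
  edges <- lapply(seq_len(nrow(e)), function(i) {
    pr <- network$pairs[network$pairs$edge_key == e$edge_key[i], , drop = FALSE]
    pr <- pr[order(pr$substrate_label, pr$product_label), , drop = FALSE]
    list(reaction = e$reaction[i],
         substrate = e$substrate_node[i],
         product = e$product_node[i],
         kind = e$kind[i],
         z = as.numeric(round3(e$z[i])),
         p = as.numeric(round3(e$p[i])),
         status = e$status[i],
         genes = e$genes[i],
         species_pairs = lapply(seq_len(nrow(pr)), function(k) {
           list(substrate = pr$substrate_label[k],
                product = pr$product_label[k],
                fa = if (is.na(pr$fa_label[k])) NULL else pr$fa_label[k])
         }))
  })
  doc <- list(level = network$level, type = network$type,
              nodes = nodes, edges = edges)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(json, con)
  invisible(path)
}

#' Re-import a network exported as node-link JSON
#'
#' @param path path to a JSON file written by [export_graph()].
#' @return a list with \code{nodes} and \code{edges} data.frames matching
#'   the exported network's node and edge sets.
#' @export
import_graph <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  list(level = doc$level, type = doc$type,
       nodes = doc$nodes, edges = doc$edges)
}

#' Export the result tables of a scored network
#'
#' Writes the four result tables (active and suppressed chains, active and
#' suppressed single reactions; columns \code{chain}, \code{z} to three
#' decimals, \code{genes}) plus a per-edge species table listing, for each
#' subclass-level edge, all molecular species of the substrate and product
#' subclasses flagged as selected (instantiating a pair) or not.
#'
#' @param network a scored \code{reaction_network}.
#' @param dir output directory (created if absent).
#' @param alpha significance level; defaults to the scoring level.
#' @param max_len chain length cap, as in [enumerate_chains()].
#' @param subset optional pathway subset name.
#' @param db the \code{reaction_db} for gene annotation.
#' @param dataset optional \code{lipid_dataset}; required for the
#'   species-pair table's non-selected species.
#' @return named character vector of the files written, invisibly.
#' @export
export_tables <- function(network, dir, alpha = NULL, max_len = 6,
                          subset = NULL, db = load_reaction_db(),
                          dataset = NULL) {
  stopifnot(isTRUE(network$scored))
  if (is.null(alpha)) alpha <- network$alpha
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv <- function(df, file) {
    con <- file(file.path(dir, file), "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    file.path(dir, file)
  }
  out <- character(0)
  for (st in c("active", "suppressed")) {
    ch <- enumerate_chains(network, status = st, alpha = alpha,
                           max_len = max_len, subset = subset, db = db)
    ch_tab <- data.frame(chain = ch$chain, z = round3(ch$z),
                         genes = ch$genes, stringsAsFactors = FALSE)
    out[paste0(st, "_pathways")] <- write_tsv(ch_tab,
                                              paste0(st, "_pathways.tsv"))
    e <- network$edges[!is.na(network$edges$z) &
                         network$edges$status == st, , drop = FALSE]
    e <- e[order(-abs(e$z)), , drop = FALSE]
    re_tab <- data.frame(
      chain = paste(e$substrate_node, e$product_node, sep = "->"),
      z = round3(e$z), genes = e$genes, stringsAsFactors = FALSE)
    out[paste0(st, "_reactions")] <- write_tsv(re_tab,
                                               paste0(st, "_reactions.tsv"))
  }
  if (!is.null(dataset)) {
    rows <- list()
    e <- network$edges
    for (i in seq_len(nrow(e))) {
      pr <- network$pairs[network$pairs$edge_key == e$edge_key[i], ]
      rid <- match(e$reaction[i], db$reactions$id)
      sub_code <- db$reactions$substrate[rid]
      prod_code <- db$reactions$product[rid]
      sel <- unique(c(pr$substrate_label, pr$product_label))
      cand <- dataset$species[dataset$species$subclass %in%
                                c(sub_code, prod_code), , drop = FALSE]
      if (!nrow(cand)) next
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = paste(e$substrate_node[i], e$product_node[i], sep = "->"),
        species = cand$label,
        role = ifelse(cand$subclass == sub_code, "substrate", "product"),
        selected = ifelse(cand$label %in% sel, "yes", "no"),
        stringsAsFactors = FALSE)
    }
    pair_tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(reaction = character(0), species = character(0),
                 role = character(0), selected = character(0))
    out["species_pairs"] <- write_tsv(pair_tab, "species_pairs.tsv")
  }
  invisible(out)
}

#' Run a full pathway analysis
#'
#' Convenience orchestrator: read (or accept) a dataset, classify its
#' species, build and score the requested network, enumerate significant
#' chains, and optionally write all exports to a directory.
#'
#' @param input path to a CSV file, or a \code{lipid_dataset}.
#' @param design a \code{condition_design}.
#' @param db a \code{reaction_db}.
#' @param level,type network flavour, see [build_network()].
#' @param status \code{"active"} or \code{"suppressed"}.
#' @param alpha significance level.
#' @param mode \code{"all"} for every significant chain,
#'   \code{"most_extreme"} for one greedy route per starting substrate.
#' @param subset optional pathway subset name.
#' @param max_len chain length cap.
#' @param statistic activity statistic, see [reaction_activity()].
#' @param require_fa_for_deacylation see [match_reactions()].
#' @param outdir optional output directory for graph + table exports.
#' @return list with \code{dataset}, \code{network} (scored),
#'   \code{chains}, and \code{files} (paths written, when \code{outdir}
#'   was given).
#' @export
run_analysis <- function(input, design, db = load_reaction_db(),
                         level = c("subclass", "species"),
                         type = c("lipid", "fa"),
                         status = c("active", "suppressed"),
                         alpha = 0.05, mode = c("all", "most_extreme"),
                         subset = NULL, max_len = 6,
                         statistic = c("log_ratio", "fraction"),
                         require_fa_for_deacylation = TRUE,
                         outdir = NULL) {
  level <- match.arg(level); type <- match.arg(type)
  status <- match.arg(status); mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  dataset <- if (inherits(input, "lipid_dataset")) input else
    read_dataset(input, db = db)
  dataset <- classify_species(dataset, db,
                              require_fa_for_deacylation = require_fa_for_deacylation)
  network <- build_network(dataset, db, level = level, type = type,
                           require_fa_for_deacylation = require_fa_for_deacylation)
  network <- score_network(network, dataset, design, alpha = alpha,
                           statistic = statistic)
  chains <- if (mode == "all") {
    enumerate_chains(network, status = status, alpha = alpha,
                     max_len = max_len, subset = subset, db = db)
  } else {
    most_extreme_routes(network, status = status, alpha = alpha,
                        max_len = max_len, subset = subset, db = db)
  }
  files <- NULL
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    files <- export_tables(network, outdir, alpha = alpha, max_len = max_len,
                           subset = subset, db = db, dataset = dataset)
    export_graph(network, file.path(outdir, "network.json"), "json")
    export_graph(network, file.path(outdir, "network.txt"), "txt")
    files <- c(files, json = file.path(outdir, "network.json"),
               txt = file.path(outdir, "network.txt"))
    cls <- data.frame(species = dataset$input$raw_name,
                      label = dataset$input$label,
                      classification = dataset$input$classification,
                      stringsAsFactors = FALSE)
    con <- file(file.path(outdir, "classification.tsv"), "wb")
    utils::write.table(cls, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    files <- c(files, classification = file.path(outdir, "classification.tsv"))
  }
  list(dataset = dataset, network = network, chains = chains, files = files)
}
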