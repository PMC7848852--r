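#' Instantiate database reactions against the species in a dataset
#'
#' Scans every reaction of the database for species pairs in the dataset
#' that satisfy the reaction's composition-balance rule:
#' \itemize{
#'   \item \code{headgroup_transfer} / \code{sphingoid_step}: substrate and
#'     product species with identical sum composition;
#'   \item \code{acylation}: product composition equals substrate plus one
#'     fatty-acid (or fatty-acyl-CoA) species present in the dataset;
#'   \item \code{deacylation}: substrate composition equals product plus one
#'     such fatty-acid species (the fatty-acid partner requirement can be
#'     relaxed with \code{require_fa_for_deacylation = FALSE}, in which case
#'     any substrate/product pair whose compositions differ by a plausible
#'     acyl chain, i.e. the difference itself, is matched without the
#'     partner being observed);
#'   \item \code{fa_elongation} / \code{fa_desaturation}: the two exact
#'     fatty-acid species named by the (composition-specific) reaction.
#' }
#'
#' @param species data.frame with columns \code{label}, \code{subclass},
#'   \code{carbons}, \code{double_bonds} (one row per distinct species).
#' @param db a \code{reaction_db}.
#' @param require_fa_for_deacylation logical; default \code{TRUE}.
#' @return data.frame of instantiated species pairs with columns
#'   \code{reaction}, \code{kind}, \code{substrate_label},
#'   \code{product_label}, \code{fa_label} (\code{NA} where no partner is
#'   involved).
#' @export
match_reactions <- function(species, db, require_fa_for_deacylation = TRUE) {
  fa_pool <- species[species$subclass %in% c("FA", "FACoA"), , drop = FALSE]
  out <- vector("list", nrow(db$reactions))
  for (i in seq_len(nrow(db$reactions))) {
    r <- db$reactions[i, ]
    out[[i]] <- match_one_reaction(r, species, fa_pool,
                                   require_fa_for_deacylation)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(reaction = character(0), kind = character(0),
                      substrate_label = character(0),
                      product_label = character(0),
                      fa_label = character(0), stringsAsFactors = FALSE)
  }
  out
}

match_one_reaction <- function(r, species, fa_pool, require_fa) {
  pair_row <- function(s_label, p_label, fa_label = NA_character_) {
    data.frame(reaction = r$id, kind = r$kind, substrate_label = s_label,
               product_label = p_label, fa_label = fa_label,
               stringsAsFactors = FALSE)
  }
  if (r$kind %in% c("fa_elongation", "fa_desaturation")) {
    s_label <- reaction_node(r, "substrate")
    p_label <- reaction_node(r, "product")
    fa_sub <- species$subclass == "FA"
    if (s_label %in% species$label[fa_sub] &&
        p_label %in% species$label[fa_sub]) {
      return(pair_row(s_label, p_label))
    }
    return(NULL)
  }
  S <- species[species$subclass == r$substrate, , drop = FALSE]
  P <- species[species$subclass == r$product, , drop = FALSE]
  if (!nrow(S) || !nrow(P)) return(NULL)
  p_key <- paste(P$carbons, P$double_bonds)
  rows <- list()
  if (r$kind %in% c("headgroup_transfer", "sphingoid_step")) {
    idx <- match(paste(S$carbons, S$double_bonds), p_key)
    hit <- which(!is.na(idx))
    for (h in hit) rows[[length(rows) + 1L]] <-
      pair_row(S$label[h], P$label[idx[h]])
  } else if (r$kind == "acylation") {
    if (nrow(fa_pool)) {
      for (si in seq_len(nrow(S))) for (fi in seq_len(nrow(fa_pool))) {
        idx <- match(paste(S$carbons[si] + fa_pool$carbons[fi],
                           S$double_bonds[si] + fa_pool$double_bonds[fi]),
                     p_key)
        if (!is.na(idx)) rows[[length(rows) + 1L]] <-
          pair_row(S$label[si], P$label[idx], fa_pool$label[fi])
      }
    }
  } else if (r$kind == "deacylation") {
    if (require_fa) {
      if (nrow(fa_pool)) {
        for (pi in seq_len(nrow(P))) for (fi in seq_len(nrow(fa_pool))) {
          s_idx <- match(paste(P$carbons[pi] + fa_pool$carbons[fi],
                               P$double_bonds[pi] + fa_pool$double_bonds[fi]),
                         paste(S$carbons, S$double_bonds))
          if (!is.na(s_idx)) rows[[length(rows) + 1L]] <-
            pair_row(S$label[s_idx], P$label[pi], fa_pool$label[fi])
        }
      }
    } else {
      # any substrate strictly larger than the product by a plausible chain
      for (si in seq_len(nrow(S))) for (pi in seq_len(nrow(P))) {
        dc <- S$carbons[si] - P$carbons[pi]
        dd <- S$double_bonds[si] - P$double_bonds[pi]
        if (dc >= 2 && dd >= 0) rows[[length(rows) + 1L]] <-
          pair_row(S$label[si], P$label[pi])
      }
    }
  }
  if (!length(rows)) return(NULL)
  unique(do.call(rbind, rows))
}

#' Classify dataset species as unrecognised, unprocessed or processed
#'
#' Every input row falls in exactly one category: \emph{unrecognised} when
#' the name could not be parsed or its subclass is outside the registry;
#' \emph{processed} when the species participates in at least one
#' instantiated reaction edge (as substrate, product or fatty-acid partner);
#' \emph{unprocessed} otherwise. Only processed species feed the downstream
#' analysis.
#'
#' @param dataset a \code{lipid_dataset}.
#' @param db a \code{reaction_db}.
#' @param require_fa_for_deacylation see [match_reactions()].
#' @return the dataset with a \code{classification} column added to its
#'   \code{input} table and a \code{classification} count summary attached.
#' @export
classify_species <- function(dataset, db, require_fa_for_deacylation = TRUE) {
  stopifnot(inherits(dataset, "lipid_dataset"))
  pairs <- match_reactions(dataset$species, db,
                           require_fa_for_deacylation = require_fa_for_deacylation)
  processed <- unique(c(pairs$substrate_label, pairs$product_label,
                        pairs$fa_label))
  processed <- processed[!is.na(processed)]
  cls <- ifelse(dataset$input$status != "parsed", "unrecognised",
                ifelse(dataset$input$label %in% processed, "processed",
                       "unprocessed"))
  dataset$input$classification <- cls
  dataset$classification <- c(
    unrecognised = sum(cls == "unrecognised"),
    unprocessed = sum(cls == "unprocessed"),
    processed = sum(cls == "processed"))
  dataset
}

#' Build the reaction network induced by a dataset
#'
#' Matches the dataset's species against the reaction database and
#' assembles the directed reaction graph, either at the lipid-species level
#' (nodes are canonical species labels such as \code{"PC(34:1)"}) or
#' aggregated at the subclass level (nodes are subclass codes). The
#' \code{"fa"} network type restricts to fatty-acid species and
#' elongation/desaturation reactions (always species-level nodes, e.g.
#' \code{"FA(22:5)"}); the \code{"lipid"} type covers everything else.
#' Nodes and edges are ordered lexicographically so that network
#' construction is deterministic.
#'
#' @param dataset a \code{lipid_dataset}.
#' @param db a \code{reaction_db}; defaults to the packaged database.
#' @param level \code{"subclass"} (default) or \code{"species"}.
#' @param type \code{"lipid"} (default) or \code{"fa"}.
#' @param require_fa_for_deacylation see [match_reactions()].
#' @return an object of class \code{reaction_network}: list with
#'   \code{nodes} (label, subclass), \code{edges} (edge_key, reaction,
#'   kind, substrate_node, product_node, genes; z/p/status after
#'   [score_network()]), \code{pairs} (per-edge species pairs),
#'   \code{level}, \code{type}, \code{scored}. A dataset with no processed
#'   species yields an empty network (with a message), not an error.
#' @export
build_network <- function(dataset, db = load_reaction_db(),
                          level = c("subclass", "species"),
                          type = c("lipid", "fa"),
                          require_fa_for_deacylation = TRUE) {
  level <- match.arg(level)
  type <- match.arg(type)
  stopifnot(inherits(dataset, "lipid_dataset"))
  pairs <- match_reactions(dataset$species, db,
                           require_fa_for_deacylation = require_fa_for_deacylation)
  fa_kinds <- c("fa_elongation", "fa_desaturation")
  if (type == "fa") {
    pairs <- pairs[pairs$kind %in% fa_kinds, , drop = FALSE]
    level <- "species"
  } else {
    pairs <- pairs[!(pairs$kind %in% fa_kinds), , drop = FALSE]
  }
  rx <- db$reactions
  if (level == "species") {
    pairs$substrate_node <- pairs$substrate_label
    pairs$product_node <- pairs$product_label
  } else {
    ri <- match(pairs$reaction, rx$id)
    pairs$substrate_node <- rx$substrate[ri]
    pairs$product_node <- rx$product[ri]
  }
  pairs$edge_key <- paste(pairs$reaction, pairs$substrate_node,
                          pairs$product_node, sep = "|")
  if (level == "species") {
    # one species pair per edge; several balancing FA partners collapse
    pairs <- pairs[!duplicated(pairs$edge_key), , drop = FALSE]
  }
  ek <- !duplicated(pairs$edge_key)
  edges <- data.frame(edge_key = pairs$edge_key[ek],
                      reaction = pairs$reaction[ek],
                      kind = pairs$kind[ek],
                      substrate_node = pairs$substrate_node[ek],
                      product_node = pairs$product_node[ek],
                      stringsAsFactors = FALSE)
  edges$genes <- vapply(edges$reaction, function(id) {
    paste(unique(rx$genes[[match(id, rx$id)]]), collapse = ", ")
  }, character(1))
  edges <- edges[order(edges$substrate_node, edges$product_node,
                       edges$reaction), , drop = FALSE]
  rownames(edges) <- NULL
  node_labels <- sort(unique(c(edges$substrate_node, edges$product_node)))
  node_subclass <- vapply(node_labels, function(l) {
    sp <- split_label(l)
    if (is.null(sp)) l else sp$subclass
  }, character(1))
  nodes <- data.frame(label = node_labels, subclass = unname(node_subclass),
                      stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    message("no reaction could be instantiated from this dataset; ",
            "the network is empty")
  }
  structure(list(nodes = nodes, edges = edges,
                 pairs = pairs[, c("edge_key", "reaction", "kind",
                                   "substrate_label", "product_label",
                                   "fa_label")],
                 level = level, type = type, scored = FALSE),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %s-level %s network: %d nodes, %d edges%s\n",
              x$level, x$type, nrow(x$nodes), nrow(x$edges),
              if (isTRUE(x$scored)) " (scored)" else ""))
  invisible(x)
}

# igraph view of the (scored) network, edges with usable z only
network_graph <- function(network) {
  edges <- network$edges
  if (!is.null(edges$z)) edges <- edges[!is.na(edges$z), , drop = FALSE]
  igraph::graph_from_data_frame(
    edges[, c("substrate_node", "product_node",
              setdiff(names(edges), c("substrate_node", "product_node")))],
    directed = TRUE,
    vertices = network$nodes$label[network$nodes$label %in%
                                     c(edges$substrate_node, edges$product_node)])
}
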