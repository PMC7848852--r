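edge_lookup <- function(network) {
  e <- network$edges
  stats::setNames(seq_len(nrow(e)), paste(e$substrate_node, e$product_node,
                                          sep = "\r"))
}

chain_frame <- function(network, db, node_seqs, alpha) {
  e <- network$edges
  lut <- edge_lookup(network)
  crit <- z_crit(alpha)
  rows <- lapply(node_seqs, function(nodes) {
    ids <- lut[paste(nodes[-length(nodes)], nodes[-1L], sep = "\r")]
    z_steps <- e$z[ids]
    zp <- combine_pathway(z_steps)
    genes <- unique(unlist(lapply(e$reaction[ids], function(rid) {
      db$reactions$genes[[match(rid, db$reactions$id)]]
    })))
    status <- if (zp > crit) "active" else if (zp < -crit) "suppressed" else "none"
    data.frame(chain = paste(nodes, collapse = "->"),
               n_steps = length(nodes) - 1L, z = zp, status = status,
               genes = paste(genes, collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chain = character(0), n_steps = integer(0),
                      z = numeric(0), status = character(0),
                      genes = character(0), stringsAsFactors = FALSE)
  }
  out
}

restrict_to_subset <- function(network, db, subset) {
  if (is.null(subset)) return(network)
  member <- db$subsets$reaction_id[db$subsets$subset == subset]
  if (!length(member)) stop("unknown pathway subset: ", subset)
  keep <- network$edges$reaction %in% member
  network$edges <- network$edges[keep, , drop = FALSE]
  network$pairs <- network$pairs[network$pairs$edge_key %in%
                                   network$edges$edge_key, , drop = FALSE]
  network
}

#' Enumerate significant reaction chains in a scored network
#'
#' Walks every simple directed path (no repeated node) of one to
#' \code{max_len} reactions starting from every node, combines the step
#' Z-scores of each path into a pathway Z-score with [combine_pathway()],
#' and keeps the chains whose score is significant in the requested
#' direction: \code{status = "active"} keeps \eqn{z_{path} > z_{crit}},
#' \code{"suppressed"} keeps \eqn{z_{path} < -z_{crit}}. Chains of every
#' length are reported, including single reactions. Edges without a usable
#' score are not traversed.
#'
#' @param network a scored \code{reaction_network}.
#' @param status \code{"active"} (default) or \code{"suppressed"}.
#' @param alpha significance level (default the level the network was
#'   scored at).
#' @param max_len maximum number of reactions per chain; the default of 6
#'   keeps enumeration finite on cyclic subgraphs.
#' @param subset optional name of a stored pathway subset; enumeration is
#'   then restricted to that subset's reactions.
#' @param db the \code{reaction_db} used for gene annotation.
#' @return data.frame with columns \code{chain} (labels joined by
#'   \code{"->"}), \code{n_steps}, \code{z}, \code{status}, \code{genes}
#'   (comma-separated, de-duplicated in chain order), sorted by
#'   \eqn{|z|} descending.
#' @export
enumerate_chains <- function(network, status = c("active", "suppressed"),
                             alpha = NULL, max_len = 6, subset = NULL,
                             db = load_reaction_db()) {
  status <- match.arg(status)
  stopifnot(isTRUE(network$scored))
  if (is.null(alpha)) alpha <- network$alpha
  network <- restrict_to_subset(network, db, subset)
  out <- all_chain_scores(network, db, alpha, max_len)
  out <- out[out$status == status, , drop = FALSE]
  out <- out[order(-abs(out$z), out$chain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# every simple path of >= 1 edge, scored; no significance filter
all_chain_scores <- function(network, db, alpha, max_len) {
  edges <- network$edges[!is.na(network$edges$z), , drop = FALSE]
  if (!nrow(edges)) {
    return(chain_frame(network, db, list(), alpha))
  }
  net <- network; net$edges <- edges
  g <- network_graph(net)
  seqs <- list()
  for (v in sort(names(igraph::V(g)))) {
    paths <- igraph::all_simple_paths(g, from = v, cutoff = max_len)
    for (p in paths) {
      if (length(p) >= 2L) seqs[[length(seqs) + 1L]] <- names(p)
    }
  }
  chain_frame(net, db, seqs, alpha)
}

#' Most active (or most suppressed) route from each starting substrate
#'
#' Where one substrate feeds several pathways, a single route per starting
#' substrate is selected by a greedy rule: at each branching the
#' continuation reaction with the highest Z-score is taken (the lowest for
#' suppressed routes), walking only through sign-consistent edges
#' (positive scores for active routes, negative for suppressed) and never
#' revisiting a node. Ties between continuations are broken toward the
#' lexicographically smaller product label, so the selection is
#' deterministic. The walk's combined score is then subjected to the usual
#' significance threshold; routes that fail it are dropped.
#'
#' @inheritParams enumerate_chains
#' @return data.frame in the same shape as [enumerate_chains()], at most
#'   one route per starting substrate.
#' @export
most_extreme_routes <- function(network, status = c("active", "suppressed"),
                                alpha = NULL, max_len = 6, subset = NULL,
                                db = load_reaction_db()) {
  status <- match.arg(status)
  stopifnot(isTRUE(network$scored))
  if (is.null(alpha)) alpha <- network$alpha
  network <- restrict_to_subset(network, db, subset)
  edges <- network$edges[!is.na(network$edges$z), , drop = FALSE]
  sgn <- if (status == "active") 1 else -1
  seqs <- list()
  for (start in sort(unique(edges$substrate_node))) {
    nodes <- start
    current <- start
    repeat {
      cand <- edges[edges$substrate_node == current &
                      !(edges$product_node %in% nodes) &
                      sgn * edges$z > 0, , drop = FALSE]
      if (!nrow(cand) || length(nodes) > max_len) break
      cand <- cand[order(-sgn * cand$z, cand$product_node), , drop = FALSE]
      nxt <- cand$product_node[1L]
      nodes <- c(nodes, nxt)
      current <- nxt
    }
    if (length(nodes) >= 2L) seqs[[length(seqs) + 1L]] <- nodes
  }
  net <- network; net$edges <- edges
  out <- chain_frame(net, db, seqs, alpha)
  out <- out[out$status == status, , drop = FALSE]
  out <- out[order(-abs(out$z), out$chain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter network nodes by one or two substring queries
#'
#' Case-insensitive substring matching on canonical node labels, optionally
#' combining two queries with \code{"AND"} (both must match) or \code{"OR"}
#' (either matches). On a species-level graph, searching \code{"PC"} AND
#' \code{"34:0"} selects \code{PC(34:0)} and \code{O-PC(34:0)}.
#'
#' @param network a \code{reaction_network}.
#' @param query1 first substring (required, non-empty).
#' @param op \code{"AND"}, \code{"OR"}, or \code{NULL} for a single query.
#' @param query2 second substring; required exactly when \code{op} is given.
#' @return sorted character vector of matching node labels.
#' @export
filter_nodes <- function(network, query1, op = NULL, query2 = NULL) {
  stopifnot(is.character(query1), nzchar(query1))
  if (!is.null(op)) {
    op <- match.arg(op, c("AND", "OR"))
    if (is.null(query2)) stop("query2 is required when op is given")
  }
  labels <- network$nodes$label
  m1 <- grepl(query1, labels, fixed = TRUE, ignore.case = FALSE) |
    grepl(tolower(query1), tolower(labels), fixed = TRUE)
  if (is.null(op)) {
    hits <- m1
  } else {
    m2 <- if (nzchar(query2)) {
      grepl(tolower(query2), tolower(labels), fixed = TRUE)
    } else rep(FALSE, length(labels))
    hits <- if (op == "AND") m1 & m2 else m1 | m2
  }
  sort(labels[hits])
}
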