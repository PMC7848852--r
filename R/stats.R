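#' One-sided normal critical value for a significance level
#'
#' The default level 0.05 gives 1.645: a reaction or pathway is called
#' significantly changed when its Z-score exceeds this value (active) or
#' falls below its negative (suppressed).
#'
#' @param alpha significance level in (0, 1).
#' @return the standard-normal quantile \eqn{\Phi^{-1}(1 - \alpha)}.
#' @examples
#' z_crit(0.05)  # 1.645
#' @export
z_crit <- function(alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  stats::qnorm(1 - alpha)
}

#' Combine reaction Z-scores into a pathway Z-score
#'
#' Stouffer combination: for a chain of k reactions with scores
#' \eqn{z_1, \dots, z_k}, the pathway score is
#' \eqn{z_{path} = \sum z_i / \sqrt{k}}. A single-reaction chain keeps its
#' reaction score unchanged.
#'
#' @param z numeric vector of reaction Z-scores (non-empty).
#' @return the combined pathway Z-score.
#' @examples
#' combine_pathway(c(3.083, 2.054))  # 3.632
#' @export
combine_pathway <- function(z) {
  if (!length(z)) stop("cannot combine an empty chain")
  if (anyNA(z)) stop("cannot combine NA scores")
  sum(z) / sqrt(length(z))
}

#' Solve a single-step Z-score from a chain score
#'
#' Inverts the Stouffer combination: given a k-step chain score and the
#' scores of k-1 of its steps, recovers the remaining step's score,
#' \eqn{z = z_{chain} \sqrt{k} - \sum z_{known}}.
#'
#' @param z_chain combined score of the full chain.
#' @param k number of reactions in the chain.
#' @param z_known scores of the known steps (length k-1, possibly empty for
#'   k = 1).
#' @return the remaining single-step Z-score.
#' @examples
#' invert_chain_z(2.657, 2, 1.668)  # the first step of a two-step chain
#' @export
invert_chain_z <- function(z_chain, k, z_known = numeric(0)) {
  stopifnot(k >= 1, length(z_known) == k - 1)
  z_chain * sqrt(k) - sum(z_known)
}

#' Per-sample reaction activity
#'
#' For each sample, the activity of an instantiated reaction edge is the log
#' ratio of total product abundance to total substrate abundance,
#' \eqn{a_j = \ln((\sum P_j + \epsilon) / (\sum S_j + \epsilon))}, with a
#' pseudo-count \eqn{\epsilon} to tolerate zeros. An alternative statistic,
#' the product fraction \eqn{\sum P_j / (\sum P_j + \sum S_j)}, is available
#' behind the same interface.
#'
#' Samples where every contributing abundance is missing, or where both
#' sides are entirely zero, yield \code{NA} and are dropped for the edge.
#'
#' @param substrate numeric matrix (species x samples) of substrate-side
#'   abundances; a vector is treated as one species.
#' @param product matching matrix for the product side.
#' @param eps pseudo-count added to both sums (log-ratio statistic only).
#' @param statistic \code{"log_ratio"} (default) or \code{"fraction"}.
#' @return numeric vector of per-sample activities.
#' @export
reaction_activity <- function(substrate, product, eps = 0,
                              statistic = c("log_ratio", "fraction")) {
  statistic <- match.arg(statistic)
  if (is.null(dim(substrate))) substrate <- matrix(substrate, nrow = 1L)
  if (is.null(dim(product))) product <- matrix(product, nrow = 1L)
  stopifnot(ncol(substrate) == ncol(product))
  s_all_na <- apply(substrate, 2L, function(x) all(is.na(x)))
  p_all_na <- apply(product, 2L, function(x) all(is.na(x)))
  s <- colSums(substrate, na.rm = TRUE)
  p <- colSums(product, na.rm = TRUE)
  a <- if (statistic == "log_ratio") {
    log((p + eps) / (s + eps))
  } else {
    p / (p + s)
  }
  a[s_all_na | p_all_na] <- NA_real_
  a[s == 0 & p == 0] <- NA_real_
  a
}

#' Z-score of a reaction between two conditions
#'
#' Compares per-sample activities between the condition of interest and the
#' control. Unpaired designs use a Welch-style statistic
#' \eqn{z = (\bar a_I - \bar a_C) / \sqrt{s_I^2/n_I + s_C^2/n_C}}; paired
#' designs use the one-sample statistic on per-pair differences,
#' \eqn{z = \bar d / (s_d / \sqrt{n})}. The score is interpreted on the
#' standard-normal scale and the one-sided tail probability is
#' \eqn{p = 1 - \Phi(z)}; a positive score means the balance is shifted
#' toward the product in the condition of interest.
#'
#' Degenerate inputs: zero variance with equal means gives z = 0; zero
#' variance with unequal means gives a signed infinite score (status decided
#' by sign).
#'
#' @param activity_interest per-sample activities in the condition of
#'   interest (paired designs: ordered to match \code{activity_control}).
#' @param activity_control per-sample activities in the control condition.
#' @param paired logical; interpret the two vectors as matched pairs.
#' @param alpha significance level used to call the status.
#' @return a list of class \code{reaction_score} with elements \code{z},
#'   \code{p}, \code{status} (\code{"active"}, \code{"suppressed"} or
#'   \code{"none"}), \code{n_interest}, \code{n_control}.
#' @export
reaction_z <- function(activity_interest, activity_control, paired = FALSE,
                       alpha = 0.05) {
  crit <- z_crit(alpha)
  if (paired) {
    if (length(activity_interest) != length(activity_control)) {
      stop("paired design needs equally many interest and control samples")
    }
    d <- activity_interest - activity_control
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < 2L) return(unscored_reaction())
    sd_d <- stats::sd(d)
    z <- if (sd_d == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else {
      mean(d) / (sd_d / sqrt(n))
    }
    n_i <- n_c <- n
  } else {
    ai <- activity_interest[!is.na(activity_interest)]
    ac <- activity_control[!is.na(activity_control)]
    n_i <- length(ai); n_c <- length(ac)
    if (n_i < 2L || n_c < 2L) return(unscored_reaction())
    se2 <- stats::var(ai) / n_i + stats::var(ac) / n_c
    dm <- mean(ai) - mean(ac)
    z <- if (se2 == 0) {
      if (dm == 0) 0 else sign(dm) * Inf
    } else {
      dm / sqrt(se2)
    }
  }
  status <- if (is.nan(z)) "none"
    else if (z > crit) "active"
    else if (z < -crit) "suppressed"
    else "none"
  structure(list(z = z, p = 1 - stats::pnorm(z), status = status,
                 n_interest = n_i, n_control = n_c),
            class = "reaction_score")
}

unscored_reaction <- function() {
  structure(list(z = NA_real_, p = NA_real_, status = "none",
                 n_interest = NA_integer_, n_control = NA_integer_),
            class = "reaction_score")
}

#' Score every edge of a reaction network
#'
#' Computes per-sample activities and the reaction Z-score for each
#' instantiated edge of a network, comparing the design's condition of
#' interest against its control.
#'
#' Edges are scored from the dataset's abundance matrix. For subclass-level
#' edges the substrate (product) side sums all distinct substrate (product)
#' species occurring in the edge's species pairs; fatty-acid partner species
#' are not part of the activity. The pseudo-count is half the smallest
#' positive abundance in the dataset. Edges with fewer than two usable
#' replicates per condition are left unscored (status \code{"none"}).
#'
#' @param network an unscored \code{reaction_network} from
#'   [build_network()].
#' @param dataset the \code{lipid_dataset} the network was built from.
#' @param design a \code{condition_design}.
#' @param alpha significance level for the status call.
#' @param statistic per-sample activity statistic, see
#'   [reaction_activity()].
#' @return the network with \code{z}, \code{p} and \code{status} filled in
#'   on its edge table, carrying the design and alpha used.
#' @export
score_network <- function(network, dataset, design, alpha = 0.05,
                          statistic = c("log_ratio", "fraction")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(network, "reaction_network"),
            inherits(dataset, "lipid_dataset"),
            inherits(design, "condition_design"))
  ab <- dataset$abundance
  missing_samples <- setdiff(names(design$assignment), colnames(ab))
  if (length(missing_samples)) {
    stop("samples in the design but not in the dataset: ",
         paste(missing_samples, collapse = ", "))
  }
  pos <- ab[!is.na(ab) & ab > 0]
  eps <- if (length(pos)) min(pos) / 2 else 0
  samp_i <- names(design$assignment)[design$assignment == design$interest]
  samp_c <- names(design$assignment)[design$assignment == design$control]
  if (design$paired) {
    samp_i <- design$pairs$interest
    samp_c <- design$pairs$control
  }
  edges <- network$edges
  edges$z <- NA_real_; edges$p <- NA_real_; edges$status <- "none"
  dropped <- character(0)
  for (i in seq_len(nrow(edges))) {
    pr <- network$pairs[network$pairs$edge_key == edges$edge_key[i], ]
    s_sp <- unique(pr$substrate_label)
    p_sp <- unique(pr$product_label)
    a_i <- reaction_activity(ab[s_sp, samp_i, drop = FALSE],
                             ab[p_sp, samp_i, drop = FALSE],
                             eps = eps, statistic = statistic)
    a_c <- reaction_activity(ab[s_sp, samp_c, drop = FALSE],
                             ab[p_sp, samp_c, drop = FALSE],
                             eps = eps, statistic = statistic)
    if (anyNA(c(a_i, a_c))) dropped <- c(dropped, edges$edge_key[i])
    sc <- reaction_z(a_i, a_c, paired = design$paired, alpha = alpha)
    edges$z[i] <- sc$z; edges$p[i] <- sc$p; edges$status[i] <- sc$status
  }
  if (length(dropped)) {
    warning("samples dropped (all-missing or all-zero sides) for edges: ",
            paste(unique(dropped), collapse = ", "))
  }
  network$edges <- edges
  network$scored <- TRUE
  network$design <- design
  network$alpha <- alpha
  network$statistic <- statistic
  network
}
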