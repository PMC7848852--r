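#' Specify a synthetic two-condition lipidomics experiment
#'
#' The generator draws every abundance from a lognormal baseline (each
#' species gets its own baseline level, samples vary around it with
#' log-scale standard deviation \code{sigma}) and plants reaction effects
#' multiplicatively: a fold-change > 1 on a reaction multiplies the
#' abundances of the reaction's product species in the condition of
#' interest, which shifts the product/substrate log ratio by exactly
#' \code{log(fold)} in expectation. Under this generator the log-ratio
#' activity statistic is exactly normal, so closed-form expected Z-scores
#' are available for oracle tests.
#'
#' @param species named list: subclass code (or \code{"FA"}) to character
#'   vector of sum compositions (\code{"34:1"}); defaults to a panel
#'   covering glycerophospholipid, glycerolipid, sphingolipid and
#'   fatty-acid reactions, including the fatty-acid partners that
#'   acylation/deacylation matching requires.
#' @param n_interest,n_control replicates per condition (default 5).
#' @param mu_log log-scale baseline centre (default \code{log(100)}).
#' @param sigma log-scale within-condition standard deviation (default 0.2).
#' @param effects list of planted effects, each
#'   \code{list(substrate =, product =, fold =)} naming a database reaction
#'   by its endpoints (\code{"FA(C:D)"} labels for fatty-acid steps);
#'   fold must be positive.
#' @param paired logical; matched-pair design.
#' @param seed integer seed fixing all randomness.
#' @return a validated list of class \code{simulation_spec}.
#' @export
simulation_spec <- function(species = default_sim_species(),
                            n_interest = 5, n_control = 5,
                            mu_log = log(100), sigma = 0.2,
                            effects = list(), paired = FALSE, seed = 1) {
  db <- load_reaction_db()
  for (ef in effects) {
    stopifnot(is.list(ef), !is.null(ef$substrate), !is.null(ef$product),
              is.numeric(ef$fold))
    if (ef$fold <= 0) stop("planted fold-change must be positive")
    if (is.null(find_reaction(db, ef$substrate, ef$product))) {
      stop("planted effect names an unknown reaction: ",
           ef$substrate, " -> ", ef$product)
    }
  }
  stopifnot(n_interest >= 2, n_control >= 2, sigma > 0)
  if (paired && n_interest != n_control) {
    stop("paired simulations need equal replicate counts")
  }
  structure(list(species = species, n_interest = n_interest,
                 n_control = n_control, mu_log = mu_log, sigma = sigma,
                 effects = effects, paired = paired, seed = seed),
            class = "simulation_spec")
}

#' Default species panel for simulations
#'
#' A compact panel whose compositions are mutually consistent under the
#' balance rules, so that headgroup, acylation, deacylation, sphingolipid
#' and fatty-acid reactions all instantiate (e.g. \code{PA 34:1 = LPA 16:0
#' + FA 18:1}, \code{TG 52:2 = DG 34:1 + FA 18:1}).
#'
#' @return named list mapping subclass codes to composition vectors.
#' @export
default_sim_species <- function() {
  list(PC = c("34:1", "36:2", "38:4"),
       PE = c("34:1", "36:2"),
       PS = c("34:1", "36:2"),
       LPS = c("16:0"),
       PA = c("34:1", "36:2"),
       LPA = c("16:0"),
       PG = c("34:1"),
       LPG = c("16:0"),
       PI = c("36:2"),
       DG = c("34:1", "36:2"),
       MG = c("16:0"),
       TG = c("52:2"),
       LPC = c("16:0"),
       Cer = c("34:1"),
       SM = c("34:1"),
       dhCer = c("34:0"),
       dhSM = c("34:0"),
       Cer1P = c("34:1"),
       Sph = c("18:1"),
       FA = c("16:0", "18:0", "18:1", "18:3", "20:3", "22:5", "24:5"))
}

#' Simulate a two-condition lipidomics dataset with planted effects
#'
#' Generates the CSV-shaped abundance table described by a
#' [simulation_spec()] together with a ground-truth manifest of the planted
#' reaction effects and their expected direction. The same seed always
#' reproduces the same table, byte for byte when written to disk.
#'
#' @param spec a \code{simulation_spec}.
#' @param path optional directory; when given, writes \code{simulated.csv}
#'   and \code{manifest.json} there.
#' @return list with \code{dataset} (a \code{lipid_dataset}), \code{design}
#'   (the matching \code{condition_design}; labels \code{"treated"} vs
#'   \code{"control"}), \code{table} (the raw data.frame as written to
#'   CSV), and \code{manifest}.
#' @export
simulate_dataset <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  db <- load_reaction_db()
  set.seed(spec$seed)
  labels <- character(0); comps <- list()
  for (code in names(spec$species)) {
    for (comp in spec$species[[code]]) {
      pc <- parse_comp(comp)
      if (is.null(pc)) stop("bad composition '", comp, "' for ", code)
      labels <- c(labels, make_label(code, pc$carbons, pc$double_bonds))
    }
  }
  samples_i <- paste0("treated", seq_len(spec$n_interest))
  samples_c <- paste0("control", seq_len(spec$n_control))
  samples <- c(samples_i, samples_c)
  n_sp <- length(labels)
  baseline <- stats::rnorm(n_sp, spec$mu_log, 1)
  ab <- matrix(stats::rlnorm(n_sp * length(samples),
                             meanlog = rep(baseline, times = length(samples)),
                             sdlog = spec$sigma),
               nrow = n_sp, dimnames = list(labels, samples))
  truth <- list()
  for (ef in spec$effects) {
    r <- find_reaction(db, ef$substrate, ef$product)
    prod_node <- reaction_node(r, "product")
    target <- if (grepl("\\(", prod_node)) {
      labels[labels == prod_node]
    } else {
      labels[startsWith(labels, paste0(prod_node, "("))]
    }
    if (!length(target)) {
      stop("planted effect's product '", prod_node,
           "' has no species in the panel")
    }
    ab[target, samples_i] <- ab[target, samples_i] * ef$fold
    truth[[length(truth) + 1L]] <- list(
      substrate = ef$substrate, product = ef$product, fold = ef$fold,
      expected_status = if (ef$fold > 1) "active"
        else if (ef$fold < 1) "suppressed" else "none",
      expected_z_sign = sign(log(ef$fold)))
  }
  tab <- data.frame(Species = labels, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (s in samples) tab[[s]] <- ab[, s]
  design <- condition_design(
    "treated", "control",
    stats::setNames(c(rep("treated", spec$n_interest),
                      rep("control", spec$n_control)), samples),
    paired = spec$paired)
  manifest <- list(seed = spec$seed, sigma = spec$sigma,
                   n_interest = spec$n_interest, n_control = spec$n_control,
                   paired = spec$paired, effects = truth)
  if (!is.null(path)) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    csv <- file.path(path, "simulated.csv")
    con <- file(csv, "wb")
    utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
    close(con)
    jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  raw <- tab
  for (s in samples) raw[[s]] <- as.character(raw[[s]])
  list(dataset = dataset_from_frame(raw, db = db), design = design,
       table = tab, manifest = manifest)
}

#' Reference table of published active reaction chains
#'
#' Bundled copy of the subclass-level active chains (and, for
#' \code{type = "fa"}, the fatty-acid chains) reported for an
#' aged-versus-young mouse liver lipidomics comparison, with their combined
#' Z-scores and predicted gene lists. The package's internal-consistency
#' checks use this table two ways: single-step Z-scores are solved from the
#' chain scores by inverting the Stouffer combination and recombined along
#' longer chains, and every printed gene list is re-derived from the
#' reaction database with [chain_genes()].
#'
#' @param type \code{"lipid"} (22 subclass chains) or \code{"fa"} (2
#'   fatty-acid chains).
#' @return data.frame with columns \code{chain} (labels joined by
#'   \code{"->"}), \code{z}, \code{genes} (comma-separated).
#' @export
reference_chains <- function(type = c("lipid", "fa")) {
  type <- match.arg(type)
  if (type == "fa") {
    return(data.frame(
      chain = c("FA(22:5)->FA(24:5)", "FA(18:3)->FA(20:3)"),
      z = c(2.108, 1.831),
      genes = c("ELOVL2", "ELOVL5, ELOVL7"),
      stringsAsFactors = FALSE))
  }
  data.frame(
    chain = c(
      "PE->PC->PS->LPS", "DG->PC->PS->LPS", "PE->PC->LPC",
      "LPA->PA->PG->LPG", "PE->PC->PA->PG->LPG", "DG->PC->LPC",
      "PG->LPG", "LPA->PA->PS->LPS", "DG->PE->LPE", "PE->PS",
      "PC->PS->LPS", "DG->MG", "DG->TG", "DG->PC->PA",
      "dhSM->dhCer->Cer->Cer1P", "DG->PA", "O-PE->O-LPE", "LPA->PA->PI",
      "PC->LPC", "PE->PC->PA->PI", "PS->LPS", "PE->PC->CL"),
    z = c(3.978, 3.686, 3.519, 3.367, 3.179, 3.161, 3.077, 2.898, 2.815,
          2.700, 2.657, 2.507, 2.301, 2.280, 2.218, 2.050, 1.942, 1.878,
          1.843, 1.837, 1.668, 1.667),
    genes = c(
      "PEMT, PTDSS1, PLA2G2E, PLA2G2A, PLA2G2F",
      "CHPT1, PTDSS1, PLA2G2E, PLA2G2A, PLA2G2F",
      "PEMT, PLA2G2E, PLA2G2A, PLA2G2D, PLA2G2F, PLA2G1B",
      "AGPAT1, AGPAT2, AGPAT3, AGPAT4, AGPAT5, CDS1, CDS2, PTPMT1, PLA2G4D, PLA2G4F, CRLS1",
      "PEMT, PLD1, PLD2, CDS1, CDS2, PTPMT1, PLA2G4D, PLA2G4F, CRLS1",
      "CHPT1, PLA2G2E, PLA2G2A, PLA2G2D, PLA2G2F, PLA2G1B",
      "PLA2G4D, PLA2G4F, CRLS1",
      "AGPAT1, AGPAT2, AGPAT3, AGPAT4, AGPAT5, CDS1, PTDSS1, PLA2G2E, PLA2G2A, PLA2G2F",
      "CEPT1, PLA2G4C",
      "PTDSS2",
      "PTDSS1, PLA2G2E, PLA2G2A, PLA2G2F",
      "PNPLA2, PNPLA3",
      "DGAT2",
      "CHPT1, PLD1, PLD2",
      "SGMS1, SGMS2, DEGS1, DEGS2, CERK",
      "DGKA, DGKB, DGKD, DGKE, DGKG, DGKH, DGKI, DGKK, DGKQ, DGKZ",
      "PLA2G4A",
      "AGPAT1, AGPAT2, AGPAT3, AGPAT4, AGPAT5, CDS1, CDS2, CDIPT",
      "PLA2G2E, PLA2G2A, PLA2G2D, PLA2G2F, PLA2G1B",
      "PEMT, PLD1, PLD2, CDS1, CDS2, CDIPT",
      "PLA2G2E, PLA2G2A, PLA2G2F",
      "PEMT, TAZ"),
    stringsAsFactors = FALSE)
}
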