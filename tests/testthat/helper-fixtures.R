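# shared fixture builders; everything is generated in code at test time

# write a species x sample table to a temp CSV and read it back as a dataset
csv_dataset <- function(tab, db = load_reaction_db()) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  read_dataset(path, db = db)
}

# a tiny two-condition table: named list species -> abundance vector
# (length = n_treated + n_control)
toy_table <- function(species_values) {
  n <- length(species_values[[1L]])
  samples <- c(paste0("t", seq_len(n / 2)), paste0("c", seq_len(n / 2)))
  tab <- data.frame(Species = names(species_values),
                    stringsAsFactors = FALSE)
  m <- do.call(rbind, species_values)
  colnames(m) <- samples
  cbind(tab, as.data.frame(m))
}

toy_design <- function(n_t = 2, n_c = 2, paired = FALSE) {
  condition_design(
    "treated", "control",
    stats::setNames(c(rep("treated", n_t), rep("control", n_c)),
                    c(paste0("t", seq_len(n_t)), paste0("c", seq_len(n_c)))),
    paired = paired)
}

# independent brute-force matcher: scans every species pair/triple and
# applies the balance rules directly, without the indexed implementation
brute_force_matches <- function(species, db, require_fa = TRUE) {
  fa <- species[species$subclass %in% c("FA", "FACoA"), , drop = FALSE]
  rows <- list()
  add <- function(rid, kind, s, p, f = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      reaction = rid, kind = kind, substrate_label = s, product_label = p,
      fa_label = f, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(db$reactions))) {
    r <- db$reactions[i, ]
    if (r$kind %in% c("fa_elongation", "fa_desaturation")) {
      s_lab <- lipidpath:::reaction_node(r, "substrate")
      p_lab <- lipidpath:::reaction_node(r, "product")
      fa_only <- species$label[species$subclass == "FA"]
      if (s_lab %in% fa_only && p_lab %in% fa_only) {
        add(r$id, r$kind, s_lab, p_lab)
      }
      next
    }
    S <- species[species$subclass == r$substrate, , drop = FALSE]
    P <- species[species$subclass == r$product, , drop = FALSE]
    for (si in seq_len(nrow(S))) for (pi in seq_len(nrow(P))) {
      if (r$kind %in% c("headgroup_transfer", "sphingoid_step")) {
        if (S$carbons[si] == P$carbons[pi] &&
            S$double_bonds[si] == P$double_bonds[pi]) {
          add(r$id, r$kind, S$label[si], P$label[pi])
        }
      } else if (r$kind == "acylation") {
        for (fi in seq_len(nrow(fa))) {
          if (P$carbons[pi] == S$carbons[si] + fa$carbons[fi] &&
              P$double_bonds[pi] == S$double_bonds[si] + fa$double_bonds[fi]) {
            add(r$id, r$kind, S$label[si], P$label[pi], fa$label[fi])
          }
        }
      } else if (r$kind == "deacylation") {
        if (require_fa) {
          for (fi in seq_len(nrow(fa))) {
            if (S$carbons[si] == P$carbons[pi] + fa$carbons[fi] &&
                S$double_bonds[si] == P$double_bonds[pi] + fa$double_bonds[fi]) {
              add(r$id, r$kind, S$label[si], P$label[pi], fa$label[fi])
            }
          }
        } else if (S$carbons[si] - P$carbons[pi] >= 2 &&
                   S$double_bonds[si] >= P$double_bonds[pi]) {
          add(r$id, r$kind, S$label[si], P$label[pi])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  unique(out)
}

# canonical sorted key set of a pair table, for set comparisons
pair_keys <- function(pairs) {
  if (is.null(pairs) || !nrow(pairs)) return(character(0))
  sort(paste(pairs$reaction, pairs$substrate_label, pairs$product_label,
             ifelse(is.na(pairs$fa_label), "-", pairs$fa_label)))
}

# scored network with injected edge scores; used by pathway-rule tests
inject_scores <- function(network, z_by_edge) {
  edges <- network$edges
  key <- paste(edges$substrate_node, edges$product_node, sep = "->")
  edges$z <- unname(z_by_edge[key])
  edges$p <- 1 - stats::pnorm(edges$z)
  crit <- z_crit(0.05)
  edges$status <- ifelse(edges$z > crit, "active",
                         ifelse(edges$z < -crit, "suppressed", "none"))
  network$edges <- edges
  network$scored <- TRUE
  network$alpha <- 0.05
  network
}
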