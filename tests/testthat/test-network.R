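db <- load_reaction_db()

test_that("species classification partitions every input row", {
  tab <- toy_table(list(
    "PA 34:2" = c(1, 2, 3, 4),
    "DG 34:2" = c(2, 2, 3, 3),
    "TG 52:2" = c(5, 5, 5, 5),     # no FA partner -> unprocessed
    "DG(aa-34:0" = c(1, 1, 1, 1))) # unparseable -> unrecognised
  ds <- suppressWarnings(csv_dataset(tab))
  ds <- classify_species(ds, db)
  cls <- ds$input$classification
  expect_identical(cls[ds$input$raw_name == "PA 34:2"], "processed")
  expect_identical(cls[ds$input$raw_name == "DG 34:2"], "processed")
  expect_identical(cls[ds$input$raw_name == "TG 52:2"], "unprocessed")
  expect_identical(cls[ds$input$raw_name == "DG(aa-34:0"], "unrecognised")
  expect_equal(sum(ds$classification), nrow(tab))
})

test_that("acylation instantiates only with a balancing fatty-acid partner", {
  base <- list("LPA 16:0" = c(1, 1, 1, 1), "PA 34:1" = c(1, 1, 1, 1))
  no_fa <- classify_species(csv_dataset(toy_table(base)), db)
  expect_equal(unname(no_fa$classification[["processed"]]), 0)
  with_fa <- c(base, list("FA 18:1" = c(1, 1, 1, 1)))
  ds <- classify_species(csv_dataset(toy_table(with_fa)), db)
  expect_equal(unname(ds$classification[["processed"]]), 3)
  pairs <- match_reactions(ds$species, db)
  acyl <- pairs[pairs$reaction == "LPA->PA", ]
  expect_identical(acyl$substrate_label, "LPA(16:0)")
  expect_identical(acyl$product_label, "PA(34:1)")
  expect_identical(acyl$fa_label, "FA(18:1)")
})

test_that("deacylation requires the partner unless the switch relaxes it", {
  sp <- parse_lipids(c("PC 34:1", "LPC 16:0"))
  strict <- match_reactions(sp, db, require_fa_for_deacylation = TRUE)
  expect_equal(nrow(strict[strict$reaction == "PC->LPC", ]), 0)
  relaxed <- match_reactions(sp, db, require_fa_for_deacylation = FALSE)
  expect_equal(nrow(relaxed[relaxed$reaction == "PC->LPC", ]), 1)
})

test_that("matching agrees with the brute-force oracle on small panels", {
  set.seed(41)
  codes <- c("PC", "LPC", "PA", "LPA", "DG", "MG", "TG", "PE", "PS", "LPS",
             "FA", "Cer", "SM", "dhCer", "dhSM")
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    species <- parse_lipids(sprintf(
      "%s %d:%d", sample(codes, n, replace = TRUE),
      sample(c(16, 18, 34, 36, 52), n, replace = TRUE),
      sample(0:3, n, replace = TRUE)))
    species <- species[!duplicated(species$label), ]
    for (req in c(TRUE, FALSE)) {
      got <- match_reactions(species, db, require_fa_for_deacylation = req)
      want <- brute_force_matches(species, db, require_fa = req)
      expect_identical(pair_keys(got), pair_keys(want))
    }
  }
})

test_that("adding species never demotes a processed species", {
  set.seed(43)
  base_names <- c("PA 34:1", "DG 34:1", "PC 36:2", "PS 36:2", "FA 18:1")
  extra_names <- c("LPA 16:0", "PE 36:2", "TG 52:2", "Cer 34:1", "SM 34:1")
  base <- parse_lipids(base_names)
  processed_before <- unique(unlist(
    match_reactions(base, db)[c("substrate_label", "product_label",
                                "fa_label")]))
  for (k in 1:5) {
    grown <- parse_lipids(c(base_names, sample(extra_names, k)))
    processed_after <- unique(unlist(
      match_reactions(grown, db)[c("substrate_label", "product_label",
                                   "fa_label")]))
    expect_true(all(setdiff(processed_before, NA) %in% processed_after))
  }
})

test_that("removing all FA rows removes exactly the FA-dependent edges", {
  tab <- toy_table(list(
    "PA 34:1" = c(1, 1, 1, 1), "DG 34:1" = c(1, 1, 1, 1),
    "LPA 16:0" = c(1, 1, 1, 1), "TG 52:2" = c(1, 1, 1, 1),
    "FA 18:1" = c(1, 1, 1, 1)))
  with_fa <- match_reactions(csv_dataset(tab)$species, db)
  without <- match_reactions(csv_dataset(tab[tab$Species != "FA 18:1", ])$species, db)
  raw_keys <- paste(with_fa$reaction, with_fa$substrate_label,
                    with_fa$product_label,
                    ifelse(is.na(with_fa$fa_label), "-", with_fa$fa_label))
  lost <- setdiff(pair_keys(with_fa), pair_keys(without))
  expect_true(length(lost) > 0)
  kinds <- with_fa$kind[raw_keys %in% lost]
  expect_true(all(kinds %in% c("acylation", "deacylation",
                               "fa_elongation", "fa_desaturation")))
  expect_identical(pair_keys(without),
                   pair_keys(with_fa[with_fa$kind == "headgroup_transfer", ]))
})

test_that("network levels and types induce the expected node sets", {
  tab <- toy_table(list(
    "PA 34:1" = c(1, 1, 1, 1), "DG 34:1" = c(1, 1, 1, 1),
    "FA 22:5" = c(1, 1, 1, 1), "FA 24:5" = c(1, 1, 1, 1)))
  ds <- csv_dataset(tab)
  sub <- build_network(ds, db, level = "subclass", type = "lipid")
  expect_setequal(sub$nodes$label, c("PA", "DG"))
  spc <- build_network(ds, db, level = "species", type = "lipid")
  expect_setequal(spc$nodes$label, c("PA(34:1)", "DG(34:1)"))
  expect_true(all(table(paste(spc$pairs$edge_key)) == 1))
  fa <- build_network(ds, db, type = "fa")
  expect_setequal(fa$nodes$label, c("FA(22:5)", "FA(24:5)"))
  expect_identical(fa$edges$kind, "fa_elongation")
  # lipid network never contains elongation edges
  expect_false(any(sub$edges$kind %in% c("fa_elongation", "fa_desaturation")))
})

test_that("a dataset with nothing to match yields an empty network", {
  tab <- toy_table(list("PC 38:4" = c(1, 1, 1, 1)))
  ds <- csv_dataset(tab)
  expect_message(net <- build_network(ds, db), "empty")
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$nodes), 0)
})
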