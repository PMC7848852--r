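db <- load_reaction_db()

# fixed network encoding a branching PC -> DG -> {MG, PA} motif with the
# published cortex scores injected on its edges
cortex_motif <- function() {
  tab <- toy_table(list(
    "PC 34:1" = c(1, 1, 1, 1), "DG 34:1" = c(1, 1, 1, 1),
    "MG 16:0" = c(1, 1, 1, 1), "PA 34:1" = c(1, 1, 1, 1),
    "FA 18:1" = c(1, 1, 1, 1)))
  net <- build_network(csv_dataset(tab), db)
  keep <- c("PC->DG", "DG->MG", "DG->PA")
  net$edges <- net$edges[net$edges$reaction %in% keep, , drop = FALSE]
  net$pairs <- net$pairs[net$pairs$edge_key %in% net$edges$edge_key, ,
                         drop = FALSE]
  inject_scores(net, c("PC->DG" = 3.083, "DG->MG" = 2.054,
                       "DG->PA" = -0.408))
}

test_that("the greedy rule picks the continuation with the highest score", {
  net <- cortex_motif()
  routes <- most_extreme_routes(net, "active")
  from_pc <- routes[startsWith(routes$chain, "PC"), ]
  expect_identical(from_pc$chain, "PC->DG->MG")
  expect_equal(from_pc$z, (3.083 + 2.054) / sqrt(2), tolerance = 1e-6)
  # exactly one route per starting substrate
  starts <- sub("->.*", "", routes$chain)
  expect_false(any(duplicated(starts)))
})

test_that("ties between continuations break to the smaller product label", {
  net <- cortex_motif()
  net$edges$z[net$edges$reaction == "DG->PA"] <- 2.054  # tie with DG->MG
  net$edges$status[net$edges$reaction == "DG->PA"] <- "active"
  routes <- most_extreme_routes(net, "active")
  expect_identical(routes$chain[startsWith(routes$chain, "PC")],
                   "PC->DG->MG")
})

test_that("a single linear path is its own most-active route", {
  net <- cortex_motif()
  net$edges <- net$edges[net$edges$reaction != "DG->PA", , drop = FALSE]
  routes <- most_extreme_routes(net, "active")
  expect_identical(routes$chain[startsWith(routes$chain, "PC")],
                   "PC->DG->MG")
})

test_that("chain enumeration reports all and only significant chains", {
  net <- cortex_motif()
  ch <- enumerate_chains(net, "active")
  expect_true(all(ch$z > z_crit(0.05)))
  expect_true(all(c("PC->DG", "DG->MG", "PC->DG->MG") %in% ch$chain))
  # the chain through the weak DG->PA step stays significant under the
  # combiner (1.891), but ranks below the branch the greedy rule selects
  expect_false("DG->PA" %in% ch$chain)
  expect_lt(ch$z[ch$chain == "PC->DG->PA"], ch$z[ch$chain == "PC->DG->MG"])
  expect_equal(ch$z, ch$z[order(-abs(ch$z))])
  # all-zero network yields nothing
  null_net <- inject_scores(cortex_motif(),
                            c("PC->DG" = 0, "DG->MG" = 0, "DG->PA" = 0))
  expect_equal(nrow(enumerate_chains(null_net, "active")), 0)
})

test_that("every greedy route that is significant is also enumerated", {
  set.seed(47)
  for (i in 1:5) {
    tab <- toy_table(list(
      "PC 34:1" = c(1, 1, 1, 1), "DG 34:1" = c(1, 1, 1, 1),
      "PA 34:1" = c(1, 1, 1, 1), "PE 34:1" = c(1, 1, 1, 1),
      "PS 34:1" = c(1, 1, 1, 1), "MG 16:0" = c(1, 1, 1, 1),
      "FA 18:1" = c(1, 1, 1, 1)))
    net <- build_network(csv_dataset(tab), db)
    z <- stats::setNames(rnorm(nrow(net$edges), sd = 2),
                         paste(net$edges$substrate_node,
                               net$edges$product_node, sep = "->"))
    net <- inject_scores(net, z)
    for (st in c("active", "suppressed")) {
      routes <- most_extreme_routes(net, st)
      all_ch <- enumerate_chains(net, st)
      expect_true(all(routes$chain %in% all_ch$chain))
    }
  }
})

test_that("chain counts shrink as alpha tightens and grow with the cap", {
  net <- cortex_motif()
  loose <- enumerate_chains(net, "active", alpha = 0.1)
  strict <- enumerate_chains(net, "active", alpha = 0.01)
  expect_true(all(strict$chain %in% loose$chain))
  short <- enumerate_chains(net, "active", max_len = 1)
  long <- enumerate_chains(net, "active", max_len = 2)
  expect_true(all(short$chain %in% long$chain))
  expect_true(all(short$n_steps <= 1))
})

test_that("prefixes of every returned chain rescore consistently", {
  net <- cortex_motif()
  lut <- stats::setNames(net$edges$z, paste(net$edges$substrate_node,
                                            net$edges$product_node,
                                            sep = "->"))
  ch <- enumerate_chains(net, "active")
  for (chain in ch$chain) {
    nodes <- strsplit(chain, "->", fixed = TRUE)[[1]]
    for (k in 2:length(nodes)) {
      steps <- paste(nodes[seq_len(k - 1)], nodes[2:k], sep = "->")
      want <- combine_pathway(lut[steps])
      if (k == length(nodes)) {
        expect_equal(ch$z[ch$chain == chain], unname(want), tolerance = 1e-9)
      }
    }
  }
})

test_that("subset restriction limits enumeration to the stored pathway", {
  tab <- toy_table(list(
    "PA 34:1" = c(1, 2, 1, 1), "DG 34:1" = c(4, 5, 1, 1),
    "LPA 16:0" = c(1, 1, 1, 1), "TG 52:2" = c(9, 9, 1, 1),
    "FA 18:1" = c(1, 1, 1, 1), "PC 34:1" = c(6, 7, 1, 1)))
  ds <- csv_dataset(tab)
  net <- score_network(build_network(ds, db), ds, toy_design())
  all_ch <- enumerate_chains(net, "active")
  sub_ch <- enumerate_chains(net, "active", subset = "de novo lipogenesis")
  expect_true(all(sub_ch$chain %in% all_ch$chain))
  expect_false(any(grepl("PC", sub_ch$chain)))
  expect_error(enumerate_chains(net, "active", subset = "no such subset"),
               "unknown pathway subset")
})

test_that("node search matches substrings with AND / OR logic", {
  tab <- toy_table(list(
    "PC 34:0" = c(1, 1, 1, 1), "O-PC 34:0" = c(1, 1, 1, 1),
    "DG 34:0" = c(1, 1, 1, 1), "O-DG 34:0" = c(1, 1, 1, 1),
    "LPC 16:0" = c(1, 1, 1, 1), "LPA 16:0" = c(1, 1, 1, 1),
    "PA 34:0" = c(1, 1, 1, 1), "FA 18:0" = c(1, 1, 1, 1)))
  ds <- csv_dataset(tab)
  spc <- build_network(ds, db, level = "species")
  expect_setequal(filter_nodes(spc, "PC", "AND", "34:0"),
                  c("PC(34:0)", "O-PC(34:0)"))
  sub <- build_network(ds, db, level = "subclass")
  expect_setequal(filter_nodes(sub, "LPC", "OR", "LPA"),
                  intersect(c("LPC", "O-LPC", "LPA"), sub$nodes$label))
  expect_length(filter_nodes(sub, "ZZZ", "OR", ""), 0)
  expect_error(filter_nodes(sub, "PC", "AND"), "query2")
})
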