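test_that("the normal critical value matches its quantile definition", {
  expect_equal(z_crit(0.05), 1.645, tolerance = 1e-3)
  expect_equal(z_crit(0.5), 0)
  expect_equal(z_crit(0.01), 2.326, tolerance = 1e-3)
  expect_error(z_crit(0))
  expect_error(z_crit(1))
  expect_error(z_crit(-2))
})

test_that("per-sample activity is the log product/substrate ratio", {
  s <- matrix(c(2, 4, 8, 2, 4, 8), nrow = 2, byrow = TRUE)
  expect_equal(reaction_activity(s, s), rep(0, 3))
  expect_equal(reaction_activity(s, 2 * s), rep(log(2), 3))
  # hand-computed 3-species edge
  sub <- matrix(c(1, 2, 3, 4), nrow = 2)        # sums 3, 7
  prod <- matrix(c(5, 1, 2, 2), nrow = 2)       # sums 6, 4
  expect_equal(reaction_activity(sub, prod), log(c(6 / 3, 4 / 7)))
  # fraction statistic behind the same interface
  expect_equal(reaction_activity(sub, prod, statistic = "fraction"),
               c(6 / 9, 4 / 11))
})

test_that("activity marks all-zero and all-missing samples as unusable", {
  sub <- matrix(c(0, 1, NA), nrow = 1)
  prod <- matrix(c(0, 2, 3), nrow = 1)
  a <- reaction_activity(sub, prod, eps = 0.5)
  expect_true(is.na(a[1]))
  expect_false(is.na(a[2]))
  expect_true(is.na(a[3]))
})

test_that("reaction z has the Welch form and exact antisymmetry", {
  set.seed(7)
  for (i in 1:20) {
    ai <- rnorm(5); ac <- rnorm(4)
    sc <- reaction_z(ai, ac)
    want <- (mean(ai) - mean(ac)) / sqrt(var(ai) / 5 + var(ac) / 4)
    expect_equal(sc$z, want)
    expect_equal(sc$p, 1 - pnorm(want))
    flipped <- reaction_z(ac, ai)
    expect_equal(flipped$z, -sc$z)
    mirror <- c(active = "suppressed", suppressed = "active", none = "none")
    expect_identical(flipped$status, unname(mirror[sc$status]))
  }
})

test_that("identical groups score zero and degenerate variance is signed", {
  sc <- reaction_z(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sc$z, 0)
  expect_equal(sc$p, 0.5)
  expect_identical(sc$status, "none")
  up <- reaction_z(c(2, 2), c(1, 1))
  expect_identical(up$z, Inf)
  expect_identical(up$status, "active")
  down <- reaction_z(c(1, 1), c(2, 2))
  expect_identical(down$z, -Inf)
  expect_identical(down$status, "suppressed")
  expect_equal(reaction_z(c(1, 1), c(1, 1))$z, 0)
})

test_that("paired designs score the per-pair differences", {
  set.seed(9)
  ai <- rnorm(6, 1); ac <- rnorm(6)
  d <- ai - ac
  sc <- reaction_z(ai, ac, paired = TRUE)
  expect_equal(sc$z, mean(d) / (sd(d) / sqrt(6)))
  expect_error(reaction_z(ai, ac[-1], paired = TRUE), "paired")
})

test_that("too few usable replicates leaves a reaction unscored", {
  sc <- reaction_z(c(1, NA, NA), c(1, 2, 3))
  expect_true(is.na(sc$z))
  expect_identical(sc$status, "none")
})

test_that("Stouffer combination and its inversion are mutually consistent", {
  expect_equal(combine_pathway(2.3), 2.3)
  expect_equal(combine_pathway(c(3.083, 2.054)), 3.632, tolerance = 5e-4)
  expect_error(combine_pathway(numeric(0)))
  set.seed(13)
  for (k in 2:6) {
    z <- rnorm(k, sd = 2)
    zc <- combine_pathway(z)
    expect_equal(invert_chain_z(zc, k, z[-1]), z[1])
  }
})

test_that("planted multiplicative effects are recovered with high power", {
  # lognormal generator, sigma = 0.1, n = 5, 2-fold product increase:
  # expected z ~ log(2)/sqrt(2*sigma^2*(1/5+1/5)) >> 1.645
  set.seed(17)
  hits <- 0
  n_sim <- 200
  for (i in 1:n_sim) {
    sub <- rlnorm(10, meanlog = 0, sdlog = 0.1)
    prod <- rlnorm(10, meanlog = 0, sdlog = 0.1)
    prod[1:5] <- prod[1:5] * 2
    a_i <- log(prod[1:5] / sub[1:5])
    a_c <- log(prod[6:10] / sub[6:10])
    if (reaction_z(a_i, a_c)$status == "active") hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("network scoring matches a by-hand Welch computation", {
  db <- load_reaction_db()
  tab <- toy_table(list(
    "PA 34:1" = c(4, 5, 1, 1), "DG 34:1" = c(8, 12, 1, 1.2)))
  ds <- csv_dataset(tab)
  net <- score_network(build_network(ds, db), ds, toy_design())
  eps <- 0.5  # half the smallest positive abundance in the table
  a <- log((c(8, 12, 1, 1.2) + eps) / (c(4, 5, 1, 1) + eps))
  want <- (mean(a[1:2]) - mean(a[3:4])) /
    sqrt(var(a[1:2]) / 2 + var(a[3:4]) / 2)
  got <- net$edges[net$edges$reaction == "PA->DG", ]
  expect_equal(got$z, want, tolerance = 1e-6)
})

test_that("swapping condition labels negates every edge score", {
  db <- load_reaction_db()
  sim <- simulate_dataset(simulation_spec(
    effects = list(list(substrate = "DG", product = "TG", fold = 2)),
    seed = 19))
  net <- build_network(classify_species(sim$dataset, db), db)
  fwd <- score_network(net, sim$dataset, sim$design)
  swapped <- condition_design("control", "treated",
                              sim$design$assignment)
  rev <- score_network(net, sim$dataset, swapped)
  expect_equal(rev$edges$z, -fwd$edges$z)
  mirror <- c(active = "suppressed", suppressed = "active", none = "none")
  expect_identical(rev$edges$status, unname(mirror[fwd$edges$status]))
})

test_that("subclass and species scores coincide with one species per subclass", {
  db <- load_reaction_db()
  tab <- toy_table(list(
    "PA 34:1" = c(4, 5, 6, 1, 1, 2), "DG 34:1" = c(9, 12, 11, 1, 1.2, 1)))
  ds <- csv_dataset(tab)
  design <- toy_design(3, 3)
  sub <- score_network(build_network(ds, db, level = "subclass"), ds, design)
  spc <- score_network(build_network(ds, db, level = "species"), ds, design)
  expect_equal(sort(sub$edges$z), sort(spc$edges$z))
})
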