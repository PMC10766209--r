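test_that("make_signed_set applies the FC and FDR thresholds", {
  det <- data.frame(
    gene_id = paste0("g", 1:12),
    log2_fc = c(0.5, -0.6, 1.2, -2.0, 0.58, 0.59, -0.1, 3.0, -3.0, 0.7, 0, 1.5),
    fdr =     c(0.001, 0.049, 0.2, 0.01, 0.05, 0.049, 0.001, 0.04, 0.06, 0.02, 0.01, 0.05)
  )
  s <- make_signed_set(det, fc_min = 1.5, fdr_max = 0.05, universe_size = 100)
  # hand enumeration: |log2fc| >= log2(1.5) ~ 0.585 AND fdr < 0.05
  expected <- c(g2 = -1L, g4 = -1L, g6 = 1L, g8 = 1L, g10 = 1L)
  expect_identical(s$members[order(names(s$members))],
                   expected[order(names(expected))])
  expect_equal(s$universe_size, 100L)

  # |FC| ~ 1.41 never passes; -0.6 at fdr 0.049 carries sign -1
  expect_false("g1" %in% names(s$members))
  expect_identical(unname(s$members["g2"]), -1L)
})

test_that("make_signed_set excludes directionless genes and bad inputs", {
  det <- data.frame(gene_id = c("a", "b"), log2_fc = c(0, 2), fdr = c(0.01, 0.01))
  expect_message(s <- make_signed_set(det, universe_size = 10), "no direction")
  expect_identical(names(s$members), "b")
  expect_error(make_signed_set(det, fc_min = 1, universe_size = 10), "fc_min")
  expect_error(make_signed_set(det, universe_size = 1), "universe_size")
})

test_that("concordant_overlap counts directional intersections", {
  a <- signed_gene_set(c(g1 = 1, g2 = -1, g3 = 1), 100)
  b <- signed_gene_set(c(g1 = 1, g2 = 1, g4 = -1), 100)
  ov <- concordant_overlap(a, b)
  expect_equal(ov, list(n_shared = 2, n_concordant = 1, n_discordant = 1))

  disjoint <- signed_gene_set(c(g9 = 1), 100)
  expect_equal(concordant_overlap(a, disjoint),
               list(n_shared = 0, n_concordant = 0, n_discordant = 0))
  expect_equal(concordant_overlap(a, a),
               list(n_shared = 3, n_concordant = 3, n_discordant = 0))
})

test_that("mc_overlap_test is deterministic and symmetric for equal sizes", {
  sim <- simulate_deg_pair(G = 500, n_a = 60, n_b = 60, n_concordant = 10,
                           n_discordant = 5, seed = 17)
  o1 <- mc_overlap_test(sim$set_a, sim$set_b, n_iter = 500, seed = 3)
  o2 <- mc_overlap_test(sim$set_a, sim$set_b, n_iter = 500, seed = 3)
  expect_identical(o1$p_table, o2$p_table)
  o_swap <- mc_overlap_test(sim$set_b, sim$set_a, n_iter = 500, seed = 3)
  expect_identical(o1$p_table$p_strict, o_swap$p_table$p_strict)
})

test_that("expected null overlap shrinks as the universe grows", {
  a <- signed_gene_set(setNames(rep(1L, 20), paste0("g", 1:20)), 1000)
  b <- signed_gene_set(setNames(rep(1L, 20), paste0("h", 1:20)), 1000)
  means <- sapply(c(50, 100, 200, 400), function(G) {
    a$universe_size <- as.integer(G)
    b$universe_size <- as.integer(G)
    mean(mc_overlap_test(a, b, n_iter = 2000, seed = 5)$nulls$shared)
  })
  expect_true(all(diff(means) < 0))
})

test_that("zero observed overlap gives a strict p near 1", {
  a <- signed_gene_set(setNames(rep(1L, 10), paste0("a", 1:10)), 30)
  b <- signed_gene_set(setNames(rep(1L, 10), paste0("b", 1:10)), 30)
  ov <- mc_overlap_test(a, b, n_iter = 2000, statistic_mode = "shared",
                        seed = 7)
  expect_equal(ov$n_shared, 0)
  # nearly every random draw shares at least one gene
  expect_gt(ov$p_value, 0.9)
})

test_that("hypergeometric overlap test matches log-space summation", {
  expect_equal(hypergeom_overlap_test(5, 4, 10, 0), 1)
  expect_equal(hypergeom_overlap_test(5, 4, 10, 3),
               oracle_hypergeom_upper(5, 4, 10, 3), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    G <- sample(20:200, 1)
    n_a <- sample(1:(G - 1), 1)
    n_b <- sample(1:(G - 1), 1)
    k <- sample(0:min(n_a, n_b), 1)
    expect_equal(hypergeom_overlap_test(n_a, n_b, G, k),
                 oracle_hypergeom_upper(n_a, n_b, G, k), tolerance = 1e-10)
  }
  expect_error(hypergeom_overlap_test(5, 4, 10, 5), "infeasible")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(19)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_equal(order(q[order(p)]), seq_along(p))  # significance order kept
  expect_error(bh_adjust(c(0.1, NaN)), "NA")
})

test_that("Spearman concordance matches rank-then-Pearson recomputation", {
  set.seed(29)
  a <- rnorm(10)
  b <- rnorm(10)
  got <- spearman_fc_concordance(a, b)
  ora <- oracle_spearman(a, b)
  expect_equal(got$rho, ora$rho, tolerance = 1e-12)
  expect_equal(got$p_value, ora$p, tolerance = 1e-12)

  # rank invariance under strictly monotone transforms
  expect_equal(spearman_fc_concordance(a, exp(a))$rho, 1)
  expect_equal(spearman_fc_concordance(a, -a)$rho, -1)
  expect_error(spearman_fc_concordance(a, rep(1, 10)), "rank-degenerate")

  # the significance rule needs both |rho| > 0.3 and FDR < 0.05
  strong <- spearman_fc_concordance(1:20 + rnorm(20, sd = 0.1), 1:20)
  expect_true(strong$significant)
  expect_false(spearman_fc_concordance(a, b, fdr = 0.5)$significant)
})
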