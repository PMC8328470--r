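test_that("differentiation is zero for identical populations and one for fixed ones", {
  # same allele composition everywhere
  same <- table_from_counts(list(P1 = c(a = 10, b = 10),
                                 P2 = c(a = 10, b = 10)))
  g0 <- gst(same, "MHC", n_perm = 0)
  expect_equal(g0$G_ST, 0, tolerance = 1e-9)
  # two large populations fixed for different alleles: standardized value 1
  fixed <- table_from_counts(list(P1 = c(a = 200), P2 = c(b = 200)))
  g1 <- gst(fixed, "MHC", n_perm = 0)
  # hand computation through the corrected formulas: Ho = 0, H_S = 0,
  # H_T = 1 - 2 * 0.25 = 0.5, G_ST = 1 up to sampling terms, G''_ST = 1
  expect_equal(g1$H_S, 0, tolerance = 1e-9)
  expect_equal(g1$H_T, 0.5, tolerance = 1e-9)
  expect_equal(g1$G_dprime_ST, 1, tolerance = 1e-6)
})

test_that("permutation p-values live on the lattice and flag real structure", {
  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 4, n_ind = 14, n_alleles = 12, f_drift = 0.25,
    n_str_loci = 2, seed = 17))
  g <- gst(sim$table, "MHC", n_perm = 99, seed = 4)
  expect_true(g$p_value %in% ((1:100) / 100))
  expect_gt(g$p_value, 0)
  expect_lt(g$p_value, 0.06)  # strong planted drift
})

test_that("G''_ST is invariant to allele relabeling and individual duplication", {
  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 3, n_ind = 40, n_alleles = 8, n_str_loci = 2, seed = 23))
  tb <- sim$table
  g <- gst(tb, "MHC", n_perm = 0)
  # relabel alleles with a fixed permutation
  alle <- sort(unique(c(tb$mhc_1, tb$mhc_2)))
  relab <- stats::setNames(rev(alle), alle)
  tb2 <- tb; tb2$mhc_1 <- unname(relab[tb$mhc_1])
  tb2$mhc_2 <- unname(relab[tb$mhc_2])
  expect_equal(gst(tb2, "MHC", n_perm = 0)$G_dprime_ST, g$G_dprime_ST,
               tolerance = 1e-12)
  # duplicating every individual only perturbs the finite-sample corrections
  tb3 <- rbind(tb, transform(tb, id = paste0(tb$id, "_dup")))
  tb3 <- genotype_table(tb3, str_loci = str_loci(tb))
  expect_equal(gst(tb3, "MHC", n_perm = 0)$G_dprime_ST, g$G_dprime_ST,
               tolerance = 0.05)
})

test_that("pairwise matrices are symmetric with zero diagonals", {
  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 4, n_ind = 10, n_alleles = 10, n_str_loci = 2, seed = 29))
  m <- gst_pairwise(sim$table, "MHC")
  expect_equal(m, t(m))
  expect_equal(diag(m), stats::setNames(rep(0, 4), rownames(m)))
})

test_that("Mantel correlation behaves on identical, random and constant input", {
  set.seed(3)
  a <- as.matrix(stats::dist(matrix(rnorm(12), 6)))
  expect_equal(mantel_test(a, a, n_perm = 99)$r, 1, tolerance = 1e-12)
  b <- as.matrix(stats::dist(matrix(rnorm(12), 6)))
  mt <- mantel_test(a, b, n_perm = 99, seed = 1)
  expect_true(abs(mt$r) <= 1)
  expect_true(mt$p_value > 0 && mt$p_value <= 1)
  # symmetry of r in the arguments
  expect_equal(mantel_test(b, a, n_perm = 0)$r, mt$r, tolerance = 1e-12)
  cons <- matrix(0, 6, 6)
  expect_error(mantel_test(cons, a), "constant")
})

test_that("AMOVA components match the balanced sums-of-squares oracle", {
  # 2 groups x 2 populations x 4 diploid individuals, 1 locus
  set.seed(41)
  pops <- rep(c("P1", "P2", "P3", "P4"), each = 4)
  alle <- list(P1 = c("a", "b"), P2 = c("a", "c"),
               P3 = c("d", "e"), P4 = c("d", "f"))
  a1 <- unlist(lapply(pops, function(p) sample(alle[[p]], 1)))
  a2 <- unlist(lapply(pops, function(p) sample(alle[[p]], 1)))
  tb <- make_table(pops, rep("A", 16), rep("A", 16),
                   str = list(loc = list(a1, a2)))
  grouping <- c(P1 = "g1", P2 = "g1", P3 = "g2", P4 = "g2")
  res <- amova(tb, "loc", grouping, n_perm = 0)
  oracle <- amova_balanced_oracle(c(a1, a2), rep(pops, 2),
                                  rep(grouping[pops], 2))
  expect_equal(res$components$sigma2, oracle, tolerance = 1e-10)
  expect_equal(sum(res$components$percent), 100, tolerance = 1e-6)
})

test_that("AMOVA among-group variance vanishes for identical groups", {
  tb <- table_from_counts(list(P1 = c(a = 12, b = 12), P2 = c(a = 12, b = 12),
                               P3 = c(a = 12, b = 12), P4 = c(a = 12, b = 12)))
  res <- amova(tb, "MHC", c(P1 = "x", P2 = "x", P3 = "y", P4 = "y"),
               n_perm = 0)
  expect_lt(abs(res$components$percent[1]), 1)
  expect_gt(res$components$sigma2[3], 0)
})

test_that("single-group AMOVA reduces to the two-level decomposition", {
  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 4, n_ind = 8, n_alleles = 8, n_str_loci = 2, seed = 47))
  one <- amova(sim$table, "MHC", stats::setNames(rep("all", 4),
                                                 unique(sim$table$population)),
               n_perm = 0)
  expect_equal(one$components$sigma2[1], 0)
  expect_equal(sum(one$components$percent), 100, tolerance = 1e-6)
  expect_gt(one$components$sigma2[3], 0)
})

test_that("AMOVA permutation p-values detect planted group structure", {
  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 4, n_ind = 12, n_alleles = 10, f_drift = 0.3,
    n_str_loci = 2, seed = 53))
  grouping <- stats::setNames(c("g1", "g1", "g2", "g2"),
                              unique(sim$table$population))
  res <- amova(sim$table, "STR", grouping, n_perm = 49, seed = 6)
  p <- res$components$p_value
  expect_true(all(p > 0 & p <= 1))
  expect_lt(p[3], 0.05)  # strong among-population structure
})
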