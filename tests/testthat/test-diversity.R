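test_that("allele frequencies count gene copies per population", {
  tb1 <- make_table("P1", "A", "A")
  f1 <- allele_frequencies(tb1)
  expect_equal(f1$freq, 1)
  tb2 <- make_table(c("P1", "P1"), c("A", "A"), c("B", "A"))
  f2 <- allele_frequencies(tb2)
  expect_equal(f2$freq[f2$allele == "A"], 0.75)
  expect_equal(f2$freq[f2$allele == "B"], 0.25)
})

test_that("frequencies sum to one for every population and marker", {
  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 4, n_ind = 10, n_alleles = 15, n_str_loci = 3, seed = 2))
  for (m in c("MHC", "LDH", str_loci(sim$table))) {
    f <- allele_frequencies(sim$table, m)
    sums <- tapply(f$freq, f$population, sum)
    expect_true(all(abs(sums - 1) < 1e-12), label = m)
  }
})

test_that("heterozygosity matches closed forms and HWE simulation", {
  expect_equal(heterozygosity(make_table("P1", "A", "A"))$He, 0)
  one_het <- heterozygosity(make_table("P1", "A", "B"))
  expect_equal(one_het$Ho, 1)
  expect_equal(one_het$He, 0.5)
  # large sample with two equifrequent alleles under HWE
  set.seed(8)
  g <- matrix(sample(c("A", "B"), 8000, replace = TRUE), ncol = 2)
  h <- heterozygosity(make_table(rep("P1", 4000), g[, 1], g[, 2]))
  expect_equal(h$Ho, 0.5, tolerance = 0.05)
  expect_equal(h$He, 0.5, tolerance = 0.05)
})

test_that("rarefied richness matches trivial cases and enumeration", {
  # g_min equal to the gene count returns the observed allele number
  tb <- table_from_counts(list(P1 = c(a = 3, b = 2, c = 1)))
  expect_equal(allelic_richness(tb, g_min = 6)$R, 3)
  # counts {2,2}, subsample 2 -> 5/3 by exhaustive enumeration
  tb2 <- table_from_counts(list(P1 = c(a = 2, b = 2)))
  expect_equal(allelic_richness(tb2, g_min = 2)$R, 5 / 3)
  expect_equal(rarefaction_oracle(c(2, 2), 2), 5 / 3)
  # a single allele rarefies to 1
  tb3 <- table_from_counts(list(P1 = c(a = 4)))
  expect_equal(allelic_richness(tb3, g_min = 2)$R, 1)
  expect_error(allelic_richness(tb3, g_min = 6), "exceeds")
})

test_that("analytic rarefaction equals Monte-Carlo subsampling", {
  set.seed(31)
  counts <- c(9, 5, 3, 2, 1)
  g <- 8
  tb <- table_from_counts(list(P1 = stats::setNames(counts, letters[1:5])))
  r <- allelic_richness(tb, g_min = g)$R
  copies <- rep(seq_along(counts), counts)
  draws <- replicate(10000, length(unique(sample(copies, g))))
  expect_lt(abs(r - mean(draws)), 3 * stats::sd(draws) / sqrt(length(draws)))
})

test_that("private variants are those seen in exactly one population", {
  tb <- table_from_counts(list(P1 = c(a = 2, b = 2), P2 = c(a = 2, c = 2)))
  p <- private_variants(tb)
  expect_equal(p$P[p$population == "P1"], 1L)  # b
  expect_equal(p$P[p$population == "P2"], 1L)  # c
  # disjoint allele sets: everything private
  tb2 <- table_from_counts(list(P1 = c(a = 2, b = 2), P2 = c(c = 2, d = 2)))
  expect_equal(private_variants(tb2)$P, c(2L, 2L))
})

test_that("Hardy-Weinberg exact test agrees with full enumeration", {
  # 2 individuals, allele counts (2,2): possible tables are
  # {2 hets} (prob 2/3) and {AA,BB} (prob 1/3)
  het2 <- make_table(c("P1", "P1"), c("A", "A"), c("B", "B"))
  hom2 <- make_table(c("P1", "P1"), c("A", "B"), c("A", "B"))
  p_het <- hwe_test(het2, "MHC", "P1", n_mc = 4000, seed = 1)
  p_hom <- hwe_test(hom2, "MHC", "P1", n_mc = 4000, seed = 1)
  # observed = modal table -> p = 1; observed = rarer table -> p = 1/3
  expect_equal(p_het, 1, tolerance = 0.03)
  expect_equal(p_hom, 1 / 3, tolerance = 0.05)
  # monomorphic locus is undefined
  expect_true(is.na(hwe_test(make_table("P1", "A", "A"), "MHC", "P1",
                             n_mc = 10)))
})

test_that("heterozygote deficits are detected and Holm adjustment applied", {
  # inbred-style sample: far fewer heterozygotes than HWE expects
  set.seed(5)
  n <- 60
  alle <- c("A", "B", "C", "D")
  hom <- sample(alle, round(n * 0.7), replace = TRUE)
  a1 <- c(hom, sample(alle, n - length(hom), replace = TRUE))
  a2 <- c(hom, sample(alle, n - length(hom), replace = TRUE))
  tb <- make_table(rep("P1", n), a1, a2)
  expect_lt(hwe_test(tb, "MHC", "P1", n_mc = 2000, seed = 3), 0.01)

  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 2, n_ind = 12, n_alleles = 6, n_str_loci = 2, seed = 9))
  fam <- hwe_tests(sim$table, markers = c("MHC", "STR"), n_mc = 500,
                   seed = 11)
  ok <- !is.na(fam$p)
  expect_true(all(fam$p_holm[ok] >= fam$p[ok] - 1e-12))
})

test_that("linkage test flags coupled loci and respects the p lattice", {
  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 1, n_ind = 30, n_alleles = 8, n_str_loci = 2, seed = 13))
  tb <- sim$table
  # duplicate locus L01 as a perfectly coupled pseudo-locus
  tb$DUP_1 <- tb$L01_1; tb$DUP_2 <- tb$L01_2
  attr(tb, "str_loci") <- c(str_loci(tb), "DUP")
  p <- ld_test(tb, c("L01", "DUP"), "P01", n_perm = 199, seed = 1)
  expect_equal(p, 1 / 200)
  # independently simulated loci are usually unremarkable
  p2 <- ld_test(tb, c("L01", "L02"), "P01", n_perm = 199, seed = 1)
  expect_gt(p2, 1 / 200)
})

test_that("linkage test holds its nominal type-I error", {
  set.seed(77)
  rej <- 0L; nrep <- 120L
  for (r in seq_len(nrep)) {
    g1 <- matrix(sample(c("a", "b"), 60, replace = TRUE), ncol = 2)
    g2 <- matrix(sample(c("x", "y"), 60, replace = TRUE), ncol = 2)
    tb <- make_table(rep("P1", 30), rep("A", 30), rep("B", 30),
                     str = list(u = list(g1[, 1], g1[, 2]),
                                v = list(g2[, 1], g2[, 2])))
    if (ld_test(tb, c("u", "v"), "P1", n_perm = 99) <= 0.05) rej <- rej + 1L
  }
  expect_gt(rej / nrep, 0.005)
  expect_lt(rej / nrep, 0.12)
})
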