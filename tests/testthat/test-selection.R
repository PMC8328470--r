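test_that("pairwise substitution counts match the pathway oracle", {
  # identical sequences carry no substitutions
  ng0 <- nei_gojobori_pair("TTTAAA", "TTTAAA")
  expect_equal(ng0$Nd, 0); expect_equal(ng0$Sd, 0)
  expect_equal(ng0$dN, 0); expect_equal(ng0$dS, 0)
  # single nonsynonymous step: Phe (TTT) -> Leu (TTA)
  ng1 <- nei_gojobori_pair("TTT", "TTA")
  expect_equal(ng1$Nd, 1); expect_equal(ng1$Sd, 0)
  # two-step difference averages over both mutational pathways
  ng2 <- nei_gojobori_pair("TTTGTAGGGCCC", "TTTGCGGGGCCC")
  o2 <- ng_pair_oracle("GTA", "GCG")
  expect_equal(ng2$Nd, unname(o2["nd"]))
  expect_equal(ng2$Sd, unname(o2["sd"]))
})

test_that("counts and sites equal the enumeration oracle over random codon pairs", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  # identical filler codons add sites but no differences, keeping the
  # Jukes-Cantor correction away from saturation for single-codon checks
  pad <- "GGGCCCGGGCCCGGGCCC"
  set.seed(19)
  for (r in 1:60) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    ndiff <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (ndiff > 2) next
    ng <- nei_gojobori_pair(paste0(c1, pad), paste0(c2, pad))
    o <- ng_pair_oracle(c1, c2)
    expect_equal(ng$Nd, unname(o["nd"]), label = paste(c1, c2))
    expect_equal(ng$Sd, unname(o["sd"]), label = paste(c1, c2))
    # potential sites for the identical pair reduce to the per-codon oracle
    self <- nei_gojobori_pair(c1, c1)
    expect_equal(self$S_sites, ng_sites_oracle(c1), tolerance = 1e-12)
  }
})

test_that("pair statistics are symmetric and sites partition 3 per codon", {
  set.seed(7)
  cat <- simulate_codon_alignment(n_seqs = 6, n_codons = 30, seed = 61,
                                  divergence = 0.4)
  for (q in 1:5) {
    i <- sample(6, 2)
    f <- nei_gojobori_pair(cat$nt_seq[i[1]], cat$nt_seq[i[2]])
    b <- nei_gojobori_pair(cat$nt_seq[i[2]], cat$nt_seq[i[1]])
    expect_equal(f$Nd, b$Nd); expect_equal(f$Sd, b$Sd)
    expect_equal(f$N_sites + f$S_sites, 3 * 30, tolerance = 1e-9)
  }
})

test_that("partitioned Z test separates selected from neutral codon classes", {
  pss <- seq(2, 60, by = 2)[1:20]
  cat <- simulate_codon_alignment(n_seqs = 15, n_codons = 60, pss = pss,
                                  omega_pss = 8, omega_background = 0.2,
                                  divergence = 0.6, seed = 71)
  zp <- dnds_partition_test(cat, pss_config(pss), "PSS", n_boot = 300,
                            seed = 1)
  zn <- dnds_partition_test(cat, pss_config(pss), "nonPSS", n_boot = 300,
                            seed = 1)
  expect_gt(zp$Z, 2)
  expect_lt(zp$p_value, 0.05)
  expect_lt(zn$Z, 2)
  expect_gt(zp$dN, zp$dS)
  # sign convention: positive Z iff dN exceeds dS
  expect_equal(zp$Z > 0, zp$dN > zp$dS)
  expect_error(dnds_partition_test(cat, pss_config(c(1, 2)), "PSS"),
               "fewer than 3")
})

test_that("supertype randomization is exact in the degenerate cases", {
  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 3, n_ind = 10, n_alleles = 8, n_str_loci = 2, seed = 83))
  # identity map: every relabeling gives back the allele-space statistic
  ident <- stats::setNames(seq_len(8), sprintf("A%03d", 1:8))
  r <- supertype_gst_randomization(sim$table, ident, n_rand = 60, seed = 2)
  expect_equal(r$p_two_sided, 1)
  expect_true(all(abs(r$null_distribution - r$observed) < 1e-12))
  expect_error(supertype_gst_randomization(
    sim$table, stats::setNames(rep(1L, 8), sprintf("A%03d", 1:8)), 10),
    "single supertype")
})

test_that("randomization p-values sit on the lattice and nulls are seed-stable", {
  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 3, n_ind = 12, n_alleles = 10, n_supertypes = 3,
    n_str_loci = 2, seed = 89))
  r1 <- supertype_gst_randomization(sim$table, sim$truth$supertype_map,
                                    n_rand = 300, seed = 5)
  r2 <- supertype_gst_randomization(sim$table, sim$truth$supertype_map,
                                    n_rand = 300, seed = 6)
  expect_gt(r1$p_two_sided, 0)
  se <- stats::sd(r1$null_distribution) / sqrt(300)
  expect_lt(abs(mean(r1$null_distribution) - mean(r2$null_distribution)),
            3 * sqrt(2) * se)
})
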