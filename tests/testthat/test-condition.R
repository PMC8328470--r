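test_that("Fulton's condition factor follows the closed form", {
  expect_equal(fulton_k(10, 10), 1.0)
  expect_equal(fulton_k(20, 10), 2 * fulton_k(10, 10))
  expect_equal(fulton_k(31.5, 13.0), 100 * 31.5 / 2197, tolerance = 1e-12)
  expect_error(fulton_k(-1, 10), "positive")
  expect_error(fulton_k(10, 0), "positive")
})

test_that("the MHC frequency index sums carried-variant frequencies", {
  # 10 individuals = 20 copies; allele a at frequency 0.3, b at 0.1
  tb <- table_from_counts(list(P1 = c(a = 6, b = 2, c = 12)))
  idx <- mhc_frequency_index(tb)
  hom_a <- which(tb$mhc_1 == "a" & tb$mhc_2 == "a")
  expect_equal(idx[hom_a], rep(0.6, length(hom_a)))
  het_ab <- which(tb$mhc_1 == "a" & tb$mhc_2 == "b" |
                  tb$mhc_1 == "b" & tb$mhc_2 == "a")
  expect_equal(idx[het_ab], rep(0.4, length(het_ab)))
  # fixed population: everyone carries the doubled frequency 2.0
  fx <- table_from_counts(list(P1 = c(z = 8)))
  expect_equal(mhc_frequency_index(fx), rep(2, 4))
  # leave-one-out variant removes the focal copies from the denominator
  loo <- mhc_frequency_index(tb, leave_one_out = TRUE)
  expect_equal(loo[hom_a][1], 2 * 4 / 18)
})

test_that("residualization removes the predictor's signal", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(residualize(x, x), rep(0, 5), tolerance = 1e-12)
  set.seed(12)
  z <- rnorm(200)
  y <- rbinom(200, 1, plogis(0.8 * z))
  r <- residualize(y, z, family = "binomial")
  expect_lt(abs(cor(r, z)), 1e-6)
  expect_error(residualize(y, rep(1, 200)), "constant")
})

test_that("richness models recover an exact linear dependence", {
  df <- data.frame(population = letters[1:6],
                   str_richness = c(5, 6, 7, 4, 9, 8),
                   mhc_dab_richness = NA,
                   ldh_admixture = c(0.1, 0.2, 0.4, 0.05, 0.45, 0.3))
  df$mhc_dab_richness <- as.numeric(scale(df$str_richness))
  fit <- suppressWarnings(fit_richness_models(df))
  co <- fit$dab$coefficients
  expect_equal(co$estimate[co$term == "str_richness"], 1, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "ldh_admixture_resid"], 0,
               tolerance = 1e-8)
  expect_equal(fit$dab$adj_r_squared, 1, tolerance = 1e-8)
})

test_that("sequential regression preserves the first predictor's simple slope", {
  set.seed(4)
  x1 <- rnorm(40); x2 <- 0.7 * x1 + rnorm(40, 0, 0.5)
  y <- 2 * x1 + 0.5 * x2 + rnorm(40, 0, 0.3)
  x2r <- residualize(x2, x1)
  fit <- lm(y ~ x1 + x2r)
  simple <- lm(y ~ x1)
  expect_equal(unname(coef(fit)["x1"]), unname(coef(simple)["x1"]),
               tolerance = 1e-10)
})

test_that("condition records derive predictors with the documented coding", {
  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 3, n_ind = 15, n_alleles = 10, n_str_loci = 4, seed = 101))
  rec <- condition_records(sim$table, catalog = sim$catalog,
                           solution = sim$truth$supertype_map)
  expect_equal(rec$K, fulton_k(sim$table$weight, sim$table$length))
  # homozygotes have zero dissimilarity by definition
  hom <- sim$table$mhc_1 == sim$table$mhc_2
  expect_true(all(rec$mhc_dissim_nt[hom] == 0))
  expect_true(all(rec$mhc_dissim_aa[hom] == 0))
  expect_true(all(rec$freq_index > 0 & rec$freq_index <= 2))
  expect_true(all(rec$str_het >= 0 & rec$str_het <= 1))
  expect_identical(levels(rec$ldh_type), c("domestic", "hybrid", "native"))
  # zygosity residuals are decorrelated from the frequency index
  expect_lt(abs(cor(rec$zygosity_resid, rec$freq_index)), 1e-6)
})

test_that("rare variants concentrate in heterozygotes under HWE", {
  sim <- simulate_population_dataset(sim_scenario(seed = 107))
  rec <- condition_records(sim$table)
  expect_lt(cor(rec$freq_index, rec$zygosity, method = "spearman"), 0)
})

test_that("the condition mixed model returns a sound fit object", {
  sim <- simulate_population_dataset(sim_scenario(seed = 113))
  rec <- condition_records(sim$table, catalog = sim$catalog)
  fit <- fit_condition_model(rec, "1_DAB")
  co <- fit$coefficients
  expect_setequal(co$term, c("(Intercept)", "freq_index", "zygosity_resid",
                             "str_het", "ldh_typehybrid", "ldh_typenative"))
  expect_true(all(is.finite(co$SE)) && all(co$SE > 0))
  expect_true(all(co$df > 1 & co$df <= fit$n))
  expect_lte(fit$R2_marginal, fit$R2_conditional)
  expect_true(is.finite(fit$AICc))
  # the planted rare-variant advantage is visible in one realization
  est <- co$estimate[co$term == "freq_index"]
  expect_lt(est, 0.05)
  expect_gt(est, -0.4)
  # dissimilarity models fit too
  f2 <- fit_condition_model(rec, "2_NU")
  expect_true(is.finite(f2$AICc))
})

test_that("mixed-model estimates are invariant to population relabeling", {
  sim <- simulate_population_dataset(sim_scenario(
    n_pops = 4, n_ind = 20, n_alleles = 12, n_str_loci = 3, seed = 127))
  rec <- condition_records(sim$table, catalog = sim$catalog)
  f1 <- fit_condition_model(rec, "1_DAB", df_method = "residual")
  rec2 <- rec
  relab <- c(P01 = "Q4", P02 = "Q1", P03 = "Q3", P04 = "Q2")
  rec2$population <- unname(relab[rec$population])
  f2 <- fit_condition_model(rec2, "1_DAB", df_method = "residual")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("adding parameters never lowers the ML log-likelihood", {
  sim <- simulate_population_dataset(sim_scenario(seed = 131))
  rec <- condition_records(sim$table, solution = sim$truth$supertype_map)
  base <- fit_condition_model(rec, "1_ST", df_method = "residual")
  set.seed(1)
  rec$noise <- rnorm(nrow(rec))
  bigger <- fit_condition_model(
    rec, K ~ freq_index_st + zygosity_st_resid + str_het + ldh_type +
      noise + (1 | population), df_method = "residual")
  expect_gte(bigger$logLik_ML, base$logLik_ML - 1e-6)
})

test_that("the supertype scan ranks models by AICc and flags planted effects", {
  sc <- sim_scenario(seed = 139, n_supertypes = 6,
                     supertype_effects = c(ST3 = 0.35))
  sim <- simulate_population_dataset(sc)
  rec <- condition_records(sim$table, solution = sim$truth$supertype_map)
  st <- genotypes_to_supertypes(sim$table, sim$truth$supertype_map)
  pres <- supertype_presence(st)
  scan <- supertype_scan(rec, pres)
  expect_false(is.unsorted(scan$AICc))
  expect_equal(scan$dAICc[scan$model == "baseline"], 0)
  hit <- scan[scan$model == "baseline + ST3", ]
  expect_true(hit$better)
  expect_gt(hit$beta, 0)
  expect_true(hit$model == scan$model[1])  # planted effect tops the ranking
})

test_that("without planted effects the scan pays the AICc penalty on average", {
  sc0 <- sim_scenario(seed = 149, n_supertypes = 6)
  sim0 <- simulate_population_dataset(sc0)
  rec0 <- condition_records(sim0$table, solution = sim0$truth$supertype_map)
  st0 <- genotypes_to_supertypes(sim0$table, sim0$truth$supertype_map)
  scan0 <- supertype_scan(rec0, supertype_presence(st0))
  d <- scan0$dAICc[scan0$model != "baseline"]
  # an uninformative indicator costs ~2 AICc points; chance can rescue one
  expect_gt(mean(d), 0)
  expect_lte(sum(d < -2), 1L)
})
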