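#' Published per-population diversity summary
#'
#' The per-population summary statistics of the six central-Italian brown
#' trout populations the pipeline was built around (sample sizes, LDH allele
#' frequencies, and allele/supertype/microsatellite counts, rarefied
#' richness, private variants and heterozygosities), shipped as a plain-text
#' fixture. These printed summary values are an *input* for the
#' across-population richness models; they are not recomputed here because
#' the underlying individual data are an external deposit.
#'
#' @return data.frame, one row per population.
#' @export
population_summary <- function() {
  path <- system.file("extdata", "population_summary.csv",
                      package = "mhcbalance", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Richness-model input from a per-population summary
#'
#' Reshapes a [population_summary()]-style data.frame into the input of
#' [fit_richness_models()]: STR and MHC rarefied richness plus the
#' LDH-admixture level, defined as the frequency of the less common LDH
#' allele in the population (0 = pure, 0.5 = completely admixed).
#'
#' @param summary data.frame in the [population_summary()] layout.
#' @return data.frame with columns `population`, `str_richness`,
#'   `mhc_dab_richness`, `mhc_st_richness`, `ldh_admixture`.
#' @export
richness_model_input <- function(summary = population_summary()) {
  data.frame(population = summary$population,
             str_richness = summary$str_R,
             mhc_dab_richness = summary$mhc_dab_R,
             mhc_st_richness = summary$mhc_st_R,
             ldh_admixture = pmin(summary$ldh_native_pct,
                                  summary$ldh_domestic_pct) / 100,
             stringsAsFactors = FALSE)
}
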