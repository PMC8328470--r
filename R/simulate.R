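#' Simulation scenario for a multi-population genotype/phenotype dataset
#'
#' The defaults mirror the field setting the pipeline targets: six stream
#' populations of 23-28 diploid individuals, one multiallelic MHC locus
#' drawn from a pool of 58 alleles with skewed base frequencies, 11
#' microsatellite loci, a biallelic LDH admixture marker with
#' population-specific domestic-allele frequencies, and body condition built
#' as `K = beta0 + beta_freq * freq_index + beta_zyg * het +
#' beta_dissim * d_nt + supertype shifts + u_pop + e` with
#' `u_pop ~ N(0, sigma_pop^2)` and `e ~ N(0, sigma_e^2)`.
#'
#' @param n_pops number of populations.
#' @param n_ind individuals per population (recycled).
#' @param n_alleles MHC allele pool size.
#' @param dirichlet_alpha concentration of the base allele frequencies;
#'   values < 1 give the skewed spectra (a few common, many rare alleles)
#'   typical of deep-sequenced MHC data.
#' @param f_drift Balding-Nichols differentiation parameter: per-population
#'   frequencies are Dirichlet with mean the base frequencies and
#'   concentration `(1 - F)/F`, so F approximates the expected fixation
#'   index.
#' @param n_str_loci,str_alleles microsatellite panel geometry.
#' @param ldh_p90 per-population frequency of the domestic LDH*90 allele.
#' @param beta0,beta_freq,beta_zyg,beta_dissim,sigma_pop,sigma_e condition
#'   model parameters (Fulton-K scale).
#' @param supertype_effects optional named vector of additive condition
#'   shifts for carriers of latent supertypes (`"ST3" = 0.07`, ...).
#' @param n_supertypes latent supertype count used to partition the allele
#'   pool.
#' @param n_codons,pss,omega_pss,omega_background,divergence passed to
#'   [simulate_codon_alignment()] for the allele sequences.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_pops = 6L,
                         n_ind = c(28L, 27L, 25L, 26L, 27L, 23L),
                         n_alleles = 58L,
                         dirichlet_alpha = 0.3,
                         f_drift = 0.2,
                         n_str_loci = 11L,
                         str_alleles = 8L,
                         ldh_p90 = c(0.143, 0.907, 0.46, 0.058, 0.389,
                                     0.457),
                         beta0 = 1.5, beta_freq = -0.15, beta_zyg = 0,
                         beta_dissim = 0, sigma_pop = 0.1, sigma_e = 0.25,
                         supertype_effects = NULL, n_supertypes = 12L,
                         n_codons = 85L, pss = NULL, omega_pss = 5,
                         omega_background = 0.3, divergence = 0.5,
                         seed) {
  if (missing(seed)) stop("'seed' is required")
  n_ind <- rep_len(as.integer(n_ind), n_pops)
  ldh_p90 <- rep_len(ldh_p90, n_pops)
  if (n_alleles < 2L) stop("allele pool must hold at least 2 alleles")
  stopifnot(all(ldh_p90 >= 0 & ldh_p90 <= 1), sigma_pop >= 0, sigma_e >= 0,
            f_drift >= 0, f_drift < 1)
  if (is.null(pss)) pss <- seq(3L, n_codons, by = 3L)[1:min(28L, n_codons %/% 3L)]
  structure(as.list(environment()), class = "sim_scenario")
}

# Evolve a codon vector by Poisson-many proposed point mutations; a
# nonsynonymous change is accepted with probability min(1, omega[codon]),
# a synonymous one with min(1, 1/omega[codon]) (the favoured class is
# certain), so the realized nonsyn/syn substitution ratio tracks omega
# times the mutational opportunity. Stop codons are always rejected.
evolve_codons <- function(cur, divergence, omega, count = FALSE,
                          pss = integer()) {
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  n_codons <- length(cur)
  p_nonsyn <- pmin(1, omega)
  p_syn <- pmin(1, 1 / omega)
  counts <- c(syn = 0L, nonsyn_pss = 0L, nonsyn_bg = 0L)
  n_mut <- stats::rpois(1L, divergence * n_codons)
  for (m in seq_len(n_mut)) {
    cpos <- sample.int(n_codons, 1L)
    ch <- strsplit(cur[cpos], "")[[1]]
    npos <- sample.int(3L, 1L)
    ch2 <- ch
    ch2[npos] <- sample(setdiff(nts, ch[npos]), 1L)
    cand <- paste(ch2, collapse = "")
    if (gc[cand] == "*") next
    syn <- unname(gc[cand] == gc[cur[cpos]])
    acc <- if (syn) p_syn[cpos] else p_nonsyn[cpos]
    if (stats::runif(1L) > acc) next
    cur[cpos] <- cand
    if (syn) counts["syn"] <- counts["syn"] + 1L
    else if (cpos %in% pss) counts["nonsyn_pss"] <- counts["nonsyn_pss"] + 1L
    else counts["nonsyn_bg"] <- counts["nonsyn_bg"] + 1L
  }
  if (count) list(codons = cur, counts = counts) else cur
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate a genotype/phenotype dataset with known ground truth
#'
#' Allele frequencies per population are drawn around shared base
#' frequencies with Balding-Nichols differentiation; diploid MHC and STR
#' genotypes are drawn under Hardy-Weinberg proportions; LDH genotypes are
#' binomial in the population's domestic-allele frequency; Fulton's K is
#' generated from the scenario's condition model and inverted into
#' weight/length pairs through a lognormal length distribution
#' (`weight = K * L^3 / 100`), so the condition factor round-trips exactly.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `table` (a [genotype_table()]), `catalog` (an
#'   [allele_catalog()] for the MHC pool) and `truth` (every parameter and
#'   latent draw needed to rerun or score the scenario).
#' @export
simulate_population_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  s <- scenario
  set.seed(s$seed)
  allele_names <- sprintf("A%03d", seq_len(s$n_alleles))
  # alleles arise in latent supertype families: founders diverge deeply from
  # a common ancestor, members shallowly from their founder, so the
  # physicochemical PSS profiles carry recoverable cluster structure
  founders <- simulate_codon_alignment(
    n_seqs = s$n_supertypes, n_codons = s$n_codons, pss = s$pss,
    omega_pss = s$omega_pss, omega_background = s$omega_background,
    divergence = s$divergence, seed = s$seed + 1L)
  family <- rep_len(seq_len(s$n_supertypes), s$n_alleles)[
    sample(s$n_alleles)]
  omega <- ifelse(seq_len(s$n_codons) %in% s$pss, s$omega_pss,
                  s$omega_background)
  seqs <- vapply(seq_len(s$n_alleles), function(i) {
    cur <- codon_split(founders$nt_seq[family[i]])
    paste(evolve_codons(cur, divergence = s$divergence / 5, omega = omega),
          collapse = "")
  }, "")
  catalog <- allele_catalog(allele_names, seqs)
  supertype_map <- stats::setNames(family, allele_names)

  base_mhc <- rdirichlet1(rep(s$dirichlet_alpha, s$n_alleles))
  bn <- function(base) {
    if (s$f_drift == 0) return(base)
    rdirichlet1(base * (1 - s$f_drift) / s$f_drift)
  }
  pops <- sprintf("P%02d", seq_len(s$n_pops))
  pop_freq_mhc <- lapply(seq_len(s$n_pops), function(i) bn(base_mhc))
  names(pop_freq_mhc) <- pops
  str_names <- sprintf("L%02d", seq_len(s$n_str_loci))
  base_str <- lapply(seq_len(s$n_str_loci),
                     function(i) rdirichlet1(rep(1, s$str_alleles)))
  pop_freq_str <- lapply(seq_len(s$n_pops), function(i)
    lapply(base_str, bn))

  rows <- list()
  u_pop <- stats::rnorm(s$n_pops, 0, s$sigma_pop)
  for (i in seq_len(s$n_pops)) {
    n <- s$n_ind[i]
    draw2 <- function(p, labels)
      matrix(sample(labels, 2L * n, replace = TRUE, prob = p), ncol = 2L)
    mhc <- draw2(pop_freq_mhc[[i]], allele_names)
    d <- data.frame(id = sprintf("%s_%03d", pops[i], seq_len(n)),
                    population = pops[i],
                    mhc_1 = mhc[, 1L], mhc_2 = mhc[, 2L],
                    stringsAsFactors = FALSE)
    for (l in seq_len(s$n_str_loci)) {
      g <- draw2(pop_freq_str[[i]][[l]],
                 as.character(100L + 2L * seq_len(s$str_alleles)))
      d[[paste0(str_names[l], "_1")]] <- g[, 1L]
      d[[paste0(str_names[l], "_2")]] <- g[, 2L]
    }
    ldh <- matrix(sample(c("90", "100"), 2L * n, replace = TRUE,
                         prob = c(s$ldh_p90[i], 1 - s$ldh_p90[i])),
                  ncol = 2L)
    d$ldh_1 <- pmin(ldh[, 1L], ldh[, 2L])
    d$ldh_2 <- pmax(ldh[, 1L], ldh[, 2L])
    d$weight <- NA_real_; d$length <- NA_real_
    rows[[i]] <- d
  }
  df <- do.call(rbind, rows)
  table <- genotype_table(df, str_loci = str_names)

  freq_index <- mhc_frequency_index(table)
  het <- as.integer(table$mhc_1 != table$mhc_2)
  dis <- if (s$beta_dissim != 0)
    sequence_dissimilarity(catalog, table$mhc_1, table$mhc_2)$d_nt
  else rep(0, nrow(table))
  st_shift <- rep(0, nrow(table))
  if (!is.null(s$supertype_effects)) {
    st <- genotypes_to_supertypes(table, supertype_map)
    pres <- supertype_presence(st)
    for (nm in names(s$supertype_effects))
      if (nm %in% colnames(pres))
        st_shift <- st_shift + s$supertype_effects[[nm]] * pres[, nm]
  }
  K <- s$beta0 + s$beta_freq * freq_index + s$beta_zyg * het +
    s$beta_dissim * dis + st_shift +
    u_pop[match(table$population, pops)] +
    stats::rnorm(nrow(table), 0, s$sigma_e)
  K <- pmax(K, 0.2)   # guard against nonphysical negative condition
  L <- stats::rlnorm(nrow(table), log(13), 0.12)
  table$length <- L
  table$weight <- K * L^3 / 100
  truth <- list(scenario = s, base_mhc = base_mhc,
                pop_freq_mhc = pop_freq_mhc, pop_freq_str = pop_freq_str,
                supertype_map = supertype_map, u_pop = u_pop, K = K,
                freq_index = freq_index, het = het, dissim = dis)
  list(table = table, catalog = catalog, truth = truth)
}

#' Simulate a codon alignment with site-class-specific dN/dS
#'
#' Sequences evolve independently from a random stop-free ancestral coding
#' sequence: each sequence receives Poisson-many point mutations (mean
#' `divergence` per codon), and a proposed mutation is accepted with
#' probability proportional to 1 for synonymous and `omega` for
#' nonsynonymous changes (scaled so the larger class is certain), with the
#' codon-specific `omega` taken from `omega_pss` at PSS codons and
#' `omega_background` elsewhere. Stop codons are always rejected.
#'
#' @param n_seqs number of sequences.
#' @param n_codons alignment length in codons.
#' @param pss codon indices of the positively selected class.
#' @param omega_pss,omega_background target dN/dS per class.
#' @param divergence expected mutations per codon per sequence.
#' @param seed RNG seed.
#' @param names optional sequence names (default `S001`, ...).
#' @return An [allele_catalog()]; the realized per-class substitution
#'   counts are attached as attribute `truth`.
#' @export
simulate_codon_alignment <- function(n_seqs, n_codons = 85L,
                                     pss = integer(), omega_pss = 1,
                                     omega_background = 1, divergence = 0.5,
                                     seed, names = NULL) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- base::names(gc)[gc != "*"]
  nts <- c("A", "C", "G", "T")
  anc <- sample(sense, n_codons, replace = TRUE)
  omega <- ifelse(seq_len(n_codons) %in% pss, omega_pss, omega_background)
  counts <- c(syn = 0L, nonsyn_pss = 0L, nonsyn_bg = 0L)
  seqs <- character(n_seqs)
  for (sq in seq_len(n_seqs)) {
    res <- evolve_codons(anc, divergence, omega, count = TRUE, pss = pss)
    seqs[sq] <- paste(res$codons, collapse = "")
    counts <- counts + res$counts
  }
  if (is.null(names)) names <- sprintf("S%03d", seq_len(n_seqs))
  cat <- allele_catalog(names, seqs)
  attr(cat, "truth") <- list(pss = pss, omega_pss = omega_pss,
                             omega_background = omega_background,
                             divergence = divergence, counts = counts)
  cat
}

#' Simulate populations whose MHC pool size tracks admixture
#'
#' Emulates the across-population setting behind the richness models: each
#' population's MHC allele pool grows with its admixture level (plus noise),
#' STR pools grow with a shared latent factor correlated with admixture (so
#' the neutral-diversity/admixture collinearity of real data is present),
#' and the per-population summary is computed with the package's own
#' estimators.
#'
#' @param n_pops number of populations (>= 4).
#' @param n_ind individuals per population.
#' @param admixture per-population minor-LDH-allele frequency in `[0, 0.5]`.
#' @param mhc_effect additional MHC alleles per unit admixture (0 = no
#'   admixture effect on the MHC pool).
#' @param base_pool minimum MHC pool size per population.
#' @param n_str_loci STR loci.
#' @param seed RNG seed.
#' @return list with `table`, `summary` (input for
#'   [fit_richness_models()]) and `truth`.
#' @export
simulate_admixture_gradient <- function(n_pops = 6L, n_ind = 26L,
                                        admixture = NULL, mhc_effect = 20,
                                        base_pool = 6L, n_str_loci = 6L,
                                        seed) {
  if (missing(seed)) stop("'seed' is required")
  if (n_pops < 4L) stop("need at least 4 populations")
  set.seed(seed)
  if (is.null(admixture))
    admixture <- stats::runif(n_pops, 0.02, 0.48)
  latent <- admixture + stats::rnorm(n_pops, 0, 0.08)
  pops <- sprintf("P%02d", seq_len(n_pops))
  pool_global <- sprintf("A%03d", 1:200)
  mhc_pool_n <- pmax(3L, round(base_pool + mhc_effect * admixture +
                                 stats::rnorm(n_pops, 0, 1)))
  str_pool_n <- pmax(3L, round(4 + 10 * pmin(pmax(latent, 0), 1)))
  str_names <- sprintf("L%02d", seq_len(n_str_loci))
  rows <- list()
  for (i in seq_len(n_pops)) {
    n <- n_ind
    palleles <- sample(pool_global, mhc_pool_n[i])
    pfreq <- rdirichlet1(rep(0.8, mhc_pool_n[i]))
    mhc <- matrix(sample(palleles, 2L * n, replace = TRUE, prob = pfreq),
                  ncol = 2L)
    d <- data.frame(id = sprintf("%s_%03d", pops[i], seq_len(n)),
                    population = pops[i], mhc_1 = mhc[, 1L],
                    mhc_2 = mhc[, 2L], stringsAsFactors = FALSE)
    for (l in seq_len(n_str_loci)) {
      k <- str_pool_n[i]
      g <- matrix(sample(as.character(100L + 2L * seq_len(k)), 2L * n,
                         replace = TRUE,
                         prob = rdirichlet1(rep(1, k))), ncol = 2L)
      d[[paste0(str_names[l], "_1")]] <- g[, 1L]
      d[[paste0(str_names[l], "_2")]] <- g[, 2L]
    }
    ldh <- matrix(sample(c("90", "100"), 2L * n, replace = TRUE,
                         prob = c(admixture[i], 1 - admixture[i])),
                  ncol = 2L)
    d$ldh_1 <- pmin(ldh[, 1L], ldh[, 2L]); d$ldh_2 <- pmax(ldh[, 1L], ldh[, 2L])
    d$weight <- 30; d$length <- 13
    rows[[i]] <- d
  }
  table <- genotype_table(do.call(rbind, rows), str_loci = str_names)
  r_mhc <- allelic_richness(table, "MHC")
  r_str <- diversity_summary(table, "STR")
  r_str <- r_str[r_str$locus == "mean", ]
  ldh_f <- allele_frequencies(table, "LDH")
  minor <- vapply(pops, function(p) {
    d <- ldh_f[ldh_f$population == p, ]
    if (nrow(d) == 1L) 0 else min(d$freq)
  }, 0)
  summary <- data.frame(
    population = pops,
    str_richness = r_str$R[match(pops, r_str$population)],
    mhc_dab_richness = r_mhc$R[match(pops, r_mhc$population)],
    ldh_admixture = minor, stringsAsFactors = FALSE)
  list(table = table, summary = summary,
       truth = list(admixture = admixture, mhc_pool_n = mhc_pool_n,
                    str_pool_n = str_pool_n, mhc_effect = mhc_effect,
                    seed = seed))
}
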