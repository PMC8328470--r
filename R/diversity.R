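#' Per-population allele frequencies
#'
#' Frequencies are computed over the non-missing gene copies (2 per scored
#' individual) within each population.
#'
#' @param table a [genotype_table()].
#' @param marker `"MHC"`, `"LDH"` or an STR locus name.
#' @return data.frame with columns `population`, `allele`, `count`, `freq`.
#' @export
allele_frequencies <- function(table, marker = "MHC") {
  pairs <- marker_pairs(table, marker)
  pops <- unique(table$population)
  out <- lapply(pops, function(p) {
    copies <- c(pairs[table$population == p, ])
    copies <- copies[!is.na(copies)]
    if (!length(copies))
      stop("population '", p, "' has no scored genotypes at ", marker)
    tab <- table(copies)
    data.frame(population = p, allele = names(tab),
               count = as.integer(tab), freq = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Internal: list of named frequency vectors per population
freq_list <- function(table, marker) {
  f <- allele_frequencies(table, marker)
  lapply(split(f, f$population),
         function(d) stats::setNames(d$freq, d$allele))
}

#' Observed and expected heterozygosity per population
#'
#' `Ho` is the fraction of scored individuals that are heterozygous; `He` is
#' Nei's gene diversity `1 - sum(p_i^2)`; `uHe` applies the small-sample
#' correction `2N/(2N-1)`.
#'
#' @inheritParams allele_frequencies
#' @return data.frame with columns `population`, `n` (scored individuals),
#'   `Ho`, `He`, `uHe`.
#' @export
heterozygosity <- function(table, marker = "MHC") {
  pairs <- marker_pairs(table, marker)
  pops <- unique(table$population)
  rows <- lapply(pops, function(p) {
    g <- pairs[table$population == p, , drop = FALSE]
    g <- g[!is.na(g[, 1L]) & !is.na(g[, 2L]), , drop = FALSE]
    n <- nrow(g)
    ho <- if (n) mean(g[, 1L] != g[, 2L]) else NA_real_
    pr <- table(c(g)) / (2 * n)
    he <- 1 - sum(pr^2)
    data.frame(population = p, n = n, Ho = ho, He = he,
               uHe = if (n > 0) 2 * n / (2 * n - 1) * he else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rarefied allelic richness per population
#'
#' Expected number of distinct alleles in a standardized subsample of
#' `g_min` gene copies, computed analytically from the hypergeometric
#' inclusion probabilities:
#' `R = sum_i (1 - choose(N - n_i, g_min) / choose(N, g_min))`.
#'
#' @inheritParams allele_frequencies
#' @param g_min standardized gene-copy count; default twice the smallest
#'   per-population number of scored individuals at the marker.
#' @return data.frame with columns `population`, `N_alleles`, `N_genes`, `R`.
#' @export
allelic_richness <- function(table, marker = "MHC", g_min = NULL) {
  f <- allele_frequencies(table, marker)
  byp <- split(f, f$population)
  n_genes <- vapply(byp, function(d) sum(d$count), 0L)
  if (is.null(g_min)) g_min <- min(n_genes)
  g_min <- as.integer(g_min)
  if (any(g_min > n_genes))
    stop("g_min = ", g_min, " exceeds the gene copies of population(s): ",
         paste(names(n_genes)[g_min > n_genes], collapse = ", "))
  rows <- lapply(names(byp), function(p) {
    d <- byp[[p]]
    N <- sum(d$count)
    r <- sum(1 - exp(lchoose(N - d$count, g_min) - lchoose(N, g_min)))
    data.frame(population = p, N_alleles = nrow(d), N_genes = N, R = r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "g_min") <- g_min
  out
}

#' Private variant counts per population
#'
#' @inheritParams allele_frequencies
#' @return data.frame with columns `population`, `P` (variants observed in
#'   that population and nowhere else).
#' @export
private_variants <- function(table, marker = "MHC") {
  f <- allele_frequencies(table, marker)
  if (length(unique(f$population)) < 2L)
    stop("private variants need at least 2 populations")
  npop <- tapply(f$population, f$allele, function(x) length(unique(x)))
  priv <- names(npop)[npop == 1L]
  pops <- unique(f$population)
  cnt <- vapply(pops, function(p)
    sum(f$allele[f$population == p] %in% priv), 0L)
  data.frame(population = pops, P = as.integer(cnt), stringsAsFactors = FALSE)
}

#' Table-style per-population diversity summary
#'
#' Combines allele counts, rarefied richness, private variants and
#' heterozygosities for one marker (per STR locus plus the across-locus mean
#' when `marker = "STR"`).
#'
#' @inheritParams allelic_richness
#' @return data.frame keyed by `population` (and `locus` for STR).
#' @export
diversity_summary <- function(table, marker = "MHC", g_min = NULL) {
  markers <- expand_markers(table, marker)
  rows <- lapply(markers, function(m) {
    r <- allelic_richness(table, m, g_min = g_min)
    h <- heterozygosity(table, m)
    p <- private_variants(table, m)
    out <- Reduce(function(a, b) merge(a, b, by = "population"),
                  list(r, p, h[, c("population", "Ho", "He", "uHe")]))
    cbind(locus = m, out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(markers) > 1L) {
    agg <- stats::aggregate(out[, c("N_alleles", "N_genes", "R", "P",
                                    "Ho", "He", "uHe")],
                            by = list(population = out$population), mean)
    out <- rbind(out, cbind(locus = "mean", agg, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' Conditional on the observed allele counts, random genotype tables are
#' generated by shuffling the gene copies and pairing them; the p-value is
#' the fraction of tables whose conditional probability is less than or equal
#' to that of the observed table (with the `(b + 1)/(m + 1)` correction so p
#' is never exactly 0).
#'
#' @inheritParams allele_frequencies
#' @param population population to test.
#' @param n_mc number of Monte-Carlo tables.
#' @param seed RNG seed.
#' @return p-value, or `NA` for a monomorphic locus.
#' @export
hwe_test <- function(table, marker, population, n_mc = 1e5, seed = NULL) {
  pairs <- marker_pairs(table, marker)
  g <- pairs[table$population == population, , drop = FALSE]
  g <- g[!is.na(g[, 1L]) & !is.na(g[, 2L]), , drop = FALSE]
  copies <- c(g)
  if (length(unique(copies)) < 2L) return(NA_real_)
  if (!is.null(seed)) set.seed(seed)
  lp_obs <- hwe_log_prob(g[, 1L], g[, 2L])
  n <- nrow(g)
  hits <- 0L
  for (b in seq_len(n_mc)) {
    perm <- sample(copies)
    a1 <- perm[seq_len(n)]; a2 <- perm[n + seq_len(n)]
    if (hwe_log_prob(a1, a2) <= lp_obs + 1e-9) hits <- hits + 1L
  }
  (hits + 1) / (n_mc + 1)
}

# log conditional probability of a diploid genotype table given allele counts
hwe_log_prob <- function(a1, a2) {
  n <- length(a1)
  het <- sum(a1 != a2)
  geno <- paste(pmin(a1, a2), pmax(a1, a2))
  ngeno <- table(geno)
  nall <- table(c(a1, a2))
  lfactorial(n) + het * log(2) + sum(lfactorial(nall)) -
    lfactorial(2 * n) - sum(lfactorial(ngeno))
}

#' Family-wise Hardy-Weinberg testing with Holm-Bonferroni adjustment
#'
#' @inheritParams hwe_test
#' @param markers markers to test (`"STR"` expands to every STR locus).
#' @return data.frame with columns `population`, `locus`, `p`, `p_holm`.
#' @export
hwe_tests <- function(table, markers = c("MHC", "STR"), n_mc = 1e5,
                      seed = NULL) {
  markers <- unlist(lapply(markers, expand_markers, table = table))
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(population = unique(table$population), locus = markers,
                      stringsAsFactors = FALSE)
  grid$p <- mapply(function(pop, m) hwe_test(table, m, pop, n_mc = n_mc),
                   grid$population, grid$locus)
  grid$p_holm <- NA_real_
  ok <- !is.na(grid$p)
  grid$p_holm[ok] <- stats::p.adjust(grid$p[ok], method = "holm")
  grid
}

#' Permutation test of genotypic linkage disequilibrium
#'
#' Log-likelihood-ratio G statistic on the contingency table of genotypes at
#' the two loci; the null is generated by permuting the genotypes at the
#' second locus among the individuals of the population.
#'
#' @param table a [genotype_table()].
#' @param locus_pair character vector of two marker names.
#' @param population population to test.
#' @param n_perm permutation count.
#' @param seed RNG seed.
#' @return p-value, or `NA` if either locus is monomorphic.
#' @export
ld_test <- function(table, locus_pair, population, n_perm = 999L,
                    seed = NULL) {
  stopifnot(length(locus_pair) == 2L)
  sub <- table[table$population == population, , drop = FALSE]
  gen <- lapply(locus_pair, function(m) {
    p <- marker_pairs(sub, m)
    ifelse(is.na(p[, 1L]) | is.na(p[, 2L]), NA_character_,
           paste(pmin(p[, 1L], p[, 2L]), pmax(p[, 1L], p[, 2L])))
  })
  keep <- !is.na(gen[[1L]]) & !is.na(gen[[2L]])
  ga <- gen[[1L]][keep]; gb <- gen[[2L]][keep]
  if (length(unique(ga)) < 2L || length(unique(gb)) < 2L) return(NA_real_)
  if (!is.null(seed)) set.seed(seed)
  g_obs <- g_statistic(ga, gb)
  hits <- sum(vapply(seq_len(n_perm),
                     function(i) g_statistic(ga, sample(gb)) >= g_obs - 1e-12,
                     logical(1L)))
  (hits + 1) / (n_perm + 1)
}

g_statistic <- function(a, b) {
  tab <- table(a, b)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  idx <- tab > 0
  2 * sum(tab[idx] * log(tab[idx] / e[idx]))
}
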