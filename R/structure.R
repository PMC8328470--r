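#' Gene differentiation among populations (G_ST family)
#'
#' Sample-size-corrected heterozygosities follow Nei & Chesser (harmonic mean
#' sample size); the standardized estimator for highly polymorphic markers is
#' Hedrick's `G'_ST`, and `G''_ST` adds the `k/(k-1)` correction for a small
#' number of sampled populations (Meirmans & Hedrick). For a multi-locus
#' marker (`"STR"`) per-locus `H_S`/`H_T` are averaged before the ratios are
#' formed. Significance comes from random reassignment of individuals to
#' populations (observed >= permuted).
#'
#' @param table a [genotype_table()].
#' @param marker `"MHC"`, `"LDH"`, `"STR"` or an STR locus name.
#' @param n_perm permutation count (0 = skip the test).
#' @param seed RNG seed.
#' @param statistic which estimator the permutation test targets.
#' @return list of class `gst_result`: `H_S`, `H_T`, `G_ST`, `G_prime_ST`,
#'   `G_dprime_ST`, `per_locus` (data.frame), `p_value`, `n_perm`,
#'   `statistic`.
#' @export
gst <- function(table, marker = "MHC", n_perm = 999L, seed = NULL,
                statistic = c("G_dprime_ST", "G_prime_ST", "G_ST")) {
  statistic <- match.arg(statistic)
  if (any(table(table$population) < 2L))
    stop("every population needs at least 2 individuals")
  markers <- expand_markers(table, marker)
  obs <- gst_compute(table, markers)
  p <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    s_obs <- obs[[statistic]]
    hits <- 0L
    pops <- table$population
    for (b in seq_len(n_perm)) {
      tb <- table
      tb$population <- sample(pops)
      if (gst_compute(tb, markers)[[statistic]] >= s_obs - 1e-12)
        hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  structure(c(obs, list(p_value = p, n_perm = n_perm, statistic = statistic)),
            class = "gst_result")
}

# Nei-Chesser corrected H_S/H_T and the standardized estimators, averaged
# over loci for multi-locus markers.
gst_compute <- function(table, markers) {
  per <- lapply(markers, function(m) gst_locus(table, m))
  hs <- mean(vapply(per, `[[`, 0, "H_S"))
  ht <- mean(vapply(per, `[[`, 0, "H_T"))
  hs_raw <- mean(vapply(per, `[[`, 0, "H_S_raw"))
  ht_raw <- mean(vapply(per, `[[`, 0, "H_T_raw"))
  k <- mean(vapply(per, `[[`, 0, "k"))
  list(H_S = hs, H_T = ht,
       G_ST = gst_ratio(hs_raw, ht_raw),
       G_ST_nc = gst_ratio(hs, ht),
       G_prime_ST = gprime(hs, ht, k),
       G_dprime_ST = gdprime(hs, ht, k),
       per_locus = data.frame(
         locus = markers,
         H_S = vapply(per, `[[`, 0, "H_S"),
         H_T = vapply(per, `[[`, 0, "H_T"),
         stringsAsFactors = FALSE))
}

gst_ratio <- function(hs, ht) if (ht <= 0) 0 else (ht - hs) / ht

gprime <- function(hs, ht, k) {
  g <- gst_ratio(hs, ht)
  if (ht <= 0 || hs >= 1) return(0)
  g * (k - 1 + hs) / ((k - 1) * (1 - hs))
}

gdprime <- function(hs, ht, k) {
  if (ht <= 0 || hs >= 1) return(0)
  k * (ht - hs) / ((k * ht - hs) * (1 - hs))
}

gst_locus <- function(table, marker) {
  pairs <- marker_pairs(table, marker)
  ok <- !is.na(pairs[, 1L]) & !is.na(pairs[, 2L])
  pairs <- pairs[ok, , drop = FALSE]
  pop <- table$population[ok]
  pops <- unique(pop)
  k <- length(pops)
  n_s <- vapply(pops, function(p) sum(pop == p), 0L)
  ntilde <- k / sum(1 / n_s)
  alleles <- sort(unique(c(pairs)))
  pmat <- vapply(pops, function(p) {
    copies <- c(pairs[pop == p, ])
    as.numeric(table(factor(copies, levels = alleles))) / length(copies)
  }, numeric(length(alleles)))
  pmat <- matrix(pmat, nrow = length(alleles))
  ho <- mean(vapply(pops, function(p) {
    g <- pairs[pop == p, , drop = FALSE]
    mean(g[, 1L] != g[, 2L])
  }, 0))
  mean_p2 <- mean(colSums(pmat^2))
  pbar <- rowMeans(pmat)
  hs <- ntilde / (ntilde - 1) * (1 - mean_p2 - ho / (2 * ntilde))
  ht <- 1 - sum(pbar^2) + hs / (ntilde * k) - ho / (2 * ntilde * k)
  list(H_S = hs, H_T = ht, k = k,
       H_S_raw = 1 - mean_p2, H_T_raw = 1 - sum(pbar^2))
}

#' Pairwise differentiation matrix
#'
#' @inheritParams gst
#' @return Symmetric matrix of the chosen statistic with population
#'   dimnames and zero diagonal.
#' @export
gst_pairwise <- function(table, marker = "MHC",
                         statistic = c("G_dprime_ST", "G_prime_ST", "G_ST")) {
  statistic <- match.arg(statistic)
  markers <- expand_markers(table, marker)
  pops <- unique(table$population)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1L]) for (j in seq_len(i - 1L)) {
    sub <- table[table$population %in% pops[c(i, j)], , drop = FALSE]
    m[i, j] <- m[j, i] <- gst_compute(sub, markers)[[statistic]]
  }
  m
}

#' Mantel correlation between two distance/differentiation matrices
#'
#' Pearson correlation of the off-diagonal elements, with significance from
#' simultaneous row/column permutation of one matrix (delegated to
#' \code{\link[vegan]{mantel}}).
#'
#' @param matrix_a,matrix_b symmetric matrices with zero diagonals.
#' @param n_perm permutation count.
#' @param seed RNG seed.
#' @return list of class `mantel_result`: `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(matrix_a, matrix_b, n_perm = 9999L, seed = NULL) {
  check_sym <- function(m, nm) {
    m <- as.matrix(m)
    if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8) ||
        any(abs(diag(m)) > 1e-12))
      stop(nm, " must be symmetric with a zero diagonal")
    m
  }
  a <- check_sym(matrix_a, "matrix_a"); b <- check_sym(matrix_b, "matrix_b")
  if (nrow(a) != nrow(b)) stop("matrices must have identical dimensions")
  off <- function(m) m[lower.tri(m)]
  if (stats::sd(off(a)) == 0 || stats::sd(off(b)) == 0)
    stop("Mantel r is undefined for a constant matrix")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(a), stats::as.dist(b),
                       permutations = n_perm)
  structure(list(r = unname(fit$statistic), p_value = fit$signif,
                 n_perm = n_perm),
            class = "mantel_result")
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Three-level decomposition (among groups of populations, among populations
#' within groups, within populations) of allele-identity distances between
#' gene copies, following the classical sums-of-squares partition with
#' unequal-sample-size coefficients. Multi-locus markers sum covariance
#' components over loci. Permutation schemes are level-appropriate: whole
#' populations among groups; individuals among populations within their
#' group; gene copies among populations.
#'
#' @param table a [genotype_table()].
#' @param marker `"MHC"`, `"LDH"`, `"STR"` or an STR locus name.
#' @param grouping named character vector mapping population to group.
#' @param n_perm permutations per level (0 = skip).
#' @param seed RNG seed.
#' @return list of class `amova_result`: `components` data.frame (source,
#'   df, sigma2, percent, phi, p_value), `n_perm`.
#' @export
amova <- function(table, marker = "STR", grouping, n_perm = 1000L,
                  seed = NULL) {
  pops <- unique(table$population)
  miss <- setdiff(pops, names(grouping))
  if (length(miss))
    stop("population(s) without a group: ", paste(miss, collapse = ", "))
  grouping <- grouping[pops]
  # a single group degrades gracefully to the two-level decomposition
  markers <- expand_markers(table, marker)
  obs <- amova_components(table, markers, grouping)
  p <- rep(NA_real_, 3L)
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    phi_obs <- obs$phi
    hits <- c(0L, 0L, 0L)
    for (b in seq_len(n_perm)) {
      # (1) populations among groups
      g1 <- stats::setNames(sample(grouping), names(grouping))
      if (amova_components(table, markers, g1)$phi[1L] >= phi_obs[1L] - 1e-12)
        hits[1L] <- hits[1L] + 1L
      # (2) individuals among populations within groups
      tb <- table
      for (g in unique(grouping)) {
        idx <- which(tb$population %in% names(grouping)[grouping == g])
        tb$population[idx] <- tb$population[sample(idx)]
      }
      if (amova_components(tb, markers, grouping)$phi[2L] >= phi_obs[2L] - 1e-12)
        hits[2L] <- hits[2L] + 1L
      # (3) gene copies among populations
      tb2 <- table
      for (m in markers) {
        cols <- if (m == "MHC") c("mhc_1", "mhc_2")
                else if (m == "LDH") c("ldh_1", "ldh_2")
                else paste0(m, c("_1", "_2"))
        copies <- c(tb2[[cols[1L]]], tb2[[cols[2L]]])
        ok <- !is.na(copies)
        copies[ok] <- sample(copies[ok])
        tb2[[cols[1L]]] <- copies[seq_len(nrow(tb2))]
        tb2[[cols[2L]]] <- copies[nrow(tb2) + seq_len(nrow(tb2))]
      }
      if (amova_components(tb2, markers, grouping)$phi[3L] >= phi_obs[3L] - 1e-12)
        hits[3L] <- hits[3L] + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  comp <- data.frame(
    source = c("among_groups", "among_pops_within_groups",
               "within_pops"),
    df = obs$df, sigma2 = obs$sigma2,
    percent = 100 * obs$sigma2 / sum(obs$sigma2),
    phi = obs$phi, p_value = p, stringsAsFactors = FALSE)
  structure(list(components = comp, n_perm = n_perm), class = "amova_result")
}

# Variance components summed over loci; phi statistics from the sums.
amova_components <- function(table, markers, grouping) {
  acc <- c(0, 0, 0); dfs <- NULL
  for (m in markers) {
    cl <- amova_locus(table, m, grouping)
    acc <- acc + cl$sigma2
    dfs <- cl$df
  }
  tot <- sum(acc)
  phi <- c(CT = if (tot > 0) acc[1L] / tot else 0,
           SC = if (sum(acc[2:3]) > 0) acc[2L] / sum(acc[2:3]) else 0,
           ST = if (tot > 0) sum(acc[1:2]) / tot else 0)
  list(sigma2 = acc, df = dfs, phi = phi)
}

amova_locus <- function(table, marker, grouping) {
  pairs <- marker_pairs(table, marker)
  ok <- !is.na(pairs[, 1L]) & !is.na(pairs[, 2L])
  copies <- c(pairs[ok, ])
  pop <- rep(table$population[ok], 2L)
  grp <- unname(grouping[pop])
  N <- length(copies)
  # SS within a set of copies, identity distances: (n - sum(c_a^2)/n)/2
  ss <- function(x) {
    n <- length(x)
    if (n < 2L) return(0)
    (n - sum(table(x)^2) / n) / 2
  }
  pops <- unique(pop); groups <- unique(grp)
  P <- length(pops); G <- length(groups)
  ss_wp <- sum(vapply(pops, function(p) ss(copies[pop == p]), 0))
  ss_wg <- sum(vapply(groups, function(g) ss(copies[grp == g]), 0))
  ss_tot <- ss(copies)
  ssd <- c(AG = ss_tot - ss_wg, AP = ss_wg - ss_wp, WP = ss_wp)
  df <- c(G - 1L, P - G, N - P)
  n_p <- vapply(pops, function(p) sum(pop == p), 0)
  n_g <- vapply(groups, function(g) sum(grp == g), 0)
  pg <- unname(grouping[pops])
  sum_np2_by_g <- vapply(groups, function(g) sum(n_p[pg == g]^2), 0)
  nprime <- (N - sum(sum_np2_by_g / n_g)) / max(df[2L], 1L)
  n2prime <- (sum(sum_np2_by_g / n_g) - sum(n_p^2) / N) / max(df[1L], 1L)
  n3prime <- (N - sum(n_g^2) / N) / max(df[1L], 1L)
  msd <- ifelse(df > 0, ssd / df, 0)
  s2_c <- msd[3L]
  s2_b <- if (df[2L] > 0) (msd[2L] - s2_c) / nprime else 0
  s2_a <- if (df[1L] > 0) (msd[1L] - s2_c - n2prime * s2_b) / n3prime else 0
  list(sigma2 = unname(c(s2_a, s2_b, s2_c)), df = df)
}
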