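#' @keywords internal
#' Cached Nei-Gojobori codon tables: per-codon synonymous site fractions and
#' pathway-averaged synonymous/nonsynonymous difference counts per codon
#' pair. Potential-site fractions at each codon position count the fraction
#' of non-stop single-nucleotide changes that are synonymous; multi-step
#' codon differences are averaged over all minimal mutational pathways,
#' excluding pathways that pass through a stop codon (if every pathway does,
#' the unweighted average over all pathways is used).
ng_env <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (!is.null(ng_env$tab)) return(ng_env$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  sense <- codons[aa != "*"]
  nts <- c("A", "C", "G", "T")
  syn_sites <- stats::setNames(numeric(length(sense)), sense)
  for (c0 in sense) {
    s <- 0
    ch <- strsplit(c0, "")[[1]]
    for (pos in 1:3) {
      alts <- vapply(setdiff(nts, ch[pos]), function(nt) {
        x <- ch; x[pos] <- nt; paste(x, collapse = "")
      }, "")
      keep <- gc[alts] != "*"
      if (any(keep))
        s <- s + sum(gc[alts[keep]] == gc[c0]) / sum(keep)
    }
    syn_sites[c0] <- s
  }
  n <- length(sense)
  ND <- matrix(0, n, n, dimnames = list(sense, sense))
  SD <- ND
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    c1 <- strsplit(sense[i], "")[[1]]
    c2 <- strsplit(sense[j], "")[[1]]
    dpos <- which(c1 != c2)
    k <- length(dpos)
    orders <- if (k == 1L) list(1L) else if (k == 2L) list(1:2, 2:1)
              else perms3
    paths <- lapply(orders, function(ord) {
      cur <- c1; nd <- 0; sd <- 0; through_stop <- FALSE
      for (p in dpos[ord]) {
        nxt <- cur; nxt[p] <- c2[p]
        a1 <- unname(gc[paste(cur, collapse = "")])
        a2 <- unname(gc[paste(nxt, collapse = "")])
        if (a2 == "*") through_stop <- TRUE
        if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      list(nd = nd, sd = sd, stop = through_stop)
    })
    valid <- !vapply(paths, `[[`, TRUE, "stop")
    use <- if (any(valid)) paths[valid] else paths
    ND[i, j] <- mean(vapply(use, `[[`, 0, "nd"))
    SD[i, j] <- mean(vapply(use, `[[`, 0, "sd"))
  }
  ng_env$tab <- list(sense = sense, syn_sites = syn_sites, ND = ND, SD = SD)
  ng_env$tab
}

#' Nei-Gojobori counts and distances for one sequence pair
#'
#' Pairwise proportions of synonymous and nonsynonymous differences per
#' potential site (sites averaged over the two sequences; codons with gaps or
#' ambiguities in either sequence are masked), with the Jukes-Cantor
#' correction `d = -3/4 log(1 - 4p/3)`.
#'
#' @param codon_seq_a,codon_seq_b aligned in-frame nucleotide strings.
#' @return list with `Nd`, `Sd`, `N_sites`, `S_sites`, `pN`, `pS`, `dN`,
#'   `dS`, `omega` (`NA` when `dS = 0`).
#' @export
nei_gojobori_pair <- function(codon_seq_a, codon_seq_b) {
  tab <- ng_tables()
  ca <- codon_split(codon_seq_a); cb <- codon_split(codon_seq_b)
  if (length(ca) != length(cb)) stop("sequences must be aligned in frame")
  ok <- ca %in% tab$sense & cb %in% tab$sense
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codons")
  s_sites <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  n_sites <- 3 * length(ca) - s_sites
  nd <- sum(tab$ND[cbind(ca, cb)])
  sd <- sum(tab$SD[cbind(ca, cb)])
  pN <- nd / n_sites
  pS <- if (s_sites > 0) sd / s_sites else 0
  jc <- function(p) {
    if (p >= 0.75) stop("Jukes-Cantor correction saturated (p = ",
                        signif(p, 3), ")")
    -0.75 * log(1 - 4 * p / 3)
  }
  dN <- jc(pN); dS <- jc(pS)
  list(Nd = nd, Sd = sd, N_sites = n_sites, S_sites = s_sites,
       pN = pN, pS = pS, dN = dN, dS = dS,
       omega = if (dS > 0) dN / dS else NA_real_)
}

codon_split <- function(x) {
  x <- toupper(x)
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Codon-partitioned test for an excess of nonsynonymous substitution
#'
#' Mean pairwise Nei-Gojobori `dN` and `dS` over all sequence pairs,
#' restricted to a codon partition (all codons, the PSS set, or its
#' complement), with a one-tailed Z test of `dN > dS`. The standard error of
#' `dN - dS` comes from a bootstrap over codons within the partition.
#'
#' @param catalog an [allele_catalog()] (aligned).
#' @param pss a [pss_config()]; codon index equals amino-acid column.
#' @param partition `"all"`, `"PSS"` or `"nonPSS"`.
#' @param n_boot bootstrap replicates for the variance.
#' @param seed RNG seed.
#' @return list of class `dnds_result`: `partition`, `dN`, `dS`, `omega`,
#'   `Z`, `p_value`, `n_boot`, `seed`, `n_pairs`, `n_codons`.
#' @export
dnds_partition_test <- function(catalog, pss, partition = c("all", "PSS",
                                                            "nonPSS"),
                                n_boot = 1000L, seed = NULL) {
  partition <- match.arg(partition)
  if (nrow(catalog) < 3L) stop("need at least 3 sequences")
  tab <- ng_tables()
  n_codons_aln <- attr(catalog, "aln_length")
  codon_set <- switch(partition,
                      all = seq_len(n_codons_aln),
                      PSS = as.integer(pss),
                      nonPSS = setdiff(seq_len(n_codons_aln),
                                       as.integer(pss)))
  if (length(codon_set) < 3L) stop("partition has fewer than 3 codons")
  cmat <- t(vapply(catalog$nt_seq, codon_split,
                   character(n_codons_aln), USE.NAMES = FALSE))
  ok_codon <- matrix(cmat %in% tab$sense, nrow = nrow(cmat))
  pairs <- utils::combn(nrow(catalog), 2L)
  np <- ncol(pairs); nc <- length(codon_set)
  nd <- sd_ <- ns <- ss <- matrix(0, np, nc)
  for (q in seq_len(np)) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    use <- ok_codon[i, codon_set] & ok_codon[j, codon_set]
    ca <- cmat[i, codon_set][use]; cb <- cmat[j, codon_set][use]
    if (!length(ca)) next
    ssites <- (tab$syn_sites[ca] + tab$syn_sites[cb]) / 2
    nd[q, use] <- tab$ND[cbind(ca, cb)]
    sd_[q, use] <- tab$SD[cbind(ca, cb)]
    ss[q, use] <- ssites
    ns[q, use] <- 3 - ssites
  }
  jc <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- is.finite(p) & p < 0.75
    out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
    out
  }
  stat <- function(idx) {
    dn <- jc(rowSums(nd[, idx, drop = FALSE]) /
             rowSums(ns[, idx, drop = FALSE]))
    ds <- jc(rowSums(sd_[, idx, drop = FALSE]) /
             pmax(rowSums(ss[, idx, drop = FALSE]), .Machine$double.eps))
    c(dN = mean(dn, na.rm = TRUE), dS = mean(ds, na.rm = TRUE))
  }
  obs <- stat(seq_len(nc))
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    s <- stat(sample.int(nc, nc, replace = TRUE))
    s[1L] - s[2L]
  }, 0)
  se <- stats::sd(boots, na.rm = TRUE)
  z <- if (se > 0) (obs[1L] - obs[2L]) / se else NA_real_
  structure(list(partition = partition,
                 dN = unname(obs[1L]), dS = unname(obs[2L]),
                 omega = if (obs[2L] > 0) unname(obs[1L] / obs[2L])
                         else NA_real_,
                 Z = unname(z),
                 p_value = if (is.na(z)) NA_real_
                           else stats::pnorm(z, lower.tail = FALSE),
                 n_boot = n_boot, seed = seed, n_pairs = np,
                 n_codons = nc),
            class = "dnds_result")
}

#' Randomization null for supertype-based population structure
#'
#' Collapsing alleles into supertypes can manufacture (or erase) apparent
#' population structure as a purely combinatorial artifact. The null keeps
#' the observed supertype size spectrum but permutes which allele carries
#' which label, recomputing the supertype-space differentiation each time;
#' the observed value is then located in this null distribution (two-sided).
#'
#' @param table a [genotype_table()] in allele space.
#' @param solution a `cluster_solution` (or named allele-to-label vector).
#' @param n_rand number of random reassignments.
#' @param seed RNG seed.
#' @param scope `"overall"` (one statistic across populations) or
#'   `"per_population"` (mean pairwise statistic involving each population).
#' @param statistic which differentiation estimator to track.
#' @param preserve_sizes permute the observed label vector (default); when
#'   `FALSE` labels are drawn uniformly at random.
#' @return list of class `randomization_gst`: `observed`,
#'   `null_distribution` (vector, or matrix for per-population scope),
#'   `p_two_sided`, `n_rand`, `seed`.
#' @export
supertype_gst_randomization <- function(table, solution, n_rand = 10000L,
                                        seed = NULL,
                                        scope = c("overall",
                                                  "per_population"),
                                        statistic = "G_dprime_ST",
                                        preserve_sizes = TRUE) {
  scope <- match.arg(scope)
  map <- if (inherits(solution, "cluster_solution")) solution$assignment
         else solution
  if (length(unique(map)) < 2L)
    stop("randomization is degenerate with a single supertype")
  if (!is.null(seed)) set.seed(seed)
  measure <- function(m) {
    tb <- genotypes_to_supertypes(table, m)
    if (scope == "overall") {
      gst_compute(tb, "MHC")[[statistic]]
    } else {
      pw <- gst_pairwise(tb, "MHC", statistic = statistic)
      rowSums(pw) / (ncol(pw) - 1L)
    }
  }
  observed <- measure(map)
  labs <- unique(map)
  null <- vapply(seq_len(n_rand), function(b) {
    m <- if (preserve_sizes) stats::setNames(sample(map), names(map))
         else stats::setNames(sample(labs, length(map), replace = TRUE),
                              names(map))
    measure(m)
  }, observed * 0)
  pfun <- function(obs, nulls) {
    lo <- (sum(nulls <= obs + 1e-12) + 1) / (length(nulls) + 1)
    hi <- (sum(nulls >= obs - 1e-12) + 1) / (length(nulls) + 1)
    min(1, 2 * min(lo, hi))
  }
  p <- if (scope == "overall") pfun(observed, null)
       else vapply(seq_along(observed),
                   function(i) pfun(observed[i], null[i, ]), 0)
  structure(list(observed = observed, null_distribution = null,
                 p_two_sided = p, n_rand = n_rand, seed = seed,
                 scope = scope, statistic = statistic),
            class = "randomization_gst")
}
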