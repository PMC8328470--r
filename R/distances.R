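#' Kimura two-parameter distance between two aligned nucleotide sequences
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions over ungapped, unambiguous sites.
#'
#' @param seq_a,seq_b aligned nucleotide strings.
#' @return list with `P`, `Q`, `d`, `n_sites`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  nts <- c("A", "C", "G", "T")
  ok <- a %in% nts & b %in% nts
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (!n) stop("no comparable sites")
  purine <- c("A", "G")
  diff <- a != b
  ts <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    stop("K2P distance saturated (P = ", signif(P, 3), ", Q = ",
         signif(Q, 3), ")")
  list(P = P, Q = Q, d = -0.5 * log(arg1) - 0.25 * log(arg2), n_sites = n)
}

#' Poisson-corrected amino-acid distance
#'
#' `d = -log(1 - p)` with `p` the proportion of differing residues over
#' ungapped, unambiguous columns.
#'
#' @param aa_a,aa_b aligned amino-acid strings.
#' @return list with `p`, `d`, `n_sites`.
#' @export
poisson_aa_distance <- function(aa_a, aa_b) {
  a <- strsplit(toupper(aa_a), "")[[1]]
  b <- strsplit(toupper(aa_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ok <- !(a %in% c("-", "X", "*")) & !(b %in% c("-", "X", "*"))
  a <- a[ok]; b <- b[ok]
  if (!length(a)) stop("no comparable residues")
  p <- mean(a != b)
  if (p >= 1) stop("Poisson-corrected distance saturated (p = 1)")
  list(p = p, d = -log(1 - p), n_sites = length(a))
}

#' Within-genotype MHC sequence dissimilarity
#'
#' Nucleotide (Kimura two-parameter) and amino-acid (Poisson-corrected)
#' distances between the two alleles an individual carries; both are defined
#' as 0 for homozygotes.
#'
#' @param catalog an [allele_catalog()].
#' @param allele_a,allele_b allele names (vectors recycle elementwise).
#' @return data.frame with columns `P`, `Q`, `d_nt`, `p_aa`, `d_aa`.
#' @export
sequence_dissimilarity <- function(catalog, allele_a, allele_b) {
  idx <- function(x) {
    i <- match(x, catalog$name)
    if (anyNA(i))
      stop("allele(s) absent from catalogue: ",
           paste(unique(x[is.na(i)]), collapse = ", "))
    i
  }
  ia <- idx(allele_a); ib <- idx(allele_b)
  out <- data.frame(P = numeric(length(ia)), Q = 0, d_nt = 0, p_aa = 0,
                    d_aa = 0)
  for (r in seq_along(ia)) {
    if (ia[r] == ib[r]) next
    k <- k2p_distance(catalog$nt_seq[ia[r]], catalog$nt_seq[ib[r]])
    p <- poisson_aa_distance(catalog$aa_seq[ia[r]], catalog$aa_seq[ib[r]])
    out$P[r] <- k$P; out$Q[r] <- k$Q; out$d_nt[r] <- k$d
    out$p_aa[r] <- p$p; out$d_aa[r] <- p$d
  }
  out
}
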