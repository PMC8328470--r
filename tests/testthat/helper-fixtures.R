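# Small builders and independent oracles used across the suite.

# genotype table from explicit vectors; STR loci optional
make_table <- function(pop, mhc1, mhc2, ldh1 = "100", ldh2 = "100",
                       weight = 30, length = 13, str = list()) {
  n <- length(pop)
  df <- data.frame(id = sprintf("i%03d", seq_len(n)), population = pop,
                   mhc_1 = mhc1, mhc_2 = mhc2, stringsAsFactors = FALSE)
  for (loc in names(str)) {
    df[[paste0(loc, "_1")]] <- str[[loc]][[1L]]
    df[[paste0(loc, "_2")]] <- str[[loc]][[2L]]
  }
  df$ldh_1 <- rep_len(ldh1, n); df$ldh_2 <- rep_len(ldh2, n)
  df$weight <- rep_len(weight, n); df$length <- rep_len(length, n)
  genotype_table(df, str_loci = names(str))
}

# population with prescribed MHC gene-copy counts, paired arbitrarily
table_from_counts <- function(counts_by_pop) {
  pops <- c(); a1 <- c(); a2 <- c()
  for (p in names(counts_by_pop)) {
    copies <- rep(names(counts_by_pop[[p]]), counts_by_pop[[p]])
    stopifnot(length(copies) %% 2 == 0)
    m <- matrix(copies, ncol = 2L, byrow = TRUE)
    pops <- c(pops, rep(p, nrow(m)))
    a1 <- c(a1, m[, 1L]); a2 <- c(a2, m[, 2L])
  }
  make_table(pops, a1, a2)
}

# exhaustive rarefaction: mean number of distinct alleles over all
# g-subsets of the gene copies
rarefaction_oracle <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2L, function(ix) length(unique(copies[ix]))))
}

# independent Nei-Gojobori oracle: recursive enumeration of all orderings
# of the differing positions; pathways through stop codons dropped (all-stop
# pairs fall back to the unweighted average over every ordering)
ng_pair_oracle <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  walk <- function(cur, target) {
    dpos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(dpos)) return(list(list(nd = 0, sd = 0, stop = FALSE)))
    out <- list()
    for (p in dpos) {
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- strsplit(target, "")[[1]][p]
      nxt <- paste(ch, collapse = "")
      step_stop <- gc[nxt] == "*"
      step_syn <- gc[nxt] == gc[cur]
      for (tail in walk(nxt, target))
        out[[length(out) + 1L]] <- list(
          nd = tail$nd + as.numeric(!step_syn),
          sd = tail$sd + as.numeric(step_syn),
          stop = tail$stop || step_stop)
    }
    out
  }
  paths <- walk(c1, c2)
  ok <- !vapply(paths, `[[`, TRUE, "stop")
  use <- if (any(ok)) paths[ok] else paths
  c(nd = mean(vapply(use, `[[`, 0, "nd")),
    sd = mean(vapply(use, `[[`, 0, "sd")))
}

# synonymous-site oracle for one codon: fraction of non-stop single changes
# that preserve the amino acid, summed over positions
ng_sites_oracle <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), ch[p])
    cods <- vapply(alts, function(x) {
      y <- ch; y[p] <- x; paste(y, collapse = "")
    }, "")
    keep <- gc[cods] != "*"
    if (any(keep)) s <- s + mean(gc[cods[keep]] == gc[codon])
  }
  s
}

# balanced-design AMOVA oracle from explicit 0/1 distance matrices:
# n gene copies per population, m populations per group, G groups
amova_balanced_oracle <- function(copies, pop, grp) {
  d <- outer(copies, copies, FUN = "!=") * 1
  ss <- function(ix) sum(d[ix, ix][lower.tri(d[ix, ix])]) / length(ix)
  pops <- unique(pop); groups <- unique(grp)
  n <- sum(pop == pops[1L]); m <- length(pops) / length(groups)
  G <- length(groups); N <- length(copies)
  ss_wp <- sum(vapply(pops, function(p) ss(which(pop == p)), 0))
  ss_wg <- sum(vapply(groups, function(g) ss(which(grp == g)), 0))
  ss_tot <- ss(seq_len(N))
  msd_ag <- (ss_tot - ss_wg) / (G - 1)
  msd_ap <- (ss_wg - ss_wp) / (G * (m - 1))
  msd_wp <- ss_wp / (N - G * m)
  s2c <- msd_wp
  s2b <- (msd_ap - msd_wp) / n
  s2a <- (msd_ag - msd_ap) / (n * m)
  c(s2a, s2b, s2c)
}

# tiny catalogue of aligned coding sequences
make_catalog <- function(seqs, names = sprintf("X%02d", seq_along(seqs))) {
  allele_catalog(names, seqs)
}

write_temp_fasta <- function(seqs, names) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names, "\n", seqs), path)
  path
}
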