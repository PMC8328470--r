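#' Extract PSS residues from an allele catalogue
#'
#' @param catalog an [allele_catalog()].
#' @param pss a [pss_config()] of amino-acid alignment columns.
#' @return Named character vector: per allele, the string of PSS residues in
#'   position order.
#' @export
extract_pss_residues <- function(catalog, pss) {
  aln <- attr(catalog, "aln_length")
  if (any(pss > aln))
    stop("PSS position(s) beyond alignment length ", aln)
  res <- vapply(catalog$aa_seq, function(aa)
    paste(strsplit(aa, "")[[1]][pss], collapse = ""), "", USE.NAMES = FALSE)
  gapped <- grepl("[-X]", res)
  if (any(gapped)) {
    detail <- vapply(which(gapped), function(i) {
      chars <- strsplit(res[i], "")[[1]]
      paste0(catalog$name[i], " (column ",
             paste(pss[chars %in% c("-", "X")], collapse = ","), ")")
    }, "")
    stop("gap/ambiguous residue at a PSS: ", paste(detail, collapse = "; "))
  }
  stats::setNames(res, catalog$name)
}

#' Encode PSS residue strings as a physicochemical feature matrix
#'
#' Each PSS residue is replaced by its five descriptor values, giving one row
#' per allele and `|PSS| * 5` columns, ordered position-major,
#' descriptor-minor (`p<position>_z1 .. p<position>_z5`).
#'
#' @param pss_residues named character vector from [extract_pss_residues()].
#' @param descriptors descriptor table ([zscale_descriptors()] by default).
#' @return Numeric matrix with allele rownames.
#' @export
encode_physicochemical <- function(pss_residues,
                                   descriptors = zscale_descriptors()) {
  chars <- strsplit(pss_residues, "")
  npos <- unique(lengths(chars))
  if (length(npos) != 1L) stop("PSS residue strings differ in length")
  all_res <- unique(unlist(chars))
  bad <- setdiff(all_res, descriptors$residue)
  if (length(bad))
    stop("residue(s) without descriptor values: ", paste(bad, collapse = ", "))
  zmat <- as.matrix(descriptors[, paste0("z", 1:5)])
  rownames(zmat) <- descriptors$residue
  feat <- t(vapply(chars, function(ch) as.vector(t(zmat[ch, , drop = FALSE])),
                   numeric(npos * 5L)))
  # position within alignment if available via names of the residue strings
  colnames(feat) <- paste0("p", rep(seq_len(npos), each = 5L), "_z",
                           rep(1:5, npos))
  rownames(feat) <- names(pss_residues)
  feat
}

#' Cluster alleles into supertypes by K-means with BIC model selection
#'
#' For each candidate K the best of `n_starts` K-means solutions (by
#' within-cluster sum of squares, WSS) is retained and scored with
#' `BIC(K) = n * log(WSS/n) + K * log(n)` (n = number of alleles); the K with
#' the lowest BIC wins, ties broken towards the smallest K. Features are used
#' raw: the descriptor scales are already commensurate, and no PCA reduction
#' is applied, so results are bit-for-bit reproducible from the inputs.
#'
#' @param features matrix from [encode_physicochemical()].
#' @param k_grid candidate cluster counts; default `1:min(40, n - 1)`.
#' @param n_starts random restarts per K.
#' @param seed RNG seed (required for reproducibility).
#' @return A `cluster_solution`: list with `K_grid`, `BIC`, `WSS`, `K_best`,
#'   `assignment` (named integer vector, labels `1..K_best`), `seed`,
#'   `n_starts`.
#' @export
select_supertypes <- function(features, k_grid = NULL, n_starts = 50L,
                              seed) {
  if (missing(seed)) stop("'seed' is required")
  n <- nrow(features)
  if (is.null(k_grid)) k_grid <- seq_len(max(1L, min(40L, n - 1L)))
  k_grid <- sort(unique(as.integer(k_grid)))
  n_distinct <- nrow(unique(features))
  keep <- k_grid <= n_distinct
  if (!all(keep)) {
    warning("skipping K > ", n_distinct, " (number of distinct profiles)")
    k_grid <- k_grid[keep]
  }
  if (!length(k_grid)) stop("empty K grid")
  set.seed(seed)
  wss <- numeric(length(k_grid))
  fits <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    K <- k_grid[i]
    if (K == 1L) {
      ctr <- colMeans(features)
      wss[i] <- sum(sweep(features, 2L, ctr)^2)
      fits[[i]] <- rep(1L, n)
    } else {
      km <- suppressWarnings(
        stats::kmeans(features, centers = K, nstart = n_starts,
                      iter.max = 100L))
      wss[i] <- km$tot.withinss
      fits[[i]] <- km$cluster
    }
  }
  bic <- n * log(pmax(wss, .Machine$double.eps) / n) + k_grid * log(n)
  bic[wss <= .Machine$double.eps * n] <- -Inf
  best <- which(bic == min(bic))[1L]   # ties: smallest K
  assignment <- as.integer(fits[[best]])
  # relabel contiguously in order of first appearance
  assignment <- match(assignment, unique(assignment))
  names(assignment) <- rownames(features)
  structure(list(K_grid = k_grid, BIC = bic, WSS = wss,
                 K_best = k_grid[best], assignment = assignment,
                 seed = seed, n_starts = n_starts),
            class = "cluster_solution")
}

#' @method print cluster_solution
#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> ", length(x$assignment), " alleles -> ",
      x$K_best, " supertypes (BIC grid ", min(x$K_grid), "..",
      max(x$K_grid), ")\n", sep = "")
  invisible(x)
}

#' Translate a genotype table from allele space to supertype space
#'
#' MHC genotype pairs are mapped label-wise through the clustering solution;
#' an allele-heterozygote whose two alleles fall in the same cluster becomes
#' a supertype-homozygote. Labels are rendered as `"ST<k>"`.
#'
#' @param table a [genotype_table()].
#' @param solution a `cluster_solution` from [select_supertypes()], or any
#'   named vector mapping allele name to supertype label.
#' @return A [genotype_table()] whose MHC columns hold supertype labels.
#' @export
genotypes_to_supertypes <- function(table, solution) {
  map <- if (inherits(solution, "cluster_solution")) solution$assignment
         else solution
  unknown <- setdiff(c(table$mhc_1, table$mhc_2), names(map))
  if (length(unknown))
    stop("allele(s) without a supertype assignment: ",
         paste(unknown, collapse = ", "))
  out <- table
  out$mhc_1 <- paste0("ST", map[table$mhc_1])
  out$mhc_2 <- paste0("ST", map[table$mhc_2])
  out
}
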