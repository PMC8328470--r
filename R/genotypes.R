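#' Individual genotype and phenotype table
#'
#' One row per individual: population of origin, the diploid genotype at the
#' multiallelic MHC locus, genotypes at a panel of microsatellite (STR) loci
#' (missing allowed), the genotype at a diagnostic biallelic admixture marker
#' (LDH-C1: allele `100` native, `90` domestic), and the two body
#' measurements (weight in grams, standard length in cm) from which Fulton's
#' condition factor is computed.
#'
#' Internally the table is a data.frame with columns `id`, `population`,
#' `mhc_1`, `mhc_2`, `<locus>_1`/`<locus>_2` per STR locus, `ldh_1`, `ldh_2`,
#' `weight`, `length`, and an attribute `str_loci` naming the STR loci.
#'
#' @param df data.frame with the columns above.
#' @param str_loci character vector of STR locus names.
#' @param catalog optional [allele_catalog()]; when given, every MHC allele
#'   name must be present in it.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(df, str_loci = character(), catalog = NULL) {
  str_cols <- if (length(str_loci))
    paste0(rep(str_loci, each = 2L), c("_1", "_2")) else character()
  need <- c("id", "population", "mhc_1", "mhc_2", "ldh_1", "ldh_2",
            "weight", "length", str_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate individual id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(is.na(df$mhc_1) | is.na(df$mhc_2)))
    stop("MHC genotypes must be complete (1 or 2 variants per individual)")
  if (any(!is.na(df$weight) & df$weight <= 0) ||
      any(!is.na(df$length) & df$length <= 0))
    stop("weight and length must be positive")
  ldh <- c(df$ldh_1, df$ldh_2)
  bad <- !is.na(ldh) & !ldh %in% c("90", "100")
  if (any(bad)) stop("LDH alleles must be '90' or '100'")
  if (!is.null(catalog)) {
    unknown <- setdiff(c(df$mhc_1, df$mhc_2), catalog$name)
    if (length(unknown))
      stop("MHC allele(s) absent from catalogue: ",
           paste(unknown, collapse = ", "))
  }
  attr(df, "str_loci") <- as.character(str_loci)
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' @method print genotype_table
#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", nrow(x), " individuals, ",
      length(unique(x$population)), " populations, ",
      length(str_loci(x)), " STR loci\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' STR locus names of a genotype table
#' @param table a [genotype_table()].
#' @export
str_loci <- function(table) attr(table, "str_loci")

#' Read a genotype/phenotype table from delimited text
#'
#' Expected layout: one row per individual with columns `id`, `population`,
#' `mhc` ("alleleA/alleleB", homozygotes "alleleA/alleleA" or a single name),
#' one column per STR locus ("132/136", empty = missing), `ldh` ("100/100",
#' "90/100" or "90/90"), `weight`, `length`. Any column not in the fixed set
#' is treated as an STR locus unless `str_loci` is given.
#'
#' @param path file path.
#' @param catalog optional [allele_catalog()] used to validate MHC names.
#' @param str_loci optional explicit STR locus column names.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, catalog = NULL, str_loci = NULL,
                                sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  fixed <- c("id", "population", "mhc", "ldh", "weight", "length")
  miss <- setdiff(fixed, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(str_loci)) str_loci <- setdiff(names(raw), fixed)

  split_pair <- function(x, what) {
    parts <- strsplit(ifelse(is.na(x) | x == "", "/", x), "/", fixed = TRUE)
    n <- lengths(parts)
    if (any(n > 2L))
      stop(what, ": more than 2 variants in '", x[n > 2L][1L], "'")
    a1 <- vapply(parts, function(p) if (length(p) >= 1L) p[1L] else "", "")
    a2 <- vapply(parts, function(p) if (length(p) == 2L) p[2L] else p[1L] %||% "", "")
    a1[a1 == ""] <- NA_character_; a2[a2 == ""] <- NA_character_
    cbind(a1, a2)
  }
  mhc <- split_pair(raw$mhc, "MHC genotype")
  ldh <- split_pair(raw$ldh, "LDH genotype")
  df <- data.frame(id = raw$id, population = raw$population,
                   mhc_1 = mhc[, 1L], mhc_2 = mhc[, 2L],
                   stringsAsFactors = FALSE)
  for (loc in str_loci) {
    p <- split_pair(raw[[loc]], paste("STR locus", loc))
    df[[paste0(loc, "_1")]] <- p[, 1L]
    df[[paste0(loc, "_2")]] <- p[, 2L]
  }
  df$ldh_1 <- ldh[, 1L]; df$ldh_2 <- ldh[, 2L]
  df$weight <- as.numeric(raw$weight)
  df$length <- as.numeric(raw$length)
  genotype_table(df, str_loci = str_loci, catalog = catalog)
}

#' Write a genotype table in the same dialect read by [read_genotype_table()]
#'
#' @param table a [genotype_table()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_genotype_table <- function(table, path, sep = ",") {
  join <- function(a, b) ifelse(is.na(a) | is.na(b), "", paste0(a, "/", b))
  out <- data.frame(id = table$id, population = table$population,
                    mhc = paste0(table$mhc_1, "/", table$mhc_2),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (loc in str_loci(table))
    out[[loc]] <- join(table[[paste0(loc, "_1")]], table[[paste0(loc, "_2")]])
  out$ldh <- join(table$ldh_1, table$ldh_2)
  out$weight <- table$weight
  out$length <- table$length
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Cross-validate a loaded dataset
#'
#' Report-only consistency checks across the allele catalogue, the genotype
#' table and the PSS configuration: out-of-bounds PSS positions, catalogue
#' alleles never observed in a genotype, and populations below a minimum
#' sample size.
#'
#' @param catalog an [allele_catalog()].
#' @param table a [genotype_table()].
#' @param pss a [pss_config()].
#' @param min_pop_size populations smaller than this are flagged.
#' @return data.frame with columns `severity` ("warning"/"note") and
#'   `message`; zero rows when nothing is flagged.
#' @export
validate_dataset <- function(catalog, table, pss, min_pop_size = 15L) {
  issues <- data.frame(severity = character(), message = character(),
                       stringsAsFactors = FALSE)
  add <- function(sev, msg) rbind(issues, data.frame(severity = sev,
                                                     message = msg))
  aln <- attr(catalog, "aln_length")
  oob <- pss[pss > aln]
  if (length(oob))
    issues <- add("warning", paste0("PSS position(s) beyond ", aln,
                                    "-column alignment: ",
                                    paste(oob, collapse = ", ")))
  unknown <- setdiff(c(table$mhc_1, table$mhc_2), catalog$name)
  if (length(unknown))
    issues <- add("warning", paste0("genotyped MHC allele(s) absent from ",
                                    "catalogue: ",
                                    paste(unknown, collapse = ", ")))
  unused <- setdiff(catalog$name, c(table$mhc_1, table$mhc_2))
  if (length(unused))
    issues <- add("note", paste0("catalogue allele(s) in no genotype: ",
                                 paste(unused, collapse = ", ")))
  sizes <- table(table$population)
  small <- names(sizes)[sizes < min_pop_size]
  if (length(small))
    issues <- add("warning", paste0("population(s) below ", min_pop_size,
                                    " individuals: ",
                                    paste(small, collapse = ", ")))
  issues
}

# Internal: 2-column character matrix of the diploid genotype at a marker.
# marker: "MHC", "LDH" or an STR locus name.
marker_pairs <- function(table, marker) {
  cols <- switch(marker,
                 MHC = c("mhc_1", "mhc_2"),
                 LDH = c("ldh_1", "ldh_2"),
                 paste0(marker, c("_1", "_2")))
  if (!all(cols %in% names(table)))
    stop("unknown marker: ", marker)
  cbind(table[[cols[1L]]], table[[cols[2L]]])
}

# Internal: expand marker="STR" to the locus vector, otherwise passthrough.
expand_markers <- function(table, marker) {
  if (identical(marker, "STR")) str_loci(table) else marker
}
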