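#' Allele catalogues
#'
#' An `allele_catalog` holds the aligned nucleotide sequences of the alleles
#' segregating at a single multiallelic coding locus (here the exon-2 fragment
#' of a salmonid MHC class II gene) together with their translations. Input
#' sequences must be pre-aligned: a 3-bp indel between length variants is
#' represented by gap characters so that every nucleotide sequence has the
#' same aligned length and every translation occupies the same amino-acid
#' alignment columns.
#'
#' @param name character vector of unique allele identifiers.
#' @param nt_seq aligned coding nucleotide sequences (may contain `-` gaps).
#' @param frame 1-based offset of the first complete codon.
#' @return An object of class `allele_catalog`: a data.frame with columns
#'   `name`, `nt_seq`, `aa_seq` and attribute `aln_length` (amino-acid
#'   alignment length).
#' @export
allele_catalog <- function(name, nt_seq, frame = 1L) {
  name <- as.character(name)
  nt_seq <- toupper(as.character(nt_seq))
  if (anyDuplicated(name))
    stop("duplicate allele name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  if (length(name) != length(nt_seq))
    stop("'name' and 'nt_seq' must have equal length")
  nt_seq <- substring(nt_seq, frame)
  # trim incomplete trailing codon (e.g. 254-bp amplicons)
  nt_seq <- substring(nt_seq, 1L, 3L * (nchar(nt_seq) %/% 3L))
  lens <- unique(nchar(nt_seq))
  if (length(lens) > 1L)
    stop("aligned nucleotide sequences differ in length (",
         paste(lens, collapse = ", "),
         "); supply pre-aligned sequences with gap characters")
  aa_seq <- vapply(nt_seq, translate_gapped, "", USE.NAMES = FALSE)
  stops <- grepl("\\*", aa_seq)
  if (any(stops))
    stop("internal stop codon in allele(s): ",
         paste(name[stops], collapse = ", "))
  out <- data.frame(name = name, nt_seq = nt_seq, aa_seq = aa_seq,
                    stringsAsFactors = FALSE)
  attr(out, "aln_length") <- if (nrow(out)) nchar(aa_seq[1L]) else 0L
  class(out) <- c("allele_catalog", "data.frame")
  out
}

# Translate an aligned in-frame CDS; a fully gapped codon becomes "-",
# a partially gapped or ambiguous codon becomes "X".
translate_gapped <- function(nt) {
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  gc <- Biostrings::GENETIC_CODE
  aa <- ifelse(codons == "---", "-",
               ifelse(codons %in% names(gc), unname(gc[codons]), "X"))
  paste(aa, collapse = "")
}

#' Read an allele catalogue from a FASTA file
#'
#' @param path path to a (optionally pre-aligned) nucleotide FASTA file.
#' @param frame 1-based codon frame offset.
#' @return An [allele_catalog()].
#' @export
read_allele_fasta <- function(path, frame = 1L) {
  seqs <- Biostrings::readBStringSet(path)
  allele_catalog(names(seqs), as.character(seqs), frame = frame)
}

#' Write an allele catalogue to FASTA
#'
#' @param catalog an [allele_catalog()].
#' @param path output path.
#' @export
write_allele_fasta <- function(catalog, path) {
  x <- Biostrings::BStringSet(stats::setNames(catalog$nt_seq, catalog$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Positively selected site (PSS) configuration
#'
#' The PSS set — amino-acid alignment columns inferred (upstream, by codon
#' model consensus) to evolve under positive selection and used as a proxy
#' for the antigen-binding residues — is an input to the pipeline, not
#' computed by it.
#'
#' @param positions integer vector of 1-based amino-acid alignment columns.
#' @param aln_length optional alignment length for bounds checking.
#' @return An integer vector of class `pss_config`.
#' @export
pss_config <- function(positions, aln_length = NULL) {
  positions <- as.integer(positions)
  if (any(is.na(positions)) || any(positions < 1L))
    stop("PSS positions must be positive integers")
  if (is.unsorted(positions, strictly = TRUE))
    stop("PSS positions must be strictly increasing")
  if (!is.null(aln_length) && any(positions > aln_length))
    stop("PSS position(s) beyond alignment length ", aln_length, ": ",
         paste(positions[positions > aln_length], collapse = ", "))
  structure(positions, class = "pss_config")
}

#' Five-dimensional physicochemical descriptor scales for amino acids
#'
#' The extended principal-property scales of Sandberg and co-workers
#' (z1..z5), summarising lipophilicity, steric bulk/polarisability,
#' electronic properties and two higher-order components for the 20 coded
#' amino acids. These are the descriptors used to encode PSS residues before
#' supertype clustering.
#'
#' @return A data.frame with columns `residue`, `z1`..`z5`.
#' @export
zscale_descriptors <- function() {
  tab <- c(
    "A",  0.24, -2.32,  0.60, -0.14,  1.30,
    "R",  3.52,  2.50, -3.50,  1.99, -0.17,
    "N",  3.05,  1.62,  1.04, -1.15,  1.61,
    "D",  3.98,  0.93,  1.93, -2.46,  0.75,
    "C",  0.84, -1.67,  3.71,  0.18, -2.65,
    "Q",  1.75,  0.50, -1.44, -1.34,  0.66,
    "E",  3.11,  0.26, -0.11, -3.04, -0.25,
    "G",  2.05, -4.06,  0.36, -0.82, -0.38,
    "H",  2.47,  1.95,  0.26,  3.90,  0.09,
    "I", -3.89, -1.73, -1.71, -0.84,  0.26,
    "L", -4.28, -1.30, -1.49, -0.72,  0.84,
    "K",  2.29,  0.89, -2.49,  1.49,  0.31,
    "M", -2.85, -0.22,  0.47,  1.94, -0.98,
    "F", -4.22,  1.94,  1.06,  0.54, -0.62,
    "P", -1.66,  0.27,  1.84,  0.70,  2.00,
    "S",  2.39, -1.07,  1.15, -1.39,  0.67,
    "T",  0.75, -2.18, -1.12, -1.46, -0.40,
    "W", -4.36,  3.94,  0.59,  3.44, -1.59,
    "Y", -2.54,  2.44,  0.43,  0.04, -1.47,
    "V", -2.59, -2.64, -1.54, -0.85, -0.02)
  m <- matrix(tab, ncol = 6L, byrow = TRUE)
  out <- data.frame(residue = m[, 1L], apply(m[, -1L], 2L, as.numeric),
                    stringsAsFactors = FALSE)
  names(out) <- c("residue", paste0("z", 1:5))
  out
}

#' Read a physicochemical descriptor table
#'
#' @param path CSV with a residue column followed by five descriptor columns.
#' @return A data.frame with columns `residue`, `z1`..`z5`.
#' @export
read_descriptor_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) < 6L) stop("descriptor table needs residue + 5 descriptor columns")
  d <- d[, 1:6]
  names(d) <- c("residue", paste0("z", 1:5))
  d$residue <- toupper(d$residue)
  miss <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], d$residue)
  if (length(miss))
    stop("descriptor table is missing residue(s): ", paste(miss, collapse = ", "))
  d
}
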