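#' Read an allele catalogue from FASTA
#'
#' Sequences must be pre-aligned (equal lengths); `N` is kept as a missing
#' base and excluded from site statistics downstream.
#'
#' @param path FASTA file of aligned allele sequences.
#' @param codon_mode Treat the alignment as in-frame codons (length divisible
#'   by 3, gap runs in multiples of 3).
#' @param locus_name Locus label; defaults to the file name without extension.
#' @return An [allele_catalog()].
#' @export
read_allele_fasta <- function(path, codon_mode = FALSE,
                              locus_name = tools::file_path_sans_ext(basename(path))) {
  dna <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(toupper(as.character(dna)),
                          sub("\\s.*$", "", names(dna)))
  allele_catalog(locus_name, seqs, codon_mode = codon_mode)
}

#' Write an allele catalogue to FASTA
#' @param catalog An [allele_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(catalog, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(catalog$sequences), path)
  invisible(path)
}

#' Read a diploid genotype table
#'
#' Tab-separated with header `sample`, `population`, `locus`, `allele_a`,
#' `allele_b`; a `"."` encodes a missing allele call.
#'
#' @param path Genotype TSV.
#' @param catalog Optional catalogue(s) for allele-id validation
#'   (see [population_genotypes()]).
#' @return A [population_genotypes()] object.
#' @export
read_genotype_table <- function(path, catalog = NULL) {
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = character(0), check.names = FALSE)
  names(df)[names(df) == "sample"] <- "sample_id"
  need <- c("sample_id", "population", "locus", "allele_a", "allele_b")
  if (!all(need %in% names(df)))
    stop("genotype table must have header sample, population, locus, ",
         "allele_a, allele_b")
  for (cc in c("allele_a", "allele_b")) df[[cc]][df[[cc]] == "."] <- NA
  population_genotypes(df, catalog = catalog)
}

#' Write a diploid genotype table
#' @param genotypes A [population_genotypes()] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  df <- as.data.frame(genotypes)
  names(df)[names(df) == "sample_id"] <- "sample"
  df$allele_a[is.na(df$allele_a)] <- "."
  df$allele_b[is.na(df$allele_b)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clone observation table
#'
#' Tab-separated with header `sample`, `pcr_replicate`, `clone_sequence_id`.
#'
#' @param path Clone TSV.
#' @return A [clone_table()].
#' @export
read_clone_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  names(df)[names(df) == "sample"] <- "sample_id"
  clone_table(df)
}

#' Read a per-site selection-model table
#'
#' Tab-separated with header `site`, `model`, `statistic_name`,
#' `statistic_value`, `evidence_kind`, `evidence_value`. Absent statistics
#' (a model that did not report a site) are simply absent rows.
#'
#' @param path Selection TSV.
#' @return A [site_selection_table()].
#' @export
read_selection_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(site = "integer", model = "character",
                                         statistic_name = "character",
                                         statistic_value = "numeric",
                                         evidence_kind = "character",
                                         evidence_value = "numeric"))
  site_selection_table(df)
}

#' Write a labelled square matrix
#'
#' Square tab-separated grid with the labels as both header row and first
#' column; `NA` entries are written as the literal `NA`. The file
#' round-trips bit-exactly through [read_matrix()].
#'
#' @param matrix A symmetric labelled matrix (see [labeled_matrix()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  matrix <- labeled_matrix(matrix)
  chr <- matrix(formatC(matrix, digits = 17, format = "g"),
                nrow = nrow(matrix), dimnames = dimnames(matrix))
  chr[is.na(matrix)] <- NA
  out <- cbind(population = rownames(matrix), as.data.frame(chr))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a labelled square matrix
#' @param path Matrix TSV written by [write_matrix()].
#' @param nonnegative Require non-negative entries (geographic distances).
#' @return A labelled symmetric matrix.
#' @export
read_matrix <- function(path, nonnegative = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  labeled_matrix(m, labels = labels, nonnegative = nonnegative)
}
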