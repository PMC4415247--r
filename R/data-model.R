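#' Allele catalogue for one locus
#'
#' An allele catalogue holds the aligned nucleotide sequences of every allele
#' known at one locus. All analyses that touch sequence (segregating sites,
#' nucleotide diversity, codon selection tests, supertyping) resolve allele
#' identifiers against a catalogue.
#'
#' @param locus_name Single string naming the locus (e.g. `"DAB"`).
#' @param sequences Named character vector of aligned nucleotide sequences
#'   over the alphabet `A,C,G,T,N,-`. Names are the allele identifiers.
#' @param codon_mode Logical; if `TRUE` the alignment is treated as in-frame
#'   codons: its length must be a multiple of 3 and gap runs must occur in
#'   multiples of 3.
#'
#' @return An object of class `allele_catalog`: a list with elements
#'   `locus_name`, `sequences` (upper-case), `alignment_length` and
#'   `codon_mode`.
#' @export
allele_catalog <- function(locus_name, sequences, codon_mode = FALSE) {
  stopifnot(is.character(locus_name), length(locus_name) == 1L)
  if (length(sequences) == 0L) stop("catalogue needs at least one allele")
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every sequence must be named by an allele id")
  if (anyDuplicated(ids)) stop("allele ids must be unique")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("sequence alphabet must be A,C,G,T,N,-: offending allele ",
         ids[which(bad)[1L]])
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop("sequences have unequal lengths; supply a pre-made alignment")
  if (codon_mode) {
    if (len %% 3L != 0L)
      stop("codon mode requires alignment length divisible by 3 (got ",
           len, ")")
    gap_ok <- vapply(sequences, function(s) {
      runs <- regmatches(s, gregexpr("-+", s))[[1L]]
      all(nchar(runs) %% 3L == 0L)
    }, logical(1L))
    if (!all(gap_ok))
      stop("codon mode requires gap runs in multiples of 3 (allele ",
           ids[which(!gap_ok)[1L]], ")")
  }
  structure(
    list(locus_name = locus_name, sequences = sequences,
         alignment_length = len, codon_mode = codon_mode),
    class = "allele_catalog")
}

#' @export
print.allele_catalog <- function(x, ...) {
  cat("<allele_catalog> locus", x$locus_name, "-", length(x$sequences),
      "alleles,", x$alignment_length, "aligned columns",
      if (x$codon_mode) "(codon mode)" else "", "\n")
  invisible(x)
}

#' Per-individual diploid genotypes grouped by population and locus
#'
#' @param records Data frame with columns `sample_id`, `population`, `locus`,
#'   `allele_a`, `allele_b` (character). Missing allele calls are `NA`.
#' @param populations Optional character vector fixing population order;
#'   defaults to order of first appearance.
#' @param catalog Optional [allele_catalog()] (or list of catalogues keyed by
#'   locus name) used to check that every allele id resolves.
#'
#' @return An object of class `population_genotypes`: a data frame with the
#'   five columns above and an attribute `populations`.
#' @export
population_genotypes <- function(records, populations = NULL, catalog = NULL) {
  need <- c("sample_id", "population", "locus", "allele_a", "allele_b")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  records <- as.data.frame(records)[, need]
  for (cc in need) records[[cc]] <- as.character(records[[cc]])
  key <- paste(records$sample_id, records$locus, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample_id, locus) pair: ",
         sub("\r", " / ", key[duplicated(key)][1L]))
  if (is.null(populations)) populations <- unique(records$population)
  if (!all(records$population %in% populations))
    stop("records name populations outside the supplied population list")
  if (!is.null(catalog)) {
    cats <- if (inherits(catalog, "allele_catalog")) {
      stats::setNames(list(catalog), catalog$locus_name)
    } else catalog
    for (loc in unique(records$locus)) {
      if (!loc %in% names(cats)) next
      ids <- names(cats[[loc]]$sequences)
      seen <- stats::na.omit(c(records$allele_a[records$locus == loc],
                               records$allele_b[records$locus == loc]))
      miss <- setdiff(seen, ids)
      if (length(miss))
        stop("unknown allele id(s) at locus ", loc, ": ",
             paste(utils::head(miss, 3L), collapse = ", "))
    }
  }
  structure(records, populations = populations,
            class = c("population_genotypes", "data.frame"))
}

#' @export
print.population_genotypes <- function(x, ...) {
  cat("<population_genotypes>", nrow(x), "records,",
      length(attr(x, "populations")), "populations,",
      length(unique(x$locus)), "locus/loci\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Population names of a genotype table
#' @param genotypes A [population_genotypes()] object.
#' @return Character vector of population names in their fixed order.
#' @export
populations <- function(genotypes) attr(genotypes, "populations")

#' Allele copy counts for one population and locus
#'
#' Counts gene copies (two per typed diploid) contributed by each allele.
#' Records with a missing allele call are excluded entirely from counting,
#' matching the convention that a partially typed individual does not enter
#' frequency estimates.
#'
#' @param genotypes A [population_genotypes()] object.
#' @param population Population name, or `NULL` to pool all populations.
#' @param locus Locus name.
#' @return Named integer vector of allele copy counts (possibly empty).
#' @export
allele_counts <- function(genotypes, population = NULL, locus) {
  g <- genotypes[genotypes$locus == locus, , drop = FALSE]
  if (!is.null(population))
    g <- g[g$population %in% population, , drop = FALSE]
  g <- g[!is.na(g$allele_a) & !is.na(g$allele_b), , drop = FALSE]
  copies <- c(g$allele_a, g$allele_b)
  if (!length(copies)) return(stats::setNames(integer(0), character(0)))
  tab <- table(copies)
  stats::setNames(as.integer(tab), names(tab))
}

#' Clone observation table
#'
#' Records which cloned sequence variants were seen in which PCR replicate of
#' which individual, the raw material for clone-based genotype validation.
#'
#' @param observations Data frame with columns `sample_id` (character),
#'   `pcr_replicate` (positive integer) and `clone_sequence_id` (character).
#' @return An object of class `clone_table` (a validated data frame).
#' @export
clone_table <- function(observations) {
  need <- c("sample_id", "pcr_replicate", "clone_sequence_id")
  if (!all(need %in% names(observations)))
    stop("observations must have columns ", paste(need, collapse = ", "))
  observations <- as.data.frame(observations)[, need]
  observations$sample_id <- as.character(observations$sample_id)
  observations$clone_sequence_id <- as.character(observations$clone_sequence_id)
  rep_num <- as.integer(observations$pcr_replicate)
  if (anyNA(rep_num) || any(rep_num < 1L))
    stop("pcr_replicate must be a positive integer")
  observations$pcr_replicate <- rep_num
  structure(observations, class = c("clone_table", "data.frame"))
}

#' Per-site selection-model statistics
#'
#' Holds per-residue output rows from codon selection models (counting-based
#' SLAC, random-effects likelihood REL, mixed-effects episodic MEME), the
#' input of the multi-model consensus rule.
#'
#' @param rows Data frame with columns `site` (1-based amino-acid position),
#'   `model` (one of `"SLAC"`, `"REL"`, `"MEME"`), `statistic_name`,
#'   `statistic_value`, `evidence_kind` (`"p_value"` or `"bayes_factor"`) and
#'   `evidence_value`.
#' @param protein_length Optional upper bound for `site`.
#' @return An object of class `site_selection_table` (a validated data frame).
#' @export
site_selection_table <- function(rows, protein_length = NULL) {
  need <- c("site", "model", "statistic_name", "statistic_value",
            "evidence_kind", "evidence_value")
  if (!all(need %in% names(rows)))
    stop("rows must have columns ", paste(need, collapse = ", "))
  rows <- as.data.frame(rows)[, need]
  rows$site <- as.integer(rows$site)
  rows$model <- as.character(rows$model)
  rows$evidence_kind <- as.character(rows$evidence_kind)
  rows$statistic_value <- as.numeric(rows$statistic_value)
  rows$evidence_value <- as.numeric(rows$evidence_value)
  if (any(rows$site < 1L)) stop("sites are 1-based positive positions")
  if (!is.null(protein_length) && any(rows$site > protein_length))
    stop("site beyond protein length ", protein_length)
  bad <- !rows$model %in% c("SLAC", "REL", "MEME")
  if (any(bad)) stop("unknown model tag: ", rows$model[which(bad)[1L]])
  if (!all(rows$evidence_kind %in% c("p_value", "bayes_factor")))
    stop("evidence_kind must be p_value or bayes_factor")
  p <- rows$evidence_kind == "p_value"
  if (any(rows$evidence_value[p] < 0 | rows$evidence_value[p] > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (any(rows$evidence_value[!p] < 0, na.rm = TRUE))
    stop("Bayes factors must be non-negative")
  structure(rows, class = c("site_selection_table", "data.frame"))
}

#' Labelled symmetric distance/differentiation matrix
#'
#' @param values Square numeric matrix, symmetric with zero diagonal. `NA`
#'   entries mark undefined pairs.
#' @param labels Optional character vector of population labels; defaults to
#'   existing dimnames.
#' @param nonnegative Require all entries `>= 0` (geographic distances);
#'   differentiation estimators under bias correction may be slightly
#'   negative, so the default is `FALSE`.
#' @return A base matrix with population dimnames, validated.
#' @export
labeled_matrix <- function(values, labels = NULL, nonnegative = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) stop("labels required")
  if (length(labels) != nrow(values)) stop("label length mismatch")
  dimnames(values) <- list(labels, labels)
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12,
                        check.attributes = FALSE)))
    stop("matrix must be symmetric")
  if (any(abs(diag(values)) > 1e-12, na.rm = TRUE))
    stop("diagonal must be zero")
  diag(values) <- 0
  if (nonnegative && any(values < 0, na.rm = TRUE))
    stop("negative entries not allowed here")
  values
}

# internal: upper-triangle vector in fixed row-major order
upper_tri_values <- function(m) m[upper.tri(m)]
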