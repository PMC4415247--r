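#' Validate cloned sequences into diploid genotypes
#'
#' Cloning a PCR product samples one molecule at a time, so artefacts
#' (polymerase error, chimaeras, contamination) appear as spurious variants.
#' The acceptance rule used here is the standard one for clone-verified MHC
#' genotyping: a cloned variant is accepted as a real allele only if it was
#' isolated from at least two independent PCR reactions, where the two
#' reactions may come from the same individual or from different individuals.
#' Each individual is then genotyped from its accepted alleles: exactly one
#' accepted allele gives a homozygote, two give a heterozygote. An individual
#' showing more than `max_alleles` accepted alleles is inconsistent with a
#' single diploid locus (contamination or gene duplication) and is rejected
#' from the genotype table.
#'
#' The filter is idempotent and order-independent: permuting clone rows never
#' changes the outcome, and adding observations can only grow the accepted
#' allele set.
#'
#' @param clones A [clone_table()].
#' @param max_alleles Maximum number of accepted alleles per individual
#'   compatible with one diploid locus (default 2).
#' @param population Population assignment for the output genotypes: either a
#'   single string or a named vector keyed by `sample_id`. Defaults to
#'   `"unknown"`.
#' @param locus Locus name for the output genotype records.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{genotypes}{[population_genotypes()] for samples with 1 or 2
#'       accepted alleles.}
#'     \item{rejected_samples}{Character vector of samples with more than
#'       `max_alleles` accepted alleles, excluded from the genotypes.}
#'     \item{untyped_samples}{Samples whose clones yielded no accepted
#'       allele.}
#'     \item{accepted_alleles}{Character vector (sorted) of accepted allele
#'       ids.}
#'   }
#' @export
validate_clone_genotypes <- function(clones, max_alleles = 2L,
                                     population = "unknown", locus = "DAB") {
  stopifnot(inherits(clones, "clone_table"))
  if (nrow(clones) == 0L)
    return(list(genotypes = population_genotypes(
                  data.frame(sample_id = character(0), population = character(0),
                             locus = character(0), allele_a = character(0),
                             allele_b = character(0))),
                rejected_samples = character(0),
                untyped_samples = character(0),
                accepted_alleles = character(0)))
  # distinct (sample, replicate) reactions per clone variant
  rx <- unique(clones[, c("sample_id", "pcr_replicate", "clone_sequence_id")])
  n_reactions <- table(rx$clone_sequence_id)
  accepted <- sort(names(n_reactions)[n_reactions >= 2L])

  samples <- unique(clones$sample_id)
  pop_of <- function(s) {
    if (length(population) == 1L && is.null(names(population)))
      population else unname(population[s])
  }
  recs <- list(); rejected <- character(0); untyped <- character(0)
  for (s in samples) {
    own <- sort(unique(clones$clone_sequence_id[clones$sample_id == s]))
    own <- intersect(own, accepted)
    if (length(own) == 0L) {
      untyped <- c(untyped, s)
    } else if (length(own) > max_alleles) {
      rejected <- c(rejected, s)
    } else {
      a <- own[1L]
      b <- if (length(own) == 2L) own[2L] else own[1L]
      recs[[length(recs) + 1L]] <-
        data.frame(sample_id = s, population = pop_of(s), locus = locus,
                   allele_a = a, allele_b = b)
    }
  }
  gdf <- if (length(recs)) do.call(rbind, recs) else
    data.frame(sample_id = character(0), population = character(0),
               locus = character(0), allele_a = character(0),
               allele_b = character(0))
  list(genotypes = population_genotypes(gdf),
       rejected_samples = sort(rejected),
       untyped_samples = sort(untyped),
       accepted_alleles = accepted)
}
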