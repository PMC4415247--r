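utils::globalVariables(c("population", "frequency", "supertype"))

#' Bundled per-site selection statistics for the frog DAB beta-1 domain
#'
#' Path to the packaged TSV of published per-residue selection-model
#' statistics for the MHC class II DAB beta-1 domain of Hochstetter's frog
#' (*Leiopelma hochstetteri*): SLAC normalized dN-dS with p-values, REL
#' expected dN-dS with Bayes factors, and MEME beta2 with p-values. Feeding
#' this table to [consensus_selected_sites()] with the conventional
#' thresholds (p < 0.05, Bayes factor > 100, at least two models) yields the
#' 11 positively selected residues used for supertype definition.
#'
#' @return Path to the TSV file.
#' @export
dab_selection_example <- function() {
  system.file("extdata", "dab_site_selection.tsv", package = "immunopop",
              mustWork = TRUE)
}
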