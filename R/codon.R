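# Codon-level utilities shared by the selection tests: genetic-code lookups,
# Nei-Gojobori site fractions and pathway-averaged change counts.

# package-local cache for codon lookup tables
.codon_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

all_codons <- function() {
  if (is.null(.codon_cache$codons)) {
    nt <- c("A", "C", "G", "T")
    .codon_cache$codons <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  }
  .codon_cache$codons
}

is_valid_codon <- function(codon) {
  !is.na(codon) & grepl("^[ACGT]{3}$", codon)
}

translate_codon <- function(codon) {
  gc <- genetic_code()
  out <- rep("X", length(codon))
  out[codon == "---"] <- "-"
  v <- is_valid_codon(codon)
  out[v] <- unname(gc[codon[v]])
  out
}

# Fraction of synonymous sites per codon: for each of the 3 positions, the
# fraction of the 3 single-nucleotide changes that preserve the amino acid.
# Changes creating a stop codon count as nonsynonymous.
syn_site_fraction <- function(codon) {
  if (is.null(.codon_cache$syn_sites)) {
    gc <- genetic_code()
    nt <- c("A", "C", "G", "T")
    s <- stats::setNames(numeric(64L), all_codons())
    for (cd in all_codons()) {
      if (gc[cd] == "*") { s[cd] <- NA_real_; next }
      tot <- 0
      for (pos in 1:3) for (b in nt) {
        if (b == substr(cd, pos, pos)) next
        mut <- cd
        substr(mut, pos, pos) <- b
        if (gc[mut] != "*" && gc[mut] == gc[cd]) tot <- tot + 1 / 3
      }
      s[cd] <- tot
    }
    .codon_cache$syn_sites <- s
  }
  out <- rep(NA_real_, length(codon))
  v <- is_valid_codon(codon)
  out[v] <- unname(.codon_cache$syn_sites[codon[v]])
  out
}

# Synonymous/nonsynonymous change counts between two codons, averaged over
# all minimal mutational pathways; pathways passing through a stop codon are
# excluded (unless every pathway does, in which case all are kept).
# Returns c(sd, nd). Memoised.
codon_pair_changes <- function(a, b) {
  if (a == b) return(c(sd = 0, nd = 0))
  key <- if (a < b) paste0(a, b) else paste0(b, a)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code()
  pos <- which(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  paths <- if (length(pos) == 1L) list(pos) else
    lapply(seq_len(nrow(perms <- permutations_of(pos))), function(i) perms[i, ])
  eval_path <- function(ord) {
    cur <- a; sd <- 0; nd <- 0; through_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (gc[nxt] == "*" && nxt != b) through_stop <- TRUE
      if (gc[cur] != "*" && gc[nxt] != "*" && gc[cur] == gc[nxt])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, through_stop = through_stop)
  }
  res <- lapply(paths, eval_path)
  keep <- !vapply(res, `[[`, logical(1L), "through_stop")
  if (!any(keep)) keep <- rep(TRUE, length(res))
  sd <- mean(vapply(res[keep], `[[`, numeric(1L), "sd"))
  nd <- mean(vapply(res[keep], `[[`, numeric(1L), "nd"))
  out <- c(sd = sd, nd = nd)
  assign(key, out, envir = .codon_cache)
  out
}

# all orderings of a small integer vector (2 or 3 elements)
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L))
  if (n == 2L) return(rbind(x, rev(x)))
  out <- NULL
  for (i in seq_len(n))
    out <- rbind(out, cbind(x[i], permutations_of(x[-i])))
  unname(out)
}

#' In-frame codon view of an allele catalogue
#'
#' Splits a codon-mode catalogue into a matrix of codon triplets (alleles in
#' rows) and its translation, rejecting internal stop codons.
#'
#' @param catalog An [allele_catalog()] built with `codon_mode = TRUE`.
#' @return List of class `codon_alignment` with `codons` (character matrix
#'   of triplets), `aa` (amino-acid matrix, `-` for a gap codon, `X` for an
#'   ambiguous one) and `n_codons`.
#' @export
codon_alignment <- function(catalog) {
  stopifnot(inherits(catalog, "allele_catalog"))
  if (!catalog$codon_mode)
    stop("catalogue must be read/built with codon_mode = TRUE")
  n_codons <- catalog$alignment_length %/% 3L
  codons <- t(vapply(catalog$sequences, function(s)
    substring(s, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons)),
    character(n_codons)))
  rownames(codons) <- names(catalog$sequences)
  aa <- matrix(translate_codon(codons), nrow = nrow(codons),
               dimnames = dimnames(codons))
  if (any(aa == "*"))
    stop("internal stop codon in allele ",
         rownames(aa)[which(aa == "*", arr.ind = TRUE)[1L, 1L]])
  structure(list(codons = codons, aa = aa, n_codons = n_codons),
            class = "codon_alignment")
}

#' Nei-Gojobori proportions for one sequence pair
#'
#' Counts synonymous and nonsynonymous differences between two codon
#' sequences, averaging multi-step codon differences over all minimal
#' mutational pathways, and divides by the Nei-Gojobori synonymous and
#' nonsynonymous site counts (averaged over the two sequences). Codons with
#' a gap or ambiguity in either sequence are skipped.
#'
#' @param codons_a,codons_b Character vectors of codon triplets of equal
#'   length.
#' @return List with `pN`, `pS`, `syn_sites`, `nonsyn_sites`, `Sd`, `Nd`.
#' @export
neigojobori_pair <- function(codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b))
  ok <- is_valid_codon(codons_a) & is_valid_codon(codons_b)
  if (!any(ok)) stop("no comparable codons (all gapped or ambiguous)")
  a <- codons_a[ok]; b <- codons_b[ok]
  s_a <- syn_site_fraction(a); s_b <- syn_site_fraction(b)
  syn_sites <- (sum(s_a) + sum(s_b)) / 2
  nonsyn_sites <- 3 * length(a) - syn_sites
  sd <- 0; nd <- 0
  for (i in seq_along(a)) {
    ch <- codon_pair_changes(a[i], b[i])
    sd <- sd + ch[["sd"]]; nd <- nd + ch[["nd"]]
  }
  list(pN = if (nonsyn_sites > 0) nd / nonsyn_sites else NA_real_,
       pS = if (syn_sites > 0) sd / syn_sites else NA_real_,
       syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
       Sd = sd, Nd = nd)
}
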