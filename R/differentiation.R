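# Differentiation estimators suited to hyperpolymorphic loci. G_ST-type
# statistics compress toward zero when within-population diversity is high,
# so the package reports Hedrick's standardized G'_ST and Jost's D instead.

#' Within- and total gene diversity components
#'
#' Computes the diversity components every deme-differentiation estimator is
#' built from. In the `naive` form, `H_S` is the unweighted mean of
#' within-population gene diversities and `H_T` the gene diversity of the
#' unweighted mean allele-frequency vector (demes weighted equally, the
#' Nei-Chesser convention). The `bias_corrected` form applies the
#' small-sample estimators
#' `H_S_est = (N_h/(N_h - 1)) * H_S` and
#' `H_T_est = H_T + H_S_est / (2 * N_h * n)`,
#' with `N_h` the harmonic mean diploid sample size across demes.
#'
#' @param freqs List (one element per population) of named allele copy-count
#'   vectors or frequency vectors for the same locus.
#' @param estimator `"naive"` or `"bias_corrected"`.
#' @param sizes Diploid sample sizes per population; required for
#'   `bias_corrected` unless `freqs` are counts (then inferred as
#'   copies / 2).
#' @return List of class `diversity_components` with `H_S`, `H_T`,
#'   `n_demes`, `estimator`, and `N_harmonic` (bias-corrected only).
#' @export
diversity_components <- function(freqs,
                                 estimator = c("bias_corrected", "naive"),
                                 sizes = NULL) {
  estimator <- match.arg(estimator)
  keep <- vapply(freqs, function(f) sum(f) > 0, logical(1L))
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " population(s) with zero gene copies")
    freqs <- freqs[keep]
    if (!is.null(sizes)) sizes <- sizes[keep]
  }
  n <- length(freqs)
  if (n < 2L) stop("need at least two populations with data")
  alleles <- sort(unique(unlist(lapply(freqs, names))))
  if (is.null(alleles))
    stop("frequency vectors must be named by allele id")
  P <- sapply(freqs, function(f) {
    v <- stats::setNames(numeric(length(alleles)), alleles)
    v[names(f)] <- f / sum(f)
    v
  })
  P <- matrix(P, nrow = length(alleles),
              dimnames = list(alleles, names(freqs)))
  H_within <- 1 - colSums(P^2)
  H_S <- mean(H_within)
  pbar <- rowMeans(P)
  H_T <- 1 - sum(pbar^2)
  out <- list(H_S = H_S, H_T = H_T, n_demes = n, estimator = estimator,
              N_harmonic = NA_real_)
  if (estimator == "bias_corrected") {
    if (is.null(sizes)) {
      copies <- vapply(freqs, sum, numeric(1L))
      if (any(copies <= 1 + 1e-9))
        stop("bias-corrected estimator needs copy counts or explicit sizes")
      sizes <- copies / 2
    }
    Nh <- length(sizes) / sum(1 / sizes)
    out$N_harmonic <- Nh
    out$H_S <- (Nh / (Nh - 1)) * H_S
    out$H_T <- H_T + out$H_S / (2 * Nh * n)
  }
  class(out) <- "diversity_components"
  out
}

#' Jost's D differentiation
#'
#' `D = (n/(n-1)) * (H_T - H_S) / (1 - H_S)`: equals 1 exactly when demes
#' share no alleles and does not shrink as within-deme diversity rises.
#'
#' @param components A [diversity_components()] object.
#' @return D, or `NA` when `H_S = 1`.
#' @export
jost_d <- function(components) {
  with(components, {
    if (1 - H_S <= 0) return(NA_real_)
    (n_demes / (n_demes - 1)) * (H_T - H_S) / (1 - H_S)
  })
}

#' Hedrick's standardized G'_ST
#'
#' `G_ST = (H_T - H_S)/H_T` rescaled by its maximum attainable value given
#' the within-deme diversity, `G_ST_max = ((n-1)(1-H_S))/(n-1+H_S)`.
#'
#' @param components A [diversity_components()] object.
#' @return G'_ST, or `NA` when `H_T = 0`.
#' @export
hedrick_gst_prime <- function(components) {
  with(components, {
    if (H_T <= 0) return(NA_real_)
    gst <- (H_T - H_S) / H_T
    gst_max <- ((n_demes - 1) * (1 - H_S)) / (n_demes - 1 + H_S)
    if (gst_max <= 0) return(NA_real_)
    gst / gst_max
  })
}

#' Plain G_ST
#' @param components A [diversity_components()] object.
#' @return `(H_T - H_S)/H_T`, or `NA` when `H_T = 0`.
#' @export
gst <- function(components) {
  with(components, if (H_T <= 0) NA_real_ else (H_T - H_S) / H_T)
}

#' Pairwise population differentiation matrices
#'
#' For every population pair, per-locus statistics are computed with
#' `n = 2` demes and combined across loci by the arithmetic mean (or the
#' harmonic mean of positive values, an alternative convention for Jost's
#' D). A locus monomorphic across a pair contributes 0 in the naive
#' estimator and is skipped (undefined) in the bias-corrected one.
#'
#' @param genotypes A [population_genotypes()] object.
#' @param loci Loci to include (multi-locus values are averaged).
#' @param statistic `"d"`, `"gst_prime"` or `"gst"`.
#' @param estimator `"bias_corrected"` or `"naive"`.
#' @param combine `"arithmetic"` (default) or `"harmonic"` across loci.
#' @param supertypes Optional named map allele_id -> supertype label; counts
#'   are pooled through the map before the statistic is computed
#'   (supertype-level differentiation).
#' @return Symmetric labelled matrix of pairwise values, zero diagonal.
#' @export
pairwise_differentiation <- function(genotypes, loci = unique(genotypes$locus),
                                     statistic = c("d", "gst_prime", "gst"),
                                     estimator = c("bias_corrected", "naive"),
                                     combine = c("arithmetic", "harmonic"),
                                     supertypes = NULL) {
  statistic <- match.arg(statistic)
  estimator <- match.arg(estimator)
  combine <- match.arg(combine)
  stat_fun <- switch(statistic, d = jost_d, gst_prime = hedrick_gst_prime,
                     gst = gst)
  pops <- populations(genotypes)
  if (length(pops) < 2L) stop("need at least two populations")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) for (j in (i + 1L):length(pops)) {
    vals <- numeric(0)
    for (loc in loci) {
      c1 <- allele_counts(genotypes, pops[i], loc)
      c2 <- allele_counts(genotypes, pops[j], loc)
      if (sum(c1) == 0 || sum(c2) == 0) next
      if (!is.null(supertypes)) {
        c1 <- tapply(c1, supertypes[names(c1)], sum)
        c2 <- tapply(c2, supertypes[names(c2)], sum)
        c1 <- stats::setNames(as.numeric(c1), names(c1))
        c2 <- stats::setNames(as.numeric(c2), names(c2))
      }
      if (length(unique(c(names(c1), names(c2)))) < 2L) {
        # monomorphic across the pair
        if (estimator == "naive") vals <- c(vals, 0)
        next
      }
      comp <- diversity_components(list(a = c1, b = c2), estimator = estimator)
      vals <- c(vals, stat_fun(comp))
    }
    v <- if (!length(vals)) NA_real_
         else if (combine == "arithmetic") mean(vals, na.rm = TRUE)
         else {
           pos <- vals[!is.na(vals) & vals > 0]
           if (!length(pos)) 0 else length(pos) / sum(1 / pos)
         }
    m[i, j] <- m[j, i] <- v
  }
  labeled_matrix(m)
}

#' Mantel matrix-correlation permutation test
#'
#' Pearson correlation between the upper off-diagonal triangles of two
#' labelled distance matrices, with significance from simultaneous
#' row/column permutations of the second matrix. The reported p-value is
#' two-sided on `|r|`.
#'
#' @param m1,m2 Labelled symmetric matrices with identical labels in
#'   identical order (see [labeled_matrix()]).
#' @param reps Number of permutations (>= 99).
#' @param seed RNG seed.
#' @return List with `r` and `p_value`.
#' @export
mantel_test <- function(m1, m2, reps = 999L, seed = 1L) {
  m1 <- labeled_matrix(m1); m2 <- labeled_matrix(m2)
  if (!identical(rownames(m1), rownames(m2)))
    stop("matrices must carry identical labels in identical order")
  if (reps < 99L) stop("use at least 99 permutations")
  v1 <- upper_tri_values(m1)
  if (stats::sd(v1) == 0 || stats::sd(upper_tri_values(m2)) == 0)
    stop("constant matrix: correlation undefined")
  r_obs <- stats::cor(v1, upper_tri_values(m2))
  hits <- with_seed(seed, {
    n <- nrow(m2)
    sum(vapply(seq_len(reps), function(i) {
      p <- sample(n)
      abs(stats::cor(v1, upper_tri_values(m2[p, p]))) >= abs(r_obs) - 1e-12
    }, logical(1L)))
  })
  list(r = r_obs, p_value = (1 + hits) / (reps + 1))
}
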