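# Functional supertype definition: encode positively selected residues with
# physicochemical z-descriptors, cluster alleles by k-means/BIC on retained
# principal components, assign supertypes by discriminant projection.

#' Amino-acid z-descriptor scales
#'
#' The five principal-property scales of Sandberg et al. (1998) for the 20
#' proteinogenic amino acids: z1 (lipophilicity/hydrophobicity), z2 (steric
#' bulk/polarisability), z3 (polarity/charge), z4 and z5 (electronic
#' effects).
#'
#' @return A 20 x 5 numeric matrix, rows named by one-letter residue codes,
#'   columns `z1..z5`.
#' @export
z_descriptor_table <- function() {
  vals <- c(
    # z1,    z2,    z3,    z4,    z5
    0.24, -2.32,  0.60, -0.14,  1.30,  # A
    3.52,  2.50, -3.50,  1.99, -0.17,  # R
    3.05,  1.62,  1.04, -1.15,  1.61,  # N
    3.98,  0.93,  1.93, -2.46,  0.75,  # D
    0.84, -1.67,  3.71,  0.18, -2.65,  # C
    1.75,  0.50, -1.44, -1.34,  0.66,  # Q
    3.11,  0.26, -0.11, -3.04, -0.25,  # E
    2.05, -4.06,  0.36, -0.82, -0.38,  # G
    2.47,  1.95,  0.26,  3.90,  0.09,  # H
   -3.89, -1.73, -1.71, -0.84,  0.26,  # I
   -4.28, -1.30, -1.49, -0.72,  0.84,  # L
    2.29,  0.89, -2.49,  1.49,  0.31,  # K
   -2.85, -0.22,  0.47,  1.94, -0.98,  # M
   -4.22,  1.94,  1.06,  0.54, -0.62,  # F
   -1.66,  0.27,  1.84,  0.70,  2.00,  # P
    2.39, -1.07,  1.15, -1.39,  0.67,  # S
    0.75, -2.18, -1.12, -1.46, -0.40,  # T
   -4.36,  3.94,  0.59,  3.44, -1.59,  # W
   -2.54,  2.44,  0.43,  0.04, -1.47,  # Y
   -2.59, -2.64, -1.54, -0.85, -0.02)  # V
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  matrix(vals, nrow = 20L, byrow = TRUE,
         dimnames = list(aa, paste0("z", 1:5)))
}

#' Encode alleles by z-descriptors at selected sites
#'
#' Each allele is represented by the concatenated z1..z5 descriptors of its
#' residues at the positively selected sites (ascending site order); all
#' other residues are ignored. A gap residue at a selected site is encoded
#' as the 5-dimensional zero vector.
#'
#' @param catalog A codon-mode [allele_catalog()].
#' @param selected_sites Integer vector of 1-based amino-acid positions.
#' @return Numeric matrix, one row per allele, `5 * length(selected_sites)`
#'   columns named `site<k>.z1` etc.
#' @export
encode_z_descriptors <- function(catalog, selected_sites) {
  ca <- codon_alignment(catalog)
  selected_sites <- sort(unique(as.integer(selected_sites)))
  if (any(selected_sites < 1L | selected_sites > ca$n_codons))
    stop("selected sites outside translated length ", ca$n_codons)
  zt <- z_descriptor_table()
  enc_res <- function(res) {
    if (res == "-") return(numeric(5L))
    if (!res %in% rownames(zt))
      stop("unknown residue symbol '", res, "' at a selected site")
    zt[res, ]
  }
  out <- t(apply(ca$aa[, selected_sites, drop = FALSE], 1L, function(row)
    unlist(lapply(row, enc_res), use.names = FALSE)))
  colnames(out) <- as.vector(t(outer(selected_sites, 1:5,
                                     function(s, z) paste0("site", s, ".z", z))))
  rownames(out) <- rownames(ca$aa)
  out
}

#' Supertype clustering of allele encodings (DAPC style)
#'
#' Centres and scales the descriptor encoding, retains principal components
#' up to a target share of variance, runs k-means for `k = 1..k_max`
#' (25 seeded restarts each) and scores each solution with
#' `BIC(k) = n * log(W_k / n) + k * log(n)` (`W_k` = total within-cluster
#' sum of squares). The chosen `k` is the smallest whose BIC lies within
#' `delta_bic` of the minimum. Final supertype assignment projects the
#' retained components through a linear discriminant fit to the k-means
#' labels.
#'
#' @param encoding Matrix from [encode_z_descriptors()] (alleles in rows).
#' @param k_max Largest cluster count to consider.
#' @param variance_retained Share of variance the retained components must
#'   reach (default 0.95).
#' @param delta_bic BIC window for choosing `k` (default 2).
#' @param seed RNG seed (k-means restarts).
#' @return List of class `supertype_model`: `retained_components`, `k`,
#'   `bic_curve` (data frame `k`, `BIC`), `assignments` (named character
#'   vector allele -> `"ST<j>"`), `cluster_centers`, plus internals used for
#'   prediction.
#' @export
dapc_cluster <- function(encoding, k_max = 10L, variance_retained = 0.95,
                         delta_bic = 2, seed = 1L) {
  n <- nrow(encoding)
  if (n < 2L) stop("need at least 2 alleles")
  k_max <- min(k_max, n)
  keep <- apply(encoding, 2L, stats::sd) > 0
  if (!any(keep)) {
    assignments <- stats::setNames(rep("ST1", n), rownames(encoding))
    return(structure(list(retained_components = 0L, k = 1L,
                          bic_curve = data.frame(k = 1L, BIC = NA_real_),
                          assignments = assignments,
                          cluster_centers = NULL),
                     class = "supertype_model"))
  }
  x <- scale(encoding[, keep, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  varexp <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  r <- which(varexp >= variance_retained)[1L]
  scores <- pc$x[, seq_len(r), drop = FALSE]
  # k-means needs at least k distinct points
  k_max <- min(k_max, nrow(unique(scores)))

  fits <- with_seed(seed, {
    lapply(seq_len(k_max), function(k) {
      if (k == 1L) {
        w <- sum(scale(scores, scale = FALSE)^2)
        list(cluster = rep(1L, n), withinss = w,
             centers = matrix(colMeans(scores), 1L))
      } else {
        km <- stats::kmeans(scores, centers = k, nstart = 25L,
                            iter.max = 100L)
        list(cluster = km$cluster, withinss = km$tot.withinss,
             centers = km$centers)
      }
    })
  })
  W <- vapply(fits, `[[`, numeric(1L), "withinss")
  bic <- ifelse(W > 0, n * log(W / n) + seq_len(k_max) * log(n), -Inf)
  # smallest k within delta_bic of the minimum (ties broken toward small k)
  k_sel <- which(bic - min(bic) <= delta_bic)[1L]
  labels <- fits[[k_sel]]$cluster

  assignments <- paste0("ST", labels)
  lda_fit <- NULL
  if (k_sel > 1L && r >= 1L) {
    lda_fit <- tryCatch(
      MASS::lda(scores, grouping = factor(labels)),
      error = function(e) NULL)
    if (!is.null(lda_fit))
      assignments <- paste0("ST", as.integer(as.character(
        stats::predict(lda_fit, scores)$class)))
  }
  names(assignments) <- rownames(encoding)
  structure(list(retained_components = r, k = k_sel,
                 bic_curve = data.frame(k = seq_len(k_max), BIC = bic),
                 assignments = assignments,
                 cluster_centers = fits[[k_sel]]$centers,
                 lda = lda_fit, kept_columns = which(keep),
                 scaling = list(center = attr(x, "scaled:center"),
                                scale = attr(x, "scaled:scale")),
                 rotation = pc$rotation[, seq_len(r), drop = FALSE]),
            class = "supertype_model")
}

#' @export
print.supertype_model <- function(x, ...) {
  cat("<supertype_model>", x$k, "supertypes,", x$retained_components,
      "retained components,", length(x$assignments), "alleles\n")
  print(table(x$assignments))
  invisible(x)
}

#' Per-population supertype frequencies
#'
#' Maps allele copy counts through the supertype assignments and normalizes
#' per population.
#'
#' @param genotypes A [population_genotypes()] object.
#' @param model A `supertype_model` (or a named allele -> supertype vector).
#' @param locus Locus name (default `"DAB"`).
#' @return Data frame: `population`, `supertype`, `count`, `frequency`.
#' @export
supertype_frequencies <- function(genotypes, model, locus = "DAB") {
  map <- if (inherits(model, "supertype_model")) model$assignments else model
  sts <- sort(unique(map))
  rows <- lapply(populations(genotypes), function(pop) {
    cc <- allele_counts(genotypes, pop, locus)
    if (sum(cc) == 0) return(NULL)
    missing <- setdiff(names(cc), names(map))
    if (length(missing))
      stop("allele(s) without supertype assignment: ",
           paste(utils::head(missing, 3L), collapse = ", "))
    agg <- tapply(cc, factor(map[names(cc)], levels = sts), sum)
    agg[is.na(agg)] <- 0
    data.frame(population = pop, supertype = sts, count = as.numeric(agg),
               frequency = as.numeric(agg) / sum(agg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
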