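# Per-population diversity statistics for sequence and microsatellite loci.

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers never perturb the global stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Observed heterozygosity
#'
#' Fraction of typed diploids carrying two different alleles.
#'
#' @param genotypes A [population_genotypes()] object.
#' @param population Population name (`NULL` pools all).
#' @param locus Locus name.
#' @return Proportion of heterozygous individuals, or `NA` if no individual
#'   is typed.
#' @export
observed_heterozygosity <- function(genotypes, population = NULL, locus) {
  g <- genotypes[genotypes$locus == locus, , drop = FALSE]
  if (!is.null(population))
    g <- g[g$population %in% population, , drop = FALSE]
  g <- g[!is.na(g$allele_a) & !is.na(g$allele_b), , drop = FALSE]
  if (nrow(g) == 0L) return(NA_real_)
  mean(g$allele_a != g$allele_b)
}

#' Expected heterozygosity (gene diversity)
#'
#' `1 - sum(p_i^2)` from allele copy counts; with `unbiased = TRUE` the
#' small-sample factor `2N/(2N - 1)` (N diploids, i.e. n copies / (n - 1))
#' is applied.
#'
#' @param counts Named or unnamed vector of allele copy counts.
#' @param unbiased Apply the `n/(n - 1)` correction (default `FALSE`).
#' @return Gene diversity in `[0, 1]`.
#' @export
expected_heterozygosity <- function(counts, unbiased = FALSE) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least two allele copies")
  h <- 1 - sum((counts / n)^2)
  if (unbiased) h <- h * n / (n - 1)
  h
}

#' Haplotype (gene) diversity
#'
#' Sample-size corrected gene diversity `(n/(n-1)) * (1 - sum(p_i^2))`, the
#' convention of sequence-polymorphism software.
#'
#' @param counts Allele (haplotype) copy counts.
#' @return Corrected diversity in `[0, 1]`; `NA` if fewer than 2 copies.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  expected_heterozygosity(counts, unbiased = TRUE)
}

# internal: character matrix of aligned sequences, one row per allele
seq_matrix <- function(catalog, ids = names(catalog$sequences)) {
  m <- do.call(rbind, strsplit(catalog$sequences[ids], ""))
  rownames(m) <- ids
  m
}

#' Sequence polymorphism from weighted allele copies
#'
#' Computes the classic sequence-diversity triple from an alignment and the
#' copy count of each allele in a sample: the number of segregating sites
#' `S`, the mean number of pairwise nucleotide differences `k` over all
#' `C(n,2)` copy pairs, and the per-site nucleotide diversity
#' `pi = k / L_used`.
#'
#' Gaps (`-`) and `N` are treated as missing under pairwise deletion: a
#' column is skipped for a pair when either member lacks a base there.
#' `L_used` counts alignment columns in which at most half of the sampled
#' copies are missing.
#'
#' @param catalog An [allele_catalog()].
#' @param counts Named vector of allele copy counts (names in the catalogue).
#' @return List with `S`, `k`, `pi`, and `L_used`.
#' @export
pairwise_diff_stats <- function(catalog, counts) {
  counts <- counts[counts > 0]
  ids <- names(counts)
  if (is.null(ids) || !all(ids %in% names(catalog$sequences)))
    stop("counts must be named by catalogue allele ids")
  n <- sum(counts)
  if (n < 2) stop("need at least two allele copies")
  m <- seq_matrix(catalog, ids)
  miss <- m == "-" | m == "N"

  # segregating sites among distinct alleles present
  n_states <- apply(m, 2L, function(col) length(unique(col[!(col %in% c("-", "N"))])))
  S <- sum(n_states >= 2L)

  # columns usable for per-site diversity: <= 50% missing copies
  miss_copies <- as.vector(counts %*% miss)
  L_used <- sum(miss_copies <= n / 2)

  k_num <- 0
  na <- length(ids)
  if (na >= 2L) {
    for (i in seq_len(na - 1L)) for (j in (i + 1L):na) {
      ok <- !miss[i, ] & !miss[j, ]
      d <- sum(m[i, ok] != m[j, ok])
      k_num <- k_num + counts[[i]] * counts[[j]] * d
    }
  }
  pairs <- n * (n - 1) / 2
  k <- k_num / pairs
  list(S = S, k = k, pi = if (L_used > 0) k / L_used else NA_real_,
       L_used = L_used)
}

#' Rarefaction allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by the hypergeometric rarefaction formula
#' `sum_i [1 - C(N - N_i, g) / C(N, g)]`. Passing a list of per-locus count
#' vectors returns the mean across loci (the multi-locus richness).
#'
#' @param counts Vector of allele copy counts for one locus, or a list of
#'   such vectors for several loci.
#' @param g Gene-copy subsample size, `1 <= g <=` total copies at each locus.
#' @return Expected allelic richness (real).
#' @export
allelic_richness_rarefaction <- function(counts, g) {
  if (is.list(counts))
    return(mean(vapply(counts, allelic_richness_rarefaction, numeric(1L),
                       g = g)))
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1) stop("subsample size g must be >= 1")
  if (g > N) stop("subsample size g exceeds total gene copies (", N, ")")
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Permutation confidence interval for the expected allele count
#'
#' How many distinct alleles would a sample of `n_pop` diploids show if it
#' were drawn at random from a common pool? Gene copies are pooled across
#' populations, `2 * n_pop` copies are repeatedly drawn without replacement,
#' and the 2.5th/97.5th percentiles of the distinct-allele count give a 95%
#' interval against which an observed allele count can be judged.
#'
#' @param pooled_counts Named vector of allele copy counts pooled across the
#'   analysed populations.
#' @param n_pop Diploid sample size of the focal population.
#' @param reps Number of permutation draws (default 10000).
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @param conf Confidence level (default 0.95).
#' @return Integer vector `c(low, high)`.
#' @export
allele_count_ci_permutation <- function(pooled_counts, n_pop, reps = 10000L,
                                        seed = 1L, conf = 0.95) {
  pooled_counts <- pooled_counts[pooled_counts > 0]
  draw <- 2L * n_pop
  if (draw > sum(pooled_counts))
    stop("2 * n_pop exceeds the pooled number of gene copies")
  if (reps < 100L) warning("fewer than 100 permutation reps; CI is unstable")
  pool <- rep(seq_along(pooled_counts), pooled_counts)
  counts <- with_seed(seed, {
    vapply(seq_len(reps),
           function(i) length(unique(sample(pool, draw, replace = FALSE))),
           integer(1L))
  })
  alpha <- (1 - conf) / 2
  q <- stats::quantile(counts, c(alpha, 1 - alpha), type = 1L, names = FALSE)
  c(low = as.integer(q[1L]), high = as.integer(q[2L]))
}

# ---- Hardy-Weinberg exact test -------------------------------------------

# log probability of a genotype-count configuration under the conditional
# (Levene) distribution given allele counts
levene_log_prob <- function(geno, allele_counts) {
  n <- sum(geno)
  het <- sum(geno[upper.tri(geno)])
  lgamma(n + 1) - sum(lgamma(geno[upper.tri(geno, diag = TRUE)] + 1)) +
    het * log(2) + sum(lgamma(allele_counts + 1)) - lgamma(sum(allele_counts) + 1)
}

# enumerate all genotype-count configurations with the given allele-count
# margins; calls visit(geno) per configuration; aborts (returns FALSE) if
# more than max_configs are generated
enumerate_levene <- function(allele_counts, visit, max_configs = 1e6) {
  K <- length(allele_counts)
  geno <- matrix(0L, K, K)
  n_seen <- 0L
  ok <- TRUE
  # for row i iterate heterozygote cells j = i+1..K, then close the row by
  # assigning the homozygote count from the remaining margin (must be even)
  recurse2 <- function(i, j, remaining) {
    if (!ok) return()
    if (i > K) {
      n_seen <<- n_seen + 1L
      if (n_seen > max_configs) { ok <<- FALSE; return() }
      visit(geno)
      return()
    }
    if (j > K) {
      if (remaining[i] %% 2L == 0L && remaining[i] >= 0L) {
        geno[i, i] <<- remaining[i] %/% 2L
        recurse2(i + 1L, i + 2L, remaining)
        geno[i, i] <<- 0L
      }
      return()
    }
    top <- min(remaining[i], remaining[j])
    for (h in 0:top) {
      geno[i, j] <<- h
      r2 <- remaining
      r2[i] <- r2[i] - h
      r2[j] <- r2[j] - h
      recurse2(i, j + 1L, r2)
      geno[i, j] <<- 0L
    }
  }
  recurse2(1L, 2L, as.integer(allele_counts))
  ok
}

# genotype count matrix (upper triangular) from a genotype table subset
genotype_count_matrix <- function(genotypes, population, locus) {
  g <- genotypes[genotypes$locus == locus, , drop = FALSE]
  if (!is.null(population))
    g <- g[g$population %in% population, , drop = FALSE]
  g <- g[!is.na(g$allele_a) & !is.na(g$allele_b), , drop = FALSE]
  alleles <- sort(unique(c(g$allele_a, g$allele_b)))
  K <- length(alleles)
  geno <- matrix(0L, K, K, dimnames = list(alleles, alleles))
  for (r in seq_len(nrow(g))) {
    i <- match(g$allele_a[r], alleles)
    j <- match(g$allele_b[r], alleles)
    a <- min(i, j); b <- max(i, j)
    geno[a, b] <- geno[a, b] + 1L
  }
  geno
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Exact test on the conditional (Levene) distribution of genotype
#' configurations given the observed allele counts. When the configuration
#' space is small (at most `max_configs` configurations) it is enumerated in
#' full; otherwise the test draws `reps` independent configurations from the
#' exact conditional distribution by randomly re-pairing the observed gene
#' copies into diploids.
#'
#' The `global` alternative sums the probability of all configurations no
#' more probable than the observed one; `het_deficit` sums configurations
#' with at most the observed number of heterozygotes, the one-sided test for
#' homozygote excess (null alleles, inbreeding).
#'
#' @param genotypes A [population_genotypes()] object (or a genotype count
#'   matrix via `geno`).
#' @param population Population name (`NULL` pools all).
#' @param locus Locus name.
#' @param alternative `"global"` or `"het_deficit"`.
#' @param reps Monte-Carlo draws when enumeration is infeasible.
#' @param seed RNG seed for the Monte-Carlo mode.
#' @param max_configs Enumeration bound (default `1e6` configurations).
#' @param geno Optionally a genotype count matrix (upper triangle filled)
#'   instead of `genotypes`/`population`/`locus`.
#' @return P-value. A monomorphic locus returns 1.
#' @export
hwe_exact_test <- function(genotypes = NULL, population = NULL, locus = NULL,
                           alternative = c("global", "het_deficit"),
                           reps = 1e5, seed = 1L, max_configs = 1e6,
                           geno = NULL) {
  alternative <- match.arg(alternative)
  if (is.null(geno))
    geno <- genotype_count_matrix(genotypes, population, locus)
  K <- nrow(geno)
  n <- sum(geno)
  if (n < 2L) stop("need at least two typed samples")
  if (K <= 1L) return(1)
  allele_counts <- integer(K)
  for (i in seq_len(K)) {
    allele_counts[i] <- 2L * geno[i, i] +
      sum(geno[i, seq_len(K) > i]) + sum(geno[seq_len(K) < i, i])
  }
  obs_lp <- levene_log_prob(geno, allele_counts)
  obs_het <- sum(geno[upper.tri(geno)])
  eps <- 1e-9

  # cheap upper bound on the number of configurations: each configuration
  # is determined by its heterozygote cells, and cell (i,j) can take at
  # most min(c_i, c_j) + 1 values
  pm <- outer(allele_counts, allele_counts, pmin)
  log_bound <- sum(log(pm[upper.tri(pm)] + 1))

  enumerated <- FALSE
  if (log_bound <= log(max_configs)) {
    probs <- numeric(0); hets <- integer(0)
    collect <- function(g2) {
      probs[length(probs) + 1L] <<- levene_log_prob(g2, allele_counts)
      hets[length(hets) + 1L] <<- sum(g2[upper.tri(g2)])
    }
    enumerated <- enumerate_levene(allele_counts, collect, max_configs)
  }
  if (enumerated) {
    p <- exp(probs)
    if (alternative == "global") sum(p[probs <= obs_lp + eps])
    else sum(p[hets <= obs_het])
  } else {
    pool <- rep(seq_len(K), allele_counts)
    n2 <- 2L * n
    hits <- with_seed(seed, {
      perms <- vapply(seq_len(reps), function(r) sample(pool), integer(n2))
      a <- perms[seq(1L, n2, by = 2L), , drop = FALSE]
      b <- perms[seq(2L, n2, by = 2L), , drop = FALSE]
      het_counts <- colSums(a != b)
      if (alternative == "het_deficit") {
        sum(het_counts <= obs_het)
      } else {
        # per-draw log-probability up to an additive constant:
        # H log 2 - sum_ij log(n_ij!)
        key <- (pmin(a, b) - 1L) * K + pmax(a, b)
        nbins <- K * K
        tab <- tabulate(as.vector(key) +
                          rep((seq_len(reps) - 1L) * nbins, each = n),
                        nbins * reps)
        lf <- lfactorial(tab)
        dim(lf) <- c(nbins, reps)
        lp <- het_counts * log(2) - colSums(lf)
        obs_rel <- obs_het * log(2) -
          sum(lgamma(geno[upper.tri(geno, diag = TRUE)] + 1))
        sum(lp <= obs_rel + eps)
      }
    })
    (1 + hits) / (reps + 1)
  }
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Association between the genotype classes of two loci in the same samples,
#' tested by the G statistic of the two-locus genotype contingency table and
#' a null built by permuting one locus's genotypes across individuals.
#'
#' @param genotypes A [population_genotypes()] object.
#' @param locus_a,locus_b Locus names.
#' @param population Population name (`NULL` pools all).
#' @param reps Number of permutations (default 999).
#' @param seed RNG seed.
#' @return P-value `(1 + #perm >= observed) / (reps + 1)`; 1 if either locus
#'   is monomorphic.
#' @export
genotypic_ld_test <- function(genotypes, locus_a, locus_b, population = NULL,
                              reps = 999L, seed = 1L) {
  pick <- function(loc) {
    g <- genotypes[genotypes$locus == loc, , drop = FALSE]
    if (!is.null(population))
      g <- g[g$population %in% population, , drop = FALSE]
    g <- g[!is.na(g$allele_a) & !is.na(g$allele_b), , drop = FALSE]
    stats::setNames(paste(pmin(g$allele_a, g$allele_b),
                          pmax(g$allele_a, g$allele_b), sep = "/"),
                    g$sample_id)
  }
  ga <- pick(locus_a); gb <- pick(locus_b)
  shared <- intersect(names(ga), names(gb))
  if (length(shared) < 5L) stop("need >= 5 samples typed at both loci")
  ga <- ga[shared]; gb <- gb[shared]
  mono <- function(gg) length(unique(unlist(strsplit(gg, "/", fixed = TRUE)))) < 2L
  if (mono(ga) || mono(gb)) return(1)
  g_stat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- as.vector(tab); e <- as.vector(e)
    2 * sum(o[o > 0] * log(o[o > 0] / e[o > 0]))
  }
  obs <- g_stat(ga, gb)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(reps),
               function(i) g_stat(ga, sample(gb)) >= obs - 1e-12,
               logical(1L)))
  })
  (1 + hits) / (reps + 1)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order as input), capped at 1.
#' @export
holm_bonferroni <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "holm")
}

#' Regression of richness at one marker set on another
#'
#' Ordinary least squares of per-population allelic richness at one marker
#' set on richness at another (e.g. an MHC locus on neutral microsatellites),
#' used to gauge the contribution of genetic drift to functional diversity.
#'
#' @param x Predictor richness values (one per population).
#' @param y Response richness values.
#' @return List with `slope`, `intercept`, `p_value` (two-sided t-test on the
#'   slope, `n - 2` df) and `n`.
#' @export
richness_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 populations")
  if (stats::var(x) == 0) stop("zero variance in the predictor")
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  p <- if (stats::var(y) == 0) 1 else cf["x", "Pr(>|t|)"]
  list(slope = unname(cf["x", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       p_value = unname(p), n = n)
}

#' Per-population polymorphism summary
#'
#' Assembles the standard per-population summary for one marker set: diploid
#' sample size `N`, mean alleles per locus `A`, rarefied allelic richness
#' `A_R`, a permutation CI for the expected allele count given the sample
#' size, observed and expected heterozygosity, and — when an aligned allele
#' catalogue is supplied (sequence loci) — haplotype diversity `Hd`,
#' segregating sites `S`, nucleotide diversity `pi` and mean pairwise
#' differences `k`.
#'
#' @param genotypes A [population_genotypes()] object.
#' @param loci Character vector of locus names forming the marker set.
#' @param catalog Optional [allele_catalog()] for a single sequence locus.
#' @param g Rarefaction size in gene copies, or `"auto"` for
#'   `2 * min(N)` over populations.
#' @param ci_reps Permutation replicates for the allele-count CI (0 skips it).
#' @param seed RNG seed for the permutation CI.
#' @return Data frame with one row per population.
#' @export
polymorphism_summary <- function(genotypes, loci, catalog = NULL, g = "auto",
                                 ci_reps = 10000L, seed = 1L) {
  pops <- populations(genotypes)
  n_of <- function(pop) {
    gg <- genotypes[genotypes$locus %in% loci &
                      genotypes$population == pop &
                      !is.na(genotypes$allele_a) &
                      !is.na(genotypes$allele_b), , drop = FALSE]
    if (length(loci) == 1L) nrow(gg) else
      max(table(factor(gg$locus, levels = loci)))
  }
  Ns <- vapply(pops, n_of, numeric(1L))
  if (identical(g, "auto")) g <- 2L * min(Ns[Ns > 0])
  rows <- lapply(pops, function(pop) {
    per_locus <- lapply(loci, function(loc) allele_counts(genotypes, pop, loc))
    names(per_locus) <- loci
    typed <- vapply(per_locus, function(cc) sum(cc) > 0, logical(1L))
    A <- mean(vapply(per_locus[typed], length, numeric(1L)))
    AR <- allelic_richness_rarefaction(per_locus[typed], g = g)
    HO <- mean(vapply(loci[typed], function(loc)
      observed_heterozygosity(genotypes, pop, loc), numeric(1L)))
    HE <- mean(vapply(per_locus[typed], expected_heterozygosity, numeric(1L)))
    ci <- c(NA_integer_, NA_integer_)
    if (ci_reps > 0L && length(loci) == 1L) {
      pooled <- allele_counts(genotypes, NULL, loci[[1L]])
      ci <- allele_count_ci_permutation(pooled, n_pop = n_of(pop),
                                        reps = ci_reps, seed = seed)
    }
    out <- data.frame(population = pop, N = n_of(pop), A = A, A_R = AR,
                      ci_NA_low = ci[[1L]], ci_NA_high = ci[[2L]],
                      H_O = HO, H_E = HE)
    if (!is.null(catalog) && length(loci) == 1L) {
      cc <- per_locus[[1L]]
      sk <- pairwise_diff_stats(catalog, cc)
      out$Hd <- haplotype_diversity(cc)
      out$S <- sk$S; out$pi <- sk$pi; out$k <- sk$k
    }
    out
  })
  do.call(rbind, rows)
}
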