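test_that("diversity components match the defining formulas", {
  freqs <- list(P1 = c(a = 10, b = 10), P2 = c(a = 4, b = 12, c = 4))
  dc <- diversity_components(freqs, estimator = "naive")
  p1 <- c(a = .5, b = .5, c = 0)
  p2 <- c(a = .2, b = .6, c = .2)
  hs <- mean(c(1 - sum(p1^2), 1 - sum(p2^2)))
  pbar <- (p1 + p2) / 2
  ht <- 1 - sum(pbar^2)
  expect_equal(dc$H_S, hs)
  expect_equal(dc$H_T, ht)

  dcb <- diversity_components(freqs, estimator = "bias_corrected")
  nh <- 2 / (1 / 10 + 1 / 10)  # harmonic mean diploid sizes (copies / 2)
  hs_est <- (nh / (nh - 1)) * hs
  expect_equal(dcb$H_S, hs_est)
  expect_equal(dcb$H_T, ht + hs_est / (2 * nh * 2))
  expect_equal(dcb$N_harmonic, nh)
})

test_that("Jost's D is 1 for disjoint allele pools and 0 for identical ones", {
  disj <- list(P1 = c(a = 5, b = 7), P2 = c(x = 3, y = 9))
  expect_equal(jost_d(diversity_components(disj, "naive")), 1)
  same <- list(P1 = c(a = 30, b = 70), P2 = c(a = 30, b = 70))
  expect_equal(jost_d(diversity_components(same, "naive")), 0)
  expect_equal(hedrick_gst_prime(diversity_components(disj, "naive")), 1)
  expect_equal(hedrick_gst_prime(diversity_components(same, "naive")), 0)
})

test_that("G'ST exceeds GST when within-deme diversity is high", {
  freqs <- list(P1 = c(a = 40, b = 30, c = 20, d = 10),
                P2 = c(a = 10, b = 20, c = 30, d = 40))
  dc <- diversity_components(freqs, "naive")
  expect_gt(hedrick_gst_prime(dc), gst(dc))
})

test_that("pairwise_differentiation returns symmetric labelled matrices", {
  cfg <- simulation_config(seed = 3L, n_populations = 3L,
                           diploids_per_population = c(12L, 15L, 10L),
                           alleles_per_population = c(5L, 6L, 4L))
  g <- simulate_genotypes(simulate_allele_pools(cfg), cfg)
  m <- pairwise_differentiation(g, statistic = "d", estimator = "naive")
  expect_identical(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 3), populations(g)))
  expect_true(all(m >= 0 & m <= 1 + 1e-12))
  # pair value equals the two-deme statistic computed directly
  c1 <- allele_counts(g, "Pop1", "DAB"); c2 <- allele_counts(g, "Pop2", "DAB")
  d12 <- jost_d(diversity_components(list(c1, c2), "naive"))
  expect_equal(m["Pop1", "Pop2"], d12)
})

test_that("supertype pooling composes with the differentiation estimator", {
  cfg <- simulation_config(seed = 4L, n_populations = 3L,
                           diploids_per_population = c(12L, 15L, 10L),
                           alleles_per_population = c(5L, 6L, 4L))
  g <- simulate_genotypes(simulate_allele_pools(cfg), cfg)
  alleles <- sort(unique(c(g$allele_a, g$allele_b)))
  map <- setNames(rep(c("ST1", "ST2"), length.out = length(alleles)), alleles)
  m <- pairwise_differentiation(g, statistic = "d", estimator = "naive",
                                supertypes = map)
  # oracle: pool counts through the map, then run the plain estimator
  pool <- function(pop) {
    cc <- allele_counts(g, pop, "DAB")
    tapply(cc, map[names(cc)], sum)
  }
  d12 <- jost_d(diversity_components(list(pool("Pop1"), pool("Pop2")),
                                     "naive"))
  expect_equal(m["Pop1", "Pop2"], d12)
})

test_that("mantel_test r equals the direct Pearson correlation", {
  set.seed(11)
  labs <- paste0("P", 1:6)
  mk <- function() {
    v <- matrix(0, 6, 6, dimnames = list(labs, labs))
    v[upper.tri(v)] <- runif(15)
    v + t(v)
  }
  m1 <- mk(); m2 <- mk()
  mt <- mantel_test(m1, m2, reps = 199, seed = 1)
  expect_equal(mt$r, cor(m1[upper.tri(m1)], m2[upper.tri(m2)]))
})

test_that("mantel_test agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  labs <- paste0("P", 1:7)
  mk <- function(base) {
    v <- matrix(0, 7, 7, dimnames = list(labs, labs))
    v[upper.tri(v)] <- base + runif(21)
    v + t(v)
  }
  m1 <- mk(0); m2 <- 0.8 * m1 + mk(0.1) * 0.2
  mt <- mantel_test(m1, m2, reps = 999, seed = 2)
  vg <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 999)
  expect_equal(mt$r, unname(vg$statistic))
  # both tests should call this strong association significant
  expect_lt(mt$p_value, 0.05)
  expect_lt(vg$signif, 0.05)
})

test_that("mantel_test is invariant to a common label permutation", {
  set.seed(13)
  labs <- paste0("P", 1:6)
  v <- matrix(0, 6, 6, dimnames = list(labs, labs))
  v[upper.tri(v)] <- runif(15)
  m1 <- v + t(v)
  w <- matrix(0, 6, 6, dimnames = list(labs, labs))
  w[upper.tri(w)] <- runif(15)
  m2 <- w + t(w)
  perm <- sample(6)
  r1 <- mantel_test(m1, m2, reps = 99, seed = 1)$r
  r2 <- mantel_test(m1[perm, perm], m2[perm, perm], reps = 99, seed = 1)$r
  expect_equal(r1, r2)
  expect_error(mantel_test(m1, m2[perm, perm]), regexp = "labels")
})
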