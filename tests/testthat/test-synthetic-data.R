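test_that("simulation_config validates its invariants", {
  expect_s3_class(simulation_config(seed = 1L), "simulation_config")
  expect_error(simulation_config(n_populations = 2L))  # length mismatch
  expect_error(simulation_config(pool_overlap = 1.5,
                                 n_populations = 2L,
                                 diploids_per_population = c(5L, 5L),
                                 alleles_per_population = c(2L, 2L)))
  expect_error(simulation_config(f_is = -0.1,
                                 n_populations = 2L,
                                 diploids_per_population = c(5L, 5L),
                                 alleles_per_population = c(2L, 2L)))
})

test_that("the full generator is byte-deterministic given a seed", {
  cfg <- simulation_config(seed = 31L, n_populations = 3L,
                           diploids_per_population = c(8L, 9L, 7L),
                           alleles_per_population = c(5L, 6L, 3L))
  p1 <- simulate_allele_pools(cfg); p2 <- simulate_allele_pools(cfg)
  expect_identical(p1, p2)
  g1 <- simulate_genotypes(p1, cfg); g2 <- simulate_genotypes(p2, cfg)
  expect_identical(g1, g2)
  m1 <- simulate_microsatellites(cfg); m2 <- simulate_microsatellites(cfg)
  expect_identical(m1, m2)
  l1 <- simulate_landscape(cfg); l2 <- simulate_landscape(cfg)
  expect_identical(l1, l2)
  # a different seed changes the data
  cfg2 <- cfg; cfg2$seed <- 32L
  expect_false(identical(simulate_allele_pools(cfg2), p1))
})

test_that("allele pools honour counts, ids and overlap settings", {
  cfg <- simulation_config(seed = 33L, n_populations = 3L,
                           diploids_per_population = c(10L, 10L, 10L),
                           alleles_per_population = c(6L, 7L, 4L),
                           pool_overlap = 0)
  pools <- simulate_allele_pools(cfg)
  expect_equal(lengths(pools$pools), c(Pop1 = 6L, Pop2 = 7L, Pop3 = 4L))
  # disjoint pools under zero overlap
  expect_length(intersect(pools$pools$Pop1, pools$pools$Pop2), 0L)
  expect_length(intersect(pools$pools$Pop2, pools$pools$Pop3), 0L)
  # all sequences distinct and translatable
  expect_equal(anyDuplicated(pools$catalog$sequences), 0L)
  expect_s3_class(codon_alignment(pools$catalog), "codon_alignment")
})

test_that("overlapping pools share alleles between neighbours", {
  cfg <- simulation_config(seed = 34L, n_populations = 3L,
                           diploids_per_population = c(10L, 10L, 10L),
                           alleles_per_population = c(8L, 8L, 8L),
                           pool_overlap = 0.5)
  pools <- simulate_allele_pools(cfg)$pools
  expect_gt(length(intersect(pools$Pop1, pools$Pop2)), 0L)
})

test_that("a single-allele pool yields only homozygotes", {
  cfg <- simulation_config(seed = 35L, n_populations = 2L,
                           diploids_per_population = c(12L, 6L),
                           alleles_per_population = c(4L, 1L))
  g <- simulate_genotypes(simulate_allele_pools(cfg), cfg)
  g5 <- g[g$population == "Pop2", ]
  expect_true(all(g5$allele_a == g5$allele_b))
})

test_that("H_E estimates track the generator frequencies", {
  # f_is = 0 so gene copies are iid draws from the true frequencies
  cfg <- simulation_config(seed = 36L, n_populations = 2L,
                           diploids_per_population = c(100L, 100L),
                           alleles_per_population = c(6L, 5L),
                           f_is = 0)
  g <- simulate_genotypes(simulate_allele_pools(cfg), cfg)
  truth <- attr(g, "true_freqs")
  for (pop in populations(g)) {
    cc <- allele_counts(g, pop, "DAB")
    m <- sum(cc)
    p <- truth[[pop]]
    he_true <- 1 - sum(p^2)
    he_hat <- 1 - sum((cc / m)^2)
    # delta-method SE of sum(p_hat^2), plus its O(1/m) small-sample bias
    se <- sqrt(max(4 * (sum(p^3) - sum(p^2)^2) / m, 1e-12))
    bias <- (1 - sum(p^2)) / m
    expect_lt(abs(he_hat - he_true + bias), 3 * se + 3 / m)
  }
})

test_that("microsatellite panels respect the allele range", {
  cfg <- simulation_config(seed = 37L)
  ms <- simulate_microsatellites(cfg)
  loci <- sprintf("ms%02d", 1:9)
  expect_setequal(unique(ms$locus), loci)
  for (loc in loci) {
    k <- length(allele_counts(ms, NULL, loc))
    expect_true(k >= 2L && k <= 5L)
  }
})

test_that("landscape distances are symmetric with an arithmetic diagonal", {
  coords <- data.frame(population = c("A", "B", "C"),
                       lat = c(0, 0, 0), lon = c(0, 1, 2))
  cfg <- simulation_config(seed = 38L, n_populations = 3L,
                           diploids_per_population = c(5L, 5L, 5L),
                           alleles_per_population = c(2L, 2L, 2L),
                           coordinates = coords)
  d <- simulate_landscape(cfg)$distance_km
  expect_identical(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  # equally spaced collinear sites: distances in arithmetic progression
  expect_equal(d["A", "C"], 2 * d["A", "B"], tolerance = 1e-6)
  expect_equal(d["B", "C"], d["A", "B"], tolerance = 1e-6)
})

test_that("derived stage seeds stay below 2^31", {
  for (st in c("tree", "sequences", "pools", "genotypes", "microsat",
               "landscape")) {
    s <- immunopop:::stage_seed(2147483646L, st)
    expect_true(s >= 0 && s < 2^31)
  }
})

test_that("recombinant alleles splice two donors at the breakpoint", {
  cfg <- simulation_config(seed = 39L, n_populations = 2L,
                           diploids_per_population = c(10L, 10L),
                           alleles_per_population = c(8L, 8L),
                           recombination_breakpoint = 108L,
                           n_recombinants = 3L)
  pools <- simulate_allele_pools(cfg)
  expect_equal(anyDuplicated(pools$catalog$sequences), 0L)
  expect_s3_class(codon_alignment(pools$catalog), "codon_alignment")
})
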