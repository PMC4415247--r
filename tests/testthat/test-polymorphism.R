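test_that("heterozygosity and haplotype diversity match hand calculation", {
  g <- otawa_genotypes()
  expect_equal(observed_heterozygosity(g, "Otawa", "DAB"), 2 / 19)
  cc <- allele_counts(g, "Otawa", "DAB")
  p <- cc / sum(cc)
  expect_equal(expected_heterozygosity(cc), 1 - sum(p^2))
  expect_equal(haplotype_diversity(cc), (38 / 37) * (1 - sum(p^2)))
})

test_that("pairwise difference stats match a brute-force oracle", {
  cat0 <- allele_catalog("DAB", c(a = "AAAAAA", b = "AACAAA", c = "CCCAAA"))
  counts <- c(a = 3, b = 2, c = 1)
  st <- pairwise_diff_stats(cat0, counts)
  # brute force over the 6 gene copies
  seqs <- strsplit(c(rep("AAAAAA", 3), rep("AACAAA", 2), "CCCAAA"), "")
  dd <- utils::combn(6, 2, function(ij)
    sum(seqs[[ij[1]]] != seqs[[ij[2]]]))
  expect_equal(st$k, mean(dd))
  expect_equal(st$S, 3L)           # segregating columns 1, 2, 3
  expect_equal(st$pi, mean(dd) / 6)
})

test_that("sites with >50% missing copies are dropped from the length", {
  cat0 <- allele_catalog("DAB", c(a = "AAN", b = "AAN", c = "AAC"))
  counts <- c(a = 1, b = 1, c = 1)
  st <- pairwise_diff_stats(cat0, counts)
  # column 3 has 2/3 missing copies -> L_used = 2
  expect_equal(st$pi, st$k / 2)
})

test_that("rarefaction equals the trivial two-copy case", {
  # g = 2: expected distinct alleles = 1 + P(two copies differ) = 1 + H_E'
  counts <- c(a = 3, b = 1)
  N <- 4
  p_same <- (3 * 2 + 1 * 0) / (N * (N - 1))
  expect_equal(allelic_richness_rarefaction(counts, g = 2),
               2 - p_same)
  expect_equal(allelic_richness_rarefaction(counts, g = 2), 1.5)
})

test_that("rarefaction over a locus list averages per-locus values", {
  l1 <- c(a = 3, b = 1); l2 <- c(x = 2, y = 2)
  expect_equal(allelic_richness_rarefaction(list(l1, l2), g = 2),
               mean(c(allelic_richness_rarefaction(l1, 2),
                      allelic_richness_rarefaction(l2, 2))))
})

test_that("rarefaction errors when g exceeds the copies", {
  expect_error(allelic_richness_rarefaction(c(a = 2, b = 1), g = 4),
               regexp = "exceeds")
})

test_that("permutation CI is deterministic and covers the pool size", {
  pooled <- c(a = 20, b = 10, c = 6, d = 2)
  ci1 <- allele_count_ci_permutation(pooled, n_pop = 8, reps = 2000, seed = 5)
  ci2 <- allele_count_ci_permutation(pooled, n_pop = 8, reps = 2000, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(ci1[["low"]] >= 1 && ci1[["high"]] <= 4)
  expect_true(ci1[["low"]] <= ci1[["high"]])
  # drawing every copy recovers every allele exactly
  ci_all <- allele_count_ci_permutation(pooled, n_pop = 19, reps = 200,
                                        seed = 1)
  expect_identical(unname(ci_all), c(4L, 4L))
})

test_that("HWE exact test is exact on small enumerable cases", {
  # 3 alleles, 6 diploids
  geno <- matrix(0L, 3, 3)
  geno[1, 1] <- 2L; geno[2, 2] <- 1L
  geno[1, 2] <- 1L; geno[1, 3] <- 1L; geno[2, 3] <- 1L
  expect_equal(hwe_exact_test(geno = geno), oracle_hwe_global(geno))

  geno2 <- matrix(0L, 2, 2)
  geno2[1, 1] <- 3L; geno2[2, 2] <- 1L; geno2[1, 2] <- 1L
  expect_equal(hwe_exact_test(geno = geno2), oracle_hwe_global(geno2))
})

test_that("Monte-Carlo HWE agrees with enumeration", {
  geno <- matrix(0L, 3, 3)
  geno[1, 1] <- 4L; geno[2, 2] <- 3L
  geno[1, 2] <- 2L; geno[1, 3] <- 3L; geno[2, 3] <- 1L
  p_enum <- hwe_exact_test(geno = geno)
  p_mc <- hwe_exact_test(geno = geno, max_configs = 1, reps = 2e5, seed = 3)
  expect_lt(abs(p_enum - p_mc), 0.01)
  ph_enum <- hwe_exact_test(geno = geno, alternative = "het_deficit")
  ph_mc <- hwe_exact_test(geno = geno, alternative = "het_deficit",
                          max_configs = 1, reps = 2e5, seed = 3)
  expect_lt(abs(ph_enum - ph_mc), 0.01)
})

test_that("HWE het-deficit flags an all-homozygote multiallelic sample", {
  geno <- diag(c(5L, 5L, 5L))
  p <- hwe_exact_test(geno = geno, alternative = "het_deficit")
  expect_lt(p, 0.001)
  # monomorphic locus is always in equilibrium
  expect_equal(hwe_exact_test(geno = matrix(10L, 1, 1)), 1)
})

test_that("genotypic LD test detects complete association, not independence", {
  n <- 30L
  recs <- rbind(
    data.frame(sample_id = sprintf("s%02d", 1:n), population = "P",
               locus = "L1",
               allele_a = rep(c("a", "b"), each = n / 2),
               allele_b = rep(c("a", "b"), each = n / 2)),
    data.frame(sample_id = sprintf("s%02d", 1:n), population = "P",
               locus = "L2",
               allele_a = rep(c("x", "y"), each = n / 2),
               allele_b = rep(c("x", "y"), each = n / 2)))
  g <- population_genotypes(recs)
  expect_lt(genotypic_ld_test(g, "L1", "L2", reps = 499, seed = 2),
            0.01)
  # shuffled second locus: no association expected
  set.seed(9)
  recs2 <- recs
  swap <- sample(n)
  l2 <- recs2$locus == "L2"
  recs2$allele_a[l2] <- recs2$allele_a[l2][swap]
  recs2$allele_b[l2] <- recs2$allele_b[l2][swap]
  g2 <- population_genotypes(recs2)
  expect_gt(genotypic_ld_test(g2, "L1", "L2", reps = 499, seed = 2),
            0.05)
})

test_that("holm_bonferroni equals stats::p.adjust and is monotone", {
  p <- c(0.01, 0.02, 0.04, 0.4, 0.9)
  expect_identical(holm_bonferroni(p), stats::p.adjust(p, "holm"))
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_error(holm_bonferroni(c(0.5, 1.2)))
})

test_that("richness regression reproduces lm and rejects degenerate input", {
  x <- c(2.33, 2.28, 2.49, 1.72, 1.11)
  y <- c(14, 18.7, 19.6, 10.4, 2)
  r <- richness_regression(x, y)
  fit <- summary(lm(y ~ x))$coefficients
  expect_equal(r$slope, unname(fit["x", "Estimate"]))
  expect_equal(r$p_value, unname(fit["x", "Pr(>|t|)"]))
  expect_error(richness_regression(rep(1, 5), y), regexp = "variance")
  expect_error(richness_regression(x[1:2], y[1:2]))
})

test_that("polymorphism_summary assembles the per-population table", {
  g <- otawa_genotypes()
  tab <- polymorphism_summary(g, "DAB", catalog = otawa_catalog(),
                              ci_reps = 500, seed = 1)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$N, 19L)
  expect_equal(tab$A, 2)
  expect_equal(tab$H_O, 2 / 19)
  expect_equal(tab$S, 23L)
  expect_true(all(c("A_R", "Hd", "pi", "k") %in% names(tab)))
})
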