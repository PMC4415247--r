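test_that("allele_catalog validates alphabet, lengths and codon structure", {
  expect_s3_class(allele_catalog("DAB", c(a1 = "ACGT", a2 = "AC-T")),
                  "allele_catalog")
  expect_error(allele_catalog("DAB", c(a1 = "ACGT", a2 = "ACG")),
               regexp = "length")
  expect_error(allele_catalog("DAB", c(a1 = "ACGX")))
  expect_error(allele_catalog("DAB", c(a1 = "ACGT", a1 = "ACGT")),
               regexp = "unique")
  expect_error(allele_catalog("DAB", c("ACGT")), regexp = "named")
  # codon mode: length divisible by 3 and no internal stop codons
  expect_s3_class(allele_catalog("DAB", c(a1 = "ATGAAA"), codon_mode = TRUE),
                  "allele_catalog")
  expect_error(allele_catalog("DAB", c(a1 = "ATGA"), codon_mode = TRUE))
})

test_that("population_genotypes rejects duplicate (sample, locus) records", {
  recs <- data.frame(sample_id = c("s1", "s1"), population = "P",
                     locus = "DAB", allele_a = "x", allele_b = "x")
  expect_error(population_genotypes(recs), regexp = "duplicate")
})

test_that("population_genotypes validates allele ids against the catalog", {
  cat2 <- allele_catalog("DAB", c(x = "ACGT", y = "AGGT"))
  ok <- data.frame(sample_id = "s1", population = "P", locus = "DAB",
                   allele_a = "x", allele_b = "y")
  expect_s3_class(population_genotypes(ok, catalog = cat2),
                  "population_genotypes")
  bad <- ok; bad$allele_b <- "zz"
  expect_error(population_genotypes(bad, catalog = cat2))
})

test_that("allele_counts excludes records with any missing allele", {
  recs <- data.frame(sample_id = c("s1", "s2", "s3"), population = "P",
                     locus = "DAB",
                     allele_a = c("x", "x", NA),
                     allele_b = c("y", NA, "y"))
  g <- population_genotypes(recs)
  cc <- allele_counts(g, "P", "DAB")
  expect_equal(sum(cc), 2L)  # only the fully typed s1 contributes 2 copies
  expect_equal(as.vector(cc[c("x", "y")]), c(1L, 1L))
})

test_that("clone validation applies the two-independent-reactions rule", {
  obs <- clone_table(data.frame(
    sample_id = c("f1", "f1", "f1", "f2", "f2", "f3"),
    pcr_replicate = c(1L, 2L, 1L, 1L, 1L, 1L),
    clone_sequence_id = c("A", "A", "B", "B", "C", "C")))
  v <- validate_clone_genotypes(obs, population = "P")
  # A: f1 reps 1+2 = 2 reactions; B: f1 rep1 + f2 rep1 = 2 reactions;
  # C: f2 rep1 + f3 rep1 = 2 reactions -> all accepted
  expect_equal(v$accepted_alleles, c("A", "B", "C"))
  gf1 <- v$genotypes[v$genotypes$sample_id == "f1", ]
  expect_equal(sort(c(gf1$allele_a, gf1$allele_b)), c("A", "B"))
  gf3 <- v$genotypes[v$genotypes$sample_id == "f3", ]
  expect_equal(c(gf3$allele_a, gf3$allele_b), c("C", "C"))  # homozygote
})

test_that("a variant seen in only one PCR reaction is not accepted", {
  obs <- clone_table(data.frame(
    sample_id = c("f1", "f1", "f1"),
    pcr_replicate = c(1L, 1L, 2L),
    clone_sequence_id = c("A", "art", "A")))
  v <- validate_clone_genotypes(obs)
  expect_equal(v$accepted_alleles, "A")
  expect_equal(nrow(v$genotypes), 1L)  # f1 becomes an A homozygote
})

test_that("clone validation is order-independent and flags excess alleles", {
  obs <- data.frame(
    sample_id = c("f1", "f1", "f1", "f2", "f2", "f2"),
    pcr_replicate = c(1L, 1L, 2L, 1L, 2L, 2L),
    clone_sequence_id = c("A", "B", "C", "A", "B", "C"))
  v1 <- validate_clone_genotypes(clone_table(obs))
  v2 <- validate_clone_genotypes(clone_table(obs[sample(nrow(obs)), ]))
  expect_identical(v1$accepted_alleles, v2$accepted_alleles)
  # both individuals carry 3 accepted alleles -> rejected
  expect_setequal(v1$rejected_samples, c("f1", "f2"))
  expect_identical(v1$rejected_samples, v2$rejected_samples)
})

test_that("FASTA and genotype tables round-trip", {
  cat0 <- otawa_catalog()
  fa <- tempfile(fileext = ".fasta")
  write_allele_fasta(cat0, fa)
  cat1 <- read_allele_fasta(fa, locus_name = "DAB")
  expect_identical(cat1$sequences, cat0$sequences)

  g0 <- otawa_genotypes()
  tsv <- tempfile(fileext = ".tsv")
  write_genotype_table(g0, tsv)
  g1 <- read_genotype_table(tsv)
  expect_identical(g1$allele_a, g0$allele_a)
  expect_identical(g1$allele_b, g0$allele_b)
})

test_that("genotype tables round-trip missing calls as '.'", {
  recs <- data.frame(sample_id = c("s1", "s2"), population = "P",
                     locus = "DAB", allele_a = c("x", NA),
                     allele_b = c("y", "y"))
  g0 <- population_genotypes(recs)
  tsv <- tempfile(fileext = ".tsv")
  write_genotype_table(g0, tsv)
  expect_true(any(grepl("\\.", readLines(tsv))))
  g1 <- read_genotype_table(tsv)
  expect_true(is.na(g1$allele_a[g1$sample_id == "s2"]))
})

test_that("labelled matrices round-trip bit-exactly", {
  set.seed(1)
  v <- matrix(0, 4, 4, dimnames = list(paste0("P", 1:4), paste0("P", 1:4)))
  v[upper.tri(v)] <- runif(6) / 3
  v <- v + t(v)
  v[1, 2] <- v[2, 1] <- NA
  m <- labeled_matrix(v)
  f <- tempfile(fileext = ".tsv")
  write_matrix(m, f)
  m2 <- read_matrix(f)
  expect_identical(m2, m)
})

test_that("labeled_matrix rejects asymmetry and nonzero diagonals", {
  m <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(labeled_matrix(m))
  m2 <- matrix(c(1, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(labeled_matrix(m2))
})

test_that("selection tables validate models and evidence", {
  rows <- data.frame(site = 1L, model = "SLAC",
                     statistic_name = "normalized_dn_ds",
                     statistic_value = 2.0, evidence_kind = "p_value",
                     evidence_value = 0.01)
  expect_s3_class(site_selection_table(rows), "site_selection_table")
  bad <- rows; bad$model <- "FUBAR"
  expect_error(site_selection_table(bad), regexp = "model")
  bad2 <- rows; bad2$evidence_value <- 1.2
  expect_error(site_selection_table(bad2), regexp = "p-values")
  expect_error(site_selection_table(rows, protein_length = 0L))
})

test_that("the bundled DAB selection table loads", {
  tab <- read_selection_table(dab_selection_example())
  expect_s3_class(tab, "site_selection_table")
  expect_setequal(unique(tab$model), c("SLAC", "REL", "MEME"))
  expect_equal(nrow(tab), 34L)
})
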