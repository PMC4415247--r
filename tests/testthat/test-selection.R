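test_that("Fitch parsimony counts site changes on a hand tree", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # one synonymous change (TTT -> TTC on B's branch)
  f1 <- immunopop:::fitch_site_changes(
    tree, c(A = "TTT", B = "TTC", C = "TTT", D = "TTT"))
  expect_equal(f1$Sd, 1); expect_equal(f1$Nd, 0)
  # one nonsynonymous change (TTT Phe -> TTA Leu)
  f2 <- immunopop:::fitch_site_changes(
    tree, c(A = "TTT", B = "TTA", C = "TTT", D = "TTT"))
  expect_equal(f2$Sd, 0); expect_equal(f2$Nd, 1)
  # two clades fixed for different codons: exactly one change in between
  f3 <- immunopop:::fitch_site_changes(
    tree, c(A = "TTT", B = "TTT", C = "TTC", D = "TTC"))
  expect_equal(f3$n_changes, 1L)
  expect_equal(f3$Sd, 1)
  # constant or gapped sites produce no changes
  f4 <- immunopop:::fitch_site_changes(
    tree, c(A = "TTT", B = "TTT", C = "---", D = "TTT"))
  expect_equal(f4$n_changes, 0L)
})

test_that("slac_sites returns a coherent per-codon table", {
  cat1 <- one_tree_catalog(101L, n_tips = 12L, n_codons = 30L)
  sl <- slac_sites(cat1)
  expect_equal(sl$site, 1:30)
  expect_true(all(sl$Sd >= 0 & sl$Nd >= 0))
  expect_true(all(sl$p_value >= 0 & sl$p_value <= 1))
  # sites that admit no synonymous change have expected proportion 1
  expect_true(all(sl$expected_nonsyn_prop > 0 &
                    sl$expected_nonsyn_prop <= 1))
  # the binomial evidence: a site whose changes are all nonsynonymous
  # against a neutral expectation of ~2/3 nonsynonymous needs >= 9 changes
  # before the two-tailed test can reject at 0.05
  p9 <- binom.test(9, 9, p = 2 / 3)$p.value
  expect_lt(p9, 0.05)
  # rows convert to a valid selection table
  rows <- slac_to_selection_rows(sl)
  expect_s3_class(rows, "site_selection_table")
  expect_true(all(rows$model == "SLAC"))
})

test_that("sbp_scan recovers a constructed breakpoint and reports AICc", {
  ct <- two_tree_catalog(7L)
  sc <- sbp_scan(ct)
  expect_true(sc$supported)
  expect_gt(sc$delta_aicc, 0)
  expect_lt(abs(sc$best_position - 108L), 15L)
  # candidates respect the flank rule (alignment is 219 nt)
  expect_true(all(sc$candidates$position >= 20L &
                    sc$candidates$position <= 219L - 20L))
})

test_that("sbp_scan does not support a breakpoint on clonal data", {
  ct <- one_tree_catalog(207L)
  sc <- sbp_scan(ct)
  expect_false(sc$supported)
})

test_that("consensus rule applies strict thresholds and >=2 models", {
  rows <- site_selection_table(data.frame(
    site = c(5L, 5L, 7L, 7L, 9L, 9L, 11L),
    model = c("SLAC", "MEME", "SLAC", "REL", "REL", "MEME", "MEME"),
    statistic_name = "s", statistic_value = 1,
    evidence_kind = c("p_value", "p_value", "p_value", "bayes_factor",
                      "bayes_factor", "p_value", "p_value"),
    evidence_value = c(0.01, 0.02,      # site 5: two models significant
                       0.05, 100,       # site 7: both exactly AT threshold
                       150, 0.003,      # site 9: two models significant
                       0.001)))         # site 11: one model only
  out <- consensus_selected_sites(rows)
  expect_equal(as.integer(out), c(5L, 9L))
  # thresholds are strict: p = 0.05 and BF = 100 do not qualify
  flags <- attr(out, "flags")
  expect_false(7L %in% flags$site)
  # min_models = 1 admits the MEME-only site
  out1 <- consensus_selected_sites(rows, min_models = 1L)
  expect_equal(as.integer(out1), c(5L, 9L, 11L))
})

test_that("the bundled DAB table yields the 11 consensus residues", {
  tab <- read_selection_table(dab_selection_example())
  sites <- consensus_selected_sites(tab)
  expect_equal(as.integer(sites),
               c(2L, 11L, 23L, 32L, 42L, 52L, 55L, 59L, 63L, 71L, 72L))
  # MEME alone flags 16 residues (the single-model re-analysis)
  meme <- consensus_selected_sites(tab, min_models = 1L)
  meme_only <- attr(meme, "flags")
  expect_equal(sum(meme_only$MEME), 16L)
})

test_that("slac_sites honours a recombination breakpoint", {
  ct <- two_tree_catalog(8L)
  sc <- sbp_scan(ct)
  expect_true(sc$supported)
  sl <- slac_sites(ct, breakpoint = sc$best_position)
  expect_equal(nrow(sl), 73L)
  expect_true(all(is.finite(sl$p_value)))
})
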