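# Shared fixtures and independent oracles used across the test files.

# ---- Otawa worked example -------------------------------------------------
# One deme of 19 diploids at a two-allele sequence locus: 2 heterozygotes
# A*73/A*74 and 17 homozygotes A*74/A*74; the two 219-column alleles differ
# at 23 sites.
otawa_catalog <- function() {
  s1 <- strrep("A", 219L)
  s2 <- s1
  diff_at <- seq(5L, by = 9L, length.out = 23L)
  for (p in diff_at) substr(s2, p, p) <- "C"
  allele_catalog("DAB", c("A*73" = s1, "A*74" = s2))
}

otawa_genotypes <- function() {
  recs <- data.frame(
    sample_id = sprintf("Ot_%02d", 1:19),
    population = "Otawa",
    locus = "DAB",
    allele_a = c(rep("A*73", 2L), rep("A*74", 17L)),
    allele_b = "A*74")
  population_genotypes(recs, populations = "Otawa")
}

# ---- exhaustive rarefaction oracle ---------------------------------------
# Expected number of distinct alleles over ALL size-g subsets of the pooled
# gene copies (feasible for small totals).
oracle_rarefaction <- function(counts, g) {
  pool <- rep(seq_along(counts), counts)
  idx <- utils::combn(length(pool), g)
  mean(apply(idx, 2L, function(ii) length(unique(pool[ii]))))
}

# ---- exact HWE oracle by enumeration of labelled pairings ----------------
# Enumerates every perfect pairing of the 2n labelled gene copies (the
# conditional null of the exact test), aggregates pairings into genotype
# tables, and computes the global p-value as the probability mass of all
# tables no more probable than the observed one.
oracle_hwe_global <- function(geno) {
  K <- nrow(geno)
  counts <- vapply(seq_len(K), function(i)
    2L * geno[i, i] + sum(geno[i, seq_len(K) > i]) +
      sum(geno[seq_len(K) < i, i]), integer(1L))
  copies <- rep(seq_len(K), counts)

  tables <- new.env(parent = emptyenv())
  key_of <- function(tab) paste(tab, collapse = ",")
  recurse <- function(rest, tab) {
    if (!length(rest)) {
      k <- key_of(tab)
      assign(k, (if (exists(k, tables)) get(k, tables) else 0) + 1, tables)
      return(invisible())
    }
    a <- rest[1L]
    rest <- rest[-1L]
    for (j in seq_along(rest)) {
      b <- rest[j]
      t2 <- tab
      i1 <- min(a, b); i2 <- max(a, b)
      t2[(i2 - 1L) * K + i1] <- t2[(i2 - 1L) * K + i1] + 1L
      recurse(rest[-j], t2)
    }
  }
  recurse(copies, integer(K * K))
  keys <- ls(tables)
  n_pair <- vapply(keys, get, numeric(1L), envir = tables)
  probs <- n_pair / sum(n_pair)

  obs <- integer(K * K)
  for (i in seq_len(K)) for (j in i:K)
    obs[(j - 1L) * K + i] <- geno[i, j]
  p_obs <- probs[match(key_of(obs), keys)]
  sum(probs[probs <= p_obs + 1e-12])
}

# ---- synthetic alignments for recombination tests ------------------------
two_tree_catalog <- function(seed, n_tips = 20L, codons_left = 36L,
                             codons_right = 37L, div = 0.15) {
  t1 <- immunopop:::yule_tree(n_tips, div, seed)
  t2 <- immunopop:::yule_tree(n_tips, div, seed + 50000L)
  t2$tip.label <- immunopop:::with_seed(seed + 90000L, sample(t1$tip.label))
  s1 <- simulate_codon_sequences(t1, codons_left, seed = seed + 1L)
  s2 <- simulate_codon_sequences(t2, codons_right, seed = seed + 2L)
  seqs <- paste0(s1[t1$tip.label], s2[t1$tip.label])
  allele_catalog("DAB", stats::setNames(seqs, t1$tip.label),
                 codon_mode = TRUE)
}

one_tree_catalog <- function(seed, n_tips = 20L, n_codons = 73L,
                             div = 0.15) {
  t1 <- immunopop:::yule_tree(n_tips, div, seed)
  s1 <- simulate_codon_sequences(t1, n_codons, seed = seed + 1L)
  allele_catalog("DAB", s1[t1$tip.label], codon_mode = TRUE)
}
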