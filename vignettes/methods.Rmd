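---
title: "Statistical methods in immunopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in immunopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the estimators and algorithms implemented in
`immunopop`, the rationale for each modelling choice, and the power
properties of the selection tests under the package's default study
conditions. Equations use $n$ for the number of diploids, $m = 2n$ for
gene copies, and $p_i$ for allele frequencies.

## 1. Polymorphism statistics

**Heterozygosity.** Observed heterozygosity $H_O$ is the fraction of typed
diploids carrying two distinct alleles. Expected heterozygosity is
reported in two conventions, because both circulate in the empirical
literature for hyperpolymorphic loci:

- uncorrected (gene diversity): $H_E = 1 - \sum_i p_i^2$;
- haplotype diversity with the small-sample correction:
  $Hd = \frac{m}{m-1}\left(1 - \sum_i p_i^2\right)$
  (`haplotype_diversity()` uses gene copies, matching sequence-based
  reporting).

For the bundled 19-diploid worked example (2 heterozygotes of 19, a
36:2 allele count) these give $H_O = 2/19 = 0.105$, $H_E = 0.100$ and
$Hd = 0.102$ — three numerically close quantities that are *not*
interchangeable and are therefore kept as separate functions.

**Sequence diversity.** With an `allele_catalog` attached,
`pairwise_diff_stats()` computes the number of segregating sites $S$, the
mean number of pairwise differences $k$ (averaged over all pairs of gene
copies, weighted by allele counts) and nucleotide diversity
$\pi = k / L_{\text{eff}}$ on the compared columns. Columns with more than
50% missing data are excluded from the comparison.

**Rarefaction allelic richness.** The expected number of distinct alleles
in a subsample of $g$ gene copies drawn without replacement:
$$A_R(g) = \sum_i \left[ 1 - \binom{m - m_i}{g} \Big/ \binom{m}{g} \right],$$
computed with log-binomials for stability. A list of per-locus count
vectors is averaged, giving multilocus rarefied richness. The test suite
checks this against exhaustive enumeration of every size-$g$ subset for
small totals. Permutation confidence intervals for the allele count at a
standard sample size (`allele_count_ci_permutation()`) resample genotypes
without replacement and report type-1 (inverted ECDF) quantiles, so the
bounds are always achievable integer counts.

**Exact Hardy–Weinberg test.** `hwe_exact_test()` works on the conditional
(Levene) distribution of genotype tables given the observed allele counts,
$$\Pr(\text{table}) = \frac{n!\,\prod_i c_i!\; 2^{h}}{(2n)!\,\prod_{i \le j} g_{ij}!},$$
with $h$ the number of heterozygotes. When a cheap upper bound on the
number of tables (each heterozygote cell $(i,j)$ takes at most
$\min(c_i, c_j) + 1$ values) is below `max_configs`, the distribution is
enumerated in full; otherwise the test draws configurations from the exact
null by randomly re-pairing the $2n$ gene copies into diploids
(a vectorised Monte-Carlo with $(1 + \text{hits})/(\text{reps} + 1)$
p-values). The `global` alternative sums the probability of all tables no
more probable than the observed one; `het_deficit` is the one-sided test
against heterozygote deficit (inbreeding, null alleles). The suite
verifies the enumeration against an independent oracle that enumerates all
labelled perfect pairings, verifies Monte-Carlo against enumeration, and
checks the realised type-I error near 5% under random mating.

**Genotypic linkage disequilibrium.** `genotypic_ld_test()` permutes the
genotype pairing between two loci across shared samples and compares a
contingency G-statistic on joint genotype classes, the standard
permutation approach when phase is unknown.

**Multiple testing.** `holm_bonferroni()` is sequential Holm correction
(a thin wrapper so the workflow's correction step is explicit and tested).

**Richness regression.** `richness_regression()` is ordinary least squares
of immune-locus rarefied richness on neutral rarefied richness with the
usual $t$ test on the slope ($n - 2$ df). With only a handful of demes
this is deliberately simple; it refuses degenerate inputs (fewer than 3
points, zero predictor variance).

## 2. Differentiation

High within-deme diversity caps $G_{ST}$ well below 1, so the package
centres on two diversity-robust statistics computed from
`diversity_components()` ($H_S$, $H_T$ over $d$ demes, demes weighted
equally):

- Hedrick's $G'_{ST} = G_{ST} / G_{ST,\max}$ with
  $G_{ST,\max} = \frac{(d-1)(1-H_S)}{d-1+H_S}$;
- Jost's $D = \frac{d}{d-1} \cdot \frac{H_T - H_S}{1 - H_S}$.

Both equal 1 for fully disjoint allele pools and 0 for identical ones; the
naive estimator reproduces these bounds *exactly*, which the acceptance
suite exploits. The bias-corrected estimator applies Nei–Chesser
corrections ($\tilde N$ the harmonic mean sample size):
$\hat H_S = \frac{\tilde N}{\tilde N - 1} H_S$ and
$\hat H_T = H_T + \hat H_S / (2 \tilde N d)$; corrected estimates can
stray slightly outside $[0, 1]$ by sampling noise, which is expected
behaviour, not an error. Multilocus statistics combine per-locus
components arithmetically (or harmonically for $D$, both conventions are
available). Supplying a supertype map pools allele counts into supertype
counts before estimation, giving functional-category differentiation with
the same estimators.

**Mantel tests.** `mantel_test()` correlates the upper triangles of two
labelled distance matrices and permutes deme labels of one matrix;
p-values are $(1 + \text{hits})/(\text{reps} + 1)$. The suite checks $r$
against the direct Pearson correlation and against `vegan::mantel()`.

## 3. Codon-level selection

**Nei–Gojobori counting.** `neigojobori_pair()` implements the 1986
pathway-counting method: synonymous site counts per codon are the expected
fraction of neutral one-step changes that are synonymous (stop codons
excluded from the neighbourhood), and multi-step codon differences average
the synonymous/nonsynonymous split over all orderings of the mutational
pathway (pathways through stop codons are dropped). Proportions are
Jukes–Cantor corrected into $d_N$ and $d_S$.

**Global Z test.** `codon_z_test()` averages $d_N - d_S$ over all sequence
pairs and estimates its standard error by bootstrap over codon sites; the
one-tailed test asks whether $d_N$ exceeds $d_S$ overall.

*Power at the default study conditions.* With 11 selected codons out of
73 and moderate divergence, the global Z test is structurally
underpowered: the bootstrap SE has a floor set by resampling the handful
of signal codons, so the realised Z rarely clears 1.64 even when selection
is real (observed power ≈ 0.4 at the generator defaults, rising to ~1
only when most codons are selected). This is a property of the test, not
of the implementation — the package therefore treats the global Z as a
coarse summary and relies on per-site methods plus the consensus rule for
site-level inference. The tests assert the achievable properties: correct
sign and high power under strong, widespread selection; negative
$d_N - d_S$ on synonymous-only alignments.

**Single-breakpoint recombination scan.** `sbp_scan()` compares a
single-tree model against all two-tree models split at a variable column
with at least `min_flank` columns on each side. Trees are neighbour
joining on Jukes–Cantor distances; each segment's Jukes–Cantor likelihood
is evaluated on its own tree by the pruning algorithm, and models are
compared by small-sample AICc (parameters = branch count per tree + one
rate; $n$ = alignment columns). NJ/JC is an approximation to full ML tree
search chosen for speed and determinism; adequacy is demonstrated by
property tests: the scan recovers a constructed breakpoint within ±15 nt
in ≥ 90% of seeded two-tree simulations and stays unsupported in ≥ 90% of
single-tree simulations.

**SLAC-style per-site counting.** For each codon site,
`slac_sites()` reconstructs ancestral codons by Fitch parsimony on the NJ
tree (ties resolved towards the parent state, then minimal nonsynonymous
cost, then lexicographic — a deterministic rule), counts synonymous and
nonsynonymous changes over branches, and tests the nonsynonymous fraction
against the site's neutral expectation with a **two-tailed** binomial
test. Two-tailed is deliberate: the same machinery flags positive
(excess nonsynonymous) and purifying (excess synonymous) sites, and a
one-tailed convention would make the reported p-values incomparable
across the two directions. Under a supported breakpoint, each codon is
assigned to the left segment iff its last nucleotide position
$3c - 1 \le b$, and changes are counted on that segment's tree.

**Multi-model consensus.** `consensus_selected_sites()` ingests a tidy
per-site table of SLAC/REL/MEME statistics and flags a site when at least
`min_models` methods individually support it under strict thresholds
(SLAC $p < 0.05$, REL Bayes factor $> 100$, MEME $p < 0.05$; boundary
values do not qualify). On the bundled example table this yields exactly
11 residues.

## 4. Supertyping

`encode_z_descriptors()` maps each allele to the concatenated Sandberg
five-descriptor z-scales of its amino acids at the positively selected
sites only (gaps encode as zero vectors — "no side chain information").
`dapc_cluster()` then follows the discriminant-analysis-of-principal-
components convention for choosing the number of clusters: PCA retaining
`variance_retained` (default 95%) of the variance, k-means for each
candidate $k$, and
$$\mathrm{BIC}(k) = n \ln(W_k / n) + k \ln n$$
with $W_k$ the total within-cluster sum of squares; the chosen $k$ is the
*smallest* one within `delta_bic` (default 2) of the minimum, a
parsimony-first reading of the usual elbow rule. Seeded multi-start
k-means makes the procedure deterministic. Supertype assignments feed back
into `supertype_frequencies()` and supertype-level differentiation.

## 5. Synthetic data

The generator produces data with the structure the analyses assume: a
phylogeny of alleles (Yule process, exponential branch lengths scaled to a
target mean pairwise divergence), codon sequences evolved along it,
overlapping per-deme allele pools of prescribed sizes, diploid genotypes
with an inbreeding coefficient, a neutral microsatellite panel with
Dirichlet frequency drift (optionally sequential along a deme chain to
create isolation by distance), and a noisy geographic transect.

**Mutation model.** Point mutations are proposed uniformly along the
sequence; a synonymous proposal is accepted with constant probability
$1/(1+\omega_{\max})$ (synonymous change is neutral at every codon) and a
nonsynonymous proposal at codon $i$ with probability
$\omega_i/(1+\omega_{\max})$. Selected codons therefore evolve faster and
almost exclusively by amino-acid replacement, while the synonymous rate
is uniform across the gene — the signature per-site counting methods look
for. The proposal intensity is rescaled by the expected acceptance rate
(~75% of uniform point mutations are nonsynonymous) so that branch
lengths remain expected substitutions per site; realised mean pairwise
divergence matches the target to within a few percent.

**Determinism.** A single root seed derives independent substreams per
stage via a hash, so adding a stage never perturbs earlier streams, and
identical configurations give byte-identical outputs — the property the
pipeline inherits.

**Parameter recovery.** The suite checks that per-deme $H_E$ estimates
fall within three binomial standard errors of the generator expectations
(after the $O(1/m)$ plug-in bias), that zero-drift microsatellite panels
give $|D| < 0.05$ at large $N$, and that $D$ increases monotonically with
drift.

## 6. Pipeline

`run_pipeline()` executes the stages in dependency order — data
(simulation block or input files), polymorphism + HWE, richness
regression, allele- and microsatellite-level differentiation, selection
(Z, breakpoint scan, per-site counting, consensus), supertyping,
supertype-level differentiation, and Mantel isolation-by-distance — and
writes TSV tables, a frequency chart, `pipeline.log` and `report.json`.
Stages with missing inputs are skipped with a logged warning and appear
as explicit nulls in the report. Log lines carry no timestamps in the
stored report, so reruns of one configuration are byte-identical. All
thresholds (SLAC p, REL BF, MEME p, minimum models, ΔBIC, variance
retained) and replicate counts live in the configuration with the
conventional defaults (0.05 / 100 / 0.05 / 2 / 2.0 / 0.95).

## 7. Limitations

- NJ/JC trees approximate ML phylogenies; fine-grained branch-length
  effects on per-site counts are not modelled.
- The microsatellite generator does not implement stepwise mutation; it
  targets frequency structure, not mutation-model realism.
- The global Z test is reported for completeness but is underpowered at
  realistic fractions of selected codons (see §3); site-level consensus
  is the intended inference path.
- The exact HWE Monte-Carlo p-value is itself an estimate; replicate
  counts are configurable where precision matters.
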