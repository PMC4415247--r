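# Codon-level tests for positive selection and recombination.

# ---- shared helpers -------------------------------------------------------

# lowercase character matrix of an alignment, rows = alleles
alignment_char_matrix <- function(catalog) {
  m <- seq_matrix(catalog)
  matrix(tolower(m), nrow = nrow(m), dimnames = dimnames(m))
}

# neighbor-joining tree on Jukes-Cantor distances for a column subset
nj_jc_tree <- function(dna, idx) {
  d <- ape::dist.dna(dna[, idx, drop = FALSE], model = "JC69",
                     pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) {
    cap <- max(dm[is.finite(dm)], 0.1)
    dm[!is.finite(dm)] <- 2 * cap
    d <- stats::as.dist(dm)
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  tr
}

# Jukes-Cantor log-likelihood of a column subset on a fixed tree
# (Felsenstein pruning, via phangorn)
segment_loglik <- function(phy, idx, tree) {
  sub <- subset(phy, select = idx, site.pattern = FALSE)
  as.numeric(phangorn::pml(tree, sub)$logLik)
}

aicc <- function(loglik, k, n) {
  pen <- if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
  -2 * loglik + 2 * k + pen
}

variable_columns <- function(m) {
  which(apply(m, 2L, function(col) {
    obs <- col[!(col %in% c("-", "n", "N"))]
    length(unique(obs)) >= 2L
  }))
}

# ---- global Z test --------------------------------------------------------

# per-pair, per-codon Nei-Gojobori contributions for fast bootstrapping
pairwise_ng_tables <- function(codons) {
  n <- nrow(codons)
  C <- ncol(codons)
  valid <- matrix(is_valid_codon(codons), n, C)
  sfrac <- matrix(syn_site_fraction(codons), n, C)
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  SD <- ND <- SS <- NS <- matrix(0, np, C)
  for (p in seq_len(np)) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    ok <- valid[i, ] & valid[j, ]
    SS[p, ok] <- (sfrac[i, ok] + sfrac[j, ok]) / 2
    NS[p, ok] <- 3 - SS[p, ok]
    for (c in which(ok)) {
      ch <- codon_pair_changes(codons[i, c], codons[j, c])
      SD[p, c] <- ch[["sd"]]; ND[p, c] <- ch[["nd"]]
    }
  }
  list(SD = SD, ND = ND, SS = SS, NS = NS)
}

#' Codon-based Z test for positive selection
#'
#' Global Nei-Gojobori test over all sequence pairs: `dN` and `dS` are the
#' mean pairwise proportions of nonsynonymous and synonymous differences,
#' the standard error of `dN - dS` comes from a bootstrap over codon sites,
#' and the one-tailed p-value tests `dN > dS` (positive selection).
#'
#' @param catalog A codon-mode [allele_catalog()], or a [codon_alignment()].
#' @param reps Bootstrap replicates over codon sites (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return List with `dN`, `dS`, `dN_minus_dS`, `SE`, `Z` and `p_one_tailed`.
#' @export
codon_z_test <- function(catalog, reps = 1000L, seed = 1L) {
  ca <- if (inherits(catalog, "codon_alignment")) catalog
        else codon_alignment(catalog)
  if (nrow(ca$codons) < 3L) stop("need at least 3 sequences")
  tb <- pairwise_ng_tables(ca$codons)
  stat <- function(idx) {
    ss <- rowSums(tb$SS[, idx, drop = FALSE])
    ns <- rowSums(tb$NS[, idx, drop = FALSE])
    sd <- rowSums(tb$SD[, idx, drop = FALSE])
    nd <- rowSums(tb$ND[, idx, drop = FALSE])
    use <- ss > 0 & ns > 0
    c(dN = mean(nd[use] / ns[use]), dS = mean(sd[use] / ss[use]))
  }
  obs <- stat(seq_len(ca$n_codons))
  D <- obs[["dN"]] - obs[["dS"]]
  boot <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- sample.int(ca$n_codons, replace = TRUE)
      s <- stat(idx)
      s[["dN"]] - s[["dS"]]
    }, numeric(1L))
  })
  se <- stats::sd(boot, na.rm = TRUE)
  z <- if (se > 0) D / se else NA_real_
  list(dN = obs[["dN"]], dS = obs[["dS"]], dN_minus_dS = D, SE = se, Z = z,
       p_one_tailed = if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE))
}

# ---- single-breakpoint recombination scan ---------------------------------

#' Single-breakpoint recombination scan by small-sample AIC
#'
#' Tests whether the alignment is better explained by two phylogenies — one
#' left and one right of a breakpoint — than by a single tree. Every
#' variable column with at least `min_flank` columns on each side is a
#' candidate; for each, neighbor-joining trees (Jukes-Cantor distances) are
#' fit to the two segments and each segment's Jukes-Cantor log-likelihood on
#' its own tree is scored by the pruning algorithm. Models are compared by
#' AICc (parameters = branch count per tree, plus one overall rate;
#' sample size = alignment columns).
#'
#' @param catalog An [allele_catalog()] (>= 4 sequences, >= 60 columns).
#' @param min_flank Minimum columns on each side of a candidate (default 20).
#' @return List with `best_position` (last nucleotide column of the left
#'   segment), `delta_aicc` (single-tree AICc minus best two-tree AICc),
#'   `supported` (`delta_aicc > 0`) and the scanned `candidates` data frame.
#' @export
sbp_scan <- function(catalog, min_flank = 20L) {
  m <- alignment_char_matrix(catalog)
  if (nrow(m) < 4L) stop("need at least 4 sequences")
  L <- ncol(m)
  if (L < 60L) stop("need at least 60 alignment columns")
  dna <- ape::as.DNAbin(m)
  phy <- phangorn::phyDat(m, type = "DNA")
  ntip <- nrow(m)
  b_per_tree <- 2L * ntip - 3L

  vc <- variable_columns(m)
  cand <- vc[vc >= min_flank & vc <= L - min_flank]
  no_support <- list(best_position = NA_integer_, delta_aicc = 0,
                     supported = FALSE,
                     candidates = data.frame(position = integer(0),
                                             delta_aicc = numeric(0)))
  if (length(cand) < 1L || length(vc) < 2L) return(no_support)

  tree_all <- nj_jc_tree(dna, seq_len(L))
  ll_all <- segment_loglik(phy, seq_len(L), tree_all)
  aicc_single <- aicc(ll_all, b_per_tree + 1L, L)

  deltas <- vapply(cand, function(b) {
    left <- seq_len(b); right <- (b + 1L):L
    ll <- segment_loglik(phy, left, nj_jc_tree(dna, left)) +
          segment_loglik(phy, right, nj_jc_tree(dna, right))
    aicc_single - aicc(ll, 2L * b_per_tree + 1L, L)
  }, numeric(1L))

  best <- which.max(deltas)
  list(best_position = as.integer(cand[best]),
       delta_aicc = deltas[best],
       supported = deltas[best] > 0,
       candidates = data.frame(position = as.integer(cand),
                               delta_aicc = deltas))
}

# ---- SLAC-style per-site counting -----------------------------------------

# Fitch parsimony codon reconstruction at one codon site on one tree.
# Returns list(Sd, Nd, n_changes) summed over branches. Ties resolved by
# preferring the parent state, then the candidate minimizing the
# nonsynonymous cost of the step, then lexicographic order.
fitch_site_changes <- function(tree, tip_codons) {
  states <- sort(unique(tip_codons[is_valid_codon(tip_codons)]))
  if (length(states) <= 1L) return(list(Sd = 0, Nd = 0, n_changes = 0L))
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  sets <- vector("list", nnode)
  for (t in seq_len(ntip)) {
    cd <- tip_codons[match(tree$tip.label[t], names(tip_codons))]
    sets[[t]] <- if (is_valid_codon(cd)) cd else states  # wildcard tip
  }
  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- split(po[, 2L], po[, 1L])
  for (node in unique(po[, 1L])) {
    ch_sets <- lapply(kids[[as.character(node)]], function(k) sets[[k]])
    cur <- ch_sets[[1L]]
    for (s2 in ch_sets[-1L]) {
      inter <- intersect(cur, s2)
      cur <- if (length(inter)) inter else union(cur, s2)
    }
    sets[[node]] <- sort(cur)
  }
  # preorder assignment
  assign_state <- numeric(0)
  state <- character(nnode)
  root <- ntip + 1L
  state[root] <- sets[[root]][1L]
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  pick <- function(candidates, parent_state) {
    if (parent_state %in% candidates) return(parent_state)
    nd_cost <- vapply(candidates, function(cd)
      codon_pair_changes(parent_state, cd)[["nd"]], numeric(1L))
    candidates[order(nd_cost, candidates)][1L]
  }
  for (r in seq_len(nrow(pre))) {
    parent <- pre[r, 1L]; child <- pre[r, 2L]
    state[child] <- pick(sets[[child]], state[parent])
  }
  Sd <- 0; Nd <- 0; n_changes <- 0L
  for (r in seq_len(nrow(edge))) {
    a <- state[edge[r, 1L]]; b <- state[edge[r, 2L]]
    if (a == b) next
    # skip branches into wildcard tips that merely echo ambiguity
    ch <- codon_pair_changes(a, b)
    Sd <- Sd + ch[["sd"]]; Nd <- Nd + ch[["nd"]]
    n_changes <- n_changes + 1L
  }
  list(Sd = Sd, Nd = Nd, n_changes = n_changes)
}

#' Counting-based per-site selection test (SLAC style)
#'
#' Reconstructs ancestral codons on a neighbor-joining tree by Fitch
#' parsimony, counts synonymous and nonsynonymous changes per codon over all
#' branches, and tests the observed nonsynonymous count against its neutral
#' expectation (the Nei-Gojobori nonsynonymous site fraction at that codon)
#' with a two-tailed binomial test. When a supported recombination
#' breakpoint is supplied, separate trees are fit left and right of it and
#' each codon is counted on its own segment's tree.
#'
#' @param catalog A codon-mode [allele_catalog()].
#' @param breakpoint Optional nucleotide column of a supported breakpoint
#'   (e.g. `sbp_scan()$best_position`).
#' @return Data frame with one row per codon: `site`, `Sd`, `Nd`,
#'   `expected_nonsyn_prop`, `normalized_dn_ds`, `p_value`.
#' @export
slac_sites <- function(catalog, breakpoint = NULL) {
  ca <- codon_alignment(catalog)
  if (nrow(ca$codons) < 4L) stop("need at least 4 sequences")
  m <- alignment_char_matrix(catalog)
  dna <- ape::as.DNAbin(m)
  L <- ncol(m)
  if (is.null(breakpoint)) {
    trees <- list(nj_jc_tree(dna, seq_len(L)))
    segment_of <- rep(1L, ca$n_codons)
  } else {
    stopifnot(breakpoint >= 1L, breakpoint < L)
    trees <- list(nj_jc_tree(dna, seq_len(breakpoint)),
                  nj_jc_tree(dna, (breakpoint + 1L):L))
    # a codon belongs to the segment holding >= 2 of its 3 positions
    segment_of <- ifelse(3L * seq_len(ca$n_codons) - 1L <= breakpoint, 1L, 2L)
  }
  tree_len <- vapply(trees, function(tr) sum(tr$edge.length), numeric(1L))
  rows <- lapply(seq_len(ca$n_codons), function(site) {
    tips <- stats::setNames(ca$codons[, site], rownames(ca$codons))
    sfrac <- syn_site_fraction(tips)
    s_bar <- mean(sfrac, na.rm = TRUE)
    if (!is.finite(s_bar)) s_bar <- 0
    p_nonsyn <- 1 - s_bar / 3
    seg <- segment_of[site]
    fs <- fitch_site_changes(trees[[seg]], tips)
    total <- fs$Sd + fs$Nd
    if (total <= 0) {
      return(data.frame(site = site, Sd = 0, Nd = 0,
                        expected_nonsyn_prop = p_nonsyn,
                        normalized_dn_ds = 0, p_value = 1))
    }
    n_tot <- max(1L, round(total))
    n_nonsyn <- min(n_tot, round(fs$Nd))
    p <- stats::binom.test(n_nonsyn, n_tot, p = p_nonsyn,
                           alternative = "two.sided")$p.value
    dn <- if (3 - s_bar > 0) fs$Nd / (3 - s_bar) else 0
    ds <- if (s_bar > 0) fs$Sd / s_bar else 0
    data.frame(site = site, Sd = fs$Sd, Nd = fs$Nd,
               expected_nonsyn_prop = p_nonsyn,
               normalized_dn_ds = (dn - ds) / tree_len[seg],
               p_value = p)
  })
  do.call(rbind, rows)
}

# ---- consensus combiner ----------------------------------------------------

#' Consensus positively selected sites across selection models
#'
#' A site is flagged per model when its evidence passes that model's
#' threshold (p-value below `slac_p`/`meme_p` for SLAC/MEME, Bayes factor
#' above `rel_bf` for REL); the consensus set keeps sites flagged by at
#' least `min_models` models.
#'
#' @param table A [site_selection_table()] holding rows from one or more
#'   models (SLAC rows may also come from [slac_sites()] via
#'   [slac_to_selection_rows()]).
#' @param slac_p,meme_p P-value thresholds (default 0.05).
#' @param rel_bf REL Bayes-factor threshold (default 100).
#' @param min_models Minimum number of flagging models (default 2).
#' @return Sorted integer vector of consensus site positions, with the
#'   per-model flag table in attribute `"flags"`.
#' @export
consensus_selected_sites <- function(table, slac_p = 0.05, rel_bf = 100,
                                     meme_p = 0.05, min_models = 2L) {
  stopifnot(inherits(table, "site_selection_table"))
  flag <- function(model, kind, thr, below) {
    rows <- table[table$model == model & table$evidence_kind == kind, ]
    if (below) unique(rows$site[rows$evidence_value < thr])
    else unique(rows$site[rows$evidence_value > thr])
  }
  flagged <- list(SLAC = flag("SLAC", "p_value", slac_p, TRUE),
                  REL = flag("REL", "bayes_factor", rel_bf, FALSE),
                  MEME = flag("MEME", "p_value", meme_p, TRUE))
  sites <- sort(unique(unlist(flagged)))
  n_models <- vapply(sites, function(s)
    sum(vapply(flagged, function(f) s %in% f, logical(1L))), integer(1L))
  out <- sites[n_models >= min_models]
  attr(out, "flags") <- data.frame(
    site = sites, n_models = n_models,
    SLAC = sites %in% flagged$SLAC, REL = sites %in% flagged$REL,
    MEME = sites %in% flagged$MEME)
  out
}

#' Convert a SLAC result frame into selection-table rows
#'
#' @param slac Output of [slac_sites()].
#' @return A [site_selection_table()] with model `"SLAC"`.
#' @export
slac_to_selection_rows <- function(slac) {
  site_selection_table(data.frame(
    site = slac$site, model = "SLAC",
    statistic_name = "normalized_dn_ds",
    statistic_value = slac$normalized_dn_ds,
    evidence_kind = "p_value", evidence_value = slac$p_value))
}
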