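# Seeded generators for synthetic data sets with the population structure
# the analyses assume: a handful of demes with nearly disjoint pools of
# hyperpolymorphic coding alleles, a low-diversity microsatellite panel,
# optional inbreeding (heterozygote deficit) and optional recombination.

# independent substream per generator stage, so adding a stage never
# perturbs the streams of earlier stages
stage_seed <- function(seed, stage) {
  offsets <- c(tree = 11L, sequences = 23L, pools = 37L, genotypes = 53L,
               microsat = 71L, landscape = 89L)
  as.integer((as.numeric(seed) * 10007 + offsets[[stage]]) %% 2147483587)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' emulate the structure of a five-deme study of a hyperpolymorphic MHC
#' class II locus: diploid sample sizes 18-41, per-deme allele pools of
#' 2-29 alleles with ~4% sharing between adjacent demes, 72-73 codon
#' alleles with a set of positively selected residues, strong heterozygote
#' deficit at the MHC locus, and nine neutral microsatellite loci with 2-5
#' alleles each.
#'
#' @param seed Root RNG seed; all stages derive independent substreams.
#' @param n_populations Number of demes.
#' @param diploids_per_population Integer vector of diploid sample sizes.
#' @param alleles_per_population Pool size (distinct alleles) per deme.
#' @param pool_overlap Fraction of the smaller adjacent pool shared between
#'   neighbouring demes (0 = fully disjoint pools).
#' @param freq_concentration Dirichlet concentration for within-deme allele
#'   frequencies (values < 1 give skewed frequencies).
#' @param f_is Within-deme inbreeding coefficient for the coding locus
#'   (0 = Hardy-Weinberg sampling).
#' @param n_codons Codons per allele sequence.
#' @param selected_codons Codon positions under positive selection.
#' @param omega_selected dN/dS target at selected codons.
#' @param neutral_omega dN/dS at all other codons.
#' @param mean_pairwise_subst Target mean pairwise substitutions per site on
#'   the allele genealogy (controls sequence divergence).
#' @param recombination_breakpoint Optional nucleotide position at which
#'   recombinant alleles are spliced; `NULL` for none.
#' @param n_recombinants Number of pool alleles replaced by splices of two
#'   donor alleles (only used with a breakpoint).
#' @param n_microsat_loci Number of microsatellite loci.
#' @param microsat_alleles_range Length-2 range of allele counts per
#'   microsatellite locus.
#' @param microsat_drift Dirichlet concentration scale tying per-deme
#'   microsatellite frequencies to the shared base frequencies (larger =
#'   less drift).
#' @param microsat_f_is Inbreeding coefficient for microsatellite sampling.
#' @param ibd_chain If `TRUE`, microsatellite frequencies drift along the
#'   deme chain (neighbouring demes most similar), producing an
#'   isolation-by-distance signal on a transect landscape.
#' @param coordinates Optional data frame `population`, `lat`, `lon`.
#' @param locus_name Name of the coding locus (default `"DAB"`).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_populations = 5L,
                              diploids_per_population = c(18L, 41L, 22L, 21L, 19L),
                              alleles_per_population = c(14L, 29L, 21L, 11L, 2L),
                              pool_overlap = 0.04,
                              freq_concentration = 1,
                              f_is = 0.5,
                              n_codons = 73L,
                              selected_codons = c(2L, 11L, 23L, 32L, 42L,
                                                  52L, 55L, 59L, 63L, 71L, 72L),
                              omega_selected = 5,
                              neutral_omega = 1,
                              mean_pairwise_subst = 0.09,
                              recombination_breakpoint = NULL,
                              n_recombinants = 0L,
                              n_microsat_loci = 9L,
                              microsat_alleles_range = c(2L, 5L),
                              microsat_drift = 30,
                              microsat_f_is = 0,
                              ibd_chain = FALSE,
                              coordinates = NULL,
                              locus_name = "DAB") {
  cfg <- as.list(environment())
  stopifnot(length(cfg$diploids_per_population) == cfg$n_populations,
            length(cfg$alleles_per_population) == cfg$n_populations,
            all(cfg$diploids_per_population >= 1L),
            all(cfg$alleles_per_population >= 1L),
            cfg$pool_overlap >= 0, cfg$pool_overlap <= 1,
            cfg$f_is >= 0, cfg$f_is <= 1,
            cfg$n_codons >= 1L)
  cfg$population_names <- paste0("Pop", seq_len(cfg$n_populations))
  class(cfg) <- "simulation_config"
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

random_root_codons <- function(n_codons) {
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  sample(sense, n_codons, replace = TRUE)
}

# Evolve a codon sequence along one branch. Point mutations are proposed
# uniformly; a nonsynonymous proposal at codon i is accepted with
# probability proportional to omega_i, a synonymous one with a constant
# probability (synonymous change is neutral at every codon), both scaled by
# a common 1/(1 + omega_max) so probabilities stay in [0, 1]. Codons with
# omega > 1 therefore evolve faster and almost exclusively by amino-acid
# change, the signature of positive selection. `proposal_scale` compensates
# the mean acceptance rate so `length_per_site` remains the expected number
# of substitutions per site.
mutate_along_branch <- function(codons, length_per_site, omega_of,
                                omega_max, proposal_scale) {
  L <- 3L * length(codons)
  n_prop <- stats::rpois(1L, proposal_scale * length_per_site * L)
  gc <- genetic_code()
  nt <- c("A", "C", "G", "T")
  for (m in seq_len(n_prop)) {
    pos <- sample.int(L, 1L)
    ci <- (pos - 1L) %/% 3L + 1L
    within <- pos - 3L * (ci - 1L)
    old_codon <- codons[ci]
    base <- substr(old_codon, within, within)
    new_base <- sample(setdiff(nt, base), 1L)
    new_codon <- old_codon
    substr(new_codon, within, within) <- new_base
    if (gc[new_codon] == "*") next
    syn <- gc[new_codon] == gc[old_codon]
    p_acc <- if (syn) 1 / (1 + omega_max) else omega_of(ci) / (1 + omega_max)
    if (stats::runif(1L) < p_acc) codons[ci] <- new_codon
  }
  codons
}

#' Simulate codon sequences along a phylogeny
#'
#' Evolves a random stop-free codon sequence along the given tree with
#' per-codon dN/dS classes: nonsynonymous proposals at codon i are accepted
#' with probability proportional to that codon's omega, synonymous
#' proposals with a constant (neutral) probability, so the synonymous rate
#' is uniform across codons while selected codons (`omega_selected`) evolve
#' faster and mostly by amino-acid replacement. The proposal intensity is
#' rescaled so branch lengths remain expected substitutions per site.
#'
#' @param tree An `ape::phylo` tree whose tips name the alleles.
#' @param n_codons Number of codons.
#' @param selected_codons Positions under positive selection.
#' @param omega_selected,neutral_omega dN/dS targets.
#' @param seed RNG seed.
#' @param root_codons Optional fixed root sequence (codon vector).
#' @return Named character vector of nucleotide sequences (tips).
#' @export
simulate_codon_sequences <- function(tree, n_codons,
                                     selected_codons = integer(0),
                                     omega_selected = 5, neutral_omega = 1,
                                     seed = 1L, root_codons = NULL) {
  with_seed(seed, {
    if (is.null(root_codons)) root_codons <- random_root_codons(n_codons)
    omega_of <- function(ci)
      if (ci %in% selected_codons) omega_selected else neutral_omega
    omega_max <- max(omega_selected, neutral_omega, 1)
    # calibrate the proposal intensity so that accepted changes per site
    # match the branch length: ~75% of uniform point mutations are
    # nonsynonymous, ~25% synonymous, and the 1.25 factor absorbs
    # stop-codon rejections and multiple hits (matches a rate of 2.5
    # proposals per target substitution in the all-neutral case)
    n_sel <- sum(selected_codons >= 1L & selected_codons <= n_codons)
    omega_bar <- (n_sel * omega_selected +
                    (n_codons - n_sel) * neutral_omega) / n_codons
    expected_acc <- (0.75 * omega_bar + 0.25) / (1 + omega_max)
    proposal_scale <- 1.25 / expected_acc
    ntip <- length(tree$tip.label)
    nnode <- max(tree$edge)
    seqs <- vector("list", nnode)
    root <- ntip + 1L
    seqs[[root]] <- root_codons
    pre <- ape::reorder.phylo(tree, "postorder")$edge
    pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]
    el <- tree$edge.length[match(paste(pre[, 1L], pre[, 2L]),
                                 paste(tree$edge[, 1L], tree$edge[, 2L]))]
    for (r in seq_len(nrow(pre))) {
      seqs[[pre[r, 2L]]] <- mutate_along_branch(seqs[[pre[r, 1L]]],
                                                el[r], omega_of,
                                                omega_max, proposal_scale)
    }
    stats::setNames(vapply(seq_len(ntip),
                           function(t) paste(seqs[[t]], collapse = ""),
                           character(1L)),
                    tree$tip.label)
  })
}

# Yule tree rescaled so the mean pairwise path length is `target`
yule_tree <- function(n_tips, target, seed) {
  with_seed(seed, {
    tr <- if (n_tips == 2L) {
      ape::read.tree(text = "(t1:1,t2:1);")
    } else ape::rphylo(n_tips, birth = 1, death = 0)
    d <- stats::cophenetic(tr)
    mean_d <- mean(d[upper.tri(d)])
    tr$edge.length <- tr$edge.length * target / mean_d
    tr
  })
}

#' Simulate per-deme pools of coding alleles
#'
#' Draws an allele genealogy (Yule tree rescaled to the target divergence),
#' evolves codon sequences along it with the configured selection classes,
#' optionally splices recombinant alleles at the configured breakpoint, and
#' assigns alleles to demes so that adjacent demes share the configured
#' fraction of their smaller pool.
#'
#' @param config A [simulation_config()].
#' @return List with `catalog` (an [allele_catalog()], codon mode) and
#'   `pools` (named list, allele ids per deme).
#' @export
simulate_allele_pools <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  a <- config$alleles_per_population
  np <- config$n_populations
  shared <- if (np > 1L)
    vapply(seq_len(np - 1L), function(i)
      as.integer(round(config$pool_overlap * min(a[i], a[i + 1L]))),
      integer(1L))
  else integer(0)
  n_new <- c(a[1L], if (np > 1L) a[-1L] - shared)
  if (any(n_new < 0L)) stop("pool_overlap too large for the pool sizes")
  n_total <- sum(n_new)
  max_seqs <- 61^min(config$n_codons, 10L)  # loose bound on distinct sequences
  if (n_total > max_seqs)
    stop("requested alleles exceed achievable distinct sequences")

  ids <- sprintf("%s*%02d", config$locus_name, seq_len(n_total))
  tree <- yule_tree(max(n_total, 2L), config$mean_pairwise_subst,
                    stage_seed(config$seed, "tree"))
  tree$tip.label <- c(ids, if (n_total < 2L) "unused")[seq_along(tree$tip.label)]
  seqs <- simulate_codon_sequences(
    tree, config$n_codons, config$selected_codons, config$omega_selected,
    config$neutral_omega, seed = stage_seed(config$seed, "sequences"))
  seqs <- seqs[ids]

  with_seed(stage_seed(config$seed, "pools"), {
    # enforce distinct sequences by extra point substitutions on duplicates
    gc <- genetic_code()
    nt <- c("A", "C", "G", "T")
    tries <- 0L
    while (anyDuplicated(seqs)) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop("requested alleles exceed achievable distinct sequences")
      dup <- which(duplicated(seqs))[1L]
      s <- seqs[[dup]]
      pos <- sample.int(nchar(s), 1L)
      base <- substr(s, pos, pos)
      new_base <- sample(setdiff(nt, base), 1L)
      s2 <- s
      substr(s2, pos, pos) <- new_base
      ci <- (pos - 1L) %/% 3L + 1L
      codon <- substr(s2, 3L * ci - 2L, 3L * ci)
      if (gc[codon] == "*") next
      seqs[dup] <- s2
    }

    # deme pools with the configured adjacent-pool sharing
    pools <- vector("list", np)
    names(pools) <- config$population_names
    next_new <- 1L
    for (i in seq_len(np)) {
      fresh <- ids[seq.int(next_new, length.out = n_new[i])]
      next_new <- next_new + n_new[i]
      carried <- if (i > 1L && shared[i - 1L] > 0L)
        sample(pools[[i - 1L]], shared[i - 1L]) else character(0)
      pools[[i]] <- c(carried, fresh)
    }

    # optional recombinant alleles: splice two donors at the breakpoint
    if (!is.null(config$recombination_breakpoint) &&
        config$n_recombinants > 0L) {
      bp <- config$recombination_breakpoint
      stopifnot(bp >= 1L, bp < 3L * config$n_codons)
      victims <- sample(ids, min(config$n_recombinants, n_total))
      for (v in victims) {
        donors <- sample(setdiff(ids, v), 2L)
        cand <- paste0(substr(seqs[[donors[1L]]], 1L, bp),
                       substr(seqs[[donors[2L]]], bp + 1L, nchar(seqs[[v]])))
        aa <- translate_codon(substring(cand, 3L * seq_len(config$n_codons) - 2L,
                                        3L * seq_len(config$n_codons)))
        if (any(aa == "*") || cand %in% seqs) next
        seqs[v] <- cand
      }
    }
    list(catalog = allele_catalog(config$locus_name, seqs, codon_mode = TRUE),
         pools = pools)
  })
}

#' Simulate diploid genotypes at the coding locus
#'
#' Per deme, allele frequencies are drawn from a symmetric Dirichlet over
#' the deme's pool and `N` diploids are sampled with inbreeding coefficient
#' `f_is`: a homozygote `ii` occurs with probability
#' `f_is * p_i + (1 - f_is) * p_i^2` and a heterozygote `ij` with
#' `(1 - f_is) * 2 p_i p_j`.
#'
#' @param pools Named list of per-deme allele id pools
#'   (from [simulate_allele_pools()]).
#' @param config A [simulation_config()].
#' @return A [population_genotypes()] object; the drawn per-deme frequency
#'   vectors are attached as attribute `"true_freqs"`.
#' @export
simulate_genotypes <- function(pools, config) {
  stopifnot(inherits(config, "simulation_config"))
  # accept the full simulate_allele_pools() result as a convenience
  if (!is.null(pools$pools) && is.list(pools$pools)) pools <- pools$pools
  with_seed(stage_seed(config$seed, "genotypes"), {
    recs <- list(); freqs <- list()
    for (i in seq_along(pools)) {
      pop <- names(pools)[i]
      pool <- pools[[i]]
      p <- rdirichlet1(rep(config$freq_concentration, length(pool)))
      names(p) <- pool
      freqs[[pop]] <- p
      N <- config$diploids_per_population[i]
      for (s in seq_len(N)) {
        if (stats::runif(1L) < config$f_is) {
          al <- sample(pool, 1L, prob = p)
          ab <- c(al, al)
        } else {
          ab <- sample(pool, 2L, replace = TRUE, prob = p)
        }
        recs[[length(recs) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%03d", pop, s), population = pop,
          locus = config$locus_name,
          allele_a = ab[1L], allele_b = ab[2L])
      }
    }
    out <- population_genotypes(do.call(rbind, recs),
                                populations = names(pools))
    attr(out, "true_freqs") <- freqs
    out
  })
}

#' Simulate a neutral microsatellite panel
#'
#' Independent loci with a shared allele set across demes; per-deme
#' frequencies are Dirichlet draws around common base frequencies (or, with
#' `ibd_chain = TRUE`, drift sequentially along the deme chain so that
#' neighbouring demes are most similar). Genotypes are sampled with
#' inbreeding coefficient `microsat_f_is`.
#'
#' @param config A [simulation_config()].
#' @param drift Overrides `config$microsat_drift` (Dirichlet concentration
#'   scale; larger = weaker drift).
#' @return A [population_genotypes()] object with loci `ms01`, `ms02`, ...;
#'   true per-deme frequencies attached as attribute `"true_freqs"`.
#' @export
simulate_microsatellites <- function(config, drift = config$microsat_drift) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(stage_seed(config$seed, "microsat"), {
    pops <- config$population_names
    recs <- list(); freqs <- list()
    for (l in seq_len(config$n_microsat_loci)) {
      loc <- sprintf("ms%02d", l)
      k <- sample(seq(config$microsat_alleles_range[1L],
                      config$microsat_alleles_range[2L]), 1L)
      alleles <- as.character(100L + 2L * seq_len(k))
      base <- rdirichlet1(rep(2, k))
      pf <- list()
      prev <- base
      for (i in seq_along(pops)) {
        anchor <- if (config$ibd_chain) prev else base
        p <- rdirichlet1(pmax(anchor * drift, 1e-6))
        names(p) <- alleles
        pf[[pops[i]]] <- p
        prev <- p
      }
      freqs[[loc]] <- pf
      for (i in seq_along(pops)) {
        p <- pf[[pops[i]]]
        for (s in seq_len(config$diploids_per_population[i])) {
          if (stats::runif(1L) < config$microsat_f_is) {
            al <- sample(alleles, 1L, prob = p)
            ab <- c(al, al)
          } else {
            ab <- sample(alleles, 2L, replace = TRUE, prob = p)
          }
          recs[[length(recs) + 1L]] <- data.frame(
            sample_id = sprintf("%s_%03d", pops[i], s),
            population = pops[i], locus = loc,
            allele_a = ab[1L], allele_b = ab[2L])
        }
      }
    }
    out <- population_genotypes(do.call(rbind, recs), populations = pops)
    attr(out, "true_freqs") <- freqs
    out
  })
}

#' Simulate sampling-site coordinates and geographic distances
#'
#' Places the demes along a noisy transect inside a bounded region and
#' returns great-circle distances in kilometres, so chain-drifted
#' microsatellites (see [simulate_microsatellites()]) show isolation by
#' distance.
#'
#' @param config A [simulation_config()] (needs >= 3 demes unless explicit
#'   coordinates are supplied).
#' @return List with `coordinates` (data frame `population`, `lat`, `lon`)
#'   and `distance_km` (labelled symmetric matrix).
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  coords <- config$coordinates
  if (is.null(coords)) {
    if (config$n_populations < 3L) stop("need at least 3 demes")
    coords <- with_seed(stage_seed(config$seed, "landscape"), {
      t_axis <- seq(0, 1, length.out = config$n_populations)
      data.frame(population = config$population_names,
                 lat = -38.2 + 1.6 * t_axis + stats::rnorm(config$n_populations, 0, 0.05),
                 lon = 175.2 + 2.4 * t_axis + stats::rnorm(config$n_populations, 0, 0.05))
    })
  }
  d <- geographic_distance_km(coords)
  list(coordinates = coords, distance_km = d)
}

#' Great-circle distance matrix from site coordinates
#'
#' @param coords Data frame with columns `population`, `lat`, `lon`
#'   (decimal degrees).
#' @return Labelled symmetric matrix of distances in kilometres.
#' @export
geographic_distance_km <- function(coords) {
  n <- nrow(coords)
  m <- matrix(0, n, n, dimnames = list(coords$population, coords$population))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      m[i, j] <- geosphere::distGeo(c(coords$lon[i], coords$lat[i]),
                                    c(coords$lon[j], coords$lat[j])) / 1000
      m[j, i] <- m[i, j]
    }
  }
  labeled_matrix(m, nonnegative = TRUE)
}
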