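# End-to-end orchestration: simulate or ingest data, then run the
# polymorphism, differentiation, selection, supertyping and
# isolation-by-distance stages and write a machine-readable report.

# retained log lines carry no timestamps so that report.json and
# pipeline.log are byte-identical across reruns with the same seed; the
# timestamped copy goes to the console only
pipeline_log <- function(stage, msg, log_lines) {
  line <- sprintf("%s: %s", stage, msg)
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), line))
  c(log_lines, line)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: data (simulation block or input
#' files), per-population polymorphism summaries and Hardy-Weinberg tests,
#' richness regression, pairwise differentiation at allele and
#' microsatellite level, codon selection tests (global Z, breakpoint scan,
#' per-site counting, multi-model consensus), supertype clustering and
#' supertype-level differentiation, and Mantel isolation-by-distance tests
#' when coordinates are available. Stages whose inputs are absent are
#' skipped with a logged warning and appear as `NULL` in the report.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognised blocks: `seed`, `simulation` (arguments of
#'   [simulation_config()]), `inputs` (`alleles`, `genotypes`,
#'   `microsatellites`, `coordinates`, `selection_tables`), `thresholds`
#'   (`slac_p`, `rel_bf`, `meme_p`, `min_models`, `delta_bic`,
#'   `variance_retained`), `reps` (`ci`, `bootstrap`, `mantel`, `hwe`).
#' @param out_dir Output directory for TSV/JSON artefacts (created if
#'   missing); `NULL` writes nothing.
#' @return The pipeline report (named list), invisibly also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  thr <- utils::modifyList(
    list(slac_p = 0.05, rel_bf = 100, meme_p = 0.05, min_models = 2L,
         delta_bic = 2, variance_retained = 0.95),
    if (is.null(config$thresholds)) list() else config$thresholds)
  reps <- utils::modifyList(
    list(ci = 2000L, bootstrap = 500L, mantel = 999L, hwe = 20000L),
    if (is.null(config$reps)) list() else config$reps)
  log_lines <- character(0)

  # ---- data stage ---------------------------------------------------------
  catalog <- genotypes <- microsat <- coords <- NULL
  ext_tables <- list()
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_args$seed <- seed
    for (f in c("diploids_per_population", "alleles_per_population",
                "selected_codons", "microsat_alleles_range"))
      if (!is.null(sim_args[[f]])) sim_args[[f]] <- as.integer(unlist(sim_args[[f]]))
    scfg <- do.call(simulation_config, sim_args)
    pools <- simulate_allele_pools(scfg)
    catalog <- pools$catalog
    genotypes <- simulate_genotypes(pools$pools, scfg)
    microsat <- simulate_microsatellites(scfg)
    land <- simulate_landscape(scfg)
    coords <- land$coordinates
    log_lines <- pipeline_log("data", sprintf(
      "simulated %d alleles, %d demes (seed %d)",
      length(catalog$sequences), scfg$n_populations, seed), log_lines)
  } else if (!is.null(config$inputs)) {
    ins <- config$inputs
    if (!is.null(ins$alleles))
      catalog <- read_allele_fasta(ins$alleles, codon_mode = TRUE,
                                   locus_name = "DAB")
    if (!is.null(ins$genotypes))
      genotypes <- read_genotype_table(ins$genotypes, catalog = catalog)
    if (!is.null(ins$microsatellites))
      microsat <- read_genotype_table(ins$microsatellites)
    if (!is.null(ins$coordinates))
      coords <- utils::read.delim(ins$coordinates)
    for (p in ins$selection_tables)
      ext_tables[[length(ext_tables) + 1L]] <- read_selection_table(p)
    log_lines <- pipeline_log("data", "loaded input files", log_lines)
  } else stop("config needs a 'simulation' or 'inputs' block")

  if (!is.null(genotypes) && !is.null(microsat)) {
    shared_loci <- intersect(unique(genotypes$locus), unique(microsat$locus))
    if (length(shared_loci))
      stop("inconsistent locus names: ", paste(shared_loci, collapse = ", "),
           " appear in both the coding and microsatellite tables")
  }

  report <- list(metadata = list(
    seed = seed, package_version = as.character(utils::packageVersion("immunopop")),
    thresholds = thr, reps = reps))

  locus <- if (!is.null(catalog)) catalog$locus_name else "DAB"
  pops <- if (!is.null(genotypes)) populations(genotypes) else NULL

  # ---- polymorphism -------------------------------------------------------
  report$polymorphism <- NULL
  if (!is.null(genotypes) && !is.null(catalog)) {
    tab <- polymorphism_summary(genotypes, locus, catalog = catalog,
                                ci_reps = reps$ci, seed = seed)
    hwe <- vapply(pops, function(pop)
      hwe_exact_test(genotypes, pop, locus, alternative = "global",
                     reps = reps$hwe, seed = seed), numeric(1L))
    hwe_def <- vapply(pops, function(pop)
      hwe_exact_test(genotypes, pop, locus, alternative = "het_deficit",
                     reps = reps$hwe, seed = seed), numeric(1L))
    tab$hwe_p_global <- hwe
    tab$hwe_p_het_deficit <- hwe_def
    report$polymorphism <- tab
    log_lines <- pipeline_log("polymorphism", "coding-locus summary done",
                              log_lines)
  }
  report$microsat_polymorphism <- NULL
  if (!is.null(microsat)) {
    ms_loci <- sort(unique(microsat$locus))
    report$microsat_polymorphism <-
      polymorphism_summary(microsat, ms_loci, ci_reps = 0L, seed = seed)
    log_lines <- pipeline_log("polymorphism", "microsatellite summary done",
                              log_lines)
  }
  report$richness_regression <- NULL
  if (!is.null(report$polymorphism) && !is.null(report$microsat_polymorphism)) {
    x <- report$microsat_polymorphism$A_R
    y <- report$polymorphism$A_R
    report$richness_regression <-
      tryCatch(richness_regression(x, y), error = function(e) {
        log_lines <<- pipeline_log("regression", conditionMessage(e), log_lines)
        NULL
      })
  }

  # ---- differentiation ----------------------------------------------------
  report$differentiation <- list()
  if (!is.null(genotypes)) {
    report$differentiation$allele_d <-
      pairwise_differentiation(genotypes, locus, "d")
    report$differentiation$allele_gst_prime <-
      pairwise_differentiation(genotypes, locus, "gst_prime")
    log_lines <- pipeline_log("differentiation", "allele-level done", log_lines)
  }
  if (!is.null(microsat)) {
    ms_loci <- sort(unique(microsat$locus))
    report$differentiation$microsat_d <-
      pairwise_differentiation(microsat, ms_loci, "d")
    report$differentiation$microsat_gst_prime <-
      pairwise_differentiation(microsat, ms_loci, "gst_prime")
    log_lines <- pipeline_log("differentiation", "microsatellite done",
                              log_lines)
  }

  # ---- selection ----------------------------------------------------------
  report$selection <- NULL
  consensus <- integer(0)
  if (!is.null(catalog) && length(catalog$sequences) >= 4L) {
    z <- codon_z_test(catalog, reps = reps$bootstrap, seed = seed)
    bp <- sbp_scan(catalog)
    slac <- slac_sites(catalog,
                       breakpoint = if (bp$supported) bp$best_position)
    tables <- do.call(rbind, c(list(slac_to_selection_rows(slac)),
                               lapply(ext_tables, as.data.frame)))
    tables <- site_selection_table(tables)
    n_models_present <- length(unique(tables$model))
    eff_min <- min(thr$min_models, n_models_present)
    if (eff_min < thr$min_models)
      log_lines <- pipeline_log("selection", sprintf(
        "only %d model(s) available; consensus uses min_models = %d",
        n_models_present, eff_min), log_lines)
    consensus <- consensus_selected_sites(
      tables, slac_p = thr$slac_p, rel_bf = thr$rel_bf, meme_p = thr$meme_p,
      min_models = eff_min)
    report$selection <- list(
      z_test = z,
      breakpoint = bp[c("best_position", "delta_aicc", "supported")],
      slac = slac, consensus_sites = as.integer(consensus))
    log_lines <- pipeline_log("selection", sprintf(
      "Z = %.2f (p = %.3f); %d consensus site(s)", z$Z, z$p_one_tailed,
      length(consensus)), log_lines)
  }

  # ---- supertyping --------------------------------------------------------
  report$supertypes <- NULL
  if (!is.null(catalog) && length(consensus) >= 1L &&
      length(catalog$sequences) >= 2L) {
    enc <- encode_z_descriptors(catalog, consensus)
    model <- dapc_cluster(enc, k_max = min(10L, nrow(enc)),
                          variance_retained = thr$variance_retained,
                          delta_bic = thr$delta_bic, seed = seed)
    st_freq <- if (!is.null(genotypes))
      supertype_frequencies(genotypes, model, locus = locus)
    st_diff <- if (!is.null(genotypes) && model$k >= 1L)
      list(d = pairwise_differentiation(genotypes, locus, "d",
                                        supertypes = model$assignments),
           gst_prime = pairwise_differentiation(genotypes, locus, "gst_prime",
                                                supertypes = model$assignments))
    report$supertypes <- list(
      k = model$k, retained_components = model$retained_components,
      bic_curve = model$bic_curve,
      assignments = as.list(model$assignments),
      frequencies = st_freq, differentiation = st_diff)
    log_lines <- pipeline_log("supertyping", sprintf("k = %d", model$k),
                              log_lines)
  } else if (!is.null(catalog)) {
    log_lines <- pipeline_log("supertyping",
                              "skipped: no consensus sites", log_lines)
  }

  # ---- isolation by distance ----------------------------------------------
  report$mantel <- NULL
  if (!is.null(coords) && !is.null(genotypes)) {
    geo <- geographic_distance_km(coords)
    geo <- geo[pops, pops]
    mt <- list()
    for (nm in names(report$differentiation)) {
      m <- report$differentiation[[nm]]
      if (anyNA(m) || stats::sd(upper_tri_values(m)) == 0) next
      mt[[nm]] <- mantel_test(m, geo, reps = reps$mantel, seed = seed)
    }
    report$mantel <- mt
    log_lines <- pipeline_log("ibd", sprintf("%d Mantel test(s)", length(mt)),
                              log_lines)
  } else {
    log_lines <- pipeline_log("ibd", "skipped: no coordinates", log_lines)
  }

  report$log <- log_lines

  # ---- outputs ------------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_file <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(config, cfg_file)
    report$metadata$config_hash <- unname(tools::md5sum(cfg_file))
    wtab <- function(x, f) if (!is.null(x))
      utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    wtab(report$polymorphism, "table1_coding.tsv")
    wtab(report$microsat_polymorphism, "table1_microsat.tsv")
    for (nm in names(report$differentiation))
      write_matrix(report$differentiation[[nm]],
                   file.path(out_dir, paste0("diff_", nm, ".tsv")))
    if (!is.null(report$selection)) wtab(report$selection$slac,
                                         "selection_sites.tsv")
    if (!is.null(report$supertypes)) {
      wtab(data.frame(allele_id = names(unlist(report$supertypes$assignments)),
                      supertype = unlist(report$supertypes$assignments)),
           "supertypes.tsv")
      wtab(report$supertypes$frequencies, "supertype_frequencies.tsv")
      if (!is.null(report$supertypes$frequencies))
        render_frequency_chart(report$supertypes$frequencies,
                               file.path(out_dir, "supertype_frequencies.png"))
    }
    jsonlite::write_json(serializable_report(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  invisible(report)
}

# matrices -> data frames so the JSON keeps labels
serializable_report <- function(x) {
  if (is.matrix(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, serializable_report))
  x
}

#' Stacked supertype-frequency bar chart
#'
#' @param freq_table Data frame from [supertype_frequencies()].
#' @param path Output image path (extension selects the device).
#' @param width,height Plot size in inches.
#' @return `path`, invisibly.
#' @export
render_frequency_chart <- function(freq_table, path, width = 7, height = 4.5) {
  if (is.null(freq_table) || nrow(freq_table) == 0L)
    stop("empty frequency table")
  p <- ggplot2::ggplot(freq_table,
                       ggplot2::aes(x = population, y = frequency,
                                    fill = supertype)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::labs(x = NULL, y = "Supertype frequency", fill = "Supertype") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}
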