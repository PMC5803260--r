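#' Run the full synthetic analysis pipeline
#'
#' Ties the stages together on synthetic data: genome simulation, coverage
#' simulation for the senataxin-like ChIP (both conditions), RNA PolII and
#' DRIP (both conditions, plus a helicase-knockdown DRIP), per-million
#' normalization, windowed site quantification, cut/uncut tests,
#' transcription stratification, heatmap matrix, averaged profiles,
#' metagene profiles, boxplot summaries, and simulated qPCR assays
#' (resection, repair kinetics, translocation, DRIP-qPCR). Every figure
#' quantity is written as a TSV; a `manifest.json` records the config,
#' seed, package version and output checksums. Given the same config
#' (including its seed), all TSV outputs are byte-identical across runs:
#' every stochastic stage draws from its own seed stream derived via
#' [stage_seed()].
#'
#' @param config A [sim_config()] (or a list of arguments for it).
#' @param out_dir Output directory, created if needed.
#' @param window_halfwidth Half-width in bp of the quantification window
#'   (default 5000: a 10 kb window).
#' @param write_tracks Also write the simulated coverage tracks as
#'   bedGraph (large; off by default).
#' @return Invisibly, a list with the in-memory results (`genome`,
#'   `quant`, `tests`, `stratified`, `heatmap`, `profiles`, `metagene`,
#'   `assays`, `manifest`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         window_halfwidth = 5000, write_tracks = FALSE) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  ok <- FALSE
  written <- character(0)
  on.exit({
    if (!ok) {
      # leave no partial outputs behind on failure
      unlink(written)
    }
  })
  emit <- function(df, name, ...) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                ...)
    written <<- c(written, path)
    path
  }

  genome <- simulate_genome(config)
  gpaths <- write_genome(genome, out_dir)
  written <- c(written, gpaths)

  tracks <- list(
    senataxin_undamaged = simulate_chip_coverage(genome, "senataxin",
                                                 "undamaged"),
    senataxin_damaged = simulate_chip_coverage(genome, "senataxin",
                                               "damaged"),
    polII_total = simulate_chip_coverage(genome, "polII_total",
                                         "undamaged"),
    drip_undamaged = simulate_drip_coverage(genome, "undamaged"),
    drip_damaged = simulate_drip_coverage(genome, "damaged"),
    drip_damaged_setx_kd = simulate_drip_coverage(genome, "damaged",
                                                  senataxin_activity = 0)
  )
  tracks <- lapply(tracks, normalize_track)
  if (write_tracks) {
    for (nm in names(tracks)) {
      p <- file.path(out_dir, paste0(nm, ".bedGraph"))
      write_bedgraph(tracks[[nm]], p)
      written <- c(written, p)
    }
  }

  quant <- quantify_sites(tracks, genome$sites, window_halfwidth, "sum")
  emit(quant, "site_quant.tsv")

  tests <- list(
    senataxin_damaged = compare_cut_uncut(quant, "senataxin_damaged"),
    senataxin_undamaged = compare_cut_uncut(quant, "senataxin_undamaged"),
    drip_damaged = compare_cut_uncut(quant, "drip_damaged"),
    drip_undamaged = compare_cut_uncut(quant, "drip_undamaged")
  )
  test_df <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(comparison = nm, n_cut = t$n_cut, n_uncut = t$n_uncut,
               U = t$statistic, p_value = t$p_value,
               direction = t$direction,
               significant = t$p_value < 0.05)
  }))
  emit(test_df, "cut_uncut_tests.tsv")

  box_df <- do.call(rbind, lapply(names(tests), function(nm) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(flag) {
      cbind(data.frame(column = nm,
                       group = if (flag) "cut" else "uncut"),
            as.data.frame(boxplot_summary(quant[[nm]][quant$cut == flag])))
    }))
  }))
  emit(box_df, "boxplot_summaries.tsv")

  cut_quant <- quant[quant$cut, , drop = FALSE]
  strat <- stratify_by_transcription(cut_quant, "polII_total",
                                     n_classes = 4L)
  emit(strat, "stratified_sites.tsv")
  strat_medians <- stats::aggregate(
    cbind(senataxin_damaged, senataxin_undamaged, polII_total) ~
      transcription_class, data = strat, FUN = median)
  emit(strat_medians, "stratified_medians.tsv")

  hm <- heatmap_matrix(tracks$senataxin_damaged, cut_quant,
                       halfwidth = window_halfwidth, bin_width = 500,
                       ordering = "cleavage_desc")
  hm_df <- data.frame(site_id = rownames(hm$matrix), hm$matrix,
                      check.names = FALSE)
  names(hm_df)[-1] <- paste0("bin_", hm$bin_starts)
  emit(hm_df, "heatmap_senataxin_damaged.tsv")

  prof <- NULL
  for (nm in c("senataxin_undamaged", "senataxin_damaged",
               "drip_undamaged", "drip_damaged", "drip_damaged_setx_kd")) {
    p <- average_profile(tracks[[nm]], cut_quant,
                         halfwidth = window_halfwidth, resolution = 50)
    p$track <- nm
    prof <- rbind(prof, p)
  }
  emit(prof, "average_profiles.tsv")

  near <- genes_near_dsb(genome$genes, genome$sites, max_distance = 1000)
  meta <- withCallingHandlers({
    mg_all <- metagene_profile(tracks$drip_undamaged, genome$genes)
    mg_all$gene_set <- "all"
    mg_all$track <- "drip_undamaged"
    out <- mg_all
    if (nrow(near) > 0) {
      for (nm in c("drip_undamaged", "drip_damaged")) {
        mg <- metagene_profile(tracks[[nm]], near)
        mg$gene_set <- "near_dsb"
        mg$track <- nm
        out <- rbind(out, mg)
      }
    }
    out
  }, message = function(m) invokeRestart("muffleMessage"))
  emit(meta, "metagene_profiles.tsv")

  assays <- simulate_assay_suite(config)
  for (nm in names(assays$tables)) {
    p <- file.path(out_dir, paste0("ct_", nm, ".tsv"))
    write_ct_table(assays$tables[[nm]], p)
    written <- c(written, p)
  }
  emit(assays$results, "assay_results.tsv")

  manifest <- list(
    tool = "breakscape",
    version = as.character(utils::packageVersion("breakscape")),
    seed = config$seed,
    config = unclass(config),
    parameters = list(window_halfwidth = window_halfwidth,
                      heatmap_bin = 500, profile_resolution = 50,
                      metagene = list(flank = 3000, flank_bin = 200,
                                      n_body_bins = 100)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(tools::md5sum(sort(written)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  written <- c(written, manifest_path)

  write_report(out_dir, tests, strat_medians, assays$results)
  written <- c(written, file.path(out_dir, "report.md"))

  ok <- TRUE
  invisible(list(genome = genome, tracks = tracks, quant = quant,
                 tests = tests, stratified = strat, heatmap = hm,
                 profiles = prof, metagene = meta, assays = assays,
                 manifest = manifest))
}

# simulated qPCR experiments exercising each assay, with known truth
simulate_assay_suite <- function(config) {
  noise <- 0.15
  seed <- stage_seed(config$seed, "qpcr")
  set.seed(seed, kind = "Mersenne-Twister")

  # resection: two loci, control vs knockdown, damaged vs not
  res_rows <- list(); k <- 0
  truth <- list(ctrl_undamaged = 0.05, ctrl_damaged = 0.25,
                setx_kd_undamaged = 0.05, setx_kd_damaged = 0.28)
  for (target in c("DSB1_335", "DSB2_364")) {
    for (cond in names(truth)) {
      for (r in 1:3) {
        m <- simulate_resection_experiment(truth[[cond]],
                                           noise_sd = noise)
        k <- k + 1
        res_rows[[k]] <- data.frame(
          sample = c("digested", "undigested"), target = target,
          condition = cond, replicate = r,
          ct = c(m$ct_digested, m$ct_undigested))
      }
    }
  }
  ct_resection <- do.call(rbind, res_rows)

  # repair kinetics: fraction of sites still broken over auxin time course
  broken <- c(t0 = 1, t30 = 0.65, t60 = 0.4, t120 = 0.15)
  rep_rows <- list(); k <- 0
  for (target in c("DSB1", "DSB2")) {
    for (cond in names(broken)) {
      for (r in 1:3) {
        ctab <- simulate_qpcr(c(0.02 * broken[[cond]], 1),
                              noise_sd = noise,
                              sample = c("pulldown", "input"),
                              target = target, condition = cond,
                              replicate = r)
        k <- k + 1
        rep_rows[[k]] <- ctab
      }
    }
  }
  ct_repair <- do.call(rbind, rep_rows)

  # translocation: junction frequency, knockdown raises it 4-fold
  freq <- c(control = 1, setx_kd = 4)
  tr_rows <- list(); k <- 0
  for (cond in names(freq)) {
    for (r in 1:5) {
      ctab <- simulate_qpcr(c(1e-4 * freq[[cond]], 1, 1),
                            noise_sd = noise, sample = "gDNA",
                            target = c("MIS12_TRIM37", "ctrl_chr1",
                                       "ctrl_chr17"),
                            condition = cond, replicate = r)
      k <- k + 1
      tr_rows[[k]] <- ctab
    }
  }
  ct_transloc <- do.call(rbind, tr_rows)

  # DRIP-qPCR: percent input at a break-proximal amplicon
  drip_enrich <- c(undamaged = 0.02, damaged = 0.05)
  dr_rows <- list(); k <- 0
  for (cond in names(drip_enrich)) {
    for (r in 1:3) {
      ctab <- simulate_qpcr(c(drip_enrich[[cond]], 0.0217),
                            noise_sd = noise,
                            sample = c("ip", "input"),
                            target = "RBMXL1", condition = cond,
                            replicate = r)
      k <- k + 1
      dr_rows[[k]] <- ctab
    }
  }
  ct_drip <- do.call(rbind, dr_rows)

  results <- rbind(
    assay_resection(ct_resection, control_condition = "ctrl_undamaged"),
    assay_repair(ct_repair, reference_condition = "t0"),
    assay_translocation(ct_transloc, target = "MIS12_TRIM37",
                        control_targets = c("ctrl_chr1", "ctrl_chr17"),
                        reference_condition = "control"),
    assay_drip(ct_drip, input_fraction = 10 / 460)
  )
  list(tables = list(resection = ct_resection, repair = ct_repair,
                     translocation = ct_transloc, drip = ct_drip),
       results = results,
       truth = list(resection = truth, repair = broken,
                    translocation = freq, drip = drip_enrich))
}

write_report <- function(out_dir, tests, strat_medians, assay_results) {
  lines <- c(
    "# Pipeline report",
    "",
    "All numbers below are also available as TSV files in this directory.",
    "",
    "## Cut vs uncut windowed signal (Mann-Whitney U)",
    "",
    sprintf("- %s: U = %g, p = %.3g (%ssignificant at 0.05), larger median: %s",
            names(tests),
            vapply(tests, function(t) t$statistic, numeric(1)),
            vapply(tests, function(t) t$p_value, numeric(1)),
            ifelse(vapply(tests, function(t) t$p_value, numeric(1)) < 0.05,
                   "", "not "),
            vapply(tests, function(t) t$direction, character(1))),
    "",
    "No multiple-testing correction is applied across these per-track",
    "tests; each p-value is reported as-is.",
    "",
    "## Median windowed signal by transcription class (cut sites)",
    "",
    paste(utils::capture.output(print(strat_medians, row.names = FALSE)),
          collapse = "\n"),
    "",
    "## qPCR assays (mean of biological replicates, s.e.m.)",
    "",
    paste(utils::capture.output(print(assay_results, row.names = FALSE,
                                      digits = 4)),
          collapse = "\n"),
    ""
  )
  writeLines(lines, file.path(out_dir, "report.md"))
}

#' Read a pipeline/simulation configuration file
#'
#' Configuration files are flat YAML key-value mappings whose keys are the
#' arguments of [sim_config()] (plus optional `preset`). Unknown keys are
#' an error naming the key.
#'
#' @param path Path to a YAML config file.
#' @return A validated [sim_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping")
  known <- names(formals(sim_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, cfg)
}
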