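#' Build and validate a pipeline configuration
#'
#' Central configuration for an end-to-end run. Defaults encode the assay's
#' three fixed parameters — the 0.7 viability cutoff, the 0.9
#' negative-control gate and the 40 um diameter filter — plus imaging,
#' calibration and statistics settings. Values can be supplied directly or
#' loaded from YAML via [read_pipeline_config()].
#'
#' @param imaging list overriding [imaging_config()] fields.
#' @param scoring list: `cutoff` (0.7), `qc_threshold` (0.9), `t0_day` (0),
#'   `t1_day` (7), `min_replicates` (2), `normalize_by_control` (FALSE).
#' @param stats list: `B` resamples (1000), `ci_method` ("delong"),
#'   `alpha` (0.05).
#' @param seed master seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(imaging = list(), scoring = list(),
                            stats = list(), seed = 1L) {
  img <- utils::modifyList(unclass(imaging_config()), imaging)
  sco <- utils::modifyList(list(cutoff = 0.7, qc_threshold = 0.9,
                                t0_day = 0, t1_day = 7,
                                min_replicates = 2L,
                                normalize_by_control = FALSE), scoring)
  sta <- utils::modifyList(list(B = 1000L, ci_method = "delong",
                                alpha = 0.05), stats)
  cfg <- list(imaging = img, scoring = sco, stats = sta,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  fail <- function(path, msg) {
    stop(sprintf("config field %s: %s", path, msg), call. = FALSE)
  }
  if (cfg$imaging$pixel_size_um <= 0) {
    fail("imaging.pixel_size_um", "must be > 0")
  }
  if (cfg$imaging$min_diameter_um < 0) {
    fail("imaging.min_diameter_um", "must be >= 0")
  }
  if (cfg$scoring$cutoff <= 0) fail("scoring.cutoff", "must be > 0")
  if (cfg$scoring$qc_threshold < 0) {
    fail("scoring.qc_threshold", "must be >= 0")
  }
  if (cfg$scoring$t1_day < cfg$scoring$t0_day) {
    fail("scoring.t1_day", "must be >= t0_day")
  }
  if (cfg$stats$B < 1) fail("stats.B", "must be >= 1")
  if (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1) {
    fail("stats.alpha", "must be in (0, 1)")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with optional `imaging:`, `scoring:`, `stats:`
#'   blocks and a `seed:`.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(imaging = y$imaging %||% list(),
                  scoring = y$scoring %||% list(),
                  stats = y$stats %||% list(),
                  seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic demonstration pipeline
#'
#' Simulates a drug assay and a validation cohort under the configured
#' seed, scores the wells, summarizes replicate reproducibility, and runs
#' the concordance analysis. Returns all stage outputs plus a run manifest
#' (config snapshot, seed, row and discard counts) so every table is
#' traceable to one run. Identical config and seed reproduce identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, stage tables are
#'   written as CSV and the manifest as JSON.
#' @return list: `wells`, `scores`, `reproducibility`, `cohort`,
#'   `concordance`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  validate_pipeline_config(config)
  seed <- config$seed

  effects <- default_drug_panel()
  wells <- simulate_drug_assay(
    growth_params(), effects$effects, effects$concentrations,
    samples = sprintf("S%02d", 1:6), replicates = 3L,
    t0_day = config$scoring$t0_day, t1_day = config$scoring$t1_day,
    noise_cv = 0.23, seed = substream_seed(seed, "assay"))
  scored <- score_assay(wells, cutoff = config$scoring$cutoff,
                        qc_threshold = config$scoring$qc_threshold,
                        min_replicates = config$scoring$min_replicates,
                        normalize_by_control =
                          config$scoring$normalize_by_control)

  rep_sim <- simulate_replicate_matrix(seed = substream_seed(seed, "repmat"))
  cv <- cv_summary(rep_sim$matrix)
  pairs <- paired_resampling_correlation(rep_sim$matrix, B = config$stats$B,
                                         seed = substream_seed(seed, "pairs"))

  cohort <- simulate_cohort(cohort_spec(seed = substream_seed(seed, "cohort")))
  conc <- analyze_concordance(cohort, cutoff = config$scoring$cutoff,
                              alpha = config$stats$alpha,
                              seed = substream_seed(seed, "ci"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ptcscreen")),
    seed = seed,
    config = unclass(config),
    counts = list(
      wells = nrow(wells),
      scored_pairs = nrow(scored$results),
      qc_discarded_samples = sum(!scored$controls$qc_pass),
      log_entries = length(scored$log),
      replicate_rows = cv$n_rows,
      replicate_rows_excluded = cv$n_excluded,
      cohort_treatments = nrow(cohort)
    )
  )

  out <- list(wells = wells, scores = scored,
              reproducibility = list(cv = cv, pairs = pairs),
              cohort = cohort, concordance = conc, manifest = manifest)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(wells, file.path(output_dir, "well_records.csv"))
    write_table_csv(scored$results,
                    file.path(output_dir, "viability_results.csv"))
    write_table_csv(cohort, file.path(output_dir, "cohort.csv"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Default synthetic ten-drug panel
#'
#' Ten drugs with log-spaced potencies and 3-6 concentration gradients per
#' drug spanning 0.01-125 uM, mirroring a chemotherapy testing panel.
#'
#' @return list with `effects` (list of [drug_effect_params()]) and
#'   `concentrations` (named list of gradients, uM).
#' @export
default_drug_panel <- function() {
  grid <- c(0.01, 0.05, 0.2, 1, 5, 25, 125)
  n_conc <- rep(3:6, length.out = 10)
  effects <- vector("list", 10)
  concentrations <- list()
  for (k in 1:10) {
    id <- sprintf("drug%02d", k)
    effects[[k]] <- drug_effect_params(id, potency = 10^((k - 5) / 2),
                                       hill = 1.2, max_kill = 0.95)
    concentrations[[id]] <- grid[seq_len(n_conc[k]) +
                                   (k %% (8 - n_conc[k]))]
  }
  list(effects = effects, concentrations = concentrations)
}
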