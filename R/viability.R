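#' Per-replicate viability ratio
#'
#' The viability of one replicate well is the ratio of summed retained
#' cluster areas at the endpoint to baseline, `S_t1 / S_t0`. Values above 1
#' (growth under drug) are permitted.
#'
#' @param s_t0,s_t1 summed cluster areas (um^2) at baseline and endpoint;
#'   vectorized.
#' @param well label(s) used in the degenerate-well error message.
#' @return nonnegative numeric ratio(s).
#' @export
replicate_viability <- function(s_t0, s_t1, well = NULL) {
  if (any(s_t1 < 0) || any(s_t0 < 0)) {
    stop("areas must be nonnegative", call. = FALSE)
  }
  bad <- s_t0 <= 0
  if (any(bad)) {
    lab <- if (is.null(well)) which(bad) else well[bad]
    stop(sprintf("degenerate well (baseline area 0): %s",
                 paste(lab, collapse = ", ")), call. = FALSE)
  }
  s_t1 / s_t0
}

#' Mean viability over replicates
#'
#' @param ratios per-replicate viability ratios (default replication is 3).
#' @return list with `pa` (arithmetic mean), `sd` (sample SD, `NA` for a
#'   single replicate) and `n`.
#' @export
mean_viability <- function(ratios) {
  if (length(ratios) == 0) stop("no replicate ratios supplied", call. = FALSE)
  list(pa = mean(ratios),
       sd = if (length(ratios) >= 2) stats::sd(ratios) else NA_real_,
       n = length(ratios))
}

#' Negative-control quality gate
#'
#' A test run is discarded when the untreated control viability falls below
#' the threshold, indicating the culture may already be in its decline
#' phase. The boundary passes: the rule is strictly "less than".
#'
#' @param pnc negative-control mean viability (>= 0); vectorized.
#' @param threshold QC threshold, default 0.9.
#' @return logical, TRUE = pass (keep), FALSE = discard.
#' @export
qc_negative_control <- function(pnc, threshold = 0.9) {
  if (any(pnc < 0)) stop("pnc must be >= 0", call. = FALSE)
  pnc >= threshold
}

#' Classify a drug as effective or not against the fixed cutoff
#'
#' Effective iff mean viability is strictly below the cutoff; the boundary
#' value itself is not effective. The rule applies identically to single
#' and combination regimens.
#'
#' @param pa mean viability (>= 0); vectorized.
#' @param cutoff efficacy cutoff, default 0.7.
#' @return factor with levels `effective`, `not_effective`.
#' @export
classify_drug <- function(pa, cutoff = 0.7) {
  if (any(pa < 0)) stop("pa must be >= 0", call. = FALSE)
  factor(ifelse(pa < cutoff, "effective", "not_effective"),
         levels = c("effective", "not_effective"))
}

#' Score a well-record table into viability results
#'
#' Groups replicate wells by (sample, drug, concentration), computes
#' per-replicate ratios and their mean, applies the negative-control QC
#' gate per sample, and classifies each drug-concentration against the
#' cutoff. Replicates with zero baseline area are excluded (with a log
#' entry) rather than failing the whole test; a pair is dropped when fewer
#' than `min_replicates` remain.
#'
#' @param wells a `well_record_table` (columns `sample_id`, `drug_id`,
#'   `concentration_um`, `replicate`, `s_t0_um2`, `s_t1_um2`); negative
#'   controls have `drug_id == "NC"` or `NA` concentration.
#' @param cutoff efficacy cutoff on mean viability; default 0.7.
#' @param qc_threshold negative-control viability threshold; default 0.9.
#' @param min_replicates minimum usable replicates per pair; default 2.
#' @param normalize_by_control divide treated viabilities by the sample's
#'   control viability (exploratory; off by default — the control is a
#'   quality gate, not a normalizer).
#' @return list with `results` (one row per sample x drug x concentration:
#'   `pa`, `sd`, `n`, `classification`, `qc_pass`), `controls` (per-sample
#'   `pnc`, `qc_pass`) and `log` (character vector of exclusions/discards).
#' @export
score_assay <- function(wells, cutoff = 0.7, qc_threshold = 0.9,
                        min_replicates = 2L, normalize_by_control = FALSE) {
  req <- c("sample_id", "drug_id", "concentration_um", "replicate",
           "s_t0_um2", "s_t1_um2")
  if (!all(req %in% names(wells))) {
    stop("well table missing columns: ",
         paste(setdiff(req, names(wells)), collapse = ", "), call. = FALSE)
  }
  log <- character(0)
  is_nc <- wells$drug_id == "NC" | is.na(wells$concentration_um)
  usable <- wells$s_t0_um2 > 0
  if (any(!usable)) {
    lab <- with(wells[!usable, ],
                sprintf("%s/%s/rep%d", sample_id, drug_id, replicate))
    log <- c(log, sprintf("excluded replicate with zero baseline area: %s",
                          lab))
  }

  ratio <- rep(NA_real_, nrow(wells))
  ratio[usable] <- replicate_viability(wells$s_t0_um2[usable],
                                       wells$s_t1_um2[usable])

  # per-sample negative-control viability and QC verdict
  nc <- wells[is_nc & usable, ]
  if (nrow(nc) > 0) {
    controls <- do.call(rbind, lapply(split(ratio[is_nc & usable],
                                            nc$sample_id), function(r) {
      mv <- mean_viability(r)
      data.frame(pnc = mv$pa, n = mv$n)
    }))
    controls <- data.frame(sample_id = rownames(controls), controls,
                           row.names = NULL)
  } else {
    controls <- data.frame(sample_id = character(0), pnc = numeric(0),
                           n = integer(0))
  }
  controls$qc_pass <- qc_negative_control(controls$pnc, qc_threshold)
  for (s in controls$sample_id[!controls$qc_pass]) {
    log <- c(log, sprintf(
      "discarded sample %s: negative-control viability below %.2f", s,
      qc_threshold))
  }

  trt <- which(!is_nc & usable)
  key <- interaction(wells$sample_id[trt], wells$drug_id[trt],
                     wells$concentration_um[trt], drop = TRUE)
  groups <- split(trt, key)
  rows <- lapply(groups, function(idx) {
    r <- ratio[idx]
    if (length(r) < min_replicates) {
      return(NULL)
    }
    mv <- mean_viability(r)
    data.frame(sample_id = wells$sample_id[idx[1]],
               drug_id = wells$drug_id[idx[1]],
               concentration_um = wells$concentration_um[idx[1]],
               pa = mv$pa, sd = mv$sd, n = mv$n)
  })
  dropped <- names(groups)[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    log <- c(log, sprintf("dropped pair with < %d usable replicates: %s",
                          min_replicates, dropped))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$qc_pass <- controls$qc_pass[match(res$sample_id, controls$sample_id)]
  res$qc_pass[is.na(res$qc_pass)] <- NA
  if (normalize_by_control) {
    pnc <- controls$pnc[match(res$sample_id, controls$sample_id)]
    res$pa <- res$pa / pnc
    res$sd <- res$sd / pnc
  }
  res$classification <- classify_drug(res$pa, cutoff)
  # QC-failed samples never reach downstream tables
  res <- res[is.na(res$qc_pass) | res$qc_pass, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("viability_result_table", "data.frame")
  list(results = res, controls = controls, log = log)
}

#' Label growth phases in a daily area trajectory
#'
#' Day-over-day relative change r classifies each transition: exponential
#' where r > delta, stationary where |r| <= delta, decline where
#' r < -delta. The plateau length is the longest stationary run.
#'
#' @param areas daily total areas (>= 3 days), all positive.
#' @param delta relative-change tolerance per day; default 0.05.
#' @return list with `phase` (factor per day-over-day step) and
#'   `plateau_length_days`.
#' @export
classify_growth_phases <- function(areas, delta = 0.05) {
  if (length(areas) < 3) stop("need at least 3 days of areas", call. = FALSE)
  if (any(areas <= 0)) stop("areas must be positive", call. = FALSE)
  r <- diff(areas) / areas[-length(areas)]
  phase <- factor(ifelse(r > delta, "exponential",
                         ifelse(r < -delta, "decline", "stationary")),
                  levels = c("exponential", "stationary", "decline"))
  runs <- rle(as.character(phase))
  stat_runs <- runs$lengths[runs$values == "stationary"]
  list(phase = phase,
       plateau_length_days = if (length(stat_runs)) max(stat_runs) else 0L)
}
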