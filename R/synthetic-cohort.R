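#' Specification of a synthetic validation cohort
#'
#' Emulates the schema of a treatment-level validation table: one row per
#' patient-treatment with mean PTC viability, a merged RECIST class
#' (CR/PR, SD or PD) and a prospective flag. Viabilities are drawn per
#' class from normal distributions truncated at 0 — lower viability in
#' responders is the concordance signal, and its strength is set entirely
#' by the class locations and spreads.
#'
#' Defaults mirror the validation cohort composition (8 CR/PR, 40 SD,
#' 12 PD; 33 of 60 treatments prospective) with class distributions chosen
#' so the expected class-wise effective fractions (viability < 0.7) match
#' the published contingency: essentially all CR/PR effective, roughly a
#' third of SD, and essentially no PD.
#'
#' @param n_crpr,n_sd,n_pd treatments per merged RECIST class.
#' @param mean_crpr,mean_sd,mean_pd class viability locations.
#' @param sd_crpr,sd_sd,sd_pd class viability spreads.
#' @param prospective_fraction fraction of treatments flagged prospective.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_crpr = 8L, n_sd = 40L, n_pd = 12L,
                        mean_crpr = 0.40, mean_sd = 0.80, mean_pd = 1.10,
                        sd_crpr = 0.15, sd_sd = 0.22, sd_pd = 0.20,
                        prospective_fraction = 33 / 60,
                        seed = 1L) {
  counts <- c(n_crpr, n_sd, n_pd)
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  if (sum(counts) == 0) {
    stop("at least one class count must be nonzero", call. = FALSE)
  }
  structure(list(n_crpr = as.integer(n_crpr), n_sd = as.integer(n_sd),
                 n_pd = as.integer(n_pd),
                 mean_crpr = mean_crpr, mean_sd = mean_sd, mean_pd = mean_pd,
                 sd_crpr = sd_crpr, sd_sd = sd_sd, sd_pd = sd_pd,
                 prospective_fraction = prospective_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Cohort spec with perfect viability separation
#'
#' All CR/PR viabilities fall strictly below the 0.7 cutoff and all SD/PD
#' viabilities at or above it, forcing downstream CR/PR-vs-PD accuracy and
#' AUC to 1 by construction.
#'
#' @inheritParams cohort_spec
#' @param ... passed through to [cohort_spec()].
#' @export
cohort_spec_separated <- function(n_crpr = 8L, n_sd = 40L, n_pd = 12L, ...) {
  spec <- cohort_spec(n_crpr = n_crpr, n_sd = n_sd, n_pd = n_pd,
                      mean_crpr = 0.35, mean_sd = 0.95, mean_pd = 1.05,
                      sd_crpr = 0.1, sd_sd = 0.1, sd_pd = 0.1, ...)
  spec$separated <- TRUE
  spec
}

#' Class viability offset that targets a given binormal AUC
#'
#' Under equal-variance normal viability models for the two classes, the
#' probability that a responder's viability is below a non-responder's is
#' `pnorm(delta / (sd * sqrt(2)))`; inverting gives the location offset
#' needed for a target AUC.
#'
#' @param target_auc desired AUC in (0, 1).
#' @param sd common class standard deviation.
#' @return location offset (non-responder mean minus responder mean).
#' @export
binormal_offset <- function(target_auc, sd = 0.15) {
  stopifnot(target_auc > 0, target_auc < 1)
  stats::qnorm(target_auc) * sd * sqrt(2)
}

#' Simulate a treatment-level validation cohort
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of class `treatment_outcome_table` with columns
#'   `patient_id`, `sample_id`, `regimen`, `pa` (mean viability), `recist`
#'   (factor CR/PR, SD, PD) and `prospective` (logical).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  draw <- function(n, mu, sd, upper = Inf) {
    if (n == 0) return(numeric(0))
    x <- stats::rnorm(n, mu, sd)
    # truncation at 0 (viability is a ratio of areas, never negative)
    for (i in seq_len(200)) {
      bad <- x < 0 | x >= upper
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), mu, sd)
    }
    x[x < 0] <- 0
    x
  }
  with_seed(spec$seed, {
    sep <- isTRUE(spec$separated)
    pa <- c(
      draw(spec$n_crpr, spec$mean_crpr, spec$sd_crpr,
           upper = if (sep) 0.7 else Inf),
      pmax(draw(spec$n_sd, spec$mean_sd, spec$sd_sd),
           if (sep) 0.7 else 0),
      pmax(draw(spec$n_pd, spec$mean_pd, spec$sd_pd),
           if (sep) 0.7 else 0)
    )
    recist <- factor(rep(c("CR/PR", "SD", "PD"),
                         c(spec$n_crpr, spec$n_sd, spec$n_pd)),
                     levels = c("CR/PR", "SD", "PD"))
    n <- length(pa)
    n_pro <- round(spec$prospective_fraction * n)
    prospective <- rep(FALSE, n)
    prospective[sample.int(n, n_pro)] <- TRUE
    out <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      sample_id = sprintf("S%03d", seq_len(n)),
      regimen = sprintf("regimen_%02d", sample.int(10, n, replace = TRUE)),
      pa = pa,
      recist = recist,
      prospective = prospective
    )
    class(out) <- c("treatment_outcome_table", "data.frame")
    out
  })
}
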