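#' Dose-response parameters for a synthetic drug
#'
#' The assay itself never fits a dose-response model; the generator only
#' needs a monotone dose dependence, supplied here as a Hill curve. The
#' fractional area reduction at concentration c for a sample with
#' sensitivity multiplier s is
#' `max_kill * (s*c)^hill / ((s*c)^hill + potency^hill)`.
#'
#' @param drug_id drug identifier.
#' @param potency concentration (uM) at half-maximal effect.
#' @param hill unitless Hill slope.
#' @param max_kill maximal fractional area reduction, in \[0, 1\].
#' @return an object of class `drug_effect_params`.
#' @export
drug_effect_params <- function(drug_id, potency, hill = 1, max_kill = 0.9) {
  if (!is.finite(potency) || potency <= 0) {
    stop("potency must be > 0", call. = FALSE)
  }
  if (!is.finite(max_kill) || max_kill < 0 || max_kill > 1) {
    stop("max_kill must be in [0, 1]", call. = FALSE)
  }
  if (!is.finite(hill)) stop("hill must be finite", call. = FALSE)
  structure(list(drug_id = as.character(drug_id), potency = potency,
                 hill = hill, max_kill = max_kill),
            class = "drug_effect_params")
}

#' Surviving area fraction under a Hill dose-response
#'
#' @param effect a [drug_effect_params()] object.
#' @param concentration_um concentration(s), uM.
#' @param sensitivity per-sample positive sensitivity multiplier.
#' @return fraction of area surviving the drug effect, in \[0, 1\].
#' @export
hill_survival <- function(effect, concentration_um, sensitivity = 1) {
  stopifnot(inherits(effect, "drug_effect_params"))
  if (any(sensitivity <= 0)) stop("sensitivity must be > 0", call. = FALSE)
  x <- (sensitivity * concentration_um)^effect$hill
  kill <- effect$max_kill * x / (x + effect$potency^effect$hill)
  1 - kill
}

#' Simulate a drug-testing assay as a table of well records
#'
#' Produces one row per (sample, drug, concentration, replicate) well plus
#' one negative-control well set per (sample, replicate) with concentration
#' `NA`. Baseline area `S_t0` is drawn from the seeding distribution; the
#' noise-free endpoint area is `S_t0 * growth_multiplier(t0, t1) *
#' hill_survival(...)`, and replicate noise is multiplicative log-normal at
#' `noise_cv`. Ground-truth (noise-free) viability is stored alongside for
#' recovery tests.
#'
#' All randomness flows from `seed` through per-well substreams indexed by
#' (sample, drug, concentration, replicate), so adding a drug never changes
#' another drug's wells.
#'
#' @param growth a [growth_params()] object (negative-control kinetics).
#' @param effects list of [drug_effect_params()].
#' @param concentrations_um concentrations (uM) tested for every drug, or a
#'   named list mapping drug_id to its own gradient (3-6 values typical).
#' @param samples sample identifiers (default one sample "S1").
#' @param replicates wells per (sample, drug, concentration); default 3.
#' @param t0_day,t1_day imaging days; default 0 and 7.
#' @param noise_cv multiplicative well-to-well noise CV; default 0.
#' @param sensitivity named numeric vector of per-sample sensitivity
#'   multipliers (default all 1).
#' @param seed master seed.
#' @return data.frame of class `well_record_table`: `sample_id`, `drug_id`,
#'   `concentration_um` (NA for negative control), `replicate`,
#'   `s_t0_um2`, `s_t1_um2`, `true_viability`.
#' @export
simulate_drug_assay <- function(growth, effects, concentrations_um,
                                samples = "S1", replicates = 3L,
                                t0_day = 0, t1_day = 7,
                                noise_cv = 0, sensitivity = NULL,
                                seed = 1L) {
  stopifnot(inherits(growth, "growth_params"))
  if (inherits(effects, "drug_effect_params")) effects <- list(effects)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  conc_for <- function(drug_id) {
    cc <- if (is.list(concentrations_um)) concentrations_um[[drug_id]]
          else concentrations_um
    if (length(cc) == 0) stop("empty concentration list", call. = FALSE)
    if (any(!is.finite(cc)) || any(cc <= 0)) {
      stop("concentrations must be strictly positive", call. = FALSE)
    }
    cc
  }
  if (is.null(sensitivity)) {
    sensitivity <- stats::setNames(rep(1, length(samples)), samples)
  }
  g <- growth_multiplier(growth, t0_day, t1_day)

  one_well <- function(sample_id, drug_id, conc, rep_i, survival) {
    ws <- substream_seed(seed, sample_id, drug_id,
                         ifelse(is.na(conc), -1, conc), rep_i)
    with_seed(ws, {
      diam <- exp(stats::rnorm(growth$initial_cluster_count,
                               growth$initial_diameter_log_mean,
                               growth$initial_diameter_log_sd))
      s_t0 <- sum(pi * (diam / 2)^2)
      true_v <- g * survival
      s_t1 <- s_t0 * true_v * lognormal_noise(1, noise_cv)
      data.frame(sample_id = sample_id, drug_id = drug_id,
                 concentration_um = conc, replicate = rep_i,
                 s_t0_um2 = s_t0, s_t1_um2 = s_t1,
                 true_viability = true_v)
    })
  }

  rows <- list()
  for (s in samples) {
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- one_well(s, "NC", NA_real_, r, 1)
    }
    for (ef in effects) {
      for (conc in conc_for(ef$drug_id)) {
        surv <- hill_survival(ef, conc, sensitivity[[s]])
        for (r in seq_len(replicates)) {
          rows[[length(rows) + 1L]] <- one_well(s, ef$drug_id, conc, r, surv)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("well_record_table", "data.frame")
  out
}
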