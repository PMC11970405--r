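#' Growth parameters for synthetic PTC wells
#'
#' Parameterizes the three-stage growth that PTC cultures exhibit:
#' exponential expansion, a stationary plateau, then decline. Defaults
#' reflect the platform's reported culture conditions: 30-50 clusters seeded
#' per well, exponential growth through the first week, and a plateau
#' lasting 5-25 days.
#'
#' @param initial_cluster_count clusters seeded per well.
#' @param initial_diameter_log_mean,initial_diameter_log_sd log-normal
#'   parameters of the initial cluster diameter, in log-micrometres.
#' @param exp_rate per-day relative area growth during the exponential phase.
#' @param plateau_start_day day the stationary phase begins.
#' @param plateau_duration_days length of the stationary phase, days.
#' @param decline_rate per-day relative area loss during decline.
#' @param measurement_noise_cv coefficient of variation of multiplicative
#'   measurement noise applied to daily totals (0 = noise-free).
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(initial_cluster_count = 40L,
                          initial_diameter_log_mean = log(70),
                          initial_diameter_log_sd = 0.25,
                          exp_rate = 0.15,
                          plateau_start_day = 7,
                          plateau_duration_days = 15,
                          decline_rate = 0.05,
                          measurement_noise_cv = 0) {
  p <- list(
    initial_cluster_count = as.integer(initial_cluster_count),
    initial_diameter_log_mean = initial_diameter_log_mean,
    initial_diameter_log_sd = initial_diameter_log_sd,
    exp_rate = exp_rate,
    plateau_start_day = plateau_start_day,
    plateau_duration_days = plateau_duration_days,
    decline_rate = decline_rate,
    measurement_noise_cv = measurement_noise_cv
  )
  num <- unlist(p)
  if (any(!is.finite(num))) {
    stop("all growth parameters must be finite", call. = FALSE)
  }
  if (p$initial_cluster_count < 0L) {
    stop("initial_cluster_count must be >= 0", call. = FALSE)
  }
  if (p$plateau_duration_days < 0) {
    stop("plateau_duration_days must be >= 0", call. = FALSE)
  }
  if (p$measurement_noise_cv < 0) {
    stop("measurement_noise_cv must be >= 0", call. = FALSE)
  }
  if (p$initial_diameter_log_sd < 0) {
    stop("initial_diameter_log_sd must be >= 0", call. = FALSE)
  }
  structure(p, class = "growth_params")
}

#' Noise-free growth multiplier between two days
#'
#' Piecewise three-stage model: area compounds at `exp_rate` per day until
#' `plateau_start_day`, stays flat for `plateau_duration_days`, then decays
#' at `decline_rate` per day.
#'
#' @param params a [growth_params()] object.
#' @param from,to day indices (numeric, `to >= from`).
#' @return multiplicative factor total_area(to) / total_area(from).
#' @export
growth_multiplier <- function(params, from, to) {
  stopifnot(inherits(params, "growth_params"), to >= from)
  decline_start <- params$plateau_start_day + params$plateau_duration_days
  phase_days <- function(a, b, lo, hi) max(0, min(b, hi) - max(a, lo))
  d_exp <- phase_days(from, to, -Inf, params$plateau_start_day)
  d_dec <- phase_days(from, to, decline_start, Inf)
  (1 + params$exp_rate)^d_exp * (1 - params$decline_rate)^d_dec
}

#' Simulate a daily total-cluster-area trajectory
#'
#' Generates per-day total cluster area (um^2) for one well under the
#' three-stage growth model, with optional multiplicative log-normal
#' measurement noise at the configured CV.
#'
#' @param params a [growth_params()] object.
#' @param days number of days to simulate (>= 1); day 0 is included, so the
#'   returned vector has `days + 1` values.
#' @param seed integer seed.
#' @return data.frame with columns `day`, `total_area_um2`,
#'   `true_area_um2` (noise-free).
#' @export
simulate_growth_trajectory <- function(params, days, seed = 1L) {
  stopifnot(inherits(params, "growth_params"))
  if (!is.numeric(days) || days < 1) stop("days must be >= 1", call. = FALSE)
  days <- as.integer(days)
  with_seed(seed, {
    diam <- exp(stats::rnorm(params$initial_cluster_count,
                             params$initial_diameter_log_mean,
                             params$initial_diameter_log_sd))
    a0 <- sum(pi * (diam / 2)^2)
    day <- 0:days
    true_area <- vapply(day, function(d) a0 * growth_multiplier(params, 0, d),
                        numeric(1))
    noise <- lognormal_noise(length(day), params$measurement_noise_cv)
    data.frame(day = day,
               total_area_um2 = true_area * noise,
               true_area_um2 = true_area)
  })
}

# Multiplicative log-normal noise with mean 1 and the requested CV.
# CV of a log-normal is sqrt(exp(sdlog^2) - 1), inverted here.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
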