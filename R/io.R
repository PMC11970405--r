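#' Write a table as CSV with explicit headers
#'
#' UTF-8, no row names; units are encoded in column names (`*_um2`,
#' `*_um`), viabilities are unitless.
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a table written by [write_table_csv()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read a treatment-outcome table
#'
#' Schema mirrors a treatment-level validation cohort export: `patient_id`,
#' `sample_id`, `regimen`, `pa`, `recist` (CR, PR, CR/PR, SD or PD — CR and
#' PR are merged on input), `prospective`.
#'
#' @param path CSV path.
#' @return `treatment_outcome_table` data.frame.
#' @export
read_treatment_outcomes <- function(path) {
  x <- read_table_csv(path)
  req <- c("pa", "recist")
  if (!all(req %in% names(x))) {
    stop("outcome table must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  rec <- toupper(trimws(as.character(x$recist)))
  rec[rec %in% c("CR", "PR", "CR/PR", "CRPR")] <- "CR/PR"
  bad <- setdiff(unique(rec), c("CR/PR", "SD", "PD"))
  if (length(bad)) {
    stop("unknown RECIST label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x$recist <- factor(rec, levels = c("CR/PR", "SD", "PD"))
  if (!"prospective" %in% names(x)) x$prospective <- NA
  x$prospective <- as.logical(x$prospective)
  class(x) <- c("treatment_outcome_table", "data.frame")
  x
}

#' Reported culture attempt tallies
#'
#' The printed culture bookkeeping for the cluster platform versus
#' conventional spheres: attempts and successes per model.
#'
#' @return data.frame with `model`, `n_success`, `n_attempt`.
#' @export
culture_success_counts <- function() {
  data.frame(model = c("PTC", "sphere"),
             n_success = c(241L, 4L),
             n_attempt = c(254L, 13L))
}

#' Culture success rate as a percentage
#'
#' @param n_success,n_attempt nonnegative integer counts,
#'   `n_success <= n_attempt`.
#' @param digits decimal places in the printed percentage; default 1.
#' @return success percentage.
#' @export
success_rate_percent <- function(n_success, n_attempt, digits = 1) {
  if (any(n_attempt <= 0) || any(n_success < 0) ||
      any(n_success > n_attempt)) {
    stop("need 0 <= n_success <= n_attempt with n_attempt > 0",
         call. = FALSE)
  }
  round(100 * n_success / n_attempt, digits)
}
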