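#' Efficacy rate of a drug at one tested concentration
#'
#' The fraction of assay-set samples whose mean viability at that
#' concentration falls below the cutoff. Samples not measured at the
#' concentration are excluded from the denominator (no imputation).
#'
#' @param panel data.frame with columns `drug_id`, `sample_id`,
#'   `concentration_um`, `pa` (one drug or filtered to one).
#' @param concentration_um a tested concentration.
#' @param cutoff efficacy cutoff; default 0.7.
#' @return efficacy rate in \[0, 1\].
#' @export
efficacy_rate <- function(panel, concentration_um, cutoff = 0.7) {
  at <- panel$concentration_um == concentration_um
  if (!any(at)) {
    stop(sprintf("concentration %g uM was not measured", concentration_um),
         call. = FALSE)
  }
  mean(panel$pa[at] < cutoff)
}

#' Calibrate a drug's testing concentration against its clinical ORR
#'
#' The efficacy concentration Ec is the tested concentration whose panel
#' efficacy rate is closest to the drug's clinical objective response rate.
#' Ties are broken toward the lowest concentration (minimizing off-target
#' toxicity in the assay).
#'
#' @param panel data.frame for one drug: `sample_id`, `concentration_um`,
#'   `pa`.
#' @param orr_ref clinical ORR in \[0, 1\].
#' @param cutoff efficacy cutoff; default 0.7.
#' @return list of class `ec_record`: `drug_id` (if present in `panel`),
#'   `concentrations_um`, `efficacy_rate` per concentration, `orr_ref`,
#'   `ec_um` and `achieved_gap` = |ER(Ec) - ORR|.
#' @export
calibrate_ec <- function(panel, orr_ref, cutoff = 0.7) {
  if (is.null(panel) || nrow(panel) == 0) {
    stop("empty dose-response panel", call. = FALSE)
  }
  if (!is.finite(orr_ref) || orr_ref < 0 || orr_ref > 1) {
    stop("orr_ref must be in [0, 1]", call. = FALSE)
  }
  conc <- sort(unique(panel$concentration_um))
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  er <- vapply(conc, function(cc) efficacy_rate(panel, cc, cutoff), numeric(1))
  gap <- abs(er - orr_ref)
  # which.min takes the first minimum; conc is ascending, so ties resolve
  # toward the lowest concentration
  pick <- which.min(gap)
  structure(list(
    drug_id = if ("drug_id" %in% names(panel)) unique(panel$drug_id)[1]
              else NA_character_,
    concentrations_um = conc,
    efficacy_rate = er,
    orr_ref = orr_ref,
    ec_um = conc[pick],
    achieved_gap = gap[pick]
  ), class = "ec_record")
}

#' Calibrate every drug in a panel table against an ORR table
#'
#' @param panel data.frame with `drug_id`, `sample_id`, `concentration_um`,
#'   `pa` across drugs.
#' @param orr data.frame with `drug_id`, `orr`.
#' @param cutoff efficacy cutoff; default 0.7.
#' @return data.frame with one row per drug: `drug_id`, `ec_um`,
#'   `er_at_ec`, `orr_ref`, `achieved_gap`.
#' @export
calibrate_panel <- function(panel, orr, cutoff = 0.7) {
  drugs <- intersect(unique(panel$drug_id), orr$drug_id)
  rows <- lapply(drugs, function(d) {
    rec <- calibrate_ec(panel[panel$drug_id == d, , drop = FALSE],
                        orr$orr[orr$drug_id == d][1], cutoff)
    data.frame(drug_id = d, ec_um = rec$ec_um,
               er_at_ec = rec$efficacy_rate[match(rec$ec_um,
                                                  rec$concentrations_um)],
               orr_ref = rec$orr_ref, achieved_gap = rec$achieved_gap)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
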