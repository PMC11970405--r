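#' Z-standardize continuous viability measures
#'
#' @param values numeric vector, length >= 2 with positive SD.
#' @return vector with mean 0 and SD 1.
#' @export
standardize_viability <- function(values) {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("standard deviation is zero; cannot standardize", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' 2 x 3 contingency table of assay classification vs RECIST class
#'
#' Each treatment is classified effective / not effective from its mean
#' viability and cross-tabulated against the merged RECIST classes.
#'
#' @param outcomes `treatment_outcome_table` (columns `pa`, `recist`).
#' @param cutoff efficacy cutoff; default 0.7.
#' @return integer matrix, rows `effective` / `not_effective`, columns
#'   `CR/PR`, `SD`, `PD`.
#' @export
build_contingency <- function(outcomes, cutoff = 0.7) {
  if (nrow(outcomes) == 0) stop("no outcomes supplied", call. = FALSE)
  recist <- as.character(outcomes$recist)
  bad <- setdiff(unique(recist), c("CR/PR", "SD", "PD"))
  if (length(bad)) {
    stop("unknown RECIST label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cls <- classify_drug(outcomes$pa, cutoff)
  tab <- table(cls, factor(recist, levels = c("CR/PR", "SD", "PD")))
  m <- matrix(as.integer(tab), 2, 3,
              dimnames = list(c("effective", "not_effective"),
                              c("CR/PR", "SD", "PD")))
  m
}

#' Concordance accuracy between assay call and clinical response
#'
#' A treatment is concordant when the assay calls it effective and the
#' clinic observed CR/PR, or calls it not effective and the clinic observed
#' the resistant class. Two inclusion modes: `"CRPR_vs_PD"` drops SD
#' treatments (responders vs progressors only); `"CRPR_vs_SDPD"` counts SD
#' with PD as the resistant class.
#'
#' @param outcomes `treatment_outcome_table`.
#' @param mode `"CRPR_vs_PD"` or `"CRPR_vs_SDPD"`.
#' @param cutoff efficacy cutoff; default 0.7.
#' @return list: `accuracy`, `n_concordant`, `n_included`.
#' @export
concordance_accuracy <- function(outcomes, mode = c("CRPR_vs_PD",
                                                    "CRPR_vs_SDPD"),
                                 cutoff = 0.7) {
  mode <- match.arg(mode)
  recist <- as.character(outcomes$recist)
  keep <- if (mode == "CRPR_vs_PD") recist %in% c("CR/PR", "PD")
          else rep(TRUE, length(recist))
  if (!any(keep)) stop("no treatments included under this mode",
                       call. = FALSE)
  pa <- outcomes$pa[keep]
  sensitive <- recist[keep] == "CR/PR"
  effective <- classify_drug(pa, cutoff) == "effective"
  concordant <- (sensitive & effective) | (!sensitive & !effective)
  list(accuracy = mean(concordant),
       n_concordant = sum(concordant),
       n_included = sum(keep))
}

#' Mann-Whitney (two-sample Wilcoxon) rank test
#'
#' U statistic with average ranks for ties. The two-sided p-value comes
#' from exact enumeration of all group labelings when both groups have at
#' most `exact_max` observations and there are no ties, otherwise from the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_max largest per-group size for exact enumeration; default 8.
#' @return list of class `group_comparison`: `u` (U for group `a`),
#'   `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    warning("all pooled values identical; p = 1")
    return(structure(list(u = n1 * n2 / 2, p_value = 1, method = "degenerate"),
                     class = "group_comparison"))
  }
  r <- rank(pooled)
  u_stat <- function(ranks_a, n1, n2) sum(ranks_a) - n1 * (n1 + 1) / 2
  u <- u_stat(r[seq_len(n1)], n1, n2)
  ties <- any(duplicated(pooled))

  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    # exact null: U for every labeling of the pooled sample
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2, function(ii) u_stat(r[ii], n1, n2))
    # two-sided: labelings at least as extreme (far from n1*n2/2) as observed
    centre <- n1 * n2 / 2
    p <- mean(abs(us - centre) >= abs(u - centre))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_corr)
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  structure(list(u = u, p_value = min(p, 1), method = method),
            class = "group_comparison")
}

#' ROC AUC by pairwise counting
#'
#' Scores are oriented so that lower viability predicts the positive
#' (sensitive) class: AUC = P(score_pos > score_neg) + 0.5 P(tie) with
#' score = -viability, equivalent to trapezoidal integration of the ROC
#' curve.
#'
#' @param outcomes `treatment_outcome_table`, or any data.frame with `pa`
#'   and `recist`.
#' @param positive classes forming the positive (sensitive) group; default
#'   `"CR/PR"`.
#' @param negative classes forming the negative group; default the rest of
#'   the cohort.
#' @return list of class `roc_result`: `auc`, `n_pos`, `n_neg`,
#'   `orientation`.
#' @export
roc_auc <- function(outcomes, positive = "CR/PR", negative = NULL) {
  recist <- as.character(outcomes$recist)
  if (is.null(negative)) negative <- setdiff(unique(recist), positive)
  pos <- -outcomes$pa[recist %in% positive]
  neg <- -outcomes$pa[recist %in% negative]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be represented", call. = FALSE)
  }
  structure(list(auc = auc_pairwise(pos, neg),
                 n_pos = length(pos), n_neg = length(neg),
                 orientation = "lower viability => predicted sensitive"),
            class = "roc_result")
}

# Pairwise-counting AUC on raw scores (higher score = more positive).
auc_pairwise <- function(score_pos, score_neg) {
  cmp <- outer(score_pos, score_neg, FUN = function(p, q) {
    (p > q) + 0.5 * (p == q)
  })
  mean(cmp)
}

#' Confidence interval for the ROC AUC
#'
#' DeLong's placement-value variance estimator by default, truncated to
#' \[0, 1\]. For degenerate separation (AUC exactly 0 or 1 the DeLong
#' variance collapses), the stratified bootstrap (default 2000 resamples,
#' seeded) is used instead, with a warning under `method = "delong"`.
#'
#' @param outcomes as in [roc_auc()].
#' @param positive,negative class definitions as in [roc_auc()].
#' @param method `"delong"` or `"bootstrap"`.
#' @param alpha two-sided miscoverage; default 0.05.
#' @param B bootstrap resamples; default 2000.
#' @param seed seed for the bootstrap.
#' @return list of class `roc_ci`: `auc`, `lower`, `upper`, `method`.
#' @export
auc_confidence_interval <- function(outcomes, positive = "CR/PR",
                                    negative = NULL,
                                    method = c("delong", "bootstrap"),
                                    alpha = 0.05, B = 2000L, seed = 1L) {
  method <- match.arg(method)
  recist <- as.character(outcomes$recist)
  if (is.null(negative)) negative <- setdiff(unique(recist), positive)
  pos <- -outcomes$pa[recist %in% positive]
  neg <- -outcomes$pa[recist %in% negative]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be represented", call. = FALSE)
  }
  auc <- auc_pairwise(pos, neg)

  if (method == "delong" && (auc == 0 || auc == 1)) {
    warning("degenerate separation (AUC 0 or 1); falling back to bootstrap")
    method <- "bootstrap"
  }

  if (method == "delong") {
    # placement values: V10_i = P(score_neg < pos_i) + 0.5 P(=),
    # V01_j likewise against the positives
    v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)),
                  numeric(1))
    v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)),
                  numeric(1))
    var_auc <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
    z <- stats::qnorm(1 - alpha / 2)
    lower <- auc - z * sqrt(var_auc)
    upper <- auc + z * sqrt(var_auc)
  } else {
    boots <- with_seed(seed, vapply(seq_len(B), function(b) {
      auc_pairwise(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    }, numeric(1)))
    qs <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lower <- qs[1]
    upper <- qs[2]
  }
  structure(list(auc = auc,
                 lower = max(0, min(lower, auc)),
                 upper = min(1, max(upper, auc)),
                 method = method),
            class = "roc_ci")
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by hypergeometric enumeration: the sum of
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's.
#'
#' @param tab 2 x 2 matrix of nonnegative integer counts.
#' @return list: `p_value`, `odds_ratio` (sample OR, `Inf`/`NA` on empty
#'   margins).
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round(tab))) {
    stop("need a 2x2 table of nonnegative integer counts", call. = FALSE)
  }
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row-1 margin
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])   # column-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # small relative slack so ties in probability are included despite
  # floating-point rounding
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = min(p, 1), odds_ratio = or)
}

#' Benjamini-Hochberg adjustment for a batch of p-values
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values (FDR), same order as input.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Plot-ready waterfall table of per-treatment viability
#'
#' Sorted descending by viability (stable for ties) with the outcome class
#' carried along for coloring; purely presentational.
#'
#' @param outcomes `treatment_outcome_table`.
#' @return the input rows sorted by decreasing `pa`, with a `rank` column.
#' @export
waterfall_table <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("no outcomes supplied", call. = FALSE)
  ord <- order(-outcomes$pa)  # order() is stable: ties keep input order
  out <- outcomes[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full concordance analysis of a treatment-outcome table
#'
#' Convenience wrapper reproducing the standard validation readout:
#' contingency table, both accuracies, rank tests, ROC/AUC with CI for the
#' CR/PR-vs-PD and CR/PR-vs-SD/PD comparisons (overall and prospective-only),
#' and the waterfall table.
#'
#' @param outcomes `treatment_outcome_table`.
#' @param cutoff efficacy cutoff; default 0.7.
#' @param alpha CI miscoverage; default 0.05.
#' @param seed seed for any bootstrap fallback.
#' @return named list of results.
#' @export
analyze_concordance <- function(outcomes, cutoff = 0.7, alpha = 0.05,
                                seed = 1L) {
  recist <- as.character(outcomes$recist)
  crpr <- outcomes$pa[recist == "CR/PR"]
  pd <- outcomes$pa[recist == "PD"]
  sdpd <- outcomes$pa[recist != "CR/PR"]
  pro <- outcomes[outcomes$prospective, , drop = FALSE]

  res <- list(
    contingency = build_contingency(outcomes, cutoff),
    accuracy_crpr_vs_pd = concordance_accuracy(outcomes, "CRPR_vs_PD", cutoff),
    accuracy_overall = concordance_accuracy(outcomes, "CRPR_vs_SDPD", cutoff),
    test_crpr_vs_pd = mann_whitney(crpr, pd),
    test_crpr_vs_sdpd = mann_whitney(crpr, sdpd),
    roc_crpr_vs_pd = roc_auc(outcomes[recist %in% c("CR/PR", "PD"), ]),
    roc_crpr_vs_sdpd = roc_auc(outcomes),
    ci_crpr_vs_sdpd = suppressWarnings(
      auc_confidence_interval(outcomes, alpha = alpha, seed = seed)),
    waterfall = waterfall_table(outcomes)
  )
  if (nrow(pro) > 0 && length(unique(pro$recist == "CR/PR")) == 2) {
    res$roc_prospective <- roc_auc(pro)
    res$ci_prospective <- suppressWarnings(
      auc_confidence_interval(pro, alpha = alpha, seed = seed))
  }
  res
}
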