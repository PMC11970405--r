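# Independent oracles used to cross-check package implementations.
# Each is written from first principles, not by calling the code it checks.

# Trapezoidal ROC integration: sweep thresholds over the pooled scores and
# integrate TPR over FPR. Higher score = more positive.
trapezoid_auc <- function(score_pos, score_neg) {
  thr <- sort(unique(c(score_pos, score_neg, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(score_pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(score_neg >= t), numeric(1))
  tpr <- c(0, tpr, 1)
  fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Fisher two-sided p by direct enumeration over all 2x2 tables with the
# observed margins, using choose() products (no dhyper).
fisher_enumeration_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  prob_a <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (b < 0 || c < 0 || d < 0) return(0)
    choose(r1, a) * choose(r2, c) / choose(n, c1)
  }
  as <- 0:min(r1, c1)
  probs <- vapply(as, prob_a, numeric(1))
  p_obs <- prob_a(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full labeling enumeration.
mw_enumeration_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  centre <- n1 * n2 / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  mean(abs(us - centre) >= abs(u_obs - centre))
}

# Spearman as rank-then-Pearson with average ranks.
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# A tiny deterministic cohort table for concordance unit tests.
toy_outcomes <- function(pa, recist, prospective = NULL) {
  n <- length(pa)
  if (is.null(prospective)) prospective <- rep(TRUE, n)
  out <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    sample_id = sprintf("S%02d", seq_len(n)),
    regimen = "rx",
    pa = pa,
    recist = factor(recist, levels = c("CR/PR", "SD", "PD")),
    prospective = prospective
  )
  class(out) <- c("treatment_outcome_table", "data.frame")
  out
}
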