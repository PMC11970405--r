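#' Coefficient of variation of replicate viabilities
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#'
#' @param values replicate viabilities for one drug-sample pair (>= 2).
#' @return nonnegative CV.
#' @export
replicate_cv <- function(values) {
  if (length(values) < 2) stop("CV needs >= 2 replicates", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("CV undefined for non-positive mean", call. = FALSE)
  stats::sd(values) / m
}

#' Summarize per-pair CVs across a replicate matrix
#'
#' @param mat numeric matrix, rows = drug-sample pairs, columns = replicate
#'   viabilities.
#' @param cv_threshold reporting threshold; default 0.50 (strict `<`).
#' @return list: `cv` per retained row, `mean_cv`, `fraction_below`
#'   (rows with CV strictly below the threshold), `n_rows`, `n_excluded`
#'   (rows failing the CV preconditions, excluded with a count rather than
#'   silently).
#' @export
cv_summary <- function(mat, cv_threshold = 0.50) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need >= 2 replicate columns", call. = FALSE)
  ok <- apply(mat, 1, function(v) all(is.finite(v)) && mean(v) > 0)
  cvs <- apply(mat[ok, , drop = FALSE], 1, replicate_cv)
  list(cv = cvs,
       mean_cv = mean(cvs),
       fraction_below = mean(cvs < cv_threshold),
       n_rows = sum(ok),
       n_excluded = sum(!ok))
}

#' Pair-resampling correlation of replicate results
#'
#' Repeatedly (B draws, with replacement across draws) selects two distinct
#' replicate columns uniformly at random and computes Pearson and Spearman
#' correlations over the drug-sample pairs, quantifying how strongly two
#' independent runs of the whole panel agree.
#'
#' @param mat replicate matrix (rows = drug-sample pairs, >= 3; columns =
#'   replicates, >= 2).
#' @param B number of resampling draws; default 1000.
#' @param seed integer seed.
#' @return list of class `pair_sampling_result`: `pearson`, `spearman`
#'   (length-B vectors), their `*_mean` and `*_sd`, `B`, `seed`.
#' @export
paired_resampling_correlation <- function(mat, B = 1000L, seed = 1L) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need >= 2 replicate columns", call. = FALSE)
  if (nrow(mat) < 3) stop("need >= 3 drug-sample pairs", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  with_seed(seed, {
    pe <- numeric(B)
    sp <- numeric(B)
    for (b in seq_len(B)) {
      cols <- sample.int(ncol(mat), 2L)
      x <- mat[, cols[1]]
      y <- mat[, cols[2]]
      pe[b] <- stats::cor(x, y, method = "pearson")
      sp[b] <- stats::cor(x, y, method = "spearman")
    }
    # snap round-off at the boundaries so identical columns give exactly 1
    snap <- function(r) ifelse(abs(abs(r) - 1) < 1e-12, sign(r), r)
    pe <- snap(pe)
    sp <- snap(sp)
    structure(list(pearson = pe, spearman = sp,
                   pearson_mean = mean(pe), pearson_sd = stats::sd(pe),
                   spearman_mean = mean(sp), spearman_sd = stats::sd(sp),
                   B = B, seed = seed),
              class = "pair_sampling_result")
  })
}

#' Build a replicate matrix emulating a drug-profile consistency study
#'
#' Draws true pair-level viabilities from a log-normal spread and adds
#' multiplicative log-normal replicate noise at `noise_cv`, the structure
#' assumed by the CV and pair-resampling analyses.
#'
#' With few replicates the sample CV underestimates the generating CV: the
#' sample SD carries the normal-theory c4(n) bias (about 0.886 at n = 3)
#' and the log-normal's right skew adds a second-order term through the
#' correlation between the replicate SD and mean. The generating CV is
#' therefore inflated by inverting
#' `E[CV_hat] ~ c4(n) * cv * (1 - skew(cv) * cv / (2n))`,
#' so the mean per-pair sample CV recovers `noise_cv` rather than a
#' biased-down value.
#'
#' @param n_pairs drug-sample pairs (rows); default 337.
#' @param replicates wells per pair; default 3.
#' @param noise_cv target mean replicate CV; default 0.23.
#' @param true_meanlog,true_sdlog log-normal parameters of the true
#'   pair-level viabilities.
#' @param seed integer seed.
#' @return list: `matrix` (n_pairs x replicates), `true_viability`.
#' @export
simulate_replicate_matrix <- function(n_pairs = 337L, replicates = 3L,
                                      noise_cv = 0.23,
                                      true_meanlog = log(0.65),
                                      true_sdlog = 0.5,
                                      seed = 1L) {
  gen_cv <- debias_cv(noise_cv, replicates)
  with_seed(seed, {
    truth <- stats::rlnorm(n_pairs, true_meanlog, true_sdlog)
    noise <- matrix(lognormal_noise(n_pairs * replicates, gen_cv),
                    n_pairs, replicates)
    list(matrix = truth * noise, true_viability = truth)
  })
}

# Generating CV whose expected n-replicate sample CV equals the target.
# E[CV_hat] ~ c4(n) * cv * (1 - skew * cv / (2n)) with the log-normal
# skewness skew(cv) = 3 cv + cv^3; inverted by root finding.
debias_cv <- function(target_cv, n) {
  if (target_cv == 0) return(0)
  c4 <- sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  expected <- function(cv) c4 * cv * (1 - (3 * cv + cv^3) * cv / (2 * n))
  stats::uniroot(function(cv) expected(cv) - target_cv,
                 interval = c(target_cv, 3 * target_cv),
                 tol = 1e-10)$root
}
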