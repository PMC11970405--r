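test_that("z-standardization centers, scales and is idempotent", {
  z <- standardize_viability(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize_viability(z), z, tolerance = 1e-12)
  expect_error(standardize_viability(rep(0.4, 5)), "zero")
  expect_error(standardize_viability(0.4), ">= 2")
})

test_that("contingency table cross-tabulates calls against RECIST", {
  co <- simulate_cohort(cohort_spec(seed = 2))
  tab <- build_contingency(co)
  expect_equal(unname(colSums(tab)), c(8, 40, 12))
  expect_equal(sum(tab), nrow(co))

  all_eff <- toy_outcomes(c(0.1, 0.2, 0.3), c("CR/PR", "SD", "PD"))
  t2 <- build_contingency(all_eff)
  expect_equal(unname(t2["effective", ]), c(1L, 1L, 1L))
  expect_equal(sum(t2["not_effective", ]), 0L)

  bad <- toy_outcomes(0.5, "SD")
  bad$recist <- "CR"
  expect_error(build_contingency(bad), "unknown RECIST")
  expect_error(build_contingency(all_eff[0, ]), "no outcomes")
})

test_that("concordance accuracy counts agreement per inclusion mode", {
  toy <- toy_outcomes(c(0.3, 0.9, 0.5), c("CR/PR", "PD", "PD"))
  a <- concordance_accuracy(toy, "CRPR_vs_PD")
  expect_equal(a$accuracy, 2 / 3)
  expect_equal(a$n_included, 3)

  # SD merges with PD under the overall mode
  toy2 <- toy_outcomes(c(0.3, 0.5, 0.9, 0.8), c("CR/PR", "SD", "SD", "PD"))
  a2 <- concordance_accuracy(toy2, "CRPR_vs_SDPD")
  expect_equal(a2$accuracy, 3 / 4)  # SD at 0.5 called effective: discordant
  # under CRPR_vs_PD the SD rows drop out
  expect_equal(concordance_accuracy(toy2, "CRPR_vs_PD")$n_included, 2)

  # row-order invariance
  perm <- toy2[c(3, 1, 4, 2), ]
  expect_equal(concordance_accuracy(perm, "CRPR_vs_SDPD")$accuracy,
               a2$accuracy)
})

test_that("Mann-Whitney matches enumeration exactly and wilcox.test", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p_value, 0.1)  # 2 of 20 labelings as extreme
  expect_equal(mw$method, "exact")

  # enumeration oracle + base-R cross-check on random tie-free draws
  set.seed(14)
  for (i in 1:10) {
    a <- round(rnorm(sample(3:8, 1)), 6)
    b <- round(rnorm(sample(3:8, 1), 0.5), 6)
    got <- mann_whitney(a, b)
    expect_equal(got$p_value, mw_enumeration_p(a, b))
    expect_equal(got$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(got$u, unname(wilcox.test(a, b)$statistic))
  }

  # identical groups -> p = 1 with warning on fully degenerate input
  expect_warning(mwd <- mann_whitney(rep(1, 4), rep(1, 4)), "identical")
  expect_equal(mwd$p_value, 1)

  # normal approximation with ties agrees with wilcox.test's corrected z
  a <- c(1, 2, 2, 3, 5, 5, 6, 8, 9)
  b <- c(2, 3, 3, 4, 5, 7, 7, 8, 10, 11)
  got <- mann_whitney(a, b)
  expect_equal(got$method, "normal_approximation")
  expect_equal(got$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)

  # exact and approximate agree closely for 8 vs 8 tie-free samples
  set.seed(3)
  a8 <- rnorm(8)
  b8 <- rnorm(8, 0.3)
  pe <- mann_whitney(a8, b8)$p_value
  pa <- mann_whitney(a8, b8, exact_max = 0)$p_value
  expect_lt(abs(pe - pa), 0.01)
})

test_that("pairwise-counting AUC equals trapezoidal integration", {
  # fixed worked example: pos scores {0.2, 0.4}, neg {0.3, 0.9} on -pa
  toy <- toy_outcomes(c(0.2, 0.4, 0.3, 0.9),
                      c("CR/PR", "CR/PR", "PD", "PD"))
  expect_equal(roc_auc(toy)$auc, 0.75)

  # property: 300 random toy cohorts, with ties induced by rounding
  set.seed(77)
  for (i in 1:300) {
    n1 <- sample(2:12, 1)
    n2 <- sample(2:12, 1)
    pa <- round(c(rnorm(n1, 0.5, 0.25), rnorm(n2, 0.9, 0.25)), 1)
    pa <- pmax(pa, 0)
    toy <- toy_outcomes(pa, rep(c("CR/PR", "PD"), c(n1, n2)))
    got <- roc_auc(toy)$auc
    expect_equal(got, trapezoid_auc(-pa[seq_len(n1)], -pa[-seq_len(n1)]))
  }
  expect_error(roc_auc(toy_outcomes(c(0.2, 0.3), c("PD", "PD"))),
               "both classes")
})

test_that("AUC recovers the generating binormal separation", {
  # cohorts with equal-variance classes at offsets targeting known AUCs
  sdv <- 0.12
  for (theta in c(0.6, 0.75, 0.9)) {
    delta <- binormal_offset(theta, sdv)
    aucs <- vapply(1:100, function(s) {
      spec <- cohort_spec(mean_crpr = 0.6, mean_sd = 0.6 + delta,
                          mean_pd = 0.6 + delta,
                          sd_crpr = sdv, sd_sd = sdv, sd_pd = sdv,
                          seed = s)
      roc_auc(simulate_cohort(spec))$auc
    }, numeric(1))
    se <- sd(aucs) / sqrt(length(aucs))
    expect_lt(abs(mean(aucs) - theta), 3 * se)
  }
})

test_that("AUC confidence intervals bracket the estimate", {
  co <- simulate_cohort(cohort_spec(seed = 8))
  ci <- auc_confidence_interval(co)
  expect_equal(ci$method, "delong")
  expect_lte(ci$lower, ci$auc)
  expect_gte(ci$upper, ci$auc)
  expect_gte(ci$lower, 0)
  expect_lte(ci$upper, 1)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- pROC::ci.auc(pROC::roc(response = co$recist == "CR/PR",
                                  predictor = -co$pa, quiet = TRUE,
                                  direction = "<"), method = "delong")
    expect_equal(ci$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(ci$lower, max(0, as.numeric(ref[1])), tolerance = 1e-8)
    expect_equal(ci$upper, min(1, as.numeric(ref[3])), tolerance = 1e-8)
  }

  # perfect separation: DeLong degenerates, bootstrap takes over, upper = 1
  sep <- simulate_cohort(cohort_spec_separated(seed = 5))
  sep_pd <- sep[sep$recist %in% c("CR/PR", "PD"), ]
  expect_warning(cis <- auc_confidence_interval(sep_pd), "degenerate")
  expect_equal(cis$method, "bootstrap")
  expect_equal(cis$upper, 1)
  # bootstrap is reproducible bit for bit under a fixed seed
  b1 <- auc_confidence_interval(co, method = "bootstrap", seed = 42)
  b2 <- auc_confidence_interval(co, method = "bootstrap", seed = 42)
  expect_identical(b1, b2)
})

test_that("Fisher exact matches enumeration and stats::fisher.test", {
  t1 <- matrix(c(10, 0, 0, 10), 2)
  f1 <- fisher_exact(t1)
  expect_equal(f1$p_value, 2 / choose(20, 10))
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)

  set.seed(19)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) > 40 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      next
    }
    got <- fisher_exact(tab)$p_value
    expect_equal(got, fisher_enumeration_p(tab), tolerance = 1e-12)
    expect_equal(got, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("BH adjustment is monotone-preserving", {
  p <- c(0.001, 0.02, 0.04, 0.3, 0.9)
  adj <- adjust_bh(p)
  expect_equal(adj, p.adjust(p, "BH"))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj >= p))
})

test_that("waterfall table sorts descending with stable ties", {
  toy <- toy_outcomes(c(0.5, 1.2, 0.5, 0.8),
                      c("SD", "PD", "CR/PR", "SD"))
  w <- waterfall_table(toy)
  expect_equal(w$pa, sort(toy$pa, decreasing = TRUE))
  expect_equal(w$pa[1], max(toy$pa))
  expect_setequal(w$patient_id, toy$patient_id)
  # tied 0.5s keep their input order
  expect_equal(w$patient_id[3:4], c("P01", "P03"))
})

test_that("full concordance analysis is coherent on one cohort", {
  co <- simulate_cohort(cohort_spec(seed = 33))
  res <- analyze_concordance(co, seed = 1)
  expect_equal(sum(res$contingency), 60)
  expect_equal(res$accuracy_overall$n_included, 60)
  expect_equal(res$accuracy_crpr_vs_pd$n_included, 20)
  expect_lt(res$test_crpr_vs_pd$p_value, 0.05)
  expect_gte(res$roc_crpr_vs_pd$auc, res$roc_crpr_vs_sdpd$auc - 0.2)
  expect_equal(nrow(res$waterfall), 60)
  expect_true(!is.null(res$roc_prospective))
})
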