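#!/usr/bin/env Rscript
# Concordance between assay viabilities and RECIST outcomes on a synthetic
# validation cohort with the study composition (8 CR/PR, 40 SD, 12 PD;
# 33 prospective treatments): 2x3 contingency, accuracies, Mann-Whitney
# tests, ROC/AUC with DeLong CI, and the waterfall table.

suppressPackageStartupMessages(library(ptcscreen))
dir.create("results", showWarnings = FALSE)
seed <- 20260927L

cohort <- simulate_cohort(cohort_spec(seed = substream_seed(seed, "cohort")))
res <- analyze_concordance(cohort, cutoff = 0.7,
                           seed = substream_seed(seed, "ci"))

write_table_csv(cohort, "results/cohort.csv")
write_table_csv(res$waterfall, "results/waterfall.csv")
jsonlite::write_json(
  list(
    contingency = as.data.frame.matrix(res$contingency),
    accuracy_crpr_vs_pd = res$accuracy_crpr_vs_pd,
    accuracy_overall = res$accuracy_overall,
    wilcoxon_crpr_vs_pd = unclass(res$test_crpr_vs_pd),
    wilcoxon_crpr_vs_sdpd = unclass(res$test_crpr_vs_sdpd),
    auc_crpr_vs_pd = res$roc_crpr_vs_pd$auc,
    auc_crpr_vs_sdpd = res$roc_crpr_vs_sdpd$auc,
    auc_ci = unclass(res$ci_crpr_vs_sdpd),
    auc_prospective = if (!is.null(res$roc_prospective))
      res$roc_prospective$auc else NULL),
  "results/concordance.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("2x3 contingency (assay call x RECIST class):\n")
print(res$contingency)
cat(sprintf("\nCR/PR vs PD: accuracy %.0f%% (%d/%d), AUC %.3f, Wilcoxon p %.2e\n",
            100 * res$accuracy_crpr_vs_pd$accuracy,
            res$accuracy_crpr_vs_pd$n_concordant,
            res$accuracy_crpr_vs_pd$n_included,
            res$roc_crpr_vs_pd$auc, res$test_crpr_vs_pd$p_value))
cat(sprintf("CR/PR vs SD/PD: accuracy %.1f%% (%d/%d), AUC %.3f (95%% CI %.1f-%.1f%%)\n",
            100 * res$accuracy_overall$accuracy,
            res$accuracy_overall$n_concordant,
            res$accuracy_overall$n_included,
            res$roc_crpr_vs_sdpd$auc,
            100 * res$ci_crpr_vs_sdpd$lower, 100 * res$ci_crpr_vs_sdpd$upper))
if (!is.null(res$roc_prospective)) {
  cat(sprintf("Prospective treatments only: AUC %.3f (n = %d)\n",
              res$roc_prospective$auc, sum(cohort$prospective)))
}
cat("Wrote results/cohort.csv, waterfall.csv, concordance.json\n")
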