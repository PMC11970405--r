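test_that("growth trajectory follows the closed-form three-stage model", {
  # identity case: no growth, no decline, no noise
  p0 <- growth_params(exp_rate = 0, decline_rate = 0,
                      measurement_noise_cv = 0)
  tr <- simulate_growth_trajectory(p0, 10, seed = 1)
  expect_true(all(tr$total_area_um2 == tr$total_area_um2[1]))

  # compounding before the plateau: day 3 = day 0 * 1.2^3
  p <- growth_params(exp_rate = 0.2, plateau_start_day = 7,
                     measurement_noise_cv = 0)
  tr <- simulate_growth_trajectory(p, 5, seed = 1)
  expect_equal(tr$total_area_um2[4], tr$total_area_um2[1] * 1.2^3,
               tolerance = 1e-12)

  # plateau is flat, decline compounds downward
  p2 <- growth_params(exp_rate = 0.2, plateau_start_day = 3,
                      plateau_duration_days = 4, decline_rate = 0.1,
                      measurement_noise_cv = 0)
  tr2 <- simulate_growth_trajectory(p2, 12, seed = 1)
  expect_equal(tr2$true_area_um2[4:8], rep(tr2$true_area_um2[4], 5))
  expect_equal(tr2$true_area_um2[10] / tr2$true_area_um2[9], 0.9,
               tolerance = 1e-12)
})

test_that("growth parameter validation rejects bad inputs", {
  expect_error(growth_params(exp_rate = NaN), "finite")
  expect_error(growth_params(plateau_duration_days = -1), ">= 0")
  expect_error(growth_params(measurement_noise_cv = -0.1), ">= 0")
  expect_error(simulate_growth_trajectory(growth_params(), 0), ">= 1")
})

test_that("plateau lengths drawn in [5, 25] days are detected in range", {
  for (s in 1:10) {
    set.seed(s)
    dur <- round(runif(1, 5, 25))
    p <- growth_params(plateau_start_day = 5, plateau_duration_days = dur,
                       measurement_noise_cv = 0)
    tr <- simulate_growth_trajectory(p, 40, seed = s)
    ph <- classify_growth_phases(tr$total_area_um2, 0.05)
    expect_gte(ph$plateau_length_days, 5)
    expect_lte(ph$plateau_length_days, 25)
    expect_equal(ph$plateau_length_days, dur)
  }
})

test_that("rendered well images carry exact disk ground truth", {
  # empty well: background only, zero segmented clusters
  empty <- render_well_image(matrix(numeric(0), 0, 2), numeric(0),
                             pixel_size_um = 1, image_shape = c(64, 64))
  expect_equal(nrow(empty$ground_truth), 0)
  expect_equal(max(segment_clusters(empty$image)), 0)

  # one 100-um disk at 1 um/px: analytic area pi * 50^2
  one <- render_well_image(matrix(c(128, 128), 1), 100, 1,
                           image_shape = c(256, 256))
  expect_equal(one$ground_truth$area_um2, pi * 50^2)
  # rasterized area within one-pixel quantization of the analytic area
  expect_lt(abs(one$ground_truth$raster_area_um2 - pi * 50^2) / (pi * 50^2),
            0.02)
  expect_error(render_well_image(matrix(c(1, 1), 1), 10, 0), "> 0")
})

test_that("noise-free assay viabilities equal growth x dose-response", {
  panel <- default_drug_panel()
  gp <- growth_params()
  wells <- simulate_drug_assay(gp, panel$effects, panel$concentrations,
                               samples = c("A", "B"), replicates = 3,
                               noise_cv = 0, seed = 42)
  g <- growth_multiplier(gp, 0, 7)
  for (ef in panel$effects) {
    sub <- wells[wells$drug_id == ef$drug_id, ]
    expected <- g * hill_survival(ef, sub$concentration_um)
    expect_equal(sub$s_t1_um2 / sub$s_t0_um2, expected, tolerance = 1e-12)
    expect_equal(sub$true_viability, expected, tolerance = 1e-12)
  }
  # negative control wells carry the pure growth ratio
  nc <- wells[wells$drug_id == "NC", ]
  expect_equal(unique(nc$true_viability), g)
})

test_that("assay generator respects dose-response limits and validation", {
  gp <- growth_params()
  inert <- drug_effect_params("inert", potency = 1, max_kill = 0)
  w0 <- simulate_drug_assay(gp, inert, c(0.1, 1, 10), noise_cv = 0)
  g <- growth_multiplier(gp, 0, 7)
  expect_equal(unique(w0$true_viability), g)

  lethal <- drug_effect_params("lethal", potency = 1, max_kill = 1)
  whi <- simulate_drug_assay(gp, lethal, 1e9, noise_cv = 0)
  expect_lt(min(whi$true_viability), 1e-6 * g)

  expect_error(simulate_drug_assay(gp, inert, numeric(0)), "empty")
  expect_error(simulate_drug_assay(gp, inert, c(-1, 1)), "positive")
  expect_error(drug_effect_params("x", potency = -1), "potency")
  expect_error(drug_effect_params("x", potency = 1, max_kill = 1.2),
               "max_kill")
})

test_that("synthetic cohorts honor class counts and composition", {
  co <- simulate_cohort(cohort_spec(n_crpr = 8, n_sd = 40, n_pd = 12,
                                    seed = 3))
  expect_equal(nrow(co), 60)
  expect_equal(as.integer(table(co$recist)), c(8, 40, 12))
  expect_true(all(co$pa >= 0))
  expect_equal(sum(co$prospective), 33)
  expect_error(simulate_cohort(cohort_spec(n_crpr = 0, n_sd = 0, n_pd = 0)),
               "nonzero")
  expect_error(cohort_spec(n_crpr = -1), ">= 0")
})

test_that("identical classes give null AUC; identical seeds reproduce", {
  # exchangeable classes: AUC approaches 1/2
  aucs <- vapply(1:60, function(s) {
    spec <- cohort_spec(mean_crpr = 0.8, mean_sd = 0.8, mean_pd = 0.8,
                        sd_crpr = 0.2, sd_sd = 0.2, sd_pd = 0.2, seed = s)
    roc_auc(simulate_cohort(spec))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)) + 0.02)

  # bit-for-bit determinism across all generators
  expect_identical(simulate_cohort(cohort_spec(seed = 9)),
                   simulate_cohort(cohort_spec(seed = 9)))
  gp <- growth_params(measurement_noise_cv = 0.2)
  expect_identical(simulate_growth_trajectory(gp, 10, seed = 5),
                   simulate_growth_trajectory(gp, 10, seed = 5))
  pan <- default_drug_panel()
  expect_identical(
    simulate_drug_assay(gp, pan$effects[1:2], pan$concentrations[1:2],
                        noise_cv = 0.2, seed = 7),
    simulate_drug_assay(gp, pan$effects[1:2], pan$concentrations[1:2],
                        noise_cv = 0.2, seed = 7))
  im1 <- render_well_image(matrix(c(30, 30), 1), 40, 1, c(64, 64),
                           noise_sd = 0.05, seed = 4)
  im2 <- render_well_image(matrix(c(30, 30), 1), 40, 1, c(64, 64),
                           noise_sd = 0.05, seed = 4)
  expect_identical(im1$image, im2$image)
})

test_that("perfect-separation cohorts force accuracy and AUC to 1", {
  co <- simulate_cohort(cohort_spec_separated(seed = 21))
  expect_true(all(co$pa[co$recist == "CR/PR"] < 0.7))
  expect_true(all(co$pa[co$recist != "CR/PR"] >= 0.7))
  expect_identical(concordance_accuracy(co, "CRPR_vs_PD")$accuracy, 1)
  expect_identical(roc_auc(co[co$recist %in% c("CR/PR", "PD"), ])$auc, 1)
  # pairwise-counting oracle on the same data
  pos <- -co$pa[co$recist == "CR/PR"]
  neg <- -co$pa[co$recist == "PD"]
  expect_identical(mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")),
                   1)
})
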