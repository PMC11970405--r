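test_that("segmentation recovers disk phantoms and rejects bad images", {
  # three well-separated noise-free disks -> exactly three regions
  img <- render_well_image(rbind(c(60, 60), c(60, 180), c(180, 120)),
                           c(50, 60, 70), pixel_size_um = 1,
                           image_shape = c(240, 240))
  labels <- segment_clusters(img)
  expect_equal(max(labels), 3)

  # constant image: zero regions, not an error
  expect_equal(max(segment_clusters(matrix(0.5, 32, 32))), 0)
  expect_error(segment_clusters(matrix(c(NA, 1, 2, 3), 2)), "non-finite")
  expect_error(segment_clusters(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("measurement converts pixels to physical units correctly", {
  # a 100-pixel region at 2 um/px -> 400 um^2
  labels <- matrix(0L, 20, 20)
  labels[1:10, 1:10] <- 1L
  m <- measure_clusters(labels, pixel_size_um = 2)
  expect_equal(m$area_um2, 400)
  expect_equal(m$equivalent_diameter_um, 2 * sqrt(400 / pi))

  # single pixel at 1 um/px -> diameter 2/sqrt(pi)
  l1 <- matrix(0L, 4, 4)
  l1[2, 2] <- 1L
  expect_equal(measure_clusters(l1, 1)$equivalent_diameter_um, 2 / sqrt(pi))
  expect_error(measure_clusters(l1, 0), "> 0")
})

test_that("scale equivariance: doubling pixel size quadruples areas", {
  img <- render_well_image(rbind(c(80, 80), c(80, 200)), c(60, 90), 1,
                           image_shape = c(280, 280))
  labels <- segment_clusters(img)
  m1 <- measure_clusters(labels, 1)
  m2 <- measure_clusters(labels, 2)
  expect_equal(m2$area_um2, 4 * m1$area_um2)
  expect_equal(m2$equivalent_diameter_um, 2 * m1$equivalent_diameter_um)
})

test_that("diameter filter is strict, order-preserving and monotone", {
  m <- data.frame(cluster = 1:3,
                  area_um2 = pi * (c(30, 40, 41) / 2)^2,
                  equivalent_diameter_um = c(30, 40, 41),
                  centroid_row_px = 0, centroid_col_px = 0)
  kept <- filter_by_diameter(m, 40)
  expect_equal(kept$equivalent_diameter_um, 41)
  expect_equal(filter_by_diameter(m, 40,
                                  inclusive = TRUE)$equivalent_diameter_um,
               c(40, 41))
  expect_equal(nrow(filter_by_diameter(m[0, ], 40)), 0)
  expect_equal(filter_by_diameter(m, 0), m)
  expect_error(filter_by_diameter(m, -1), ">= 0")

  # raising the threshold never increases retained count or total area
  ths <- c(0, 20, 35, 40, 45, 100)
  sums <- vapply(ths, function(t) total_area(filter_by_diameter(m, t),
                                             "w", "t0")$total_area_um2,
                 numeric(1))
  ns <- vapply(ths, function(t) nrow(filter_by_diameter(m, t)), numeric(1))
  expect_true(all(diff(sums) <= 0))
  expect_true(all(diff(ns) <= 0))
})

test_that("total area sums retained clusters and rejects mixed wells", {
  m <- data.frame(area_um2 = c(100, 200, 300))
  s <- total_area(m, "w1", "t0")
  expect_equal(s$total_area_um2, 600)
  expect_equal(s$n_clusters_retained, 3)
  # permutation invariance
  expect_equal(total_area(m[c(3, 1, 2), , drop = FALSE])$total_area_um2, 600)
  # empty retained list
  s0 <- total_area(m[0, , drop = FALSE], "w1", "t1")
  expect_equal(s0$total_area_um2, 0)
  expect_equal(s0$n_clusters_retained, 0)
  mm <- data.frame(area_um2 = c(1, 2), well_id = c("a", "b"))
  expect_error(total_area(mm), "multiple wells")
})

test_that("noise-free pipeline closure recovers ground truth within 1%", {
  pl <- place_clusters(30, pixel_size_um = 2, image_shape = c(512, 512),
                       seed = 8)
  well <- render_well_image(pl$centers, pl$diameters_um, pixel_size_um = 2)
  q <- quantify_well(well, imaging_config(pixel_size_um = 2))
  gt <- sum(well$ground_truth$area_um2[well$ground_truth$diameter_um > 40])
  expect_lt(abs(q$summary$total_area_um2 - gt) / gt, 0.01)
  # measured equivalent diameters within 2 px-equivalents of the truth
  meas_d <- sort(q$measurements$equivalent_diameter_um)
  true_d <- sort(pl$diameters_um)
  expect_true(all(abs(meas_d - true_d) < 2 * 2))
})

test_that("segmentation tolerates blur and noise at SNR 5", {
  # contrast 0.6, noise SD 0.12 -> SNR 5, plus 2 px Gaussian blur
  img <- render_well_image(rbind(c(70, 70), c(70, 190), c(190, 130)),
                           c(60, 80, 100), 1, image_shape = c(256, 256),
                           background = 0.85, foreground = 0.25,
                           noise_sd = 0.12, blur_sigma_px = 2, seed = 5)
  q <- quantify_well(img, imaging_config())
  expect_equal(nrow(q$measurements), 3)
  meas <- sort(q$measurements$area_um2)
  truth <- sort(img$ground_truth$area_um2)
  expect_true(all(abs(meas - truth) / truth < 0.05))
})

test_that("well images round-trip through TIFF plus sidecar", {
  pl <- place_clusters(5, seed = 3)
  well <- render_well_image(pl$centers, pl$diameters_um, 1,
                            image_shape = c(128, 128))
  path <- tempfile(fileext = ".tiff")
  write_well_image(well, path)
  back <- read_well_image(path)
  expect_equal(back$pixel_size_um, 1)
  expect_equal(back$ground_truth$area_um2, well$ground_truth$area_um2)
  # 16-bit quantization: intensities equal within 1/65535
  expect_lt(max(abs(back$image - well$image)), 1 / 65000)
  q1 <- quantify_well(well)
  q2 <- quantify_well(back)
  expect_equal(q2$summary$total_area_um2, q1$summary$total_area_um2)
})
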