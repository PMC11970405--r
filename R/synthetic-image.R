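#' Render a synthetic brightfield well image from disk phantoms
#'
#' Clusters appear as darker disks on a brighter background, mimicking
#' transmitted-light micrographs of PTC wells. A pixel belongs to a disk if
#' its centre falls inside the circle; ground-truth rasterized and analytic
#' areas per cluster are recorded in the metadata so segmentation accuracy
#' can be audited.
#'
#' @param centers two-column matrix of disk centres (row, col) in pixels;
#'   may have zero rows for an empty well.
#' @param diameters_um disk diameters, um (one per centre).
#' @param pixel_size_um physical pixel size, um per pixel (> 0).
#' @param image_shape c(rows, cols) of the image grid.
#' @param background,foreground background and disk intensities in \[0, 1\].
#' @param noise_sd additive Gaussian noise SD (0 = noise-free).
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 = none).
#' @param seed integer seed for the noise.
#' @return a `well_image` list: `image` (numeric matrix), `pixel_size_um`,
#'   and `ground_truth` data.frame (`cluster`, `diameter_um`,
#'   `area_um2` = analytic disk area, `raster_area_um2` = rasterized area).
#' @export
render_well_image <- function(centers, diameters_um, pixel_size_um,
                              image_shape = c(512L, 512L),
                              background = 0.85, foreground = 0.25,
                              noise_sd = 0, blur_sigma_px = 0, seed = 1L) {
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0", call. = FALSE)
  }
  centers <- matrix(as.numeric(centers), ncol = 2)
  n <- nrow(centers)
  if (n != length(diameters_um)) {
    stop("one diameter per centre required", call. = FALSE)
  }
  img <- matrix(background, image_shape[1], image_shape[2])
  raster_px <- numeric(n)
  if (n > 0) {
    rr <- matrix(seq_len(image_shape[1]), image_shape[1], image_shape[2])
    cc <- matrix(seq_len(image_shape[2]), image_shape[1], image_shape[2],
                 byrow = TRUE)
    for (k in seq_len(n)) {
      r_px <- (diameters_um[k] / 2) / pixel_size_um
      inside <- (rr - centers[k, 1])^2 + (cc - centers[k, 2])^2 <= r_px^2
      raster_px[k] <- sum(inside)
      img[inside] <- foreground
    }
  }
  if (blur_sigma_px > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma_px))
  }
  if (noise_sd > 0) {
    img <- with_seed(seed, img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img)))
  }
  gt <- data.frame(
    cluster = seq_len(n),
    diameter_um = if (n > 0) diameters_um else numeric(0),
    area_um2 = if (n > 0) pi * (diameters_um / 2)^2 else numeric(0),
    raster_area_um2 = raster_px * pixel_size_um^2
  )
  structure(list(image = img, pixel_size_um = pixel_size_um,
                 ground_truth = gt),
            class = "well_image")
}

#' Place non-overlapping disk phantoms in a well
#'
#' Convenience sampler used by the imaging tests and the demo pipeline:
#' draws `n` cluster diameters from the seeding log-normal and rejection-
#' samples centres so disks are separated by at least `margin_px`.
#'
#' @param n number of clusters (seeding default is 30-50 per well).
#' @param params a [growth_params()] object supplying the diameter
#'   distribution.
#' @param pixel_size_um um per pixel.
#' @param image_shape image grid dimensions.
#' @param margin_px minimum gap between disk rims, pixels.
#' @param seed integer seed.
#' @return list with `centers` and `diameters_um`, usable directly by
#'   [render_well_image()].
#' @export
place_clusters <- function(n, params = growth_params(), pixel_size_um = 1,
                           image_shape = c(512L, 512L), margin_px = 4,
                           seed = 1L) {
  with_seed(seed, {
    diam <- exp(stats::rnorm(n, params$initial_diameter_log_mean,
                             params$initial_diameter_log_sd))
    r_px <- (diam / 2) / pixel_size_um
    centers <- matrix(NA_real_, n, 2)
    for (k in seq_len(n)) {
      for (try in 1:2000) {
        cand <- c(stats::runif(1, r_px[k] + 1, image_shape[1] - r_px[k] - 1),
                  stats::runif(1, r_px[k] + 1, image_shape[2] - r_px[k] - 1))
        ok <- TRUE
        if (k > 1) {
          d <- sqrt(rowSums((centers[seq_len(k - 1), , drop = FALSE] -
                               matrix(cand, k - 1, 2, byrow = TRUE))^2))
          ok <- all(d > r_px[k] + r_px[seq_len(k - 1)] + margin_px)
        }
        if (ok) {
          centers[k, ] <- cand
          break
        }
      }
      if (anyNA(centers[k, ])) {
        stop("could not place clusters without overlap; reduce n or sizes",
             call. = FALSE)
      }
    }
    list(centers = centers, diameters_um = diam)
  })
}

#' Write a well image as TIFF with a JSON sidecar
#'
#' The sidecar records the pixel size and ground-truth cluster table so a
#' written image round-trips losslessly through [read_well_image()].
#'
#' @param well a `well_image` from [render_well_image()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @export
write_well_image <- function(well, path) {
  stopifnot(inherits(well, "well_image"))
  img <- pmin(pmax(well$image, 0), 1)
  EBImage::writeImage(EBImage::Image(img), path, type = "tiff",
                      bits.per.sample = 16L)
  meta <- list(pixel_size_um = well$pixel_size_um,
               ground_truth = well$ground_truth)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a well image written by [write_well_image()]
#'
#' @param path TIFF path with a `<path>.json` sidecar.
#' @return a `well_image` list.
#' @export
read_well_image <- function(path) {
  img <- as.matrix(EBImage::readImage(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(image = img, pixel_size_um = meta$pixel_size_um,
                 ground_truth = as.data.frame(meta$ground_truth)),
            class = "well_image")
}
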