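#' Default imaging configuration
#'
#' @param pixel_size_um physical pixel size, um per pixel.
#' @param min_diameter_um diameter filter threshold, um; clusters must
#'   exceed this to be retained (strict by default).
#' @param inclusive_filter if TRUE the diameter filter keeps clusters equal
#'   to the threshold as well (sensitivity-analysis switch; default FALSE).
#' @param opening_radius_px radius of the morphological opening brush; must
#'   be smaller than the smallest cluster of interest.
#' @param polarity `"auto"` detects whether clusters are darker or brighter
#'   than background from the Otsu split; `"dark"`/`"bright"` force it.
#' @return a list of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size_um = 1, min_diameter_um = 40,
                           inclusive_filter = FALSE,
                           opening_radius_px = 3, polarity = "auto") {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  if (min_diameter_um < 0) stop("min_diameter_um must be >= 0", call. = FALSE)
  polarity <- match.arg(polarity, c("auto", "dark", "bright"))
  structure(list(pixel_size_um = pixel_size_um,
                 min_diameter_um = min_diameter_um,
                 inclusive_filter = inclusive_filter,
                 opening_radius_px = opening_radius_px,
                 polarity = polarity),
            class = "imaging_config")
}

#' Segment PTC clusters in a well image
#'
#' Global Otsu threshold on the (polarity-corrected) intensities, hole
#' filling, morphological opening with a brush smaller than the minimum
#' cluster, then connected-component labelling. Background is 0 and cluster
#' labels are positive integers. A constant image yields zero regions.
#'
#' @param image numeric intensity matrix, or a `well_image`.
#' @param config an [imaging_config()].
#' @return integer label matrix of the same shape as the image.
#' @export
segment_clusters <- function(image, config = imaging_config()) {
  if (inherits(image, "well_image")) image <- image$image
  if (!is.matrix(image) || length(image) == 0) {
    stop("image must be a non-empty matrix", call. = FALSE)
  }
  if (any(!is.finite(image))) {
    stop("image contains non-finite pixel values", call. = FALSE)
  }
  rng <- range(image)
  if (rng[1] == rng[2]) {
    return(matrix(0L, nrow(image), ncol(image)))
  }
  # scale to [0, 1] for a stable Otsu split
  x <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  mask <- x > thr
  if (config$polarity == "dark" ||
      (config$polarity == "auto" && mean(mask) > 0.5)) {
    # clusters darker than background: foreground is the low side
    mask <- !mask
  }
  mask <- EBImage::Image(mask * 1)
  mask <- EBImage::fillHull(mask)
  if (config$opening_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * config$opening_radius_px + 1,
                                shape = "disc")
    mask <- EBImage::opening(mask, brush)
  }
  labels <- EBImage::bwlabel(mask)
  matrix(as.integer(labels), nrow(image), ncol(image))
}

#' Measure segmented clusters in physical units
#'
#' Area is pixel count times `pixel_size_um^2`; the equivalent diameter is
#' that of the circle with the same area, `2 * sqrt(area / pi)`.
#'
#' @param labels integer label matrix from [segment_clusters()].
#' @param pixel_size_um um per pixel (> 0).
#' @return data.frame of class `cluster_measurements`: `cluster`,
#'   `area_um2`, `equivalent_diameter_um`, `centroid_row_px`,
#'   `centroid_col_px`.
#' @export
measure_clusters <- function(labels, pixel_size_um) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0) {
    out <- data.frame(cluster = integer(0), area_um2 = numeric(0),
                      equivalent_diameter_um = numeric(0),
                      centroid_row_px = numeric(0),
                      centroid_col_px = numeric(0))
  } else {
    px <- tabulate(labels, nbins = max(ids))[ids]
    rows <- row(labels)
    cols <- col(labels)
    cr <- vapply(ids, function(i) mean(rows[labels == i]), numeric(1))
    cc <- vapply(ids, function(i) mean(cols[labels == i]), numeric(1))
    area <- px * pixel_size_um^2
    out <- data.frame(cluster = ids, area_um2 = area,
                      equivalent_diameter_um = 2 * sqrt(area / pi),
                      centroid_row_px = cr, centroid_col_px = cc)
  }
  class(out) <- c("cluster_measurements", "data.frame")
  out
}

#' Filter clusters by equivalent diameter
#'
#' Retains clusters whose equivalent diameter exceeds `min_diameter_um`
#' (strict inequality, matching a "diameters exceeding" selection rule);
#' input order is preserved. Set `inclusive = TRUE` to keep boundary
#' clusters as well.
#'
#' @param measurements a `cluster_measurements` data.frame.
#' @param min_diameter_um threshold, um (>= 0); default 40.
#' @param inclusive keep clusters exactly at the threshold too.
#' @return the retained rows, same class and order.
#' @export
filter_by_diameter <- function(measurements, min_diameter_um = 40,
                               inclusive = FALSE) {
  if (min_diameter_um < 0) {
    stop("min_diameter_um must be >= 0", call. = FALSE)
  }
  d <- measurements$equivalent_diameter_um
  keep <- if (inclusive) d >= min_diameter_um else d > min_diameter_um
  measurements[keep, , drop = FALSE]
}

#' Total retained cluster area for one well and timepoint
#'
#' @param retained a `cluster_measurements` data.frame (post-filter).
#' @param well_id well identifier.
#' @param timepoint `"t0"` or `"t1"`.
#' @return one-row data.frame: `well_id`, `timepoint`,
#'   `n_clusters_retained`, `total_area_um2`.
#' @export
total_area <- function(retained, well_id = "well", timepoint = "t0") {
  if (!is.null(retained$well_id) &&
      length(unique(retained$well_id)) > 1L) {
    stop("measurements span multiple wells; summarise one well at a time",
         call. = FALSE)
  }
  data.frame(well_id = well_id, timepoint = timepoint,
             n_clusters_retained = nrow(retained),
             total_area_um2 = sum(retained$area_um2))
}

#' Quantify a well image end to end
#'
#' segment -> measure -> diameter filter -> total area, returning both the
#' per-cluster table and the well summary.
#'
#' @param well a `well_image` (or plain matrix plus `pixel_size_um` in the
#'   config).
#' @param config an [imaging_config()].
#' @param well_id,timepoint identifiers copied into the summary.
#' @return list with `measurements` (all clusters), `retained` and
#'   `summary` (one row).
#' @export
quantify_well <- function(well, config = imaging_config(),
                          well_id = "well", timepoint = "t0") {
  px <- if (inherits(well, "well_image")) well$pixel_size_um
        else config$pixel_size_um
  labels <- segment_clusters(well, config)
  meas <- measure_clusters(labels, px)
  kept <- filter_by_diameter(meas, config$min_diameter_um,
                             inclusive = config$inclusive_filter)
  list(measurements = meas, retained = kept,
       summary = total_area(kept, well_id, timepoint))
}
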