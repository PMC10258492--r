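# Per-fiber morphometry and per-section aggregation.
#
# The two exported metrics per fiber are the lesser diameter — the
# minimum Feret (caliper) diameter of the region's convex hull, the
# standard reading of "maximum diameter across the lesser aspect", robust
# to oblique sectioning — and the cross-sectional area. Interior holes in
# a fiber region are unstained artifacts (a myofiber cross-section is
# simply connected) and are filled before measurement.

#' Cross-sectional area of a fiber region
#'
#' Pixel count after hole filling, divided by the squared calibration.
#' Holes — background pixels fully enclosed by the region — are counted
#' as fiber.
#'
#' @param pixels Either an `n x 2` matrix of pixel coordinates (columns
#'   x, y) or a single pixel count. Coordinate input is hole-filled
#'   before counting.
#' @param px_per_um Pixels per micrometer.
#' @return Area in um^2.
#' @examples
#' fiber_area(1089, px_per_um = 1)    # 1089 um^2
#' fiber_area(19008, px_per_um = 6.6) # ~436.36 um^2
#' @export
fiber_area <- function(pixels, px_per_um) {
  if (px_per_um <= 0) stop_validation("px_per_um must be positive")
  n <- if (is.matrix(pixels)) sum(fill_region(pixels)) else as.numeric(pixels)
  if (length(n) != 1 || n <= 0) stop_validation("pixel set must be nonempty")
  n / px_per_um^2
}

# hole-filled logical window of a pixel-coordinate set (x, y columns)
fill_region <- function(pixels) {
  x <- pixels[, 1]; y <- pixels[, 2]
  x0 <- min(x); y0 <- min(y)
  win <- matrix(FALSE, max(y) - y0 + 1L, max(x) - x0 + 1L)
  win[cbind(y - y0 + 1L, x - x0 + 1L)] <- TRUE
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(win))) != 0
  attr(filled, "origin") <- c(x = x0, y = y0)
  filled
}

measure_region <- function(region, px_per_um) {
  filled <- fill_region(region$pixels)
  list(
    lesser_diameter_um = min_feret_diameter(region$polygon, px_per_um),
    area_um2 = sum(filled) / px_per_um^2,
    centroid = region$centroid
  )
}

#' Measure every fiber of a label mask
#'
#' Converts the mask to regions ([labels_to_regions()]), measures the
#' lesser diameter and cross-sectional area of each, and aggregates a
#' per-section summary: fiber count, mean and SEM of diameter and area,
#' diameter CV, tissue area and fiber densities. SEM uses the sample
#' standard deviation (n - 1).
#'
#' Density denominators: `tissue_area_mm2` is the section's stained
#' support — pixels whose stain score exceeds 0.05 or that belong to a
#' fiber, closed with a 5 um disc to bridge the endomysium — when
#' `image` is supplied; without an image it falls back to the closed
#' union of the fiber labels. The raw image area is also reported
#' (`image_area_mm2`, with `fibers_per_mm2_image`) since either
#' normalization is defensible; the tissue-area density is the default.
#'
#' @param mask A [label_mask()], typically after [filter_labels()].
#' @param source_id Identifier stored in every record.
#' @param image Optional [calibrated_image()] the mask derives from,
#'   used for the tissue-support estimate.
#' @param connectivity Label connectivity passed to [labels_to_regions()].
#' @param validate Passed to [labels_to_regions()].
#' @return A list with `records` (data frame: `source_id`, `fiber_id`,
#'   `lesser_diameter_um`, `area_um2`, `centroid_x_px`, `centroid_y_px`)
#'   and `summary` (one-row data frame). An empty mask yields zero rows
#'   and `n_fibers = 0` with NA means.
#' @export
measure_section <- function(mask, source_id = "", image = NULL,
                            connectivity = 8L, validate = TRUE) {
  stopifnot(inherits(mask, "label_mask"))
  ppu <- mask$px_per_um
  regions <- labels_to_regions(mask, connectivity = connectivity, validate = validate)
  if (length(regions) == 0) {
    records <- data.frame(source_id = character(0), fiber_id = integer(0),
                          lesser_diameter_um = numeric(0), area_um2 = numeric(0),
                          centroid_x_px = numeric(0), centroid_y_px = numeric(0))
  } else {
    meas <- lapply(regions, measure_region, px_per_um = ppu)
    records <- data.frame(
      source_id = source_id,
      fiber_id = vapply(regions, `[[`, integer(1), "label"),
      lesser_diameter_um = vapply(meas, `[[`, numeric(1), "lesser_diameter_um"),
      area_um2 = vapply(meas, `[[`, numeric(1), "area_um2"),
      centroid_x_px = vapply(regions, function(r) r$centroid[["x"]], numeric(1)),
      centroid_y_px = vapply(regions, function(r) r$centroid[["y"]], numeric(1))
    )
  }
  list(records = records,
       summary = summarize_section(records, mask, source_id, image))
}

summarize_section <- function(records, mask, source_id, image = NULL) {
  ppu <- mask$px_per_um
  n <- nrow(records)
  px_per_mm2 <- (ppu * 1000)^2
  image_area_mm2 <- length(mask$labels) / px_per_mm2
  tissue_area_mm2 <- tissue_support_px(mask, image) / px_per_mm2
  m_or_na <- function(x) if (n >= 1) mean(x) else NA_real_
  sem <- function(x) if (n >= 2) sd(x) / sqrt(n) else if (n == 1) 0 else NA_real_
  data.frame(
    source_id = source_id,
    n_fibers = n,
    mean_diameter_um = m_or_na(records$lesser_diameter_um),
    sem_diameter_um = sem(records$lesser_diameter_um),
    cv_diameter_percent = if (n >= 2 && mean(records$lesser_diameter_um) != 0) {
      coefficient_of_variance(records$lesser_diameter_um)
    } else NA_real_,
    mean_area_um2 = m_or_na(records$area_um2),
    sem_area_um2 = sem(records$area_um2),
    tissue_area_mm2 = tissue_area_mm2,
    image_area_mm2 = image_area_mm2,
    fibers_per_mm2 = if (tissue_area_mm2 > 0) n / tissue_area_mm2 else NA_real_,
    fibers_per_mm2_image = n / image_area_mm2
  )
}

# pixels counted as muscle tissue for the density denominator
tissue_support_px <- function(mask, image = NULL) {
  support <- mask$labels > 0L
  if (!is.null(image)) {
    support <- support | stain_separation(image, 0) > 0.05
  }
  if (!any(support)) return(0)
  radius_px <- max(1, round(5 * mask$px_per_um))
  brush <- EBImage::makeBrush(2 * radius_px + 1, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(support), brush)
  sum(as.matrix(closed) != 0)
}

#' Bin a diameter distribution
#'
#' Clusters lesser diameters into left-closed, right-open bins
#' (`[0, w), [w, 2w), ...`) of width `bin_width_um` (default 5 um, the
#' conventional presentation for myofiber size distributions), up to the
#' bin containing the maximum.
#'
#' @param records Per-fiber data frame with a `lesser_diameter_um`
#'   column, or a numeric vector of diameters.
#' @param bin_width_um Positive bin width in um.
#' @return A data frame with `bin_low_um`, `bin_high_um`, `count` and
#'   `percent` (of total; sums to 100). Empty input yields zero rows.
#' @export
bin_diameters <- function(records, bin_width_um = 5) {
  if (bin_width_um <= 0) stop_validation("bin_width_um must be positive")
  d <- if (is.data.frame(records)) records$lesser_diameter_um else as.numeric(records)
  if (length(d) == 0) {
    return(data.frame(bin_low_um = numeric(0), bin_high_um = numeric(0),
                      count = integer(0), percent = numeric(0)))
  }
  if (anyNA(d) || any(d < 0)) stop_validation("diameters must be nonnegative")
  idx <- floor(d / bin_width_um)           # [0,w) -> 0, [w,2w) -> 1, ...
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  data.frame(
    bin_low_um = (seq_along(counts) - 1) * bin_width_um,
    bin_high_um = seq_along(counts) * bin_width_um,
    count = counts,
    percent = counts / sum(counts) * 100
  )
}
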