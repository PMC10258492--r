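# Synthetic SRFG-like muscle cross-sections with exact ground truth.
#
# Construction: fiber centers on a jittered grid; a power (Laguerre)
# diagram — a Voronoi tessellation whose generator weights come from
# per-fiber diameter draws (zero-truncated normal, matching the
# near-Gaussian fiber-size histograms of real muscle) — allocates more
# space to fibers drawn large; each cell is then shrunk to its drawn
# lesser diameter
# plus half the endomysium width using the distance-to-tessellation-edge
# map, which guarantees a background gap of at least border_width_um
# between any two fibers. Rendering paints fibers green-dominant and
# background red-dominant with mild multiplicative noise, mimicking
# Picrosirius Red Fast Green staining.

#' Parameters of a synthetic muscle cross-section
#'
#' Defaults emulate the morphology reported for 14-day-old broiler
#' pectoral muscle: mean lesser diameter about 22.8 um with a coefficient
#' of variance around 32%, fibers separated by a thin (~2 um) endomysium.
#'
#' @param image_size_px Integer `(height, width)` of the output, pixels.
#' @param px_per_um Pixels per micrometer (default 6.6).
#' @param target_mean_diameter_um Target mean lesser diameter, um.
#' @param target_cv_percent Target coefficient of variance of the lesser
#'   diameter, percent.
#' @param border_width_um Endomysium (background) thickness separating
#'   neighboring fibers, um; must be smaller than the mean diameter.
#' @param jitter Fiber-center irregularity in `[0, 1]`: 0 gives a regular
#'   grid, 1 displaces centers by up to half the grid spacing.
#' @param seed Integer seed; identical parameters (including the seed)
#'   produce bit-identical sections.
#' @return A list of class `section_params`.
#' @export
section_params <- function(image_size_px = c(600L, 600L),
                           px_per_um = 6.6,
                           target_mean_diameter_um = 22.8,
                           target_cv_percent = 32,
                           border_width_um = 2,
                           jitter = 0.5,
                           seed = 1L) {
  p <- list(image_size_px = as.integer(image_size_px),
            px_per_um = as.numeric(px_per_um),
            target_mean_diameter_um = as.numeric(target_mean_diameter_um),
            target_cv_percent = as.numeric(target_cv_percent),
            border_width_um = as.numeric(border_width_um),
            jitter = as.numeric(jitter),
            seed = as.integer(seed))
  validate_section_params(p)
  structure(p, class = "section_params")
}

validate_section_params <- function(p) {
  if (length(p$image_size_px) != 2 || any(p$image_size_px < 1)) {
    stop_validation("image_size_px must be two positive integers (height, width)")
  }
  if (p$px_per_um <= 0) stop_validation("px_per_um must be positive")
  if (p$target_mean_diameter_um <= 0) stop_validation("target_mean_diameter_um must be positive")
  if (p$target_cv_percent < 0) stop_validation("target_cv_percent must be nonnegative")
  if (p$target_mean_diameter_um * p$px_per_um < 6) {
    stop_validation(paste0("fibers would span < 6 px (mean diameter ",
                           p$target_mean_diameter_um, " um at ", p$px_per_um,
                           " px/um); increase the resolution or the diameter"))
  }
  if (p$border_width_um <= 0) stop_validation("border_width_um must be positive")
  if (p$border_width_um >= p$target_mean_diameter_um) {
    stop_validation("border_width_um must be smaller than target_mean_diameter_um")
  }
  if (p$jitter < 0 || p$jitter > 1) stop_validation("jitter must lie in [0, 1]")
  invisible(p)
}

# run fn with the RNG seeded, restoring the caller's RNG state afterwards
with_rng_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic stained cross-section with ground truth
#'
#' Produces a green-fiber / red-background RGB image together with the
#' exact integer label mask it was rendered from and per-fiber ground
#' truth measured by the package's own geometry engine
#' ([min_feret_diameter()], [fiber_area()]). Fibers clipped by the image
#' edge are still labeled; downstream QC ([filter_labels()]) decides
#' their fate, exactly as for real sections.
#'
#' @param params A [section_params()] object.
#' @return A list with elements `image` (a [calibrated_image()]) and
#'   `gt`, itself a list with `mask` (a [label_mask()]) and
#'   `true_records` (the ground-truth fiber table, see
#'   [measure_section()] for the schema).
#' @export
generate_section <- function(params) {
  validate_section_params(params)
  with_rng_seed(params$seed, function() generate_section_impl(params))
}

generate_section_impl <- function(params) {
  h <- params$image_size_px[1]; w <- params$image_size_px[2]
  ppu <- params$px_per_um
  mean_d <- params$target_mean_diameter_um * ppu      # px
  cv <- params$target_cv_percent / 100
  border <- params$border_width_um * ppu              # px

  # grid spacing from the expected fiber footprint (diameter + border),
  # inflated by the relative size spread so upper-tail draws still fit
  # their (weight-enlarged) cells instead of being truncated
  spacing <- (mean_d + border) * (1 + cv)
  gi_n <- max(1L, ceiling(h / spacing) + 2L)   # grid rows (extends past edges)
  gj_n <- max(1L, ceiling(w / spacing) + 2L)
  gy0 <- (h - gi_n * spacing) / 2
  gx0 <- (w - gj_n * spacing) / 2
  n_cells <- gi_n * gj_n

  # jittered centers, row-major over the grid
  cy <- gy0 + (rep(seq_len(gi_n), each = gj_n) - 0.5) * spacing
  cx <- gx0 + (rep(seq_len(gj_n), times = gi_n) - 0.5) * spacing
  cy <- cy + runif(n_cells, -0.5, 0.5) * params$jitter * spacing
  cx <- cx + runif(n_cells, -0.5, 0.5) * params$jitter * spacing

  # zero-truncated normal lesser-diameter draws with the target mean and
  # CV: fiber-size histograms are near-Gaussian, and at these parameters
  # the truncation point sits ~3 sigma below the mean, so mean/CV are
  # preserved to well below measurement noise while sizes stay positive
  draw_d <- if (cv > 0) {
    d <- rnorm(n_cells, mean_d, cv * mean_d)
    while (any(bad <- d < 1)) d[bad] <- rnorm(sum(bad), mean_d, cv * mean_d)
    d
  } else {
    rep(mean_d, n_cells)
  }

  # power-diagram assignment: label(p) = argmin_k |p - c_k|^2 - (d_k/2)^2,
  # restricted to the 5x5 grid neighborhood of each pixel (weights are
  # bounded by cell sizes, so farther generators cannot win)
  py <- rep(seq_len(h), times = w)   # column-major like R matrices
  px <- rep(seq_len(w), each = h)
  pgi <- pmin(pmax(floor((py - gy0) / spacing) + 1, 1), gi_n)
  pgj <- pmin(pmax(floor((px - gx0) / spacing) + 1, 1), gj_n)
  best <- rep(Inf, h * w)
  lab <- integer(h * w)
  wgt <- (draw_d / 2)^2
  for (di in -2:2) {
    gi <- pgi + di
    ok_i <- gi >= 1L & gi <= gi_n
    for (dj in -2:2) {
      gj <- pgj + dj
      ok <- ok_i & gj >= 1L & gj <= gj_n
      k <- (gi - 1L) * gj_n + gj            # candidate cell index
      k[!ok] <- 1L                          # placeholder, masked below
      val <- (py - cy[k])^2 + (px - cx[k])^2 - wgt[k]
      val[!ok] <- Inf
      upd <- val < best
      best[upd] <- val[upd]
      lab[upd] <- k[upd]
    }
  }
  lab_m <- matrix(lab, h, w)

  # tessellation edges: pixels whose 4-neighbor carries a different label
  edge <- matrix(FALSE, h, w)
  dif <- lab_m[-h, ] != lab_m[-1, ]
  edge[-h, ][dif] <- TRUE; edge[-1, ][dif] <- TRUE
  dif <- lab_m[, -w] != lab_m[, -1]
  edge[, -w][dif] <- TRUE; edge[, -1][dif] <- TRUE

  # distance of each pixel to the nearest tessellation-edge pixel, i.e.
  # to its own cell's boundary (image borders do not count as edges, so
  # edge cells extend to the image rim and get clipped)
  dedge <- as.numeric(EBImage::distmap(EBImage::Image(!edge)))
  dim(dedge) <- c(h, w)

  # per-cell shrink: erode to the drawn diameter (cell inradius m_k down
  # to d_k/2) but never less than half the endomysium width; +0.5 px
  # guards the >= border gap against pixel quantization
  # per-cell erosion: eroding a convex cell by a disc of radius e
  # reduces its minimum caliper width by exactly 2e, so the erosion that
  # realizes the drawn width d_k is (c_k - d_k) / 2 with c_k the cell's
  # own minimum Feret width (measured on its crack boundary). The floor
  # border/2 + 0.5 keeps the >= border gap under pixel quantization.
  cell_regions <- labels_to_regions(label_mask(lab_m, ppu), validate = FALSE)
  c_k <- rep(0, n_cells)
  for (reg in cell_regions) {
    c_k[reg$label] <- min_feret_diameter(reg$polygon, 1)
  }
  # digitization correction: the distance map is measured from pixel
  # centers half a pixel inside the crack boundary, and thresholding a
  # quantized distance rounds the kept band inward by a further fraction
  # of a pixel; together they shave ~0.9 px per side off the realized
  # width, so the erosion threshold is relaxed by that amount (the
  # border floor is not, keeping the >= border gap guarantee)
  e_k <- pmax(border / 2 + 0.5, (c_k - draw_d) / 2 - 0.875)
  keep <- dedge >= e_k[lab]
  lab_m[!keep] <- 0L

  # relabel surviving fibers 1..N in raster order of centroid
  nzi <- which(lab_m > 0L)
  if (length(nzi)) {
    v <- lab_m[nzi]
    r_i <- ((nzi - 1L) %% h) + 1L
    c_i <- ((nzi - 1L) %/% h) + 1L
    cnt <- rowsum(rep(1, length(v)), v)
    cy_f <- rowsum(as.numeric(r_i), v) / cnt
    cx_f <- rowsum(as.numeric(c_i), v) / cnt
    ord <- order(cy_f, cx_f)
    remap <- integer(n_cells)
    remap[as.integer(rownames(cnt))[ord]] <- seq_along(ord)
    lab_m[nzi] <- remap[v]
  }
  mask <- label_mask(lab_m, ppu)

  # render: fiber interiors green-dominant, everything else red-dominant
  fiber <- lab_m > 0L
  base_bg <- c(185, 95, 105); base_fg <- c(80, 175, 110)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(base_bg[ch], h, w)
    plane[fiber] <- base_fg[ch]
    img[, , ch] <- plane
  }
  # +/-5% multiplicative noise; base colours stay within 0..255 under it
  img <- round(img * runif(h * w * 3, 0.95, 1.05))
  source_id <- sprintf("synthetic_seed%d", params$seed)
  image <- calibrated_image(img, ppu, source_id)

  gt <- list(mask = mask,
             true_records = true_metrics(list(mask = mask), source_id = source_id))
  list(image = image, gt = gt)
}

#' Ground-truth metrics of a generated section
#'
#' Measures every label of a ground-truth mask with the same geometry
#' engine used by the main pipeline, yielding the oracle fiber table for
#' parameter-recovery and segmentation-quality tests.
#'
#' @param gt A ground-truth list with element `mask` (a [label_mask()]),
#'   as returned in `generate_section()$gt`.
#' @param source_id Identifier stored in the records.
#' @return A per-fiber data frame (see [measure_section()] for columns).
#' @export
true_metrics <- function(gt, source_id = "ground_truth") {
  measure_section(gt$mask, source_id = source_id, validate = FALSE)$records
}
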