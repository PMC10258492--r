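# Classical segmentation backend and label post-processing.
#
# The detection contract of the pipeline is the label mask, so any
# external segmenter (e.g. a deep-learning detector) can be plugged in
# via read_label_mask(). The in-package backend exploits the staining
# contrast directly: a green-vs-red stain score, Otsu foreground
# thresholding, and marker-controlled watershed on the Euclidean distance
# transform with h-maxima marker suppression.

#' Segmentation parameters
#'
#' @param smoothing_sigma_um Gaussian smoothing of the stain score, um
#'   (0 disables smoothing; default 1).
#' @param h_maxima_um Marker-suppression depth for the watershed, in
#'   distance-map units (um). Distance-map maxima shallower than this are
#'   merged with their neighbor basin, preventing over-segmentation of
#'   single fibers; default 2.
#' @param min_area_um2 Minimum fiber area kept by [filter_labels()], um^2
#'   (default 50, about an 8 um equivalent diameter — debris below the
#'   smallest populated histogram bin).
#' @param exclude_border Drop labels touching the image edge (default
#'   TRUE: partial fibers bias the lesser diameter downward).
#' @param connectivity Pixel connectivity for label components, 4 or 8
#'   (default 8).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma_um = 1,
                                h_maxima_um = 2,
                                min_area_um2 = 50,
                                exclude_border = TRUE,
                                connectivity = 8L) {
  if (smoothing_sigma_um < 0) stop_validation("smoothing_sigma_um must be >= 0")
  if (h_maxima_um <= 0) stop_validation("h_maxima_um must be positive")
  if (min_area_um2 < 0) stop_validation("min_area_um2 must be >= 0")
  if (!connectivity %in% c(4L, 8L)) stop_validation("connectivity must be 4 or 8")
  structure(list(smoothing_sigma_um = as.numeric(smoothing_sigma_um),
                 h_maxima_um = as.numeric(h_maxima_um),
                 min_area_um2 = as.numeric(min_area_um2),
                 exclude_border = isTRUE(exclude_border),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Fiber-probability map from staining colour
#'
#' Picrosirius Red Fast Green stains myofibers green and connective
#' tissue red, so the per-pixel score `s = (G - R + 255) / 510` on 8-bit
#' channels is 1 for pure green, 0 for pure red and 0.5 for neutral gray.
#' The score is optionally smoothed with a Gaussian kernel whose sigma is
#' given in micrometers and converted through the image calibration.
#'
#' @param image A [calibrated_image()].
#' @param smoothing_sigma_um Gaussian sigma in um; 0 returns the raw score.
#' @return A `height x width` matrix in `[0, 1]`.
#' @export
stain_separation <- function(image, smoothing_sigma_um = 1) {
  stopifnot(inherits(image, "calibrated_image"))
  s <- (image$pixels[, , 2] - image$pixels[, , 1] + 255) / 510
  dim(s) <- dim(image$pixels)[1:2]   # keep matrix shape for 1-px edges
  if (smoothing_sigma_um > 0) {
    sigma_px <- smoothing_sigma_um * image$px_per_um
    s <- as.matrix(EBImage::gblur(EBImage::Image(s), sigma = sigma_px))
    s <- pmin(pmax(s, 0), 1)
  }
  s
}

#' Segment myofibers in a stained image
#'
#' Classical marker-controlled watershed backend: (1) foreground is the
#' stain score above its Otsu threshold; (2) the Euclidean distance
#' transform of the foreground is computed; (3) watershed basins are
#' grown from distance-map maxima, with maxima shallower than
#' `h_maxima_um` (converted to pixels) merged into their neighbors
#' (h-maxima marker suppression); (4) labels are positive integers on a
#' zero background. Apply [filter_labels()] afterwards for size/border QC.
#'
#' @param image A [calibrated_image()].
#' @param params A [segmentation_params()] object.
#' @return A [label_mask()]. An image with no detectable foreground
#'   yields an empty mask with a warning, not an error.
#' @export
segment_fibers <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "calibrated_image"))
  score <- stain_separation(image, params$smoothing_sigma_um)
  rng <- range(score)
  fg <- if (rng[2] > rng[1]) {
    th <- EBImage::otsu(EBImage::Image(score), range = c(0, 1))
    score > th
  } else {
    matrix(FALSE, nrow(score), ncol(score))
  }
  if (!any(fg)) {
    warning("no foreground detected; returning an empty mask")
    return(label_mask(matrix(0L, nrow(score), ncol(score)), image$px_per_um))
  }
  d <- EBImage::distmap(EBImage::Image(fg))
  labels <- EBImage::watershed(d, tolerance = params$h_maxima_um * image$px_per_um,
                               ext = 1)
  lab <- as.matrix(EBImage::imageData(labels))
  storage.mode(lab) <- "integer"
  label_mask(lab, image$px_per_um)
}

#' Quality-control filtering of a label mask
#'
#' Removes labels smaller than `min_area_um2` (converted through the
#' calibration) and, when `exclude_border` is set, labels with any pixel
#' on the outermost image row or column. Survivors are renumbered
#' `1..K`, preserving the original label order. The operation is
#' idempotent.
#'
#' @param mask A [label_mask()].
#' @param params A [segmentation_params()] object.
#' @return A filtered [label_mask()].
#' @export
filter_labels <- function(mask, params = segmentation_params()) {
  stopifnot(inherits(mask, "label_mask"))
  lab <- mask$labels
  ids <- label_ids(mask)
  if (length(ids) == 0) return(mask)
  min_area_px <- params$min_area_um2 * mask$px_per_um^2
  areas <- tabulate(lab[lab > 0L], nbins = max(ids))
  drop <- which(areas > 0 & areas < min_area_px)
  if (params$exclude_border) {
    rim <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
    drop <- union(drop, unique(rim[rim > 0L]))
  }
  keep <- setdiff(ids, drop)
  remap <- integer(max(ids))
  remap[keep] <- seq_along(keep)
  nz <- lab > 0L
  lab[nz] <- remap[lab[nz]]
  label_mask(lab, mask$px_per_um)
}

#' Convert a label mask to per-fiber regions
#'
#' One region per distinct nonzero label, mirroring the label-to-ROI
#' conversion step of the automated workflow: the pixel set, the
#' centroid, and the outer boundary polygon traced on the half-integer
#' pixel-corner grid (pixels are unit squares, so the polygon of a 2x2
#' block is a square of area 4 px^2). Regions partition the nonzero mask
#' support.
#'
#' @param mask A [label_mask()].
#' @param connectivity 4 or 8; every label must form a single connected
#'   component at this connectivity, otherwise a validation error names
#'   the offending label.
#' @param validate Set `FALSE` to skip the single-component check (used
#'   on masks the package generated itself).
#' @return A list of regions, ids ascending; each has `label` (integer),
#'   `pixels` (`n x 2` matrix, columns x, y), `centroid` (x, y) and
#'   `polygon` (`m x 2` matrix of corner vertices).
#' @export
labels_to_regions <- function(mask, connectivity = 8L, validate = TRUE) {
  stopifnot(inherits(mask, "label_mask"))
  lab <- mask$labels
  ids <- label_ids(mask)
  if (length(ids) == 0) return(list())
  if (!connectivity %in% c(4L, 8L)) stop_validation("connectivity must be 4 or 8")
  nz <- which(lab > 0L)
  nr <- nrow(lab)
  rows <- ((nz - 1L) %% nr) + 1L
  cols <- ((nz - 1L) %/% nr) + 1L
  vals <- lab[nz]
  ord <- order(vals)
  rows <- rows[ord]; cols <- cols[ord]; vals <- vals[ord]
  bounds <- c(0L, cumsum(tabulate(vals)[ids]))
  lapply(seq_along(ids), function(i) {
    sel <- (bounds[i] + 1L):bounds[i + 1L]
    r <- rows[sel]; cc <- cols[sel]
    r0 <- min(r); c0 <- min(cc)
    win <- matrix(FALSE, max(r) - r0 + 1L, max(cc) - c0 + 1L)
    win[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
    if (validate && n_components(win, connectivity) > 1L) {
      stop_validation(sprintf(
        "label %d forms multiple %d-connected components; not a valid label mask",
        ids[i], connectivity))
    }
    poly <- trace_boundary(win)
    poly[, 1] <- poly[, 1] + (c0 - 1L)
    poly[, 2] <- poly[, 2] + (r0 - 1L)
    list(label = ids[i],
         pixels = cbind(x = cc, y = r),
         centroid = c(x = mean(cc), y = mean(r)),
         polygon = poly)
  })
}

# number of connected components of a logical window. bwlabel gives the
# 4-connected partition; for 8-connectivity the (few) 4-components are
# merged through diagonal adjacencies with a tiny union-find.
n_components <- function(win, connectivity = 8L) {
  l4 <- EBImage::bwlabel(win)
  k <- max(l4)
  if (k <= 1L || connectivity == 4L) return(as.integer(k))
  nr <- nrow(l4); nc <- ncol(l4)
  a <- rbind(cbind(as.vector(l4[-nr, -nc]), as.vector(l4[-1, -1])),
             cbind(as.vector(l4[-nr, -1]), as.vector(l4[-1, -nc])))
  a <- a[a[, 1] > 0 & a[, 2] > 0 & a[, 1] != a[, 2], , drop = FALSE]
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_len(nrow(a))) {
    ra <- find(a[e, 1]); rb <- find(a[e, 2])
    if (ra != rb) parent[rb] <- ra
  }
  length(unique(vapply(seq_len(k), find, integer(1))))
}

#' Match detected labels against a reference mask
#'
#' One-to-one object matching between a reference (e.g. ground-truth)
#' label mask and a test mask: candidate pairs are labels that overlap,
#' scored by intersection-over-union (IoU) and matched greedily in
#' decreasing IoU order, each label used at most once. The standard way
#' to score an instance segmentation against ground truth.
#'
#' @param reference,test Two [label_mask()]s of identical dimensions.
#' @param iou_threshold Minimum IoU for a pair to count as matched
#'   (default 0.5).
#' @return A list: `matches` (data frame `reference_label`, `test_label`,
#'   `iou`), `recall` (matched fraction of reference labels), `precision`
#'   (matched fraction of test labels).
#' @export
match_labels <- function(reference, test, iou_threshold = 0.5) {
  stopifnot(inherits(reference, "label_mask"), inherits(test, "label_mask"))
  if (!identical(dim(reference$labels), dim(test$labels))) {
    stop_validation("masks must have identical dimensions")
  }
  a <- as.vector(reference$labels); b <- as.vector(test$labels)
  n_ref <- length(unique(a[a > 0L])); n_test <- length(unique(b[b > 0L]))
  empty <- data.frame(reference_label = integer(0), test_label = integer(0),
                      iou = numeric(0))
  if (n_ref == 0 || n_test == 0) {
    return(list(matches = empty, recall = NA_real_, precision = NA_real_))
  }
  area_a <- tabulate(a, nbins = max(a))
  area_b <- tabulate(b, nbins = max(b))
  both <- a > 0L & b > 0L
  if (!any(both)) return(list(matches = empty, recall = 0, precision = 0))
  key <- (a[both] - 1) * as.double(max(b)) + b[both]   # pair id
  inter <- rowsum(rep(1L, length(key)), key)
  pair <- as.numeric(rownames(inter))
  pa <- floor((pair - 1) / max(b)) + 1
  pb <- pair - (pa - 1) * max(b)
  iou <- inter[, 1] / (area_a[pa] + area_b[pb] - inter[, 1])
  ord <- order(iou, decreasing = TRUE)
  used_a <- logical(max(a)); used_b <- logical(max(b))
  keep <- logical(length(ord))
  for (i in ord) {
    if (iou[i] < iou_threshold) break
    if (!used_a[pa[i]] && !used_b[pb[i]]) {
      used_a[pa[i]] <- TRUE; used_b[pb[i]] <- TRUE; keep[i] <- TRUE
    }
  }
  matches <- data.frame(reference_label = as.integer(pa[keep]),
                        test_label = as.integer(pb[keep]),
                        iou = iou[keep])
  matches <- matches[order(matches$reference_label), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       recall = nrow(matches) / n_ref,
       precision = nrow(matches) / n_test)
}
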