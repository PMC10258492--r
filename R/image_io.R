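# Image and table input/output.
#
# Pixel conventions used throughout the package: rasters are stored
# [row, col(, channel)] with row 1 at the top; pixel (r, c) has its center
# at (x = c, y = r) and spans corners at +/- 0.5. Calibration (px_per_um)
# is metadata only — it never rescales stored pixels and is applied when
# metrics are extracted.

#' Calibrated RGB histology image
#'
#' Container for an 8-bit RGB raster plus its spatial calibration. The
#' calibration is pixels per micrometer; at the magnification used for
#' myofiber work a typical value is 6.6 px/um (about 0.15 um per pixel).
#'
#' @param pixels Numeric or integer array `height x width x 3` with values
#'   in 0..255. A `height x width` matrix is accepted and replicated to
#'   three identical channels.
#' @param px_per_um Positive scalar, pixels per micrometer.
#' @param source_id Free-text identifier carried into per-fiber records.
#' @return An object of class `calibrated_image` with fields `pixels`
#'   (integer array), `px_per_um` and `source_id`.
#' @seealso [read_image()], [segment_fibers()]
#' @export
calibrated_image <- function(pixels, px_per_um, source_id = "") {
  if (!is.numeric(px_per_um) || length(px_per_um) != 1 || !is.finite(px_per_um) ||
      px_per_um <= 0) {
    stop_validation("px_per_um must be a positive finite scalar")
  }
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_validation("pixels must be a height x width x 3 array")
  }
  if (any(dim(pixels)[1:2] < 1L)) stop_validation("image must be at least 1 x 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_validation("pixel values must lie in 0..255")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, px_per_um = as.numeric(px_per_um),
         source_id = as.character(source_id)),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px, %.3f px/um, source '%s'\n",
              d[1], d[2], x$px_per_um, x$source_id))
  invisible(x)
}

#' Integer label mask
#'
#' The hand-off contract between any segmentation backend and the
#' morphometry stage: an integer raster in which 0 is background (here,
#' connective tissue / endomysium) and each positive value identifies one
#' myofiber. Label values need not be contiguous, but each label must form
#' a single connected component (checked by [labels_to_regions()]).
#'
#' @param labels Integer matrix `height x width`, all values >= 0.
#' @param px_per_um Positive scalar, pixels per micrometer.
#' @return An object of class `label_mask` with fields `labels` and
#'   `px_per_um`.
#' @export
label_mask <- function(labels, px_per_um) {
  if (!is.numeric(px_per_um) || length(px_per_um) != 1 || !is.finite(px_per_um) ||
      px_per_um <= 0) {
    stop_validation("px_per_um must be a positive finite scalar")
  }
  if (!is.matrix(labels)) stop_validation("labels must be a matrix")
  if (anyNA(labels)) stop_validation("labels must not contain NA")
  if (is.double(labels)) {
    if (max(abs(labels - round(labels))) > 0) {
      stop_validation("label values must be integral")
    }
  }
  if (min(labels) < 0) stop_validation("label values must be >= 0")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, px_per_um = as.numeric(px_per_um)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %.3f px/um, %d labels\n",
              nrow(x$labels), ncol(x$labels), x$px_per_um,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

n_labels <- function(mask) length(label_ids(mask))

label_ids <- function(mask) {
  u <- unique(as.vector(mask$labels))
  sort(u[u != 0L])
}

read_raster <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  v <- tryCatch(
    switch(ext,
      tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
      png = {
        x <- png::readPNG(path, info = TRUE)
        depth <- attr(x, "info")$bit.depth %||% 8L
        round(x * (2^depth - 1))
      },
      stop_io(sprintf("unsupported image format '%s' for '%s' (use TIFF or PNG)",
                      ext, path))
    ),
    error = function(e) {
      if (inherits(e, "myofibr_io_error")) stop(e)
      stop_io(sprintf("cannot decode '%s': %s", path, conditionMessage(e)))
    }
  )
  v
}

#' Read a calibrated histology image
#'
#' Reads a TIFF (any bit depth) or PNG image and attaches the pixel-size
#' calibration. 8-bit data are kept verbatim; deeper or floating-point
#' data are converted to 8 bits by linear min-max scaling per channel.
#' Grayscale input is replicated to three channels; an alpha channel is
#' dropped.
#'
#' @param path Path to a TIFF or PNG file.
#' @param px_per_um Pixels per micrometer (default 6.6).
#' @param source_id Identifier for the image; defaults to the file name.
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, px_per_um = 6.6, source_id = basename(path)) {
  v <- read_raster(path)
  if (is.matrix(v)) v <- array(rep(v, 3L), dim = c(dim(v), 3L))
  if (length(dim(v)) == 3L && dim(v)[3] == 1L) {
    v <- array(rep(v[, , 1L], 3L), dim = c(dim(v)[1:2], 3L))
  }
  if (length(dim(v)) == 3L && dim(v)[3] == 4L) v <- v[, , 1:3, drop = FALSE]
  if (length(dim(v)) != 3L || dim(v)[3] != 3L) {
    stop_io(sprintf("'%s' has unsupported channel layout", path))
  }
  integral <- max(abs(v - round(v))) == 0
  if (!integral || max(v) > 255 || min(v) < 0) {
    # not native 8-bit: min-max scale each channel into 0..255
    for (ch in 1:3) {
      x <- v[, , ch]
      rng <- range(x)
      v[, , ch] <- if (rng[2] > rng[1]) {
        round((x - rng[1]) / (rng[2] - rng[1]) * 255)
      } else {
        x * 0
      }
    }
  }
  calibrated_image(v, px_per_um, source_id)
}

#' Read an integer label mask
#'
#' Entry point for masks produced by an external segmenter (for example a
#' deep-learning detector): a single-channel TIFF or PNG whose pixel
#' values are the fiber labels, 0 meaning background.
#'
#' @param path Path to a single-channel TIFF or PNG file.
#' @param px_per_um Pixels per micrometer of the source image.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, px_per_um) {
  v <- read_raster(path)
  if (length(dim(v)) == 3L && dim(v)[3] == 1L) v <- v[, , 1L]
  if (!is.matrix(v)) {
    stop_io(sprintf("'%s' is not a single-channel raster", path))
  }
  if (max(abs(v - round(v))) > 0) {
    stop_validation(sprintf("'%s' contains non-integral pixel values", path))
  }
  if (min(v) < 0) stop_validation(sprintf("'%s' contains negative labels", path))
  label_mask(round(v), px_per_um)
}

#' Write an 8-bit image or a 16-bit label mask
#'
#' `write_image()` stores a [calibrated_image()] as an 8-bit RGB TIFF or
#' PNG; `write_label_mask()` stores a [label_mask()] as a 16-bit
#' single-channel TIFF or PNG (labels must not exceed 65535). Both
#' round-trip exactly through their read counterparts.
#'
#' @param image A [calibrated_image()].
#' @param mask A [label_mask()].
#' @param path Destination path ending in `.tif`, `.tiff` or `.png`.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  v <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    png = png::writePNG(v, path),
    stop_io(sprintf("unsupported output format '%s'", ext))
  )
  invisible(path)
}

#' @rdname write_image
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) {
    stop_validation("label values above 65535 cannot be stored in 16 bits")
  }
  v <- mask$labels / 65535
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(v, path, bits.per.sample = 16L),
    png = png::writePNG(v, path, bitdepth = 16L),
    stop_io(sprintf("unsupported output format '%s'", ext))
  )
  invisible(path)
}

fiber_table_columns <- c("source_id", "fiber_id", "lesser_diameter_um",
                         "area_um2", "centroid_x_px", "centroid_y_px")

#' Write and read per-fiber measurement tables
#'
#' The canonical per-fiber table has one row per fiber and columns
#' `source_id`, `fiber_id`, `lesser_diameter_um`, `area_um2`,
#' `centroid_x_px`, `centroid_y_px`. Files are UTF-8 CSV (RFC 4180) with a
#' header row; numeric values are written with 6 decimal places.
#'
#' @param records Data frame of fiber records as produced by
#'   [measure_section()] (the columns above; extra columns are dropped).
#' @param path Destination `.csv` path.
#' @return `write_fiber_table()` returns the path invisibly;
#'   `read_fiber_table()` returns the records data frame.
#' @export
write_fiber_table <- function(records, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    stop_io(paste0("XLSX output is not supported by this build; ",
                   "write a .csv and open it in a spreadsheet instead"))
  }
  records <- as.data.frame(records)
  if (nrow(records) > 0 && !all(fiber_table_columns %in% names(records))) {
    stop_validation(paste("fiber records must have columns:",
                          paste(fiber_table_columns, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(fiber_table_columns)),
                                  fiber_table_columns))
  } else {
    out <- records[, fiber_table_columns]
    for (col in c("lesser_diameter_um", "area_um2", "centroid_x_px", "centroid_y_px")) {
      out[[col]] <- formatC(out[[col]], format = "f", digits = 6)
    }
  }
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop_io(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_fiber_table
#' @export
read_fiber_table <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read '%s': no such file", path))
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(fiber_table_columns, names(df))
  if (length(missing)) {
    stop_validation(sprintf("'%s' is not a fiber table (missing: %s)",
                            path, paste(missing, collapse = ", ")))
  }
  df$source_id <- as.character(df$source_id)
  df
}

#' Write per-section summaries
#'
#' One row per section with the aggregate fields of [measure_section()]'s
#' summary (fiber count, mean +/- SEM diameter and area, diameter CV,
#' tissue and image area, fiber densities).
#'
#' @param summaries Data frame with one row per section summary.
#' @param path Destination `.csv` path.
#' @return The path, invisibly.
#' @export
write_section_summary <- function(summaries, path) {
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop_io(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  write.csv(as.data.frame(summaries), con, row.names = FALSE, quote = TRUE)
  invisible(path)
}
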