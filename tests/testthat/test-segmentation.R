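# Stain separation, watershed backend, label QC and region conversion.

test_that("stain score hits the color anchors exactly", {
  px1 <- function(r, g, b) {
    calibrated_image(array(c(r, g, b), dim = c(1, 1, 3)), px_per_um = 1)
  }
  expect_equal(stain_separation(px1(0, 255, 0), 0)[1, 1], 1)     # pure green
  expect_equal(stain_separation(px1(255, 0, 0), 0)[1, 1], 0)     # pure red
  expect_equal(stain_separation(px1(90, 90, 90), 0)[1, 1], 0.5)  # neutral gray
})

test_that("a uniform red image yields zero labels with a warning", {
  px <- array(0L, dim = c(40, 40, 3)); px[, , 1] <- 200L
  img <- calibrated_image(px, px_per_um = 1)
  expect_warning(mask <- segment_fibers(img), "no foreground")
  expect_equal(sum(mask$labels), 0)
})

test_that("one green disk on red background is found with matching area", {
  n <- 101; r <- 30; cc <- 51
  disk <- (row(matrix(0, n, n)) - cc)^2 + (col(matrix(0, n, n)) - cc)^2 <= r^2
  px <- array(0L, dim = c(n, n, 3))
  px[, , 1] <- ifelse(disk, 60L, 200L)
  px[, , 2] <- ifelse(disk, 200L, 60L)
  img <- calibrated_image(px, px_per_um = 1)
  mask <- filter_labels(segment_fibers(img), segmentation_params())
  expect_equal(length(setdiff(unique(as.vector(mask$labels)), 0L)), 1L)
  expect_lt(abs(sum(mask$labels > 0) - sum(disk)) / sum(disk), 0.1)
})

test_that("filter_labels applies the area threshold in calibrated units", {
  m <- rect_mask(40, 40, list(c(5, 7, 5, 7, 1),      # ~9 px^2
                              c(15, 37, 15, 37, 2)))  # ~529 px^2
  f <- filter_labels(m, segmentation_params(min_area_um2 = 50, exclude_border = FALSE))
  expect_identical(sort(setdiff(unique(as.vector(f$labels)), 0L)), 1L)
  expect_equal(sum(f$labels == 1L), 23^2)
})

test_that("border-touching labels are dropped when exclude_border is set", {
  m <- rect_mask(30, 30, list(c(1, 6, 10, 20, 1),    # touches row 1
                              c(10, 20, 10, 20, 2)))
  f <- filter_labels(m, segmentation_params(min_area_um2 = 0))
  expect_equal(sum(f$labels == 1L), 11^2)   # interior label renumbered to 1
  expect_equal(max(f$labels), 1L)
  keep_all <- filter_labels(m, segmentation_params(min_area_um2 = 0,
                                                   exclude_border = FALSE))
  expect_equal(sort(setdiff(unique(as.vector(keep_all$labels)), 0L)), c(1L, 2L))
})

test_that("filter_labels is idempotent and renumbers 1..K in order", {
  mask <- small_section()$gt$mask
  p <- segmentation_params()
  once <- filter_labels(mask, p)
  twice <- filter_labels(once, p)
  expect_identical(once$labels, twice$labels)
  ids <- sort(setdiff(unique(as.vector(once$labels)), 0L))
  expect_identical(ids, seq_along(ids))
})

test_that("regions partition the nonzero mask support", {
  mask <- small_section()$gt$mask
  regions <- labels_to_regions(mask)
  expect_equal(sum(vapply(regions, function(r) nrow(r$pixels), 0L)),
               sum(mask$labels > 0L))
  expect_identical(vapply(regions, `[[`, integer(1), "label"),
                   sort(setdiff(unique(as.vector(mask$labels)), 0L)))
  # disjointness: every pixel claimed exactly once
  seen <- matrix(FALSE, nrow(mask$labels), ncol(mask$labels))
  for (r in regions) {
    idx <- cbind(r$pixels[, "y"], r$pixels[, "x"])
    expect_false(any(seen[idx]))
    seen[idx] <- TRUE
  }
})

test_that("region polygons carry pixel-corner geometry", {
  m <- rect_mask(10, 10, list(c(3, 4, 5, 6, 7)))  # one 2x2 block, label 7
  regions <- labels_to_regions(m)
  expect_length(regions, 1L)
  expect_equal(regions[[1]]$label, 7L)
  expect_equal(nrow(regions[[1]]$pixels), 4L)
  expect_equal(polygon_area(regions[[1]]$polygon), 4)
  expect_equal(regions[[1]]$centroid, c(x = 5.5, y = 3.5))
})

test_that("a label split into two components is rejected by name", {
  m <- rect_mask(20, 20, list(c(2, 4, 2, 4, 3), c(10, 12, 10, 12, 3)))
  expect_error(labels_to_regions(m), regexp = "label 3",
               class = "myofibr_validation_error")
  # 4-connectivity also rejects a diagonal-only bridge
  md <- matrix(0L, 8, 8); md[2, 2] <- 5L; md[3, 3] <- 5L
  expect_error(labels_to_regions(label_mask(md, 1), connectivity = 4L),
               class = "myofibr_validation_error")
  expect_length(labels_to_regions(label_mask(md, 1), connectivity = 8L), 1L)
})

test_that("detected fiber count tracks ground truth on a clean section", {
  sec <- medium_section()
  p <- segmentation_params()
  n_true <- length(setdiff(unique(as.vector(filter_labels(sec$gt$mask, p)$labels)), 0L))
  det <- filter_labels(segment_fibers(sec$image), p)
  n_det <- length(setdiff(unique(as.vector(det$labels)), 0L))
  expect_gt(n_true, 100)
  expect_lte(abs(n_det - n_true) / n_true, 0.1)
})

test_that("match_labels scores identical masks as perfect and is one-to-one", {
  mask <- small_section()$gt$mask
  m <- match_labels(mask, mask)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_true(all(m$matches$iou == 1))
  expect_false(any(duplicated(m$matches$test_label)))
})
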