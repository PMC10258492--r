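# Per-fiber metrics and per-section aggregation.

test_that("fiber area converts pixel counts through the calibration", {
  expect_equal(fiber_area(1089, px_per_um = 1), 1089)
  expect_equal(fiber_area(19008, px_per_um = 6.6), 19008 / 6.6^2)
})

test_that("interior holes count as fiber area", {
  # 9x9 square with a 5 px plus-shaped hole in the middle
  full <- expand.grid(x = 1:9, y = 1:9)
  hole <- (full$x == 5 & full$y %in% 4:6) | (full$y == 5 & full$x %in% 4:6)
  pix <- as.matrix(full[!hole, ])
  expect_equal(fiber_area(pix, px_per_um = 1), 81)
})

test_that("two 10x10 squares summarize exactly", {
  m <- rect_mask(40, 40, list(c(5, 14, 5, 14, 1), c(22, 31, 22, 31, 2)))
  out <- measure_section(m, source_id = "sq")
  expect_equal(out$summary$n_fibers, 2L)
  expect_equal(out$summary$mean_diameter_um, 10)
  expect_equal(out$summary$mean_area_um2, 100)
  expect_equal(out$summary$sem_area_um2, 0)
  expect_equal(out$records$source_id, c("sq", "sq"))
  expect_equal(out$records$centroid_x_px, c(9.5, 26.5))
})

test_that("an empty mask yields zero fibers and missing means", {
  out <- measure_section(label_mask(matrix(0L, 30, 30), 1), "empty")
  expect_equal(nrow(out$records), 0L)
  expect_equal(out$summary$n_fibers, 0L)
  expect_true(is.na(out$summary$mean_diameter_um))
})

test_that("fiber density divides count by tissue area", {
  m <- small_section()$gt$mask
  s <- measure_section(m, "d", validate = FALSE)$summary
  expect_equal(s$fibers_per_mm2, s$n_fibers / s$tissue_area_mm2)
  expect_equal(s$fibers_per_mm2_image, s$n_fibers / s$image_area_mm2)
  # fiber area <= tissue area <= image area
  total_fiber_mm2 <- sum(
    measure_section(m, "d", validate = FALSE)$records$area_um2) / 1e6
  expect_lte(total_fiber_mm2, s$tissue_area_mm2 + 1e-9)
  expect_lte(s$tissue_area_mm2, s$image_area_mm2 + 1e-9)
})

test_that("summary totals are invariant under label permutation", {
  m <- small_section()$gt$mask
  lab <- m$labels
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  withr::local_seed(3)
  perm <- sample(ids)
  remap <- integer(max(ids)); remap[ids] <- perm
  shuffled <- lab; shuffled[lab > 0L] <- remap[lab[lab > 0L]]
  a <- measure_section(m, "a", validate = FALSE)$summary
  b <- measure_section(label_mask(shuffled, m$px_per_um), "a",
                       validate = FALSE)$summary
  for (col in c("n_fibers", "mean_diameter_um", "sem_diameter_um",
                "cv_diameter_percent", "mean_area_um2", "fibers_per_mm2")) {
    expect_equal(a[[col]], b[[col]])
  }
})

test_that("lesser diameter never exceeds the maximum Feret diameter", {
  regions <- labels_to_regions(small_section()$gt$mask, validate = FALSE)
  ppu <- small_section()$gt$mask$px_per_um
  for (r in regions[seq_len(min(25, length(regions)))]) {
    expect_lte(min_feret_diameter(r$polygon, ppu),
               max_feret_diameter(r$polygon, ppu) + 1e-12)
  }
})

test_that("diameter bins are left-closed right-open and normalize to 100", {
  b <- bin_diameters(c(4.9, 5.0, 7.2), bin_width_um = 5)
  expect_equal(b$count, c(1L, 2L))
  expect_equal(b$bin_low_um, c(0, 5))
  expect_equal(sum(b$percent), 100)

  withr::local_seed(1)
  b2 <- bin_diameters(make_records(runif(500, 0, 60)))
  expect_equal(sum(b2$percent), 100, tolerance = 1e-9)
  expect_equal(sum(b2$count), 500L)

  expect_equal(nrow(bin_diameters(numeric(0))), 0L)
  expect_error(bin_diameters(1:3, bin_width_um = 0),
               class = "myofibr_validation_error")
})
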