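# Synthetic SRFG-like section generator and its ground truth.

test_that("invalid section parameters are refused before any sampling", {
  expect_error(section_params(target_mean_diameter_um = 5, px_per_um = 1),
               class = "myofibr_validation_error")  # < 6 px across
  expect_error(section_params(border_width_um = 25),
               class = "myofibr_validation_error")  # wider than a fiber
  expect_error(section_params(jitter = 1.5), class = "myofibr_validation_error")
  expect_error(section_params(image_size_px = c(0, 10)),
               class = "myofibr_validation_error")
})

test_that("identical parameters give bit-identical sections", {
  p <- section_params(image_size_px = c(260L, 260L), px_per_um = 2, seed = 5L)
  a <- generate_section(p)
  b <- generate_section(p)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$gt$mask$labels, b$gt$mask$labels)
  expect_equal(a$gt$true_records, b$gt$true_records)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(generate_section(section_params(image_size_px = c(260L, 260L),
                                            px_per_um = 2, seed = 5L)))
  expect_identical(runif(3), before)
})

test_that("every label has exactly one ground-truth record", {
  gt <- small_section()$gt
  ids <- sort(setdiff(unique(as.vector(gt$mask$labels)), 0L))
  expect_gt(length(ids), 20)
  expect_identical(gt$true_records$fiber_id, ids)
  expect_identical(true_metrics(gt)$lesser_diameter_um,
                   gt$true_records$lesser_diameter_um)
})

test_that("labels are numbered 1..N in raster order of centroid", {
  rec <- small_section()$gt$true_records
  expect_identical(rec$fiber_id, seq_len(nrow(rec)))
  expect_false(is.unsorted(round(rec$centroid_y_px)))
})

test_that("no two distinct labels touch, even diagonally", {
  lab <- small_section()$gt$mask$labels
  nr <- nrow(lab); nc <- ncol(lab)
  touches <- function(a, b) any(a > 0L & b > 0L & a != b)
  expect_false(touches(lab[-nr, ], lab[-1, ]))
  expect_false(touches(lab[, -nc], lab[, -1]))
  expect_false(touches(lab[-nr, -nc], lab[-1, -1]))
  expect_false(touches(lab[-nr, -1], lab[-1, -nc]))
})

test_that("neighboring fibers are separated by at least the border width", {
  # 2 um endomysium at 6.6 px/um -> background gap >= 13 px, checked by
  # brute-force nearest-pixel distance between all nearby label pairs
  sec <- cached_fixture("gap_section", function() {
    generate_section(section_params(image_size_px = c(600L, 600L), px_per_um = 6.6,
                                    border_width_um = 2, seed = 31L))
  })
  lab <- sec$gt$mask$labels
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  expect_gt(length(ids), 4)
  # boundary pixels suffice for nearest-pair distances
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2, nc + 2); pad[2:(nr + 1), 2:(nc + 1)] <- lab
  interior <- pad[2:(nr + 1), 1:nc] == lab & pad[2:(nr + 1), 3:(nc + 2)] == lab &
              pad[1:nr, 2:(nc + 1)] == lab & pad[3:(nr + 2), 2:(nc + 1)] == lab
  pix <- lapply(ids, function(k) which(lab == k & !interior, arr.ind = TRUE))
  boxes <- t(vapply(pix, function(p) c(range(p[, 1]), range(p[, 2])), numeric(4)))
  min_gap <- Inf
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    # skip pairs whose bounding boxes are far apart
    if (boxes[i, 1] > boxes[j, 2] + 30 || boxes[j, 1] > boxes[i, 2] + 30 ||
        boxes[i, 3] > boxes[j, 4] + 30 || boxes[j, 3] > boxes[i, 4] + 30) next
    d2 <- outer(pix[[i]][, 1], pix[[j]][, 1], "-")^2 +
          outer(pix[[i]][, 2], pix[[j]][, 2], "-")^2
    min_gap <- min(min_gap, sqrt(min(d2)))
  }
  expect_true(is.finite(min_gap))        # some pair was adjacent
  expect_gte(min_gap - 1, 13)            # background between facing pixels
})

test_that("fiber pixels are green-dominant and background red-dominant", {
  sec <- small_section()
  g_minus_r <- sec$image$pixels[, , 2] - sec$image$pixels[, , 1]
  fiber <- sec$gt$mask$labels > 0L
  expect_gt(mean(g_minus_r[fiber]), 0)
  expect_lt(mean(g_minus_r[!fiber]), 0)
})

test_that("raising the target mean diameter does not shrink realized fibers", {
  mk <- function(target) {
    p <- section_params(image_size_px = c(420L, 420L), px_per_um = 2,
                        target_mean_diameter_um = target, seed = 77L)
    mean(generate_section(p)$gt$true_records$lesser_diameter_um)
  }
  expect_gte(mk(23), mk(18))
})

test_that("true_metrics measures a solid square exactly", {
  m <- rect_mask(40, 40, list(c(4, 36, 4, 36, 1)))  # 33 x 33 px square
  rec <- true_metrics(list(mask = m))
  expect_equal(rec$area_um2, 33^2)
  expect_equal(rec$lesser_diameter_um, 33)
  expect_equal(nrow(true_metrics(list(mask = label_mask(matrix(0L, 5, 5), 1)))), 0L)
})
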