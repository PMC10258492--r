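# Shared fixtures. Sections are generated once per test run and cached;
# sizes are chosen so the whole suite stays at desk scale.

.fixtures <- new.env(parent = emptyenv())

cached_fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# ~40 fibers, ~0.5 um/px: the workhorse for invariant tests
small_section <- function() {
  cached_fixture("small", function() {
    generate_section(section_params(image_size_px = c(420L, 420L), px_per_um = 2,
                                    seed = 101L))
  })
}

# ~140 fibers: segmentation-quality checks
medium_section <- function() {
  cached_fixture("medium", function() {
    generate_section(section_params(image_size_px = c(900L, 900L), px_per_um = 2,
                                    seed = 19L))
  })
}

# >= 1000 fibers at the morphology of 14-day-old broiler pectoral muscle;
# shared by the parameter-recovery and segmentation acceptance checks
acceptance_section <- function() {
  cached_fixture("acceptance", function() {
    generate_section(section_params(image_size_px = c(2200L, 2200L), px_per_um = 2,
                                    seed = 7L))
  })
}

acceptance_detection <- function() {
  cached_fixture("acceptance_det", function() {
    sec <- acceptance_section()
    filter_labels(segment_fibers(sec$image), segmentation_params())
  })
}

run_cli <- function(...) suppressMessages(myofibr_main(c(...)))

# star-shaped (hence simple) random polygon around the origin. Radii are
# kept in a moderate band so the shapes are fiber-like blobs rather than
# slivers: on near-degenerate slivers a fixed-step projection sweep has
# first-order angular quantization error and stops being a valid oracle
# at sub-0.1% tolerances.
random_simple_polygon <- function(n_vertices = NULL) {
  n <- n_vertices %||% sample(5:20, 1)
  angles <- sort(runif(n, 0, 2 * pi))
  radii <- runif(n, 6, 10)
  cbind(x = radii * cos(angles), y = radii * sin(angles))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fiber-record data frame from raw vectors
make_records <- function(diameters, areas = diameters^2, source_id = "synthetic") {
  data.frame(source_id = source_id,
             fiber_id = seq_along(diameters),
             lesser_diameter_um = diameters,
             area_um2 = areas,
             centroid_x_px = seq_along(diameters),
             centroid_y_px = seq_along(diameters))
}

# mask with filled rectangles; rects = list(c(r1, r2, c1, c2, label))
rect_mask <- function(nrow, ncol, rects, px_per_um = 1) {
  m <- matrix(0L, nrow, ncol)
  for (r in rects) m[r[1]:r[2], r[3]:r[4]] <- as.integer(r[5])
  label_mask(m, px_per_um)
}
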