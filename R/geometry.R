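# Planar geometry for fiber regions: convex hulls, Feret (caliper)
# diameters, and crack-boundary tracing of label regions.
#
# Polygons are n x 2 matrices with columns x, y. Region pixels are unit
# squares centered on integer coordinates, so traced boundary vertices lie
# on the half-integer grid and the shoelace area of the traced polygon
# equals the pixel count of a hole-free region.

as_polygon <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 1 || anyNA(polygon)) {
    stop_validation("polygon must be an n x 2 matrix of finite coordinates")
  }
  storage.mode(polygon) <- "double"
  polygon
}

# Convex hull vertices in counter-clockwise order (y increasing downward
# flips chull()'s clockwise convention; order itself is irrelevant here).
convex_hull <- function(points) {
  points <- unique(as_polygon(points))
  if (nrow(points) <= 2) return(points)
  points[rev(grDevices::chull(points[, 1], points[, 2])), , drop = FALSE]
}

#' Minimum and maximum Feret (caliper) diameters of a polygon
#'
#' The minimum Feret diameter is the smallest distance between two
#' parallel lines that enclose the shape, over all orientations — the
#' standard geometric reading of a fiber's "lesser diameter", robust to
#' oblique sectioning. It is computed on the convex hull by rotating
#' calipers: the minimum width is attained with one caliper flush against
#' a hull edge, so it equals the minimum over hull edges of the largest
#' vertex distance to that edge's supporting line. The maximum Feret
#' diameter is the largest inter-vertex distance of the hull.
#'
#' @param polygon An `n x 2` matrix of x, y vertex coordinates in pixels
#'   (any simple polygon, or a point cloud: only the convex hull matters).
#' @param px_per_um Pixels per micrometer used to convert to micrometers
#'   (default 1, i.e. return pixels).
#' @return A length-1 numeric, in micrometers. Degenerate (collinear)
#'   input yields 0 for the minimum with a warning.
#' @examples
#' sq <- cbind(c(0, 30, 30, 0), c(0, 0, 30, 30))
#' min_feret_diameter(sq, px_per_um = 6.6)  # 30 px side -> ~4.55 um
#' @export
min_feret_diameter <- function(polygon, px_per_um = 1) {
  h <- convex_hull(polygon)
  n <- nrow(h)
  if (n < 3) {
    warning("degenerate polygon: minimum Feret diameter is 0")
    return(0)
  }
  x <- h[, 1]; y <- h[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  ex <- x2 - x; ey <- y2 - y
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  if (!any(keep)) {
    warning("degenerate polygon: minimum Feret diameter is 0")
    return(0)
  }
  # width against edge i = max_j |cross((v_j - v_i), e_i)| / |e_i|
  dx <- outer(x, x, "-")   # dx[j, i] = x_j - x_i
  dy <- outer(y, y, "-")
  cross <- abs(sweep(dx, 2, ey, "*") - sweep(dy, 2, ex, "*"))
  widths <- apply(cross[, keep, drop = FALSE], 2, max) / len[keep]
  min(widths) / px_per_um
}

#' @rdname min_feret_diameter
#' @export
max_feret_diameter <- function(polygon, px_per_um = 1) {
  h <- convex_hull(polygon)
  if (nrow(h) < 2) return(0)
  d2 <- outer(h[, 1], h[, 1], "-")^2 + outer(h[, 2], h[, 2], "-")^2
  sqrt(max(d2)) / px_per_um
}

# Independent slow reference: project hull points on a dense sweep of
# directions and take the smallest projection spread. Used by tests as the
# oracle for the rotating-calipers implementation.
feret_width_sweep <- function(polygon, step_deg = 0.01) {
  h <- convex_hull(polygon)
  if (nrow(h) < 3) return(0)
  theta <- seq(0, 180, by = step_deg) * pi / 180
  proj <- outer(sin(theta), h[, 1]) - outer(cos(theta), h[, 2])
  min(apply(proj, 1, max) - apply(proj, 1, min))
}

polygon_area <- function(polygon) {
  p <- as_polygon(polygon)
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Outer crack boundary of a logical matrix containing one connected
# region (holes are irrelevant: only the outer contour is traced).
# Vertices are pixel corners (x = col +/- 0.5, y = row +/- 0.5), walked
# with the region on the right-hand side in image coordinates (y down).
# Diagonal saddle corners are resolved by the turn that keeps an
# 8-connected component on a single outer contour.
trace_boundary <- function(region) {
  stopifnot(is.logical(region) || is.numeric(region))
  m <- region != 0
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_validation("cannot trace an empty region")
  # start at the corner up-left of the first region pixel in raster order
  first <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
  nr <- nrow(m); nc <- ncol(m)
  px <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && m[r, c]
  # corner (i, j) sits up-left of pixel (i, j); moving direction encoded
  # 1=right, 2=down, 3=left, 4=up in image coords (y grows downward).
  # From the raster-first pixel's up-left corner the unique outgoing
  # crack moves right, so arrival back at the start closes the loop.
  i0 <- first[1]; j0 <- first[2]
  i <- i0; j <- j0; dir <- 1L
  saddle_turn <- c(4L, 1L, 2L, 3L)  # incoming right/down/left/up
  cap <- 256L; used <- 0L
  verts_x <- numeric(cap); verts_y <- numeric(cap)
  max_steps <- 4L * (nr + 2L) * (nc + 2L)
  repeat {
    used <- used + 1L
    if (used > cap) {
      cap <- cap * 2L
      length(verts_x) <- cap; length(verts_y) <- cap
    }
    verts_x[used] <- j - 0.5
    verts_y[used] <- i - 0.5
    # advance one corner in direction dir
    if (dir == 1L) j <- j + 1L else if (dir == 2L) i <- i + 1L
    else if (dir == 3L) j <- j - 1L else i <- i - 1L
    if (i == i0 && j == j0) break
    # 2x2 pixel block around corner (i, j)
    ul <- px(i - 1L, j - 1L); ur <- px(i - 1L, j)
    ll <- px(i, j - 1L);      lr <- px(i, j)
    # valid outgoing cracks (region on the right of travel)
    vr <- lr && !ur; vd <- ll && !lr; vl <- ul && !ll; vu <- ur && !ul
    nv <- vr + vd + vl + vu
    dir <- if (nv == 1L) {
      if (vr) 1L else if (vd) 2L else if (vl) 3L else 4L
    } else {
      saddle_turn[dir]
    }
    if (used > max_steps) stop("boundary tracing failed to close")  # nocov
  }
  verts_x <- verts_x[seq_len(used)]
  verts_y <- verts_y[seq_len(used)]
  # drop collinear mid-points so straight runs become single segments
  p <- cbind(x = verts_x, y = verts_y)
  n <- nrow(p)
  if (n >= 3) {
    prev <- rbind(p[n, ], p[-n, ])
    nxt <- rbind(p[-1, ], p[1, ])
    turn <- (p[, 1] - prev[, 1]) * (nxt[, 2] - p[, 2]) -
            (p[, 2] - prev[, 2]) * (nxt[, 1] - p[, 1])
    p <- p[turn != 0, , drop = FALSE]
  }
  p
}

# Corners of the pixels that touch background — a cheap superset of the
# outer boundary whose convex hull equals the traced polygon's hull.
# Used where only hull-based metrics (Feret diameters) are needed.
boundary_corner_points <- function(region) {
  m <- region != 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  inner <- pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)] &
           pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)]
  b <- which(m & !inner, arr.ind = TRUE)
  if (nrow(b) == 0) b <- which(m, arr.ind = TRUE)
  x <- b[, 2]; y <- b[, 1]
  cbind(x = c(x - 0.5, x + 0.5, x - 0.5, x + 0.5),
        y = c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
}
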