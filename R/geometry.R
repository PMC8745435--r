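# Low-level planar geometry on pixel grids and polygons.
#
# Coordinate convention used throughout the package: images are matrices
# indexed [row, col] (1-based, R native); a pixel (i, j) is the unit square
# centred at (x = j, y = i), so pixel corners sit at half-integer
# coordinates. Polygons are data frames with columns x, y in this frame.

#' Signed area of a polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order in a y-up frame; callers that
#' only need the magnitude should take `abs()`.
#'
#' @param x,y numeric vertex coordinates (closing edge implied).
#' @return scalar signed area.
#' @keywords internal
polygon_signed_area <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n)
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' @keywords internal
polygon_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
}

#' Area, centroid and second-order central moments of a polygon
#'
#' Exact closed forms via Green's theorem. The returned `sxx`, `syy`, `sxy`
#' are per-unit-area central second moments (the covariance of the uniform
#' distribution over the polygon's interior), which feed the
#' moment-equivalent ellipse used for the roundness descriptor.
#'
#' @return list with `area` (unsigned), `cx`, `cy`, `sxx`, `syy`, `sxy`.
#' @keywords internal
polygon_moments <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L)
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps^0.5) {
    stop("degenerate polygon: zero area")
  }
  cx <- sum((x + xn) * cross) / (6 * a)
  cy <- sum((y + yn) * cross) / (6 * a)
  # raw moments about the origin
  ixx <- sum((y^2 + y * yn + yn^2) * cross) / 12      # integral of y^2 dA
  iyy <- sum((x^2 + x * xn + xn^2) * cross) / 12      # integral of x^2 dA
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cross) / 24
  list(
    area = abs(a),
    cx = cx, cy = cy,
    sxx = iyy / a - cx^2,
    syy = ixx / a - cy^2,
    sxy = ixy / a - cx * cy
  )
}

#' Major/minor axes of the moment-equivalent ellipse
#'
#' Given a covariance (per-unit-area second central moments), returns the
#' full axis lengths of the ellipse with identical second moments: a uniform
#' ellipse with semi-axes (a, b) has variance a^2/4 along its major axis,
#' hence axis length = 4 * sqrt(eigenvalue).
#'
#' @keywords internal
equivalent_ellipse_axes <- function(sxx, syy, sxy) {
  tr <- (sxx + syy) / 2
  det <- sqrt(max(0, ((sxx - syy) / 2)^2 + sxy^2))
  l1 <- max(tr + det, 0)
  l2 <- max(tr - det, 0)
  c(major = 4 * sqrt(l1), minor = 4 * sqrt(l2))
}

#' Convex hull area of a vertex set
#' @keywords internal
convex_hull_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  abs(polygon_signed_area(x[h], y[h]))
}

#' Even-odd point-in-polygon test, vectorised over query points
#'
#' Ray casting along +x. Points lying exactly on an edge may fall on either
#' side; callers rasterising polygons accept that half-open behaviour.
#'
#' @param px,py query point coordinates.
#' @param vx,vy polygon vertices.
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py[crosses] - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

#' Rasterise a polygon onto a pixel grid
#'
#' A pixel belongs to the mask when its centre (x = col, y = row) lies inside
#' the polygon (even-odd rule). Only the polygon's bounding box is tested.
#'
#' @param polygon data frame with columns `x`, `y`.
#' @param shape integer c(nrow, ncol) of the target raster.
#' @return integer 0/1 matrix.
#' @keywords internal
rasterize_polygon <- function(polygon, shape) {
  stopifnot(is.data.frame(polygon), all(c("x", "y") %in% names(polygon)))
  nr <- shape[1L]; nc <- shape[2L]
  mask <- matrix(0L, nr, nc)
  rows <- max(1L, floor(min(polygon$y))):min(nr, ceiling(max(polygon$y)))
  cols <- max(1L, floor(min(polygon$x))):min(nc, ceiling(max(polygon$x)))
  if (length(rows) == 0L || length(cols) == 0L) return(mask)
  g <- expand.grid(row = rows, col = cols)
  inside <- point_in_polygon(g$col, g$row, polygon$x, polygon$y)
  mask[cbind(g$row[inside], g$col[inside])] <- 1L
  mask
}

# --- boundary tracing ------------------------------------------------------

#' Trace the outer boundary of a binary mask along pixel cracks
#'
#' Walks the inter-pixel edges ("cracks") of the foreground's outer boundary
#' keeping foreground on the right of the walking direction, i.e. a
#' clockwise circuit in row-down display orientation. Foreground is treated
#' as 4-connected, consistent with `EBImage::bwlabel`. The walk starts at
#' the top-left corner of the first foreground pixel in row-major order and
#' terminates on return to the start corner.
#'
#' The traced crack polygon has vertices at pixel corners; its enclosed area
#' equals the pixel count of the traced component exactly, which the shape
#' code uses as a connectivity self-check.
#'
#' @param mask integer/logical matrix, nonzero = foreground.
#' @return list with integer vectors `r`, `c` (corner grid coordinates,
#'   where corner (r, c) sits at x = c + 0.5, y = r + 0.5) and `d`
#'   (direction leaving each corner: 1 = E, 2 = S, 3 = W, 4 = N).
#' @keywords internal
trace_boundary <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  P <- matrix(0L, n + 2L, m + 2L)
  P[2:(n + 1L), 2:(m + 1L)] <- (mask != 0) + 0L
  idx <- which(t(P) == 1L)[1L]  # row-major scan
  if (is.na(idx)) stop("empty ROI")
  r0 <- (idx - 1L) %/% (m + 2L) + 1L
  c0 <- (idx - 1L) %% (m + 2L) + 1L
  # edge validity with foreground on the right of travel
  valid <- function(r, c, d) {
    if (d == 1L)       P[r + 2L, c + 2L] == 1L && P[r + 1L, c + 2L] == 0L  # E
    else if (d == 2L)  P[r + 2L, c + 1L] == 1L && P[r + 2L, c + 2L] == 0L  # S
    else if (d == 3L)  P[r + 1L, c + 1L] == 1L && P[r + 2L, c + 1L] == 0L  # W
    else               P[r + 1L, c + 2L] == 1L && P[r + 1L, c + 1L] == 0L  # N
  }
  dr <- c(0L, 1L, 0L, -1L)
  dc <- c(1L, 0L, -1L, 0L)
  r <- r0 - 2L; c <- c0 - 2L; d <- 1L
  max_steps <- 8L * length(mask) + 8L
  rs <- integer(max_steps); cs <- integer(max_steps); ds <- integer(max_steps)
  k <- 0L
  start_r <- r; start_c <- c
  repeat {
    k <- k + 1L
    if (k > max_steps) stop("boundary trace failed to close")
    rs[k] <- r; cs[k] <- c; ds[k] <- d
    r <- r + dr[d]; c <- c + dc[d]
    if (r == start_r && c == start_c) break
    # hug the wall: prefer right turn, then straight, left, back
    cand <- c(d %% 4L + 1L, d, (d + 2L) %% 4L + 1L, (d + 1L) %% 4L + 1L)
    d <- NA_integer_
    for (dd in cand) {
      if (valid(r, c, dd)) { d <- dd; break }
    }
    if (is.na(d)) stop("boundary trace stuck")
  }
  list(r = rs[1:k], c = cs[1:k], d = ds[1:k])
}

#' Circular moving average used to de-jag traced boundary polygons
#' @keywords internal
smooth_closed <- function(v, window) {
  n <- length(v)
  if (window <= 1L || n <= window) return(v)
  half <- window %/% 2L
  vv <- c(v[(n - half + 1L):n], v, v[1:half])
  as.numeric(stats::filter(vv, rep(1 / window, window), sides = 2L)[(half + 1L):(half + n)])
}

#' Boundary polygons and perimeter estimates for a mask
#'
#' Produces, from one crack trace: the crack polygon (vertices at pixel
#' corners, area = pixel count), the corner-cut mid-crack polygon (vertices
#' at crack midpoints), and a lightly smoothed version of the latter whose
#' perimeter is the package's default perimeter estimate. The raw crack
#' length (city-block boundary length) is retained as the "pixel_edge"
#' alternative; it is exact for axis-aligned shapes but overestimates curved
#' boundaries by up to ~30%.
#'
#' @param mask binary matrix (single 4-connected component, holes filled by
#'   the caller).
#' @param smooth_window odd integer, vertex smoothing window (default 5).
#' @return list: `crack` and `midcrack` polygons (data frames x, y),
#'   `perimeter_smooth`, `perimeter_crack`, `area_px`.
#' @keywords internal
boundary_polygon <- function(mask, smooth_window = 5L) {
  tr <- trace_boundary(mask)
  dr <- c(0, 1, 0, -1)
  dc <- c(1, 0, -1, 0)
  # crack corners: corner (r, c) is at x = c + 0.5, y = r + 0.5
  crack <- data.frame(x = tr$c + 0.5, y = tr$r + 0.5)
  mid <- data.frame(
    x = tr$c + 0.5 + dc[tr$d] / 2,
    y = tr$r + 0.5 + dr[tr$d] / 2
  )
  sx <- smooth_closed(mid$x, smooth_window)
  sy <- smooth_closed(mid$y, smooth_window)
  list(
    crack = crack,
    midcrack = mid,
    perimeter_smooth = polygon_perimeter(sx, sy),
    perimeter_crack = nrow(crack),  # unit steps
    area_px = abs(polygon_signed_area(crack$x, crack$y))
  )
}
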