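# Fixtures built in code: masks, polygon ROIs and small image sets.

disk_mask <- function(r, n = 2L * r + 21L, center = c((n + 1) / 2, (n + 1) / 2)) {
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  m <- matrix(as.integer((g$row - center[1L])^2 + (g$col - center[2L])^2 <= r^2), n, n)
  m
}

ellipse_mask <- function(a, b, theta = 0, n = 2L * max(a, b) + 21L) {
  cx <- (n + 1) / 2
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  x <- g$col - cx
  y <- g$row - cx
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), n, n)
}

square_polygon_roi <- function(a = 20, origin = c(5, 5), shape = c(64L, 64L)) {
  p <- data.frame(x = origin[1L] + c(0, a, a, 0), y = origin[2L] + c(0, 0, a, a))
  lesion_roi(polygon = p, shape = shape)
}

rect_polygon_roi <- function(w, h, origin = c(5, 5), shape = c(128L, 128L)) {
  p <- data.frame(x = origin[1L] + c(0, w, w, 0), y = origin[2L] + c(0, 0, h, h))
  lesion_roi(polygon = p, shape = shape)
}

# cross of 5 unit squares (scaled by `s`), centred square plus 4 arms
plus_polygon_roi <- function(s = 10, origin = c(5, 5), shape = c(64L, 64L)) {
  v <- rbind(
    c(1, 0), c(2, 0), c(2, 1), c(3, 1), c(3, 2), c(2, 2),
    c(2, 3), c(1, 3), c(1, 2), c(0, 2), c(0, 1), c(1, 1)
  )
  p <- data.frame(x = origin[1L] + v[, 1L] * s, y = origin[2L] + v[, 2L] * s)
  lesion_roi(polygon = p, shape = shape)
}

# dense polygon approximation of an axis-aligned ellipse
ellipse_polygon_roi <- function(a, b, center = c(60, 60), shape = c(128L, 128L),
                                n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  p <- data.frame(x = center[1L] + a * cos(th), y = center[2L] + b * sin(th))
  lesion_roi(polygon = p, shape = shape)
}

# uniform-channel image set matching a mask's raster
uniform_image_set <- function(shape, g = 20, r = 50, ir = 150, ...) {
  mk <- function(v) matrix(v, shape[1L], shape[2L])
  msi_image_set(list(G = mk(g), R = mk(r), IR = mk(ir)), ...)
}

# random star-shaped mask (no polygon attached) for raster-path tests
random_star_mask <- function(shape = c(120L, 120L), radius = c(25, 40),
                             irregularity = c(0.1, 0.4)) {
  params <- list(radius = radius, irregularity = irregularity, harmonics = 2:6)
  roi <- generate_lesion_shape(params, image_size = shape)
  roi$mask
}

# scaled-down generator settings for fast unit tests (not the reference
# study conditions; those are the generator defaults)
small_generator_config <- function(...) {
  cp <- default_class_params()
  scale <- 1 / 3
  for (cls in names(cp)) cp[[cls]]$radius <- cp[[cls]]$radius * scale
  generator_config(image_size = c(180L, 180L), class_params = cp,
                   center_jitter_px = 8, ...)
}

# O(n^2) gift-wrapping convex hull area, independent of grDevices::chull
brute_hull_area <- function(x, y) {
  n <- length(x)
  start <- which.min(y + x * 1e-9)
  h <- start
  repeat {
    p <- h[length(h)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1L]
    for (r in cand[-1L]) {
      cr <- (x[q] - x[p]) * (y[r] - y[p]) - (y[q] - y[p]) * (x[r] - x[p])
      d_q <- (x[q] - x[p])^2 + (y[q] - y[p])^2
      d_r <- (x[r] - x[p])^2 + (y[r] - y[p])^2
      if (cr < 0 || (abs(cr) < 1e-12 && d_r > d_q)) q <- r
    }
    if (q == start) break
    h <- c(h, q)
    if (length(h) > n) stop("hull failed")
  }
  xx <- x[h]; yy <- y[h]
  abs(sum(xx * c(yy[-1L], yy[1L]) - c(xx[-1L], xx[1L]) * yy)) / 2
}
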