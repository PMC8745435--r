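# Parameter s': formula, skin reference, map and rendering

test_that("s' matches direct arithmetic and its log-decomposed form", {
  expect_equal(s_prime_value(50, 50, 120, 120), 0)
  expect_equal(s_prime_value(10, 100, 10, 100), 1)
  expect_equal(s_prime_value(50, 100, 25, 100), log10(8))

  set.seed(3)
  n <- 10000
  ig <- runif(n, 1, 255); igs <- runif(n, 1, 255)
  ir <- runif(n, 1, 255); irs <- runif(n, 1, 255)
  direct <- mapply(s_prime_value, ig, igs, ir, irs)
  decomposed <- log10(ig / igs) + 2 * log10(irs / ir)
  expect_lt(max(abs(direct - decomposed)), 1e-12)

  expect_error(s_prime_value(NaN, 1, 1, 1), "I_G")
})

test_that("s' clamps saturated-dark intensities at the floor", {
  expect_equal(s_prime_value(0, 100, 0.2, 100), s_prime_value(1, 100, 1, 100))
  expect_true(is.finite(s_prime_value(0, 100, 0, 100)))
})

test_that("s' responds monotonically to its channels", {
  igs <- 120; irs <- 140
  ig <- seq(5, 250, length.out = 40)
  expect_true(all(diff(s_prime_value(ig, igs, 80, irs)) > 0))
  ir <- seq(5, 250, length.out = 40)
  expect_true(all(diff(s_prime_value(80, igs, ir, irs)) < 0))
  # common per-channel rescaling cancels
  expect_equal(s_prime_value(30, 100, 60, 140),
               s_prime_value(30 * 2.5, 100 * 2.5, 60 * 0.3, 140 * 0.3))
})

test_that("skin reference comes from the annulus or an explicit mask", {
  shape <- c(80L, 80L)
  img <- uniform_image_set(shape, g = 100, r = 100, ir = 150)
  m <- disk_mask(12L, n = 80L)
  img$channels$G[m == 1L] <- 30  # darker lesion
  roi <- lesion_roi(mask = m)

  ref <- estimate_skin_reference(img, roi, inner_margin_px = 5, width_px = 10)
  expect_equal(ref$I_G_skin, 100)
  expect_equal(ref$I_R_skin, 100)

  skin <- matrix(0L, 80, 80); skin[1:10, 1:10] <- 1L
  ref2 <- estimate_skin_reference(img, roi, skin_mask = skin)
  expect_equal(ref2$n_pixels, 100L)
  expect_equal(ref2$I_G_skin, 100)

  expect_error(estimate_skin_reference(img, roi, skin_mask = skin,
                                       min_pixels = 500L),
               "insufficient skin reference")
})

test_that("annulus clipped at the image edge matches a pixel-loop oracle", {
  shape <- c(60L, 60L)
  set.seed(13)
  g <- matrix(runif(3600, 50, 150), 60, 60)
  r <- matrix(runif(3600, 50, 150), 60, 60)
  img <- msi_image_set(list(G = g, R = r, IR = matrix(100, 60, 60)))
  m <- disk_mask(10L, n = 60L, center = c(12, 12))  # near the corner
  roi <- lesion_roi(mask = m)
  inner <- 4; width <- 8
  ref <- estimate_skin_reference(img, roi, inner, width, min_pixels = 10L)

  # oracle: brute-force distance from every pixel to the nearest ROI pixel
  fg <- which(m == 1L, arr.ind = TRUE)
  sel <- matrix(FALSE, 60, 60)
  for (i in 1:60) for (j in 1:60) {
    if (m[i, j] == 1L) next
    d <- sqrt(min((fg[, 1] - i)^2 + (fg[, 2] - j)^2))
    sel[i, j] <- d > inner && d <= inner + width
  }
  expect_equal(ref$n_pixels, sum(sel))
  expect_equal(ref$I_G_skin, mean(g[sel]))
  expect_equal(ref$I_R_skin, mean(r[sel]))
})

test_that("the s' map maximum equals brute-force per-pixel evaluation", {
  shape <- c(70L, 70L)
  img <- uniform_image_set(shape, g = 100, r = 100, ir = 120)
  m <- disk_mask(14L, n = 70L)
  roi <- lesion_roi(mask = m)
  skin <- skin_reference(100, 100, 500L)

  # lesion identical to skin -> all-zero map
  res0 <- s_prime_map(img, roi, skin)
  expect_equal(res0$lesion_s_prime, 0)
  expect_true(all(res0$map[m == 1L] == 0))
  expect_true(all(is.na(res0$map[m == 0L])))

  # one standout pixel at (10, 10) relative values
  img$channels$G[35, 35] <- 10
  img$channels$R[35, 35] <- 10
  res1 <- s_prime_map(img, roi, skin)
  expect_equal(res1$lesion_s_prime, 1)

  set.seed(17)
  img$channels$G[m == 1L] <- runif(sum(m), 5, 200)
  img$channels$R[m == 1L] <- runif(sum(m), 5, 200)
  res2 <- s_prime_map(img, roi, skin)
  brute <- -Inf
  for (i in 1:70) for (j in 1:70) if (m[i, j] == 1L) {
    v <- log10((max(img$channels$G[i, j], 1) * 100^2) /
                 (100 * max(img$channels$R[i, j], 1)^2))
    brute <- max(brute, v)
  }
  expect_equal(res2$lesion_s_prime, brute)
  expect_equal(res2$lesion_s_prime, max(res2$map, na.rm = TRUE))

  # values outside the ROI never affect the lesion score
  img2 <- img
  img2$channels$R[m == 0L] <- 1
  expect_equal(s_prime_map(img2, roi, skin)$lesion_s_prime, res2$lesion_s_prime)
})

test_that("melanoma/nevus decision thresholds at 0.511 with tie to melanoma", {
  expect_equal(melanoma_vs_nevus(0.9), "melanoma")
  expect_equal(melanoma_vs_nevus(0.3), "nevus")
  expect_equal(melanoma_vs_nevus(0.511), "melanoma")
  expect_error(melanoma_vs_nevus(NaN), "finite")
})

test_that("map rendering clamps and uses a diverging blue-white-red scale", {
  m <- matrix(0L, 10, 10); m[3:8, 3:8] <- 1L
  mk_res <- function(v) {
    map <- matrix(NA_real_, 10, 10); map[m == 1L] <- v
    structure(list(map = map, lesion_s_prime = v,
                   skin_ref = skin_reference(100, 100, 500L), statistic = "max"),
              class = "s_prime_result")
  }
  hi <- render_s_prime_map(mk_res(1.5))
  lo <- render_s_prime_map(mk_res(-1.5))
  mid <- render_s_prime_map(mk_res(0))
  over <- render_s_prime_map(mk_res(2.0))
  # clamping: +2.0 renders as +1.5
  expect_equal(over, hi)
  # extremes: red end has R dominant, blue end B dominant; midpoint white
  expect_gt(hi[5, 5, 1], hi[5, 5, 3])
  expect_gt(lo[5, 5, 3], lo[5, 5, 1])
  expect_equal(as.numeric(mid[5, 5, 1:3]), c(1, 1, 1), tolerance = 0.02)
  # outside ROI transparent
  expect_equal(hi[1, 1, 4], 0)
  expect_equal(hi[5, 5, 4], 1)
})

test_that("the float map round trips exactly through its text format", {
  img <- uniform_image_set(c(40L, 40L), g = 60, r = 90, ir = 120)
  roi <- lesion_roi(mask = disk_mask(8L, n = 40L))
  set.seed(29)
  img$channels$G[roi$mask == 1L] <- runif(sum(roi$mask), 5, 250)
  res <- s_prime_map(img, roi, skin_reference(100, 110, 400L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_s_prime_map(res, map_path = path)
  back <- read_s_prime_map(path)
  expect_identical(dim(back), dim(res$map))
  expect_identical(back, res$map)
})
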