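# Shape descriptors and intensity statistics

test_that("mean gray value is integrated density over area", {
  m <- matrix(0L, 20, 20)
  m[5:14, 5:14] <- 1L
  roi <- lesion_roi(mask = m)

  expect_equal(mean_gray_value(matrix(42, 20, 20), roi), 42)

  half <- matrix(0, 20, 20)
  half[, 10:20] <- 200  # ROI cols 5:14 -> 50 px at 0, 50 at 200
  expect_equal(mean_gray_value(half, roi), 100)

  set.seed(7)
  img <- matrix(runif(400, 0, 255), 20, 20)
  acc <- 0; cnt <- 0
  for (i in 1:20) for (j in 1:20) if (m[i, j] == 1L) {
    acc <- acc + img[i, j]; cnt <- cnt + 1
  }
  expect_equal(mean_gray_value(img, roi), acc / cnt)

  expect_error(mean_gray_value(matrix(1, 10, 10), roi),
               "channel dimension mismatch")
})

test_that("circularity matches closed forms on polygon ROIs", {
  expect_equal(circularity(square_polygon_roi(20)), pi / 4)
  expect_equal(circularity(rect_polygon_roi(40, 20)), 2 * pi / 9)
})

test_that("rasterized disk is round by every descriptor", {
  roi <- lesion_roi(mask = disk_mask(100L))
  expect_equal(circularity(roi), 1, tolerance = 0.02)
  expect_equal(roundness(roi), 1, tolerance = 0.02)
  expect_equal(solidity(roi), 1, tolerance = 0.01)
})

test_that("solidity closed forms and hull oracle agree", {
  expect_equal(solidity(square_polygon_roi(20)), 1)
  expect_equal(solidity(plus_polygon_roi()), 5 / 7)

  # random star polygons vs an independent gift-wrapping hull
  set.seed(31)
  for (i in 1:5) {
    star <- generate_lesion_shape(list(radius = c(25, 35),
                                       irregularity = c(0.2, 0.5),
                                       harmonics = 2:7),
                                  image_size = c(120L, 120L))
    p <- star$polygon
    expected <- abs(msibreslow:::polygon_signed_area(p$x, p$y)) /
      brute_hull_area(p$x, p$y)
    expect_equal(solidity(star), min(1, expected), tolerance = 1e-9)
  }
})

test_that("roundness follows the moment-equivalent ellipse", {
  expect_equal(roundness(lesion_roi(mask = disk_mask(60L))), 1, tolerance = 0.02)
  # polygon ellipse with a = 2b -> roundness b/a = 0.5
  expect_equal(roundness(ellipse_polygon_roi(40, 20)), 0.5, tolerance = 1e-3)
  # rasterized 3:1 ellipse, rotated off-axis
  roi <- lesion_roi(mask = ellipse_mask(90L, 30L, theta = pi / 5))
  expect_equal(roundness(roi), 1 / 3, tolerance = 0.02)
})

test_that("descriptors are translation and 90-degree-rotation invariant", {
  set.seed(11)
  m <- random_star_mask()
  base <- c(circularity(lesion_roi(mask = m)),
            solidity(lesion_roi(mask = m)),
            roundness(lesion_roi(mask = m)))
  # translate by (7, 13)
  shifted <- matrix(0L, nrow(m) + 20L, ncol(m) + 20L)
  shifted[7 + seq_len(nrow(m)), 13 + seq_len(ncol(m))] <- m
  expect_equal(c(circularity(lesion_roi(mask = shifted)),
                 solidity(lesion_roi(mask = shifted)),
                 roundness(lesion_roi(mask = shifted))), base)
  # rotate the grid by 90 degrees
  rot <- t(m[nrow(m):1, ])
  expect_equal(c(circularity(lesion_roi(mask = rot)),
                 solidity(lesion_roi(mask = rot)),
                 roundness(lesion_roi(mask = rot))), base)
})

test_that("descriptors are scale invariant", {
  # exact for polygon ROIs
  for (k in c(0.5, 1.7)) {
    p1 <- plus_polygon_roi(s = 10)
    pk <- plus_polygon_roi(s = 10 * k, shape = c(128L, 128L))
    expect_equal(circularity(pk), circularity(p1))
    expect_equal(solidity(pk), solidity(p1))
    expect_equal(roundness(pk), roundness(p1))
  }
  # within 2% for rasterized masks, scale factors 0.5 and 2 around r = 80
  vals <- sapply(c(40L, 80L, 160L), function(r) {
    roi <- lesion_roi(mask = ellipse_mask(r, r %/% 2L))
    c(circularity(roi), solidity(roi), roundness(roi))
  })
  expect_lt(max(abs(vals[, 1] / vals[, 2] - 1)), 0.02)
  expect_lt(max(abs(vals[, 3] / vals[, 2] - 1)), 0.02)
})

test_that("descriptor ranges and hull bound hold on random masks", {
  set.seed(19)
  for (i in 1:8) {
    roi <- lesion_roi(mask = random_star_mask())
    f <- extract_features(uniform_image_set(dim(roi$mask)), roi)
    expect_lte(f$area_px, f$convex_area_px)
    for (v in c(f$circularity, f$solidity, f$roundness)) {
      expect_gt(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("holes are filled and disconnected masks are rejected", {
  m <- disk_mask(20L)
  m_holed <- m
  m_holed[28:34, 28:34] <- 0L  # interior hole
  expect_equal(circularity(lesion_roi(mask = m_holed)),
               circularity(lesion_roi(mask = m)))
  f <- extract_features(uniform_image_set(dim(m), g = 20), lesion_roi(mask = m_holed))
  expect_equal(f$area_px, sum(m))  # hole included in filled area

  two <- matrix(0L, 40, 40)
  two[5:10, 5:10] <- 1L
  two[25:35, 25:35] <- 1L
  expect_error(circularity(lesion_roi(mask = two)), "disconnected mask")
  expect_equal(
    extract_features(uniform_image_set(c(40L, 40L)), lesion_roi(mask = two),
                     largest_component = TRUE)$area_px,
    11 * 11
  )
})

test_that("degenerate thin ROIs still yield finite descriptors", {
  line <- matrix(0L, 12, 12)
  line[6, 3:9] <- 1L
  roi <- lesion_roi(mask = line)
  expect_gt(circularity(roi), 0)
  expect_gt(roundness(roi), 0)
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_true(is.finite(circularity(lesion_roi(mask = one))))
})

test_that("extract_features composes the single-descriptor operations", {
  set.seed(23)
  m <- random_star_mask()
  roi <- lesion_roi(mask = m)
  img <- uniform_image_set(dim(m), g = 20, r = 50, ir = 150)
  f <- extract_features(img, roi)
  expect_equal(f$mean_G, 20)
  expect_equal(f$mean_R, 50)
  expect_equal(f$mean_IR, 150)
  expect_equal(f$circularity, circularity(roi))
  expect_equal(f$solidity, solidity(roi))
  expect_equal(f$roundness, roundness(roi))
  expect_equal(f$area_mm2, f$area_px * img$pixel_size_mm^2)

  # purity: a different ROI on the same image gives different features
  roi2 <- lesion_roi(mask = disk_mask(15L, n = nrow(m)))
  f2 <- extract_features(img, roi2)
  expect_false(isTRUE(all.equal(f$circularity, f2$circularity)))
  # and recomputing the first is unchanged
  expect_equal(extract_features(img, roi)$circularity, f$circularity)
})
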