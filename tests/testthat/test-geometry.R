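test_that("slice MLS matches hand geometry and handles coincident midpoints", {
  # falx (256,100)-(256,400), septum (260,240)-(264,260), 0.5 mm pixels:
  # midpoints (256,250) and (262,250) -> 6 px -> 3.0 mm
  k <- keypoint_set(c(256, 100), c(256, 400), c(260, 240), c(264, 260))
  expect_equal(compute_mls_slice(k, c(0.5, 0.5)), 3.0)

  k0 <- keypoint_set(c(256, 100), c(256, 400), c(256, 200), c(256, 300))
  expect_equal(compute_mls_slice(k0, c(0.5, 0.5)), 0.0)
})

test_that("slice MLS agrees with an independent mm-space oracle", {
  # oracle: convert every point to mm first, then take the plain euclidean
  # distance between averaged points
  oracle <- function(k, sp) {
    tomm <- function(p) c(p[1] * sp[2], p[2] * sp[1])
    a <- (tomm(k$falx_anterior) + tomm(k$falx_posterior)) / 2
    b <- (tomm(k$septum_anterior) + tomm(k$septum_posterior)) / 2
    sqrt(sum((a - b)^2))
  }
  set.seed(41)
  for (i in 1:1000) {
    k <- random_keypoint_set()
    sp <- runif(2, 0.2, 2)   # anisotropic
    expect_equal(compute_mls_slice(k, sp), oracle(k, sp), tolerance = 1e-9)
  }
})

test_that("slice MLS is rigid-motion invariant and scales with spacing", {
  set.seed(42)
  for (i in 1:50) {
    k <- random_keypoint_set()
    sp <- runif(1, 0.3, 1.5)
    base <- compute_mls_slice(k, c(sp, sp))

    shift <- runif(2, 0, 50)
    kt <- structure(lapply(unclass(k), function(p) p + shift),
                    class = "keypoint_set")
    expect_equal(compute_mls_slice(kt, c(sp, sp)), base, tolerance = 1e-9)

    th <- runif(1, 0, 2 * pi)
    rot <- function(p) {
      q <- p - 300
      c(cos(th) * q[1] - sin(th) * q[2],
        sin(th) * q[1] + cos(th) * q[2]) + 300
    }
    kr <- structure(lapply(unclass(k), rot), class = "keypoint_set")
    expect_equal(compute_mls_slice(kr, c(sp, sp)), base, tolerance = 1e-9)

    expect_equal(compute_mls_slice(k, c(2 * sp, 2 * sp)), 2 * base,
                 tolerance = 1e-12)
  }
})

test_that("perpendicular symmetric septum displacement is recovered exactly", {
  set.seed(43)
  for (i in 1:20) {
    sp <- runif(1, 0.3, 1.2)
    d_mm <- runif(1, 0, 12)
    # vertical falx: perpendicular = x direction
    fa <- c(200, 50); fp <- c(200, 350)
    off <- d_mm / sp
    k <- keypoint_set(fa, fp, c(200 + off, 150), c(200 + off, 250))
    expect_equal(compute_mls_slice(k, c(sp, sp)), d_mm, tolerance = 1e-9)
  }
})

test_that("perpendicular mode measures distance to the falx line", {
  # septum midpoint offset along the falx direction contributes in
  # midpoint mode but not in perpendicular mode
  k <- keypoint_set(c(200, 50), c(200, 350), c(210, 240), c(210, 280))
  mid <- compute_mls_slice(k, c(1, 1), mode = "midpoint_distance")
  perp <- compute_mls_slice(k, c(1, 1), mode = "perpendicular_to_falx")
  expect_equal(perp, 10)
  expect_equal(mid, sqrt(10^2 + 60^2))
})

test_that("degenerate falx and bad spacing are rejected", {
  expect_error(keypoint_set(c(1, 1), c(1, 1), c(2, 2), c(3, 3)),
               "degenerate falx")
  expect_error(keypoint_set(c(-1, 1), c(1, 5), c(2, 2), c(3, 3)), "negative")
  k <- keypoint_set(c(1, 1), c(1, 9), c(2, 2), c(3, 3))
  expect_error(compute_mls_slice(k, c(0, 1)), "spacing")
})

test_that("ground-truth bounding box follows the 1.2 / 0.8 construction", {
  # vertical falx of length 300: height 360, width 288
  k <- keypoint_set(c(256, 100), c(256, 400), c(260, 240), c(260, 260))
  b <- keypoints_to_bbox(k)
  expect_equal(c(b$x_min, b$x_max), c(112, 400))
  expect_equal(c(b$y_min, b$y_max), c(70, 430))

  set.seed(44)
  for (i in 1:200) {
    k <- random_keypoint_set()
    b <- keypoints_to_bbox(k)
    w <- b$x_max - b$x_min
    h <- b$y_max - b$y_min
    len <- sqrt(sum((k$falx_posterior - k$falx_anterior)^2))
    expect_equal(w / h, 0.8, tolerance = 1e-6)
    expect_equal(h, 1.2 * len, tolerance = 1e-9)
    for (p in list(k$falx_anterior, k$falx_posterior)) {
      expect_gte(p[1], b$x_min); expect_lte(p[1], b$x_max)
      expect_gte(p[2], b$y_min); expect_lte(p[2], b$y_max)
    }
  }
})

test_that("bounding box clips to image bounds when a shape is given", {
  k <- keypoint_set(c(20, 10), c(20, 500), c(25, 200), c(25, 300))
  b <- keypoints_to_bbox(k, image_shape = c(512, 512))
  expect_gte(b$x_min, 0)
  expect_gte(b$y_min, 0)
  expect_lte(b$y_max, 511)
})

test_that("scan aggregation takes the max with a low-index tie-break", {
  r <- aggregate_scan(data.frame(slice_index = c(3, 4, 5),
                                 mls_mm = c(1.2, 3.4, 0.5)), "s1", "annotation")
  expect_equal(r$scan_mls_mm, 3.4)
  expect_equal(r$argmax_slice_index, 4L)
  expect_true(r$defined)

  tie <- aggregate_scan(data.frame(slice_index = c(2, 1),
                                   mls_mm = c(2, 2)), "s1", "annotation")
  expect_equal(tie$argmax_slice_index, 1L)

  empty <- aggregate_scan(data.frame(slice_index = integer(),
                                     mls_mm = numeric()), "s1", "prediction")
  expect_false(empty$defined)
  expect_true(is.na(empty$scan_mls_mm))

  expect_error(aggregate_scan(data.frame(slice_index = 1, mls_mm = -0.1),
                              "s1", "annotation"), "non-negative")
})

test_that("adding a larger slice never decreases the scan MLS", {
  set.seed(45)
  for (i in 1:20) {
    ps <- data.frame(slice_index = 0:4, mls_mm = runif(5, 0, 10))
    base <- aggregate_scan(ps, "s", "annotation")$scan_mls_mm
    ps2 <- rbind(ps, data.frame(slice_index = 5,
                                mls_mm = base + runif(1, 0, 5)))
    expect_gte(aggregate_scan(ps2, "s", "annotation")$scan_mls_mm, base)
  }
})

test_that("keypoint rescaling is exact and invertible", {
  k <- keypoint_set(c(100, 50), c(100, 200), c(110, 120), c(110, 140))
  expect_equal(unclass(rescale_keypoints(k, 256, 256)),
               unclass(k)[c("falx_anterior", "falx_posterior",
                            "septum_anterior", "septum_posterior")])
  k2 <- rescale_keypoints(k, 256, 512)
  expect_equal(k2$falx_anterior, c(200, 100))
  k3 <- rescale_keypoints(rescale_keypoints(k, c(256, 320), c(512, 200)),
                          c(512, 200), c(256, 320))
  for (nm in names(unclass(k)))
    expect_equal(k3[[nm]], k[[nm]], tolerance = 1e-9)
})
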