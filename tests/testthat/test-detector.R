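# Small phantom cohorts keep these tests fast; the end-to-end learning check
# at full desk scale lives in the acceptance suite.

tiny_cfg <- function(lr_initial = 1e-3, ...) {
  detector_config(image_size = 96L, heatmap_size = 16L, roi_size = 5L,
                  batch_size = 8L, lr_initial = lr_initial, val_every = 5L,
                  seed = 7L, ...)
}

tiny_dataset <- function(n_scans = 3, seed0 = 0, image_size = 96L) {
  scans <- lapply(seq_len(n_scans), function(i)
    generate_phantom(phantom_spec(
      patient_id = sprintf("p%02d", i), scan_id = sprintf("s%02d", i + seed0),
      image_size = 128L, n_slices = 8L, true_mls_mm = runif(1, 2, 12),
      shift_direction = sample(c(-1, 1), 1), seed = i + seed0)))
  list(scans = scans,
       ds = detector_dataset(scans, image_size = image_size, seed = seed0 + 1))
}

test_that("the learning-rate schedule is a single step drop", {
  cfg <- detector_config()
  expect_equal(lr_schedule(cfg, 0), 1e-4)
  expect_equal(lr_schedule(cfg, 99), 1e-4)
  expect_equal(lr_schedule(cfg, cfg$lr_drop_epoch), 1e-4 / 10)
  expect_equal(lr_schedule(cfg, 199), 1e-5)
  trace <- lr_schedule(cfg, 0:199)
  expect_equal(sum(diff(trace) != 0), 1)       # exactly one drop
  expect_error(detector_config(lr_initial = 0), "lr_initial")
  expect_equal(cfg$n_keypoints, 4L)
  expect_equal(cfg$optimizer$beta1, 0.9)
  expect_equal(cfg$optimizer$beta2, 0.999)
  expect_equal(cfg$optimizer$weight_decay, 0)
  expect_equal(cfg$batch_size, 16L)
  expect_equal(cfg$epochs, 200L)
})

test_that("augmentation with all flags off is the identity", {
  set.seed(61)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  kp <- keypoint_set(c(32, 10), c(32, 54), c(35, 28), c(35, 36))
  cfg <- detector_config(augment = list(flip_sagittal = FALSE, affine = FALSE,
                                        erasing = FALSE, metal_streaks = FALSE))
  out <- augment_sample(img, kp, cfg, seed = 1)
  expect_identical(out$image, img)
  expect_identical(unclass(out$keypoints), unclass(kp))
})

test_that("the sagittal flip is an involution that reflects x about the centre", {
  set.seed(62)
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))
  kp <- keypoint_set(c(256, 100), c(256, 400), c(270, 240), c(270, 260))
  fl <- mlshift:::.flip_sagittal(img, kp)
  # falx x = 256 reflects about 255.5 -> 255; identities preserved
  expect_equal(fl$keypoints$falx_anterior, c(255, 100))
  expect_equal(fl$keypoints$falx_posterior, c(255, 400))
  expect_equal(fl$keypoints$septum_anterior, c(241, 240))
  fl2 <- mlshift:::.flip_sagittal(fl$image, fl$keypoints)
  expect_identical(fl2$image, img)
  expect_equal(unclass(fl2$keypoints), unclass(kp))
})

test_that("flipping commutes with the ground-truth box construction", {
  set.seed(63)
  for (i in 1:20) {
    kp <- random_keypoint_set(512)
    img <- array(0, c(512, 512, 3))
    b0 <- keypoints_to_bbox(kp)
    bf <- keypoints_to_bbox(mlshift:::.flip_sagittal(img, kp)$keypoints)
    expect_equal(bf$x_min, (512 - 1) - b0$x_max, tolerance = 1e-12)
    expect_equal(bf$x_max, (512 - 1) - b0$x_min, tolerance = 1e-12)
    expect_equal(bf$y_min, b0$y_min)
    expect_equal(bf$y_max, b0$y_max)
  }
})

test_that("augmentation is deterministic under seed and keeps keypoints in bounds", {
  set.seed(64)
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  kp <- keypoint_set(c(48, 14), c(48, 82), c(52, 42), c(52, 54))
  cfg <- detector_config()
  a1 <- augment_sample(img, kp, cfg, seed = 5)
  a2 <- augment_sample(img, kp, cfg, seed = 5)
  expect_identical(a1$image, a2$image)
  expect_equal(unclass(a1$keypoints), unclass(a2$keypoints))
  for (s in 1:10) {
    a <- augment_sample(img, kp, cfg, seed = s)
    for (p in unclass(a$keypoints)) {
      expect_true(all(p >= 0))
      expect_true(p[1] <= 95 && p[2] <= 95)
    }
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
})

test_that("network gradients match finite differences", {
  set.seed(65)
  cfg <- detector_config(image_size = 64L, heatmap_size = 8L, roi_size = 3L)
  net <- mlshift:::.detector_init(cfg)
  kp <- keypoint_set(c(32, 10), c(33, 54), c(36, 26), c(36, 38))
  s <- list(x = array(runif(64 * 64 * 3), c(64, 64, 3)), keypoints = kp,
            bbox = keypoints_to_bbox(kp))
  lossfn <- function(params) {
    set.seed(99)
    mlshift:::.sample_loss(s, params, net$bb, cfg)$loss
  }
  set.seed(99)
  sl <- mlshift:::.sample_loss(s, net$params, net$bb, cfg)
  eps <- 1e-6
  bump <- function(setter) {
    p <- setter(net$params, eps); q <- setter(net$params, -eps)
    (lossfn(p) - lossfn(q)) / (2 * eps)
  }
  expect_equal(sl$grads$backbone[[1]]$W[5, 2],
               bump(function(p, e) { p$backbone[[1]]$W[5, 2] <- p$backbone[[1]]$W[5, 2] + e; p }),
               tolerance = 1e-5)
  expect_equal(sl$grads$rpn$W[10, 1],
               bump(function(p, e) { p$rpn$W[10, 1] <- p$rpn$W[10, 1] + e; p }),
               tolerance = 1e-5)
  ii <- which(abs(sl$grads$kp$W) > 1e-4, arr.ind = TRUE)[1, ]
  expect_equal(sl$grads$kp$W[ii[1], ii[2]],
               bump(function(p, e) { p$kp$W[ii[1], ii[2]] <- p$kp$W[ii[1], ii[2]] + e; p }),
               tolerance = 1e-5)
})

test_that("training is deterministic, logged, and aborts on bad input", {
  set.seed(66)
  td <- tiny_dataset(2)
  cfg <- tiny_cfg(epochs = 1L)
  m1 <- train_detector(td$ds, NULL, cfg)
  m2 <- train_detector(td$ds, NULL, cfg)
  expect_equal(m1$log$loss_total, m2$log$loss_total)  # epoch-0 determinism
  expect_named(m1$log, c("epoch", "lr", "loss_total", "loss_proposal",
                         "loss_cls", "loss_box", "loss_kp", "val_kp_err_mm"))
  expect_true(all(is.finite(m1$log$loss_total)))
  expect_equal(m1$log$lr[1], 1e-3)

  empty <- structure(list(samples = list(), image_size = 96L),
                     class = "detector_dataset")
  expect_error(train_detector(empty, NULL, cfg), "empty")
  expect_error(train_detector(td$ds, NULL, detector_config(image_size = 128L)),
               "image_size")
})

test_that("a briefly trained detector beats an untrained one on keypoint error", {
  set.seed(67)
  td <- tiny_dataset(6)
  cfg0 <- tiny_cfg(epochs = 1L, lr_initial = 1e-12)   # effectively untrained
  cfg <- tiny_cfg(epochs = 8L)
  base <- train_detector(td$ds, td$ds, cfg0)
  trained <- train_detector(td$ds, td$ds, cfg)
  e0 <- base$log$val_kp_err_mm[nrow(base$log)]
  e1 <- trained$log$val_kp_err_mm[nrow(trained$log)]
  expect_true(is.finite(e0) && is.finite(e1))
  expect_lt(e1, e0)
})

test_that("prediction honours the score threshold and the box contract", {
  set.seed(68)
  td <- tiny_dataset(4)
  cfg <- tiny_cfg(epochs = 6L)
  m <- train_detector(td$ds, NULL, cfg)

  vol <- td$scans[[1]]$volume
  inputs <- preprocess_volume(vol)
  none <- predict_keypoints(m, inputs, score_threshold = 1.01)
  expect_true(all(vapply(none, is.null, TRUE)))

  dets <- predict_keypoints(m, inputs, score_threshold = 0)
  dets <- Filter(Negate(is.null), dets)
  expect_gt(length(dets), 0)
  for (d in dets) {
    expect_gte(d$score, 0); expect_lte(d$score, 1)
    b <- d$box
    dw <- 0.1 * (b$x_max - b$x_min); dh <- 0.1 * (b$y_max - b$y_min)
    for (p in unclass(d$keypoints)) {
      expect_gte(p[1], b$x_min - dw); expect_lte(p[1], b$x_max + dw)
      expect_gte(p[2], b$y_min - dh); expect_lte(p[2], b$y_max + dh)
    }
  }

  # an all-air volume must trigger no detection at the default threshold
  air <- ct_volume(array(-1000, c(4, 128, 128)), c(5, 0.5, 0.5),
                   scan_id = "air")
  r <- run_pipeline(air, m)
  expect_false(r$defined)
})

test_that("the fpn50 backbone builds and runs forward", {
  set.seed(69)
  cfg <- detector_config(backbone_depth = "fpn50", image_size = 64L,
                         heatmap_size = 8L, roi_size = 3L)
  net <- mlshift:::.detector_init(cfg)
  kp <- keypoint_set(c(32, 10), c(33, 54), c(36, 26), c(36, 38))
  s <- list(x = array(runif(64 * 64 * 3), c(64, 64, 3)), keypoints = kp,
            bbox = keypoints_to_bbox(kp))
  sl <- mlshift:::.sample_loss(s, net$params, net$bb, cfg)
  expect_true(is.finite(sl$loss))
  expect_equal(net$bb$stride, 16L)
})

test_that("the oracle detector reproduces ground truth and drops slices", {
  scan <- small_phantom(true_mls = 7.5, seed = 71, n_slices = 10,
                        image_size = 128)
  om <- oracle_detector(scan$annotations, sigma_px = 0, dropout_rate = 0)
  r <- run_pipeline(scan$volume, om)
  expect_true(r$defined)
  expect_equal(r$scan_mls_mm, 7.5, tolerance = 1e-9)
  expect_equal(r$source, "prediction")

  one <- scan$annotations[1]
  dropped <- oracle_detector(one, sigma_px = 0, dropout_rate = 0.999,
                             seed = 2)
  r2 <- run_pipeline(scan$volume, dropped)
  expect_false(r2$defined)

  noisy1 <- oracle_detector(scan$annotations, 2, 0.2, seed = 5)
  noisy2 <- oracle_detector(scan$annotations, 2, 0.2, seed = 5)
  mi <- preprocess_volume(scan$volume)
  expect_identical(predict_keypoints(noisy1, mi), predict_keypoints(noisy2, mi))
  expect_error(oracle_detector(scan$annotations, -1), "sigma")
  expect_error(oracle_detector(scan$annotations, 0, 1), "dropout")
})

test_that("run_pipeline composes preprocess, detect, and aggregation", {
  scan <- small_phantom(true_mls = 0, seed = 72, n_slices = 8,
                        image_size = 128)
  om <- oracle_detector(scan$annotations, 0, 0)
  r <- run_pipeline(scan$volume, om)
  expect_equal(r$scan_mls_mm, 0)
  expect_equal(nrow(r$per_slice), length(scan$annotations))
})
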