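# Two-stage keypoint detector: a convolutional backbone, a region-proposal
# head (objectness + box deltas over a single anchor per feature cell), and a
# second stage that crops ROI features and runs classification, box-refinement
# and keypoint-heatmap heads. The keypoint head predicts a one-hot spatial
# heatmap per landmark inside the ROI, decoded by argmax. The `tiny` backbone
# trains on phantoms in minutes on one CPU; `fpn50` is the large
# residual-FPN-style variant of the same contract.

#' Detector configuration
#'
#' Defaults follow the training schedule of the reference protocol: Adam
#' (beta1 0.9, beta2 0.999, weight decay 0) at an initial learning rate of
#' 1e-4, divided by 10 after 100 epochs, batch size 16, 200 epochs, with
#' sagittal-flip / affine / erasing / metal-streak augmentation. The number
#' of keypoints is fixed at 4.
#'
#' @param backbone_depth `"tiny"` (desk-scale strided CNN, default) or
#'   `"fpn50"` (bottleneck-residual feature-pyramid backbone).
#' @param image_size side of the square input the network consumes; model
#'   inputs are rescaled to this size internally (default 256).
#' @param epochs number of training epochs (default 200).
#' @param lr_initial initial learning rate (default 1e-4).
#' @param lr_drop_epoch 0-based epoch from which the rate is divided by
#'   `lr_drop_factor` (default 100).
#' @param lr_drop_factor step-drop factor (default 10).
#' @param batch_size minibatch size (default 16).
#' @param augment named logical list: `flip_sagittal`, `affine`, `erasing`,
#'   `metal_streaks` (all default `TRUE`).
#' @param heatmap_size side of the per-keypoint ROI heatmap (default 56).
#' @param roi_size side of the ROI feature crop (default 7).
#' @param score_threshold default detection score cutoff (default 0.5).
#' @param val_every compute the validation keypoint error every this many
#'   epochs (and always on the last); 1 = every epoch.
#' @param seed RNG seed controlling initialisation, sampling and augmentation.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(backbone_depth = c("tiny", "fpn50"),
                            image_size = 256L,
                            epochs = 200L,
                            lr_initial = 1e-4,
                            lr_drop_epoch = 100L,
                            lr_drop_factor = 10,
                            batch_size = 16L,
                            augment = list(flip_sagittal = TRUE, affine = TRUE,
                                           erasing = TRUE, metal_streaks = TRUE),
                            heatmap_size = 56L,
                            roi_size = 7L,
                            score_threshold = 0.5,
                            val_every = 1L,
                            seed = 42L) {
  backbone_depth <- match.arg(backbone_depth)
  if (lr_initial <= 0) stop("lr_initial must be > 0", call. = FALSE)
  aug <- list(flip_sagittal = TRUE, affine = TRUE, erasing = TRUE,
              metal_streaks = TRUE)
  aug[names(augment)] <- augment
  structure(list(backbone_depth = backbone_depth,
                 image_size = as.integer(image_size),
                 n_keypoints = 4L,
                 epochs = as.integer(epochs),
                 lr_initial = lr_initial,
                 lr_drop_epoch = as.integer(lr_drop_epoch),
                 lr_drop_factor = lr_drop_factor,
                 batch_size = as.integer(batch_size),
                 optimizer = list(name = "adam", beta1 = 0.9, beta2 = 0.999,
                                  weight_decay = 0),
                 augment = aug,
                 heatmap_size = as.integer(heatmap_size),
                 roi_size = as.integer(roi_size),
                 score_threshold = score_threshold,
                 val_every = as.integer(val_every),
                 seed = as.integer(seed)),
            class = "detector_config")
}

#' Learning rate at a given epoch
#'
#' A step schedule: `lr_initial` before `lr_drop_epoch`, divided by
#' `lr_drop_factor` from that (0-based) epoch on -- exactly one drop.
#'
#' @param cfg a [detector_config()].
#' @param epoch 0-based epoch index.
#' @return learning rate.
#' @export
lr_schedule <- function(cfg, epoch) {
  ifelse(epoch >= cfg$lr_drop_epoch,
         cfg$lr_initial / cfg$lr_drop_factor, cfg$lr_initial)
}

## ---- network assembly -----------------------------------------------------

.make_backbone <- function(cfg) {
  switch(cfg$backbone_depth,
         tiny = make_backbone_tiny(),
         fpn50 = make_backbone_fpn50())
}

.detector_init <- function(cfg) {
  bb <- .make_backbone(cfg)
  fc_in <- cfg$roi_size^2 * bb$cout
  G <- cfg$heatmap_size
  params <- list(backbone = bb$params,
                 rpn = .fc_param(bb$cout, 5L),
                 fc1 = .fc_param(fc_in, 128L),
                 score = .fc_param(128L, 1L),
                 box = .fc_param(128L, 4L),
                 kp = .fc_param(128L, 4L * G * G))
  list(params = params, bb = bb)
}

# single anchor per feature cell, sized for a head-filling brain box
.anchor_at <- function(cell_row, cell_col, stride, size) {
  cx <- (cell_col + 0.5) * stride
  cy <- (cell_row + 0.5) * stride
  w <- 0.45 * size
  h <- w / 0.8
  list(x0 = cx - w / 2, y0 = cy - h / 2, x1 = cx + w / 2, y1 = cy + h / 2)
}

# bbox in cfg pixels -> list(x0, y0, x1, y1)
.bb_list <- function(b) list(x0 = b$x_min, y0 = b$y_min,
                             x1 = b$x_max, y1 = b$y_max)

# forward pass of the RPN over a feature map; returns (ncells x 5) logits
.rpn_fwd <- function(feat, p) {
  fm <- matrix(feat, ncol = dim(feat)[3])
  sweep(fm %*% p$W, 2L, p$b, `+`)
}

# ROI head: crop -> fc -> (score, box deltas, keypoint heatmap logits)
.roi_fwd <- function(feat, box, params, cfg, stride) {
  fbox <- list(x0 = box$x0 / stride, y0 = box$y0 / stride,
               x1 = box$x1 / stride, y1 = box$y1 / stride)
  rc <- roi_crop_fwd(feat, fbox, cfg$roi_size)
  z1 <- fc_fwd(rc$crop, params$fc1)
  h1 <- relu_fwd(z1)
  G <- cfg$heatmap_size
  list(score = fc_fwd(h1, params$score),
       boxd = fc_fwd(h1, params$box),
       kp = matrix(fc_fwd(h1, params$kp), nrow = G * G, ncol = 4L),
       crop = rc, z1 = z1, h1 = h1)
}

# backward through the ROI head given gradients on its three outputs;
# returns dfeat plus parameter grads. Box/keypoint gradients are NULL for
# background ROIs (their losses are not taken there).
.roi_bwd <- function(fw, dscore, dboxd, dkp, params, cfg) {
  dh1 <- as.numeric(params$score$W %*% dscore)
  g_box <- g_kp <- NULL
  if (!is.null(dboxd)) {
    dh1 <- dh1 + as.numeric(params$box$W %*% dboxd)
    g_box <- list(W = outer(fw$h1, dboxd), b = dboxd)
  }
  if (!is.null(dkp)) {
    dkpv <- as.numeric(dkp)
    dh1 <- dh1 + as.numeric(params$kp$W %*% dkpv)
    g_kp <- list(W = outer(fw$h1, dkpv), b = dkpv)
  }
  g_score <- list(W = outer(fw$h1, dscore), b = dscore)
  dz1 <- relu_bwd(dh1, fw$h1)
  g1 <- fc_bwd(dz1, fw$crop$crop, params$fc1)
  dfeat <- roi_crop_bwd(g1$dx, fw$crop)
  list(dfeat = dfeat,
       grads = list(fc1 = list(W = g1$dW, b = g1$db),
                    score = g_score, box = g_box, kp = g_kp))
}

# keypoint -> heatmap cell index (1-based) within a box, or NA if outside
.kp_cell <- function(p, box, G) {
  gx <- floor((p[1] - box$x0) / (box$x1 - box$x0) * G)
  gy <- floor((p[2] - box$y0) / (box$y1 - box$y0) * G)
  if (gx < 0 || gx >= G || gy < 0 || gy >= G) return(NA_integer_)
  as.integer(gy + G * gx + 1L)   # column-major (row, col) = (gy, gx)
}

.cell_to_xy <- function(idx, box, G) {
  idx0 <- idx - 1L
  gy <- idx0 %% G
  gx <- idx0 %/% G
  c(box$x0 + (gx + 0.5) * (box$x1 - box$x0) / G,
    box$y0 + (gy + 0.5) * (box$y1 - box$y0) / G)
}

.jitter_box <- function(box, size) {
  bc <- .box_ctr(box)
  s <- exp(stats::runif(1, -0.12, 0.12))
  cx <- bc$cx + stats::rnorm(1, 0, 0.05 * bc$w)
  cy <- bc$cy + stats::rnorm(1, 0, 0.05 * bc$h)
  clip_box(list(x0 = cx - s * bc$w / 2, y0 = cy - s * bc$h / 2,
                x1 = cx + s * bc$w / 2, y1 = cy + s * bc$h / 2), size)
}

.box_iou <- function(a, b) {
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ix * iy
  ua <- (a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  inter / ua
}

.random_neg_box <- function(size, gt = NULL) {
  for (i in 1:10) {
    w <- stats::runif(1, 0.2, 0.6) * size
    h <- w / 0.8
    cx <- stats::runif(1, 0.1, 0.9) * size
    cy <- stats::runif(1, 0.1, 0.9) * size
    box <- clip_box(list(x0 = cx - w / 2, y0 = cy - h / 2,
                         x1 = cx + w / 2, y1 = cy + h / 2), size)
    if (is.null(gt) || .box_iou(box, gt) < 0.3) return(box)
  }
  box
}

## ---- per-sample loss and gradient ----

# sample: list(x = (S,S,3) array, keypoints = keypoint_set or NULL,
#              bbox = bounding_box or NULL)
.sample_loss <- function(sample, params, bb, cfg) {
  S <- cfg$image_size
  stride <- bb$stride
  fwd <- bb$forward(params$backbone, sample$x)
  feat <- fwd$out
  gh <- dim(feat)[1]; gw <- dim(feat)[2]
  rpn <- .rpn_fwd(feat, params$rpn)
  ncell <- gh * gw
  drpn <- matrix(0, ncell, 5L)

  losses <- c(proposal = 0, cls = 0, box = 0, kp = 0)
  positive <- !is.null(sample$keypoints)
  G <- cfg$heatmap_size

  if (positive) {
    gt <- .bb_list(sample$bbox)
    gc <- .box_ctr(gt)
    pr <- min(max(floor(gc$cy / stride), 0), gh - 1)
    pc <- min(max(floor(gc$cx / stride), 0), gw - 1)
    # positives: the 3x3 cell neighbourhood of the box centre, each cell
    # regressing the gt box against its own anchor; negatives are sampled
    # well clear of the centre (nearby cells look identical and would give
    # contradictory objectness labels)
    prs <- pr + (-1):1; pcs <- pc + (-1):1
    prs <- prs[prs >= 0 & prs < gh]; pcs <- pcs[pcs >= 0 & pcs < gw]
    pos_cells <- as.integer(outer(prs, pcs, function(r, co) r + gh * co)) + 1L
    excl <- max(2L, min(4L, floor(min(gh, gw) / 5)))  # grid-scaled margin
    cand <- sample.int(ncell, min(40L, ncell)) - 1L
    far <- cand[pmax(abs(cand %% gh - pr), abs(cand %/% gh - pc)) > excl] + 1L
    neg_idx <- far[seq_len(min(8L, length(far)))]
    ob_pos <- bce_logit(rpn[pos_cells, 1L], rep(1, length(pos_cells)))
    losses["proposal"] <- ob_pos$loss
    drpn[pos_cells, 1L] <- ob_pos$dz
    if (length(neg_idx)) {
      ob_neg <- bce_logit(rpn[neg_idx, 1L], numeric(length(neg_idx)))
      losses["proposal"] <- losses["proposal"] + ob_neg$loss
      drpn[neg_idx, 1L] <- ob_neg$dz
    }
    box_l <- 0
    for (cell in pos_cells) {
      anc <- .anchor_at((cell - 1L) %% gh, (cell - 1L) %/% gh, stride, S)
      bl <- smooth_l1(rpn[cell, 2:5], box_to_delta(gt, anc))
      box_l <- box_l + bl$loss / length(pos_cells)
      drpn[cell, 2:5] <- bl$dz / length(pos_cells)
    }
    losses["proposal"] <- losses["proposal"] + box_l
    rois <- list(list(box = .jitter_box(gt, S), target = 1),
                 list(box = .random_neg_box(S, gt), target = 0))
  } else {
    sel <- sample.int(ncell, min(9L, ncell))
    ob <- bce_logit(rpn[sel, 1L], numeric(length(sel)))
    losses["proposal"] <- ob$loss
    drpn[sel, 1L] <- ob$dz
    rois <- list(list(box = .random_neg_box(S), target = 0))
  }

  dfeat <- array(0, dim(feat))
  grads <- list(rpn = list(W = crossprod(matrix(feat, ncol = dim(feat)[3]), drpn),
                           b = colSums(drpn)),
                fc1 = NULL, score = NULL, box = NULL, kp = NULL)
  dfeat <- dfeat + {
    dfm <- tcrossprod(drpn, params$rpn$W)
    dim(dfm) <- dim(feat)
    dfm
  }

  for (roi in rois) {
    fw <- .roi_fwd(feat, roi$box, params, cfg, stride)
    sc <- bce_logit(fw$score, roi$target)
    losses["cls"] <- losses["cls"] + sc$loss / length(rois)
    dscore <- sc$dz / length(rois)
    dboxd <- NULL
    dkp <- NULL
    if (roi$target == 1) {
      dkp <- matrix(0, G * G, 4L)
      gt <- .bb_list(sample$bbox)
      bl <- smooth_l1(fw$boxd, box_to_delta(gt, roi$box))
      losses["box"] <- bl$loss
      dboxd <- bl$dz
      kps <- sample$keypoints
      cells <- vapply(KEYPOINT_NAMES,
                      function(nm) .kp_cell(kps[[nm]], roi$box, G), 0L)
      vis <- which(!is.na(cells))
      if (length(vis)) {
        for (j in vis) {
          ce <- softmax_ce(fw$kp[, j], cells[j])
          losses["kp"] <- losses["kp"] + ce$loss / length(vis)
          dkp[, j] <- ce$dz / length(vis)
        }
      }
    }
    rb <- .roi_bwd(fw, dscore, dboxd, dkp, params, cfg)
    dfeat <- dfeat + rb$dfeat
    for (nm in names(rb$grads)) {
      if (is.null(rb$grads[[nm]])) next
      grads[[nm]] <- if (is.null(grads[[nm]])) rb$grads[[nm]]
        else .tree_add(grads[[nm]], rb$grads[[nm]])
    }
  }
  # background-only samples leave box/kp untouched: zero-fill so every
  # sample's gradient tree has the same shape
  for (nm in c("box", "kp"))
    if (is.null(grads[[nm]]))
      grads[[nm]] <- list(W = params[[nm]]$W * 0, b = params[[nm]]$b * 0)

  grads$backbone <- bb$backward(params$backbone, fwd$cache, dfeat)
  list(loss = sum(losses), components = losses, grads = grads)
}

## ---- inference on one prepared sample ----

# x: (S,S,3) in cfg resolution. Returns NULL or detection in cfg pixel space.
.predict_sample <- function(x, params, bb, cfg, score_threshold) {
  S <- cfg$image_size
  stride <- bb$stride
  feat <- bb$forward(params$backbone, x)$out
  gh <- dim(feat)[1]; gw <- dim(feat)[2]
  rpn <- .rpn_fwd(feat, params$rpn)
  top <- which.max(rpn[, 1L])
  pr <- (top - 1L) %% gh
  pc <- (top - 1L) %/% gh
  anc <- .anchor_at(pr, pc, stride, S)
  proposal <- clip_box(delta_to_box(rpn[top, 2:5], anc), S)
  fw1 <- .roi_fwd(feat, proposal, params, cfg, stride)
  refined <- clip_box(delta_to_box(fw1$boxd, proposal), S)
  fw2 <- .roi_fwd(feat, refined, params, cfg, stride)
  score <- stats::plogis(fw2$score)
  if (score < score_threshold) return(NULL)
  G <- cfg$heatmap_size
  kp <- lapply(1:4, function(j)
    .cell_to_xy(which.max(fw2$kp[, j]), refined, G))
  names(kp) <- KEYPOINT_NAMES
  list(box = refined, score = score,
       keypoints = structure(kp, class = "keypoint_set"))
}

## ---- datasets ----

#' Build a detector dataset from labelled scans
#'
#' Preprocesses each scan, pairs every annotated slice with its keypoints
#' (rescaled to `image_size`) and the falx-derived ground-truth box, and adds
#' up to `negatives_per_scan` septum-free slices as background samples.
#'
#' @param scans list of `labeled_scan`s with rendered volumes.
#' @param image_size square size the network consumes (must match the
#'   config's `image_size`).
#' @param windows the three [window_spec()]s.
#' @param negatives_per_scan background slices per scan (default 1).
#' @param air_negatives empty (all-air) background samples per scan
#'   (default 1), standing in for slices beyond the skull.
#' @param seed RNG seed for negative-slice sampling.
#' @return an object of class `detector_dataset`.
#' @export
detector_dataset <- function(scans, image_size = 256L,
                             windows = default_windows(),
                             negatives_per_scan = 1L, air_negatives = 1L,
                             seed = 1L) {
  samples <- list()
  with_seed(seed, {
    for (scan in scans) {
      if (is.null(scan$volume))
        stop("detector_dataset needs rendered volumes ",
             "(generate_phantom(render_voxels = TRUE))", call. = FALSE)
      vol <- scan$volume
      native <- dim(vol$voxels)[2:3]
      mis <- preprocess_volume(vol, windows)
      ann_slices <- vapply(scan$annotations, function(a) a$slice_index, 0L)
      sp_cfg <- mis[[1]]$effective_spacing * (512 / image_size)
      for (a in scan$annotations) {
        kp <- rescale_keypoints(a$keypoints, native, c(image_size, image_size))
        x <- EBImage::resize(mis[[a$slice_index + 1L]]$pixels,
                             w = image_size, h = image_size,
                             filter = "bilinear")
        samples[[length(samples) + 1L]] <- list(
          x = x, keypoints = kp, bbox = keypoints_to_bbox(kp),
          scan_id = vol$scan_id, slice_index = a$slice_index,
          spacing = sp_cfg)
      }
      bg <- setdiff(seq_len(dim(vol$voxels)[1]) - 1L, ann_slices)
      if (negatives_per_scan > 0L && length(bg)) {
        for (i in sample(bg, min(negatives_per_scan, length(bg)))) {
          x <- EBImage::resize(mis[[i + 1L]]$pixels,
                               w = image_size, h = image_size,
                               filter = "bilinear")
          samples[[length(samples) + 1L]] <- list(
            x = x, keypoints = NULL, bbox = NULL,
            scan_id = vol$scan_id, slice_index = i, spacing = sp_cfg)
        }
      }
      if (air_negatives > 0L) {
        for (j in seq_len(air_negatives))
          samples[[length(samples) + 1L]] <- list(
            x = array(0, c(image_size, image_size, 3L)),
            keypoints = NULL, bbox = NULL,
            scan_id = vol$scan_id, slice_index = NA_integer_,
            spacing = sp_cfg)
      }
    }
  })
  structure(list(samples = samples, image_size = as.integer(image_size)),
            class = "detector_dataset")
}

#' @export
print.detector_dataset <- function(x, ...) {
  pos <- sum(vapply(x$samples, function(s) !is.null(s$keypoints), TRUE))
  cat(sprintf("<detector_dataset> %d samples (%d keypoint, %d background) at %dx%d\n",
              length(x$samples), pos, length(x$samples) - pos,
              x$image_size, x$image_size))
  invisible(x)
}

## ---- augmentation ----

.flip_sagittal <- function(image, keypoints) {
  W <- dim(image)[2]
  image <- image[, rev(seq_len(W)), , drop = FALSE]
  if (!is.null(keypoints)) {
    kp <- lapply(unclass(keypoints)[KEYPOINT_NAMES],
                 function(p) c((W - 1) - p[1], p[2]))
    keypoints <- structure(kp, class = "keypoint_set")
  }
  list(image = image, keypoints = keypoints)
}

# inverse-mapped bilinear affine warp; source outside the image samples 0
.warp_affine <- function(image, theta, scale, tx, ty) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  xo <- rep(0:(W - 1), each = H) - cx - tx
  yo <- rep(0:(H - 1), times = W) - cy - ty
  ct <- cos(theta); st <- sin(theta)
  xs <- (ct * xo + st * yo) / scale + cx   # inverse rotation
  ys <- (-st * xo + ct * yo) / scale + cy
  ok <- which(xs >= 0 & xs <= W - 1 & ys >= 0 & ys <= H - 1)
  xs <- xs[ok]; ys <- ys[ok]
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  i00 <- y0 + H * x0 + 1; i10 <- y1 + H * x0 + 1
  i01 <- y0 + H * x1 + 1; i11 <- y1 + H * x1 + 1
  w00 <- (1 - fx) * (1 - fy); w10 <- (1 - fx) * fy
  w01 <- fx * (1 - fy); w11 <- fx * fy
  out <- array(0, d)
  hw <- H * W
  for (ch in seq_len(d[3])) {
    off <- hw * (ch - 1)
    out[ok + off] <- w00 * image[i00 + off] + w10 * image[i10 + off] +
      w01 * image[i01 + off] + w11 * image[i11 + off]
  }
  out
}

.affine_point <- function(p, theta, scale, tx, ty, W, H) {
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  x <- p[1] - cx; y <- p[2] - cy
  c(scale * (cos(theta) * x - sin(theta) * y) + cx + tx,
    scale * (sin(theta) * x + cos(theta) * y) + cy + ty)
}

#' Augment a training sample
#'
#' Applies (in order) random sagittal flip, random affine
#' (rotation/scale/translation of image and keypoints together), random
#' erasing (a blanked rectangle; keypoints are never relocated) and
#' simplified metal streaks, each gated by its flag in `cfg$augment`. An
#' affine draw that pushes any keypoint out of bounds is resampled up to 10
#' times, after which the affine step is skipped. All transforms are the
#' identity when their flags are off; deterministic under `seed`.
#'
#' @param image `(H, W, C)` array in `[0, 1]`.
#' @param keypoints [keypoint_set()] in the image's pixel space, or `NULL`
#'   for a background sample.
#' @param cfg a [detector_config()] (its `augment` flags are honoured).
#' @param seed optional RNG seed; `NULL` uses the current stream.
#' @return list with `image` and `keypoints`.
#' @export
augment_sample <- function(image, keypoints, cfg, seed = NULL) {
  run <- function() {
    d <- dim(image)
    H <- d[1]; W <- d[2]
    flags <- cfg$augment
    if (isTRUE(flags$flip_sagittal) && stats::runif(1) < 0.5) {
      fl <- .flip_sagittal(image, keypoints)
      image <- fl$image; keypoints <- fl$keypoints
    }
    if (isTRUE(flags$affine)) {
      for (attempt in 1:10) {
        theta <- stats::runif(1, -8, 8) * pi / 180
        scale <- stats::runif(1, 0.9, 1.1)
        tx <- stats::runif(1, -0.04, 0.04) * W
        ty <- stats::runif(1, -0.04, 0.04) * H
        kp_new <- NULL
        ok <- TRUE
        if (!is.null(keypoints)) {
          kp_new <- lapply(unclass(keypoints)[KEYPOINT_NAMES],
                           .affine_point, theta, scale, tx, ty, W, H)
          ok <- all(vapply(kp_new, function(p)
            all(p >= 0) && p[1] <= W - 1 && p[2] <= H - 1, TRUE))
        }
        if (ok) {
          image <- .warp_affine(image, theta, scale, tx, ty)
          if (!is.null(kp_new))
            keypoints <- structure(kp_new, class = "keypoint_set")
          break
        }
      }
    }
    if (isTRUE(flags$erasing) && stats::runif(1) < 0.5) {
      area <- stats::runif(1, 0.02, 0.1) * H * W
      asp <- stats::runif(1, 0.5, 2)
      eh <- min(H, max(2L, round(sqrt(area * asp))))
      ew <- min(W, max(2L, round(sqrt(area / asp))))
      y0 <- sample.int(H - eh + 1L, 1L)
      x0 <- sample.int(W - ew + 1L, 1L)
      image[y0:(y0 + eh - 1L), x0:(x0 + ew - 1L), ] <- 0
    }
    if (isTRUE(flags$metal_streaks) && stats::runif(1) < 0.3) {
      streaks <- simulate_metal_streaks(matrix(0, H, W),
                                        n_streaks = sample(1:3, 1L),
                                        amplitude = 0.25)
      for (ch in seq_len(d[3]))
        image[, , ch] <- pmin(pmax(image[, , ch] + streaks, 0), 1)
    }
    list(image = image, keypoints = keypoints)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## ---- training ----

#' Train the two-stage keypoint detector
#'
#' Minibatch Adam with the step learning-rate schedule of [lr_schedule()].
#' Per epoch the log records the mean proposal (RPN objectness + box),
#' classification, box-refinement and keypoint losses and the validation
#' mean keypoint error in mm. Deterministic under `cfg$seed` (given
#' single-threaded BLAS).
#'
#' @param train,valid [detector_dataset()]s; `valid` may be `NULL`.
#' @param cfg a [detector_config()].
#' @return an object of class `mls_detector` with elements `params`, `cfg`
#'   and `log` (data.frame `epoch, lr, loss_total, loss_proposal, loss_cls,
#'   loss_box, loss_kp, val_kp_err_mm`).
#' @export
train_detector <- function(train, valid = NULL, cfg = detector_config()) {
  stopifnot(inherits(train, "detector_dataset"), inherits(cfg, "detector_config"))
  if (!length(train$samples)) stop("empty training dataset", call. = FALSE)
  if (train$image_size != cfg$image_size)
    stop("dataset image_size (", train$image_size,
         ") does not match cfg$image_size (", cfg$image_size, ")",
         call. = FALSE)

  with_seed(cfg$seed, {
    net <- .detector_init(cfg)
    params <- net$params
    bb <- net$bb
    opt <- adam_init(params)
    n <- length(train$samples)
    log <- NULL

    for (epoch in seq_len(cfg$epochs) - 1L) {
      lr <- lr_schedule(cfg, epoch)
      ord <- sample.int(n)
      comp_sum <- c(proposal = 0, cls = 0, box = 0, kp = 0)
      total_sum <- 0
      nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        bgrads <- NULL
        for (i in idx) {
          s <- train$samples[[i]]
          if (any(unlist(cfg$augment))) {
            aug <- augment_sample(s$x, s$keypoints, cfg)
            s$x <- aug$image
            s$keypoints <- aug$keypoints
            if (!is.null(s$keypoints))
              s$bbox <- keypoints_to_bbox(s$keypoints)
          }
          sl <- .sample_loss(s, params, bb, cfg)
          if (!is.finite(sl$loss))
            stop("non-finite loss at epoch ", epoch, ", sample ", i,
                 " (scan ", s$scan_id, ", slice ", s$slice_index, ")",
                 call. = FALSE)
          comp_sum <- comp_sum + sl$components
          total_sum <- total_sum + sl$loss
          bgrads <- if (is.null(bgrads)) sl$grads
            else .tree_add(bgrads, sl$grads)
        }
        bgrads <- .tree_scale(bgrads, 1 / length(idx))
        st <- adam_step(params, bgrads, opt, lr,
                        beta1 = cfg$optimizer$beta1,
                        beta2 = cfg$optimizer$beta2)
        params <- st$params
        opt <- st$state
        nb <- nb + 1L
      }
      val_err <- if ((epoch + 1L) %% cfg$val_every == 0L ||
                     epoch == cfg$epochs - 1L)
        .validation_kp_error(valid, params, bb, cfg) else NA_real_
      log <- rbind(log, data.frame(
        epoch = epoch, lr = lr, loss_total = total_sum / n,
        loss_proposal = comp_sum[["proposal"]] / n,
        loss_cls = comp_sum[["cls"]] / n,
        loss_box = comp_sum[["box"]] / n,
        loss_kp = comp_sum[["kp"]] / n,
        val_kp_err_mm = val_err))
    }
    structure(list(params = params, cfg = cfg, log = log),
              class = "mls_detector")
  })
}

# mean keypoint localisation error (mm) over a dataset's keypoint samples,
# using the top proposal regardless of score (localisation, not detection)
.validation_kp_error <- function(ds, params, bb, cfg) {
  if (is.null(ds)) return(NA_real_)
  errs <- c()
  for (s in ds$samples) {
    if (is.null(s$keypoints)) next
    det <- .predict_sample(s$x, params, bb, cfg, score_threshold = 0)
    if (is.null(det)) next
    e <- vapply(KEYPOINT_NAMES, function(nm) {
      dp <- det$keypoints[[nm]] - s$keypoints[[nm]]
      sqrt(sum((dp * c(s$spacing[2], s$spacing[1]))^2))
    }, 0)
    errs <- c(errs, mean(e))
  }
  if (length(errs)) mean(errs) else NA_real_
}

#' @export
print.mls_detector <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<mls_detector> %s backbone, %d params, trained %d epoch(s)\n",
              x$cfg$backbone_depth, np, nrow(x$log)))
  if (!is.null(x$log) && nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final loss %.4f (kp %.4f), val keypoint error %s mm\n",
                last$loss_total, last$loss_kp,
                ifelse(is.na(last$val_kp_err_mm), "NA",
                       sprintf("%.2f", last$val_kp_err_mm))))
  }
  invisible(x)
}

## ---- prediction ----

#' Predict keypoints on preprocessed slices
#'
#' Runs detection on each model input and returns at most one instance per
#' slice (the highest-scoring proposal, refined, re-pooled). Slices scoring
#' below `score_threshold` yield `NULL`. Returned boxes and keypoints are
#' mapped back to the native pixel space of the originating volume.
#'
#' @param model an `mls_detector` or an [oracle_detector()].
#' @param inputs list of `model_input`s from [preprocess_volume()].
#' @param score_threshold detection cutoff in `[0, 1]` (a value above 1
#'   suppresses every detection).
#' @return list (one element per input) of `NULL` or
#'   `list(slice_index, box, score, keypoints)` with native-space coordinates.
#' @export
predict_keypoints <- function(model, inputs,
                              score_threshold = 0.5) {
  UseMethod("predict_keypoints")
}

#' @export
predict_keypoints.mls_detector <- function(model, inputs,
                                           score_threshold = 0.5) {
  cfg <- model$cfg
  bb <- .make_backbone(cfg)
  S <- cfg$image_size
  lapply(inputs, function(mi) {
    stopifnot(inherits(mi, "model_input"))
    in512 <- dim(mi$pixels)[1]
    x <- if (in512 == S) mi$pixels
      else EBImage::resize(mi$pixels, w = S, h = S, filter = "bilinear")
    det <- .predict_sample(x, model$params, bb, cfg, score_threshold)
    if (is.null(det)) return(NULL)
    native <- mi$native_shape
    sc <- native / S  # (rows, cols) scale cfg -> native
    kp <- lapply(unclass(det$keypoints)[KEYPOINT_NAMES],
                 function(p) c(p[1] * sc[2], p[2] * sc[1]))
    box <- list(x_min = det$box$x0 * sc[2], y_min = det$box$y0 * sc[1],
                x_max = det$box$x1 * sc[2], y_max = det$box$y1 * sc[1])
    list(slice_index = mi$center_slice_index,
         box = structure(box, class = "bounding_box"),
         score = as.numeric(det$score),
         keypoints = structure(kp, class = "keypoint_set"))
  })
}

#' @export
#' @method predict mls_detector
predict.mls_detector <- function(object, inputs,
                                 score_threshold = object$cfg$score_threshold,
                                 ...) {
  predict_keypoints(object, inputs, score_threshold)
}

## ---- oracle detector ----

#' Noise-injection oracle detector
#'
#' A test double that stands in for a trained model: it returns the
#' ground-truth keypoints perturbed by i.i.d. Gaussian pixel noise and drops
#' each annotated slice with a fixed probability, isolating downstream MLS
#' computation and evaluation from training. Deterministic under `seed`
#' (noise and dropout are drawn once, at construction).
#'
#' @param ground_truth list of `annotation_record`s (native pixel space).
#' @param sigma_px per-coordinate noise sd in pixels (`>= 0`).
#' @param dropout_rate probability of dropping an annotated slice
#'   (`0 <= rate < 1`).
#' @param seed RNG seed.
#' @return an object of class `oracle_detector` usable wherever a trained
#'   model is (e.g. [predict_keypoints()], [run_pipeline()]).
#' @export
oracle_detector <- function(ground_truth, sigma_px = 0, dropout_rate = 0,
                            seed = 1L) {
  if (sigma_px < 0) stop("sigma_px must be >= 0", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  det <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (rec in ground_truth) {
      key <- paste(rec$scan_id, rec$slice_index, sep = "\r")
      if (stats::runif(1) < dropout_rate) {
        assign(key, NULL, envir = det)
        next
      }
      kp <- lapply(unclass(rec$keypoints)[KEYPOINT_NAMES], function(p)
        pmax(p + stats::rnorm(2L, 0, sigma_px), 0))
      assign(key, structure(kp, class = "keypoint_set"), envir = det)
    }
  })
  structure(list(detections = det, sigma_px = sigma_px,
                 dropout_rate = dropout_rate, seed = seed),
            class = "oracle_detector")
}

#' @export
predict_keypoints.oracle_detector <- function(model, inputs,
                                              score_threshold = 0.5) {
  lapply(inputs, function(mi) {
    key <- paste(mi$scan_id, mi$center_slice_index, sep = "\r")
    if (!exists(key, envir = model$detections, inherits = FALSE)) return(NULL)
    kp <- get(key, envir = model$detections)
    if (is.null(kp) || score_threshold > 1) return(NULL)
    box <- tryCatch(keypoints_to_bbox(kp), error = function(e) NULL)
    list(slice_index = mi$center_slice_index, box = box, score = 1,
         keypoints = kp)
  })
}

## ---- end-to-end pipeline ----

#' Measure the midline shift of a CT volume
#'
#' The full pipeline: preprocess the volume, detect keypoints on every slice,
#' convert each detection to a per-slice MLS in mm (native spacing), and take
#' the per-scan maximum. Slices without a detection (or with a degenerate
#' falx prediction) are excluded; if nothing is detected the result has
#' `defined = FALSE` and the function returns without error.
#'
#' @param vol a [ct_volume()].
#' @param model an `mls_detector` or [oracle_detector()].
#' @param windows the three [window_spec()]s.
#' @param score_threshold detection cutoff.
#' @param mls_mode see [compute_mls_slice()].
#' @return an `mls_result` with `source = "prediction"`.
#' @export
run_pipeline <- function(vol, model, windows = default_windows(),
                         score_threshold = 0.5,
                         mls_mode = "midpoint_distance") {
  stopifnot(inherits(vol, "ct_volume"))
  inputs <- preprocess_volume(vol, windows)
  dets <- predict_keypoints(model, inputs, score_threshold)
  sp <- vol$spacing[2:3]
  rows <- list()
  for (d in dets) {
    if (is.null(d)) next
    mls <- tryCatch(compute_mls_slice(d$keypoints, sp, mode = mls_mode),
                    error = function(e) NA_real_)
    if (is.na(mls)) next
    rows[[length(rows) + 1L]] <- data.frame(slice_index = d$slice_index,
                                            mls_mm = mls)
  }
  per_slice <- if (length(rows)) do.call(rbind, rows)
    else data.frame(slice_index = integer(), mls_mm = numeric())
  aggregate_scan(per_slice, vol$scan_id, source = "prediction")
}
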