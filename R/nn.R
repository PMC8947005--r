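# Minimal neural-network layer zoo used by the keypoint detector: hand-written
# forward/backward passes over base-R matrix algebra, with the im2col/col2im
# patch extraction in C++. No general autodiff -- each composite (backbone,
# heads) wires its own backward pass, verified by finite-difference tests.

## ---- initialisation ----

.he_conv <- function(k, cin, cout)
  matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         nrow = k * k * cin, ncol = cout)

.he_fc <- function(nin, nout)
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nrow = nin, ncol = nout)

.conv_param <- function(k, cin, cout)
  list(W = .he_conv(k, cin, cout), b = numeric(cout), k = k, cin = cin)

.fc_param <- function(nin, nout)
  list(W = .he_fc(nin, nout), b = numeric(nout))

## ---- conv / relu / fc ----

# x: array (H, W, Cin); returns y (outH, outW, Cout) plus cache
conv_fwd <- function(x, p, stride = 1L, pad = 1L) {
  d <- dim(x)
  cols <- im2col_cpp(as.numeric(x), d[1], d[2], d[3], p$k, stride, pad)
  y <- cols %*% p$W
  y <- sweep(y, 2L, p$b, `+`)
  outH <- (d[1] + 2L * pad - p$k) %/% stride + 1L
  outW <- (d[2] + 2L * pad - p$k) %/% stride + 1L
  dim(y) <- c(outH, outW, ncol(p$W))
  list(y = y, cache = list(cols = cols, din = d, stride = stride, pad = pad))
}

conv_bwd <- function(dy, p, cache) {
  cout <- ncol(p$W)
  dym <- matrix(dy, ncol = cout)
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dcols <- tcrossprod(dym, p$W)
  d <- cache$din
  dx <- col2im_cpp(dcols, d[1], d[2], d[3], p$k, cache$stride, cache$pad)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(dy, y) dy * (y > 0)

fc_fwd <- function(x, p) as.numeric(crossprod(p$W, x)) + p$b

fc_bwd <- function(dy, x, p)
  list(dx = as.numeric(p$W %*% dy), dW = outer(x, dy), db = dy)

# nearest-neighbour 2x upsample of (H, W, C)
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample2_bwd <- function(dy, din) {
  d <- dim(dy)
  ih <- rep(seq_len(din[1]), each = 2L)[seq_len(d[1])]
  iw <- rep(seq_len(din[2]), each = 2L)[seq_len(d[2])]
  out <- array(0, din)
  # accumulate each 2x2 block back onto its source cell
  for (a in 1:2) for (b in 1:2) {
    sh <- seq(a, d[1], by = 2L)
    sw <- seq(b, d[2], by = 2L)
    out[ih[sh], iw[sw], ] <- out[ih[sh], iw[sw], , drop = FALSE] +
      dy[sh, sw, , drop = FALSE]
  }
  out
}

## ---- ROI bilinear crop ----

# Sampling matrix S (P*P x gh*gw) for a P x P bilinear crop of the box
# (x0, y0, x1, y1) given in continuous 0-based feature-map coordinates.
roi_sample_matrix <- function(box, gh, gw, P) {
  sx <- box$x0 + (seq_len(P) - 0.5) * (box$x1 - box$x0) / P
  sy <- box$y0 + (seq_len(P) - 0.5) * (box$y1 - box$y0) / P
  sx <- pmin(pmax(sx, 0), gw - 1)
  sy <- pmin(pmax(sy, 0), gh - 1)
  S <- matrix(0, P * P, gh * gw)
  for (j in seq_len(P)) {       # crop column (x)
    x0 <- floor(sx[j]); fx <- sx[j] - x0
    x0 <- min(x0, gw - 2); x1 <- x0 + 1
    for (i in seq_len(P)) {     # crop row (y)
      y0 <- floor(sy[i]); fy <- sy[i] - y0
      y0 <- min(y0, gh - 2); y1 <- y0 + 1
      r <- i + P * (j - 1)
      S[r, (y0 + 1) + gh * x0] <- (1 - fy) * (1 - fx)
      S[r, (y1 + 1) + gh * x0] <- fy * (1 - fx)
      S[r, (y0 + 1) + gh * x1] <- (1 - fy) * fx
      S[r, (y1 + 1) + gh * x1] <- fy * fx
    }
  }
  S
}

roi_crop_fwd <- function(feat, box, P) {
  d <- dim(feat)
  S <- roi_sample_matrix(box, d[1], d[2], P)
  crop <- S %*% matrix(feat, ncol = d[3])
  list(crop = as.numeric(crop), S = S, din = d)
}

roi_crop_bwd <- function(dcrop, cache) {
  d <- cache$din
  dfeat <- crossprod(cache$S, matrix(dcrop, ncol = d[3]))
  dim(dfeat) <- d
  dfeat
}

## ---- losses ----

# binary cross entropy on a logit; returns loss and d(loss)/d(logit)
bce_logit <- function(z, target) {
  loss <- mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
  list(loss = loss, dz = (stats::plogis(z) - target) / length(z))
}

# softmax cross entropy of one one-hot target over a logit vector
softmax_ce <- function(logits, target_idx) {
  m <- max(logits)
  p <- exp(logits - m)
  p <- p / sum(p)
  dz <- p
  dz[target_idx] <- dz[target_idx] - 1
  list(loss = -log(max(p[target_idx], 1e-12)), dz = dz, p = p)
}

# smooth L1 (Huber, delta = 1), mean over elements
smooth_l1 <- function(x, target) {
  d <- x - target
  a <- abs(d)
  loss <- mean(ifelse(a < 1, 0.5 * d^2, a - 0.5))
  list(loss = loss, dz = ifelse(a < 1, d, sign(d)) / length(d))
}

## ---- box / delta transforms ----

.box_ctr <- function(b)
  list(cx = (b$x0 + b$x1) / 2, cy = (b$y0 + b$y1) / 2,
       w = b$x1 - b$x0, h = b$y1 - b$y0)

box_to_delta <- function(box, anchor) {
  bc <- .box_ctr(box); ac <- .box_ctr(anchor)
  c((bc$cx - ac$cx) / ac$w, (bc$cy - ac$cy) / ac$h,
    log(bc$w / ac$w), log(bc$h / ac$h))
}

delta_to_box <- function(delta, anchor) {
  ac <- .box_ctr(anchor)
  # clamp log-scale deltas so an untrained head cannot explode the box
  dw <- min(max(delta[3], -2), 2)
  dh <- min(max(delta[4], -2), 2)
  cx <- ac$cx + delta[1] * ac$w
  cy <- ac$cy + delta[2] * ac$h
  w <- ac$w * exp(dw)
  h <- ac$h * exp(dh)
  list(x0 = cx - w / 2, y0 = cy - h / 2, x1 = cx + w / 2, y1 = cy + h / 2)
}

clip_box <- function(box, size, min_side = 4) {
  box$x0 <- min(max(box$x0, 0), size - 1 - min_side)
  box$y0 <- min(max(box$y0, 0), size - 1 - min_side)
  box$x1 <- min(max(box$x1, box$x0 + min_side), size - 1)
  box$y1 <- min(max(box$y1, box$y0 + min_side), size - 1)
  box
}

## ---- backbones ----
# A backbone is list(params, forward(params, x) -> list(out, cache),
#                    backward(params, cache, dout) -> grads, stride, cout).

# Plain strided CNN: the desk-scale backbone.
make_backbone_tiny <- function(channels = c(8, 16, 32)) {
  strides <- rep(2L, length(channels))
  cins <- c(3L, channels[-length(channels)])
  build <- function() {
    ps <- vector("list", length(channels) + 1L)
    for (i in seq_along(channels)) ps[[i]] <- .conv_param(3L, cins[i], channels[i])
    # stride-1 context conv on top
    ps[[length(ps)]] <- .conv_param(3L, channels[length(channels)],
                                    channels[length(channels)])
    ps
  }
  forward <- function(params, x) {
    caches <- vector("list", length(params))
    h <- x
    for (i in seq_along(params)) {
      s <- if (i <= length(channels)) 2L else 1L
      cf <- conv_fwd(h, params[[i]], stride = s, pad = 1L)
      h <- relu_fwd(cf$y)
      caches[[i]] <- list(conv = cf$cache, act = h)
    }
    list(out = h, cache = caches)
  }
  backward <- function(params, cache, dout) {
    grads <- vector("list", length(params))
    dh <- dout
    for (i in rev(seq_along(params))) {
      dh <- relu_bwd(dh, cache[[i]]$act)
      g <- conv_bwd(dh, params[[i]], cache[[i]]$conv)
      grads[[i]] <- list(W = g$dW, b = g$db)
      dh <- g$dx
    }
    grads
  }
  list(params = build(), forward = forward, backward = backward,
       stride = 8L, cout = channels[length(channels)])
}

# Bottleneck residual stages (3, 4, 6, 3) with a single-level feature-pyramid
# merge of the last two stages -- the large backbone, structured like the
# 50-layer residual FPN family but width-configurable.
make_backbone_fpn50 <- function(width = 8L, fpn_channels = 4L * width) {
  counts <- c(3L, 4L, 6L, 3L)
  mids <- width * c(1L, 2L, 4L, 8L)
  couts <- 4L * mids
  stem_c <- 2L * width

  new_block <- function(cin, cmid, cout, stride) {
    p <- list(c1 = .conv_param(1L, cin, cmid),
              c2 = .conv_param(3L, cmid, cmid),
              c3 = .conv_param(1L, cmid, cout),
              stride = stride)
    if (cin != cout || stride != 1L) p$proj <- .conv_param(1L, cin, cout)
    p
  }
  build <- function() {
    stages <- list()
    cin <- stem_c
    for (s in seq_along(counts)) {
      blocks <- list()
      for (bidx in seq_len(counts[s])) {
        stride <- if (bidx == 1L && s > 1L) 2L else 1L
        blocks[[bidx]] <- new_block(cin, mids[s], couts[s], stride)
        cin <- couts[s]
      }
      stages[[s]] <- blocks
    }
    list(stem = .conv_param(3L, 3L, stem_c),
         stages = stages,
         lat3 = .conv_param(1L, couts[3], fpn_channels),
         lat4 = .conv_param(1L, couts[4], fpn_channels),
         smooth = .conv_param(3L, fpn_channels, fpn_channels))
  }

  block_fwd <- function(x, p) {
    f1 <- conv_fwd(x, p$c1, stride = 1L, pad = 0L); a1 <- relu_fwd(f1$y)
    f2 <- conv_fwd(a1, p$c2, stride = p$stride, pad = 1L); a2 <- relu_fwd(f2$y)
    f3 <- conv_fwd(a2, p$c3, stride = 1L, pad = 0L)
    if (!is.null(p$proj)) {
      fp <- conv_fwd(x, p$proj, stride = p$stride, pad = 0L)
      skip <- fp$y; pcache <- fp$cache
    } else {
      skip <- x; pcache <- NULL
    }
    y <- relu_fwd(f3$y + skip)
    list(y = y, cache = list(f1 = f1$cache, a1 = a1, f2 = f2$cache, a2 = a2,
                             f3 = f3$cache, proj = pcache, out = y))
  }
  block_bwd <- function(dy, p, cache) {
    dsum <- relu_bwd(dy, cache$out)
    g3 <- conv_bwd(dsum, p$c3, cache$f3)
    da2 <- relu_bwd(g3$dx, cache$a2)
    g2 <- conv_bwd(da2, p$c2, cache$f2)
    da1 <- relu_bwd(g2$dx, cache$a1)
    g1 <- conv_bwd(da1, p$c1, cache$f1)
    grads <- list(c1 = list(W = g1$dW, b = g1$db),
                  c2 = list(W = g2$dW, b = g2$db),
                  c3 = list(W = g3$dW, b = g3$db))
    if (!is.null(p$proj)) {
      gp <- conv_bwd(dsum, p$proj, cache$proj)
      grads$proj <- list(W = gp$dW, b = gp$db)
      dx <- g1$dx + gp$dx
    } else {
      dx <- g1$dx + dsum
    }
    list(dx = dx, grads = grads)
  }

  forward <- function(params, x) {
    st <- conv_fwd(x, params$stem, stride = 2L, pad = 1L)
    h <- relu_fwd(st$y)
    caches <- list(stem = st$cache, stem_act = h, stages = list())
    feats <- list()
    for (s in seq_along(params$stages)) {
      scache <- list()
      for (bidx in seq_along(params$stages[[s]])) {
        bf <- block_fwd(h, params$stages[[s]][[bidx]])
        h <- bf$y
        scache[[bidx]] <- bf$cache
      }
      caches$stages[[s]] <- scache
      feats[[s]] <- h
    }
    l3 <- conv_fwd(feats[[3]], params$lat3, stride = 1L, pad = 0L)
    l4 <- conv_fwd(feats[[4]], params$lat4, stride = 1L, pad = 0L)
    up <- upsample2_fwd(l4$y)
    # crop in case of odd sizes
    d3 <- dim(l3$y)
    merged <- l3$y + up[seq_len(d3[1]), seq_len(d3[2]), , drop = FALSE]
    sm <- conv_fwd(merged, params$smooth, stride = 1L, pad = 1L)
    out <- relu_fwd(sm$y)
    caches$l3 <- l3$cache; caches$l4 <- l4$cache
    caches$sm <- sm$cache; caches$out <- out
    caches$d_up <- dim(up); caches$d_l4 <- dim(l4$y)
    list(out = out, cache = caches)
  }

  backward <- function(params, cache, dout) {
    dsm <- relu_bwd(dout, cache$out)
    gsm <- conv_bwd(dsm, params$smooth, cache$sm)
    dmerged <- gsm$dx
    g3 <- conv_bwd(dmerged, params$lat3, cache$l3)
    dup <- array(0, cache$d_up)
    d3 <- dim(dmerged)
    dup[seq_len(d3[1]), seq_len(d3[2]), ] <- dmerged
    dl4 <- upsample2_bwd(dup, cache$d_l4)
    g4 <- conv_bwd(dl4, params$lat4, cache$l4)
    grads <- list(lat3 = list(W = g3$dW, b = g3$db),
                  lat4 = list(W = g4$dW, b = g4$db),
                  smooth = list(W = gsm$dW, b = gsm$db),
                  stages = vector("list", length(params$stages)))
    dh <- g4$dx
    for (s in rev(seq_along(params$stages))) {
      if (s == 3L) dh <- dh + g3$dx   # lateral branch joins stage-3 output
      sgrads <- vector("list", length(params$stages[[s]]))
      for (bidx in rev(seq_along(params$stages[[s]]))) {
        bb <- block_bwd(dh, params$stages[[s]][[bidx]],
                        cache$stages[[s]][[bidx]])
        sgrads[[bidx]] <- bb$grads
        dh <- bb$dx
      }
      grads$stages[[s]] <- sgrads
    }
    dstem <- relu_bwd(dh, cache$stem_act)
    gst <- conv_bwd(dstem, params$stem, cache$stem)
    grads$stem <- list(W = gst$dW, b = gst$db)
    grads
  }

  list(params = build(), forward = forward, backward = backward,
       stride = 16L, cout = fpn_channels)
}

## ---- Adam over a nested parameter tree ----

# Leaves of the parameter tree are the numeric arrays named W or b; everything
# else (k, cin, stride) is static metadata. Lists may be unnamed (e.g. the
# backbone's layer list), so walk by position.
.tree_map2 <- function(f, a, b) {
  if (!is.list(a)) return(f(a, b))
  out <- a
  nms <- names(a)
  for (i in seq_along(a)) {
    bi <- if (!is.null(nms) && nzchar(nms[i])) b[[nms[i]]] else b[[i]]
    if (is.list(a[[i]])) out[[i]] <- .tree_map2(f, a[[i]], bi)
    else if (!is.null(nms) && nms[i] %in% c("W", "b"))
      out[[i]] <- f(a[[i]], bi)
  }
  out
}

adam_init <- function(params) {
  zero <- function(p, ...) p * 0
  list(m = .tree_map2(zero, params, params),
       v = .tree_map2(zero, params, params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- .tree_map2(function(m, .) m / bc1, state$m, state$m)
  vhat <- .tree_map2(function(v, .) v / bc2, state$v, state$v)
  upd <- .tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- .tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# accumulate one gradient tree into another (same shape)
.tree_add <- function(a, b) .tree_map2(`+`, a, b)
.tree_scale <- function(a, s) .tree_map2(function(x, .) x * s, a, a)
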