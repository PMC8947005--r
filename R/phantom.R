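# Synthetic axial head-CT phantoms with exact ground truth.
#
# Phantoms are deliberately schematic -- an elliptical skull ring at bone HU,
# uniform noisy parenchyma, a falx line on the midline, a septum pellucidum
# segment between two dark ventricles displaced laterally by a known,
# per-slice-profiled shift, an optional hyperdense lesion and optional metal
# streaks. They exercise the geometry, preprocessing, detection and
# evaluation machinery end to end; they make no claim of anatomical realism.

HEMORRHAGE_TYPES <- c("ICH", "IVH", "SAH", "SDH_acute", "SDH_chronic", "EDH")

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Specify one synthetic head phantom
#'
#' @param patient_id,scan_id identifiers.
#' @param image_size axial image side in px (default 512).
#' @param spacing `(slice_mm, row_mm, col_mm)` (default 5 mm slices,
#'   0.5 mm in-plane, a typical axial brain reconstruction).
#' @param n_slices number of axial slices (default 24).
#' @param skull_axes `(a, b)` outer skull semi-axes in px (x and y); default
#'   `(0.33, 0.42) * image_size`.
#' @param true_mls_mm the scan-level midline shift the phantom encodes; the
#'   per-slice shift follows a truncated raised cosine peaking at exactly
#'   this value on the central ventricle slice.
#' @param shift_direction `+1` (shift toward +x) or `-1`.
#' @param lesion `NULL` or `list(center = c(x, y) px, radius = px, hu = HU)`
#'   for a hyperdense blob.
#' @param lesion_type_label one of `"ICH"`, `"IVH"`, `"SAH"`, `"SDH_acute"`,
#'   `"SDH_chronic"`, `"EDH"` or `"none"`; stratification metadata only.
#' @param artifacts `NULL` or `list(n_streaks =, amplitude = HU)` for
#'   simplified metal-streak artifacts.
#' @param noise_sigma Gaussian HU noise sd inside the skull (default 4).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(patient_id = "p001", scan_id = "s001",
                         image_size = 512L,
                         spacing = c(5, 0.5, 0.5),
                         n_slices = 24L,
                         skull_axes = NULL,
                         true_mls_mm = 0,
                         shift_direction = 1,
                         lesion = NULL,
                         lesion_type_label = "none",
                         artifacts = NULL,
                         noise_sigma = 4,
                         seed = 1L) {
  if (is.null(skull_axes)) skull_axes <- c(0.33, 0.42) * image_size
  if (true_mls_mm < 0) stop("true_mls_mm must be >= 0", call. = FALSE)
  if (any(skull_axes <= 0)) stop("skull axes must be positive", call. = FALSE)
  if (!lesion_type_label %in% c("none", HEMORRHAGE_TYPES))
    stop("unknown lesion_type_label: ", lesion_type_label, call. = FALSE)
  structure(list(patient_id = patient_id, scan_id = scan_id,
                 image_size = as.integer(image_size),
                 spacing = as.numeric(spacing), n_slices = as.integer(n_slices),
                 skull_axes = skull_axes, true_mls_mm = true_mls_mm,
                 shift_direction = sign(shift_direction),
                 lesion = lesion, lesion_type_label = lesion_type_label,
                 artifacts = artifacts, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# HU palette: air -1000, brain 30, CSF/ventricle 5, falx/septum membrane 60/45,
# blood 70, bone 1000 -- values land in distinct regions of the three windows.
.PHANTOM_HU <- list(air = -1000, brain = 30, csf = 5, falx = 60, septum = 45,
                    blood = 70, bone = 1000)

# Per-slice geometry shared by rendering and annotation: returns NULL when the
# septum is not drawn on this slice, else keypoints (float px) and shift.
.phantom_slice_geometry <- function(spec, i) {
  S <- spec$image_size
  n <- spec$n_slices
  cx <- (S - 1) / 2
  cy <- (S - 1) / 2
  zc <- (n - 1) / 2
  # mild cranio-caudal taper of the skull
  sz <- sqrt(pmax(0.55, 1 - ((i - zc) / (0.75 * n))^2))
  ax <- spec$skull_axes[1] * sz
  ay <- spec$skull_axes[2] * sz
  thick <- 0.045 * S
  in_ax <- ax - thick
  in_ay <- ay - thick
  margin <- 2
  falx_a <- c(cx, cy - in_ay + margin)
  falx_p <- c(cx, cy + in_ay - margin)

  # ventricle-level slices: odd window centred on the middle slice
  h <- max(1L, floor(n / 5))
  peak <- floor(n / 2)
  d <- abs(i - peak)
  geom <- list(cx = cx, cy = cy, ax = ax, ay = ay, in_ax = in_ax,
               in_ay = in_ay, falx_a = falx_a, falx_p = falx_p,
               septum = NULL)
  if (d > h) return(geom)
  w <- 0.5 * (1 + cos(pi * d / (h + 1)))     # 1 at the peak slice
  shift_mm <- spec$true_mls_mm * w * spec$shift_direction
  shift_px <- shift_mm / spec$spacing[3]
  if (abs(shift_px) > 0.8 * in_ax)
    stop("true_mls_mm pushes the septum outside the skull", call. = FALSE)
  sept_len <- 25 / spec$spacing[2]           # 25 mm along y
  sx <- cx + shift_px
  geom$septum <- list(a = c(sx, cy - sept_len / 2),
                      p = c(sx, cy + sept_len / 2),
                      shift_px = shift_px, len_px = sept_len, weight = w)
  geom
}

.render_phantom_slice <- function(spec, i, geom) {
  S <- spec$image_size
  hu <- .PHANTOM_HU
  x <- matrix(rep(0:(S - 1), each = S), nrow = S)   # x[row, col] = col index
  y <- matrix(rep(0:(S - 1), times = S), nrow = S)  # y[row, col] = row index
  g <- geom
  img <- matrix(hu$air, S, S)
  r_out <- ((x - g$cx) / g$ax)^2 + ((y - g$cy) / g$ay)^2
  r_in <- ((x - g$cx) / g$in_ax)^2 + ((y - g$cy) / g$in_ay)^2
  img[r_out <= 1] <- hu$bone
  inside <- r_in <= 1
  img[inside] <- hu$brain
  if (spec$noise_sigma > 0)
    img[inside] <- img[inside] + stats::rnorm(sum(inside), 0, spec$noise_sigma)

  # falx: thin bright line on the midline extending inward from both ends
  flen <- g$falx_p[2] - g$falx_a[2]
  seg <- abs(x - g$cx) <= 1 &
    ((y >= g$falx_a[2] & y <= g$falx_a[2] + 0.2 * flen) |
       (y <= g$falx_p[2] & y >= g$falx_p[2] - 0.2 * flen)) & inside
  img[seg] <- hu$falx

  if (!is.null(g$septum)) {
    sp <- g$septum
    vw <- 0.02 * S; vh <- sp$len_px / 2; vsep <- 0.035 * S
    for (side in c(-1, 1)) {
      vc <- sp$a[1] + side * vsep
      vent <- ((x - vc) / vw)^2 + ((y - g$cy) / vh)^2 <= 1 & inside
      img[vent] <- hu$csf
    }
    smask <- abs(x - sp$a[1]) <= 1 & y >= sp$a[2] & y <= sp$p[2] & inside
    img[smask] <- hu$septum
  }

  if (!is.null(spec$lesion)) {
    le <- spec$lesion
    lm <- (x - le$center[1])^2 + (y - le$center[2])^2 <= le$radius^2 & inside
    img[lm] <- if (is.null(le$hu)) hu$blood else le$hu
  }

  if (!is.null(spec$artifacts) && isTRUE(spec$artifacts$n_streaks > 0))
    img <- simulate_metal_streaks(img, spec$artifacts$n_streaks,
                                  spec$artifacts$amplitude)
  img
}

#' Generate one synthetic head phantom with ground truth
#'
#' Renders the volume described by a [phantom_spec()] and emits ground-truth
#' keypoint annotations for every slice on which the septum is drawn.
#' Keypoints carry sub-pixel (float) coordinates, so the geometry module
#' reproduces `true_mls_mm` to machine precision at the peak slice.
#' Deterministic under the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @param render_voxels render the HU volume (`TRUE`, default). With `FALSE`
#'   only the geometry is computed (`volume = NULL`); useful for large cohort
#'   simulations that consume annotations but never read voxels.
#' @return an object of class `labeled_scan`: `volume` ([ct_volume()] or
#'   `NULL`), `annotations` (list of `annotation_record`), `true_mls_mm`,
#'   `lesion_type_label`, `spec`.
#' @export
generate_phantom <- function(spec, render_voxels = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    n <- spec$n_slices
    S <- spec$image_size
    anns <- list()
    vox <- if (render_voxels) array(NA_real_, dim = c(n, S, S)) else NULL
    for (i in seq_len(n) - 1L) {
      g <- .phantom_slice_geometry(spec, i)
      if (render_voxels) vox[i + 1L, , ] <- .render_phantom_slice(spec, i, g)
      if (!is.null(g$septum)) {
        kp <- keypoint_set(g$falx_a, g$falx_p, g$septum$a, g$septum$p)
        anns[[length(anns) + 1L]] <-
          annotation_record(spec$scan_id, i, kp, annotator = "ground_truth")
      }
    }
    vol <- if (render_voxels)
      ct_volume(vox, spec$spacing, spec$scan_id, spec$patient_id) else NULL
    structure(list(volume = vol, annotations = anns,
                   true_mls_mm = spec$true_mls_mm,
                   lesion_type_label = spec$lesion_type_label,
                   spec = spec),
              class = "labeled_scan")
  })
}

#' @export
print.labeled_scan <- function(x, ...) {
  cat(sprintf("<labeled_scan> %s (patient %s): true MLS %.2f mm, type %s, %d annotated slice(s)%s\n",
              x$spec$scan_id, x$spec$patient_id, x$true_mls_mm,
              x$lesion_type_label, length(x$annotations),
              if (is.null(x$volume)) ", voxels not rendered" else ""))
  invisible(x)
}

#' Simplified metal-streak artifacts
#'
#' Adds `n_streaks` alternating-sign linear streaks radiating through one
#' random point inside the central region of the slice -- a schematic
#' stand-in for beam-hardening streaks, not a sinogram-based simulation.
#' Zero amplitude or zero streaks is the identity. Deterministic under
#' `seed`; with `seed = NULL` the current RNG stream is used.
#'
#' @param slice_hu 2-D HU matrix.
#' @param n_streaks number of streaks.
#' @param amplitude streak amplitude in HU, `>= 0`.
#' @param seed optional RNG seed.
#' @return the slice with streaks added.
#' @export
simulate_metal_streaks <- function(slice_hu, n_streaks, amplitude, seed = NULL) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (n_streaks <= 0 || amplitude == 0) return(slice_hu)
  run <- function() {
    d <- dim(slice_hu)
    x <- matrix(rep(0:(d[2] - 1), each = d[1]), nrow = d[1])
    y <- matrix(rep(0:(d[1] - 1), times = d[2]), nrow = d[1])
    px <- stats::runif(1, 0.35, 0.65) * d[2]
    py <- stats::runif(1, 0.35, 0.65) * d[1]
    out <- slice_hu
    theta <- stats::runif(n_streaks, 0, pi)
    for (s in seq_len(n_streaks)) {
      # distance from the line through (px, py) at angle theta
      dist <- abs(-sin(theta[s]) * (x - px) + cos(theta[s]) * (y - py))
      out[dist <= 0.75] <- out[dist <= 0.75] +
        (if (s %% 2 == 0) -1 else 1) * amplitude
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## ---- dataset assembly -----------------------------------------------------

.parse_mls_dist <- function(spec) {
  if (is.function(spec)) return(spec)
  parts <- strsplit(spec, "[:,]")[[1]]
  kind <- parts[1]
  args <- as.numeric(parts[-1])
  switch(kind,
         uniform = function(n) stats::runif(n, args[1], args[2]),
         constant = function(n) rep(args[1], n),
         normal = function(n) pmax(0, stats::rnorm(n, args[1], args[2])),
         stop("unknown MLS distribution: ", spec, call. = FALSE))
}

# largest-remainder apportionment of n into ratio (8, 1, 1)
.split_counts <- function(n, ratio = c(8, 1, 1)) {
  q <- n * ratio / sum(ratio)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)  # ties: train > valid > test
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  stats::setNames(as.integer(base), c("train", "valid", "test"))
}

#' Build a stratified, patient-disjoint phantom dataset
#'
#' Generates a cohort of phantom scans and splits it 8:1:1 into
#' train/valid/test. The split is by patient, never by scan (all scans of a
#' patient land in one partition), and is stratified: within each lesion type
#' the patient counts follow largest-remainder 8:1:1 apportionment. A lesion
#' type with fewer than 3 patients is assigned entirely to train, with a
#' warning. Deterministic under `seed`.
#'
#' @param n_patients number of patients (`>= 10`).
#' @param mls_distribution distribution of per-scan true MLS in mm:
#'   `"uniform:a,b"` (default `"uniform:0,15"`), `"constant:v"`,
#'   `"normal:mu,sd"` (truncated at 0), or a function `n -> n draws`.
#' @param type_mix named probabilities over the six hemorrhage classes
#'   (default equal).
#' @param seed RNG seed.
#' @param multi_scan_prob probability a patient has a second scan (default 0.1).
#' @param render_voxels render HU volumes (see [generate_phantom()]).
#' @param image_size,n_slices,spacing,noise_sigma passed to [phantom_spec()].
#' @param lesion_prob probability a scan carries a hyperdense lesion blob.
#' @param artifact_prob probability a scan carries metal streaks.
#' @return list with elements `train`, `valid`, `test` (lists of
#'   `labeled_scan`) and `manifest` (data.frame `patient_id, scan_id, split,
#'   lesion_type, true_mls_mm`).
#' @export
build_dataset <- function(n_patients,
                          mls_distribution = "uniform:0,15",
                          type_mix = NULL,
                          seed = 1L,
                          multi_scan_prob = 0.1,
                          render_voxels = TRUE,
                          image_size = 512L,
                          n_slices = 24L,
                          spacing = c(5, 0.5, 0.5),
                          noise_sigma = 4,
                          lesion_prob = 0.7,
                          artifact_prob = 0.15) {
  if (n_patients < 10) stop("n_patients must be >= 10", call. = FALSE)
  if (is.null(type_mix)) {
    type_mix <- rep(1 / length(HEMORRHAGE_TYPES), length(HEMORRHAGE_TYPES))
    names(type_mix) <- HEMORRHAGE_TYPES
  }
  type_mix <- type_mix / sum(type_mix)
  draw_mls <- .parse_mls_dist(mls_distribution)

  with_seed(seed, {
    patients <- sprintf("P%04d", seq_len(n_patients))
    types <- sample(names(type_mix), n_patients, replace = TRUE,
                    prob = type_mix)

    # patient-level stratified split
    split_of <- stats::setNames(character(n_patients), patients)
    for (ty in unique(types)) {
      ps <- patients[types == ty]
      if (length(ps) < 3) {
        warning("lesion type ", ty, " has fewer than 3 patients; ",
                "all assigned to train", call. = FALSE)
        split_of[ps] <- "train"
        next
      }
      cnt <- .split_counts(length(ps))
      ps <- sample(ps)
      split_of[ps] <- rep(c("train", "valid", "test"), times = cnt)
    }

    out <- list(train = list(), valid = list(), test = list())
    manifest <- NULL
    scan_no <- 0L
    for (j in seq_len(n_patients)) {
      n_scans <- 1L + stats::rbinom(1, 1, multi_scan_prob)
      for (s in seq_len(n_scans)) {
        scan_no <- scan_no + 1L
        mls <- draw_mls(1)
        lesion <- if (stats::runif(1) < lesion_prob) {
          ctr <- c(image_size / 2 + sample(c(-1, 1), 1) * stats::runif(1, 0.12, 0.2) * image_size,
                   image_size / 2 + stats::runif(1, -0.1, 0.1) * image_size)
          list(center = ctr, radius = stats::runif(1, 0.03, 0.08) * image_size,
               hu = 70)
        } else NULL
        artifacts <- if (stats::runif(1) < artifact_prob)
          list(n_streaks = sample(2:5, 1), amplitude = stats::runif(1, 100, 400))
        else NULL
        sp <- phantom_spec(
          patient_id = patients[j],
          scan_id = sprintf("S%04d", scan_no),
          image_size = image_size, spacing = spacing, n_slices = n_slices,
          true_mls_mm = mls,
          shift_direction = sample(c(-1, 1), 1),
          lesion = lesion, lesion_type_label = types[j],
          artifacts = artifacts, noise_sigma = noise_sigma,
          seed = sample.int(.Machine$integer.max, 1))
        scan <- generate_phantom(sp, render_voxels = render_voxels)
        part <- split_of[patients[j]]
        out[[part]][[length(out[[part]]) + 1L]] <- scan
        manifest <- rbind(manifest, data.frame(
          patient_id = patients[j], scan_id = sp$scan_id, split = part,
          lesion_type = types[j], true_mls_mm = mls,
          stringsAsFactors = FALSE))
      }
    }
    out$manifest <- manifest
    out
  })
}
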