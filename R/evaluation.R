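# Cohort evaluation: MAE, ICC(2,1) agreement, threshold sensitivity and
# specificity at 2/5/10 mm, Pearson correlation with an optional covariate.

#' Mean and maximum absolute error between paired MLS measurements
#'
#' @param gt,pred numeric vectors of MLS in mm, paired by position (same
#'   scan order), equal length `>= 1`.
#' @return list with `mean_ae` and `max_ae` in mm.
#' @export
mae <- function(gt, pred) {
  if (length(gt) != length(pred))
    stop("gt and pred must have equal length (", length(gt), " vs ",
         length(pred), ")", call. = FALSE)
  if (length(gt) < 1) stop("need at least one pair", call. = FALSE)
  ae <- abs(gt - pred)
  list(mean_ae = mean(ae), max_ae = max(ae))
}

#' Classify MLS values against a threshold
#'
#' Positive iff `mls > threshold_mm` -- strictly greater, so a value exactly
#' at the threshold is negative ("MLS greater than 2 mm").
#'
#' @param mls numeric vector of MLS in mm (`>= 0`).
#' @param threshold_mm threshold in mm.
#' @return integer vector of labels (1 = positive, 0 = negative).
#' @export
threshold_classify <- function(mls, threshold_mm) {
  if (any(mls < 0)) stop("MLS values must be >= 0", call. = FALSE)
  as.integer(mls > threshold_mm)
}

#' Sensitivity and specificity of binary labels
#'
#' Rates that are undefined because the ground truth has no positives (or no
#' negatives) are reported as `NA`, not 0.
#'
#' @param gt_labels,pred_labels binary vectors (1 = positive), equal length.
#' @return list with `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`.
#' @export
sens_spec <- function(gt_labels, pred_labels) {
  if (!length(gt_labels)) stop("empty input", call. = FALSE)
  if (length(gt_labels) != length(pred_labels))
    stop("label vectors must have equal length", call. = FALSE)
  gt <- as.integer(gt_labels)
  pr <- as.integer(pred_labels)
  tp <- sum(gt == 1 & pr == 1)
  fp <- sum(gt == 0 & pr == 1)
  tn <- sum(gt == 0 & pr == 0)
  fn <- sum(gt == 1 & pr == 0)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC from the
#' two-way ANOVA mean squares, with the F statistic (MSR/MSE) and the 95%
#' confidence interval of McGraw & Wong. Absolute agreement penalizes a
#' systematic between-rater bias, unlike the consistency form.
#'
#' @param ratings numeric matrix, `n_subjects x k_raters`, no missing cells,
#'   `n >= 3`, `k >= 2`.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `estimate`, `F`, `ci_low`, `ci_high`, `df1`, `df2`.
#' @export
icc_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 3 || k < 2)
    stop("need at least 3 subjects and 2 raters", call. = FALSE)
  if (any(!is.finite(ratings)))
    stop("missing or non-finite cells in ratings (no imputation is done)",
         call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)          # subjects
  ssc <- n * sum((col_m - grand)^2)          # raters
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  est <- if (denom <= 0) NA_real_ else (msr - mse) / denom
  fstat <- if (mse > 0) msr / mse else Inf

  alpha <- 1 - conf_level
  if (!is.na(est) && mse > 0 && est < 1) {
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  } else {
    lo <- hi <- est
  }
  list(estimate = est, F = fstat, ci_low = lo, ci_high = hi,
       df1 = n - 1, df2 = (n - 1) * (k - 1))
}

#' Evaluate a cohort of predicted against ground-truth MLS results
#'
#' Pairs results by `scan_id`, computes MAE, ICC(2,1) agreement between the
#' two measurement series, sensitivity/specificity at each threshold, and
#' (when a covariate is supplied) the Pearson correlation of predicted scan
#' MLS with it. Undefined predictions (no slice detected) are scored as 0 mm
#' and counted, so a missed detection cannot silently drop a scan.
#'
#' @param gt,pred lists of `mls_result`s covering the same set of `scan_id`s.
#' @param thresholds MLS thresholds in mm (default `c(2, 5, 10)`).
#' @param covariate optional named numeric vector (names = scan_ids) of a
#'   per-scan clinical covariate.
#' @return an object of class `mls_eval_report`: `n_scans`, `mae_mm`,
#'   `max_ae_mm`, `n_undefined_pred`, `icc` (list), `per_threshold`
#'   (data.frame), `pearson` (list or `NULL`), `paired` (data.frame
#'   `scan_id, gt_mm, pred_mm, abs_err_mm`).
#' @export
evaluate_cohort <- function(gt, pred, thresholds = c(2, 5, 10),
                            covariate = NULL) {
  gid <- vapply(gt, function(r) as.character(r$scan_id), "")
  pid <- vapply(pred, function(r) as.character(r$scan_id), "")
  miss <- c(setdiff(gid, pid), setdiff(pid, gid))
  if (length(miss))
    stop("unmatched scan_ids between gt and pred: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  pred <- pred[match(gid, pid)]

  val <- function(r) if (r$defined) r$scan_mls_mm else 0  # missed detection -> 0 mm
  g <- vapply(gt, val, 0)
  p <- vapply(pred, val, 0)
  n <- length(g)
  err <- mae(g, p)

  per_thr <- do.call(rbind, lapply(thresholds, function(t) {
    ss <- sens_spec(threshold_classify(g, t), threshold_classify(p, t))
    data.frame(threshold_mm = t, sensitivity = ss$sensitivity,
               specificity = ss$specificity, tp = ss$tp, fp = ss$fp,
               tn = ss$tn, fn = ss$fn)
  }))

  icc <- if (n >= 3) icc_agreement(cbind(gt = g, pred = p)) else NULL

  pearson <- NULL
  if (!is.null(covariate)) {
    cv <- covariate[gid]
    if (any(is.na(cv)))
      stop("covariate missing for scan(s): ",
           paste(gid[is.na(cv)], collapse = ", "), call. = FALSE)
    ct <- stats::cor.test(p, cv, method = "pearson")
    pearson <- list(r = unname(ct$estimate), p_value = ct$p.value)
  }

  structure(list(
    n_scans = n,
    mae_mm = err$mean_ae,
    max_ae_mm = err$max_ae,
    n_undefined_pred = sum(!vapply(pred, function(r) r$defined, TRUE)),
    icc = icc,
    per_threshold = per_thr,
    pearson = pearson,
    paired = data.frame(scan_id = gid, gt_mm = g, pred_mm = p,
                        abs_err_mm = abs(g - p), stringsAsFactors = FALSE)),
    class = "mls_eval_report")
}

#' @export
print.mls_eval_report <- function(x, ...) {
  cat("<mls_eval_report>", x$n_scans, "scans\n")
  cat(sprintf("  MAE %.3f mm (max %.3f mm), %d undefined prediction(s)\n",
              x$mae_mm, x$max_ae_mm, x$n_undefined_pred))
  if (!is.null(x$icc))
    cat(sprintf("  ICC(2,1) %.4f (F = %.3f, 95%% CI %.4f-%.4f)\n",
                x$icc$estimate, x$icc$F, x$icc$ci_low, x$icc$ci_high))
  for (i in seq_len(nrow(x$per_threshold))) {
    r <- x$per_threshold[i, ]
    cat(sprintf("  > %g mm: sensitivity %s, specificity %s (tp %d fp %d tn %d fn %d)\n",
                r$threshold_mm,
                ifelse(is.na(r$sensitivity), "NA", sprintf("%.3f", r$sensitivity)),
                ifelse(is.na(r$specificity), "NA", sprintf("%.3f", r$specificity)),
                r$tp, r$fp, r$tn, r$fn))
  }
  if (!is.null(x$pearson))
    cat(sprintf("  Pearson r = %.3f (p = %.3g)\n",
                x$pearson$r, x$pearson$p_value))
  invisible(x)
}

#' Write an evaluation report to JSON (plus the paired per-scan CSV)
#'
#' @param report an `mls_eval_report`.
#' @param path output JSON path; the paired per-scan table is written next to
#'   it as `<path minus .json>_paired.csv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  obj <- unclass(report)
  obj$paired <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  csv <- sub("\\.json$", "", path)
  utils::write.csv(report$paired, paste0(csv, "_paired.csv"),
                   row.names = FALSE)
  invisible(path)
}
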