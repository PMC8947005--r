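test_that("MAE matches hand arithmetic and a brute-force oracle", {
  e <- mae(c(2, 4), c(3, 2))
  expect_equal(e$mean_ae, 1.5)
  expect_equal(e$max_ae, 2.0)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), list(mean_ae = 0, max_ae = 0))
  expect_error(mae(1:3, 1:2), "equal length")

  set.seed(51)
  gt <- runif(1000, 0, 20); pr <- runif(1000, 0, 20)
  acc <- 0; mx <- 0
  for (i in seq_along(gt)) {           # independent sum-loop oracle
    d <- abs(gt[i] - pr[i])
    acc <- acc + d
    if (d > mx) mx <- d
  }
  e <- mae(gt, pr)
  expect_equal(e$mean_ae, acc / 1000, tolerance = 1e-12)
  expect_equal(e$max_ae, mx, tolerance = 1e-12)

  # permutation invariance and absolute homogeneity
  p <- sample(1000)
  expect_equal(mae(gt[p], pr[p]), e)
  expect_equal(mae(3 * gt, 3 * pr)$mean_ae, 3 * e$mean_ae, tolerance = 1e-12)
})

test_that("threshold classification is strictly greater-than", {
  expect_equal(threshold_classify(c(1.9, 2.0, 2.1), 2), c(0L, 0L, 1L))
  expect_equal(threshold_classify(c(0.1, 5), 0), c(1L, 1L))
  set.seed(52)
  x <- runif(200, 0, 15)
  pos5 <- which(threshold_classify(x, 5) == 1)
  pos10 <- which(threshold_classify(x, 10) == 1)
  expect_true(all(pos10 %in% pos5))    # threshold nesting
  expect_error(threshold_classify(c(-1, 2), 2), ">= 0")
})

test_that("sensitivity/specificity match the 2x2 table", {
  s <- sens_spec(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(s$sensitivity, 0.5)
  expect_equal(s$specificity, 1.0)
  expect_equal(c(s$tp, s$fp, s$tn, s$fn), c(1, 0, 2, 1))

  g <- c(1, 0, 1, 0); expect_equal(sens_spec(g, g)[1:2],
                                   list(sensitivity = 1, specificity = 1))

  set.seed(53)
  gt <- rbinom(500, 1, 0.4); pr <- rbinom(500, 1, 0.5)
  tp <- fp <- tn <- fn <- 0
  for (i in 1:500) {                   # brute-force confusion matrix
    if (gt[i] == 1 && pr[i] == 1) tp <- tp + 1
    if (gt[i] == 0 && pr[i] == 1) fp <- fp + 1
    if (gt[i] == 0 && pr[i] == 0) tn <- tn + 1
    if (gt[i] == 1 && pr[i] == 0) fn <- fn + 1
  }
  s <- sens_spec(gt, pr)
  expect_equal(c(s$tp, s$fp, s$tn, s$fn), c(tp, fp, tn, fn))
  expect_equal(s$sensitivity, tp / (tp + fn))
  expect_equal(s$specificity, tn / (tn + fp))

  # undefined rates are NA, not 0
  expect_true(is.na(sens_spec(c(0, 0), c(0, 1))$sensitivity))
  expect_true(is.na(sens_spec(c(1, 1), c(0, 1))$specificity))
  expect_error(sens_spec(integer(), integer()), "empty")
})

test_that("ICC(2,1) is 1 under perfect agreement and penalizes bias", {
  subj <- c(0.3, 0.9, 1.6, 0.1, 2.0, 1.2, 0.6, 1.9)
  perfect <- cbind(subj, subj, subj)
  r <- icc_agreement(perfect)
  expect_equal(r$estimate, 1.0)

  biased <- cbind(subj, subj + 5)      # constant 5 mm rater bias
  rb <- icc_agreement(biased)
  expect_lt(rb$estimate, 1)

  # consistency-style agreement would be perfect here; absolute is not
  expect_lt(rb$estimate, 0.2)
})

test_that("ICC(2,1) matches the reference implementation on a fixture", {
  # expected values computed with an independent ICC(A,1) implementation
  # (two-way random effects, absolute agreement, single rater)
  set.seed(7)
  subj <- rnorm(12, 8, 5)
  m <- outer(subj, rep(1, 3)) + matrix(rnorm(36, 0, 1), 12, 3) +
    matrix(rep(c(0, 1, -0.5), each = 12), 12, 3)
  r <- icc_agreement(m)
  expect_equal(r$estimate, 0.975782900902, tolerance = 1e-9)
  expect_equal(r$F, 221.91810858, tolerance = 1e-7)
  expect_equal(r$ci_low, 0.898313351755, tolerance = 1e-6)
  expect_equal(r$ci_high, 0.993386190544, tolerance = 1e-6)
  expect_equal(c(r$df1, r$df2), c(11, 22))
})

test_that("ICC estimate stays in (-1, 1] and input is validated", {
  set.seed(54)
  for (i in 1:20) {
    m <- matrix(rnorm(30), 10, 3)
    r <- icc_agreement(m)
    expect_gt(r$estimate, -1)
    expect_lte(r$estimate, 1)
  }
  expect_error(icc_agreement(matrix(1:4, 2, 2)), "at least 3 subjects")
  m <- matrix(rnorm(30), 10, 3); m[2, 2] <- NA
  expect_error(icc_agreement(m), "missing")
})

test_that("simulated two-way data reproduce the closed-form ICC", {
  # subjects sd 5, rater noise sd 0.5 -> ICC = 25 / 25.25
  closed <- 25 / (25 + 0.25)
  set.seed(55)
  est <- replicate(20, {
    subj <- rnorm(100, 5, 5)
    m <- outer(subj, rep(1, 3)) + matrix(rnorm(300, 0, 0.5), 100, 3)
    icc_agreement(m)$estimate
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - closed), 3 * se)
})

test_that("cohort evaluation assembles a consistent report", {
  mk <- function(id, mls, src = "prediction") {
    if (is.na(mls))
      aggregate_scan(data.frame(slice_index = integer(), mls_mm = numeric()),
                     id, src)
    else aggregate_scan(data.frame(slice_index = 0L, mls_mm = mls), id, src)
  }
  set.seed(56)
  vals <- runif(30, 0, 15)
  gt <- mapply(mk, sprintf("s%02d", 1:30), vals, "annotation",
               SIMPLIFY = FALSE)
  same <- mapply(mk, sprintf("s%02d", 1:30), vals, SIMPLIFY = FALSE)
  rep0 <- evaluate_cohort(gt, same)
  expect_equal(rep0$mae_mm, 0)
  expect_equal(rep0$icc$estimate, 1)
  expect_true(all(rep0$per_threshold$sensitivity == 1))
  expect_true(all(rep0$per_threshold$specificity == 1))

  # a missed detection is scored as 0 mm, not dropped
  pred <- same
  pred[[3]] <- mk("s03", NA)
  rep1 <- evaluate_cohort(gt, pred)
  expect_equal(rep1$n_scans, 30)
  expect_equal(rep1$n_undefined_pred, 1)
  expect_equal(rep1$max_ae_mm, vals[3])
  for (i in seq_len(nrow(rep1$per_threshold))) {
    row <- rep1$per_threshold[i, ]
    expect_equal(row$tp + row$fn, sum(vals > row$threshold_mm))
    expect_equal(row$tn + row$fp, sum(vals <= row$threshold_mm))
  }

  expect_error(evaluate_cohort(gt[1:3], same[2:4]), "unmatched")

  cov <- stats::setNames(vals * 2 + rnorm(30, 0, 0.1), sprintf("s%02d", 1:30))
  rep2 <- evaluate_cohort(gt, same, covariate = cov)
  expect_gt(rep2$pearson$r, 0.99)
  expect_lt(rep2$pearson$p_value, 1e-6)
})

test_that("evaluation reports serialize to JSON plus a paired CSV", {
  mk <- function(id, mls) aggregate_scan(
    data.frame(slice_index = 0L, mls_mm = mls), id, "prediction")
  gt <- list(mk("a", 1), mk("b", 6), mk("c", 11))
  pr <- list(mk("a", 2), mk("b", 5), mk("c", 12))
  rep <- evaluate_cohort(gt, pr)
  f <- tempfile(fileext = ".json")
  write_eval_report(rep, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$mae_mm, 1)
  paired <- utils::read.csv(sub("\\.json$", "_paired.csv", f))
  expect_equal(nrow(paired), 3)
  expect_equal(paired$abs_err_mm, c(1, 1, 1))
})
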