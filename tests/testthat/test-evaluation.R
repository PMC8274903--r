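test_that("confusion counts match a brute-force pixel loop", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(confusion_counts(pred, pred)$fp, 0)
  expect_equal(confusion_counts(pred, pred)$fn, 0)
  all1 <- matrix(1, 10, 10); all0 <- matrix(0, 10, 10)
  cc <- confusion_counts(all1, all0)
  expect_equal(cc$fp, 100)
  expect_equal(cc$tp + cc$tn + cc$fn, 0)
  # randomized oracle with a FOV restriction
  set.seed(10)
  for (q in 1:5) {
    pred <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
    truth <- matrix(rbinom(32 * 32, 1, 0.2), 32, 32)
    fov <- matrix(rbinom(32 * 32, 1, 0.8), 32, 32)
    cc <- confusion_counts(pred, truth, fov)
    tp <- fp <- tn <- fn <- 0
    for (i in 1:32) for (j in 1:32) {
      if (fov[i, j] == 0) next
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
      if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1
      if (pred[i, j] == 0 && truth[i, j] == 0) tn <- tn + 1
      if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1
    }
    expect_equal(unclass(cc), list(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, sum(fov))
  }
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("the six scores follow their defining ratios", {
  mk <- function(tp, fp, tn, fn)
    structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
              class = "confusion_counts")
  m <- segmentation_metrics(mk(1, 0, 1, 0))
  expect_equal(unlist(m[c("sensitivity", "specificity", "accuracy",
                          "precision", "recall", "f1")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1,
                 precision = 1, recall = 1, f1 = 1))
  expect_equal(segmentation_metrics(mk(50, 5, 40, 10))$sensitivity, 50 / 60)
  # harmonic-mean oracle: precision 0.8, recall 0.6
  m <- segmentation_metrics(mk(24, 6, 10, 16))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.8 * 0.6 / (0.8 + 0.6))
  # degenerate 0/0 is flagged, not thrown
  m0 <- segmentation_metrics(mk(0, 0, 10, 0))
  expect_true(is.na(m0$sensitivity))
  expect_true("sensitivity" %in% m0$undefined)
  # accuracy always lies between sensitivity and specificity
  set.seed(3)
  for (q in 1:20) {
    cc <- mk(sample(1:50, 1), sample(1:50, 1), sample(1:50, 1), sample(1:50, 1))
    m <- segmentation_metrics(cc)
    expect_gte(m$accuracy, min(m$sensitivity, m$specificity) - 1e-12)
    expect_lte(m$accuracy, max(m$sensitivity, m$specificity) + 1e-12)
  }
})

test_that("AUROC equals the tie-corrected Mann-Whitney statistic", {
  # perfect separation
  truth <- matrix(rep(c(0, 1), each = 50), 10, 10)
  r <- roc_pr_curves(truth, truth)
  expect_equal(r$auroc, 1)
  expect_equal(r$aupr, 1)
  # rank-statistic oracle on instances with heavy ties
  set.seed(21)
  for (q in 1:5) {
    truth <- matrix(rbinom(200, 1, 0.3), 10, 20)
    prob <- matrix(round(runif(200), 1), 10, 20)
    r <- roc_pr_curves(prob, truth)
    s <- as.vector(prob); y <- as.vector(truth)
    rk <- rank(s)  # midranks handle ties
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    mw <- (sum(rk[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    expect_equal(r$auroc, mw, tolerance = 1e-12)
  }
  # labels independent of scores: area near 1/2
  set.seed(2)
  truth <- matrix(rbinom(5000, 1, 0.5), 50, 100)
  prob <- matrix(runif(5000), 50, 100)
  expect_lt(abs(roc_pr_curves(prob, truth)$auroc - 0.5), 0.05)
  # single-class truth is flagged degenerate
  r0 <- roc_pr_curves(matrix(runif(25), 5, 5), matrix(0, 5, 5))
  expect_true(r0$degenerate)
  expect_true(is.na(r0$auroc))
})

test_that("per-image F1 composes prediction, confusion and metrics", {
  model <- build_mfinet(unet_config(base_width = 4L), seed = 3)
  sm <- generate_sample(synth_config(image_size = c(64L, 64L), seed = 321))
  cfg <- train_config(stride = 16L)
  f1 <- per_image_f1(model, list(sm, sm), cfg)
  expect_length(f1, 2L)
  expect_identical(f1[1], f1[2])  # duplicate image, equal entries
  pr <- predict_sample(model, sm, cfg)
  met <- segmentation_metrics(confusion_counts(pr$pred, sm$vessel, sm$fov))
  expect_equal(f1[1], met$f1)
})

test_that("paired one-sided tests behave on degenerate and shifted data", {
  a <- c(0.8, 0.82, 0.79, 0.85)
  expect_equal(paired_f1_pvalue(a, a), 0.5)
  # constant positive shift, zero variance: exact sign-flip tail
  b <- rep(0.7, 10)
  expect_equal(paired_f1_pvalue(b + 0.1, b), 2^-10)
  expect_lt(paired_f1_pvalue(b + 0.1, b), 1e-3)
  # t-test and its complement are symmetric
  set.seed(8)
  x <- runif(12, 0.7, 0.9); y <- x + rnorm(12, 0.02, 0.01)
  expect_equal(paired_f1_pvalue(x, y) + paired_f1_pvalue(y, x), 1,
               tolerance = 1e-9)
  # exact permutation enumeration agrees with the closed form for a
  # constant shift: only the all-positive assignment reaches the observed mean
  expect_equal(paired_f1_pvalue(b[1:8] + 0.1, b[1:8], method = "permutation"),
               2^-8)
  expect_error(paired_f1_pvalue(1:3 / 10, 1:4 / 10), "length")
})
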