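#' Confusion counts inside the field of view
#'
#' Pixel-level TP/FP/TN/FN with vessel as the positive class, restricted to
#' FOV pixels.
#'
#' @param pred,truth binary matrices (0/1).
#' @param fov binary FOV matrix (`NULL` = evaluate every pixel).
#' @return a `confusion_counts` list `(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(pred, truth, fov = NULL) {
  chk <- function(x, nm) {
    if (!all(x %in% c(0, 1))) stop("confusion_counts: ", nm, " is not binary")
  }
  chk(pred, "pred"); chk(truth, "truth")
  if (!is.null(fov)) {
    chk(fov, "fov")
    keep <- fov == 1
    pred <- pred[keep]; truth <- truth[keep]
  }
  structure(list(tp = sum(pred == 1 & truth == 1),
                 fp = sum(pred == 1 & truth == 0),
                 tn = sum(pred == 0 & truth == 0),
                 fn = sum(pred == 0 & truth == 1)),
            class = "confusion_counts")
}

#' Segmentation scores from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(FP+TN), accuracy
#' (TP+TN)/total, precision TP/(TP+FP), recall TP/(TP+FN), and F1 the
#' harmonic mean of precision and recall. Degenerate 0/0 ratios are
#' returned as `NA` (flagged in `$undefined`), never as an error.
#'
#' @param counts a [confusion_counts()] result.
#' @return a `segmentation_metrics` list of the six scores plus the names
#'   of any undefined ones.
#' @export
segmentation_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fp + tn + fn == 0) stop("segmentation_metrics: no evaluated pixels")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rat(tp, tp + fn)
  spec <- rat(tn, fp + tn)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  prec <- rat(tp, tp + fp)
  rec <- sens
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
    if (identical(tp + fp + fn, 0)) NA_real_ else if (tp == 0) 0 else NA_real_
  } else {
    2 * prec * rec / (prec + rec)
  }
  out <- list(sensitivity = sens, specificity = spec, accuracy = acc,
              precision = prec, recall = rec, f1 = f1)
  out$undefined <- names(out)[vapply(out, function(v) length(v) == 1 && is.na(v), NA)]
  class(out) <- "segmentation_metrics"
  out
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  v <- unlist(x[c("sensitivity", "specificity", "accuracy",
                  "precision", "recall", "f1")])
  print(round(v, 4))
  if (length(x$undefined)) cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC and precision-recall curves with areas
#'
#' Sweeps every distinct score as a threshold (in-FOV pixels only),
#' integrating ROC by trapezoids (equal to the tie-corrected Mann-Whitney
#' statistic) and PR by rectangular steps in recall.
#'
#' @param prob probability map in `[0,1]`.
#' @param truth binary vessel truth.
#' @param fov binary FOV (`NULL` = all pixels).
#' @return list with `roc` and `pr` data frames, `auroc`, `aupr`, and a
#'   `degenerate` flag (single-class truth yields `NA` areas).
#' @export
roc_pr_curves <- function(prob, truth, fov = NULL) {
  if (min(prob) < -1e-12 || max(prob) > 1 + 1e-12)
    stop("roc_pr_curves: probabilities must lie in [0, 1]")
  if (!is.null(fov)) {
    keep <- fov == 1
    prob <- prob[keep]; truth <- truth[keep]
  }
  s <- as.vector(prob); y <- as.vector(truth)
  P <- sum(y == 1); Nn <- sum(y == 0)
  if (P == 0 || Nn == 0) {
    return(list(roc = NULL, pr = NULL, auroc = NA_real_, aupr = NA_real_,
                degenerate = TRUE))
  }
  o <- order(s, decreasing = TRUE)
  sy <- y[o]; ss <- s[o]
  ctp <- cumsum(sy == 1)
  cfp <- cumsum(sy == 0)
  last <- which(c(diff(ss) != 0, TRUE))  # end of each tie block
  tpr <- c(0, ctp[last] / P)
  fpr <- c(0, cfp[last] / Nn)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  rec <- ctp[last] / P
  prec <- ctp[last] / (ctp[last] + cfp[last])
  aupr <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(threshold = c(Inf, ss[last]), fpr = fpr, tpr = tpr),
       pr = data.frame(recall = rec, precision = prec),
       auroc = auroc, aupr = aupr, degenerate = FALSE)
}

#' Per-image F1 over a dataset
#'
#' Segments each sample with [predict_sample()] and returns the in-FOV F1
#' per full reconstructed image, in dataset order.
#'
#' @param model trained model.
#' @param samples list of `fundus_sample` objects.
#' @inheritParams predict_sample
#' @return numeric vector of F1 scores.
#' @export
per_image_f1 <- function(model, samples, config = train_config(),
                         pre_config = preprocess_config()) {
  if (!length(samples)) stop("per_image_f1: need at least one sample")
  vapply(samples, function(sm) {
    pr <- predict_sample(model, sm, config, pre_config)
    segmentation_metrics(confusion_counts(pr$pred, sm$vessel, sm$fov))$f1
  }, 0)
}

#' Paired one-sided test on per-image F1
#'
#' Tests whether method A has a larger mean F1 than method B on the same
#' images: one-sided paired t-test by default, or an exact sign-flip
#' permutation test (all `2^n` sign assignments for n <= 20, otherwise
#' Monte Carlo).
#'
#' @param f1_a,f1_b equal-length paired score vectors.
#' @param method `"ttest"` or `"permutation"`.
#' @param n_mc Monte Carlo draws when exact enumeration is too large.
#' @return p-value in (0, 1]; identical inputs give 0.5 (degenerate).
#' @export
paired_f1_pvalue <- function(f1_a, f1_b, method = c("ttest", "permutation"),
                             n_mc = 20000L) {
  method <- match.arg(method)
  if (length(f1_a) != length(f1_b))
    stop("paired_f1_pvalue: unpaired input (length mismatch)")
  if (length(f1_a) < 2L) stop("paired_f1_pvalue: need at least 2 pairs")
  d <- f1_a - f1_b
  if (all(d == 0)) return(0.5)
  if (method == "ttest") {
    if (stats::sd(d) == 0) {
      # zero-variance differences: t is infinite; report the exact
      # sign-flip tail instead of failing
      n <- length(d)
      return(if (mean(d) > 0) 2^-n else 1 - 2^-n)
    }
    return(unname(stats::t.test(f1_a, f1_b, paired = TRUE,
                                alternative = "greater")$p.value))
  }
  n <- length(d)
  obs <- mean(d)
  if (n <= 20L) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- as.vector(signs %*% d) / n
    mean(stat >= obs - 1e-15)
  } else {
    stat <- replicate(n_mc, mean(d * sample(c(-1, 1), n, replace = TRUE)))
    (sum(stat >= obs - 1e-15) + 1) / (n_mc + 1)
  }
}
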