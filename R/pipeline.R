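#' End-to-end segmentation run
#'
#' Preprocess -> patch sampling -> training -> patch prediction -> overlap
#' reconstruction -> thresholding -> evaluation, on a train/test split of a
#' dataset. Optionally writes probability maps, binary masks, per-image
#' metrics (CSV) and a JSON run manifest.
#'
#' @param data a dataset directory (see [load_dataset()]) or a list of
#'   `fundus_sample` objects.
#' @param train_idx,test_idx sample indices for the two roles.
#' @param config a [model_config()].
#' @param tcfg a [train_config()]; its seed fixes patch sampling and batch
#'   order, and also initializes the weights unless `seed` is given.
#' @param pre_config a [preprocess_config()].
#' @param seed weight-initialization seed (default `tcfg$seed`).
#' @param out_dir optional output directory.
#' @param verbose print training progress.
#' @return list with the trained `model`, per-image `metrics` data frame,
#'   and the run `manifest`.
#' @export
run_pipeline <- function(data, train_idx, test_idx,
                         config = model_config(), tcfg = train_config(),
                         pre_config = preprocess_config(), seed = NULL,
                         out_dir = NULL, verbose = FALSE) {
  samples <- if (is.character(data)) load_dataset(data) else data
  if (is.null(seed)) seed <- tcfg$seed
  stopifnot(length(train_idx) >= 1L, length(test_idx) >= 1L)

  # training patches: preprocess each training image, then sample patches
  # under one RNG stream so the whole draw is a function of the seed
  pre <- lapply(samples[train_idx], function(sm)
    preprocess_image(sm$image, pre_config))
  set.seed(tcfg$seed)
  per_img <- ceiling(tcfg$n_patches / length(train_idx))
  plist <- vector("list", length(train_idx))
  for (q in seq_along(train_idx)) {
    sm <- samples[[train_idx[q]]]
    plist[[q]] <- sample_random_patches(pre[[q]], sm$vessel, sm$fov,
                                        per_img, tcfg$patch_size,
                                        source_id = sm$id)
  }
  S <- tcfg$patch_size
  n_tot <- per_img * length(train_idx)
  patches <- array(0, c(S, S, n_tot))
  masks <- array(0, c(S, S, n_tot))
  for (q in seq_along(plist)) {
    sl <- ((q - 1L) * per_img + 1L):(q * per_img)
    patches[, , sl] <- plist[[q]]$patches
    masks[, , sl] <- plist[[q]]$mask_patches
  }

  model <- build_mfinet(config, seed = seed)
  model <- train_mfinet(model, patches, masks, tcfg, verbose = verbose)

  rows <- list()
  outputs <- list()
  for (j in test_idx) {
    sm <- samples[[j]]
    pr <- predict_sample(model, sm, tcfg, pre_config)
    met <- segmentation_metrics(confusion_counts(pr$pred, sm$vessel, sm$fov))
    curves <- roc_pr_curves(pr$prob, sm$vessel, sm$fov)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sm$id, f1 = met$f1, accuracy = met$accuracy,
      sensitivity = met$sensitivity, specificity = met$specificity,
      precision = met$precision, recall = met$recall,
      auroc = curves$auroc, aupr = curves$aupr)
    outputs[[sm$id]] <- pr
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_pnm(pr$prob * 255, file.path(out_dir, paste0(sm$id, "_prob.pgm")))
      write_pnm(pr$pred * 255, file.path(out_dir, paste0(sm$id, "_pred.pgm")))
    }
  }
  metrics <- do.call(rbind, rows)
  manifest <- list(
    seed = seed, train_ids = vapply(samples[train_idx], `[[`, "", "id"),
    test_ids = vapply(samples[test_idx], `[[`, "", "id"),
    model_config = unclass(config), train_config = unclass(tcfg),
    preprocess_config = unclass(pre_config),
    n_parameters = count_parameters(model),
    metrics = metrics)
  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(model = model, metrics = metrics, manifest = manifest,
       predictions = outputs)
}

#' Structural ablation matrix
#'
#' Trains and evaluates a set of architecture variants under identical
#' seeds and identical training patches (only the architecture differs),
#' optionally over several seeds, and reports mean test metrics per variant
#' plus one-sided paired p-values on the pooled per-image F1 pairs.
#'
#' @inheritParams run_pipeline
#' @param variants subset of `c("unet", "mi", "fas", "mr", "mrfas")`.
#' @param base_width encoder base width for every variant.
#' @param seeds one run per seed; metrics are averaged.
#' @return list with `table` (one row per variant: mean F1, accuracy,
#'   sensitivity, specificity), `per_image` (variant x seed x image F1),
#'   and `pvalues` (one-sided, row-variant better than column-variant).
#' @export
run_ablation <- function(data, train_idx, test_idx,
                         variants = c("unet", "mi", "fas", "mr", "mrfas"),
                         base_width = 8L, tcfg = train_config(),
                         pre_config = preprocess_config(),
                         seeds = 1234L, verbose = FALSE) {
  samples <- if (is.character(data)) load_dataset(data) else data
  per_image <- list()
  rows <- list()
  for (v in variants) {
    f1s <- c()
    agg <- c(f1 = 0, accuracy = 0, sensitivity = 0, specificity = 0)
    nr <- 0L
    for (sd_ in seeds) {
      tc <- tcfg
      tc$seed <- as.integer(sd_)
      res <- run_pipeline(samples, train_idx, test_idx,
                          config = ablation_config(v, base_width = base_width),
                          tcfg = tc, pre_config = pre_config,
                          seed = as.integer(sd_), verbose = verbose)
      f1s <- c(f1s, res$metrics$f1)
      agg <- agg + colMeans(res$metrics[, c("f1", "accuracy", "sensitivity",
                                            "specificity")])
      nr <- nr + 1L
    }
    per_image[[v]] <- f1s
    rows[[v]] <- data.frame(variant = v, t(agg / nr))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  pv <- matrix(NA_real_, length(variants), length(variants),
               dimnames = list(variants, variants))
  for (a in variants) for (b in variants) if (a != b)
    pv[a, b] <- paired_f1_pvalue(per_image[[a]], per_image[[b]])
  list(table = tab, per_image = per_image, pvalues = pv)
}
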