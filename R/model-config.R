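#' Network configuration
#'
#' Describes an encoder-decoder vessel-segmentation network with optional
#' multi-resolution fusion input (MR), fully aggregated skip connections
#' (FAS), or a plain multi-scale input (MI) ablation. Encoder widths double
#' per level from `base_width`; the MR stream has its own per-level widths
#' (`mr_widths`), calibrated by default so the full model's trainable
#' parameter count matches the published budget (27.6M; the plain U-Net
#' baseline at `base_width = 32` matches 7.8M).
#'
#' @param n_levels number of resolution levels (input halves per level).
#' @param input_size patch side in pixels; must be divisible by
#'   `2^(n_levels - 1)`.
#' @param base_width channels at the first encoder level.
#' @param width_multiplier per-level channel growth factor.
#' @param mr_stages number of fusion stages in the MR module.
#' @param use_mr,use_fas,use_mi architecture flags; at most one of
#'   `use_mr`/`use_mi` may be active.
#' @param use_residual replace double-conv blocks with residual units
#'   (the full model does; the plain U-Net baseline does not).
#' @param mr_widths integer vector of MR-stream channel widths per level;
#'   `NULL` scales the calibrated defaults by `base_width / 32`.
#' @param attn_reduction channel-attention MLP reduction ratio.
#' @param spatial_kernel spatial-attention convolution kernel size (odd).
#' @param n_classes output classes (vessel / background).
#' @return an object of class `mfinet_config`.
#' @export
model_config <- function(n_levels = 5L, input_size = 48L, base_width = 32L,
                         width_multiplier = 2L, mr_stages = 4L,
                         use_mr = TRUE, use_fas = TRUE, use_mi = FALSE,
                         use_residual = TRUE, mr_widths = NULL,
                         attn_reduction = 16L, spatial_kernel = 7L,
                         n_classes = 2L) {
  n_levels <- as.integer(n_levels)
  if (use_mr && use_mi) stop("use_mr and use_mi are mutually exclusive")
  if (input_size %% 2^(n_levels - 1L) != 0L)
    stop("input_size must be divisible by 2^(n_levels - 1)")
  if (spatial_kernel %% 2L != 1L) stop("spatial_kernel must be odd")
  if (mr_stages != n_levels - 1L)
    stop("mr_stages must be n_levels - 1 (one new level per stage)")
  widths <- as.integer(base_width * width_multiplier^(seq_len(n_levels) - 1L))
  if (is.null(mr_widths)) {
    mr_widths <- pmax(1L, as.integer(round(.mr_widths_calibrated *
                                             base_width / 32)))
  }
  mr_widths <- as.integer(mr_widths)
  if (length(mr_widths) != n_levels) stop("mr_widths must have one entry per level")
  cfg <- list(
    n_levels = n_levels, input_size = as.integer(input_size),
    base_width = as.integer(base_width),
    width_multiplier = as.integer(width_multiplier),
    widths = widths, mr_widths = mr_widths, mr_stages = as.integer(mr_stages),
    use_mr = isTRUE(use_mr), use_fas = isTRUE(use_fas), use_mi = isTRUE(use_mi),
    use_residual = isTRUE(use_residual),
    attn_reduction = as.integer(attn_reduction),
    spatial_kernel = as.integer(spatial_kernel),
    n_classes = as.integer(n_classes)
  )
  class(cfg) <- "mfinet_config"
  cfg
}

# MR-stream widths at base_width 32, fixed so that the full model counts
# 27.6M trainable parameters (rounded to 0.1M); see the methods vignette.
.mr_widths_calibrated <- c(36L, 72L, 144L, 288L, 563L)

#' Plain U-Net baseline configuration
#'
#' Double-convolution U-Net with one-to-one skips: no MR stream, no FAS,
#' no residual units. At the default `base_width = 32` it counts 7.8M
#' trainable parameters.
#'
#' @inheritParams model_config
#' @return an `mfinet_config`.
#' @export
unet_config <- function(base_width = 32L, input_size = 48L) {
  model_config(base_width = base_width, input_size = input_size,
               use_mr = FALSE, use_fas = FALSE, use_mi = FALSE,
               use_residual = FALSE)
}

#' Ablation-variant configurations
#'
#' The five architecture variants of the structural ablation: the plain
#' U-Net baseline, U-Net plus multi-scale input (MI), plus fully aggregated
#' skips (FAS), plus the multi-resolution fusion input (MR), and the full
#' model (MR + FAS).
#'
#' @param variant one of `"unet"`, `"mi"`, `"fas"`, `"mr"`, `"mrfas"`.
#' @inheritParams model_config
#' @return an `mfinet_config`.
#' @export
ablation_config <- function(variant = c("unet", "mi", "fas", "mr", "mrfas"),
                            base_width = 32L, input_size = 48L) {
  variant <- match.arg(variant)
  switch(variant,
    unet  = unet_config(base_width, input_size),
    mi    = model_config(base_width = base_width, input_size = input_size,
                         use_mr = FALSE, use_fas = FALSE, use_mi = TRUE),
    fas   = model_config(base_width = base_width, input_size = input_size,
                         use_mr = FALSE, use_fas = TRUE),
    mr    = model_config(base_width = base_width, input_size = input_size,
                         use_mr = TRUE, use_fas = FALSE),
    mrfas = model_config(base_width = base_width, input_size = input_size,
                         use_mr = TRUE, use_fas = TRUE)
  )
}

#' @export
print.mfinet_config <- function(x, ...) {
  cat("mfinet_config:", x$n_levels, "levels, input", x$input_size, "px\n")
  cat("  encoder widths:", paste(x$widths, collapse = " "), "\n")
  if (x$use_mr) cat("  MR widths:     ", paste(x$mr_widths, collapse = " "), "\n")
  cat("  flags: use_mr =", x$use_mr, "| use_fas =", x$use_fas,
      "| use_mi =", x$use_mi, "| residual =", x$use_residual, "\n")
  invisible(x)
}

#' Indicator gate
#'
#' The indicator used when summing multi-resolution contributions: 0 for an
#' absent term (argument 0), 1 otherwise.
#'
#' @param x numeric/integer vector.
#' @return integer vector of 0/1.
#' @export
indicator <- function(x) as.integer(x != 0)
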