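#' Preprocessing configuration
#'
#' Parameters of the fundus preprocessing chain: weighted channel fusion to
#' grayscale, per-image normalization, contrast-limited adaptive histogram
#' equalization (CLAHE), and gamma correction.
#'
#' @param channel_weights red/green/blue fusion weights (non-negative,
#'   summing to ~1); the defaults put most weight on the green channel,
#'   where vessel contrast is strongest.
#' @param gamma power-law exponent (> 0); the default 1.2 darkens slightly.
#' @param clahe_clip_limit CLAHE clip limit (> 0), in multiples of the
#'   uniform histogram level.
#' @param clahe_tile_grid integer pair: tile grid (rows, cols).
#' @param normalize_mode normalization rule; per-image z-score followed by
#'   an affine rescale to `[0, 255]`.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(channel_weights = c(0.299, 0.587, 0.114),
                              gamma = 1.2,
                              clahe_clip_limit = 2.0,
                              clahe_tile_grid = c(8L, 8L),
                              normalize_mode = "zscore_then_rescale") {
  if (length(channel_weights) != 3L || any(channel_weights < 0) ||
      any(channel_weights > 1))
    stop("channel_weights must be three fractions in [0, 1]")
  if (gamma <= 0) stop("gamma must be positive")
  if (clahe_clip_limit <= 0) stop("clahe_clip_limit must be positive")
  if (length(clahe_tile_grid) != 2L || any(clahe_tile_grid < 1))
    stop("clahe_tile_grid must be two positive integers")
  normalize_mode <- match.arg(normalize_mode, "zscore_then_rescale")
  structure(list(channel_weights = as.numeric(channel_weights),
                 gamma = gamma, clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 normalize_mode = normalize_mode),
            class = "preprocess_config")
}

#' Split an RGB image into channel planes
#'
#' @param rgb `[H,W,3]` array of intensities.
#' @return list with `red`, `green`, `blue` `[H,W]` matrices, values
#'   unchanged.
#' @export
split_channels <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L)
    stop("split_channels: expected an HxWx3 array, got ",
         paste(d, collapse = "x"))
  list(red = rgb[, , 1L], green = rgb[, , 2L], blue = rgb[, , 3L])
}

#' Weighted grayscale fusion
#'
#' `round(wr*R + wg*G + wb*B)`, clipped to `[0, 255]`. Rounding is
#' half-away-from-zero for bit-reproducibility.
#'
#' @param rgb `[H,W,3]` array.
#' @param weights non-negative weight triple (red, green, blue).
#' @return `[H,W]` matrix of 8-bit intensities.
#' @export
fuse_grayscale <- function(rgb, weights = c(0.299, 0.587, 0.114)) {
  if (any(weights < 0)) stop("fuse_grayscale: weights must be non-negative")
  ch <- split_channels(rgb)
  g <- weights[1] * ch$red + weights[2] * ch$green + weights[3] * ch$blue
  pmin(pmax(.round_half_away(g), 0), 255)
}

# round half away from zero (R's round() rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-image intensity normalization
#'
#' Standardizes the image to zero mean / unit variance, then rescales
#' affinely so the minimum maps to 0 and the maximum to 255. A constant
#' image (zero variance) maps to the mid-gray value.
#'
#' @param gray `[H,W]` matrix.
#' @param mid value assigned to constant images.
#' @param center,scale optional fixed statistics (e.g. dataset-wide mean and
#'   sd) to standardize with instead of the per-image defaults.
#' @return `[H,W]` matrix in `[0, 255]` (not rounded).
#' @export
normalize_image <- function(gray, mid = 127.5, center = NULL, scale = NULL) {
  if (length(gray) == 0L) stop("normalize_image: empty image")
  s <- if (is.null(scale)) stats::sd(as.vector(gray)) else scale
  m <- if (is.null(center)) mean(gray) else center
  if (!is.finite(s) || s == 0) return(array(mid, dim(gray)))
  z <- (gray - m) / s
  if (min(z) == max(z)) return(array(mid, dim(gray)))
  (z - min(z)) / (max(z) - min(z)) * 255
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-based CLAHE on an 8-bit single-channel image: per-tile 256-bin
#' histograms are clipped at `clip_limit` times the uniform level, the
#' excess is redistributed evenly, and per-tile cumulative mappings are
#' blended bilinearly between tile centers.
#'
#' @param gray `[H,W]` matrix with values in `[0, 255]`.
#' @param clip_limit positive clip factor.
#' @param tile_grid integer pair (rows, cols) of tiles.
#' @return `[H,W]` matrix in `[0, 255]`.
#' @export
clahe <- function(gray, clip_limit = 2.0, tile_grid = c(8L, 8L)) {
  if (clip_limit <= 0) stop("clahe: clip_limit must be positive")
  d <- dim(gray)
  H <- d[1]; W <- d[2]
  gy <- as.integer(tile_grid[1]); gx <- as.integer(tile_grid[2])
  v <- pmin(pmax(round(gray), 0), 255)
  ty <- ceiling(H / gy); tx <- ceiling(W / gx)
  # tile LUTs
  luts <- array(0, c(gy, gx, 256L))
  for (a in seq_len(gy)) for (b in seq_len(gx)) {
    rows <- ((a - 1L) * ty + 1L):min(a * ty, H)
    cols <- ((b - 1L) * tx + 1L):min(b * tx, W)
    tv <- v[rows, cols]
    n <- length(tv)
    h <- tabulate(tv + 1L, nbins = 256L)
    clip <- max(1, clip_limit * n / 256)
    excess <- sum(pmax(h - clip, 0))
    h <- pmin(h, clip) + excess / 256
    luts[a, b, ] <- pmin(round(cumsum(h) / n * 255), 255)
  }
  # bilinear interpolation between tile-center mappings
  centers_y <- (seq_len(gy) - 0.5) * ty
  centers_x <- (seq_len(gx) - 0.5) * tx
  fy <- pmin(pmax((seq_len(H) - centers_y[1]) / ty, 0), gy - 1)
  fx <- pmin(pmax((seq_len(W) - centers_x[1]) / tx, 0), gx - 1)
  iy0 <- pmin(floor(fy) + 1L, gy); iy1 <- pmin(iy0 + 1L, gy)
  ix0 <- pmin(floor(fx) + 1L, gx); ix1 <- pmin(ix0 + 1L, gx)
  wy <- fy - (iy0 - 1L); wx <- fx - (ix0 - 1L)
  vi <- as.integer(v) + 1L
  ri <- rep(seq_len(H), times = W)
  ci <- rep(seq_len(W), each = H)
  g00 <- luts[cbind(iy0[ri], ix0[ci], vi)]
  g01 <- luts[cbind(iy0[ri], ix1[ci], vi)]
  g10 <- luts[cbind(iy1[ri], ix0[ci], vi)]
  g11 <- luts[cbind(iy1[ri], ix1[ci], vi)]
  wyv <- wy[ri]; wxv <- wx[ci]
  out <- (1 - wyv) * ((1 - wxv) * g00 + wxv * g01) +
    wyv * ((1 - wxv) * g10 + wxv * g11)
  matrix(out, H, W)
}

#' Gamma correction
#'
#' Power-law remapping `out = 255 * (in / 255)^gamma`, rounded; strictly
#' monotone on `[0, 255]` for any positive gamma.
#'
#' @param gray `[H,W]` matrix in `[0, 255]`.
#' @param gamma positive exponent.
#' @return `[H,W]` matrix of rounded intensities in `[0, 255]`.
#' @export
gamma_correct <- function(gray, gamma = 1.2) {
  if (gamma <= 0) stop("gamma_correct: gamma must be positive")
  .round_half_away(255 * (pmin(pmax(gray, 0), 255) / 255)^gamma)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: weighted grayscale fusion, per-image normalization,
#' CLAHE, and gamma correction.
#'
#' @param rgb `[H,W,3]` array of 8-bit intensities.
#' @param config a [preprocess_config()].
#' @return `[H,W]` matrix in `[0, 255]`.
#' @export
preprocess_image <- function(rgb, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  g <- fuse_grayscale(rgb, config$channel_weights)
  g <- normalize_image(g)
  g <- clahe(g, config$clahe_clip_limit, config$clahe_tile_grid)
  gamma_correct(g, config$gamma)
}
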