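#' Pad an image so a stride-aligned patch grid covers it exactly
#'
#' Pads bottom/right with black (zero) pixels to the smallest `H' >= H`,
#' `W' >= W` with `(H' - S) %% stride == 0` (same for width), so an `S x S`
#' sliding window at the given stride tiles the canvas exactly.
#'
#' @param image `[H,W]` matrix.
#' @param patch_size window side `S` (>= 1).
#' @param stride window step (1 <= stride <= patch_size for gapless cover).
#' @return list with `image` (padded matrix), `padded_shape`,
#'   `original_shape`, `patch_size`, `stride`.
#' @export
pad_to_grid <- function(image, patch_size, stride = patch_size) {
  S <- as.integer(patch_size); st <- as.integer(stride)
  if (S < 1L) stop("pad_to_grid: patch_size must be >= 1")
  if (st < 1L || st > S) stop("pad_to_grid: stride must be in [1, patch_size]")
  d <- dim(image)
  grow <- function(n) if (n <= S) S else S + st * as.integer(ceiling((n - S) / st))
  Hp <- grow(d[1]); Wp <- grow(d[2])
  out <- matrix(0, Hp, Wp)
  out[seq_len(d[1]), seq_len(d[2])] <- image
  list(image = out, padded_shape = c(Hp, Wp), original_shape = d,
       patch_size = S, stride = st)
}

.new_patch_set <- function(patches, coords, padded_shape, original_shape,
                           patch_size, stride, source_id = "",
                           mask_patches = NULL) {
  structure(list(patches = patches, coords = coords,
                 padded_shape = as.integer(padded_shape),
                 original_shape = as.integer(original_shape),
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 source_id = source_id, mask_patches = mask_patches),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("patch_set:", dim(x$patches)[3], "patches of", x$patch_size, "x",
      x$patch_size, "| canvas", paste(x$padded_shape, collapse = "x"),
      "| original", paste(x$original_shape, collapse = "x"), "\n")
  invisible(x)
}

#' Extract the deterministic sliding-window patch grid
#'
#' Row-major enumeration of all stride-spaced `S x S` windows of a padded
#' canvas; the count is `((H'-S)/stride + 1) * ((W'-S)/stride + 1)`.
#'
#' @param padded a padded matrix from [pad_to_grid()], or the list it
#'   returns.
#' @inheritParams pad_to_grid
#' @param source_id provenance label.
#' @return a `patch_set`: `patches` `[S,S,n]`, 0-based top-left `coords`.
#' @export
extract_grid_patches <- function(padded, patch_size = NULL, stride = NULL,
                                 source_id = "") {
  if (is.list(padded)) {
    patch_size <- padded$patch_size
    stride <- padded$stride
    orig <- padded$original_shape
    padded <- padded$image
  } else {
    orig <- dim(padded)
  }
  S <- as.integer(patch_size); st <- as.integer(stride)
  d <- dim(padded)
  if (d[1] < S || d[2] < S || (d[1] - S) %% st != 0L || (d[2] - S) %% st != 0L)
    stop("extract_grid_patches: canvas is not padded to the (patch_size, stride) grid")
  ny <- (d[1] - S) %/% st + 1L
  nx <- (d[2] - S) %/% st + 1L
  n <- ny * nx
  patches <- array(0, c(S, S, n))
  coords <- matrix(0L, n, 2L, dimnames = list(NULL, c("row", "col")))
  q <- 0L
  for (iy in seq_len(ny)) {
    r0 <- (iy - 1L) * st
    for (ix in seq_len(nx)) {
      c0 <- (ix - 1L) * st
      q <- q + 1L
      patches[, , q] <- padded[(r0 + 1L):(r0 + S), (c0 + 1L):(c0 + S)]
      coords[q, ] <- c(r0, c0)
    }
  }
  .new_patch_set(patches, coords, d, orig, S, st, source_id)
}

#' Sample random training patches
#'
#' Draws `n` top-left positions uniformly among those whose patch center
#' falls inside the field of view, and cuts image and mask patches at
#' identical coordinates. Reproducible for a fixed RNG state / seed.
#'
#' @param image,mask,fov same-shape matrices; `mask` binary vessel truth,
#'   `fov` binary field-of-view.
#' @param n number of patches.
#' @param patch_size patch side.
#' @param seed optional integer seed.
#' @param require_fov_center keep only positions whose patch center lies in
#'   the FOV.
#' @param source_id provenance label.
#' @return a `patch_set` with `patches` (image) and `mask_patches`.
#' @export
sample_random_patches <- function(image, mask, fov, n, patch_size = 48L,
                                  seed = NULL, require_fov_center = TRUE,
                                  source_id = "") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  S <- as.integer(patch_size)
  d <- dim(image)
  if (!identical(d, dim(mask)) || !identical(d, dim(fov)))
    stop("sample_random_patches: image/mask/fov shapes differ")
  if (n < 1L) stop("sample_random_patches: n must be >= 1")
  if (d[1] < S || d[2] < S) stop("sample_random_patches: image smaller than patch")
  ny <- d[1] - S + 1L; nx <- d[2] - S + 1L
  if (require_fov_center) {
    half <- S %/% 2L
    cy <- seq_len(ny) + half; cx <- seq_len(nx) + half
    ok <- fov[cy, cx, drop = FALSE] > 0
    valid <- which(ok)
    if (!length(valid)) stop("sample_random_patches: FOV admits no valid patch position")
    pick <- valid[sample.int(length(valid), n, replace = TRUE)]
    r0 <- (pick - 1L) %% ny
    c0 <- (pick - 1L) %/% ny
  } else {
    r0 <- sample.int(ny, n, replace = TRUE) - 1L
    c0 <- sample.int(nx, n, replace = TRUE) - 1L
  }
  patches <- array(0, c(S, S, n))
  mpatch <- array(0, c(S, S, n))
  for (q in seq_len(n)) {
    rows <- (r0[q] + 1L):(r0[q] + S)
    cols <- (c0[q] + 1L):(c0[q] + S)
    patches[, , q] <- image[rows, cols]
    mpatch[, , q] <- mask[rows, cols]
  }
  .new_patch_set(patches, cbind(row = r0, col = c0), d, d, S, S, source_id,
                 mask_patches = mpatch)
}

#' Reconstruct a full-size probability map from overlapping patches
#'
#' Every pixel of the padded canvas receives the mean of all patch
#' predictions covering it; the canvas is then cropped to the original
#' shape. With `stride = patch_size` this inverts [extract_grid_patches()]
#' exactly.
#'
#' @param patch_set a `patch_set` whose `patches` hold probabilities in
#'   `[0,1]` (e.g. the vessel channel of the network output).
#' @return `[H,W]` probability matrix at the original shape.
#' @export
reconstruct_from_patches <- function(patch_set) {
  stopifnot(inherits(patch_set, "patch_set"))
  p <- patch_set$patches
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
    stop("reconstruct_from_patches: patch values outside [0, 1]")
  S <- patch_set$patch_size
  d <- patch_set$padded_shape
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0, d[1], d[2])
  for (q in seq_len(dim(p)[3])) {
    rows <- (patch_set$coords[q, 1L] + 1L):(patch_set$coords[q, 1L] + S)
    cols <- (patch_set$coords[q, 2L] + 1L):(patch_set$coords[q, 2L] + S)
    acc[rows, cols] <- acc[rows, cols] + p[, , q]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  if (any(cnt == 0))
    stop("reconstruct_from_patches: some canvas pixels are covered by no patch")
  out <- acc / cnt
  out[seq_len(patch_set$original_shape[1L]),
      seq_len(patch_set$original_shape[2L]), drop = FALSE]
}

#' Threshold a probability map inside the field of view
#'
#' A pixel is vessel iff its probability is `>= threshold` and it lies in
#' the FOV; everything outside the FOV is background.
#'
#' @param prob `[H,W]` probabilities in `[0,1]`.
#' @param threshold scalar in `[0,1]` (0.47 for DRIVE/CHASE_DB1, 0.52 for
#'   STARE in the published recipe).
#' @param fov binary FOV matrix (`NULL` = whole canvas).
#' @return binary `[H,W]` matrix.
#' @export
binarize_probmap <- function(prob, threshold = 0.47, fov = NULL) {
  if (threshold < 0 || threshold > 1)
    stop("binarize_probmap: threshold must be in [0, 1]")
  out <- (prob >= threshold) * 1
  if (!is.null(fov)) out <- out * (fov > 0)
  out
}
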