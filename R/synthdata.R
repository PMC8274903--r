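#' Synthetic fundus generator configuration
#'
#' The generator emulates the geometry of a fundus photograph at desk scale:
#' a dark background with a circular field of view (FOV), recursive
#' branching vessel trees rendered as anti-aliased tubes whose caliber
#' decays toward 1-2 px capillaries, strongest vessel contrast in the green
#' channel, a smooth illumination gradient, optional bright lesion blobs,
#' and additive Gaussian noise. Vessel and FOV masks are exact.
#'
#' @param image_size `(H, W)` in pixels.
#' @param n_trees number of vessel trees.
#' @param branch_depth branching generations per tree.
#' @param caliber_range `(min, max)` vessel diameter in px; children shrink
#'   by `caliber_decay` per generation, floored at the minimum.
#' @param caliber_decay per-generation caliber factor.
#' @param tortuosity per-step direction jitter (radians sd).
#' @param contrast vessel-background intensity gap in the green channel.
#' @param illumination_gradient amplitude of the smooth shading field.
#' @param lesion_blobs number of bright lesion blobs.
#' @param noise_sigma additive Gaussian noise sd.
#' @param seed integer seed; the sample is a pure function of the config.
#' @return a `synth_config` list.
#' @export
synth_config <- function(image_size = c(128L, 128L), n_trees = 3L,
                         branch_depth = 4L, caliber_range = c(1, 4),
                         caliber_decay = 0.7, tortuosity = 0.18,
                         contrast = 70, illumination_gradient = 18,
                         lesion_blobs = 1L, noise_sigma = 4, seed = 1234L) {
  if (caliber_range[1] < 1) stop("synth_config: minimum caliber is 1 px")
  if (any(c(tortuosity, contrast, illumination_gradient, noise_sigma) < 0))
    stop("synth_config: scales must be >= 0")
  structure(list(image_size = as.integer(image_size), n_trees = as.integer(n_trees),
                 branch_depth = as.integer(branch_depth),
                 caliber_range = as.numeric(caliber_range),
                 caliber_decay = caliber_decay, tortuosity = tortuosity,
                 contrast = contrast,
                 illumination_gradient = illumination_gradient,
                 lesion_blobs = as.integer(lesion_blobs),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synth_config")
}

# stamp one disc of radius r (coverage = clamp(r + 0.5 - dist, 0, 1)) into
# the coverage field, keeping the per-pixel maximum
.stamp_disc <- function(cov, y, x, r) {
  H <- nrow(cov); W <- ncol(cov)
  w <- ceiling(r + 1)
  rows <- max(1L, floor(y - w)):min(H, ceiling(y + w))
  cols <- max(1L, floor(x - w)):min(W, ceiling(x + w))
  if (!length(rows) || !length(cols)) return(cov)
  dy <- rows - y
  dx <- cols - x
  d <- sqrt(outer(dy^2, dx^2, "+"))
  a <- pmin(pmax(r + 0.5 - d, 0), 1)
  cov[rows, cols] <- pmax(cov[rows, cols], a)
  cov
}

# draw one branch as a jittered polyline; returns updated coverage and the
# endpoint/direction for children
.draw_branch <- function(cov, y, x, ang, len, caliber, tort, fov_r, cy, cx) {
  step <- 0.75
  n <- max(2L, ceiling(len / step))
  r <- caliber / 2
  for (q in seq_len(n)) {
    ang <- ang + stats::rnorm(1L, 0, tort)
    y <- y + step * sin(ang)
    x <- x + step * cos(ang)
    if ((y - cy)^2 + (x - cx)^2 > (0.96 * fov_r)^2) break
    cov <- .stamp_disc(cov, y, x, r)
  }
  list(cov = cov, y = y, x = x, ang = ang)
}

#' Generate one synthetic fundus sample
#'
#' @param config a [synth_config()].
#' @return a `fundus_sample` list: `image` (`[H,W,3]`, 0-255), binary
#'   `vessel` mask (rendered tube support at anti-aliasing coverage >= 0.5),
#'   binary `fov` mask, and an `id` string.
#' @export
generate_sample <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  H <- config$image_size[1]; W <- config$image_size[2]
  fov_r <- 0.47 * min(H, W)
  if (fov_r < 24) stop("generate_sample: FOV radius below half a 48 px patch")
  set.seed(config$seed)
  cy <- H / 2; cx <- W / 2
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  fov <- ((yy - cy)^2 + (xx - cx)^2 <= fov_r^2) * 1

  cov <- matrix(0, H, W)
  for (t in seq_len(config$n_trees)) {
    # root on a disc-like ring near the center, heading outward
    a0 <- stats::runif(1, 0, 2 * pi)
    rr <- stats::runif(1, 0.05, 0.25) * fov_r
    y0 <- cy + rr * sin(a0)
    x0 <- cx + rr * cos(a0)
    heads <- list(list(y = y0, x = x0, ang = a0 + stats::rnorm(1, 0, 0.3),
                       cal = config$caliber_range[2], depth = 0L))
    while (length(heads)) {
      hd <- heads[[1L]]
      heads <- heads[-1L]
      len <- stats::runif(1, 0.22, 0.34) * fov_r * (0.85^hd$depth)
      br <- .draw_branch(cov, hd$y, hd$x, hd$ang, len, hd$cal,
                         config$tortuosity, fov_r, cy, cx)
      cov <- br$cov
      if (hd$depth + 1L < config$branch_depth) {
        cal <- max(config$caliber_range[1], hd$cal * config$caliber_decay)
        spread <- stats::runif(2, 0.25, 0.7)
        heads <- c(heads,
                   list(list(y = br$y, x = br$x, ang = br$ang + spread[1],
                             cal = cal, depth = hd$depth + 1L),
                        list(y = br$y, x = br$x, ang = br$ang - spread[2],
                             cal = cal, depth = hd$depth + 1L)))
      }
    }
  }
  cov <- cov * fov
  vessel <- (cov >= 0.5) * 1

  # background + illumination + lesions; vessels are bright, strongest in G
  grad_ang <- stats::runif(1, 0, 2 * pi)
  shade <- config$illumination_gradient *
    (((xx - cx) / W) * cos(grad_ang) + ((yy - cy) / H) * sin(grad_ang)) +
    0.5 * config$illumination_gradient * (1 - ((yy - cy)^2 + (xx - cx)^2) / fov_r^2)
  base <- 60 + shade
  chan_gain <- c(red = 0.55, green = 1.0, blue = 0.25)
  lesions <- matrix(0, H, W)
  for (q in seq_len(config$lesion_blobs)) {
    la <- stats::runif(1, 0, 2 * pi)
    lr <- stats::runif(1, 0.2, 0.7) * fov_r
    ly <- cy + lr * sin(la); lx <- cx + lr * cos(la)
    sg <- stats::runif(1, 3, 7)
    lesions <- lesions + stats::runif(1, 15, 30) *
      exp(-(((yy - ly)^2 + (xx - lx)^2) / (2 * sg^2)))
  }
  img <- array(0, c(H, W, 3L))
  for (c_ in 1:3) {
    plane <- (base * c(1.15, 1.0, 0.55)[c_] + chan_gain[c_] * config$contrast * cov +
                0.8 * lesions) * fov + 2 * (1 - fov)
    plane <- plane + matrix(stats::rnorm(H * W, 0, config$noise_sigma), H, W)
    img[, , c_] <- pmin(pmax(round(plane), 0), 255)
  }
  structure(list(image = img, vessel = vessel, fov = fov,
                 id = sprintf("synth%06d", config$seed)),
            class = "fundus_sample")
}

#' @export
print.fundus_sample <- function(x, ...) {
  frac <- sum(x$vessel[x$fov > 0]) / sum(x$fov)
  cat("fundus_sample", x$id, ":", paste(dim(x$vessel), collapse = "x"),
      sprintf("| vessel fraction in FOV %.3f\n", frac))
  invisible(x)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` samples in a DRIVE-like layout (`images/`, `1st_manual/`,
#' `mask/`, PNM files) plus a JSON manifest with the per-sample seeds and
#' the generator configuration, from which the data can be regenerated
#' bit-identically.
#'
#' @param n number of samples.
#' @param config base [synth_config()]; sample `k` uses `seed + k - 1`.
#' @param out_dir output directory (created).
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(n, config = synth_config(), out_dir) {
  if (n < 1L) stop("generate_dataset: n must be >= 1")
  for (sub in c("images", "1st_manual", "mask"))
    dir.create(file.path(out_dir, sub), recursive = TRUE, showWarnings = FALSE)
  seeds <- config$seed + seq_len(n) - 1L
  ids <- character(n)
  for (k in seq_len(n)) {
    cfg_k <- config
    cfg_k$seed <- seeds[k]
    sm <- generate_sample(cfg_k)
    ids[k] <- sm$id
    write_pnm(sm$image, file.path(out_dir, "images", paste0(sm$id, ".ppm")))
    write_pnm(sm$vessel * 255, file.path(out_dir, "1st_manual", paste0(sm$id, ".pgm")))
    write_pnm(sm$fov * 255, file.path(out_dir, "mask", paste0(sm$id, ".pgm")))
  }
  manifest <- list(n = n, ids = ids, seeds = seeds,
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a dataset of fundus samples from disk
#'
#' Reads the DRIVE-like layout written by [generate_dataset()] (PNM files in
#' `images/`, `1st_manual/`, `mask/`); masks are binarized at 128.
#'
#' @param dir dataset directory.
#' @return list of `fundus_sample` objects.
#' @export
load_dataset <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  if (!length(imgs)) stop("load_dataset: no images under ", dir)
  lapply(imgs, function(f) {
    id <- tools::file_path_sans_ext(basename(f))
    find1 <- function(sub) {
      g <- list.files(file.path(dir, sub), pattern = paste0("^", id, "\\."),
                      full.names = TRUE)
      if (!length(g)) stop("load_dataset: no ", sub, " entry for ", id)
      g[1L]
    }
    structure(list(image = read_pnm(f),
                   vessel = (read_pnm(find1("1st_manual")) >= 128) * 1,
                   fov = (read_pnm(find1("mask")) >= 128) * 1,
                   id = id),
              class = "fundus_sample")
  })
}
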