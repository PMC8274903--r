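# Portable anymap (PGM/PPM) reading and writing. No image-format package is
# assumed; PNM is the supported on-disk format for images, masks and FOVs
# (real datasets can be converted externally, e.g. ImageMagick `convert`).

#' Read a PGM/PPM image
#'
#' Supports ASCII (P2/P3) and binary 8-bit (P5/P6) portable anymaps.
#'
#' @param path file path.
#' @return `[H,W]` matrix (grayscale) or `[H,W,3]` array (color), values
#'   `0..maxval`.
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("read_pnm: unsupported format ", magic)
  toks <- integer(0)
  # read header tokens (width, height, maxval), skipping comments
  buf <- character(0)
  while (length(toks) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r")) break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      toks <- c(toks, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  W <- toks[1]; H <- toks[2]; maxval <- toks[3]
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- W * H * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.integer(readBin(con, "raw", n))
  } else {
    txt <- rawToChar(readBin(con, "raw", file.size(path)))
    txt <- gsub("#[^\n]*", "", txt)
    as.integer(scan(text = txt, what = integer(), n = n, quiet = TRUE))
  }
  if (length(vals) < n) stop("read_pnm: truncated file")
  if (nch == 1L) {
    matrix(vals, H, W, byrow = TRUE)
  } else {
    a <- array(0L, c(H, W, 3L))
    for (c_ in 1:3) a[, , c_] <- matrix(vals[seq(c_, n, by = 3L)], H, W, byrow = TRUE)
    a
  }
}

#' Write a PGM/PPM image
#'
#' Writes ASCII P2 (grayscale matrix) or P3 (HxWx3 array), maxval 255.
#'
#' @param image matrix or `[H,W,3]` array, values clipped/rounded to 0..255.
#' @param path destination path.
#' @export
write_pnm <- function(image, path) {
  v <- pmin(pmax(round(image), 0), 255)
  d <- dim(v)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  if (length(d) == 2L) {
    wr(sprintf("P2\n%d %d\n255\n", d[2], d[1]))
    body <- apply(v, 1L, paste, collapse = " ")
  } else {
    wr(sprintf("P3\n%d %d\n255\n", d[2], d[1]))
    inter <- matrix(0L, d[1], 3L * d[2])
    inter[, seq(1L, 3L * d[2], 3L)] <- v[, , 1L]
    inter[, seq(2L, 3L * d[2], 3L)] <- v[, , 2L]
    inter[, seq(3L, 3L * d[2], 3L)] <- v[, , 3L]
    body <- apply(inter, 1L, paste, collapse = " ")
  }
  wr(paste(body, collapse = "\n"))
  wr("\n")
  invisible(path)
}
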