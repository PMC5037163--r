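#' Manders pixel-overlap coefficients
#'
#' The fluorescence-microscopy counterpart of the particle coefficients:
#' for two registered single-channel intensity images,
#' \deqn{M_1 = \frac{\sum_{i: B_i > t_B} A_i}{\sum_{i: A_i > t_A} A_i}}
#' is the fraction of channel-A signal residing in pixels where channel B
#' is above its threshold, and \eqn{M_2} symmetrically for B.  Pixels
#' count as "above threshold" strictly (`> t`), so `t = 0` is correct for
#' 0/1 (or 0/255) binary masks, for which the formula reduces to pixel
#' count ratios.
#'
#' @param channel_a,channel_b Equally-shaped non-negative numeric
#'   matrices (intensities or binary masks).
#' @param threshold_a,threshold_b Intensity cutoffs (default 0, i.e.
#'   binary-mask semantics).
#' @return A one-row tibble with columns `m1`, `m2`.
#' @examples
#' a <- matrix(0, 4, 8); a[1:3, ] <- 1              # 24 A pixels
#' b <- matrix(0, 4, 8); b[4, ] <- 1; b[3, 1:4] <- 1 # 12 B, 4 overlapping
#' manders(a, b)                                    # 4/24, 4/12
#' @export
manders <- function(channel_a, channel_b, threshold_a = 0, threshold_b = 0) {
  if (!is.matrix(channel_a) || !is.matrix(channel_b) ||
      !identical(dim(channel_a), dim(channel_b))) {
    abort("channels must be matrices of identical shape")
  }
  if (any(channel_a < 0) || any(channel_b < 0)) {
    abort("channel intensities must be non-negative")
  }
  if (threshold_a < 0 || threshold_b < 0) abort("thresholds must be >= 0")
  above_a <- channel_a > threshold_a
  above_b <- channel_b > threshold_b
  if (!any(above_a)) abort("m1 undefined: no pixel above threshold in channel A")
  if (!any(above_b)) abort("m2 undefined: no pixel above threshold in channel B")
  tibble(m1 = sum(channel_a[above_b]) / sum(channel_a[above_a]),
         m2 = sum(channel_b[above_a]) / sum(channel_b[above_b]))
}

#' Read a single-channel image for the Manders comparison
#'
#' Supports single-channel TIFF (via the tiff package) and PGM (both the
#' ASCII `P2` and binary `P5` variants).  Multi-channel TIFFs are
#' rejected; the caller should split channels upstream.
#'
#' @param path Path to a `.tif`/`.tiff` or `.pgm` file.
#' @return A numeric matrix of intensities.
#' @export
read_channel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) {
      if (dim(img)[3] != 1) abort("multi-channel TIFF: supply one channel")
      img <- img[, , 1]
    }
    return(img)
  }
  if (ext == "pgm") return(read_pgm(path))
  abort(sprintf("unsupported image format: .%s (need TIFF or PGM)", ext))
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) abort("not a PGM file (magic != P2/P5)")
  # header tokens: width, height, maxval; '#' comments allowed
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0) abort("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (magic == "P5") {
    size <- if (maxval > 255) 2L else 1L
    vals <- readBin(con, "integer", n = w * h, size = size, signed = FALSE,
                    endian = "big")
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE,
                 comment.char = "#")
  }
  if (length(vals) != w * h) abort("truncated PGM pixel data")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
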