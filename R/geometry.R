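#' Rectangular study window
#'
#' The study window is the image rectangle within which particle
#' coordinates live.  Its origin is fixed at (0, 0) and the y axis follows
#' the image convention (y increases downward); only the extent matters for
#' any computation here.
#'
#' @param width,height Window extent in nm; both must be positive.
#'
#' @return A `coloc_window` object (named list with `width` and `height`).
#' @examples
#' study_window(2000, 2000)
#' @export
study_window <- function(width, height) {
  if (!is.numeric(width) || !is.numeric(height) ||
      length(width) != 1L || length(height) != 1L ||
      !is.finite(width) || !is.finite(height) || width <= 0 || height <= 0) {
    abort("`width` and `height` must be single positive numbers (nm).")
  }
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "coloc_window")
}

#' @export
print.coloc_window <- function(x, ...) {
  cat(sprintf("<study window %g x %g nm>\n", x$width, x$height))
  invisible(x)
}

#' Colocalization distance band
#'
#' The half-open annulus of distances \eqn{[r', r'')} within which an A--B
#' particle pair counts as a colocalizing pair.  The lower limit may be 0,
#' in which case the band is a disc.
#'
#' @param r_lo Lower distance limit \eqn{r'} in nm (inclusive), `>= 0`.
#' @param r_hi Upper distance limit \eqn{r''} in nm (exclusive), `> r_lo`.
#'
#' @return A `coloc_band` object.
#' @examples
#' distance_band(25, 125)
#' @export
distance_band <- function(r_lo, r_hi) {
  if (!is.numeric(r_lo) || !is.numeric(r_hi) ||
      length(r_lo) != 1L || length(r_hi) != 1L ||
      !is.finite(r_lo) || !is.finite(r_hi) || r_lo < 0 || r_hi <= r_lo) {
    abort("Need 0 <= r_lo < r_hi (nm).")
  }
  structure(list(r_lo = as.numeric(r_lo), r_hi = as.numeric(r_hi)),
            class = "coloc_band")
}

#' @export
print.coloc_band <- function(x, ...) {
  cat(sprintf("<distance band [%g, %g) nm>\n", x$r_lo, x$r_hi))
  invisible(x)
}

as_band <- function(band) {
  if (inherits(band, "coloc_band")) return(band)
  if (is.numeric(band) && length(band) == 2L) {
    return(distance_band(band[[1]], band[[2]]))
  }
  abort("`band` must be a distance_band() or a numeric length-2 vector.")
}

as_window <- function(window) {
  if (inherits(window, "coloc_window")) return(window)
  if (is.numeric(window) && length(window) == 2L) {
    return(study_window(window[[1]], window[[2]]))
  }
  abort("`window` must be a study_window() or a numeric length-2 vector.")
}

#' Boundary-correction weight of a point
#'
#' Fraction of the distance annulus around a particle that falls inside the
#' study window.  Particles near the image boundary lose part of their
#' annulus; dividing their pair counts by this weight compensates for the
#' unobservable area.  With `mode = "none"` every weight is exactly 1.
#'
#' The `"annulus_fraction"` weight is
#' \deqn{w(x) = \frac{|A(x, r', r'') \cap W|}{\pi (r''^2 - r'^2)}}
#' computed from the exact circle--rectangle intersection area.  A
#' deterministic angular quadrature (`quadrature = TRUE`) is available as an
#' independent cross-check of the exact geometry.
#'
#' @param x,y Point coordinates in nm (vectorised); must lie inside the
#'   window.
#' @param band A [distance_band()].
#' @param window A [study_window()].
#' @param mode `"none"` or `"annulus_fraction"`.
#' @param quadrature If `TRUE`, use the 3600-point angular quadrature
#'   instead of the exact geometry.
#' @param quadrature_points Number of angular nodes for the quadrature.
#'
#' @return Numeric vector of weights in (0, 1].
#' @examples
#' w <- study_window(1000, 1000)
#' edge_weight(500, 500, distance_band(0, 50), w)   # interior: 1
#' edge_weight(0, 0, distance_band(0, 50), w)       # corner: 0.25
#' @export
edge_weight <- function(x, y, band, window,
                        mode = c("annulus_fraction", "none"),
                        quadrature = FALSE, quadrature_points = 3600L) {
  mode <- match.arg(mode)
  band <- as_band(band)
  window <- as_window(window)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  bad <- x < 0 | x > window$width | y < 0 | y > window$height
  if (any(bad)) {
    abort(sprintf("point outside window (first offending index: %d)",
                  which(bad)[1]))
  }
  if (mode == "none") return(rep(1, length(x)))
  if (quadrature) {
    return(annulus_fraction_quadrature(x, y, band, window, quadrature_points))
  }
  denom <- pi * (band$r_hi^2 - band$r_lo^2)
  a_hi <- disc_rect_area_cpp(x, y, band$r_hi, window$width, window$height)
  a_lo <- if (band$r_lo > 0) {
    disc_rect_area_cpp(x, y, band$r_lo, window$width, window$height)
  } else {
    0
  }
  pmin((a_hi - a_lo) / denom, 1)
}

# Angular quadrature of the annulus-inside fraction: for each of n angles,
# the radial segment [r_lo, r_hi] is intersected with the window and the
# inside radial measure r dr is accumulated.  Used only as a cross-check.
annulus_fraction_quadrature <- function(x, y, band, window, n = 3600L) {
  theta <- (seq_len(n) - 0.5) / n * 2 * pi
  ct <- cos(theta); st <- sin(theta)
  vapply(seq_along(x), function(i) {
    # max inside radius along each ray, clipped by the four window edges
    tmax <- rep(Inf, n)
    ray_clip <- function(num, den) {
      # constraint den * t <= num for t >= 0
      lim <- ifelse(den > 0, num / den, Inf)
      lim[den > 0 & num < 0] <- 0
      lim
    }
    tmax <- pmin(tmax, ray_clip(window$width - x[i], ct))
    tmax <- pmin(tmax, ray_clip(x[i], -ct))
    tmax <- pmin(tmax, ray_clip(window$height - y[i], st))
    tmax <- pmin(tmax, ray_clip(y[i], -st))
    hi <- pmin(tmax, band$r_hi)
    lo <- pmin(tmax, band$r_lo)
    sum(pmax(hi^2 - lo^2, 0)) / (n * (band$r_hi^2 - band$r_lo^2))
  }, numeric(1))
}
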