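#' Pair cross-correlation curve
#'
#' For each distance bin \eqn{[r_1, r_2)} and each image, the number of
#' A--B pairs at a distance in the bin is divided by its expectation under
#' complete spatial randomness,
#' \eqn{n_i^A n_i^B \, \pi (r_2^2 - r_1^2) / |W|}; the curve `g` is the
#' unweighted mean of these per-image ratios over all images with
#' \eqn{n_i^A n_i^B > 0} (others are skipped and recorded).  Values above
#' 1 indicate more pairs at that distance than expected for independent
#' random labels.  With `edge = "annulus_fraction"` each pair is counted
#' as \eqn{1/w} with \eqn{w} the A particle's annulus-inside fraction for
#' that bin, which makes the per-bin estimator exactly unbiased under
#' CSR; with `edge = "none"` (default) the raw count is used and `g`
#' drifts below 1 at distances comparable to the window size.
#'
#' @inheritParams cc3
#' @param bin_width Width of the uniform distance bins, nm.
#' @param r_max Upper end of the last bin, nm (rounded up to a whole
#'   number of bins).
#' @return A tibble with one row per bin: `r_lo`, `r_hi`, `g`; the
#'   per-image curves are kept in the `per_image` attribute.
#' @export
pccf_curve <- function(particles, bin_width = 25, r_max = 500,
                       edge = c("none", "annulus_fraction")) {
  edge <- match.arg(edge)
  prep <- pccf_prepare(particles, bin_width, r_max, edge)
  gmat <- vapply(prep$images, function(im) {
    pccf_g_image(im, im$xb, im$yb, prep)
  }, numeric(prep$n_bins))
  gmat <- matrix(gmat, nrow = prep$n_bins)
  out <- tibble(r_lo = prep$edges[-length(prep$edges)],
                r_hi = prep$edges[-1],
                g = rowMeans(gmat))
  attr(out, "per_image") <- gmat
  attr(out, "skipped") <- prep$skipped
  out
}

pccf_prepare <- function(particles, bin_width, r_max, edge) {
  if (!is.numeric(bin_width) || bin_width <= 0 || r_max < bin_width) {
    abort("need bin_width > 0 and r_max >= bin_width")
  }
  n_bins <- as.integer(ceiling(r_max / bin_width - 1e-9))
  edges <- bin_width * (0:n_bins)
  imgs <- split_images(particles)
  keep <- vapply(imgs, function(im) length(im$xa) > 0 && length(im$xb) > 0,
                 logical(1))
  skipped <- vapply(imgs, `[[`, character(1), "image_id")[!keep]
  imgs <- imgs[keep]
  if (length(imgs) == 0) {
    abort("every image has n_A * n_B = 0; the curve is undefined")
  }
  imgs <- lapply(imgs, function(im) {
    area <- im$window$width * im$window$height
    im$expect <- length(im$xa) * length(im$xb) *
      pi * diff(edges^2) / area
    if (edge == "annulus_fraction") {
      im$invw <- vapply(seq_len(n_bins), function(b) {
        1 / edge_weight(im$xa, im$ya, distance_band(edges[b], edges[b + 1]),
                        im$window, mode = "annulus_fraction")
      }, numeric(length(im$xa)))
      im$invw <- matrix(im$invw, nrow = length(im$xa))
    }
    im
  })
  list(images = imgs, edges = edges, n_bins = n_bins,
       bin_width = bin_width, edge = edge, skipped = skipped)
}

pccf_g_image <- function(im, xb, yb, prep) {
  counts <- if (prep$edge == "annulus_fraction") {
    cross_bin_counts_weighted_cpp(im$xa, im$ya, xb, yb,
                                  prep$bin_width, prep$n_bins, im$invw)
  } else {
    as.numeric(cross_bin_counts_cpp(im$xa, im$ya, xb, yb,
                                    prep$bin_width, prep$n_bins))
  }
  counts / im$expect
}

#' Pair cross-correlation function with Monte-Carlo CSR envelopes
#'
#' Computes the observed pair cross-correlation curve ([pccf_curve()])
#' and a pointwise two-sided Monte-Carlo envelope under the null of no
#' association: in each of `n_sims` simulations the B particles of every
#' image are replaced by a uniform CSR sample of the same size in the
#' same window (the A pattern is kept fixed, so each pattern's own
#' clustering is conditioned on), the curve is recomputed, and the
#' per-bin empirical quantiles at \eqn{(1-level)/2} and
#' \eqn{1-(1-level)/2} across simulations form the envelope bounds.
#' The envelope is *pointwise*, not simultaneous: under the null about
#' \eqn{1-level} of bins individually fall outside it.
#'
#' @inheritParams pccf_curve
#' @param n_sims Number of null simulations (at least 19).
#' @param seed Mandatory integer seed; results are bit-reproducible.
#' @param level Two-sided envelope level, e.g. 0.95.
#' @return A `pccf_result` object: list with `bins` (tibble `r_lo`,
#'   `r_hi`, `g`, `lower`, `upper`), `parameters`, and per-image observed
#'   curves under `per_image`.  Methods: [tidy()], `autoplot()`,
#'   `print()`; feed to [significant_bands()] to extract the distance
#'   band for the colocalization coefficients.
#' @examples
#' p <- simulate_patterns("csr", n_images = 4, seed = 7)
#' r <- pccf(p, r_max = 200, n_sims = 19, seed = 1)
#' significant_bands(r)
#' @export
pccf <- function(particles, bin_width = 25, r_max = 500,
                 edge = c("none", "annulus_fraction"),
                 n_sims = 999, seed, level = 0.95) {
  edge <- match.arg(edge)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    abort("`seed` is mandatory")
  }
  if (n_sims < 19) abort("`n_sims` must be at least 19")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1)")
  prep <- pccf_prepare(particles, bin_width, r_max, edge)
  gmat <- vapply(prep$images, function(im) {
    pccf_g_image(im, im$xb, im$yb, prep)
  }, numeric(prep$n_bins))
  gmat <- matrix(gmat, nrow = prep$n_bins)
  obs <- tibble(r_lo = prep$edges[-length(prep$edges)],
                r_hi = prep$edges[-1],
                g = rowMeans(gmat))
  withr::local_seed(as.integer(seed))
  sims <- matrix(NA_real_, nrow = n_sims, ncol = prep$n_bins)
  for (s in seq_len(n_sims)) {
    acc <- numeric(prep$n_bins)
    for (im in prep$images) {
      nb <- length(im$xb)
      xb <- runif(nb, 0, im$window$width)
      yb <- runif(nb, 0, im$window$height)
      acc <- acc + pccf_g_image(im, xb, yb, prep)
    }
    sims[s, ] <- acc / length(prep$images)
  }
  alpha <- (1 - level) / 2
  k <- max(1L, as.integer(floor(alpha * (n_sims + 1))))
  sorted <- apply(sims, 2, sort)
  bins <- obs |>
    mutate(lower = sorted[k, ], upper = sorted[n_sims + 1L - k, ])
  structure(list(
    bins = bins,
    parameters = list(bin_width = bin_width, r_max = prep$n_bins * bin_width,
                      edge_mode = edge, n_sims = n_sims,
                      seed = as.integer(seed), level = level,
                      envelope = "pointwise",
                      k = length(prep$images),
                      skipped = prep$skipped,
                      version = as.character(packageVersion("emcoloc"))),
    per_image = gmat
  ), class = "pccf_result")
}

#' @export
print.pccf_result <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "PCCF: %d image(s), %g-nm bins to %g nm, %d CSR sims, %g%% pointwise envelope\n",
    p$k, p$bin_width, p$r_max, p$n_sims, 100 * p$level))
  print(x$bins, n = 8)
  invisible(x)
}

#' @rdname pccf
#' @param x A `pccf_result` object.
#' @param ... Unused.
#' @export
tidy.pccf_result <- function(x, ...) as_tibble(x$bins)

#' Plot a pair cross-correlation curve with its envelope
#'
#' @param object A `pccf_result` object.
#' @param ... Unused.
#' @return A ggplot object: observed curve, shaded pointwise CSR
#'   envelope, and the reference level 1.
#' @export
autoplot.pccf_result <- function(object, ...) {
  df <- object$bins |> mutate(r_mid = (.data$r_lo + .data$r_hi) / 2)
  ggplot(df, aes(x = .data$r_mid)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "grey80") +
    geom_hline(yintercept = 1, linetype = 2) +
    geom_line(aes(y = .data$g)) +
    labs(x = "distance (nm)", y = "pair cross-correlation g",
         title = sprintf("PCCF with %g%% pointwise CSR envelope (%d sims)",
                         100 * object$parameters$level,
                         object$parameters$n_sims)) +
    theme_minimal()
}

#' Distance bands where the curve exceeds the CSR envelope
#'
#' Returns the maximal runs of contiguous bins whose observed `g` lies
#' strictly above the upper envelope bound, merged into distance bands.
#' These are the candidate colocalization bands to feed into
#' [em_coloc()].
#'
#' @param result A `pccf_result` object.
#' @return A tibble with columns `r_lo`, `r_hi` (one row per band);
#'   zero rows when no bin is significant.
#' @export
significant_bands <- function(result) {
  if (!inherits(result, "pccf_result")) abort("need a pccf_result object")
  b <- result$bins
  sig <- b$g > b$upper
  if (!any(sig)) return(tibble(r_lo = numeric(), r_hi = numeric()))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  tibble(r_lo = b$r_lo[starts[runs]], r_hi = b$r_hi[ends[runs]])
}
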