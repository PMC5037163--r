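#' Stage-1 frequency coefficients
#'
#' Characterises the average particle content per image: the average
#' absolute number of particles of both types,
#' \deqn{CC_1^{abs(A+B)} = \frac{1}{k}\sum_i (n_i^A + n_i^B),}
#' and the average per-image proportions of each type,
#' \deqn{CC_1^{rel(A)} = \frac{1}{k}\sum_i \frac{n_i^A}{n_i^A + n_i^B}}
#' (and likewise for B).  Images with no particles at all are excluded
#' from the proportion averages (their ratio is undefined); the effective
#' image count is reported.
#'
#' @inheritParams find_pairs
#' @return A one-row tibble: `cc1_abs`, `cc1_rel_a`, `cc1_rel_b`, `k`
#'   (number of images), `k_rel` (images entering the proportion
#'   averages).
#' @examples
#' p <- worked_example()
#' cc1(p$particles)   # 7, 4/7, 3/7
#' @export
cc1 <- function(particles) {
  tab <- image_counts(particles)
  if (nrow(tab) == 0) abort("no images in particle table")
  tot <- tab$n_a + tab$n_b
  ok <- tot > 0
  if (!any(ok)) abort("all images are empty; relative frequencies undefined")
  tibble(cc1_abs = mean(tot),
         cc1_rel_a = mean(tab$n_a[ok] / tot[ok]),
         cc1_rel_b = mean(tab$n_b[ok] / tot[ok]),
         k = nrow(tab), k_rel = sum(ok))
}

image_counts <- function(particles) {
  imgs <- split_images(particles)
  bind_rows(map(imgs, function(im) {
    tibble(image_id = im$image_id, n_a = length(im$xa), n_b = length(im$xb))
  }))
}

#' Stage-2 relative aggregated colocalization
#'
#' The average fraction of particles of one type that colocalize with at
#' least one particle of the other type:
#' \deqn{CC_2^A = \frac{1}{k}\sum_i \frac{n_i^{colA}}{n_i^A}}
#' where \eqn{n_i^{colA}} counts A particles having at least one B
#' particle within the distance band.  `cc2_a` and `cc2_b` are not
#' complementary (their sum is in general not 1).  Images with
#' \eqn{n_i^A = 0} are excluded from the `cc2_a` average (and analogously
#' for B); if every image is excluded the coefficient is undefined and an
#' error is raised.
#'
#' @inheritParams find_pairs
#' @return A one-row tibble: `cc2_a`, `cc2_b`, `k_a`, `k_b` (effective
#'   image counts per coefficient).
#' @examples
#' p <- worked_example()
#' cc2(p$particles, p$band)   # 3/4, 2/3
#' @export
cc2 <- function(particles, band) {
  pc <- pair_counts(particles, band)
  if (nrow(pc) == 0) abort("no images in particle table")
  ok_a <- pc$n_a > 0
  ok_b <- pc$n_b > 0
  if (!any(ok_a)) abort("cc2_a undefined: every image has n_A = 0")
  if (!any(ok_b)) abort("cc2_b undefined: every image has n_B = 0")
  tibble(cc2_a = mean(pc$n_col_a[ok_a] / pc$n_a[ok_a]),
         cc2_b = mean(pc$n_col_b[ok_b] / pc$n_b[ok_b]),
         k_a = sum(ok_a), k_b = sum(ok_b))
}

#' Summary colocalization coefficients
#'
#' Combines the stage-1 proportions with the stage-2 colocalization
#' fractions into four summary measures partitioning the average image:
#' \deqn{CC^{coloc}_{A/(A+B)} = CC_1^{rel(A)} \cdot CC_2^A, \qquad
#'       CC^{non\text{-}coloc}_{A/(A+B)} = CC_1^{rel(A)} \cdot (1 - CC_2^A)}
#' and analogously for B.  When `cc1_rel_a + cc1_rel_b = 1` the four
#' values sum exactly to 1.
#'
#' @param cc1_rel_a,cc1_rel_b,cc2_a,cc2_b Coefficient values in `[0, 1]`.
#' @return A one-row tibble: `coloc_a`, `noncoloc_a`, `coloc_b`,
#'   `noncoloc_b`.
#' @examples
#' summary_coefficients(4 / 7, 3 / 7, 3 / 4, 2 / 3)
#' @export
summary_coefficients <- function(cc1_rel_a, cc1_rel_b, cc2_a, cc2_b) {
  vals <- c(cc1_rel_a, cc1_rel_b, cc2_a, cc2_b)
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1)) {
    abort("all inputs must lie in [0, 1]")
  }
  tibble(coloc_a = cc1_rel_a * cc2_a,
         noncoloc_a = cc1_rel_a * (1 - cc2_a),
         coloc_b = cc1_rel_b * cc2_b,
         noncoloc_b = cc1_rel_b * (1 - cc2_b))
}

#' Stage-3 relative density of colocalization
#'
#' The average fraction of opposite-type particles paired with an average
#' colocalizing particle:
#' \deqn{CC_3^{B/A} = \frac{1}{k}\sum_i \sum_j \frac{1}{w(x_{ij}^A)}
#'   \cdot \frac{\sum_q I(r' \le d(x_{ij}^A, x_{iq}^B) < r'')}
#'              {n_i^{colA} \cdot n_i^B}}
#' and symmetrically for \eqn{CC_3^{A/B}}.  The weight \eqn{w} is the
#' optional boundary correction of [edge_weight()]; with
#' `edge = "none"` (the default) every weight is 1 and
#' \eqn{CC_3^{B/A} \in [0, 1]}.  Images where \eqn{n_i^{colA} \cdot
#' n_i^B = 0} contribute 0 to the sum (the numerator is then necessarily
#' zero) but still count in the outer \eqn{1/k}.
#'
#' @inheritParams find_pairs
#' @param edge Edge-correction mode, `"none"` or `"annulus_fraction"`.
#' @return A one-row tibble: `cc3_ba`, `cc3_ab`, `k`.
#' @examples
#' p <- worked_example()
#' cc3(p$particles, p$band)   # 4/9, 1/2
#' @export
cc3 <- function(particles, band, edge = c("none", "annulus_fraction")) {
  edge <- match.arg(edge)
  band <- as_band(band)
  imgs <- split_images(particles)
  if (length(imgs) == 0) abort("no images in particle table")
  terms <- map(imgs, function(im) cc3_image_terms(im, band, edge))
  tibble(cc3_ba = mean(map_dbl(terms, "ba")),
         cc3_ab = mean(map_dbl(terms, "ab")),
         k = length(imgs))
}

cc3_image_terms <- function(im, band, edge) {
  one_side <- function(xa, ya, xb, yb) {
    cnt <- neighbour_counts_cpp(xa, ya, xb, yb, band$r_lo, band$r_hi)
    n_col <- sum(cnt > 0L)
    if (n_col == 0L || length(xb) == 0L) return(0)
    w <- if (edge == "none") rep(1, length(xa)) else
      edge_weight(xa, ya, band, im$window, mode = "annulus_fraction")
    sum((cnt / w)) / (n_col * length(xb))
  }
  list(ba = one_side(im$xa, im$ya, im$xb, im$yb),
       ab = one_side(im$xb, im$yb, im$xa, im$ya))
}

#' Full colocalization coefficient pipeline
#'
#' Runs all three coefficient stages on a particle table under one
#' distance band and collects per-image values, image-averaged aggregates
#' and per-coefficient effective image counts into a single object.
#' The aggregate summary coefficients are formed from the aggregate
#' stage-1 and stage-2 values, so the algebraic identities checked by
#' [verify_identities()] hold exactly whenever no image was excluded from
#' any average.
#'
#' @inheritParams cc3
#' @return A `coloc_coefficients` object: a list with `parameters`
#'   (band, edge mode, k, package version), `per_image` (tibble of
#'   per-image counts and coefficients), `aggregate` (named numeric
#'   vector) and `effective_k` (named integer vector).  Methods:
#'   [tidy()], [glance()], `autoplot()`, `print()`.
#' @examples
#' p <- worked_example()
#' fit <- em_coloc(p$particles, p$band)
#' glance(fit)
#' @export
em_coloc <- function(particles, band, edge = c("none", "annulus_fraction")) {
  edge <- match.arg(edge)
  band <- as_band(band)
  pc <- pair_counts(particles, band)
  if (nrow(pc) == 0) abort("no images in particle table")
  imgs <- split_images(particles)
  terms <- map(imgs, function(im) cc3_image_terms(im, band, edge))

  per_image <- pc |>
    mutate(cc1_abs = .data$n_a + .data$n_b,
           cc1_rel_a = ifelse(.data$cc1_abs > 0,
                              .data$n_a / .data$cc1_abs, NA_real_),
           cc1_rel_b = ifelse(.data$cc1_abs > 0,
                              .data$n_b / .data$cc1_abs, NA_real_),
           cc2_a = ifelse(.data$n_a > 0,
                          .data$n_col_a / .data$n_a, NA_real_),
           cc2_b = ifelse(.data$n_b > 0,
                          .data$n_col_b / .data$n_b, NA_real_),
           coloc_a = .data$cc1_rel_a * .data$cc2_a,
           noncoloc_a = .data$cc1_rel_a * (1 - .data$cc2_a),
           coloc_b = .data$cc1_rel_b * .data$cc2_b,
           noncoloc_b = .data$cc1_rel_b * (1 - .data$cc2_b),
           cc3_ba = map_dbl(terms, "ba"),
           cc3_ab = map_dbl(terms, "ab"))

  c1 <- cc1(particles)
  c2 <- cc2(particles, band)
  sm <- summary_coefficients(c1$cc1_rel_a, c1$cc1_rel_b, c2$cc2_a, c2$cc2_b)
  c3 <- cc3(particles, band, edge)

  aggregate <- c(cc1_abs = c1$cc1_abs,
                 cc1_rel_a = c1$cc1_rel_a, cc1_rel_b = c1$cc1_rel_b,
                 cc2_a = c2$cc2_a, cc2_b = c2$cc2_b,
                 coloc_a = sm$coloc_a, noncoloc_a = sm$noncoloc_a,
                 coloc_b = sm$coloc_b, noncoloc_b = sm$noncoloc_b,
                 cc3_ba = c3$cc3_ba, cc3_ab = c3$cc3_ab)

  structure(list(
    parameters = list(r_lo = band$r_lo, r_hi = band$r_hi,
                      edge_mode = edge, k = nrow(pc),
                      version = as.character(packageVersion("emcoloc"))),
    per_image = per_image,
    aggregate = aggregate,
    effective_k = c(cc1_abs = nrow(pc),
                    cc1_rel_a = c1$k_rel, cc1_rel_b = c1$k_rel,
                    cc2_a = c2$k_a, cc2_b = c2$k_b,
                    cc3_ba = c3$k, cc3_ab = c3$k)
  ), class = "coloc_coefficients")
}

#' @export
print.coloc_coefficients <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("EM colocalization coefficients: %d image(s), band [%g, %g) nm, edge %s\n",
              p$k, p$r_lo, p$r_hi, p$edge_mode))
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Tidy per-image coefficient values
#'
#' @param x A `coloc_coefficients` object.
#' @param ... Unused.
#' @return A long tibble with columns `image_id`, `coefficient`, `value`.
#' @export
tidy.coloc_coefficients <- function(x, ...) {
  x$per_image |>
    tidyr::pivot_longer(-"image_id", names_to = "coefficient",
                        values_to = "value")
}

#' One-row aggregate summary of a coefficient set
#'
#' @param x A `coloc_coefficients` object.
#' @param ... Unused.
#' @return A one-row tibble of the image-averaged coefficients plus `k`.
#' @export
glance.coloc_coefficients <- function(x, ...) {
  dplyr::bind_cols(as_tibble(as.list(x$aggregate)),
                   tibble(k = x$parameters$k))
}

#' Stacked-bar view of the summary coefficients
#'
#' Shows, for each label, the colocalizing and non-colocalizing fraction
#' of the average image (the four summary coefficients, which sum to 1).
#'
#' @param object A `coloc_coefficients` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coloc_coefficients <- function(object, ...) {
  agg <- object$aggregate
  df <- tibble(
    label = factor(c("A", "A", "B", "B")),
    fraction = factor(c("colocalizing", "non-colocalizing",
                        "colocalizing", "non-colocalizing"),
                      levels = c("non-colocalizing", "colocalizing")),
    value = unname(agg[c("coloc_a", "noncoloc_a", "coloc_b", "noncoloc_b")]))
  ggplot(df, aes(x = .data$label, y = .data$value, fill = .data$fraction)) +
    geom_col() +
    labs(x = "label", y = "fraction of particles in the average image",
         fill = NULL,
         title = sprintf("Summary colocalization, band [%g, %g) nm",
                         object$parameters$r_lo, object$parameters$r_hi)) +
    theme_minimal()
}

#' Check the intrinsic algebraic identities of a coefficient set
#'
#' The coefficient system satisfies five exact identities: the four
#' summary coefficients sum to 1; the colocalizing and non-colocalizing
#' fractions of each label sum to that label's stage-1 proportion; and
#' each stage-2 coefficient equals the ratio of the label's colocalizing
#' summary fraction to its stage-1 proportion.  Residuals are reported,
#' never raised.  When images were excluded from some averages
#' (per-coefficient effective counts differ from k) the identities hold
#' only approximately and the result is flagged accordingly.
#'
#' @param cs A `coloc_coefficients` object.
#' @param tol Pass tolerance for each absolute residual.
#' @return A tibble with columns `identity`, `residual`, `pass`, and an
#'   attribute `exact` (FALSE when exclusions make the identities
#'   approximate).
#' @examples
#' p <- worked_example()
#' verify_identities(em_coloc(p$particles, p$band))
#' @export
verify_identities <- function(cs, tol = 1e-12) {
  a <- as.list(cs$aggregate)
  res <- tibble(
    identity = c("summary coefficients sum to 1",
                 "coloc_a + noncoloc_a = cc1_rel_a",
                 "coloc_b + noncoloc_b = cc1_rel_b",
                 "cc2_a = coloc_a / cc1_rel_a",
                 "cc2_b = coloc_b / cc1_rel_b"),
    residual = c(
      a$coloc_a + a$noncoloc_a + a$coloc_b + a$noncoloc_b - 1,
      a$coloc_a + a$noncoloc_a - a$cc1_rel_a,
      a$coloc_b + a$noncoloc_b - a$cc1_rel_b,
      a$coloc_a / a$cc1_rel_a - a$cc2_a,
      a$coloc_b / a$cc1_rel_b - a$cc2_b))
  res$pass <- abs(res$residual) <= tol
  # with per-coefficient exclusions the identities are only approximate
  attr(res, "exact") <- all(cs$effective_k == cs$parameters$k)
  res
}
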