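#' Find colocalizing A--B pairs
#'
#' Enumerates, per image, every cross-label pair (j, q) whose Euclidean
#' distance d satisfies `r_lo <= d < r_hi` (strictly half-open, exact
#' floating comparison).  Each such pair is a *colocalizing pair*; a
#' particle belonging to at least one pair is a *colocalizing particle*.
#'
#' @param particles A `coloc_particles` tibble (see [read_particles()]).
#' @param band A [distance_band()] or numeric `c(r_lo, r_hi)` in nm.
#'
#' @return A tibble with one row per colocalizing pair: `image_id`, `a`
#'   (index of the A particle within its image, by row order), `b`
#'   (likewise for B) and `distance` (nm).
#' @examples
#' p <- worked_example()
#' find_pairs(p$particles, p$band)
#' @export
find_pairs <- function(particles, band) {
  band <- as_band(band)
  imgs <- split_images(particles)
  rows <- map(imgs, function(im) {
    pr <- cross_pairs_cpp(im$xa, im$ya, im$xb, im$yb, band$r_lo, band$r_hi)
    tibble(image_id = rep(im$image_id, length(pr$a)),
           a = pr$a, b = pr$b, distance = pr$d)
  })
  bind_rows(rows)
}

#' Per-image pair and colocalizing-particle counts
#'
#' Summarises the colocalization structure of every image under a band:
#' particle counts of each type, the number of colocalizing pairs, the
#' per-type counts of colocalizing particles (particles in at least one
#' pair), and the sum of per-particle neighbour counts, which equals the
#' pair count from either side (pair symmetry).
#'
#' @inheritParams find_pairs
#' @return A tibble with one row per image: `image_id`, `n_a`, `n_b`,
#'   `n_pairs`, `n_col_a`, `n_col_b`.
#' @export
pair_counts <- function(particles, band) {
  band <- as_band(band)
  imgs <- split_images(particles)
  bind_rows(map(imgs, function(im) {
    ca <- neighbour_counts_cpp(im$xa, im$ya, im$xb, im$yb,
                               band$r_lo, band$r_hi)
    cb <- neighbour_counts_cpp(im$xb, im$yb, im$xa, im$ya,
                               band$r_lo, band$r_hi)
    tibble(image_id = im$image_id,
           n_a = length(im$xa), n_b = length(im$xb),
           n_pairs = sum(ca),
           n_col_a = sum(ca > 0L), n_col_b = sum(cb > 0L))
  }))
}
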