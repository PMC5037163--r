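#' Simulate dual-labeled point patterns
#'
#' Generates image stacks under the statistical structures the
#' colocalization coefficients assume:
#'
#' * `"csr"` — A and B are independent homogeneous Poisson processes in
#'   the window (complete spatial randomness, the null model);
#' * `"linked"` — A is Poisson; each B particle is, with probability
#'   `link_probability`, attached to a uniformly chosen A particle at a
#'   position drawn uniformly from the `link_band` annulus around it
#'   (positions falling outside the window are re-drawn, keeping the
#'   particle count), and otherwise placed uniformly in the window;
#' * `"thomas"` — a bivariate cluster process: Poisson parents, and each
#'   label's particles are Gaussian displacements of a parent
#'   (`offspring_mean` expected offspring per parent per label,
#'   displacement sd `offspring_sd`; out-of-window draws re-drawn).
#'
#' Defaults mirror a typical immunogold EM acquisition: 21 images of
#' 2000 x 2000 nm with on average 14 A and 13 B particles per image.
#'
#' @param process One of `"csr"`, `"linked"`, `"thomas"`.
#' @param window A [study_window()] (one window for all images).
#' @param intensity_a,intensity_b Expected points per nm^2 for labels A
#'   and B (`csr`, `linked`).
#' @param link_probability Probability that a B particle is linked to an
#'   A parent (`linked` only).
#' @param link_band A [distance_band()]: the annulus in which a linked B
#'   is placed around its parent (`linked` only).
#' @param parent_intensity Expected cluster parents per nm^2 (`thomas`).
#' @param offspring_mean Expected offspring per parent per label
#'   (`thomas`).
#' @param offspring_sd Gaussian displacement sd in nm (`thomas`).
#' @param n_images Number of images in the stack.
#' @param seed Mandatory integer seed; the generator is fully
#'   deterministic given the seed and leaves the global RNG state
#'   untouched.
#'
#' @return A `coloc_particles` tibble (see [read_particles()]) with
#'   images `img001`, `img002`, ...
#' @examples
#' simulate_patterns("csr", n_images = 2, seed = 1)
#' @export
simulate_patterns <- function(process = c("csr", "linked", "thomas"),
                              window = study_window(2000, 2000),
                              intensity_a = 14 / (2000 * 2000),
                              intensity_b = 13 / (2000 * 2000),
                              link_probability = 1,
                              link_band = distance_band(25, 75),
                              parent_intensity = 3 / (2000 * 2000),
                              offspring_mean = 5,
                              offspring_sd = 50,
                              n_images = 21,
                              seed) {
  process <- match.arg(process)
  window <- as_window(window)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    abort("`seed` is mandatory and must be a single integer")
  }
  if (link_probability < 0 || link_probability > 1) {
    abort("`link_probability` must be in [0, 1]")
  }
  area <- window$width * window$height
  expected <- switch(process,
    csr = ,
    linked = (intensity_a + intensity_b) * area * n_images,
    thomas = 2 * parent_intensity * area * offspring_mean * n_images)
  if (expected > 1e7) {
    abort(sprintf("refusing to simulate ~%.3g expected points (> 1e7)",
                  expected))
  }
  withr::local_seed(as.integer(seed))
  ids <- sprintf("img%03d", seq_len(n_images))
  rows <- lapply(ids, function(id) {
    im <- switch(process,
      csr = sim_csr(window, intensity_a, intensity_b),
      linked = sim_linked(window, intensity_a, intensity_b,
                          link_probability, as_band(link_band)),
      thomas = sim_thomas(window, parent_intensity, offspring_mean,
                          offspring_sd))
    tibble(image_id = id,
           label = factor(rep(c("A", "B"), c(length(im$xa), length(im$xb))),
                          levels = c("A", "B")),
           x = c(im$xa, im$xb), y = c(im$ya, im$yb))
  })
  new_particles(bind_rows(rows),
                tibble(image_id = NA_character_, width = window$width,
                       height = window$height))
}

runif_window <- function(n, window) {
  list(x = runif(n, 0, window$width), y = runif(n, 0, window$height))
}

sim_csr <- function(window, ia, ib) {
  area <- window$width * window$height
  na <- rpois(1, ia * area); nb <- rpois(1, ib * area)
  a <- runif_window(na, window); b <- runif_window(nb, window)
  list(xa = a$x, ya = a$y, xb = b$x, yb = b$y)
}

sim_linked <- function(window, ia, ib, p, band) {
  # p = 0 delegates to the CSR sampler so that, seed-matched, the two
  # processes are bit-identical (they are the same distribution).
  if (p == 0) return(sim_csr(window, ia, ib))
  area <- window$width * window$height
  na <- rpois(1, ia * area); nb <- rpois(1, ib * area)
  a <- runif_window(na, window)
  xb <- numeric(nb); yb <- numeric(nb)
  linked <- if (nb > 0) runif(nb) < p else logical(0)
  if (na == 0) linked[] <- FALSE  # nothing to link to
  for (q in seq_len(nb)) {
    if (linked[q]) {
      parent <- if (na == 1) 1L else sample.int(na, 1L)
      repeat {
        r <- sqrt(runif(1, band$r_lo^2, band$r_hi^2))
        th <- runif(1, 0, 2 * pi)
        px <- a$x[parent] + r * cos(th)
        py <- a$y[parent] + r * sin(th)
        if (px >= 0 && px <= window$width && py >= 0 &&
            py <= window$height) break
      }
      xb[q] <- px; yb[q] <- py
    } else {
      xb[q] <- runif(1, 0, window$width)
      yb[q] <- runif(1, 0, window$height)
    }
  }
  list(xa = a$x, ya = a$y, xb = xb, yb = yb)
}

sim_thomas <- function(window, ip, mu, sd) {
  area <- window$width * window$height
  np <- rpois(1, ip * area)
  par <- runif_window(np, window)
  one_label <- function() {
    if (np == 0) return(list(x = numeric(), y = numeric()))
    counts <- rpois(np, mu)
    xs <- numeric(sum(counts)); ys <- numeric(sum(counts))
    k <- 0L
    for (i in seq_len(np)) {
      for (j in seq_len(counts[i])) {
        repeat {
          px <- par$x[i] + rnorm(1, 0, sd)
          py <- par$y[i] + rnorm(1, 0, sd)
          if (px >= 0 && px <= window$width && py >= 0 &&
              py <= window$height) break
        }
        k <- k + 1L
        xs[k] <- px; ys[k] <- py
      }
    }
    list(x = xs, y = ys)
  }
  a <- one_label(); b <- one_label()
  list(xa = a$x, ya = a$y, xb = b$x, yb = b$y)
}

#' Worked-example pattern: four A and three B particles
#'
#' A packaged single-image pattern reproducing the adjacency structure of
#' the coefficient system's standard worked example under its declared
#' distance band \eqn{[0, 50)} nm: four colocalizing pairs (A2--B1,
#' A2--B3, A3--B1, A4--B1), colocalizing particles \{A2, A3, A4\} and
#' \{B1, B3\}.  All coefficients on this image have simple closed forms:
#' \eqn{CC_1^{abs} = 7}, \eqn{CC_1^{rel} = (4/7, 3/7)},
#' \eqn{CC_2 = (3/4, 2/3)}, \eqn{CC_3 = (4/9, 1/2)}.
#'
#' The coordinates are a construction of this package (any placement with
#' the same adjacency gives identical coefficients); no pair distance is
#' within 1\% of a band boundary.
#'
#' @return A list with elements `particles` (a `coloc_particles` tibble),
#'   `window` (200 x 200 nm) and `band` (`[0, 50)` nm).
#' @examples
#' p <- worked_example()
#' em_coloc(p$particles, p$band)
#' @export
worked_example <- function() {
  window <- study_window(200, 200)
  df <- tibble(
    image_id = "img1",
    label = factor(c("A", "A", "A", "A", "B", "B", "B"),
                   levels = c("A", "B")),
    # A1 isolated; A2 near B1 and B3; A3, A4 near B1 only; B2 isolated
    x = c(180, 70, 100, 130, 100, 20, 40),
    y = c(180, 100, 140, 100, 100, 180, 80))
  list(particles = new_particles(df, tibble(image_id = NA_character_,
                                            width = 200, height = 200)),
       window = window,
       band = distance_band(0, 50))
}
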