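test_that("a single pair lands in exactly its distance bin", {
  df <- tibble::tibble(image_id = "i",
                       label = factor(c("A", "B"), levels = c("A", "B")),
                       x = c(100, 160), y = c(100, 100))
  p <- as_particles(df, study_window(1000, 1000))
  curve <- pccf_curve(p, bin_width = 25, r_max = 200)
  hot <- curve$g > 0
  expect_equal(sum(hot), 1)
  expect_equal(curve$r_lo[hot], 50)
  expect_equal(curve$r_hi[hot], 75)
})

test_that("the edge-weighted estimator is centred on 1 under CSR", {
  p <- simulate_patterns("csr", window = study_window(2000, 2000),
                         intensity_a = 200 / 4e6, intensity_b = 200 / 4e6,
                         n_images = 100, seed = 2024)
  curve <- pccf_curve(p, bin_width = 25, r_max = 500,
                      edge = "annulus_fraction")
  far <- curve$r_lo >= 50
  expect_true(all(abs(curve$g[far] - 1) < 0.1))
})

test_that("uncorrected long-range bias shrinks as the window grows", {
  mk <- function(side, seed) {
    simulate_patterns("csr", window = study_window(side, side),
                      intensity_a = 100 / side^2, intensity_b = 100 / side^2,
                      n_images = 200, seed = seed)
  }
  band_mean <- function(p) {
    curve <- pccf_curve(p, bin_width = 25, r_max = 150)
    mean(curve$g[curve$r_lo >= 50])
  }
  small <- band_mean(mk(2000, 31))
  large <- band_mean(mk(4000, 32))
  expect_lt(abs(large - 1), 0.05)       # long-range limit approaches 1
  expect_lt(abs(large - 1), abs(small - 1))  # bias decreases with window size
})

test_that("a linked process is enriched in its generative annulus", {
  p <- simulate_patterns("linked", link_band = distance_band(25, 75),
                         link_probability = 1, n_images = 21, seed = 5)
  curve <- pccf_curve(p, bin_width = 25, r_max = 500)
  g_link <- mean(curve$g[curve$r_lo >= 25 & curve$r_hi <= 75])
  g_far <- mean(curve$g[curve$r_lo >= 200])
  expect_gte(g_link, 3 * g_far)
})

test_that("the curve is symmetric under label exchange without edge weights", {
  withr::local_seed(61)
  p <- random_stack(3)
  df <- tibble::as_tibble(p)
  swapped <- dplyr::mutate(df, label = factor(ifelse(label == "A", "B", "A"),
                                              levels = c("A", "B")))
  p2 <- as_particles(swapped, study_window(1000, 1000))
  expect_equal(pccf_curve(p2, 25, 300)$g, pccf_curve(p, 25, 300)$g)
})

test_that("envelopes are deterministic in the seed and obey rank arithmetic", {
  p <- simulate_patterns("csr", n_images = 5, seed = 9)
  r1 <- pccf(p, r_max = 200, n_sims = 19, seed = 123)
  r2 <- pccf(p, r_max = 200, n_sims = 19, seed = 123)
  expect_identical(r1$bins, r2$bins)
  r3 <- pccf(p, r_max = 200, n_sims = 19, seed = 124)
  expect_false(identical(r1$bins$upper, r3$bins$upper))

  # with 19 simulations at level 0.95 the envelope is the per-bin min/max
  prep <- emcoloc:::pccf_prepare(p, 25, 200, "none")
  withr::with_seed(123L, {
    sims <- matrix(NA_real_, 19, prep$n_bins)
    for (s in 1:19) {
      acc <- numeric(prep$n_bins)
      for (im in prep$images) {
        nb <- length(im$xb)
        xb <- runif(nb, 0, im$window$width)
        yb <- runif(nb, 0, im$window$height)
        acc <- acc + emcoloc:::pccf_g_image(im, xb, yb, prep)
      }
      sims[s, ] <- acc / length(prep$images)
    }
    expect_equal(r1$bins$lower, apply(sims, 2, min))
    expect_equal(r1$bins$upper, apply(sims, 2, max))
  })
})

test_that("pointwise envelope coverage under CSR is near the nominal rate", {
  p <- simulate_patterns("csr", window = study_window(2000, 2000),
                         intensity_a = 50 / 4e6, intensity_b = 50 / 4e6,
                         n_images = 20, seed = 42)
  res <- pccf(p, bin_width = 25, r_max = 500, n_sims = 999, seed = 43)
  outside <- res$bins$g > res$bins$upper | res$bins$g < res$bins$lower
  expect_lt(mean(outside), 0.15)
})

test_that("significant band extraction merges runs and is strict", {
  p <- simulate_patterns("csr", n_images = 3, seed = 14)
  res <- pccf(p, r_max = 100, n_sims = 19, seed = 15)
  # g equal to the upper bound everywhere: nothing is significant
  res$bins$g <- res$bins$upper
  expect_equal(nrow(significant_bands(res)), 0)
  # two contiguous hot bins merge into one band
  res$bins$g <- res$bins$upper
  res$bins$g[res$bins$r_lo %in% c(25, 50)] <-
    res$bins$upper[res$bins$r_lo %in% c(25, 50)] + 1
  bands <- significant_bands(res)
  expect_equal(nrow(bands), 1)
  expect_equal(bands$r_lo, 25)
  expect_equal(bands$r_hi, 75)
})

test_that("a linked process exceeds the envelope across its annulus", {
  p <- simulate_patterns("linked", link_band = distance_band(25, 75),
                         link_probability = 1, n_images = 21, seed = 77)
  res <- pccf(p, bin_width = 25, r_max = 300, n_sims = 199, seed = 78)
  inside <- res$bins$r_lo >= 25 & res$bins$r_hi <= 75
  expect_true(all(res$bins$g[inside] > res$bins$upper[inside]))
  bands <- significant_bands(res)
  expect_true(any(bands$r_lo < 75 & bands$r_hi > 25))
})

test_that("images without both labels are skipped and reported", {
  df <- tibble::tibble(
    image_id = c("i1", "i1", "i2"),
    label = factor(c("A", "B", "A"), levels = c("A", "B")),
    x = c(100, 150, 100), y = c(100, 100, 100))
  p <- as_particles(df, study_window(1000, 1000))
  curve <- pccf_curve(p, 25, 100)
  expect_equal(attr(curve, "skipped"), "i2")
  only_a <- as_particles(df[3, ], study_window(1000, 1000))
  expect_error(pccf_curve(only_a, 25, 100), "undefined")
})

test_that("pccf results expose tidy, plot and print methods", {
  p <- simulate_patterns("csr", n_images = 3, seed = 1)
  res <- pccf(p, r_max = 100, n_sims = 19, seed = 2)
  td <- tidy(res)
  expect_true(all(c("r_lo", "r_hi", "g", "lower", "upper") %in% names(td)))
  expect_true(all(td$lower <= td$upper))
  expect_s3_class(autoplot(res), "ggplot")
  expect_output(print(res), "pointwise envelope")
  expect_equal(res$parameters$envelope, "pointwise")
})
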