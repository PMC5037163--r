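test_that("worked-example pattern reproduces the known pair structure", {
  p <- worked_example()
  pairs <- find_pairs(p$particles, p$band)
  expect_equal(nrow(pairs), 4)
  expect_setequal(paste(pairs$a, pairs$b),
                  c("2 1", "2 3", "3 1", "4 1"))
  pc <- pair_counts(p$particles, p$band)
  expect_equal(pc$n_col_a, 3)
  expect_equal(pc$n_col_b, 2)
  # per-particle neighbour counts from the pair list
  expect_equal(tabulate(pairs$a, 4), c(0, 2, 1, 1))
  expect_equal(tabulate(pairs$b, 3), c(3, 0, 1))
  # no pair distance within 1% of the band boundary
  expect_true(all(abs(pairs$distance - 50) / 50 > 0.01))
})

test_that("the distance band is half-open: r_lo in, r_hi out", {
  w <- study_window(1000, 1000)
  mk <- function(bx) as_particles(
    tibble::tibble(image_id = "i", label = factor(c("A", "B")),
                   x = c(0, bx), y = c(0, 0)), w)
  band <- distance_band(25, 125)
  expect_equal(nrow(find_pairs(mk(125), band)), 0)  # at r_hi: excluded
  expect_equal(nrow(find_pairs(mk(25), band)), 1)   # at r_lo: included
  expect_equal(nrow(find_pairs(mk(24.999), band)), 0)
})

test_that("pair finding agrees with the brute-force double loop", {
  withr::local_seed(101)
  band <- distance_band(25, 125)
  for (rep in 1:25) {
    na <- sample(0:200, 1); nb <- sample(0:200, 1)
    xa <- runif(na, 0, 1000); ya <- runif(na, 0, 1000)
    xb <- runif(nb, 0, 1000); yb <- runif(nb, 0, 1000)
    df <- tibble::tibble(
      image_id = "i",
      label = factor(rep(c("A", "B"), c(na, nb)), levels = c("A", "B")),
      x = c(xa, xb), y = c(ya, yb))
    got <- find_pairs(as_particles(df, study_window(1000, 1000)), band)
    want <- oracle_pairs(xa, ya, xb, yb, 25, 125)
    expect_setequal(paste(got$a, got$b), paste(want$a, want$b))
  }
})

test_that("stage-1 coefficients average counts and proportions per image", {
  p <- worked_example()
  c1 <- cc1(p$particles)
  expect_equal(c1$cc1_abs, 7)
  expect_equal(c1$cc1_rel_a, 4 / 7)
  expect_equal(c1$cc1_rel_b, 3 / 7)

  # single-label image
  one <- as_particles(tibble::tibble(image_id = "i",
                                     label = factor(rep("A", 5),
                                                    levels = c("A", "B")),
                                     x = 1:5, y = 1:5),
                      study_window(10, 10))
  expect_equal(unlist(cc1(one)[1, 1:3]),
               c(cc1_abs = 5, cc1_rel_a = 1, cc1_rel_b = 0))

  # two images (2,2) and (6,2): average of ratios, not ratio of sums
  two <- as_particles(tibble::tibble(
    image_id = rep(c("i1", "i2"), c(4, 8)),
    label = factor(c("A", "A", "B", "B", rep("A", 6), "B", "B"),
                   levels = c("A", "B")),
    x = 1:12, y = 1:12), study_window(20, 20))
  c1 <- cc1(two)
  expect_equal(c1$cc1_abs, (4 + 8) / 2)
  expect_equal(c1$cc1_rel_a, (0.5 + 0.75) / 2)
})

test_that("stage-2 coefficients match the worked example and handle zeros", {
  p <- worked_example()
  c2 <- cc2(p$particles, p$band)
  expect_equal(c2$cc2_a, 3 / 4)
  expect_equal(c2$cc2_b, 2 / 3)

  # no B particles: cc2_a is 0 for that image, cc2_b undefined -> error
  only_a <- as_particles(tibble::tibble(image_id = "i",
                                        label = factor(rep("A", 3),
                                                       levels = c("A", "B")),
                                        x = 1:3, y = 1:3),
                         study_window(10, 10))
  expect_error(cc2(only_a, distance_band(0, 5)), "cc2_b undefined")

  # an image with only-B rows: excluded from cc2_a but not cc2_b
  df2 <- dplyr::bind_rows(
    tibble::as_tibble(p$particles),
    tibble::tibble(image_id = "bonly",
                   label = factor("B", levels = c("A", "B")),
                   x = 100, y = 100))
  c2b <- cc2(as_particles(df2, study_window(200, 200)), p$band)
  expect_equal(c2b$k_a, 1)
  expect_equal(c2b$k_b, 2)
  expect_equal(c2b$cc2_a, 3 / 4)        # only the first image counts
  expect_equal(c2b$cc2_b, (2 / 3) / 2)  # lone B colocalizes with nothing
})

test_that("summary coefficients obey the product definitions and sum to one", {
  sm <- summary_coefficients(4 / 7, 3 / 7, 3 / 4, 2 / 3)
  expect_equal(sm$coloc_a, 3 / 7)
  expect_equal(sm$noncoloc_a, 1 / 7)
  expect_equal(sm$coloc_b, 2 / 7)
  expect_equal(sm$noncoloc_b, 1 / 7)

  # no colocalization: coloc terms vanish, noncoloc terms carry cc1_rel
  sm0 <- summary_coefficients(0.3, 0.7, 0, 0)
  expect_equal(unlist(sm0), c(coloc_a = 0, noncoloc_a = 0.3,
                              coloc_b = 0, noncoloc_b = 0.7))

  withr::local_seed(5)
  for (i in 1:100) {
    ra <- runif(1)
    sm <- summary_coefficients(ra, 1 - ra, runif(1), runif(1))
    expect_equal(sum(unlist(sm)), 1, tolerance = 1e-12)
  }
  expect_error(summary_coefficients(1.2, 0.3, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("identity report passes on a clean pipeline and flags corruption", {
  p <- worked_example()
  fit <- em_coloc(p$particles, p$band)
  rep <- verify_identities(fit)
  expect_true(all(rep$pass))
  expect_true(all(abs(rep$residual) <= 1e-12))
  expect_true(attr(rep, "exact"))

  bad <- fit
  bad$aggregate[["coloc_a"]] <- bad$aggregate[["coloc_a"]] + 0.01
  rep2 <- verify_identities(bad)
  expect_equal(rep2$pass, c(FALSE, FALSE, TRUE, FALSE, TRUE))
})

test_that("pair symmetry holds: counts agree from the A and B side", {
  withr::local_seed(21)
  for (i in 1:20) {
    p <- random_stack(2, min_n = 0)
    pc <- pair_counts(p, distance_band(25, 125))
    pairs <- find_pairs(p, distance_band(25, 125))
    for (r in seq_len(nrow(pc))) {
      expect_equal(pc$n_pairs[r], sum(pairs$image_id == pc$image_id[r]))
    }
  }
})

test_that("enlarging r_hi never decreases cc2", {
  withr::local_seed(31)
  for (i in 1:10) {
    p <- random_stack(3)
    r_his <- c(50, 100, 150, 200)
    vals <- sapply(r_his, function(rh) unlist(cc2(p, c(25, rh))[1, 1:2]))
    expect_true(all(diff(vals["cc2_a", ]) >= 0))
    expect_true(all(diff(vals["cc2_b", ]) >= 0))
  }
})

test_that("swapping the labels swaps the paired coefficients exactly", {
  withr::local_seed(41)
  p <- random_stack(3)
  df <- tibble::as_tibble(p)
  swapped <- dplyr::mutate(df, label = factor(ifelse(label == "A", "B", "A"),
                                              levels = c("A", "B")))
  band <- distance_band(25, 125)
  a1 <- em_coloc(p, band)$aggregate
  a2 <- em_coloc(as_particles(swapped, study_window(1000, 1000)),
                 band)$aggregate
  expect_equal(a2[["cc2_a"]], a1[["cc2_b"]])
  expect_equal(a2[["cc2_b"]], a1[["cc2_a"]])
  expect_equal(a2[["cc1_rel_a"]], a1[["cc1_rel_b"]])
  expect_equal(a2[["coloc_a"]], a1[["coloc_b"]])
  expect_equal(a2[["noncoloc_b"]], a1[["noncoloc_a"]])
  expect_equal(a2[["cc3_ba"]], a1[["cc3_ab"]])
  expect_equal(a2[["cc3_ab"]], a1[["cc3_ba"]])
})

test_that("tidy, glance and autoplot expose the fitted coefficients", {
  p <- worked_example()
  fit <- em_coloc(p$particles, p$band)
  td <- tidy(fit)
  expect_true(all(c("image_id", "coefficient", "value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$cc2_a, 3 / 4)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "band \\[0, 50\\)")
})
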