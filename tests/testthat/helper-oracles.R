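# Independent brute-force oracles: literal transcriptions of the coefficient
# definitions (double/triple loops, no shared code with the implementation).

oracle_pairs <- function(xa, ya, xb, yb, r_lo, r_hi) {
  a <- integer(0); b <- integer(0)
  for (j in seq_along(xa)) {
    for (q in seq_along(xb)) {
      d <- sqrt((xa[j] - xb[q])^2 + (ya[j] - yb[q])^2)
      if (r_lo <= d && d < r_hi) {
        a <- c(a, j); b <- c(b, q)
      }
    }
  }
  list(a = a, b = b)
}

# one image's contribution to CC2^A: sum_j f(x_j^A) / n_A
oracle_cc2_image <- function(xa, ya, xb, yb, r_lo, r_hi) {
  if (length(xa) == 0) return(NA_real_)
  f_sum <- 0
  for (j in seq_along(xa)) {
    s <- 0
    for (q in seq_along(xb)) {
      d <- sqrt((xa[j] - xb[q])^2 + (ya[j] - yb[q])^2)
      s <- s + as.integer(r_lo <= d && d < r_hi)
    }
    if (s > 0) f_sum <- f_sum + 1
  }
  f_sum / length(xa)
}

# one image's contribution to CC3^{B/A} (weights identically 1):
# sum_j [ sum_q I ] / (n_colA * n_B)
oracle_cc3_image <- function(xa, ya, xb, yb, r_lo, r_hi) {
  counts <- integer(length(xa))
  for (j in seq_along(xa)) {
    s <- 0L
    for (q in seq_along(xb)) {
      d <- sqrt((xa[j] - xb[q])^2 + (ya[j] - yb[q])^2)
      if (r_lo <= d && d < r_hi) s <- s + 1L
    }
    counts[j] <- s
  }
  n_col <- sum(counts > 0L)
  if (n_col == 0L || length(xb) == 0L) return(0)
  sum(counts) / (n_col * length(xb))
}

# Random stack of k images in a common window; every image gets at least
# min_n particles of each type so that no coefficient average excludes
# an image.
random_stack <- function(k, window = study_window(1000, 1000),
                         min_n = 1, max_n = 30) {
  rows <- lapply(seq_len(k), function(i) {
    na <- sample(min_n:max_n, 1)
    nb <- sample(min_n:max_n, 1)
    tibble::tibble(
      image_id = sprintf("img%03d", i),
      label = factor(rep(c("A", "B"), c(na, nb)), levels = c("A", "B")),
      x = stats::runif(na + nb, 0, window$width),
      y = stats::runif(na + nb, 0, window$height))
  })
  as_particles(dplyr::bind_rows(rows), window)
}

model_masks <- function() {
  # 32-pixel grid: 24 A pixels, 12 B pixels, 4 overlapping
  a <- matrix(0, 4, 8); a[1:3, ] <- 1
  b <- matrix(0, 4, 8); b[4, ] <- 1; b[3, 1:4] <- 1
  list(a = a, b = b)
}
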