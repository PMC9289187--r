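# Independent oracle: exhaustive between-class-variance search over every
# candidate bin edge, written from the definition.
otsu_bruteforce <- function(x, n_bins = 256L) {
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  best_t <- NA_real_
  best_v <- -Inf
  for (b in seq_len(n_bins - 1L)) {
    t <- edges[b + 1L]
    # assign by bin, matching the histogram construction
    bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
    lo <- x[bin <= b]; hi <- x[bin > b]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x)
    # class means over bin midpoints, as in the histogram formulation
    mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
    m0 <- mean(mids[bin[bin <= b]]); m1 <- mean(mids[bin[bin > b]])
    v <- w0 * (1 - w0) * (m0 - m1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

test_that("otsu_threshold equals the exhaustive maximizer on two-valued data", {
  x <- c(rep(10, 900), rep(200, 100))
  v <- voxel_grid(array(x, c(10, 10, 10)), c(3, 0.5, 0.5))
  t <- otsu_threshold(v)
  expect_gt(t, 10); expect_lt(t, 200)
  expect_equal(t, otsu_bruteforce(x))
})

test_that("otsu_threshold matches the brute-force oracle on randomized data", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(200:2000, 1)
    x <- c(rnorm(n, 50, sample(2:20, 1)),
           rnorm(sample(50:500, 1), sample(100:300, 1), sample(2:30, 1)))
    x <- pmax(x, 0)
    nb <- sample(c(64L, 128L, 256L), 1)
    expect_equal(otsu_threshold(x, nb), otsu_bruteforce(x, nb))
  }
})

test_that("constant images raise a degenerate-histogram error", {
  expect_error(otsu_threshold(array(7, c(4, 4, 4))), "degenerate")
})

test_that("the threshold is shift-equivariant up to one bin width", {
  set.seed(5)
  x <- c(rnorm(500, 30, 5), rnorm(100, 120, 10))
  nb <- 256L
  binw <- diff(range(x)) / nb
  for (shift in c(13.7, 100, -5)) {
    expect_lte(abs(otsu_threshold(x + shift, nb) - otsu_threshold(x, nb) - shift),
               binw + 1e-9)
  }
})
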