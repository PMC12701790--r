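test_that("lag-product array matches the brute-force double loop", {
  expect_equal(lagProductArray(numeric(8)), matrix(0, 8, 15),
               ignore_attr = TRUE)
  imp <- c(0, 1, 0, 0)
  A <- lagProductArray(imp)
  expect_equal(unname(A[2, 4]), 1)  # lag 0 at the impulse time
  A[2, 4] <- 0
  expect_true(all(A == 0))
  set.seed(5)
  x <- rnorm(16)
  expect_equal(lagProductArray(x), lagArrayBrute(x), ignore_attr = TRUE)
  expect_error(lagProductArray(c(1, NaN, 2)), "non-finite")
})

test_that("plain WVD equals the direct-sum evaluation and is zero for zero input", {
  expect_equal(wvdPlain(numeric(6)), matrix(0, 6, 6))
  set.seed(11)
  for (rep in 1:3) {
    x <- rnorm(16)
    expect_equal(wvdPlain(x), wvdDirect(x), tolerance = 1e-8)
  }
})

test_that("WVD time marginal is proportional to |x(n)|^2 with constant N", {
  # summing e^{-2*pi*i*k*m/N} over k kills every lag but m = 0, leaving N * x(n)^2
  set.seed(3)
  for (N in c(15, 16, 33)) {
    x <- rnorm(N)
    expect_equal(rowSums(wvdPlain(x)), N * x^2, tolerance = 1e-10)
  }
})

test_that("kaiser window matches the Bessel-series formula and its degenerate cases", {
  expect_equal(kaiserWindow(1, 3), 1)
  expect_equal(kaiserWindow(5, 0), rep(1, 5))
  # even sizes are bumped to the next odd integer for a well-defined centre
  w <- kaiserWindow(8, 0.5)
  expect_length(w, 9)
  expect_equal(w, kaiserDirect(9, 0.5), tolerance = 1e-12)
  expect_equal(w, rev(w))
  expect_equal(w[5], 1)
  expect_true(all(w > 0 & w <= 1))
  expect_error(kaiserWindow(0), "integer")
  expect_error(kaiserWindow(5, -1), "nonnegative")
})

test_that("swvd equals the direct-sum oracle for random signals and windows", {
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(32)
    g <- kaiserWindow(11, 0.5)
    H <- kaiserWindow(15, 0.5)
    expect_equal(swvd(x, g = g, H = H), swvdDirect(x, g, H), tolerance = 1e-8)
  }
})

test_that("degenerate smoothing reduces swvd to |plain WVD|", {
  set.seed(8)
  for (N in c(17, 24)) {
    x <- rnorm(N)
    H <- rep(1, 2 * ((N - 1) %/% 2) + 1)  # all-ones over the full lag support
    expect_equal(swvd(x, g = 1, H = H), abs(wvdPlain(x)))
    expect_equal(swvd(numeric(N), g = 5, H = 7), matrix(0, N, N))
  }
})

test_that("swvd output is nonnegative and finite everywhere", {
  set.seed(13)
  for (rep in 1:5) {
    x <- rnorm(sample(16:40, 1)) * 10^sample(-2:2, 1)
    S <- swvd(x, g = 7, H = 11)
    expect_true(all(is.finite(S)))
    expect_true(all(S >= 0))
  }
})

test_that("swvd validates its windows and input", {
  expect_error(swvd(rnorm(16), g = 21), "longer than the signal")
  expect_error(swvd(c(rnorm(15), NA)), "non-finite")
  expect_error(swvd(rnorm(16), g = c(0.5, 1, 0.5, 0.2)), "odd length")
})

test_that("a sinusoid localizes at its doubled frequency bin", {
  N <- 64
  interior <- 9:(N - 8)
  set.seed(17)
  for (rep in 1:4) {
    k0 <- sample(2:14, 1)
    x <- makeTone(N, k0, runif(1, 0, 2 * pi))
    # plain WVD: read off the analytic-signal form (the real-signal WVD has a
    # DC interference line between the +/- frequency components)
    bins <- tfArgmaxBins(wvdPlain(x, analytic = TRUE))
    expect_true(all(abs(bins[interior] - 2 * k0) <= 1))
    # smoothed WVD: time smoothing suppresses the oscillating DC line
    S <- swvd(x, g = 21, H = 21)
    expect_true(all(abs(tfArgmaxBins(S)[interior] - 2 * k0) <= 1))
  }
})

test_that("Kaiser smoothing suppresses the two-tone cross term", {
  N <- 64
  x <- makeTone(N, 6) + makeTone(N, 18)
  Wp <- abs(wvdPlain(x)); Wp <- Wp / max(Wp)
  midband <- (6 + 18) + (-1:1) + 1   # doubled midpoint frequency columns
  for (seed in 1:5) {
    M <- sampleWindowSizes(N, seed)
    S <- swvd(x, g = M[2], H = M[2]); S <- S / max(S)
    expect_lt(max(S[, midband]), max(Wp[, midband]))
  }
})
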