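test_that("window-size sampling obeys the uniform ranges and ordering", {
  draws <- t(vapply(1:500, function(s) sampleWindowSizes(100, s), integer(3)))
  expect_true(all(draws[, 1] >= 29 & draws[, 1] <= 51))
  expect_true(all(draws[, 2] >= 49 & draws[, 2] <= 71))
  expect_true(all(draws[, 3] >= 69 & draws[, 3] <= 91))
  expect_true(all(draws[, 1] <= draws[, 2] & draws[, 2] <= draws[, 3]))
  expect_true(all(draws %% 2 == 1))
  expect_identical(sampleWindowSizes(100, 7), sampleWindowSizes(100, 7))
  expect_error(sampleWindowSizes(9, 1), "integer >= 10")
})

test_that("wigner encoding is channel-wise identical to standalone swvd calls", {
  set.seed(2)
  x <- rnorm(64)
  tens <- encodeWigner(x, seed = 5)
  M <- attr(tens, "window_sizes")
  expect_identical(M, sampleWindowSizes(64, 5))
  for (i in 1:3)
    expect_identical(tens[, , i], swvd(x, g = M[i], H = M[i]))
  expect_true(all(tens >= 0))
  expect_equal(dim(tens), c(64L, 64L, 3L))
  expect_equal(encodeWigner(numeric(16), seed = 1), array(0, c(16, 16, 3)),
               ignore_attr = TRUE)
})

test_that("different seeds draw different window triples (ensemble diversity)", {
  triples <- vapply(1:20, function(s) sampleWindowSizes(64, s), integer(3))
  expect_gt(ncol(unique(t(triples))), 1)
})

test_that("quadrant composition equals block assembly of per-segment encodings", {
  set.seed(4)
  x <- rnorm(256)
  comp <- quadrantCompose(x, seed = 9)
  expect_equal(dim(comp), c(128L, 128L, 3L))
  seeds <- wvdimage:::.subSeeds(9, 4)
  segs <- split(x, rep(1:4, each = 64))
  tl <- encodeWigner(segs[[1]], seed = seeds[1])
  br <- encodeWigner(segs[[4]], seed = seeds[4])
  expect_identical(comp[1:64, 1:64, ], unclass(tl)[, , ])
  expect_identical(comp[65:128, 65:128, ], unclass(br)[, , ])
  expect_equal(attr(comp, "window_sizes")[1, ], attr(tl, "window_sizes"))
})

test_that("identical segments with a shared window triple give identical quadrants", {
  set.seed(6)
  seg <- rnorm(40)
  comp <- quadrantCompose(rep(seg, 4), seed = 3, share_windows = TRUE)
  expect_identical(comp[1:40, 1:40, ], comp[41:80, 41:80, ])
  expect_identical(comp[1:40, 41:80, ], comp[41:80, 1:40, ])
  expect_equal(quadrantCompose(numeric(160), seed = 1),
               array(0, c(80, 80, 3)), ignore_attr = TRUE)
})

test_that("quadrant composition zero-pads lengths not divisible by four", {
  x <- rnorm(250)                       # segments of ceiling(250/4) = 63
  comp <- quadrantCompose(x, seed = 1)
  expect_equal(dim(comp)[1:2], c(126L, 126L))
  expect_error(quadrantCompose(rnorm(20)), "length >= 40")
})

test_that("reshape encoder is a padded row-major bijection with 3 equal channels", {
  tens <- encodeReshape(1:9)
  expect_equal(tens[, , 1], matrix(1:9, 3, 3, byrow = TRUE))
  expect_identical(tens[, , 1], tens[, , 2])
  expect_identical(tens[, , 1], tens[, , 3])
  t8 <- encodeReshape(1:8)
  expect_equal(t8[3, 3, 1], 0)          # padded last cell
  # round-trip: flattening channel 0 row-major and dropping the pad recovers x
  set.seed(1)
  x <- rnorm(23)
  tr <- encodeReshape(x)
  expect_equal(as.vector(t(tr[, , 1]))[seq_along(x)], x)
})

test_that("cwt encoder localizes a sinusoid at the matching scale", {
  L <- 64
  x <- sin(2 * pi * (0:(L - 1)) / 8)    # period 8
  tens <- encodeCwt(x)
  expect_equal(dim(tens), c(L, L, 3L))
  expect_true(all(tens >= 0))
  scales <- attr(tens, "scales")
  for (i in 1:3) {
    best <- scales[which.max(rowSums(tens[, , i]^2))]
    omega0 <- c(5, 6, 8)[i]
    expected <- omega0 * 8 / (2 * pi)   # scale where the Morlet peak hits 2*pi/8
    step <- scales[2] / scales[1]
    expect_lt(abs(log(best / expected)), 1.5 * log(step))
  }
  expect_equal(encodeCwt(numeric(16)), array(0, c(16, 16, 3)),
               ignore_attr = TRUE)
})

test_that("dwt encoder: vanishing moments, zero input, perfect reconstruction", {
  z <- encodeDwt(numeric(16))   # 16 coefficients tile a 4 x 4 grid
  expect_equal(z, array(0, c(4, 4, 3)), ignore_attr = TRUE)
  dec <- dwtMultilevel(rep(3, 64), family = "d4")
  expect_lt(max(abs(unlist(dec$detail))), 1e-10)
  expect_gt(max(abs(dec$approx)), 1)
  set.seed(9)
  for (fam in c("haar", "d4", "d6")) {
    x <- rnorm(100)
    expect_equal(idwtMultilevel(dwtMultilevel(x, fam)), x, tolerance = 1e-8)
  }
  tens <- encodeDwt(rnorm(64))
  expect_equal(dim(tens)[3], 3L)
  expect_equal(dim(tens)[1], dim(tens)[2])
})

test_that("0-255 normalization is train-anchored, unclipped, constant-safe", {
  train <- cbind(c(0, 1, 2), c(5, 5, 5))
  norm <- normalize0255(train)
  expect_equal(norm[, 1], c(0, 127.5, 255))
  expect_equal(norm[, 2], c(0, 0, 0))
  test <- matrix(c(3, 5), 1)
  expect_equal(normalize0255(train, test)[1, 1], 382.5)  # extrapolated, no clip
  # leakage: permuting the rows passed through apply_to never changes parameters
  set.seed(2)
  tr <- matrix(rnorm(50), 10)
  te <- matrix(rnorm(25), 5)
  n1 <- normalize0255(tr, te)
  n2 <- normalize0255(tr, te[sample(5), ])
  expect_identical(attr(n1, "shift"), attr(n2, "shift"))
  expect_identical(attr(n1, "scale"), attr(n2, "scale"))
})

test_that("feature permutation is seeded, shared across partitions, invertible", {
  set.seed(3)
  tr <- matrix(rnorm(40), 4); te <- matrix(rnorm(30), 3)
  p1 <- permuteFeatures(list(train = tr, test = te), seed = 42)
  p2 <- permuteFeatures(list(train = tr, test = te), seed = 42)
  expect_identical(attr(p1, "permutation"), attr(p2, "permutation"))
  perm <- attr(p1, "permutation")
  expect_identical(p1$train, tr[, perm])
  expect_identical(p1$test, te[, perm])        # same permutation on both
  inv <- order(perm)
  expect_identical(p1$train[, inv], tr)
})

test_that("bilinear resize preserves constants, bounds, and matches 1D interpolation", {
  const <- array(2.5, c(16, 16, 3))
  expect_equal(resizeToBackbone(const, 24), array(2.5, c(24, 24, 3)))
  set.seed(4)
  tens <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(resizeToBackbone(tens, 16), tens)
  up <- resizeToBackbone(tens, 48)
  expect_gte(min(up), min(tens))
  expect_lte(max(up), max(tens))
  expect_error(resizeToBackbone(tens, 4), "integer >= 8")
  # separable oracle: rows then columns through stats::approx on the same
  # centre-aligned sampling grid
  grid <- function(ns, nd) pmin(pmax((seq_len(nd) - 0.5) * ns / nd + 0.5, 1), ns)
  M <- tens[, , 1]
  tmp <- t(apply(M, 1, function(r) approx(seq_len(16), r, xout = grid(16, 48))$y))
  oracle <- apply(tmp, 2, function(cl) approx(seq_len(16), cl, xout = grid(16, 48))$y)
  expect_equal(up[, , 1], oracle, tolerance = 1e-12)
})

test_that("encoders are pure functions of (input, seed)", {
  set.seed(5)
  x <- rnorm(64)
  expect_identical(encodeWigner(x, seed = 3), encodeWigner(x, seed = 3))
  expect_identical(encodeCwt(x), encodeCwt(x))
  expect_identical(encodeDwt(x), encodeDwt(x))
  X <- matrix(rnorm(5 * 32), 5)
  expect_identical(encodeBatch(X, "wigner", seed = 2),
                   encodeBatch(X, "wigner", seed = 2))
})
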