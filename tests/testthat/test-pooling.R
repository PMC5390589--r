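test_that("binarize applies a strict Heaviside step", {
  expect_equal(binarize(matrix(-0.5, 3, 3)), matrix(0L, 3, 3))
  expect_equal(binarize(matrix(0.5, 3, 3)), matrix(1L, 3, 3))
  expect_equal(binarize(matrix(0, 3, 3)), matrix(0L, 3, 3))
  expect_error(binarize(matrix(1, 2, 2), source = "post_nt"), "unknown")
  # nt_centered thresholds at the map mean
  m <- matrix(c(1, 1, 1, 5), 2, 2)
  expect_equal(binarize(m, source = "nt_centered"),
               matrix(c(0L, 0L, 0L, 1L), 2, 2))
})

test_that("hashGroup combines bit-planes with powers of two", {
  ones <- replicate(8, matrix(1L, 4, 4), simplify = FALSE)
  zeros <- replicate(8, matrix(0L, 4, 4), simplify = FALSE)
  expect_equal(hashGroup(ones), matrix(255, 4, 4))
  expect_equal(hashGroup(zeros), matrix(0, 4, 4))
  onlyK3 <- zeros; onlyK3[[3]] <- matrix(1L, 4, 4)
  expect_equal(hashGroup(onlyK3), matrix(4, 4, 4))
  bad <- ones; bad[[2]] <- matrix(1L, 3, 3)
  expect_error(hashGroup(bad), "shape")
  # permuting the branch order permutes bit-planes but conserves pixels:
  # word counts change, total mass does not
  set.seed(61)
  bm <- replicate(8, matrix(rbinom(16, 1, 0.5), 4, 4), simplify = FALSE)
  h1 <- hashGroup(bm); h2 <- hashGroup(rev(bm))
  expect_equal(length(h1), length(h2))
  expect_false(isTRUE(all.equal(h1, h2)))   # order matters for words
  expect_true(all(h1 >= 0 & h1 <= 255) && all(h2 >= 0 & h2 <= 255))
})

test_that("rescaleHash maps per-image extremes to [0, 255]", {
  m <- matrix(0:255, 16, 16)
  expect_equal(rescaleHash(m), m)
  expect_equal(rescaleHash(matrix(7, 3, 3)), matrix(0, 3, 3))
  # half-away-from-zero rounding on the midpoint
  m2 <- matrix(c(0, 510, 255, 0), 2, 2)
  expect_equal(rescaleHash(m2), matrix(c(0, 255, 128, 0), 2, 2))
})

test_that("pyramid histograms partition counts level by level", {
  set.seed(62)
  hm <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  pf <- pyramidHistogram(hm, L = 2)
  expect_equal(dim(pf), c(21L, 256L))
  # conservation at every level
  expect_equal(sum(pf[1, ]), 1024)
  expect_equal(sum(pf[2:5, ]), 1024)
  expect_equal(sum(pf[6:21, ]), 1024)
  # level-0 histogram equals a direct tabulation
  expect_equal(pf[1, ], as.numeric(tabulate(as.integer(hm) + 1L, 256)))
  # level-1 top-left cell covers rows/cols 1..16
  expect_equal(pf[2, ], as.numeric(tabulate(as.integer(hm[1:16, 1:16]) + 1L,
                                            256)))
  expect_equal(dim(pyramidHistogram(hm, L = 0)), c(1L, 256L))
  cons <- pyramidHistogram(matrix(7L, 8, 8), L = 1)
  expect_true(all(cons[, 8] == c(64, rep(16, 4))))
  expect_true(all(cons[, -8] == 0))
  expect_error(pyramidHistogram(matrix(0L, 4, 4), L = 3), "exceeds")
})

test_that("uneven map sizes still conserve counts per level", {
  set.seed(63)
  hm <- matrix(sample(0:255, 11 * 13, replace = TRUE), 11, 13)
  pf <- pyramidHistogram(hm, L = 2)
  for (rows in list(1, 2:5, 6:21))
    expect_equal(sum(pf[rows, ]), 11 * 13)
})

test_that("high dispersal fixes the Frobenius norm at sigma", {
  set.seed(64)
  pf <- matrix(rpois(21 * 256, 2), 21, 256)
  out <- highDispersal(pf, sigma = 2.238)
  expect_equal(sqrt(sum(out^2)), 2.238, tolerance = 1e-9)
  unitish <- matrix(0, 3, 4); unitish[2, 2] <- 1
  expect_equal(highDispersal(unitish, 2.238)[2, 2], 2.238)
  expect_equal(highDispersal(matrix(0, 3, 4), 2.238), matrix(0, 3, 4))
  # no-sqrt variant divides by the bare sum of squares
  expect_equal(highDispersal(unitish, 2.238, useSqrt = FALSE)[2, 2], 2.238)
  expect_equal(highDispersal(2 * unitish, 1, useSqrt = FALSE)[2, 2], 0.5)
  expect_error(highDispersal(pf, -1), "sigma")
})

test_that("local response normalization follows the windowed formula", {
  # V2 = 1, single unit entry: 1 / (2 + 1e-4)^0.75
  f <- matrix(0, 2, 3); f[1, 2] <- 1
  out <- localResponseNormalize(list(f), gamma = 2, alpha = 1e-4,
                                beta = 0.75, nLrn = 5)
  expect_equal(out[[1]][1, 2], 1 / (2 + 1e-4)^0.75, tolerance = 1e-12)
  expect_equal(out[[1]][1, 2], 0.59458, tolerance = 1e-4)
  expect_equal(localResponseNormalize(list(matrix(0, 2, 2)),
                                      2, 1e-4, 0.75, 5)[[1]],
               matrix(0, 2, 2))
  # alpha = 0: uniform division by gamma^beta
  set.seed(65)
  fs <- replicate(4, matrix(rnorm(6), 2, 3), simplify = FALSE)
  out0 <- localResponseNormalize(fs, gamma = 3, alpha = 0, beta = 0.5,
                                 nLrn = 3)
  for (j in 1:4) expect_equal(out0[[j]], fs[[j]] / sqrt(3))
  # window clipping at the ends: direct recomputation for V2 = 3, n = 3
  out3 <- localResponseNormalize(fs[1:3], 2, 0.1, 0.75, 3)
  den1 <- (2 + 0.1 * (fs[[1]]^2 + fs[[2]]^2))^0.75
  expect_equal(out3[[1]], fs[[1]] / den1)
  den2 <- (2 + 0.1 * (fs[[1]]^2 + fs[[2]]^2 + fs[[3]]^2))^0.75
  expect_equal(out3[[2]], fs[[2]] / den2)
  bad <- fs; bad[[2]] <- matrix(0, 3, 3)
  expect_error(localResponseNormalize(bad, 2, 1e-4, 0.75, 5), "shape")
})

test_that("vectorize concatenates filters then cells then bins", {
  set.seed(66)
  fs <- replicate(2, matrix(rnorm(2 * 256), 2, 256), simplify = FALSE)
  v <- vectorizeFeatures(fs)
  expect_length(v, 2 * 2 * 256)
  expect_equal(v[1:256], fs[[1]][1, ])          # first cell's bins first
  expect_equal(v[257:512], fs[[1]][2, ])
  expect_equal(v[513:768], fs[[2]][1, ])
  # round-trip de-concatenation
  back <- lapply(0:1, function(j)
    matrix(v[j * 512 + 1:512], 2, 256, byrow = TRUE))
  expect_equal(back, fs)
})

test_that("extractFeatures meets the length contracts and ablations", {
  p <- netParams()
  imgs <- lapply(1:2, function(i) randomImage(32, seed = 70 + i))
  banks <- learnCascade(imgs, p)
  X <- extractFeatures(imgs, banks$bank1, banks$bank2, p)
  expect_equal(dim(X), c(2L, 43008L))
  expect_true(all(is.finite(X)))
  # determinism
  expect_identical(X, extractFeatures(imgs, banks$bank1, banks$bank2, p))
  # PCANet-style baseline: all four components off
  p0 <- netParams(useNT = FALSE, useMFA = FALSE, useHD = FALSE,
                  useLRN = FALSE)
  X0 <- extractFeatures(imgs, banks$bank1, banks$bank2, p0)
  expect_equal(ncol(X0), 8L * 256L)
  # raw counts in the baseline: every map histogram sums to 1024
  expect_equal(sum(X0[1, 1:256]), 1024)
  # constant image takes the degenerate all-zero-word path without error
  Xc <- extractFeatures(matrix(5, 32, 32), banks$bank1, banks$bank2, p)
  expect_equal(dim(Xc), c(1L, 43008L))
  expect_true(all(is.finite(Xc)))
})
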