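test_that("rolling-ball subtraction obeys its contract and preserves narrow spots", {
  # opening of flat = flat -> all zeros
  expect_true(all(rollingBallSubtract(matrix(11, 60, 60), 20) == 0))

  # narrow spot on zero background survives within 5% (oracle: direct
  # erosion + dilation with the same spherical-cap element is the
  # definition; here the background under a narrow peak must collapse)
  img <- matrix(0, 60, 60)
  img[30, 30] <- 80; img[30, 31] <- 60; img[29, 30] <- 60
  sub <- rollingBallSubtract(img, 20)
  expect_gt(sub[30, 30], 0.95 * 80)

  # bounded: 0 <= out <= in
  set.seed(1)
  r <- matrix(runif(80 * 80, 0, 50), 80, 80)
  s <- rollingBallSubtract(r, 15)
  expect_true(all(s >= 0) && all(s <= r + 1e-9))

  expect_error(rollingBallSubtract(matrix(0, 30, 30), 30), "radius")
})

test_that("difference-of-Gaussian filter is linear and kills constants", {
  expect_lt(max(abs(dogFilter(matrix(4, 40, 40), 1, 3))), 1e-6)

  img <- matrix(0, 41, 41); img[21, 21] <- 1
  # closed form: response equals difference of the two discrete kernels
  d <- dogFilter(img, 1, 4)
  k <- function(s) {
    g <- gaussianPreprocess(img, 2 * s)
    g
  }
  expect_equal(d, k(1) - k(4), tolerance = 1e-12)
  expect_gt(d[21, 21], 0)          # centre positive
  expect_lt(min(d), 0)             # surround negative

  # linearity
  set.seed(2)
  a <- matrix(runif(900), 30, 30)
  expect_equal(dogFilter(3 * a, 1, 2), 3 * dogFilter(a, 1, 2),
               tolerance = 1e-9)

  expect_error(dogFilter(a, 2, 2), "s1 < s2")
})

test_that("prominence maxima resolve peaks, valleys and plateaus as specified", {
  # single Gaussian spot: one maximum at the centre
  img <- matrix(0, 31, 31)
  xs <- matrix(0:30, 31, 31, byrow = TRUE); ys <- matrix(0:30, 31, 31)
  img <- 100 * exp(-((xs - 15)^2 + (ys - 15)^2) / (2 * 2^2))
  m <- findMaxima(img, 50)
  expect_identical(nrow(m), 1L)
  expect_lte(abs(m$x - 15) + abs(m$y - 15), 1)

  # two peaks with a controlled saddle: prominence gates the count
  prof <- matrix(0, 5, 21)
  peak <- c(rep(0, 3), seq(20, 100, length.out = 4), 80,
            seq(100, 20, length.out = 4), rep(0, 3))
  prof <- matrix(rep(c(0, 0, 100, 80, 100, 0, 0), each = 5), 5, 7)
  expect_identical(nrow(findMaxima(prof, 30)), 1L)  # saddle gap 20 < 30
  expect_identical(nrow(findMaxima(prof, 10)), 2L)

  # plateau: reported once at the centroid
  plat <- matrix(0, 9, 9); plat[4:6, 4:6] <- 5
  mp <- findMaxima(plat, 2)
  expect_identical(nrow(mp), 1L)
  expect_identical(c(mp$x, mp$y), c(4, 4))

  # constant image: none
  expect_identical(nrow(findMaxima(matrix(3, 8, 8), 1)), 0L)
})

test_that("prominence maxima agree exactly with the brute-force oracle", {
  set.seed(7)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 12 * 12, replace = TRUE), 12, 12)
    oracle <- oracle_prominences(img)
    for (p in c(1, 5, 20, 50)) {
      got <- findMaxima(img, p)
      want <- oracle[oracle$prominence >= p, , drop = FALSE]
      expect_identical(point_key(got), point_key(want))
    }
  }
})

test_that("prominence is monotone and the chain is offset-invariant", {
  set.seed(9)
  img <- matrix(sample(0:60, 24 * 24, replace = TRUE), 24, 24)
  prev <- findMaxima(img, 1)
  for (p in c(5, 10, 20)) {
    cur <- findMaxima(img, p)
    expect_lte(nrow(cur), nrow(prev))
    expect_true(all(point_key(cur) %in% point_key(prev)))
    prev <- cur
  }

  # offset invariance of subtract + DoG
  a <- matrix(runif(50 * 50, 0, 30), 50, 50)
  f1 <- dogFilter(rollingBallSubtract(a, 10), 1, 3)
  f2 <- dogFilter(rollingBallSubtract(a + 17, 10), 1, 3)
  expect_lt(max(abs(f1 - f2)), 1e-6)
})

test_that("the probe registry reproduces the published settings table", {
  reg <- probeRegistry()
  expect_identical(reg$probe, c("E2", "E7/8", "Cre", "Fev", "Gad2"))
  gad2 <- probeSettings("Gad2")
  expect_identical(c(gad2@s1, gad2@s2, gad2@prominence), c(0.25, 16, 150))
  e2 <- probeSettings("E2")
  expect_identical(c(e2@s1, e2@s2, e2@prominence), c(0.25, 1, 175))
  e78 <- probeSettings("E7/8")
  expect_identical(c(e78@s1, e78@s2, e78@prominence), c(0.5, 1, 100))
  cre <- probeSettings("Cre")
  expect_identical(c(cre@s1, cre@s2, cre@prominence), c(0.5, 1, 100))
  fev <- probeSettings("Fev")
  expect_identical(c(fev@s1, fev@s2, fev@prominence), c(0.25, 2, 75))
  expect_error(probeSettings("nope"), "registry")
})

test_that("detection returns an empty set on blank input and finds synthetic spots", {
  st <- probeSettings("synthetic", s1 = 1, s2 = 4, prominence = 25)
  blank <- detectPuncta(matrix(0, 64, 64), st, ball_radius = 20)
  expect_identical(nPuncta(blank), 0L)

  cfg <- sceneConfig(width = 360, height = 360, n_nuclei = 6,
                     puncta_range = c(3, 20), seed = 31)
  scene <- makeFishScene(cfg, probes = "p")
  det <- detectPuncta(scene@probes$p, st)
  f1 <- match_f1(punctaCoords(det), scene@puncta, radius = 2)
  expect_gte(f1["f1"], 0.9)
})
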