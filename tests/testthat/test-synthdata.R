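test_that("nucleus scene generation honours geometry, emptiness and determinism", {
  # empty case
  blank <- makeNucleiScene(sceneConfig(n_nuclei = 0, noise_sigma = 0,
                                       dapi_background = 0, seed = 1))
  expect_true(all(blank$dapi == 0))
  expect_identical(nLabels(blank$labels), 0L)

  # forced geometry: one circular nucleus of radius 20
  s <- makeNucleiScene(sceneConfig(n_nuclei = 1, radius_range = c(20, 20),
                                   axis_ratio_range = c(1, 1),
                                   noise_sigma = 0, seed = 2))
  area <- sum(s$labels@.Data > 0)
  expect_lt(abs(area - pi * 20^2) / (pi * 20^2), 0.05)

  # determinism: same config, same seed, bit-identical
  a <- makeNucleiScene(sceneConfig(n_nuclei = 6, seed = 9))
  b <- makeNucleiScene(sceneConfig(n_nuclei = 6, seed = 9))
  expect_identical(a$dapi, b$dapi)
  expect_identical(a$labels@.Data, b$labels@.Data)

  # infeasible placement errors out
  expect_error(makeNucleiScene(sceneConfig(width = 128, height = 128,
                                           n_nuclei = 40, seed = 1)),
               "place|fit")
})

test_that("touching pairs are rendered with both members labelled distinctly", {
  sc <- makeNucleiScene(sceneConfig(width = 600, height = 600, n_nuclei = 8,
                                    touching_fraction = 1, seed = 4))
  expect_identical(nLabels(sc$labels), 8L)
  nuc <- sc$nuclei
  expect_true(all(nuc$pair > 0))
  for (p in unique(nuc$pair)) {
    idx <- which(nuc$pair == p)
    sep <- sqrt(diff(nuc$cx[idx])^2 + diff(nuc$cy[idx])^2)
    rbar <- mean(nuc$r[idx])
    expect_gte(sep, 0.8 * rbar - 1e-9)
    expect_lte(sep, 1.2 * rbar + 1e-9)
  }
})

test_that("puncta channels place exact counts inside their cells", {
  cfg <- sceneConfig(width = 300, height = 300, n_nuclei = 3,
                     bg_blob_density = 0, noise_sigma = 0, seed = 5)
  sc <- makeNucleiScene(cfg)

  # all-zero counts, no blobs, no noise -> all-zero image
  zero <- makePunctaChannel(sc$labels, cfg, setNames(rep(0, 3), 1:3))
  expect_true(all(zero$image == 0))
  expect_identical(nrow(zero$puncta), 0L)

  # forced count inside one cell
  one <- makePunctaChannel(sc$labels, cfg, c("2" = 5))
  expect_identical(nrow(one$puncta), 5L)
  px <- floor(one$puncta$x + 0.5) + 1
  py <- floor(one$puncta$y + 0.5) + 1
  expect_true(all(sc$labels@.Data[cbind(py, px)] == 2))

  # minimum separation honoured
  d <- as.matrix(dist(one$puncta[, c("x", "y")]))
  expect_gte(min(d[upper.tri(d)]), cfg@spot_min_sep)

  # analytic Gaussian integral: total intensity ~ n * 2 pi sigma^2 A
  many <- makePunctaChannel(sc$labels, cfg,
                            setNames(c(10, 8, 12), 1:3), seed = 11)
  expected <- 30 * 2 * pi * cfg@spot_sigma^2 * cfg@spot_amplitude
  expect_lt(abs(sum(many$image) - expected) / expected, 0.01)

  # unknown cell and unplaceable count are errors
  expect_error(makePunctaChannel(sc$labels, cfg, c("9" = 1)), "absent")
  expect_error(makePunctaChannel(sc$labels, cfg, c("1" = 100000)),
               "cannot place")
})

test_that("full scenes keep truth bookkeeping consistent", {
  scene <- makeFishScene(sceneConfig(width = 420, height = 420, n_nuclei = 6,
                                     puncta_range = c(0, 12), seed = 8),
                         probes = c("pA", "pB"))
  # validity already asserts puncta-in-label and count tallies; spot-check
  expect_true(validObject(scene))
  for (p in c("pA", "pB")) {
    tallies <- table(factor(scene@puncta$cell[scene@puncta$probe == p],
                            levels = 1:6))
    cnt <- scene@counts[scene@counts$probe == p, ]
    expect_identical(as.integer(tallies), cnt$count)
  }
  # determinism of the composite scene
  scene2 <- makeFishScene(sceneConfig(width = 420, height = 420, n_nuclei = 6,
                                      puncta_range = c(0, 12), seed = 8),
                          probes = c("pA", "pB"))
  expect_identical(scene@probes$pB, scene2@probes$pB)
  expect_identical(scene@puncta, scene2@puncta)
})

test_that("innervation stacks hit the requested occupied fraction", {
  blank <- makeInnervationStack(0, noise_sigma = 0, seed = 1)
  expect_true(all(blank$stack == 0))
  expect_identical(blank$truth_fraction, 0)

  st <- makeInnervationStack(0.05, seed = 3)
  expect_gte(st$truth_fraction, 0.0475)
  expect_lte(st$truth_fraction, 0.0525)
  expect_identical(dim(st$stack), c(128L, 128L, 21L))

  # doubling the target doubles the above-threshold pixel count (counting
  # oracle on the noiseless generated stack)
  a <- makeInnervationStack(0.04, noise_sigma = 0, seed = 7)
  b <- makeInnervationStack(0.08, noise_sigma = 0, seed = 7)
  na <- sum(a$stack > 50); nb <- sum(b$stack > 50)
  expect_lt(abs(nb / na - 2), 0.1)

  expect_error(makeInnervationStack(0.7), "target_fraction")
})

test_that("group samples reproduce mean and SEM exactly and are symmetric at n = 2", {
  x <- makeGroupSamples(10, 1, 5, seed = 2)
  expect_equal(mean(x), 10, tolerance = 1e-9)
  expect_equal(sd(x) / sqrt(5), 1, tolerance = 1e-9)

  y <- makeGroupSamples(0, 1, 2, seed = 3)
  expect_equal(y[1], -y[2], tolerance = 1e-9)

  expect_error(makeGroupSamples(0, 1, 1), "n must be")
  expect_error(makeGroupSamples(0, 0, 4), "sem")
})

test_that("synthetic region cohorts carry the requested correlation structure", {
  regs <- c("SOC", "IC", "CNC")
  corr <- matrix(c(1, 0.8, 0, 0.8, 1, 0, 0, 0, 1), 3, 3)
  coh <- makeRegionCohort(200, regs, mean_percent = 3, sd_percent = 0.4,
                          corr = corr, seed = 5)
  wide <- matrix(coh$percent_area, ncol = 3, byrow = TRUE)
  expect_equal(cor(wide[, 1], wide[, 2]), 0.8, tolerance = 0.1)
  expect_lt(abs(cor(wide[, 1], wide[, 3])), 0.2)
})
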