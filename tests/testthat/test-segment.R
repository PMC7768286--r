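test_that("gaussian preprocessing preserves constants and total intensity", {
  const <- matrix(7, 30, 30)
  expect_lt(max(abs(gaussianPreprocess(const, 18) - 7)), 1e-6)

  # centred point source: peak drops, integral conserved (reflective edges)
  img <- matrix(0, 41, 41); img[21, 21] <- 100
  sm <- gaussianPreprocess(img, 6)
  expect_lt(max(sm), 100)
  expect_lt(abs(sum(sm) - 100) / 100, 0.01)

  # scale-space sanity: a stronger blur never adds interior maxima
  sc <- makeNucleiScene(sceneConfig(width = 360, height = 360, n_nuclei = 4,
                                    noise_sigma = 0, seed = 6))
  n_max <- function(img) {
    m <- findMaxima(img, 1e-6)
    nrow(m)
  }
  expect_lte(n_max(gaussianPreprocess(sc$dapi, 36)),
             n_max(gaussianPreprocess(sc$dapi, 18)))

  expect_error(gaussianPreprocess(array(0, c(3, 3, 3))), "matrix")
})

test_that("minimum cross-entropy threshold matches the exhaustive objective", {
  # separation forced for a two-valued image
  two <- matrix(c(rep(10, 90), rep(200, 10)), 10, 10)
  th <- minCrossEntropyThreshold(two)
  expect_gt(th, 10); expect_lt(th, 200)

  # histogram-only statistic: invariant under rotation/translation
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  expect_identical(minCrossEntropyThreshold(img),
                   minCrossEntropyThreshold(t(img)[, 20:1]))

  # exhaustive oracle on random 8-bit images: identical partition
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(sample(0:255, 16 * 16, replace = TRUE,
                       prob = runif(256)^2), 16, 16)
    if (length(unique(as.vector(m))) < 2) next
    cut <- oracle_li_cut(m)
    th <- minCrossEntropyThreshold(m)
    expect_identical(m > th, m > cut)
  }

  expect_error(minCrossEntropyThreshold(matrix(3, 5, 5)), "degenerate")
})

test_that("segmentation recovers synthetic nuclei and respects all gates", {
  params <- segmentationParams()

  # blank image
  expect_identical(nLabels(segmentNuclei(matrix(0, 64, 64), params)), 0L)

  # well-separated nuclei: one label each
  sc <- makeNucleiScene(sceneConfig(width = 512, height = 512, n_nuclei = 10,
                                    seed = 13))
  lab <- segmentNuclei(sc$dapi, params)
  expect_identical(nLabels(lab), 10L)

  # gates: equivalent diameter in range, no border contact
  areas <- labelAreas(lab)
  eqd <- 2 * sqrt(areas / pi)
  expect_true(all(eqd >= params@min_diameter & eqd <= params@max_diameter))
  m <- lab@.Data
  expect_true(all(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]) == 0))
})

test_that("objects outside the diameter range are excluded", {
  # one small (10 px) and one large (150 px) disk plus two valid nuclei
  sc <- makeNucleiScene(sceneConfig(width = 700, height = 700, n_nuclei = 2,
                                    noise_sigma = 0, seed = 3))
  img <- sc$dapi
  stamp_disk <- function(img, cx, cy, r, amp = 100) {
    for (dr in -r:r) for (dc in -r:r)
      if (dr^2 + dc^2 <= r^2) img[cy + dr, cx + dc] <- amp
    img
  }
  img <- stamp_disk(img, 90, 90, 5)      # diameter 10: below range
  img <- stamp_disk(img, 520, 520, 75)   # diameter 150: above range
  lab <- segmentNuclei(img)
  expect_identical(nLabels(lab), 2L)
  # neither extreme object's centre pixel is labelled
  expect_identical(lab@.Data[90, 90], 0L)
  expect_identical(lab@.Data[520, 520], 0L)
})

test_that("manual edits remove, add and keep existing labels intact", {
  sc <- makeNucleiScene(sceneConfig(width = 512, height = 512, n_nuclei = 5,
                                    seed = 17))
  lab <- segmentNuclei(sc$dapi)
  expect_identical(nLabels(lab), 5L)

  # identity
  same <- applyManualEdits(lab, manualEdits())
  expect_identical(same@.Data, lab@.Data)

  # removal
  rm3 <- applyManualEdits(lab, manualEdits(removals = 3))
  expect_identical(nLabels(rm3), 4L)
  expect_true(all(rm3@.Data[lab@.Data == 3] == 0))

  # addition of a disk in background (borders are object-free after gating)
  add <- applyManualEdits(lab, manualEdits(
    additions = data.frame(x = 30, y = 256, radius = 8)))
  expect_identical(nLabels(add), 6L)

  # polygon addition
  poly <- applyManualEdits(lab, manualEdits(additions = list(
    data.frame(x = c(5, 25, 25, 5), y = c(5, 5, 25, 25)))))
  expect_identical(nLabels(poly), 6L)

  # unknown removal id errors, listing the id
  expect_error(applyManualEdits(lab, manualEdits(removals = 99)), "99")
})

test_that("label maps validate their invariants", {
  expect_error(LabelMap(matrix(c(0, 2, 2, 2), 2, 2)), "contiguous")
  expect_silent(LabelMap(matrix(c(0L, 1L, 1L, 2L), 2, 2)))
  lm <- LabelMap(matrix(c(0, 3, 3, 7), 2, 2), relabel = TRUE)
  expect_identical(sort(unique(as.vector(lm@.Data))), c(0L, 1L, 2L))
})
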