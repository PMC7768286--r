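make_label_grid <- function() {
  # two 10x10 square cells in a 30x30 frame
  m <- matrix(0L, 30, 30)
  m[5:14, 5:14] <- 1L
  m[18:27, 18:27] <- 2L
  LabelMap(m)
}

test_that("puncta are routed to containing cells, dropped outside, never double-counted", {
  lab <- make_label_grid()
  ps <- new("PunctaSet", probe = "p",
            points = data.frame(x = c(6, 7, 8, 1, 20), y = c(6, 7, 8, 1, 20)),
            peak_values = rep(1, 5))
  expect_message(rec <- countPunctaPerCell(ps, lab), "dropped")
  expect_identical(rec$count, c(3L, 1L))
  expect_identical(unname(attr(rec, "dropped")["p"]), 1L)
  # conservation: assigned + dropped = total
  expect_identical(sum(rec$count) + unname(attr(rec, "dropped")["p"]),
                   nPuncta(ps))

  # zero puncta: all zero, all negative
  empty <- new("PunctaSet", probe = "p",
               points = data.frame(x = numeric(), y = numeric()),
               peak_values = numeric())
  rec0 <- countPunctaPerCell(empty, lab)
  expect_true(all(rec0$count == 0) && all(!rec0$positive))
})

test_that("polygon (soma outline) mode contains boundary points and honours priority", {
  rois <- rbind(
    data.frame(cell_id = "A", x = c(0, 10, 10, 0), y = c(0, 0, 10, 10)),
    data.frame(cell_id = "B", x = c(8, 20, 20, 8), y = c(8, 8, 20, 20)))
  mk <- function(x, y) new("PunctaSet", probe = "p",
                           points = data.frame(x = x, y = y),
                           peak_values = rep(1, length(x)))
  # boundary-inclusive: a point on A's edge counts as inside
  rec <- countPunctaPerCell(mk(c(5, 10), c(5, 5)), rois)
  expect_identical(rec$count[rec$cell_id == "A"], 2L)

  # overlapping containment errors without a priority, resolves with one
  expect_error(countPunctaPerCell(mk(9, 9), rois), "priority")
  rec2 <- countPunctaPerCell(mk(9, 9), rois, priority = c("B", "A"))
  expect_identical(rec2$count[rec2$cell_id == "B"], 1L)
  expect_identical(rec2$count[rec2$cell_id == "A"], 0L)
  expect_identical(rec2$roi_kind[1], "soma_outline")
})

test_that("true puncta route back to exactly the generating counts", {
  scene <- makeFishScene(sceneConfig(width = 420, height = 420, n_nuclei = 6,
                                     puncta_range = c(0, 15), seed = 23),
                         probes = "p")
  truth <- scene@puncta
  ps <- new("PunctaSet", probe = "p",
            points = data.frame(x = truth$x, y = truth$y),
            peak_values = rep(1, nrow(truth)))
  rec <- countPunctaPerCell(ps, scene@labels)
  expect_identical(rec$count, scene@counts$count)
})

test_that("percent positive follows the threshold rule and is monotone in it", {
  rec <- data.frame(cell_id = as.character(1:10), probe = "p",
                    count = c(rep(0L, 8), 3L, 7L))
  pp <- percentPositive(rec, "p")
  expect_equal(pp$percent, 20)
  expect_identical(c(pp$n_positive, pp$n_total), c(2L, 10L))

  zero <- data.frame(cell_id = "1", probe = "p", count = 0L)
  expect_equal(percentPositive(zero, "p")$percent, 0)

  thr <- data.frame(cell_id = as.character(1:3), probe = "p",
                    count = c(4L, 5L, 6L))
  expect_equal(percentPositive(thr, "p", threshold = 5)$percent, 200 / 3)

  # non-increasing in threshold
  prev <- 100
  for (t in 1:8) {
    cur <- percentPositive(rec, "p", threshold = t)$percent
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_error(percentPositive(rec, "nope"), "no records")
})

test_that("sampled-section totals scale by the interval", {
  expect_identical(estimateTotalCells(c(10, 12, 8)), 180L)
  expect_identical(estimateTotalCells(integer(0)), 0L)
  expect_identical(estimateTotalCells(1, sampling_interval = 1), 1L)
  expect_error(estimateTotalCells(c(3, -1)), ">= 0")
})

test_that("animal aggregation averages within, never across, animals", {
  rec <- data.frame(
    cell_id = as.character(1:6),
    animal_id = c("m1", "m1", "m2", "m2", "m2", "m1"),
    sex = "M", genotype = "ctrl", roi_kind = "nucleus",
    roi_area = c(100, 110, 90, 95, 100, 105),
    probe = "p", count = c(2L, 4L, 10L, 0L, 5L, 6L),
    positive = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  agg <- perAnimalAggregate(rec)
  expect_identical(nrow(agg), 2L)
  expect_equal(agg$mean_count[agg$animal_id == "m1"], 4)
  expect_equal(agg$mean_count[agg$animal_id == "m2"], 5)
  expect_equal(agg$percent_positive[agg$animal_id == "m2"], 200 / 3)
  expect_identical(agg$n_cells, c(3L, 3L))

  rec$animal_id[1] <- NA
  expect_error(perAnimalAggregate(rec), "animal_id")
})

test_that("truth-driven cohort round trip: animal means equal generator truth", {
  cfgs <- list(sceneConfig(width = 420, height = 420, n_nuclei = 5,
                           puncta_range = c(2, 18), seed = 41),
               sceneConfig(width = 420, height = 420, n_nuclei = 5,
                           puncta_range = c(2, 18), seed = 42))
  rows <- list()
  for (i in seq_along(cfgs)) {
    scene <- makeFishScene(cfgs[[i]], probes = "p")
    truth <- scene@puncta
    ps <- new("PunctaSet", probe = "p",
              points = data.frame(x = truth$x, y = truth$y),
              peak_values = rep(1, nrow(truth)))
    meta <- data.frame(cell_id = as.character(1:5),
                       animal_id = paste0("m", i))
    rows[[i]] <- countPunctaPerCell(ps, scene@labels, metadata = meta)
  }
  agg <- perAnimalAggregate(do.call(rbind, rows))
  for (i in seq_along(cfgs)) {
    scene <- makeFishScene(cfgs[[i]], probes = "p")
    expect_equal(agg$mean_count[agg$animal_id == paste0("m", i)],
                 mean(scene@counts$count))
  }
})
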