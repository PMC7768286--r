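#' Assign detected puncta to cells and count them
#'
#' Each punctum is assigned to the ROI containing its pixel: label identity
#' for nucleus label maps, boundary-inclusive even-odd containment for soma
#' outline polygons. Puncta falling in no ROI are dropped (tallied in the
#' `dropped` attribute). With polygon ROIs a punctum contained in several
#' overlapping outlines is an error unless `priority` orders the cells, in
#' which case the earliest listed cell wins -- this guarantees no punctum is
#' counted for more than one cell.
#'
#' @param puncta a [PunctaSet-class], or a list of them (one per probe).
#' @param rois a [LabelMap-class] (nucleus mode) or a data.frame of polygon
#'   vertices with columns `cell_id`, `x`, `y` (soma-outline mode).
#' @param metadata optional data.frame with `cell_id` and any of
#'   `animal_id`, `sex`, `genotype`.
#' @param positivity_threshold minimum count to call a cell positive
#'   (default 1, the "having puncta" rule).
#' @param priority optional cell-id vector resolving polygon overlaps.
#' @return data.frame of cell records, one row per cell x probe, with
#'   columns `cell_id`, `animal_id`, `sex`, `genotype`, `roi_kind`,
#'   `roi_area`, `probe`, `count`, `positive`; attribute `dropped` gives
#'   per-probe counts of unassigned puncta.
#' @export
countPunctaPerCell <- function(puncta, rois, metadata = NULL,
                               positivity_threshold = 1, priority = NULL) {
  if (is(puncta, "PunctaSet")) puncta <- list(puncta)
  stopifnot(all(vapply(puncta, is, logical(1), "PunctaSet")))

  if (is(rois, "LabelMap")) {
    roi_kind <- "nucleus"
    lab <- rois@.Data
    ids <- seq_len(nLabels(rois))
    areas <- as.numeric(labelAreas(rois))
    assign_fun <- function(pts) {
      if (!nrow(pts)) return(integer(0))
      r <- floor(pts$y + 0.5) + 1
      c <- floor(pts$x + 0.5) + 1
      ok <- r >= 1 & r <= nrow(lab) & c >= 1 & c <= ncol(lab)
      out <- integer(nrow(pts))
      out[ok] <- lab[cbind(r[ok], c[ok])]
      out
    }
  } else if (is.data.frame(rois) &&
             all(c("cell_id", "x", "y") %in% names(rois))) {
    roi_kind <- "soma_outline"
    polys <- split(rois, rois$cell_id)
    ids <- names(polys)
    areas <- vapply(polys, function(p) {
      # shoelace
      x <- p$x; y <- p$y
      abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    }, numeric(1))
    assign_fun <- function(pts) {
      if (!nrow(pts)) return(character(0))
      out <- rep(NA_character_, nrow(pts))
      for (i in seq_len(nrow(pts))) {
        hits <- names(polys)[vapply(polys, function(p)
          point_in_polygon(pts$x[i], pts$y[i], p$x, p$y), logical(1))]
        if (length(hits) > 1) {
          if (is.null(priority))
            stop("punctum at (", pts$x[i], ", ", pts$y[i],
                 ") lies in overlapping outlines ",
                 paste(hits, collapse = ", "),
                 "; supply a priority order")
          hits <- hits[order(match(hits, priority))]
        }
        if (length(hits)) out[i] <- hits[1]
      }
      out
    }
  } else stop("rois must be a LabelMap or a cell_id/x/y polygon data.frame")

  records <- list()
  dropped <- integer(0)
  for (ps in puncta) {
    asg <- assign_fun(ps@points)
    assigned <- asg[!is.na(asg) & asg != 0]
    counts <- table(factor(as.character(assigned), levels = as.character(ids)))
    ndrop <- nPuncta(ps) - length(assigned)
    dropped[ps@probe] <- ndrop
    if (ndrop > 0)
      message(ndrop, " puncta of probe '", ps@probe,
              "' fell outside all ROIs and were dropped")
    records[[ps@probe]] <- data.frame(
      cell_id = as.character(ids), roi_kind = roi_kind, roi_area = areas,
      probe = ps@probe, count = as.integer(counts),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  for (col in c("animal_id", "sex", "genotype")) {
    out[[col]] <- if (!is.null(metadata) && col %in% names(metadata))
      metadata[[col]][match(out$cell_id, as.character(metadata$cell_id))]
    else NA
  }
  out$positive <- out$count >= positivity_threshold
  out <- out[, c("cell_id", "animal_id", "sex", "genotype", "roi_kind",
                 "roi_area", "probe", "count", "positive")]
  attr(out, "dropped") <- dropped
  out
}

#' Percent of cells positive for a probe
#'
#' A cell is positive when its puncta count reaches the threshold
#' (default 1). Returns the percentage together with the counts it is
#' built from.
#'
#' @param records cell-record data.frame from [countPunctaPerCell()].
#' @param probe probe name to score.
#' @param threshold positivity threshold (default 1 punctum).
#' @return list with `percent`, `n_positive`, `n_total`.
#' @examples
#' rec <- data.frame(cell_id = as.character(1:10), probe = "p",
#'                   count = c(rep(0, 8), 3, 7))
#' percentPositive(rec, "p")$percent  # 20
#' @export
percentPositive <- function(records, probe, threshold = 1) {
  r <- records[records$probe == probe, , drop = FALSE]
  if (!nrow(r)) stop("no records for probe '", probe, "'")
  n_pos <- sum(r$count >= threshold)
  list(percent = 100 * n_pos / nrow(r), n_positive = n_pos,
       n_total = nrow(r))
}

#' Estimate total cells from systematically sampled sections
#'
#' Cells counted in every k-th section are scaled by the sampling interval:
#' the estimate is `sampling_interval` times the summed counts (counting in
#' every sixth section and multiplying by 6 by default).
#'
#' @param per_section_counts integer vector of counts in the sampled
#'   sections.
#' @param sampling_interval section sampling interval (default 6).
#' @return integer estimate of total cells.
#' @examples
#' estimateTotalCells(c(10, 12, 8))  # 180
#' @export
estimateTotalCells <- function(per_section_counts, sampling_interval = 6) {
  if (length(per_section_counts) && any(per_section_counts < 0))
    stop("counts must be >= 0")
  as.integer(sampling_interval * sum(per_section_counts))
}

#' Aggregate cell records to animal-level summaries
#'
#' Animal averages, not pooled cells, are the statistical units: per animal
#' and probe this returns the mean puncta per cell, percent positive, the
#' number of cells and the mean ROI area. Cells are never pooled across
#' animals.
#'
#' @param records cell-record data.frame from [countPunctaPerCell()]; every
#'   record must carry `animal_id`.
#' @return data.frame with one row per animal x probe.
#' @export
perAnimalAggregate <- function(records) {
  if (any(is.na(records$animal_id)))
    stop("every record must carry an animal_id")
  key <- interaction(records$animal_id, records$probe, drop = TRUE)
  rows <- lapply(split(records, key), function(r) {
    data.frame(animal_id = r$animal_id[1],
               sex = r$sex[1], genotype = r$genotype[1],
               probe = r$probe[1],
               mean_count = mean(r$count),
               percent_positive = 100 * mean(r$positive),
               n_cells = nrow(r),
               mean_roi_area = mean(r$roi_area),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$probe, out$animal_id), ]
}
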