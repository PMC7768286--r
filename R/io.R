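#' Write a synthetic scene to a directory of TIFFs and CSVs
#'
#' Writes `dapi.tif` and one `<probe>.tif` per channel as 32-bit float
#' TIFFs, `truth_labels.tif` as 16-bit, plus `truth_puncta.csv`
#' (probe, cell_id, x, y), `truth_counts.csv` and the resolved scene
#' configuration as `config.csv`.
#'
#' Intensities are stored as 32-bit floats scaled into `[0, 1]`; the
#' per-channel scale factors are written to `scales.csv` so raw units can be
#' reconstructed (see [readImageTiff()]).
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeScene <- function(scene, dir) {
  stopifnot(is(scene, "SyntheticScene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- data.frame(file = character(), scale = numeric(),
                       offset = numeric())
  wf <- function(img, path) {
    off <- min(0, min(img, na.rm = TRUE))
    sc <- max(1, max(img, na.rm = TRUE) - off)
    tiff::writeTIFF(pmin(pmax((img - off) / sc, 0), 1), path,
                    bits.per.sample = 32L, reduce = FALSE)
    scales[nrow(scales) + 1, ] <<- list(basename(path), sc, off)
  }
  wf(scene@dapi, file.path(dir, "dapi.tif"))
  for (p in names(scene@probes))
    wf(scene@probes[[p]], file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", p), ".tif")))
  utils::write.csv(scales, file.path(dir, "scales.csv"), row.names = FALSE)
  tiff::writeTIFF(scene@labels@.Data / 65535, file.path(dir, "truth_labels.tif"),
                  bits.per.sample = 16L)
  pts <- scene@puncta
  names(pts)[names(pts) == "cell"] <- "cell_id"
  utils::write.csv(pts, file.path(dir, "truth_puncta.csv"), row.names = FALSE)
  utils::write.csv(scene@counts, file.path(dir, "truth_counts.csv"),
                   row.names = FALSE)
  cf <- scene@config
  fields <- slotNames(cf)
  utils::write.csv(
    data.frame(field = fields,
               value = vapply(fields, function(f)
                 paste(slot(cf, f), collapse = ";"), character(1))),
    file.path(dir, "config.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a single-channel intensity TIFF as a matrix
#'
#' @param path TIFF file path.
#' @param scale,offset multiplier and shift restoring raw intensity units
#'   (see [writeScene()]'s `scales.csv`); defaults 1 and 0.
#' @return numeric matrix.
#' @export
readImageTiff <- function(path, scale = 1, offset = 0) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  as_image_matrix(img) * scale + offset
}

#' Read a 16-bit label TIFF back into a LabelMap
#'
#' Inverse of the `truth_labels.tif` written by [writeScene()].
#'
#' @param path TIFF file path.
#' @return a [LabelMap-class].
#' @export
readLabelsTiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  LabelMap(round(img))
}
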