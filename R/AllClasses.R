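#' @import methods
NULL

#' Label map of segmented objects
#'
#' An integer matrix in which 0 marks background and positive values
#' 1..K index segmented objects (nuclei or cell bodies). Coordinates used
#' with a `LabelMap` are 0-based with `x` = column and `y` = row.
#'
#' @slot .Data integer matrix of labels.
#' @export
setClass("LabelMap", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (length(v) == 0) return("empty label map")
  if (any(is.na(v))) return("labels must not contain NA")
  if (any(v != round(v)) || any(v < 0)) return("labels must be non-negative integers")
  k <- max(v)
  if (k > 0 && !all(seq_len(k) %in% unique(as.vector(v))))
    return("labels must be contiguous 1..K")
  TRUE
})

#' Construct a LabelMap
#'
#' @param m integer matrix (0 = background, labels 1..K).
#' @param relabel if `TRUE`, relabel non-zero values contiguously 1..K in
#'   raster order of first occurrence.
#' @return a [LabelMap-class] object.
#' @export
LabelMap <- function(m, relabel = FALSE) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (relabel) m <- relabel_contiguous(m)
  new("LabelMap", m)
}

relabel_contiguous <- function(m) {
  ids <- unique(as.vector(m))
  ids <- ids[ids > 0]
  if (length(ids)) {
    lut <- integer(max(ids))
    lut[ids] <- seq_along(ids)
    pos <- m > 0
    m[pos] <- lut[m[pos]]
  }
  m
}

#' Configuration of a synthetic microscopy scene
#'
#' Parameters controlling rendered nuclei, FISH spot channels, diffuse
#' background and noise. All lengths are in pixels, intensities in arbitrary
#' units. The signal-to-noise ratio of a spot channel is
#' `spot_amplitude / noise_sigma`.
#'
#' @slot width,height image size in pixels.
#' @slot n_nuclei number of nuclei to place.
#' @slot radius_range range of nucleus equivalent radii (px).
#' @slot touching_fraction fraction of nuclei placed as touching pairs
#'   (centre separation 0.8-1.2 x mean radius).
#' @slot axis_ratio_range range of minor/major semi-axis ratios of the
#'   rendered ellipses (area is preserved at pi * r^2).
#' @slot nucleus_amplitude peak DAPI intensity of a nucleus.
#' @slot dapi_background nonspecific tissue background level of the DAPI
#'   channel (arbitrary units; real sections are never truly black).
#' @slot puncta_range integer range of puncta per cell (uniform).
#' @slot spot_sigma Gaussian sigma of a rendered punctum (px).
#' @slot spot_amplitude peak intensity of a punctum.
#' @slot spot_min_sep minimum centre separation between puncta of one cell
#'   (px); must be at least `2 * spot_sigma`.
#' @slot bg_blob_density expected diffuse background blobs per pixel.
#' @slot bg_blob_sigma,bg_blob_amplitude size and peak intensity of the
#'   diffuse background blobs.
#' @slot noise_sigma standard deviation of the additive Gaussian noise.
#' @slot seed integer random seed; fixes the scene bit-for-bit.
#' @export
setClass("SceneConfig",
  representation(width = "numeric", height = "numeric", n_nuclei = "numeric",
    radius_range = "numeric", touching_fraction = "numeric",
    axis_ratio_range = "numeric", nucleus_amplitude = "numeric",
    dapi_background = "numeric",
    puncta_range = "numeric", spot_sigma = "numeric",
    spot_amplitude = "numeric", spot_min_sep = "numeric",
    bg_blob_density = "numeric", bg_blob_sigma = "numeric",
    bg_blob_amplitude = "numeric", noise_sigma = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@width < 8 || object@height < 8) msg <- c(msg, "image too small")
    if (object@n_nuclei < 0) msg <- c(msg, "n_nuclei must be >= 0")
    if (length(object@radius_range) != 2 || any(object@radius_range <= 0) ||
        diff(object@radius_range) < 0)
      msg <- c(msg, "radius_range must be an increasing positive pair")
    if (object@touching_fraction < 0 || object@touching_fraction > 1)
      msg <- c(msg, "touching_fraction must be in [0, 1]")
    if (any(object@axis_ratio_range <= 0) || any(object@axis_ratio_range > 1))
      msg <- c(msg, "axis_ratio_range must be in (0, 1]")
    if (object@spot_sigma <= 0 || object@bg_blob_sigma <= 0)
      msg <- c(msg, "all sigma must be > 0")
    if (object@spot_min_sep < 2 * object@spot_sigma)
      msg <- c(msg, "spot_min_sep must be >= 2 * spot_sigma")
    if (object@noise_sigma < 0) msg <- c(msg, "noise_sigma must be >= 0")
    if (length(object@puncta_range) != 2 || any(object@puncta_range < 0) ||
        diff(object@puncta_range) < 0)
      msg <- c(msg, "puncta_range must be a non-decreasing non-negative pair")
    if (length(msg)) msg else TRUE
  })

#' @describeIn SceneConfig-class constructor with study-condition defaults.
#' @param width,height,n_nuclei,radius_range,touching_fraction,axis_ratio_range
#'   see slots.
#' @param nucleus_amplitude,dapi_background see slots.
#' @param puncta_range,spot_sigma,spot_amplitude,spot_min_sep
#'   see slots.
#' @param bg_blob_density,bg_blob_sigma,bg_blob_amplitude,noise_sigma,seed
#'   see slots.
#' @export
sceneConfig <- function(width = 512, height = 512, n_nuclei = 20,
                        radius_range = c(28, 34), touching_fraction = 0,
                        axis_ratio_range = c(0.85, 1),
                        nucleus_amplitude = 100, dapi_background = 20,
                        puncta_range = c(0, 30), spot_sigma = 1.2,
                        spot_amplitude = 100, spot_min_sep = 4 * spot_sigma,
                        bg_blob_density = 2e-4, bg_blob_sigma = 12,
                        bg_blob_amplitude = 10, noise_sigma = 5,
                        seed = 1L) {
  new("SceneConfig", width = width, height = height, n_nuclei = n_nuclei,
      radius_range = radius_range, touching_fraction = touching_fraction,
      axis_ratio_range = axis_ratio_range,
      nucleus_amplitude = nucleus_amplitude,
      dapi_background = dapi_background, puncta_range = puncta_range,
      spot_sigma = spot_sigma, spot_amplitude = spot_amplitude,
      spot_min_sep = spot_min_sep, bg_blob_density = bg_blob_density,
      bg_blob_sigma = bg_blob_sigma, bg_blob_amplitude = bg_blob_amplitude,
      noise_sigma = noise_sigma, seed = seed)
}

#' A synthetic multi-channel FISH scene with ground truth
#'
#' @slot dapi DAPI intensity matrix.
#' @slot probes named list of probe-channel intensity matrices.
#' @slot labels ground-truth [LabelMap-class] of nuclei.
#' @slot puncta data.frame (probe, cell, x, y) of true spot centres.
#' @slot counts data.frame (probe, cell, count) of true per-cell counts.
#' @slot config the generating [SceneConfig-class].
#' @export
setClass("SyntheticScene",
  representation(dapi = "matrix", probes = "list", labels = "LabelMap",
                 puncta = "data.frame", counts = "data.frame",
                 config = "SceneConfig"),
  validity = function(object) {
    d <- dim(object@dapi)
    if (!identical(d, dim(object@labels@.Data)))
      return("dapi and labels must share dimensions")
    for (p in object@probes)
      if (!identical(dim(p), d)) return("all channels must share dimensions")
    # truth bookkeeping: counts match puncta, puncta inside their label
    pts <- object@puncta
    if (nrow(pts)) {
      px <- floor(pts$x + 0.5) + 1
      py <- floor(pts$y + 0.5) + 1
      inlab <- object@labels@.Data[cbind(py, px)]
      if (!all(inlab == pts$cell))
        return("every true punctum must lie inside its cell's label region")
    }
    tab <- table(factor(pts$probe), factor(pts$cell))
    for (i in seq_len(nrow(object@counts))) {
      cc <- object@counts[i, ]
      got <- if (nrow(pts)) sum(pts$probe == cc$probe & pts$cell == cc$cell) else 0
      if (got != cc$count) return("counts must equal per-cell puncta tallies")
    }
    TRUE
  })

#' Nucleus segmentation parameters
#'
#' Defaults mirror the semi-automated DAPI segmentation protocol: an 18 px
#' Gaussian blur diameter, a 30-100 px object diameter range, minimum
#' cross-entropy global thresholding with a threshold smoothing scale of
#' 1.3488, intensity-based declumping, border exclusion and hole filling.
#'
#' @slot blur_diameter Gaussian preprocessing blur diameter (px);
#'   interpreted as 2 * sigma.
#' @slot min_diameter,max_diameter allowed object equivalent-diameter range (px).
#' @slot threshold_smoothing_scale smoothing scale before thresholding;
#'   applied as a Gaussian with sigma = scale / 1.3488, so 1.3488 means sigma 1.
#' @slot declump `"intensity"` or `"none"`.
#' @slot exclude_edges drop objects touching the image border.
#' @slot fill_holes fill enclosed background holes per object.
#' @export
setClass("SegmentationParams",
  representation(blur_diameter = "numeric", min_diameter = "numeric",
    max_diameter = "numeric", threshold_smoothing_scale = "numeric",
    declump = "character", exclude_edges = "logical", fill_holes = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@blur_diameter <= 0) msg <- c(msg, "blur_diameter must be > 0")
    if (object@min_diameter <= 0 || object@min_diameter >= object@max_diameter)
      msg <- c(msg, "need 0 < min_diameter < max_diameter")
    if (object@threshold_smoothing_scale < 0)
      msg <- c(msg, "threshold_smoothing_scale must be >= 0")
    if (!object@declump %in% c("intensity", "none"))
      msg <- c(msg, "declump must be 'intensity' or 'none'")
    if (length(msg)) msg else TRUE
  })

#' @describeIn SegmentationParams-class constructor.
#' @param blur_diameter,min_diameter,max_diameter,threshold_smoothing_scale
#'   see slots.
#' @param declump,exclude_edges,fill_holes see slots.
#' @export
segmentationParams <- function(blur_diameter = 18, min_diameter = 30,
                               max_diameter = 100,
                               threshold_smoothing_scale = 1.3488,
                               declump = c("intensity", "none"),
                               exclude_edges = TRUE, fill_holes = TRUE) {
  new("SegmentationParams", blur_diameter = blur_diameter,
      min_diameter = min_diameter, max_diameter = max_diameter,
      threshold_smoothing_scale = threshold_smoothing_scale,
      declump = match.arg(declump), exclude_edges = exclude_edges,
      fill_holes = fill_holes)
}

#' Manual segmentation edits
#'
#' Removals name existing label ids to delete; additions are disks
#' (`x`, `y`, `radius`) or polygons rasterised as fresh labels that never
#' overwrite existing objects.
#'
#' @slot removals integer label ids to remove.
#' @slot additions data.frame with columns `x`, `y`, `radius` (disk seeds),
#'   or a list of polygon data.frames with columns `x`, `y`.
#' @export
setClass("ManualEdits",
  representation(removals = "integer", additions = "ANY"),
  validity = function(object) {
    a <- object@additions
    if (is.null(a) || is.data.frame(a) && all(c("x", "y", "radius") %in% names(a)))
      return(TRUE)
    if (is.list(a) && all(vapply(a, function(p)
          is.data.frame(p) && all(c("x", "y") %in% names(p)), logical(1))))
      return(TRUE)
    "additions must be NULL, a (x, y, radius) data.frame, or polygon list"
  })

#' @describeIn ManualEdits-class constructor.
#' @param removals,additions see slots.
#' @export
manualEdits <- function(removals = integer(), additions = NULL) {
  new("ManualEdits", removals = as.integer(removals), additions = additions)
}

#' Per-probe spot detector settings
#'
#' `s1` and `s2` are the fine and coarse Gaussian sigmas of the
#' difference-of-Gaussian filter; `prominence` is the topographic-prominence
#' cutoff applied to maxima of the filtered image.
#'
#' @slot probe probe name.
#' @slot s1,s2 Gaussian sigmas (px), `0 < s1 < s2`.
#' @slot prominence prominence cutoff (intensity units), > 0.
#' @export
setClass("ProbeSettings",
  representation(probe = "character", s1 = "numeric", s2 = "numeric",
                 prominence = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@s1 > 0 && object@s1 < object@s2))
      msg <- c(msg, "need 0 < s1 < s2")
    if (object@prominence <= 0) msg <- c(msg, "prominence must be > 0")
    if (length(msg)) msg else TRUE
  })

#' A set of detected puncta for one probe channel
#'
#' @slot probe probe name.
#' @slot points data.frame with 0-based pixel coordinates `x` (column) and
#'   `y` (row).
#' @slot peak_values filtered-image intensities at the points.
#' @export
setClass("PunctaSet",
  representation(probe = "character", points = "data.frame",
                 peak_values = "numeric"),
  validity = function(object) {
    p <- object@points
    if (!all(c("x", "y") %in% names(p))) return("points needs columns x, y")
    if (nrow(p) != length(object@peak_values))
      return("peak_values must match points")
    if (anyDuplicated(p[, c("x", "y")])) return("duplicate coordinates")
    TRUE
  })

#' Calibration of automated counts against hand counts
#'
#' Ordinary least squares of automated on hand counts; RMSE and MAE are
#' computed on the raw paired differences (automated minus hand), so they
#' measure absolute count agreement rather than scatter about the fit.
#'
#' @slot probe probe name (may be empty).
#' @slot slope,intercept OLS coefficients.
#' @slot r_squared coefficient of determination of the fit.
#' @slot rmse,mae root-mean-square and mean absolute error of auto - hand.
#' @slot n number of paired observations.
#' @export
setClass("CalibrationResult",
  representation(probe = "character", slope = "numeric", intercept = "numeric",
    r_squared = "numeric", rmse = "numeric", mae = "numeric", n = "integer"),
  validity = function(object) {
    if (object@r_squared < -1e-12 || object@r_squared > 1 + 1e-12)
      return("r_squared must be in [0, 1]")
    if (object@rmse + 1e-12 < object@mae) return("rmse must be >= mae")
    TRUE
  })

#' Pairwise Pearson correlation structure of region densities
#'
#' @slot regions region codes (row/column order of the matrices).
#' @slot r Pearson correlation matrix.
#' @slot p two-tailed p-value matrix.
#' @slot n matrix of pairwise complete-case counts.
#' @export
setClass("CorrelationMatrix",
  representation(regions = "character", r = "matrix", p = "matrix",
                 n = "matrix"),
  validity = function(object) {
    r <- object@r
    if (!isTRUE(all.equal(r, t(r), tolerance = 1e-12)))
      return("r must be symmetric")
    if (any(abs(diag(r)) - 1 > 1e-12)) return("diagonal of r must be 1")
    if (any(r < -1 - 1e-12 | r > 1 + 1e-12)) return("r must lie in [-1, 1]")
    TRUE
  })

#' Result of a group-comparison test
#'
#' @slot method test name.
#' @slot statistic named test statistic (t, U or F).
#' @slot df degrees of freedom (length 1, or 2 for ANOVA).
#' @slot p.value two-tailed p-value.
#' @export
setClass("StatResult",
  representation(method = "character", statistic = "numeric", df = "numeric",
                 p.value = "numeric"),
  validity = function(object) {
    if (object@p.value < 0 || object@p.value > 1)
      return("p must be in [0, 1]")
    TRUE
  })

stat_result <- function(method, statistic, df, p) {
  new("StatResult", method = method, statistic = statistic, df = df,
      p.value = as.numeric(p))
}
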