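#' Number of labelled objects
#'
#' @param x a [LabelMap-class].
#' @return integer count of labels.
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))

#' @rdname nLabels
#' @export
setMethod("nLabels", "LabelMap", function(x) max(0L, max(x@.Data)))

#' Pixel areas of labelled objects
#'
#' @param x a [LabelMap-class].
#' @return named integer vector of pixel areas, one per label.
#' @export
setGeneric("labelAreas", function(x) standardGeneric("labelAreas"))

#' @rdname labelAreas
#' @export
setMethod("labelAreas", "LabelMap", function(x) {
  v <- as.vector(x@.Data)
  v <- v[v > 0]
  k <- nLabels(x)
  out <- integer(k)
  if (k > 0) {
    tab <- tabulate(v, nbins = k)
    out <- tab
    names(out) <- as.character(seq_len(k))
  }
  out
})

#' Detected spot coordinates
#'
#' @param x a [PunctaSet-class].
#' @return data.frame with 0-based columns `x`, `y`.
#' @export
setGeneric("punctaCoords", function(x) standardGeneric("punctaCoords"))

#' @rdname punctaCoords
#' @export
setMethod("punctaCoords", "PunctaSet", function(x) x@points)

#' Number of detected puncta
#'
#' @param x a [PunctaSet-class].
#' @export
setGeneric("nPuncta", function(x) standardGeneric("nPuncta"))

#' @rdname nPuncta
#' @export
setMethod("nPuncta", "PunctaSet", function(x) nrow(x@points))

#' Probe name of a settings or puncta object
#'
#' @param x a [ProbeSettings-class] or [PunctaSet-class].
#' @export
setGeneric("probeName", function(x) standardGeneric("probeName"))

#' @rdname probeName
#' @export
setMethod("probeName", "ProbeSettings", function(x) x@probe)

#' @rdname probeName
#' @export
setMethod("probeName", "PunctaSet", function(x) x@probe)

#' Correlation estimates of a CorrelationMatrix
#'
#' @param x a [CorrelationMatrix-class].
#' @return the Pearson r matrix.
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname corValues
#' @export
setMethod("corValues", "CorrelationMatrix", function(x) x@r)

#' Two-tailed p-values of a CorrelationMatrix
#'
#' @param x a [CorrelationMatrix-class].
#' @export
setGeneric("corPValues", function(x) standardGeneric("corPValues"))

#' @rdname corPValues
#' @export
setMethod("corPValues", "CorrelationMatrix", function(x) x@p)

setMethod("show", "LabelMap", function(object) {
  cat("LabelMap:", nrow(object@.Data), "x", ncol(object@.Data),
      "pixels,", nLabels(object), "objects\n")
})

setMethod("show", "SceneConfig", function(object) {
  cat("SceneConfig:", object@width, "x", object@height, "px,",
      object@n_nuclei, "nuclei (radius", object@radius_range[1], "-",
      object@radius_range[2], "px, touching fraction",
      object@touching_fraction, ")\n")
  cat("  spots: sigma", object@spot_sigma, "amplitude", object@spot_amplitude,
      "| noise sigma", object@noise_sigma, "| seed", object@seed, "\n")
})

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene:", nrow(object@dapi), "x", ncol(object@dapi),
      "px,", nLabels(object@labels), "nuclei,",
      length(object@probes), "probe channel(s),",
      nrow(object@puncta), "true puncta\n")
})

setMethod("show", "ProbeSettings", function(object) {
  cat(sprintf("ProbeSettings '%s': s1 = %g, s2 = %g, prominence = %g\n",
              object@probe, object@s1, object@s2, object@prominence))
})

setMethod("show", "PunctaSet", function(object) {
  cat(sprintf("PunctaSet '%s': %d puncta\n", object@probe, nPuncta(object)))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult%s: n = %d, slope = %.4f, intercept = %.4f\n  R^2 = %.4f, RMSE = %.4f, MAE = %.4f\n",
    if (nzchar(object@probe)) paste0(" '", object@probe, "'") else "",
    object@n, object@slope, object@intercept, object@r_squared,
    object@rmse, object@mae))
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat("CorrelationMatrix over", length(object@regions), "regions:",
      paste(object@regions, collapse = ", "), "\n")
  print(round(object@r, 3))
})

setMethod("show", "StatResult", function(object) {
  stat <- paste(sprintf("%s = %.4f", names(object@statistic),
                        object@statistic), collapse = ", ")
  cat(sprintf("%s: %s, df = %s, p = %.4g\n", object@method, stat,
              paste(object@df, collapse = ", "), object@p.value))
})
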