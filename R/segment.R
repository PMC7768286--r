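#' Gaussian preprocessing blur
#'
#' Smooths an image with an isotropic Gaussian whose sigma is half the
#' stated blur diameter (the stated diameter is treated as 2 sigma), using
#' reflective (half-sample symmetric) boundary handling. The default
#' diameter of 18 px therefore applies sigma = 9.
#'
#' @param image 2D numeric matrix.
#' @param blur_diameter blur diameter in px (> 0).
#' @return smoothed matrix of the same size.
#' @export
gaussianPreprocess <- function(image, blur_diameter = 18) {
  image <- as_image_matrix(image)
  if (blur_diameter <= 0) stop("blur_diameter must be > 0")
  conv_gauss_reflect(image, blur_diameter / 2)
}

#' Minimum cross-entropy (Li) global threshold
#'
#' Selects the global threshold minimising the cross-entropy criterion
#' between the image and its two-class reconstruction,
#' eta(t) = sum(g <= t) g h(g) log(g / mu_b) + sum(g > t) g h(g) log(g / mu_f),
#' evaluated at every candidate cut between distinct intensity values (the
#' term sum g h(g) log g is constant in t and dropped). The returned
#' threshold is the midpoint between the optimal background and foreground
#' classes; pixels strictly above it are foreground. Negative intensities
#' are shifted out before optimisation (the cut is shifted back).
#'
#' @param image 2D numeric matrix with at least two distinct values.
#' @return scalar threshold.
#' @export
minCrossEntropyThreshold <- function(image) {
  image <- as_image_matrix(image)
  v <- sort(as.vector(image))
  r <- rle(v)
  vals <- r$values
  counts <- as.numeric(r$lengths)
  if (length(vals) < 2)
    stop("degenerate histogram: image must contain at least two distinct values")
  shift <- 0
  if (vals[1] < 0) {
    shift <- -vals[1]
    vals <- vals + shift
  }
  n <- length(vals)
  cw <- cumsum(counts)
  cm <- cumsum(vals * counts)
  i <- seq_len(n - 1)
  Mb <- cm[i];      Nb <- cw[i]
  Mf <- cm[n] - Mb; Nf <- cw[n] - Nb
  term_b <- ifelse(Mb > 0, Mb * log(Mb / Nb), 0)
  term_f <- ifelse(Mf > 0, Mf * log(Mf / Nf), 0)
  best <- which.min(-(term_b + term_f))
  (vals[best] + vals[best + 1]) / 2 - shift
}

# local maxima of img inside mask with minimum separation enforced by a
# flat max-filter window; returns labelled seed clusters (ties grouped)
.intensity_seeds <- function(img, mask, min_sep) {
  off <- disk_offsets(min_sep)
  mx <- gray_morph(img, as.integer(off$dx), as.integer(off$dy),
                   rep(0, nrow(off)), dilate = TRUE)
  cand <- (img >= mx) & mask
  seeds <- label_components(matrix(as.integer(cand), nrow(img)), 8L)
  # guarantee one seed per binary component
  comp <- label_components(matrix(as.integer(mask), nrow(img)), 4L)
  kc <- max(comp)
  if (kc > 0) {
    have <- unique(comp[seeds > 0])
    missing <- setdiff(seq_len(kc), have)
    nxt <- max(seeds)
    for (m in missing) {
      pix <- which(comp == m)
      nxt <- nxt + 1L
      seeds[pix[which.max(img[pix])]] <- nxt
    }
  }
  seeds
}

#' Segment nuclei from a DAPI channel
#'
#' Pipeline: Gaussian preprocessing blur (diameter treated as 2 sigma) ->
#' additional smoothing with sigma = `threshold_smoothing_scale` / 1.3488 ->
#' minimum cross-entropy global threshold -> intensity-based declumping of
#' touching objects (seeds at local maxima of the preprocessed intensity
#' separated by at least `min_diameter` / 2, then seeded watershed on the
#' inverted preprocessed intensity restricted to the mask) -> per-object
#' hole filling -> removal of objects with equivalent diameter
#' 2 sqrt(area / pi) outside `[min_diameter, max_diameter]` -> removal of
#' border-touching objects -> contiguous relabelling.
#'
#' @param dapi_image 2D numeric matrix (DAPI channel).
#' @param params a [SegmentationParams-class].
#' @return a [LabelMap-class]; an all-zero map when nothing is found.
#' @export
segmentNuclei <- function(dapi_image, params = segmentationParams()) {
  stopifnot(is(params, "SegmentationParams"))
  validObject(params)
  img <- as_image_matrix(dapi_image, "dapi_image")
  pre <- gaussianPreprocess(img, params@blur_diameter)
  sm <- pre
  s_th <- params@threshold_smoothing_scale / 1.3488
  if (s_th > 0) sm <- conv_gauss_reflect(pre, s_th)
  if (length(unique(as.vector(sm))) < 2)
    return(LabelMap(matrix(0L, nrow(img), ncol(img))))
  th <- minCrossEntropyThreshold(sm)
  mask <- sm > th
  if (!any(mask)) return(LabelMap(matrix(0L, nrow(img), ncol(img))))
  maski <- matrix(as.integer(mask), nrow(img))
  if (params@declump == "intensity") {
    seeds <- .intensity_seeds(pre, mask, params@min_diameter / 2)
    lab <- watershed_seeded(-pre, seeds, maski)
  } else {
    lab <- label_components(maski, 4L)
  }
  if (params@fill_holes) lab <- fill_holes_labels(lab)
  k <- max(lab)
  if (k > 0) {
    areas <- tabulate(lab[lab > 0], nbins = k)
    eqd <- 2 * sqrt(areas / pi)
    drop <- which(eqd < params@min_diameter | eqd > params@max_diameter)
    if (params@exclude_edges) {
      border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      drop <- union(drop, border[border > 0])
    }
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  LabelMap(lab, relabel = TRUE)
}

.rasterize_addition <- function(dim_hw, add) {
  H <- dim_hw[1]; W <- dim_hw[2]
  m <- matrix(FALSE, H, W)
  if (is.data.frame(add) && all(c("x", "y", "radius") %in% names(add))) {
    # disk at seed
    off <- disk_offsets(add$radius)
    rows <- floor(add$y + 0.5) + 1 + off$dy
    cols <- floor(add$x + 0.5) + 1 + off$dx
    keep <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
    m[cbind(rows[keep], cols[keep])] <- TRUE
  } else {
    # polygon fill (boundary-inclusive even-odd)
    vx <- add$x; vy <- add$y
    r0 <- max(1, floor(min(vy)) ); r1 <- min(H, ceiling(max(vy)) + 2)
    c0 <- max(1, floor(min(vx)) ); c1 <- min(W, ceiling(max(vx)) + 2)
    for (r in r0:r1) for (c in c0:c1)
      if (point_in_polygon(c - 1, r - 1, vx, vy)) m[r, c] <- TRUE
  }
  m
}

#' Apply manual edits to a label map
#'
#' Listed labels are removed (zeroed); additions (disks at seed points or
#' filled polygons) become fresh labels that never overwrite existing
#' objects -- pixels already labelled keep their label. The result is
#' relabelled contiguously.
#'
#' @param labels a [LabelMap-class].
#' @param edits a [ManualEdits-class].
#' @return an edited [LabelMap-class].
#' @export
applyManualEdits <- function(labels, edits) {
  stopifnot(is(labels, "LabelMap"), is(edits, "ManualEdits"))
  lab <- labels@.Data
  if (length(edits@removals)) {
    unknown <- setdiff(edits@removals, unique(as.vector(lab)))
    if (length(unknown))
      stop("cannot remove unknown label id(s): ",
           paste(unknown, collapse = ", "))
    lab[lab %in% edits@removals] <- 0L
  }
  adds <- edits@additions
  if (!is.null(adds)) {
    add_list <- if (is.data.frame(adds) && "radius" %in% names(adds))
      split(adds, seq_len(nrow(adds))) else adds
    nxt <- max(lab)
    for (a in add_list) {
      m <- .rasterize_addition(dim(lab), a)
      m[lab > 0] <- FALSE
      if (any(m)) {
        nxt <- nxt + 1L
        lab[m] <- nxt
      }
    }
  }
  LabelMap(lab, relabel = TRUE)
}
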