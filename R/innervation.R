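#' Brain-region codes of the innervation analysis
#'
#' The fixed vocabulary of target regions for per-animal percent-area
#' densities: dorsal paragigantocellular nucleus, periaqueductal gray,
#' medial preoptic area, dorsal lateral geniculate, medial habenula, caudal
#' pontine reticular nucleus, inferior colliculus, lateral lemniscus,
#' superior olivary complex and cochlear nucleus complex.
#'
#' @return character vector of region codes.
#' @export
regionCodes <- function() {
  c("DPGi", "PAG", "mPOA", "dLGN", "mHb", "PnC", "IC", "LL", "SOC", "CNC")
}

#' Auditory subset of the region vocabulary
#' @return character vector.
#' @export
auditoryRegions <- function() c("CNC", "SOC", "LL", "IC", "PnC")

#' Percent area occupied by projection signal in a z-stack
#'
#' Per slice: rolling-ball background subtraction, a global threshold, and
#' connected-component filtering by minimum particle size; the percent area
#' is 100 times the summed above-threshold particle pixels over all slices
#' divided by the total pixel count of the stack. The default threshold is
#' a robust background estimate of the background-subtracted slice,
#' median + k * 1.4826 * MAD (`method = "mad"`, k = 3), insensitive to the
#' sparse signal itself; `method = "mean_sd"` uses mean + k * sd instead.
#'
#' @param zstack 3D array (rows x cols x slices) or a list of matrices.
#' @param k threshold multiplier (default 3).
#' @param method `"mad"` (default) or `"mean_sd"`.
#' @param ball_radius rolling-ball radius per slice (default 25 px).
#' @param min_particle minimum connected-particle size in px (default 4).
#' @return percent area in `[0, 100]`.
#' @export
percentAreaStack <- function(zstack, k = 3, method = c("mad", "mean_sd"),
                             ball_radius = 25, min_particle = 4) {
  method <- match.arg(method)
  if (is.list(zstack)) {
    slices <- lapply(zstack, as_image_matrix)
  } else {
    d <- dim(zstack)
    if (length(d) != 3) stop("zstack must be a 3D array or list of matrices")
    slices <- lapply(seq_len(d[3]), function(s) zstack[, , s])
  }
  if (!length(slices)) stop("stack is empty")
  occupied <- 0
  total <- 0
  for (sl in slices) {
    total <- total + length(sl)
    sub <- rollingBallSubtract(sl, ball_radius)
    th <- if (method == "mad") median(sub) + k * mad(sub) else
      mean(sub) + k * sd(sub)
    bw <- sub > th
    if (!any(bw)) next
    lab <- label_components(matrix(as.integer(bw), nrow(sl)), 4L)
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_particle)
    occupied <- occupied + sum(sizes[keep])
  }
  100 * occupied / total
}

#' Average per-image percent areas into per-animal region densities
#'
#' Bilateral (or replicate) stacks of the same region are averaged within
#' each animal; animal-level densities are the statistical units downstream.
#'
#' @param per_image data.frame with columns `animal_id`, `region`,
#'   `percent_area` and optionally `sex`.
#' @return data.frame with one row per animal x region (columns `animal_id`,
#'   `sex`, `region`, `percent_area`).
#' @export
aggregateRegion <- function(per_image) {
  stopifnot(all(c("animal_id", "region", "percent_area") %in% names(per_image)))
  bad <- setdiff(unique(per_image$region), regionCodes())
  if (length(bad))
    stop("unknown region code(s): ", paste(bad, collapse = ", "))
  key <- interaction(per_image$animal_id, per_image$region, drop = TRUE)
  rows <- lapply(split(per_image, key), function(r)
    data.frame(animal_id = r$animal_id[1],
               sex = if ("sex" %in% names(r)) r$sex[1] else NA,
               region = r$region[1],
               percent_area = mean(r$percent_area),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$animal_id, out$region), ]
}

#' Pearson correlation with a two-tailed p-value
#'
#' Sample Pearson r with significance from t = r sqrt((n - 2) / (1 - r^2))
#' on n - 2 degrees of freedom (two-tailed).
#'
#' @param x,y numeric vectors (n >= 3, both non-constant).
#' @return list with `r`, `p`, `n`.
#' @export
pearsonRP <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pairwise cross-region correlation matrix of innervation densities
#'
#' Computes every pairwise Pearson correlation (with two-tailed p-values)
#' over animals of the per-animal region-density table, optionally within
#' one group (e.g. a sex). Pairs with missing values use complete cases; a
#' pair with fewer than 3 complete animals is left `NA` with a warning.
#'
#' @param densities data.frame with `animal_id`, `region`, `percent_area`
#'   and optionally `sex`.
#' @param regions region codes to include (default: those present, in
#'   [regionCodes()] order).
#' @param sex optional group filter applied to the `sex` column.
#' @return a [CorrelationMatrix-class].
#' @export
correlationMatrix <- function(densities, regions = NULL, sex = NULL) {
  if (!is.null(sex)) densities <- densities[densities$sex %in% sex, ]
  if (is.null(regions))
    regions <- intersect(regionCodes(), unique(densities$region))
  k <- length(regions)
  if (k < 2) stop("need at least two regions")
  animals <- unique(densities$animal_id)
  if (length(animals) < 3) stop("need at least 3 animals in the group")
  wide <- matrix(NA_real_, length(animals), k,
                 dimnames = list(animals, regions))
  for (i in seq_len(nrow(densities))) {
    if (densities$region[i] %in% regions)
      wide[as.character(densities$animal_id[i]), densities$region[i]] <-
        densities$percent_area[i]
  }
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  diag(r) <- 1; diag(p) <- 0
  diag(n) <- colSums(!is.na(wide))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- complete.cases(wide[, i], wide[, j])
    if (sum(ok) < 3) {
      warning("fewer than 3 complete animals for pair ", regions[i], "-",
              regions[j], "; left NA")
      next
    }
    pr <- pearsonRP(wide[ok, i], wide[ok, j])
    r[i, j] <- r[j, i] <- pr$r
    p[i, j] <- p[j, i] <- pr$p
    n[i, j] <- n[j, i] <- pr$n
  }
  new("CorrelationMatrix", regions = regions, r = r, p = p, n = n)
}

#' Heatmap of a cross-region correlation matrix
#'
#' Renders the r matrix with the green (positive) to black (negative)
#' diverging scale used for innervation covariance displays. Requires the
#' pheatmap package.
#'
#' @param cm a [CorrelationMatrix-class].
#' @param filename optional path to write the plot to.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plotCorrelationMatrix <- function(cm, filename = NA, ...) {
  stopifnot(is(cm, "CorrelationMatrix"))
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotCorrelationMatrix requires the pheatmap package")
  pal <- grDevices::colorRampPalette(c("black", "#003300", "#00CC44",
                                       "#66FF99"))(100)
  ph <- pheatmap::pheatmap(corValues(cm), cluster_rows = FALSE,
    cluster_cols = FALSE, breaks = seq(-1, 1, length.out = 101),
    color = pal, filename = filename, ...)
  invisible(ph)
}
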