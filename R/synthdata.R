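## Synthetic microscopy scenes with exact ground truth.
##
## Nuclei are rendered as anisotropic ellipses with a smooth edge falloff and
## a centre-weighted interior gradient (chromatin-like bright core), composed
## by per-pixel maximum so touching nuclei keep an intensity dip along their
## contact line. FISH channels carry Gaussian puncta placed inside nucleus
## label regions, diffuse large-sigma background blobs and additive Gaussian
## noise. All randomness is controlled by the config seed.

# elliptical normalised distance of pixel grid to one nucleus
.ellipse_dist <- function(rows, cols, cx, cy, a, b, theta) {
  # rows/cols are 1-based pixel indices; centre in 0-based coords
  u <- (cols - 1) - cx
  v <- (rows - 1) - cy
  ct <- cos(theta); st <- sin(theta)
  sqrt(((u * ct + v * st) / a)^2 + ((-u * st + v * ct) / b)^2)
}

# radial intensity profile: plateau + central bump, steep edge beyond d = 1
.nucleus_profile <- function(d, amplitude) {
  core <- 0.5 + 0.5 * exp(-d^2 / (2 * 0.30^2))
  edge_val <- 0.5 + 0.5 * exp(-1 / (2 * 0.30^2))
  out <- ifelse(d <= 1, core, edge_val * exp(-((d - 1) / 0.08)^2))
  amplitude * out
}

.place_nuclei <- function(config) {
  n <- config@n_nuclei
  if (n == 0)
    return(data.frame(cx = numeric(), cy = numeric(), r = numeric(),
                      a = numeric(), b = numeric(), theta = numeric(),
                      pair = integer()))
  W <- config@width; H <- config@height
  rmax <- config@radius_range[2]
  margin <- 1.4 * rmax + 3
  if (2 * margin >= W || 2 * margin >= H)
    stop("nuclei do not fit: image too small for the requested radius range")
  n_pairnuc <- round(config@touching_fraction * n)
  if (n_pairnuc %% 2 == 1) n_pairnuc <- n_pairnuc - 1
  n_pairs <- n_pairnuc / 2
  n_single <- n - n_pairnuc

  for (restart in 1:25) {
    ok <- TRUE
    cx <- cy <- r <- theta <- q <- numeric(0)
    pair <- integer(0)
    clear_of_others <- function(x, y, rad, exclude = integer(0)) {
      if (!length(cx)) return(TRUE)
      keep <- setdiff(seq_along(cx), exclude)
      if (!length(keep)) return(TRUE)
      d <- sqrt((cx[keep] - x)^2 + (cy[keep] - y)^2)
      all(d >= 1.35 * (r[keep] + rad) + 4)
    }
    draw_radius <- function() runif(1, config@radius_range[1], config@radius_range[2])
    place_one <- function(rad, exclude = integer(0)) {
      for (i in 1:400) {
        x <- runif(1, margin, W - 1 - margin)
        y <- runif(1, margin, H - 1 - margin)
        if (clear_of_others(x, y, rad, exclude)) return(c(x, y))
      }
      NULL
    }
    pid <- 0L
    for (p in seq_len(n_pairs)) {
      r1 <- draw_radius(); r2 <- draw_radius()
      placed <- FALSE
      for (i in 1:400) {
        anchor <- place_one(r1 + r2)  # reserve room for the partner too
        if (is.null(anchor)) break
        sep <- runif(1, 0.8, 1.2) * mean(c(r1, r2))
        ang <- runif(1, 0, 2 * pi)
        px <- anchor[1] + sep * cos(ang); py <- anchor[2] + sep * sin(ang)
        if (px < margin || px > W - 1 - margin ||
            py < margin || py > H - 1 - margin) next
        if (!clear_of_others(px, py, r2)) next
        pid <- pid + 1L
        cx <- c(cx, anchor[1], px); cy <- c(cy, anchor[2], py)
        r <- c(r, r1, r2); pair <- c(pair, pid, pid)
        theta <- c(theta, runif(2, 0, pi))
        q <- c(q, runif(2, config@axis_ratio_range[1], config@axis_ratio_range[2]))
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) for (s in seq_len(n_single)) {
      rad <- draw_radius()
      pos <- place_one(rad)
      if (is.null(pos)) { ok <- FALSE; break }
      cx <- c(cx, pos[1]); cy <- c(cy, pos[2]); r <- c(r, rad)
      pair <- c(pair, 0L)
      theta <- c(theta, runif(1, 0, pi))
      q <- c(q, runif(1, config@axis_ratio_range[1], config@axis_ratio_range[2]))
    }
    if (ok)
      return(data.frame(cx = cx, cy = cy, r = r, a = r / sqrt(q),
                        b = r * sqrt(q), theta = theta, pair = pair))
  }
  stop("could not place ", n, " nuclei in a ", W, "x", H,
       " image after bounded retries")
}

.render_nuclei <- function(config, nuclei) {
  W <- config@width; H <- config@height
  img <- matrix(0, H, W)
  lab <- matrix(0L, H, W)
  dbest <- matrix(Inf, H, W)
  for (i in seq_len(nrow(nuclei))) {
    ni <- nuclei[i, ]
    ext <- ceiling(max(ni$a, ni$b) * 1.4) + 2
    r0 <- max(1, floor(ni$cy + 1 - ext)); r1 <- min(H, ceiling(ni$cy + 1 + ext))
    c0 <- max(1, floor(ni$cx + 1 - ext)); c1 <- min(W, ceiling(ni$cx + 1 + ext))
    rows <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)
    cols <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
    d <- .ellipse_dist(rows, cols, ni$cx, ni$cy, ni$a, ni$b, ni$theta)
    val <- .nucleus_profile(d, config@nucleus_amplitude)
    sub <- img[r0:r1, c0:c1]
    img[r0:r1, c0:c1] <- pmax(sub, val)
    inside <- d <= 1
    closer <- inside & d < dbest[r0:r1, c0:c1]
    labsub <- lab[r0:r1, c0:c1]
    labsub[closer] <- i
    lab[r0:r1, c0:c1] <- labsub
    dsub <- dbest[r0:r1, c0:c1]
    dsub[closer] <- d[closer]
    dbest[r0:r1, c0:c1] <- dsub
  }
  img <- img + config@dapi_background
  if (config@noise_sigma > 0)
    img <- img + matrix(rnorm(H * W, 0, config@noise_sigma), H, W)
  list(dapi = img, labels = LabelMap(lab), nuclei = nuclei)
}

.make_nuclei <- function(config) .render_nuclei(config, .place_nuclei(config))

#' Generate a synthetic DAPI scene of nuclei with ground-truth labels
#'
#' Renders `n_nuclei` smooth-edged elliptical nuclei with a centre-weighted
#' interior gradient; the requested fraction is placed as touching pairs
#' (centre separation 0.8-1.2 x mean radius) to exercise declumping. The
#' returned label map records every nucleus (both members of a pair) as a
#' distinct label; overlap pixels go to the nucleus with the smaller
#' normalised elliptical distance.
#'
#' @param config a [SceneConfig-class].
#' @return list with `dapi` (intensity matrix), `labels` (a
#'   [LabelMap-class]), and `nuclei` (data.frame of centres, radii,
#'   orientations, pair ids).
#' @examples
#' sc <- makeNucleiScene(sceneConfig(n_nuclei = 4, seed = 7))
#' nLabels(sc$labels)
#' @export
makeNucleiScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  with_seed(config@seed, .make_nuclei(config))
}

.render_spot <- function(img, x, y, sigma, amplitude) {
  H <- nrow(img); W <- ncol(img)
  w <- ceiling(4 * sigma) + 1
  r0 <- max(1, floor(y + 1 - w)); r1 <- min(H, ceiling(y + 1 + w))
  c0 <- max(1, floor(x + 1 - w)); c1 <- min(W, ceiling(x + 1 + w))
  rows <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)
  cols <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  g <- amplitude * exp(-(((cols - 1) - x)^2 + ((rows - 1) - y)^2) / (2 * sigma^2))
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + g
  img
}

.make_puncta <- function(labels, config, counts) {
  lab <- if (is(labels, "LabelMap")) labels@.Data else labels
  H <- nrow(lab); W <- ncol(lab)
  img <- matrix(0, H, W)
  pts <- list()
  ids <- as.integer(names(counts))
  for (k in seq_along(counts)) {
    id <- ids[k]; cnt <- as.integer(counts[k])
    if (cnt == 0) next
    pix <- which(lab == id)
    if (!length(pix)) stop("cell ", id, " not present in label map")
    prow <- (pix - 1) %% H      # 0-based row
    pcol <- (pix - 1) %/% H     # 0-based col
    accx <- accy <- numeric(0)
    fail_streak <- 0L
    while (length(accx) < cnt) {
      if (fail_streak > 2000L || length(pix) < cnt)
        stop("cannot place ", cnt, " puncta in cell ", id,
             " under the minimum-separation constraint")
      j <- sample.int(length(pix), 1)
      x <- pcol[j] + runif(1, -0.49, 0.49)
      y <- prow[j] + runif(1, -0.49, 0.49)
      if (length(accx) &&
          min((accx - x)^2 + (accy - y)^2) < config@spot_min_sep^2) {
        fail_streak <- fail_streak + 1L
        next
      }
      fail_streak <- 0L
      accx <- c(accx, x); accy <- c(accy, y)
    }
    for (j in seq_len(cnt))
      img <- .render_spot(img, accx[j], accy[j], config@spot_sigma,
                          config@spot_amplitude)
    pts[[length(pts) + 1]] <- data.frame(cell = id, x = accx, y = accy)
  }
  nb <- if (config@bg_blob_density > 0) rpois(1, config@bg_blob_density * W * H) else 0
  for (b in seq_len(nb))
    img <- .render_spot(img, runif(1, 0, W - 1), runif(1, 0, H - 1),
                        config@bg_blob_sigma, config@bg_blob_amplitude)
  if (config@noise_sigma > 0)
    img <- img + matrix(rnorm(H * W, 0, config@noise_sigma), H, W)
  puncta <- if (length(pts)) do.call(rbind, pts) else
    data.frame(cell = integer(), x = numeric(), y = numeric())
  list(image = img, puncta = puncta)
}

#' Render a synthetic FISH probe channel into a labelled scene
#'
#' Places exactly `counts[cell]` Gaussian puncta uniformly inside each
#' cell's label region with centre separation at least `spot_min_sep`
#' (itself constrained to at least twice the spot sigma), then adds diffuse
#' background blobs and Gaussian noise.
#'
#' @param labels a [LabelMap-class] (or integer matrix) of cells.
#' @param config a [SceneConfig-class].
#' @param counts named vector mapping cell label to the number of puncta.
#' @param seed seed for this channel; defaults to the config seed.
#' @return list with `image` and `puncta` (data.frame `cell`, `x`, `y` with
#'   0-based coordinates).
#' @export
makePunctaChannel <- function(labels, config, counts, seed = config@seed) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  if (is.null(names(counts)))
    names(counts) <- seq_along(counts)
  lab <- if (is(labels, "LabelMap")) labels@.Data else labels
  present <- unique(as.vector(lab))
  bad <- setdiff(as.integer(names(counts)), present)
  if (length(bad))
    stop("counts refer to labels absent from the map: ",
         paste(bad, collapse = ", "))
  with_seed(seed, .make_puncta(labels, config, counts))
}

#' Generate a complete synthetic FISH scene with ground truth
#'
#' Builds the DAPI nucleus scene plus one channel per probe with per-cell
#' puncta counts drawn uniformly from `config@puncta_range`, and returns a
#' validated [SyntheticScene-class] whose invariants (puncta inside their
#' cell's label, counts equal to coordinate tallies) are checked on
#' construction.
#'
#' @param config a [SceneConfig-class].
#' @param probes character vector of probe names.
#' @return a [SyntheticScene-class].
#' @export
makeFishScene <- function(config, probes = "probeA") {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  with_seed(config@seed, {
    nuc <- .make_nuclei(config)
    k <- nLabels(nuc$labels)
    probe_imgs <- list()
    puncta <- list()
    counts <- list()
    for (p in probes) {
      cnt <- if (k > 0)
        sample(config@puncta_range[1]:config@puncta_range[2], k, replace = TRUE)
      else integer(0)
      names(cnt) <- seq_len(k)
      ch <- .make_puncta(nuc$labels, config, cnt)
      probe_imgs[[p]] <- ch$image
      if (nrow(ch$puncta))
        puncta[[p]] <- cbind(probe = p, ch$puncta)
      counts[[p]] <- data.frame(probe = p, cell = seq_len(k),
                                count = as.integer(cnt))
    }
    new("SyntheticScene", dapi = nuc$dapi, probes = probe_imgs,
        labels = nuc$labels,
        puncta = if (length(puncta)) do.call(rbind, puncta) else
          data.frame(probe = character(), cell = integer(),
                     x = numeric(), y = numeric()),
        counts = do.call(rbind, counts), config = config)
  })
}

#' Generate a sparse synthetic bouton z-stack with known occupied fraction
#'
#' Bright disk-shaped boutons are stamped into random slices until the
#' pooled fraction of occupied pixels reaches the target; the achieved
#' fraction (exact by construction, within one bouton footprint of the
#' target) is returned as truth.
#'
#' @param target_fraction target occupied-area fraction pooled over slices,
#'   in `[0, 0.5]`.
#' @param n_slices number of optical slices (default 21).
#' @param width,height slice size in pixels.
#' @param bouton_radius bouton disk radius (px).
#' @param amplitude bouton intensity; per-bouton brightness jitters by +/-15%.
#' @param noise_sigma additive Gaussian noise sd.
#' @param seed random seed.
#' @return list with `stack` (array height x width x n_slices) and
#'   `truth_fraction`.
#' @export
makeInnervationStack <- function(target_fraction, n_slices = 21,
                                 width = 128, height = 128,
                                 bouton_radius = 2, amplitude = 100,
                                 noise_sigma = 5, seed = 1L) {
  if (target_fraction < 0 || target_fraction > 0.5)
    stop("target_fraction must be in [0, 0.5]")
  with_seed(seed, {
    total <- width * height * n_slices
    covered <- array(FALSE, dim = c(height, width, n_slices))
    stack <- array(0, dim = c(height, width, n_slices))
    off <- disk_offsets(bouton_radius)
    goal <- target_fraction * total
    ncov <- 0
    guard <- 0L
    while (ncov < goal) {
      guard <- guard + 1L
      if (guard > 50 * goal) stop("bouton placement did not converge")
      s <- sample.int(n_slices, 1)
      cx <- sample.int(width - 2 * bouton_radius - 1, 1) + bouton_radius
      cy <- sample.int(height - 2 * bouton_radius - 1, 1) + bouton_radius
      rows <- cy + off$dy; cols <- cx + off$dx
      idx <- cbind(rows, cols, s)
      fresh <- !covered[idx]
      covered[idx] <- TRUE
      ncov <- ncov + sum(fresh)
      amp <- amplitude * runif(1, 0.85, 1.15)
      old <- stack[idx]
      stack[idx] <- pmax(old, amp)
    }
    if (noise_sigma > 0)
      stack <- stack + array(rnorm(total, 0, noise_sigma), dim = dim(stack))
    list(stack = stack, truth_fraction = ncov / total)
  })
}

#' Draw a sample with exactly the requested mean and SEM
#'
#' Random values are affinely rescaled so the sample mean and sample SEM
#' (sd / sqrt(n)) match the request exactly; useful for round-trip checks of
#' summary-statistics tests against published mean +/- SEM values.
#'
#' @param mean,sem target sample mean and standard error of the mean.
#' @param n sample size (>= 2).
#' @param seed random seed.
#' @return numeric vector of length `n`.
#' @examples
#' x <- makeGroupSamples(10, 1, 5, seed = 1)
#' c(mean(x), sd(x) / sqrt(5))
#' @export
makeGroupSamples <- function(mean, sem, n, seed = 1L) {
  if (n < 2) stop("n must be >= 2 (SEM undefined otherwise)")
  if (sem <= 0) stop("sem must be > 0")
  with_seed(seed, {
    x <- rnorm(n)
    while (sd(x) == 0) x <- rnorm(n)
    z <- (x - base::mean(x)) / sd(x)
    mean + z * sem * sqrt(n)
  })
}

#' Generate a synthetic per-animal innervation cohort with known correlation
#'
#' Per-animal percent-area densities are drawn from a multivariate normal
#' with the requested cross-region correlation structure (values clamped to
#' `[0, 100]`), emulating the per-animal region-density table that feeds the
#' correlation analysis.
#'
#' @param n_animals number of animals.
#' @param regions character vector of region codes (see [regionCodes()]).
#' @param mean_percent,sd_percent per-region mean and sd of percent area;
#'   recycled to `length(regions)`.
#' @param corr generating correlation matrix (default identity).
#' @param sex optional vector of sexes recycled over animals.
#' @param seed random seed.
#' @return data.frame with columns `animal_id`, `sex`, `region`,
#'   `percent_area`.
#' @export
makeRegionCohort <- function(n_animals, regions, mean_percent = 2,
                             sd_percent = 0.5, corr = NULL, sex = NA,
                             seed = 1L) {
  k <- length(regions)
  mu <- rep_len(mean_percent, k)
  sdv <- rep_len(sd_percent, k)
  if (is.null(corr)) corr <- diag(k)
  if (!isTRUE(all.equal(corr, t(corr))) || any(diag(corr) != 1))
    stop("corr must be a correlation matrix")
  Sigma <- diag(sdv) %*% corr %*% diag(sdv)
  with_seed(seed, {
    m <- MASS::mvrnorm(n_animals, mu, Sigma)
    m <- pmin(pmax(m, 0), 100)
    data.frame(
      animal_id = rep(sprintf("a%02d", seq_len(n_animals)), each = k),
      sex = rep(rep_len(sex, n_animals), each = k),
      region = rep(regions, n_animals),
      percent_area = as.vector(t(m)))
  })
}
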