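# Independent oracles used across tests. These reimplement the checked
# quantities from their definitions (brute force / exhaustive / closed form)
# and share no code with the package internals they validate.

# ---- topographic prominence, brute force ----------------------------------
# 8-connected binary dilation by one step, via matrix shifts
shift_pad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

dilate8_once <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- out | shift_pad(m, dr, dc)
  out
}

# grow seed region S within mask to the connected fixpoint
flood_grow <- function(S, mask) {
  repeat {
    grown <- (dilate8_once(S) & mask) | S
    if (identical(grown, S)) return(S)
    S <- grown
  }
}

# Enumerate all plateau maxima of img and their prominences by definition:
# a plateau is an 8-connected set of equal-valued pixels with no strictly
# higher neighbour; its saddle is the highest level at which the connected
# super-level region containing it reaches dominating terrain -- a strictly
# higher pixel, or (elder rule for ties) an equal-height plateau maximum
# whose first pixel comes earlier in column-major order. Maxima never
# dominated use the image minimum as reference.
oracle_prominences <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  vmin <- min(img)
  levels_desc <- sort(unique(as.vector(img)), decreasing = TRUE)
  seen <- matrix(FALSE, nr, nc)
  plats <- list()
  # pass 1: find all plateau maxima with their pixel sets and birth indices
  for (v in levels_desc) {
    eq <- img == v
    todo <- eq & !seen
    while (any(todo)) {
      idx <- which(todo)[1]
      S0 <- matrix(FALSE, nr, nc); S0[idx] <- TRUE
      plat <- flood_grow(S0, eq)
      seen <- seen | plat
      todo <- eq & !seen
      if (any(dilate8_once(plat) & img > v)) next  # not a maximum
      plats[[length(plats) + 1]] <-
        list(mask = plat, value = v, birth = min(which(plat)))
    }
  }
  if (!length(plats))
    return(data.frame(x = numeric(), y = numeric(), value = numeric(),
                      prominence = numeric()))
  out <- list()
  for (pl in plats) {
    v <- pl$value
    # union of equal-height plateaus that dominate this one
    comp <- matrix(FALSE, nr, nc)
    for (q in plats)
      if (q$value == v && q$birth < pl$birth) comp <- comp | q$mask
    dominated <- function(S) any(img[S] > v) || any(comp[S])
    if (!dominated(matrix(TRUE, nr, nc))) {
      prom <- v - vmin
    } else {
      S <- pl$mask
      prom <- v - vmin
      for (lev in levels_desc[levels_desc < v]) {
        S <- flood_grow(S, img >= lev)
        if (dominated(S)) { prom <- v - lev; break }
      }
    }
    w <- which(pl$mask, arr.ind = TRUE)
    out[[length(out) + 1]] <- c(x = floor(mean(w[, 2] - 1) + 0.5),
                                y = floor(mean(w[, 1] - 1) + 0.5),
                                value = v, prominence = prom)
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$y, df$x), , drop = FALSE]
}

# canonical key for point-set comparison
point_key <- function(df) sort(paste(df$x, df$y, sep = ","))

# ---- minimum cross-entropy, exhaustive ------------------------------------
# Full criterion over all integer cuts t (background: value <= t):
# eta(t) = sum_{g<=t} g h(g) log(g/mu_b) + sum_{g>t} g h(g) log(g/mu_f)
oracle_li_cut <- function(img, cuts = 0:255) {
  v <- as.vector(img)
  eta <- sapply(cuts, function(t) {
    b <- v[v <= t]; f <- v[v > t]
    if (!length(b) || !length(f)) return(Inf)
    tot <- 0
    if (sum(b) > 0) {
      mub <- mean(b); bz <- b[b > 0]
      tot <- tot + sum(bz * log(bz / mub))
    }
    if (sum(f) > 0) {
      muf <- mean(f); fz <- f[f > 0]
      tot <- tot + sum(fz * log(fz / muf))
    }
    tot
  })
  cuts[which.min(eta)]
}

# ---- matching helpers ------------------------------------------------------
# greedy one-to-one matching of detections to truth within a radius
match_f1 <- function(det, truth, radius = 2) {
  if (!nrow(truth)) return(c(precision = NA, recall = NA, f1 = NA))
  if (!nrow(det)) return(c(precision = NA, recall = 0, f1 = 0))
  used <- rep(FALSE, nrow(det))
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    d2 <- (det$x - truth$x[i])^2 + (det$y - truth$y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= radius^2) { tp <- tp + 1; used[j] <- TRUE }
  }
  precision <- tp / nrow(det); recall <- tp / nrow(truth)
  c(precision = precision, recall = recall,
    f1 = 2 * precision * recall / (precision + recall))
}

# per-truth-object Jaccard with its best-overlapping output label
jaccard_per_object <- function(truth_labels, out_labels) {
  tl <- truth_labels@.Data; ol <- out_labels@.Data
  sapply(seq_len(nLabels(truth_labels)), function(i) {
    ti <- tl == i
    hit <- ol[ti]; hit <- hit[hit > 0]
    if (!length(hit)) return(0)
    j <- as.integer(names(which.max(table(hit))))
    sum(ti & (ol == j)) / sum(ti | (ol == j))
  })
}

# fraction of touching pairs resolved into two output labels whose centroids
# each lie within one mean radius of a distinct truth centre
pair_split_stats <- function(scene_nuclei, truth_labels, out_labels) {
  nuc <- scene_nuclei
  tl <- truth_labels@.Data; ol <- out_labels@.Data
  pairs <- setdiff(unique(nuc$pair), 0)
  ok <- 0
  for (p in pairs) {
    idx <- which(nuc$pair == p)
    matched <- integer(0)
    for (i in idx) {
      ti <- tl == i
      hit <- ol[ti]; hit <- hit[hit > 0]
      if (!length(hit)) next
      j <- as.integer(names(which.max(table(hit))))
      w <- which(ol == j, arr.ind = TRUE)
      d <- sqrt((mean(w[, 2]) - 1 - nuc$cx[i])^2 +
                (mean(w[, 1]) - 1 - nuc$cy[i])^2)
      if (d <= mean(nuc$r[idx])) matched <- c(matched, j)
    }
    if (length(unique(matched)) == 2) ok <- ok + 1
  }
  c(split = ok, pairs = length(pairs))
}
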