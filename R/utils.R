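#' @useDynLib raphequant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef pt pnorm pwilcox rnorm runif rpois sd mad median
#'   cor.test t.test oneway.test var complete.cases
#' @importFrom utils head
NULL

# Evaluate expr under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

as_image_matrix <- function(image, arg = "image") {
  if (is.matrix(image) && is.numeric(image)) return(image)
  d <- dim(image)
  if (!is.null(d) && length(d) == 2) return(matrix(as.numeric(image), d[1], d[2]))
  stop(sprintf("'%s' must be a 2D numeric matrix", arg))
}

# Even-odd point-in-polygon test, boundary-inclusive.
# px, py: point; vx, vy: polygon vertices (closed implicitly).
point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # on-segment test
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      if (abs(px - x1) < eps && abs(py - y1) < eps) return(TRUE)
    } else {
      t <- ((px - x1) * dx + (py - y1) * dy) / len2
      if (t >= -eps && t <= 1 + eps) {
        qx <- x1 + t * dx; qy <- y1 + t * dy
        if (abs(px - qx) < eps && abs(py - qy) < eps) return(TRUE)
      }
    }
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# disk structuring element offsets (flat)
disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  keep <- g$dx^2 + g$dy^2 <= radius^2
  g[keep, , drop = FALSE]
}
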