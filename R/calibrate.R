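#' Regression metrics of automated versus hand counts
#'
#' Fits ordinary least squares of the automated counts on the hand counts
#' (with intercept) and reports the fit's R-squared together with RMSE and
#' MAE. By default RMSE/MAE are computed on the raw paired differences
#' (automated minus hand), so they measure absolute count agreement -- the
#' biologically reported quantity; `residual_based = TRUE` switches to OLS
#' residuals.
#'
#' @param auto,hand equal-length paired count vectors (n >= 3; `hand` must
#'   vary).
#' @param probe optional probe name carried into the result.
#' @param residual_based compute RMSE/MAE on OLS residuals instead of raw
#'   differences.
#' @return a [CalibrationResult-class].
#' @examples
#' regressionMetrics(c(1, 3, 3, 5), c(1, 2, 3, 4))
#' @export
regressionMetrics <- function(auto, hand, probe = "",
                              residual_based = FALSE) {
  if (length(auto) != length(hand)) stop("auto and hand must be paired")
  n <- length(auto)
  if (n < 3) stop("need at least 3 pairs")
  if (var(hand) == 0) stop("hand counts have zero variance")
  fit <- lm(auto ~ hand)
  # R^2 of the fit; a constant `auto` has no explainable variance -> 0
  ss_tot <- sum((auto - mean(auto))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  r2 <- min(max(r2, 0), 1)
  err <- if (residual_based) stats::residuals(fit) else auto - hand
  new("CalibrationResult", probe = probe,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = r2,
      rmse = sqrt(mean(err^2)), mae = mean(abs(err)), n = as.integer(n))
}

#' Grid search for per-probe detector settings against hand counts
#'
#' Runs the full detection chain for every valid `(s1, s2, prominence)`
#' combination (`s1 < s2` enforced pairwise), scores each by
#' [regressionMetrics()] of automated per-cell counts against the hand
#' counts pooled over scenes, and returns the winner: highest R-squared,
#' ties broken by lowest MAE, then lowest RMSE. The background-subtracted
#' image is computed once per scene and reused across the grid.
#'
#' @param scenes list of scenes; each a list with `image` (probe channel),
#'   `labels` (a [LabelMap-class]) and `hand` (per-cell hand counts, named
#'   by cell label or in label order).
#' @param s1_grid,s2_grid,prominence_grid candidate values.
#' @param ball_radius rolling-ball radius used for every combination.
#' @param probe name stored in the winning settings.
#' @return list with `best` (a [ProbeSettings-class]) and `table` (the full
#'   audit data.frame of metrics per combination).
#' @export
gridSearchSettings <- function(scenes, s1_grid, s2_grid, prominence_grid,
                               ball_radius = 50, probe = "calibrated") {
  if (!length(s1_grid) || !length(s2_grid) || !length(prominence_grid))
    stop("grids must be non-empty")
  combos <- expand.grid(s1 = s1_grid, s2 = s2_grid)
  combos <- combos[combos$s1 < combos$s2, , drop = FALSE]
  if (!nrow(combos)) stop("no valid (s1, s2) pair with s1 < s2")

  subs <- lapply(scenes, function(sc)
    rollingBallSubtract(as_image_matrix(sc$image), ball_radius))
  hands <- unlist(lapply(scenes, function(sc) as.numeric(sc$hand)))

  rows <- list()
  for (i in seq_len(nrow(combos))) {
    s1 <- combos$s1[i]; s2 <- combos$s2[i]
    dogs <- lapply(subs, dogFilter, s1 = s1, s2 = s2)
    for (prom in prominence_grid) {
      autos <- numeric(0)
      for (j in seq_along(scenes)) {
        mx <- findMaxima(dogs[[j]], prom)
        ps <- new("PunctaSet", probe = probe,
                  points = data.frame(x = mx$x, y = mx$y),
                  peak_values = mx$value)
        rec <- suppressMessages(
          countPunctaPerCell(ps, scenes[[j]]$labels))
        autos <- c(autos, rec$count)
      }
      cal <- regressionMetrics(autos, hands, probe = probe)
      rows[[length(rows) + 1]] <- data.frame(
        s1 = s1, s2 = s2, prominence = prom,
        r_squared = cal@r_squared, rmse = cal@rmse, mae = cal@mae,
        slope = cal@slope, intercept = cal@intercept)
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$r_squared, tab$mae, tab$rmse)
  best <- tab[ord[1], ]
  list(best = probeSettings(probe, s1 = best$s1, s2 = best$s2,
                            prominence = best$prominence),
       table = tab)
}
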