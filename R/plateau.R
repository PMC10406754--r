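#' Predicted Dice of an exponential-plateau learning curve
#'
#' The learning-curve model is
#' \deqn{D(x) = D_M - (D_M - D_0) e^{-kx}}
#' where \eqn{D_M} is the maximum achievable Dice, \eqn{D_0} the minimum
#' Dice (the value at x = 0), \eqn{k > 0} the exponential rate constant and
#' x the number of training + validation images. The curve is strictly
#' increasing in x when \eqn{D_M > D_0} and bounded in \eqn{[D_0, D_M]}.
#'
#' @param fit a `plateau_fit` (from [fit_plateau]) or any list with fields
#'   `d_max`, `d_zero`, `k`.
#' @param x non-negative dataset size(s); vectorized.
#' @return Predicted Dice value(s).
#' @export
predict_dice <- function(fit, x) {
  stopifnot(all(x >= 0))
  fit$d_max - (fit$d_max - fit$d_zero) * exp(-fit$k * x)
}

#' Plateau point of a fitted learning curve
#'
#' The plateau point is the smallest positive integer dataset size x at
#' which the predicted Dice is within `tolerance` (default 0.01 Dice) of
#' the maximum predicted Dice \eqn{D_M}. Since
#' \eqn{D_M - D(x) = (D_M - D_0) e^{-kx}}, the closed form is
#' \deqn{x^* = \lceil \ln((D_M - D_0)/tolerance) / k \rceil}
#' clipped below at 1; a flat curve (\eqn{D_M - D_0 \le} tolerance) has
#' plateau point 1. Reported as a whole image count via the ceiling.
#'
#' @param fit a `plateau_fit` or list with `d_max`, `d_zero`, `k` and
#'   optionally `tolerance`.
#' @param tolerance Dice tolerance; defaults to the fit's own.
#' @return Smallest positive integer x with `d_max - predict_dice(fit, x)
#'   <= tolerance`.
#' @export
plateau_point <- function(fit, tolerance = NULL) {
  tol <- if (!is.null(tolerance)) tolerance
         else if (!is.null(fit$tolerance)) fit$tolerance else 0.01
  stopifnot(tol > 0, fit$k > 0)
  gap <- fit$d_max - fit$d_zero
  if (gap <= tol) return(1L)
  as.integer(max(1, ceiling(log(gap / tol) / fit$k)))
}

#' Fit the exponential-plateau model to learning-curve observations
#'
#' Least-squares estimation of \eqn{(D_M, D_0, k)} minimizing
#' \eqn{\sum_i (dice_i - D(x_i))^2} by Levenberg-Marquardt
#' ([minpack.lm::nlsLM]). The fit is parameterized as
#' \eqn{D_0 = s \cdot D_M} with box constraints \eqn{D_M \in [0, 1]},
#' \eqn{s \in [0, 1]}, \eqn{k \in (10^{-6}, k_{cap}]}, which enforces
#' \eqn{0 \le D_0 \le D_M \le 1} throughout — Dice is bounded, so an
#' unconstrained fit that could extrapolate beyond 1 is not meaningful.
#'
#' Starting values are deterministic: \eqn{D_M^0} = max observed Dice,
#' \eqn{D_0^0} = mean Dice at the smallest x, and \eqn{k^0} from the slope
#' of a log-linear regression of \eqn{\ln(D_M^0 + 10^{-3} - dice)} on x.
#'
#' If all observations are (numerically) identical the degenerate flat fit
#' \eqn{D_M = D_0 =} mean Dice is returned with `flat_curve = TRUE` and
#' plateau point 1, without invoking the optimizer.
#'
#' @param observations `data.frame` with columns `x` (positive integer
#'   dataset size) and `dice` in `[0, 1]`; an optional `kind` column tags
#'   rows `"ensemble"` or `"fold"`.
#' @param tolerance plateau tolerance in Dice units (default 0.01).
#' @param use `"ensemble_only"` (default; fits the per-size ensemble
#'   points) or `"all_points"` (folds included, unweighted).
#' @param k_cap upper box constraint on k (default 1).
#' @return An object of class `plateau_fit`: list with `d_max`, `d_zero`,
#'   `k`, `tolerance`, `plateau_x`, `residual_sum_squares`, `n_points`,
#'   `converged`, `flat_curve`, `extrapolated` (plateau beyond the largest
#'   observed x, signalling reduced confidence), `max_x_observed`.
#' @export
fit_plateau <- function(observations, tolerance = 0.01,
                        use = c("ensemble_only", "all_points"), k_cap = 1) {
  use <- match.arg(use)
  obs <- validate_observations(observations, use)
  x <- obs$x; dice <- obs$dice
  if (length(unique(x)) < 3L)
    stop("need observations at >= 3 distinct dataset sizes (3 free parameters), got ",
         length(unique(x)))
  stopifnot(tolerance > 0, k_cap > 1e-6)

  if (diff(range(dice)) < 1e-12) {
    return(new_plateau_fit(d_max = mean(dice), d_zero = mean(dice), k = 1e-6,
                           tolerance = tolerance,
                           rss = sum((dice - mean(dice))^2), n = length(x),
                           converged = TRUE, flat = TRUE, max_x = max(x)))
  }

  d_max0 <- min(max(dice), 1)
  d_zero0 <- max(min(mean(dice[x == min(x)]), d_max0), 0)
  resid0 <- pmax(d_max0 + 1e-3 - dice, 1e-9)
  k0 <- -unname(stats::coef(stats::lm(log(resid0) ~ x))[2L])
  if (!is.finite(k0)) k0 <- 1e-2
  k0 <- min(max(k0, 1e-5), k_cap)
  s0 <- if (d_max0 > 0) min(d_zero0 / d_max0, 1) else 0.5

  fit <- tryCatch(
    minpack.lm::nlsLM(
      dice ~ dmax - dmax * (1 - s) * exp(-k * x),
      data = data.frame(x = x, dice = dice),
      start = list(dmax = d_max0, s = s0, k = k0),
      lower = c(0, 0, 1e-6), upper = c(1, 1, k_cap),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("exponential-plateau fit failed to converge: ", conditionMessage(fit))

  co <- stats::coef(fit)
  converged <- isTRUE(fit$convInfo$isConv) ||
    fit$convInfo$finIter < fit$convInfo$maxIter
  new_plateau_fit(d_max = unname(co["dmax"]),
                  d_zero = unname(co["dmax"] * co["s"]),
                  k = unname(co["k"]), tolerance = tolerance,
                  rss = sum(stats::resid(fit)^2), n = length(x),
                  converged = converged, flat = FALSE, max_x = max(x))
}

new_plateau_fit <- function(d_max, d_zero, k, tolerance, rss, n, converged,
                            flat, max_x) {
  fit <- structure(list(d_max = d_max, d_zero = d_zero, k = k,
                        tolerance = tolerance, plateau_x = NA_integer_,
                        residual_sum_squares = rss, n_points = n,
                        converged = converged, flat_curve = flat,
                        extrapolated = NA, max_x_observed = max_x),
                   class = "plateau_fit")
  fit$plateau_x <- plateau_point(fit)
  fit$extrapolated <- fit$plateau_x > max_x
  fit
}

validate_observations <- function(observations, use = "all_points") {
  if (!is.data.frame(observations) || !all(c("x", "dice") %in% names(observations)))
    stop("observations must be a data.frame with columns `x` and `dice`")
  obs <- observations
  if (use == "ensemble_only" && "kind" %in% names(obs) && any(obs$kind == "ensemble"))
    obs <- obs[obs$kind == "ensemble", , drop = FALSE]
  if (nrow(obs) < 3L) stop("need >= 3 observations")
  if (any(obs$x < 1)) stop("dataset sizes `x` must be >= 1")
  if (any(obs$dice < 0 | obs$dice > 1)) stop("`dice` must lie in [0, 1]")
  obs
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat(sprintf(paste0("Exponential-plateau fit (n = %d):\n",
                     "  D_max = %.4f, D_0 = %.4f, k = %.5f\n",
                     "  plateau point (within %.3g Dice of D_max): x = %d%s%s\n",
                     "  RSS = %.3g, converged: %s\n"),
              x$n_points, x$d_max, x$d_zero, x$k, x$tolerance, x$plateau_x,
              if (x$extrapolated) "  [extrapolated beyond observed sizes]" else "",
              if (x$flat_curve) "  [flat curve]" else "",
              x$residual_sum_squares, x$converged))
  invisible(x)
}

#' Stability of the plateau estimate under dropout of the largest sizes
#'
#' Refits the model on the full data and then repeatedly after removing all
#' observations at the current largest dataset size, up to `max_drops`
#' times — emulating the question "would we have estimated the same plateau
#' with a smaller study?". A large jump in successive \eqn{D_M} estimates
#' indicates the curve has not yet stabilized; congruent fits indicate a
#' real plateau is being reached.
#'
#' @inheritParams fit_plateau
#' @param max_drops number of progressive dropouts (default 2).
#' @param gap_threshold largest tolerated change in `d_max` between
#'   successive fits for the estimate to be called stable (default 0.02
#'   Dice; a configurable heuristic).
#' @return An object of class `stability_report`: list with `fits` (list of
#'   `plateau_fit`), `table` (`data.frame` of `n_dropped, dropped_sizes,
#'   d_max, d_zero, k, plateau_x, extrapolated`), `max_dmax_gap`, `stable`,
#'   `gap_threshold`.
#' @export
stability_analysis <- function(observations, max_drops = 2L, tolerance = 0.01,
                               gap_threshold = 0.02,
                               use = c("ensemble_only", "all_points")) {
  use <- match.arg(use)
  obs <- validate_observations(observations, use)
  sizes <- sort(unique(obs$x), decreasing = TRUE)
  if (length(sizes) - max_drops < 3L)
    stop("after ", max_drops, " drops only ", length(sizes) - max_drops,
         " distinct sizes would remain; >= 3 required")
  fits <- vector("list", max_drops + 1L)
  rows <- vector("list", max_drops + 1L)
  cur <- obs
  for (i in 0:max_drops) {
    dropped <- if (i == 0L) integer(0) else sizes[seq_len(i)]
    fits[[i + 1L]] <- fit_plateau(cur, tolerance = tolerance, use = use)
    f <- fits[[i + 1L]]
    rows[[i + 1L]] <- data.frame(
      n_dropped = i,
      dropped_sizes = paste(dropped, collapse = ";"),
      d_max = f$d_max, d_zero = f$d_zero, k = f$k,
      plateau_x = f$plateau_x, extrapolated = f$extrapolated,
      stringsAsFactors = FALSE)
    if (i < max_drops) cur <- cur[cur$x != sizes[i + 1L], , drop = FALSE]
  }
  tab <- do.call(rbind, rows)
  gaps <- abs(diff(tab$d_max))
  max_gap <- if (length(gaps)) max(gaps) else 0
  structure(list(fits = fits, table = tab, max_dmax_gap = max_gap,
                 stable = max_gap <= gap_threshold,
                 gap_threshold = gap_threshold),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Plateau stability under dropout of the largest dataset sizes:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("max successive |d_max| gap: %.4f (threshold %.3g) -> %s\n",
              x$max_dmax_gap, x$gap_threshold,
              if (x$stable) "stable" else "NOT stable"))
  invisible(x)
}

#' Learning-curve analysis within reference-volume quartiles
#'
#' Small structures are systematically harder to segment; this analysis
#' partitions test cases into quartiles of the reference segmentation
#' volume and fits a separate learning curve per quartile (the lowest
#' quartile holds the smallest volumes). Quartile boundaries come from the
#' test set itself: cases are ranked by reference volume with ties broken
#' deterministically by `case_id` order, and the ranking splits into four
#' groups as equal as possible.
#'
#' @param metrics `data.frame` with columns `x` (dataset size), `case_id`,
#'   `dice` and `ref_volume_ml` — one row per test case per dataset size
#'   for a single label. Reference volumes must not depend on `x`; the
#'   per-case volume is taken as the mean over sizes.
#' @param tolerance plateau tolerance passed to [fit_plateau].
#' @return List with `assignments` (`case_id`, `ref_volume_ml`,
#'   `quartile`), `observations` (mean Dice per size per quartile) and
#'   `fits` (list of `plateau_fit` or error message, one per quartile).
#' @export
quartile_curve_analysis <- function(metrics, tolerance = 0.01) {
  needed <- c("x", "case_id", "dice", "ref_volume_ml")
  if (!all(needed %in% names(metrics)))
    stop("metrics must have columns ", paste(needed, collapse = ", "))
  vols <- stats::aggregate(ref_volume_ml ~ case_id, metrics, mean)
  vols <- vols[order(vols$case_id), , drop = FALSE]
  rk <- rank(vols$ref_volume_ml, ties.method = "first")
  vols$quartile <- as.integer(ceiling(rk * 4 / length(rk)))
  metrics$quartile <- vols$quartile[match(metrics$case_id, vols$case_id)]

  obs <- stats::aggregate(dice ~ x + quartile, metrics, mean)
  obs <- obs[order(obs$quartile, obs$x), , drop = FALSE]

  fits <- lapply(sort(unique(obs$quartile)), function(q) {
    sub <- obs[obs$quartile == q, c("x", "dice")]
    tryCatch(fit_plateau(sub, tolerance = tolerance, use = "all_points"),
             error = function(e) conditionMessage(e))
  })
  names(fits) <- paste0("quartile_", sort(unique(obs$quartile)))
  list(assignments = vols, observations = obs, fits = fits)
}

#' Read learning-curve observations from CSV
#'
#' Expected columns: `x,dice` and optionally `kind` (`ensemble`/`fold`) and
#' `fold_id`.
#' @param path CSV path.
#' @return `data.frame` of observations.
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "dice") %in% names(df)))
    stop("curve CSV must have columns `x` and `dice`: ", path)
  df$x <- suppressWarnings(as.numeric(df$x))
  df$dice <- suppressWarnings(as.numeric(df$dice))
  bad <- which(!is.finite(df$x) | !is.finite(df$dice))
  if (length(bad))
    stop("malformed curve CSV at data row(s) ", paste(bad, collapse = ", "),
         ": non-numeric x or dice")
  df
}

# Serializable summary of a plateau fit (for JSON reports).
plateau_fit_report <- function(fit) {
  list(d_max = fit$d_max, d_zero = fit$d_zero, k = fit$k,
       tolerance = fit$tolerance, plateau_x = fit$plateau_x,
       extrapolated = fit$extrapolated, rss = fit$residual_sum_squares,
       n_points = fit$n_points, converged = fit$converged,
       flat_curve = fit$flat_curve)
}
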