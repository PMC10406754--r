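# Run `expr` under a local RNG stream so generators are deterministic for a
# given seed without disturbing the caller's random state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Specification of a kidney/tumor phantom
#'
#' Describes a synthetic 3D multi-label scene: two kidney ellipsoids and
#' one tumor sphere on a regular grid. Geometry is given in voxel (grid)
#' coordinates; physical size follows from `spacing`. Defaults produce a
#' 48 x 48 x 32 grid at 1.5 x 1.5 x 3 mm (an abdominal-CT-like anisotropy)
#' with two parenchyma ellipsoids and a tumor sphere carved into one of
#' them — tumor takes precedence over kidney where they overlap, as an
#' endophytic lesion replaces parenchyma.
#'
#' @param shape grid dimensions (3 positive integers).
#' @param spacing voxel size in mm (3 positive reals).
#' @param kidney_centers list of two length-3 centers (voxel coords).
#' @param kidney_axes list of two length-3 ellipsoid semi-axes (voxels).
#' @param tumor_center length-3 sphere center (voxel coords).
#' @param tumor_radius sphere radius in voxels (0 for no tumor).
#' @param labels a [label_map] naming kidney and tumor values.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 32L), spacing = c(1.5, 1.5, 3),
                         kidney_centers = list(c(14, 24, 16), c(34, 24, 16)),
                         kidney_axes = list(c(7, 10, 9), c(7, 10, 9)),
                         tumor_center = c(34, 30, 19), tumor_radius = 5,
                         labels = default_label_map()) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            length(kidney_centers) == 2L, length(kidney_axes) == 2L,
            tumor_radius >= 0)
  for (i in 1:2) {
    c0 <- kidney_centers[[i]]; ax <- kidney_axes[[i]]
    if (any(c0 - ax < 1) || any(c0 + ax > shape))
      stop("kidney ellipsoid ", i, " exceeds the grid")
  }
  if (tumor_radius > 0 &&
      (any(tumor_center - tumor_radius < 1) || any(tumor_center + tumor_radius > shape)))
    stop("tumor sphere exceeds the grid")
  structure(list(shape = shape, spacing = spacing,
                 kidney_centers = kidney_centers, kidney_axes = kidney_axes,
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 labels = labels),
            class = "phantom_spec")
}

#' Generate a phantom label volume
#'
#' Voxels whose centers fall inside either kidney ellipsoid get the kidney
#' label; voxels inside the tumor sphere get the tumor label (precedence
#' over kidney). Deterministic for a given spec.
#'
#' @param spec a [phantom_spec].
#' @param source_id case identifier for the returned volume.
#' @return A [label_volume].
#' @export
make_phantom <- function(spec = phantom_spec(), source_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  ix <- slice.index(array(0L, d), 1L)
  iy <- slice.index(array(0L, d), 2L)
  iz <- slice.index(array(0L, d), 3L)
  vox <- array(attr(spec$labels, "background"), d)
  for (i in 1:2) {
    c0 <- spec$kidney_centers[[i]]; ax <- spec$kidney_axes[[i]]
    inside <- ((ix - c0[1]) / ax[1])^2 + ((iy - c0[2]) / ax[2])^2 +
      ((iz - c0[3]) / ax[3])^2 <= 1
    vox[inside] <- spec$labels[["kidney"]]
  }
  if (spec$tumor_radius > 0) {
    c0 <- spec$tumor_center
    inside <- (ix - c0[1])^2 + (iy - c0[2])^2 + (iz - c0[3])^2 <= spec$tumor_radius^2
    vox[inside] <- spec$labels[["tumor"]]
  }
  label_volume(vox, spec$spacing, source_id)
}

#' Degrade one label of a volume to a target Dice
#'
#' Produces a controlled-quality "prediction" from a reference mask.
#' Modes:
#' \describe{
#'   \item{`boundary_flip`}{iteratively flips boundary voxels — removing
#'     mask-boundary voxels (false negatives) and adding background voxels
#'     adjacent to the mask (false positives) in equal proportion — and
#'     re-measures Dice until it falls within `achieve_tol` of
#'     `target_dice`.}
#'   \item{`erode`}{removes boundary voxels only (shrinks the mask).}
#'   \item{`dilate`}{adds adjacent background voxels only (grows the mask).}
#'   \item{`delete_component`}{empties the label entirely (a model that
#'     produced no prediction for the structure); `target_dice` is ignored
#'     and the result has Dice 0.}
#' }
#' Voxels carrying other labels are never altered: removals turn mask
#' voxels into background and additions claim background voxels only.
#' Exact targets are generally unreachable by discrete voxel flips, hence
#' the iterate-and-measure loop with tolerance `achieve_tol` and an
#' iteration cap; an unreachable target raises an error reporting the Dice
#' actually achieved.
#'
#' @param volume a [label_volume].
#' @param label label value to degrade (must be present unless
#'   `target_dice` is 1).
#' @param target_dice requested Dice of the result against `volume`,
#'   in (0, 1].
#' @param mode degradation mode, see above.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param achieve_tol acceptable |achieved - target| (default 0.05).
#' @param max_iter iteration cap for the flip loop.
#' @return A degraded copy of `volume`.
#' @export
degrade_volume <- function(volume, label, target_dice,
                           mode = c("boundary_flip", "erode", "dilate",
                                    "delete_component"),
                           seed = 1L, achieve_tol = 0.05, max_iter = 200L) {
  mode <- match.arg(mode)
  stopifnot(is_label_volume(volume), target_dice > 0, target_dice <= 1)
  background <- 0L
  vox <- volume$voxels
  orig <- vox == label
  n0 <- sum(orig)
  if (mode == "delete_component") {
    vox[orig] <- background
    return(label_volume(vox, volume$spacing, volume$source_id))
  }
  if (target_dice == 1)
    return(label_volume(vox, volume$spacing, volume$source_id))
  if (n0 == 0L) stop("label ", label, " not present in volume")

  cur_dice <- function(v) {
    m <- v == label
    tp <- sum(m & orig)
    dice_score(tp, sum(m & !orig), sum(orig & !m))
  }
  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      d <- cur_dice(vox)
      if (d <= target_dice) break  # monotone descent crosses the target closely
      # batch shrinks as the target nears, so discrete flips cannot overshoot
      # the tolerance band
      batch <- max(1L, min(as.integer(round(0.02 * n0)),
                           as.integer(ceiling((d - target_dice) * n0 / 4))))
      mask <- vox == label
      if (mode %in% c("boundary_flip", "erode")) {
        bnd <- which(boundary_mask(mask))
        if (length(bnd)) {
          take <- sample(bnd, min(batch, length(bnd)))
          vox[take] <- background
        } else if (mode == "erode") break  # mask exhausted
      }
      if (mode %in% c("boundary_flip", "dilate")) {
        outer_b <- which(outer_boundary(mask) & vox == background)
        if (length(outer_b)) {
          take <- sample(outer_b, min(batch, length(outer_b)))
          vox[take] <- label
        } else if (mode == "dilate") break  # grid saturated around the mask
      }
    }
  })
  achieved <- cur_dice(vox)
  if (abs(achieved - target_dice) > achieve_tol)
    stop(sprintf("target Dice %.3f unreachable in mode '%s': achieved %.3f",
                 target_dice, mode, achieved))
  label_volume(vox, volume$spacing, volume$source_id)
}

# Background voxels face-adjacent (6-connectivity) to the mask.
outer_boundary <- function(mask) {
  d <- dim(mask)
  nb <- array(FALSE, d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n == 1L) next
    nb <- nb | assign_slab(array(FALSE, d), ax, 2:n, slab(mask, ax, 1:(n - 1)))
    nb <- nb | assign_slab(array(FALSE, d), ax, 1:(n - 1), slab(mask, ax, 2:n))
  }
  nb & !mask
}

#' Simulate K cross-validation fold predictions
#'
#' Generates K independent degradations of a reference volume with Dice
#' targets drawn uniformly from `quality_spread`, emulating the per-fold
#' prediction variability that majority voting is meant to average out.
#'
#' @param volume reference [label_volume].
#' @param label label value to degrade.
#' @param K number of folds (>= 1).
#' @param quality_spread length-2 range of per-fold Dice targets, or a
#'   single value for identical targets.
#' @param seed integer seed; byte-identical output for a given seed.
#' @return List of K [label_volume]s.
#' @export
simulate_folds <- function(volume, label, K = 5L, quality_spread = c(0.80, 0.95),
                           seed = 1L) {
  stopifnot(K >= 1L)
  if (length(quality_spread) == 1L) quality_spread <- rep(quality_spread, 2L)
  targets <- with_seed(seed, stats::runif(K, quality_spread[1L], quality_spread[2L]))
  lapply(seq_len(K), function(i) {
    if (targets[i] >= 1) volume
    else degrade_volume(volume, label, targets[i], mode = "boundary_flip",
                        seed = seed + i)
  })
}

#' Simulate learning-curve observations from a known plateau law
#'
#' Forward model for the exponential-plateau learning curve: for each
#' dataset size x and fold, `dice = clamp(D(x) + e, 0, 1)` with
#' `e ~ N(0, noise_sd)` (truncation by clamping keeps Dice in range); the
#' ensemble observation at each size is the mean of its folds. Defaults
#' mirror a typical saturation experiment: sizes 50-300 in steps of 50,
#' five folds per size.
#'
#' @param d_max,d_zero,k true curve parameters (`0 <= d_zero <= d_max <= 1`,
#'   `k > 0`).
#' @param sizes dataset sizes at which observations are drawn.
#' @param folds folds per size.
#' @param noise_sd fold-level Gaussian noise SD on the Dice scale
#'   (default 0.02, the typical fold scatter of a stable segmentation
#'   experiment).
#' @param seed integer seed.
#' @return `data.frame` with columns `x, dice, kind, fold_id`: one `fold`
#'   row per size and fold plus one `ensemble` row per size (`fold_id`
#'   `NA`).
#' @export
simulate_learning_curve <- function(d_max = 0.93, d_zero = 0.40, k = 0.02,
                                    sizes = seq(50L, 300L, by = 50L),
                                    folds = 5L, noise_sd = 0.02, seed = 1L) {
  stopifnot(d_zero >= 0, d_max >= d_zero, d_max <= 1, k > 0,
            all(sizes >= 1), folds >= 1, noise_sd >= 0)
  truth <- list(d_max = d_max, d_zero = d_zero, k = k)
  rows <- with_seed(seed, {
    do.call(rbind, lapply(sizes, function(x) {
      d <- pmin(pmax(predict_dice(truth, x) +
                       stats::rnorm(folds, 0, noise_sd), 0), 1)
      rbind(
        data.frame(x = x, dice = d, kind = "fold", fold_id = seq_len(folds),
                   stringsAsFactors = FALSE),
        data.frame(x = x, dice = mean(d), kind = "ensemble", fold_id = NA_integer_,
                   stringsAsFactors = FALSE))
    }))
  })
  rownames(rows) <- NULL
  rows
}
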