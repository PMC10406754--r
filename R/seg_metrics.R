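#' Confusion counts for one label
#'
#' @param reference,prediction comparable [label_volume] objects.
#' @param label integer label value.
#' @return Named integer vector `c(tp, fp, fn)`: voxels where both volumes
#'   carry `label`, prediction-only voxels, and reference-only voxels.
#' @export
binary_counts <- function(reference, prediction, label) {
  check_comparable(reference, prediction)
  r <- reference$voxels == label
  p <- prediction$voxels == label
  c(tp = sum(r & p), fp = sum(p & !r), fn = sum(r & !p))
}

#' Dice similarity coefficient from confusion counts
#'
#' `2*TP / (2*TP + FP + FN)`; 1 when both masks are empty (perfect
#' agreement on absence), 0 for disjoint non-empty masks.
#' @param tp,fp,fn non-negative counts.
#' @return Dice in `[0, 1]`.
#' @export
dice_score <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  ifelse(den == 0, 1, 2 * tp / den)
}

#' Jaccard index from confusion counts
#'
#' `TP / (TP + FP + FN)`; 1 when both masks are empty. Related to Dice by
#' `J = D / (2 - D)`.
#' @inheritParams dice_score
#' @return Jaccard in `[0, 1]`.
#' @export
jaccard_index <- function(tp, fp, fn) {
  den <- tp + fp + fn
  ifelse(den == 0, 1, tp / den)
}

#' True positive rate (sensitivity) from confusion counts
#'
#' `TP / (TP + FN)`; 1 when the reference mask is empty.
#' @inheritParams dice_score
#' @return TPR in `[0, 1]`.
#' @export
true_positive_rate <- function(tp, fn) {
  den <- tp + fn
  ifelse(den == 0, 1, tp / den)
}

# Boundary voxels of a logical 3D mask under 6-connectivity: mask voxels
# with at least one face-adjacent neighbour outside the mask, the grid edge
# counting as outside.
boundary_mask <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n == 1L) { interior[] <- FALSE; break }
    lo <- slab(mask, ax, 1:(n - 1)); hi <- slab(mask, ax, 2:n)
    nb_lo <- array(FALSE, d); nb_hi <- array(FALSE, d)
    # neighbour towards lower index exists and is inside the mask
    nb_lo <- assign_slab(nb_lo, ax, 2:n, lo)
    nb_hi <- assign_slab(nb_hi, ax, 1:(n - 1), hi)
    interior <- interior & nb_lo & nb_hi
  }
  mask & !interior
}

slab <- function(a, axis, idx) {
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
}
assign_slab <- function(a, axis, idx, value) {
  switch(axis,
         { a[idx, , ] <- value; a },
         { a[, idx, ] <- value; a },
         { a[, , idx] <- value; a })
}

# Physical (mm) coordinates of TRUE voxels: voxel centres scaled by spacing.
boundary_coords <- function(mask, spacing) {
  ind <- which(mask, arr.ind = TRUE)
  sweep(ind, 2L, spacing, `*`)
}

# Mean over rows of A of the distance to the nearest row of B, chunked so
# the cross-distance matrix never exceeds ~2e6 entries.
directed_mean_distance <- function(a, b, chunk = 2048L) {
  nb2 <- rowSums(b^2)
  tot <- 0
  for (start in seq(1L, nrow(a), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(a))
    ac <- a[rows, , drop = FALSE]
    d2 <- outer(rowSums(ac^2), nb2, `+`) - 2 * tcrossprod(ac, b)
    d2[d2 < 0] <- 0  # guard tiny negative round-off
    tot <- tot + sum(sqrt(apply(d2, 1L, min)))
  }
  tot / nrow(a)
}

#' Surface distances between two masks of one label
#'
#' Boundary voxels are extracted under 6-connectivity (face neighbours,
#' grid edge counting as outside); distances are Euclidean between voxel
#' centres in mm (indices scaled by spacing). Returns both directed mean
#' distances and their symmetric arithmetic mean.
#'
#' @inheritParams binary_counts
#' @return List with `msd` (symmetric mean), `ref_to_pred`, `pred_to_ref`
#'   (directed means, mm); all `NA` if either mask is empty.
#' @export
surface_distances <- function(reference, prediction, label) {
  check_comparable(reference, prediction)
  rm_ <- reference$voxels == label
  pm_ <- prediction$voxels == label
  if (!any(rm_) || !any(pm_))
    return(list(msd = NA_real_, ref_to_pred = NA_real_, pred_to_ref = NA_real_))
  ra <- boundary_coords(boundary_mask(rm_), reference$spacing)
  pa <- boundary_coords(boundary_mask(pm_), reference$spacing)
  d_rp <- directed_mean_distance(ra, pa)
  d_pr <- directed_mean_distance(pa, ra)
  list(msd = (d_rp + d_pr) / 2, ref_to_pred = d_rp, pred_to_ref = d_pr)
}

#' Mean surface distance for one label
#'
#' Symmetric mean of the two directed mean nearest-boundary distances, in
#' mm; `NA` (MISSING) if either mask is empty — an empty prediction has no
#' surface, and a sentinel value would distort cohort means.
#'
#' @inheritParams binary_counts
#' @return MSD in mm, or `NA_real_`.
#' @export
mean_surface_distance <- function(reference, prediction, label) {
  surface_distances(reference, prediction, label)$msd
}

#' Physical volume of one label in mL
#'
#' Voxel count times the voxel volume (product of spacings, mm^3), divided
#' by 1000.
#' @param volume a [label_volume].
#' @param label integer label value.
#' @return Volume in mL.
#' @export
label_volume_ml <- function(volume, label) {
  stopifnot(is_label_volume(volume))
  sum(volume$voxels == label) * prod(volume$spacing) / 1000
}

#' Per-case agreement metrics for every named label
#'
#' Combines overlap metrics (Dice, Jaccard, TPR), the mean surface
#' distance and physical volumes into one record per named label.
#'
#' @param reference,prediction comparable [label_volume] objects.
#' @param labels a [label_map]; defaults to kidney/tumor = 1/2.
#' @param case_id case identifier; defaults to the reference `source_id`.
#' @return A `data.frame` with one row per named label and columns
#'   `case_id, label, dice, jaccard, tpr, msd_mm, ref_volume_ml,
#'   pred_volume_ml, ref_empty, pred_empty`. `msd_mm` is `NA` iff either
#'   mask is empty.
#' @export
evaluate_case <- function(reference, prediction, labels = default_label_map(),
                          case_id = reference$source_id) {
  check_comparable(reference, prediction)
  rows <- lapply(seq_along(labels), function(i) {
    lab <- labels[[i]]
    cnt <- binary_counts(reference, prediction, lab)
    ref_empty <- (cnt[["tp"]] + cnt[["fn"]]) == 0L
    pred_empty <- (cnt[["tp"]] + cnt[["fp"]]) == 0L
    data.frame(
      case_id = case_id,
      label = names(labels)[i],
      dice = dice_score(cnt[["tp"]], cnt[["fp"]], cnt[["fn"]]),
      jaccard = jaccard_index(cnt[["tp"]], cnt[["fp"]], cnt[["fn"]]),
      tpr = true_positive_rate(cnt[["tp"]], cnt[["fn"]]),
      msd_mm = if (ref_empty || pred_empty) NA_real_
               else mean_surface_distance(reference, prediction, lab),
      ref_volume_ml = label_volume_ml(reference, lab),
      pred_volume_ml = label_volume_ml(prediction, lab),
      ref_empty = ref_empty,
      pred_empty = pred_empty,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-label mean and SD summary of a metrics table
#'
#' Sample SD uses the n-1 denominator; a single record gets SD 0 with the
#' `n = 1` count making that visible. Missing MSD values (empty masks) are
#' excluded from the MSD mean/SD, with the exclusion count reported.
#'
#' @param records a metrics `data.frame` as produced by [evaluate_case]
#'   (rows from several cases may be concatenated).
#' @return A `data.frame` with columns `label, metric, mean, sd, n,
#'   n_missing`.
#' @export
summarize_metrics <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty metrics data.frame")
  metrics <- c("dice", "jaccard", "tpr", "msd_mm", "ref_volume_ml", "pred_volume_ml")
  out <- list()
  for (lab in unique(records$label)) {
    sub <- records[records$label == lab, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      miss <- sum(is.na(v))
      v <- v[!is.na(v)]
      n <- length(v)
      out[[length(out) + 1L]] <- data.frame(
        label = lab, metric = m,
        mean = if (n > 0L) mean(v) else NA_real_,
        sd = if (n > 1L) stats::sd(v) else if (n == 1L) 0 else NA_real_,
        n = n, n_missing = miss, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write / read a per-case metrics table as CSV
#'
#' Columns `case_id,label,dice,jaccard,tpr,msd_mm,ref_volume_ml,
#' pred_volume_ml,ref_empty,pred_empty`; MISSING MSD is serialized as an
#' empty cell.
#' @param records metrics `data.frame`.
#' @param path CSV path.
#' @return `path` / the metrics `data.frame`.
#' @export
write_metrics_csv <- function(records, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  needed <- c("case_id", "label", "dice")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("metrics CSV lacks required columns: ", paste(missing, collapse = ", "))
  df
}
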