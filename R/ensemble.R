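#' Per-voxel majority-vote label fusion
#'
#' Combines K fold-model predictions for one case into a single ensemble
#' prediction: each output voxel is the modal label across the K inputs.
#' With 5 voters over 3 labels, 2-2-1 ties occur; ties are resolved
#' deterministically by `tie_rule`:
#' \describe{
#'   \item{`lowest_label`}{the numerically smallest tied label wins (with
#'     the background/kidney/tumor = 0/1/2 map this prefers background, the
#'     conservative choice). Default.}
#'   \item{`background_wins`}{background wins any tie it participates in;
#'     ties among non-background labels fall back to the lowest label.}
#' }
#' Votes are over hard labels only (fold models ensemble label predictions,
#' not probabilities).
#'
#' @param predictions list of K >= 1 pairwise comparable [label_volume]s.
#' @param tie_rule tie-resolution rule, see above.
#' @param background background label for `background_wins` (default 0).
#' @return A [label_volume] with the input grid and spacing.
#' @export
majority_vote <- function(predictions, tie_rule = c("lowest_label", "background_wins"),
                          background = 0L) {
  tie_rule <- match.arg(tie_rule)
  if (!is.list(predictions) || length(predictions) == 0L)
    stop("`predictions` must be a non-empty list of label volumes")
  stopifnot(all(vapply(predictions, is_label_volume, logical(1))))
  first <- predictions[[1L]]
  for (p in predictions[-1L]) check_comparable(first, p)
  k <- length(predictions)
  if (k == 1L)
    return(label_volume(first$voxels, first$spacing, first$source_id))

  labs <- sort(unique(unlist(lapply(predictions, function(p) unique(as.vector(p$voxels))))))
  if (tie_rule == "background_wins" && background %in% labs)
    labs <- c(background, setdiff(labs, background))  # background first, rest ascending

  d <- dim(first$voxels)
  best_count <- array(-1L, d)
  best_label <- array(labs[1L], d)
  # iterate candidates in tie-priority order; strict > keeps the earlier
  # (higher-priority) label on ties
  for (lab in labs) {
    cnt <- Reduce(`+`, lapply(predictions, function(p) (p$voxels == lab) * 1L))
    take <- cnt > best_count
    best_count[take] <- cnt[take]
    best_label[take] <- lab
  }
  label_volume(best_label, first$spacing, first$source_id)
}
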