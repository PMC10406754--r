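#' Linear regression of predicted on reference volumes
#'
#' Ordinary least squares of predicted volume on reference volume,
#' summarizing cohort-level volumetric concordance; `r_squared` is the
#' squared Pearson correlation.
#'
#' @param ref_ml,pred_ml equal-length numeric vectors of per-case volumes
#'   (mL); at least 3 pairs, reference values not all equal.
#' @return List with `slope`, `intercept`, `r_squared`, `n_cases`.
#' @export
volume_regression <- function(ref_ml, pred_ml) {
  if (length(ref_ml) != length(pred_ml)) stop("volume vectors differ in length")
  if (length(ref_ml) < 3L) stop("need >= 3 volume pairs")
  if (diff(range(ref_ml)) == 0) stop("degenerate input: all reference volumes equal")
  fit <- stats::lm(pred_ml ~ ref_ml)
  co <- stats::coef(fit)
  # collinear input is a legitimate (and tested) case: silence the
  # "essentially perfect fit" note summary.lm emits for it
  r2 <- withCallingHandlers(
    summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       r_squared = r2, n_cases = length(ref_ml))
}

#' Bland-Altman analysis of percent volume differences
#'
#' Per-case percent difference is `100 * (pred - ref) / denominator`. The
#' default denominator is the reference volume (percent error relative to
#' ground truth); the classical Bland-Altman mean-of-pair denominator is
#' available via `denominator_rule = "mean"`. Bias is the mean percent
#' difference, SD the sample standard deviation, and the limits of
#' agreement bias +/- 1.96 SD. Cases with a zero denominator are excluded
#' with a warning and listed in the result.
#'
#' @param ref_ml,pred_ml per-case volumes (mL); >= 2 usable pairs.
#' @param denominator_rule `"reference"` (default) or `"mean"`.
#' @param case_ids optional identifiers used to report excluded cases.
#' @return An object of class `agreement_report`: list with `ba_bias_pct`,
#'   `ba_sd_pct`, `ba_loa_low_pct`, `ba_loa_high_pct`, `n_cases`,
#'   `excluded_cases`, `denominator_rule`.
#' @export
bland_altman_percent <- function(ref_ml, pred_ml,
                                 denominator_rule = c("reference", "mean"),
                                 case_ids = NULL) {
  denominator_rule <- match.arg(denominator_rule)
  if (length(ref_ml) != length(pred_ml)) stop("volume vectors differ in length")
  if (is.null(case_ids)) case_ids <- as.character(seq_along(ref_ml))
  den <- switch(denominator_rule, reference = ref_ml, mean = (ref_ml + pred_ml) / 2)
  zero <- den == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " case(s) with zero denominator: ",
            paste(case_ids[zero], collapse = ", "))
  }
  pct <- 100 * (pred_ml[!zero] - ref_ml[!zero]) / den[!zero]
  if (length(pct) < 2L) stop("need >= 2 usable volume pairs")
  bias <- mean(pct); s <- stats::sd(pct)
  structure(list(ba_bias_pct = bias, ba_sd_pct = s,
                 ba_loa_low_pct = bias - 1.96 * s,
                 ba_loa_high_pct = bias + 1.96 * s,
                 n_cases = length(pct),
                 excluded_cases = case_ids[zero],
                 denominator_rule = denominator_rule),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("Bland-Altman percent volume difference (denominator: %s, n = %d):\n",
                     "  bias %.3f%% +/- %.3f%%, limits of agreement [%.3f%%, %.3f%%]\n"),
              x$denominator_rule, x$n_cases, x$ba_bias_pct, x$ba_sd_pct,
              x$ba_loa_low_pct, x$ba_loa_high_pct))
  if (length(x$excluded_cases))
    cat("  excluded (zero denominator):", paste(x$excluded_cases, collapse = ", "), "\n")
  invisible(x)
}

#' Two-sided paired Student's t-test on per-case Dice scores
#'
#' Compares matched per-case scores between two conditions (e.g. two
#' training-set sizes evaluated on the same test cases). Significance
#' stars follow the conventional coding: `***` p <= 0.001, `**` p <= 0.01,
#' `*` p <= 0.05. Two degenerate inputs are handled explicitly: all
#' differences zero gives t = 0, p = 1 (flagged); nonzero constant
#' differences have zero variance, so t is infinite and p is reported at
#' the smallest positive double, with a warning.
#'
#' @param dice_a,dice_b equal-length per-case score vectors, matched by
#'   position (or by `case_ids`).
#' @param case_ids optional identifiers; checked for pairing only.
#' @return An object of class `paired_test`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `n_pairs`, `significance_stars`,
#'   `mean_difference`, `degenerate`.
#' @export
paired_t_test <- function(dice_a, dice_b, case_ids = NULL) {
  if (length(dice_a) != length(dice_b))
    stop("paired vectors differ in length: ", length(dice_a), " vs ", length(dice_b))
  n <- length(dice_a)
  if (n < 2L) stop("need >= 2 pairs")
  d <- dice_a - dice_b
  if (all(d == 0)) {
    res <- list(t_statistic = 0, degrees_of_freedom = n - 1L, p_value = 1,
                n_pairs = n, mean_difference = 0, degenerate = TRUE)
  } else if (stats::sd(d) == 0) {
    warning("zero-variance nonzero differences: t is unbounded, p reported ",
            "at the machine floor")
    res <- list(t_statistic = sign(mean(d)) * Inf, degrees_of_freedom = n - 1L,
                p_value = .Machine$double.xmin, n_pairs = n,
                mean_difference = mean(d), degenerate = TRUE)
  } else {
    tt <- stats::t.test(dice_a, dice_b, paired = TRUE)
    res <- list(t_statistic = unname(tt$statistic),
                degrees_of_freedom = unname(tt$parameter),
                p_value = tt$p.value, n_pairs = n,
                mean_difference = unname(tt$estimate), degenerate = FALSE)
  }
  res$significance_stars <- significance_stars(res$p_value)
  structure(res, class = "paired_test")
}

significance_stars <- function(p) {
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired t-test (n = %d): t = %.4f, df = %d, p = %.4g %s\n",
              x$n_pairs, x$t_statistic, x$degrees_of_freedom, x$p_value,
              x$significance_stars))
  invisible(x)
}

#' Paired t-tests between consecutive dataset sizes
#'
#' Tests, for each pair of adjacent training-set sizes, whether the
#' per-case test Dice differs — locating where adding images still changes
#' performance. No multiple-testing correction is applied across the
#' comparisons (each is reported as-is; noted in the output).
#'
#' @param tables named list mapping dataset size (coercible to numeric) to
#'   a `data.frame` with columns `case_id` and `dice`; every table must
#'   contain exactly the same case set.
#' @return `data.frame` with one row per adjacent pair: `size_a, size_b,
#'   t_statistic, degrees_of_freedom, p_value, n_pairs, significance_stars`.
#' @export
adjacent_size_tests <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need metric tables for >= 2 dataset sizes")
  sizes <- as.numeric(names(tables))
  if (anyNA(sizes)) stop("table names must be numeric dataset sizes")
  ord <- order(sizes)
  tables <- tables[ord]; sizes <- sizes[ord]
  ids <- sort(tables[[1L]]$case_id)
  for (i in seq_along(tables)) {
    ti <- sort(tables[[i]]$case_id)
    if (!identical(ti, ids))
      stop("case-set mismatch: size ", sizes[i],
           " does not contain the same case_ids as size ", sizes[1L])
  }
  rows <- lapply(seq_len(length(tables) - 1L), function(i) {
    a <- tables[[i]]; b <- tables[[i + 1L]]
    a <- a[order(a$case_id), ]; b <- b[order(b$case_id), ]
    tt <- paired_t_test(a$dice, b$dice, case_ids = a$case_id)
    data.frame(size_a = sizes[i], size_b = sizes[i + 1L],
               t_statistic = tt$t_statistic,
               degrees_of_freedom = tt$degrees_of_freedom,
               p_value = tt$p_value, n_pairs = tt$n_pairs,
               significance_stars = tt$significance_stars,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
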