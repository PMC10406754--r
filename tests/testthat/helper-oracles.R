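# Independent oracles: deliberately naive routes (explicit loops, closed
# forms, exhaustive scans) against which the package implementations are
# checked. They never share code with the implementation.

# Confusion counts by an explicit triple loop over voxel indices.
oracle_counts <- function(ref, pred, label) {
  r <- ref$voxels; p <- pred$voxels
  d <- dim(r)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    rr <- r[i, j, k] == label; pp <- p[i, j, k] == label
    if (rr && pp) tp <- tp + 1L
    else if (pp) fp <- fp + 1L
    else if (rr) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

# Boundary voxels by explicitly inspecting all 6 face neighbours of every
# mask voxel (grid edge counts as outside); physical coordinates in mm.
oracle_boundary_coords <- function(mask, spacing) {
  d <- dim(mask)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    on_boundary <- FALSE
    for (o in seq_len(6)) {
      ni <- i + offs[o, 1]; nj <- j + offs[o, 2]; nk <- k + offs[o, 3]
      outside <- ni < 1 || nj < 1 || nk < 1 ||
        ni > d[1] || nj > d[2] || nk > d[3] || !mask[ni, nj, nk]
      if (outside) { on_boundary <- TRUE; break }
    }
    if (on_boundary) out <- rbind(out, c(i, j, k) * spacing)
  }
  out
}

# Symmetric mean surface distance by exhaustive nearest-neighbour search.
oracle_msd <- function(ref, pred, label) {
  rm_ <- ref$voxels == label; pm_ <- pred$voxels == label
  if (!any(rm_) || !any(pm_)) return(NA_real_)
  a <- oracle_boundary_coords(rm_, ref$spacing)
  b <- oracle_boundary_coords(pm_, ref$spacing)
  directed <- function(from, to) {
    mean(vapply(seq_len(nrow(from)), function(i) {
      sqrt(min(colSums((t(to) - from[i, ])^2)))
    }, numeric(1)))
  }
  (directed(a, b) + directed(b, a)) / 2
}

# Modal label of one voxel's votes, lowest tied label winning.
oracle_majority_voxel <- function(votes) {
  tab <- table(votes)
  cands <- as.integer(names(tab)[tab == max(tab)])
  min(cands)
}

# Streaming (Welford) mean and sample SD.
oracle_mean_sd <- function(x) {
  n <- 0L; m <- 0; m2 <- 0
  for (v in x) {
    n <- n + 1L
    delta <- v - m
    m <- m + delta / n
    m2 <- m2 + delta * (v - m)
  }
  c(mean = m, sd = if (n > 1L) sqrt(m2 / (n - 1L)) else 0)
}

# OLS slope/intercept/r^2 from the textbook normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y); syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  c(slope = slope, intercept = intercept, r_squared = r^2)
}

# Paired t statistic and two-sided p from first principles.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  c(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Smallest integer x >= 1 whose predicted Dice is within `tol` of d_max, by
# brute-force scanning of integers.
oracle_plateau_scan <- function(d_max, d_zero, k, tol, x_cap = 10^7) {
  gap <- d_max - d_zero
  if (gap <= tol) return(1L)
  x <- 1L
  while (gap * exp(-k * x) > tol) {
    x <- x + 1L
    if (x > x_cap) stop("scan cap exceeded")
  }
  x
}
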