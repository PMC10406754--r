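test_that("predicted Dice follows the exponential-plateau law", {
  fit <- list(d_max = 0.85, d_zero = 0.40, k = 0.02)
  expect_equal(predict_dice(fit, 0), 0.40)               # e^0 = 1 -> D_0
  expect_equal(predict_dice(fit, 40 / 0.02), 0.85, tolerance = 1e-15)
  # frozen from an arbitrary-precision evaluation of 0.85 - 0.45 e^{-2}
  expect_equal(predict_dice(fit, 100), 0.78909912254352428865, tolerance = 1e-15)
  # strictly increasing and bounded when d_max > d_zero
  xs <- seq(0, 500, by = 10)
  d <- predict_dice(fit, xs)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 0.40 & d <= 0.85))
})

test_that("rescaling x by c and k by 1/c leaves the curve unchanged", {
  fit <- list(d_max = 0.9, d_zero = 0.5, k = 0.015)
  fit_scaled <- list(d_max = 0.9, d_zero = 0.5, k = 0.015 / 3)
  xs <- c(1, 10, 50, 400)
  expect_equal(predict_dice(fit, xs), predict_dice(fit_scaled, xs * 3),
               tolerance = 1e-14)
})

test_that("plateau point: closed form, flat curve, and tolerance monotonicity", {
  fit <- list(d_max = 0.85, d_zero = 0.40, k = 0.02, tolerance = 0.01)
  expect_identical(plateau_point(fit), 191L)  # ceil(ln(0.45/0.01)/0.02)
  expect_gte(fit$d_max - predict_dice(fit, 191) , -1e-12)
  expect_lte(fit$d_max - predict_dice(fit, 191), 0.01)
  expect_gt(fit$d_max - predict_dice(fit, 190), 0.01)
  flat <- list(d_max = 0.7, d_zero = 0.7, k = 0.05, tolerance = 0.01)
  expect_identical(plateau_point(flat), 1L)
  # halving the tolerance never decreases the plateau point
  for (seed in 1:20) {
    set.seed(seed)
    f <- list(d_max = runif(1, 0.5, 1), d_zero = runif(1, 0, 0.5),
              k = runif(1, 0.005, 0.3))
    expect_gte(plateau_point(f, tolerance = 0.005), plateau_point(f, tolerance = 0.01))
  }
})

test_that("plateau closed form equals the brute-force integer scan", {
  set.seed(42)
  for (i in 1:50) {
    d_max <- runif(1, 0.3, 1); d_zero <- runif(1, 0, d_max)
    k <- runif(1, 0.002, 0.8); tol <- sample(c(0.01, 0.02, 0.005), 1)
    fit <- list(d_max = d_max, d_zero = d_zero, k = k)
    expect_identical(plateau_point(fit, tolerance = tol),
                     oracle_plateau_scan(d_max, d_zero, k, tol))
  }
})

test_that("noiseless curves are refit to the generating parameters", {
  truth <- list(d_max = 0.85, d_zero = 0.40, k = 0.02)
  obs <- data.frame(x = seq(50, 300, by = 50),
                    dice = predict_dice(truth, seq(50, 300, by = 50)))
  fit <- fit_plateau(obs)
  expect_equal(fit$d_max, 0.85, tolerance = 1e-6)
  expect_equal(fit$d_zero, 0.40, tolerance = 1e-6)
  expect_equal(fit$k, 0.02, tolerance = 1e-6)
  expect_identical(fit$plateau_x, 191L)
  expect_true(fit$converged)
  expect_false(fit$flat_curve)
  expect_false(fit$extrapolated)
  expect_lt(fit$residual_sum_squares, 1e-12)
})

test_that("degenerate flat observations return the flat-curve fit", {
  obs <- data.frame(x = c(50, 100, 150, 200), dice = rep(0.7, 4))
  fit <- fit_plateau(obs)
  expect_equal(fit$d_max, 0.7)
  expect_equal(fit$d_zero, 0.7)
  expect_true(fit$flat_curve)
  expect_identical(fit$plateau_x, 1L)
})

test_that("fitting preconditions are enforced", {
  expect_error(fit_plateau(data.frame(x = c(50, 50, 100), dice = c(0.5, 0.6, 0.7))),
               "3 distinct")
  expect_error(fit_plateau(data.frame(x = 1:5, dice = c(0.5, 0.6, 0.7, 0.8, 1.2))),
               "\\[0, 1\\]")
  expect_error(fit_plateau(data.frame(x = c(0, 50, 100), dice = c(0.5, 0.6, 0.7))),
               ">= 1")
})

test_that("ensemble_only uses ensemble rows; all_points uses folds too", {
  obs <- simulate_learning_curve(noise_sd = 0.03, seed = 5)
  fe <- fit_plateau(obs, use = "ensemble_only")
  fa <- fit_plateau(obs, use = "all_points")
  expect_identical(fe$n_points, 6L)
  expect_identical(fa$n_points, 36L)  # 5 folds + 1 ensemble row per size
  # both recover the truth approximately
  expect_equal(fe$d_max, 0.93, tolerance = 0.05)
  expect_equal(fa$d_max, 0.93, tolerance = 0.05)
})

test_that("the extrapolation flag fires iff the plateau exceeds observed sizes", {
  truth <- list(d_max = 0.85, d_zero = 0.4, k = 0.004)  # slow curve
  xs <- seq(50, 300, by = 50)
  obs <- data.frame(x = xs, dice = predict_dice(truth, xs))
  fit <- fit_plateau(obs)
  expect_gt(fit$plateau_x, 300)
  expect_true(fit$extrapolated)
})

test_that("stability analysis with no drops equals a single fit", {
  obs <- simulate_learning_curve(seed = 8)
  st <- stability_analysis(obs, max_drops = 0L)
  fit <- fit_plateau(obs)
  expect_identical(nrow(st$table), 1L)
  expect_equal(st$table$d_max, fit$d_max)
  expect_equal(st$max_dmax_gap, 0)
  expect_true(st$stable)
})

test_that("noiseless stability gives identical fits; gaps match direct refits", {
  truth <- list(d_max = 0.85, d_zero = 0.40, k = 0.02)
  xs <- seq(50, 300, by = 50)
  obs <- data.frame(x = xs, dice = predict_dice(truth, xs))
  st <- stability_analysis(obs, max_drops = 2L)
  expect_lt(st$max_dmax_gap, 1e-6)
  expect_true(st$stable)

  # perturb the two largest sizes upward: drops change d_max as direct refits say
  obs2 <- obs
  obs2$dice[obs2$x >= 250] <- pmin(obs2$dice[obs2$x >= 250] + 0.08, 1)
  st2 <- stability_analysis(obs2, max_drops = 2L)
  f_full <- fit_plateau(obs2)
  f_d1 <- fit_plateau(obs2[obs2$x < 300, ])
  f_d2 <- fit_plateau(obs2[obs2$x < 250, ])
  expect_equal(st2$table$d_max, c(f_full$d_max, f_d1$d_max, f_d2$d_max),
               tolerance = 1e-8)
  expect_equal(st2$max_dmax_gap,
               max(abs(diff(c(f_full$d_max, f_d1$d_max, f_d2$d_max)))),
               tolerance = 1e-8)
  expect_false(st2$stable)
})

test_that("stability refuses to drop below three distinct sizes", {
  obs <- data.frame(x = c(50, 100, 150, 200), dice = c(0.5, 0.6, 0.65, 0.67))
  expect_error(stability_analysis(obs, max_drops = 2L), ">= 3 required")
})

test_that("quartile analysis groups by reference volume and refits per quartile", {
  # synthetic cohort: 20 cases, small volumes systematically harder
  set.seed(14)
  n <- 20
  vols <- sort(runif(n, 5, 120))
  ids <- sprintf("case%02d", 1:n)
  xs <- seq(50, 300, by = 50)
  truth_small <- list(d_max = 0.70, d_zero = 0.30, k = 0.015)
  truth_large <- list(d_max = 0.92, d_zero = 0.45, k = 0.02)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    w <- (i - 1) / (n - 1)  # 0 = smallest volume, 1 = largest
    d_max <- (1 - w) * truth_small$d_max + w * truth_large$d_max
    d_zero <- (1 - w) * truth_small$d_zero + w * truth_large$d_zero
    k <- (1 - w) * truth_small$k + w * truth_large$k
    data.frame(x = xs, case_id = ids[i], ref_volume_ml = vols[i],
               dice = predict_dice(list(d_max = d_max, d_zero = d_zero, k = k), xs))
  }))
  qa <- quartile_curve_analysis(rows)
  expect_identical(sort(unique(qa$assignments$quartile)), 1:4)
  expect_identical(as.integer(table(qa$assignments$quartile)), rep(5L, 4))
  # quartile mean Dice equals a hand-grouped recomputation
  q1_ids <- qa$assignments$case_id[qa$assignments$quartile == 1]
  by_hand <- sapply(xs, function(xx)
    mean(rows$dice[rows$case_id %in% q1_ids & rows$x == xx]))
  got <- qa$observations[qa$observations$quartile == 1, ]
  expect_equal(got$dice[order(got$x)], by_hand, tolerance = 1e-12)
  # smallest-volume quartile plateaus lower than the full cohort
  overall <- fit_plateau(stats::aggregate(dice ~ x, rows, mean), use = "all_points")
  expect_lt(qa$fits$quartile_1$d_max, overall$d_max)
})

test_that("quartile ties are broken deterministically by case order", {
  rows <- expand.grid(case_id = sprintf("c%02d", 1:8), x = c(10, 20, 30))
  rows$ref_volume_ml <- 50          # all identical volumes
  rows$dice <- 0.8
  qa <- quartile_curve_analysis(rows)
  expect_identical(qa$assignments$quartile, rep(1:4, each = 2))
  qa2 <- quartile_curve_analysis(rows)
  expect_identical(qa$assignments, qa2$assignments)
})

test_that("curve CSV reading validates structure and names bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  obs <- simulate_learning_curve(seed = 2)
  utils::write.csv(obs, f, row.names = FALSE)
  back <- read_curve_csv(f)
  expect_equal(back$dice, obs$dice)
  writeLines(c("x,dice", "50,0.5", "oops,0.6"), f)
  expect_error(read_curve_csv(f), "row.* 2")
  writeLines(c("a,b", "1,2"), f)
  expect_error(read_curve_csv(f), "must have columns")
})
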