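# Map construction and per-cell / per-pair statistics.

test_that("baseline_sd: degenerate and analytic cases", {
  sr <- 1000
  expect_identical(baseline_sd(rep(0, 300), sr, 200), 0)
  # alternating +/-1 baseline: SD -> 1 (sample SD, so up to n/(n-1))
  x <- rep(c(-1, 1), 150)
  expect_equal(baseline_sd(c(x, rep(0, 100)), sr, 300, baseline_ms = 300), 1,
               tolerance = 2e-3)
  expect_error(baseline_sd(rep(0, 100), sr, 0),
               class = "scracmap_window_error")
})

test_that("baseline_sd of the repetition average scales as sigma/sqrt(reps)", {
  set.seed(101)
  sds <- replicate(400, {
    sw <- matrix(rnorm(5 * 250, sd = 2), 5, 250)
    baseline_sd(sw, 1000, 200, baseline_ms = 200)
  })
  expect_equal(mean(sds), 2 / sqrt(5), tolerance = 0.02)
})

test_that("compute_pixel_response: trivial cases and error", {
  sr <- 1000
  expect_identical(compute_pixel_response(rep(0, 300), sr, 100), 0)
  tr <- c(rep(0, 100), rep(-10, 75))
  expect_equal(compute_pixel_response(tr, sr, 100), 10)
  expect_error(compute_pixel_response(rep(0, 120), sr, 100),
               class = "scracmap_window_error")
})

test_that("pixel statistic matches the brute-force per-sample oracle", {
  set.seed(7)
  sr <- 2000
  for (i in 1:25) {
    reps <- sample(3:5, 1)
    sw <- matrix(rnorm(reps * 250, sd = runif(1, 0.5, 5)), reps, 250)
    expect_equal(compute_pixel_response(sw, sr, 50),
                 oracle_pixel_response(sw, sr, 50), tolerance = 1e-9)
  }
})

test_that("build_map reproduces ground truth exactly without noise and
           rejects incomplete grids", {
  ds <- generate_scracm_dataset(fast_cfg(n_pairs = 1, noise_sd = 0, seed = 8L))
  for (id in names(ds$cells)) {
    m <- build_map(ds$cells[[id]])
    expect_identical(dim(m$values), c(16L, 8L))
    expect_equal(m$values, ds$ground_truth$amplitudes[[id]],
                 tolerance = 1e-12)
    m0 <- build_map(ds$cells[[id]], threshold_mult = 0)
    expect_equal(m0$values, m$values, tolerance = 1e-12)
  }
  broken <- ds$cells[[1]]
  broken$sweeps <- broken$sweeps[1:100, , , drop = FALSE]
  expect_error(build_map(broken), "missing",
               class = "scracmap_sites_error")
})

test_that("map summaries: totals, per-area mean, responsive area", {
  v <- matrix(0, 16, 8)
  v[3, 2] <- 5; v[10, 7] <- 7
  m <- manual_map(v)
  expect_identical(total_input(m), 12)
  expect_equal(mean_epsc_per_area(m), 6 / 5625)
  expect_identical(responsive_area(m), 2 * 5625)

  m1 <- manual_map(matrix(c(56.25, rep(0, 127)), 16, 8))
  expect_equal(mean_epsc_per_area(m1), 0.01)
  expect_equal(mean_epsc_per_area(manual_map(matrix(c(10, 20, rep(0, 126)),
                                                    16, 8))), 15 / 5625)

  z <- manual_map(matrix(0, 16, 8))
  expect_warning(res <- mean_epsc_per_area(z), class = "scracmap_undefined")
  expect_true(is.na(res))
  expect_identical(responsive_area(z), 0)

  # elementwise oracle on a random map
  set.seed(9)
  v <- matrix(rexp(128), 16, 8)
  s <- 0
  for (i in 1:16) for (j in 1:8) s <- s + v[i, j]
  expect_equal(total_input(manual_map(v)), s)
  expect_identical(responsive_area(manual_map(v)), sum(v > 0) * 5625)
})

test_that("time_to_peak matches the analytic kernel peak and orders PV before
           Pyr", {
  tr_pv <- 0.5; tr_pyr <- 2; td <- 6
  cfg <- scracm_sim_config(n_pairs = 1, sampling_rate = 10000,
                           baseline_duration = 50, noise_sd = 0,
                           tau_rise_pv = tr_pv, tau_rise_pyr = tr_pyr,
                           tau_decay = td, seed = 10L)
  ds <- generate_scracm_dataset(cfg)
  dt <- 1000 / cfg$sampling_rate
  expect_equal(time_to_peak(ds$cells[["pair01_pv"]]),
               kernel_time_to_peak(tr_pv, td), tolerance = dt * 1.01)
  expect_equal(time_to_peak(ds$cells[["pair01_pyr"]]),
               kernel_time_to_peak(tr_pyr, td), tolerance = dt * 1.01)
  expect_lt(time_to_peak(ds$cells[["pair01_pv"]]),
            time_to_peak(ds$cells[["pair01_pyr"]]))

  # single-sample impulse 10 ms after onset
  imp <- ds$cells[["pair01_pv"]]
  sw <- array(0, dim = dim(imp$sweeps))
  sw[, , 500 + 100 + 1] <- -50 # onset sample index 500, +10 ms at 10 kHz
  imp$sweeps <- sw
  expect_equal(time_to_peak(imp, threshold_mult = 0), 10)

  # no significant pixels -> undefined
  none <- ds$cells[["pair01_pv"]]
  none$sweeps <- array(0, dim = dim(none$sweeps))
  expect_warning(res <- time_to_peak(none), class = "scracmap_undefined")
  expect_true(is.na(res))
})

test_that("pair_ratio recovers the planted fold exactly without noise and
           applies the pairing rules", {
  ds <- generate_scracm_dataset(fast_cfg(n_pairs = 1, noise_sd = 0,
                                         pv_fold = 4, pv_fold_spread = 0,
                                         seed = 12L))
  pv <- ds$cells[["pair01_pv"]]; pyr <- ds$cells[["pair01_pyr"]]
  pc <- pair_ratio(pv, pyr)
  expect_equal(pc$fold, 4, tolerance = 1e-12)
  # conductance normalization: fold 4 with g_pv/g_pyr = 2 -> fold_norm 2
  pv$conductance <- 10; pyr$conductance <- 5
  expect_equal(pair_ratio(pv, pyr)$fold_norm, 2, tolerance = 1e-12)

  # noiseless monotonicity: scaling PV sweeps by c scales the fold by c
  pv3 <- pv
  pv3$sweeps <- pv3$sweeps * 3
  expect_equal(pair_ratio(pv3, pyr)$fold, 12, tolerance = 1e-12)

  far <- pv
  far$soma <- pyr$soma + c(2, 0) # 150 um away
  expect_error(pair_ratio(far, pyr), class = "scracmap_pairing_error")
  other <- pv
  other$layer <- "L5"
  expect_error(pair_ratio(other, pyr), class = "scracmap_pairing_error")
  expect_error(pair_ratio(pyr, pv), class = "scracmap_pairing_error")

  # zero Pyr total -> excluded, not dropped silently
  mute <- pyr
  mute$sweeps <- array(0, dim = dim(mute$sweeps))
  expect_warning(pc0 <- pair_ratio(pv, mute),
                 class = "scracmap_excluded_pair")
  expect_true(pc0$excluded)
  expect_true(is.na(pc0$fold))
})

test_that("cohort_slope is the geometric mean of folds", {
  expect_equal(as.numeric(cohort_slope(c(2, 8))), 4)
  expect_equal(as.numeric(cohort_slope(c(4, 9))), 6)
  expect_equal(as.numeric(cohort_slope(rep(1, 10))), 1)
  s <- cohort_slope(c(2, 8, NA))
  expect_identical(attr(s, "n_excluded"), 1L)
  expect_identical(attr(s, "n"), 2L)
  expect_error(cohort_slope(c(2, -1)), class = "scracmap_input_error")
  expect_error(cohort_slope(NA_real_), class = "scracmap_input_error")
})

test_that("laminar profile normalizes rows to 100% and assigns rows to
           bands by centre depth", {
  # uniform map: 16 rows x 6.25% each; rows 1-2 (depths 37.5, 112.5) in L1
  lp <- laminar_profile(manual_map(matrix(1, 16, 8)))
  expect_equal(lp$row_totals_pct, rep(6.25, 16))
  expect_equal(sum(lp$row_totals_pct), 100, tolerance = 1e-9)
  expect_equal(unname(lp$layer_fractions["L1"]), 6.25)
  expect_identical(lp$rows_per_layer$L1, 1:2)
  expect_equal(layer_fraction(lp, c("L2/3", "L4")), 6.25)

  # all input in L1 rows
  v <- matrix(0, 16, 8); v[1:2, ] <- 3
  lp1 <- laminar_profile(manual_map(v))
  expect_equal(sum(lp1$row_totals_pct[1:2]), 100, tolerance = 1e-9)
  expect_equal(unname(lp1$layer_fractions["L1"]), 50) # mean of two 50% rows
  expect_equal(unname(lp1$layer_fractions["L5"]), 0)

  # normalization holds for random maps
  set.seed(13)
  for (i in 1:20) {
    lp2 <- laminar_profile(manual_map(matrix(rexp(128), 16, 8)))
    expect_equal(sum(lp2$row_totals_pct), 100, tolerance = 1e-9)
  }
  expect_warning(laminar_profile(manual_map(matrix(0, 16, 8))),
                 class = "scracmap_undefined")
})

test_that("average_map normalizes, averages and preserves mass under
           interpolation", {
  set.seed(14)
  m1 <- manual_map(matrix(rexp(128), 16, 8))
  a1 <- average_map(list(m1), "panel_max")
  expect_equal(max(a1$values), 1, tolerance = 1e-12)
  a2 <- average_map(list(m1, m1), "panel_max")
  expect_equal(a2$coarse, a1$coarse)
  # pair_max: each pair normalized by its own maximum
  m2 <- manual_map(2 * m1$values)
  ap <- average_map(list(m1, m2), "pair_max", pair_id = c("a", "a"))
  expect_equal(max(ap$values), 1, tolerance = 1e-12)
  # integral agreement between coarse and fine rasters (trapezoidal rule)
  trapz2 <- function(m) {
    w <- function(n) c(0.5, rep(1, n - 2), 0.5)
    as.numeric(w(nrow(m)) %*% m %*% w(ncol(m)))
  }
  expect_equal(trapz2(a1$values) / a1$upsample^2, trapz2(a1$coarse),
               tolerance = 0.02 * trapz2(a1$coarse))
  act <- average_map(list(m1, m2), "cell_total")
  expect_equal(sum(act$coarse), 1, tolerance = 1e-12) # totals normalized to 1
  bad <- manual_map(matrix(1, 8, 8))
  expect_error(average_map(list(m1, bad), "panel_max"),
               class = "scracmap_input_error")
  expect_error(average_map(list(m1, m2), "pair_max"),
               class = "scracmap_input_error")
})

test_that("compare_pathways dispatches the right tests with sane degenerate
           behaviour", {
  g <- list(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  kw <- compare_pathways(g, "kruskal")
  expect_equal(kw$statistic, 0, tolerance = 1e-9)
  expect_gt(kw$p_value, 0.99)
  w <- compare_pathways(list(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5)),
                        "wilcoxon_paired")
  expect_equal(w$p_value, 1)
  mw <- compare_pathways(list(rnorm(10) + 10, rnorm(10)), "mwu")
  expect_lt(mw$p_value, 0.01)
  tt <- compare_pathways(list(c(1, 2, 3, 4), c(1.5, 2.4, 3.6, 4.5)),
                         "t_paired")
  expect_lt(tt$p_value, 0.05)
  expect_error(compare_pathways(list(1:5), "kruskal"),
               class = "scracmap_input_error")
  expect_error(compare_pathways(list(1:5, 1:4), "t_paired"),
               class = "scracmap_input_error")
  expect_error(compare_pathways(list(1:5, 1:5, 1:5), "mwu"),
               class = "scracmap_input_error")
})
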