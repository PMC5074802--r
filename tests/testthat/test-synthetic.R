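# Synthetic-data generator: config validation, determinism, and the
# ground-truth construction invariants every downstream recovery test
# relies on.

test_that("config validation rejects invalid parameters", {
  expect_error(scracm_sim_config(window_duration = -1),
               class = "scracmap_config_error")
  expect_error(scracm_sim_config(pv_fold = 0), class = "scracmap_config_error")
  expect_error(scracm_sim_config(reps_per_site = 2),
               class = "scracmap_config_error")
  expect_error(scracm_sim_config(reps_per_site = 6),
               class = "scracmap_config_error")
  expect_error(scracm_sim_config(layer_boundaries = c(L1 = 300, `L2/3` = 100)),
               class = "scracmap_config_error")
  expect_error(scracm_sim_config(tau_rise_pyr = 10, tau_decay = 6),
               class = "scracmap_config_error")
  expect_error(generate_projection_image(planted_dr = 0),
               class = "scracmap_config_error")
  expect_error(generate_paired_recording(TRUE, spikes_per_step = c(2, 1, 1, 1)),
               class = "scracmap_config_error")
  expect_error(generate_paired_recording(TRUE, unitary_ipsc = -5),
               class = "scracmap_config_error")
})

test_that("identical config and seed give identical datasets", {
  cfg <- fast_cfg(n_pairs = 2, seed = 42L)
  a <- generate_scracm_dataset(cfg)
  b <- generate_scracm_dataset(cfg)
  expect_identical(a, b)
  expect_identical(generate_projection_image(1.8, seed = 9L),
                   generate_projection_image(1.8, seed = 9L))
  expect_identical(generate_paired_recording(TRUE, seed = 5L),
                   generate_paired_recording(TRUE, seed = 5L))
  # different seed actually changes the draw
  expect_false(identical(
    a$cells[[1]]$sweeps,
    generate_scracm_dataset(fast_cfg(n_pairs = 2, seed = 43L))$cells[[1]]$sweeps))
})

test_that("degenerate configs produce exactly-zero recordings", {
  ds <- generate_scracm_dataset(
    fast_cfg(n_pairs = 1, noise_sd = 0, pyr_peak_amplitude = 0))
  for (cell in ds$cells) expect_true(all(cell$sweeps == 0))
  for (a in ds$ground_truth$amplitudes) expect_true(all(a == 0))
})

test_that("zero fold spread plants the fold exactly; log-normal spread has the
           stated geometric mean", {
  ds <- generate_scracm_dataset(
    fast_cfg(n_pairs = 5, pv_fold = 4, pv_fold_spread = 0))
  expect_identical(ds$ground_truth$folds, rep(4, 5))
  # geometric mean converges on the planted fold (sampling error ~ sigma/sqrt(n))
  set.seed(1)
  f <- exp(log(4) + rnorm(4000, 0, 0.15))
  expect_equal(exp(mean(log(f))), 4, tolerance = 0.01)
})

test_that("conservation: ground-truth amplitude equals the noiseless windowed
           mean at every site", {
  cfg <- fast_cfg(n_pairs = 2, noise_sd = 0, pv_fold = 3,
                  pv_fold_spread = 0.2, seed = 11L)
  ds <- generate_scracm_dataset(cfg)
  for (id in names(ds$cells)) {
    cell <- ds$cells[[id]]
    amp <- as.vector(ds$ground_truth$amplitudes[[id]])
    got <- vapply(seq_along(amp), function(s)
      compute_pixel_response(cell$sweeps[s, , ], cell$sampling_rate,
                             cell$stim_onset_ms), numeric(1))
    expect_equal(got, amp, tolerance = 1e-9)
  }
})

test_that("PV to Pyr ground-truth totals equal the planted per-pair fold
           exactly", {
  ds <- generate_scracm_dataset(fast_cfg(n_pairs = 4, pv_fold = 7,
                                         pv_fold_spread = 0.3, seed = 2L))
  for (i in seq_len(nrow(ds$pairs))) {
    r <- sum(ds$ground_truth$amplitudes[[ds$pairs$pv_id[i]]]) /
      sum(ds$ground_truth$amplitudes[[ds$pairs$pyr_id[i]]])
    expect_equal(r, ds$ground_truth$folds[i], tolerance = 1e-12)
  }
})

test_that("off-footprint baseline noise has the configured SD", {
  cfg <- fast_cfg(n_pairs = 1, noise_sd = 2, input_sigma_rows = 1,
                  input_center_row = 8, seed = 3L)
  ds <- generate_scracm_dataset(cfg)
  amp <- as.vector(ds$ground_truth$amplitudes[[1]])
  cold <- which(amp == 0)
  x <- as.vector(ds$cells[[1]]$sweeps[cold, , ])
  expect_gt(length(x), 10000)
  expect_equal(sd(x), 2, tolerance = 0.05 * 2)
})

test_that("projection image plants the band-mean ratio exactly when
           noiseless", {
  bands <- layer_bands()
  for (dr in c(1, 2.5)) {
    img <- generate_projection_image(dr, bands, noise_sd = 0, seed = 4L)
    d <- (seq_len(nrow(img$pixels)) - 0.5) * img$pixel_size_um
    m1 <- mean(img$pixels[d < 150, ])
    m24 <- mean(img$pixels[d >= 150 & d < 600, ])
    expect_equal(m24 / m1, dr, tolerance = 1e-9)
  }
})

test_that("paired-recording construction: spike counts, connectivity and
           pulse summation", {
  pr <- generate_paired_recording(TRUE, unitary_ipsc = 20,
                                  spikes_per_step = c(0, 1, 2, 4),
                                  noise_sd = 0, seed = 6L)
  counts <- vapply(seq_along(pr$steps), function(j)
    length(detect_spikes(colMeans(pr$pv[[j]]), pr$sampling_rate)), numeric(1))
  expect_identical(counts, c(0, 1, 2, 4))
  # non-overlapping IPSCs: windowed mean proportional to spike count
  resp <- vapply(seq_along(pr$steps), function(j)
    ipsc_response(pr$pyr[[j]], pr$sampling_rate, pr$step_onset_ms),
    numeric(1))
  expect_equal(resp[1], 0, tolerance = 1e-12)
  expect_equal(resp[3] / resp[2], 2, tolerance = 1e-3)
  expect_equal(resp[4] / resp[2], 4, tolerance = 1e-3)
  # unconnected pair: pure noise responses near zero
  pr0 <- generate_paired_recording(FALSE, noise_sd = 0, seed = 6L)
  for (j in seq_along(pr0$steps))
    expect_equal(ipsc_response(pr0$pyr[[j]], pr0$sampling_rate,
                               pr0$step_onset_ms), 0, tolerance = 1e-12)
})
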