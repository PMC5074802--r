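# Shared fixtures, all generated in code. Test configs run at 2 kHz with a
# 50 ms baseline (instead of the 10 kHz / 100 ms defaults) purely to keep
# the suite inside its time budget; every assertion is rate-agnostic.

fast_cfg <- function(...) {
  args <- list(...)
  defaults <- list(sampling_rate = 2000, baseline_duration = 50, seed = 1L)
  do.call(scracm_sim_config, utils::modifyList(defaults, args))
}

# A bare scracm_map for unit tests that need exact pixel values.
manual_map <- function(values, pitch = 75, pia_offset = 37.5,
                       boundaries = c(L1 = 150, `L2/3` = 400, L4 = 500,
                                      L5 = 750, L6 = 1200)) {
  structure(list(values = values, pixel_pitch_um = pitch,
                 pia_offset_um = pia_offset, soma = c(6, 4),
                 cell_id = "manual", cell_type = "Pyr", layer = "L2/3",
                 layer_boundaries = boundaries, threshold_mult = 4,
                 window_ms = 75, polarity_flags = integer(0)),
            class = "scracm_map")
}

# A bare density_map (already filtered/normalized) with named row bands.
manual_dmap <- function(values, pixel_size_um = 5,
                        bands = layer_bands(), filter_radius = NULL) {
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 bands = bands, filter_radius = filter_radius),
            class = "density_map")
}

# Brute-force windowed-mean oracle: per-sample loops, no vectorized means.
oracle_pixel_response <- function(sweeps, sampling_rate, stim_onset_ms,
                                  window_ms = 75, baseline_ms = 100) {
  if (is.null(dim(sweeps))) sweeps <- matrix(sweeps, nrow = 1)
  n <- ncol(sweeps)
  avg <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(nrow(sweeps))) s <- s + sweeps[i, j]
    avg[j] <- s / nrow(sweeps)
  }
  n_on <- as.integer(round(stim_onset_ms * sampling_rate / 1000))
  n_base <- min(n_on, as.integer(round(baseline_ms * sampling_rate / 1000)))
  n_win <- as.integer(round(window_ms * sampling_rate / 1000))
  b <- 0
  for (j in (n_on - n_base + 1):n_on) b <- b + avg[j]
  b <- b / n_base
  w <- 0
  for (j in (n_on + 1):(n_on + n_win)) w <- w + avg[j]
  w <- w / n_win
  abs(w - b)
}

# Naive disk-convolution oracle matching the normalized-convolution rule.
oracle_disk_filter <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    s <- 0; n <- 0
    for (dy in -radius:radius) for (dx in -radius:radius) {
      if (dy^2 + dx^2 > radius^2) next
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc) {
        s <- s + img[yy, xx]
        n <- n + 1
      }
    }
    out[y, x] <- s / n
  }
  out
}
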