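#' Configuration for the synthetic sCRACM dataset generator
#'
#' Bundles every tunable of the gridded-photostimulation simulator with
#' validation. Defaults reproduce the mapping protocol: an 8 x 16
#' photostimulation grid with 75 um spacing, responses quantified as the
#' mean EPSC over 75 ms after the stimulus, 3-5 repetitions per site, and
#' cells voltage-clamped at -70 mV (inward EPSCs are negative).
#'
#' Amplitude defaults state the simulated world once: pyramidal-cell peak
#' windowed-mean amplitude 20 pA with raw noise SD 2 pA (peak signal-to-noise
#' about 10), a Gaussian input footprint with SD 2 grid rows (~150 um,
#' centred near the bottom of L2/3), and a log-normal per-pair PV:Pyr fold
#' spread of 0.15 (log scale). The recordings never state these levels; see
#' the methods vignette for the rationale.
#'
#' @param n_pairs Number of PV/Pyr cell pairs to simulate.
#' @param grid_rows,grid_cols Photostimulation grid size (default 16 x 8).
#' @param pixel_pitch Grid spacing in um (default 75).
#' @param reps_per_site Stimulus repetitions per grid site, must be in 3..5.
#' @param sampling_rate Acquisition rate in Hz.
#' @param baseline_duration Pre-stimulus baseline per sweep, ms.
#' @param window_duration Response window after the stimulus, ms (default 75).
#' @param noise_sd Gaussian recording-noise SD per raw sweep, pA.
#' @param pyr_peak_amplitude Windowed-mean EPSC magnitude at the footprint
#'   centre for pyramidal cells, pA.
#' @param pv_fold Planted EPSC_PV/EPSC_Pyr ratio (geometric mean across pairs).
#' @param pv_fold_spread Log-normal sigma of the per-pair fold.
#' @param input_center_row,input_sigma_rows Gaussian input footprint along the
#'   pia-to-white-matter axis, in grid-row units.
#' @param tau_rise_pv,tau_rise_pyr,tau_decay EPSC kinetics, ms. PV rise is
#'   faster than Pyr, matching the faster recruitment of PV interneurons.
#' @param layer_boundaries Named, strictly increasing depths of layer bottoms
#'   in um from the pia.
#' @param pia_offset Depth of row-1 grid centres below the pia, um.
#' @param layer Layer label assigned to all simulated somata.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An object of class `scracm_sim_config` (validated list).
#' @export
scracm_sim_config <- function(n_pairs = 14,
                              grid_rows = 16, grid_cols = 8,
                              pixel_pitch = 75,
                              reps_per_site = 3,
                              sampling_rate = 10000,
                              baseline_duration = 100,
                              window_duration = 75,
                              noise_sd = 2,
                              pyr_peak_amplitude = 20,
                              pv_fold = 4,
                              pv_fold_spread = 0.15,
                              input_center_row = 6,
                              input_sigma_rows = 2,
                              tau_rise_pv = 0.5,
                              tau_rise_pyr = 2,
                              tau_decay = 6,
                              layer_boundaries = c(L1 = 100, `L2/3` = 400,
                                                   L4 = 500, L5 = 750,
                                                   L6 = 1000),
                              pia_offset = 37.5,
                              layer = "L2/3",
                              seed = 1L) {
  cfg <- as.list(environment())
  pos <- c("pixel_pitch", "sampling_rate", "baseline_duration",
           "window_duration", "pv_fold", "input_sigma_rows",
           "tau_rise_pv", "tau_rise_pyr", "tau_decay")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      abort(sprintf("'%s' must be a positive scalar", f),
            "scracmap_config_error")
  for (f in c("noise_sd", "pyr_peak_amplitude", "pv_fold_spread"))
    if (cfg[[f]] < 0)
      abort(sprintf("'%s' must be >= 0", f), "scracmap_config_error")
  if (n_pairs < 1L) abort("'n_pairs' must be >= 1", "scracmap_config_error")
  if (!reps_per_site %in% 3:5)
    abort("'reps_per_site' must be 3, 4 or 5", "scracmap_config_error")
  if (is.unsorted(layer_boundaries, strictly = TRUE) ||
      any(layer_boundaries <= 0) || is.null(names(layer_boundaries)))
    abort("'layer_boundaries' must be named, positive, strictly increasing",
          "scracmap_config_error")
  if (cfg$tau_decay <= max(cfg$tau_rise_pv, cfg$tau_rise_pyr))
    abort("'tau_decay' must exceed both rise constants",
          "scracmap_config_error")
  structure(cfg, class = "scracm_sim_config")
}

# Noiseless windowed-mean amplitude of the Pyr-cell response at each grid
# site: Gaussian along depth (rows), uniform across columns (the footprint is
# modeled as a laminar slab), truncated to zero beyond 3 sigma.
footprint_amplitudes <- function(cfg) {
  rows <- seq_len(cfg$grid_rows)
  a <- cfg$pyr_peak_amplitude *
    exp(-((rows - cfg$input_center_row)^2) / (2 * cfg$input_sigma_rows^2))
  a[abs(rows - cfg$input_center_row) > 3 * cfg$input_sigma_rows] <- 0
  matrix(a, nrow = cfg$grid_rows, ncol = cfg$grid_cols)
}

# Build the sweep array for one cell. amplitudes: grid_rows x grid_cols
# noiseless windowed-mean magnitudes (pA). Returns [site, rep, sample] with
# sites in column-major grid order (row fastest).
simulate_cell_sweeps <- function(amplitudes, cfg, tau_rise) {
  n_sites <- cfg$grid_rows * cfg$grid_cols
  n_base <- ms_to_samples(cfg$baseline_duration, cfg$sampling_rate)
  n_win <- ms_to_samples(cfg$window_duration, cfg$sampling_rate)
  n_samp <- n_base + n_win
  dt <- 1000 / cfg$sampling_rate
  k <- psc_kernel(n_win, dt, tau_rise, cfg$tau_decay)
  k <- k / mean(k) # windowed mean of k is now exactly 1
  sw <- array(rnorm(n_sites * cfg$reps_per_site * n_samp, sd = cfg$noise_sd),
              dim = c(n_sites, cfg$reps_per_site, n_samp))
  amp <- as.vector(amplitudes) # site order: row fastest
  hot <- which(amp > 0)
  for (s in hot) {
    ev <- -amp[s] * k # inward EPSC at -70 mV: negative current
    sw[s, , (n_base + 1):n_samp] <-
      sw[s, , (n_base + 1):n_samp, drop = FALSE] +
      rep(ev, each = cfg$reps_per_site)
  }
  sw
}

new_cell_recording <- function(cell_id, cell_type, conductance, soma, sweeps,
                               cfg) {
  structure(list(
    cell_id = cell_id,
    cell_type = cell_type,
    layer = cfg$layer,
    conductance = conductance,
    soma = soma, # c(row, col), fractional grid units
    sweeps = sweeps, # [site, rep, sample]
    grid_rows = cfg$grid_rows,
    grid_cols = cfg$grid_cols,
    sampling_rate = cfg$sampling_rate,
    stim_onset_ms = cfg$baseline_duration,
    pixel_pitch_um = cfg$pixel_pitch,
    pia_offset_um = cfg$pia_offset,
    layer_boundaries = cfg$layer_boundaries
  ), class = "cell_recording")
}

#' Generate a synthetic gridded sCRACM dataset with planted ground truth
#'
#' For each simulated pair, one PV and one pyramidal cell are "recorded":
#' every grid site yields `reps_per_site` sweeps of Gaussian baseline noise
#' plus, at sites inside the input footprint, a difference-of-exponentials
#' EPSC whose noiseless windowed mean equals the ground-truth amplitude
#' exactly. PV amplitudes are the pair's planted fold times the Pyr
#' amplitudes at homologous sites, so the ratio of ground-truth totals equals
#' the planted fold exactly. Per-pair folds are log-normal around `pv_fold`
#' (geometric mean).
#'
#' @param config A [scracm_sim_config()].
#' @return An object of class `scracm_dataset`: list with `cells` (named list
#'   of `cell_recording`), `pairs` (data.frame pair_id/pv_id/pyr_id/distance),
#'   `ground_truth` (per-pair folds, per-cell noiseless amplitude matrices),
#'   and `config`.
#' @export
generate_scracm_dataset <- function(config) {
  stopifnot(inherits(config, "scracm_sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  base_amp <- footprint_amplitudes(cfg)
  folds <- exp(log(cfg$pv_fold) + rnorm(cfg$n_pairs, 0, cfg$pv_fold_spread))

  cells <- list()
  gt_amp <- list()
  pairs <- vector("list", cfg$n_pairs)
  for (i in seq_len(cfg$n_pairs)) {
    # Somata near the footprint centre; PV placed < 100 um from its Pyr.
    pyr_soma <- c(cfg$input_center_row + runif(1, -1, 1), 4 + runif(1, -1, 1))
    pv_soma <- pyr_soma + runif(2, -0.6, 0.6)
    dist_um <- cfg$pixel_pitch * sqrt(sum((pv_soma - pyr_soma)^2))
    g_pv <- max(1, rnorm(1, 8, 0.8))
    g_pyr <- max(0.5, rnorm(1, 4, 0.4))

    amp_pyr <- base_amp
    amp_pv <- folds[i] * base_amp
    pyr_id <- sprintf("pair%02d_pyr", i)
    pv_id <- sprintf("pair%02d_pv", i)
    cells[[pv_id]] <- new_cell_recording(
      pv_id, "PV", g_pv, pv_soma,
      simulate_cell_sweeps(amp_pv, cfg, cfg$tau_rise_pv), cfg)
    cells[[pyr_id]] <- new_cell_recording(
      pyr_id, "Pyr", g_pyr, pyr_soma,
      simulate_cell_sweeps(amp_pyr, cfg, cfg$tau_rise_pyr), cfg)
    gt_amp[[pv_id]] <- amp_pv
    gt_amp[[pyr_id]] <- amp_pyr
    pairs[[i]] <- data.frame(pair_id = sprintf("pair%02d", i),
                             pv_id = pv_id, pyr_id = pyr_id,
                             distance_um = dist_um)
  }
  structure(list(
    cells = cells,
    pairs = do.call(rbind, pairs),
    ground_truth = list(folds = folds, amplitudes = gt_amp,
                        pv_fold = cfg$pv_fold),
    config = cfg
  ), class = "scracm_dataset")
}

#' Generate a synthetic axonal projection-density image with a planted DR
#'
#' Emulates a grayscale image of anterogradely labelled axonal terminations
#' in a target area: per-layer base intensity modulated by an axon-like
#' multiplicative texture (disk-smoothed log-normal field, renormalized to
#' mean 1 within each band so band-mean intensities are exact), plus additive
#' Gaussian pixel noise. Before noise, mean(L2-4)/mean(L1) equals
#' `planted_dr` exactly.
#'
#' @param planted_dr Target L2-4:L1 band-mean intensity ratio (> 0).
#' @param bands A [layer_bands()] annotation (depth intervals, um).
#' @param n_cols Image width in pixels.
#' @param pixel_size_um Pixel edge in um (rows map to depth below the pia).
#' @param texture_scale Disk radius (px) of the texture correlation length.
#' @param texture_strength Log-SD of the multiplicative texture field.
#' @param noise_sd Additive noise SD as a fraction of the mean intensity.
#' @param seed Integer seed.
#' @return Object of class `density_image`: list with `pixels` (matrix,
#'   rows = depth), `pixel_size_um`, `bands`, and `ground_truth$planted_dr`.
#' @export
generate_projection_image <- function(planted_dr,
                                      bands = layer_bands(),
                                      n_cols = 160,
                                      pixel_size_um = 5,
                                      texture_scale = 8,
                                      texture_strength = 0.35,
                                      noise_sd = 0.05,
                                      seed = 1L) {
  if (!is.numeric(planted_dr) || planted_dr <= 0)
    abort("'planted_dr' must be > 0", "scracmap_config_error")
  stopifnot(inherits(bands, "layer_bands"))
  set.seed(seed)

  depth_max <- max(bands$boundaries)
  n_rows <- as.integer(ceiling(depth_max / pixel_size_um))
  row_depth <- (seq_len(n_rows) - 0.5) * pixel_size_um
  masks <- band_row_masks(bands, row_depth)

  # Base intensity per layer; only the L1 / L2-4 ratio is contractual.
  base_l1 <- 0.4
  lv <- c(L1 = base_l1, `L2-4` = base_l1 * planted_dr,
          L5 = base_l1 * (1 + planted_dr) * 0.3, L6 = base_l1 * 0.8)
  base <- numeric(n_rows)
  for (nm in names(masks)) base[masks[[nm]]] <- lv[[nm]]
  img <- matrix(base, n_rows, n_cols)

  # Axon-like texture: smoothed Gaussian field -> log-normal multiplier,
  # renormalized per band so planted band means survive exactly.
  z <- disk_filter(matrix(rnorm(n_rows * n_cols), n_rows, n_cols),
                   radius = texture_scale)
  z <- (z - mean(z)) / sd(z)
  tex <- exp(texture_strength * z)
  for (nm in names(masks)) {
    r <- masks[[nm]]
    tex[r, ] <- tex[r, ] / mean(tex[r, ])
  }
  img <- img * tex
  if (noise_sd > 0) {
    img <- img + rnorm(length(img), sd = noise_sd * mean(img))
    img[img < 0] <- 0
  }
  structure(list(pixels = img, pixel_size_um = pixel_size_um,
                 bands = bands,
                 ground_truth = list(planted_dr = planted_dr)),
            class = "density_image")
}

#' Generate a synthetic PV/Pyr paired recording
#'
#' Simulates one PV - pyramidal pair probed with successively increasing
#' 50 ms current steps (100, 200, 300, 400 pA) injected into the PV cell
#' under current clamp while the pyramidal cell is held at 0 mV in voltage
#' clamp. The PV membrane-potential trace carries the stated number of spike
#' waveforms per step; if `connected`, each PV spike evokes one outward IPSC
#' of peak amplitude `unitary_ipsc` (1 ms synaptic delay) in the Pyr current
#' trace, on top of Gaussian noise.
#'
#' @param connected Logical ground truth: is the pair synaptically connected?
#' @param unitary_ipsc Peak amplitude of the unitary IPSC, pA.
#' @param spikes_per_step Non-decreasing integer spike counts for the four
#'   current steps.
#' @param noise_sd Gaussian noise SD on the Pyr current trace, pA.
#' @param seed Integer seed.
#' @param steps Injected current amplitudes, pA.
#' @param n_reps Sweeps per step.
#' @param sampling_rate Hz.
#' @param step_onset_ms,step_duration_ms Current-step timing, ms.
#' @param trace_ms Total sweep length, ms.
#' @param tau_rise,tau_decay IPSC kinetics, ms.
#' @param layer Layer label for the pair.
#' @return Object of class `paired_recording`: per-step lists `pv` and `pyr`
#'   of rep x sample matrices plus timing metadata and the ground truth.
#' @export
generate_paired_recording <- function(connected,
                                      unitary_ipsc = 20,
                                      spikes_per_step = c(0, 1, 2, 4),
                                      noise_sd = 2,
                                      seed = 1L,
                                      steps = c(100, 200, 300, 400),
                                      n_reps = 5,
                                      sampling_rate = 10000,
                                      step_onset_ms = 100,
                                      step_duration_ms = 50,
                                      trace_ms = 250,
                                      tau_rise = 0.3,
                                      tau_decay = 3,
                                      layer = "L2/3") {
  if (length(spikes_per_step) != length(steps))
    abort("'spikes_per_step' must match 'steps' in length",
          "scracmap_config_error")
  if (is.unsorted(spikes_per_step))
    abort("'spikes_per_step' must be non-decreasing",
          "scracmap_config_error")
  if (unitary_ipsc < 0 || noise_sd < 0)
    abort("amplitudes must be >= 0", "scracmap_config_error")
  set.seed(seed)

  n_samp <- ms_to_samples(trace_ms, sampling_rate)
  dt <- 1000 / sampling_rate
  t_ms <- (seq_len(n_samp) - 1) * dt
  on <- step_onset_ms

  # Stereotyped spike waveform: 100 mV overshoot decaying in ~0.5 ms.
  spike_wave <- function(t0) 100 * exp(-pmax(t_ms - t0, 0) / 0.5) *
    (t_ms >= t0) * (t_ms < t0 + 3)
  ipsc_kernel <- {
    k <- psc_kernel(n_samp, dt, tau_rise, tau_decay)
    k / max(k) # peak-normalized: unitary amplitude is the IPSC peak
  }
  pv <- pyr <- vector("list", length(steps))
  spike_times <- vector("list", length(steps))
  for (j in seq_along(steps)) {
    s <- spikes_per_step[j]
    st <- if (s > 0) on + 5 + (seq_len(s) - 1) * 10 else numeric(0)
    spike_times[[j]] <- st
    vm <- -70 + 8 * (t_ms >= on & t_ms < on + step_duration_ms)
    for (t0 in st) vm <- vm + spike_wave(t0)
    pv[[j]] <- matrix(rep(vm, each = n_reps), n_reps, n_samp) +
      matrix(rnorm(n_reps * n_samp, sd = 0.2), n_reps, n_samp)
    ip <- numeric(n_samp)
    if (isTRUE(connected) && s > 0) {
      for (t0 in st) {
        i0 <- ms_to_samples(t0 + 1, sampling_rate) + 1L # 1 ms synaptic delay
        len <- n_samp - i0 + 1L
        ip[i0:n_samp] <- ip[i0:n_samp] + unitary_ipsc * ipsc_kernel[1:len]
      }
    }
    pyr[[j]] <- matrix(rep(ip, each = n_reps), n_reps, n_samp) +
      matrix(rnorm(n_reps * n_samp, sd = noise_sd), n_reps, n_samp)
  }
  structure(list(
    steps = steps, pv = pv, pyr = pyr,
    spike_times = spike_times,
    sampling_rate = sampling_rate,
    step_onset_ms = step_onset_ms,
    step_duration_ms = step_duration_ms,
    layer = layer, distance_um = 50,
    ground_truth = list(connected = isTRUE(connected),
                        unitary_ipsc = unitary_ipsc,
                        spikes_per_step = spikes_per_step)
  ), class = "paired_recording")
}
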