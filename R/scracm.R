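# sCRACM map construction and per-cell / per-pair / per-pathway statistics.
#
# Conventions: sweeps are matrices (rep x sample) or per-cell arrays
# [site, rep, sample]; sites are in column-major grid order (row fastest,
# row 1 nearest the pia). Maps store response magnitudes in pA (>= 0),
# with non-significant pixels set to 0.

# Repetition-averaged trace; accepts a vector (single sweep), rep x sample
# matrix, or [site, rep, sample] array (averaged to site x sample).
avg_trace <- function(sweeps) {
  if (is.null(dim(sweeps))) return(sweeps)
  if (length(dim(sweeps)) == 2L) return(colMeans(sweeps))
  colMeans(aperm(sweeps, c(2, 1, 3)))
}

baseline_index <- function(sampling_rate, stim_onset_ms, baseline_ms = 100) {
  n_on <- ms_to_samples(stim_onset_ms, sampling_rate)
  if (n_on < 2L)
    abort("no pre-stimulus baseline samples", "scracmap_window_error")
  n_base <- min(n_on, ms_to_samples(baseline_ms, sampling_rate))
  (n_on - n_base + 1L):n_on
}

window_index <- function(n_samp, sampling_rate, stim_onset_ms, window_ms) {
  n_on <- ms_to_samples(stim_onset_ms, sampling_rate)
  n_win <- ms_to_samples(window_ms, sampling_rate)
  if (n_on + n_win > n_samp)
    abort("response window exceeds trace length", "scracmap_window_error")
  (n_on + 1L):(n_on + n_win)
}

#' Baseline noise SD of a repetition-averaged sweep set
#'
#' SD of the repetition-averaged trace over the pre-stimulus baseline (the
#' `baseline_ms` immediately preceding stimulus onset). This is the
#' denominator of the 4-SD pixel significance rule: averaging the 3-5
#' repetitions first means the SD scales as \eqn{\sigma/\sqrt{n_{rep}}}.
#'
#' @param sweeps Numeric vector (one sweep) or rep x sample matrix.
#' @param sampling_rate Hz.
#' @param stim_onset_ms Stimulus onset, ms from sweep start.
#' @param baseline_ms Baseline window length, ms (clipped to the pre-stimulus
#'   segment).
#' @return Baseline SD in pA.
#' @export
baseline_sd <- function(sweeps, sampling_rate, stim_onset_ms,
                        baseline_ms = 100) {
  tr <- avg_trace(sweeps)
  sd(tr[baseline_index(sampling_rate, stim_onset_ms, baseline_ms)])
}

#' Windowed-mean pixel response of a sweep set
#'
#' The per-pixel sCRACM statistic: magnitude of the mean of the
#' repetition-averaged, baseline-subtracted trace over `window_ms` after
#' stimulus onset, in pA.
#'
#' @inheritParams baseline_sd
#' @param window_ms Response window after stimulus onset, ms (default 75).
#' @return Response magnitude in pA.
#' @export
compute_pixel_response <- function(sweeps, sampling_rate, stim_onset_ms,
                                   window_ms = 75, baseline_ms = 100) {
  tr <- avg_trace(sweeps)
  bi <- baseline_index(sampling_rate, stim_onset_ms, baseline_ms)
  wi <- window_index(length(tr), sampling_rate, stim_onset_ms, window_ms)
  abs(mean(tr[wi]) - mean(tr[bi]))
}

# Vectorized per-site windowed statistics for one cell. Returns a list with
# per-site response (signed, baseline-subtracted), baseline SD, and the
# rep-averaged site x sample traces.
site_statistics <- function(recording, window_ms, baseline_ms = 100) {
  tr <- avg_trace(recording$sweeps) # site x sample
  bi <- baseline_index(recording$sampling_rate, recording$stim_onset_ms,
                       baseline_ms)
  wi <- window_index(ncol(tr), recording$sampling_rate,
                     recording$stim_onset_ms, window_ms)
  bmean <- rowMeans(tr[, bi, drop = FALSE])
  bsd <- apply(tr[, bi, drop = FALSE], 1L, sd)
  resp <- rowMeans(tr[, wi, drop = FALSE]) - bmean
  list(resp = resp, bsd = bsd, traces = tr, bmean = bmean, win_idx = wi)
}

#' Build an sCRACM input map from a gridded cell recording
#'
#' Each grid pixel is the windowed-mean response magnitude
#' ([compute_pixel_response()]) if it exceeds `threshold_mult` times that
#' site's baseline SD, else 0. Repetitions are averaged before thresholding.
#' Pixels whose retained response has a polarity inconsistent with the
#' holding potential (outward current at -70 mV) are counted in the
#' `polarity_flags` attribute.
#'
#' @param recording A `cell_recording`.
#' @param threshold_mult Significance multiple of the baseline SD (default 4).
#' @param window_ms Response window, ms (default 75).
#' @param baseline_ms Baseline window, ms.
#' @return An object of class `scracm_map`.
#' @export
build_map <- function(recording, threshold_mult = 4, window_ms = 75,
                      baseline_ms = 100) {
  n_sites <- recording$grid_rows * recording$grid_cols
  have <- dim(recording$sweeps)[1]
  if (have != n_sites)
    abort(sprintf("recording has %d sites, expected %d (missing: %s)",
                  have, n_sites,
                  paste(setdiff(seq_len(n_sites), seq_len(have)),
                        collapse = ",")),
          "scracmap_sites_error")
  st <- site_statistics(recording, window_ms, baseline_ms)
  keep <- abs(st$resp) > threshold_mult * st$bsd
  vals <- ifelse(keep, abs(st$resp), 0)
  flagged <- which(keep & st$resp > 0) # outward current at -70 mV holding
  structure(list(
    values = matrix(vals, recording$grid_rows, recording$grid_cols),
    pixel_pitch_um = recording$pixel_pitch_um,
    pia_offset_um = recording$pia_offset_um,
    soma = recording$soma,
    cell_id = recording$cell_id,
    cell_type = recording$cell_type,
    layer = recording$layer,
    layer_boundaries = recording$layer_boundaries,
    threshold_mult = threshold_mult,
    window_ms = window_ms,
    polarity_flags = flagged
  ), class = "scracm_map")
}

#' Total sCRACM input to a cell
#'
#' Sum of all (significant) pixel magnitudes of the map, pA.
#' @param map An `scracm_map`.
#' @return Total input, pA.
#' @export
total_input <- function(map) sum(map$values)

#' Mean EPSC per stimulated area
#'
#' Mean of the significant (nonzero) pixel values divided by the pixel area
#' (pitch squared, 5625 um^2 for the default 75 um grid), in pA/um^2.
#' @param map An `scracm_map`.
#' @return pA/um^2, or `NA` with an undefined-result warning if the map has
#'   no significant pixels.
#' @export
mean_epsc_per_area <- function(map) {
  nz <- map$values[map$values > 0]
  if (length(nz) == 0L)
    return(undefined_result("no significant pixels in map"))
  mean(nz) / map$pixel_pitch_um^2
}

#' Responsive area of a map
#'
#' Number of significant pixels times the pixel area, um^2.
#' @param map An `scracm_map`.
#' @return Area in um^2.
#' @export
responsive_area <- function(map) sum(map$values > 0) * map$pixel_pitch_um^2

#' Mean EPSC time to peak over significant pixels
#'
#' For every significant pixel, the latency from stimulus onset to the
#' extremum of the repetition-averaged, baseline-subtracted trace within the
#' response window; returned as the mean over significant pixels, ms.
#'
#' @inheritParams build_map
#' @return Mean time to peak, ms; `NA` with an undefined-result warning if
#'   no pixel is significant.
#' @export
time_to_peak <- function(recording, threshold_mult = 4, window_ms = 75,
                         baseline_ms = 100) {
  st <- site_statistics(recording, window_ms, baseline_ms)
  keep <- which(abs(st$resp) > threshold_mult * st$bsd)
  if (length(keep) == 0L)
    return(undefined_result("no significant pixels in recording"))
  dt <- 1000 / recording$sampling_rate
  tp <- vapply(keep, function(s) {
    w <- st$traces[s, st$win_idx] - st$bmean[s]
    (which.max(abs(w)) - 1L) * dt
  }, numeric(1))
  mean(tp)
}

#' Compare total input of a neighboring PV/Pyr cell pair
#'
#' Builds both maps, checks the pairing rule (same layer, somata within
#' `max_dist_um`, default ~100 um), and returns the fold ratio
#' EPSC_PV/EPSC_Pyr of total inputs plus the conductance-normalized variant
#' (each total divided by its cell's conductance before the ratio). A pair
#' whose Pyr total is 0 is flagged `excluded` (fold `NA`) rather than
#' silently dropped.
#'
#' @param pv,pyr `cell_recording`s for the PV and pyramidal cell.
#' @param max_dist_um Maximum soma separation, um.
#' @inheritParams build_map
#' @return Object of class `pair_comparison`.
#' @export
pair_ratio <- function(pv, pyr, max_dist_um = 100, threshold_mult = 4,
                       window_ms = 75, baseline_ms = 100) {
  if (!identical(pv$cell_type, "PV") || !identical(pyr$cell_type, "Pyr"))
    abort("pair_ratio() expects a PV and a Pyr recording, in that order",
          "scracmap_pairing_error")
  if (!identical(pv$layer, pyr$layer))
    abort("paired cells must be in the same layer", "scracmap_pairing_error")
  dist_um <- pv$pixel_pitch_um * sqrt(sum((pv$soma - pyr$soma)^2))
  if (dist_um > max_dist_um)
    abort(sprintf("somata %.1f um apart exceed pairing threshold %g um",
                  dist_um, max_dist_um), "scracmap_pairing_error")
  pv_total <- total_input(build_map(pv, threshold_mult, window_ms, baseline_ms))
  pyr_total <- total_input(build_map(pyr, threshold_mult, window_ms, baseline_ms))
  excluded <- pyr_total == 0
  if (excluded)
    warning(structure(
      class = c("scracmap_excluded_pair", "warning", "condition"),
      list(message = sprintf("pair (%s, %s): Pyr total is 0; pair excluded",
                             pv$cell_id, pyr$cell_id), call = sys.call())))
  structure(list(
    pv_id = pv$cell_id, pyr_id = pyr$cell_id,
    pv_total = pv_total, pyr_total = pyr_total,
    fold = if (excluded) NA_real_ else pv_total / pyr_total,
    fold_norm = if (excluded) NA_real_ else
      (pv_total / pv$conductance) / (pyr_total / pyr$conductance),
    distance_um = dist_um, layer = pv$layer, excluded = excluded
  ), class = "pair_comparison")
}

#' Cohort slope: geometric mean of PV:Pyr fold ratios
#'
#' The slope of the line from the origin through the cohort in the
#' PV-vs-Pyr total-EPSC scatter, defined as the geometric mean of the
#' per-pair fold ratios. Excluded pairs (`NA` fold) are dropped with their
#' count recorded in the `n_excluded` attribute.
#'
#' @param pairs List of `pair_comparison` objects, or a numeric vector of
#'   fold ratios.
#' @param normalized Use the conductance-normalized folds instead.
#' @return Geometric-mean fold (attributes `n`, `n_excluded`).
#' @export
cohort_slope <- function(pairs, normalized = FALSE) {
  folds <- if (is.numeric(pairs)) pairs else
    vapply(pairs, function(p) if (normalized) p$fold_norm else p$fold,
           numeric(1))
  n_excl <- sum(is.na(folds))
  folds <- folds[!is.na(folds)]
  if (length(folds) == 0L)
    abort("no valid pairs", "scracmap_input_error")
  if (any(folds <= 0))
    abort("fold ratios must be positive", "scracmap_input_error")
  structure(exp(mean(log(folds))), n = length(folds), n_excluded = n_excl)
}

#' Laminar profile of an sCRACM map
#'
#' Row totals of the map as percentages of the cell's total input, plus, for
#' every named layer band, the mean of the row percentages whose row-centre
#' depths fall inside the band (the per-layer input fraction). A row resides
#' in a layer iff its centre depth (pia offset + (row-1) * pitch) lies in the
#' band.
#'
#' @param map An `scracm_map`.
#' @param layer_boundaries Named increasing vector of band bottom depths
#'   (um from pia); defaults to the boundaries carried by the map.
#' @return Object of class `laminar_profile`: `row_totals_pct` (sums to 100),
#'   `row_depths_um`, `layer_fractions` (mean row percentage per band), and
#'   `rows_per_layer`.
#' @export
laminar_profile <- function(map, layer_boundaries = NULL) {
  bounds <- layer_boundaries %||% map$layer_boundaries
  if (is.null(bounds))
    abort("no layer boundaries available", "scracmap_input_error")
  total <- sum(map$values)
  if (total == 0) {
    undefined_result("map total is 0; laminar profile undefined")
    return(structure(list(row_totals_pct = rep(NA_real_, nrow(map$values)),
                          row_depths_um = NULL, layer_fractions = NULL),
                     class = "laminar_profile"))
  }
  depths <- map$pia_offset_um + (seq_len(nrow(map$values)) - 1L) *
    map$pixel_pitch_um
  pct <- 100 * rowSums(map$values) / total
  lower <- c(0, head(bounds, -1L))
  frac <- numeric(length(bounds))
  rows_in <- vector("list", length(bounds))
  for (i in seq_along(bounds)) {
    r <- which(depths >= lower[i] & depths < bounds[i])
    rows_in[[i]] <- r
    frac[i] <- if (length(r)) mean(pct[r]) else NA_real_
  }
  names(frac) <- names(rows_in) <- names(bounds)
  structure(list(row_totals_pct = pct, row_depths_um = depths,
                 layer_fractions = frac, rows_per_layer = rows_in),
            class = "laminar_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Input fraction of a (possibly merged) layer band
#'
#' Mean of the row percentages over all rows residing in any of the named
#' bands, e.g. `c("L2/3", "L4")` for an L2-4 fraction.
#'
#' @param profile A [laminar_profile()].
#' @param layers Character vector of band names to merge.
#' @return Mean row percentage of the merged band.
#' @export
layer_fraction <- function(profile, layers) {
  rows <- unlist(profile$rows_per_layer[layers], use.names = FALSE)
  if (length(rows) == 0L)
    abort("no grid rows reside in the requested layers",
          "scracmap_input_error")
  mean(profile$row_totals_pct[rows])
}

# Bilinear upsampling on a node-aligned fine raster (coarse nodes are a
# subset of the fine ones, so peaks survive interpolation exactly and the
# trapezoidal integral of the surface is preserved to machine precision).
interp_grid <- function(m, factor) {
  up1 <- function(mat, f) {
    n <- nrow(mat)
    xout <- seq(1, n, length.out = (n - 1L) * f + 1L)
    apply(mat, 2L, function(col) approx(seq_len(n), col, xout)$y)
  }
  t(up1(t(up1(m, factor)), factor))
}

#' Average and smooth a set of sCRACM maps
#'
#' Per-map normalization, elementwise mean, then smooth interpolation to a
#' finer raster, as used for cohort heat maps. Modes: `"pair_max"` divides
#' each map by the largest pixel within its pair (requires `pair_id`),
#' `"panel_max"` applies no per-map scaling, `"cell_total"` divides each map
#' by its total input. Under `"pair_max"` and `"panel_max"` the averaged map
#' is rescaled so its peak is exactly 1.
#'
#' @param maps List of `scracm_map`s sharing shape and alignment.
#' @param mode Normalization mode.
#' @param pair_id Vector (length of `maps`) of pair labels for `"pair_max"`.
#' @param upsample Integer raster-refinement factor (default 4).
#' @return List with `values` (fine raster), `coarse` (pre-interpolation
#'   average), `mode`, `upsample`.
#' @export
average_map <- function(maps, mode = c("pair_max", "panel_max", "cell_total"),
                        pair_id = NULL, upsample = 4L) {
  mode <- match.arg(mode)
  dims <- vapply(maps, function(m) dim(m$values), integer(2))
  if (nrow(unique(t(dims))) != 1L)
    abort("maps have mixed shapes", "scracmap_input_error")
  vals <- lapply(maps, `[[`, "values")
  scale <- switch(mode,
    pair_max = {
      if (is.null(pair_id) || length(pair_id) != length(maps))
        abort("'pair_id' required for mode 'pair_max'",
              "scracmap_input_error")
      pk <- tapply(vapply(vals, max, numeric(1)), pair_id, max)
      as.numeric(pk[as.character(pair_id)])
    },
    panel_max = rep(1, length(maps)),
    cell_total = vapply(vals, sum, numeric(1))
  )
  if (any(scale == 0))
    abort("normalization scale is 0 for at least one map",
          "scracmap_input_error")
  avg <- Reduce(`+`, Map(`/`, vals, scale)) / length(vals)
  if (mode %in% c("pair_max", "panel_max") && max(avg) > 0)
    avg <- avg / max(avg)
  fine <- if (upsample > 1L) interp_grid(avg, as.integer(upsample)) else avg
  list(values = fine, coarse = avg, mode = mode, upsample = upsample)
}

#' Nonparametric and paired comparisons between pathways or cell types
#'
#' Thin dispatcher over the test battery used for cohort statistics:
#' Kruskal-Wallis across >= 2 pathway groups, Mann-Whitney U (rank-sum)
#' between two groups, Wilcoxon signed-rank within pairs, and the paired
#' t-test used for time-to-peak comparisons. All tests are two-sided.
#'
#' @param groups List of numeric vectors (one per group); exactly two for
#'   the two-sample tests, equal lengths for the paired tests.
#' @param test One of `"kruskal"`, `"mwu"`, `"wilcoxon_paired"`,
#'   `"t_paired"`.
#' @return List with `test`, `statistic`, `p_value`, `n`.
#' @export
compare_pathways <- function(groups,
                             test = c("kruskal", "mwu", "wilcoxon_paired",
                                      "t_paired")) {
  test <- match.arg(test)
  if (!is.list(groups)) abort("'groups' must be a list", "scracmap_input_error")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- lengths(groups)
  two <- test != "kruskal"
  if (test == "kruskal" && (length(groups) < 2L || any(sizes < 2L)))
    abort("Kruskal-Wallis needs >= 2 groups with >= 2 values each",
          "scracmap_input_error")
  if (two && length(groups) != 2L)
    abort(sprintf("'%s' needs exactly 2 groups", test),
          "scracmap_input_error")
  if (test %in% c("wilcoxon_paired", "t_paired") && sizes[1] != sizes[2])
    abort("paired tests need equal group sizes", "scracmap_input_error")
  if (two && any(sizes < 2L))
    abort("need >= 2 observations per group", "scracmap_input_error")
  if (test == "wilcoxon_paired" && all(groups[[1]] == groups[[2]]))
    return(list(test = test, statistic = 0, p_value = 1, n = sizes))
  ht <- switch(test,
    kruskal = kruskal.test(groups),
    mwu = wilcox.test(groups[[1]], groups[[2]], exact = FALSE),
    wilcoxon_paired = wilcox.test(groups[[1]], groups[[2]], paired = TRUE,
                                  exact = FALSE),
    t_paired = t.test(groups[[1]], groups[[2]], paired = TRUE)
  )
  list(test = test, statistic = unname(ht$statistic),
       p_value = ht$p.value, n = sizes)
}
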