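# Feedforward-inhibition analysis of PV -> Pyr paired recordings: spike
# detection in the PV current-clamp trace, step-wise IPSC means in the Pyr
# voltage-clamp trace (held at 0 mV, outward IPSCs positive), connection
# classification and probability, and the IPSC-vs-excitation curve.

#' Detect spikes in a membrane-potential trace
#'
#' Upward threshold crossings with a refractory guard: a crossing within
#' `refractory_ms` of the previously accepted spike is ignored.
#'
#' @param vm Membrane-potential vector, mV.
#' @param sampling_rate Hz.
#' @param threshold_mv Crossing threshold (default 0 mV).
#' @param refractory_ms Refractory guard (default 2 ms).
#' @return Spike times in ms from trace start (possibly empty).
#' @export
detect_spikes <- function(vm, sampling_rate, threshold_mv = 0,
                          refractory_ms = 2) {
  if (length(vm) == 0L) abort("empty trace", "scracmap_input_error")
  n <- length(vm)
  up <- which(vm[-1L] > threshold_mv & vm[-n] <= threshold_mv) + 1L
  if (length(up) == 0L) return(numeric(0))
  dt <- 1000 / sampling_rate
  keep <- up[1]
  last <- up[1]
  for (i in up[-1L]) {
    if ((i - last) * dt >= refractory_ms) {
      keep <- c(keep, i)
      last <- i
    }
  }
  (keep - 1L) * dt
}

#' Windowed-mean IPSC response of a Pyr voltage-clamp trace
#'
#' Magnitude of the baseline-subtracted mean current over `window_ms` after
#' the current-step onset, in pA — the same windowed-mean statistic as the
#' sCRACM pixel response.
#'
#' @param trace Current vector or rep x sample matrix (averaged first), pA.
#' @param sampling_rate Hz.
#' @param step_onset_ms Current-step onset, ms from trace start.
#' @param window_ms Response window (default 75 ms).
#' @param baseline_ms Baseline window before the step, ms.
#' @return IPSC magnitude, pA.
#' @export
ipsc_response <- function(trace, sampling_rate, step_onset_ms,
                          window_ms = 75, baseline_ms = 100) {
  compute_pixel_response(trace, sampling_rate, step_onset_ms, window_ms,
                         baseline_ms)
}

#' Classify a PV/Pyr pair as synaptically connected
#'
#' Connected iff the IPSC response at the largest current step that evoked
#' at least one PV spike exceeds `k` times the baseline SD of the averaged
#' Pyr trace at that step — the same k-SD significance rule as the sCRACM
#' pixel threshold. If no step evokes a spike the result is indeterminate
#' (`NA` with a classed warning).
#'
#' @param pair A `paired_recording`.
#' @param k Significance multiple (default 4).
#' @param window_ms IPSC window (default 75 ms).
#' @return Logical (or `NA` if indeterminate), with attributes `ipsc` and
#'   `threshold`.
#' @export
classify_connected <- function(pair, k = 4, window_ms = 75) {
  spikes <- vapply(seq_along(pair$steps), function(j)
    length(detect_spikes(avg_trace(pair$pv[[j]]), pair$sampling_rate)),
    numeric(1))
  with_spk <- which(spikes > 0)
  if (length(with_spk) == 0L) {
    warning(structure(
      class = c("scracmap_indeterminate", "warning", "condition"),
      list(message = "no PV spikes at any step; connectivity indeterminate",
           call = sys.call())))
    return(NA)
  }
  j <- max(with_spk)
  tr <- avg_trace(pair$pyr[[j]])
  resp <- ipsc_response(tr, pair$sampling_rate, pair$step_onset_ms, window_ms)
  bsd <- baseline_sd(tr, pair$sampling_rate, pair$step_onset_ms)
  structure(resp > k * bsd, ipsc = resp, threshold = k * bsd, step = j)
}

#' Connection probability of a tested cohort
#'
#' Percentage of tested pairs that are connected: either a logical vector of
#' per-pair outcomes (`NA`s dropped with a count) or explicit counts
#' `connection_probability(n_connected, n_tested)`.
#'
#' @param x Logical vector of outcomes, or the connected count.
#' @param n Total tested count when `x` is a count.
#' @return Percentage (0-100), attribute `n_tested`.
#' @export
connection_probability <- function(x, n = NULL) {
  if (is.null(n)) {
    if (length(x) == 0L) abort("no pairs", "scracmap_input_error")
    x <- x[!is.na(x)]
    structure(100 * sum(x) / length(x), n_tested = length(x))
  } else {
    if (n < 1L || x > n) abort("invalid counts", "scracmap_input_error")
    structure(100 * x / n, n_tested = n)
  }
}

#' IPSC-vs-excitation curve of one pair
#'
#' Per current step: PV spike count (from the averaged PV trace) and the
#' per-sweep IPSC responses of the Pyr cell, with a one-way ANOVA of IPSC
#' across steps testing whether stronger PV excitation drives stronger
#' inhibition.
#'
#' @param pair A `paired_recording`.
#' @param window_ms IPSC window (default 75 ms).
#' @return List: `table` (data.frame step, spikes, mean_ipsc), `responses`
#'   (data.frame step, rep, ipsc), `anova_p`, `anova_F`.
#' @export
ie_curve <- function(pair, window_ms = 75) {
  if (length(pair$steps) < 2L)
    abort("need >= 2 current steps", "scracmap_input_error")
  rows <- list()
  for (j in seq_along(pair$steps)) {
    spikes <- length(detect_spikes(avg_trace(pair$pv[[j]]),
                                   pair$sampling_rate))
    mat <- pair$pyr[[j]]
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
    ip <- apply(mat, 1L, ipsc_response, sampling_rate = pair$sampling_rate,
                step_onset_ms = pair$step_onset_ms, window_ms = window_ms)
    rows[[j]] <- data.frame(step = pair$steps[j], spikes = spikes,
                            rep = seq_along(ip), ipsc = ip)
  }
  resp <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(split(resp, resp$step), function(d)
    data.frame(step = d$step[1], spikes = d$spikes[1],
               mean_ipsc = mean(d$ipsc))))
  rownames(tab) <- NULL
  fit <- stats::anova(aov(ipsc ~ factor(step), data = resp))
  list(table = tab, responses = resp,
       anova_F = fit$`F value`[1], anova_p = fit$`Pr(>F)`[1])
}
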