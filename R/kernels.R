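#' Difference-of-exponentials synaptic current kernel
#'
#' Unit-free postsynaptic-current waveform
#' \eqn{k(t) = e^{-t/\tau_d} - e^{-t/\tau_r}} for \eqn{t \ge 0}, the standard
#' two-time-constant model of an EPSC/IPSC. The kernel is returned raw
#' (peak < 1); callers normalize it to a target peak or windowed mean.
#'
#' @param n Number of samples.
#' @param dt_ms Sample interval in ms.
#' @param tau_rise,tau_decay Rise and decay time constants in ms;
#'   `tau_decay > tau_rise > 0`.
#' @return Numeric vector of length `n`, starting at `t = 0`.
#' @seealso [kernel_time_to_peak()] for the analytic peak latency.
#' @export
psc_kernel <- function(n, dt_ms, tau_rise, tau_decay) {
  if (tau_rise <= 0 || tau_decay <= tau_rise)
    abort("need tau_decay > tau_rise > 0", "scracmap_config_error")
  t <- (seq_len(n) - 1) * dt_ms
  exp(-t / tau_decay) - exp(-t / tau_rise)
}

#' Analytic time to peak of the difference-of-exponentials kernel
#'
#' \eqn{t^* = \ln(\tau_d/\tau_r)\,\tau_d\tau_r/(\tau_d-\tau_r)}, in ms.
#' Monotonically increasing in `tau_rise`, so faster-rising PV-cell EPSCs
#' peak earlier than pyramidal-cell EPSCs by construction.
#'
#' @inheritParams psc_kernel
#' @return Peak latency in ms.
#' @export
kernel_time_to_peak <- function(tau_rise, tau_decay) {
  if (tau_rise <= 0 || tau_decay <= tau_rise)
    abort("need tau_decay > tau_rise > 0", "scracmap_config_error")
  log(tau_decay / tau_rise) * tau_decay * tau_rise / (tau_decay - tau_rise)
}
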