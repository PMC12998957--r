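#' Simulate a leaky integrate-and-fire neuron for one trial
#'
#' Forward-Euler integration of
#' `C dV/dt = -(V - V_l)/R + i_syn` at step `dt`, with a spike recorded
#' whenever the updated voltage reaches `V_theta`, followed by an
#' immediate reset to `V_l` (no refractory period).  The drive is either a
#' current trace (pA) or, in conductance mode, a list
#' `list(gE=, gI=, VE=, VI=)` of conductance traces (nS) with their
#' reversal potentials (mV), in which case
#' `i_syn = gE*(VE - V) + gI*(VI - V)`.
#'
#' @param drive Numeric vector of synaptic current (pA) sampled at
#'   `lif$dt`, or a conductance list as above.
#' @param lif A [lif_params()] object.
#' @param record_v Keep the full membrane trace (mV)?
#' @return A `lif_trial` list: `spike_times` (ms), `n_spikes`, `rate`
#'   (Hz over the trace duration), `duration` (ms), and `V` (mV, or
#'   `NULL`).
#' @examples
#' lif <- lif_params()
#' tr <- simulate_lif(rep(400, 5000), lif) # 2x rheobase, 50 ms
#' diff(tr$spike_times)[1] # ~ tau_m * log(2) = 6.93 ms
#' @export
simulate_lif <- function(drive, lif = lif_params(), record_v = FALSE) {
  stopifnot(inherits(lif, "lif_params"))
  if (is.list(drive)) {
    for (nm in c("gE", "gI", "VE", "VI"))
      if (is.null(drive[[nm]]))
        stop("conductance drive needs fields gE, gI, VE, VI", call. = FALSE)
    res <- cpp_lif_conductance(drive$gE, drive$gI, drive$VE, drive$VI,
                               lif$dt, lif$R, lif$tau_m, lif$V_l,
                               lif$V_theta, record_v)
    n <- length(drive$gE)
  } else {
    if (!is.numeric(drive)) stop("'drive' must be numeric", call. = FALSE)
    res <- cpp_lif_current(drive, lif$dt, lif$R, lif$tau_m, lif$V_l,
                           lif$V_theta, record_v)
    n <- length(drive)
  }
  duration <- n * lif$dt
  out <- list(spike_times = res$spike_times,
              n_spikes = length(res$spike_times),
              rate = length(res$spike_times) / duration * 1000,
              duration = duration,
              V = res$V)
  class(out) <- "lif_trial"
  out
}

#' @export
print.lif_trial <- function(x, ...) {
  cat(sprintf("LIF trial: %d spikes in %g ms (%.2f Hz)\n",
              x$n_spikes, x$duration, x$rate))
  invisible(x)
}
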