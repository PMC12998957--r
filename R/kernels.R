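#' Alpha-function synaptic kernel
#'
#' Unitary postsynaptic current (or conductance) time course
#' `u(t) = amplitude * (t/tau) * exp(1 - t/tau)`, peaking at `t = tau`
#' with peak value `amplitude`.  The untruncated integral is
#' `amplitude * tau * e`; the default 15 ms support (7.5 tau) truncates
#' that by ~0.5%, which is what the default charge-transfer constant of
#' 0.0557 pC reflects.
#'
#' @param amplitude Peak value: pA for `mode = "current"` (negative for
#'   inhibition), nS for `mode = "conductance"` (always positive; the sign
#'   of the drive comes from the reversal potential).
#' @param tau Alpha time constant (ms).
#' @param mode `"current"` or `"conductance"`.
#' @param V_rev Reversal potential (mV); required in conductance mode
#'   (0 mV for excitation, -80 mV for inhibition).
#' @param support Truncation window (ms).
#' @return An object of class `synaptic_kernel`.
#' @examples
#' k <- synaptic_kernel(10.3)
#' kernel_charge(k) # ~0.0557 pC
#' @export
synaptic_kernel <- function(amplitude, tau = 2,
                            mode = c("current", "conductance"),
                            V_rev = NULL, support = 15) {
  mode <- match.arg(mode)
  if (!is.finite(amplitude)) stop("'amplitude' must be finite", call. = FALSE)
  if (mode == "conductance") {
    if (amplitude < 0)
      stop("conductance amplitudes are magnitudes (>= 0); the sign comes from 'V_rev'",
           call. = FALSE)
    if (is.null(V_rev))
      stop("conductance mode requires a reversal potential 'V_rev'",
           call. = FALSE)
  }
  if (tau <= 0 || support <= 0)
    stop("'tau' and 'support' must be positive", call. = FALSE)
  out <- list(amplitude = amplitude, tau = tau, mode = mode,
              V_rev = V_rev, support = support)
  class(out) <- "synaptic_kernel"
  out
}

#' Sample an alpha kernel on a regular time grid
#'
#' @param kernel A [synaptic_kernel()].
#' @param dt Sampling step (ms); must satisfy `dt <= tau/10`.
#' @return Numeric vector of kernel samples at `t = 0, dt, ..., support`,
#'   with attributes `t` (times) and `dt`.
#' @export
alpha_kernel <- function(kernel, dt = 0.01) {
  stopifnot(inherits(kernel, "synaptic_kernel"))
  if (dt > kernel$tau / 10)
    stop(sprintf("'dt' (%g ms) must be <= tau/10 (%g ms)", dt,
                 kernel$tau / 10), call. = FALSE)
  if (kernel$support < 5 * kernel$tau)
    warning("kernel support < 5*tau: charge transfer will be undercounted",
            call. = FALSE)
  t <- seq(0, kernel$support, by = dt)
  k <- kernel$amplitude * (t / kernel$tau) * exp(1 - t / kernel$tau)
  attr(k, "t") <- t
  attr(k, "dt") <- dt
  k
}

#' Charge (or conductance-time) transfer of a unitary synaptic event
#'
#' Numerical integral of the sampled kernel over its support window
#' (trapezoidal rule).  For the default current kernel (10.3 pA, tau 2 ms,
#' 15 ms support) this is 0.0557 pC; the closed form over an infinite
#' window is `amplitude * tau * e` = 0.0560 pC.
#'
#' @param kernel A [synaptic_kernel()].
#' @param dt Sampling step (ms).
#' @param closed_form If `TRUE`, return the untruncated analytic integral
#'   instead.
#' @return Charge in pC (current mode) or nS*ms (conductance mode).
#' @export
kernel_charge <- function(kernel, dt = 0.01, closed_form = FALSE) {
  stopifnot(inherits(kernel, "synaptic_kernel"))
  if (closed_form)
    return(kernel$amplitude * kernel$tau * exp(1) / 1000)
  k <- alpha_kernel(kernel, dt)
  sum((k[-1] + k[-length(k)]) / 2) * dt / 1000 # pA*ms -> pC
}

#' Closed-form membrane response to a unitary alpha synaptic current
#'
#' Convolution of the alpha current `a*(t/tau)*exp(1 - t/tau)` with the
#' membrane impulse response `(R/tau_m)*exp(-t/tau_m)` of a passive LIF at
#' rest.  With `alpha = 1/tau`, `beta = 1/tau_m` (`tau != tau_m`):
#' \deqn{V(t) - V_l = \frac{aRe}{\tau\,\tau_m\,(\alpha-\beta)^2}
#'   e^{-\beta t}\left[1 - (1 + (\alpha-\beta)t)e^{-(\alpha-\beta)t}\right]
#'   \times 10^{-3}\ \mathrm{mV}.}
#' For the default parameters (10.3 pA, tau 2 ms, R 75 MOhm, tau_m 10 ms)
#' the peak depolarisation is ~251 uV at ~6.7 ms.
#'
#' @param t Times (ms) at which to evaluate the deflection.
#' @param amplitude Peak synaptic current (pA).
#' @param tau Alpha time constant (ms).
#' @param lif A [lif_params()] object.
#' @return Deflection `V(t) - V_l` in mV.
#' @export
psp_waveform <- function(t, amplitude = 10.3, tau = 2, lif = lif_params()) {
  al <- 1 / tau
  be <- 1 / lif$tau_m
  if (abs(al - be) < 1e-9) { # degenerate tau == tau_m limit
    return(amplitude * lif$R * exp(1) / (tau * lif$tau_m) *
             exp(-be * t) * t^2 / 2 * 1e-3)
  }
  d <- al - be
  amplitude * lif$R * exp(1) / (tau * lif$tau_m) *
    exp(-be * t) * (1 - (1 + d * t) * exp(-d * t)) / d^2 * 1e-3
}

#' Peak of the unitary postsynaptic potential
#'
#' @inheritParams psp_waveform
#' @return List with `peak` (mV) and `t_peak` (ms).
#' @examples
#' psp_peak()$peak * 1000 # ~251 uV
#' @export
psp_peak <- function(amplitude = 10.3, tau = 2, lif = lif_params()) {
  opt <- optimize(function(t) psp_waveform(t, amplitude, tau, lif),
                  interval = c(0, 20 * tau + 3 * lif$tau_m),
                  maximum = TRUE)
  list(peak = opt$objective, t_peak = opt$maximum)
}

#' Peak-normalised unitary PSP shape sampled on a grid
#'
#' The voltage shape used by the transient-regime probability traces: the
#' alpha current filtered through the membrane, then divided by its peak
#' so the kernel maximum is exactly 1.
#'
#' @param lif A [lif_params()] object.
#' @param tau Alpha time constant (ms).
#' @param dt Sampling step (ms).
#' @param support Truncation window (ms); default covers the peak and
#'   several membrane time constants of decay.
#' @return Numeric vector with attributes `t`, `dt` and `peak_mV`
#'   (the pre-normalisation peak for `amplitude = 1` pA input, times 1).
#' @export
unit_psp_kernel <- function(lif = lif_params(), tau = 2, dt = 0.01,
                            support = 5 * lif$tau_m) {
  t <- seq(0, support, by = dt)
  v <- psp_waveform(t, amplitude = 1, tau = tau, lif = lif)
  pk <- max(v)
  out <- v / pk
  attr(out, "t") <- t
  attr(out, "dt") <- dt
  attr(out, "peak_mV_per_pA") <- pk
  out
}
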