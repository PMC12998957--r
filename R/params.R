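#' Feedforward-network parameters
#'
#' Container for the probabilities, counts, rates and unitary synaptic
#' properties of the feedforward inhibitory circuit: `nE` afferents that
#' drive a reference cell (with per-spike transmission probability
#' `pE_to_R`) and `nI` interneurons (transmission `pE_to_I`), which in turn
#' inhibit the reference cell (transmission `pI_to_R`).
#'
#' Defaults follow the typical simulation values: 250 afferents at 50 Hz,
#' 50 interneurons, 10.3 pA alpha-function unitary currents whose integral
#' (2 ms time constant, 15 ms truncation) carries 0.0557 pC.
#'
#' @param nE,nI Positive integer counts of excitatory afferents and
#'   inhibitory neurons.
#' @param pE Probability that a stimulus activates an afferent, in `[0,1]`.
#' @param pE_to_R,pE_to_I,pI_to_R Synaptic transmission probabilities, in
#'   `[0,1]`.
#' @param rE,rI Firing rates (Hz) of active afferents and interneurons.
#' @param aE,aI Unitary PSC peak amplitudes (pA); `aI` must be `<= 0`.
#' @param qE,qI Unitary charge-transfer magnitudes (pC).  Defaults are the
#'   integrals of the default alpha kernels.
#' @param pI_hat Probability that an interneuron fires during the stimulus.
#' @return An object of class `network_params` (a validated list).
#' @examples
#' p <- network_params(pE = 0.35)
#' ei_ratios(p)
#' @export
network_params <- function(nE = 250L, nI = 50L, pE = 0.35,
                           pE_to_R = 1, pE_to_I = 1, pI_to_R = 1,
                           rE = 50, rI = 50,
                           aE = 10.3, aI = -10.3,
                           qE = 0.0557, qI = 0.0557,
                           pI_hat = 1) {
  p <- list(nE = as.integer(nE), nI = as.integer(nI), pE = pE,
            pE_to_R = pE_to_R, pE_to_I = pE_to_I, pI_to_R = pI_to_R,
            rE = rE, rI = rI, aE = aE, aI = aI, qE = qE, qI = qI,
            pI_hat = pI_hat)
  class(p) <- "network_params"
  validate_network_params(p)
  p
}

validate_network_params <- function(p) {
  probs <- c("pE", "pE_to_R", "pE_to_I", "pI_to_R", "pI_hat")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a probability in [0,1], got %s",
                   nm, format(p[[nm]])), call. = FALSE)
  }
  for (nm in c("nE", "nI")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 1L)
      stop(sprintf("'%s' must be a positive integer", nm), call. = FALSE)
  }
  for (nm in c("rE", "rI")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop(sprintf("'%s' must be a nonnegative rate (Hz)", nm),
           call. = FALSE)
  }
  if (p$aI > 0)
    stop("'aI' is an inhibitory amplitude and must be <= 0", call. = FALSE)
  if (p$qE <= 0 || p$qI < 0)
    stop("charge magnitudes must be positive ('qE') / nonnegative ('qI')",
         call. = FALSE)
  r <- ei_ratios(p)
  if (!all(vapply(r, function(x) is.finite(x) && x >= 0, logical(1L))))
    stop("derived ratios kn, kq, kr, ka, kEI must be finite and >= 0",
         call. = FALSE)
  invisible(p)
}

#' Derived inhibitory-to-excitatory ratio constants
#'
#' @param params A [network_params()] object.
#' @return Named list with `kn = nI/nE`, `kq = |qI/qE|`, `kr = rI/rE`,
#'   `ka = |aI/aE|` and `kEI = pI_to_R/pE_to_R`.
#' @export
ei_ratios <- function(params) {
  stopifnot(inherits(params, "network_params"))
  list(kn = params$nI / params$nE,
       kq = abs(params$qI / params$qE),
       kr = params$rI / params$rE,
       ka = abs(params$aI / params$aE),
       kEI = params$pI_to_R / params$pE_to_R)
}

#' Effective excitatory drive onto the interneuron pool
#'
#' Always derived as `pE * pE_to_I`; never stored, so it cannot drift out
#' of sync with its factors.
#'
#' @param params A [network_params()] object.
#' @return The product `pE * pE_to_I`.
#' @export
pi_E_to_I <- function(params) {
  stopifnot(inherits(params, "network_params"))
  params$pE * params$pE_to_I
}

#' @export
print.network_params <- function(x, ...) {
  r <- ei_ratios(x)
  cat("Feedforward network parameters\n")
  cat(sprintf("  afferents:    nE = %d, rE = %g Hz, pE = %g\n",
              x$nE, x$rE, x$pE))
  cat(sprintf("  interneurons: nI = %d, rI = %g Hz, pI_hat = %g\n",
              x$nI, x$rI, x$pI_hat))
  cat(sprintf("  transmission: pE_to_R = %g, pE_to_I = %g, pI_to_R = %g\n",
              x$pE_to_R, x$pE_to_I, x$pI_to_R))
  cat(sprintf("  unitary:      aE = %g pA, aI = %g pA, qE = %g pC, qI = %g pC\n",
              x$aE, x$aI, x$qE, x$qI))
  cat(sprintf("  ratios:       kn = %.3g, kq = %.3g, kr = %.3g, ka = %.3g, kEI = %.3g\n",
              r$kn, r$kq, r$kr, r$ka, r$kEI))
  invisible(x)
}

#' Update network parameters
#'
#' Returns a revalidated copy with the named fields replaced.
#'
#' @param params A [network_params()] object.
#' @param ... Fields to replace, e.g. `pE = 0.5`.
#' @return A new `network_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "network_params"))
  new <- modifyList(unclass(params), list(...))
  do.call(network_params, new)
}

#' Inhibitory scaling modes
#'
#' How the effective inhibitory probability `pI` co-varies with the afferent
#' probability `pE` along an input-output sweep:
#' \describe{
#'   \item{`fixed_pI`}{`pI` held at `pi_fixed` across the sweep (tonic,
#'     stimulus-independent inhibition).}
#'   \item{`linear_kc`}{the interneuron-to-afferent ratio grows with the
#'     stimulus, `kn = kc * pE`, so `pI` is linear in `pE` (progressive
#'     interneuron recruitment).}
#'   \item{`ffwd_recruit`}{the afferent-to-interneuron transmission scales
#'     as `pE_to_I = kp * pE`; interneuron firing probability and rate are
#'     then predicted from the interneurons' own I-O function, so `pI`
#'     follows their recruitment curve.}
#' }
#'
#' @param mode One of `"fixed_pI"`, `"linear_kc"`, `"ffwd_recruit"`.
#' @param pi_fixed Constant `pI` for the fixed mode, in `[0,1]`.
#' @param kc Slope of `kn = kc * pE` for the linear mode, in `[0,1]`.
#' @param kp Slope of `pE_to_I = kp * pE` for the recruit mode, in `[0,1]`.
#' @return An object of class `scaling_mode`.
#' @export
scaling_mode <- function(mode = c("fixed_pI", "linear_kc", "ffwd_recruit"),
                         pi_fixed = NULL, kc = NULL, kp = NULL) {
  mode <- match.arg(mode)
  chk01 <- function(v, nm) {
    if (is.null(v) || !is.finite(v) || v < 0 || v > 1)
      stop(sprintf("mode '%s' requires '%s' in [0,1]", mode, nm),
           call. = FALSE)
    v
  }
  out <- switch(mode,
    fixed_pI = list(mode = mode, pi_fixed = chk01(pi_fixed, "pi_fixed")),
    linear_kc = list(mode = mode, kc = chk01(kc, "kc")),
    ffwd_recruit = list(mode = mode, kp = chk01(kp, "kp")))
  class(out) <- "scaling_mode"
  out
}

#' @export
print.scaling_mode <- function(x, ...) {
  cat("Inhibitory scaling mode:", x$mode, "\n")
  extra <- setdiff(names(x), "mode")
  for (nm in extra) cat(sprintf("  %s = %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Leaky integrate-and-fire membrane parameters
#'
#' Internal units are ms, mV, pA, nS, pF, MOhm throughout, which are
#' self-consistent: `pA * MOhm = uV` and `MOhm * pF = ms`, so the membrane
#' time constant must satisfy `tau_m ~ R * C / 1000` (checked to 1%).
#'
#' @param R Input resistance (MOhm).
#' @param V_l Resting/reset potential (mV).
#' @param tau_m Membrane time constant (ms).
#' @param C Capacitance (pF).
#' @param V_theta Spike threshold (mV); must exceed `V_l`.
#' @param dt Integration step (ms).
#' @return An object of class `lif_params`.
#' @examples
#' lif <- lif_params()
#' rheobase(lif) # 200 pA
#' @export
lif_params <- function(R = 75, V_l = -70, tau_m = 10, C = 133,
                       V_theta = -55, dt = 0.01) {
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (V_theta <= V_l) stop("'V_theta' must exceed 'V_l'", call. = FALSE)
  if (R <= 0 || C <= 0 || tau_m <= 0)
    stop("'R', 'C' and 'tau_m' must be positive", call. = FALSE)
  rc <- R * C / 1000 # MOhm * pF -> ms (factor 1000 from M * p = 1e-6)
  if (abs(rc - tau_m) / tau_m > 0.01)
    stop(sprintf(
      "inconsistent membrane constants: R*C = %.3f ms but tau_m = %.3f ms",
      rc, tau_m), call. = FALSE)
  out <- list(R = R, V_l = V_l, tau_m = tau_m, C = C, V_theta = V_theta,
              dt = dt)
  class(out) <- "lif_params"
  out
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "LIF neuron: R = %g MOhm, tau_m = %g ms, C = %g pF\n  V_l = %g mV, V_theta = %g mV, dt = %g ms, rheobase = %g pA\n",
    x$R, x$tau_m, x$C, x$V_l, x$V_theta, x$dt, rheobase(x)))
  invisible(x)
}

#' Read or write parameter sets as flat JSON configs
#'
#' Keys are the field names of [network_params()] and [lif_params()]
#' (`nE`, `nI`, `pE`, `pE_to_R`, ..., `R`, `V_l`, `tau_m`, ...), stored as
#' a flat key-value map so configs are hand-editable.
#'
#' @param params A `network_params` or `lif_params` object.
#' @param path File path of the JSON config.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the reconstructed, revalidated object.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, c("network_params", "lif_params")))
  x <- c(list(.class = class(params)[1L]), unclass(params))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  switch(cls,
    network_params = do.call(network_params, x),
    lif_params = do.call(lif_params, x),
    stop("unknown config class: ", cls, call. = FALSE))
}
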