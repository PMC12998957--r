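#' Survival probability of excitation under feedforward inhibition
#'
#' The probability that an excitatory input occurs (`pE`) and is not
#' cancelled by a coincident inhibitory input (`1 - pI`):
#' `pnet = pE * (1 - pI)`.  Over `n` independent trials the number of
#' uncancelled EPSPs is binomial with mean `n * pnet`.
#'
#' @param pE,pI Probabilities in `[0,1]` (vectorised; recycled).
#' @return `pE * (1 - pI)`, always in `[0,1]`.
#' @examples
#' compute_pnet(0.5, 0.5) # 0.25
#' @export
compute_pnet <- function(pE, pI) {
  check_prob(pE, "pE")
  check_prob(pI, "pI")
  pE * (1 - pI)
}

check_prob <- function(x, nm) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stop(sprintf("'%s' must be a probability in [0,1]", nm), call. = FALSE)
  invisible(x)
}

#' Effective inhibitory probability from network ratio constants
#'
#' Collapses interneuron recruitment and relative synaptic weight into a
#' single probability: `pI = pI_hat * kn * kq * kr * kEI`, where `pI_hat`
#' is the probability that an interneuron fires during the stimulus,
#' `kn = nI/nE`, `kq = |qI/qE|` (charge ratio; for brief stimuli the
#' amplitude ratio `ka` takes its place), `kr = rI/rE` and
#' `kEI = pI_to_R/pE_to_R`.  The product must remain below unity to stay
#' interpretable as a probability; exceeding 1 signals a misparameterised
#' network and is an error, not a clip.
#'
#' @param pI_hat Interneuron firing probability in `[0,1]`.
#' @param kn,kq,kr,kEI Nonnegative ratio constants.
#' @return The product, a probability in `[0,1]`.
#' @examples
#' compute_effective_pI(1, kn = 0.2, kq = 1, kr = 2.3, kEI = 1) # 0.46
#' @export
compute_effective_pI <- function(pI_hat, kn, kq, kr, kEI) {
  check_prob(pI_hat, "pI_hat")
  f <- c(kn = kn, kq = kq, kr = kr, kEI = kEI)
  if (anyNA(f) || any(f < 0) || any(!is.finite(f)))
    stop("ratio constants kn, kq, kr, kEI must be finite and >= 0",
         call. = FALSE)
  pI <- pI_hat * kn * kq * kr * kEI
  if (any(pI > 1)) {
    big <- names(f)[f > 1]
    stop(sprintf(
      "effective pI = %.4g exceeds 1 and is not a probability; factors > 1: %s",
      max(pI), if (length(big)) paste(big, collapse = ", ") else "(none individually)"),
      call. = FALSE)
  }
  pI
}

#' Mean steady-state synaptic currents in the feedforward circuit
#'
#' For a sustained stimulus the mean currents are rate-charge products:
#' excitatory drive to the reference cell
#' `iE_to_R = pE * pE_to_R * nE * qE * rE`, drive to the interneurons
#' `iE_to_I = pE * pE_to_I * nE * qE * rE`, and inhibitory drive
#' `iI_to_R = pI_hat * pI_to_R * nI * qI * rI`, which by the definition of
#' the ratio constants equals `pI * pE_to_R * nE * qE * rE` (checked to
#' relative 1e-9).  The net drive is `i_net = nE*qE*rE*pE_to_R * pnet`.
#'
#' @param params A [network_params()] object.
#' @param pI Effective inhibitory probability; by default derived from the
#'   stored `pI_hat` and ratio constants via [compute_effective_pI()].
#' @return An object of class `mean_currents` with fields `iE_to_R`,
#'   `iE_to_I`, `iI_to_R` (magnitude of inhibitory drive), `i_net` (pA),
#'   plus the `pI` and `pnet` used.
#' @examples
#' mc <- mean_currents(network_params(pE = 0.35, nI = 10, rI = 115))
#' mc$iE_to_R # ~243.7 pA
#' @export
mean_currents <- function(params, pI = NULL) {
  stopifnot(inherits(params, "network_params"))
  r <- ei_ratios(params)
  if (is.null(pI))
    pI <- compute_effective_pI(params$pI_hat, r$kn, r$kq, r$kr, r$kEI)
  check_prob(pI, "pI")
  base <- params$nE * params$qE * params$rE # pC * Hz = pA
  iE_to_R <- params$pE * params$pE_to_R * base
  iE_to_I <- params$pE * params$pE_to_I * base
  iI_to_R_a <- params$pI_hat * params$pI_to_R * params$nI * params$qI *
    params$rI
  iI_to_R_b <- pI * params$pE_to_R * base
  pnet <- compute_pnet(params$pE, pI)
  i_net <- base * params$pE_to_R * pnet
  out <- list(iE_to_R = iE_to_R, iE_to_I = iE_to_I, iI_to_R = iI_to_R_a,
              i_net = i_net, pI = pI, pnet = pnet)
  # consistency of the two factorizations, only meaningful when pI was
  # derived from the stored ratios
  attr(out, "factorization_reldiff") <-
    if (iI_to_R_a > 0) abs(iI_to_R_a - iI_to_R_b) / iI_to_R_a else
      abs(iI_to_R_a - iI_to_R_b)
  class(out) <- "mean_currents"
  out
}

#' @export
print.mean_currents <- function(x, ...) {
  cat(sprintf(
    "Mean currents (pA): iE_to_R = %.4g, iE_to_I = %.4g, iI_to_R = %.4g, i_net = %.4g\n  (pI = %.4g, pnet = %.4g)\n",
    x$iE_to_R, x$iE_to_I, x$iI_to_R, x$i_net, x$pI, x$pnet))
  invisible(x)
}

#' Resolve the effective pI along a pE sweep for a scaling mode
#'
#' @param pE Vector of afferent probabilities.
#' @param scaling A [scaling_mode()] object.
#' @param params A [network_params()] object supplying the ratio constants.
#' @param recruit_fn For `ffwd_recruit` mode, a function
#'   `f(pi_E_to_I, params)` returning `list(pI_hat=, rI=)` for a given
#'   interneuron drive (e.g. an analytic predictor or a simulation probe).
#'   Required in that mode.
#' @param amplitude_ratio Use the amplitude ratio `ka` instead of the
#'   charge ratio `kq` (brief-stimulus convention, where each cell fires at
#'   most once so the rate ratio `kr` is also dropped).
#' @return Numeric vector of effective `pI`, same length as `pE`.
#' @export
resolve_pI <- function(pE, scaling, params, recruit_fn = NULL,
                       amplitude_ratio = FALSE) {
  stopifnot(inherits(scaling, "scaling_mode"),
            inherits(params, "network_params"))
  check_prob(pE, "pE")
  r <- ei_ratios(params)
  kw <- if (amplitude_ratio) r$ka else r$kq
  krate <- if (amplitude_ratio) 1 else r$kr
  switch(scaling$mode,
    fixed_pI = rep(scaling$pi_fixed, length(pE)),
    linear_kc = compute_effective_pI(params$pI_hat, scaling$kc * pE,
                                     kw, krate, r$kEI),
    ffwd_recruit = {
      if (is.null(recruit_fn))
        stop("'ffwd_recruit' mode needs a recruit_fn(pi_E_to_I, params)",
             call. = FALSE)
      vapply(pE, function(p) {
        drive <- p * scaling$kp * p # pE_to_I = kp * pE
        rec <- recruit_fn(drive, params)
        kr_i <- if (amplitude_ratio) 1 else rec$rI / params$rE
        compute_effective_pI(rec$pI_hat, r$kn, kw, kr_i, r$kEI)
      }, numeric(1L))
    })
}

#' Net-probability curve along a pE sweep
#'
#' For fixed `pI` the curve is linear with slope `(1 - pI)`.  For the
#' linear-recruitment mode `pI = kc * pE` (the `linear_kc` scaling with
#' `pI_hat = kq = kr = kEI = 1`) it is `pE * (1 - kc * pE)`, which is
#' non-monotonic on `[0,1]` exactly when `kc > 0.5`, peaking at
#' `pE = 1/(2*kc)` with value `1/(4*kc)`.
#'
#' @param pE_grid Vector of afferent probabilities.
#' @param scaling A [scaling_mode()] object.
#' @param params Optional [network_params()]; defaults to unit ratio
#'   constants so `linear_kc` reduces to `pI = kc * pE`.
#' @param ... Passed to [resolve_pI()] (e.g. `recruit_fn`).
#' @return Numeric vector `pnet(pE)` on the grid.
#' @export
pnet_curve <- function(pE_grid, scaling, params = NULL, ...) {
  if (is.null(params))
    params <- network_params(rI = 50, qI = 0.0557) # unit ratios via defaults
  pI <- resolve_pI(pE_grid, scaling, params, ...)
  compute_pnet(pE_grid, pI)
}

#' Conductance correction of the mean net drive
#'
#' Linear current summation breaks down when synaptic conductance is an
#' appreciable fraction of the leak: the extra conductance divides the
#' effective drive.  The default strategy scales the net current by
#' `g_leak / (g_leak + g_syn_mean)`, i.e. by the leak's share of the total
#' membrane conductance; it is exact for the shift of the steady-state
#' voltage of a conductance-clamped membrane and is documented as an
#' approximation for fluctuating input.  Alternative forms can be supplied
#' via `strategy`.
#'
#' @param i_net Mean net drive (pA).
#' @param g_syn_mean Mean total synaptic conductance (nS); must be `>= 0`.
#' @param lif A [lif_params()] object (supplies the leak `g_l = 1000/R`
#'   nS).
#' @param strategy Function `f(i_net, g_syn_mean, g_leak)` returning the
#'   corrected current; default is the divisive form above.
#' @return Corrected effective drive (pA), `<= i_net` for
#'   `g_syn_mean >= 0` and equal to it at zero conductance.
#' @export
conductance_correction <- function(i_net, g_syn_mean, lif = lif_params(),
                                   strategy = NULL) {
  if (any(!is.finite(g_syn_mean)) || any(g_syn_mean < 0))
    stop("'g_syn_mean' must be a nonnegative conductance (nS)",
         call. = FALSE)
  g_leak <- 1000 / lif$R # MOhm -> nS
  if (is.null(strategy))
    strategy <- function(i, g, gl) i * gl / (gl + g)
  strategy(i_net, g_syn_mean, g_leak)
}

#' Mean synaptic conductance of a Poisson barrage
#'
#' Rate-charge product in conductance units: [kernel_charge()] returns
#' the kernel integral in nS*s for a conductance kernel, so the
#' stationary mean conductance at total event rate `rate_hz` (1/s) is
#' simply their product.
#'
#' @param rate_hz Total event rate (Hz).
#' @param kernel A conductance-mode [synaptic_kernel()].
#' @return Mean conductance (nS).
#' @export
mean_conductance <- function(rate_hz, kernel) {
  stopifnot(inherits(kernel, "synaptic_kernel"))
  rate_hz * abs(kernel_charge(kernel))
}
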