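#' Rheobase current of an LIF neuron
#'
#' Minimum constant current for sustained firing:
#' `(V_theta - V_l)/R`, returned in pA (mV/MOhm = nA, hence the factor
#' 1000).  Defaults give 200 pA.
#'
#' @param lif A [lif_params()] object.
#' @return Rheobase (pA).
#' @export
rheobase <- function(lif = lif_params()) {
  (lif$V_theta - lif$V_l) / lif$R * 1000
}

#' Deterministic (oscillatory-regime) LIF firing rate
#'
#' Standard f-I relation of the LIF with reset to `V_l` and no refractory
#' period: 0 at or below rheobase, otherwise
#' `r = 1000 / (tau_m * log(i*R / (i*R - (V_theta - V_l))))` Hz.
#'
#' @param i_net Mean net drive (pA); vectorised.
#' @param lif A [lif_params()] object.
#' @return Firing rate (Hz).
#' @examples
#' osc_rate(400) # ~144.3 Hz (interspike interval tau_m * log 2)
#' @export
osc_rate <- function(i_net, lif = lif_params()) {
  if (any(!is.finite(i_net))) stop("'i_net' must be finite", call. = FALSE)
  dv <- (lif$V_theta - lif$V_l) * 1000 # uV
  ir <- i_net * lif$R                  # pA * MOhm = uV
  out <- numeric(length(i_net))
  sup <- ir > dv
  out[sup] <- 1000 / (lif$tau_m * log(ir[sup] / (ir[sup] - dv)))
  out
}

#' Threshold EPSP count
#'
#' Number of simultaneous unitary EPSPs needed to reach threshold from
#' rest, `ceiling((V_theta - V_l)/psp_peak)`.  With the default 10.3 pA
#' input (unitary PSP peak ~0.251 mV) and a 15 mV threshold distance this
#' is 60.
#'
#' @param lif A [lif_params()] object.
#' @param psp_peak_mV Unitary EPSP peak (mV); default from [psp_peak()]
#'   at `amplitude` pA.
#' @param amplitude Unitary EPSC peak (pA) used when `psp_peak_mV` is not
#'   given.
#' @return Integer threshold count (`>= 1`, else an error: a single
#'   suprathreshold input is outside the model's assumptions).
#' @export
threshold_count <- function(lif = lif_params(), psp_peak_mV = NULL,
                            amplitude = 10.3) {
  if (is.null(psp_peak_mV))
    psp_peak_mV <- psp_peak(amplitude = amplitude, lif = lif)$peak
  if (psp_peak_mV >= lif$V_theta - lif$V_l)
    stop("a single unitary input is suprathreshold, outside the model's assumptions",
         call. = FALSE)
  as.integer(ceiling((lif$V_theta - lif$V_l) / psp_peak_mV))
}

#' Fluctuation-regime (sub-oscillatory) firing rate
#'
#' Below rheobase, spikes arise from fluctuations in the count of
#' surviving EPSPs.  The count `X` within one integration window is
#' modelled as Poisson with mean
#' `nE * pnet * pE_to_R * rE * window/1000`, and
#' `r_fluct = Pr(X >= n_theta) * r_rh`, where `n_theta` is the threshold
#' EPSP count and `r_rh` the minimum oscillatory rate at rheobase.  The
#' exact Poisson tail is used (no normal approximation).
#'
#' `r_rh` is ill-defined for a pure LIF (the deterministic rate vanishes
#' at rheobase); the default, the oscillatory rate at `1.05 * irh`
#' (~32.8 Hz), stands in for the lowest observed oscillatory rate and is
#' this module's largest approximation.
#'
#' The default window is the time rheobase current takes to deliver
#' `n_theta` unitary charges, `n_theta * qE / irh` (~16.7 ms at
#' defaults).  This anchors the sigmoid to the oscillatory onset --
#' `Pr(X >= n_theta) = 1/2` exactly where the mean drive crosses
#' rheobase -- so the fluctuation branch peaks near the onset of the
#' oscillatory regime rather than far beyond it.
#'
#' @param pnet Survival probability of excitation (vectorised).
#' @param params A [network_params()] object.
#' @param lif A [lif_params()] object.
#' @param window Integration window (ms); `NULL` for the rheobase-anchored
#'   default above.
#' @param r_rh Rate at oscillatory onset (Hz); see above.
#' @param n_theta Threshold count; default [threshold_count()] with the
#'   network's `aE`.
#' @return Fluctuation-driven rate (Hz), sigmoidal and nondecreasing in
#'   `pnet`.
#' @export
fluct_rate <- function(pnet, params = network_params(),
                       lif = lif_params(), window = NULL,
                       r_rh = NULL, n_theta = NULL) {
  check_prob(pnet, "pnet")
  if (is.null(r_rh)) r_rh <- osc_rate(1.05 * rheobase(lif), lif)
  if (r_rh < 0) stop("'r_rh' must be >= 0", call. = FALSE)
  if (is.null(n_theta))
    n_theta <- threshold_count(lif, amplitude = params$aE)
  if (is.null(window))
    window <- 1000 * n_theta * params$qE / rheobase(lif) # ms
  if (window <= 0) stop("'window' must be positive", call. = FALSE)
  mu <- params$nE * pnet * params$pE_to_R * params$rE * window / 1000
  ppois(n_theta - 1L, mu, lower.tail = FALSE) * r_rh
}

#' Predict the sustained-stimulus input-output curve analytically
#'
#' Per grid point: resolve the effective `pI` for the scaling mode,
#' compute `pnet` and the mean net drive, apply the conductance
#' correction when in conductance mode, evaluate both the oscillatory and
#' fluctuation-regime rates, and take the larger of the two as the
#' overall rate.
#'
#' @param pE_grid Vector of afferent activation probabilities.
#' @param scaling A [scaling_mode()] object.
#' @param params A [network_params()] object.
#' @param lif A [lif_params()] object.
#' @param mode `"current"` or `"conductance"`; conductance mode
#'   divisively corrects the net drive by the mean synaptic conductance
#'   (excitatory plus recruited inhibitory).
#' @param gE_kernel,gI_kernel Conductance kernels used for the correction
#'   in conductance mode.
#' @param ... Passed to [resolve_pI()] (e.g. `recruit_fn` for
#'   `ffwd_recruit` scaling).
#' @return A data frame with columns `pE`, `pI`, `pnet`, `i_net_pA`,
#'   `r_osc_Hz`, `r_fluct_Hz`, `r_combined_Hz`, `regime`.
#' @export
predict_io_curve <- function(pE_grid, scaling, params = network_params(),
                             lif = lif_params(),
                             mode = c("current", "conductance"),
                             gE_kernel = synaptic_kernel(0.147,
                               mode = "conductance", V_rev = 0),
                             gI_kernel = synaptic_kernel(1.045,
                               mode = "conductance", V_rev = -80),
                             ...) {
  mode <- match.arg(mode)
  pI <- tryCatch(resolve_pI(pE_grid, scaling, params, ...),
                 error = function(e) stop(
                   "effective pI invalid along the grid: ",
                   conditionMessage(e), call. = FALSE))
  pnet <- compute_pnet(pE_grid, pI)
  base <- params$nE * params$qE * params$rE * params$pE_to_R
  i_net <- base * pnet
  if (mode == "conductance") {
    rate_E <- params$nE * pE_grid * params$pE_to_R * params$rE
    # pI * nI interneuron trains at rI reach the reference cell
    rate_I <- pI * params$nI * params$rI * params$pI_to_R
    # g from rate-charge products of both barrages
    gE <- mean_conductance(rate_E, gE_kernel)
    gI <- mean_conductance(rate_I, gI_kernel)
    i_net <- conductance_correction(i_net, gE + gI, lif)
  }
  r_osc <- osc_rate(i_net, lif)
  r_fl <- fluct_rate(pnet, params, lif)
  data.frame(pE = pE_grid, pI = pI, pnet = pnet, i_net_pA = i_net,
             r_osc_Hz = r_osc, r_fluct_Hz = r_fl,
             r_combined_Hz = pmax(r_osc, r_fl),
             regime = ifelse(i_net > rheobase(lif), "oscillatory",
                             "sub_oscillatory"))
}
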