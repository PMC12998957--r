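#' Gaussian arrival-time histogram for a brief stimulus
#'
#' For a brief stimulus each afferent fires a single action potential
#' with Gaussian timing jitter, so the expected EPSC arrival histogram is
#' `h(t) = pE * nE * transmission_prob * N(mu_t, sigma_t^2)`.  In
#' expected mode the exact per-bin Gaussian mass is returned; in sampled
#' mode each afferent participates with probability
#' `pE * transmission_prob` and contributes one `N(mu_t, sigma_t)` spike
#' time.
#'
#' @param pE Afferent activation probability.
#' @param nE Number of afferents.
#' @param mu_t,sigma_t Mean and SD of arrival times (ms).
#' @param dt Bin width (ms).
#' @param t_max Histogram window (ms).
#' @param transmission_prob Per-spike synaptic transmission probability.
#' @param sampled Draw a stochastic realisation instead of the expected
#'   histogram.
#' @return An `arrival_histogram`: list with `counts` (per bin), `mids`
#'   (bin centres, ms), `scale` (`pE * nE * transmission_prob`, the
#'   expected total mass), `dt`, `sampled`, and in sampled mode `times`.
#' @export
gaussian_arrivals <- function(pE, nE, mu_t = 5, sigma_t = 1, dt = 0.01,
                              t_max = 30, transmission_prob = 1,
                              sampled = FALSE) {
  check_prob(pE, "pE")
  check_prob(transmission_prob, "transmission_prob")
  if (sigma_t <= 0) stop("'sigma_t' must be positive", call. = FALSE)
  edges <- seq(0, t_max, by = dt)
  n <- length(edges) - 1L
  scale <- pE * nE * transmission_prob
  times <- NULL
  if (sampled) {
    n_part <- rbinom(1L, nE, pE * transmission_prob)
    times <- rnorm(n_part, mu_t, sigma_t)
    times <- times[times >= 0 & times < t_max]
    counts <- tabulate(as.integer(floor(times / dt)) + 1L, nbins = n)
  } else {
    counts <- scale * diff(pnorm(edges, mu_t, sigma_t))
  }
  out <- list(counts = counts, mids = edges[-1L] - dt / 2, scale = scale,
              dt = dt, sampled = sampled, times = times)
  class(out) <- "arrival_histogram"
  out
}

#' @export
print.arrival_histogram <- function(x, ...) {
  cat(sprintf(
    "Arrival histogram: %d bins of %g ms, mass %.3f (scale %.3f)%s\n",
    length(x$counts), x$dt, sum(x$counts), x$scale,
    if (x$sampled) ", sampled" else ", expected"))
  invisible(x)
}

# Causal discrete convolution, truncated to the length of x.
conv_causal <- function(x, k) {
  n <- length(x)
  m <- length(k)
  N <- stats::nextn(n + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(N - n))) *
                       stats::fft(c(k, numeric(N - m))), inverse = TRUE)) / N
  pmax(y[seq_len(n)], 0) # clamp FFT ringing on nonnegative inputs
}

#' Instantaneous excitatory/inhibitory probability traces and net drive
#'
#' Convolves peak-normalised unitary PSP shapes with the arrival-time
#' densities to obtain the per-afferent activation profiles `ptilde_E(t)`
#' and `ptilde_I(t)` (each in `[0,1]`), then forms the excitatory trace
#' `pE * ptilde_E(t)`, the inhibitory trace `pI * ptilde_I(t)` (the
#' inhibitory histogram is conditional on stimulus-evoked inhibition, so
#' no additional factor of `pE` is applied), and the rectified net drive
#' `ptilde_net(t) = max(0, pE*ptilde_E(t) - pI*ptilde_I(t))`.
#'
#' @param histE Excitatory [gaussian_arrivals()] histogram (mass
#'   `scale`).
#' @param histI Inhibitory arrival histogram, conditional on inhibition
#'   (its density is `counts/sum(counts)`); `NULL` for no inhibition.
#' @param unit_epsp,unit_ipsp Peak-normalised unitary PSP shapes from
#'   [unit_psp_kernel()] (an error if their maximum is not 1).
#' @param pE,pI Scalar probabilities.
#' @return A `probability_traces` list: `t`, `p_E_t`, `p_I_t`, `p_net_t`,
#'   `dt`.
#' @export
probability_traces <- function(histE, histI = NULL, unit_epsp, unit_ipsp = NULL,
                               pE, pI = 0) {
  stopifnot(inherits(histE, "arrival_histogram"))
  check_prob(pE, "pE")
  check_prob(pI, "pI")
  chk_norm <- function(u, nm) {
    if (abs(max(u) - 1) > 1e-6)
      stop(sprintf("'%s' must be peak-normalised to 1 (max is %.4g)",
                   nm, max(u)), call. = FALSE)
  }
  chk_norm(unit_epsp, "unit_epsp")
  phiE <- histE$counts / histE$scale
  if (histE$sampled && sum(histE$counts) > 0)
    phiE <- histE$counts / sum(histE$counts)
  ptE <- conv_causal(phiE, as.numeric(unit_epsp))
  p_E_t <- pE * ptE
  n <- length(p_E_t)
  if (!is.null(histI) && pI > 0) {
    chk_norm(unit_ipsp, "unit_ipsp")
    tot <- sum(histI$counts)
    phiI <- if (tot > 0) histI$counts / tot else histI$counts
    p_I_t <- pI * conv_causal(phiI, as.numeric(unit_ipsp))
  } else {
    p_I_t <- numeric(n)
  }
  out <- list(t = histE$mids, p_E_t = p_E_t, p_I_t = p_I_t,
              p_net_t = pmax(0, p_E_t - p_I_t), dt = histE$dt)
  class(out) <- "probability_traces"
  out
}

#' Threshold-crossing probability trace
#'
#' Per bin, the number of surviving effective inputs is modelled as
#' `Binomial(nE, p_net_t)`; the trace is the exact upper tail
#' `Pr(count >= n_theta)` (a Gaussian approximation is available for
#' speed).  Monotone in `p_net_t`.
#'
#' @param p_net_t Rectified net drive trace (values in `[0,1]`).
#' @param nE Number of afferents.
#' @param n_theta Threshold count (`>= 1`), see [threshold_count()].
#' @param approx `"exact"` binomial tail or `"normal"` approximation
#'   with continuity correction.
#' @return Numeric trace of crossing probabilities.
#' @export
threshold_crossing <- function(p_net_t, nE, n_theta,
                               approx = c("exact", "normal")) {
  approx <- match.arg(approx)
  if (n_theta < 1) stop("'n_theta' must be >= 1", call. = FALSE)
  check_prob(p_net_t, "p_net_t")
  if (approx == "exact") {
    pbinom(n_theta - 1L, nE, p_net_t, lower.tail = FALSE)
  } else {
    mu <- nE * p_net_t
    s <- sqrt(pmax(nE * p_net_t * (1 - p_net_t), 1e-12))
    pnorm((n_theta - 0.5 - mu) / s, lower.tail = FALSE)
  }
}

#' First-spike probability from a crossing-probability trace
#'
#' Hazard construction honouring the one-spike constraint: the
#' probability of firing first in bin `k` is
#' `f(t_k) = h(t_k) * prod_{j<k} (1 - h(t_j))` with `h` the per-bin
#' crossing probability, and the total firing probability is
#' `pf = sum_k f(t_k) <= 1`.
#'
#' @param p_cross_t Per-bin crossing probabilities in `[0,1]`.
#' @return List with `p_fire_t` (per-bin first-spike probability) and
#'   `pf`.
#' @export
first_spike_probability <- function(p_cross_t) {
  check_prob(p_cross_t, "p_cross_t")
  surv <- cumprod(1 - p_cross_t)
  prev <- c(1, head(surv, -1L))
  f <- p_cross_t * prev
  list(p_fire_t = f, pf = min(sum(f), 1))
}

#' Conditional first-crossing hazards from a crossing-probability trace
#'
#' The raw crossing trace gives the probability that the input count is
#' above threshold *at* each instant.  Treating those per-bin
#' probabilities as independent hazards overweights the leading edge of
#' the trace (thousands of 0.01 ms bins act as thousands of independent
#' chances to fire).  Under the nested-trajectory reading -- trials with
#' stronger input are above threshold whenever weaker trials are -- the
#' probability of having crossed by time `t` is the running maximum of
#' the trace, and the per-bin hazard is its conditional increment:
#' `g_k = (M_k - M_{k-1}) / (1 - M_{k-1})` with `M_k = max_{j<=k} h_j`.
#' Feeding `g` to [first_spike_probability()] then yields
#' `p_fire_t = diff(M)` and `pf = max(h)`.
#'
#' @param p_cross_t Per-bin crossing probabilities in `[0,1]`.
#' @return Vector of conditional hazards, same length.
#' @export
crossing_hazard <- function(p_cross_t) {
  check_prob(p_cross_t, "p_cross_t")
  M <- cummax(p_cross_t)
  Mprev <- c(0, head(M, -1L))
  ifelse(Mprev < 1, pmin(1, pmax(0, (M - Mprev) / (1 - Mprev))), 0)
}

#' Analytic transient-response prediction for the full circuit
#'
#' Runs the brief-stimulus predictor end to end.  The interneuron stage
#' is itself predicted with the same machinery: the per-afferent drive to
#' an interneuron is `pE * pE_to_I * ptilde_E(t)`, its first-spike trace
#' gives both the interneuron firing probability `pI_hat = pf_I` and the
#' conditional inhibitory timing density `hI = f_I / pf_I`.  The
#' effective `pI` uses the brief-stimulus convention: the amplitude ratio
#' `ka` replaces the charge ratio `kq` and the rate ratio is 1 (each cell
#' fires at most once).
#'
#' @param params A [network_params()] object (`nE`, `aE`, `aI`,
#'   transmission probabilities, `nI`).
#' @param lif A [lif_params()] object.
#' @param pI Effective inhibitory probability; `NULL` derives it from the
#'   predicted interneuron recruitment and the ratio constants.
#' @param mu_t,sigma_t Arrival-time mean and SD (ms).
#' @param t_max Analysis window (ms).
#' @param ipsp_lag Fixed synaptic lag added to the inhibitory timing
#'   (ms); 0 by default (the interneuron integration delay already
#'   emerges from the predictor).
#' @return A list: `traces` ([probability_traces()]), `p_cross_t`,
#'   `p_fire_t`, `pf`, `pI`, `pI_hat`, `interneuron` (first-spike trace
#'   of the interneuron stage), `n_theta`, `t`.
#' @export
predict_transient <- function(params, lif = lif_params(), pI = NULL,
                              mu_t = 5, sigma_t = 1, t_max = 30,
                              ipsp_lag = 0) {
  dt <- lif$dt
  u_e <- unit_psp_kernel(lif, dt = dt)
  u_i <- u_e # same membrane and alpha time constant for E and I
  n_theta <- threshold_count(lif, amplitude = abs(params$aE))
  histE <- gaussian_arrivals(params$pE, params$nE, mu_t, sigma_t, dt,
                             t_max, transmission_prob = params$pE_to_R)

  # interneuron stage: same afferents, transmission pE_to_I, no inhibition
  histEI <- gaussian_arrivals(params$pE, params$nE, mu_t, sigma_t, dt,
                              t_max, transmission_prob = 1)
  trI_in <- probability_traces(histEI, NULL, u_e, NULL,
                               pE = params$pE * params$pE_to_I)
  crossI <- threshold_crossing(trI_in$p_net_t, params$nE, n_theta)
  fsI <- first_spike_probability(crossing_hazard(crossI))
  pI_hat <- fsI$pf

  # Conditional inhibitory timing: the density of interneuron first
  # spikes given that one occurred.  It stays defined even when pI_hat is
  # tiny, which matters in fixed-pI protocols where the inhibitory
  # magnitude is the control variable and only the timing comes from the
  # interneuron stage.
  histI <- NULL
  if (pI_hat > 1e-12) {
    cnt <- fsI$p_fire_t
    if (ipsp_lag > 0) {
      sh <- round(ipsp_lag / dt)
      cnt <- c(numeric(sh), head(cnt, -sh))
    }
    histI <- list(counts = cnt, mids = trI_in$t, scale = pI_hat, dt = dt,
                  sampled = FALSE, times = NULL)
    class(histI) <- "arrival_histogram"
  }
  if (is.null(pI)) {
    r <- ei_ratios(params)
    pI <- compute_effective_pI(pI_hat, r$kn, r$ka, 1, r$kEI)
  }
  traces <- probability_traces(histE, histI, u_e, u_i,
                               pE = params$pE, pI = pI)
  p_cross <- threshold_crossing(traces$p_net_t, params$nE, n_theta)
  fs <- first_spike_probability(crossing_hazard(p_cross))
  list(traces = traces, p_cross_t = p_cross, p_fire_t = fs$p_fire_t,
       pf = fs$pf, pI = pI, pI_hat = pI_hat,
       interneuron = fsI, n_theta = n_theta, t = traces$t)
}

#' Monte-Carlo simulation of the transient protocol
#'
#' Per trial: each afferent fires once with Gaussian jitter and reaches
#' the reference cell (probability `pE * pE_to_R`) and each interneuron
#' (probability `pE * pE_to_I`, independent realisations per cell);
#' interneurons are integrated as LIF units and all their spikes,
#' transmitted with `pI_to_R`, form the inhibitory current to the
#' reference cell.  The reference neuron's first spike per trial is
#' recorded.
#'
#' @param params A [network_params()] object.
#' @param lif A [lif_params()] object.
#' @param n_trials Number of trials.
#' @param mu_t,sigma_t Arrival-time mean and SD (ms).
#' @param t_max Simulated window (ms).
#' @param mode `"current"` or `"conductance"` synapses.
#' @param seed Optional RNG seed.
#' @return A list: `pf` (fraction of trials with at least one spike),
#'   `first_spike_times` (ms, `NA` when silent), `psth_first` (per-bin
#'   first-spike probability), `pI_hat` (fraction of interneuron-trial
#'   pairs that fired), `inh_spike_times` (pooled interneuron spike
#'   times), `n_trials`, `dt`, `t`.
#' @export
simulate_transient_trials <- function(params, lif = lif_params(),
                                      n_trials = 1000L, mu_t = 5,
                                      sigma_t = 1, t_max = 30,
                                      mode = c("current", "conductance"),
                                      seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  dt <- lif$dt
  n_bins <- round(t_max / dt)
  if (mode == "current") {
    kE <- as.numeric(alpha_kernel(synaptic_kernel(params$aE), dt))
    kI <- as.numeric(alpha_kernel(synaptic_kernel(params$aI), dt))
  } else {
    kE <- as.numeric(alpha_kernel(
      synaptic_kernel(0.147, mode = "conductance", V_rev = 0), dt))
    kI <- as.numeric(alpha_kernel(
      synaptic_kernel(1.045, mode = "conductance", V_rev = -80), dt))
  }
  draw_bins <- function(p_part) {
    k <- rbinom(1L, params$nE, p_part)
    tt <- rnorm(k, mu_t, sigma_t)
    as.integer(ceiling(tt[tt > 0 & tt <= t_max] / dt))
  }
  first <- rep(NA_real_, n_trials)
  psth_first <- numeric(n_bins)
  inh_times <- vector("list", n_trials)
  n_int_fired <- 0L
  for (tr in seq_len(n_trials)) {
    iE <- cpp_events_to_current(draw_bins(params$pE * params$pE_to_R),
                                n_bins, kE)
    isp <- numeric(0)
    if (params$nI > 0L && params$pE_to_I > 0) {
      for (j in seq_len(params$nI)) {
        dj <- cpp_events_to_current(draw_bins(params$pE * params$pE_to_I),
                                    n_bins, kE)
        sj <- if (mode == "current")
          simulate_lif(dj, lif)$spike_times
        else
          simulate_lif(list(gE = dj, gI = numeric(n_bins), VE = 0,
                            VI = -80), lif)$spike_times
        if (length(sj)) {
          n_int_fired <- n_int_fired + 1L
          keep <- runif(length(sj)) < params$pI_to_R
          isp <- c(isp, sj[keep])
        }
      }
    }
    inh_times[[tr]] <- isp
    iI <- cpp_events_to_current(as.integer(ceiling(isp / dt)), n_bins, kI)
    ref <- if (mode == "current")
      simulate_lif(iE + iI, lif)
    else
      simulate_lif(list(gE = iE, gI = iI, VE = 0, VI = -80), lif)
    if (ref$n_spikes > 0L) {
      first[tr] <- ref$spike_times[1L]
      b <- as.integer(round(first[tr] / dt))
      if (b >= 1L && b <= n_bins) psth_first[b] <- psth_first[b] + 1
    }
  }
  list(pf = mean(!is.na(first)),
       first_spike_times = first,
       psth_first = psth_first / n_trials,
       pI_hat = if (params$nI > 0L) n_int_fired / (params$nI * n_trials)
                else 0,
       inh_spike_times = unlist(inh_times),
       n_trials = n_trials, dt = dt,
       t = (seq_len(n_bins) - 0.5) * dt)
}

#' Transient-regime input-output curve
#'
#' Predicted (and optionally simulated) total firing probability `pf`
#' versus `pE`, under a [scaling_mode()].  The brief-stimulus convention
#' applies: the amplitude ratio `ka` replaces the charge ratio and the
#' rate ratio is 1.  For `ffwd_recruit` scaling, `pE_to_I = kp * pE` and
#' the interneuron recruitment comes from the predictor itself.
#'
#' @param pE_grid Vector of afferent probabilities.
#' @param scaling A [scaling_mode()] object.
#' @param params A [network_params()] object.
#' @param lif A [lif_params()] object.
#' @param n_trials Trials per grid point when `simulate = TRUE`.
#' @param simulate Also run the Monte-Carlo oracle per point.
#' @param ... Passed to [predict_transient()] (e.g. `mu_t`, `t_max`).
#' @return Data frame with `pE`, `pI`, `pf_pred` and (optionally)
#'   `pf_sim`.
#' @export
transient_io_curve <- function(pE_grid, scaling, params = network_params(nE = 100L, nI = 20L),
                               lif = lif_params(), n_trials = 500L,
                               simulate = FALSE, ...) {
  stopifnot(inherits(scaling, "scaling_mode"))
  out <- lapply(pE_grid, function(pe) {
    p <- update_params(params, pE = pe)
    if (scaling$mode == "ffwd_recruit")
      p <- update_params(p, pE_to_I = min(1, scaling$kp * pe))
    pI <- switch(scaling$mode,
      fixed_pI = scaling$pi_fixed,
      linear_kc = {
        r <- ei_ratios(p)
        compute_effective_pI(p$pI_hat, scaling$kc * pe, r$ka, 1, r$kEI)
      },
      ffwd_recruit = NULL) # derived from predicted interneuron recruitment
    pred <- predict_transient(p, lif, pI = pI, ...)
    row <- data.frame(pE = pe, pI = pred$pI, pf_pred = pred$pf)
    if (simulate) {
      sim <- simulate_transient_trials(p, lif, n_trials = n_trials, ...)
      row$pf_sim <- sim$pf
    }
    row
  })
  do.call(rbind, out)
}

#' Align input-output curves by their activation threshold
#'
#' Shifts each curve horizontally by the interpolated `pE` at which it
#' first reaches `threshold` (linear interpolation between grid points),
#' so that purely additive (rightward-shift) families collapse onto a
#' single profile.
#'
#' @param pE Grid of input probabilities.
#' @param pf_mat Matrix of curves (rows = grid points, columns = curves).
#' @param threshold Activation level defining the alignment point.
#' @return List with `shifts` (per curve) and `aligned`, a function
#'   `f(x, j)` evaluating curve `j` at threshold-relative abscissa `x`.
#' @export
align_io_curves <- function(pE, pf_mat, threshold = 0.05) {
  pf_mat <- as.matrix(pf_mat)
  shifts <- apply(pf_mat, 2L, function(y) {
    above <- which(y >= threshold)
    if (!length(above)) return(NA_real_)
    i <- above[1L]
    if (i == 1L) return(pE[1L])
    # linear interpolation of the crossing
    pE[i - 1L] + (threshold - y[i - 1L]) / (y[i] - y[i - 1L]) *
      (pE[i] - pE[i - 1L])
  })
  aligned <- function(x, j)
    approx(pE - shifts[j], pf_mat[, j], xout = x, rule = 1)$y
  list(shifts = shifts, aligned = aligned)
}
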