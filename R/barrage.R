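round_half_up <- function(x) floor(x + 0.5)

# Accept a scalar, a vector of per-bin values, or a function of time (ms)
# and return a per-bin profile of length n.
as_profile <- function(p, n, dt) {
  if (is.function(p)) p <- p((seq_len(n) - 0.5) * dt)
  if (length(p) == 1L) p <- rep(p, n)
  if (length(p) != n)
    stop("profile length does not match the number of time bins",
         call. = FALSE)
  check_prob(p, "pE profile")
  p
}

#' Generate a Poisson synaptic barrage for a sustained stimulus
#'
#' Draws an (inhomogeneous) Poisson event train at instantaneous total
#' rate `nE * pE(t) * rE * transmission` and convolves it with the unitary
#' synaptic kernel.  Event counts are drawn per bin from a Poisson
#' distribution, so multiple events per bin are representable even at high
#' aggregate rates.  The long-run time average of the returned trace
#' matches the rate-charge product of [mean_currents()].
#'
#' @param params A [network_params()] object.
#' @param pE_profile Afferent activation probability: scalar, per-bin
#'   vector, or function of time (ms); values in `[0,1]`.
#' @param duration Trace duration (ms).
#' @param kernel Unitary [synaptic_kernel()] (current or conductance).
#' @param dt Time step (ms).
#' @param target `"reference"` scales the rate by `pE_to_R`,
#'   `"interneuron"` by `pE_to_I`.
#' @param rate_scale Extra multiplicative factor on the event rate (used
#'   by the bypassed-inhibition temporal protocol).
#' @return Numeric trace (pA or nS) of length `duration/dt`, with
#'   attributes `n_events` and `dt`.
#' @export
generate_sustained_barrage <- function(params, pE_profile, duration,
                                       kernel = synaptic_kernel(params$aE),
                                       dt = 0.01,
                                       target = c("reference", "interneuron"),
                                       rate_scale = 1) {
  stopifnot(inherits(params, "network_params"),
            inherits(kernel, "synaptic_kernel"))
  target <- match.arg(target)
  n <- round(duration / dt)
  p <- as_profile(pE_profile, n, dt)
  trans <- if (target == "reference") params$pE_to_R else params$pE_to_I
  lam <- params$nE * p * params$rE * trans * rate_scale / 1000 # events/ms
  counts <- rpois(n, lam * dt)
  k <- alpha_kernel(kernel, dt)
  out <- cpp_counts_to_current(counts, as.numeric(k))
  attr(out, "n_events") <- sum(counts)
  attr(out, "dt") <- dt
  out
}

#' Simulate the interneuron pool and measure its recruitment
#'
#' Each of `n_pool` (default `3 * nI`) interneurons receives an
#' independent excitatory barrage scaled by `pE_to_I` and is integrated as
#' an LIF unit.  Returns the spike trains plus the measured recruitment
#' statistics: `pI_hat`, the fraction of interneurons that fired at least
#' once, and `rI`, the mean firing rate conditional on firing.
#'
#' @param params A [network_params()] object.
#' @param pE_profile Afferent activation profile (see
#'   [generate_sustained_barrage()]).
#' @param duration Duration (ms).
#' @param lif A [lif_params()] for the interneurons.
#' @param kernel_E Excitatory [synaptic_kernel()].
#' @param n_pool Number of interneurons to simulate.
#' @param dt Time step (ms).
#' @return List with `trains` (list of spike-time vectors), `pI_hat`,
#'   `rI` (Hz), and `duration`.
#' @export
simulate_inhibitory_population <- function(params, pE_profile, duration,
                                           lif = lif_params(),
                                           kernel_E = synaptic_kernel(params$aE),
                                           n_pool = 3L * params$nI,
                                           dt = lif$dt) {
  stopifnot(n_pool >= 1L)
  trains <- vector("list", n_pool)
  for (i in seq_len(n_pool)) {
    drv <- generate_sustained_barrage(params, pE_profile, duration,
                                      kernel_E, dt, target = "interneuron")
    trains[[i]] <- simulate_lif(drv, lif)$spike_times
  }
  nsp <- lengths(trains)
  fired <- nsp > 0L
  list(trains = trains,
       pI_hat = mean(fired),
       rI = if (any(fired)) mean(nsp[fired]) / duration * 1000 else 0,
       duration = duration)
}

#' Build the inhibitory barrage from stored interneuron spike trains
#'
#' Selects a uniform random subset of `round(pI * nI)` trains
#' (round-half-up), sums their spikes, and convolves the summed train with
#' the inhibitory kernel -- selection precedes convolution.
#'
#' @param trains List of interneuron spike-time vectors (ms).
#' @param params A [network_params()] object (supplies `nI`).
#' @param kernel_I Inhibitory [synaptic_kernel()] (negative amplitude in
#'   current mode).
#' @param pI Effective inhibitory probability controlling the subset size.
#' @param duration Trace duration (ms).
#' @param dt Time step (ms).
#' @return Numeric trace of length `duration/dt` with attribute
#'   `n_selected`.
#' @export
build_inhibitory_barrage <- function(trains, params, kernel_I, pI,
                                     duration, dt = 0.01) {
  check_prob(pI, "pI")
  n_sel <- round_half_up(pI * params$nI)
  if (n_sel > length(trains))
    stop(sprintf("need %d interneuron trains but only %d available",
                 n_sel, length(trains)), call. = FALSE)
  n <- round(duration / dt)
  if (n_sel == 0L) {
    out <- numeric(n)
  } else {
    sel <- sample.int(length(trains), n_sel)
    spikes <- unlist(trains[sel], use.names = FALSE)
    bins <- as.integer(ceiling(spikes / dt))
    k <- alpha_kernel(kernel_I, dt)
    out <- cpp_events_to_current(bins, n, as.numeric(k))
  }
  attr(out, "n_selected") <- n_sel
  attr(out, "dt") <- dt
  out
}

#' Run repeated LIF trials and compile rate statistics and a PSTH
#'
#' `exc_gen` and `inh_gen` are functions of the trial index returning
#' fresh realisations of the excitatory and inhibitory drive.  In current
#' mode the two traces are summed; in conductance mode they are the
#' excitatory and inhibitory conductances (nS) with reversal potentials
#' `VE`, `VI`.
#'
#' @param exc_gen Function `f(trial)` returning the excitatory drive.
#' @param inh_gen Optional function `f(trial)` for the inhibitory drive;
#'   `NULL` means no inhibition.
#' @param lif A [lif_params()] object.
#' @param n_trials Number of independent trials (`>= 1`).
#' @param mode `"current"` or `"conductance"`.
#' @param VE,VI Reversal potentials (mV) for conductance mode.
#' @return A `sim_result` list: `spike_times` (per trial), `psth`
#'   (per-bin spike probability across trials at bin width `lif$dt`),
#'   `mean_rate`, `rate_sd` (Hz across trials), `n_trials`, `duration`,
#'   `dt`.
#' @export
run_trials <- function(exc_gen, inh_gen = NULL, lif = lif_params(),
                       n_trials = 100L, mode = c("current", "conductance"),
                       VE = 0, VI = -80) {
  mode <- match.arg(mode)
  stopifnot(n_trials >= 1L)
  spikes <- vector("list", n_trials)
  rates <- numeric(n_trials)
  psth_counts <- NULL
  duration <- NA_real_
  for (tr in seq_len(n_trials)) {
    e <- exc_gen(tr)
    i <- if (is.null(inh_gen)) NULL else inh_gen(tr)
    drive <- if (mode == "current") {
      if (is.null(i)) as.numeric(e) else as.numeric(e) + as.numeric(i)
    } else {
      list(gE = as.numeric(e),
           gI = if (is.null(i)) numeric(length(e)) else as.numeric(i),
           VE = VE, VI = VI)
    }
    res <- simulate_lif(drive, lif)
    spikes[[tr]] <- res$spike_times
    rates[tr] <- res$rate
    if (is.null(psth_counts)) {
      psth_counts <- numeric(round(res$duration / lif$dt))
      duration <- res$duration
    }
    if (res$n_spikes > 0L) {
      b <- as.integer(round(res$spike_times / lif$dt))
      b <- b[b >= 1L & b <= length(psth_counts)]
      psth_counts[b] <- psth_counts[b] + 1
    }
  }
  out <- list(spike_times = spikes,
              psth = psth_counts / n_trials,
              mean_rate = mean(rates),
              rate_sd = if (n_trials > 1L) sd(rates) else 0,
              rates = rates,
              n_trials = n_trials,
              duration = duration,
              dt = lif$dt)
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "Simulation result: %d trials x %g ms; mean rate %.2f +/- %.2f Hz\n",
    x$n_trials, x$duration, x$mean_rate, x$rate_sd))
  invisible(x)
}

#' Full sustained-stimulus protocol
#'
#' The three-stage procedure for long stimuli: (1) drive a pool of
#' `3 * nI` interneurons with independent excitatory barrages and store
#' their spike trains; (2) per trial, randomly select `round(pI * nI)`
#' trains, sum and convolve them into the inhibitory barrage; (3) deliver
#' a fresh excitatory barrage plus the inhibitory barrage to the reference
#' LIF neuron, repeating over trials.  `pI` is computed from the measured
#' interneuron recruitment (`pI_hat`, `rI`) and the ratio constants,
#' unless supplied.
#'
#' @param params A [network_params()] object.
#' @param duration Stimulus duration (ms).
#' @param n_trials Number of trials.
#' @param lif A [lif_params()] object.
#' @param pI Effective inhibitory probability; `NULL` derives it from the
#'   simulated interneuron pool via the ratio-constant product.
#' @param ramp Linear onset ramp of `pE(t)` (ms); 0 for a step.
#' @param mode `"current"` or `"conductance"`.
#' @param inh_source With a supplied `pI`, `"lif_pool"` runs the full
#'   interneuron-LIF stage while `"poisson"` replaces the stored trains
#'   with Poisson trains at rate `rI` (same first-order statistics, much
#'   cheaper for parameter sweeps).
#' @param seed Optional RNG seed for reproducibility.
#' @return A `sim_result` with extra fields `pI`, `pI_hat`, `rI`
#'   (`NA` when the interneuron stage was skipped because `pI = 0`).
#' @export
run_sustained <- function(params, duration = 1000, n_trials = 100L,
                          lif = lif_params(), pI = NULL, ramp = 20,
                          mode = c("current", "conductance"),
                          inh_source = c("lif_pool", "poisson"),
                          seed = NULL) {
  mode <- match.arg(mode)
  inh_source <- match.arg(inh_source)
  if (inh_source == "poisson" && is.null(pI))
    stop("'poisson' inhibition requires an explicit 'pI'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dt <- lif$dt
  n <- round(duration / dt)
  t_mid <- (seq_len(n) - 0.5) * dt
  prof <- if (ramp > 0) pmin(1, t_mid / ramp) * params$pE else
    rep(params$pE, n)

  if (mode == "current") {
    kE <- synaptic_kernel(params$aE)
    kI <- synaptic_kernel(params$aI)
  } else {
    kE <- synaptic_kernel(0.147, mode = "conductance", V_rev = 0)
    kI <- synaptic_kernel(1.045, mode = "conductance", V_rev = -80)
  }

  pI_hat <- rI <- NA_real_
  trains <- NULL
  need_inh <- (is.null(pI) || pI > 0) && inh_source == "lif_pool"
  if (need_inh && params$pE_to_I > 0 && pi_E_to_I(params) > 0) {
    pool <- simulate_inhibitory_population(params, prof, duration, lif,
                                           synaptic_kernel(params$aE),
                                           dt = dt)
    trains <- pool$trains
    pI_hat <- pool$pI_hat
    rI <- pool$rI
    if (is.null(pI)) {
      r <- ei_ratios(params)
      pI <- compute_effective_pI(pI_hat, r$kn, r$kq, rI / params$rE, r$kEI)
    }
  } else if (is.null(pI)) {
    pI <- 0
  }

  exc_gen <- function(tr)
    generate_sustained_barrage(params, prof, duration, kE, dt)
  inh_gen <- if (pI > 0 && inh_source == "lif_pool") {
    function(tr) {
      b <- build_inhibitory_barrage(trains, params, kI, pI, duration, dt)
      if (mode == "conductance") abs(b) else b
    }
  } else if (pI > 0) {
    # Conditioned-inhibition stand-in: inhomogeneous Poisson events at
    # rate pE(t) * pI * nE * rE * pE_to_R * (qE/qI), so the mean net
    # drive matches the survival-probability theory for any parameters
    # (the bypassed-population recipe of the temporal protocol).
    kIs <- as.numeric(alpha_kernel(kI, dt))
    lam_I <- prof * pI * params$nE * params$rE * params$pE_to_R *
      (params$qE / params$qI) * dt / 1000
    function(tr) {
      counts <- rpois(n, lam_I)
      cpp_counts_to_current(counts, kIs)
    }
  }
  res <- run_trials(exc_gen, if (pI > 0) inh_gen else NULL, lif,
                    n_trials, mode = mode)
  res$pI <- pI
  res$pI_hat <- pI_hat
  res$rI <- rI
  res
}
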