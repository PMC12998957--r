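#' Time-varying stimulus profile
#'
#' Trapezoidal activation profile used by the temporal-profile protocol:
#' silence, a linear 20 ms onset ramp to the steady value, a plateau, a
#' linear offset ramp, and a tail.  The inhibitory profile shares the
#' shape but can be lagged (positive `lag`: inhibition follows
#' excitation).
#'
#' @param steady Steady-state probability in `[0,1]`.
#' @param plateau Plateau duration (ms).
#' @param ramp Ramp duration (ms).
#' @param pre,post Silent padding before and after the stimulus (ms).
#' @param lag Shift applied when evaluating the inhibitory copy (ms),
#'   in `[-2, 2]` by convention.
#' @return A `stimulus_profile` object; evaluate it with
#'   [profile_values()].
#' @export
stimulus_profile <- function(steady, plateau = 100, ramp = 20, pre = 20,
                             post = 60, lag = 0) {
  check_prob(steady, "steady")
  stopifnot(ramp >= 0, plateau >= 0, pre >= 0, post >= 0)
  out <- list(steady = steady, plateau = plateau, ramp = ramp, pre = pre,
              post = post, lag = lag,
              duration = pre + ramp + plateau + ramp + post)
  class(out) <- "stimulus_profile"
  out
}

#' Evaluate a stimulus profile on a time grid
#'
#' @param profile A [stimulus_profile()].
#' @param dt Step (ms).
#' @param lagged Apply the profile's `lag` (for the inhibitory copy).
#' @return Per-bin values over `profile$duration`.
#' @export
profile_values <- function(profile, dt = 0.01, lagged = FALSE) {
  n <- round(profile$duration / dt)
  t <- (seq_len(n) - 0.5) * dt
  if (lagged) t <- t - profile$lag
  up0 <- profile$pre
  dn0 <- profile$pre + profile$ramp + profile$plateau
  v <- numeric(n)
  r <- profile$ramp
  in_up <- t > up0 & t <= up0 + r
  v[in_up] <- (t[in_up] - up0) / r
  v[t > up0 + r & t <= dn0] <- 1
  in_dn <- t > dn0 & t <= dn0 + r
  v[in_dn] <- 1 - (t[in_dn] - dn0) / r
  v * profile$steady
}

#' Temporal firing profiles with controlled E-I magnitude and lag
#'
#' The inhibitory population is bypassed: both excitatory and inhibitory
#' inputs are inhomogeneous Poisson barrages at rates
#' `lambda_E(t) = pE(t) * rE * nE` and
#' `lambda_I(t) = pE(t) * pI(t) * rI * nI` (conditioned inhibition), so
#' the E-I overlap can be varied directly via the steady value and the
#' lag of `pI(t)` relative to `pE(t)`.
#'
#' @param profile A [stimulus_profile()]; its `steady` value is used for
#'   both `pE(t)` and `pI(t)` and its `lag` shifts `pI(t)`.
#' @param params A [network_params()]; the temporal protocol defaults to
#'   `nE = nI = 250`, `rE = rI = 50` Hz.
#' @param lif A [lif_params()] object.
#' @param n_trials Number of trials.
#' @param seed Optional RNG seed.
#' @return A `sim_result` with extra fields `pnet_t` (the predicted
#'   `pE(t) * (1 - pI(t))` trace), `pE_t`, `pI_t`, `profile`, and
#'   `classification` (see [classify_temporal_response()]).
#' @export
run_temporal_profiles <- function(profile,
                                  params = network_params(nE = 250L, nI = 250L,
                                                          rE = 50, rI = 50),
                                  lif = lif_params(), n_trials = 200L,
                                  seed = NULL) {
  stopifnot(inherits(profile, "stimulus_profile"))
  if (abs(profile$lag) > 2)
    stop("lag must lie in [-2, 2] ms", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dt <- lif$dt
  pE_t <- profile_values(profile, dt)
  pI_t <- profile_values(profile, dt, lagged = TRUE)
  n <- length(pE_t)
  kE <- as.numeric(alpha_kernel(synaptic_kernel(params$aE), dt))
  kI <- as.numeric(alpha_kernel(synaptic_kernel(params$aI), dt))
  lamE <- pE_t * params$rE * params$nE * dt / 1000
  lamI <- pE_t * pI_t * params$rI * params$nI * dt / 1000
  exc_gen <- function(tr) cpp_counts_to_current(rpois(n, lamE), kE)
  inh_gen <- function(tr) cpp_counts_to_current(rpois(n, lamI), kI)
  res <- run_trials(exc_gen, inh_gen, lif, n_trials)
  res$pnet_t <- pE_t * (1 - pI_t)
  res$pE_t <- pE_t
  res$pI_t <- pI_t
  res$profile <- profile
  res$classification <- classify_temporal_response(res, profile)
  res
}

#' Classify a temporal response into tonic and transient components
#'
#' Segments the PSTH into onset (30 ms from ramp start), tonic
#' (interior of the plateau) and offset (30 ms from ramp-down start)
#' windows.  The tonic component is the mean rate over the interior and
#' is present when it exceeds the 1 Hz evoked-firing floor.  Transients
#' are peaks, so they are detected on the boxcar-smoothed PSTH
#' (`smooth_ms` window): an onset/offset transient is present when the
#' peak smoothed rate in that window exceeds both the same 1 Hz floor
#' and `transient_factor` times the tonic mean (membrane filtering
#' attenuates the ramp-product transients, so requiring the peak to
#' stand half again above the plateau separates a genuine peak from
#' plateau fluctuations).
#'
#' @param res A `sim_result` holding a PSTH at step `res$dt`.
#' @param profile The [stimulus_profile()] that generated it.
#' @param tonic_min Evoked-firing floor (Hz) for both components.
#' @param transient_factor Required ratio of transient peak to tonic
#'   mean.
#' @param smooth_ms Boxcar width (ms) for the peak-rate estimate.
#' @return List with `onset_peak`, `tonic_rate`, `offset_peak` (Hz),
#'   logical flags `tonic`, `onset`, `offset`, and a `label` among
#'   `"silent"`, `"tonic"`, `"tonic+transient"`, `"transient_only"`.
#' @export
classify_temporal_response <- function(res, profile, tonic_min = 1,
                                       transient_factor = 1.5,
                                       smooth_ms = 2) {
  dt <- res$dt
  w <- max(1L, round(smooth_ms / dt))
  sm <- as.numeric(stats::filter(res$psth, rep(1 / w, w), sides = 2)) /
    dt * 1000 # Hz
  idx <- function(from, to)
    seq(max(1L, round(from / dt)), min(length(sm), round(to / dt)))
  up0 <- profile$pre
  dn0 <- profile$pre + profile$ramp + profile$plateau
  tonic_rate <- sum(res$psth[idx(up0 + 30, dn0)]) /
    length(idx(up0 + 30, dn0)) / dt * 1000
  onset_peak <- max(sm[idx(up0, up0 + 30)], na.rm = TRUE)
  offset_peak <- max(sm[idx(dn0, dn0 + 30)], na.rm = TRUE)
  tonic <- tonic_rate > tonic_min
  thr <- max(transient_factor * tonic_rate, tonic_min)
  onset <- onset_peak > thr
  offset <- offset_peak > thr
  label <- if (!tonic && !onset && !offset) "silent"
    else if (tonic && !onset && !offset) "tonic"
    else if (tonic) "tonic+transient"
    else "transient_only"
  list(onset_peak = onset_peak, tonic_rate = tonic_rate,
       offset_peak = offset_peak, tonic = tonic, onset = onset,
       offset = offset, label = label)
}

#' Analytic interneuron recruitment for sustained stimuli
#'
#' Stand-in for simulating the interneuron pool when resolving the
#' `ffwd_recruit` scaling analytically: the interneuron's own net drive
#' probability equals its afferent drive `pi_E_to_I` (it receives no
#' inhibition), its rate is the combined oscillatory/fluctuation rate at
#' the corresponding mean current, and its firing probability over a
#' stimulus of `duration` ms is `1 - exp(-r * duration/1000)`.
#'
#' @param pi_E_to_I Effective drive `pE * pE_to_I` onto an interneuron.
#' @param params A [network_params()] object.
#' @param lif A [lif_params()] object.
#' @param duration Stimulus duration (ms) for the firing-probability
#'   conversion.
#' @return List with `pI_hat` and `rI` (Hz).
#' @export
analytic_recruit <- function(pi_E_to_I, params, lif = lif_params(),
                             duration = 500) {
  check_prob(pi_E_to_I, "pi_E_to_I")
  i_mean <- pi_E_to_I * params$nE * params$qE * params$rE
  r <- max(osc_rate(i_mean, lif),
           fluct_rate(pi_E_to_I, params, lif))
  list(pI_hat = 1 - exp(-r * duration / 1000), rI = r)
}

#' Gain modulation of a tuned input
#'
#' The afferent probability follows a Gaussian tuning curve
#' `pE(x) = a * exp(-(x - x_center)^2 / (2 * sigma_x^2))` and the circuit
#' transforms it through its I-O function under one of three inhibitory
#' modes: (1) fixed `pI`, (2) `pI` linear in `pE` (`kn = kc * pE`), or
#' (3) `pI` following the interneurons' own I-O curve (`pE_to_I` set per
#' level).  Returns raw and peak-normalised tuning curves plus their
#' full width at half maximum.
#'
#' @param mode Integer 1, 2 or 3.
#' @param levels Per-mode inhibition levels: `pI` values (mode 1), `kc`
#'   values (mode 2) or `pE_to_I` values (mode 3).  Defaults follow the
#'   canonical protocol: `c(0, 0.08, 0.13)`, `c(0, 0.2, 0.4)`,
#'   `c(0.7, 0.8, 0.9)`.
#' @param params A [network_params()] object; `pE` is ignored (the peak
#'   `a` drives the sweep).
#' @param lif A [lif_params()] object.
#' @param a Peak input probability (default 0.35).
#' @param x_center,sigma_x Tuning centre and width (stimulus-feature
#'   units).
#' @param x_grid Stimulus-feature grid.
#' @param simulate Also measure rates by LIF simulation (Poisson
#'   inhibitory trains at the resolved `pI`).
#' @param n_trials,duration Simulation trials and duration (ms) when
#'   `simulate = TRUE`.
#' @param seed Optional RNG seed.
#' @return Data frame with `x`, `pE`, `level`, `pI`, `rate_Hz`
#'   (analytic), optionally `rate_sim_Hz`, `rate_norm`, plus an `fwhm`
#'   attribute (per level, analytic curve).
#' @export
run_tuning <- function(mode = 1L, levels = NULL,
                       params = network_params(), lif = lif_params(),
                       a = 0.35, x_center = 0, sigma_x = 1,
                       x_grid = seq(-3, 3, by = 0.25),
                       simulate = FALSE, n_trials = 20L, duration = 500,
                       seed = NULL) {
  stopifnot(mode %in% 1:3)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(levels))
    levels <- switch(mode, c(0, 0.08, 0.13), c(0, 0.2, 0.4),
                     c(0.7, 0.8, 0.9))
  pE_x <- a * exp(-(x_grid - x_center)^2 / (2 * sigma_x^2))
  rows <- list()
  for (lv in levels) {
    pI_x <- switch(mode,
      rep(lv, length(pE_x)),
      {
        r <- ei_ratios(params)
        compute_effective_pI(params$pI_hat, lv * pE_x, r$kq, r$kr, r$kEI)
      },
      {
        p2 <- update_params(params, pE_to_I = lv)
        r <- ei_ratios(p2)
        vapply(pE_x, function(pe) {
          rec <- analytic_recruit(pe * lv, p2, lif, duration)
          compute_effective_pI(rec$pI_hat, r$kn, r$kq,
                               rec$rI / p2$rE, r$kEI)
        }, numeric(1L))
      })
    pnet <- compute_pnet(pE_x, pI_x)
    i_net <- params$nE * params$qE * params$rE * params$pE_to_R * pnet
    rate <- pmax(osc_rate(i_net, lif), fluct_rate(pnet, params, lif))
    df <- data.frame(x = x_grid, pE = pE_x, level = lv, pI = pI_x,
                     rate_Hz = rate)
    if (simulate) {
      df$rate_sim_Hz <- vapply(seq_along(x_grid), function(i) {
        p <- update_params(params, pE = pE_x[i])
        run_sustained(p, duration = duration, n_trials = n_trials,
                      lif = lif, pI = pI_x[i],
                      inh_source = "poisson")$mean_rate
      }, numeric(1L))
    }
    pk <- max(df$rate_Hz)
    df$rate_norm <- if (pk > 0) df$rate_Hz / pk else 0
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  attr(out, "fwhm") <- vapply(levels, function(lv) {
    y <- out$rate_Hz[out$level == lv]
    curve_fwhm(x_grid, y)
  }, numeric(1L))
  out
}

# Full width at half maximum by linear interpolation; NA when the curve
# never drops below half max inside the grid.
curve_fwhm <- function(x, y) {
  if (max(y) <= 0) return(NA_real_)
  h <- max(y) / 2
  i_pk <- which.max(y)
  left <- right <- NA_real_
  for (i in seq_len(i_pk - 1L))
    if (y[i] < h && y[i + 1L] >= h) {
      left <- x[i] + (h - y[i]) / (y[i + 1L] - y[i]) * (x[i + 1L] - x[i])
      break
    }
  for (i in seq(i_pk, length(y) - 1L))
    if (y[i] >= h && y[i + 1L] < h) {
      right <- x[i] + (h - y[i]) / (y[i + 1L] - y[i]) * (x[i + 1L] - x[i])
      break
    }
  right - left
}

#' Sustained input-output sweep: simulation joined with theory
#'
#' For each grid point the effective `pI` is resolved from the scaling
#' mode, the reference neuron is simulated (Poisson inhibitory trains at
#' the resolved `pI`), and the analytic prediction of
#' [predict_io_curve()] is joined column-wise.
#'
#' @param pE_grid Vector of afferent probabilities.
#' @param scaling A [scaling_mode()] object.
#' @param params,lif Circuit and membrane parameters.
#' @param n_trials,duration Trials and duration (ms) per grid point.
#' @param simulate Skip the simulation columns when `FALSE`.
#' @param onset_rate Firing-onset criterion (Hz) for the `evoked`
#'   column.
#' @param seed Optional RNG seed.
#' @param ... Passed to [resolve_pI()] via [predict_io_curve()].
#' @return Data frame: the [predict_io_curve()] columns plus
#'   `r_sim_Hz`, `r_sim_sd`, and logical `evoked`.
#' @export
run_io_sweep <- function(pE_grid, scaling, params = network_params(),
                         lif = lif_params(), n_trials = 30L,
                         duration = 500, simulate = TRUE,
                         onset_rate = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pred <- predict_io_curve(pE_grid, scaling, params, lif, ...)
  if (simulate) {
    sim <- vapply(seq_along(pE_grid), function(i) {
      p <- update_params(params, pE = pE_grid[i])
      res <- run_sustained(p, duration = duration, n_trials = n_trials,
                           lif = lif, pI = pred$pI[i],
                           inh_source = "poisson")
      c(res$mean_rate, res$rate_sd)
    }, numeric(2L))
    pred$r_sim_Hz <- sim[1L, ]
    pred$r_sim_sd <- sim[2L, ]
    pred$evoked <- pred$r_sim_Hz > onset_rate
  } else {
    pred$evoked <- pred$r_combined_Hz > onset_rate
  }
  pred
}

#' Deterministic small fixtures for unit tests and examples
#'
#' Writes a bundle of small synthetic inputs -- a short excitatory
#' barrage trace, an expected arrival histogram, and a set of interneuron
#' spike trains -- as plain CSV files, regenerated bit-identically from
#' the seed.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named list of file paths.
#' @export
make_fixtures <- function(seed, dir = tempdir()) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- network_params()
  barr <- generate_sustained_barrage(params, params$pE, duration = 400,
                                     dt = 0.05,
                                     kernel = synaptic_kernel(params$aE))
  f1 <- file.path(dir, "barrage.csv")
  write.csv(data.frame(time_ms = seq_along(barr) * 0.05,
                       i_pA = as.numeric(barr)), f1, row.names = FALSE)
  h <- gaussian_arrivals(params$pE, params$nE, dt = 0.1, t_max = 10)
  f2 <- file.path(dir, "arrivals.csv")
  write.csv(data.frame(bin_start_ms = h$mids - h$dt / 2,
                       count = h$counts), f2, row.names = FALSE)
  pool <- simulate_inhibitory_population(params, params$pE, duration = 100,
                                         n_pool = 6L)
  f3 <- file.path(dir, "interneuron_spikes.csv")
  sp <- data.frame(
    cell = rep(seq_along(pool$trains), lengths(pool$trains)),
    time_ms = unlist(pool$trains))
  write.csv(sp, f3, row.names = FALSE)
  meta <- file.path(dir, "fixtures.json")
  jsonlite::write_json(list(seed = seed, pI_hat = pool$pI_hat,
                            rI = pool$rI, n_events = attr(barr, "n_events")),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(list(barrage = f1, arrivals = f2, interneurons = f3,
                 meta = meta))
}
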