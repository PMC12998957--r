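test_that("Gaussian arrival histograms have the right mass and mode", {
  h <- gaussian_arrivals(1, 100L, transmission_prob = 1, t_max = 15)
  expect_equal(sum(h$counts), 100, tolerance = 1e-6)
  expect_equal(h$mids[which.max(h$counts)], 5, tolerance = 0.011)
  h2 <- gaussian_arrivals(0.35, 250L, transmission_prob = 0.8)
  expect_equal(sum(h2$counts), 0.35 * 250 * 0.8, tolerance = 1e-4)
  expect_error(gaussian_arrivals(0.5, 100L, sigma_t = 0), "sigma_t")

  # sampled mode: total count ~ Binomial(nE, pE * p_trans)
  set.seed(401)
  tot <- replicate(2000, sum(gaussian_arrivals(0.6, 100L, sampled = TRUE,
                                               dt = 0.1)$counts))
  mu <- 100 * 0.6
  s2 <- 100 * 0.6 * 0.4
  expect_lt(abs(mean(tot) - mu), 4 * sqrt(s2 / 2000))
  expect_lt(abs(var(tot) - s2), 5 * s2 / sqrt(2000))
})

test_that("probability traces obey the rectified-difference algebra", {
  u <- unit_psp_kernel(default_lif)
  hE <- gaussian_arrivals(0.8, 100L, t_max = 30)
  # no inhibition: p_net is the excitatory trace exactly
  tr0 <- probability_traces(hE, NULL, u, NULL, pE = 0.8)
  expect_equal(tr0$p_net_t, tr0$p_E_t)
  expect_true(all(tr0$p_E_t >= 0 & tr0$p_E_t <= 0.8 + 1e-9))
  # overwhelming inhibition: full rectification to zero
  hI <- gaussian_arrivals(1, 100L, mu_t = 5, t_max = 30)
  trF <- probability_traces(hE, hI, u, u, pE = 0.1, pI = 1)
  expect_true(all(trF$p_net_t >= 0))
  expect_true(all(trF$p_net_t[trF$t > 3] == 0))
  # ratio form equals difference form wherever excitation is present
  tr <- probability_traces(hE, hI, u, u, pE = 0.8, pI = 0.3)
  pos <- tr$p_E_t > 1e-8
  ratio_form <- tr$p_E_t[pos] * (1 - tr$p_I_t[pos] / tr$p_E_t[pos])
  expect_equal(pmax(0, ratio_form), tr$p_net_t[pos], tolerance = 1e-12)
  # un-normalised kernels are rejected
  expect_error(probability_traces(hE, NULL, u * 0.7, NULL, pE = 0.5),
               "peak-normalised")
})

test_that("threshold crossing is the exact binomial tail", {
  expect_equal(threshold_crossing(0, 100L, 60L), 0)
  expect_equal(threshold_crossing(1, 100L, 60L), 1)
  expect_error(threshold_crossing(0.5, 100L, 0L), "n_theta")
  # Monte-Carlo oracle at nE = 100
  set.seed(402)
  for (pp in c(0.55, 0.6, 0.65)) {
    mc <- mean(rbinom(2e5, 100L, pp) >= 60L)
    expect_lt(abs(threshold_crossing(pp, 100L, 60L) - mc), 0.005)
  }
  # monotone in the drive
  g <- seq(0, 1, by = 0.01)
  expect_true(all(diff(threshold_crossing(g, 100L, 60L)) >= 0))
  # normal approximation is close in the transition region
  expect_equal(threshold_crossing(0.6, 100L, 60L, approx = "normal"),
               threshold_crossing(0.6, 100L, 60L), tolerance = 0.02)
})

test_that("first-spike hazard construction matches closed forms", {
  z <- first_spike_probability(numeric(50))
  expect_equal(z$pf, 0)
  expect_equal(z$p_fire_t, numeric(50))
  # constant hazard: geometric f and pf = 1 - (1-h)^K
  h <- rep(0.03, 200)
  fs <- first_spike_probability(h)
  expect_equal(fs$p_fire_t, 0.03 * 0.97^(0:199), tolerance = 1e-12)
  expect_equal(fs$pf, 1 - 0.97^200, tolerance = 1e-12)
  # sum of first-spike probabilities never exceeds 1
  set.seed(403)
  for (i in 1:20) {
    fs <- first_spike_probability(runif(500, 0, 0.2))
    expect_lte(fs$pf, 1)
    expect_true(all(fs$p_fire_t >= 0))
  }
  # conditional crossing hazards: product construction recovers the
  # running maximum of the crossing trace
  h <- c(seq(0, 0.8, length.out = 50), seq(0.8, 0.2, length.out = 50))
  fs2 <- first_spike_probability(crossing_hazard(h))
  expect_equal(fs2$pf, max(h), tolerance = 1e-12)
  expect_equal(cumsum(fs2$p_fire_t), cummax(h), tolerance = 1e-12)
})

test_that("predicted transient response matches the LIF Monte-Carlo oracle", {
  p <- params_transient # pE = 0.95, Fig-6A-like configuration
  pred <- predict_transient(p, default_lif)
  expect_equal(pred$n_theta, 60L)
  set.seed(404)
  sim <- simulate_transient_trials(p, default_lif, n_trials = 400L)
  se <- sqrt(max(sim$pf * (1 - sim$pf), 0.25 / sim$n_trials) / sim$n_trials)
  expect_lt(abs(pred$pf - sim$pf), 3 * se + 0.01)
  # first-spike timing: means within 0.2 ms, output narrower than the
  # 1 ms input jitter
  mp <- pmf_moments(pred$t, pred$p_fire_t)
  fs <- sim$first_spike_times[!is.na(sim$first_spike_times)]
  expect_lt(abs(mp$mean - mean(fs)), 0.2)
  expect_lt(mp$sd, 1)
  expect_lt(sd(fs), 1)
  # overlay claim: normalized RMS error < 15% of the PSTH peak (0.25 ms
  # comparison bins)
  a <- rebin(pred$p_fire_t, 25L)
  b <- rebin(sim$psth_first, 25L)
  expect_lt(sqrt(mean((a - b)^2)) / max(b), 0.15)

  # intermediate drive: pf still agrees
  p2 <- update_params(p, pE = 0.65)
  pred2 <- predict_transient(p2, default_lif)
  set.seed(405)
  sim2 <- simulate_transient_trials(p2, default_lif, n_trials = 400L)
  se2 <- sqrt(sim2$pf * (1 - sim2$pf) / sim2$n_trials)
  expect_lt(abs(pred2$pf - sim2$pf), 4 * se2 + 0.02)
})

test_that("pf is nonincreasing in pI at fixed pE", {
  p <- params_transient
  pfs <- vapply(c(0, 0.15, 0.3, 0.45), function(piv)
    predict_transient(update_params(p, pE = 0.65), default_lif,
                      pI = piv)$pf, numeric(1))
  expect_true(all(diff(pfs) <= 0))
})

test_that("transient I-O families shift, collapse and modulate as claimed", {
  p <- network_params(nE = 100L, nI = 20L, pE_to_I = 0.8)
  grid <- seq(0.35, 1, by = 0.05)
  # uninhibited baseline is monotone nondecreasing
  base <- transient_io_curve(grid, scaling_mode("fixed_pI", pi_fixed = 0),
                             p, default_lif)
  expect_true(all(diff(base$pf_pred) >= -1e-9))
  # fixed-pI family: rightward shift, collapse after threshold alignment
  pfm <- sapply(c(0, 0.25, 0.5), function(piv)
    transient_io_curve(grid, scaling_mode("fixed_pI", pi_fixed = piv), p,
                       default_lif)$pf_pred)
  al <- align_io_curves(grid, pfm, threshold = 0.05)
  expect_true(all(diff(al$shifts) > 0))
  xs <- seq(0, 0.2, by = 0.01)
  dev <- max(abs(al$aligned(xs, 1) - al$aligned(xs, 2)),
             abs(al$aligned(xs, 1) - al$aligned(xs, 3)), na.rm = TRUE)
  expect_lt(dev, 0.1)
  # linear recruitment: rightward shift with unchanged slope (collapse)
  pfl <- sapply(c(0, 0.4, 0.8), function(kc)
    transient_io_curve(grid, scaling_mode("linear_kc", kc = kc), p,
                       default_lif)$pf_pred)
  all_ <- align_io_curves(grid, pfl, threshold = 0.05)
  expect_true(all(diff(all_$shifts) > 0))
  devl <- max(abs(all_$aligned(xs, 1) - all_$aligned(xs, 3)), na.rm = TRUE)
  expect_lt(devl, 0.1)
  # feedforward recruitment: constant threshold, stronger recruitment
  # suppresses the saturated branch
  p_r <- update_params(p, nI = 100L)
  pfr <- sapply(c(0.85, 1), function(kp)
    transient_io_curve(grid, scaling_mode("ffwd_recruit", kp = kp), p_r,
                       default_lif)$pf_pred)
  alr <- align_io_curves(grid, pfr, threshold = 0.05)
  expect_lt(abs(diff(alr$shifts)), 0.02)
  hi <- grid >= 0.75
  expect_true(all(pfr[hi, 2] <= pfr[hi, 1] + 1e-9))
  expect_lt(min(pfr[hi, 2]), min(pfr[hi, 1]))
})

test_that("conductance-mode transient retains prediction accuracy", {
  p <- params_transient
  pred <- predict_transient(p, default_lif)
  set.seed(406)
  sim <- simulate_transient_trials(p, default_lif, n_trials = 300L,
                                   mode = "conductance")
  expect_lt(abs(pred$pf - sim$pf), 0.03)
  fs <- sim$first_spike_times[!is.na(sim$first_spike_times)]
  expect_lt(sd(fs), 1) # narrower than the input jitter
  mp <- pmf_moments(pred$t, pred$p_fire_t)
  expect_lt(abs(mp$mean - mean(fs)), 0.5)
})
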