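test_that("compute_pnet matches its limits and the Monte-Carlo oracle", {
  expect_equal(compute_pnet(0.35, 0), 0.35)
  expect_equal(compute_pnet(0.7, 1), 0)
  expect_equal(compute_pnet(0.5, 0.5), 0.25)

  # oracle: Bernoulli EPSP occurrences cancelled by independent coincident
  # IPSPs; the surviving fraction estimates pE*(1-pI)
  set.seed(101)
  n <- 1e6
  surv <- mean(rbinom(n, 1L, 0.5) * (1L - rbinom(n, 1L, 0.5)))
  expect_lt(abs(surv - 0.25), 4 * sqrt(0.25 * 0.75 / n))

  expect_error(compute_pnet(1.2, 0.5), "pE")
  expect_error(compute_pnet(0.5, -0.1), "pI")
})

test_that("binomial cancellation oracle agrees with n*pnet within 4 SE", {
  set.seed(102)
  n <- 1e5
  for (pp in list(c(0.35, 0.46), c(0.8, 0.2), c(0.5, 0.9))) {
    pnet <- compute_pnet(pp[1], pp[2])
    count <- sum(rbinom(n, 1L, pp[1]) * (1L - rbinom(n, 1L, pp[2])))
    se <- sqrt(n * pnet * (1 - pnet))
    expect_lt(abs(count - n * pnet), 4 * se)
  }
})

test_that("effective pI is the ratio product and rejects products above 1", {
  expect_equal(compute_effective_pI(1, 0.2, 1, 2.3, 1), 0.46)
  expect_equal(compute_effective_pI(0.9, 0, 1, 3, 1), 0)
  expect_equal(compute_effective_pI(0.5, 0.4, 1, 2, 1), 0.4)
  err <- expect_error(compute_effective_pI(1, 0.8, 1, 2.3, 1),
                      "exceeds 1")
  expect_match(conditionMessage(err), "kr") # names the offending factor
  expect_error(compute_effective_pI(1, -0.1, 1, 1, 1), "finite and >= 0")
})

test_that("mean currents follow the rate-charge products of the circuit", {
  p <- network_params(pE = 0.35, pE_to_R = 1, nE = 250L, qE = 0.0557,
                      rE = 50, nI = 10L, rI = 115)
  mc <- mean_currents(p)
  expect_equal(mc$iE_to_R, 0.35 * 250 * 0.0557 * 50, tolerance = 1e-12)
  expect_equal(mc$iE_to_R, 243.6875)
  # the two factorizations of the inhibitory drive agree
  expect_lt(attr(mc, "factorization_reldiff"), 1e-9)
  # barrage time-average oracle (30 s; SE of the mean < 0.5%)
  set.seed(103)
  b <- generate_sustained_barrage(p, 0.35, 30000, synaptic_kernel(10.3))
  expect_lt(abs(mean(b) - mc$iE_to_R) / mc$iE_to_R, 0.02)

  expect_equal(mean_currents(update_params(p, pE = 0))$i_net, 0)
  mc0 <- mean_currents(p, pI = 0)
  expect_equal(mc0$i_net, mc0$iE_to_R)
})

test_that("pnet curves: fixed-pI slope, linear-mode maximum, monotonicity", {
  grid <- seq(0, 1, by = 0.05)
  # fixed pI: linear with slope (1 - pI) to 1e-12
  y <- pnet_curve(grid, scaling_mode("fixed_pI", pi_fixed = 0.75))
  expect_equal(unname(coef(lm(y ~ grid))[2]), 0.25, tolerance = 1e-12)
  expect_equal(pnet_curve(0.4, scaling_mode("fixed_pI", pi_fixed = 0.75)),
               0.1)
  # linear mode kc = 1: global max 1/(4 kc) at pE = 1/(2 kc)
  y1 <- pnet_curve(grid, scaling_mode("linear_kc", kc = 1))
  expect_equal(max(y1), 0.25)
  expect_equal(grid[which.max(y1)], 0.5)
  # kc = 0 reduces to the identity
  expect_equal(pnet_curve(grid, scaling_mode("linear_kc", kc = 0)), grid)
  # strictly increasing on [0,1] iff kc <= 0.5
  for (kc in c(0.2, 0.5, 0.6, 0.9)) {
    y <- pnet_curve(grid, scaling_mode("linear_kc", kc = kc))
    expect_identical(all(diff(y) > 0), kc <= 0.5, label = paste("kc =", kc))
  }
  # output always within [0,1]
  set.seed(104)
  for (i in 1:20) {
    y <- compute_pnet(runif(50), runif(50))
    expect_true(all(y >= 0 & y <= 1))
  }
})

test_that("conductance correction is divisive in the leak share", {
  expect_equal(conductance_correction(243.7, 0), 243.7)
  g_leak <- 1000 / default_lif$R
  expect_equal(conductance_correction(243.7, g_leak), 243.7 / 2)
  expect_error(conductance_correction(100, -1), "nonnegative")
  # monotone: more conductance, less effective drive
  g <- seq(0, 20, by = 2)
  expect_true(all(diff(conductance_correction(243.7, g)) < 0))
  # strategy hook
  expect_equal(conductance_correction(100, 5, strategy = function(i, g, gl) i),
               100)
})

test_that("parameter validation and config round-trip", {
  expect_error(network_params(pE = 1.5), "pE")
  expect_error(network_params(aI = 5), "aI")
  expect_error(network_params(nE = 0), "nE")
  expect_error(lif_params(tau_m = 12), "inconsistent")
  expect_error(lif_params(V_theta = -80), "V_theta")
  expect_equal(ei_ratios(network_params())$kn, 0.2)
  expect_equal(pi_E_to_I(network_params(pE = 0.5, pE_to_I = 0.8)), 0.4)

  f <- tempfile(fileext = ".json")
  p <- network_params(pE = 0.42, nI = 30L, rI = 80)
  write_config(p, f)
  p2 <- read_config(f)
  expect_equal(unclass(p2), unclass(p))
  l <- lif_params(dt = 0.02)
  write_config(l, f)
  expect_equal(unclass(read_config(f)), unclass(l))
})
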