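---
title: "Probabilistic E-I balance in feedforward inhibitory circuits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic E-I balance in feedforward inhibitory circuits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(einet)
```

## The circuit and the survival probability of excitation

A feedforward inhibitory circuit routes a common pool of `nE` excitatory
afferents onto a reference neuron and onto `nI` local interneurons, which in
turn inhibit the reference neuron.  During a stimulus each afferent is active
with probability `pE`; an excitatory event reaches the reference cell with
transmission probability `pE_to_R` and an interneuron with `pE_to_I`.
Because the inhibition a stimulus evokes is contingent on the same afferent
drive, excitation and inhibition largely cancel rather than add: the
probability that an excitatory input occurs *and survives* coincident
inhibition is

    pnet = pE * (1 - pI),

with `pI` the *effective* probability that an inhibitory input reaches the
reference cell.  `pI` folds the circuit's bookkeeping into one number,

    pI = pI_hat * kn * kq * kr * kEI,

where `pI_hat` is the probability an interneuron fires during the stimulus,
`kn = nI/nE`, `kq = |qI/qE|` (unitary charge ratio), `kr = rI/rE` (rate
ratio) and `kEI = pI_to_R/pE_to_R` (synaptic reliability ratio).  A product
above 1 is not a probability; `compute_effective_pI()` treats it as a
misparameterised network and raises an error rather than clipping, which
would silently mask the problem.  `pi_E_to_I()` is always derived as
`pE * pE_to_I` and never stored, so it cannot drift out of sync with its
factors.

Mean steady-state currents are rate-charge products
(`mean_currents()`): `iE_to_R = pE * pE_to_R * nE * qE * rE`, and the net
drive `i_net = nE * qE * rE * pE_to_R * pnet`.  The two factorizations of
the inhibitory drive (via the interneuron population, or via `pI` and the
excitatory base current) agree identically under the ratio definitions and
are checked to a relative 1e-9.

## The neuron model and its units

Neurons are leaky integrate-and-fire (LIF) units,
`C dV/dt = -(V - V_l)/R + i_syn`, integrated by forward Euler at
`dt = 0.01` ms, with a spike registered when the updated voltage reaches
`V_theta` and an immediate reset to `V_l` (no refractory period).  Internal
units are ms, mV, pA, nS, pF and MOhm, which are mutually consistent
(`pA * MOhm = uV`, `MOhm * pF / 1000 = ms`); `lif_params()` enforces
`tau_m = R*C` to 1%.  Defaults: `R = 75` MOhm, `tau_m = 10` ms,
`C = 133` pF, `V_l = -70` mV, `V_theta = -55` mV, hence a rheobase of
200 pA.

Unitary synaptic events are alpha functions
`a * (t/tau) * exp(1 - t/tau)` with `tau = 2` ms, truncated at 15 ms
(7.5 tau).  The truncation is deliberate: it reproduces the tabulated
unitary charge `qE = 0.0557` pC, whereas the untruncated closed form
`a * tau * e` gives 0.0560 pC.  Filtering the unitary 10.3 pA EPSC through
the membrane gives a PSP peaking at ~251 uV about 6.7 ms after onset
(`psp_peak()`); conductance-mode synapses (0.147 nS excitatory at 0 mV,
1.045 nS inhibitory at -80 mV) produce the same ~250 uV deflections at
rest.

## Sustained stimuli

`generate_sustained_barrage()` draws per-bin Poisson event counts at total
rate `nE * pE(t) * rE * transmission` — counts, not Bernoulli, so several
events may share a 0.01 ms bin — and superposes the unitary kernel.  The
three-stage protocol (`run_sustained()`) simulates `3*nI` interneurons,
stores their spike trains, and per trial selects a uniform random subset of
`round(pI * nI)` trains (round half up) to sum and convolve into the
inhibitory barrage; `pI` is computed from the *measured* recruitment
(`pI_hat`, `rI`) unless supplied.

For parameter sweeps a cheaper inhibition source is provided
(`inh_source = "poisson"`): inhomogeneous Poisson inhibitory events at rate
`pE(t) * pI * nE * rE * pE_to_R * (qE/qI)`.  This is the bypassed-population
recipe of the temporal-profile protocol, and it is used for sweeps because
it reproduces the conditioned mean — simulated net drive equal to
`i_net(pnet)` — for *any* parameter combination, whereas the literal
stored-train subset matches that mean only when `kn*kq*kr` happens to equal
`pE` (which the canonical calibration satisfies).

### Analytic input-output theory

Above rheobase the rate follows the deterministic LIF f-I relation
(`osc_rate()`).  Below it, firing is fluctuation-driven: `fluct_rate()`
models the count `X` of surviving EPSPs in an integration window as Poisson
and returns `Pr(X >= n_theta) * r_rh` using the exact Poisson tail.  Three
stand-ins deserve emphasis, all exposed as parameters:

* `n_theta` — the threshold count, `ceiling((V_theta - V_l)/PSP peak)`,
  60 at defaults.
* `r_rh` — the rate at oscillatory onset.  A pure LIF has rate 0 at
  rheobase (logarithmic divergence), so the package uses the oscillatory
  rate at `1.05 * irh` (~32.8 Hz).  This is the module's largest
  approximation.
* the window — chosen as `n_theta * qE / irh` (~16.7 ms), the time rheobase
  current needs to deliver `n_theta` unitary charges.  This anchors
  `Pr(X >= n_theta) = 1/2` exactly at the rheobase crossing, so the
  fluctuation branch saturates near the oscillatory onset.  A plain
  one-membrane-time-constant window (10 ms) instead centres the sigmoid at
  about 1.7x the rheobase drive, leaving the sub-oscillatory branch
  essentially zero everywhere it is needed.

The combined prediction (`predict_io_curve()`) takes the larger of the two
rates per grid point.  Against full simulations with conditioned Poisson
inhibition the combined curve stays within a few percent of the peak rate
across fixed-`pI` families (measured 2-6% mean absolute error for
`pI` up to 0.6); the count model underestimates genuinely noise-dominated
configurations, which is a known limitation of a threshold-count stand-in
(no diffusion-approximation rate is attempted by design).

One structural consequence of cancellation-type inhibition: in the
linear-recruitment family `pI = kc*pE`, the firing-onset probability obeys
`pE*(1 - kc*pE) = const`, which has no `kc`-invariant root.  The measured
onset therefore spreads by about 0.06 across `kc` in [0, 1], and the
corresponding regression test asserts a 0.1 bound rather than the 0.05 one
might hope for from eyeballing published I-O figures.

### Conductance correction

Linear current summation fails when synaptic conductance loads the
membrane.  `conductance_correction()` rescales the net drive by the leak's
share of the total conductance, `g_l / (g_l + g_syn)` — exact for the
steady-state voltage of a conductance-clamped membrane, approximate for
fluctuating barrages — and accepts alternative forms through a strategy
function.  In conductance-mode sweeps this roughly halves the
analytic-versus-simulated rate error; it over-corrects at high rates
because the time-averaged driving force exceeds its resting value once the
neuron spends time near threshold.

## Brief stimuli and first-spike prediction

For a brief stimulus each afferent fires once, with Gaussian arrival-time
jitter (`mu_t = 5` ms, `sigma_t = 1` ms).  The predictor
(`predict_transient()`) works in per-afferent probability space:

1. `gaussian_arrivals()` gives the expected arrival histogram
   `pE * nE * N(mu_t, sigma_t^2)`.
2. Convolving the arrival *density* with the peak-normalised unitary PSP
   shape (`unit_psp_kernel()`: the alpha current filtered by the membrane,
   then scaled to peak 1) yields `ptilde_E(t)`, the probability that a
   participating afferent's input is "effectively present" at `t`; the
   excitatory trace is `pE * ptilde_E(t)`.
3. The interneuron stage is predicted with the same machinery at drive
   `pE * pE_to_I`; its first-spike distribution provides both the
   recruitment probability `pI_hat` and the *conditional* inhibitory timing
   density.  Conditioning mirrors the estimation of inhibitory timing from
   trials in which inhibition occurred, so no extra factor of `pE` enters
   the inhibitory trace.  In fixed-`pI` protocols the magnitude is the
   control variable and only the timing comes from this stage; the
   conditional density therefore remains in use even when `pI_hat` is
   tiny.
4. The net drive is the rectified difference
   `ptilde_net(t) = max(0, pE*ptilde_E - pI*ptilde_I)`; rectification lives
   here, not in the steady-state algebra, because only the difference form
   can go negative.  For brief stimuli the amplitude ratio `ka = |aI/aE|`
   replaces the charge ratio in the `pI` product and the rate ratio is 1
   (every cell fires at most once).
5. `threshold_crossing()` turns the net drive into
   `Pr(Binomial(nE, ptilde_net) >= n_theta)` with the exact tail (a normal
   approximation is available behind a flag).
6. `first_spike_probability()` applies the hazard product
   `f_k = h_k * prod_{j<k}(1 - h_j)`, honouring the one-spike constraint.

Step 6 needs care about what counts as a hazard.  The raw crossing trace is
the probability of being above threshold *at* an instant; treating each
0.01 ms bin as an independent chance to fire lets thousands of bins
accumulate, which in validation placed the predicted first-spike mass about
0.4 ms early and inflated `pf` at intermediate drive.  The package instead
converts the trace to conditional first-crossing hazards
(`crossing_hazard()`): under the nested-trajectory reading — trials with
stronger input are above threshold whenever weaker ones are — the
probability of having crossed by `t` is the running maximum of the trace,
and the hazard is its conditional increment.  The product construction then
gives `p_fire_t = diff(cummax(h))` and `pf = max(h)`.  With this reading
the predictor matches the event-level Monte-Carlo oracle
(`simulate_transient_trials()`) to within Monte-Carlo error across the I-O
curve, and the predicted and simulated first-spike time distributions agree
in their means to ~0.01 ms, both several-fold narrower than the 1 ms input
jitter.

## Temporal profiles

To decouple inhibitory timing from interneuron biophysics, the
temporal-profile protocol (`run_temporal_profiles()`) bypasses the
interneurons: excitatory and inhibitory events are inhomogeneous Poisson
barrages at `lambda_E(t) = pE(t) * rE * nE` and
`lambda_I(t) = pE(t) * pI(t) * rI * nI`, with both probability profiles
trapezoids (20 ms linear ramps) and the inhibitory copy laggable by
-2..+2 ms.  The predicted overlay is `pnet(t) = pE(t)(1 - pI(t))`; its ramp
product peaks at 0.25 mid-ramp, which is *sub-rheobase* at the canonical
parameters, so onset/offset transients are fluctuation-driven and strongly
attenuated by the 10 ms membrane (the ramp product lasts only ~10 ms).
`classify_temporal_response()` therefore detects transients on a
2-ms-smoothed PSTH *peak* — a mean over a 30 ms window would dilute them —
requiring the peak to exceed the 1 Hz evoked-firing floor (the same floor
used for I-O onset detection) and 1.5x the tonic mean.  At steady
probabilities 0.5 / 0.75 / 1.0 this reproduces the tonic-only /
tonic-plus-transient / transient-only regime map; the transient-only peaks
are real but small (a few Hz).

## Gain modulation of tuned input

`run_tuning()` drives the circuit with a Gaussian tuning profile
`pE(x) = a * exp(-(x - x_c)^2 / (2 sigma_x^2))` (peak `a = 0.35`) under
three inhibitory modes: fixed `pI` (0, 0.08, 0.13), linear recruitment
(`kn = kc*pE`, `kc` = 0, 0.2, 0.4), and feedforward recruitment (`pE_to_I`
= 0.7, 0.8, 0.9), where `pI` follows the interneurons' own I-O function via
`analytic_recruit()` (combined-rate prediction plus
`pI_hat = 1 - exp(-r T / 1000)` over the stimulus duration).  The control
peak is ~58-60 Hz.  Mode-2 normalized curves superimpose on *simulated*
tuning curves; the analytic stand-in's fluctuation sigmoid is steeper than
real shot-noise firing, so its normalized flanks deviate — a documented
limitation, and the reason the superposition test runs on simulation.  With
a large peak input (`a = 0.8`) mode 3 produces the central dip / bimodal
tuning expected when the peak drives the non-monotonic branch.

## What the synthetic world does and does not establish

All inputs are generated: Poisson barrages, Gaussian arrival jitter and LIF
interneurons at the parameter values tabulated for the canonical circuit
(250 afferents at 50 Hz, 50 interneurons, 10.3 pA / 0.0557 pC unitary
events, and the membrane constants above).  Green tests establish internal
consistency — probability algebra against binomial/Monte-Carlo oracles,
simulator against closed-form LIF results, predictors against event-level
simulation — under homogeneous synaptic amplitudes, exactly coincident
cancellation statistics, no recurrence, no background activity and no
synaptic plasticity.  They do not establish anything about heterogeneous
amplitude distributions, dendritic interactions, or real recordings.

## Numerical choices

* Forward Euler at `dt = 0.01` ms; spike test after the update; reset with
  no refractory period.  At 2x rheobase the simulated interspike interval
  matches `tau_m * log 2` to <0.5%.
* Kernel truncation at 15 ms (see above); kernels sampled at `dt` with an
  error if `dt > tau/10`, and a warning below 5 tau of support.
* Event superposition by direct kernel addition in C++ (sparse events beat
  FFT in every protocol here); probability-trace convolutions by FFT with
  negative ringing clamped at 0.
* Exact Poisson and binomial tails throughout; the normal approximation to
  the crossing probability exists only behind a flag.
* Subset sizes use round-half-up, pinning down the "approximately
  `pI * nI`" selection rule.
* Reproducibility: every runner takes a seed; identical seeds give
  bit-identical spike times.

## Known limitations

* The fluctuation-regime rate is a threshold-count stand-in; it
  underestimates firing when voltage noise, not count noise, dominates.
  `r_rh`, `n_theta` and the window are explicit knobs.
* The conductance correction is a steady-state argument applied to a
  fluctuating process; it over-corrects at high rates.
* Transient-regime rightward shifts under fixed `pI` are modest because
  interneurons share the reference cell's threshold and therefore fire
  after it; circuits with more excitable interneurons would shift more.
* The interneuron pool is integrated with current-mode synapses even when
  the reference cell runs in conductance mode; the pool only contributes
  spike trains and recruitment statistics.
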