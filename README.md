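# einet

Probabilistic excitation–inhibition balance in feedforward inhibitory
circuits: a tested leaky integrate-and-fire (LIF) simulator plus analytic
predictors for firing rates and first-spike probabilities.

## The problem

In sensory pathways a common motif routes the same excitatory afferents
onto a principal ("reference") neuron and onto local interneurons that
inhibit it. Because stimulus-evoked inhibition is contingent on the same
drive, excitation and inhibition largely *cancel*, and the neuron's
input–output (I–O) curve, gain and temporal firing pattern are set by how
the inhibitory probability co-varies with the excitatory one. This package
implements a probabilistic account of that interaction for computational
neuroscientists who want to simulate the circuit, predict its behaviour
analytically, and test the two against each other.

The core quantity is the survival probability of excitation,

```
pnet = pE (1 − pI),        pI = p̂I · kn · kq · kr · kEI
```

where `pE` is the probability a stimulus activates an afferent and the
effective inhibitory probability `pI` collects interneuron recruitment
(`p̂I`), the interneuron-to-afferent ratio `kn = nI/nE`, the unitary
charge ratio `kq = |qI/qE|` (amplitude ratio `ka` for brief stimuli), the
rate ratio `kr = rI/rE`, and synaptic reliability `kEI`. Mean currents are
rate–charge products, e.g. `i̅net = nE qE rE pE→R pnet`. Above rheobase
the rate follows the deterministic LIF f–I relation; below it a Poisson
threshold-count model supplies the fluctuation-driven branch, and the
predicted rate is the larger of the two. For brief stimuli the package
convolves Gaussian arrival-time histograms with peak-normalised unitary
PSPs, rectifies the E–I difference, and converts the binomial
threshold-crossing trace into a first-spike probability under the
fire-once constraint.

## A worked example

```r
library(einet)
lif <- lif_params()            # R = 75 MΩ, τm = 10 ms, threshold −55 mV
p   <- network_params(pE = 0.35)

compute_effective_pI(1, kn = 0.2, kq = 1, kr = 2.3, kEI = 1)
#> [1] 0.46

mean_currents(p, pI = 0)$i_net # pA: 0.35 · 250 · 0.0557 pC · 50 Hz
#> [1] 243.6875

osc_rate(243.6875, lif)        # analytic oscillatory rate at that drive
#> [1] 58.17929

res <- run_sustained(p, duration = 1000, n_trials = 100, lif = lif,
                     pI = 0, ramp = 0, seed = 1)
res$mean_rate                  # simulated control rate, 100 × 1 s trials
#> [1] 55.79
```

The analytic 58.2 Hz and simulated 55.8 Hz bracket the canonical ~60 Hz
control rate; the simulated value sits a few percent below the
deterministic one because shot noise interacts with the concave f–I
curve. A transient (brief-stimulus) example:

```r
pt <- network_params(nE = 100, nI = 20, pE = 0.95, pE_to_I = 0.8)
pred <- predict_transient(pt, lif)
pred$pf                        # predicted probability of firing ≥ once
#> [1] 1
sim <- simulate_transient_trials(pt, lif, n_trials = 1000, seed = 1)
sim$pf                         # Monte-Carlo oracle agrees
#> [1] 1
```

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/einet.R", package="einet"))')" \
  simulate-sustained --trials 100 --seed 1 --pI 0 --out out/
```

Subcommands: `simulate-sustained`, `io-curve`, `tuning`, `temporal`,
`transient`, `fixtures`. Outputs are CSVs with a JSON metadata sidecar.

## Scope

Feedforward circuits only: no recurrence, no synaptic plasticity, no
background activity, homogeneous unitary amplitudes. See the methods
vignette (`vignettes/ei-balance-methods.Rmd`) for the model assumptions,
the stand-ins used in the fluctuation-regime and first-spike predictors,
and known limitations.
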