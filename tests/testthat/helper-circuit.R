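# Shared fixtures: canonical parameter sets and small utilities.

default_lif <- lif_params()

# Reference-network defaults (sustained protocols)
params_sustained <- network_params(pE = 0.35)

# Brief-stimulus network (transient protocols)
params_transient <- network_params(nE = 100L, nI = 20L, pE = 0.95,
                                   pE_to_I = 0.8)

# Sum adjacent bins: coarsen a per-bin trace by an integer factor.
rebin <- function(x, f) {
  n <- (length(x) %/% f) * f
  colSums(matrix(x[seq_len(n)], nrow = f))
}

# Mean and SD of a (sub)probability mass function over times t.
pmf_moments <- function(t, p) {
  w <- p / sum(p)
  m <- sum(t * w)
  list(mean = m, sd = sqrt(sum((t - m)^2 * w)))
}
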