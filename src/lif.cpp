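#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of a current-driven LIF neuron.
//
// Internal units: ms, mV, pA, MOhm.  R * i is in microvolts (pA * MOhm),
// hence the 1e-3 factor to obtain mV.  The threshold test runs after the
// voltage update; on a spike the membrane is reset to V_l in the same step
// (no absolute refractory period).
//
// [[Rcpp::export]]
List cpp_lif_current(NumericVector drive, double dt, double R, double tau_m,
                     double V_l, double V_theta, bool record_v) {
  const int n = drive.size();
  NumericVector v_out;
  if (record_v) v_out = NumericVector(n);
  std::vector<double> spikes;
  double V = V_l;
  const double k = dt / tau_m;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(drive[i]))
      stop("non-finite input drive at step %d", i + 1);
    V += k * (-(V - V_l) + R * drive[i] * 1e-3);
    if (V >= V_theta) {
      spikes.push_back((i + 1) * dt);
      V = V_l;
    }
    if (record_v) v_out[i] = V;
  }
  List out = List::create(_["spike_times"] = wrap(spikes),
                          _["V"] = record_v ? (SEXP)v_out : R_NilValue);
  return out;
}

// Conductance-mode LIF: synaptic currents g * (V_rev - V) with g in nS and
// V in mV, giving pA directly.
//
// [[Rcpp::export]]
List cpp_lif_conductance(NumericVector gE, NumericVector gI, double VE,
                         double VI, double dt, double R, double tau_m,
                         double V_l, double V_theta, bool record_v) {
  const int n = gE.size();
  if (gI.size() != n) stop("gE and gI must have equal length");
  NumericVector v_out;
  if (record_v) v_out = NumericVector(n);
  std::vector<double> spikes;
  double V = V_l;
  const double k = dt / tau_m;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(gE[i]) || !R_finite(gI[i]))
      stop("non-finite conductance at step %d", i + 1);
    double i_syn = gE[i] * (VE - V) + gI[i] * (VI - V); // pA
    V += k * (-(V - V_l) + R * i_syn * 1e-3);
    if (V >= V_theta) {
      spikes.push_back((i + 1) * dt);
      V = V_l;
    }
    if (record_v) v_out[i] = V;
  }
  List out = List::create(_["spike_times"] = wrap(spikes),
                          _["V"] = record_v ? (SEXP)v_out : R_NilValue);
  return out;
}

// Superpose a sampled synaptic kernel at integer event bins (1-based, may
// repeat for multiple events per bin).  Direct summation beats FFT here
// because transient windows hold few events.
//
// [[Rcpp::export]]
NumericVector cpp_events_to_current(IntegerVector event_bins, int n_bins,
                                    NumericVector kernel) {
  NumericVector out(n_bins);
  double *o = REAL(out);
  const double *k = REAL(kernel);
  const int m = kernel.size();
  for (int e = 0; e < event_bins.size(); ++e) {
    int b = event_bins[e] - 1;
    if (b < 0 || b >= n_bins) continue;
    int jmax = std::min(m, n_bins - b);
    double *ob = o + b;
    for (int j = 0; j < jmax; ++j) ob[j] += k[j];
  }
  return out;
}

// Superpose a kernel weighted by per-bin event counts (Poisson barrages).
//
// [[Rcpp::export]]
NumericVector cpp_counts_to_current(IntegerVector counts,
                                    NumericVector kernel) {
  const int n = counts.size(), m = kernel.size();
  NumericVector out(n);
  double *o = REAL(out);
  const double *k = REAL(kernel);
  const int *c = INTEGER(counts);
  for (int i = 0; i < n; ++i) {
    if (c[i] == 0) continue;
    const double w = c[i];
    int jmax = std::min(m, n - i);
    double *oi = o + i;
    for (int j = 0; j < jmax; ++j) oi[j] += w * k[j];
  }
  return out;
}
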