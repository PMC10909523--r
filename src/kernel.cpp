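#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step (default 1 ms) stochastic integration of the modified
// integrate-and-fire neuron
//
//   V = V_rest + V_syn - HAP - AHP + DAP
//
// PSPs arrive as Poisson counts per step; each afterpotential is a single
// variable incremented at spike time and decaying exponentially with its
// half-life. Within a step the order is: decay the previous synaptic
// perturbation, add this step's PSPs at full amplitude, decay the
// afterpotentials, test threshold, then apply spike increments. There is no
// explicit membrane reset; refractoriness arises from the HAP. Random counts
// are drawn from R's RNG so that runs are reproducible with set.seed().
//
// segs: one row per protocol segment, columns (duration_s, rate0_Hz,
// slope_Hz_per_s) applied to the excitatory arrival rate.

// [[Rcpp::export(name = ".sim_protocol_cpp")]]
NumericVector sim_protocol_cpp(NumericMatrix segs, double i_ratio,
                               double e_h, double i_h, double lambda_syn,
                               double k_hap, double lambda_hap,
                               double k_dap, double lambda_dap,
                               double k_ahp, double lambda_ahp,
                               double v_rest, double v_thresh,
                               double dt_ms) {
  const double dt_s = dt_ms / 1000.0;
  const double d_syn = std::pow(2.0, -dt_ms / lambda_syn);
  const double d_hap = std::pow(2.0, -dt_ms / lambda_hap);
  const double d_dap = std::pow(2.0, -dt_ms / lambda_dap);
  const double d_ahp = std::pow(2.0, -dt_ms / lambda_ahp);

  double v_syn = 0.0, hap = 0.0, dap = 0.0, ahp = 0.0;
  std::vector<double> spikes;
  double t0 = 0.0;

  for (int s = 0; s < segs.nrow(); ++s) {
    const long nsteps = (long)std::llround(segs(s, 0) / dt_s);
    const double r0 = segs(s, 1), slope = segs(s, 2);
    for (long i = 0; i < nsteps; ++i) {
      double rate = r0 + slope * (i * dt_s);
      if (rate < 0.0) rate = 0.0;
      const int ne = (int)R::rpois(rate * dt_s);
      const int ni = (int)R::rpois(i_ratio * rate * dt_s);
      v_syn = v_syn * d_syn + ne * e_h + ni * i_h;
      hap *= d_hap;
      dap *= d_dap;
      ahp *= d_ahp;
      const double v = v_rest + v_syn - hap - ahp + dap;
      if (v >= v_thresh) {
        spikes.push_back(t0 + (i + 1) * dt_s);
        hap += k_hap;
        dap += k_dap;
        ahp += k_ahp;
      }
    }
    t0 += nsteps * dt_s;
  }
  return wrap(spikes);
}

// Per-spike hormone release with activity-dependent facilitation, binned
// into a rate signal. The facilitation variable f decays between spikes with
// half-life `halflife_s`; at each spike the release is
// base * (1 + f)^power with f evaluated before this spike's own increment,
// after which f is incremented by `gain` and capped at `fmax`.
// Returns per-bin release rate (units per second) over n_bins bins of dt_s.

// [[Rcpp::export(name = ".secretion_signal_cpp")]]
NumericVector secretion_signal_cpp(NumericVector times, double dt_s,
                                   int n_bins, double gain,
                                   double halflife_s, double fmax,
                                   double base, double power) {
  NumericVector sig(n_bins);
  double f = 0.0, tprev = 0.0;
  const int n = times.size();
  for (int i = 0; i < n; ++i) {
    f *= std::pow(2.0, -(times[i] - tprev) / halflife_s);
    const double rel = base * std::pow(1.0 + f, power);
    f += gain;
    if (f > fmax) f = fmax;
    tprev = times[i];
    int idx = (int)(times[i] / dt_s);
    if (idx >= n_bins) idx = n_bins - 1;
    sig[idx] += rel / dt_s;
  }
  return sig;
}
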