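#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler substeps for the whole conductance-based LIF population.
// State vectors are modified in place (the engine owns them exclusively).
// refrac holds remaining refractory substeps; dec_* are (1 - dt/tau).
// Returns spike (state-index, time ms) pairs detected in this block.
// [[Rcpp::export]]
List cs_step_block(NumericVector u, NumericVector g_exc, NumericVector g_inh,
                   IntegerVector refrac,
                   NumericVector dt_over_Cm, NumericVector g_L,
                   NumericVector E_L, NumericVector I_e,
                   NumericVector V_th, NumericVector V_r,
                   IntegerVector n_ref,
                   NumericVector dec_exc, NumericVector dec_inh,
                   double E_exc, double E_inh,
                   double t0, double dt, int n_sub) {
  const int n = u.size();
  std::vector<int> sp_id;
  std::vector<double> sp_t;
  for (int s = 0; s < n_sub; ++s) {
    const double t_now = t0 + (s + 1) * dt;
    for (int i = 0; i < n; ++i) {
      if (refrac[i] > 0) {
        refrac[i] -= 1;
        u[i] = V_r[i];
      } else {
        const double ui = u[i];
        const double I = -g_L[i] * (ui - E_L[i]) + I_e[i]
          - g_exc[i] * (ui - E_exc) - g_inh[i] * (ui - E_inh);
        double un = ui + dt_over_Cm[i] * I;
        if (un >= V_th[i]) {
          sp_id.push_back(i + 1);
          sp_t.push_back(t_now);
          un = V_r[i];
          refrac[i] = n_ref[i];
        }
        u[i] = un;
      }
      g_exc[i] *= dec_exc[i];
      g_inh[i] *= dec_inh[i];
    }
  }
  for (int i = 0; i < n; ++i) {
    if (!R_finite(u[i])) {
      stop("non-finite membrane potential at state index %d, t = %f ms",
           i + 1, t0 + n_sub * dt);
    }
  }
  return List::create(_["id"] = wrap(sp_id), _["time"] = wrap(sp_t));
}

// Scatter a constant synaptic weight from spiking presynaptic cells onto
// their targets. p/tgt is the presynaptic-major adjacency (p has length
// n_pre + 1; tgt holds 0-based indices into g). spk holds 0-based
// presynaptic local ids. g is modified in place.
// [[Rcpp::export]]
void cs_scatter_add(IntegerVector p, IntegerVector tgt, IntegerVector spk,
                    double w, NumericVector g) {
  const int ns = spk.size();
  for (int m = 0; m < ns; ++m) {
    const int j = spk[m];
    for (int k = p[j]; k < p[j + 1]; ++k) g[tgt[k]] += w;
  }
}

// Scatter per-synapse plastic weights (factor * base weight, nS).
// [[Rcpp::export]]
void cs_scatter_add_w(IntegerVector p, IntegerVector tgt, NumericVector w,
                      IntegerVector spk, double base_w, NumericVector g) {
  const int ns = spk.size();
  for (int m = 0; m < ns; ++m) {
    const int j = spk[m];
    for (int k = p[j]; k < p[j + 1]; ++k) g[tgt[k]] += base_w * w[k];
  }
}

// Per-millisecond bidirectional plasticity update for every PF->PC synapse:
//   w <- w + ltp (w_init - w) * L_j - ltd * w * CF(t) * elig[pre]
// where elig[j] counts the 1-ms bins in the trailing window in which
// presynaptic parallel fiber j spiked, and L_j is 1 in the ungated variant
// or PF_j(t) (did fiber j spike this ms) in the PF-gated variant.
// w is modified in place.
// [[Rcpp::export]]
void cs_pfpc_update(NumericVector w, IntegerVector p, IntegerVector elig,
                    bool cf, double ltp, double ltd, double w_init,
                    double w_floor, bool ltp_gated, IntegerVector pf_now) {
  const int n_pre = p.size() - 1;
  for (int j = 0; j < n_pre; ++j) {
    const double e = cf ? static_cast<double>(elig[j]) : 0.0;
    const double lj = ltp_gated ? static_cast<double>(pf_now[j]) : 1.0;
    if (lj == 0.0 && e == 0.0) continue;
    for (int k = p[j]; k < p[j + 1]; ++k) {
      const double wk = w[k];
      double wn = wk + ltp * (w_init - wk) * lj - ltd * wk * e;
      if (wn < w_floor) wn = w_floor;
      w[k] = wn;
    }
  }
}
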