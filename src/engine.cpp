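#include <Rcpp.h>
using namespace Rcpp;

// Protocol simulator: TD(lambda) over a complete serial compound with dual
// clamped weight populations, arousal-gated learning in extinction, and
// break-only forgetting.  Mirrors the pure-R reference engine operation for
// operation (same order of floating-point updates) so the two can be
// compared bit-for-bit in tests.
//
// phase codes: 1 acquisition, 2 extinction, 3 break, 4 reacquisition
// drug direction codes: 0 none, 1 enhance, 2 reduce

static inline double drug(double delta, int dir, double dose) {
  if (dir == 1) return delta + dose * std::fabs(delta);
  if (dir == 2) return delta - dose * std::fabs(delta);
  return delta;
}

// [[Rcpp::export(name = ".sim_protocol_cpp")]]
List sim_protocol_cpp(IntegerVector phase, LogicalVector rewarded,
                      NumericVector probability,
                      double alpha, double beta, double lambda_trace,
                      double psi_plus, double psi_minus, double eta,
                      double gamma, int trial_length, int cs_time,
                      int reward_time, double reward_magnitude,
                      bool use_arousal, bool init_learned,
                      bool arousal_max_abs, bool drug_both_windows,
                      int drug_dir, double dose, bool keep_traces) {
  const int n = phase.size();
  const int nf = trial_length - cs_time + 1;

  std::vector<double> wp(nf, 0.0), wm(nf, 0.0), e(nf, 0.0);
  double arousal = 1.0;
  double last_acq_dcs = 0.0;
  bool have_acq = false;

  NumericVector delta_cs(n), delta_out(n), arousal_rec(n);
  NumericMatrix delta_mat = keep_traces ? NumericMatrix(n, trial_length)
                                        : NumericMatrix(0, 0);
  NumericMatrix value_mat = keep_traces ? NumericMatrix(n, trial_length)
                                        : NumericMatrix(0, 0);

  for (int i = 0; i < n; ++i) {
    const int ph = phase[i];
    if (ph == 3) {  // break: forgetting only, no prediction errors
      for (int k = 0; k < nf; ++k) {
        wp[k] *= psi_plus;
        wm[k] *= psi_minus;
      }
      arousal_rec[i] = arousal;
      continue;
    }
    const bool acq_like = (ph == 1 || ph == 4);
    if (ph == 2 && use_arousal && i > 0 &&
        (phase[i - 1] == 1 || phase[i - 1] == 4)) {
      // extinction begins: arousal reflects the expectation built during
      // acquisition
      arousal = init_learned ? std::fabs(last_acq_dcs) : probability[i];
    }
    const double a_i = (!use_arousal || acq_like) ? 1.0 : arousal;
    const bool drug_active = drug_both_windows || acq_like;

    std::fill(e.begin(), e.end(), 0.0);
    double v_prev = 0.0;
    int k_prev = 0;  // 1-based feature index, 0 = no feature
    double d_cs = 0.0, d_out = 0.0, d_maxabs = 0.0;

    for (int t = 1; t <= trial_length; ++t) {
      const int k = (t >= cs_time) ? (t - cs_time + 1) : 0;
      const double v_t = (k > 0) ? wp[k - 1] + wm[k - 1] : 0.0;
      const double r =
          (rewarded[i] && t == reward_time) ? reward_magnitude : 0.0;
      double delta = r + gamma * v_t - v_prev;
      if (drug_active) delta = drug(delta, drug_dir, dose);

      const double gl = gamma * lambda_trace;
      for (int k2 = 0; k2 < nf; ++k2) e[k2] *= gl;
      if (k_prev > 0) e[k_prev - 1] += 1.0;

      for (int k2 = 0; k2 < nf; ++k2) {
        wp[k2] = std::max(wp[k2] + alpha * a_i * delta * e[k2], 0.0);
        wm[k2] = std::min(wm[k2] + beta * a_i * delta * e[k2], 0.0);
      }
      v_prev = (k > 0) ? wp[k - 1] + wm[k - 1] : 0.0;
      k_prev = k;

      if (t == cs_time) d_cs = delta;
      if (t == reward_time) d_out = delta;
      if (std::fabs(delta) > d_maxabs) d_maxabs = std::fabs(delta);
      if (keep_traces) {
        delta_mat(i, t - 1) = delta;
        value_mat(i, t - 1) = v_t;
      }
    }

    delta_cs[i] = d_cs;
    delta_out[i] = d_out;
    arousal_rec[i] = a_i;
    if (acq_like) {
      last_acq_dcs = d_cs;
      have_acq = true;
    }
    if (use_arousal && ph == 2) {
      const double driver = arousal_max_abs ? d_maxabs : std::fabs(d_out);
      arousal = eta * arousal + (1.0 - eta) * driver;
    }
  }

  List out = List::create(
      _["delta_cs"] = delta_cs, _["delta_outcome"] = delta_out,
      _["arousal"] = arousal_rec, _["w_plus"] = NumericVector(wp.begin(), wp.end()),
      _["w_minus"] = NumericVector(wm.begin(), wm.end()),
      _["have_acquisition"] = have_acq);
  if (keep_traces) {
    out["delta"] = delta_mat;
    out["value"] = value_mat;
  }
  return out;
}
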