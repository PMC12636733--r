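#include <Rcpp.h>
using namespace Rcpp;

// Parameter column order (matches PARAM_NAMES on the R side):
// 0 alpha_gather, 1 beta_dCs, 2 beta_dcolor, 3 beta_time, 4 tau,
// 5 alpha_look_right, 6 beta_look_color, 7 beta_look_Cs, 8 beta_look_stay,
// 9 beta_choose, 10 omega_color, 11 tau_color, 12 epsilon

static const double LOG_FLOOR = std::log(1e-12);

// log of logistic(x), floored at LOG_FLOOR (probabilities floored at 1e-12)
static inline double log_sig(double x) {
  double v = (x > 0) ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
  return v < LOG_FLOOR ? LOG_FLOOR : v;
}

// [[Rcpp::export]]
NumericVector participant_loglik_cpp(List prep, NumericMatrix theta,
                                     bool gate_gather, bool gate_look) {
  const int n_trials = as<int>(prep["n_trials"]);
  const int n_colors = as<int>(prep["n_colors"]);
  const IntegerVector tt = prep["trial_tt"];
  const IntegerVector cl = prep["cl"], cr = prep["cr"], chosen = prep["chosen"];
  const NumericVector reward = prep["reward"], vcs_chosen = prep["vcs_chosen"];
  const IntegerVector g_tr = prep["g_tr"], g_t = prep["g_t"], g_y = prep["g_y"];
  const NumericVector g_dvcs = prep["g_dvcs"];
  const IntegerVector l_tr = prep["l_tr"], l_t = prep["l_t"], l_y = prep["l_y"];
  const NumericVector l_dvcs = prep["l_dvcs"], l_stay = prep["l_stay"];
  const IntegerVector c_tr = prep["c_tr"], c_t = prep["c_t"], c_y = prep["c_y"];
  const NumericVector c_dvcs = prep["c_dvcs"];
  const int t_max = as<int>(prep["t_max"]);

  const int S = theta.nrow();
  NumericVector out(S);
  std::vector<double> v(n_colors), dvcol(n_trials);
  std::vector<int> nout(n_colors);
  std::vector<double> urg(t_max + 1), ret(t_max + 1);

  for (int s = 0; s < S; ++s) {
    const double a_g = theta(s, 0), b_dcs = theta(s, 1), b_dcol = theta(s, 2),
                 b_time = theta(s, 3), tau = theta(s, 4), a_lr = theta(s, 5),
                 b_lc = theta(s, 6), b_lcs = theta(s, 7), b_stay = theta(s, 8),
                 b_ch = theta(s, 9), omega = theta(s, 10), tauc = theta(s, 11),
                 eps = theta(s, 12);

    double tp = 1.0, tcp = 1.0;
    for (int t = 1; t <= t_max; ++t) {
      tp *= tau; tcp *= tauc;
      urg[t] = 1.0 - tp;
      ret[t] = 1.0 - tcp;
    }

    // across-trial colour learning (depends on epsilon only)
    std::fill(v.begin(), v.end(), 0.0);
    std::fill(nout.begin(), nout.end(), 0);
    for (int i = 0; i < n_trials; ++i) {
      const double vl = (cl[i] > 0) ? v[cl[i] - 1] : 0.0;
      const double vr = (cr[i] > 0) ? v[cr[i] - 1] : 0.0;
      dvcol[i] = vr - vl;
      const int ch = chosen[i];
      if (ch > 0) {
        const int k = ++nout[ch - 1];
        const double eta = 1.0 / (eps + 0.5 * k);
        const double delta = reward[i] - (vcs_chosen[i] + v[ch - 1]);
        v[ch - 1] += eta * delta;
      }
    }

    double ll = 0.0;
    const int Ng = g_tr.size();
    for (int k = 0; k < Ng; ++k) {
      const int i = g_tr[k] - 1;
      const double dvc = dvcol[i] * ret[g_t[k]];
      double x = a_g + b_dcs * std::fabs(g_dvcs[k]) + b_time * urg[g_t[k]];
      if (gate_gather) x += b_dcol * std::fabs(dvc);
      ll += g_y[k] ? log_sig(x) : log_sig(-x);
    }
    const int Nl = l_tr.size();
    for (int k = 0; k < Nl; ++k) {
      const int i = l_tr[k] - 1;
      double x = a_lr + b_lcs * l_dvcs[k] + b_stay * l_stay[k];
      if (gate_look) x += b_lc * dvcol[i] * ret[l_t[k]];
      ll += l_y[k] ? log_sig(x) : log_sig(-x);
    }
    for (int i = 0; i < n_trials; ++i) {
      double dv;
      if (tt[i] == 1) {            // cs_only: no colour
        dv = c_dvcs[i];
      } else if (tt[i] == 2) {     // color_only: no Cs
        dv = omega * dvcol[i] * ret[c_t[i]];
      } else {
        dv = c_dvcs[i] + omega * dvcol[i] * ret[c_t[i]];
      }
      const double x = b_ch * dv;
      ll += c_y[i] ? log_sig(x) : log_sig(-x);
    }
    out[s] = ll;
  }
  return out;
}
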