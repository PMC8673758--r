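#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of the reinforcement-learning model: three Q values, a
// global reward trace (R-trace), a choice-location trace (CL-trace) and
// per-stimulus choice traces (CS-traces).  The same state-advance code is
// used by the likelihood pass and by the generative simulator so that
// simulate-then-evaluate round trips are bit-consistent.

namespace {

struct Params {
  double a_pos, a_neg, a_R, w_R, a_CL, lam, w_CL, w_CS, bias, beta;
};

Params unpack(const NumericVector& par, bool dual) {
  Params p;
  int k = 0;
  if (dual) {
    p.a_pos = par[k++];
    p.a_neg = par[k++];
  } else {
    p.a_pos = p.a_neg = par[k++];
  }
  p.a_R  = par[k++];
  p.w_R  = par[k++];
  p.a_CL = par[k++];
  p.lam  = par[k++];
  p.w_CL = par[k++];
  p.w_CS = par[k++];
  p.bias = par[k++];
  p.beta = par[k++];
  return p;
}

struct State {
  double Q[3];
  double R;
  double CL;
  double CS[3];
};

void reset(State& s) {
  s.Q[0] = s.Q[1] = s.Q[2] = 0.5;  // Q values start at 0.5 each session
  s.R = 0.0;
  s.CL = 0.0;
  s.CS[0] = s.CS[1] = s.CS[2] = 0.0;
}

// numerically stable log(1/(1+exp(-x)))
inline double log_sigmoid(double x) {
  return (x >= 0.0) ? -log1p(std::exp(-x)) : x - log1p(std::exp(x));
}

struct TrialComp {
  double csd[3];     // CS traces after trial-wise decay (feed the DV)
  double dv;         // evidence for a rightward choice
  double lp_right;   // log p(right)
};

// Pre-choice computation: decay CS traces, build the decision value.
TrialComp pre_choice(const State& s, const Params& p, int l, int r) {
  TrialComp c;
  for (int i = 0; i < 3; ++i) c.csd[i] = p.lam * s.CS[i];
  double dv_simple = s.Q[r] - s.Q[l] + p.bias;
  double cl_bonus = -s.CL;
  double cs_bonus = c.csd[r] - c.csd[l];
  c.dv = dv_simple + p.w_CL * cl_bonus + p.w_CS * cs_bonus;
  c.lp_right = log_sigmoid(p.beta * c.dv);
  return c;
}

// Post-choice state advance.  PE uses the R-trace value from before this
// trial's R-trace update; the chosen CS trace is set to 1 after the decayed
// values have been stored.
double advance(State& s, const Params& p, const TrialComp& c,
               int chosen, int rew, bool right_chosen) {
  double pe = rew + p.w_R * s.R - s.Q[chosen];
  double a = (pe > 0.0) ? p.a_pos : p.a_neg;
  s.Q[chosen] += a * pe;
  s.R += p.a_R * (rew - s.R);
  for (int i = 0; i < 3; ++i) s.CS[i] = c.csd[i];
  s.CS[chosen] = 1.0;
  double L = right_chosen ? -1.0 : 1.0;  // right coded -1, left +1
  s.CL += p.a_CL * (L - s.CL);
  return pe;
}

}  // namespace

// [[Rcpp::export]]
List cpp_session_pass(NumericVector par, bool dual,
                      IntegerVector left, IntegerVector right,
                      IntegerVector chosen, IntegerVector reward,
                      bool details) {
  const Params p = unpack(par, dual);
  const int n = left.size();
  State s;
  reset(s);

  double ll = 0.0;
  NumericMatrix out;
  CharacterVector cn;
  if (details) {
    cn = CharacterVector::create(
        "q_a", "q_b", "q_c", "r_trace", "cl_trace",
        "cs_a", "cs_b", "cs_c", "dv", "p_right", "p_choice",
        "log_p_choice", "pe", "cho_v", "unc_v", "unp_v",
        "cho_t_minus_unc_t", "unp_ct", "loc");
    out = NumericMatrix(n, cn.size());
  }

  for (int t = 0; t < n; ++t) {
    int l = left[t], r = right[t], c = chosen[t];
    TrialComp tc = pre_choice(s, p, l, r);
    bool right_chosen = (c == r);
    double lp = right_chosen ? tc.lp_right
                             : log_sigmoid(-p.beta * tc.dv);
    ll += lp;

    if (details) {
      int u = l + r - c;        // unchosen offered option
      int m = 3 - l - r;        // unpresented option
      out(t, 0) = s.Q[0];
      out(t, 1) = s.Q[1];
      out(t, 2) = s.Q[2];
      out(t, 3) = s.R;
      out(t, 4) = s.CL;
      out(t, 5) = tc.csd[0];
      out(t, 6) = tc.csd[1];
      out(t, 7) = tc.csd[2];
      out(t, 8) = tc.dv;
      out(t, 9) = std::exp(tc.lp_right);
      out(t, 10) = std::exp(lp);
      out(t, 11) = lp;
      out(t, 13) = s.Q[c];
      out(t, 14) = s.Q[u];
      out(t, 15) = s.Q[m];
      out(t, 16) = tc.csd[c] - tc.csd[u];
      out(t, 17) = tc.csd[m];
      out(t, 18) = right_chosen ? -1.0 : 1.0;
    }

    double pe = advance(s, p, tc, c, reward[t], right_chosen);
    if (details) out(t, 12) = pe;
  }

  List res = List::create(_["loglik"] = ll);
  if (details) {
    colnames(out) = cn;
    res["trials"] = out;
    res["final_state"] = List::create(
        _["Q"] = NumericVector::create(s.Q[0], s.Q[1], s.Q[2]),
        _["R_trace"] = s.R,
        _["CL_trace"] = s.CL,
        _["CS_trace"] = NumericVector::create(s.CS[0], s.CS[1], s.CS[2]));
  }
  return res;
}

// Negative log-posterior in unconstrained space, evaluated entirely in
// compiled code so the optimizer's finite-difference gradients stay cheap.
// link codes: 0 = logistic sigmoid to (0,1), 1 = doubled sigmoid to
// (-1,1), 2 = exp to (0, Inf).  A non-finite prior variance means "no
// prior term" (plain negative log-likelihood).
// [[Rcpp::export]]
double cpp_neg_objective(NumericVector x, IntegerVector link_code,
                         bool dual,
                         IntegerVector left, IntegerVector right,
                         IntegerVector chosen, IntegerVector reward,
                         NumericVector prior_mean,
                         NumericVector prior_var) {
  const int k = x.size();
  NumericVector par(k);
  for (int j = 0; j < k; ++j) {
    switch (link_code[j]) {
    case 0: par[j] = 1.0 / (1.0 + std::exp(-x[j])); break;
    case 1: par[j] = 2.0 / (1.0 + std::exp(-x[j])) - 1.0; break;
    default: par[j] = std::exp(x[j]);
    }
  }
  const Params p = unpack(par, dual);
  const int n = left.size();
  State s;
  reset(s);
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int l = left[t], r = right[t], c = chosen[t];
    TrialComp tc = pre_choice(s, p, l, r);
    bool right_chosen = (c == r);
    ll += right_chosen ? tc.lp_right : log_sigmoid(-p.beta * tc.dv);
    advance(s, p, tc, c, reward[t], right_chosen);
  }
  double val = -ll;
  if (prior_var.size() == k) {
    for (int j = 0; j < k; ++j) {
      if (!std::isfinite(prior_var[j])) continue;
      double d = x[j] - prior_mean[j];
      val += 0.5 * (d * d / prior_var[j] +
                    std::log(2.0 * M_PI * prior_var[j]));
    }
  }
  if (!std::isfinite(val)) val = 1e12;
  return val;
}

// [[Rcpp::export]]
List cpp_simulate_pass(NumericVector par, bool dual,
                       NumericMatrix probs,
                       IntegerVector left, IntegerVector right,
                       NumericVector u_choice, NumericVector u_reward) {
  const Params p = unpack(par, dual);
  const int n = left.size();
  State s;
  reset(s);

  IntegerVector chosen(n), reward(n);
  NumericVector p_right(n), lp_choice(n);
  for (int t = 0; t < n; ++t) {
    int l = left[t], r = right[t];
    TrialComp tc = pre_choice(s, p, l, r);
    double pr = std::exp(tc.lp_right);
    bool right_chosen = (u_choice[t] < pr);
    int c = right_chosen ? r : l;
    int rew = (u_reward[t] < probs(t, c)) ? 1 : 0;
    chosen[t] = c;
    reward[t] = rew;
    p_right[t] = pr;
    lp_choice[t] = right_chosen ? tc.lp_right : log_sigmoid(-p.beta * tc.dv);
    advance(s, p, tc, c, rew, right_chosen);
  }
  return List::create(_["chosen"] = chosen, _["reward"] = reward,
                      _["p_right"] = p_right, _["log_p_choice"] = lp_choice);
}
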