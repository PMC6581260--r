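#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Model ids (kept in sync with .model_id() on the R side):
//  1 rl              bandit2   par: beta, alpha            fixed: q0
//  2 dual_alpha      bandit2   par: beta, a_plus, a_minus  fixed: q0
//  3 kalman          bandit2   par: beta, omega            fixed: m0, v0
//  4 actor_critic    bandit2   par: beta, alpha            fixed: v0
//  5 last_outcome    bandit2   par: beta                   fixed: v0
//  6 rl_persev       bandit2   par: beta, alpha, persev    fixed: q0
//  7 dual_alpha_persev bandit2 par: beta, ap, am, persev   fixed: q0
//  8 biased_rl       gonogo    par: beta, alpha, bias      fixed: q0
//  9 mf              twostep   par: beta, alpha            fixed: q0, lambda
// 10 mb              twostep   par: beta, alpha            fixed: q0
// 11 hybrid          twostep   par: beta, alpha, w         fixed: q0, lambda
//
// Parameters arrive on the constrained scale (transforms applied in R).
// Choice coding is 0-based. All learning loops are strictly sequential,
// so likelihood and simulator share the same stepper (sim flag).

static inline double log_sigm(double x) {
  if (x >= 0.0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}
static inline double sigm(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// P(choice 0) = sigm(u0 - u1); returns log p of the realized choice
static inline double logp_binary(int choice, double u0, double u1) {
  double d = u0 - u1;
  return log_sigm(choice == 0 ? d : -d);
}

static inline int draw_binary_p0(double p0) {
  // 0 with probability p0
  return (unif_rand() < p0) ? 0 : 1;
}

// ---------------------------------------------------------------- bandit ----

static double bandit2_loop(int model, const NumericVector& par,
                           const NumericVector& fixed,
                           IntegerVector& choice, NumericVector& outcome,
                           const NumericMatrix& prob, bool sim) {
  const int T = sim ? prob.nrow() : choice.size();
  const double beta = par[0];
  double q[2], s2[2], v_crit = 0.0;
  double q0 = fixed.size() > 0 ? fixed[0] : 0.5;
  if (model == 3) { q[0] = q[1] = fixed[0]; s2[0] = s2[1] = fixed[1]; }
  else if (model == 4) { q[0] = q[1] = 0.0; v_crit = fixed[0]; }
  else { q[0] = q[1] = q0; }

  int prev = -1;
  double persev = 0.0;
  if (model == 6) persev = par[2];
  if (model == 7) persev = par[3];

  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double u0 = beta * q[0], u1 = beta * q[1];
    if (prev >= 0 && (model == 6 || model == 7)) {
      if (prev == 0) u0 += persev; else u1 += persev;
    }
    int c;
    if (sim) {
      c = draw_binary_p0(sigm(u0 - u1));
      choice[t] = c;
      outcome[t] = (unif_rand() < prob(t, c)) ? 1.0 : 0.0;
    } else {
      c = choice[t];
      ll += logp_binary(c, u0, u1);
    }
    const double r = outcome[t];
    switch (model) {
    case 1: case 6: {               // constant learning rate
      double a = par[1];
      q[c] += a * (r - q[c]);
      break;
    }
    case 2: case 7: {               // dual learning rates
      double pe = r - q[c];
      q[c] += (pe > 0 ? par[1] : par[2]) * pe;
      break;
    }
    case 3: {                       // Kalman filter, decaying gain
      double omega = par[1];
      double k = s2[c] / (s2[c] + omega);
      q[c] += k * (r - q[c]);
      s2[c] *= (1.0 - k);
      break;
    }
    case 4: {                       // actor-critic: TD critic, actor prefs
      double a = par[1];
      double delta = r - v_crit;
      v_crit += a * delta;
      q[c] += a * delta;
      break;
    }
    case 5: {                       // value = most recent outcome
      q[c] = r;
      break;
    }
    }
    prev = c;
  }
  return ll;
}

// ---------------------------------------------------------------- go/no-go --

static double gonogo_loop(const NumericVector& par, const NumericVector& fixed,
                          const IntegerVector& stim,
                          IntegerVector& choice, NumericVector& outcome,
                          const NumericMatrix& prob, bool sim) {
  const int T = stim.size();
  const double beta = par[0], alpha = par[1], bias = par[2];
  const double q0 = fixed.size() > 0 ? fixed[0] : 0.5;
  double q[2][2] = {{q0, q0}, {q0, q0}};   // [stimulus][action]; 0 = go
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    const int st = stim[t];
    // +bias toward "go" for appetitive (1), -bias for aversive (0)
    double u_go = beta * q[st][0] + (st == 1 ? bias : -bias);
    double u_ng = beta * q[st][1];
    int c;
    if (sim) {
      c = draw_binary_p0(sigm(u_go - u_ng));
      choice[t] = c;
      outcome[t] = (unif_rand() < prob(t, 2 * st + c)) ? 1.0 : 0.0;
    } else {
      c = choice[t];
      ll += logp_binary(c, u_go, u_ng);
    }
    q[st][c] += alpha * (outcome[t] - q[st][c]);
  }
  return ll;
}

// ---------------------------------------------------------------- two-step --

static double twostep_loop(int model, const NumericVector& par,
                           const NumericVector& fixed,
                           IntegerVector& choice, IntegerVector& state2,
                           IntegerVector& choice2, NumericVector& outcome,
                           const NumericMatrix& prob, bool sim) {
  const int T = sim ? prob.nrow() : choice.size();
  const double beta = par[0], alpha = par[1];
  const double w = (model == 11) ? par[2] : (model == 10 ? 1.0 : 0.0);
  const double q0 = fixed.size() > 0 ? fixed[0] : 0.5;
  const double lambda = fixed.size() > 1 ? fixed[1] : 1.0;
  const double p_common = 0.7;     // action a commonly leads to state a
  double qmf[2] = {q0, q0};
  double q2[2][2] = {{q0, q0}, {q0, q0}};
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double best0 = std::max(q2[0][0], q2[0][1]);
    double best1 = std::max(q2[1][0], q2[1][1]);
    double qmb0 = p_common * best0 + (1.0 - p_common) * best1;
    double qmb1 = p_common * best1 + (1.0 - p_common) * best0;
    double q1_0 = w * qmb0 + (1.0 - w) * qmf[0];
    double q1_1 = w * qmb1 + (1.0 - w) * qmf[1];
    int c1, s, c2;
    if (sim) {
      c1 = draw_binary_p0(sigm(beta * (q1_0 - q1_1)));
      s = (unif_rand() < p_common) ? c1 : 1 - c1;
      c2 = draw_binary_p0(sigm(beta * (q2[s][0] - q2[s][1])));
      choice[t] = c1; state2[t] = s; choice2[t] = c2;
      outcome[t] = (unif_rand() < prob(t, 2 * s + c2)) ? 1.0 : 0.0;
    } else {
      c1 = choice[t]; s = state2[t]; c2 = choice2[t];
      ll += logp_binary(c1, beta * q1_0, beta * q1_1);
      ll += logp_binary(c2, beta * q2[s][0], beta * q2[s][1]);
    }
    const double r = outcome[t];
    double d1 = q2[s][c2] - qmf[c1];
    qmf[c1] += alpha * d1;
    double d2 = r - q2[s][c2];
    q2[s][c2] += alpha * d2;
    qmf[c1] += alpha * lambda * d2;
    (void)q1_0; (void)q1_1;
  }
  return ll;
}

// ---------------------------------------------------------------- exports ---

static void check_par(const NumericVector& par) {
  for (int i = 0; i < par.size(); ++i)
    if (!R_finite(par[i])) stop("non-finite model parameter");
}

// [[Rcpp::export]]
double cpp_loglik(int model, NumericVector par, List data, NumericVector fixed) {
  check_par(par);
  IntegerVector choice = data["choice"];
  if (choice.size() == 0) return 0.0;
  NumericVector outcome = data["outcome"];
  NumericMatrix dummy(0, 0);
  if (model >= 1 && model <= 7) {
    return bandit2_loop(model, par, fixed, choice, outcome, dummy, false);
  } else if (model == 8) {
    IntegerVector stim = data["stimulus"];
    return gonogo_loop(par, fixed, stim, choice, outcome, dummy, false);
  } else if (model >= 9 && model <= 11) {
    IntegerVector s2 = data["state2"], c2 = data["choice2"];
    return twostep_loop(model, par, fixed, choice, s2, c2, outcome, dummy, false);
  }
  stop("unknown model id");
}

// [[Rcpp::export]]
List cpp_simulate(int model, NumericVector par, List task, NumericVector fixed) {
  check_par(par);
  NumericMatrix prob = task["outcome_prob"];
  const int T = prob.nrow();
  IntegerVector choice(T);
  NumericVector outcome(T);
  RNGScope rng;
  if (model >= 1 && model <= 7) {
    bandit2_loop(model, par, fixed, choice, outcome, prob, true);
    return List::create(_["choice"] = choice, _["outcome"] = outcome);
  } else if (model == 8) {
    IntegerVector stim = task["stimulus"];
    gonogo_loop(par, fixed, stim, choice, outcome, prob, true);
    return List::create(_["choice"] = choice, _["outcome"] = outcome,
                        _["stimulus"] = stim);
  } else if (model >= 9 && model <= 11) {
    IntegerVector s2(T), c2(T);
    twostep_loop(model, par, fixed, choice, s2, c2, outcome, prob, true);
    return List::create(_["choice"] = choice, _["outcome"] = outcome,
                        _["state2"] = s2, _["choice2"] = c2);
  }
  stop("unknown model id");
}
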