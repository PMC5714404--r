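#include <Rcpp.h>
using namespace Rcpp;

// log density of the inverse-Gaussian distribution in (mean, sd) form
static inline double ig_logpdf(double x, double mu, double sigma) {
  if (x <= 0.0) return R_NegInf;
  double lambda = mu * mu * mu / (sigma * sigma);
  return 0.5 * (std::log(lambda) - std::log(2.0 * M_PI) - 3.0 * std::log(x))
       - lambda * (x - mu) * (x - mu) / (2.0 * mu * mu * x);
}

// Scaled forward-backward recursion for the two-state HMM with IG emissions.
// States are ordered (S, U). Returns normalized forward/backward variables,
// scaling constants, posteriors gamma and pairwise posteriors xi.
// [[Rcpp::export]]
List fb_cpp(NumericVector d, double muS, double sgS, double muU, double sgU,
            double pSS, double pUU, double piS) {
  int n = d.size();
  NumericMatrix at(n, 2), bt(n, 2), gamma(n, 2);
  NumericVector c(n);
  NumericMatrix xi(std::max(n - 1, 0), 4); // columns: SS, SU, US, UU
  double pSU = 1.0 - pSS, pUS = 1.0 - pUU;

  NumericMatrix f(n, 2);
  for (int i = 0; i < n; ++i) {
    f(i, 0) = std::exp(ig_logpdf(d[i], muS, sgS));
    f(i, 1) = std::exp(ig_logpdf(d[i], muU, sgU));
  }

  double aS = piS * f(0, 0), aU = (1.0 - piS) * f(0, 1);
  c[0] = aS + aU;
  if (!(c[0] > 0.0))
    stop("forward variable underflow at interval 1: both state densities vanish");
  at(0, 0) = aS / c[0];
  at(0, 1) = aU / c[0];
  for (int i = 1; i < n; ++i) {
    aS = f(i, 0) * (at(i - 1, 0) * pSS + at(i - 1, 1) * pUS);
    aU = f(i, 1) * (at(i - 1, 0) * pSU + at(i - 1, 1) * pUU);
    c[i] = aS + aU;
    if (!(c[i] > 0.0))
      stop("forward variable underflow at interval %d: both state densities vanish",
           i + 1);
    at(i, 0) = aS / c[i];
    at(i, 1) = aU / c[i];
  }

  bt(n - 1, 0) = 1.0 / c[n - 1];
  bt(n - 1, 1) = 1.0 / c[n - 1];
  for (int i = n - 2; i >= 0; --i) {
    double bS = pSS * f(i + 1, 0) * bt(i + 1, 0) + pSU * f(i + 1, 1) * bt(i + 1, 1);
    double bU = pUS * f(i + 1, 0) * bt(i + 1, 0) + pUU * f(i + 1, 1) * bt(i + 1, 1);
    bt(i, 0) = bS / c[i];
    bt(i, 1) = bU / c[i];
  }

  for (int i = 0; i < n; ++i) {
    double gS = at(i, 0) * bt(i, 0), gU = at(i, 1) * bt(i, 1);
    double s = gS + gU;
    gamma(i, 0) = gS / s;
    gamma(i, 1) = gU / s;
  }

  for (int i = 0; i + 1 < n; ++i) {
    double xSS = at(i, 0) * pSS * f(i + 1, 0) * bt(i + 1, 0);
    double xSU = at(i, 0) * pSU * f(i + 1, 1) * bt(i + 1, 1);
    double xUS = at(i, 1) * pUS * f(i + 1, 0) * bt(i + 1, 0);
    double xUU = at(i, 1) * pUU * f(i + 1, 1) * bt(i + 1, 1);
    double s = xSS + xSU + xUS + xUU;
    xi(i, 0) = xSS / s;
    xi(i, 1) = xSU / s;
    xi(i, 2) = xUS / s;
    xi(i, 3) = xUU / s;
  }

  double ll = 0.0;
  for (int i = 0; i < n; ++i) ll += std::log(c[i]);

  return List::create(_["alpha_tilde"] = at, _["beta_tilde"] = bt,
                      _["c"] = c, _["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = ll);
}

// One full Baum-Welch run. With stationary_pi = true (the default
// procedure) the start distribution is reset to the stationary distribution
// of the current transition matrix each iteration; otherwise pi is updated
// by the standard EM rule (posterior of the first state). Returns the
// parameter estimates, the log-likelihood trace and a collapse flag (a
// state lost all posterior mass or produced a degenerate sigma).
// [[Rcpp::export]]
List bw_cpp(NumericVector d, double muS, double sgS, double muU, double sgU,
            double pSS, double pUU, double tol, int max_iter,
            bool stationary_pi, double piS0) {
  int n = d.size();
  std::vector<double> trace;
  trace.reserve(64);
  bool collapsed = false;
  double ll_prev = R_NegInf;
  double piS = piS0;

  NumericMatrix at(n, 2), bt(n, 2);
  NumericVector c(n);

  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    if (stationary_pi) {
      double den = pSS + pUU - 2.0;
      piS = (den < -1e-12) ? (pUU - 1.0) / den : 0.5;
    }

    // E step (scaled forward-backward, inline for speed)
    double pSU = 1.0 - pSS, pUS = 1.0 - pUU;
    bool under = false;
    std::vector<double> fS(n), fU(n);
    for (int i = 0; i < n; ++i) {
      fS[i] = std::exp(ig_logpdf(d[i], muS, sgS));
      fU[i] = std::exp(ig_logpdf(d[i], muU, sgU));
    }
    double aS = piS * fS[0], aU = (1.0 - piS) * fU[0];
    c[0] = aS + aU;
    if (!(c[0] > 0.0)) { collapsed = true; break; }
    at(0, 0) = aS / c[0]; at(0, 1) = aU / c[0];
    for (int i = 1; i < n && !under; ++i) {
      aS = fS[i] * (at(i - 1, 0) * pSS + at(i - 1, 1) * pUS);
      aU = fU[i] * (at(i - 1, 0) * pSU + at(i - 1, 1) * pUU);
      c[i] = aS + aU;
      if (!(c[i] > 0.0)) { under = true; break; }
      at(i, 0) = aS / c[i]; at(i, 1) = aU / c[i];
    }
    if (under) { collapsed = true; break; }
    bt(n - 1, 0) = 1.0 / c[n - 1];
    bt(n - 1, 1) = 1.0 / c[n - 1];
    for (int i = n - 2; i >= 0; --i) {
      double bS = pSS * fS[i + 1] * bt(i + 1, 0) + pSU * fU[i + 1] * bt(i + 1, 1);
      double bU = pUS * fS[i + 1] * bt(i + 1, 0) + pUU * fU[i + 1] * bt(i + 1, 1);
      bt(i, 0) = bS / c[i];
      bt(i, 1) = bU / c[i];
    }

    double ll = 0.0;
    for (int i = 0; i < n; ++i) ll += std::log(c[i]);
    trace.push_back(ll);

    // M step
    double gS_sum = 0.0, gU_sum = 0.0;           // over all i
    double gS_sum1 = 0.0, gU_sum1 = 0.0;         // over i = 1..n-1
    double xSS_sum = 0.0, xUU_sum = 0.0;
    double gS_d = 0.0, gU_d = 0.0, gS_inv = 0.0, gU_inv = 0.0;
    for (int i = 0; i < n; ++i) {
      double gS = at(i, 0) * bt(i, 0), gU = at(i, 1) * bt(i, 1);
      double s = gS + gU;
      gS /= s; gU /= s;
      gS_sum += gS; gU_sum += gU;
      gS_d += gS * d[i]; gU_d += gU * d[i];
      gS_inv += gS / d[i]; gU_inv += gU / d[i];
      if (i < n - 1) {
        gS_sum1 += gS; gU_sum1 += gU;
        double xSS = at(i, 0) * pSS * fS[i + 1] * bt(i + 1, 0);
        double xSU = at(i, 0) * pSU * fU[i + 1] * bt(i + 1, 1);
        double xUS = at(i, 1) * pUS * fS[i + 1] * bt(i + 1, 0);
        double xUU = at(i, 1) * pUU * fU[i + 1] * bt(i + 1, 1);
        double xs = xSS + xSU + xUS + xUU;
        xSS_sum += xSS / xs;
        xUU_sum += xUU / xs;
      }
    }
    if (gS_sum < 1e-8 || gU_sum < 1e-8) { collapsed = true; break; }

    double muS_new = gS_d / gS_sum;
    double muU_new = gU_d / gU_sum;
    double s2S = muS_new * muS_new * muS_new *
      (gS_inv / gS_sum - 1.0 / muS_new);
    double s2U = muU_new * muU_new * muU_new *
      (gU_inv / gU_sum - 1.0 / muU_new);
    if (!(s2S > 0.0) || !(s2U > 0.0)) { collapsed = true; break; }

    double pSS_new = (n > 1) ? xSS_sum / gS_sum1 : pSS;
    double pUU_new = (n > 1) ? xUU_sum / gU_sum1 : pUU;
    pSS_new = std::min(std::max(pSS_new, 0.0), 1.0);
    pUU_new = std::min(std::max(pUU_new, 0.0), 1.0);

    muS = muS_new; sgS = std::sqrt(s2S);
    muU = muU_new; sgU = std::sqrt(s2U);
    pSS = pSS_new; pUU = pUU_new;
    if (!stationary_pi) {
      double g1S = at(0, 0) * bt(0, 0), g1U = at(0, 1) * bt(0, 1);
      piS = g1S / (g1S + g1U);
    }

    if (it > 0 && std::fabs(ll - ll_prev) < tol) { ll_prev = ll; break; }
    ll_prev = ll;
  }

  return List::create(
    _["mu_S"] = muS, _["sigma_S"] = sgS, _["mu_U"] = muU, _["sigma_U"] = sgU,
    _["p_SS"] = pSS, _["p_UU"] = pUU, _["pi_S"] = piS,
    _["loglik"] = ll_prev, _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["collapsed"] = collapsed, _["iterations"] = it + 1);
}

// Forward log-likelihood of the hierarchical Brownian model for intermittent
// viewing: IG emissions per state with duration-dependent transition
// probabilities computed from the previous dominance time d[i-1]:
//   p(stay stable   | d) = 1 - Phi((btS - nuB d) / sqrt(d))
//   p(stay unstable | d) =     Phi((btU + nuB d) / sqrt(d))
// [[Rcpp::export]]
double hbmi_loglik_cpp(NumericVector d, double muS, double sgS,
                       double muU, double sgU, double btS, double btU,
                       double nuB, double piS) {
  int n = d.size();
  double ll = 0.0;
  double aS = piS * std::exp(ig_logpdf(d[0], muS, sgS));
  double aU = (1.0 - piS) * std::exp(ig_logpdf(d[0], muU, sgU));
  double c = aS + aU;
  if (!(c > 0.0)) return R_NegInf;
  aS /= c; aU /= c;
  ll += std::log(c);
  for (int i = 1; i < n; ++i) {
    double dp = d[i - 1], sq = std::sqrt(dp);
    double pSS = 1.0 - R::pnorm(btS, nuB * dp, sq, 1, 0);
    double pUU = R::pnorm(btU, -nuB * dp, sq, 1, 0);
    double fS = std::exp(ig_logpdf(d[i], muS, sgS));
    double fU = std::exp(ig_logpdf(d[i], muU, sgU));
    double nS = fS * (aS * pSS + aU * (1.0 - pUU));
    double nU = fU * (aS * (1.0 - pSS) + aU * pUU);
    c = nS + nU;
    if (!(c > 0.0)) return R_NegInf;
    aS = nS / c; aU = nU / c;
    ll += std::log(c);
  }
  return ll;
}

// Evaluate the HBMi log-likelihood for a matrix of parameter rows
// (columns: b_S, nu_S*, b_U, nu_U*, btilde_S, btilde_U, nu_B*). Used to
// screen the starting-value grid before running the optimizer.
// [[Rcpp::export]]
NumericVector hbmi_loglik_grid_cpp(NumericVector d, NumericMatrix theta,
                                   double piS) {
  int m = theta.nrow();
  NumericVector out(m);
  for (int r = 0; r < m; ++r) {
    double bS = theta(r, 0), nuS = theta(r, 1), bU = theta(r, 2),
           nuU = theta(r, 3), btS = theta(r, 4), btU = theta(r, 5),
           nuB = theta(r, 6);
    double muS = 2.0 * bS / nuS, sgS = std::sqrt(2.0 * bS / (nuS * nuS * nuS));
    double muU = 2.0 * bU / nuU, sgU = std::sqrt(2.0 * bU / (nuU * nuU * nuU));
    out[r] = hbmi_loglik_cpp(d, muS, sgS, muU, sgU, btS, btU, nuB, piS);
  }
  return out;
}

static inline double rinvgauss1(double mu, double sigma) {
  double lambda = mu * mu * mu / (sigma * sigma);
  double y = R::rchisq(1.0);
  double x1 = mu + mu * mu * y / (2.0 * lambda)
    - mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  double u = R::unif_rand();
  return (u <= mu / (mu + x1)) ? x1 : mu * mu / x1;
}

// Interval-level simulation of the hierarchical Brownian model for
// intermittent viewing: per state, draw an IG dominance time, then the
// background-process endpoint (normal with mean +/- nuB * d, variance d)
// and compare it with the state's background border to decide whether the
// regime switches. Exact in distribution under the mean-drift description.
// [[Rcpp::export]]
List hbmi_sim_cpp(double T, double muS, double sgS, double muU, double sgU,
                  double btS, double btU, double nuB, double piS) {
  std::vector<double> dur;
  std::vector<int> st; // 1 = S, 0 = U
  int state = (R::unif_rand() < piS) ? 1 : 0;
  int state0 = state;
  double total = 0.0;
  bool haveS = R_finite(muS), haveU = R_finite(muU);
  while (true) {
    double dnew = (state == 1) ? rinvgauss1(muS, sgS) : rinvgauss1(muU, sgU);
    if (total + dnew > T) break;
    dur.push_back(dnew);
    st.push_back(state);
    total += dnew;
    double bend;
    if (state == 1) {
      bend = R::rnorm(nuB * dnew, std::sqrt(dnew));
      if (!(bend > btS) && haveU) state = 0;   // fell short: go unstable
    } else {
      bend = R::rnorm(-nuB * dnew, std::sqrt(dnew));
      if (bend > btU && haveS) state = 1;      // overshot: go stable
    }
  }
  return List::create(_["durations"] = NumericVector(dur.begin(), dur.end()),
                      _["states"] = IntegerVector(st.begin(), st.end()),
                      _["first_state"] = state0);
}

// Euler-Maruyama simulation of the full hierarchical Brownian path:
// perception process P with drift nu0 during presentation and nu_S / nu_U
// (by hidden state) during blanks, background process B with drift 0 during
// presentation and +/- nu_B during blanks. First hits of +/- b_state flip
// the percept, the value of B at the hit decides the regime, B is reset to
// zero, and P is reset to sgn(P) * (new border) when the regime changes.
// l_b = 0 encodes continuous viewing (single state, border b_S, drift nu0).
// [[Rcpp::export]]
List hbm_path_cpp(double T, double dt, double bS, double bU, double btS,
                  double btU, double nu0, double nuS, double nuU, double nuB,
                  double lp, double lb, int start_state, double diffusion,
                  bool keep_paths) {
  int nstep = (int)std::floor(T / dt);
  bool continuous = (lb <= 0.0);
  int state = continuous ? 1 : start_state; // 1 = S, 0 = U
  double border = (state == 1) ? bS : bU;
  double P = -border, B = 0.0;
  double sgn = 1.0; // drift sign of P (percept L)
  double cycle = lp + lb;
  double sq = std::sqrt(dt) * diffusion;

  std::vector<double> hits;
  std::vector<int> hit_state;
  std::vector<double> Ppath, Bpath;
  std::vector<int> Spath;
  if (keep_paths) {
    Ppath.reserve(nstep);
    Bpath.reserve(nstep);
    Spath.reserve(nstep);
  }

  double t = 0.0;
  for (int i = 0; i < nstep; ++i) {
    double phase = t - std::floor(t / cycle) * cycle;
    bool pr = continuous || (phase < lp);
    double drift = pr ? nu0 : ((state == 1) ? nuS : nuU);
    double bdrift = (continuous || pr) ? 0.0 : ((state == 1) ? nuB : -nuB);
    P += sgn * drift * dt + sq * norm_rand();
    if (!continuous) B += bdrift * dt + sq * norm_rand();
    t += dt;
    if ((sgn > 0.0 && P >= border) || (sgn < 0.0 && P <= -border)) {
      // first hit: percept flips; B decides the regime
      hits.push_back(t);
      hit_state.push_back(state);
      if (!continuous) {
        int newstate = state;
        if (state == 1) { if (!(B > btS)) newstate = 0; }
        else           { if (B > btU) newstate = 1; }
        B = 0.0;
        if (newstate != state) {
          state = newstate;
          border = (state == 1) ? bS : bU;
          P = (P > 0 ? 1.0 : -1.0) * border;
        }
      }
      sgn = (P > 0) ? -1.0 : 1.0;
    }
    if (keep_paths) {
      Ppath.push_back(P);
      Bpath.push_back(B);
      Spath.push_back(state);
    }
  }

  List out = List::create(
    _["hits"] = NumericVector(hits.begin(), hits.end()),
    _["hit_state"] = IntegerVector(hit_state.begin(), hit_state.end()));
  if (keep_paths) {
    out["P"] = NumericVector(Ppath.begin(), Ppath.end());
    out["B"] = NumericVector(Bpath.begin(), Bpath.end());
    out["state"] = IntegerVector(Spath.begin(), Spath.end());
  }
  return out;
}
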