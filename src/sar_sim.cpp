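#include <Rcpp.h>
using namespace Rcpp;

// Per-bin update order at spike bins (fixed throughout the package):
//   1. facilitation jumps (gives u(t+))
//   2. synchronous release from the pre-spike pool (u_sr(t+) * x(t-))
//   3. asynchronous release from what remains
//   4. replenishment, then exponential decay of u_sr / u_ar over the bin.
// Decay uses exact exponential factors, not Euler, so the state bounds
// u_sr in [0,1], u_ar in [U0, U_max] hold for any bin width.

// Deterministic mean-field simulation on a fixed grid.
// theta = (tau_sr, U_sr, tau_ar, U_ar, tau_d, U_max, X_F, U0)
// spike_bin: 0-based bin index per spike, strictly increasing.
// Returns per-bin u_sr, u_ar, x (state at bin start, after any spike jump
// is reported post-jump), q_sr (amount, nonzero only at spike bins) and
// q_ar (amount released during the bin).
// [[Rcpp::export]]
List cpp_sim_det(NumericVector theta, IntegerVector spike_bin, int nbins,
                 double dt) {
  const double tau_sr = theta[0], U_sr = theta[1], tau_ar = theta[2],
               U_ar = theta[3], tau_d = theta[4], U_max = theta[5],
               X_F = theta[6], U0 = theta[7];
  const double dec_sr = std::exp(-dt / tau_sr);
  const double dec_ar = std::exp(-dt / tau_ar);

  NumericVector usr(nbins), uar(nbins), xv(nbins), qsr(nbins), qar(nbins);
  double u_s = 0.0, u_a = U0, x = X_F;
  int si = 0, ns = spike_bin.size();

  for (int i = 0; i < nbins; ++i) {
    bool spike = (si < ns && spike_bin[si] == i);
    if (spike) {
      ++si;
      u_s += U_sr * (1.0 - u_s);
      u_a += U_ar * (U_max - u_a);
      double qs = u_s * x;  // u_sr(t+) * x(t-)
      x -= qs;
      qsr[i] = qs;
    }
    usr[i] = u_s;
    uar[i] = u_a;
    xv[i] = x;
    double qa = x * u_a * dt;
    qar[i] = qa;
    // dx/dt = (X_F - x)/tau_d - x*u_ar with u_ar frozen over the bin:
    // exponential update with effective rate 1/tau_d + u_ar.
    double a = 1.0 / tau_d + u_a;
    double xeq = X_F / (tau_d * a);
    x = xeq + (x - xeq) * std::exp(-a * dt);
    u_s *= dec_sr;
    u_a = U0 + (u_a - U0) * dec_ar;
  }
  return List::create(_["u_sr"] = usr, _["u_ar"] = uar, _["x"] = xv,
                      _["q_sr"] = qsr, _["q_ar"] = qar);
}

// Deterministic simulation evaluated over a grid of parameter vectors,
// accumulating released amounts into release periods. Theta rows are
// (tau_sr, U_sr, tau_ar, U_ar, tau_d, U_max); X_F and U0 are shared.
// period_id: 0-based period index per bin, -1 for bins outside any period.
// Returns a n_theta x n_period matrix of integrated amounts.
// [[Rcpp::export]]
NumericMatrix cpp_det_periods(NumericMatrix Theta, IntegerVector spike_bin,
                              IntegerVector period_id, int nperiods,
                              int nbins, double dt, double X_F, double U0) {
  int G = Theta.nrow();
  NumericMatrix M(G, nperiods);
  int ns = spike_bin.size();

  for (int g = 0; g < G; ++g) {
    const double tau_sr = Theta(g, 0), U_sr = Theta(g, 1),
                 tau_ar = Theta(g, 2), U_ar = Theta(g, 3),
                 tau_d = Theta(g, 4), U_max = Theta(g, 5);
    const double dec_sr = std::exp(-dt / tau_sr);
    const double dec_ar = std::exp(-dt / tau_ar);
    double u_s = 0.0, u_a = U0, x = X_F;
    int si = 0;
    for (int i = 0; i < nbins; ++i) {
      int pid = period_id[i];
      if (si < ns && spike_bin[si] == i) {
        ++si;
        u_s += U_sr * (1.0 - u_s);
        u_a += U_ar * (U_max - u_a);
        double qs = u_s * x;
        x -= qs;
        if (pid >= 0) M(g, pid) += qs;
      }
      if (pid >= 0) M(g, pid) += x * u_a * dt;
      double a = 1.0 / tau_d + u_a;
      double xeq = X_F / (tau_d * a);
      x = xeq + (x - xeq) * std::exp(-a * dt);
      u_s *= dec_sr;
      u_a = U0 + (u_a - U0) * dec_ar;
    }
  }
  return M;
}

// Stochastic (binomial quantal) simulation.
// theta = (tau_sr, U_sr, tau_ar, U_ar, tau_d, U_max, N_F, x0, U0)
// Draw order per bin: n_sr (spike bins only), n_ar, r — each via R's rbinom,
// so the sequence is reproducible from set.seed() and can be mirrored in R.
// Replenishment is drawn from the vacancies at bin start (N_F - N(t-)).
// [[Rcpp::export]]
List cpp_sim_stoch(NumericVector theta, IntegerVector spike_bin, int nbins,
                   double dt) {
  const double tau_sr = theta[0], U_sr = theta[1], tau_ar = theta[2],
               U_ar = theta[3], tau_d = theta[4], U_max = theta[5];
  const int N_F = (int)theta[6];
  const double U0 = theta[8];
  const double dec_sr = std::exp(-dt / tau_sr);
  const double dec_ar = std::exp(-dt / tau_ar);
  const double p_rep = dt / tau_d;

  IntegerVector nsr(nbins), nar(nbins), rr(nbins), Nv(nbins);
  NumericVector usr(nbins), uar(nbins);
  double u_s = 0.0, u_a = U0;
  int N = N_F;
  int si = 0, ns = spike_bin.size();

  RNGScope scope;
  for (int i = 0; i < nbins; ++i) {
    bool spike = (si < ns && spike_bin[si] == i);
    int n_s = 0, n_a, r;
    int N_pre = N;
    if (spike) {
      ++si;
      u_s += U_sr * (1.0 - u_s);
      u_a += U_ar * (U_max - u_a);
      n_s = (int)R::rbinom((double)N, u_s);
    }
    n_a = (int)R::rbinom((double)(N - n_s), u_a * dt);
    r = (int)R::rbinom((double)(N_F - N_pre), p_rep);
    N = N - n_s - n_a + r;
    nsr[i] = n_s;
    nar[i] = n_a;
    rr[i] = r;
    Nv[i] = N;
    usr[i] = u_s;
    uar[i] = u_a;
    u_s *= dec_sr;
    u_a = U0 + (u_a - U0) * dec_ar;
  }
  return List::create(_["n_sr"] = nsr, _["n_ar"] = nar, _["r"] = rr,
                      _["N"] = Nv, _["u_sr"] = usr, _["u_ar"] = uar);
}

// Sequential constrained deconvolution of a magnitude current trace.
// I: |leak-corrected current| (>= 0); kernel K(i-j) = A exp(-(i-j)dt/tau).
// One pass i = 1..N: carried prediction C(i) = J(i-1) exp(-dt/tau); the
// unconstrained optimum p_u = (I(i) - C(i))/(A dt); the predicted current
// J(i) = C(i) + A p dt may never exceed the measured trace within the
// lookahead window once decayed: J(i) <= min_k I(k) exp((k-i)dt/tau).
// Returns q~ = A*p per bin (release-time indexed: value at bin i - delta).
// [[Rcpp::export]]
NumericVector cpp_deconvolve(NumericVector I, double A, double tau, double dt,
                             int lookahead, int delta) {
  int N = I.size();
  NumericVector qt(N);
  const double dec = std::exp(-dt / tau);
  const double grow = std::exp(dt / tau);
  double Jprev = 0.0;
  for (int i = 0; i < N; ++i) {
    double C = Jprev * dec;
    double cap = I[i];
    double f = 1.0;
    int kmax = std::min(N - 1, i + lookahead);
    for (int k = i + 1; k <= kmax; ++k) {
      f *= grow;
      double v = I[k] * f;
      if (v < cap) cap = v;
    }
    double p_u = (I[i] - C) / (A * dt);
    double p_cap = (cap - C) / (A * dt);
    double p = p_u < p_cap ? p_u : p_cap;
    if (p < 0.0) p = 0.0;
    int j = i - delta;
    if (j >= 0) qt[j] = A * p;
    Jprev = C + A * p * dt;
  }
  return qt;
}
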