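#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigm(double v, double e0, double r, double v0) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v)));
}

// Euler-Maruyama integration of the coupled two-population system.
//
// State layout: y[0..9] population 1, y[10..19] population 2, each block
// ordered y0..y9. Per step n the right-hand side is evaluated at the left
// endpoint t = n*dt; stimulus and ramp values are supplied per step.
// The coupling delay is handled with a ring buffer of y1 history per
// population (zeros before enough history has accumulated).
//
// pars: numeric vector
//   [0..5]   A1 B1 G1 A2 B2 G2
//   [6..8]   a b g
//   [9..15]  C1..C7
//   [16..18] v0 e0 r
//   [19]     K
//   [20..23] mu1 sd1 mu2 sd2   (sd already scaled for the noise mode)
// ramp_which: 0 none, 1 A1, 2 B1, 3 K (ramp_par then holds per-step values)
// [[Rcpp::export]]
List em_integrate_cpp(NumericVector pars, int n_steps, double dt,
                      int delay_steps, int ramp_which,
                      NumericVector ramp_par,
                      NumericVector stim1, NumericVector stim2,
                      bool lfp_couple, int couple_sig, bool record_states) {
  double A[2] = {pars[0], pars[3]};
  double B[2] = {pars[1], pars[4]};
  double G[2] = {pars[2], pars[5]};
  const double a = pars[6], b = pars[7], g = pars[8];
  const double C1 = pars[9], C2 = pars[10], C3 = pars[11], C4 = pars[12];
  const double C5 = pars[13], C6 = pars[14], C7 = pars[15];
  const double v0 = pars[16], e0 = pars[17], r = pars[18];
  double K = pars[19];
  const double mu[2] = {pars[20], pars[22]};
  const double sdv[2] = {pars[21], pars[23]};

  std::vector<double> y(20, 0.0), dy(20, 0.0);
  std::vector<double> buf1, buf2;  // y1 history of pop 1 / pop 2
  if (delay_steps > 0) {
    buf1.assign(delay_steps, 0.0);
    buf2.assign(delay_steps, 0.0);
  }

  NumericVector lfp1(n_steps), lfp2(n_steps);
  NumericMatrix states;
  if (record_states) states = NumericMatrix(n_steps, 20);

  for (int n = 0; n < n_steps; ++n) {
    if (ramp_which == 1) A[0] = ramp_par[n];
    else if (ramp_which == 2) B[0] = ramp_par[n];
    else if (ramp_which == 3) K = ramp_par[n];

    // delayed partner signal (y1, or y1-y2-y3 for couple_sig = 1) as seen
    // by each population
    double sig1 = (couple_sig == 1) ? y[1] - y[2] - y[3] : y[1];
    double sig2 = (couple_sig == 1) ? y[11] - y[12] - y[13] : y[11];
    double del[2];
    if (delay_steps > 0) {
      int pos = n % delay_steps;
      del[0] = (n >= delay_steps) ? buf2[pos] : 0.0;
      del[1] = (n >= delay_steps) ? buf1[pos] : 0.0;
      buf1[pos] = sig1;
      buf2[pos] = sig2;
    } else {
      del[0] = sig2;
      del[1] = sig1;
    }

    double p[2];
    p[0] = mu[0] + sdv[0] * norm_rand();
    p[1] = mu[1] + sdv[1] * norm_rand();
    double s[2] = {stim1[n], stim2[n]};

    for (int i = 0; i < 2; ++i) {
      const double *yi = &y[10 * i];
      double *di = &dy[10 * i];
      const double Ai = A[i], Bi = B[i], Gi = G[i];
      di[0] = yi[5];
      di[5] = Ai * a * sigm(K * del[i] + yi[1] - yi[2] - yi[3], e0, r, v0)
              - 2.0 * a * yi[5] - a * a * yi[0];
      di[1] = yi[6];
      di[6] = Ai * a * (s[i] + p[i] + C2 * sigm(C1 * yi[0], e0, r, v0))
              - 2.0 * a * yi[6] - a * a * yi[1];
      di[2] = yi[7];
      di[7] = Bi * b * C4 * sigm(C3 * yi[0], e0, r, v0)
              - 2.0 * b * yi[7] - b * b * yi[2];
      di[3] = yi[8];
      di[8] = Gi * g * C7 * sigm(C5 * yi[0] - C6 * yi[4], e0, r, v0)
              - 2.0 * g * yi[8] - g * g * yi[3];
      di[4] = yi[9];
      di[9] = Bi * b * sigm(C3 * yi[0], e0, r, v0)
              - 2.0 * b * yi[9] - b * b * yi[4];
    }

    bool ok = true;
    for (int k = 0; k < 20; ++k) {
      y[k] += dt * dy[k];
      if (!std::isfinite(y[k])) ok = false;
    }
    if (!ok)
      stop("integration diverged (non-finite state) at step %d (t = %.4f s)",
           n + 1, (n + 1) * dt);

    double kt1 = lfp_couple ? K * del[0] : 0.0;
    double kt2 = lfp_couple ? K * del[1] : 0.0;
    lfp1[n] = kt1 + y[1] - y[2] - y[3];
    lfp2[n] = kt2 + y[11] - y[12] - y[13];
    if (record_states)
      for (int k = 0; k < 20; ++k) states(n, k) = y[k];
  }

  List out = List::create(Named("lfp1") = lfp1, Named("lfp2") = lfp2);
  if (record_states) out["states"] = states;
  return out;
}
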