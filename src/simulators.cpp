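#include <Rcpp.h>
using namespace Rcpp;

// Sum-of-Gaussians potential U(z) = offset + sum_k h_k exp(-(z-c_k)^2 / (2 w_k^2)).
// Returns force -dU/dz and writes U through *u_out.
static inline double gauss_force(double z,
                                 const NumericVector &h,
                                 const NumericVector &c,
                                 const NumericVector &w,
                                 double *u_out) {
  double u = 0.0, f = 0.0;
  const int n = h.size();
  for (int k = 0; k < n; ++k) {
    double d = (z - c[k]) / w[k];
    double e = h[k] * std::exp(-0.5 * d * d);
    u += e;
    f += e * d / w[k]; // -dU/dz for this term
  }
  *u_out = u;
  return f;
}

// Overdamped (Brownian) propagator with reflecting boundaries.
// z <- z - (D dt / kT) dU/dz + sqrt(2 D dt) xi, optionally with a harmonic
// bias (1/2) k_bias (z - c_bias)^2. bias_k is in kJ/mol/A^2. Samples are
// recorded every `sample_every` steps. Uses R's RNG (seed set by caller).
// [[Rcpp::export]]
NumericVector langevin_core(NumericVector heights, NumericVector centers,
                            NumericVector widths, double zmin, double zmax,
                            double D, double dt, double kT, double init_z,
                            int n_steps, double bias_k, double bias_c,
                            int sample_every) {
  if (n_steps < 1 || sample_every < 1) stop("n_steps and sample_every must be >= 1");
  int n_out = n_steps / sample_every;
  NumericVector out(n_out);
  double z = init_z;
  const double drift = D * dt / kT;
  const double noise = std::sqrt(2.0 * D * dt);
  int oi = 0;
  for (int s = 1; s <= n_steps; ++s) {
    double u;
    double f = gauss_force(z, heights, centers, widths, &u);
    if (bias_k > 0.0) f -= bias_k * (z - bias_c);
    if (!std::isfinite(f))
      stop("non-finite force at step %d (z = %g)", s, z);
    z += drift * f + noise * norm_rand();
    // reflecting walls; loop in case a step overshoots past both
    while (z < zmin || z > zmax) {
      if (z < zmin) z = 2.0 * zmin - z;
      if (z > zmax) z = 2.0 * zmax - z;
    }
    if (s % sample_every == 0) out[oi++] = z;
  }
  return out;
}

// Exact discrete-time sampling of a two-state continuous-time Markov chain
// with stationary probability p_stat of state 1 and total exchange rate
// k_ex = k_01 + k_10. Per-step switching probabilities follow the exact
// propagator P(switch) = p_target * (1 - exp(-k_ex dt)).
// [[Rcpp::export]]
IntegerVector two_state_chain_core(int n_steps, double p_stat, double k_ex,
                                   double dt, int init_state) {
  if (n_steps < 1) stop("n_steps must be >= 1");
  const double relax = 1.0 - std::exp(-k_ex * dt);
  const double p01 = p_stat * relax;         // 0 -> 1
  const double p10 = (1.0 - p_stat) * relax; // 1 -> 0
  IntegerVector out(n_steps);
  int s = (init_state != 0) ? 1 : 0;
  for (int i = 0; i < n_steps; ++i) {
    double u = unif_rand();
    if (s == 1) {
      if (u < p10) s = 0;
    } else {
      if (u < p01) s = 1;
    }
    out[i] = s;
  }
  return out;
}

// Independence-Metropolis sampler for one umbrella window. Proposals are
// drawn from the bias Gaussian N(center, kT/k) and accepted with the
// Boltzmann factor of the unbiased potential, so samples follow
// exp(-(U(z) + k/2 (z-c)^2)/kT) exactly (no integrator discretization
// error and near-unit statistical efficiency). Proposals outside
// [zmin, zmax] are rejected, which restricts the target to the domain.
// [[Rcpp::export]]
NumericVector umbrella_mc_core(NumericVector heights, NumericVector centers,
                               NumericVector widths, double zmin, double zmax,
                               double kT, double bias_k, double bias_c,
                               int n_steps, double init_z) {
  if (n_steps < 1) stop("n_steps must be >= 1");
  NumericVector out(n_steps);
  const double sd = std::sqrt(kT / bias_k);
  double z = init_z;
  double u_cur;
  (void)gauss_force(z, heights, centers, widths, &u_cur);
  for (int s = 0; s < n_steps; ++s) {
    double zp = bias_c + sd * norm_rand();
    if (zp >= zmin && zp <= zmax) {
      double u_prop;
      (void)gauss_force(zp, heights, centers, widths, &u_prop);
      if (!std::isfinite(u_prop))
        stop("non-finite energy at step %d (z = %g)", s + 1, zp);
      if (u_prop <= u_cur || unif_rand() < std::exp(-(u_prop - u_cur) / kT)) {
        z = zp;
        u_cur = u_prop;
      }
    }
    out[s] = z;
  }
  return out;
}
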