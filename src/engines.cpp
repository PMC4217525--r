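#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direct-method Gillespie SSA for Ca2+ + M buffers in a well-mixed voxel,
// with optional diffusive exchange with an equilibrated surrounding pool
// (efflux rate cd*X, constant influx rate cd*X_eq, X_eq real-valued).
// State: X (free Ca) and Z[j] (bound complex); Y[j] = YT[j] - Z[j] with
// YT[j] the conserved per-buffer total. Uses R's RNG (seed via set.seed).
// [[Rcpp::export]]
List ssa_path_cpp(double x0, NumericVector yT, NumericVector z0,
                  NumericVector cplus, NumericVector cminus,
                  double cd, double influx, double t_end,
                  double max_events) {
  const int M = cplus.size();
  double X = x0;
  std::vector<double> Z(z0.begin(), z0.end());

  std::vector<double> times;
  std::vector<double> Xs;
  std::vector<double> Zs;  // row-major M columns
  times.reserve(1024); Xs.reserve(1024);
  times.push_back(0.0); Xs.push_back(X);
  for (int j = 0; j < M; ++j) Zs.push_back(Z[j]);

  std::vector<double> a(2 * M + 2);
  double t = 0.0;
  bool absorbed = false, truncated = false;
  long long n_events = 0;

  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < M; ++j) {
      a[2 * j]     = cplus[j] * X * (yT[j] - Z[j]);  // binding
      a[2 * j + 1] = cminus[j] * Z[j];               // unbinding
      a0 += a[2 * j] + a[2 * j + 1];
    }
    a[2 * M]     = cd * X;   // efflux
    a[2 * M + 1] = influx;   // constant-pool influx
    a0 += a[2 * M] + a[2 * M + 1];

    if (a0 <= 0.0) { absorbed = true; break; }
    t += exp_rand() / a0;
    if (t > t_end) break;

    double r = unif_rand() * a0, acc = 0.0;
    int k = 2 * M + 1;
    for (int i = 0; i < 2 * M + 2; ++i) {
      acc += a[i];
      if (r <= acc) { k = i; break; }
    }
    if (k < 2 * M) {
      int j = k / 2;
      if (k % 2 == 0) { X -= 1.0; Z[j] += 1.0; }
      else            { X += 1.0; Z[j] -= 1.0; }
    } else if (k == 2 * M) {
      X -= 1.0;
    } else {
      X += 1.0;
    }

    times.push_back(t); Xs.push_back(X);
    for (int j = 0; j < M; ++j) Zs.push_back(Z[j]);
    if (++n_events >= (long long) max_events) { truncated = true; break; }
  }

  const int n = (int) times.size();
  NumericMatrix Zmat(n, M);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < M; ++j) Zmat(i, j) = Zs[(size_t) i * M + j];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["X"] = NumericVector(Xs.begin(), Xs.end()),
                      _["Z"] = Zmat,
                      _["absorbed"] = absorbed,
                      _["truncated"] = truncated,
                      _["n_events"] = (double) n_events);
}

// Euler-Maruyama integration of the chemical Langevin equation for
// Ca2+ + M buffers (optionally with diffusion under the constant-pool
// assumption). One combined Gaussian increment per buffer channel,
// applied anti-symmetrically to (X, Z[j]) so per-buffer mass is conserved
// pathwise; one combined increment for the two diffusion channels on X.
// eba = true pins the free buffer at its equilibrium value yfix[j]
// (excess buffer approximation); otherwise Y[j] = yT[j] - Z[j].
// Propensity arguments are clamped at 0 inside square roots and species
// at 0 after each step; occurrences are counted.
// [[Rcpp::export]]
List cle_path_cpp(double x0, NumericVector z0, NumericVector yT,
                  NumericVector yfix, bool eba,
                  NumericVector cplus, NumericVector cminus,
                  double cd, double xeq,
                  double dt, int n_steps, double noise_scale) {
  const int M = cplus.size();
  const double sdt = std::sqrt(dt);
  double X = x0;
  std::vector<double> Z(z0.begin(), z0.end());

  NumericVector Xs(n_steps + 1);
  NumericMatrix Zmat(n_steps + 1, M);
  Xs[0] = X;
  for (int j = 0; j < M; ++j) Zmat(0, j) = Z[j];

  long long n_clamp_prop = 0, n_clamp_species = 0;

  for (int k = 1; k <= n_steps; ++k) {
    double dX = 0.0;
    std::vector<double> dZ(M, 0.0);
    for (int j = 0; j < M; ++j) {
      double Y = eba ? yfix[j] : (yT[j] - Z[j]);
      double ab = cplus[j] * X * Y;   // binding propensity
      double au = cminus[j] * Z[j];   // unbinding propensity
      dX += (-ab + au) * dt;
      dZ[j] += (ab - au) * dt;
      if (noise_scale != 0.0) {
        if (ab < 0.0) { ab = 0.0; ++n_clamp_prop; }
        if (au < 0.0) { au = 0.0; ++n_clamp_prop; }
        double eta = std::sqrt(ab + au) * sdt * norm_rand() * noise_scale;
        dX -= eta;
        dZ[j] += eta;
      }
    }
    if (cd > 0.0) {
      double aout = cd * X, ain = cd * xeq;
      dX += (-aout + ain) * dt;
      if (noise_scale != 0.0) {
        if (aout < 0.0) { aout = 0.0; ++n_clamp_prop; }
        dX += std::sqrt(aout + ain) * sdt * norm_rand() * noise_scale;
      }
    }
    X += dX;
    if (X < 0.0) { X = 0.0; ++n_clamp_species; }
    for (int j = 0; j < M; ++j) {
      Z[j] += dZ[j];
      if (Z[j] < 0.0) { Z[j] = 0.0; ++n_clamp_species; }
      if (!eba && Z[j] > yT[j]) { Z[j] = yT[j]; ++n_clamp_species; }
    }
    Xs[k] = X;
    for (int j = 0; j < M; ++j) Zmat(k, j) = Z[j];
  }

  return List::create(_["X"] = Xs, _["Z"] = Zmat,
                      _["n_clamp_propensity"] = (double) n_clamp_prop,
                      _["n_clamp_species"] = (double) n_clamp_species);
}

// First-order Euler integration of motion in the double-well potential
// V(x) = -a/2 x^2 + b/4 x^4, driven by a supplied noise sequence whose
// samples enter as per-step additive increments:
//   X[k+1] = X[k] + (a X[k] - b X[k]^3) dt + xi[k].
// [[Rcpp::export]]
NumericVector dw_path_cpp(double x0, double a, double b, double dt,
                          NumericVector xi) {
  const int n = xi.size();
  NumericVector X(n + 1);
  double x = x0;
  X[0] = x;
  for (int k = 0; k < n; ++k) {
    x += (a * x - b * x * x * x) * dt + xi[k];
    X[k + 1] = x;
  }
  return X;
}
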