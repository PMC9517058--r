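#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic 1-D potential: constant + cosine series + Gaussian terms.
// Periodic potentials wrap Gaussians over +/-2 images of the period.
struct Potential {
  bool periodic;
  double lo, hi, period;
  std::vector<double> cos_a;          // F += a_k cos(k s), k = 1..K
  double c0;
  std::vector<double> gh, gc, gw;     // Gaussian height, center, width

  void init(const List& spec) {
    periodic = as<bool>(spec["periodic"]);
    lo = as<double>(spec["lo"]);
    hi = as<double>(spec["hi"]);
    period = hi - lo;
    c0 = as<double>(spec["c0"]);
    NumericVector ca = spec["cos_a"];
    cos_a.assign(ca.begin(), ca.end());
    NumericMatrix g = spec["gauss"];
    for (int i = 0; i < g.nrow(); ++i) {
      gh.push_back(g(i, 0)); gc.push_back(g(i, 1)); gw.push_back(g(i, 2));
    }
  }

  double value(double s) const {
    double f = c0;
    for (size_t k = 0; k < cos_a.size(); ++k) f += cos_a[k] * std::cos((k + 1) * s);
    for (size_t i = 0; i < gh.size(); ++i) {
      if (periodic) {
        for (int m = -2; m <= 2; ++m) {
          double d = s - gc[i] - m * period;
          f += gh[i] * std::exp(-0.5 * d * d / (gw[i] * gw[i]));
        }
      } else {
        double d = s - gc[i];
        f += gh[i] * std::exp(-0.5 * d * d / (gw[i] * gw[i]));
      }
    }
    return f;
  }

  double deriv(double s) const {
    double df = 0.0;
    for (size_t k = 0; k < cos_a.size(); ++k)
      df += -cos_a[k] * (k + 1) * std::sin((k + 1) * s);
    for (size_t i = 0; i < gh.size(); ++i) {
      double w2 = gw[i] * gw[i];
      if (periodic) {
        for (int m = -2; m <= 2; ++m) {
          double d = s - gc[i] - m * period;
          df += -gh[i] * (d / w2) * std::exp(-0.5 * d * d / w2);
        }
      } else {
        double d = s - gc[i];
        df += -gh[i] * (d / w2) * std::exp(-0.5 * d * d / w2);
      }
    }
    return df;
  }
};

// [[Rcpp::export]]
NumericVector eval_potential_cpp(List spec, NumericVector s) {
  Potential pot; pot.init(spec);
  NumericVector out(s.size());
  for (R_xlen_t i = 0; i < s.size(); ++i) out[i] = pot.value(s[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector eval_potential_deriv_cpp(List spec, NumericVector s) {
  Potential pot; pot.init(spec);
  NumericVector out(s.size());
  for (R_xlen_t i = 0; i < s.size(); ++i) out[i] = pot.deriv(s[i]);
  return out;
}

// Gridded metadynamics bias with linearly interpolated value/gradient.
struct BiasGrid {
  bool periodic;
  double lo, hi, period, h;
  int n;
  std::vector<double> V, dV;

  void init(bool per, double lo_, double hi_, int n_) {
    periodic = per; lo = lo_; hi = hi_; period = hi - lo; n = n_;
    h = periodic ? period / n : period / (n - 1);
    V.assign(n, 0.0); dV.assign(n, 0.0);
  }

  double xat(int i) const { return lo + i * h; }

  void deposit(double c, double hgt, double sigma) {
    double w2 = sigma * sigma;
    if (periodic) {
      // one pass over a window no wider than the period (each grid point
      // visited at most once); the wrapped Gaussian value sums the images
      int i0 = (int)std::floor((c - 6.0 * sigma - lo) / h);
      int i1 = (int)std::ceil((c + 6.0 * sigma - lo) / h);
      if (i1 - i0 + 1 > n) { i0 = 0; i1 = n - 1; }
      for (int i = i0; i <= i1; ++i) {
        int j = i % n; if (j < 0) j += n;
        double x = xat(i);
        for (int m = -1; m <= 1; ++m) {
          double d = x - c - m * period;
          if (std::fabs(d) > 8.0 * sigma) continue;
          double e = std::exp(-0.5 * d * d / w2);
          V[j] += hgt * e;
          dV[j] += -hgt * (d / w2) * e;
        }
      }
    } else {
      int i0 = std::max(0, (int)std::floor((c - 6.0 * sigma - lo) / h));
      int i1 = std::min(n - 1, (int)std::ceil((c + 6.0 * sigma - lo) / h));
      for (int i = i0; i <= i1; ++i) {
        double d = xat(i) - c;
        double e = std::exp(-0.5 * d * d / w2);
        V[i] += hgt * e;
        dV[i] += -hgt * (d / w2) * e;
      }
    }
  }

  double value(double s) const {
    double u = (s - lo) / h;
    int i = (int)std::floor(u);
    double f = u - i;
    int i2 = i + 1;
    if (periodic) {
      i = ((i % n) + n) % n; i2 = (i + 1) % n;
    } else {
      if (i < 0) { i = 0; i2 = 0; f = 0; }
      if (i >= n - 1) { i = n - 1; i2 = n - 1; f = 0; }
    }
    return (1 - f) * V[i] + f * V[i2];
  }

  double grad(double s) const {
    double u = (s - lo) / h;
    int i = (int)std::floor(u);
    double f = u - i;
    int i2 = i + 1;
    if (periodic) {
      i = ((i % n) + n) % n; i2 = (i + 1) % n;
    } else {
      if (i < 0) { i = 0; i2 = 0; f = 0; }
      if (i >= n - 1) { i = n - 1; i2 = n - 1; f = 0; }
    }
    return (1 - f) * dV[i] + f * dV[i2];
  }
};

static inline double apply_boundary(double s, bool periodic, double lo, double hi) {
  double period = hi - lo;
  if (periodic) {
    double u = (s - lo) / period;
    u -= std::floor(u);
    return lo + u * period;
  }
  // reflecting
  int guard = 0;
  while ((s < lo || s > hi) && guard++ < 64) {
    if (s < lo) s = 2 * lo - s;
    if (s > hi) s = 2 * hi - s;
  }
  if (s < lo) s = lo;
  if (s > hi) s = hi;
  return s;
}

// Unbiased overdamped Langevin (Euler-Maruyama). Returns CV at save_stride frames.
// [[Rcpp::export]]
NumericVector run_langevin_cpp(List spec, double dt, double D, double kT,
                               double n_steps, int save_stride, double s0) {
  Potential pot; pot.init(spec);
  bool per = pot.periodic;
  double beta = 1.0 / kT, lo = pot.lo, hi = pot.hi;
  double noise = std::sqrt(2.0 * D * dt);
  long nst = (long)n_steps;
  long nsave = nst / save_stride;
  NumericVector out(nsave);
  double s = s0;
  long k = 0;
  for (long t = 1; t <= nst; ++t) {
    double ds = -beta * D * pot.deriv(s) * dt + noise * norm_rand();
    if (std::fabs(ds) > (hi - lo) / 2.0)
      stop("step-size error: |delta s| exceeded half the domain; reduce dt or D");
    s = apply_boundary(s + ds, per, lo, hi);
    if (t % save_stride == 0) out[k++] = s;
  }
  return out;
}

// Well-tempered metadynamics. gamma <= 0 encodes the non-tempered (gamma -> Inf)
// limit: constant hill heights.
// [[Rcpp::export]]
List run_wtmetad_cpp(List spec, double dt, double D, double kT,
                     double n_steps, int save_stride, double s0,
                     double h0, double sigma, int stride, double gamma,
                     int n_grid) {
  Potential pot; pot.init(spec);
  bool per = pot.periodic;
  double beta = 1.0 / kT, lo = pot.lo, hi = pot.hi;
  double noise = std::sqrt(2.0 * D * dt);
  double kdT = (gamma > 0) ? (gamma - 1.0) * kT : R_PosInf;
  BiasGrid bias; bias.init(per, lo, hi, n_grid);

  long nst = (long)n_steps;
  long nsave = nst / save_stride;
  NumericVector cv(nsave), bias_at(nsave);
  std::vector<double> h_time, h_center, h_height;
  h_time.reserve(nst / stride + 1);

  double s = s0;
  long k = 0;
  for (long t = 1; t <= nst; ++t) {
    double force = pot.deriv(s) + bias.grad(s);
    double ds = -beta * D * force * dt + noise * norm_rand();
    if (std::fabs(ds) > (hi - lo) / 2.0)
      stop("step-size error: |delta s| exceeded half the domain; reduce dt or D");
    s = apply_boundary(s + ds, per, lo, hi);
    if (t % stride == 0) {
      double hgt = (gamma > 0) ? h0 * std::exp(-bias.value(s) / kdT) : h0;
      bias.deposit(s, hgt, sigma);
      h_time.push_back(t * dt);
      h_center.push_back(s);
      h_height.push_back(hgt);
    }
    if (t % save_stride == 0) { cv[k] = s; bias_at[k] = bias.value(s); ++k; }
  }

  NumericVector grid(bias.n), Vfin(bias.n);
  for (int i = 0; i < bias.n; ++i) { grid[i] = bias.xat(i); Vfin[i] = bias.V[i]; }
  return List::create(
    _["cv"] = cv, _["bias_at"] = bias_at,
    _["hill_time"] = NumericVector(h_time.begin(), h_time.end()),
    _["hill_center"] = NumericVector(h_center.begin(), h_center.end()),
    _["hill_height"] = NumericVector(h_height.begin(), h_height.end()),
    _["grid"] = grid, _["bias_final"] = Vfin);
}

// Infrequent metadynamics to first commitment into [commit_lo, commit_hi].
// Accumulates the acceleration factor alpha = sum dt * exp(beta V(s_t, t)).
// Stops (and never deposits) once committed.
// [[Rcpp::export]]
List run_infrequent_cpp(List spec, double dt, double D, double kT,
                        double max_steps, double s0,
                        double h0, double sigma, int stride, double gamma,
                        int n_grid, double commit_lo, double commit_hi) {
  Potential pot; pot.init(spec);
  bool per = pot.periodic;
  double beta = 1.0 / kT, lo = pot.lo, hi = pot.hi;
  double noise = std::sqrt(2.0 * D * dt);
  double kdT = (gamma > 0) ? (gamma - 1.0) * kT : R_PosInf;
  BiasGrid bias; bias.init(per, lo, hi, n_grid);

  std::vector<double> h_time, h_center, h_height;
  double s = s0, alpha = 0.0;
  long nst = (long)max_steps;
  bool hit = false;
  long t = 0;
  for (t = 1; t <= nst; ++t) {
    alpha += dt * std::exp(beta * bias.value(s));
    double force = pot.deriv(s) + bias.grad(s);
    double ds = -beta * D * force * dt + noise * norm_rand();
    if (std::fabs(ds) > (hi - lo) / 2.0)
      stop("step-size error: |delta s| exceeded half the domain; reduce dt or D");
    s = apply_boundary(s + ds, per, lo, hi);
    // commit_lo > commit_hi encodes a window wrapping the periodic edge
    bool inside = (commit_lo <= commit_hi)
      ? (s >= commit_lo && s <= commit_hi)
      : (s >= commit_lo || s <= commit_hi);
    if (inside) { hit = true; break; }
    if (t % stride == 0) {
      double hgt = (gamma > 0) ? h0 * std::exp(-bias.value(s) / kdT) : h0;
      bias.deposit(s, hgt, sigma);
      h_time.push_back(t * dt);
      h_center.push_back(s);
      h_height.push_back(hgt);
    }
  }
  if (!hit) t = nst;
  return List::create(
    _["physical_steps"] = (double)t,
    _["rescaled_time"] = alpha,
    _["committed"] = hit,
    _["final_cv"] = s,
    _["hill_time"] = NumericVector(h_time.begin(), h_time.end()),
    _["hill_center"] = NumericVector(h_center.begin(), h_center.end()),
    _["hill_height"] = NumericVector(h_height.begin(), h_height.end()));
}
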