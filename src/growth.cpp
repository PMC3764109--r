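#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Integer division threshold: a cell with m molecules (founder n0) divides iff
// m/n0 >= phi, i.e. m >= ceiling(phi*n0). The 1e-9 slack absorbs binary
// representation error in phi*n0 for decimal grid values (e.g. 0.01 * 100).
static inline int int_threshold(double phi, int n0) {
  int thr = (int) std::ceil(phi * (double) n0 - 1e-9);
  if (thr < 1) thr = 1;
  return thr;
}

// ---------------------------------------------------------------------------
// deterministic engine: fractional content, divide iff content >= phi
// ---------------------------------------------------------------------------

// [[Rcpp::export(rng = false)]]
List cpp_sweep_det(NumericVector p, NumericVector phi, int max_iter, double max_cells) {
  R_xlen_t n = p.size();
  IntegerVector nf(n), duration(n);
  LogicalVector linear(n);
  std::vector<double> cur, nxt;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double pp = p[i], ph = phi[i];
    cur.clear();
    cur.push_back(1.0);
    double leaves = 0, total = 1;
    int t = 0;
    bool lin = true;
    while (!cur.empty()) {
      if (t >= max_iter)
        stop("runaway growth: iteration cap (%d) exceeded at p = %g, phi = %g",
             max_iter, pp, ph);
      if (cur.size() != 1) lin = false;
      nxt.clear();
      for (size_t k = 0; k < cur.size(); ++k) {
        const double x = cur[k];
        const double b = (1.0 - pp) * x;  // large side (p canonicalised <= 0.5)
        const double a = pp * x;          // p side
        total += 2;
        if (total > max_cells)
          stop("runaway growth: cell cap (%.0f) exceeded at p = %g, phi = %g",
               max_cells, pp, ph);
        if (b >= ph) nxt.push_back(b); else leaves += 1;
        if (a >= ph) nxt.push_back(a); else leaves += 1;
      }
      cur.swap(nxt);
      ++t;
    }
    nf[i] = (int) leaves;
    duration[i] = t;
    linear[i] = lin;
    if ((i & 2047) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["nf"] = nf, _["duration"] = duration, _["linear"] = linear);
}

// [[Rcpp::export(rng = false)]]
IntegerVector cpp_curve_det(double p, double phi, int max_iter, double max_cells) {
  std::vector<double> cur, nxt;
  cur.push_back(1.0);
  std::vector<int> curve;
  curve.push_back(1);
  double total = 1;
  int t = 0;
  while (!cur.empty()) {
    if (t >= max_iter)
      stop("runaway growth: iteration cap (%d) exceeded at p = %g, phi = %g",
           max_iter, p, phi);
    nxt.clear();
    for (size_t k = 0; k < cur.size(); ++k) {
      const double x = cur[k];
      const double b = (1.0 - p) * x, a = p * x;
      total += 2;
      if (total > max_cells)
        stop("runaway growth: cell cap (%.0f) exceeded at p = %g, phi = %g",
             max_cells, p, phi);
      if (b >= phi) nxt.push_back(b);
      if (a >= phi) nxt.push_back(a);
    }
    curve.push_back(curve.back() + (int) cur.size());
    cur.swap(nxt);
    ++t;
  }
  return wrap(curve);
}

// [[Rcpp::export(rng = false)]]
List cpp_grow_det_tree(double p, double phi, int max_iter, double max_cells) {
  std::vector<double> content;
  std::vector<int> parent, gen;
  std::vector<bool> divided;
  content.push_back(1.0);
  parent.push_back(NA_INTEGER);
  gen.push_back(0);
  divided.push_back(false);
  std::vector<int> cur, nxt;
  cur.push_back(0);
  std::vector<int> curve;
  curve.push_back(1);
  int t = 0;
  while (!cur.empty()) {
    if (t >= max_iter)
      stop("runaway growth: iteration cap (%d) exceeded at p = %g, phi = %g",
           max_iter, p, phi);
    nxt.clear();
    for (size_t k = 0; k < cur.size(); ++k) {
      const int idx = cur[k];
      divided[idx] = true;
      const double x = content[idx];
      const double b = (1.0 - p) * x, a = p * x;
      if ((double) content.size() + 2 > max_cells)
        stop("runaway growth: cell cap (%.0f) exceeded at p = %g, phi = %g",
             max_cells, p, phi);
      // large daughter first, p-side daughter second
      content.push_back(b); parent.push_back(idx + 1); gen.push_back(t + 1); divided.push_back(false);
      if (b >= phi) nxt.push_back((int) content.size() - 1);
      content.push_back(a); parent.push_back(idx + 1); gen.push_back(t + 1); divided.push_back(false);
      if (a >= phi) nxt.push_back((int) content.size() - 1);
    }
    curve.push_back(curve.back() + (int) cur.size());
    cur.swap(nxt);
    ++t;
  }
  return List::create(_["content"] = wrap(content), _["parent"] = wrap(parent),
                      _["generation"] = wrap(gen), _["divided"] = wrap(divided),
                      _["curve"] = wrap(curve), _["duration"] = t);
}

// ---------------------------------------------------------------------------
// stochastic engine: integer molecules, binomial partitioning
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_grow_stoch_tree(double p, double phi, int n0, int max_iter, double max_cells) {
  const int thr = int_threshold(phi, n0);
  std::vector<int> content, parent, gen;
  std::vector<bool> divided;
  content.push_back(n0);
  parent.push_back(NA_INTEGER);
  gen.push_back(0);
  divided.push_back(false);
  std::vector<int> cur, nxt;   // indices of cells that will divide
  cur.push_back(0);            // root always eligible: n0 >= thr
  std::vector<int> curve;
  curve.push_back(1);
  int t = 0;
  while (!cur.empty()) {
    if (t >= max_iter)
      stop("runaway growth: iteration cap (%d) exceeded at p = %g, phi = %g, n0 = %d",
           max_iter, p, phi, n0);
    nxt.clear();
    for (size_t k = 0; k < cur.size(); ++k) {
      const int idx = cur[k];
      divided[idx] = true;
      const int m = content[idx];
      const int a = (int) R::rbinom((double) m, p);  // p-side daughter
      const int b = m - a;
      if ((double) content.size() + 2 > max_cells)
        stop("runaway growth: cell cap (%.0f) exceeded at p = %g, phi = %g, n0 = %d",
             max_cells, p, phi, n0);
      content.push_back(b); parent.push_back(idx + 1); gen.push_back(t + 1); divided.push_back(false);
      if (b >= thr) nxt.push_back((int) content.size() - 1);
      content.push_back(a); parent.push_back(idx + 1); gen.push_back(t + 1); divided.push_back(false);
      if (a >= thr) nxt.push_back((int) content.size() - 1);
    }
    curve.push_back(curve.back() + (int) cur.size());
    cur.swap(nxt);
    ++t;
  }
  return List::create(_["content"] = wrap(content), _["parent"] = wrap(parent),
                      _["generation"] = wrap(gen), _["divided"] = wrap(divided),
                      _["curve"] = wrap(curve), _["duration"] = t);
}

// Replicate loop, counts only. Cap hits are recorded, not fatal; the caller
// decides whether a capped replicate aborts the analysis or marks the point.
// [[Rcpp::export]]
List cpp_stoch_reps(double p, double phi, int n0, int reps, int max_iter, double max_cells) {
  const int thr = int_threshold(phi, n0);
  IntegerVector nf(reps), duration(reps);
  LogicalVector linear(reps), cap(reps);
  std::vector<int> cur, nxt;
  for (int r = 0; r < reps; ++r) {
    cur.clear();
    cur.push_back(n0);
    double leaves = 0, total = 1;
    int t = 0;
    bool lin = true, hit = false;
    while (!cur.empty()) {
      if (t >= max_iter) { hit = true; break; }
      if (cur.size() != 1) lin = false;
      nxt.clear();
      for (size_t k = 0; k < cur.size(); ++k) {
        const int m = cur[k];
        const int a = (int) R::rbinom((double) m, p);
        const int b = m - a;
        total += 2;
        if (total > max_cells) { hit = true; break; }
        if (b >= thr) nxt.push_back(b); else leaves += 1;
        if (a >= thr) nxt.push_back(a); else leaves += 1;
      }
      if (hit) break;
      cur.swap(nxt);
      ++t;
    }
    if (hit) {
      nf[r] = NA_INTEGER; duration[r] = NA_INTEGER; linear[r] = NA_LOGICAL; cap[r] = true;
    } else {
      nf[r] = (int) leaves; duration[r] = t; linear[r] = lin; cap[r] = false;
    }
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["nf"] = nf, _["duration"] = duration,
                      _["linear"] = linear, _["cap"] = cap);
}

// ---------------------------------------------------------------------------
// perturbed engine: fresh Gaussian draws of phi (eligibility test) and p
// (partition) per cell per division; failed cells are permanently quiescent
// ---------------------------------------------------------------------------

static inline double draw_phi(double phi, double sigma_phi) {
  double v = R::rnorm(phi, sigma_phi * phi);
  return v < 0.0 ? 0.0 : v;  // clipped below at 0
}

static inline double draw_p(double p, double sigma_p) {
  double v = R::rnorm(p, sigma_p * p);
  if (v < 0.0) v = 0.0;
  if (v > 1.0) v = 1.0;
  return v;
}

// [[Rcpp::export]]
List cpp_grow_perturbed_tree(double p, double phi, double sigma_p, double sigma_phi,
                             int n0, int max_iter, double max_cells) {
  const int thr0 = int_threshold(phi, n0);
  std::vector<int> content, parent, gen;
  std::vector<bool> divided;
  content.push_back(n0);
  parent.push_back(NA_INTEGER);
  gen.push_back(0);
  divided.push_back(false);
  std::vector<int> cur, nxt;   // indices of cells awaiting their eligibility test
  cur.push_back(0);
  std::vector<int> curve;
  curve.push_back(1);
  int t = 0, dur = 0;
  while (!cur.empty()) {
    if (t >= max_iter)
      stop("runaway growth: iteration cap (%d) exceeded at p = %g, phi = %g, n0 = %d",
           max_iter, p, phi, n0);
    nxt.clear();
    int ndiv = 0;
    for (size_t k = 0; k < cur.size(); ++k) {
      const int idx = cur[k];
      const int m = content[idx];
      bool eligible;
      if (sigma_phi > 0.0) {
        eligible = (double) m >= draw_phi(phi, sigma_phi) * (double) n0;
      } else {
        eligible = m >= thr0;
      }
      if (!eligible) continue;  // permanently quiescent
      divided[idx] = true;
      ++ndiv;
      const double p_eff = sigma_p > 0.0 ? draw_p(p, sigma_p) : p;
      const int a = (int) R::rbinom((double) m, p_eff);
      const int b = m - a;
      if ((double) content.size() + 2 > max_cells)
        stop("runaway growth: cell cap (%.0f) exceeded at p = %g, phi = %g, n0 = %d",
             max_cells, p, phi, n0);
      content.push_back(b); parent.push_back(idx + 1); gen.push_back(t + 1); divided.push_back(false);
      nxt.push_back((int) content.size() - 1);
      content.push_back(a); parent.push_back(idx + 1); gen.push_back(t + 1); divided.push_back(false);
      nxt.push_back((int) content.size() - 1);
    }
    if (ndiv > 0) {
      curve.push_back(curve.back() + ndiv);
      dur = t + 1;
    }
    cur.swap(nxt);
    ++t;
  }
  return List::create(_["content"] = wrap(content), _["parent"] = wrap(parent),
                      _["generation"] = wrap(gen), _["divided"] = wrap(divided),
                      _["curve"] = wrap(curve), _["duration"] = dur);
}

// [[Rcpp::export]]
List cpp_perturbed_reps(double p, double phi, double sigma_p, double sigma_phi,
                        int n0, int reps, int max_iter, double max_cells) {
  const int thr0 = int_threshold(phi, n0);
  IntegerVector nf(reps);
  LogicalVector cap(reps);
  std::vector<int> cur, nxt;
  for (int r = 0; r < reps; ++r) {
    cur.clear();
    cur.push_back(n0);
    double leaves = 0, total = 1;
    int t = 0;
    bool hit = false;
    while (!cur.empty()) {
      if (t >= max_iter) { hit = true; break; }
      nxt.clear();
      for (size_t k = 0; k < cur.size(); ++k) {
        const int m = cur[k];
        bool eligible;
        if (sigma_phi > 0.0) {
          eligible = (double) m >= draw_phi(phi, sigma_phi) * (double) n0;
        } else {
          eligible = m >= thr0;
        }
        if (!eligible) { leaves += 1; continue; }
        const double p_eff = sigma_p > 0.0 ? draw_p(p, sigma_p) : p;
        const int a = (int) R::rbinom((double) m, p_eff);
        const int b = m - a;
        total += 2;
        if (total > max_cells) { hit = true; break; }
        nxt.push_back(b);
        nxt.push_back(a);
      }
      if (hit) break;
      cur.swap(nxt);
      ++t;
    }
    if (hit) {
      nf[r] = NA_INTEGER; cap[r] = true;
    } else {
      nf[r] = (int) leaves; cap[r] = false;
    }
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["nf"] = nf, _["cap"] = cap);
}

// ---------------------------------------------------------------------------
// closed forms
// ---------------------------------------------------------------------------

// Linear-chain final size: the big daughter keeps dividing until its content
// (1-p)^n drops below phi. The product is accumulated by repeated
// multiplication so the floating-point path matches the simulation engine.
// Caller guarantees 0 < p < phi <= 1.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_linear_chain_size(NumericVector p, NumericVector phi) {
  R_xlen_t n = p.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = 1.0;
    int steps = 0;
    while (x >= phi[i]) {
      x *= (1.0 - p[i]);
      ++steps;
    }
    out[i] = steps + 1;
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
int cpp_int_threshold(double phi, int n0) {
  return int_threshold(phi, n0);
}
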