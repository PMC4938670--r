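#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-point recombination-fraction estimation from resolved parental
// transmissions, with parental linkage phase unknown.
//
// T is an integer matrix (markers x meioses); entry = allele state (0/1)
// transmitted by the focal parent of that meiosis when the parent is
// heterozygous at the marker and the transmission is resolvable, else -1.
// `unit` groups meioses by focal parent: a parent has one (unknown) phase
// shared by all of its offspring, so the likelihood for a marker pair is
//
//   L(theta) = prod_parents 0.5 * [ theta^r (1-theta)^(n-r)
//                                 + theta^(n-r) (1-theta)^r ]
//
// where r counts apparent recombinants under an arbitrary reference phase.
// L is symmetric under theta -> 1-theta, so the MLE is taken in [0, 0.5].

static inline double pair_loglik(const std::vector<int>& n,
                                 const std::vector<int>& r,
                                 double th) {
  const double eps = 1e-12;
  th = std::min(std::max(th, eps), 1.0 - eps);
  double lt = std::log(th), l1 = std::log(1.0 - th), ll = 0.0;
  for (size_t k = 0; k < n.size(); ++k) {
    double a = r[k] * lt + (n[k] - r[k]) * l1;
    double b = (n[k] - r[k]) * lt + r[k] * l1;
    double m = std::max(a, b);
    ll += std::log(0.5) + m + std::log(std::exp(a - m) + std::exp(b - m));
  }
  return ll;
}

// EM over the phase mixture; returns theta-hat in [0, 0.5].
static double pair_em(const std::vector<int>& n, const std::vector<int>& r,
                      int max_iter = 200, double tol = 1e-7) {
  long ntot = 0, rmin = 0;
  for (size_t k = 0; k < n.size(); ++k) {
    ntot += n[k];
    rmin += std::min(r[k], n[k] - r[k]);
  }
  if (ntot == 0) return NA_REAL;
  double th = std::min(0.45, std::max(0.01, (double)rmin / (double)ntot));
  for (int it = 0; it < max_iter; ++it) {
    double eps = 1e-12;
    double t = std::min(std::max(th, eps), 1.0 - eps);
    double lt = std::log(t), l1 = std::log(1.0 - t);
    double num = 0.0, den = 0.0;
    for (size_t k = 0; k < n.size(); ++k) {
      double a = r[k] * lt + (n[k] - r[k]) * l1;
      double b = (n[k] - r[k]) * lt + r[k] * l1;
      double m = std::max(a, b);
      double wa = std::exp(a - m), wb = std::exp(b - m);
      double w = wa / (wa + wb);
      num += w * r[k] + (1.0 - w) * (n[k] - r[k]);
      den += n[k];
    }
    double th_new = num / den;
    if (th_new > 0.5) th_new = 1.0 - th_new;  // fold (symmetric likelihood)
    if (std::fabs(th_new - th) < tol) { th = th_new; break; }
    th = th_new;
  }
  return th;
}

// [[Rcpp::export(name = ".tp_pairs_cpp")]]
List tp_pairs_cpp(IntegerMatrix T, IntegerVector unit, int n_units,
                  IntegerVector unit_sex, IntegerVector ii, IntegerVector jj,
                  int sex_mode) {
  int npair = ii.size(), nmei = T.ncol();
  NumericVector theta(npair), lod(npair);
  IntegerVector ninf(npair);
  std::vector<int> nbuf(n_units), rbuf(n_units);
  std::vector<int> used;
  used.reserve(n_units);

  for (int p = 0; p < npair; ++p) {
    int i = ii[p], j = jj[p];
    used.clear();
    for (int m = 0; m < nmei; ++m) {
      int a = T(i, m), b = T(j, m);
      if (a < 0 || b < 0) continue;
      int u = unit[m];
      if (sex_mode != 2 && unit_sex[u] != sex_mode) continue;
      if (nbuf[u] == 0 && rbuf[u] == 0) used.push_back(u);
      nbuf[u] += 1;
      rbuf[u] += (a != b);
    }
    std::vector<int> n, r;
    long ntot = 0;
    n.reserve(used.size()); r.reserve(used.size());
    for (int u : used) {
      if (nbuf[u] > 0) { n.push_back(nbuf[u]); r.push_back(rbuf[u]); ntot += nbuf[u]; }
      nbuf[u] = 0; rbuf[u] = 0;
    }
    ninf[p] = (int)ntot;
    if (ntot == 0) { theta[p] = NA_REAL; lod[p] = 0.0; continue; }
    double th = pair_em(n, r);
    double ll1 = pair_loglik(n, r, th);
    double ll0 = pair_loglik(n, r, 0.5);
    double L = (ll1 - ll0) / std::log(10.0);
    theta[p] = th;
    lod[p] = (L > 0.0) ? L : 0.0;
  }
  return List::create(_["theta"] = theta, _["lod"] = lod, _["n_inf"] = ninf);
}

// Profile log10-likelihood of a pair on a theta grid (used by the
// exhaustive-grid oracle exposed for cross-checking).
// [[Rcpp::export(name = ".tp_grid_cpp")]]
NumericVector tp_grid_cpp(IntegerVector n, IntegerVector r, NumericVector grid) {
  std::vector<int> nn(n.begin(), n.end()), rr(r.begin(), r.end());
  NumericVector out(grid.size());
  for (int g = 0; g < grid.size(); ++g)
    out[g] = pair_loglik(nn, rr, grid[g]) / std::log(10.0);
  return out;
}

// Pairwise minimum-recombinant counts: for each pair, the number of
// recombination events implied by the best phase choice of every parent,
// sum over parents of min(r, n - r). Unlike theta-hat, a distant pair
// cannot score 0 by chance (every parent would have to be all-recombinant
// or all-non-recombinant simultaneously), which makes this the robust
// ordering objective at high marker density.
// [[Rcpp::export(name = ".tp_minrec_cpp")]]
NumericVector tp_minrec_cpp(IntegerMatrix T, IntegerVector unit, int n_units,
                            IntegerVector ii, IntegerVector jj) {
  int npair = ii.size(), nmei = T.ncol();
  NumericVector out(npair);
  std::vector<int> nbuf(n_units), rbuf(n_units);
  std::vector<int> used;
  used.reserve(n_units);
  for (int p = 0; p < npair; ++p) {
    int i = ii[p], j = jj[p];
    used.clear();
    for (int m = 0; m < nmei; ++m) {
      int a = T(i, m), b = T(j, m);
      if (a < 0 || b < 0) continue;
      int u = unit[m];
      if (nbuf[u] == 0 && rbuf[u] == 0) used.push_back(u);
      nbuf[u] += 1;
      rbuf[u] += (a != b);
    }
    double s = 0.0;
    for (int u : used) {
      s += std::min(rbuf[u], nbuf[u] - rbuf[u]);
      nbuf[u] = 0; rbuf[u] = 0;
    }
    out[p] = s;
  }
  return out;
}
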