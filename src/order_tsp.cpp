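#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

// Marker ordering as an open-path TSP on a pairwise genetic-distance matrix:
// greedy nearest-neighbour construction from random starts, then 2-opt
// (segment reversal) and single-marker reinsertion until no improvement.

static double path_len(const std::vector<int>& p, const NumericMatrix& D) {
  double s = 0.0;
  for (size_t k = 1; k < p.size(); ++k) s += D(p[k - 1], p[k]);
  return s;
}

static void two_opt(std::vector<int>& p, const NumericMatrix& D) {
  int n = p.size();
  bool improved = true;
  while (improved) {
    improved = false;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        // reverse segment [i..j]; path edges (i-1,i) and (j,j+1)
        double d0 = 0.0, d1 = 0.0;
        if (i > 0)     { d0 += D(p[i - 1], p[i]); d1 += D(p[i - 1], p[j]); }
        if (j < n - 1) { d0 += D(p[j], p[j + 1]); d1 += D(p[i], p[j + 1]); }
        if (d1 < d0 - 1e-12) {
          std::reverse(p.begin() + i, p.begin() + j + 1);
          improved = true;
        }
      }
    }
    // single-marker reinsertion
    for (int i = 0; i < n; ++i) {
      int v = p[i];
      double rem = 0.0;
      if (i > 0) rem += D(p[i - 1], v);
      if (i < n - 1) rem += D(v, p[i + 1]);
      if (i > 0 && i < n - 1) rem -= D(p[i - 1], p[i + 1]);
      double best_gain = -1e-12;
      int best_pos = -1;
      std::vector<int> q;
      q.reserve(n - 1);
      for (int k = 0; k < n; ++k) if (k != i) q.push_back(p[k]);
      for (int pos = 0; pos <= (int)q.size(); ++pos) {
        double add = 0.0;
        if (pos > 0) add += D(q[pos - 1], v);
        if (pos < (int)q.size()) add += D(v, q[pos]);
        if (pos > 0 && pos < (int)q.size()) add -= D(q[pos - 1], q[pos]);
        double gain = rem - add;
        if (gain > best_gain + 1e-12) { best_gain = gain; best_pos = pos; }
      }
      if (best_pos >= 0 && best_gain > 1e-9) {
        q.insert(q.begin() + best_pos, v);
        p = q;
        improved = true;
      }
    }
  }
}

// [[Rcpp::export(name = ".order_tsp_cpp")]]
List order_tsp_cpp(NumericMatrix D, int n_restarts, int seed) {
  int n = D.nrow();
  std::vector<int> best;
  double best_len = R_PosInf;
  NumericVector restart_len(n_restarts);
  for (int rs = 0; rs < n_restarts; ++rs) {
    std::mt19937 gen((unsigned)seed + 7919u * (unsigned)rs);
    std::uniform_int_distribution<int> pick(0, n - 1);
    int start = pick(gen);
    std::vector<int> p;
    p.reserve(n);
    std::vector<bool> vis(n, false);
    p.push_back(start);
    vis[start] = true;
    for (int k = 1; k < n; ++k) {
      int cur = p.back(), nxt = -1;
      double dmin = R_PosInf;
      for (int v = 0; v < n; ++v)
        if (!vis[v] && D(cur, v) < dmin) { dmin = D(cur, v); nxt = v; }
      p.push_back(nxt);
      vis[nxt] = true;
    }
    two_opt(p, D);
    double len = path_len(p, D);
    restart_len[rs] = len;
    if (len < best_len) { best_len = len; best = p; }
  }
  IntegerVector ord(best.begin(), best.end());
  return List::create(_["order"] = ord, _["length"] = best_len,
                      _["restart_lengths"] = restart_len);
}

// Polish a given order by 2-opt/reinsertion only (no reconstruction).
// [[Rcpp::export(name = ".order_polish_cpp")]]
List order_polish_cpp(NumericMatrix D, IntegerVector init) {
  std::vector<int> p(init.begin(), init.end());
  two_opt(p, D);
  IntegerVector ord(p.begin(), p.end());
  return List::create(_["order"] = ord, _["length"] = path_len(p, D));
}

// Windowed local search: 2-opt segment reversals and single-marker
// reinsertions restricted to a neighbourhood of `window` positions, so
// long-range structure from a global seriation is preserved while local
// inversions are repaired against the map-length objective.
// [[Rcpp::export(name = ".order_polish_window_cpp")]]
List order_polish_window_cpp(NumericMatrix D, IntegerVector init, int window) {
  std::vector<int> p(init.begin(), init.end());
  int n = p.size();
  bool improved = true;
  int guard = 0;
  while (improved && guard++ < 200) {
    improved = false;
    for (int i = 0; i < n - 1; ++i) {
      int jmax = std::min(n - 1, i + window);
      for (int j = i + 1; j <= jmax; ++j) {
        double d0 = 0.0, d1 = 0.0;
        if (i > 0)     { d0 += D(p[i - 1], p[i]); d1 += D(p[i - 1], p[j]); }
        if (j < n - 1) { d0 += D(p[j], p[j + 1]); d1 += D(p[i], p[j + 1]); }
        if (d1 < d0 - 1e-12) {
          std::reverse(p.begin() + i, p.begin() + j + 1);
          improved = true;
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      int v = p[i];
      double rem = 0.0;
      if (i > 0) rem += D(p[i - 1], v);
      if (i < n - 1) rem += D(v, p[i + 1]);
      if (i > 0 && i < n - 1) rem -= D(p[i - 1], p[i + 1]);
      std::vector<int> q;
      q.reserve(n - 1);
      for (int k = 0; k < n; ++k) if (k != i) q.push_back(p[k]);
      int lo = std::max(0, i - window), hi = std::min((int)q.size(), i + window);
      double best_gain = 1e-9;
      int best_pos = -1;
      for (int pos = lo; pos <= hi; ++pos) {  // insert before q[pos]
        double add = 0.0;
        if (pos > 0) add += D(q[pos - 1], v);
        if (pos < (int)q.size()) add += D(v, q[pos]);
        if (pos > 0 && pos < (int)q.size()) add -= D(q[pos - 1], q[pos]);
        double gain = rem - add;
        if (gain > best_gain) { best_gain = gain; best_pos = pos; }
      }
      if (best_pos >= 0) {
        q.insert(q.begin() + best_pos, v);
        p = q;
        improved = true;
      }
    }
  }
  IntegerVector ord(p.begin(), p.end());
  return List::create(_["order"] = ord, _["length"] = path_len(p, D));
}
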