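#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Labels are 1-based positive integers throughout the interface.
// nb is the n x k matrix of out-neighbours (directed kNN relation);
// in_ptr / in_idx store the reverse edges in CSR form: the in-neighbours of
// cell i (1-based) are in_idx[in_ptr[i-1] .. in_ptr[i]-1], also 1-based.
// The site conditional of the directed Potts joint collects every term of
// the double sum that involves C_i, i.e. both out- and in-neighbours.

static const double XI_EPS = 1e-12;

// [[Rcpp::export]]
IntegerMatrix knn_build_cpp(NumericMatrix coords, int k) {
  int n = coords.nrow();
  IntegerMatrix nb(n, k);
  std::vector<std::pair<double, int> > d(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      d[m++] = std::make_pair(dx * dx + dy * dy, j);
    }
    // ties broken by lower cell index via pair ordering
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int s = 0; s < k; ++s) nb(i, s) = d[s].second + 1;
  }
  return nb;
}

// [[Rcpp::export]]
int agreement_count_cpp(IntegerVector C, IntegerMatrix nb) {
  int n = nb.nrow(), k = nb.ncol(), tot = 0;
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < k; ++s)
      if (C[nb(i, s) - 1] == C[i]) ++tot;
  return tot;
}

// count, for site i (0-based), neighbours in the interaction neighbourhood
// (out + in) carrying each label 1..Lmax; returns counts in a[0..Lmax-1]
static inline void agree_counts(int i, const IntegerVector& C,
                                const IntegerMatrix& nb,
                                const IntegerVector& in_ptr,
                                const IntegerVector& in_idx,
                                std::vector<int>& a) {
  int k = nb.ncol();
  for (int s = 0; s < k; ++s) {
    int l = C[nb(i, s) - 1];
    if (l <= (int)a.size()) ++a[l - 1];
  }
  for (int p = in_ptr[i]; p < in_ptr[i + 1]; ++p) {
    int l = C[in_idx[p] - 1];
    if (l <= (int)a.size()) ++a[l - 1];
  }
}

// One-or-more sequential slice-augmented label sweeps (steps (b)+(c)).
// pi must cover every instantiated cluster; eta is H x L, Y is H x n.
// If resample_u, u_i ~ Unif(0, pi[C_i]) is redrawn at the top of each sweep;
// otherwise the supplied u0 is used (single-sweep use inside the main chain).
// [[Rcpp::export]]
List label_sweep_cpp(IntegerVector C0, NumericMatrix Y, NumericMatrix eta,
                     NumericVector sigma2, double beta, NumericVector pi,
                     NumericVector u0, IntegerMatrix nb, IntegerVector in_ptr,
                     IntegerVector in_idx, int n_sweeps, bool resample_u,
                     bool store_trace) {
  int n = nb.nrow(), H = Y.nrow(), L = pi.size();
  IntegerVector C = clone(C0);
  NumericVector u = clone(u0);
  IntegerMatrix trace;
  if (store_trace) trace = IntegerMatrix(n, n_sweeps);
  std::vector<double> logw(L);
  std::vector<int> cand(L);
  for (int t = 0; t < n_sweeps; ++t) {
    if (resample_u)
      for (int i = 0; i < n; ++i) u[i] = R::runif(0.0, pi[C[i] - 1]);
    for (int i = 0; i < n; ++i) {
      int nc = 0;
      for (int l = 0; l < L; ++l)
        if (pi[l] >= u[i]) cand[nc++] = l;
      if (nc == 0) continue;  // cannot happen when sticks are extended first
      double mx = R_NegInf;
      for (int c = 0; c < nc; ++c) {
        int l = cand[c];
        int cnt = 0, k = nb.ncol();
        for (int s = 0; s < k; ++s)
          if (C[nb(i, s) - 1] == l + 1) ++cnt;
        for (int p = in_ptr[i]; p < in_ptr[i + 1]; ++p)
          if (C[in_idx[p] - 1] == l + 1) ++cnt;
        double q = 0.0;
        for (int h = 0; h < H; ++h) {
          double r = Y(h, i) - eta(h, l);
          q += r * r / sigma2[h];
        }
        logw[c] = beta * cnt - 0.5 * q;
        if (logw[c] > mx) mx = logw[c];
      }
      double tot = 0.0;
      for (int c = 0; c < nc; ++c) {
        logw[c] = std::exp(logw[c] - mx);
        tot += logw[c];
      }
      double v = R::runif(0.0, 1.0) * tot, cum = 0.0;
      int pick = cand[nc - 1];
      for (int c = 0; c < nc; ++c) {
        cum += logw[c];
        if (v <= cum) { pick = cand[c]; break; }
      }
      C[i] = pick + 1;
    }
    if (store_trace)
      for (int i = 0; i < n; ++i) trace(i, t) = C[i];
  }
  List out = List::create(_["C"] = C, _["u"] = u);
  if (store_trace) out["trace"] = trace;
  return out;
}

// Auxiliary-variable sweep of the exchange (double-MH) update: sequential
// draws of C*_i with P(C*_i = l) = pi*_l exp(beta* a_il) / D_i for l <= R_i
// and pi*_l / D_i beyond, via the inverse-CDF method; sticks are extended
// with Beta(1, alpha) prior draws when the uniform falls in the tail.
// [[Rcpp::export]]
List aux_sweep_cpp(IntegerVector C0, IntegerMatrix nb, IntegerVector in_ptr,
                   IntegerVector in_idx, double beta_star, NumericVector xi0,
                   double alpha, int n_sweeps, bool store_trace) {
  int n = nb.nrow();
  IntegerVector C = clone(C0);
  std::vector<double> xi(xi0.begin(), xi0.end());
  std::vector<double> pi;
  double tail = 1.0;
  for (size_t l = 0; l < xi.size(); ++l) {
    pi.push_back(tail * xi[l]);
    tail *= 1.0 - xi[l];
  }
  IntegerMatrix trace;
  if (store_trace) trace = IntegerMatrix(n, n_sweeps);
  const int max_len = 200000;
  for (int t = 0; t < n_sweeps; ++t) {
    for (int i = 0; i < n; ++i) {
      int Ri = 0, k = nb.ncol();
      for (int s = 0; s < k; ++s) Ri = std::max(Ri, C[nb(i, s) - 1]);
      for (int p = in_ptr[i]; p < in_ptr[i + 1]; ++p)
        Ri = std::max(Ri, C[in_idx[p] - 1]);
      while ((int)xi.size() < Ri) {
        double x = R::rbeta(1.0, alpha);
        x = std::min(std::max(x, XI_EPS), 1.0 - XI_EPS);
        xi.push_back(x);
        pi.push_back(tail * x);
        tail *= 1.0 - x;
      }
      std::vector<int> a(Ri, 0);
      agree_counts(i, C, nb, in_ptr, in_idx, a);
      double D = 1.0;
      for (int l = 0; l < Ri; ++l)
        D += pi[l] * (std::exp(beta_star * a[l]) - 1.0);
      double v = R::runif(0.0, 1.0), cum = 0.0;
      int l = 0, pick = -1;
      while (true) {
        if (l >= (int)xi.size()) {
          if ((int)xi.size() >= max_len) { pick = l - 1; break; }
          double x = R::rbeta(1.0, alpha);
          x = std::min(std::max(x, XI_EPS), 1.0 - XI_EPS);
          xi.push_back(x);
          pi.push_back(tail * x);
          tail *= 1.0 - x;
        }
        double pl = (l < Ri) ? pi[l] * std::exp(beta_star * a[l]) / D
                             : pi[l] / D;
        cum += pl;
        if (v <= cum) { pick = l; break; }
        ++l;
      }
      C[i] = pick + 1;
    }
    if (store_trace)
      for (int i = 0; i < n; ++i) trace(i, t) = C[i];
  }
  List out = List::create(_["C"] = C,
                          _["xi"] = NumericVector(xi.begin(), xi.end()));
  if (store_trace) out["trace"] = trace;
  return out;
}

// Finite-K sequential Gibbs sweeps targeting the truncated Potts law:
// P(C_i = l | rest) \propto pi_l exp(beta * a_il), l = 1..K. Used by the
// synthetic-data generator.
// [[Rcpp::export]]
List potts_sim_cpp(IntegerVector C0, IntegerMatrix nb, IntegerVector in_ptr,
                   IntegerVector in_idx, double beta, NumericVector pi,
                   int n_sweeps, bool store_trace) {
  int n = nb.nrow(), K = pi.size();
  IntegerVector C = clone(C0);
  IntegerMatrix trace;
  if (store_trace) trace = IntegerMatrix(n, n_sweeps);
  std::vector<int> a(K);
  std::vector<double> w(K);
  for (int t = 0; t < n_sweeps; ++t) {
    for (int i = 0; i < n; ++i) {
      std::fill(a.begin(), a.end(), 0);
      agree_counts(i, C, nb, in_ptr, in_idx, a);
      double mx = R_NegInf;
      for (int l = 0; l < K; ++l) {
        w[l] = std::log(pi[l]) + beta * a[l];
        if (w[l] > mx) mx = w[l];
      }
      double tot = 0.0;
      for (int l = 0; l < K; ++l) { w[l] = std::exp(w[l] - mx); tot += w[l]; }
      double v = R::runif(0.0, 1.0) * tot, cum = 0.0;
      int pick = K - 1;
      for (int l = 0; l < K; ++l) {
        cum += w[l];
        if (v <= cum) { pick = l; break; }
      }
      C[i] = pick + 1;
    }
    if (store_trace)
      for (int i = 0; i < n; ++i) trace(i, t) = C[i];
  }
  List out = List::create(_["C"] = C);
  if (store_trace) out["trace"] = trace;
  return out;
}

// Exhaustive enumeration of the truncated Potts law over L^n configurations.
// Configuration index maps cell 1 to the least significant base-L digit.
// Returns unnormalised log scores; normalisation done in R via log-sum-exp.
// [[Rcpp::export]]
NumericVector enumerate_potts_scores_cpp(IntegerMatrix nb, double beta,
                                         NumericVector pi) {
  int n = nb.nrow(), k = nb.ncol(), L = pi.size();
  double Nd = std::pow((double)L, n);
  if (Nd > 1e6 + 0.5) stop("enumeration instance too large (L^n > 1e6)");
  int N = (int)(Nd + 0.5);
  NumericVector logp(N);
  std::vector<double> lpi(L);
  for (int l = 0; l < L; ++l) lpi[l] = std::log(pi[l]);
  std::vector<int> C(n);
  for (int idx = 0; idx < N; ++idx) {
    int r = idx;
    double s = 0.0;
    for (int i = 0; i < n; ++i) { C[i] = r % L; r /= L; s += lpi[C[i]]; }
    int agree = 0;
    for (int i = 0; i < n; ++i)
      for (int t = 0; t < k; ++t)
        if (C[nb(i, t) - 1] == C[i]) ++agree;
    logp[idx] = s + beta * agree;
  }
  return logp;
}
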