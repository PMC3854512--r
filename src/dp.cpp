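#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  return (x > 0) ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// log(sum(exp(x))) over a buffer, stabilized by the running max
static double logsumexp_buf(const std::vector<double>& x) {
  double m = R_NegInf;
  for (double v : x) if (v > m) m = v;
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (double v : x) s += std::exp(v - m);
  return m + std::log(s);
}

// log partition function over sites [lo, hi) of one region, restricted to
// sites with use[i] == keep_flag (or all sites when use == nullptr).
// Linear-chain recursion over sites sorted by start:
//   logF(i) = logq_i + log(1 + sum_{j<i, end_j <= start_i} F(j) * w(j,i))
// with w = omega when the gap start_i - end_j <= coop_dist, else 1.
static double region_logZ(int lo, int hi,
                          const double* start, const double* end,
                          const double* logq, const int* use,
                          double log_omega, double coop_dist,
                          std::vector<int>& idx, std::vector<double>& logF,
                          std::vector<double>& terms) {
  idx.clear();
  for (int i = lo; i < hi; ++i) if (use == nullptr || use[i]) idx.push_back(i);
  int n = (int)idx.size();
  if (n == 0) return 0.0;
  logF.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    terms.clear();
    terms.push_back(0.0); // i is the leftmost bound site
    double si = start[idx[i]];
    for (int j = 0; j < i; ++j) {
      double ej = end[idx[j]];
      if (ej <= si) {
        double lw = (si - ej <= coop_dist) ? log_omega : 0.0;
        terms.push_back(logF[j] + lw);
      }
    }
    logF[i] = logq[idx[i]] + logsumexp_buf(terms);
  }
  terms.assign(logF.begin(), logF.end());
  terms.push_back(0.0); // empty configuration
  return logsumexp_buf(terms);
}

// [[Rcpp::export]]
NumericVector dp_prob_batch(IntegerVector ptr, NumericVector start,
                            NumericVector end, NumericVector logq,
                            LogicalVector is_target, double omega,
                            double coop_dist) {
  int nr = ptr.size() - 1;
  NumericVector out(nr);
  double log_omega = std::log(omega);
  const double* ps = REAL(start);
  const double* pe = REAL(end);
  const double* pq = REAL(logq);
  const int* pt = LOGICAL(is_target);
  std::vector<int> idx, not_target;
  std::vector<double> logF, terms;
  std::vector<int> usebuf(logq.size());
  for (int r = 0; r < nr; ++r) {
    int lo = ptr[r], hi = ptr[r + 1];
    if (lo == hi) { out[r] = 0.0; continue; }
    bool has_target = false, all_target = true, disjoint = true;
    for (int i = lo; i < hi; ++i) {
      if (pt[i]) has_target = true; else all_target = false;
      if (i > lo && ps[i] < pe[i - 1]) disjoint = false;
    }
    if (!has_target) { out[r] = 0.0; continue; }
    double p;
    if (omega == 1.0 && disjoint) {
      // sites bind independently: Z = prod(1 + q_i)
      double logZ = 0.0, logZex = 0.0;
      for (int i = lo; i < hi; ++i) {
        double l1p = softplus(pq[i]);
        logZ += l1p;
        if (!pt[i]) logZex += l1p;
      }
      p = -std::expm1(logZex - logZ);
    } else {
      double logZ = region_logZ(lo, hi, ps, pe, pq, nullptr, log_omega,
                                coop_dist, idx, logF, terms);
      double logZex = 0.0;
      if (!all_target) {
        for (int i = lo; i < hi; ++i) usebuf[i] = pt[i] ? 0 : 1;
        logZex = region_logZ(lo, hi, ps, pe, pq, usebuf.data(), log_omega,
                             coop_dist, idx, logF, terms);
      }
      p = -std::expm1(logZex - logZ);
    }
    if (p < 0) p = 0;
    if (p > 1) p = 1;
    out[r] = p;
  }
  return out;
}
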