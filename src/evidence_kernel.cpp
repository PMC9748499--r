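#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Log-likelihood log P(n | N2) for N2 = 0..N under the convolution of two
// beta-binomial terms:
//
//   P(n | N2) = sum_j BB(j | N - N2, a1, b1) * BB(n - j | N2, b2, a2)
//
// where the first term models errors among the N - N2 local-origin reads
// (error rate theta1 ~ Beta(a1, b1), an error is observed as distal) and the
// second models the N2 distal-origin reads each being observed as distal
// with probability 1 - theta2, theta2 ~ Beta(a2, b2) (hence the swapped
// shape parameters).  With two_rate = false, theta2 is identically 0 and
// P(n | N2) = BB(n - N2 | N - N2, a1, b1) for N2 <= n, 0 otherwise.
//
// All beta-binomial terms reduce to log-gamma differences.  Because every
// argument is an integer offset from one of a fixed set of constants, the
// log-gamma values are precomputed in lookup tables, so each term costs a
// handful of table reads; the dominant cost is the exp() in the
// log-sum-exp over the convolution index j.

namespace {

// table[x] = lgamma(x + c) for x = 0..len-1
inline std::vector<double> lgamma_table(int len, double c) {
  std::vector<double> t(len);
  for (int x = 0; x < len; ++x) t[x] = std::lgamma(x + c);
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".bb_n2_loglik")]]
NumericVector bb_n2_loglik(int N, int n, double a1, double b1,
                           double a2, double b2, bool two_rate) {
  if (N < 0 || n < 0 || n > N)
    stop("require 0 <= n <= N");
  if (a1 <= 0.0 || b1 <= 0.0)
    stop("local shape parameters must be > 0");
  if (two_rate && (a2 <= 0.0 || b2 <= 0.0))
    stop("distal shape parameters must be > 0");

  NumericVector out(N + 1);
  if (N == 0) {           // single degenerate cell N2 = 0, P = 1
    out[0] = 0.0;
    return out;
  }

  const int len = N + 2;
  // lchoose(m, k) = T1[m] - T1[k] - T1[m - k]
  std::vector<double> T1 = lgamma_table(len, 1.0);
  std::vector<double> Ta1 = lgamma_table(len, a1);
  std::vector<double> Tb1 = lgamma_table(len, b1);
  std::vector<double> Tab1 = lgamma_table(len, a1 + b1);
  const double lbeta1 = std::lgamma(a1) + std::lgamma(b1) - std::lgamma(a1 + b1);

  // BB(k | m, a1, b1) in log space
  auto lbb_loc = [&](int k, int m) {
    return T1[m] - T1[k] - T1[m - k] + Ta1[k] + Tb1[m - k] - Tab1[m] - lbeta1;
  };

  if (!two_rate) {
    for (int N2 = 0; N2 <= N; ++N2) {
      const int k = n - N2;        // errors among the N - N2 local reads
      const int M = N - N2;
      out[N2] = (k >= 0 && k <= M) ? lbb_loc(k, M) : R_NegInf;
    }
    return out;
  }

  std::vector<double> Ta2 = lgamma_table(len, a2);
  std::vector<double> Tb2 = lgamma_table(len, b2);
  std::vector<double> Tab2 = lgamma_table(len, a2 + b2);
  const double lbeta2 = std::lgamma(a2) + std::lgamma(b2) - std::lgamma(a2 + b2);

  // BB(k | m, b2, a2): swapped shapes, success prob 1 - theta2
  auto lbb_dist = [&](int k, int m) {
    return T1[m] - T1[k] - T1[m - k] + Tb2[k] + Ta2[m - k] - Tab2[m] - lbeta2;
  };

  std::vector<double> terms(n + 1);
  for (int N2 = 0; N2 <= N; ++N2) {
    const int M = N - N2;
    const int jlo = std::max(0, n - N2);
    const int jhi = std::min(n, M);
    if (jlo > jhi) {              // cannot happen for 0 <= n <= N, kept for safety
      out[N2] = R_NegInf;
      continue;
    }
    double mx = R_NegInf;
    int nt = 0;
    for (int j = jlo; j <= jhi; ++j) {
      const double t = lbb_loc(j, M) + lbb_dist(n - j, N2);
      terms[nt++] = t;
      if (t > mx) mx = t;
    }
    if (!std::isfinite(mx)) {
      out[N2] = R_NegInf;
      continue;
    }
    double s = 0.0;
    for (int i = 0; i < nt; ++i) s += std::exp(terms[i] - mx);
    out[N2] = mx + std::log(s);
  }
  return out;
}
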