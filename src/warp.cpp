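#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dynamic-programming dissimilarity between two 2-D traces in derivative
// form. Cell (i, j) compares the local increment of A at i with that of B
// at j and adds the cheapest admissible predecessor, where admissible warp
// steps are {(1, m), (m, 1) | 1 <= m <= M}. Predecessor indices are clamped
// at the first sample, and tau(1, 1) = 0.
//
// In time-warping mode (positional = false) increments are always taken
// with respect to the immediate predecessor in each sequence, and the
// minimization runs over the predecessor cost alone. In positional mode
// (DPW) the increments are taken with respect to the predecessor selected
// by the warp step, so warping acts on the value axis as well as time, and
// the minimization runs jointly over the step-relative increment cost plus
// the predecessor cost. Steps are enumerated as (1, 1), (1, 2), ...,
// (1, M), (2, 1), ..., (M, 1); ties take the first step in this order.
//
// dist_type: 1 = L1 across axes, 2 = L2.

static inline double inc_cost(const NumericMatrix &A, const NumericMatrix &B,
                              int i, int j, int pi, int pj, int dist_type) {
  double dx = (A(i, 0) - A(pi, 0)) - (B(j, 0) - B(pj, 0));
  double dy = (A(i, 1) - A(pi, 1)) - (B(j, 1) - B(pj, 1));
  if (dist_type == 2) return std::sqrt(dx * dx + dy * dy);
  return std::fabs(dx) + std::fabs(dy);
}

// [[Rcpp::export]]
List warp_dp(NumericMatrix A, NumericMatrix B, int M, bool positional,
             int dist_type, bool keep_table) {
  const int n = A.nrow(), m = B.nrow();
  if (n < 2 || m < 2) stop("both traces need at least 2 points");
  if (M < 1) stop("M must be >= 1");

  const int n_steps = 2 * M - 1;
  std::vector<int> ca(n_steps), cb(n_steps);
  int s = 0;
  for (int k = 1; k <= M; ++k) { ca[s] = 1; cb[s] = k; ++s; } // (1, m)
  for (int k = 2; k <= M; ++k) { ca[s] = k; cb[s] = 1; ++s; } // (m, 1)

  NumericMatrix tau(n, m);
  tau(0, 0) = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (i == 0 && j == 0) continue;
      if (positional) {
        double best = R_PosInf;
        for (int c = 0; c < n_steps; ++c) {
          int pi = i - ca[c]; if (pi < 0) pi = 0;
          int pj = j - cb[c]; if (pj < 0) pj = 0;
          double v = inc_cost(A, B, i, j, pi, pj, dist_type) + tau(pi, pj);
          if (v < best) best = v;
        }
        tau(i, j) = best;
      } else {
        double best = R_PosInf;
        for (int c = 0; c < n_steps; ++c) {
          int pi = i - ca[c]; if (pi < 0) pi = 0;
          int pj = j - cb[c]; if (pj < 0) pj = 0;
          double w = tau(pi, pj);
          if (w < best) best = w;
        }
        int pi = i > 0 ? i - 1 : 0;
        int pj = j > 0 ? j - 1 : 0;
        tau(i, j) = inc_cost(A, B, i, j, pi, pj, dist_type) + best;
      }
    }
  }
  List out = List::create(
    Named("d") = tau(n - 1, m - 1),
    Named("L_A") = n, Named("L_B") = m
  );
  if (keep_table) out["table"] = tau;
  return out;
}
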