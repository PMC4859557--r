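#include <Rcpp.h>
#include "dd.h"
using namespace Rcpp;

// Core of the binomial-moment method for a Markov-modulated birth-death
// process: the promoter switches between N states with generator A (columns
// sum to zero, entry A[i][j] = rate j -> i), transcribes at rate
// lambda_diag[i] in state i, and transcripts decay at rate delta per copy.
//
// Stationary per-state binomial moments b_k solve
//     (k * delta * I - A) b_k = Lambda b_{k-1},   b_0 = stationary law of A,
// and the stationary copy-number distribution is recovered from the totals
// B_k = sum_i b_k[i] by the alternating sum
//     P(m) = sum_{k >= m} (-1)^{k-m} C(k, m) B_k.
//
// Everything runs in double-double arithmetic: the recursion itself is well
// conditioned, but the alternating sum cancels catastrophically and the
// reconstruction tolerance (1e-8 against FSP) requires the moments to carry
// more than double precision end to end.

// [[Rcpp::export(name = ".bm_core_dd")]]
List bm_core_dd(NumericMatrix A, NumericVector lambda_diag, double delta,
                int K, int Mrec) {
  int n = A.nrow();
  if (A.ncol() != n) stop("A must be square");
  if (lambda_diag.size() != n) stop("lambda_diag length must match A");
  if (K < 0) stop("K must be >= 0");
  bool ok = true;

  // b_0: null vector of A, normalized (last balance equation replaced by
  // the normalization sum_i b_0[i] = 1).
  ddmat M0(n, ddvec(n));
  ddvec r0(n, dd_make(0.0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      M0[i][j] = dd_make(i == n - 1 ? 1.0 : A(i, j));
  r0[n - 1] = dd_make(1.0);
  ddvec b = dd_solve(M0, r0, &ok);
  if (!ok) stop("singular system while solving for the stationary promoter law");

  std::vector<ddvec> bs;
  bs.reserve(K + 1);
  bs.push_back(b);

  for (int k = 1; k <= K; ++k) {
    ddmat M(n, ddvec(n));
    ddvec rhs(n);
    dd kd = two_prod(static_cast<double>(k), delta);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        M[i][j] = dd_make(-A(i, j));
        if (i == j) M[i][j] = dd_add(M[i][j], kd);
      }
      rhs[i] = dd_mul(dd_make(lambda_diag[i]), bs[k - 1][i]);
    }
    ddvec bk = dd_solve(M, rhs, &ok);
    if (!ok) stop("singular system in moment recursion at order %d", k);
    bs.push_back(bk);
  }

  NumericMatrix per_state(K + 1, n);
  NumericVector totals(K + 1);
  ddvec Btot(K + 1);
  for (int k = 0; k <= K; ++k) {
    dd s = dd_make(0.0);
    for (int i = 0; i < n; ++i) {
      per_state(k, i) = bs[k][i].hi + bs[k][i].lo;
      s = dd_add(s, bs[k][i]);
    }
    Btot[k] = s;
    totals[k] = s.hi + s.lo;
  }

  List out = List::create(
    _["b0"] = per_state(0, _),
    _["per_state"] = per_state,
    _["totals"] = totals);

  if (Mrec >= 0) {
    NumericVector probs(Mrec + 1);
    double max_term = 0.0, tail = 0.0;
    for (int m = 0; m <= Mrec && m <= K; ++m) {
      dd acc = dd_make(0.0);
      dd binom = dd_make(1.0);  // C(k, m), starting at k = m
      double last = 0.0;
      for (int k = m; k <= K; ++k) {
        dd term = dd_mul(binom, Btot[k]);
        double ta = dd_abs(term);
        if (ta > max_term) max_term = ta;
        if ((k - m) % 2 == 0) acc = dd_add(acc, term); else acc = dd_sub(acc, term);
        last = ta;
        // C(k+1, m) = C(k, m) * (k+1) / (k+1-m)
        binom = dd_div(dd_mul(binom, dd_make(k + 1.0)), dd_make(k + 1.0 - m));
      }
      probs[m] = acc.hi + acc.lo;
      if (last > tail) tail = last;
    }
    out["probs"] = probs;
    out["max_term"] = max_term;
    out["tail_term"] = tail;  // largest magnitude of the final retained term
  }
  return out;
}

// Probability mass function of the p = q confluent-hypergeometric family
//   P(m) = mu^m / m! * prod_j (gam_j)_m / (alp_j)_m * qFq(m + gam; m + alp; -mu)
// evaluated term by term in double-double arithmetic (the series alternates,
// and machine evaluation loses digits once mu is a few tens).

// [[Rcpp::export(name = ".hyper_pmf_dd")]]
NumericVector hyper_pmf_dd(double mu, NumericVector gam, NumericVector alp,
                           int M) {
  int p = gam.size();
  if (alp.size() != p) stop("gamma and alpha parameter counts must match");
  if (M < 0) stop("M must be >= 0");
  NumericVector probs(M + 1);
  // factors like (m + gam + n - 1) must be formed exactly in double-double
  // (integer part and parameter combined by an error-free two_sum): rounding
  // each factor to a double separately injects incoherent noise that the
  // cancelling series amplifies far above the target accuracy
  dd pref = dd_make(1.0);  // mu^m/m! * prod (gam_j)_m/(alp_j)_m
  for (int m = 0; m <= M; ++m) {
    if (m > 0) {
      pref = dd_div(dd_mul(pref, dd_make(mu)), dd_make(static_cast<double>(m)));
      for (int j = 0; j < p; ++j)
        pref = dd_div(dd_mul(pref, two_sum(m - 1.0, gam[j])),
                      two_sum(m - 1.0, alp[j]));
    }
    // qFq(m + gam; m + alp; -mu) = sum_n t_n,
    // t_0 = 1, t_n = t_{n-1} * (-mu)/n * prod (m+gam_j+n-1)/(m+alp_j+n-1)
    dd sum = dd_make(1.0);
    dd t = dd_make(1.0);
    const int nmax = 100000;
    int nrun = 0;
    for (int nn = 1; nn <= nmax; ++nn) {
      t = dd_div(dd_mul(t, dd_make(-mu)), dd_make(static_cast<double>(nn)));
      for (int j = 0; j < p; ++j)
        t = dd_div(dd_mul(t, two_sum(m + nn - 1.0, gam[j])),
                   two_sum(m + nn - 1.0, alp[j]));
      sum = dd_add(sum, t);
      nrun = nn;
      if (dd_abs(t) < 1e-40 * (dd_abs(sum) + 1e-300) && nn > mu) break;
    }
    if (nrun == nmax) stop("hypergeometric series failed to converge");
    dd val = dd_mul(pref, sum);
    probs[m] = val.hi + val.lo;
  }
  return probs;
}
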