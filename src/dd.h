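#ifndef LOOPNOISE_DD_H
#define LOOPNOISE_DD_H

#include <cmath>
#include <vector>

// Compensated double-double arithmetic (~31 significant decimal digits).
// Needed because the alternating-sum reconstruction of P(m) from binomial
// moments cancels up to ~mu^2m/(m!)^2 against results of order 1, which
// exhausts plain doubles well before the 1e-8 oracle tolerances.

struct dd {
  double hi, lo;
};

inline dd dd_make(double a) { dd r; r.hi = a; r.lo = 0.0; return r; }

// |a| >= |b| assumed
inline dd qtwo_sum(double a, double b) {
  double s = a + b;
  dd r; r.hi = s; r.lo = b - (s - a);
  return r;
}

inline dd two_sum(double a, double b) {
  double s = a + b;
  double v = s - a;
  dd r; r.hi = s; r.lo = (a - (s - v)) + (b - v);
  return r;
}

inline dd two_prod(double a, double b) {
  double p = a * b;
  dd r; r.hi = p; r.lo = std::fma(a, b, -p);
  return r;
}

inline dd dd_add(const dd &a, const dd &b) {
  dd s = two_sum(a.hi, b.hi);
  dd t = two_sum(a.lo, b.lo);
  s.lo += t.hi;
  s = qtwo_sum(s.hi, s.lo);
  s.lo += t.lo;
  return qtwo_sum(s.hi, s.lo);
}

inline dd dd_neg(const dd &a) { dd r; r.hi = -a.hi; r.lo = -a.lo; return r; }

inline dd dd_sub(const dd &a, const dd &b) { return dd_add(a, dd_neg(b)); }

inline dd dd_mul(const dd &a, const dd &b) {
  dd p = two_prod(a.hi, b.hi);
  p.lo += a.hi * b.lo + a.lo * b.hi;
  return qtwo_sum(p.hi, p.lo);
}

inline dd dd_div(const dd &a, const dd &b) {
  double q1 = a.hi / b.hi;
  dd r = dd_sub(a, dd_mul(dd_make(q1), b));
  double q2 = r.hi / b.hi;
  r = dd_sub(r, dd_mul(dd_make(q2), b));
  double q3 = r.hi / b.hi;
  dd q = qtwo_sum(q1, q2);
  return dd_add(q, dd_make(q3));
}

inline double dd_abs(const dd &a) { return std::fabs(a.hi); }

typedef std::vector<dd> ddvec;
typedef std::vector<ddvec> ddmat;

// Gaussian elimination with partial pivoting, in place.
inline ddvec dd_solve(ddmat M, ddvec b, bool *ok) {
  int n = static_cast<int>(b.size());
  *ok = true;
  for (int c = 0; c < n; ++c) {
    int piv = c;
    for (int r = c + 1; r < n; ++r)
      if (dd_abs(M[r][c]) > dd_abs(M[piv][c])) piv = r;
    if (M[piv][c].hi == 0.0) { *ok = false; return ddvec(n, dd_make(0.0)); }
    std::swap(M[piv], M[c]);
    std::swap(b[piv], b[c]);
    for (int r = c + 1; r < n; ++r) {
      dd f = dd_div(M[r][c], M[c][c]);
      for (int cc = c; cc < n; ++cc) M[r][cc] = dd_sub(M[r][cc], dd_mul(f, M[c][cc]));
      b[r] = dd_sub(b[r], dd_mul(f, b[c]));
    }
  }
  ddvec x(n, dd_make(0.0));
  for (int r = n - 1; r >= 0; --r) {
    dd s = b[r];
    for (int cc = r + 1; cc < n; ++cc) s = dd_sub(s, dd_mul(M[r][cc], x[cc]));
    x[r] = dd_div(s, M[r][r]);
  }
  return x;
}

#endif
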