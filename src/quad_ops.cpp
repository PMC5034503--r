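// Vectorised binary128 arithmetic on decimal strings.  These are the
// primitives the R layer uses whenever a coefficient must be combined
// without dropping to double precision (fixed-mu substitution b - mu*c,
// residual accumulation, power-of-two rescaling, comparisons).
#include <Rcpp.h>
#include "qnum.h"

using namespace Rcpp;

static quad qs(const CharacterVector& v, R_xlen_t i) {
  return q_parse(CHAR(STRING_ELT(v, i % v.size())));
}

// [[Rcpp::export(name = ".q_op")]]
CharacterVector q_op(std::string op, CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  CharacterVector out(n);
  int code = op == "+" ? 0 : op == "-" ? 1 : op == "*" ? 2 : op == "/" ? 3 : -1;
  if (code < 0) stop("unknown op '%s'", op.c_str());
  for (R_xlen_t i = 0; i < n; ++i) {
    quad x = qs(a, i), y = qs(b, i), r = 0;
    switch (code) {
      case 0: r = x + y; break;
      case 1: r = x - y; break;
      case 2: r = x * y; break;
      case 3: r = x / y; break;
    }
    out[i] = q_format(r);
  }
  return out;
}

// b - mu * c, elementwise (the fixed-growth-rate substitution).
// [[Rcpp::export(name = ".q_axmy")]]
CharacterVector q_axmy(CharacterVector b, CharacterVector c, std::string mu) {
  quad m = q_parse(mu.c_str());
  R_xlen_t n = std::max(b.size(), c.size());
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = q_format(qs(b, i) - m * qs(c, i));
  return out;
}

// Exact multiplication by 2^k (scaling factors are powers of two).
// [[Rcpp::export(name = ".q_scalbn")]]
CharacterVector q_scalbn(CharacterVector x, IntegerVector k) {
  R_xlen_t n = std::max(x.size(), k.size());
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = q_format(ldexpq(qs(x, i), k[i % k.size()]));
  return out;
}

// [[Rcpp::export(name = ".q_double")]]
NumericVector q_to_double(CharacterVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = q_double(qs(x, i));
  return out;
}

// [[Rcpp::export(name = ".q_sum")]]
std::string q_sum(CharacterVector x) {
  quad s = 0;
  for (R_xlen_t i = 0; i < x.size(); ++i) s += qs(x, i);
  return q_format(s);
}

// Dense dot product (used as an independent accumulation path in tests).
// [[Rcpp::export(name = ".q_dot")]]
std::string q_dot(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("length mismatch in dot product");
  quad s = 0;
  for (R_xlen_t i = 0; i < a.size(); ++i) s += qs(a, i) * qs(b, i);
  return q_format(s);
}

// Grouped sparse accumulation: out[row[t]] += coef[t] * v[col[t]].
// row/col are 1-based.  This evaluates S v, b^T v, c^T v per row in quad.
// [[Rcpp::export(name = ".q_row_sums")]]
CharacterVector q_row_sums(IntegerVector row, IntegerVector col,
                           CharacterVector coef, CharacterVector v,
                           int nrows) {
  std::vector<quad> acc(nrows, quad(0));
  R_xlen_t nnz = row.size();
  if (col.size() != nnz || coef.size() != nnz) stop("triplet length mismatch");
  std::vector<quad> vq(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) vq[i] = qs(v, i);
  for (R_xlen_t t = 0; t < nnz; ++t) {
    int r = row[t], c = col[t];
    if (r < 1 || r > nrows || c < 1 || c > (int)vq.size())
      stop("triplet index out of range");
    acc[r - 1] += q_parse(CHAR(STRING_ELT(coef, t))) * vq[c - 1];
  }
  CharacterVector out(nrows);
  for (int i = 0; i < nrows; ++i) out[i] = q_format(acc[i]);
  return out;
}

// |a - b| / max(1, |b|), returned as a double (the quotient is tiny and
// representable even when the operands differ only at the 30th digit).
// [[Rcpp::export(name = ".q_rel_diff")]]
NumericVector q_rel_diff(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    quad x = qs(a, i), y = qs(b, i);
    quad d = fabsq(x - y) / fmaxq(quad(1), fabsq(y));
    out[i] = q_double(d);
  }
  return out;
}

// Sign of a - b: -1, 0, +1 (exact comparison of two decimal strings).
// [[Rcpp::export(name = ".q_cmp")]]
IntegerVector q_cmp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    quad x = qs(a, i), y = qs(b, i);
    out[i] = x < y ? -1 : (x > y ? 1 : 0);
  }
  return out;
}

// Canonicalise a decimal string to the 36-digit round-trip form.
// [[Rcpp::export(name = ".q_norm")]]
CharacterVector q_normalize(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = q_format(qs(x, i));
  return out;
}
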