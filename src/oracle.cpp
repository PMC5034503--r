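// Exact rational vertex enumeration for small LPs — the independent oracle
// used to certify the simplex.  Every candidate vertex is the solution of an
// n-by-n rational system built from n active constraints chosen among rows
// and bounds; the optimum over feasible candidates is exact.  Infinite
// bounds are boxed at +/- 2^40 and the enumeration is repeated at +/- 2^44:
// if the optimum moves, the problem is unbounded.  Arithmetic is on
// __int128 fractions with overflow detection (fail loudly, never silently).
#include <Rcpp.h>
#include "qnum.h"
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

typedef __int128 i128;

i128 igcd(i128 a, i128 b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b != 0) { i128 t = a % b; a = b; b = t; }
  return a == 0 ? 1 : a;
}

struct Rat {
  i128 p, q;  // q > 0
  Rat() : p(0), q(1) {}
  Rat(i128 pp, i128 qq) : p(pp), q(qq) { norm(); }
  void norm() {
    if (q == 0) throw std::runtime_error("rational division by zero");
    if (q < 0) { p = -p; q = -q; }
    i128 g = igcd(p, q);
    p /= g; q /= g;
  }
};

i128 mul_ck(i128 a, i128 b) {
  i128 r;
  if (__builtin_mul_overflow(a, b, &r))
    throw std::runtime_error("rational overflow in oracle (instance too large)");
  return r;
}
i128 add_ck(i128 a, i128 b) {
  i128 r;
  if (__builtin_add_overflow(a, b, &r))
    throw std::runtime_error("rational overflow in oracle (instance too large)");
  return r;
}

Rat radd(const Rat& a, const Rat& b) {
  return Rat(add_ck(mul_ck(a.p, b.q), mul_ck(b.p, a.q)), mul_ck(a.q, b.q));
}
Rat rsub(const Rat& a, const Rat& b) {
  return Rat(add_ck(mul_ck(a.p, b.q), -mul_ck(b.p, a.q)), mul_ck(a.q, b.q));
}
Rat rmul(const Rat& a, const Rat& b) { return Rat(mul_ck(a.p, b.p), mul_ck(a.q, b.q)); }
Rat rdiv(const Rat& a, const Rat& b) { return Rat(mul_ck(a.p, b.q), mul_ck(a.q, b.p)); }
int rcmp(const Rat& a, const Rat& b) {
  i128 l = mul_ck(a.p, b.q), r = mul_ck(b.p, a.q);
  return l < r ? -1 : (l > r ? 1 : 0);
}
bool rzero(const Rat& a) { return a.p == 0; }

// Parse a decimal string (optionally with exponent) into an exact rational.
Rat rparse(const char* s) {
  while (*s == ' ') ++s;
  bool neg = false;
  if (*s == '+' || *s == '-') { neg = (*s == '-'); ++s; }
  i128 num = 0;
  long frac_digits = 0, expo = 0;
  bool any = false, in_frac = false;
  for (; *s; ++s) {
    if (*s >= '0' && *s <= '9') {
      num = add_ck(mul_ck(num, 10), *s - '0');
      if (in_frac) ++frac_digits;
      any = true;
    } else if (*s == '.' && !in_frac) {
      in_frac = true;
    } else if ((*s == 'e' || *s == 'E') && any) {
      const char* t = s + 1;
      bool eneg = false;
      if (*t == '+' || *t == '-') { eneg = (*t == '-'); ++t; }
      long ev = 0;
      for (; *t >= '0' && *t <= '9'; ++t) ev = ev * 10 + (*t - '0');
      expo = eneg ? -ev : ev;
      break;
    } else {
      throw std::runtime_error(std::string("oracle requires decimal data, got '") + s + "'");
    }
  }
  if (!any) throw std::runtime_error("empty number in oracle input");
  i128 den = 1;
  long net = expo - frac_digits;
  for (long k = 0; k < (net < 0 ? -net : net); ++k) {
    if (net > 0) num = mul_ck(num, 10);
    else den = mul_ck(den, 10);
  }
  return Rat(neg ? -num : num, den);
}

// Solve an n x n rational system by Gaussian elimination; false if singular.
bool rsolve(std::vector<Rat> M, std::vector<Rat> b, int n, std::vector<Rat>& x) {
  for (int k = 0; k < n; ++k) {
    int p = -1;
    for (int i = k; i < n; ++i)
      if (!rzero(M[(size_t)k * n + i])) { p = i; break; }
    if (p < 0) return false;
    if (p != k) {
      for (int j = 0; j < n; ++j) std::swap(M[(size_t)j * n + p], M[(size_t)j * n + k]);
      std::swap(b[p], b[k]);
    }
    for (int i = k + 1; i < n; ++i) {
      if (rzero(M[(size_t)k * n + i])) continue;
      Rat f = rdiv(M[(size_t)k * n + i], M[(size_t)k * n + k]);
      for (int j = k; j < n; ++j)
        M[(size_t)j * n + i] = rsub(M[(size_t)j * n + i], rmul(f, M[(size_t)j * n + k]));
      b[i] = rsub(b[i], rmul(f, b[k]));
    }
  }
  x.assign(n, Rat());
  for (int k = n - 1; k >= 0; --k) {
    Rat s = b[k];
    for (int j = k + 1; j < n; ++j)
      s = rsub(s, rmul(M[(size_t)j * n + k], x[j]));
    x[k] = rdiv(s, M[(size_t)k * n + k]);
  }
  return true;
}

struct Verdict {
  bool feasible = false;
  bool artificial_best = false;  // best objective only at an artificial box bound
  Rat best;
  Rat best_real;                 // best over vertices not touching the box
  bool has_real = false;
};

// Enumerate candidate vertices for the boxed problem.
Verdict enumerate_box(int m, int n, const std::vector<Rat>& A,
                      const std::vector<int>& sense, const std::vector<Rat>& rhs,
                      const std::vector<Rat>& obj,
                      const std::vector<Rat>& lo, const std::vector<Rat>& hi,
                      const std::vector<bool>& lo_art, const std::vector<bool>& hi_art) {
  // constraint list: m rows, then lower bounds, then upper bounds
  int ncon = m + 2 * n;
  std::vector<int> pick(n);
  for (int i = 0; i < n; ++i) pick[i] = i;
  Verdict V;
  bool done = n > ncon;
  long guard = 0;
  while (!done) {
    if (++guard % 4096 == 0) Rcpp::checkUserInterrupt();
    // build system from picked constraints
    std::vector<Rat> M((size_t)n * n), b(n);
    for (int r = 0; r < n; ++r) {
      int c = pick[r];
      if (c < m) {
        for (int j = 0; j < n; ++j) M[(size_t)j * n + r] = A[(size_t)j * m + c];
        b[r] = rhs[c];
      } else if (c < m + n) {
        int j = c - m;
        for (int jj = 0; jj < n; ++jj) M[(size_t)jj * n + r] = Rat(jj == j ? 1 : 0, 1);
        b[r] = lo[j];
      } else {
        int j = c - m - n;
        for (int jj = 0; jj < n; ++jj) M[(size_t)jj * n + r] = Rat(jj == j ? 1 : 0, 1);
        b[r] = hi[j];
      }
    }
    std::vector<Rat> x;
    if (rsolve(M, b, n, x)) {
      // feasibility of the candidate against every constraint
      bool ok = true;
      for (int i = 0; i < m && ok; ++i) {
        Rat act(0, 1);
        for (int j = 0; j < n; ++j)
          if (!rzero(A[(size_t)j * m + i])) act = radd(act, rmul(A[(size_t)j * m + i], x[j]));
        int c = rcmp(act, rhs[i]);
        if (sense[i] == 0) ok = (c == 0);        // eq
        else if (sense[i] == 1) ok = (c >= 0);   // ge
        else ok = (c <= 0);                      // le
      }
      bool touches_art = false;
      for (int j = 0; j < n && ok; ++j) {
        int cl = rcmp(x[j], lo[j]), cu = rcmp(x[j], hi[j]);
        if (cl < 0 || cu > 0) ok = false;
        if (cl == 0 && lo_art[j]) touches_art = true;
        if (cu == 0 && hi_art[j]) touches_art = true;
      }
      if (ok) {
        Rat z(0, 1);
        for (int j = 0; j < n; ++j)
          if (!rzero(obj[j])) z = radd(z, rmul(obj[j], x[j]));
        if (!V.feasible || rcmp(z, V.best) > 0) V.best = z;
        V.feasible = true;
        if (!touches_art) {
          if (!V.has_real || rcmp(z, V.best_real) > 0) V.best_real = z;
          V.has_real = true;
        }
      }
    }
    // next combination
    int r = n - 1;
    while (r >= 0 && pick[r] == ncon - n + r) --r;
    if (r < 0) done = true;
    else {
      ++pick[r];
      for (int rr = r + 1; rr < n; ++rr) pick[rr] = pick[rr - 1] + 1;
    }
  }
  V.artificial_best = V.feasible && (!V.has_real || rcmp(V.best, V.best_real) > 0);
  return V;
}

}  // namespace

// [[Rcpp::export(name = ".vertex_oracle_core")]]
List cpp_vertex_oracle(int m, int n, IntegerVector ai, IntegerVector aj,
                       CharacterVector ax, CharacterVector sense,
                       CharacterVector rhs, CharacterVector obj, bool maximize,
                       CharacterVector lb, CharacterVector ub) {
  if (n > 8 || m > 8)
    stop("vertex oracle is capped at 8 variables and 8 rows (got %d x %d)", m, n);
  std::vector<Rat> A((size_t)n * m);  // column-major m rows
  for (R_xlen_t t = 0; t < ai.size(); ++t) {
    int i = ai[t] - 1, j = aj[t] - 1;
    if (i < 0 || i >= m || j < 0 || j >= n) stop("triplet index out of range");
    A[(size_t)j * m + i] = radd(A[(size_t)j * m + i], rparse(CHAR(STRING_ELT(ax, t))));
  }
  std::vector<int> sen(m);
  std::vector<Rat> rr(m), cc(n);
  for (int i = 0; i < m; ++i) {
    const char* s = CHAR(STRING_ELT(sense, i));
    sen[i] = (s[0] == 'E' || s[0] == '=') ? 0 : (s[0] == 'G' || s[0] == '>') ? 1 : 2;
    rr[i] = rparse(CHAR(STRING_ELT(rhs, i)));
  }
  for (int j = 0; j < n; ++j) {
    cc[j] = rparse(CHAR(STRING_ELT(obj, j)));
    if (!maximize) cc[j] = Rat(-cc[j].p, cc[j].q);
  }

  auto run_at = [&](long boxexp) {
    std::vector<Rat> lo(n), hi(n);
    std::vector<bool> lo_art(n, false), hi_art(n, false);
    i128 big = (i128)1 << boxexp;
    for (int j = 0; j < n; ++j) {
      std::string ls = as<std::string>(lb[j]), us = as<std::string>(ub[j]);
      if (ls == "-Inf" || ls == "-inf") { lo[j] = Rat(-big, 1); lo_art[j] = true; }
      else lo[j] = rparse(ls.c_str());
      if (us == "Inf" || us == "inf" || us == "+Inf") { hi[j] = Rat(big, 1); hi_art[j] = true; }
      else hi[j] = rparse(us.c_str());
    }
    return enumerate_box(m, n, A, sen, rr, cc, lo, hi, lo_art, hi_art);
  };

  Verdict v1 = run_at(40);
  std::string status;
  Rat best = v1.best;
  if (!v1.feasible) {
    status = "infeasible";
  } else if (v1.artificial_best) {
    // confirm unboundedness by growing the box
    Verdict v2 = run_at(44);
    status = (rcmp(v2.best, v1.best) > 0) ? "unbounded" : "optimal";
    best = v2.best;
  } else {
    status = "optimal";
  }

  std::string obj_chr = "NA";
  double obj_dbl = NA_REAL;
  std::string frac = "NA";
  if (status == "optimal") {
    quad z = (quad)(double)0;
    // exact conversion of p/q through binary128
    quad p = 0, q = 0;
    {
      i128 pp = best.p, qq = best.q;
      bool neg = pp < 0; if (neg) pp = -pp;
      p = (quad)(unsigned long long)(pp >> 64) * powq(2.0Q, 64) +
          (quad)(unsigned long long)(pp & 0xFFFFFFFFFFFFFFFFULL);
      if (neg) p = -p;
      q = (quad)(unsigned long long)(qq >> 64) * powq(2.0Q, 64) +
          (quad)(unsigned long long)(qq & 0xFFFFFFFFFFFFFFFFULL);
    }
    z = p / q;
    if (!maximize) z = -z;   // undo the internal max(-c) flip
    obj_chr = q_format(z);
    obj_dbl = q_double(z);
    i128 fp = maximize ? best.p : -best.p;
    char buf[100];
    snprintf(buf, sizeof(buf), "%lld/%lld", (long long)fp, (long long)best.q);
    frac = (fp > INT64_MAX || fp < INT64_MIN || best.q > INT64_MAX)
               ? std::string("(big)") : std::string(buf);
  }
  return List::create(_["status"] = status,
                      _["objective"] = obj_dbl,
                      _["objective_chr"] = obj_chr,
                      _["objective_fraction"] = frac);
}
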