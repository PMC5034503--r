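// Bounded-variable two-phase revised simplex, templated over the working
// precision (double or IEEE binary128).  Design notes:
//   * dense LU of the basis with partial pivoting, product-form (eta) updates,
//     periodic refactorisation;
//   * phase 1 drives the sum of bound violations of basic variables to zero
//     (no artificial columns, no big-M: big-M would poison multiscale data);
//   * Dantzig pricing, switching to Bland's rule after a run of degenerate
//     pivots; ratio-test ties broken by lowest variable index (determinism);
//   * warm starts accept any status vector and repair it (rank-deficient
//     basic sets completed by slacks in row order);
//   * geometric-mean scaling with power-of-two factors (exactly invertible);
//     a scaled solve is followed by a warm-started polish on the original
//     data, so every certified solution refers to the unscaled problem.
#include <Rcpp.h>
#include "qnum.h"
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

enum VStat { BASIC = 0, AT_LOWER = 1, AT_UPPER = 2, FREE_NB = 3 };
enum RowSense { ROW_EQ = 0, ROW_GE = 1, ROW_LE = 2 };

template <class Real>
struct Problem {
  int m = 0, n = 0;               // rows, structural columns
  std::vector<Real> A;            // dense m*n, column-major
  std::vector<int> sense;         // per row
  std::vector<Real> rhs;
  std::vector<Real> obj;          // minimisation objective on structurals
  std::vector<Real> lb, ub;       // length n+m (structurals then slacks)
  int nvar() const { return n + m; }
  // column j of [A | I] into dense buffer
  void col(int j, std::vector<Real>& out) const {
    std::fill(out.begin(), out.end(), Real(0));
    if (j < n) {
      const Real* a = &A[(size_t)j * m];
      for (int i = 0; i < m; ++i) out[i] = a[i];
    } else {
      out[j - n] = Real(1);
    }
  }
  Real entry(int i, int j) const {
    if (j < n) return A[(size_t)j * m + i];
    return j - n == i ? Real(1) : Real(0);
  }
};

template <class Real>
struct Solver {
  typedef real_traits<Real> T;
  const Problem<Real>* P = nullptr;
  Real feas_tol, opt_tol;
  long iter_limit;
  long iters = 0;           // cumulative across calls (scaled + polish)
  int m = 0, n = 0, N = 0;

  std::vector<int> vstat, basic, bpos;
  std::vector<Real> xval;   // value of every variable
  // factorisation of the basis
  std::vector<Real> LU;
  std::vector<int> prow;    // row permutation (LU row i <- original row prow[i])
  struct Eta { int r; std::vector<Real> v; };
  std::vector<Eta> etas;

  int degen_run = 0;
  bool bland = false;
  std::string status = "optimal";
  Real phase1_inf = 0;

  static const int REFACTOR_EVERY = 40;
  static const int BLAND_AFTER = 50;

  void attach(const Problem<Real>* p, Real ftol, Real otol, long ilim) {
    P = p; feas_tol = ftol; opt_tol = otol; iter_limit = ilim;
    m = p->m; n = p->n; N = p->nvar();
  }

  // ---- basis factorisation -------------------------------------------------
  bool lu_factor(int* fail_col) {
    LU.assign((size_t)m * m, Real(0));
    prow.resize(m);
    for (int i = 0; i < m; ++i) prow[i] = i;
    std::vector<Real> colbuf(m);
    for (int k = 0; k < m; ++k) {
      P->col(basic[k], colbuf);
      for (int i = 0; i < m; ++i) LU[(size_t)k * m + i] = colbuf[prow[i]];
    }
    // in-place elimination; LU stored column-major
    for (int k = 0; k < m; ++k) {
      int p = k;
      Real best = T::fabs_(LU[(size_t)k * m + k]);
      for (int i = k + 1; i < m; ++i) {
        Real a = T::fabs_(LU[(size_t)k * m + i]);
        if (a > best) { best = a; p = i; }
      }
      if (!(best > T::drop())) { if (fail_col) *fail_col = k; return false; }
      if (p != k) {
        std::swap(prow[p], prow[k]);
        for (int j = 0; j < m; ++j) std::swap(LU[(size_t)j * m + p], LU[(size_t)j * m + k]);
      }
      Real pivot = LU[(size_t)k * m + k];
      for (int i = k + 1; i < m; ++i) {
        Real f = LU[(size_t)k * m + i] / pivot;
        LU[(size_t)k * m + i] = f;
        if (f != Real(0))
          for (int j = k + 1; j < m; ++j)
            LU[(size_t)j * m + i] -= f * LU[(size_t)j * m + k];
      }
    }
    etas.clear();
    return true;
  }

  void demote(int j) {
    bool lf = !T::isinf_(P->lb[j]), uf = !T::isinf_(P->ub[j]);
    if (lf && uf)
      vstat[j] = (xval[j] - P->lb[j] <= P->ub[j] - xval[j]) ? AT_LOWER : AT_UPPER;
    else if (lf) vstat[j] = AT_LOWER;
    else if (uf) vstat[j] = AT_UPPER;
    else vstat[j] = FREE_NB;
    xval[j] = nb_value(j);
  }

  Real nb_value(int j) const {
    switch (vstat[j]) {
      case AT_LOWER: return P->lb[j];
      case AT_UPPER: return P->ub[j];
      default: return Real(0);
    }
  }

  // Repairing factorisation: on rank deficiency replace the offending basic
  // variable by the slack of the first unpivoted row (slacks in row order).
  bool factor_repair() {
    for (int attempt = 0; attempt <= m + 1; ++attempt) {
      int fail = -1;
      if (lu_factor(&fail)) return true;
      // rows prow[fail..m-1] never became pivot rows
      std::vector<int> cand(prow.begin() + fail, prow.end());
      std::sort(cand.begin(), cand.end());
      int r = -1;
      for (int c : cand) if (vstat[n + c] != BASIC) { r = c; break; }
      if (r < 0) return false;
      int old = basic[fail];
      demote(old);
      bpos[old] = -1;
      basic[fail] = n + r;
      vstat[n + r] = BASIC;
      bpos[n + r] = fail;
    }
    return false;
  }

  // Solve B x = v (overwrites v), applying LU then the eta file.
  void ftran(std::vector<Real>& v) const {
    std::vector<Real> w(m);
    for (int i = 0; i < m; ++i) w[i] = v[prow[i]];
    for (int k = 0; k < m; ++k) {          // L solve (unit lower)
      Real wk = w[k];
      if (wk != Real(0))
        for (int i = k + 1; i < m; ++i) w[i] -= LU[(size_t)k * m + i] * wk;
    }
    for (int k = m - 1; k >= 0; --k) {     // U solve
      Real wk = w[k] / LU[(size_t)k * m + k];
      w[k] = wk;
      if (wk != Real(0))
        for (int i = 0; i < k; ++i) w[i] -= LU[(size_t)k * m + i] * wk;
    }
    // product-form updates: E = I + (eta - e_r) e_r^T, eta stored densely
    for (const Eta& e : etas) {
      Real t = w[e.r];
      if (t == Real(0)) continue;
      for (int i = 0; i < m; ++i) if (i != e.r) w[i] += e.v[i] * t;
      w[e.r] = e.v[e.r] * t;
    }
    v = w;
  }

  // Solve B^T y = v (overwrites v).
  void btran(std::vector<Real>& v) const {
    std::vector<Real> w = v;
    // E^T y leaves every component but r untouched: y_r <- eta^T y
    for (auto it = etas.rbegin(); it != etas.rend(); ++it) {
      Real yr = 0;
      for (int i = 0; i < m; ++i) yr += it->v[i] * w[i];
      w[it->r] = yr;
    }
    // U^T solve then L^T solve
    for (int k = 0; k < m; ++k) {
      Real s = w[k];
      for (int i = 0; i < k; ++i) s -= LU[(size_t)k * m + i] * w[i];
      w[k] = s / LU[(size_t)k * m + k];
    }
    for (int k = m - 1; k >= 0; --k) {
      Real s = w[k];
      for (int i = k + 1; i < m; ++i) s -= LU[(size_t)k * m + i] * w[i];
      w[k] = s;
    }
    std::vector<Real> out(m);
    for (int i = 0; i < m; ++i) out[prow[i]] = w[i];
    v = out;
  }

  void push_eta(const std::vector<Real>& w, int r) {
    Eta e; e.r = r; e.v.assign(m, Real(0));
    Real wr = w[r];
    for (int i = 0; i < m; ++i) e.v[i] = (i == r) ? Real(1) / wr : -w[i] / wr;
    etas.push_back(std::move(e));
  }

  void compute_basics() {
    std::vector<Real> r(m);
    for (int i = 0; i < m; ++i) r[i] = P->rhs[i];
    std::vector<Real> colbuf(m);
    for (int j = 0; j < N; ++j) {
      if (vstat[j] == BASIC) continue;
      Real xj = nb_value(j);
      xval[j] = xj;
      if (xj == Real(0)) continue;
      P->col(j, colbuf);
      for (int i = 0; i < m; ++i) if (colbuf[i] != Real(0)) r[i] -= colbuf[i] * xj;
    }
    ftran(r);
    for (int i = 0; i < m; ++i) xval[basic[i]] = r[i];
  }

  Real infeas_sum() const {
    Real s = 0;
    for (int i = 0; i < m; ++i) {
      int j = basic[i];
      Real x = xval[j];
      if (x < P->lb[j]) s += P->lb[j] - x;
      else if (x > P->ub[j]) s += x - P->ub[j];
    }
    return s;
  }

  // Initialise statuses from a warm vector (or cold: slacks basic).
  void init_basis(const IntegerVector& warm) {
    vstat.assign(N, AT_LOWER);
    xval.assign(N, Real(0));
    bpos.assign(N, -1);
    basic.clear();
    if (warm.size() == N) {
      for (int j = 0; j < N; ++j) {
        int s = warm[j];
        vstat[j] = (s >= 0 && s <= 3) ? s : AT_LOWER;
      }
    } else {
      for (int j = 0; j < n; ++j) vstat[j] = AT_LOWER;
      for (int i = 0; i < m; ++i) vstat[n + i] = BASIC;
    }
    // legalise nonbasic statuses
    for (int j = 0; j < N; ++j) {
      if (vstat[j] == BASIC) continue;
      bool lf = !T::isinf_(P->lb[j]), uf = !T::isinf_(P->ub[j]);
      if (vstat[j] == AT_LOWER && !lf) vstat[j] = uf ? AT_UPPER : FREE_NB;
      if (vstat[j] == AT_UPPER && !uf) vstat[j] = lf ? AT_LOWER : FREE_NB;
      if (vstat[j] == FREE_NB && (lf || uf)) vstat[j] = lf ? AT_LOWER : AT_UPPER;
    }
    for (int j = 0; j < N; ++j) if (vstat[j] == BASIC) basic.push_back(j);
    if ((int)basic.size() > m) {
      for (size_t k = m; k < basic.size(); ++k) demote(basic[k]);
      basic.resize(m);
    }
    while ((int)basic.size() < m) {
      bool added = false;
      for (int i = 0; i < m && (int)basic.size() < m; ++i) {
        if (vstat[n + i] != BASIC) {
          vstat[n + i] = BASIC;
          basic.push_back(n + i);
          added = true;
        }
      }
      if (!added) break;
    }
    for (int k = 0; k < (int)basic.size(); ++k) bpos[basic[k]] = k;
  }

  // One pricing + pivot step.  phase: 1 or 2.
  // Returns: 0 pivoted/flipped, 1 no improving column, 3 unbounded, 5 numerical.
  int step(int phase, const std::vector<Real>& cost) {
    // dual estimates for the phase cost
    std::vector<Real> y(m);
    for (int i = 0; i < m; ++i) {
      int j = basic[i];
      if (phase == 1) {
        Real x = xval[j];
        y[i] = (x < P->lb[j] - feas_tol) ? Real(-1)
             : (x > P->ub[j] + feas_tol) ? Real(1) : Real(0);
      } else {
        y[i] = (j < n) ? cost[j] : Real(0);
      }
    }
    btran(y);
    Real thresh = (phase == 1) ? T::tiny() : opt_tol;
    int q = -1, qdir = 0;
    Real best = 0;
    std::vector<Real> colbuf(m);
    for (int j = 0; j < N; ++j) {
      if (vstat[j] == BASIC) continue;
      if (P->lb[j] == P->ub[j] && !T::isinf_(P->lb[j])) continue; // fixed
      Real cj = (phase == 2 && j < n) ? cost[j] : Real(0);
      Real d;
      if (j < n) {
        const Real* a = &P->A[(size_t)j * m];
        Real s = 0;
        for (int i = 0; i < m; ++i) s += y[i] * a[i];
        d = cj - s;
      } else {
        d = cj - y[j - n];
      }
      int dir = 0;
      Real score = 0;
      if (vstat[j] == AT_LOWER) { if (d < -thresh) { dir = 1; score = -d; } }
      else if (vstat[j] == AT_UPPER) { if (d > thresh) { dir = -1; score = d; } }
      else { // free
        if (d < -thresh) { dir = 1; score = -d; }
        else if (d > thresh) { dir = -1; score = d; }
      }
      if (dir != 0) {
        if (bland) { q = j; qdir = dir; break; }
        if (score > best) { best = score; q = j; qdir = dir; }
      }
    }
    if (q < 0) return 1;

    // direction through the basis
    std::vector<Real> w(m);
    P->col(q, w);
    ftran(w);

    for (int attempt = 0; attempt < 2; ++attempt) {
      Real sigma = (Real)qdir;
      Real tbest = T::inf();
      int leave_pos = -1, leave_bound = 0, tie_idx = N + 1;
      bool own_bound = false;
      // entering variable's own range
      {
        Real range = P->ub[q] - P->lb[q];
        if (!T::isinf_(range)) { tbest = range; own_bound = true; tie_idx = q; }
      }
      for (int i = 0; i < m; ++i) {
        Real delta = -sigma * w[i];
        if (T::fabs_(delta) <= T::tiny()) continue;
        int j = basic[i];
        Real x = xval[j], l = P->lb[j], u = P->ub[j];
        Real ti = T::inf();
        int bnd = 0;
        if (phase == 1 && x < l - feas_tol) {
          if (delta > Real(0)) { ti = (l - x) / delta; bnd = 1; }
        } else if (phase == 1 && x > u + feas_tol) {
          if (delta < Real(0)) { ti = (u - x) / delta; bnd = 2; }
        } else {
          if (delta > Real(0) && !T::isinf_(u)) { ti = (u - x) / delta; bnd = 2; }
          else if (delta < Real(0) && !T::isinf_(l)) { ti = (l - x) / delta; bnd = 1; }
        }
        if (bnd == 0 || T::isinf_(ti)) continue;
        if (ti < Real(0)) ti = 0;
        if (ti < tbest || (ti == tbest && j < tie_idx)) {
          tbest = ti; leave_pos = i; leave_bound = bnd; tie_idx = j; own_bound = false;
        }
      }
      if (T::isinf_(tbest)) {
        if (phase == 2) return 3;   // unbounded
        return 5;                   // phase-1 descent unbounded: numerical trouble
      }
      if (own_bound || leave_pos < 0) {
        // bound flip
        for (int i = 0; i < m; ++i)
          if (w[i] != Real(0)) xval[basic[i]] -= sigma * tbest * w[i];
        vstat[q] = (vstat[q] == AT_LOWER) ? AT_UPPER : AT_LOWER;
        xval[q] = nb_value(q);
        note_degen(tbest);
        ++iters;
        return 0;
      }
      // pivot: check eta stability
      if (T::fabs_(w[leave_pos]) <= T::tiny()) {
        if (attempt == 0 && !etas.empty()) {
          if (!factor_repair()) return 5;
          compute_basics();
          P->col(q, w);
          ftran(w);
          continue;
        }
        return 5;
      }
      Real xq_new = xval[q] + sigma * tbest;
      for (int i = 0; i < m; ++i)
        if (w[i] != Real(0)) xval[basic[i]] -= sigma * tbest * w[i];
      int leaving = basic[leave_pos];
      vstat[leaving] = (leave_bound == 1) ? AT_LOWER : AT_UPPER;
      xval[leaving] = nb_value(leaving);
      bpos[leaving] = -1;
      push_eta(w, leave_pos);
      basic[leave_pos] = q;
      bpos[q] = leave_pos;
      vstat[q] = BASIC;
      xval[q] = xq_new;
      note_degen(tbest);
      ++iters;
      if ((int)etas.size() >= REFACTOR_EVERY) {
        if (!factor_repair()) return 5;
        compute_basics();
      }
      return 0;
    }
    return 5;
  }

  void note_degen(Real t) {
    if (T::fabs_(t) <= T::tiny()) {
      if (++degen_run > BLAND_AFTER) bland = true;
    } else {
      degen_run = 0;
      bland = false;
    }
  }

  // Full solve from current statuses.  cost = minimisation objective.
  void run(const std::vector<Real>& cost) {
    if (!factor_repair()) { status = "numerical"; return; }
    compute_basics();
    status = "optimal";
    int phase = 1;
    long since_refresh = 0;
    while (true) {
      if (iters >= iter_limit) { status = "iteration_limit"; break; }
      if (++since_refresh % 2000 == 0) Rcpp::checkUserInterrupt();
      if (phase == 1) {
        phase1_inf = infeas_sum();
        if (!(phase1_inf > feas_tol)) { phase = 2; continue; }
      }
      int rc = step(phase, cost);
      if (rc == 0) {
        if (phase == 2) {
          // numerical safety: fall back to phase 1 if feasibility drifts
          Real s = infeas_sum();
          if (s > feas_tol * Real(16)) phase = 1;
        }
        continue;
      }
      if (rc == 1) {
        if (phase == 1) {
          phase1_inf = infeas_sum();
          if (phase1_inf > feas_tol) { status = "infeasible"; break; }
          phase = 2;
          continue;
        }
        // optimal
        if (!factor_repair()) { status = "numerical"; break; }
        compute_basics();
        phase1_inf = infeas_sum();
        if (phase1_inf > feas_tol) { phase = 1; continue; }
        status = "optimal";
        break;
      }
      if (rc == 3) { status = "unbounded"; break; }
      status = "numerical";
      break;
    }
  }
};

// ---------------------------------------------------------------------------
// geometric-mean scaling with power-of-two factors (mode 2)
// ---------------------------------------------------------------------------
static void scale_exponents(int m, int n, const std::vector<double>& lg,
                            const std::vector<char>& nz,
                            std::vector<int>& rowe, std::vector<int>& cole,
                            int passes = 10) {
  rowe.assign(m, 0);
  cole.assign(n, 0);
  if (m == 0 || n == 0) return;
  std::vector<double> re(m, 0.0), ce(n, 0.0);
  double prev_change = 1e300;
  for (int p = 0; p < passes; ++p) {
    double change = 0;
    for (int i = 0; i < m; ++i) {
      double lo = 1e300, hi = -1e300;
      for (int j = 0; j < n; ++j) {
        if (!nz[(size_t)j * m + i]) continue;
        double v = lg[(size_t)j * m + i] + re[i] + ce[j];
        lo = std::min(lo, v); hi = std::max(hi, v);
      }
      if (hi < lo) continue;
      double adj = -0.5 * (lo + hi);
      re[i] += adj;
      change = std::max(change, std::fabs(adj));
    }
    for (int j = 0; j < n; ++j) {
      double lo = 1e300, hi = -1e300;
      for (int i = 0; i < m; ++i) {
        if (!nz[(size_t)j * m + i]) continue;
        double v = lg[(size_t)j * m + i] + re[i] + ce[j];
        lo = std::min(lo, v); hi = std::max(hi, v);
      }
      if (hi < lo) continue;
      double adj = -0.5 * (lo + hi);
      ce[j] += adj;
      change = std::max(change, std::fabs(adj));
    }
    if (change < std::log2(1.10)) break;   // factor change under 10%
    prev_change = change;
    (void)prev_change;
  }
  for (int i = 0; i < m; ++i) rowe[i] = (int)std::lround(re[i]);
  // final column pass: bring each column's largest scaled entry near 1
  for (int j = 0; j < n; ++j) {
    double hi = -1e300;
    for (int i = 0; i < m; ++i)
      if (nz[(size_t)j * m + i]) hi = std::max(hi, lg[(size_t)j * m + i] + rowe[i] + ce[j]);
    double adj = (hi > -1e300) ? -hi : 0.0;
    cole[j] = (int)std::lround(ce[j] + adj);
  }
}

// [[Rcpp::export(name = ".scale_factors")]]
List cpp_scale_factors(int m, int n, IntegerVector ai, IntegerVector aj,
                       CharacterVector ax) {
  std::vector<double> lg((size_t)m * n, 0.0);
  std::vector<char> nz((size_t)m * n, 0);
  for (R_xlen_t t = 0; t < ai.size(); ++t) {
    int i = ai[t] - 1, j = aj[t] - 1;
    if (i < 0 || i >= m || j < 0 || j >= n) stop("triplet index out of range");
    quad v = q_parse(CHAR(STRING_ELT(ax, t)));
    if (v == 0) continue;
    lg[(size_t)j * m + i] = q_double(log2q(fabsq(v)));
    nz[(size_t)j * m + i] = 1;
  }
  std::vector<int> rowe, cole;
  scale_exponents(m, n, lg, nz, rowe, cole);
  return List::create(_["row_exp"] = IntegerVector(rowe.begin(), rowe.end()),
                      _["col_exp"] = IntegerVector(cole.begin(), cole.end()));
}

// ---------------------------------------------------------------------------
// main entry
// ---------------------------------------------------------------------------
template <class Real>
static List solve_with(int m, int n, IntegerVector ai, IntegerVector aj,
                       CharacterVector ax, CharacterVector sense,
                       CharacterVector rhs, CharacterVector obj, bool maximize,
                       CharacterVector lb, CharacterVector ub,
                       double feas_tol, double opt_tol, int iter_limit,
                       int scaling, IntegerVector warm) {
  typedef real_traits<Real> T;
  Problem<Real> P;
  P.m = m; P.n = n;
  P.A.assign((size_t)m * n, Real(0));
  for (R_xlen_t t = 0; t < ai.size(); ++t) {
    int i = ai[t] - 1, j = aj[t] - 1;
    if (i < 0 || i >= m || j < 0 || j >= n) stop("triplet index out of range");
    P.A[(size_t)j * m + i] += T::parse(CHAR(STRING_ELT(ax, t)));
  }
  P.sense.resize(m);
  P.rhs.resize(m);
  for (int i = 0; i < m; ++i) {
    const char* s = CHAR(STRING_ELT(sense, i));
    P.sense[i] = (s[0] == 'E' || s[0] == 'e' || s[0] == '=') ? ROW_EQ
               : (s[0] == 'G' || s[0] == 'g' || s[0] == '>') ? ROW_GE : ROW_LE;
    P.rhs[i] = T::parse(CHAR(STRING_ELT(rhs, i)));
    if (T::isinf_(P.rhs[i])) stop("non-finite right-hand side in row %d", i + 1);
  }
  P.obj.resize(n);
  for (int j = 0; j < n; ++j) P.obj[j] = T::parse(CHAR(STRING_ELT(obj, j)));
  P.lb.resize(n + m);
  P.ub.resize(n + m);
  for (int j = 0; j < n; ++j) {
    P.lb[j] = T::parse(CHAR(STRING_ELT(lb, j)));
    P.ub[j] = T::parse(CHAR(STRING_ELT(ub, j)));
    if (P.lb[j] > P.ub[j]) {
      // contradictory bounds: report infeasible without pivoting
      return List::create(_["status"] = "infeasible",
                          _["objective"] = NA_REAL,
                          _["objective_chr"] = "0",
                          _["phase1_infeasibility"] = q_format(quad(1)),
                          _["phase1_infeasibility_dbl"] = 1.0,
                          _["iterations"] = 0L,
                          _["vstatus"] = IntegerVector(0));
    }
  }
  for (int i = 0; i < m; ++i) {
    // row a^T x + s = b;  s >= 0 encodes <=, s <= 0 encodes >=, s = 0 equality
    switch (P.sense[i]) {
      case ROW_EQ: P.lb[n + i] = 0; P.ub[n + i] = 0; break;
      case ROW_GE: P.lb[n + i] = -T::inf(); P.ub[n + i] = 0; break;
      default:     P.lb[n + i] = 0; P.ub[n + i] = T::inf(); break;
    }
  }
  // minimisation objective
  std::vector<Real> cost(P.obj);
  if (maximize) for (auto& c : cost) c = -c;

  Solver<Real> S;
  S.attach(&P, (Real)feas_tol, (Real)opt_tol, iter_limit);
  S.init_basis(warm);

  if (scaling == 2 && m > 0 && n > 0) {
    // scaled solve first, then warm-started polish on original data below
    std::vector<double> lg((size_t)m * n, 0.0);
    std::vector<char> nz((size_t)m * n, 0);
    for (size_t idx = 0; idx < P.A.size(); ++idx) {
      if (P.A[idx] == Real(0)) continue;
      nz[idx] = 1;
      lg[idx] = std::log2(std::fabs((double)q_double((quad)P.A[idx])) + 1e-300);
    }
    std::vector<int> rowe, cole;
    scale_exponents(m, n, lg, nz, rowe, cole);
    Problem<Real> PS = P;
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < m; ++i) {
        Real& a = PS.A[(size_t)j * m + i];
        if (a != Real(0)) a = T::ldexp_(a, rowe[i] + cole[j]);
      }
    for (int i = 0; i < m; ++i) PS.rhs[i] = T::ldexp_(PS.rhs[i], rowe[i]);
    for (int j = 0; j < n; ++j) {
      if (!T::isinf_(PS.lb[j])) PS.lb[j] = T::ldexp_(PS.lb[j], -cole[j]);
      if (!T::isinf_(PS.ub[j])) PS.ub[j] = T::ldexp_(PS.ub[j], -cole[j]);
      PS.obj[j] = T::ldexp_(PS.obj[j], cole[j]);
    }
    std::vector<Real> costS(PS.obj);
    if (maximize) for (auto& c : costS) c = -c;
    Solver<Real> SS;
    SS.attach(&PS, (Real)feas_tol, (Real)opt_tol, iter_limit);
    SS.init_basis(warm);
    SS.run(costS);
    if (SS.status == "optimal" || SS.status == "infeasible") {
      // adopt the final statuses for the authoritative unscaled solve
      IntegerVector ws(P.nvar());
      for (int j = 0; j < P.nvar(); ++j) ws[j] = SS.vstat[j];
      S.init_basis(ws);
      S.iters = SS.iters;
    } else {
      S.iters = SS.iters;   // fall through: cold polish still correct
    }
  }

  S.run(cost);

  // outputs -----------------------------------------------------------------
  std::string st = S.status;
  CharacterVector x_chr(n);
  NumericVector x_dbl(n);
  NumericVector slack_dbl(m);
  for (int j = 0; j < n; ++j) {
    x_chr[j] = T::format(S.xval[j]);
    x_dbl[j] = q_double((quad)S.xval[j]);
  }
  for (int i = 0; i < m; ++i) slack_dbl[i] = q_double((quad)S.xval[n + i]);
  // duals / reduced costs at the final basis
  NumericVector y_dbl(m), d_dbl(n + m);
  Real max_dual = 0, max_compl = 0;
  {
    std::vector<Real> y(m);
    for (int i = 0; i < m; ++i) {
      int j = S.basic[i];
      y[i] = (j < n) ? cost[j] : Real(0);
    }
    S.btran(y);
    for (int i = 0; i < m; ++i) y_dbl[i] = q_double((quad)(maximize ? -y[i] : y[i]));
    for (int j = 0; j < n + m; ++j) {
      Real cj = (j < n) ? cost[j] : Real(0);
      Real s = 0;
      if (j < n) for (int i = 0; i < m; ++i) s += y[i] * P.A[(size_t)j * m + i];
      else s = y[j - n];
      Real d = cj - s;
      d_dbl[j] = q_double((quad)(maximize ? -d : d));
      if (S.vstat[j] == BASIC) {
        Real v = T::fabs_(d);
        if (v > max_compl) max_compl = v;
      } else if (st == "optimal") {
        Real viol = 0;
        if (S.vstat[j] == AT_LOWER) viol = d < Real(0) ? -d : Real(0);
        else if (S.vstat[j] == AT_UPPER) viol = d > Real(0) ? d : Real(0);
        else viol = T::fabs_(d);
        if (P.lb[j] == P.ub[j]) viol = 0;  // fixed variables carry no sign condition
        if (viol > max_dual) max_dual = viol;
      }
    }
  }
  // primal residuals recomputed from scratch
  Real max_row = 0, max_bound = 0;
  {
    for (int i = 0; i < m; ++i) {
      Real act = 0;
      for (int j = 0; j < n; ++j) act += P.A[(size_t)j * m + i] * S.xval[j];
      Real viol = 0;
      switch (P.sense[i]) {
        case ROW_EQ: viol = T::fabs_(act - P.rhs[i]); break;
        case ROW_GE: viol = act < P.rhs[i] ? P.rhs[i] - act : Real(0); break;
        default:     viol = act > P.rhs[i] ? act - P.rhs[i] : Real(0); break;
      }
      if (viol > max_row) max_row = viol;
    }
    for (int j = 0; j < n; ++j) {
      Real v = 0;
      if (S.xval[j] < P.lb[j]) v = P.lb[j] - S.xval[j];
      else if (S.xval[j] > P.ub[j]) v = S.xval[j] - P.ub[j];
      if (v > max_bound) max_bound = v;
    }
  }
  Real objv = 0;
  for (int j = 0; j < n; ++j) objv += P.obj[j] * S.xval[j];

  IntegerVector vst(n + m);
  for (int j = 0; j < n + m; ++j) vst[j] = S.vstat[j];
  IntegerVector bas(S.basic.begin(), S.basic.end());

  return List::create(
      _["status"] = st,
      _["objective"] = q_double((quad)objv),
      _["objective_chr"] = T::format(objv),
      _["x"] = x_dbl,
      _["x_chr"] = x_chr,
      _["slack"] = slack_dbl,
      _["dual"] = y_dbl,
      _["reduced_cost"] = d_dbl,
      _["vstatus"] = vst,
      _["basic"] = bas,
      _["iterations"] = (double)S.iters,
      _["phase1_infeasibility"] = q_double((quad)S.phase1_inf),
      _["phase1_infeasibility_chr"] = T::format(S.phase1_inf),
      _["residuals"] = NumericVector::create(
          _["max_primal"] = q_double((quad)max_row),
          _["max_bound"] = q_double((quad)max_bound),
          _["max_dual"] = q_double((quad)max_dual),
          _["max_complementarity"] = q_double((quad)max_compl)));
}

// [[Rcpp::export(name = ".solve_lp_core")]]
List cpp_solve_lp(int m, int n, IntegerVector ai, IntegerVector aj,
                  CharacterVector ax, CharacterVector sense,
                  CharacterVector rhs, CharacterVector obj, bool maximize,
                  CharacterVector lb, CharacterVector ub, bool quad_mode,
                  double feas_tol, double opt_tol, int iter_limit, int scaling,
                  IntegerVector warm) {
  if (quad_mode)
    return solve_with<quad>(m, n, ai, aj, ax, sense, rhs, obj, maximize, lb, ub,
                            feas_tol, opt_tol, iter_limit, scaling, warm);
  return solve_with<double>(m, n, ai, aj, ax, sense, rhs, obj, maximize, lb, ub,
                            feas_tol, opt_tol, iter_limit, scaling, warm);
}
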