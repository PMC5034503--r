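// Minimal IEEE binary128 helpers shared by the simplex core and the
// vectorised string-arithmetic entry points.  All numeric interchange with R
// is via decimal strings so that coefficients survive round-trips at full
// extended precision (an R double would truncate to 53 bits).
#ifndef MEMAX_QNUM_H
#define MEMAX_QNUM_H

#include <quadmath.h>
#include <cmath>
#include <cstdio>
#include <cstring>
#include <string>
#include <stdexcept>

typedef __float128 quad;

inline quad q_inf() { return HUGE_VALQ; }

inline bool q_is_inf(quad x) { return isinfq(x) != 0; }

// Parse a decimal string; "Inf"/"-Inf"/"inf" accepted for bounds.
inline quad q_parse(const char* s) {
  if (s == nullptr) throw std::runtime_error("NULL numeric string");
  while (*s == ' ') ++s;
  if (std::strcmp(s, "Inf") == 0 || std::strcmp(s, "inf") == 0 ||
      std::strcmp(s, "+Inf") == 0)
    return HUGE_VALQ;
  if (std::strcmp(s, "-Inf") == 0 || std::strcmp(s, "-inf") == 0)
    return -HUGE_VALQ;
  char* end = nullptr;
  quad v = strtoflt128(s, &end);
  if (end == s) throw std::runtime_error(std::string("not a number: '") + s + "'");
  return v;
}

// Shortest-ish round-trippable representation: 36 significant digits is
// enough to reproduce any binary128 value exactly on re-parse.
inline std::string q_format(quad x, int digits = 36) {
  if (q_is_inf(x)) return x > 0 ? "Inf" : "-Inf";
  char buf[128];
  quadmath_snprintf(buf, sizeof(buf), "%.*Qe", digits - 1, x);
  return std::string(buf);
}

inline double q_double(quad x) {
  if (q_is_inf(x)) return x > 0 ? INFINITY : -INFINITY;
  return static_cast<double>(x);
}

// Working-precision traits so the simplex template can run in either mode.
template <class Real> struct real_traits;

template <> struct real_traits<double> {
  static double parse(const char* s) {
    quad v = q_parse(s);
    return q_double(v);
  }
  static std::string format(double x) {
    if (std::isinf(x)) return x > 0 ? "Inf" : "-Inf";
    char buf[64];
    snprintf(buf, sizeof(buf), "%.17g", x);
    return std::string(buf);
  }
  static double fabs_(double x) { return std::fabs(x); }
  static bool isinf_(double x) { return std::isinf(x); }
  static double inf() { return INFINITY; }
  static double ldexp_(double x, int k) { return std::ldexp(x, k); }
  // below this, a pivot/ratio denominator is treated as zero
  static double tiny() { return 1e-11; }
  static double drop() { return 1e-13; }
};

template <> struct real_traits<quad> {
  static quad parse(const char* s) { return q_parse(s); }
  static std::string format(quad x) { return q_format(x); }
  static quad fabs_(quad x) { return fabsq(x); }
  static bool isinf_(quad x) { return q_is_inf(x); }
  static quad inf() { return HUGE_VALQ; }
  static quad ldexp_(quad x, int k) { return ldexpq(x, k); }
  static quad tiny() { return quad(1e-25); }
  static quad drop() { return quad(1e-28); }
};

#endif
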