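#ifndef EDNEGUQ_DUAL_H
#define EDNEGUQ_DUAL_H

#include <cmath>

// First-order forward-mode dual number: value + one directional derivative.
// Used to obtain the exact Jacobian of the model right-hand side (one seeded
// pass per state variable), so the implicit solver sees derivatives that are
// exact to the implemented equations.
struct Dual {
  double v;  // value
  double d;  // derivative
  Dual() : v(0.0), d(0.0) {}
  Dual(double v_) : v(v_), d(0.0) {}
  Dual(double v_, double d_) : v(v_), d(d_) {}
};

inline double val(double x) { return x; }
inline double val(const Dual &x) { return x.v; }

inline Dual operator+(const Dual &a, const Dual &b) { return Dual(a.v + b.v, a.d + b.d); }
inline Dual operator+(const Dual &a, double b) { return Dual(a.v + b, a.d); }
inline Dual operator+(double a, const Dual &b) { return Dual(a + b.v, b.d); }
inline Dual operator-(const Dual &a) { return Dual(-a.v, -a.d); }
inline Dual operator-(const Dual &a, const Dual &b) { return Dual(a.v - b.v, a.d - b.d); }
inline Dual operator-(const Dual &a, double b) { return Dual(a.v - b, a.d); }
inline Dual operator-(double a, const Dual &b) { return Dual(a - b.v, -b.d); }
inline Dual operator*(const Dual &a, const Dual &b) { return Dual(a.v * b.v, a.d * b.v + a.v * b.d); }
inline Dual operator*(const Dual &a, double b) { return Dual(a.v * b, a.d * b); }
inline Dual operator*(double a, const Dual &b) { return Dual(a * b.v, a * b.d); }
inline Dual operator/(const Dual &a, const Dual &b) {
  double inv = 1.0 / b.v;
  return Dual(a.v * inv, (a.d - a.v * inv * b.d) * inv);
}
inline Dual operator/(const Dual &a, double b) { return Dual(a.v / b, a.d / b); }
inline Dual operator/(double a, const Dual &b) {
  double inv = 1.0 / b.v;
  return Dual(a * inv, -a * inv * inv * b.d);
}

inline Dual exp(const Dual &a) { double e = std::exp(a.v); return Dual(e, e * a.d); }
inline Dual expm1(const Dual &a) { double e = std::exp(a.v); return Dual(std::expm1(a.v), e * a.d); }
inline Dual log(const Dual &a) { return Dual(std::log(a.v), a.d / a.v); }
inline Dual sqrt(const Dual &a) { double s = std::sqrt(a.v); return Dual(s, 0.5 * a.d / s); }

// Non-smooth primitives: derivative taken from the active branch.
inline Dual dmax(const Dual &a, double b) { return a.v >= b ? a : Dual(b, 0.0); }
inline double dmax(double a, double b) { return a >= b ? a : b; }
inline Dual dmin(const Dual &a, double b) { return a.v <= b ? a : Dual(b, 0.0); }
inline double dmin(double a, double b) { return a <= b ? a : b; }

#endif
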