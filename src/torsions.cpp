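#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Apply absolute backbone torsion targets to a coordinate matrix.
// Torsion t rotates the atom set moving[t] (the Fab side of the bond)
// about the axisA->axisB bond so that the measured dihedral
// (ref, axisA, axisB, fourth) equals target[t]; when a reference atom is
// absent (index 0) the target acts as a relative rotation.

namespace {

inline double dihedral(const double* x, int p1, int p2, int p3, int p4) {
  double b1[3], b2[3], b3[3];
  for (int d = 0; d < 3; ++d) {
    b1[d] = x[3 * p2 + d] - x[3 * p1 + d];
    b2[d] = x[3 * p3 + d] - x[3 * p2 + d];
    b3[d] = x[3 * p4 + d] - x[3 * p3 + d];
  }
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1], b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1], b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  double nb = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double m1[3] = {n1[1] * b2[2] - n1[2] * b2[1], n1[2] * b2[0] - n1[0] * b2[2],
                  n1[0] * b2[1] - n1[1] * b2[0]};
  double xdot = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double ydot = (m1[0] * n2[0] + m1[1] * n2[1] + m1[2] * n2[2]) / nb;
  return std::atan2(ydot, xdot) * 180.0 / M_PI;
}

// wrap into (-180, 180] without fmod
inline double wrap(double a) {
  double y = (a + 180.0) - 360.0 * std::floor((a + 180.0) / 360.0) - 180.0;
  if (y == -180.0) y = 180.0;
  return y;
}

}  // namespace

// [[Rcpp::export(name = ".apply_torsions")]]
NumericMatrix apply_torsions(NumericMatrix coords, IntegerVector axisA,
                             IntegerVector axisB, IntegerVector ref,
                             IntegerVector fourth, List moving,
                             NumericVector targets) {
  const int n = coords.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);

  const int nt = axisA.size();
  for (int t = 0; t < nt; ++t) {
    int a = axisA[t] - 1, b = axisB[t] - 1;
    double delta;
    if (ref[t] > 0 && fourth[t] > 0) {
      double cur = dihedral(&x[0], ref[t] - 1, a, b, fourth[t] - 1);
      delta = wrap(targets[t] - cur);
    } else {
      delta = wrap(targets[t]);
    }
    if (std::fabs(delta) < 1e-12) continue;
    double u[3] = {x[3 * b] - x[3 * a], x[3 * b + 1] - x[3 * a + 1],
                   x[3 * b + 2] - x[3 * a + 2]};
    double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    for (int d = 0; d < 3; ++d) u[d] /= nu;
    double th = delta * M_PI / 180.0;
    double ct = std::cos(th), st = std::sin(th);
    IntegerVector mv = moving[t];
    for (int k = 0; k < mv.size(); ++k) {
      int i = mv[k] - 1;
      double v[3] = {x[3 * i] - x[3 * b], x[3 * i + 1] - x[3 * b + 1],
                     x[3 * i + 2] - x[3 * b + 2]};
      double cx[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                      u[0] * v[1] - u[1] * v[0]};
      double ud = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
      for (int d = 0; d < 3; ++d)
        x[3 * i + d] = x[3 * b + d] + v[d] * ct + cx[d] * st +
                       u[d] * ud * (1 - ct);
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3 * i + d];
  return out;
}
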