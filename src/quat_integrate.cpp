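#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Exact per-sample axis-angle integration of body angular rates.
// omega: n x 3 in deg/s; q0: starting unit quaternion (w x y z);
// returns the n x 4 attitude path (row t is the attitude after applying
// the rates of rows 1..t; row 1 equals q0 rotated by row 1's rate).

// [[Rcpp::export(name = ".integrate_gyro_cpp")]]
NumericMatrix integrate_gyro_cpp(NumericMatrix omega, double rate_hz,
                                 NumericVector q0) {
  const int n = omega.nrow();
  const double dt = 1.0 / rate_hz;
  const double D2R = M_PI / 180.0;
  NumericMatrix out(n, 4);
  double w = q0[0], x = q0[1], y = q0[2], z = q0[3];
  for (int t = 0; t < n; ++t) {
    double rx = omega(t, 0) * D2R * dt;
    double ry = omega(t, 1) * D2R * dt;
    double rz = omega(t, 2) * D2R * dt;
    double a = std::sqrt(rx * rx + ry * ry + rz * rz);
    double dw, dx, dy, dz;
    if (a < 1e-12) {
      dw = 1.0; dx = 0.5 * rx; dy = 0.5 * ry; dz = 0.5 * rz;
    } else {
      double s = std::sin(0.5 * a) / a;
      dw = std::cos(0.5 * a); dx = rx * s; dy = ry * s; dz = rz * s;
    }
    double nw = w * dw - x * dx - y * dy - z * dz;
    double nx = w * dx + x * dw + y * dz - z * dy;
    double ny = w * dy - x * dz + y * dw + z * dx;
    double nz = w * dz + x * dy - y * dx + z * dw;
    double nn = std::sqrt(nw * nw + nx * nx + ny * ny + nz * nz);
    w = nw / nn; x = nx / nn; y = ny / nn; z = nz / nn;
    out(t, 0) = w; out(t, 1) = x; out(t, 2) = y; out(t, 3) = z;
  }
  return out;
}
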