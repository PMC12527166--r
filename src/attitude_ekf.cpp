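#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Quaternion-based error-state extended Kalman filter for head attitude.
//
// State: unit quaternion q mapping head-frame vectors into a gravity-
// polarized Earth frame, plus a 3x3 covariance P of the small-angle
// attitude error expressed in the head frame.  The gyroscope drives the
// process model (exact per-sample axis-angle integration); the
// accelerometer's direction supplies the gravity observation.  var_gyr
// scales the process noise, var_acc the measurement noise.  Yaw is
// unobservable from gravity and therefore drifts only with gyro error,
// which is the intended behavior: azimuth is used relatively downstream.

struct Quat { double w, x, y, z; };

static inline Quat qmul(const Quat &a, const Quat &b) {
  Quat r;
  r.w = a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z;
  r.x = a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y;
  r.y = a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x;
  r.z = a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w;
  return r;
}

static inline void qnormalize(Quat &q) {
  double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  q.w /= n; q.x /= n; q.y /= n; q.z /= n;
}

// quaternion for a rotation vector (axis * angle, radians)
static inline Quat qexp(double rx, double ry, double rz) {
  double a = std::sqrt(rx * rx + ry * ry + rz * rz);
  Quat q;
  if (a < 1e-12) {
    q.w = 1.0; q.x = 0.5 * rx; q.y = 0.5 * ry; q.z = 0.5 * rz;
  } else {
    double s = std::sin(0.5 * a) / a;
    q.w = std::cos(0.5 * a); q.x = rx * s; q.y = ry * s; q.z = rz * s;
  }
  qnormalize(q);
  return q;
}

// R(q) applied to v (head -> Earth)
static inline void qrot(const Quat &q, const double v[3], double out[3]) {
  // out = v + 2*qv x (qv x v + w*v)
  double tx = 2.0 * (q.y * v[2] - q.z * v[1]);
  double ty = 2.0 * (q.z * v[0] - q.x * v[2]);
  double tz = 2.0 * (q.x * v[1] - q.y * v[0]);
  out[0] = v[0] + q.w * tx + (q.y * tz - q.z * ty);
  out[1] = v[1] + q.w * ty + (q.z * tx - q.x * tz);
  out[2] = v[2] + q.w * tz + (q.x * ty - q.y * tx);
}

static inline Quat qconj(const Quat &q) {
  Quat r = {q.w, -q.x, -q.y, -q.z};
  return r;
}

// 3x3 helpers (row-major double[9])
static void mat3_mul(const double *A, const double *B, double *C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A[3 * i + k] * B[3 * k + j];
      C[3 * i + j] = s;
    }
}

static bool mat3_inv(const double *A, double *inv) {
  double a = A[0], b = A[1], c = A[2], d = A[3], e = A[4], f = A[5],
         g = A[6], h = A[7], i = A[8];
  double det = a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g);
  if (std::fabs(det) < 1e-300) return false;
  double id = 1.0 / det;
  inv[0] = (e * i - f * h) * id;  inv[1] = (c * h - b * i) * id;  inv[2] = (b * f - c * e) * id;
  inv[3] = (f * g - d * i) * id;  inv[4] = (a * i - c * g) * id;  inv[5] = (c * d - a * f) * id;
  inv[6] = (d * h - e * g) * id;  inv[7] = (b * g - a * h) * id;  inv[8] = (a * e - b * d) * id;
  return true;
}

static void rotmat_from_rotvec(double rx, double ry, double rz, double *R) {
  Quat q = qexp(rx, ry, rz);
  double w = q.w, x = q.x, y = q.y, z = q.z;
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

// [[Rcpp::export(name = ".ekf_attitude_cpp")]]
List ekf_attitude_cpp(NumericMatrix accel, NumericMatrix gyro, double rate_hz,
                      double var_acc, double var_gyr) {
  const int n = accel.nrow();
  const double dt = 1.0 / rate_hz;
  const double D2R = M_PI / 180.0;
  const double ez[3] = {0.0, 0.0, 1.0};
  const double ex[3] = {1.0, 0.0, 0.0};

  NumericMatrix quat(n, 4), aG(n, 3), heading(n, 3);

  // --- initialization: tilt from the first accelerometer sample, azimuth 0
  double a0[3] = {accel(0, 0), accel(0, 1), accel(0, 2)};
  double na0 = std::sqrt(a0[0] * a0[0] + a0[1] * a0[1] + a0[2] * a0[2]);
  if (na0 < 1e-9) { a0[0] = 0; a0[1] = 0; a0[2] = 1; na0 = 1; }
  a0[0] /= na0; a0[1] /= na0; a0[2] /= na0;
  // minimal rotation taking a0 (head frame) onto Earth z
  double cx = a0[1] * ez[2] - a0[2] * ez[1];
  double cy = a0[2] * ez[0] - a0[0] * ez[2];
  double cz = a0[0] * ez[1] - a0[1] * ez[0];
  double sn = std::sqrt(cx * cx + cy * cy + cz * cz);
  double cs = a0[2];  // dot(a0, ez)
  Quat q;
  if (sn < 1e-12) {
    if (cs > 0) { q.w = 1; q.x = q.y = q.z = 0; }
    else { q.w = 0; q.x = 1; q.y = 0; q.z = 0; }  // upside down: flip about x
  } else {
    double ang = std::atan2(sn, cs);
    q = qexp(cx / sn * ang, cy / sn * ang, cz / sn * ang);
  }
  // zero the initial azimuth: pre-rotate about Earth z
  {
    double h[3];
    qrot(q, ex, h);
    double az = std::atan2(h[1], h[0]);
    Quat qz = qexp(0.0, 0.0, -az);
    q = qmul(qz, q);
    qnormalize(q);
  }

  double P[9] = {0.01, 0, 0, 0, 0.01, 0, 0, 0, 0.01};

  for (int t = 0; t < n; ++t) {
    if (t > 0) {
      // process: integrate gyro (deg/s -> rad)
      double rx = gyro(t, 0) * D2R * dt;
      double ry = gyro(t, 1) * D2R * dt;
      double rz = gyro(t, 2) * D2R * dt;
      q = qmul(q, qexp(rx, ry, rz));
      qnormalize(q);
      // covariance: error expressed in the (rotated) head frame
      double A[9], AP[9], APA[9];
      rotmat_from_rotvec(-rx, -ry, -rz, A);
      mat3_mul(A, P, AP);
      double At[9] = {A[0], A[3], A[6], A[1], A[4], A[7], A[2], A[5], A[8]};
      mat3_mul(AP, At, APA);
      for (int k = 0; k < 9; ++k) P[k] = APA[k];
      // var_gyr is in (deg/s)^2 per unit bandwidth; error state is radians
      double qproc = var_gyr * dt * D2R * D2R;
      P[0] += qproc; P[4] += qproc; P[8] += qproc;

      // measurement: accelerometer direction ~ gravity in head frame
      double am[3] = {accel(t, 0), accel(t, 1), accel(t, 2)};
      double na = std::sqrt(am[0] * am[0] + am[1] * am[1] + am[2] * am[2]);
      if (na > 0.5 && na < 1.5) {  // gate out free-fall / impact samples
        double z[3] = {am[0] / na, am[1] / na, am[2] / na};
        double gb[3];
        qrot(qconj(q), ez, gb);  // predicted gravity direction, head frame
        double nu[3] = {z[0] - gb[0], z[1] - gb[1], z[2] - gb[2]};
        // H = [gb]_x
        double H[9] = {0, -gb[2], gb[1], gb[2], 0, -gb[0], -gb[1], gb[0], 0};
        double Ht[9] = {H[0], H[3], H[6], H[1], H[4], H[7], H[2], H[5], H[8]};
        double PH[9], S[9], Sinv[9], HP[9], K[9];
        mat3_mul(P, Ht, PH);
        mat3_mul(H, PH, S);
        S[0] += var_acc; S[4] += var_acc; S[8] += var_acc;
        if (mat3_inv(S, Sinv)) {
          mat3_mul(PH, Sinv, K);
          double dth[3];
          for (int i = 0; i < 3; ++i)
            dth[i] = K[3 * i] * nu[0] + K[3 * i + 1] * nu[1] + K[3 * i + 2] * nu[2];
          q = qmul(q, qexp(dth[0], dth[1], dth[2]));
          qnormalize(q);
          mat3_mul(K, H, HP);       // K H
          double IKH[9];
          for (int k = 0; k < 9; ++k) IKH[k] = -HP[k];
          IKH[0] += 1; IKH[4] += 1; IKH[8] += 1;
          double Pn[9];
          mat3_mul(IKH, P, Pn);
          for (int k = 0; k < 9; ++k) P[k] = Pn[k];
        }
      }
    }

    quat(t, 0) = q.w; quat(t, 1) = q.x; quat(t, 2) = q.y; quat(t, 3) = q.z;
    double g_head[3], h[3];
    qrot(qconj(q), ez, g_head);
    aG(t, 0) = g_head[0]; aG(t, 1) = g_head[1]; aG(t, 2) = g_head[2];
    qrot(q, ex, h);
    heading(t, 0) = h[0]; heading(t, 1) = h[1]; heading(t, 2) = h[2];
  }

  return List::create(_["quat"] = quat, _["aG"] = aG, _["heading"] = heading);
}
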