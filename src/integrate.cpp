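#include <Rcpp.h>
using namespace Rcpp;

// Per-sample integration of the orientation-feedback controller that stands
// in for the child's hands. R maps body to world; world up is +z.
//
//   w_cmd (world)  = gain * (R * target_body[i]) x target_world[i]
//   w_body         = R^T w_cmd + wobble[i]          (wobble moves the cube)
//   accel[i]       = R^T (0,0,-g) + jitter[i]       (gravity in body frame)
//   gyro[i]        = w_body + gyro_noise[i]
//   align[i]       = (R * align_body[i]) . z        (ground-truth alignment)
//   R             <- R * exp([w_body * dt]x)
//
// Outputs are recorded at the pre-update state so sample i reflects the
// orientation at time t_i. The rotation is re-orthonormalised periodically
// to keep drift below numerical noise over session-length integrations.

static void reorthonormalise(double R[3][3]) {
  // Gram-Schmidt on rows
  double n0 = std::sqrt(R[0][0] * R[0][0] + R[0][1] * R[0][1] + R[0][2] * R[0][2]);
  for (int j = 0; j < 3; ++j) R[0][j] /= n0;
  double d = R[1][0] * R[0][0] + R[1][1] * R[0][1] + R[1][2] * R[0][2];
  for (int j = 0; j < 3; ++j) R[1][j] -= d * R[0][j];
  double n1 = std::sqrt(R[1][0] * R[1][0] + R[1][1] * R[1][1] + R[1][2] * R[1][2]);
  for (int j = 0; j < 3; ++j) R[1][j] /= n1;
  R[2][0] = R[0][1] * R[1][2] - R[0][2] * R[1][1];
  R[2][1] = R[0][2] * R[1][0] - R[0][0] * R[1][2];
  R[2][2] = R[0][0] * R[1][1] - R[0][1] * R[1][0];
}

// [[Rcpp::export(name = ".integrate_controller")]]
List integrate_controller(NumericMatrix target_body, NumericMatrix target_world,
                          NumericMatrix align_body, NumericMatrix wobble,
                          NumericMatrix jitter, NumericMatrix gyro_noise,
                          double gain, double dt, double g,
                          NumericMatrix R0) {
  const int n = target_body.nrow();
  NumericMatrix accel(n, 3), gyro(n, 3);
  NumericVector align(n);
  double R[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[i][j] = R0(i, j);

  for (int i = 0; i < n; ++i) {
    // world coords of the body-frame target direction
    double c[3];
    for (int r = 0; r < 3; ++r)
      c[r] = R[r][0] * target_body(i, 0) + R[r][1] * target_body(i, 1) +
             R[r][2] * target_body(i, 2);
    double u0 = target_world(i, 0), u1 = target_world(i, 1), u2 = target_world(i, 2);
    // proportional feedback: rotate c toward the world target
    double wx = gain * (c[1] * u2 - c[2] * u1);
    double wy = gain * (c[2] * u0 - c[0] * u2);
    double wz = gain * (c[0] * u1 - c[1] * u0);
    // body-frame angular velocity = R^T w_cmd + wobble
    double wb[3];
    for (int r = 0; r < 3; ++r)
      wb[r] = R[0][r] * wx + R[1][r] * wy + R[2][r] * wz + wobble(i, r);

    for (int r = 0; r < 3; ++r) {
      accel(i, r) = -g * R[2][r] + jitter(i, r);  // R^T (0,0,-g)
      gyro(i, r) = wb[r] + gyro_noise(i, r);
    }
    double a0 = R[2][0] * align_body(i, 0) + R[2][1] * align_body(i, 1) +
                R[2][2] * align_body(i, 2);
    align[i] = a0;

    // R <- R * exp([wb dt]x)  (Rodrigues)
    double th = std::sqrt(wb[0] * wb[0] + wb[1] * wb[1] + wb[2] * wb[2]) * dt;
    if (th > 1e-14) {
      double kx = wb[0] * dt / th, ky = wb[1] * dt / th, kz = wb[2] * dt / th;
      double ct = std::cos(th), st = std::sin(th), vt = 1.0 - ct;
      double E[3][3] = {
        {ct + kx * kx * vt, kx * ky * vt - kz * st, kx * kz * vt + ky * st},
        {ky * kx * vt + kz * st, ct + ky * ky * vt, ky * kz * vt - kx * st},
        {kz * kx * vt - ky * st, kz * ky * vt + kx * st, ct + kz * kz * vt}};
      double Rn[3][3];
      for (int r = 0; r < 3; ++r)
        for (int col = 0; col < 3; ++col)
          Rn[r][col] = R[r][0] * E[0][col] + R[r][1] * E[1][col] + R[r][2] * E[2][col];
      for (int r = 0; r < 3; ++r)
        for (int col = 0; col < 3; ++col) R[r][col] = Rn[r][col];
    }
    if (i % 1000 == 999) reorthonormalise(R);
  }

  NumericMatrix Rf(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Rf(i, j) = R[i][j];
  return List::create(_["accel"] = accel, _["gyro"] = gyro,
                      _["align"] = align, _["rotation"] = Rf);
}
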