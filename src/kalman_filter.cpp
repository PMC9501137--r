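#include <Rcpp.h>
using namespace Rcpp;

// Constant-acceleration Kalman filter over a scalar measurement series.
//
// State s = (p, v, a): signal value, first and second derivative.
// Transition A = [[1, h, h^2/2], [0, 1, h], [0, 0, 1]], observation
// H = [1, 0, 0]. The covariance update uses the Joseph form so the error
// covariance stays symmetric positive semi-definite in floating point.
//
// z: measurement series (possibly lag-resampled by the R wrapper)
// h: time step; q: 3x3 process-noise covariance; r: measurement variance
// s0: initial state (3); P0: initial covariance (3x3)
// keep_trajectory: also return per-step states and covariances
// [[Rcpp::export]]
List kalman_filter_cpp(NumericVector z, double h, NumericMatrix q, double r,
                       NumericVector s0, NumericMatrix P0,
                       bool keep_trajectory = false) {
  const R_xlen_t n = z.size();
  double s[3] = {s0[0], s0[1], s0[2]};
  double P[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) P[i][j] = P0(i, j);

  NumericVector p_out(n);
  NumericMatrix states;
  NumericMatrix covs;  // rows: flattened 3x3 per step
  if (keep_trajectory) {
    states = NumericMatrix(n, 3);
    covs = NumericMatrix(n, 9);
  }

  const double h2 = 0.5 * h * h;

  for (R_xlen_t t = 0; t < n; ++t) {
    // predict: s = A s
    double sp[3];
    sp[0] = s[0] + h * s[1] + h2 * s[2];
    sp[1] = s[1] + h * s[2];
    sp[2] = s[2];

    // P = A P A' + Q
    double AP[3][3];
    for (int j = 0; j < 3; ++j) {
      AP[0][j] = P[0][j] + h * P[1][j] + h2 * P[2][j];
      AP[1][j] = P[1][j] + h * P[2][j];
      AP[2][j] = P[2][j];
    }
    double Pp[3][3];
    for (int i = 0; i < 3; ++i) {
      Pp[i][0] = AP[i][0] + h * AP[i][1] + h2 * AP[i][2];
      Pp[i][1] = AP[i][1] + h * AP[i][2];
      Pp[i][2] = AP[i][2];
    }
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Pp[i][j] += q(i, j);

    // update with scalar measurement: S = Pp[0][0] + r, K = Pp[,0] / S
    const double S = Pp[0][0] + r;
    double K[3] = {Pp[0][0] / S, Pp[1][0] / S, Pp[2][0] / S};
    const double innov = z[t] - sp[0];
    for (int i = 0; i < 3; ++i) s[i] = sp[i] + K[i] * innov;

    // Joseph form: P = (I - K H) Pp (I - K H)' + K r K'
    double IKH[3][3] = {{1.0 - K[0], 0.0, 0.0},
                        {-K[1], 1.0, 0.0},
                        {-K[2], 0.0, 1.0}};
    double T1[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        T1[i][j] = IKH[i][0] * Pp[0][j] + IKH[i][1] * Pp[1][j] +
                   IKH[i][2] * Pp[2][j];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        P[i][j] = T1[i][0] * IKH[j][0] + T1[i][1] * IKH[j][1] +
                  T1[i][2] * IKH[j][2] + K[i] * r * K[j];
      }

    p_out[t] = s[0];
    if (keep_trajectory) {
      for (int i = 0; i < 3; ++i) states(t, i) = s[i];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) covs(t, 3 * i + j) = P[i][j];
    }
  }

  if (keep_trajectory) {
    return List::create(_["p"] = p_out, _["states"] = states,
                        _["covariances"] = covs);
  }
  return List::create(_["p"] = p_out);
}
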