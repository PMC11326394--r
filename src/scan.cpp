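// Selective state-space scan kernel.
//
// Recurrence (backward-Euler discretization of h' = A h + B x, A < 0):
//   abar_t = 1 / (1 - dt_t * A)            elementwise over (channel, state)
//   h_t    = abar_t * (h_{t-1} + dt_t * B_t * x_t)
//   y_t    = sum_s C_t[s] * h_t[., s]
//
// Token layout: row (t * N + n) of every (tokens x d) / (tokens x S) matrix,
// i.e. time-major blocks of batch rows, so for a fixed time step and channel
// the batch elements are contiguous and the innermost loops run over the
// batch dimension (SIMD-friendly). The hidden-state history H is stored as
// ((t * d + j) * S + s) * N + n for the backward pass.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List ssm_scan_forward(const NumericMatrix& x, const NumericMatrix& dt,
                      const NumericMatrix& B, const NumericMatrix& C,
                      const NumericMatrix& A, const int n_batch,
                      const int n_time, Nullable<NumericVector> H_buf =
                        R_NilValue) {
  const int d = x.ncol(), S = B.ncol();
  const int tokens = n_batch * n_time;
  if (x.nrow() != tokens) stop("token count mismatch");
  const R_xlen_t h_len = static_cast<R_xlen_t>(tokens) * d * S;
  NumericMatrix y(tokens, d);
  NumericVector H;
  if (H_buf.isNotNull()) {
    H = H_buf.get();                     // scratch reused across batches
    if (H.size() < h_len) stop("H buffer too small");
  } else {
    H = NumericVector(no_init(h_len));
  }
  double* Hp = H.begin();
  const double* xp = x.begin();
  const double* dtp = dt.begin();
  const double* Bp = B.begin();
  const double* Cp = C.begin();
  double* yp = y.begin();

  for (int t = 0; t < n_time; ++t) {
    const int row0 = t * n_batch;                    // first token this step
    for (int j = 0; j < d; ++j) {
      const double* xcol = xp + static_cast<R_xlen_t>(j) * tokens + row0;
      const double* dtcol = dtp + static_cast<R_xlen_t>(j) * tokens + row0;
      double* ycol = yp + static_cast<R_xlen_t>(j) * tokens + row0;
      for (int s = 0; s < S; ++s) {
        const double Ajs = A(j, s);
        const double* Bcol = Bp + static_cast<R_xlen_t>(s) * tokens + row0;
        const double* Ccol = Cp + static_cast<R_xlen_t>(s) * tokens + row0;
        double* hcur = Hp +
          ((static_cast<R_xlen_t>(t) * d + j) * S + s) * n_batch;
        const double* hprev = hcur -
          static_cast<R_xlen_t>(d) * S * n_batch;
        if (t > 0) {
          for (int n = 0; n < n_batch; ++n) {
            const double dtv = dtcol[n];
            const double ab = 1.0 / (1.0 - dtv * Ajs);
            const double h = ab * (hprev[n] + dtv * Bcol[n] * xcol[n]);
            hcur[n] = h;
            ycol[n] += Ccol[n] * h;
          }
        } else {
          for (int n = 0; n < n_batch; ++n) {
            const double dtv = dtcol[n];
            const double ab = 1.0 / (1.0 - dtv * Ajs);
            const double h = ab * (dtv * Bcol[n] * xcol[n]);
            hcur[n] = h;
            ycol[n] += Ccol[n] * h;
          }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["H"] = H);
}

// [[Rcpp::export]]
List ssm_scan_backward(const NumericMatrix& dy, const NumericMatrix& x,
                       const NumericMatrix& dt, const NumericMatrix& B,
                       const NumericMatrix& C, const NumericMatrix& A,
                       const NumericVector& H, const int n_batch,
                       const int n_time) {
  const int d = x.ncol(), S = B.ncol();
  const int tokens = n_batch * n_time;
  NumericMatrix dx(tokens, d), ddt(tokens, d), dB(tokens, S), dC(tokens, S);
  NumericMatrix dA(d, S);
  // dL/dh carried backward, laid out (j, s, n)
  std::vector<double> dhbuf(static_cast<size_t>(d) * S * n_batch, 0.0);
  const double* Hp = H.begin();
  const double* xp = x.begin();
  const double* dtp = dt.begin();
  const double* Bp = B.begin();
  const double* Cp = C.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* ddtp = ddt.begin();
  double* dBp = dB.begin();
  double* dCp = dC.begin();

  for (int t = n_time - 1; t >= 0; --t) {
    const int row0 = t * n_batch;
    for (int j = 0; j < d; ++j) {
      const double* xcol = xp + static_cast<R_xlen_t>(j) * tokens + row0;
      const double* dtcol = dtp + static_cast<R_xlen_t>(j) * tokens + row0;
      const double* dycol = dyp + static_cast<R_xlen_t>(j) * tokens + row0;
      double* dxcol = dxp + static_cast<R_xlen_t>(j) * tokens + row0;
      double* ddtcol = ddtp + static_cast<R_xlen_t>(j) * tokens + row0;
      for (int s = 0; s < S; ++s) {
        const double Ajs = A(j, s);
        const double* Bcol = Bp + static_cast<R_xlen_t>(s) * tokens + row0;
        const double* Ccol = Cp + static_cast<R_xlen_t>(s) * tokens + row0;
        double* dBcol = dBp + static_cast<R_xlen_t>(s) * tokens + row0;
        double* dCcol = dCp + static_cast<R_xlen_t>(s) * tokens + row0;
        const double* hcur = Hp +
          ((static_cast<R_xlen_t>(t) * d + j) * S + s) * n_batch;
        const double* hprev = hcur -
          static_cast<R_xlen_t>(d) * S * n_batch;
        double* dhrow = dhbuf.data() +
          (static_cast<size_t>(j) * S + s) * n_batch;
        double dA_acc = 0.0;
        for (int n = 0; n < n_batch; ++n) {
          const double dtv = dtcol[n];
          const double xv = xcol[n];
          const double dyv = dycol[n];
          const double ab = 1.0 / (1.0 - dtv * Ajs);
          const double hp = (t > 0) ? hprev[n] : 0.0;
          const double Bs = Bcol[n];
          const double u = hp + dtv * Bs * xv;
          const double dh = dhrow[n] + Ccol[n] * dyv;
          dCcol[n] += dyv * hcur[n];
          ddtcol[n] += dh * (Ajs * ab * ab * u + ab * Bs * xv);
          dA_acc += dh * dtv * ab * ab * u;
          dBcol[n] += dh * ab * dtv * xv;
          dxcol[n] += dh * ab * dtv * Bs;
          dhrow[n] = dh * ab;            // becomes dL/dh_{t-1}
        }
        dA(j, s) += dA_acc;
      }
    }
  }
  return List::create(_["dx"] = dx, _["ddt"] = ddt, _["dB"] = dB,
                      _["dC"] = dC, _["dA"] = dA);
}
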