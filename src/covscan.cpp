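// Compiled kernels for the training-critical inner loops: the selective-SSM
// recurrence (forward and adjoint), im2col patch extraction, depthwise
// causal convolution, and the GELU activation.
//
// Scan kernels take the per-position inputs in transposed (D, L) layout so
// the innermost channel loop is stride-1; the R wrappers transpose.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Selective-SSM recurrence, Euler discretization.
// xaT, deltaT: (D, L); A: (D, N); B, C: (L, N).
// Returns yT (D, L), states h and decays abar in (K = D*N, L) layout
// (row n*D + d) for the backward pass.
// [[Rcpp::export]]
List scan_full_fwd_cpp(NumericMatrix xaT, NumericMatrix deltaT,
                       NumericMatrix A, NumericMatrix B, NumericMatrix C) {
  const int D = xaT.nrow(), L = xaT.ncol(), N = A.ncol(), K = D * N;
  NumericMatrix yT(D, L), h(K, L), abar(K, L);
  const double *xa = xaT.begin(), *dt = deltaT.begin(), *Ap = A.begin(),
               *Bp = B.begin(), *Cp = C.begin();
  double *yp = yT.begin(), *hp = h.begin(), *ap = abar.begin();
  for (int t = 0; t < L; ++t) {
    const double *xat = xa + (size_t)t * D;
    const double *dtt = dt + (size_t)t * D;
    double *ht = hp + (size_t)t * K;
    const double *hprev = (t > 0) ? ht - K : nullptr;
    double *at = ap + (size_t)t * K;
    double *yt = yp + (size_t)t * D;
    for (int n = 0; n < N; ++n) {
      const double Bt = Bp[n * L + t], Ct = Cp[n * L + t];
      const double *An = Ap + (size_t)n * D;
      double *hn = ht + n * D;
      const double *hn_prev = hprev ? hprev + n * D : nullptr;
      double *an = at + n * D;
      for (int d = 0; d < D; ++d) {
        const double a = std::exp(dtt[d] * An[d]);
        const double u = dtt[d] * xat[d] * Bt;
        const double hh = (hn_prev ? a * hn_prev[d] : 0.0) + u;
        an[d] = a;
        hn[d] = hh;
        yt[d] += hh * Ct;
      }
    }
  }
  return List::create(_["yT"] = yT, _["h"] = h, _["abar"] = abar);
}

// Adjoint of the recurrence; gradients returned in transposed (D, L)
// layout for the per-position quantities.
// [[Rcpp::export]]
List scan_full_bwd_cpp(NumericMatrix dyT, NumericMatrix xaT,
                       NumericMatrix deltaT, NumericMatrix A,
                       NumericMatrix B, NumericMatrix C,
                       NumericMatrix h, NumericMatrix abar) {
  const int D = xaT.nrow(), L = xaT.ncol(), N = A.ncol(), K = D * N;
  NumericMatrix dxT(D, L), ddeltaT(D, L), dA(D, N), dB(L, N), dC(L, N);
  const double *xa = xaT.begin(), *dt = deltaT.begin(), *dy = dyT.begin(),
               *Ap = A.begin(), *Bp = B.begin(), *Cp = C.begin(),
               *hp = h.begin(), *ap = abar.begin();
  double *dxp = dxT.begin(), *ddp = ddeltaT.begin(), *dAp = dA.begin(),
         *dBp = dB.begin(), *dCp = dC.begin();
  std::vector<double> gnext(K, 0.0);
  for (int t = L - 1; t >= 0; --t) {
    const double *xat = xa + (size_t)t * D;
    const double *dtt = dt + (size_t)t * D;
    const double *dyt = dy + (size_t)t * D;
    const double *ht = hp + (size_t)t * K;
    const double *hprev = (t > 0) ? ht - K : nullptr;
    const double *at = ap + (size_t)t * K;
    const double *anext = (t < L - 1) ? at + K : nullptr;
    double *dxt = dxp + (size_t)t * D;
    double *ddt = ddp + (size_t)t * D;
    for (int n = 0; n < N; ++n) {
      const double Bt = Bp[n * L + t], Ct = Cp[n * L + t];
      const double *An = Ap + (size_t)n * D;
      const double *hn = ht + n * D;
      const double *hn_prev = hprev ? hprev + n * D : nullptr;
      const double *an = at + n * D;
      const double *an_next = anext ? anext + n * D : nullptr;
      double *gn = gnext.data() + n * D;
      double *dAn = dAp + (size_t)n * D;
      double dBt = 0.0, dCt = 0.0;
      for (int d = 0; d < D; ++d) {
        const double e = dyt[d] * Ct;
        const double g = e + (an_next ? an_next[d] * gn[d] : 0.0);
        const double t1 = g * (hn_prev ? hn_prev[d] : 0.0) * an[d];
        dAn[d] += t1 * dtt[d];
        ddt[d] += t1 * An[d] + g * Bt * xat[d];
        dxt[d] += g * Bt * dtt[d];
        dBt += g * dtt[d] * xat[d];
        dCt += dyt[d] * hn[d];
        gn[d] = g;
      }
      dBp[n * L + t] = dBt;
      dCp[n * L + t] = dCt;
    }
  }
  return List::create(_["dxT"] = dxT, _["ddeltaT"] = ddeltaT, _["dA"] = dA,
                      _["dB"] = dB, _["dC"] = dC);
}

// im2col for 1-D "same" convolution: output (L, width * C), tap-major.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericMatrix x, int width) {
  const int L = x.nrow(), C = x.ncol();
  const int pad = (width - 1) / 2;
  NumericMatrix cols(L, width * C);
  const double *xp = x.begin();
  double *cp = cols.begin();
  for (int k = 0; k < width; ++k) {
    const int off = k - pad;
    const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
    for (int c = 0; c < C; ++c) {
      const double *src = xp + (size_t)c * L + off;
      double *dst = cp + (size_t)(k * C + c) * L;
      for (int t = t0; t < t1; ++t) dst[t] = src[t];
    }
  }
  return cols;
}

// scatter-add inverse of im2col.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(NumericMatrix dcols, int L, int C, int width) {
  const int pad = (width - 1) / 2;
  NumericMatrix dx(L, C);
  const double *cp = dcols.begin();
  double *dp = dx.begin();
  for (int k = 0; k < width; ++k) {
    const int off = k - pad;
    const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
    for (int c = 0; c < C; ++c) {
      double *dst = dp + (size_t)c * L + off;
      const double *src = cp + (size_t)(k * C + c) * L;
      for (int t = t0; t < t1; ++t) dst[t] += src[t];
    }
  }
  return dx;
}

// depthwise causal convolution, width w:
// y[t,c] = b[c] + sum_k W(k,c) x(t-w+1+k, c)
// [[Rcpp::export]]
NumericMatrix dwconv_causal_fwd_cpp(NumericMatrix x, NumericMatrix W,
                                    NumericVector b) {
  const int L = x.nrow(), C = x.ncol(), w = W.nrow();
  NumericMatrix y(L, C);
  const double *xp = x.begin(), *Wp = W.begin();
  double *yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (size_t)c * L;
    const double *Wc = Wp + (size_t)c * w;
    double *yc = yp + (size_t)c * L;
    const double bc = b[c];
    for (int t = 0; t < L; ++t) {
      double s = bc;
      const int kmin = std::max(0, w - 1 - t);
      for (int k = kmin; k < w; ++k) s += Wc[k] * xc[t - (w - 1 - k)];
      yc[t] = s;
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv_causal_bwd_cpp(NumericMatrix x, NumericMatrix W,
                           NumericMatrix dy) {
  const int L = x.nrow(), C = x.ncol(), w = W.nrow();
  NumericMatrix dx(L, C), dW(w, C);
  NumericVector db(C);
  const double *xp = x.begin(), *Wp = W.begin(), *dyp = dy.begin();
  double *dxp = dx.begin(), *dWp = dW.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (size_t)c * L;
    const double *Wc = Wp + (size_t)c * w;
    const double *dyc = dyp + (size_t)c * L;
    double *dxc = dxp + (size_t)c * L;
    double *dWc = dWp + (size_t)c * w;
    double dbs = 0.0;
    for (int t = 0; t < L; ++t) {
      const double d = dyc[t];
      dbs += d;
      const int kmin = std::max(0, w - 1 - t);
      for (int k = kmin; k < w; ++k) {
        const int src = t - (w - 1 - k);
        dWc[k] += d * xc[src];
        dxc[src] += d * Wc[k];
      }
    }
    db[c] = dbs;
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
NumericMatrix gelu_cpp(NumericMatrix x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double c0 = 0.7978845608028654;  // sqrt(2/pi)
  const double *xp = x.begin();
  double *yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = xp[i];
    yp[i] = 0.5 * v * (1.0 + std::tanh(c0 * (v + 0.044715 * v * v * v)));
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix gelu_grad_cpp(NumericMatrix x) {
  NumericMatrix g(x.nrow(), x.ncol());
  const double c0 = 0.7978845608028654;
  const double *xp = x.begin();
  double *gp = g.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = xp[i];
    const double t = std::tanh(c0 * (v + 0.044715 * v * v * v));
    const double dinner = c0 * (1.0 + 3.0 * 0.044715 * v * v);
    gp[i] = 0.5 * (1.0 + t) + 0.5 * v * (1.0 - t * t) * dinner;
  }
  return g;
}
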