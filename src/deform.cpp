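// Batched 1-D deformable convolution / pooling kernels.
//
// Layout contract (shared with the R driver code): a mini-batch is
// concatenated along the length axis with one zero separator column between
// samples; `lo`/`hi` give, for every output column, the 1-based range of
// input columns belonging to the same sample (lo > hi marks separator
// columns). Fractional sampling uses the triangular kernel
// max(0, 1 - |v - it|); positions outside [lo, hi] contribute zero, exactly
// as for an isolated sample.

#include <Rcpp.h>
using namespace Rcpp;

// Offset generator: ordinary same-padding convolution (kernel J, J odd).
// X: in x W, OW: K x in x J (passed as vector with dims). Out: K x W.
static void offset_conv_c(const double* X, int nin, int W,
                          const double* OW, int K, int J, double* delta) {
  int half = (J - 1) / 2;
  for (int i = 0; i < W; ++i) {
    for (int k = 0; k < K; ++k) delta[k + (size_t)i * K] = 0.0;
    for (int j = 0; j < J; ++j) {
      int ii = i + j - half;
      if (ii < 0 || ii >= W) continue;
      const double* xc = X + (size_t)ii * nin;
      for (int c = 0; c < nin; ++c) {
        double xv = xc[c];
        if (xv == 0.0) continue;
        for (int k = 0; k < K; ++k)
          delta[k + (size_t)i * K] += OW[k + K * (c + (size_t)nin * j)] * xv;
      }
    }
  }
}

// Backward of the offset generator: dOut (K x W) -> dOW, and optionally dX.
static void offset_conv_bwd_c(const double* X, int nin, int W,
                              const double* OW, int K, int J,
                              const double* dOut, double* dOW, double* dX,
                              bool want_dX) {
  int half = (J - 1) / 2;
  for (int i = 0; i < W; ++i) {
    for (int j = 0; j < J; ++j) {
      int ii = i + j - half;
      if (ii < 0 || ii >= W) continue;
      const double* xc = X + (size_t)ii * nin;
      double* dxc = dX + (size_t)ii * nin;
      for (int k = 0; k < K; ++k) {
        double d = dOut[k + (size_t)i * K];
        if (d == 0.0) continue;
        for (int c = 0; c < nin; ++c) {
          dOW[k + K * (c + (size_t)nin * j)] += d * xc[c];
          if (want_dX) dxc[c] += OW[k + K * (c + (size_t)nin * j)] * d;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".dc_conv_fwd")]]
List dc_conv_fwd(NumericMatrix Xg, NumericVector Warr, NumericVector OWarr,
                 IntegerVector lo, IntegerVector hi) {
  IntegerVector wd = Warr.attr("dim");
  int out_ch = wd[0], nin = wd[1], K = wd[2];
  IntegerVector od = OWarr.attr("dim");
  int J = od[2];
  int W = Xg.ncol();
  if (Xg.nrow() != nin) stop("channel mismatch");
  NumericMatrix delta(K, W), Y(out_ch, W);
  offset_conv_c(REAL(Xg), nin, W, REAL(OWarr), K, J, REAL(delta));
  const double* X = REAL(Xg);
  const double* Wp = REAL(Warr);
  double rel0 = -(K - 1) / 2.0;
  // transpose each kernel-tap slice to (c, o) for contiguous inner dots
  std::vector<double> Wt((size_t)K * nin * out_ch);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < nin; ++c)
      for (int o = 0; o < out_ch; ++o)
        Wt[((size_t)k * out_ch + o) * nin + c] =
          Wp[o + (size_t)out_ch * (c + (size_t)nin * k)];
  std::vector<double> s(nin);
  double* Yp = REAL(Y);
  for (int i = 0; i < W; ++i) {
    if (lo[i] > hi[i]) continue;           // separator column stays zero
    int l0 = lo[i] - 1, h0 = hi[i] - 1;
    double* ycol = Yp + (size_t)i * out_ch;
    for (int k = 0; k < K; ++k) {
      double pos = (i + 1) + rel0 + k + delta(k, i);   // 1-based position
      double fpos = std::floor(pos);
      int f0 = (int)fpos - 1;                           // 0-based floor index
      double w = pos - fpos;
      bool vlo = (f0 >= l0 && f0 <= h0);
      bool vhi = (f0 + 1 >= l0 && f0 + 1 <= h0);
      if (!vlo && !vhi) continue;
      const double* Xf = X + (size_t)std::min(std::max(f0, 0), W - 1) * nin;
      const double* Xf1 = X + (size_t)std::min(std::max(f0 + 1, 0), W - 1) * nin;
      if (vlo && vhi)
        for (int c = 0; c < nin; ++c) s[c] = (1.0 - w) * Xf[c] + w * Xf1[c];
      else if (vlo)
        for (int c = 0; c < nin; ++c) s[c] = (1.0 - w) * Xf[c];
      else
        for (int c = 0; c < nin; ++c) s[c] = w * Xf1[c];
      const double* wk = &Wt[(size_t)k * out_ch * nin];
      for (int o = 0; o < out_ch; ++o) {
        const double* wo = wk + (size_t)o * nin;
        double acc = 0.0;
        for (int c = 0; c < nin; ++c) acc += wo[c] * s[c];
        ycol[o] += acc;
      }
    }
  }
  return List::create(_["Y"] = Y, _["delta"] = delta);
}

// [[Rcpp::export(name = ".dc_conv_bwd")]]
List dc_conv_bwd(NumericMatrix Xg, NumericVector Warr, NumericVector OWarr,
                 NumericMatrix delta, IntegerVector lo, IntegerVector hi,
                 NumericMatrix dY, bool want_dX) {
  IntegerVector wd = Warr.attr("dim");
  int out_ch = wd[0], nin = wd[1], K = wd[2];
  IntegerVector od = OWarr.attr("dim");
  int J = od[2];
  int W = Xg.ncol();
  NumericVector dW(Warr.size()); dW.attr("dim") = wd;
  NumericVector dOW(OWarr.size()); dOW.attr("dim") = od;
  NumericMatrix dX(nin, W);
  NumericMatrix dDelta(K, W);
  const double* X = REAL(Xg);
  const double* Wp = REAL(Warr);
  double* dWp = REAL(dW);
  double* dXp = REAL(dX);
  double rel0 = -(K - 1) / 2.0;
  // (c, o)-transposed weight taps and a matching accumulator for dW
  std::vector<double> Wt((size_t)K * nin * out_ch);
  std::vector<double> dWt((size_t)K * nin * out_ch, 0.0);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < nin; ++c)
      for (int o = 0; o < out_ch; ++o)
        Wt[((size_t)k * out_ch + o) * nin + c] =
          Wp[o + (size_t)out_ch * (c + (size_t)nin * k)];
  std::vector<double> s(nin), ds(nin);
  for (int i = 0; i < W; ++i) {
    if (lo[i] > hi[i]) continue;
    int l0 = lo[i] - 1, h0 = hi[i] - 1;
    const double* dycol = REAL(dY) + (size_t)i * out_ch;
    bool any_dy = false;
    for (int o = 0; o < out_ch; ++o) if (dycol[o] != 0.0) { any_dy = true; break; }
    if (!any_dy) continue;
    for (int k = 0; k < K; ++k) {
      double pos = (i + 1) + rel0 + k + delta(k, i);
      double fpos = std::floor(pos);
      int f0 = (int)fpos - 1;
      double w = pos - fpos;
      bool vlo = (f0 >= l0 && f0 <= h0);
      bool vhi = (f0 + 1 >= l0 && f0 + 1 <= h0);
      const double* Xf = X + (size_t)std::min(std::max(f0, 0), W - 1) * nin;
      const double* Xf1 = X + (size_t)std::min(std::max(f0 + 1, 0), W - 1) * nin;
      for (int c = 0; c < nin; ++c) {
        double xlo = vlo ? Xf[c] : 0.0;
        double xhi = vhi ? Xf1[c] : 0.0;
        s[c] = (1.0 - w) * xlo + w * xhi;
        ds[c] = 0.0;
      }
      const double* wk = &Wt[(size_t)k * out_ch * nin];
      double* dwk = &dWt[(size_t)k * out_ch * nin];
      for (int o = 0; o < out_ch; ++o) {
        double d = dycol[o];
        if (d == 0.0) continue;
        const double* wo = wk + (size_t)o * nin;
        double* dwo = dwk + (size_t)o * nin;
        for (int c = 0; c < nin; ++c) {
          dwo[c] += d * s[c];
          ds[c] += wo[c] * d;
        }
      }
      double dpos = 0.0;
      for (int c = 0; c < nin; ++c) {
        double xlo = vlo ? Xf[c] : 0.0;
        double xhi = vhi ? Xf1[c] : 0.0;
        dpos += ds[c] * (xhi - xlo);
        if (want_dX) {
          if (vlo) dXp[c + (size_t)(f0)*nin] += ds[c] * (1.0 - w);
          if (vhi) dXp[c + (size_t)(f0 + 1) * nin] += ds[c] * w;
        }
      }
      dDelta(k, i) = dpos;
    }
  }
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < nin; ++c)
      for (int o = 0; o < out_ch; ++o)
        dWp[o + (size_t)out_ch * (c + (size_t)nin * k)] =
          dWt[((size_t)k * out_ch + o) * nin + c];
  offset_conv_bwd_c(X, nin, W, REAL(OWarr), K, J, REAL(dDelta), REAL(dOW),
                    dXp, want_dX);
  return List::create(_["dW"] = dW, _["dOW"] = dOW, _["dX"] = dX);
}

// [[Rcpp::export(name = ".dc_pool_fwd")]]
List dc_pool_fwd(NumericMatrix Xg, NumericVector OWarr, IntegerMatrix base,
                 IntegerVector lo_in, IntegerVector hi_in) {
  IntegerVector od = OWarr.attr("dim");
  int win = od[0], nin = od[1], J = od[2];
  int W = Xg.ncol();
  int Wo = base.ncol();
  NumericMatrix delta(win, W), Y(nin, Wo);
  offset_conv_c(REAL(Xg), nin, W, REAL(OWarr), win, J, REAL(delta));
  const double* X = REAL(Xg);
  for (int j = 0; j < Wo; ++j) {
    if (lo_in[j] > hi_in[j]) continue;     // separator output column
    int l0 = lo_in[j] - 1, h0 = hi_in[j] - 1;
    for (int w = 0; w < win; ++w) {
      int b = base(w, j);                  // 1-based input column of this tap
      double pos = b + delta(w, b - 1);
      double fpos = std::floor(pos);
      int f0 = (int)fpos - 1;
      double fr = pos - fpos;
      bool vlo = (f0 >= l0 && f0 <= h0);
      bool vhi = (f0 + 1 >= l0 && f0 + 1 <= h0);
      const double* Xf = X + (size_t)std::min(std::max(f0, 0), W - 1) * nin;
      const double* Xf1 = X + (size_t)std::min(std::max(f0 + 1, 0), W - 1) * nin;
      for (int c = 0; c < nin; ++c) {
        double v = (1.0 - fr) * (vlo ? Xf[c] : 0.0) + fr * (vhi ? Xf1[c] : 0.0);
        Y(c, j) += v / win;
      }
    }
  }
  return List::create(_["Y"] = Y, _["delta"] = delta);
}

// [[Rcpp::export(name = ".dc_pool_bwd")]]
List dc_pool_bwd(NumericMatrix Xg, NumericVector OWarr, NumericMatrix delta,
                 IntegerMatrix base, IntegerVector lo_in, IntegerVector hi_in,
                 NumericMatrix dY) {
  IntegerVector od = OWarr.attr("dim");
  int win = od[0], nin = od[1], J = od[2];
  int W = Xg.ncol();
  int Wo = base.ncol();
  NumericVector dOW(OWarr.size()); dOW.attr("dim") = od;
  NumericMatrix dX(nin, W), dDelta(win, W);
  const double* X = REAL(Xg);
  double* dXp = REAL(dX);
  for (int j = 0; j < Wo; ++j) {
    if (lo_in[j] > hi_in[j]) continue;
    int l0 = lo_in[j] - 1, h0 = hi_in[j] - 1;
    for (int w = 0; w < win; ++w) {
      int b = base(w, j);
      double pos = b + delta(w, b - 1);
      double fpos = std::floor(pos);
      int f0 = (int)fpos - 1;
      double fr = pos - fpos;
      bool vlo = (f0 >= l0 && f0 <= h0);
      bool vhi = (f0 + 1 >= l0 && f0 + 1 <= h0);
      const double* Xf = X + (size_t)std::min(std::max(f0, 0), W - 1) * nin;
      const double* Xf1 = X + (size_t)std::min(std::max(f0 + 1, 0), W - 1) * nin;
      double dpos = 0.0;
      for (int c = 0; c < nin; ++c) {
        double d = dY(c, j) / win;
        if (d == 0.0) continue;
        double xlo = vlo ? Xf[c] : 0.0;
        double xhi = vhi ? Xf1[c] : 0.0;
        dpos += d * (xhi - xlo);
        if (vlo) dXp[c + (size_t)f0 * nin] += d * (1.0 - fr);
        if (vhi) dXp[c + (size_t)(f0 + 1) * nin] += d * fr;
      }
      dDelta(w, b - 1) += dpos;
    }
  }
  offset_conv_bwd_c(X, nin, W, REAL(OWarr), win, J, REAL(dDelta), REAL(dOW),
                    dXp, true);
  return List::create(_["dOW"] = dOW, _["dX"] = dX);
}
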