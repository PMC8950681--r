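// Minimal 3x3 same-padding convolution and 2x2 max-pool kernels (forward
// and backward) for the VGG19-style backbone. Tensors are R arrays in
// column-major (H, W, C, B) layout. Convolution is im2col + gemm; the
// gemm runs in single precision (activation gradients do not need more,
// and parameter updates are accumulated in double on the R side).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

// im2col for a 3x3 kernel with zero padding: (H*W*B) x (9*C), float
arma::fmat im2col3(const double *x, int H, int W, int C, int B) {
  const int P = H * W;
  arma::fmat cols(static_cast<arma::uword>(P) * B, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kw = -1; kw <= 1; ++kw)
      for (int kh = -1; kh <= 1; ++kh) {
        const int kidx = (kh + 1) + 3 * ((kw + 1) + 3 * c);
        float *dst = cols.colptr(kidx);
        for (int b = 0; b < B; ++b) {
          const double *xc = x + static_cast<size_t>(P) * (c + static_cast<size_t>(C) * b);
          float *dp = dst + static_cast<size_t>(P) * b;
          for (int w = 0; w < W; ++w) {
            int w2 = w + kw;
            if (w2 < 0 || w2 >= W) continue;
            int h_lo = std::max(0, -kh), h_hi = std::min(H, H - kh);
            const double *src = xc + static_cast<size_t>(H) * w2 + kh;
            float *out = dp + static_cast<size_t>(H) * w;
            for (int h = h_lo; h < h_hi; ++h)
              out[h] = static_cast<float>(src[h]);
          }
        }
      }
  return cols;
}

arma::fmat weight_mat(const NumericVector &w, int C, int Cout) {
  arma::fmat wm(9 * C, Cout);
  const double *wp = w.begin();
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i)
          wm(i + 3 * (j + 3 * c), co) = static_cast<float>(
            wp[i + 3 * (j + 3 * (c + static_cast<size_t>(C) * co))]);
  return wm;
}

} // namespace

// [[Rcpp::export(name = ".conv3x3_fwd_cpp")]]
NumericVector conv3x3_fwd(NumericVector x, IntegerVector xdim,
                          NumericVector w, NumericVector bias) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int P = H * W;
  const int Cout = bias.size();
  arma::fmat cols = im2col3(x.begin(), H, W, C, B);
  arma::fmat wm = weight_mat(w, C, Cout);
  arma::fmat y = cols * wm;                    // (P*B) x Cout
  NumericVector out(static_cast<R_xlen_t>(P) * Cout * B);
  out.attr("dim") = IntegerVector::create(H, W, Cout, B);
  double *op = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const double bv = bias[co];
    const float *yc = y.colptr(co);
    for (int b = 0; b < B; ++b) {
      double *dst = op + static_cast<size_t>(P) * (co + static_cast<size_t>(Cout) * b);
      const float *src = yc + static_cast<size_t>(P) * b;
      for (int p = 0; p < P; ++p) dst[p] = static_cast<double>(src[p]) + bv;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3x3_bwd_cpp")]]
List conv3x3_bwd(NumericVector x, IntegerVector xdim,
                 NumericVector w, NumericVector dy, int n_out) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int P = H * W;
  const int Cout = n_out;
  arma::fmat cols = im2col3(x.begin(), H, W, C, B);
  arma::fmat wm = weight_mat(w, C, Cout);

  // reorder dy (H,W,Cout,B) into (P*B) x Cout
  arma::fmat dym(static_cast<arma::uword>(P) * B, Cout);
  const double *dp = dy.begin();
  for (int co = 0; co < Cout; ++co) {
    float *dst = dym.colptr(co);
    for (int b = 0; b < B; ++b) {
      const double *src = dp + static_cast<size_t>(P) * (co + static_cast<size_t>(Cout) * b);
      float *dd = dst + static_cast<size_t>(P) * b;
      for (int p = 0; p < P; ++p) dd[p] = static_cast<float>(src[p]);
    }
  }

  arma::fmat dwm = cols.t() * dym;             // (9C) x Cout
  arma::frowvec dbv = arma::sum(dym, 0);
  arma::fmat dcols = dym * wm.t();             // (P*B) x (9C)

  NumericVector dw(w.size());
  dw.attr("dim") = IntegerVector::create(3, 3, C, Cout);
  double *dwp = dw.begin();
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i)
          dwp[i + 3 * (j + 3 * (c + static_cast<size_t>(C) * co))] =
            static_cast<double>(dwm(i + 3 * (j + 3 * c), co));

  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) db[co] = static_cast<double>(dbv(co));

  // col2im scatter-add
  NumericVector dx(x.size());
  dx.attr("dim") = xdim;
  double *dxp = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int kw = -1; kw <= 1; ++kw)
      for (int kh = -1; kh <= 1; ++kh) {
        const int kidx = (kh + 1) + 3 * ((kw + 1) + 3 * c);
        const float *src0 = dcols.colptr(kidx);
        for (int b = 0; b < B; ++b) {
          double *xc = dxp + static_cast<size_t>(P) * (c + static_cast<size_t>(C) * b);
          const float *sp = src0 + static_cast<size_t>(P) * b;
          for (int w2 = 0; w2 < W; ++w2) {
            int wi = w2 + kw;
            if (wi < 0 || wi >= W) continue;
            int h_lo = std::max(0, -kh), h_hi = std::min(H, H - kh);
            double *out = xc + static_cast<size_t>(H) * wi + kh;
            const float *in = sp + static_cast<size_t>(H) * w2;
            for (int h = h_lo; h < h_hi; ++h) out[h] += in[h];
          }
        }
      }

  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fwd_cpp")]]
List maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * B);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  size_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t base = static_cast<size_t>(H) * W * (c + static_cast<size_t>(C) * b);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = base + static_cast<size_t>(H) * (2 * w) + 2 * h;
          size_t best = i00;
          double v = xp[i00];
          size_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > v) { v = xp[cand[k]]; best = cand[k]; }
          yp[o] = v;
          ip[o] = static_cast<int>(best);
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd_cpp")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           IntegerVector xdim) {
  NumericVector dx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double *dxp = dx.begin();
  const double *dyp = dy.begin();
  const int *ip = idx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dxp[ip[i]] += dyp[i];
  return dx;
}
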