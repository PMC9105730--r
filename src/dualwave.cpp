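// Core numeric kernels: parallel-beam projector / exact adjoint, and
// 3x3 reflect-padded convolution (im2col + gemm) with its backward pass.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Bilinear gather with zero outside the image grid.
static inline double bilin(const arma::mat &img, double r, double c) {
  const int n = img.n_rows, m = img.n_cols;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0, v = 0.0;
  for (int dr = 0; dr <= 1; ++dr) {
    int rr = r0 + dr;
    if (rr < 0 || rr >= n) continue;
    double wr = dr ? fr : 1.0 - fr;
    for (int dc = 0; dc <= 1; ++dc) {
      int cc = c0 + dc;
      if (cc < 0 || cc >= m) continue;
      double wc = dc ? fc : 1.0 - fc;
      v += wr * wc * img(rr, cc);
    }
  }
  return v;
}

// Forward projector: line integrals along parallel rays, unit sample spacing.
// Rows of the result index detector bins, columns index view angles.
// [[Rcpp::export]]
arma::mat cpp_radon_forward(const arma::mat &img, const arma::vec &angles_rad,
                            const int n_det) {
  const int n = img.n_rows;
  const int n_views = angles_rad.n_elem;
  const double cen = 0.5 * (n - 1);
  const double dcen = 0.5 * (n_det - 1);
  const int ns = 2 * n;                  // half-pixel steps over the inscribed circle
  const double ds = 0.5;
  const double scen = 0.5 * (ns - 1);
  arma::mat sino(n_det, n_views, arma::fill::zeros);
  for (int j = 0; j < n_views; ++j) {
    const double ct = std::cos(angles_rad[j]), st = std::sin(angles_rad[j]);
    for (int k = 0; k < n_det; ++k) {
      const double t = k - dcen;
      double acc = 0.0;
      for (int is = 0; is < ns; ++is) {
        const double s = (is - scen) * ds;
        const double x = cen + t * ct - s * st;  // column coordinate
        const double y = cen + t * st + s * ct;  // row coordinate
        acc += bilin(img, y, x);
      }
      sino(k, j) = acc * ds;
    }
  }
  return sino;
}

// Exact adjoint of cpp_radon_forward: scatter with identical bilinear weights.
// [[Rcpp::export]]
arma::mat cpp_radon_adjoint(const arma::mat &sino, const arma::vec &angles_rad,
                            const int n) {
  const int n_det = sino.n_rows;
  const int n_views = angles_rad.n_elem;
  const double cen = 0.5 * (n - 1);
  const double dcen = 0.5 * (n_det - 1);
  const int ns = 2 * n;
  const double ds = 0.5;
  const double scen = 0.5 * (ns - 1);
  arma::mat img(n, n, arma::fill::zeros);
  for (int j = 0; j < n_views; ++j) {
    const double ct = std::cos(angles_rad[j]), st = std::sin(angles_rad[j]);
    for (int k = 0; k < n_det; ++k) {
      const double v = sino(k, j) * ds;
      if (v == 0.0) continue;
      const double t = k - dcen;
      for (int is = 0; is < ns; ++is) {
        const double s = (is - scen) * ds;
        const double x = cen + t * ct - s * st;
        const double y = cen + t * st + s * ct;
        int r0 = (int)std::floor(y), c0 = (int)std::floor(x);
        double fr = y - r0, fc = x - c0;
        for (int dr = 0; dr <= 1; ++dr) {
          int rr = r0 + dr;
          if (rr < 0 || rr >= n) continue;
          double wr = dr ? fr : 1.0 - fr;
          for (int dc = 0; dc <= 1; ++dc) {
            int cc = c0 + dc;
            if (cc < 0 || cc >= n) continue;
            double wc = dc ? fc : 1.0 - fc;
            img(rr, cc) += wr * wc * v;
          }
        }
      }
    }
  }
  return img;
}

static inline int reflect_idx(int i, int n) {
  // np.pad 'reflect' style: -1 -> 1, n -> n-2 (requires n >= 2)
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

// im2col for a 3x3 neighbourhood with one-pixel reflective padding.
// x: H x W x C cube -> (9*C) x (H*W) matrix, column-major over (row, col).
static arma::mat im2col3(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(9 * C, (size_t)H * W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const size_t col = (size_t)c * H + r;
      double *dst = out.colptr(col);
      for (int ch = 0; ch < C; ++ch) {
        const arma::mat &sl = x.slice(ch);
        int p = 0;
        for (int dc = -1; dc <= 1; ++dc) {
          const int cc = reflect_idx(c + dc, W);
          for (int dr = -1; dr <= 1; ++dr) {
            const int rr = reflect_idx(r + dr, H);
            dst[ch * 9 + p] = sl(rr, cc);
            ++p;
          }
        }
      }
    }
  }
  return out;
}

// Forward conv: x (H,W,Cin,N) flat, w (9*Cin, Cout), b (Cout) -> y (H,W,Cout,N).
// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(const NumericVector &x, const IntegerVector &xdim,
                            const arma::mat &w, const arma::vec &b) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Cout = w.n_cols;
  NumericVector y((size_t)H * W * Cout * N);
  const size_t xs = (size_t)H * W * C, ys = (size_t)H * W * Cout;
  for (int nidx = 0; nidx < N; ++nidx) {
    const arma::cube xc(const_cast<double *>(x.begin()) + nidx * xs, H, W, C,
                        false, true);
    arma::mat col = im2col3(xc);
    arma::mat out = w.t() * col;              // Cout x (H*W)
    out.each_col() += b;
    arma::mat outT = out.t();                 // (H*W) x Cout, column-major ok
    std::copy(outT.begin(), outT.end(), y.begin() + nidx * ys);
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// Backward conv: given dy, return dx, dw, db. Accumulates the gradient of the
// reflective padding back into the interior (exact transpose of the forward).
// [[Rcpp::export]]
List cpp_conv3_bwd(const NumericVector &x, const IntegerVector &xdim,
                   const arma::mat &w, const NumericVector &dy) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Cout = w.n_cols;
  NumericVector dx((size_t)H * W * C * N);
  arma::mat dw(9 * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  const size_t xs = (size_t)H * W * C, ys = (size_t)H * W * Cout;
  for (int nidx = 0; nidx < N; ++nidx) {
    const arma::cube xc(const_cast<double *>(x.begin()) + nidx * xs, H, W, C,
                        false, true);
    arma::mat col = im2col3(xc);
    // dy sample as Cout x (H*W)
    arma::mat dyT(const_cast<double *>(dy.begin()) + nidx * ys, (size_t)H * W,
                  Cout, false, true);
    arma::mat dys = dyT.t();
    dw += col * dyT;
    db += arma::sum(dys, 1);
    arma::mat dcol = w * dys;                 // (9*C) x (H*W)
    arma::cube dxc(dx.begin() + nidx * xs, H, W, C, false, true);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        const size_t cix = (size_t)c * H + r;
        const double *src = dcol.colptr(cix);
        for (int ch = 0; ch < C; ++ch) {
          arma::mat &sl = dxc.slice(ch);
          int p = 0;
          for (int dc = -1; dc <= 1; ++dc) {
            const int cc = reflect_idx(c + dc, W);
            for (int dr = -1; dr <= 1; ++dr) {
              const int rr = reflect_idx(r + dr, H);
              sl(rr, cc) += src[ch * 9 + p];
              ++p;
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// Per-channel mean and variance over (H, W, N) of an (H,W,C,N) array.
// [[Rcpp::export]]
List cpp_bn_stats(const NumericVector &z, const IntegerVector &zdim) {
  const int H = zdim[0], W = zdim[1], C = zdim[2], N = zdim[3];
  const size_t hw = (size_t)H * W, cs = hw * C;
  arma::vec mu(C, arma::fill::zeros), var(C, arma::fill::zeros);
  const double M = (double)hw * N;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = z.begin() + n * cs + c * hw;
      double s = 0.0, s2 = 0.0;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      mu[c] += s; var[c] += s2;
    }
  mu /= M;
  var = var / M - mu % mu;
  return List::create(Named("mu") = mu, Named("var") = var);
}

// Normalize, scale-shift and (optionally) rectify. Returns the output and
// the normalized activations needed by the backward pass.
// [[Rcpp::export]]
List cpp_bn_fwd(const NumericVector &z, const IntegerVector &zdim,
                const arma::vec &mu, const arma::vec &istd,
                const arma::vec &g, const arma::vec &be, const bool relu) {
  const int H = zdim[0], W = zdim[1], C = zdim[2], N = zdim[3];
  const size_t hw = (size_t)H * W, cs = hw * C;
  NumericVector out(z.size()), xhat(z.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = z.begin() + n * cs + c * hw;
      double *po = out.begin() + n * cs + c * hw;
      double *px = xhat.begin() + n * cs + c * hw;
      const double m = mu[c], is = istd[c], gc = g[c], bc = be[c];
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (p[i] - m) * is;
        px[i] = xh;
        double o = xh * gc + bc;
        if (relu && o < 0) o = 0;
        po[i] = o;
      }
    }
  out.attr("dim") = zdim;
  xhat.attr("dim") = zdim;
  return List::create(Named("out") = out, Named("xhat") = xhat);
}

// Backward through (optional ReLU +) batch norm with batch statistics.
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericVector &dy, const IntegerVector &zdim,
                const NumericVector &xhat, const NumericVector &out,
                const arma::vec &g, const arma::vec &istd, const bool relu) {
  const int H = zdim[0], W = zdim[1], C = zdim[2], N = zdim[3];
  const size_t hw = (size_t)H * W, cs = hw * C;
  const double M = (double)hw * N;
  arma::vec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
  arma::vec dg(C, arma::fill::zeros), dbe(C, arma::fill::zeros);
  // first pass: per-channel reductions of dxhat and dxhat * xhat
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *pd = dy.begin() + n * cs + c * hw;
      const double *px = xhat.begin() + n * cs + c * hw;
      const double *po = out.begin() + n * cs + c * hw;
      const double gc = g[c];
      double a1 = 0.0, a2 = 0.0, ag = 0.0, ab = 0.0;
      for (size_t i = 0; i < hw; ++i) {
        double d = pd[i];
        if (relu && po[i] <= 0) d = 0;
        ag += d * px[i]; ab += d;
        const double dxh = d * gc;
        a1 += dxh; a2 += dxh * px[i];
      }
      s1[c] += a1; s2[c] += a2; dg[c] += ag; dbe[c] += ab;
    }
  NumericVector dz(dy.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *pd = dy.begin() + n * cs + c * hw;
      const double *px = xhat.begin() + n * cs + c * hw;
      const double *po = out.begin() + n * cs + c * hw;
      double *pz = dz.begin() + n * cs + c * hw;
      const double gc = g[c], is = istd[c];
      const double m1 = s1[c] / M, m2 = s2[c] / M;
      for (size_t i = 0; i < hw; ++i) {
        double d = pd[i];
        if (relu && po[i] <= 0) d = 0;
        pz[i] = (d * gc - m1 - px[i] * m2) * is;
      }
    }
  dz.attr("dim") = zdim;
  return List::create(Named("dz") = dz, Named("dg") = dg,
                      Named("dbe") = dbe);
}
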