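// Low-level numerical kernels: im2col-based 2D convolution (forward and the two
// backward passes, from which transpose convolution is also assembled at the R
// level), reflect-padded median / soft weighted median filters, separable 1D
// convolution, image resizing, and Chebyshev-connected component labeling.
//
// Tensor layout throughout: column-major R arrays of dim (H, W, C, N) for
// feature maps and (kh, kw, Cin, Cout) for convolution weights.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // scipy-style 'reflect' (edge value repeated): -1 -> 0, -2 -> 1, n -> n-1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int ph, int pw,
                   int Ho, int Wo, arma::mat& cols) {
  // cols: (kh*kw*C) x (Ho*Wo); row = khi + kh*(kwi + kw*c); col = oh + Ho*ow
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        int r = khi + kh * (kwi + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pw + kwi;
          if (iw < 0 || iw >= W) continue;
          const double* xcol = xc + (size_t)iw * H;
          double* ccol = cols.colptr(0) + r; // stride cols.n_rows per col
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - ph + khi;
            if (ih < 0 || ih >= H) continue;
            ccol[(size_t)(oh + Ho * ow) * cols.n_rows] = xcol[ih];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int ph, int pw,
                   int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        int r = khi + kh * (kwi + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pw + kwi;
          if (iw < 0 || iw >= W) continue;
          double* xcol = xc + (size_t)iw * H;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - ph + khi;
            if (ih < 0 || ih >= H) continue;
            xcol[ih] += cols((size_t)r, (size_t)(oh + Ho * ow));
          }
        }
      }
    }
  }
}

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           int stride, int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv_fwd");
  int Ho = out_dim(H, kh, stride, ph), Wo = out_dim(W, kw, stride, pw);
  if (Ho < 1 || Wo < 1) stop("conv output would be empty");
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), kh * kw * Cin, Cout, false);
  arma::mat cols(kh * kw * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, ph, pw,
           Ho, Wo, cols);
    arma::mat ym(y.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout, false, true);
    ym = cols.t() * Wm;
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv_bwd_data")]]
NumericVector cpp_conv_bwd_data(NumericVector dy, NumericVector w,
                                int stride, int ph, int pw, int H, int W) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  int Ho = yd[0], Wo = yd[1], Cout = yd[2], N = yd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2];
  NumericVector dx(H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat Wm(w.begin(), kh * kw * Cin, Cout, false);
  for (int n = 0; n < N; ++n) {
    arma::mat dym(dy.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout, false);
    arma::mat dcols = Wm * dym.t();
    col2im(dcols, H, W, Cin, kh, kw, stride, ph, pw, Ho, Wo,
           dx.begin() + (size_t)n * H * W * Cin);
  }
  return dx;
}

// [[Rcpp::export(name = ".cpp_conv_bwd_weight")]]
NumericVector cpp_conv_bwd_weight(NumericVector x, NumericVector dy,
                                  int stride, int ph, int pw, int kh, int kw) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  NumericVector dw(kh * kw * C * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  arma::mat dwm(dw.begin(), kh * kw * C, Cout, false);
  arma::mat cols(kh * kw * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, ph, pw,
           Ho, Wo, cols);
    arma::mat dym(dy.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout, false);
    dwm += cols * dym;
  }
  return dw;
}

// ---------------------------------------------------------------- filters ----

static double weighted_median(std::vector<std::pair<double,double> >& vw) {
  // vw: (value, weight) pairs; returns smallest value whose cumulative weight
  // reaches half the total.
  std::sort(vw.begin(), vw.end());
  double tot = 0.0;
  for (size_t i = 0; i < vw.size(); ++i) tot += vw[i].second;
  double cum = 0.0, half = tot / 2.0;
  for (size_t i = 0; i < vw.size(); ++i) {
    cum += vw[i].second;
    if (cum >= half) return vw[i].first;
  }
  return vw.back().first;
}

// [[Rcpp::export(name = ".cpp_median_filter2")]]
NumericMatrix cpp_median_filter2(NumericMatrix x, int wh, int ww) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(H, W);
  int rh = wh / 2, rw = ww / 2;
  std::vector<double> buf(wh * ww);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int k = 0;
      for (int dj = -rw; dj <= rw; ++dj)
        for (int di = -rh; di <= rh; ++di)
          buf[k++] = x(reflect_idx(i + di, H), reflect_idx(j + dj, W));
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      y(i, j) = buf[k / 2];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_swmf_filter2")]]
NumericMatrix cpp_swmf_filter2(NumericMatrix x, int wh, int ww, double temp) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(H, W);
  int rh = wh / 2, rw = ww / 2;
  int nwin = wh * ww;
  std::vector<double> buf(nwin);
  std::vector<std::pair<double,double> > vw(nwin);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int k = 0;
      for (int dj = -rw; dj <= rw; ++dj)
        for (int di = -rh; di <= rh; ++di)
          buf[k++] = x(reflect_idx(i + di, H), reflect_idx(j + dj, W));
      std::vector<double> tmp(buf);
      std::nth_element(tmp.begin(), tmp.begin() + k / 2, tmp.end());
      double med = tmp[k / 2];
      for (int t = 0; t < k; ++t)
        vw[t] = std::make_pair(buf[t], std::exp(-std::fabs(buf[t] - med) / temp));
      y(i, j) = weighted_median(vw);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv1d_cols")]]
NumericMatrix cpp_conv1d_cols(NumericMatrix x, NumericVector kern) {
  // Convolve every column of x with kern under reflect padding.
  int n = x.nrow(), m = x.ncol(), kl = kern.size(), c = kl / 2;
  NumericMatrix y(n, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int t = 0; t < kl; ++t)
        s += kern[t] * x(reflect_idx(i + t - c, n), j);
      y(i, j) = s;
    }
  return y;
}

// ----------------------------------------------------------------- resize ----

static inline double cubic_w(double t) {
  // Catmull-Rom (a = -0.5)
  double a = -0.5, at = std::fabs(t);
  if (at <= 1.0) return (a + 2.0) * at * at * at - (a + 3.0) * at * at + 1.0;
  if (at < 2.0)  return a * at * at * at - 5.0 * a * at * at + 8.0 * a * at - 4.0 * a;
  return 0.0;
}

// [[Rcpp::export(name = ".cpp_resize2")]]
NumericMatrix cpp_resize2(NumericMatrix x, int Ht, int Wt, int method) {
  // method: 0 nearest, 1 bilinear, 2 cubic (Catmull-Rom); pixel-center mapping
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(Ht, Wt);
  double sh = (double)H / Ht, sw = (double)W / Wt;
  for (int j = 0; j < Wt; ++j) {
    double sx = (j + 0.5) * sw - 0.5;
    for (int i = 0; i < Ht; ++i) {
      double sy = (i + 0.5) * sh - 0.5;
      if (method == 0) {
        int ii = std::min(H - 1, std::max(0, (int)std::floor(sy + 0.5)));
        int jj = std::min(W - 1, std::max(0, (int)std::floor(sx + 0.5)));
        y(i, j) = x(ii, jj);
      } else if (method == 1) {
        double cy = std::min((double)(H - 1), std::max(0.0, sy));
        double cx = std::min((double)(W - 1), std::max(0.0, sx));
        int y0 = (int)std::floor(cy), x0 = (int)std::floor(cx);
        int y1 = std::min(H - 1, y0 + 1), x1 = std::min(W - 1, x0 + 1);
        double fy = cy - y0, fx = cx - x0;
        y(i, j) = (1 - fy) * (1 - fx) * x(y0, x0) + (1 - fy) * fx * x(y0, x1)
                + fy * (1 - fx) * x(y1, x0) + fy * fx * x(y1, x1);
      } else {
        int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
        double s = 0.0, wsum = 0.0;
        for (int dj = -1; dj <= 2; ++dj) {
          double wx = cubic_w(sx - (x0 + dj));
          if (wx == 0.0) continue;
          int jj = std::min(W - 1, std::max(0, x0 + dj));
          for (int di = -1; di <= 2; ++di) {
            double wy = cubic_w(sy - (y0 + di));
            if (wy == 0.0) continue;
            int ii = std::min(H - 1, std::max(0, y0 + di));
            s += wx * wy * x(ii, jj);
            wsum += wx * wy;
          }
        }
        y(i, j) = s / wsum;
      }
    }
  }
  return y;
}

// ------------------------------------------------- connected components ------

// [[Rcpp::export(name = ".cpp_label_zones")]]
IntegerVector cpp_label_zones(IntegerVector lev) {
  // Label Chebyshev-connected (8-connected 2D / 26-connected 3D) zones of
  // equal positive level. Background (0) stays 0.
  IntegerVector dims = lev.attr("dim");
  int nd = dims.size();
  int H = dims[0], W = dims[1], D = (nd == 3) ? dims[2] : 1;
  size_t n = (size_t)H * W * D;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (lev[s] <= 0 || lab[s] != 0) continue;
    int v = lev[s];
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int ch = cur % H, cw = (cur / H) % W, cd = cur / ((size_t)H * W);
      for (int dd = -1; dd <= 1; ++dd) {
        int zd = cd + dd; if (zd < 0 || zd >= D) continue;
        for (int dw = -1; dw <= 1; ++dw) {
          int zw = cw + dw; if (zw < 0 || zw >= W) continue;
          for (int dh = -1; dh <= 1; ++dh) {
            int zh = ch + dh; if (zh < 0 || zh >= H) continue;
            if (dd == 0 && dw == 0 && dh == 0) continue;
            size_t q = zh + (size_t)H * (zw + (size_t)W * zd);
            if (lev[q] == v && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
        }
      }
    }
  }
  return lab;
}
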