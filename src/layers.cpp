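// Low-level numerical kernels for the correspondence network and the
// connected-component labeller. Activation tensors are dense R arrays in
// [H, W, C, N] layout (column-major, H fastest); convolution weights are
// [k, k, Cin, Cout]. Convolutions are 'same' (zero padding k/2, k odd) and
// implemented as im2col + GEMM so that a single-threaded BLAS does the heavy
// lifting; backward passes return exact analytic gradients.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C,
                             int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d [H,W,C,N] array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill the im2col matrix (HW x k*k*Cin) for sample n; column order
// (dh, dw, ci) with dh fastest matches the native [k,k,Cin,Cout] weight
// layout, so the weight array reshapes to the GEMM operand with no copy.
static void im2col(const double* xs, int H, int W, int Cin, int k, int pad,
                   arma::mat& Xcol) {
  const int HW = H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = xs + (size_t)ci * HW;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int q = dh + k * dw + k * k * ci;
        double* col = Xcol.colptr(q);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw - pad;
          double* colw = col + (size_t)w * H;
          if (iw < 0 || iw >= W) {
            std::fill(colw, colw + H, 0.0);
            continue;
          }
          const double* xcw = xc + (size_t)iw * H;
          for (int h = 0; h < H; ++h) {
            const int ih = h + dh - pad;
            colw[h] = (ih < 0 || ih >= H) ? 0.0 : xcw[ih];
          }
        }
      }
    }
  }
}

// Scatter-add the im2col-shaped gradient back onto the input tensor.
static void col2im(const arma::mat& dXcol, int H, int W, int Cin, int k,
                   int pad, double* dxs) {
  const int HW = H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    double* dxc = dxs + (size_t)ci * HW;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int q = dh + k * dw + k * k * ci;
        const double* col = dXcol.colptr(q);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw - pad;
          if (iw < 0 || iw >= W) continue;
          double* dxcw = dxc + (size_t)iw * H;
          const double* colw = col + (size_t)w * H;
          for (int h = 0; h < H; ++h) {
            const int ih = h + dh - pad;
            if (ih >= 0 && ih < H) dxcw[ih] += colw[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight/input channel mismatch");
  const int pad = k / 2, HW = H * W;

  NumericVector y((size_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wmat(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  arma::mat Xcol(HW, k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * Cin, H, W, Cin, k, pad, Xcol);
    arma::mat Y(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    Y = Xcol * Wmat;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  const int pad = k / 2, HW = H * W;

  NumericVector dx((size_t)HW * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  arma::mat Wmat(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  arma::mat dWmat(dw.begin(), k * k * Cin, Cout, false, true);
  arma::mat Xcol(HW, k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * Cin, H, W, Cin, k, pad, Xcol);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * HW * Cout, HW,
                 Cout, false);
    dWmat += Xcol.t() * dY;
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dY.col(co));
    arma::mat dXcol = dY * Wmat.t();
    col2im(dXcol, H, W, Cin, k, pad, dx.begin() + (size_t)n * HW * Cin);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution, fixed 2x2 kernel with stride 2 (exact upsampling
// by a factor of two): y[2h+dh, 2w+dw, co] = b[co] + sum_ci x[h,w,ci] *
// w[dh,dw,ci,co].

// [[Rcpp::export]]
NumericVector cpp_tconv2_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != Cin) stop("bad tconv weights");
  const int Cout = wd[3], HW = H * W, H2 = 2 * H, W2 = 2 * W;

  // V(ci, s) with s = dh + 2*dw + 4*co
  arma::mat V(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int dw_ = 0; dw_ < 2; ++dw_)
      for (int dh = 0; dh < 2; ++dh)
        for (int ci = 0; ci < Cin; ++ci)
          V(ci, dh + 2 * dw_ + 4 * co) =
              w[dh + 2 * (dw_ + 2 * (ci + (size_t)Cin * co))];

  NumericVector y((size_t)H2 * W2 * Cout * N);
  y.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * Cin, HW, Cin,
                false);
    arma::mat Y2 = X * V;  // HW x 4*Cout
    double* yn = y.begin() + (size_t)n * H2 * W2 * Cout;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)co * H2 * W2;
      for (int dw_ = 0; dw_ < 2; ++dw_) {
        for (int dh = 0; dh < 2; ++dh) {
          const double* src = Y2.colptr(dh + 2 * dw_ + 4 * co);
          for (int ww = 0; ww < W; ++ww) {
            double* dst = yc + (size_t)(2 * ww + dw_) * H2 + dh;
            const double* s = src + (size_t)ww * H;
            for (int h = 0; h < H; ++h) dst[2 * h] = s[h] + b[co];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3], HW = H * W, H2 = 2 * H, W2 = 2 * W;

  arma::mat V(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int dw_ = 0; dw_ < 2; ++dw_)
      for (int dh = 0; dh < 2; ++dh)
        for (int ci = 0; ci < Cin; ++ci)
          V(ci, dh + 2 * dw_ + 4 * co) =
              w[dh + 2 * (dw_ + 2 * (ci + (size_t)Cin * co))];

  NumericVector dx((size_t)HW * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dV(Cin, 4 * Cout, arma::fill::zeros);

  arma::mat dY2(HW, 4 * Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)n * H2 * W2 * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + (size_t)co * H2 * W2;
      double bs = 0.0;
      for (int dw_ = 0; dw_ < 2; ++dw_) {
        for (int dh = 0; dh < 2; ++dh) {
          double* dst = dY2.colptr(dh + 2 * dw_ + 4 * co);
          for (int ww = 0; ww < W; ++ww) {
            const double* s = dyc + (size_t)(2 * ww + dw_) * H2 + dh;
            double* d = dst + (size_t)ww * H;
            for (int h = 0; h < H; ++h) {
              d[h] = s[2 * h];
              bs += s[2 * h];
            }
          }
        }
      }
      db[co] += bs;
    }
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * Cin, HW, Cin,
                false);
    arma::mat dX(dx.begin() + (size_t)n * HW * Cin, HW, Cin, false, true);
    dX = dY2 * V.t();
    dV += X.t() * dY2;
  }
  for (int co = 0; co < Cout; ++co)
    for (int dw_ = 0; dw_ < 2; ++dw_)
      for (int dh = 0; dh < 2; ++dh)
        for (int ci = 0; ci < Cin; ++ci)
          dw[dh + 2 * (dw_ + 2 * (ci + (size_t)Cin * co))] =
              dV(ci, dh + 2 * dw_ + 4 * co);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Ties resolved to the first element in
// (dh, dw) scan order so the pass is deterministic.

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("max pooling needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector amax(y.size());  // linear index into x
  const double* xp = x.begin();
  double* yp = y.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = -HUGE_VAL;
          size_t bi = 0;
          for (int dw_ = 0; dw_ < 2; ++dw_)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t i = base + (size_t)(2 * w + dw_) * H + 2 * h + dh;
              if (xp[i] > best) {
                best = xp[i];
                bi = i;
              }
            }
          yp[o] = best;
          amax[o] = (int)bi;
          ++o;
        }
    }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector amax,
                               IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[amax[i]] += dy[i];
  return dx;
}

// Connected-component labelling of a binary mask with 4- or 8-adjacency
// (iterative flood fill; labels assigned in column-major scan order).

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  const int n4dh[] = {-1, 1, 0, 0}, n4dw[] = {0, 0, -1, 1};
  const int n8dh[] = {-1, 1, 0, 0, -1, -1, 1, 1},
            n8dw[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dh = (connectivity == 8) ? n8dh : n4dh;
  const int* dw = (connectivity == 8) ? n8dw : n4dw;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      lab(h, w) = ++next;
      stack.emplace_back(h, w);
      while (!stack.empty()) {
        auto p = stack.back();
        stack.pop_back();
        for (int t = 0; t < nn; ++t) {
          const int hh = p.first + dh[t], ww = p.second + dw[t];
          if (hh < 0 || hh >= H || ww < 0 || ww >= W) continue;
          if (mask(hh, ww) != 0 && lab(hh, ww) == 0) {
            lab(hh, ww) = next;
            stack.emplace_back(hh, ww);
          }
        }
      }
    }
  return lab;
}
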