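#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Minimal CPU kernels for the baseline classifiers: im2col-based 2D/3D
// convolution (forward/backward) and max pooling. Batches are dense matrices
// with ONE SAMPLE PER COLUMN (feature-major layout, so every sample is a
// contiguous memory block); per-sample feature layout is channel-major with
// spatial dimensions fastest-last ((c, z, y, x) for 3D with x fastest).

static inline int out_size(int in, int k, int stride, int pad) {
  return (in - k + 2 * pad) / stride + 1;
}

// ---- 3D ----

static void im2col3d(const double *x, int C, int D, int H, int W, int k,
                     int stride, int pad, arma::mat &col) {
  const int oD = out_size(D, k, stride, pad), oH = out_size(H, k, stride, pad),
            oW = out_size(W, k, stride, pad);
  int oc = 0;
  for (int od = 0; od < oD; ++od)
    for (int oh = 0; oh < oH; ++oh)
      for (int ow = 0; ow < oW; ++ow, ++oc) {
        double *dst = col.colptr(oc);
        int r = 0;
        for (int c = 0; c < C; ++c)
          for (int dz = 0; dz < k; ++dz) {
            int z = od * stride + dz - pad;
            for (int dy = 0; dy < k; ++dy) {
              int y = oh * stride + dy - pad;
              const bool zy_ok = z >= 0 && z < D && y >= 0 && y < H;
              const double *src = zy_ok ? x + ((c * D + z) * H + y) * W : 0;
              for (int dx = 0; dx < k; ++dx, ++r) {
                int xx = ow * stride + dx - pad;
                dst[r] = (!zy_ok || xx < 0 || xx >= W) ? 0.0 : src[xx];
              }
            }
          }
      }
}

static void col2im3d(const arma::mat &col, int C, int D, int H, int W, int k,
                     int stride, int pad, double *x) {
  const int oD = out_size(D, k, stride, pad), oH = out_size(H, k, stride, pad),
            oW = out_size(W, k, stride, pad);
  int oc = 0;
  for (int od = 0; od < oD; ++od)
    for (int oh = 0; oh < oH; ++oh)
      for (int ow = 0; ow < oW; ++ow, ++oc) {
        const double *src = col.colptr(oc);
        int r = 0;
        for (int c = 0; c < C; ++c)
          for (int dz = 0; dz < k; ++dz) {
            int z = od * stride + dz - pad;
            for (int dy = 0; dy < k; ++dy) {
              int y = oh * stride + dy - pad;
              const bool zy_ok = z >= 0 && z < D && y >= 0 && y < H;
              double *dst = zy_ok ? x + ((c * D + z) * H + y) * W : 0;
              for (int dx = 0; dx < k; ++dx, ++r) {
                int xx = ow * stride + dx - pad;
                if (zy_ok && xx >= 0 && xx < W) dst[xx] += src[r];
              }
            }
          }
      }
}

// X: (C*D*H*W) x n, Wt: K x (C*k^3); returns (K*oN) x n
// [[Rcpp::export(name = ".conv3d_fw_cpp")]]
NumericMatrix conv3d_fw_cpp(NumericMatrix X, IntegerVector dims,
                            NumericMatrix Wt, NumericVector b, int k,
                            int stride, int pad) {
  const int n = X.ncol(), C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int K = Wt.nrow();
  const int oD = out_size(D, k, stride, pad), oH = out_size(H, k, stride, pad),
            oW = out_size(W, k, stride, pad);
  const int oN = oD * oH * oW;
  arma::mat Wm(Wt.begin(), K, Wt.ncol(), false);
  NumericMatrix Y(K * oN, n);
  arma::mat col(C * k * k * k, oN);
  for (int s = 0; s < n; ++s) {
    im2col3d(&X(0, s), C, D, H, W, k, stride, pad, col);
    // output layout per sample: channel-major -> row block per channel
    // the oN x K view writes column-major into the sample column: spatial
    // index fastest within each channel block = the channel-major layout
    arma::mat Ys(&Y(0, s), oN, K, false, true);
    Ys = col.t() * Wm.t();
  }
  for (int s = 0; s < n; ++s)
    for (int kk = 0; kk < K; ++kk) {
      double *yp = &Y(kk * oN, s);
      for (int i = 0; i < oN; ++i) yp[i] += b[kk];
    }
  return Y;
}

// [[Rcpp::export(name = ".conv3d_bw_cpp")]]
List conv3d_bw_cpp(NumericMatrix X, NumericMatrix dY, IntegerVector dims,
                   NumericMatrix Wt, int k, int stride, int pad,
                   bool need_dx) {
  const int n = X.ncol(), C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int K = Wt.nrow();
  const int oD = out_size(D, k, stride, pad), oH = out_size(H, k, stride, pad),
            oW = out_size(W, k, stride, pad);
  const int oN = oD * oH * oW;
  arma::mat Wm(Wt.begin(), K, Wt.ncol(), false);
  arma::mat dW(K, Wt.ncol(), arma::fill::zeros);
  arma::vec db(K, arma::fill::zeros);
  NumericMatrix dX(need_dx ? C * D * H * W : 1, need_dx ? n : 1);
  arma::mat col(C * k * k * k, oN);
  for (int s = 0; s < n; ++s) {
    im2col3d(&X(0, s), C, D, H, W, k, stride, pad, col);
    arma::mat dYs(const_cast<double *>(&dY(0, s)), oN, K, false, true);
    dW += dYs.t() * col.t();
    db += arma::sum(dYs, 0).t();
    if (need_dx) {
      arma::mat dcol = Wm.t() * dYs.t();
      std::fill(&dX(0, s), &dX(0, s) + C * D * H * W, 0.0);
      col2im3d(dcol, C, D, H, W, k, stride, pad, &dX(0, s));
    }
  }
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dX"] = dX);
}

// ---- 2D ----

static void im2col2d(const double *x, int C, int H, int W, int k, int stride,
                     int pad, arma::mat &col) {
  const int oH = out_size(H, k, stride, pad), oW = out_size(W, k, stride, pad);
  int oc = 0;
  for (int oh = 0; oh < oH; ++oh)
    for (int ow = 0; ow < oW; ++ow, ++oc) {
      double *dst = col.colptr(oc);
      int r = 0;
      for (int c = 0; c < C; ++c)
        for (int dy = 0; dy < k; ++dy) {
          int y = oh * stride + dy - pad;
          const bool y_ok = y >= 0 && y < H;
          const double *src = y_ok ? x + (c * H + y) * W : 0;
          for (int dx = 0; dx < k; ++dx, ++r) {
            int xx = ow * stride + dx - pad;
            dst[r] = (!y_ok || xx < 0 || xx >= W) ? 0.0 : src[xx];
          }
        }
    }
}

static void col2im2d(const arma::mat &col, int C, int H, int W, int k,
                     int stride, int pad, double *x) {
  const int oH = out_size(H, k, stride, pad), oW = out_size(W, k, stride, pad);
  int oc = 0;
  for (int oh = 0; oh < oH; ++oh)
    for (int ow = 0; ow < oW; ++ow, ++oc) {
      const double *src = col.colptr(oc);
      int r = 0;
      for (int c = 0; c < C; ++c)
        for (int dy = 0; dy < k; ++dy) {
          int y = oh * stride + dy - pad;
          const bool y_ok = y >= 0 && y < H;
          double *dst = y_ok ? x + (c * H + y) * W : 0;
          for (int dx = 0; dx < k; ++dx, ++r) {
            int xx = ow * stride + dx - pad;
            if (y_ok && xx >= 0 && xx < W) dst[xx] += src[r];
          }
        }
    }
}

// [[Rcpp::export(name = ".conv2d_fw_cpp")]]
NumericMatrix conv2d_fw_cpp(NumericMatrix X, IntegerVector dims,
                            NumericMatrix Wt, NumericVector b, int k,
                            int stride, int pad) {
  const int n = X.ncol(), C = dims[0], H = dims[1], W = dims[2];
  const int K = Wt.nrow();
  const int oH = out_size(H, k, stride, pad), oW = out_size(W, k, stride, pad);
  const int oN = oH * oW;
  arma::mat Wm(Wt.begin(), K, Wt.ncol(), false);
  NumericMatrix Y(K * oN, n);
  arma::mat col(C * k * k, oN);
  for (int s = 0; s < n; ++s) {
    im2col2d(&X(0, s), C, H, W, k, stride, pad, col);
    arma::mat Ys(&Y(0, s), oN, K, false, true);
    Ys = col.t() * Wm.t();
  }
  for (int s = 0; s < n; ++s)
    for (int kk = 0; kk < K; ++kk) {
      double *yp = &Y(kk * oN, s);
      for (int i = 0; i < oN; ++i) yp[i] += b[kk];
    }
  return Y;
}

// [[Rcpp::export(name = ".conv2d_bw_cpp")]]
List conv2d_bw_cpp(NumericMatrix X, NumericMatrix dY, IntegerVector dims,
                   NumericMatrix Wt, int k, int stride, int pad,
                   bool need_dx) {
  const int n = X.ncol(), C = dims[0], H = dims[1], W = dims[2];
  const int K = Wt.nrow();
  const int oH = out_size(H, k, stride, pad), oW = out_size(W, k, stride, pad);
  const int oN = oH * oW;
  arma::mat Wm(Wt.begin(), K, Wt.ncol(), false);
  arma::mat dW(K, Wt.ncol(), arma::fill::zeros);
  arma::vec db(K, arma::fill::zeros);
  NumericMatrix dX(need_dx ? C * H * W : 1, need_dx ? n : 1);
  arma::mat col(C * k * k, oN);
  for (int s = 0; s < n; ++s) {
    im2col2d(&X(0, s), C, H, W, k, stride, pad, col);
    arma::mat dYs(const_cast<double *>(&dY(0, s)), oN, K, false, true);
    dW += dYs.t() * col.t();
    db += arma::sum(dYs, 0).t();
    if (need_dx) {
      arma::mat dcol = Wm.t() * dYs.t();
      std::fill(&dX(0, s), &dX(0, s) + C * H * W, 0.0);
      col2im2d(dcol, C, H, W, k, stride, pad, &dX(0, s));
    }
  }
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dX"] = dX);
}

// ---- max pooling (dims: C, spatial...) ----

// [[Rcpp::export(name = ".maxpool_fw_cpp")]]
List maxpool_fw_cpp(NumericMatrix X, IntegerVector dims, int k, int stride,
                    int pad) {
  const int n = X.ncol(), C = dims[0];
  const int nd = dims.size() - 1;
  std::vector<int> sp(nd), osp(nd);
  int inN = 1, oN = 1;
  for (int i = 0; i < nd; ++i) {
    sp[i] = dims[i + 1];
    osp[i] = out_size(sp[i], k, stride, pad);
    inN *= sp[i];
    oN *= osp[i];
  }
  int total = 1;
  for (int i = 0; i < nd; ++i) total *= k;
  NumericMatrix Y(C * oN, n);
  IntegerMatrix A(C * oN, n);
  std::vector<int> dd(nd), oc(nd);
  for (int s = 0; s < n; ++s) {
    const double *xs = &X(0, s);
    for (int c = 0; c < C; ++c) {
      std::fill(oc.begin(), oc.end(), 0);
      for (int o = 0; o < oN; ++o) {
        double best = R_NegInf;
        int bestIdx = -1;
        for (int w = 0; w < total; ++w) {
          int rem = w;
          for (int i = nd - 1; i >= 0; --i) { dd[i] = rem % k; rem /= k; }
          bool ok = true;
          int lin = 0;
          for (int i = 0; i < nd; ++i) {
            int pos = oc[i] * stride + dd[i] - pad;
            if (pos < 0 || pos >= sp[i]) { ok = false; break; }
            lin = lin * sp[i] + pos;
          }
          if (ok) {
            double v = xs[c * inN + lin];
            if (v > best) { best = v; bestIdx = c * inN + lin; }
          }
        }
        Y(c * oN + o, s) = best;
        A(c * oN + o, s) = bestIdx;
        for (int i = nd - 1; i >= 0; --i) {
          if (++oc[i] < osp[i]) break;
          oc[i] = 0;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["argmax"] = A);
}

// [[Rcpp::export(name = ".maxpool_bw_cpp")]]
NumericMatrix maxpool_bw_cpp(NumericMatrix dY, IntegerMatrix A, int in_size) {
  const int n = dY.ncol(), m = dY.nrow();
  NumericMatrix dX(in_size, n);
  for (int s = 0; s < n; ++s) {
    double *dst = &dX(0, s);
    const double *src = &dY(0, s);
    const int *aa = &A(0, s);
    for (int j = 0; j < m; ++j)
      if (aa[j] >= 0) dst[aa[j]] += src[j];
  }
  return dX;
}
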