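// Low-level volumetric operators used by the U-Net, the losses and the
// geometry layer. Feature maps are R arrays with dim (D, H, W, C) in
// column-major order; single-channel volumes use (D, H, W).
//
// Convolutions are computed by im2col lowering followed by a BLAS GEMM
// (through Armadillo); this keeps desk-scale CPU training tractable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Build the lowered patch matrix in N x K layout: rows index output
// voxels (od fastest), columns index (kd, kh, kw, c_in) with kd fastest
// (matching the column-major flattening of an R weight array of dim
// (kd, kh, kw, Cin, Cout)). Zero padding. The N x K layout keeps both
// the source reads and the destination writes contiguous along od.
static arma::mat im2col(const double* x, int D, int H, int W, int C,
                        int kd, int kh, int kw,
                        int sd, int sh, int sw,
                        int pd, int ph, int pw) {
  const int oD = out_extent(D, kd, sd, pd);
  const int oH = out_extent(H, kh, sh, ph);
  const int oW = out_extent(W, kw, sw, pw);
  const int K = kd * kh * kw * C;
  const arma::uword N = (arma::uword)oD * oH * oW;
  arma::mat col(N, K, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * D * H * W;
    for (int iw = 0; iw < kw; ++iw)
      for (int ih = 0; ih < kh; ++ih)
        for (int id = 0; id < kd; ++id) {
          const int k = id + kd * (ih + kh * iw) + kd * kh * kw * c;
          double* dst = col.colptr(k);
          for (int ow = 0; ow < oW; ++ow) {
            const int w = ow * sw - pw + iw;
            if (w < 0 || w >= W) continue;
            for (int oh = 0; oh < oH; ++oh) {
              const int h = oh * sh - ph + ih;
              if (h < 0 || h >= H) continue;
              const double* src = xc + (size_t)(w * H + h) * D;
              double* d2 = dst + (size_t)(ow * oH + oh) * oD;
              if (sd == 1) {
                // contiguous run of od where d = od - pd + id is in range
                const int od0 = std::max(0, pd - id);
                const int od1 = std::min(oD, D + pd - id);
                const double* s2 = src + od0 - pd + id;
                for (int od = od0; od < od1; ++od) d2[od] = s2[od - od0];
              } else {
                for (int od = 0; od < oD; ++od) {
                  const int d = od * sd - pd + id;
                  if (d >= 0 && d < D) d2[od] = src[d];
                }
              }
            }
          }
        }
  }
  return col;
}

// Scatter-add of an N x K patch matrix back onto the input grid
// (adjoint of im2col).
static void col2im(const arma::mat& col, double* x, int D, int H, int W, int C,
                   int kd, int kh, int kw,
                   int sd, int sh, int sw,
                   int pd, int ph, int pw) {
  const int oD = out_extent(D, kd, sd, pd);
  const int oH = out_extent(H, kh, sh, ph);
  const int oW = out_extent(W, kw, sw, pw);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * D * H * W;
    for (int iw = 0; iw < kw; ++iw)
      for (int ih = 0; ih < kh; ++ih)
        for (int id = 0; id < kd; ++id) {
          const int k = id + kd * (ih + kh * iw) + kd * kh * kw * c;
          const double* srck = col.colptr(k);
          for (int ow = 0; ow < oW; ++ow) {
            const int w = ow * sw - pw + iw;
            if (w < 0 || w >= W) continue;
            for (int oh = 0; oh < oH; ++oh) {
              const int h = oh * sh - ph + ih;
              if (h < 0 || h >= H) continue;
              double* dst = xc + (size_t)(w * H + h) * D;
              const double* s2 = srck + (size_t)(ow * oH + oh) * oD;
              if (sd == 1) {
                const int od0 = std::max(0, pd - id);
                const int od1 = std::min(oD, D + pd - id);
                double* d2 = dst + od0 - pd + id;
                for (int od = od0; od < od1; ++od) d2[od - od0] += s2[od];
              } else {
                for (int od = 0; od < oD; ++od) {
                  const int d = od * sd - pd + id;
                  if (d >= 0 && d < D) dst[d] += s2[od];
                }
              }
            }
          }
        }
  }
}

// x: array (D,H,W,Cin); w: array (kd,kh,kw,Cin,Cout); b: length Cout.
// 'same' convolution when pad = (k-1)/2 and stride 1.
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim,
                           NumericVector w, IntegerVector kdim, int cin, int cout,
                           NumericVector b, IntegerVector stride, IntegerVector pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  arma::mat col = im2col(x.begin(), D, H, W, cin,
                         kdim[0], kdim[1], kdim[2],
                         stride[0], stride[1], stride[2],
                         pad[0], pad[1], pad[2]);
  const int K = kdim[0] * kdim[1] * kdim[2] * cin;
  arma::mat Wm(const_cast<double*>(w.begin()), K, cout, false, true);
  const int oD = out_extent(D, kdim[0], stride[0], pad[0]);
  const int oH = out_extent(H, kdim[1], stride[1], pad[1]);
  const int oW = out_extent(W, kdim[2], stride[2], pad[2]);
  NumericVector res((R_xlen_t)oD * oH * oW * cout);
  arma::mat outm(res.begin(), col.n_rows, cout, false, true);
  outm = col * Wm;                                    // N x Cout
  for (int c = 0; c < cout; ++c) outm.col(c) += b[c];
  res.attr("dim") = IntegerVector::create(oD, oH, oW, cout);
  return res;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, IntegerVector xdim,
                  NumericVector w, IntegerVector kdim, int cin, int cout,
                  NumericVector dout, IntegerVector stride, IntegerVector pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  arma::mat col = im2col(x.begin(), D, H, W, cin,
                         kdim[0], kdim[1], kdim[2],
                         stride[0], stride[1], stride[2],
                         pad[0], pad[1], pad[2]);
  const int K = kdim[0] * kdim[1] * kdim[2] * cin;
  const arma::uword N = col.n_rows;
  // dout arrives as (oD,oH,oW,Cout) -> N x Cout
  arma::mat dOut(const_cast<double*>(dout.begin()), N, cout, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), K, cout, false, true);
  arma::mat dW = col.t() * dOut;                      // K x Cout
  arma::mat dCol = dOut * Wm.t();                     // N x K
  NumericVector dx((R_xlen_t)D * H * W * cin);
  col2im(dCol, dx.begin(), D, H, W, cin,
         kdim[0], kdim[1], kdim[2],
         stride[0], stride[1], stride[2],
         pad[0], pad[1], pad[2]);
  dx.attr("dim") = IntegerVector::create(D, H, W, cin);
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = IntegerVector::create(kdim[0], kdim[1], kdim[2], cin, cout);
  NumericVector db(cout);
  for (int c = 0; c < cout; ++c) db[c] = arma::accu(dOut.col(c));
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// 2x2x2 max pooling, stride 2; extents must be even. Returns the pooled
// map and 1-based argmax indices into the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int oD = D / 2, oH = H / 2, oW = W / 2;
  NumericVector out((R_xlen_t)oD * oH * oW * C);
  IntegerVector idx((R_xlen_t)oD * oH * oW * C);
  const double* xp = x.begin();
  R_xlen_t n = 0;
  for (int c = 0; c < C; ++c) {
    const size_t coff = (size_t)c * D * H * W;
    for (int ow = 0; ow < oW; ++ow)
      for (int oh = 0; oh < oH; ++oh)
        for (int od = 0; od < oD; ++od) {
          double best = R_NegInf; size_t bi = 0;
          for (int iw = 0; iw < 2; ++iw)
            for (int ih = 0; ih < 2; ++ih)
              for (int id = 0; id < 2; ++id) {
                const size_t pos = coff + (size_t)(2 * ow + iw) * H * D +
                                   (size_t)(2 * oh + ih) * D + (2 * od + id);
                if (xp[pos] > best) { best = xp[pos]; bi = pos; }
              }
          out[n] = best; idx[n] = (int)(bi + 1); ++n;
        }
  }
  out.attr("dim") = IntegerVector::create(oD, oH, oW, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[idx[i] - 1] += dout[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Trilinear 2x upsampling with half-voxel alignment: input coordinate of
// output voxel j is (j + 0.5)/2 - 0.5, clamped at the boundary.
static inline void lin_taps(int j, int n_in, int& i0, int& i1, double& w1) {
  double t = (j + 0.5) / 2.0 - 0.5;
  if (t < 0) t = 0;
  if (t > n_in - 1) t = n_in - 1;
  i0 = (int)std::floor(t);
  i1 = std::min(i0 + 1, n_in - 1);
  w1 = t - i0;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2x_fwd(NumericVector x, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int oD = 2 * D, oH = 2 * H, oW = 2 * W;
  NumericVector out((R_xlen_t)oD * oH * oW * C);
  const double* xp = x.begin(); double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const size_t coff = (size_t)c * D * H * W, ooff = (size_t)c * oD * oH * oW;
    for (int ow = 0; ow < oW; ++ow) {
      int w0, w1i; double ww; lin_taps(ow, W, w0, w1i, ww);
      for (int oh = 0; oh < oH; ++oh) {
        int h0, h1i; double wh; lin_taps(oh, H, h0, h1i, wh);
        for (int od = 0; od < oD; ++od) {
          int d0, d1i; double wd; lin_taps(od, D, d0, d1i, wd);
          double v = 0;
          for (int a = 0; a < 2; ++a)
            for (int bb = 0; bb < 2; ++bb)
              for (int cc = 0; cc < 2; ++cc) {
                const double wt = (a ? wd : 1 - wd) * (bb ? wh : 1 - wh) * (cc ? ww : 1 - ww);
                const size_t pos = coff + (size_t)(cc ? w1i : w0) * H * D +
                                   (size_t)(bb ? h1i : h0) * D + (a ? d1i : d0);
                v += wt * xp[pos];
              }
          op[ooff + (size_t)ow * oH * oD + (size_t)oh * oD + od] = v;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oD, oH, oW, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2x_bwd(NumericVector dout, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int oD = 2 * D, oH = 2 * H, oW = 2 * W;
  NumericVector dx((R_xlen_t)D * H * W * C);
  const double* gp = dout.begin(); double* dp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const size_t coff = (size_t)c * D * H * W, ooff = (size_t)c * oD * oH * oW;
    for (int ow = 0; ow < oW; ++ow) {
      int w0, w1i; double ww; lin_taps(ow, W, w0, w1i, ww);
      for (int oh = 0; oh < oH; ++oh) {
        int h0, h1i; double wh; lin_taps(oh, H, h0, h1i, wh);
        for (int od = 0; od < oD; ++od) {
          int d0, d1i; double wd; lin_taps(od, D, d0, d1i, wd);
          const double g = gp[ooff + (size_t)ow * oH * oD + (size_t)oh * oD + od];
          for (int a = 0; a < 2; ++a)
            for (int bb = 0; bb < 2; ++bb)
              for (int cc = 0; cc < 2; ++cc) {
                const double wt = (a ? wd : 1 - wd) * (bb ? wh : 1 - wh) * (cc ? ww : 1 - ww);
                dp[coff + (size_t)(cc ? w1i : w0) * H * D +
                   (size_t)(bb ? h1i : h0) * D + (a ? d1i : d0)] += wt * g;
              }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Grid resampling of a single-channel volume. Output voxel j along axis a
// samples input index coordinate j * scale[a] + shift[a] (0-based),
// clamped to the support; trilinear or nearest-neighbour interpolation.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, IntegerVector xdim,
                             IntegerVector odim, NumericVector scale,
                             NumericVector shift, bool nearest) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int oD = odim[0], oH = odim[1], oW = odim[2];
  NumericVector out((R_xlen_t)oD * oH * oW);
  const double* xp = x.begin(); double* op = out.begin();
  R_xlen_t n = 0;
  for (int ow = 0; ow < oW; ++ow) {
    const double tw = clampd(ow * scale[2] + shift[2], 0, W - 1);
    for (int oh = 0; oh < oH; ++oh) {
      const double th = clampd(oh * scale[1] + shift[1], 0, H - 1);
      for (int od = 0; od < oD; ++od) {
        const double td = clampd(od * scale[0] + shift[0], 0, D - 1);
        if (nearest) {
          const int d = (int)std::lround(td), h = (int)std::lround(th), w = (int)std::lround(tw);
          op[n++] = xp[(size_t)w * H * D + (size_t)h * D + d];
        } else {
          const int d0 = (int)std::floor(td), h0 = (int)std::floor(th), w0 = (int)std::floor(tw);
          const int d1 = std::min(d0 + 1, D - 1), h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1);
          const double fd = td - d0, fh = th - h0, fw = tw - w0;
          double v = 0;
          for (int a = 0; a < 2; ++a)
            for (int bb = 0; bb < 2; ++bb)
              for (int cc = 0; cc < 2; ++cc) {
                const double wt = (a ? fd : 1 - fd) * (bb ? fh : 1 - fh) * (cc ? fw : 1 - fw);
                v += wt * xp[(size_t)(cc ? w1 : w0) * H * D + (size_t)(bb ? h1 : h0) * D + (a ? d1 : d0)];
              }
          op[n++] = v;
        }
      }
    }
  }
  out.attr("dim") = odim;
  return out;
}

// Sample a single-channel volume at arbitrary 0-based index coordinates
// (N x 3 matrix), clamped to the support. Used by spatial augmentation.
// [[Rcpp::export]]
NumericVector cpp_sample_at(NumericVector x, IntegerVector xdim,
                            NumericMatrix coords, bool nearest) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const R_xlen_t N = coords.nrow();
  NumericVector out(N);
  const double* xp = x.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double td = clampd(coords(n, 0), 0, D - 1);
    const double th = clampd(coords(n, 1), 0, H - 1);
    const double tw = clampd(coords(n, 2), 0, W - 1);
    if (nearest) {
      const int d = (int)std::lround(td), h = (int)std::lround(th), w = (int)std::lround(tw);
      out[n] = xp[(size_t)w * H * D + (size_t)h * D + d];
    } else {
      const int d0 = (int)std::floor(td), h0 = (int)std::floor(th), w0 = (int)std::floor(tw);
      const int d1 = std::min(d0 + 1, D - 1), h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1);
      const double fd = td - d0, fh = th - h0, fw = tw - w0;
      double v = 0;
      for (int a = 0; a < 2; ++a)
        for (int bb = 0; bb < 2; ++bb)
          for (int cc = 0; cc < 2; ++cc)
            v += (a ? fd : 1 - fd) * (bb ? fh : 1 - fh) * (cc ? fw : 1 - fw) *
                 xp[(size_t)(cc ? w1 : w0) * H * D + (size_t)(bb ? h1 : h0) * D + (a ? d1 : d0)];
      out[n] = v;
    }
  }
  return out;
}

static inline int reflect_idx(int j, int n) {
  while (j < 0 || j >= n) {
    if (j < 0) j = -j - 1;
    if (j >= n) j = 2 * n - j - 1;
  }
  return j;
}

// Separable Gaussian blur with reflected boundaries; kernel truncated at
// ceil(3*sigma). sigma in voxels, one value per axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector x, IntegerVector xdim, NumericVector sigma) {
  const int dims[3] = {xdim[0], xdim[1], xdim[2]};
  std::vector<double> buf(x.begin(), x.end()), tmp(buf.size());
  const int D = dims[0], H = dims[1], W = dims[2];
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); sum += k[i + r]; }
    for (double& v : k) v /= sum;
    const int n = dims[ax];
    if (ax == 0) {
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const size_t off = (size_t)w * H * D + (size_t)h * D;
          for (int d = 0; d < n; ++d) {
            double v = 0;
            for (int i = -r; i <= r; ++i) {
              int j = reflect_idx(d + i, n);
              v += k[i + r] * buf[off + j];
            }
            tmp[off + d] = v;
          }
        }
    } else if (ax == 1) {
      for (int w = 0; w < W; ++w)
        for (int d = 0; d < D; ++d) {
          const size_t base = (size_t)w * H * D + d;
          for (int h = 0; h < n; ++h) {
            double v = 0;
            for (int i = -r; i <= r; ++i) {
              int j = reflect_idx(h + i, n);
              v += k[i + r] * buf[base + (size_t)j * D];
            }
            tmp[base + (size_t)h * D] = v;
          }
        }
    } else {
      for (int h = 0; h < H; ++h)
        for (int d = 0; d < D; ++d) {
          const size_t base = (size_t)h * D + d;
          for (int w = 0; w < n; ++w) {
            double v = 0;
            for (int i = -r; i <= r; ++i) {
              int j = reflect_idx(w + i, n);
              v += k[i + r] * buf[base + (size_t)j * H * D];
            }
            tmp[base + (size_t)w * H * D] = v;
          }
        }
    }
    buf.swap(tmp);
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = xdim;
  return out;
}

// Non-overlapping boxcar average along one axis (1-based axis), modelling
// uniform slab excitation; output has floor(n / width) slabs.
// [[Rcpp::export]]
NumericVector cpp_slab_average(NumericVector x, IntegerVector xdim, int axis, int width) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int n = xdim[axis - 1];
  const int m = n / width;
  int od = D, oh = H, ow = W;
  if (axis == 1) od = m; else if (axis == 2) oh = m; else ow = m;
  NumericVector out((R_xlen_t)od * oh * ow);
  const double* xp = x.begin(); double* op = out.begin();
  for (int w = 0; w < ow; ++w)
    for (int h = 0; h < oh; ++h)
      for (int d = 0; d < od; ++d) {
        double v = 0;
        for (int i = 0; i < width; ++i) {
          int sd = d, sh = h, sw = w;
          if (axis == 1) sd = d * width + i;
          else if (axis == 2) sh = h * width + i;
          else sw = w * width + i;
          v += xp[(size_t)sw * H * D + (size_t)sh * D + sd];
        }
        op[(size_t)w * oh * od + (size_t)h * od + d] = v / width;
      }
  out.attr("dim") = IntegerVector::create(od, oh, ow);
  return out;
}
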