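// Minimal CPU kernels for the network: stride-1 2-D convolution (zero or
// reflective padding), transposed convolution with kernel == stride, and
// max pooling with kernel == stride. All tensors are R arrays in [H, W, C, N]
// layout (column-major); conv weights are [kh, kw, Cin, Cout].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int reflect_idx(int q, int n) {
  // edge-inclusive reflection: -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2
  if (q < 0) return -q - 1;
  if (q >= n) return 2 * n - 1 - q;
  return q;
}

static void pad_plane(const double* x, int H, int W, int C,
                      double* xp, int pad, bool reflect) {
  // x: one sample [H, W, C]; xp: [H+2p, W+2p, C]
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    double* xpc = xp + (size_t)c * Hp * Wp;
    for (int jp = 0; jp < Wp; ++jp) {
      int j = jp - pad;
      double* col = xpc + (size_t)jp * Hp;
      if (!reflect && (j < 0 || j >= W)) {
        std::fill(col, col + Hp, 0.0);
        continue;
      }
      int js = reflect ? reflect_idx(j, W) : j;
      const double* src = xc + (size_t)js * H;
      if (reflect) {
        for (int ip = 0; ip < Hp; ++ip) col[ip] = src[reflect_idx(ip - pad, H)];
      } else {
        for (int ip = 0; ip < pad; ++ip) col[ip] = 0.0;
        std::copy(src, src + H, col + pad);
        for (int ip = pad + H; ip < Hp; ++ip) col[ip] = 0.0;
      }
    }
  }
}


// grow-only scratch buffers: conv kernels are called hundreds of times per
// optimizer step and repeated large alloc/free dominates otherwise
static std::vector<float>& scratch_P() { static std::vector<float> b; return b; }
static std::vector<float>& scratch_Y() { static std::vector<float> b; return b; }
static std::vector<float>& scratch_dP() { static std::vector<float> b; return b; }

static float* ensure_f(std::vector<float>& b, size_t n) {
  if (b.size() < n) b.resize(n);
  return b.data();
}

static void im2col_batch(const double* x, int H, int W, int C, int N,
                         int kh, int kw, int pad, bool reflect,
                         std::vector<double>& xp, arma::fmat& P) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = Hp - kh + 1, Wo = Wp - kw + 1;
  for (int n = 0; n < N; ++n) {
    pad_plane(x + (size_t)n * H * W * C, H, W, C, xp.data(), pad, reflect);
    // rows n*Ho*Wo .. of P
    for (int c = 0; c < C; ++c)
      for (int b = 0; b < kw; ++b)
        for (int a = 0; a < kh; ++a) {
          float* Pcol = P.colptr(a + kh * (b + kw * c)) + (size_t)n * Ho * Wo;
          for (int j = 0; j < Wo; ++j) {
            const double* src = xp.data() + (size_t)c * Hp * Wp + (size_t)(j + b) * Hp + a;
            float* dst = Pcol + (size_t)j * Ho;
            for (int i = 0; i < Ho; ++i) dst[i] = (float)src[i];
          }
        }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int pad, bool reflect) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = Hp - kh + 1, Wo = Wp - kw + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: kernel larger than padded input");
  if (reflect && pad > std::min(H, W)) stop("conv2d: reflect pad too large");

  arma::mat Wd(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout,
               false, true);
  arma::fmat Wmat = arma::conv_to<arma::fmat>::from(Wd);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  std::vector<double> xp((size_t)Hp * Wp * C);
  arma::fmat P(ensure_f(scratch_P(), (size_t)N * Ho * Wo * kh * kw * C),
               (size_t)N * Ho * Wo, (size_t)kh * kw * C, false, true);
  im2col_batch(x.begin(), H, W, C, N, kh, kw, pad, reflect, xp, P);
  arma::fmat Yall(ensure_f(scratch_Y(), (size_t)N * Ho * Wo * Cout),
                  (size_t)N * Ho * Wo, Cout, false, true);
  Yall = P * Wmat;  // one sgemm for the whole batch
  double* ys = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const float* src = Yall.colptr(co) + (size_t)n * Ho * Wo;
      double* dst = ys + ((size_t)n * Cout + co) * Ho * Wo;
      const double bco = b[co];
      for (size_t q = 0; q < (size_t)Ho * Wo; ++q) dst[q] = (double)src[q] + bco;
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int pad, bool reflect) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = Hp - kh + 1, Wo = Wp - kw + 1;

  arma::mat Wd(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout,
               false, true);
  arma::fmat Wmat = arma::conv_to<arma::fmat>::from(Wd);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  std::vector<double> xp((size_t)Hp * Wp * C);
  std::vector<double> dxp((size_t)Hp * Wp * C);
  arma::fmat P(ensure_f(scratch_P(), (size_t)N * Ho * Wo * kh * kw * C),
               (size_t)N * Ho * Wo, (size_t)kh * kw * C, false, true);
  im2col_batch(x.begin(), H, W, C, N, kh, kw, pad, reflect, xp, P);
  // stack per-sample dY into one (N*Ho*Wo) x Cout matrix
  arma::fmat dYall(ensure_f(scratch_Y(), (size_t)N * Ho * Wo * Cout),
                   (size_t)N * Ho * Wo, Cout, false, true);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = dy.begin() + ((size_t)n * Cout + co) * Ho * Wo;
      float* dst = dYall.colptr(co) + (size_t)n * Ho * Wo;
      for (size_t q = 0; q < (size_t)Ho * Wo; ++q) dst[q] = (float)src[q];
    }
  {
    arma::fmat dWf = P.t() * dYall;
    for (R_xlen_t q = 0; q < dw.size(); ++q) dw[q] = (double)dWf.memptr()[q];
    arma::frowvec dbf = arma::sum(dYall, 0);
    for (int co = 0; co < Cout; ++co) db[co] = (double)dbf[co];
  }
  arma::fmat dP(ensure_f(scratch_dP(), (size_t)N * Ho * Wo * kh * kw * C),
                (size_t)N * Ho * Wo, (size_t)kh * kw * C, false, true);
  dP = dYall * Wmat.t();
  for (int n = 0; n < N; ++n) {
    // col2im into padded grad, then fold padding back
    std::fill(dxp.begin(), dxp.end(), 0.0);
    for (int c = 0; c < C; ++c)
      for (int b = 0; b < kw; ++b)
        for (int a = 0; a < kh; ++a) {
          const float* Pcol = dP.colptr(a + kh * (b + kw * c)) + (size_t)n * Ho * Wo;
          for (int j = 0; j < Wo; ++j) {
            double* dst = dxp.data() + (size_t)c * Hp * Wp + (size_t)(j + b) * Hp + a;
            const float* src = Pcol + (size_t)j * Ho;
            for (int i = 0; i < Ho; ++i) dst[i] += (double)src[i];
          }
        }
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int jp = 0; jp < Wp; ++jp)
        for (int ip = 0; ip < Hp; ++ip) {
          int i = ip - pad, j = jp - pad;
          if (reflect) {
            i = reflect_idx(i, H);
            j = reflect_idx(j, W);
          } else if (i < 0 || i >= H || j < 0 || j >= W) {
            continue;
          }
          dxn[(size_t)c * H * W + (size_t)j * H + i] +=
            dxp[(size_t)c * Hp * Wp + (size_t)jp * Hp + ip];
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_convT_fwd")]]
NumericVector cpp_convT_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int s = stride, Cin = wd[2], Cout = wd[3];
  if (wd[0] != s || wd[1] != s) stop("convT: kernel must equal stride");
  if (Cin != C) stop("convT: channel mismatch");
  const int Ho = H * s, Wo = W * s;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  // Wmat: (Cin) x (s*s*Cout), column r = a + s*b + s*s*co
  arma::mat Wmat(C, (size_t)s * s * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int b2 = 0; b2 < s; ++b2)
      for (int a = 0; a < s; ++a)
        for (int ci = 0; ci < C; ++ci)
          Wmat(ci, a + s * (b2 + s * co)) =
            w[a + s * ((size_t)b2 + s * ((size_t)ci + (size_t)C * co))];

  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                (size_t)H * W, C, false, true);
    arma::mat Y2 = X * Wmat;  // (H*W) x (s*s*Cout)
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bco = b[co];
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const size_t row = (size_t)i + (size_t)H * j;
          for (int b2 = 0; b2 < s; ++b2) {
            double* dst = yn + (size_t)co * Ho * Wo + (size_t)(j * s + b2) * Ho + i * s;
            for (int a = 0; a < s; ++a)
              dst[a] = Y2(row, a + s * (b2 + s * co)) + bco;
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_convT_bwd")]]
List cpp_convT_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int s = stride, Cout = wd[3];
  const int Ho = H * s, Wo = W * s;

  arma::mat Wmat(C, (size_t)s * s * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int b2 = 0; b2 < s; ++b2)
      for (int a = 0; a < s; ++a)
        for (int ci = 0; ci < C; ++ci)
          Wmat(ci, a + s * (b2 + s * co)) =
            w[a + s * ((size_t)b2 + s * ((size_t)ci + (size_t)C * co))];

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWmat(C, (size_t)s * s * Cout, arma::fill::zeros);

  arma::mat dY2((size_t)H * W, (size_t)s * s * Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double acc = 0.0;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const size_t row = (size_t)i + (size_t)H * j;
          for (int b2 = 0; b2 < s; ++b2)
            for (int a = 0; a < s; ++a) {
              const double v =
                dyn[(size_t)co * Ho * Wo + (size_t)(j * s + b2) * Ho + i * s + a];
              dY2(row, a + s * (b2 + s * co)) = v;
              acc += v;
            }
        }
      db[co] += acc;
    }
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                (size_t)H * W, C, false, true);
    dWmat += X.t() * dY2;
    arma::mat dX(dx.begin() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
    dX += dY2 * Wmat.t();
  }
  for (int co = 0; co < Cout; ++co)
    for (int b2 = 0; b2 < s; ++b2)
      for (int a = 0; a < s; ++a)
        for (int ci = 0; ci < C; ++ci)
          dw[a + s * ((size_t)b2 + s * ((size_t)ci + (size_t)C * co))] =
            dWmat(ci, a + s * (b2 + s * co));
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % k != 0 || W % k != 0)
    stop("maxpool: spatial size (%d x %d) not divisible by %d", H, W, k);
  const int Ho = H / k, Wo = W / k;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 0-based linear index into x
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double best = R_NegInf;
          size_t bi = 0;
          for (int b = 0; b < k; ++b) {
            const size_t coloff = base + (size_t)(j * k + b) * H + (size_t)i * k;
            const double* col = x.begin() + coloff;
            for (int a = 0; a < k; ++a)
              if (col[a] > best) { best = col[a]; bi = coloff + a; }
          }
          // output layout is [Ho, Wo, C, N]; enumeration order must match
          const size_t qo = ((size_t)n * C + c) * Ho * Wo + (size_t)j * Ho + i;
          y[qo] = best;
          idx[qo] = (int)bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd")]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy,
                              IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  const size_t m = dy.size();
  for (size_t q = 0; q < m; ++q) dx[idx[q]] += dy[q];
  return dx;
}

// ---- elementwise / broadcast helpers (hot paths of the R tape) ----

// y = x * gate, gate broadcast over channels (spatial=[H,W,1,N]) or over
// space (channel=[1,1,C,N])
// [[Rcpp::export(name = ".cpp_bcast_mul")]]
NumericVector cpp_bcast_mul(NumericVector x, NumericVector g, bool spatial) {
  IntegerVector xd = x.attr("dim");
  const size_t H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xs = x.begin();
  const double* gs = g.begin();
  double* ys = y.begin();
  if (spatial) {
    for (size_t n = 0; n < N; ++n)
      for (size_t c = 0; c < C; ++c) {
        const double* gp = gs + n * H * W;
        const double* xq = xs + (n * C + c) * H * W;
        double* yq = ys + (n * C + c) * H * W;
        for (size_t q = 0; q < H * W; ++q) yq[q] = xq[q] * gp[q];
      }
  } else {
    for (size_t n = 0; n < N; ++n)
      for (size_t c = 0; c < C; ++c) {
        const double gc = gs[n * C + c];
        const double* xq = xs + (n * C + c) * H * W;
        double* yq = ys + (n * C + c) * H * W;
        for (size_t q = 0; q < H * W; ++q) yq[q] = xq[q] * gc;
      }
  }
  return y;
}

// sum over channels -> [H,W,1,N]
// [[Rcpp::export(name = ".cpp_reduce_c")]]
NumericVector cpp_reduce_c(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(H * W * N);
  y.attr("dim") = IntegerVector::create(xd[0], xd[1], 1, xd[3]);
  const double* xs = x.begin();
  double* ys = y.begin();
  for (size_t n = 0; n < N; ++n)
    for (size_t c = 0; c < C; ++c) {
      const double* xq = xs + (n * C + c) * H * W;
      double* yq = ys + n * H * W;
      for (size_t q = 0; q < H * W; ++q) yq[q] += xq[q];
    }
  return y;
}

// sum over space -> [1,1,C,N]
// [[Rcpp::export(name = ".cpp_reduce_hw")]]
NumericVector cpp_reduce_hw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(C * N);
  y.attr("dim") = IntegerVector::create(1, 1, xd[2], xd[3]);
  const double* xs = x.begin();
  for (size_t q = 0; q < C * N; ++q) {
    const double* xq = xs + q * H * W;
    double acc = 0.0;
    for (size_t p = 0; p < H * W; ++p) acc += xq[p];
    y[q] = acc;
  }
  return y;
}

// per-channel sum over H, W and N -> vector [C]
// [[Rcpp::export(name = ".cpp_sum_per_channel")]]
NumericVector cpp_sum_per_channel(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(C);
  const double* xs = x.begin();
  for (size_t n = 0; n < N; ++n)
    for (size_t c = 0; c < C; ++c) {
      const double* xq = xs + (n * C + c) * H * W;
      double acc = 0.0;
      for (size_t q = 0; q < H * W; ++q) acc += xq[q];
      y[c] += acc;
    }
  return y;
}

// y = x * a[c] + b[c]
// [[Rcpp::export(name = ".cpp_scale_shift_c")]]
NumericVector cpp_scale_shift_c(NumericVector x, NumericVector a,
                                NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const size_t H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xs = x.begin();
  double* ys = y.begin();
  for (size_t n = 0; n < N; ++n)
    for (size_t c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      const double* xq = xs + (n * C + c) * H * W;
      double* yq = ys + (n * C + c) * H * W;
      for (size_t q = 0; q < H * W; ++q) yq[q] = xq[q] * ac + bc;
    }
  return y;
}

// y = u * a[c] + v * b[c] + d[c]
// [[Rcpp::export(name = ".cpp_lincomb_c")]]
NumericVector cpp_lincomb_c(NumericVector u, NumericVector v, NumericVector a,
                            NumericVector b, NumericVector d) {
  IntegerVector xd = u.attr("dim");
  const size_t H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(u.size());
  y.attr("dim") = xd;
  const double* us = u.begin();
  const double* vs = v.begin();
  double* ys = y.begin();
  for (size_t n = 0; n < N; ++n)
    for (size_t c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c], dc = d[c];
      const size_t off = (n * C + c) * H * W;
      for (size_t q = 0; q < H * W; ++q)
        ys[off + q] = us[off + q] * ac + vs[off + q] * bc + dc;
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_fwd")]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t q = 0; q < x.size(); ++q) y[q] = x[q] > 0 ? x[q] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
NumericVector cpp_relu_bwd(NumericVector y, NumericVector g) {
  NumericVector dx(y.size());
  dx.attr("dim") = y.attr("dim");
  for (R_xlen_t q = 0; q < y.size(); ++q) dx[q] = y[q] > 0 ? g[q] : 0.0;
  return dx;
}

// channel-wise mean and max -> [H,W,2,N] plus argmax channel (0-based)
// [[Rcpp::export(name = ".cpp_cmeanmax_fwd")]]
List cpp_cmeanmax_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(H * W * 2 * N);
  y.attr("dim") = IntegerVector::create(xd[0], xd[1], 2, xd[3]);
  IntegerVector arg(H * W * N);
  const double* xs = x.begin();
  double* ys = y.begin();
  for (size_t n = 0; n < N; ++n) {
    double* mean_out = ys + n * 2 * H * W;
    double* max_out = mean_out + H * W;
    int* arg_out = arg.begin() + n * H * W;
    const double* x0 = xs + n * C * H * W;
    for (size_t q = 0; q < H * W; ++q) {
      double acc = 0.0, best = R_NegInf;
      int bi = 0;
      for (size_t c = 0; c < C; ++c) {
        const double v = x0[c * H * W + q];
        acc += v;
        if (v > best) { best = v; bi = (int)c; }
      }
      mean_out[q] = acc / C;
      max_out[q] = best;
      arg_out[q] = bi;
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".cpp_cmeanmax_bwd")]]
NumericVector cpp_cmeanmax_bwd(IntegerVector arg, NumericVector g,
                               IntegerVector xdim) {
  const size_t H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx(H * W * C * N);
  dx.attr("dim") = xdim;
  const double* gs = g.begin();
  double* ds = dx.begin();
  for (size_t n = 0; n < N; ++n) {
    const double* gmean = gs + n * 2 * H * W;
    const double* gmax = gmean + H * W;
    const int* arg_in = arg.begin() + n * H * W;
    double* d0 = ds + n * C * H * W;
    for (size_t q = 0; q < H * W; ++q) {
      const double gm = gmean[q] / C;
      for (size_t c = 0; c < C; ++c) d0[c * H * W + q] += gm;
      d0[(size_t)arg_in[q] * H * W + q] += gmax[q];
    }
  }
  return dx;
}
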