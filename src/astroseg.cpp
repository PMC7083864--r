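// Low-level numerical kernels: batched 2D convolution (same padding, stride 1)
// with forward/backward passes via im2col + BLAS, 2x2 max pooling, nearest
// 2x upsampling, and connected-component labeling. Feature maps are R arrays
// with dim = c(H, W, C, N) (column-major, H fastest).
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void get_dims4(const NumericVector &x, int &H, int &W, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// column-major offset into (H, W, C, N)
static inline R_xlen_t off4(int h, int w, int c, int n, int H, int W, int C) {
  return ((R_xlen_t)n * C + c) * W * H + (R_xlen_t)w * H + h;
}

// Build im2col matrix for one sample, transposed layout: rows = H*W pixels
// (contiguous writes), cols = C*k*k (zero pad k/2).
static void im2col(const double *x, int H, int W, int C, int k, arma::mat &M) {
  const int p = k / 2;
  const arma::uword HW = (arma::uword)H * W;
  M.zeros(HW, C * k * k);
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (R_xlen_t)c * H * W;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = c * k * k + kx * k + ky;
        double *Mcol = M.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int iw = w + kx - p;
          if (iw < 0 || iw >= W) continue;
          const double *src = xc + (R_xlen_t)iw * H;
          double *dst = Mcol + (R_xlen_t)w * H;
          const int h0 = std::max(0, p - ky), h1 = std::min(H, H + p - ky);
          for (int h = h0; h < h1; ++h) dst[h] = src[h + ky - p];
        }
      }
    }
  }
}

// scatter-add the columns of M (H*W x C*k*k) back into an image (col2im)
static void col2im_add(const arma::mat &M, int H, int W, int C, int k,
                       double *x) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    double *xc = x + (R_xlen_t)c * H * W;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = c * k * k + kx * k + ky;
        const double *Mcol = M.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int iw = w + kx - p;
          if (iw < 0 || iw >= W) continue;
          double *dst = xc + (R_xlen_t)iw * H;
          const double *src = Mcol + (R_xlen_t)w * H;
          const int h0 = std::max(0, p - ky), h1 = std::min(H, H + p - ky);
          for (int h = h0; h < h1; ++h) dst[h + ky - p] += src[h];
        }
      }
    }
  }
}

// weights w: dim (k, k, Cin, Cout) -> matrix (Cin*k*k x Cout), rows matching
// im2col's column order (ci*k*k + kx*k + ky).
static arma::mat weight_mat(const NumericVector &w, int k, int Cin, int Cout) {
  arma::mat Wm(Cin * k * k, Cout);
  const double *wp = w.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kx = 0; kx < k; ++kx)
        for (int ky = 0; ky < k; ++ky)
          Wm(ci * k * k + kx * k + ky, co) =
              wp[((R_xlen_t)co * Cin + ci) * k * k + (R_xlen_t)kx * k + ky];
  return Wm;
}


static NumericVector make_num4(int H, int W, int C, int N) {
  NumericVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}
static IntegerVector make_int4(int H, int W, int C, int N) {
  IntegerVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector dw = w.attr("dim");
  if (dw.size() != 4 || dw[0] != dw[1] || dw[2] != C)
    stop("weight array must have dim (k, k, Cin, Cout) with Cin matching input");
  const int k = dw[0], Cout = dw[3];
  if (k % 2 == 0) stop("kernel size must be odd");
  arma::mat Wm = weight_mat(w, k, C, Cout);
  NumericVector y = make_num4(H, W, Cout, N);
  const arma::uword HW = (arma::uword)H * W;
  arma::mat M;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + off4(0, 0, 0, n, H, W, C), H, W, C, k, M);
    // alias the output sample as an (H*W x Cout) matrix: no copies
    arma::mat Y(y.begin() + off4(0, 0, 0, n, H, W, Cout), HW, Cout,
                false, true);
    Y = M * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector dw = w.attr("dim");
  const int k = dw[0], Cout = dw[3];
  arma::mat Wm = weight_mat(w, k, C, Cout);
  NumericVector gx = make_num4(H, W, C, N);
  arma::mat GW(C * k * k, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  const arma::uword HW = (arma::uword)H * W;
  arma::mat M, GX;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + off4(0, 0, 0, n, H, W, C), H, W, C, k, M);
    const arma::mat G(const_cast<double *>(gy.begin()) +
                      off4(0, 0, 0, n, H, W, Cout), HW, Cout, false, true);
    GW += M.t() * G;
    gb += arma::sum(G, 0).t();
    GX = G * Wm.t(); // H*W x C*k*k
    col2im_add(GX, H, W, C, k, gx.begin() + off4(0, 0, 0, n, H, W, C));
  }
  NumericVector gwv = make_num4(k, k, C, Cout);
  double *gwp = gwv.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int kx = 0; kx < k; ++kx)
        for (int ky = 0; ky < k; ++ky)
          gwp[((R_xlen_t)co * C + ci) * k * k + (R_xlen_t)kx * k + ky] =
              GW(ci * k * k + kx * k + ky, co);
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make_num4(Ho, Wo, C, N);
  IntegerVector idx = make_int4(Ho, Wo, C, N); // 1-based offset into x
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          double best = -HUGE_VAL;
          R_xlen_t bi = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh) {
              R_xlen_t xi = off4(2 * h + dh, 2 * w + dw2, c, n, H, W, C);
              if (xp[xi] > best) { best = xp[xi]; bi = xi; }
            }
          yp[o] = best;
          ip[o] = (int)(bi + 1);
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector gy,
                           IntegerVector xdim) {
  NumericVector gx = make_num4(xdim[0], xdim[1], xdim[2], xdim[3]);
  const int *ip = idx.begin();
  const double *gp = gy.begin();
  double *gxp = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) gxp[ip[i] - 1] += gp[i];
  return gx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  NumericVector y = make_num4(2 * H, 2 * W, C, N);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = xp[off4(h, w, c, n, H, W, C)];
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh)
              yp[off4(2 * h + dh, 2 * w + dw2, c, n, 2 * H, 2 * W, C)] = v;
        }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector gy) {
  int H2, W2, C, N;
  get_dims4(gy, H2, W2, C, N);
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx = make_num4(H, W, C, N);
  const double *gp = gy.begin();
  double *gxp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W2; ++w)
        for (int h = 0; h < H2; ++h)
          gxp[off4(h / 2, w / 2, c, n, H, W, C)] +=
              gp[off4(h, w, c, n, H2, W2, C)];
  return gx;
}

// Connected-component labeling of a binary matrix (BFS), 4- or 8-connectivity.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 8) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  const int dx8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dy8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dx4[] = {-1, 1, 0, 0};
  const int dy4[] = {0, 0, -1, 1};
  const int *dx = connectivity == 8 ? dx8 : dx4;
  const int *dy = connectivity == 8 ? dy8 : dy4;
  const int nd = connectivity == 8 ? 8 : 4;
  std::queue<std::pair<int, int> > q;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w)) continue;
      lab(h, w) = ++next;
      q.push(std::make_pair(h, w));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int d = 0; d < nd; ++d) {
          const int nh = p.first + dy[d], nw = p.second + dx[d];
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          if (!mask(nh, nw) || lab(nh, nw)) continue;
          lab(nh, nw) = next;
          q.push(std::make_pair(nh, nw));
        }
      }
    }
  return lab;
}
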