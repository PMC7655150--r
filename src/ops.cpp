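// Low-level numerical kernels: im2col convolution forward/backward,
// max pooling, transpose convolution, pyramidal Horn-Schunck optical flow,
// and multi-source Dijkstra on a gradient-weighted pixel grid.
//
// Array layout convention throughout: images/feature maps are R arrays with
// dim c(H, W, C, N) in column-major order; kernels are c(kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather one image (H x W x C, contiguous) into a K x L column matrix,
// K = kh*kw*C, L = Ho*Wo.  Row index = ki + kh*(kj + kw*c); column index
// enumerates output pixels in column-major (i fastest) order.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, arma::mat& col) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  col.zeros(kh * kw * C, Ho * Wo);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          const double* xcj = xc + (size_t)j * H;
          double* dst = col.colptr(0) + row; // stride kh*kw*C per column
          const size_t ld = (size_t)kh * kw * C;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            dst[ld * ((size_t)oj * Ho + oi)] = xcj[i];
          }
        }
      }
    }
  }
}

// Scatter-add a K x L column matrix back into an H x W x C image.
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad, double* x) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          double* xcj = xc + (size_t)j * H;
          const size_t ld = (size_t)kh * kw * C;
          const double* src = col.colptr(0) + row;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            xcj[i] += src[ld * ((size_t)oj * Ho + oi)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Ci = wd[2], F = wd[3];
  if (Ci != C) stop("channel mismatch in conv");
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  NumericVector y((size_t)Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, col);
    arma::mat out = Wm.t() * col; // F x L
    double* yn = y.begin() + (size_t)n * Ho * Wo * F;
    for (int f = 0; f < F; ++f) {
      const double bf = b[f];
      double* yf = yn + (size_t)f * Ho * Wo;
      for (int l = 0; l < Ho * Wo; ++l) yf[l] = out(f, l) + bf;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericVector w, NumericVector dy,
                 int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  NumericVector dx((size_t)H * W * C * N), dw(w.size()), db(F);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  arma::mat dWm(dw.begin(), kh * kw * C, F, false, true);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, col);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * F,
                 Ho * Wo, F, false, true); // L x F (each channel contiguous)
    dWm += col * dY;
    arma::mat dcol = Wm * dY.t(); // K x L
    col2im(dcol, H, W, C, kh, kw, stride, pad,
           dx.begin() + (size_t)n * H * W * C);
    for (int f = 0; f < F; ++f) db[f] += arma::accu(dY.col(f));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / k, Wo = W / k;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * H * W;
      double* yc = y.begin() + (size_t)(n * C + c) * Ho * Wo;
      int* ic = idx.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int oj = 0; oj < Wo; ++oj)
        for (int oi = 0; oi < Ho; ++oi) {
          double best = -1e300; int barg = 0;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di) {
              const int i = oi * k + di, j = oj * k + dj;
              const double v = xc[(size_t)j * H + i];
              if (v > best) { best = v; barg = (int)((size_t)j * H + i); }
            }
          yc[(size_t)oj * Ho + oi] = best;
          ic[(size_t)oj * Ho + oi] = barg;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector dy,
                             IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dyc = dy.begin() + (size_t)(n * C + c) * Ho * Wo;
      const int* ic = idx.begin() + (size_t)(n * C + c) * Ho * Wo;
      double* dxc = dx.begin() + (size_t)(n * C + c) * H * W;
      for (int l = 0; l < Ho * Wo; ++l) dxc[ic[l]] += dyc[l];
    }
  return dx;
}

// Transpose convolution (a.k.a. deconvolution); w has dim (kh, kw, Cin, Cout).
// Output size: (H-1)*stride - 2*pad + kh.
// [[Rcpp::export]]
NumericVector cpp_tconv_fw(NumericVector x, NumericVector w,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = (H - 1) * stride - 2 * pad + kh;
  const int Wo = (W - 1) * stride - 2 * pad + kw;
  NumericVector y((size_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double* yc = y.begin() + (size_t)(n * Co + co) * Ho * Wo;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = x.begin() + (size_t)(n * C + ci) * H * W;
        const double* wk = w.begin() + (size_t)(co * C + ci) * kh * kw;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = xc[(size_t)j * H + i];
            if (v == 0.0) continue;
            const int oi0 = i * stride - pad, oj0 = j * stride - pad;
            for (int kj = 0; kj < kw; ++kj) {
              const int oj = oj0 + kj;
              if (oj < 0 || oj >= Wo) continue;
              for (int ki = 0; ki < kh; ++ki) {
                const int oi = oi0 + ki;
                if (oi < 0 || oi >= Ho) continue;
                yc[(size_t)oj * Ho + oi] += v * wk[(size_t)kj * kh + ki];
              }
            }
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv_bw(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = (H - 1) * stride - 2 * pad + kh;
  const int Wo = (W - 1) * stride - 2 * pad + kw;
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* dyc = dy.begin() + (size_t)(n * Co + co) * Ho * Wo;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = x.begin() + (size_t)(n * C + ci) * H * W;
        double* dxc = dx.begin() + (size_t)(n * C + ci) * H * W;
        const double* wk = w.begin() + (size_t)(co * C + ci) * kh * kw;
        double* dwk = dw.begin() + (size_t)(co * C + ci) * kh * kw;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const int oi0 = i * stride - pad, oj0 = j * stride - pad;
            const double xv = xc[(size_t)j * H + i];
            double acc = 0.0;
            for (int kj = 0; kj < kw; ++kj) {
              const int oj = oj0 + kj;
              if (oj < 0 || oj >= Wo) continue;
              for (int ki = 0; ki < kh; ++ki) {
                const int oi = oi0 + ki;
                if (oi < 0 || oi >= Ho) continue;
                const double g = dyc[(size_t)oj * Ho + oi];
                acc += g * wk[(size_t)kj * kh + ki];
                dwk[(size_t)kj * kh + ki] += g * xv;
              }
            }
            dxc[(size_t)j * H + i] += acc;
          }
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ---------------------------------------------------------------- optical flow

static arma::mat downsample2(const arma::mat& a) {
  const int H = (int)a.n_rows / 2, W = (int)a.n_cols / 2;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = 0.25 * (a(2 * i, 2 * j) + a(2 * i + 1, 2 * j) +
                          a(2 * i, 2 * j + 1) + a(2 * i + 1, 2 * j + 1));
  return out;
}

static arma::mat resize_bilinear(const arma::mat& a, int H, int W) {
  arma::mat out(H, W);
  const double si = (double)a.n_rows / H, sj = (double)a.n_cols / W;
  for (int j = 0; j < W; ++j) {
    double fj = (j + 0.5) * sj - 0.5;
    int j0 = (int)std::floor(fj);
    double wj = fj - j0;
    int j1 = std::min(j0 + 1, (int)a.n_cols - 1);
    j0 = std::max(j0, 0);
    for (int i = 0; i < H; ++i) {
      double fi = (i + 0.5) * si - 0.5;
      int i0 = (int)std::floor(fi);
      double wi = fi - i0;
      int i1 = std::min(i0 + 1, (int)a.n_rows - 1);
      i0 = std::max(i0, 0);
      out(i, j) = (1 - wi) * (1 - wj) * a(i0, j0) + wi * (1 - wj) * a(i1, j0) +
                  (1 - wi) * wj * a(i0, j1) + wi * wj * a(i1, j1);
    }
  }
  return out;
}

static double sample_bilinear(const arma::mat& a, double i, double j) {
  const int H = (int)a.n_rows, W = (int)a.n_cols;
  i = std::min(std::max(i, 0.0), H - 1.0);
  j = std::min(std::max(j, 0.0), W - 1.0);
  int i0 = (int)std::floor(i), j0 = (int)std::floor(j);
  int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
  double wi = i - i0, wj = j - j0;
  return (1 - wi) * (1 - wj) * a(i0, j0) + wi * (1 - wj) * a(i1, j0) +
         (1 - wi) * wj * a(i0, j1) + wi * wj * a(i1, j1);
}

static arma::mat neighbor_avg(const arma::mat& a) {
  const int H = (int)a.n_rows, W = (int)a.n_cols;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int im = std::max(i - 1, 0), ip = std::min(i + 1, H - 1);
      const int jm = std::max(j - 1, 0), jp = std::min(j + 1, W - 1);
      out(i, j) = (a(im, j) + a(ip, j) + a(i, jm) + a(i, jp)) * (1.0 / 6.0) +
                  (a(im, jm) + a(im, jp) + a(ip, jm) + a(ip, jp)) * (1.0 / 12.0);
    }
  return out;
}

// Coarse-to-fine Horn-Schunck with incremental warping.  Inputs are
// grayscale matrices in [0, 1]; returns per-pixel (u = horizontal/column,
// v = vertical/row) displacement in pixels of the fine grid.
// [[Rcpp::export]]
List cpp_hs_flow(arma::mat im1, arma::mat im2, double alpha, int n_levels,
                 int n_warps, int n_iters) {
  std::vector<arma::mat> p1(1, im1), p2(1, im2);
  while ((int)p1.size() < n_levels &&
         (int)p1.back().n_rows >= 16 && (int)p1.back().n_cols >= 16) {
    p1.push_back(downsample2(p1.back()));
    p2.push_back(downsample2(p2.back()));
  }
  arma::mat u, v;
  for (int lev = (int)p1.size() - 1; lev >= 0; --lev) {
    const arma::mat& A = p1[lev];
    const arma::mat& B = p2[lev];
    const int H = (int)A.n_rows, W = (int)A.n_cols;
    if (lev == (int)p1.size() - 1) {
      u.zeros(H, W);
      v.zeros(H, W);
    } else {
      u = 2.0 * resize_bilinear(u, H, W);
      v = 2.0 * resize_bilinear(v, H, W);
    }
    for (int wrp = 0; wrp < n_warps; ++wrp) {
      arma::mat Bw(H, W), Ix(H, W), Iy(H, W), It(H, W);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          Bw(i, j) = sample_bilinear(B, i + v(i, j), j + u(i, j));
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const int im = std::max(i - 1, 0), ip = std::min(i + 1, H - 1);
          const int jm = std::max(j - 1, 0), jp = std::min(j + 1, W - 1);
          // average spatial gradient of both images for stability
          Ix(i, j) = 0.25 * ((Bw(i, jp) - Bw(i, jm)) + (A(i, jp) - A(i, jm)));
          Iy(i, j) = 0.25 * ((Bw(ip, j) - Bw(im, j)) + (A(ip, j) - A(im, j)));
          It(i, j) = Bw(i, j) - A(i, j);
        }
      arma::mat du(H, W, arma::fill::zeros), dv(H, W, arma::fill::zeros);
      for (int it = 0; it < n_iters; ++it) {
        arma::mat dub = neighbor_avg(du), dvb = neighbor_avg(dv);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double ix = Ix(i, j), iy = Iy(i, j);
            const double r = (ix * dub(i, j) + iy * dvb(i, j) + It(i, j)) /
                             (alpha * alpha + ix * ix + iy * iy);
            du(i, j) = dub(i, j) - ix * r;
            dv(i, j) = dvb(i, j) - iy * r;
          }
      }
      u += du;
      v += dv;
    }
  }
  return List::create(_["u"] = u, _["v"] = v);
}

// --------------------------------------------------------------- geodesic grid

// Multi-source Dijkstra on an 8-connected H x W grid.  Edge weight between
// neighboring pixels p, q: euclidean step * (1 + gamma * (g(p) + g(q)) / 2)
// where g is a gradient-magnitude map.  Returns 1-based parent indices
// (0 for sources) and distances.
// [[Rcpp::export]]
List cpp_geodesic_parents(arma::mat g, IntegerVector sources, double gamma) {
  const int H = (int)g.n_rows, W = (int)g.n_cols, n = H * W;
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<int> parent(n, -1);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int k = 0; k < sources.size(); ++k) {
    const int s = sources[k] - 1;
    if (s < 0 || s >= n) stop("source index out of range");
    dist[s] = 0.0;
    pq.push(Node(0.0, s));
  }
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double step[8] = {1, 1, 1, 1, M_SQRT2, M_SQRT2, M_SQRT2, M_SQRT2};
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    const int p = top.second;
    if (top.first > dist[p]) continue;
    const int pi = p % H, pj = p / H;
    for (int d = 0; d < 8; ++d) {
      const int qi = pi + di[d], qj = pj + dj[d];
      if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
      const int q = qj * H + qi;
      const double w = step[d] * (1.0 + gamma * 0.5 * (g(pi, pj) + g(qi, qj)));
      if (dist[p] + w < dist[q]) {
        dist[q] = dist[p] + w;
        parent[q] = p;
        pq.push(Node(dist[q], q));
      }
    }
  }
  IntegerVector par(n);
  NumericVector ds(n);
  for (int i = 0; i < n; ++i) {
    par[i] = parent[i] + 1;
    ds[i] = dist[i];
  }
  return List::create(_["parent"] = par, _["dist"] = ds);
}
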