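// Low-level kernels for the ConvLSTM stack.
//
// Activation layout: a feature map batch is an arma::mat with
// (B * H * W) rows and C columns; row index r = b*H*W + w*H + h
// (pixels column-major within each sample, samples stacked).
// Patch-matrix column order: col = o*C + c with offsets o enumerated
// dw-major then dh, dw/dh in -r..r (same-padding, k odd).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col_fill(const arma::mat& X, arma::mat& P, int H, int W,
                        int B, int k) {
  const int HW = H * W, C = X.n_cols, r = k / 2;
  int o = 0;
  for (int dw = -r; dw <= r; ++dw) {
    for (int dh = -r; dh <= r; ++dh, ++o) {
      const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
      for (int c = 0; c < C; ++c) {
        const double* src_col = X.colptr(c);
        double* dst_col = P.colptr(o * C + c);
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int sw = w + dw;
            double* dst = dst_col + static_cast<size_t>(b) * HW + w * H;
            if (sw < 0 || sw >= W || h1 <= h0) {
              std::memset(dst, 0, sizeof(double) * H);
              continue;
            }
            if (h0 > 0) std::memset(dst, 0, sizeof(double) * h0);
            if (h1 < H) std::memset(dst + h1, 0, sizeof(double) * (H - h1));
            std::memcpy(dst + h0,
                        src_col + static_cast<size_t>(b) * HW + sw * H + h0 + dh,
                        sizeof(double) * (h1 - h0));
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat im2col_same(const arma::mat& X, int H, int W, int B, int k) {
  arma::mat P(static_cast<size_t>(B) * H * W,
              static_cast<size_t>(k) * k * X.n_cols);
  im2col_fill(X, P, H, W, B, k);
  return P;
}

// Adjoint of im2col_same: scatter-add patch gradients back to pixels.
// [[Rcpp::export]]
arma::mat col2im_same(const arma::mat& P, int H, int W, int B, int C, int k) {
  const int HW = H * W, r = k / 2;
  arma::mat X(static_cast<size_t>(B) * HW, C, arma::fill::zeros);
  int o = 0;
  for (int dw = -r; dw <= r; ++dw) {
    for (int dh = -r; dh <= r; ++dh, ++o) {
      const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
      if (h1 <= h0) continue;
      for (int c = 0; c < C; ++c) {
        const double* src_col = P.colptr(o * C + c);
        double* dst_col = X.colptr(c);
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int sw = w + dw;
            if (sw < 0 || sw >= W) continue;
            const size_t from = static_cast<size_t>(b) * HW + w * H + h0;
            const size_t to = static_cast<size_t>(b) * HW + sw * H + h0 + dh;
            for (int h = 0; h < h1 - h0; ++h) dst_col[to + h] += src_col[from + h];
          }
        }
      }
    }
  }
  return X;
}

static inline void sigmoid_inplace(arma::mat& M) {
  double* p = M.memptr();
  const size_t n = M.n_elem;
  for (size_t i = 0; i < n; ++i) p[i] = 1.0 / (1.0 + std::exp(-p[i]));
}

static inline void tanh_inplace(arma::mat& M) {
  double* p = M.memptr();
  const size_t n = M.n_elem;
  for (size_t i = 0; i < n; ++i) p[i] = std::tanh(p[i]);
}

// One ConvLSTM cell step: gates = conv(x_t) + conv(h_prev) + b with gate
// blocks i, f, g, o; c = f.c_prev + i.g; h = o.tanh(c).
// [[Rcpp::export]]
List clstm_step_fwd(const arma::mat& Xt, const arma::mat& h_prev,
                    const arma::mat& c_prev, const arma::mat& Wx,
                    const arma::mat& Wh, const arma::vec& b,
                    int H, int W, int B, int k) {
  arma::mat Px(static_cast<size_t>(B) * H * W,
               static_cast<size_t>(k) * k * Xt.n_cols);
  im2col_fill(Xt, Px, H, W, B, k);
  arma::mat Ph(static_cast<size_t>(B) * H * W,
               static_cast<size_t>(k) * k * h_prev.n_cols);
  im2col_fill(h_prev, Ph, H, W, B, k);
  arma::mat Z = Px * Wx + Ph * Wh;
  Z.each_row() += b.t();
  const int F = Z.n_cols / 4;
  arma::mat gi = Z.cols(0, F - 1);            sigmoid_inplace(gi);
  arma::mat gf = Z.cols(F, 2 * F - 1);        sigmoid_inplace(gf);
  arma::mat gg = Z.cols(2 * F, 3 * F - 1);    tanh_inplace(gg);
  arma::mat go = Z.cols(3 * F, 4 * F - 1);    sigmoid_inplace(go);
  arma::mat c = gf % c_prev + gi % gg;
  arma::mat tc = arma::mat(c);                tanh_inplace(tc);
  arma::mat h = go % tc;
  return List::create(Named("h") = h, Named("c") = c, Named("gi") = gi,
                      Named("gf") = gf, Named("gg") = gg, Named("go") = go,
                      Named("tc") = tc);
}

// Backward through one cell step. dh = incoming gradient on h_t (upstream
// plus recurrent), dc_in = recurrent gradient on c_t. Returns parameter
// gradient contributions, dh_prev, dc_prev and (optionally) dx.
// [[Rcpp::export]]
List clstm_step_bwd(const arma::mat& Xt, const arma::mat& h_prev,
                    const arma::mat& c_prev, const arma::mat& gi,
                    const arma::mat& gf, const arma::mat& gg,
                    const arma::mat& go, const arma::mat& tc,
                    const arma::mat& Wx, const arma::mat& Wh,
                    const arma::mat& dh, const arma::mat& dc_in,
                    int H, int W, int B, int k, bool need_dx) {
  arma::mat dgo = dh % tc % go % (1.0 - go);
  arma::mat dc = dc_in + dh % go % (1.0 - tc % tc);
  arma::mat dgi = dc % gg % gi % (1.0 - gi);
  arma::mat dgf = dc % c_prev % gf % (1.0 - gf);
  arma::mat dgg = dc % gi % (1.0 - gg % gg);
  arma::mat dc_prev = dc % gf;
  arma::mat dZ = arma::join_rows(dgi, dgf, dgg, dgo);
  arma::mat Px(static_cast<size_t>(B) * H * W,
               static_cast<size_t>(k) * k * Xt.n_cols);
  im2col_fill(Xt, Px, H, W, B, k);
  arma::mat Ph(static_cast<size_t>(B) * H * W,
               static_cast<size_t>(k) * k * h_prev.n_cols);
  im2col_fill(h_prev, Ph, H, W, B, k);
  arma::mat dWx = Px.t() * dZ;
  arma::mat dWh = Ph.t() * dZ;
  arma::vec db = arma::sum(dZ, 0).t();
  arma::mat dh_prev = col2im_same(dZ * Wh.t(), H, W, B, h_prev.n_cols, k);
  List out = List::create(Named("dWx") = dWx, Named("dWh") = dWh,
                          Named("db") = db, Named("dh_prev") = dh_prev,
                          Named("dc_prev") = dc_prev);
  if (need_dx)
    out["dx"] = col2im_same(dZ * Wx.t(), H, W, B, Xt.n_cols, k);
  return out;
}

// [[Rcpp::export]]
List maxpool_fwd(const arma::mat& X, int H, int W, int B, int p) {
  const int HW = H * W, H2 = H / p, W2 = W / p, C = X.n_cols;
  const size_t n_out = static_cast<size_t>(B) * H2 * W2;
  arma::mat out(n_out, C);
  arma::umat arg(n_out, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    for (int b = 0; b < B; ++b) {
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          double best = -std::numeric_limits<double>::infinity();
          size_t best_idx = 0;
          for (int dw = 0; dw < p; ++dw) {
            for (int dh = 0; dh < p; ++dh) {
              const size_t idx = static_cast<size_t>(b) * HW +
                (w2 * p + dw) * H + h2 * p + dh;
              if (xc[idx] > best) { best = xc[idx]; best_idx = idx; }
            }
          }
          const size_t r = static_cast<size_t>(b) * H2 * W2 + w2 * H2 + h2;
          out(r, c) = best;
          arg(r, c) = best_idx;
        }
      }
    }
  }
  return List::create(Named("out") = out, Named("argmax") = arg);
}

// [[Rcpp::export]]
arma::mat maxpool_bwd(const arma::mat& dY, const arma::umat& arg, int n_in) {
  const int C = dY.n_cols;
  arma::mat dX(n_in, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dxc = dX.colptr(c);
    const double* dyc = dY.colptr(c);
    for (size_t r = 0; r < dY.n_rows; ++r) dxc[arg(r, c)] += dyc[r];
  }
  return dX;
}
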