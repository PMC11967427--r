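// Small convolutional network for binary grain/fiber classification of
// 100x100 particle crops, trained from scratch on CPU.
//
// Architecture (valid convolutions, ReLU, max-pooling):
//   input 100x100x1 -> fixed 2x2 average pool -> 50x50
//   conv 5x5 x8  -> 46x46x8  -> maxpool2 -> 23x23x8
//   conv 3x3 x16 -> 21x21x16 -> maxpool2 -> 10x10x16
//   conv 3x3 x32 -> 8x8x32   -> maxpool2 -> 4x4x32
//   dense 512 -> 64 (ReLU) -> 2, softmax
// Mini-batch SGD with momentum; early stop on training error rate.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::fmat;
using arma::fcube;
using arma::fvec;

namespace {

struct Dims {
  static const int IN = 100, P0 = 50;
  static const int K1 = 5, C1 = 8, O1 = 46, Q1 = 23;
  static const int K2 = 3, C2 = 16, O2 = 21, Q2 = 10;
  static const int K3 = 3, C3 = 32, O3 = 8, Q3 = 4;
  static const int F = Q3 * Q3 * C3;  // 512
  static const int H = 64, OUT = 2;
};

struct Params {
  fmat W1, W2, W3, W4, W5;
  fvec b1, b2, b3, b4, b5;
};

void im2col(const fcube& in, int k, int osz, fmat& out) {
  // out: (k*k*C) x (osz*osz); column p = patch at (ox, oy), p = ox*osz + oy
  const int C = in.n_slices;
  out.set_size(k * k * C, osz * osz);
  for (int ox = 0; ox < osz; ++ox) {
    for (int oy = 0; oy < osz; ++oy) {
      float* dst = out.colptr(ox * osz + oy);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        const fmat& sl = in.slice(c);
        for (int b = 0; b < k; ++b)
          for (int a = 0; a < k; ++a)
            dst[r++] = sl(oy + a, ox + b);
      }
    }
  }
}

void col2im_add(const fmat& cols, int k, int osz, fcube& grad) {
  const int C = grad.n_slices;
  for (int ox = 0; ox < osz; ++ox) {
    for (int oy = 0; oy < osz; ++oy) {
      const float* src = cols.colptr(ox * osz + oy);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        fmat& sl = grad.slice(c);
        for (int b = 0; b < k; ++b)
          for (int a = 0; a < k; ++a)
            sl(oy + a, ox + b) += src[r++];
      }
    }
  }
}

// rows of z are channels, columns are spatial positions -> cube
void rows_to_cube(const fmat& z, int osz, fcube& out) {
  const int C = z.n_rows;
  out.set_size(osz, osz, C);
  for (int c = 0; c < C; ++c) {
    for (int p = 0; p < osz * osz; ++p)
      out.slice(c)(p % osz, p / osz) = z(c, p);
  }
}

void cube_to_rows(const fcube& in, fmat& z) {
  const int C = in.n_slices, osz = in.n_rows;
  z.set_size(C, osz * osz);
  for (int c = 0; c < C; ++c)
    for (int p = 0; p < osz * osz; ++p)
      z(c, p) = in.slice(c)(p % osz, p / osz);
}

void maxpool2(const fcube& in, int osz, fcube& out, arma::umat& idx) {
  const int C = in.n_slices;
  out.set_size(osz, osz, C);
  idx.set_size(osz * osz, C);
  for (int c = 0; c < C; ++c) {
    for (int ox = 0; ox < osz; ++ox) {
      for (int oy = 0; oy < osz; ++oy) {
        float best = -1e30f;
        int bi = 0;
        for (int b = 0; b < 2; ++b) {
          for (int a = 0; a < 2; ++a) {
            const int y = 2 * oy + a, x = 2 * ox + b;
            const float v = in.slice(c)(y, x);
            if (v > best) { best = v; bi = x * in.n_rows + y; }
          }
        }
        out.slice(c)(oy, ox) = best;
        idx(ox * osz + oy, c) = bi;
      }
    }
  }
}

void maxpool2_back(const fcube& dout, const arma::umat& idx, int isz,
                   fcube& din) {
  const int C = dout.n_slices, osz = dout.n_rows;
  din.zeros(isz, isz, C);
  for (int c = 0; c < C; ++c)
    for (int p = 0; p < osz * osz; ++p)
      din.slice(c)(idx(p, c)) += dout.slice(c)(p % osz, p / osz);
}

struct Cache {
  fcube a0, c1, p1, c2, p2, c3, p3;
  fmat k1, k2, k3, z1, z2, z3;
  arma::umat i1, i2, i3;
  fvec f, h, prob;
};

void forward(const Params& P, const fvec& img, Cache& C) {
  using D = Dims;
  // fixed 2x2 average pool of the 100x100 input (column-major y-fast)
  C.a0.set_size(D::P0, D::P0, 1);
  for (int x = 0; x < D::P0; ++x)
    for (int y = 0; y < D::P0; ++y)
      C.a0.slice(0)(y, x) = 0.25f *
        (img(2 * x * D::IN + 2 * y) + img(2 * x * D::IN + 2 * y + 1) +
         img((2 * x + 1) * D::IN + 2 * y) + img((2 * x + 1) * D::IN + 2 * y + 1));
  im2col(C.a0, D::K1, D::O1, C.k1);
  C.z1 = P.W1 * C.k1;
  C.z1.each_col() += P.b1;
  C.z1.transform([](float v) { return v > 0 ? v : 0; });
  fcube a1; rows_to_cube(C.z1, D::O1, a1);
  maxpool2(a1, D::Q1, C.p1, C.i1);

  im2col(C.p1, D::K2, D::O2, C.k2);
  C.z2 = P.W2 * C.k2;
  C.z2.each_col() += P.b2;
  C.z2.transform([](float v) { return v > 0 ? v : 0; });
  fcube a2; rows_to_cube(C.z2, D::O2, a2);
  // 21 -> 10: drop last row/col before pooling
  fcube a2c(2 * D::Q2, 2 * D::Q2, D::C2);
  for (int c = 0; c < D::C2; ++c)
    a2c.slice(c) = a2.slice(c).submat(0, 0, 2 * D::Q2 - 1, 2 * D::Q2 - 1);
  C.c2 = a2c;
  maxpool2(a2c, D::Q2, C.p2, C.i2);

  im2col(C.p2, D::K3, D::O3, C.k3);
  C.z3 = P.W3 * C.k3;
  C.z3.each_col() += P.b3;
  C.z3.transform([](float v) { return v > 0 ? v : 0; });
  fcube a3; rows_to_cube(C.z3, D::O3, a3);
  maxpool2(a3, D::Q3, C.p3, C.i3);

  C.f.set_size(D::F);
  int r = 0;
  for (int c = 0; c < D::C3; ++c)
    for (int p = 0; p < D::Q3 * D::Q3; ++p) C.f(r++) = C.p3.slice(c)(p);
  C.h = P.W4 * C.f + P.b4;
  C.h.transform([](float v) { return v > 0 ? v : 0; });
  fvec logits = P.W5 * C.h + P.b5;
  logits -= logits.max();
  C.prob = arma::exp(logits);
  C.prob /= arma::accu(C.prob);
}

void backward(const Params& P, const Cache& C, int y, Params& G) {
  using D = Dims;
  fvec dlog = C.prob;
  dlog(y) -= 1.0f;
  G.W5 += dlog * C.h.t();
  G.b5 += dlog;
  fvec dh = P.W5.t() * dlog;
  for (int i = 0; i < D::H; ++i) if (C.h(i) <= 0) dh(i) = 0;
  G.W4 += dh * C.f.t();
  G.b4 += dh;
  fvec df = P.W4.t() * dh;

  fcube dp3(D::Q3, D::Q3, D::C3);
  int r = 0;
  for (int c = 0; c < D::C3; ++c)
    for (int p = 0; p < D::Q3 * D::Q3; ++p) dp3.slice(c)(p) = df(r++);
  fcube da3;
  maxpool2_back(dp3, C.i3, D::O3, da3);
  fmat dz3; cube_to_rows(da3, dz3);
  for (arma::uword i = 0; i < dz3.n_elem; ++i)
    if (C.z3(i) <= 0) dz3(i) = 0;
  G.W3 += dz3 * C.k3.t();
  G.b3 += arma::sum(dz3, 1);
  fmat dk3 = P.W3.t() * dz3;
  fcube dp2; dp2.zeros(D::Q2, D::Q2, D::C2);
  col2im_add(dk3, D::K3, D::O3, dp2);

  fcube da2c;
  maxpool2_back(dp2, C.i2, 2 * D::Q2, da2c);
  // re-embed into 21x21 (last row/col received no gradient)
  fcube da2; da2.zeros(D::O2, D::O2, D::C2);
  for (int c = 0; c < D::C2; ++c)
    da2.slice(c).submat(0, 0, 2 * D::Q2 - 1, 2 * D::Q2 - 1) = da2c.slice(c);
  fmat dz2; cube_to_rows(da2, dz2);
  for (arma::uword i = 0; i < dz2.n_elem; ++i)
    if (C.z2(i) <= 0) dz2(i) = 0;
  G.W2 += dz2 * C.k2.t();
  G.b2 += arma::sum(dz2, 1);
  fmat dk2 = P.W2.t() * dz2;
  fcube dp1; dp1.zeros(D::Q1, D::Q1, D::C1);
  col2im_add(dk2, D::K2, D::O2, dp1);

  fcube da1;
  maxpool2_back(dp1, C.i1, D::O1, da1);
  fmat dz1; cube_to_rows(da1, dz1);
  for (arma::uword i = 0; i < dz1.n_elem; ++i)
    if (C.z1(i) <= 0) dz1(i) = 0;
  G.W1 += dz1 * C.k1.t();
  G.b1 += arma::sum(dz1, 1);
  // input gradient not needed
}

void zero_like(const Params& P, Params& G) {
  G.W1.zeros(P.W1.n_rows, P.W1.n_cols); G.b1.zeros(P.b1.n_elem);
  G.W2.zeros(P.W2.n_rows, P.W2.n_cols); G.b2.zeros(P.b2.n_elem);
  G.W3.zeros(P.W3.n_rows, P.W3.n_cols); G.b3.zeros(P.b3.n_elem);
  G.W4.zeros(P.W4.n_rows, P.W4.n_cols); G.b4.zeros(P.b4.n_elem);
  G.W5.zeros(P.W5.n_rows, P.W5.n_cols); G.b5.zeros(P.b5.n_elem);
}

Params init_params(unsigned int seed) {
  using D = Dims;
  std::mt19937 rng(seed);
  auto he = [&](fmat& W, int rows, int cols, int fan_in) {
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / fan_in));
    W.set_size(rows, cols);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
  };
  Params P;
  he(P.W1, D::C1, D::K1 * D::K1, D::K1 * D::K1);
  he(P.W2, D::C2, D::K2 * D::K2 * D::C1, D::K2 * D::K2 * D::C1);
  he(P.W3, D::C3, D::K3 * D::K3 * D::C2, D::K3 * D::K3 * D::C2);
  he(P.W4, D::H, D::F, D::F);
  he(P.W5, D::OUT, D::H, D::H);
  P.b1.zeros(D::C1); P.b2.zeros(D::C2); P.b3.zeros(D::C3);
  P.b4.zeros(D::H); P.b5.zeros(D::OUT);
  return P;
}

List params_to_list(const Params& P) {
  auto M = [](const fmat& W) {
    NumericMatrix out(W.n_rows, W.n_cols);
    for (arma::uword i = 0; i < W.n_elem; ++i) out[i] = W(i);
    return out;
  };
  auto V = [](const fvec& b) {
    NumericVector out(b.n_elem);
    for (arma::uword i = 0; i < b.n_elem; ++i) out[i] = b(i);
    return out;
  };
  return List::create(
    _["W1"] = M(P.W1), _["b1"] = V(P.b1), _["W2"] = M(P.W2), _["b2"] = V(P.b2),
    _["W3"] = M(P.W3), _["b3"] = V(P.b3), _["W4"] = M(P.W4), _["b4"] = V(P.b4),
    _["W5"] = M(P.W5), _["b5"] = V(P.b5));
}

Params params_from_list(const List& L) {
  Params P;
  auto M = [&](const char* nm, fmat& W) {
    NumericMatrix x = L[nm];
    W.set_size(x.nrow(), x.ncol());
    for (int i = 0; i < x.nrow() * x.ncol(); ++i) W(i) = (float)x[i];
  };
  auto V = [&](const char* nm, fvec& b) {
    NumericVector x = L[nm];
    b.set_size(x.size());
    for (int i = 0; i < x.size(); ++i) b(i) = (float)x[i];
  };
  M("W1", P.W1); V("b1", P.b1); M("W2", P.W2); V("b2", P.b2);
  M("W3", P.W3); V("b3", P.b3); M("W4", P.W4); V("b4", P.b4);
  M("W5", P.W5); V("b5", P.b5);
  return P;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(const NumericMatrix& X, const IntegerVector& y,
                   int max_epochs, double lr, double momentum, int batch_size,
                   double error_tol, int seed, int min_epochs) {
  using D = Dims;
  const int n = X.nrow();
  if (X.ncol() != D::IN * D::IN) stop("crops must be 100x100");
  if (y.size() != n) stop("label length mismatch");
  // images as float columns
  fmat Xf(D::IN * D::IN, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < D::IN * D::IN; ++j) Xf(j, i) = (float)X(i, j);

  Params P = init_params((unsigned int)seed);
  Params V, G;
  zero_like(P, V);
  std::mt19937 rng((unsigned int)seed + 1u);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Cache C;
  std::vector<double> err_hist;
  bool converged = false;
  int epochs_run = 0;
  for (int ep = 0; ep < max_epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    int wrong = 0;
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      const int b1 = std::min(b0 + batch_size, n);
      zero_like(P, G);
      for (int i = b0; i < b1; ++i) {
        const int ix = order[i];
        fvec img = Xf.col(ix);
        forward(P, img, C);
        if ((int)C.prob.index_max() != y[ix]) ++wrong;
        backward(P, C, y[ix], G);
      }
      const float scale = (float)(lr / (b1 - b0));
      auto upd = [&](fmat& W, fmat& Vw, const fmat& Gw) {
        Vw = (float)momentum * Vw - scale * Gw;
        W += Vw;
      };
      auto updv = [&](fvec& b, fvec& Vb, const fvec& Gb) {
        Vb = (float)momentum * Vb - scale * Gb;
        b += Vb;
      };
      upd(P.W1, V.W1, G.W1); updv(P.b1, V.b1, G.b1);
      upd(P.W2, V.W2, G.W2); updv(P.b2, V.b2, G.b2);
      upd(P.W3, V.W3, G.W3); updv(P.b3, V.b3, G.b3);
      upd(P.W4, V.W4, G.W4); updv(P.b4, V.b4, G.b4);
      upd(P.W5, V.W5, G.W5); updv(P.b5, V.b5, G.b5);
    }
    const double err = (double)wrong / n;
    err_hist.push_back(err);
    epochs_run = ep + 1;
    Rcpp::checkUserInterrupt();
    if (err < error_tol) {
      converged = true;
      if (epochs_run >= min_epochs) break;  // keep sharpening before stopping
    }
  }
  List out = params_to_list(P);
  out["epochs_run"] = epochs_run;
  out["error_history"] = NumericVector(err_hist.begin(), err_hist.end());
  out["final_error"] = err_hist.empty() ? NA_REAL : err_hist.back();
  out["converged"] = converged;
  return out;
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
NumericMatrix cnn_predict_cpp(const List& weights, const NumericMatrix& X) {
  using D = Dims;
  const int n = X.nrow();
  if (X.ncol() != D::IN * D::IN) stop("crops must be 100x100");
  Params P = params_from_list(weights);
  NumericMatrix prob(n, 2);
  Cache C;
  fvec img(D::IN * D::IN);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < D::IN * D::IN; ++j) img(j) = (float)X(i, j);
    forward(P, img, C);
    prob(i, 0) = C.prob(0);
    prob(i, 1) = C.prob(1);
  }
  return prob;
}
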