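// Supervised 1D convolutional encoder + softmax head, trained with Adam on
// categorical cross-entropy.  Fixed architecture:
//   conv(64, k7, ReLU) - conv(64, k7, ReLU) - maxpool(6) - dropout(.25) -
//   conv(64, k7, ReLU) - conv(256, k7, ReLU) - maxpool(6) - dropout(.25) -
//   global max pool (256) - dense softmax (n_classes)
// Valid (unpadded) convolutions; pooling drops partial windows.  Inference
// (encoding / prediction) disables dropout and is deterministic.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int KW = 7;     // kernel width of every conv layer
static const int POOL = 6;   // pooling kernel/stride

// columns of M are the KW-wide patches of A (channels column-major within
// a patch), so a convolution is a single GEMM: W (F x C*KW) * M
static mat im2col(const mat& A, int k) {
  const int out = A.n_cols - k + 1;
  mat M(A.n_rows * k, out);
  for (int j = 0; j < out; ++j)
    M.col(j) = vectorise(A.cols(j, j + k - 1));
  return M;
}

// scatter-add the patch-space gradient back onto the input grid
static mat col2im(const mat& dM, int channels, int L, int k) {
  mat dA(channels, L, fill::zeros);
  const int out = L - k + 1;
  for (int j = 0; j < out; ++j) {
    mat patch(const_cast<double*>(dM.colptr(j)), channels, k, false, true);
    dA.cols(j, j + k - 1) += patch;
  }
  return dA;
}

static mat relu(const mat& Z) {
  mat A = Z;
  A.transform([](double v) { return v > 0 ? v : 0.0; });
  return A;
}

struct PoolOut { mat P; umat idx; };

static PoolOut maxpool(const mat& A) {
  const int P = A.n_cols / POOL;  // partial windows dropped
  PoolOut o;
  o.P.set_size(A.n_rows, P);
  o.idx.set_size(A.n_rows, P);
  for (int j = 0; j < P; ++j) {
    for (uword r = 0; r < A.n_rows; ++r) {
      uword rel;
      o.P(r, j) = A(r, span(j * POOL, j * POOL + POOL - 1)).max(rel);
      o.idx(r, j) = j * POOL + rel;
    }
  }
  return o;
}

static mat maxpool_back(const mat& dP, const umat& idx, int L) {
  mat dA(dP.n_rows, L, fill::zeros);
  for (uword j = 0; j < dP.n_cols; ++j)
    for (uword r = 0; r < dP.n_rows; ++r)
      dA(r, idx(r, j)) += dP(r, j);
  return dA;
}

struct Params {
  mat W1, W2, W3, W4, W5;
  vec b1, b2, b3, b4, b5;
};

static Params unpack(const Rcpp::List& p) {
  Params P;
  P.W1 = Rcpp::as<mat>(p["W1"]); P.b1 = Rcpp::as<vec>(p["b1"]);
  P.W2 = Rcpp::as<mat>(p["W2"]); P.b2 = Rcpp::as<vec>(p["b2"]);
  P.W3 = Rcpp::as<mat>(p["W3"]); P.b3 = Rcpp::as<vec>(p["b3"]);
  P.W4 = Rcpp::as<mat>(p["W4"]); P.b4 = Rcpp::as<vec>(p["b4"]);
  P.W5 = Rcpp::as<mat>(p["W5"]); P.b5 = Rcpp::as<vec>(p["b5"]);
  return P;
}

static Rcpp::List pack(const Params& P) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = P.W1, Rcpp::Named("b1") = P.b1,
    Rcpp::Named("W2") = P.W2, Rcpp::Named("b2") = P.b2,
    Rcpp::Named("W3") = P.W3, Rcpp::Named("b3") = P.b3,
    Rcpp::Named("W4") = P.W4, Rcpp::Named("b4") = P.b4,
    Rcpp::Named("W5") = P.W5, Rcpp::Named("b5") = P.b5);
}

// per-sample forward state kept for backprop
struct Fwd {
  mat A0, C1, Z1, C2, Z2, C3, Z3, C4, Z4;  // im2col inputs & pre-activations
  mat A1, A2, P1, D1, A3, A4, P2, D2;
  umat i1, i2;
  uvec gidx;          // global-max column per latent unit
  vec latent, prob;
  mat M1, M2, M3, M4; // dropout masks applied (empty at inference)
};

static void forward(const Params& P, const rowvec& xrow, int C, int L,
                    Fwd& f, bool train, double keep, std::mt19937_64* rng) {
  f.A0.set_size(C, L);
  for (int c = 0; c < C; ++c)
    f.A0.row(c) = xrow.subvec(c * L, c * L + L - 1);

  f.C1 = im2col(f.A0, KW);
  f.Z1 = P.W1 * f.C1; f.Z1.each_col() += P.b1;
  f.A1 = relu(f.Z1);

  f.C2 = im2col(f.A1, KW);
  f.Z2 = P.W2 * f.C2; f.Z2.each_col() += P.b2;
  f.A2 = relu(f.Z2);

  PoolOut p1 = maxpool(f.A2);
  f.P1 = p1.P; f.i1 = p1.idx;
  if (train) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    f.M1.set_size(f.P1.n_rows, f.P1.n_cols);
    for (uword i = 0; i < f.M1.n_elem; ++i)
      f.M1(i) = (U(*rng) < keep) ? 1.0 / keep : 0.0;
    f.D1 = f.P1 % f.M1;
  } else f.D1 = f.P1;

  f.C3 = im2col(f.D1, KW);
  f.Z3 = P.W3 * f.C3; f.Z3.each_col() += P.b3;
  f.A3 = relu(f.Z3);

  f.C4 = im2col(f.A3, KW);
  f.Z4 = P.W4 * f.C4; f.Z4.each_col() += P.b4;
  f.A4 = relu(f.Z4);

  PoolOut p2 = maxpool(f.A4);
  f.P2 = p2.P; f.i2 = p2.idx;
  if (train) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    f.M2.set_size(f.P2.n_rows, f.P2.n_cols);
    for (uword i = 0; i < f.M2.n_elem; ++i)
      f.M2(i) = (U(*rng) < keep) ? 1.0 / keep : 0.0;
    f.D2 = f.P2 % f.M2;
  } else f.D2 = f.P2;

  f.latent.set_size(f.D2.n_rows);
  f.gidx.set_size(f.D2.n_rows);
  for (uword r = 0; r < f.D2.n_rows; ++r) {
    uword c;
    f.latent(r) = f.D2.row(r).max(c);
    f.gidx(r) = c;
  }

  vec logits = P.W5 * f.latent + P.b5;
  logits -= logits.max();
  vec e = exp(logits);
  f.prob = e / accu(e);
}

static void backward(const Params& P, const Fwd& f, const vec& dlogits,
                     Params& G, int C, int L) {
  G.W5 += dlogits * f.latent.t();
  G.b5 += dlogits;
  vec dlat = P.W5.t() * dlogits;

  mat dD2(f.D2.n_rows, f.D2.n_cols, fill::zeros);
  for (uword r = 0; r < f.D2.n_rows; ++r) dD2(r, f.gidx(r)) += dlat(r);
  if (!f.M2.is_empty()) dD2 %= f.M2;
  mat dA4 = maxpool_back(dD2, f.i2, f.A4.n_cols);
  mat dZ4 = dA4 % conv_to<mat>::from(f.Z4 > 0);
  G.W4 += dZ4 * f.C4.t();
  G.b4 += sum(dZ4, 1);
  mat dA3 = col2im(P.W4.t() * dZ4, f.A3.n_rows, f.A3.n_cols, KW);
  mat dZ3 = dA3 % conv_to<mat>::from(f.Z3 > 0);
  G.W3 += dZ3 * f.C3.t();
  G.b3 += sum(dZ3, 1);
  mat dD1 = col2im(P.W3.t() * dZ3, f.D1.n_rows, f.D1.n_cols, KW);
  if (!f.M1.is_empty()) dD1 %= f.M1;
  mat dA2 = maxpool_back(dD1, f.i1, f.A2.n_cols);
  mat dZ2 = dA2 % conv_to<mat>::from(f.Z2 > 0);
  G.W2 += dZ2 * f.C2.t();
  G.b2 += sum(dZ2, 1);
  mat dA1 = col2im(P.W2.t() * dZ2, f.A1.n_rows, f.A1.n_cols, KW);
  mat dZ1 = dA1 % conv_to<mat>::from(f.Z1 > 0);
  G.W1 += dZ1 * f.C1.t();
  G.b1 += sum(dZ1, 1);
}

static mat glorot(int rows, int cols, std::mt19937_64& rng) {
  double lim = std::sqrt(6.0 / (rows + cols));
  std::uniform_real_distribution<double> U(-lim, lim);
  mat W(rows, cols);
  for (uword i = 0; i < W.n_elem; ++i) W(i) = U(rng);
  return W;
}

// [[Rcpp::export(name = ".cnn_init_cpp")]]
Rcpp::List cnn_init_cpp(int n_channels, int n_classes, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  Params P;
  P.W1 = glorot(64, n_channels * KW, rng); P.b1 = vec(64, fill::zeros);
  P.W2 = glorot(64, 64 * KW, rng);         P.b2 = vec(64, fill::zeros);
  P.W3 = glorot(64, 64 * KW, rng);         P.b3 = vec(64, fill::zeros);
  P.W4 = glorot(256, 64 * KW, rng);        P.b4 = vec(256, fill::zeros);
  P.W5 = glorot(n_classes, 256, rng);      P.b5 = vec(n_classes, fill::zeros);
  return pack(P);
}

struct Adam {
  Params m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Params& P) {
    m.W1 = zeros(size(P.W1)); v.W1 = zeros(size(P.W1));
    m.W2 = zeros(size(P.W2)); v.W2 = zeros(size(P.W2));
    m.W3 = zeros(size(P.W3)); v.W3 = zeros(size(P.W3));
    m.W4 = zeros(size(P.W4)); v.W4 = zeros(size(P.W4));
    m.W5 = zeros(size(P.W5)); v.W5 = zeros(size(P.W5));
    m.b1 = zeros(size(P.b1)); v.b1 = zeros(size(P.b1));
    m.b2 = zeros(size(P.b2)); v.b2 = zeros(size(P.b2));
    m.b3 = zeros(size(P.b3)); v.b3 = zeros(size(P.b3));
    m.b4 = zeros(size(P.b4)); v.b4 = zeros(size(P.b4));
    m.b5 = zeros(size(P.b5)); v.b5 = zeros(size(P.b5));
  }
  template <typename T>
  void upd(T& w, const T& g, T& mm, T& vv, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    T mh = mm / (1 - std::pow(b1, (double)t));
    T vh = vv / (1 - std::pow(b2, (double)t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
  void step(Params& P, const Params& G, double lr) {
    ++t;
    upd(P.W1, G.W1, m.W1, v.W1, lr); upd(P.b1, G.b1, m.b1, v.b1, lr);
    upd(P.W2, G.W2, m.W2, v.W2, lr); upd(P.b2, G.b2, m.b2, v.b2, lr);
    upd(P.W3, G.W3, m.W3, v.W3, lr); upd(P.b3, G.b3, m.b3, v.b3, lr);
    upd(P.W4, G.W4, m.W4, v.W4, lr); upd(P.b4, G.b4, m.b4, v.b4, lr);
    upd(P.W5, G.W5, m.W5, v.W5, lr); upd(P.b5, G.b5, m.b5, v.b5, lr);
  }
};

static void zero_like(Params& G, const Params& P) {
  G.W1 = zeros(size(P.W1)); G.b1 = zeros(size(P.b1));
  G.W2 = zeros(size(P.W2)); G.b2 = zeros(size(P.b2));
  G.W3 = zeros(size(P.W3)); G.b3 = zeros(size(P.b3));
  G.W4 = zeros(size(P.W4)); G.b4 = zeros(size(P.b4));
  G.W5 = zeros(size(P.W5)); G.b5 = zeros(size(P.b5));
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(Rcpp::List params, const arma::mat& X,
                         const arma::ivec& y, int n_channels, int epochs,
                         int batch, double lr, double dropout, int seed) {
  Params P = unpack(params);
  const int N = X.n_rows;
  const int L = X.n_cols / n_channels;
  const double keep = 1.0 - dropout;
  std::mt19937_64 rng(static_cast<uint64_t>(seed) + 0x9e3779b9ULL);
  Adam opt; opt.init(P);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  vec loss_hist(epochs, fill::zeros);
  Fwd f;
  Params G;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    for (int start = 0; start < N; start += batch) {
      int stop = std::min(start + batch, N);
      zero_like(G, P);
      for (int b = start; b < stop; ++b) {
        int i = order[b];
        forward(P, X.row(i), n_channels, L, f, true, keep, &rng);
        double li = -std::log(std::max(f.prob(y(i)), 1e-12));
        ep_loss += li;
        vec dlogits = f.prob;
        dlogits(y(i)) -= 1.0;
        backward(P, f, dlogits, G, n_channels, L);
      }
      double scale = 1.0 / (stop - start);
      G.W1 *= scale; G.b1 *= scale; G.W2 *= scale; G.b2 *= scale;
      G.W3 *= scale; G.b3 *= scale; G.W4 *= scale; G.b4 *= scale;
      G.W5 *= scale; G.b5 *= scale;
      opt.step(P, G, lr);
    }
    loss_hist(ep) = ep_loss / N;
    if (!std::isfinite(loss_hist(ep)))
      Rcpp::stop("CNN training diverged (non-finite loss at epoch %d)",
                 ep + 1);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = pack(P),
                            Rcpp::Named("loss") = loss_hist);
}

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
arma::mat cnn_forward_cpp(Rcpp::List params, const arma::mat& X,
                          int n_channels, bool encode_only) {
  Params P = unpack(params);
  const int N = X.n_rows;
  const int L = X.n_cols / n_channels;
  const int out_dim = encode_only ? P.W5.n_cols : P.W5.n_rows;
  mat out(N, out_dim);
  Fwd f;
  for (int i = 0; i < N; ++i) {
    forward(P, X.row(i), n_channels, L, f, false, 1.0, nullptr);
    out.row(i) = encode_only ? f.latent.t() : f.prob.t();
  }
  return out;
}
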