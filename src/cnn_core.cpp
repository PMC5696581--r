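// Inner loops of the multi-channel text CNN: forward pass and
// forward+backward over a minibatch of note matrices. Each note is an
// n x d embedding matrix; channel c applies k_c filters of height h_c
// (stored as a k_c x (h_c * d) matrix, window rows concatenated), followed
// by ReLU and max pooling over windows; pooled features feed a logistic
// output unit. Dropout masks are generated in R and passed in (values 0 or
// 1/(1-rate)) so all randomness stays under R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Convolution response of one channel on one note: (nw x k) matrix of
// window dot-products (bias not yet added).
static arma::mat channel_conv(const arma::mat& M, const arma::mat& W, int h) {
  const int n = M.n_rows, d = M.n_cols;
  const int nw = n - h + 1;
  arma::mat conv(nw, W.n_rows, arma::fill::zeros);
  for (int o = 0; o < h; ++o) {
    conv += M.rows(o, o + nw - 1) * W.cols(o * d, (o + 1) * d - 1).t();
  }
  return conv;
}

// [[Rcpp::export]]
List cpp_cnn_forward(List notes, List W, List b, IntegerVector heights,
                     arma::vec w_out, double b_out,
                     Nullable<NumericMatrix> dropout_mask) {
  const int N = notes.size();
  const int C = W.size();
  int K = 0;
  for (int c = 0; c < C; ++c) K += as<arma::mat>(W[c]).n_rows;

  std::vector<arma::mat> Wv(C);
  std::vector<arma::vec> bv(C);
  for (int c = 0; c < C; ++c) {
    Wv[c] = as<arma::mat>(W[c]);
    bv[c] = as<arma::vec>(b[c]);
  }
  arma::mat mask;
  bool use_mask = dropout_mask.isNotNull();
  if (use_mask) mask = as<arma::mat>(dropout_mask.get());

  arma::mat pooled(N, K);
  arma::imat tstar(N, K);
  arma::vec prob(N);

  for (int i = 0; i < N; ++i) {
    arma::mat M = as<arma::mat>(notes[i]);
    int off = 0;
    for (int c = 0; c < C; ++c) {
      const int h = heights[c];
      if ((int)M.n_rows < h)
        stop("note matrix has fewer rows than filter height");
      arma::mat conv = channel_conv(M, Wv[c], h);
      const int k = Wv[c].n_rows;
      for (int f = 0; f < k; ++f) {
        arma::uword am;
        double mx = conv.col(f).max(am);
        tstar(i, off + f) = (int)am;
        double a = mx + bv[c](f);
        pooled(i, off + f) = a > 0 ? a : 0.0;
      }
      off += k;
    }
    arma::rowvec z = pooled.row(i);
    if (use_mask) z %= mask.row(i);
    prob(i) = sigmoid(arma::dot(z.t(), w_out) + b_out);
  }
  return List::create(_["prob"] = prob, _["pooled"] = pooled,
                      _["tstar"] = tstar);
}

// [[Rcpp::export]]
List cpp_cnn_grad(List notes, List W, List b, IntegerVector heights,
                  arma::vec w_out, double b_out, arma::vec y,
                  Nullable<NumericMatrix> dropout_mask, double l2) {
  const int N = notes.size();
  const int C = W.size();
  std::vector<arma::mat> Wv(C), gW(C);
  std::vector<arma::vec> bv(C), gb(C);
  int K = 0;
  for (int c = 0; c < C; ++c) {
    Wv[c] = as<arma::mat>(W[c]);
    bv[c] = as<arma::vec>(b[c]);
    gW[c] = arma::mat(Wv[c].n_rows, Wv[c].n_cols, arma::fill::zeros);
    gb[c] = arma::vec(bv[c].n_elem, arma::fill::zeros);
    K += Wv[c].n_rows;
  }
  arma::mat mask;
  bool use_mask = dropout_mask.isNotNull();
  if (use_mask) mask = as<arma::mat>(dropout_mask.get());

  arma::vec g_wout(K, arma::fill::zeros);
  double g_bout = 0.0, loss = 0.0;
  arma::vec prob(N);
  const double eps = 1e-12;

  for (int i = 0; i < N; ++i) {
    arma::mat M = as<arma::mat>(notes[i]);
    const int d = M.n_cols;
    arma::vec pooled(K);
    arma::ivec ts(K);
    int off = 0;
    for (int c = 0; c < C; ++c) {
      const int h = heights[c];
      if ((int)M.n_rows < h)
        stop("note matrix has fewer rows than filter height");
      arma::mat conv = channel_conv(M, Wv[c], h);
      const int k = Wv[c].n_rows;
      for (int f = 0; f < k; ++f) {
        arma::uword am;
        double mx = conv.col(f).max(am);
        ts(off + f) = (int)am;
        double a = mx + bv[c](f);
        pooled(off + f) = a > 0 ? a : 0.0;
      }
      off += k;
    }
    arma::vec z = pooled;
    if (use_mask) z %= mask.row(i).t();
    double p = sigmoid(arma::dot(z, w_out) + b_out);
    prob(i) = p;
    double pc = std::min(std::max(p, eps), 1.0 - eps);
    loss += -(y(i) * std::log(pc) + (1.0 - y(i)) * std::log(1.0 - pc));

    double dlogit = p - y(i);
    g_wout += dlogit * z;
    g_bout += dlogit;
    arma::vec dz = dlogit * w_out;
    if (use_mask) dz %= mask.row(i).t();
    off = 0;
    for (int c = 0; c < C; ++c) {
      const int h = heights[c];
      const int k = Wv[c].n_rows;
      for (int f = 0; f < k; ++f) {
        double gf = dz(off + f);
        if (gf != 0.0 && pooled(off + f) > 0.0) {
          gb[c](f) += gf;
          const int t0 = ts(off + f);
          for (int o = 0; o < h; ++o) {
            gW[c].submat(f, o * d, f, (o + 1) * d - 1) +=
              gf * M.row(t0 + o);
          }
        }
      }
      off += k;
    }
  }

  double wsq = arma::dot(w_out, w_out);
  List gW_out(C), gb_out(C);
  for (int c = 0; c < C; ++c) {
    wsq += arma::accu(arma::square(Wv[c]));
    gW_out[c] = gW[c] / N + l2 * Wv[c];
    gb_out[c] = gb[c] / N;
  }
  loss = loss / N + 0.5 * l2 * wsq;

  return List::create(
    _["gW"] = gW_out, _["gb"] = gb_out,
    _["g_wout"] = g_wout / N + l2 * w_out,
    _["g_bout"] = g_bout / N,
    _["loss"] = loss, _["prob"] = prob);
}
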