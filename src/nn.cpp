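// Forward/backward engine for the threshold-sharpened detectors.
//
// Layers are passed from R as a list of lists:
//   lstm:   list(type = "lstm",  W (D x 4H), U (H x 4H), b (4H), alpha, beta)
//   dense:  list(type = "dense", W (D x K),  b (K),      alpha, beta)
//   output: list(type = "output", ...) -- same as dense; its pre-activation
//           is the score surface, its bRELU output enters the MSE loss.
//
// Gate order in the 4H blocks: [input | forget | cell | output].
// Only the *emitted* activation of a recurrent layer (what the next layer
// consumes, and the layer's final-step feature vector) passes through the
// bounded ReLU; the recurrence itself stays smooth so that gradients flow
// through time during sharpening.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::as;

static mat brelu_mat(const mat& x, double a, double b) {
  mat out(size(x));
  if (b > a) {
    out = (x - a) / (b - a);
    out.elem(find(x >= b)).ones();
    out.elem(find(x <= a)).zeros();
  } else {
    // fully sharpened: step at 0.5, value 1 at exactly 0.5 (x >= beta branch)
    out = conv_to<mat>::from(x >= 0.5);
  }
  return out;
}

static mat brelu_grad_mat(const mat& x, double a, double b) {
  mat d(size(x), fill::zeros);
  if (b > a) {
    uvec in = find((x > a) % (x < b));
    d.elem(in).fill(1.0 / (b - a));
  }
  return d;
}

struct LstmCache {
  cube I, F, G, O, C, TC, H, E; // B x H x L each
  cube Xin;                     // B x D x L input sequence
};

// run one LSTM layer over an input cube (B x D x L); returns emitted cube
static cube lstm_forward(const mat& W, const mat& U, const rowvec& b,
                         double alpha, double beta, const cube& Xin,
                         LstmCache* cache) {
  const uword B = Xin.n_rows, L = Xin.n_slices, H = U.n_rows;
  cube E(B, H, L);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  if (cache) {
    cache->I.set_size(B, H, L); cache->F.set_size(B, H, L);
    cache->G.set_size(B, H, L); cache->O.set_size(B, H, L);
    cache->C.set_size(B, H, L); cache->TC.set_size(B, H, L);
    cache->H.set_size(B, H, L); cache->E.set_size(B, H, L);
    cache->Xin = Xin;
  }
  for (uword t = 0; t < L; ++t) {
    mat z = Xin.slice(t) * W + h * U;
    z.each_row() += b;
    mat zi = z.cols(0, H - 1), zf = z.cols(H, 2 * H - 1),
        zg = z.cols(2 * H, 3 * H - 1), zo = z.cols(3 * H, 4 * H - 1);
    mat gi = 1.0 / (1.0 + exp(-zi));
    mat gf = 1.0 / (1.0 + exp(-zf));
    mat gg = tanh(zg);
    mat go = 1.0 / (1.0 + exp(-zo));
    c = gf % c + gi % gg;
    mat tc = tanh(c);
    h = go % tc;
    // map the LSTM output range [-1, 1] onto the bRELU domain [0, 1]
    mat e = brelu_mat(0.5 * (h + 1.0), alpha, beta);
    E.slice(t) = e;
    if (cache) {
      cache->I.slice(t) = gi; cache->F.slice(t) = gf;
      cache->G.slice(t) = gg; cache->O.slice(t) = go;
      cache->C.slice(t) = c;  cache->TC.slice(t) = tc;
      cache->H.slice(t) = h;  cache->E.slice(t) = e;
    }
  }
  return E;
}

// backward through one LSTM layer; dE is gradient w.r.t. emitted cube.
// Returns gradient w.r.t. the layer input cube; fills gW, gU, gb.
static cube lstm_backward(const mat& W, const mat& U, double alpha, double beta,
                          const LstmCache& cc, const cube& dE,
                          mat& gW, mat& gU, rowvec& gb) {
  const uword B = cc.I.n_rows, H = cc.I.n_cols, L = cc.I.n_slices;
  const uword D = cc.Xin.n_cols;
  gW.zeros(D, 4 * H); gU.zeros(H, 4 * H); gb.zeros(4 * H);
  cube dX(B, D, L, fill::zeros);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  for (uword t = L; t-- > 0;) {
    mat dh = 0.5 * (dE.slice(t) %
                    brelu_grad_mat(0.5 * (cc.H.slice(t) + 1.0), alpha, beta)) +
             dh_next;
    const mat& gi = cc.I.slice(t); const mat& gf = cc.F.slice(t);
    const mat& gg = cc.G.slice(t); const mat& go = cc.O.slice(t);
    const mat& tc = cc.TC.slice(t);
    mat dc = dh % go % (1.0 - tc % tc) + dc_next;
    mat c_prev = (t == 0) ? mat(B, H, fill::zeros) : cc.C.slice(t - 1);
    mat h_prev = (t == 0) ? mat(B, H, fill::zeros) : cc.H.slice(t - 1);
    mat dzo = (dh % tc) % go % (1.0 - go);
    mat dzi = (dc % gg) % gi % (1.0 - gi);
    mat dzf = (dc % c_prev) % gf % (1.0 - gf);
    mat dzg = (dc % gi) % (1.0 - gg % gg);
    dc_next = dc % gf;
    mat dZ = join_rows(join_rows(dzi, dzf), join_rows(dzg, dzo)); // B x 4H
    gW += cc.Xin.slice(t).t() * dZ;
    gU += h_prev.t() * dZ;
    gb += sum(dZ, 0);
    dh_next = dZ * U.t();
    dX.slice(t) = dZ * W.t();
  }
  return dX;
}

// ---- prediction-only forward ------------------------------------------------

// X: B x L (sequence, consumed by a leading lstm layer) or B x D (flat input
// for a leading dense layer). Returns out_pre (B x 2), out_post (B x 2) and,
// if collect_hidden, the post-bRELU activation of every hidden layer
// (final-step matrix for recurrent layers).
// [[Rcpp::export]]
List cpp_nn_forward(List layers, const arma::mat& X, bool collect_hidden) {
  const uword n_layers = layers.size();
  cube seq;       // current sequence representation
  mat flat;       // current flat representation
  bool is_seq;
  {
    List l0 = layers[0];
    std::string t0 = as<std::string>(l0["type"]);
    if (t0 == "lstm") {
      seq.set_size(X.n_rows, 1, X.n_cols);
      for (uword t = 0; t < X.n_cols; ++t) seq.slice(t) = X.col(t);
      is_seq = true;
    } else {
      flat = X;
      is_seq = false;
    }
  }
  List hidden(n_layers);
  mat out_pre, out_post;
  for (uword li = 0; li < n_layers; ++li) {
    List lay = layers[li];
    std::string type = as<std::string>(lay["type"]);
    double alpha = as<double>(lay["alpha"]), beta = as<double>(lay["beta"]);
    if (type == "lstm") {
      if (!is_seq) Rcpp::stop("lstm layer after flat representation");
      mat W = as<mat>(lay["W"]), U = as<mat>(lay["U"]);
      rowvec b = as<rowvec>(lay["b"]);
      seq = lstm_forward(W, U, b, alpha, beta, seq, nullptr);
      if (collect_hidden) hidden[li] = seq.slice(seq.n_slices - 1);
    } else {
      if (is_seq) { flat = seq.slice(seq.n_slices - 1); is_seq = false; seq.reset(); }
      mat W = as<mat>(lay["W"]);
      rowvec b = as<rowvec>(lay["b"]);
      mat A = flat * W;
      A.each_row() += b;
      flat = brelu_mat(A, alpha, beta);
      if (type == "output") { out_pre = A; out_post = flat; }
      if (collect_hidden && type != "output") hidden[li] = flat;
    }
  }
  List res = List::create(Rcpp::Named("out_pre") = out_pre,
                          Rcpp::Named("out_post") = out_post);
  if (collect_hidden) res["hidden"] = hidden;
  return res;
}

// ---- training step: forward + MSE loss + gradients --------------------------

// Y: B x 2 one-hot targets. Loss = mean over all B*2 elements of squared error.
// [[Rcpp::export]]
List cpp_nn_grad(List layers, const arma::mat& X, const arma::mat& Y) {
  const uword n_layers = layers.size();
  const uword B = X.n_rows;

  std::vector<LstmCache> lcache(n_layers);
  std::vector<mat> dense_in(n_layers), dense_pre(n_layers);
  std::vector<std::string> types(n_layers);
  std::vector<double> alphas(n_layers), betas(n_layers);

  cube seq;
  mat flat;
  bool is_seq;
  {
    List l0 = layers[0];
    std::string t0 = as<std::string>(l0["type"]);
    if (t0 == "lstm") {
      seq.set_size(B, 1, X.n_cols);
      for (uword t = 0; t < X.n_cols; ++t) seq.slice(t) = X.col(t);
      is_seq = true;
    } else {
      flat = X;
      is_seq = false;
    }
  }
  uword last_lstm = 0; bool any_lstm = false;
  for (uword li = 0; li < n_layers; ++li) {
    List lay = layers[li];
    types[li] = as<std::string>(lay["type"]);
    alphas[li] = as<double>(lay["alpha"]);
    betas[li] = as<double>(lay["beta"]);
    if (types[li] == "lstm") {
      mat W = as<mat>(lay["W"]), U = as<mat>(lay["U"]);
      rowvec b = as<rowvec>(lay["b"]);
      seq = lstm_forward(W, U, b, alphas[li], betas[li], seq, &lcache[li]);
      last_lstm = li; any_lstm = true;
    } else {
      if (is_seq) { flat = seq.slice(seq.n_slices - 1); is_seq = false; seq.reset(); }
      mat W = as<mat>(lay["W"]);
      rowvec b = as<rowvec>(lay["b"]);
      dense_in[li] = flat;
      mat A = flat * W;
      A.each_row() += b;
      dense_pre[li] = A;
      flat = brelu_mat(A, alphas[li], betas[li]);
    }
  }
  mat out_post = flat;
  mat diff = out_post - Y;
  double loss = accu(diff % diff) / (double)(B * out_post.n_cols);

  // backward
  List grads(n_layers);
  mat dflat = (2.0 / (double)(B * out_post.n_cols)) * diff;
  // dense stack, in reverse, down to (but not including) lstm layers
  uword li = n_layers;
  while (li-- > 0) {
    if (types[li] == "lstm") { ++li; break; }
    List lay = layers[li];
    mat W = as<mat>(lay["W"]);
    mat dA = dflat % brelu_grad_mat(dense_pre[li], alphas[li], betas[li]);
    mat gW = dense_in[li].t() * dA;
    rowvec gb = sum(dA, 0);
    grads[li] = List::create(Rcpp::Named("W") = gW, Rcpp::Named("b") = gb);
    dflat = dA * W.t();
    if (li == 0) break;
  }
  if (any_lstm) {
    // dflat is the gradient w.r.t. the final-step emitted vector of the last lstm
    uword L = lcache[last_lstm].E.n_slices;
    cube dE(B, lcache[last_lstm].E.n_cols, L, fill::zeros);
    dE.slice(L - 1) = dflat;
    for (uword lj = last_lstm + 1; lj-- > 0;) {
      List lay = layers[lj];
      mat W = as<mat>(lay["W"]), U = as<mat>(lay["U"]);
      mat gW, gU; rowvec gb;
      cube dX = lstm_backward(W, U, alphas[lj], betas[lj], lcache[lj], dE,
                              gW, gU, gb);
      grads[lj] = List::create(Rcpp::Named("W") = gW, Rcpp::Named("U") = gU,
                               Rcpp::Named("b") = gb);
      dE = dX;
      if (lj == 0) break;
    }
  }
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("grads") = grads,
                      Rcpp::Named("out_post") = out_post);
}
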