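// Miniature U-net-style encoder-decoder for per-pixel classification.
//
// Architecture (width w, K output classes), all convolutions 3x3 with
// zero padding 1 unless noted:
//   conv1: 3 -> w, ReLU                       (full resolution)
//   maxpool 2x2                               (half resolution)
//   conv2: w -> 2w, ReLU
//   nearest upsample x2                       (back to full resolution)
//   concat with conv1 activations (skip)      (3w channels)
//   conv3: 3w -> w, ReLU
//   conv4: 1x1, w -> K, softmax over classes
//
// Training minimises the multi-class soft Dice loss
//   L = (1/K) * sum_k [ 1 - (2*sum(p_k*t_k) + eps) / (sum p_k + sum t_k + eps) ].
// Forward and the full analytic backward pass are implemented here; the
// optimiser loop lives in R. Spatial dimensions must be even (the R side
// pads). Everything is deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat kernel_at(const Rcpp::NumericVector& w, int ci, int i, int o) {
  // w has dim (3, 3, ci, co); returns the 3x3 kernel for input i, output o
  mat k(3, 3);
  const double* p = w.begin() + 9 * (i + ci * o);
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) k(r, c) = p[r + 3 * c];
  return k;
}

static inline mat flipk(const mat& k) { return fliplr(flipud(k)); }

// correlation with zero padding 1 (the conv layer forward primitive)
static inline mat corr_same(const mat& x, const mat& k) {
  return conv2(x, flipk(k), "same");
}

static cube conv_forward(const cube& x, const Rcpp::NumericVector& w,
                         const Rcpp::NumericVector& b, int co) {
  int ci = x.n_slices;
  cube out(x.n_rows, x.n_cols, co);
  for (int o = 0; o < co; ++o) {
    mat acc(x.n_rows, x.n_cols, fill::value(b[o]));
    for (int i = 0; i < ci; ++i) acc += corr_same(x.slice(i), kernel_at(w, ci, i, o));
    out.slice(o) = acc;
  }
  return out;
}

// gradient of the loss w.r.t. the conv input
static cube conv_backward_input(const cube& dy, const Rcpp::NumericVector& w,
                                int ci) {
  int co = dy.n_slices;
  cube dx(dy.n_rows, dy.n_cols, ci, fill::zeros);
  for (int i = 0; i < ci; ++i)
    for (int o = 0; o < co; ++o)
      dx.slice(i) += conv2(dy.slice(o), kernel_at(w, ci, i, o), "same");
  return dx;
}

// gradient w.r.t. kernels and biases; dW has layout (3,3,ci,co)
static void conv_backward_weights(const cube& x, const cube& dy,
                                  Rcpp::NumericVector& dW, Rcpp::NumericVector& db) {
  int ci = x.n_slices, co = dy.n_slices;
  int H = x.n_rows, W = x.n_cols;
  for (int o = 0; o < co; ++o) {
    db[o] += accu(dy.slice(o));
    for (int i = 0; i < ci; ++i) {
      double* p = dW.begin() + 9 * (i + ci * o);
      for (int dv = -1; dv <= 1; ++dv) {      // kernel column offset
        for (int du = -1; du <= 1; ++du) {    // kernel row offset
          int r0y = std::max(0, -du), r1y = H - 1 - std::max(0, du);
          int c0y = std::max(0, -dv), c1y = W - 1 - std::max(0, dv);
          if (r1y < r0y || c1y < c0y) continue;
          double acc = accu(dy.slice(o).submat(r0y, c0y, r1y, c1y) %
                            x.slice(i).submat(r0y + du, c0y + dv, r1y + du, c1y + dv));
          p[(du + 1) + 3 * (dv + 1)] += acc;
        }
      }
    }
  }
}

static cube maxpool(const cube& x, ucube& argr, ucube& argc) {
  int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube out(H, W, C);
  argr.set_size(H, W, C);
  argc.set_size(H, W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -datum::inf;
        int br = 0, bc = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = x(2 * i + di, 2 * j + dj, ch);
            if (v > best) { best = v; br = 2 * i + di; bc = 2 * j + dj; }
          }
        out(i, j, ch) = best;
        argr(i, j, ch) = br;
        argc(i, j, ch) = bc;
      }
  return out;
}

static cube maxpool_backward(const cube& dy, const ucube& argr, const ucube& argc,
                             int H, int W) {
  cube dx(H, W, dy.n_slices, fill::zeros);
  for (unsigned ch = 0; ch < dy.n_slices; ++ch)
    for (unsigned j = 0; j < dy.n_cols; ++j)
      for (unsigned i = 0; i < dy.n_rows; ++i)
        dx(argr(i, j, ch), argc(i, j, ch), ch) += dy(i, j, ch);
  return dx;
}

static cube upsample2(const cube& x) {
  cube out(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (unsigned ch = 0; ch < x.n_slices; ++ch)
    for (unsigned j = 0; j < out.n_cols; ++j)
      for (unsigned i = 0; i < out.n_rows; ++i)
        out(i, j, ch) = x(i / 2, j / 2, ch);
  return out;
}

static cube upsample2_backward(const cube& dy) {
  cube dx(dy.n_rows / 2, dy.n_cols / 2, dy.n_slices, fill::zeros);
  for (unsigned ch = 0; ch < dy.n_slices; ++ch)
    for (unsigned j = 0; j < dy.n_cols; ++j)
      for (unsigned i = 0; i < dy.n_rows; ++i)
        dx(i / 2, j / 2, ch) += dy(i, j, ch);
  return dx;
}

struct ForwardState {
  cube a1, p1, a2, cat, a3, probs;
  ucube argr, argc;
};

static void forward_pass(const cube& x, const Rcpp::List& weights, ForwardState& st) {
  Rcpp::NumericVector W1 = weights["W1"], b1 = weights["b1"];
  Rcpp::NumericVector W2 = weights["W2"], b2 = weights["b2"];
  Rcpp::NumericVector W3 = weights["W3"], b3 = weights["b3"];
  Rcpp::NumericMatrix W4 = weights["W4"];
  Rcpp::NumericVector b4 = weights["b4"];
  int w = b1.size(), K = b4.size();

  st.a1 = conv_forward(x, W1, b1, w);
  st.a1.transform([](double v) { return v > 0 ? v : 0.0; });
  cube pooled = maxpool(st.a1, st.argr, st.argc);
  st.p1 = pooled;
  st.a2 = conv_forward(pooled, W2, b2, 2 * w);
  st.a2.transform([](double v) { return v > 0 ? v : 0.0; });
  cube up = upsample2(st.a2);
  st.cat = join_slices(up, st.a1);
  st.a3 = conv_forward(st.cat, W3, b3, w);
  st.a3.transform([](double v) { return v > 0 ? v : 0.0; });

  cube logits(x.n_rows, x.n_cols, K);
  for (int k = 0; k < K; ++k) {
    mat acc(x.n_rows, x.n_cols, fill::value(b4[k]));
    for (int j = 0; j < w; ++j) acc += W4(j, k) * st.a3.slice(j);
    logits.slice(k) = acc;
  }
  // numerically stable softmax over the class axis
  mat mx = logits.slice(0);
  for (int k = 1; k < K; ++k) mx = arma::max(mx, logits.slice(k));
  cube ex(logits.n_rows, logits.n_cols, K);
  mat denom(logits.n_rows, logits.n_cols, fill::zeros);
  for (int k = 0; k < K; ++k) {
    ex.slice(k) = exp(logits.slice(k) - mx);
    denom += ex.slice(k);
  }
  for (int k = 0; k < K; ++k) ex.slice(k) /= denom;
  st.probs = ex;
}

static cube one_hot(const imat& mask, int K) {
  cube t(mask.n_rows, mask.n_cols, K, fill::zeros);
  for (unsigned j = 0; j < mask.n_cols; ++j)
    for (unsigned i = 0; i < mask.n_rows; ++i)
      t(i, j, (int)mask(i, j)) = 1.0;
  return t;
}

static double dice_from_probs(const cube& probs, const cube& t, double eps) {
  int K = probs.n_slices;
  double loss = 0.0;
  for (int k = 0; k < K; ++k) {
    double A = accu(probs.slice(k) % t.slice(k));
    double B = accu(probs.slice(k)) + accu(t.slice(k));
    loss += 1.0 - (2.0 * A + eps) / (B + eps);
  }
  return loss / K;
}

// [[Rcpp::export]]
arma::cube segnet_forward(const arma::cube& x, const Rcpp::List& weights) {
  ForwardState st;
  forward_pass(x, weights, st);
  return st.probs;
}

// [[Rcpp::export]]
double segnet_loss(const arma::cube& x, const arma::imat& mask,
                   const Rcpp::List& weights, int classes, double eps) {
  ForwardState st;
  forward_pass(x, weights, st);
  return dice_from_probs(st.probs, one_hot(mask, classes), eps);
}

// [[Rcpp::export]]
Rcpp::List segnet_grad(const arma::cube& x, const arma::imat& mask,
                       const Rcpp::List& weights, int classes, double eps) {
  ForwardState st;
  forward_pass(x, weights, st);
  int K = classes, w = st.a3.n_slices;
  cube t = one_hot(mask, K);
  double loss = dice_from_probs(st.probs, t, eps);

  // d(dice)/d(probs), then softmax backward to logits
  cube dP(x.n_rows, x.n_cols, K);
  for (int k = 0; k < K; ++k) {
    double A = accu(st.probs.slice(k) % t.slice(k));
    double B = accu(st.probs.slice(k)) + accu(t.slice(k));
    double num = 2.0 * A + eps, den = B + eps;
    dP.slice(k) = (-2.0 * t.slice(k) / den + num / (den * den)) / K;
  }
  mat dot(x.n_rows, x.n_cols, fill::zeros);
  for (int k = 0; k < K; ++k) dot += dP.slice(k) % st.probs.slice(k);
  cube dZ(x.n_rows, x.n_cols, K);
  for (int k = 0; k < K; ++k) dZ.slice(k) = st.probs.slice(k) % (dP.slice(k) - dot);

  Rcpp::NumericVector W1 = weights["W1"], W2 = weights["W2"], W3 = weights["W3"];
  Rcpp::NumericMatrix W4 = weights["W4"];
  Rcpp::NumericVector dW1(W1.size()), db1(w);
  Rcpp::NumericVector dW2(W2.size()), db2(2 * w);
  Rcpp::NumericVector dW3(W3.size()), db3(w);
  Rcpp::NumericMatrix dW4(w, K);
  Rcpp::NumericVector db4(K);

  // conv4 (1x1) backward
  cube dA3(x.n_rows, x.n_cols, w, fill::zeros);
  for (int k = 0; k < K; ++k) {
    db4[k] = accu(dZ.slice(k));
    for (int j = 0; j < w; ++j) {
      dW4(j, k) = accu(dZ.slice(k) % st.a3.slice(j));
      dA3.slice(j) += W4(j, k) * dZ.slice(k);
    }
  }
  // ReLU + conv3 backward
  for (int j = 0; j < w; ++j)
    dA3.slice(j) %= conv_to<mat>::from(st.a3.slice(j) > 0);
  conv_backward_weights(st.cat, dA3, dW3, db3);
  cube dCat = conv_backward_input(dA3, W3, 3 * w);

  // split concat into the upsample branch and the skip branch
  cube dUp = dCat.slices(0, 2 * w - 1);
  cube dA1 = dCat.slices(2 * w, 3 * w - 1);

  // upsample, ReLU, conv2 backward
  cube dA2 = upsample2_backward(dUp);
  for (int j = 0; j < 2 * w; ++j)
    dA2.slice(j) %= conv_to<mat>::from(st.a2.slice(j) > 0);
  conv_backward_weights(st.p1, dA2, dW2, db2);
  cube dP1 = conv_backward_input(dA2, W2, w);

  // maxpool backward joins the skip gradient
  dA1 += maxpool_backward(dP1, st.argr, st.argc, x.n_rows, x.n_cols);
  for (int j = 0; j < w; ++j)
    dA1.slice(j) %= conv_to<mat>::from(st.a1.slice(j) > 0);
  conv_backward_weights(x, dA1, dW1, db1);

  dW1.attr("dim") = W1.attr("dim");
  dW2.attr("dim") = W2.attr("dim");
  dW3.attr("dim") = W3.attr("dim");
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("W1") = dW1, Rcpp::Named("b1") = db1,
      Rcpp::Named("W2") = dW2, Rcpp::Named("b2") = db2,
      Rcpp::Named("W3") = dW3, Rcpp::Named("b3") = db3,
      Rcpp::Named("W4") = dW4, Rcpp::Named("b4") = db4));
}
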