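// Two-step trainer for the circular-bottleneck autoencoder.
//
// The encoder maps the 2N-vector of per-gene standardized (spliced,
// unspliced) values, concatenated with (cos, sin) of the atan2 seed angle,
// through two leaky-ReLU hidden layers to a single real number theta; the
// Circularize layer turns theta into (cos theta, sin theta), which the
// decoder expands back to 2N values. Step 1 fits the encoder to the seed
// angles; step 2 fits encoder+decoder on reconstruction MSE. Optimization
// is Adam on minibatches with plateau learning-rate decay and early
// stopping on validation loss (best weights restored).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// local RNG so training is reproducible independently of R's RNG state
static std::mt19937_64 g_eng;

static mat randn_mat(unsigned r, unsigned c) {
  std::normal_distribution<double> nd(0.0, 1.0);
  mat out(r, c);
  for (uword j = 0; j < c; ++j)
    for (uword i = 0; i < r; ++i) out(i, j) = nd(g_eng);
  return out;
}

static uvec shuffled(const uvec& v) {
  uvec out = v;
  for (uword i = out.n_elem - 1; i > 0; --i) {
    std::uniform_int_distribution<uword> ud(0, i);
    std::swap(out(i), out(ud(g_eng)));
  }
  return out;
}

static mat lrelu(const mat& a) { return arma::max(a, 0.1 * a); }

static mat dlrelu(const mat& a) {
  mat d(a.n_rows, a.n_cols, fill::ones);
  d.elem(find(a < 0)).fill(0.1);
  return d;
}

struct AdamVar {
  mat m, v;
  AdamVar() {}
  explicit AdamVar(const mat& w) : m(size(w), fill::zeros),
                                   v(size(w), fill::zeros) {}
  void step(mat& w, const mat& g, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    mat mhat = m / (1 - std::pow(b1, t));
    mat vhat = v / (1 - std::pow(b2, t));
    w -= lr * mhat / (sqrt(vhat) + eps);
  }
};

struct Net {
  mat W1, W2, W3, V1, V2, V3;        // W3 is 1 x H, biases kept as col vecs
  vec b1, b2, b3, c1, c2, c3;
};

static Net init_net(unsigned n_in, unsigned H, unsigned n_out) {
  Net net;
  net.W1 = randn_mat(H, n_in) * std::sqrt(2.0 / n_in);
  net.b1 = zeros<vec>(H);
  net.W2 = randn_mat(H, H) * std::sqrt(2.0 / H);
  net.b2 = zeros<vec>(H);
  net.W3 = randn_mat(1, H) * std::sqrt(2.0 / H);
  net.b3 = zeros<vec>(1);
  net.V1 = randn_mat(H, 2) * std::sqrt(2.0 / 2.0);
  net.c1 = zeros<vec>(H);
  net.V2 = randn_mat(H, H) * std::sqrt(2.0 / H);
  net.c2 = zeros<vec>(H);
  net.V3 = randn_mat(n_out, H) * std::sqrt(2.0 / H);
  net.c3 = zeros<vec>(n_out);
  return net;
}

struct Cache {
  mat xin, a1, h1, a2, h2, th, z, d1, g1, d2, g2, y;
};

// angle features from the (possibly noisy) standardized inputs of the
// seed gene: atan2(z(u), z(s)) as a (cos, sin) pair
static mat angle_features(const mat& Xb, unsigned iu, unsigned is) {
  rowvec zu = Xb.row(iu), zs = Xb.row(is);
  rowvec th(Xb.n_cols);
  for (uword j = 0; j < Xb.n_cols; ++j) th(j) = std::atan2(zu(j), zs(j));
  mat feat(2, Xb.n_cols);
  feat.row(0) = cos(th);
  feat.row(1) = sin(th);
  return feat;
}

static void enc_forward(const Net& n, const mat& xin, Cache& c) {
  c.xin = xin;
  c.a1 = n.W1 * xin;  c.a1.each_col() += n.b1;  c.h1 = lrelu(c.a1);
  c.a2 = n.W2 * c.h1; c.a2.each_col() += n.b2;  c.h2 = lrelu(c.a2);
  c.th = n.W3 * c.h2; c.th += n.b3(0);
  c.z = join_cols(cos(c.th), sin(c.th));
}

static void dec_forward(const Net& n, Cache& c) {
  c.d1 = n.V1 * c.z;  c.d1.each_col() += n.c1;  c.g1 = lrelu(c.d1);
  c.d2 = n.V2 * c.g1; c.d2.each_col() += n.c2;  c.g2 = lrelu(c.d2);
  c.y = n.V3 * c.g2;  c.y.each_col() += n.c3;
}

// backprop from dth (1 x B) through the encoder, accumulating into g
static void enc_backward(const Net& n, const Cache& c, const mat& dth,
                         Net& g) {
  g.W3 = dth * c.h2.t();
  g.b3 = vec(1, fill::value(accu(dth)));
  mat dh2 = n.W3.t() * dth;
  mat da2 = dh2 % dlrelu(c.a2);
  g.W2 = da2 * c.h1.t();
  g.b2 = sum(da2, 1);
  mat dh1 = n.W2.t() * da2;
  mat da1 = dh1 % dlrelu(c.a1);
  g.W1 = da1 * c.xin.t();
  g.b1 = sum(da1, 1);
}

static double step1_loss(const Net& net, const mat& xin, const mat& tgt) {
  Cache c;
  enc_forward(net, xin, c);
  return accu(square(c.z - tgt)) / tgt.n_elem;
}

static double step2_loss(const Net& net, const mat& xin, const mat& tgt) {
  Cache c;
  enc_forward(net, xin, c);
  dec_forward(net, c);
  return accu(square(c.y - tgt)) / tgt.n_elem;
}

// [[Rcpp::export]]
Rcpp::List cpp_train_deepcycle(const arma::mat& X,      // 2N x n_cells
                               arma::uvec train_idx,    // 0-based
                               arma::uvec val_idx,
                               unsigned iu, unsigned is, // seed gene rows
                               unsigned hidden,
                               double noise_std,
                               unsigned batch_size,
                               unsigned max_epochs,
                               unsigned es_patience,
                               double es_min_delta,
                               double lr_init,
                               double lr_factor,
                               unsigned lr_patience,
                               double min_lr,
                               unsigned seed) {
  g_eng.seed(seed);
  const unsigned n_in = X.n_rows + 2, n_out = X.n_rows;
  Net net = init_net(n_in, hidden, n_out);

  const mat Xtr = X.cols(train_idx), Xval = X.cols(val_idx);
  const mat xin_val = join_cols(Xval, angle_features(Xval, iu, is));
  const mat th_val_tgt = angle_features(Xval, iu, is);

  std::vector<double> hist1_tr, hist1_val, hist2_tr, hist2_val;

  for (int step = 1; step <= 2; ++step) {
    AdamVar aW1(net.W1), aW2(net.W2), aW3(net.W3);
    AdamVar ab1(net.b1), ab2(net.b2), ab3(net.b3);
    AdamVar aV1(net.V1), aV2(net.V2), aV3(net.V3);
    AdamVar ac1(net.c1), ac2(net.c2), ac3(net.c3);
    double lr = lr_init, t_adam = 0;
    double best_val = datum::inf;
    Net best = net;
    unsigned es_wait = 0, lr_wait = 0;
    std::vector<double>& htr = (step == 1) ? hist1_tr : hist2_tr;
    std::vector<double>& hval = (step == 1) ? hist1_val : hist2_val;

    for (unsigned epoch = 0; epoch < max_epochs; ++epoch) {
      uvec perm = shuffled(train_idx);
      double tr_loss = 0; unsigned n_batches = 0;
      for (uword start = 0; start + batch_size <= perm.n_elem;
           start += batch_size) {
        uvec bidx = perm.subvec(start, start + batch_size - 1);
        mat Xb = X.cols(bidx);
        mat Xn = Xb + noise_std * randn_mat(Xb.n_rows, Xb.n_cols);
        mat ang = angle_features(Xn, iu, is);
        mat xin = join_cols(Xn, ang);

        Cache c;
        enc_forward(net, xin, c);
        Net g;
        double loss;
        if (step == 1) {
          loss = accu(square(c.z - ang)) / ang.n_elem;
          mat dz = 2.0 * (c.z - ang) / ang.n_elem;
          mat dth = -sin(c.th) % dz.row(0) + cos(c.th) % dz.row(1);
          enc_backward(net, c, dth, g);
        } else {
          dec_forward(net, c);
          loss = accu(square(c.y - Xb)) / Xb.n_elem;
          mat dy = 2.0 * (c.y - Xb) / Xb.n_elem;
          g.V3 = dy * c.g2.t();
          g.c3 = sum(dy, 1);
          mat dg2 = net.V3.t() * dy;
          mat dd2 = dg2 % dlrelu(c.d2);
          g.V2 = dd2 * c.g1.t();
          g.c2 = sum(dd2, 1);
          mat dg1 = net.V2.t() * dd2;
          mat dd1 = dg1 % dlrelu(c.d1);
          g.V1 = dd1 * c.z.t();
          g.c1 = sum(dd1, 1);
          mat dz = net.V1.t() * dd1;
          mat dth = -sin(c.th) % dz.row(0) + cos(c.th) % dz.row(1);
          enc_backward(net, c, dth, g);
        }
        if (!std::isfinite(loss)) {
          Rcpp::stop("training loss became non-finite at epoch %d", epoch + 1);
        }
        tr_loss += loss; ++n_batches;
        t_adam += 1;
        aW1.step(net.W1, g.W1, lr, t_adam);
        mat gb1 = g.b1, gb2 = g.b2, gb3 = g.b3;
        ab1.step(net.b1, gb1, lr, t_adam);
        aW2.step(net.W2, g.W2, lr, t_adam);
        ab2.step(net.b2, gb2, lr, t_adam);
        aW3.step(net.W3, g.W3, lr, t_adam);
        ab3.step(net.b3, gb3, lr, t_adam);
        if (step == 2) {
          mat gc1 = g.c1, gc2 = g.c2, gc3 = g.c3;
          aV1.step(net.V1, g.V1, lr, t_adam);
          ac1.step(net.c1, gc1, lr, t_adam);
          aV2.step(net.V2, g.V2, lr, t_adam);
          ac2.step(net.c2, gc2, lr, t_adam);
          aV3.step(net.V3, g.V3, lr, t_adam);
          ac3.step(net.c3, gc3, lr, t_adam);
        }
      }
      double val = (step == 1) ? step1_loss(net, xin_val, th_val_tgt)
                               : step2_loss(net, xin_val, Xval);
      htr.push_back(tr_loss / std::max(n_batches, 1u));
      hval.push_back(val);
      if (!std::isfinite(val)) {
        Rcpp::stop("validation loss became non-finite at epoch %d", epoch + 1);
      }
      if (val < best_val - es_min_delta) {
        best_val = val; best = net; es_wait = 0; lr_wait = 0;
      } else {
        ++es_wait; ++lr_wait;
        if (lr_wait >= lr_patience && lr > min_lr) {
          lr = std::max(lr * lr_factor, min_lr);
          lr_wait = 0;
        }
        if (es_wait >= es_patience) break;
      }
    }
    net = best;  // restore_best_weights
  }

  return Rcpp::List::create(
    Rcpp::Named("W1") = net.W1, Rcpp::Named("b1") = net.b1,
    Rcpp::Named("W2") = net.W2, Rcpp::Named("b2") = net.b2,
    Rcpp::Named("W3") = net.W3, Rcpp::Named("b3") = net.b3,
    Rcpp::Named("V1") = net.V1, Rcpp::Named("c1") = net.c1,
    Rcpp::Named("V2") = net.V2, Rcpp::Named("c2") = net.c2,
    Rcpp::Named("V3") = net.V3, Rcpp::Named("c3") = net.c3,
    Rcpp::Named("history") = Rcpp::List::create(
      Rcpp::Named("step1_train") = hist1_tr,
      Rcpp::Named("step1_val") = hist1_val,
      Rcpp::Named("step2_train") = hist2_tr,
      Rcpp::Named("step2_val") = hist2_val));
}
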