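// Compact CNN engine: convolution via im2col GEMM, max pooling,
// cross-channel local response normalization, fully-connected layers,
// inverted dropout, softmax + cross-entropy, and SGD with momentum and
// step learning-rate decay. Single-threaded and deterministic for a fixed
// seed. Layer stacks come from the R-side architecture descriptors.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

enum Kind { INPUT, CONV, POOL, NORM, FC, DROPOUT, RELU, SOFTMAX, LOSS };

struct Layer {
  int kind = INPUT;
  int k = 0, S = 1, P = 0, Cout = 0;
  double rate = 0.5;
  // geometry filled during parsing
  int in_H = 0, in_C = 0, out_H = 0, out_C = 0;
  bool in_spatial = true;  // input still a feature map (not yet flattened)
};

// LRN constants (AlexNet/Caffe defaults)
static const int    LRN_N = 5;
static const double LRN_ALPHA = 1e-4;
static const double LRN_BETA = 0.75;
static const double LRN_K = 1.0;

static int kind_code(const std::string& s) {
  if (s == "input") return INPUT;
  if (s == "convolution") return CONV;
  if (s == "pooling") return POOL;
  if (s == "normalization") return NORM;
  if (s == "fully_connected") return FC;
  if (s == "dropout") return DROPOUT;
  if (s == "relu") return RELU;
  if (s == "softmax") return SOFTMAX;
  if (s == "loss") return LOSS;
  stop("unknown layer kind: " + s);
}

static std::vector<Layer> parse_layers(DataFrame df, int input_size,
                                       int input_channels) {
  CharacterVector kind = df["kind"];
  IntegerVector k = df["k"], S = df["S"], P = df["P"], C = df["C_out"];
  NumericVector rate = df["rate"];
  int n = kind.size();
  std::vector<Layer> layers(n);
  for (int i = 0; i < n; ++i) {
    Layer& l = layers[i];
    l.kind = kind_code(as<std::string>(kind[i]));
    if (!IntegerVector::is_na(k[i])) l.k = k[i];
    if (!IntegerVector::is_na(S[i])) l.S = S[i];
    if (!IntegerVector::is_na(P[i])) l.P = P[i];
    if (!IntegerVector::is_na(C[i])) l.Cout = C[i];
    if (!NumericVector::is_na(rate[i])) l.rate = rate[i];
  }
  // shape walk
  int H = input_size, Cc = input_channels;
  bool spatial = true;
  for (int i = 0; i < n; ++i) {
    Layer& l = layers[i];
    l.in_H = H; l.in_C = Cc; l.in_spatial = spatial;
    switch (l.kind) {
    case CONV:
    case POOL: {
      if (!spatial) stop("convolution/pooling after a fully-connected layer");
      int num = H - l.k + 2 * l.P;
      if (num < 0) stop("layer " + std::to_string(i + 1) +
                        ": receptive field larger than padded input");
      H = num / l.S + 1;
      if (l.kind == CONV) Cc = l.Cout;
      break;
    }
    case FC:
      Cc = l.Cout; H = 1; spatial = false;
      break;
    default: break;
    }
    l.out_H = H; l.out_C = Cc;
  }
  return layers;
}

// ---------------------------------------------------------------------------
// parameter store

struct Params {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
  explicit Params(size_t n) : W(n), b(n) {}
};

static Params params_from_r(List weights, size_t n_layers) {
  Params p(n_layers);
  for (size_t i = 0; i < n_layers; ++i) {
    RObject wi = weights[i];
    if (wi.isNULL()) continue;
    List li(wi);
    p.W[i] = as<arma::mat>(li["W"]);
    p.b[i] = as<arma::vec>(li["b"]);
  }
  return p;
}

static List params_to_r(const Params& p) {
  List out(p.W.size());
  for (size_t i = 0; i < p.W.size(); ++i) {
    if (p.W[i].n_elem == 0) { out[i] = R_NilValue; continue; }
    out[i] = List::create(Named("W") = p.W[i], Named("b") = p.b[i]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// per-sample forward/backward caches

struct Cache {
  std::vector<arma::cube> cube_out;   // output of each layer (spatial phase)
  std::vector<arma::vec>  vec_out;    // output of each layer (vector phase)
  std::vector<arma::mat>  im2col;     // conv layers
  std::vector<arma::umat> pool_arg;   // pooling argmax (linear index per slice)
  std::vector<arma::cube> lrn_in, lrn_den;
  std::vector<arma::vec>  fc_in;
  std::vector<arma::vec>  drop_mask;
  arma::vec probs;
  explicit Cache(size_t n)
      : cube_out(n), vec_out(n), im2col(n), pool_arg(n), lrn_in(n),
        lrn_den(n), fc_in(n), drop_mask(n) {}
};

static void im2col_fill(const arma::cube& A, int k, int S, int P, int Ho,
                        arma::mat& Xc) {
  const int H = A.n_rows, Cin = A.n_slices;
  Xc.zeros(k * k * Cin, Ho * Ho);
  for (int c = 0; c < Cin; ++c) {
    const arma::mat& sl = A.slice(c);
    for (int j = 0; j < Ho; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int col = i + Ho * j;
        double* dst = Xc.colptr(col) + k * k * c;
        for (int dj = 0; dj < k; ++dj) {
          const int ic = j * S + dj - P;
          for (int di = 0; di < k; ++di) {
            const int ir = i * S + di - P;
            dst[di + k * dj] =
                (ir >= 0 && ir < H && ic >= 0 && ic < H) ? sl(ir, ic) : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& dXc, int k, int S, int P, int Ho,
                       arma::cube& dA) {
  const int H = dA.n_rows, Cin = dA.n_slices;
  for (int c = 0; c < Cin; ++c) {
    arma::mat& sl = dA.slice(c);
    for (int j = 0; j < Ho; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int col = i + Ho * j;
        const double* src = dXc.colptr(col) + k * k * c;
        for (int dj = 0; dj < k; ++dj) {
          const int ic = j * S + dj - P;
          if (ic < 0 || ic >= H) continue;
          for (int di = 0; di < k; ++di) {
            const int ir = i * S + di - P;
            if (ir >= 0 && ir < H) sl(ir, ic) += src[di + k * dj];
          }
        }
      }
    }
  }
}

// forward one sample; fills cache. `training` draws dropout masks from rng.
static void forward_one(const std::vector<Layer>& layers, const Params& p,
                        const arma::mat& img, Cache& cc, bool training,
                        std::mt19937& rng) {
  const size_t n = layers.size();
  arma::cube cur(img.n_rows, img.n_cols, 1);
  cur.slice(0) = img;
  arma::vec curv;
  bool isvec = false;
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  for (size_t i = 0; i < n; ++i) {
    const Layer& l = layers[i];
    switch (l.kind) {
    case INPUT: break;
    case CONV: {
      const int Ho = l.out_H;
      im2col_fill(cur, l.k, l.S, l.P, Ho, cc.im2col[i]);
      arma::mat O = p.W[i].t() * cc.im2col[i];
      O.each_col() += p.b[i];
      arma::cube out(Ho, Ho, l.Cout);
      for (int c = 0; c < l.Cout; ++c)
        out.slice(c) = arma::reshape(O.row(c), Ho, Ho);
      cur = std::move(out);
      break;
    }
    case POOL: {
      const int Ho = l.out_H, C = l.in_C, Hi = l.in_H;
      arma::cube out(Ho, Ho, C);
      cc.pool_arg[i].set_size(Ho * Ho, C);
      for (int c = 0; c < C; ++c) {
        const arma::mat& sl = cur.slice(c);
        for (int j = 0; j < Ho; ++j) {
          for (int i2 = 0; i2 < Ho; ++i2) {
            double best = -1e300; int arg = 0;
            for (int dj = 0; dj < l.k; ++dj) {
              const int ic = j * l.S + dj;
              if (ic >= Hi) continue;
              for (int di = 0; di < l.k; ++di) {
                const int ir = i2 * l.S + di;
                if (ir >= Hi) continue;
                const double v = sl(ir, ic);
                if (v > best) { best = v; arg = ir + Hi * ic; }
              }
            }
            out(i2, j, c) = best;
            cc.pool_arg[i](i2 + Ho * j, c) = arg;
          }
        }
      }
      cur = std::move(out);
      break;
    }
    case NORM: {
      const int C = l.in_C;
      cc.lrn_in[i] = cur;
      arma::cube den(cur.n_rows, cur.n_cols, C);
      arma::cube out(cur.n_rows, cur.n_cols, C);
      const int half = LRN_N / 2;
      for (arma::uword px = 0; px < cur.n_rows * cur.n_cols; ++px) {
        for (int c = 0; c < C; ++c) {
          double s = 0.0;
          const int lo = std::max(0, c - half), hi = std::min(C - 1, c + half);
          for (int c2 = lo; c2 <= hi; ++c2) {
            const double a = cur.slice(c2)(px);
            s += a * a;
          }
          const double d = LRN_K + (LRN_ALPHA / LRN_N) * s;
          den.slice(c)(px) = d;
          out.slice(c)(px) = cur.slice(c)(px) * std::pow(d, -LRN_BETA);
        }
      }
      cc.lrn_den[i] = den;
      cur = std::move(out);
      break;
    }
    case FC: {
      arma::vec x = isvec ? curv : arma::vectorise(cur);
      cc.fc_in[i] = x;
      curv = p.W[i].t() * x + p.b[i];
      isvec = true;
      break;
    }
    case RELU: {
      if (isvec) curv.transform([](double v) { return v > 0 ? v : 0.0; });
      else cur.transform([](double v) { return v > 0 ? v : 0.0; });
      break;
    }
    case DROPOUT: {
      if (!isvec) stop("dropout supported after fully-connected layers only");
      if (training) {
        arma::vec mask(curv.n_elem);
        const double keep = 1.0 - l.rate;
        for (arma::uword j = 0; j < mask.n_elem; ++j)
          mask[j] = (unif(rng) < keep) ? 1.0 / keep : 0.0;
        cc.drop_mask[i] = mask;
        curv %= mask;
      }
      break;
    }
    case SOFTMAX: {
      arma::vec z = curv - curv.max();
      arma::vec e = arma::exp(z);
      curv = e / arma::accu(e);
      cc.probs = curv;
      break;
    }
    case LOSS: break;
    }
    if (isvec) cc.vec_out[i] = curv;
    else cc.cube_out[i] = cur;
  }
}

// backward one sample, accumulating gradients into g.
static void backward_one(const std::vector<Layer>& layers, const Params& p,
                         const Cache& cc, int label, bool training,
                         Params& g) {
  const int n = (int)layers.size();
  // start below softmax: d(cross-entropy)/d(logits) = probs - onehot
  arma::vec dv = cc.probs;
  dv[label] -= 1.0;
  arma::cube dc;
  bool isvec = true;

  for (int i = n - 1; i >= 0; --i) {
    const Layer& l = layers[i];
    switch (l.kind) {
    case LOSS: case SOFTMAX: break;  // handled by the combined gradient
    case DROPOUT:
      if (training && cc.drop_mask[i].n_elem > 0) dv %= cc.drop_mask[i];
      break;
    case RELU: {
      if (isvec) {
        const arma::vec& out = cc.vec_out[i];
        for (arma::uword j = 0; j < dv.n_elem; ++j)
          if (out[j] <= 0) dv[j] = 0;
      } else {
        const arma::cube& out = cc.cube_out[i];
        for (arma::uword j = 0; j < dc.n_elem; ++j)
          if (out(j) <= 0) dc(j) = 0;
      }
      break;
    }
    case FC: {
      g.W[i] += cc.fc_in[i] * dv.t();
      g.b[i] += dv;
      arma::vec dx = p.W[i] * dv;
      if (l.in_spatial) {
        // un-flatten back to the upstream feature map
        dc = arma::cube(dx.memptr(), l.in_H, l.in_H, l.in_C);
        isvec = false;
      } else {
        dv = dx;
      }
      break;
    }
    case NORM: {
      const arma::cube& a = cc.lrn_in[i];
      const arma::cube& den = cc.lrn_den[i];
      const int C = l.in_C, half = LRN_N / 2;
      arma::cube da(a.n_rows, a.n_cols, C, arma::fill::zeros);
      for (arma::uword px = 0; px < a.n_rows * a.n_cols; ++px) {
        for (int c = 0; c < C; ++c) {
          const double d = den.slice(c)(px);
          const double db = dc.slice(c)(px);
          da.slice(c)(px) += db * std::pow(d, -LRN_BETA);
          const double common =
              db * a.slice(c)(px) * (-LRN_BETA) *
              std::pow(d, -LRN_BETA - 1.0) * (2.0 * LRN_ALPHA / LRN_N);
          const int lo = std::max(0, c - half), hi = std::min(C - 1, c + half);
          for (int m = lo; m <= hi; ++m)
            da.slice(m)(px) += common * a.slice(m)(px);
        }
      }
      dc = std::move(da);
      break;
    }
    case POOL: {
      const int Ho = l.out_H, C = l.in_C, Hi = l.in_H;
      arma::cube da(Hi, Hi, C, arma::fill::zeros);
      for (int c = 0; c < C; ++c) {
        arma::mat& sl = da.slice(c);
        for (int j = 0; j < Ho; ++j)
          for (int i2 = 0; i2 < Ho; ++i2)
            sl(cc.pool_arg[i](i2 + Ho * j, c)) += dc(i2, j, c);
      }
      dc = std::move(da);
      break;
    }
    case CONV: {
      const int Ho = l.out_H;
      arma::mat D(l.Cout, Ho * Ho);
      for (int c = 0; c < l.Cout; ++c)
        D.row(c) = arma::vectorise(dc.slice(c)).t();
      g.W[i] += cc.im2col[i] * D.t();
      g.b[i] += arma::sum(D, 1);
      arma::mat dXc = p.W[i] * D;
      arma::cube da(l.in_H, l.in_H, l.in_C, arma::fill::zeros);
      col2im_add(dXc, l.k, l.S, l.P, Ho, da);
      dc = std::move(da);
      break;
    }
    case INPUT: break;
    }
  }
}

// ---------------------------------------------------------------------------
// exported API

// [[Rcpp::export]]
List cpp_cnn_init(DataFrame layer_df, int input_size, int input_channels,
                  int seed) {
  std::vector<Layer> layers = parse_layers(layer_df, input_size,
                                           input_channels);
  Params p(layers.size());
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  for (size_t i = 0; i < layers.size(); ++i) {
    const Layer& l = layers[i];
    if (l.kind == CONV) {
      const int fan_in = l.k * l.k * l.in_C;
      p.W[i].set_size(fan_in, l.Cout);
      const double sd = std::sqrt(2.0 / fan_in);
      for (arma::uword j = 0; j < p.W[i].n_elem; ++j)
        p.W[i](j) = sd * norm(rng);
      p.b[i] = arma::zeros(l.Cout);
    } else if (l.kind == FC) {
      const int fan_in = l.in_H * l.in_H * l.in_C;
      p.W[i].set_size(fan_in, l.Cout);
      const double sd = std::sqrt(2.0 / fan_in);
      for (arma::uword j = 0; j < p.W[i].n_elem; ++j)
        p.W[i](j) = sd * norm(rng);
      p.b[i] = arma::zeros(l.Cout);
    }
  }
  return params_to_r(p);
}

// FC fan-in uses the layer's recorded input geometry; for the first FC that
// is in_H * in_H * in_C (the flattened spatial block), afterwards in_C.

// [[Rcpp::export]]
List cpp_cnn_forward(DataFrame layer_df, List weights, arma::cube X,
                     int input_size, int input_channels,
                     bool want_features) {
  std::vector<Layer> layers = parse_layers(layer_df, input_size,
                                           input_channels);
  Params p = params_from_r(weights, layers.size());
  const int N = X.n_slices;
  // locate the final fully-connected layer (its input is the penultimate
  // feature vector) and the softmax layer
  int last_fc = -1;
  for (size_t i = 0; i < layers.size(); ++i)
    if (layers[i].kind == FC) last_fc = (int)i;
  if (last_fc < 0) stop("architecture has no fully-connected layer");
  const int L = layers[last_fc].Cout;

  arma::mat scores(N, L);
  arma::mat feats;
  if (want_features) feats.set_size(N, layers[last_fc].in_C);
  std::mt19937 rng(0);
  Cache cc(layers.size());
  for (int s = 0; s < N; ++s) {
    forward_one(layers, p, X.slice(s), cc, false, rng);
    scores.row(s) = cc.probs.t();
    if (want_features) feats.row(s) = cc.fc_in[last_fc].t();
  }
  return List::create(Named("scores") = scores, Named("features") = feats);
}

static double top1_accuracy(const std::vector<Layer>& layers, const Params& p,
                            const arma::cube& X, const arma::ivec& y) {
  if (X.n_slices == 0) return NA_REAL;
  std::mt19937 rng(0);
  Cache cc(layers.size());
  int hits = 0;
  for (arma::uword s = 0; s < X.n_slices; ++s) {
    forward_one(layers, p, X.slice(s), cc, false, rng);
    if ((int)cc.probs.index_max() == y[s]) ++hits;
  }
  return (double)hits / X.n_slices;
}

// [[Rcpp::export]]
List cpp_cnn_train(DataFrame layer_df, List weights, arma::cube Xtr,
                   arma::ivec ytr, arma::cube Xval, arma::ivec yval,
                   List hp, int input_size, int input_channels, int seed) {
  std::vector<Layer> layers = parse_layers(layer_df, input_size,
                                           input_channels);
  Params p = params_from_r(weights, layers.size());
  const int iterations = as<int>(hp["iterations"]);
  const int batch_size = as<int>(hp["batch_size"]);
  const double lr0 = as<double>(hp["learning_rate"]);
  const double lr_decay = as<double>(hp["lr_decay"]);
  const int lr_step = as<int>(hp["lr_step"]);
  const double momentum = as<double>(hp["momentum"]);
  const double weight_decay = as<double>(hp["weight_decay"]);
  const int val_interval = as<int>(hp["validation_interval"]);

  const int Ntr = Xtr.n_slices;
  if (Ntr == 0) stop("empty training set");
  std::mt19937 rng((unsigned)seed);

  Params grad(layers.size()), vel(layers.size());
  for (size_t i = 0; i < layers.size(); ++i) {
    if (p.W[i].n_elem > 0) {
      grad.W[i] = arma::zeros(arma::size(p.W[i]));
      grad.b[i] = arma::zeros(arma::size(p.b[i]));
      vel.W[i] = arma::zeros(arma::size(p.W[i]));
      vel.b[i] = arma::zeros(arma::size(p.b[i]));
    }
  }

  std::vector<int> order(Ntr);
  for (int i = 0; i < Ntr; ++i) order[i] = i;

  std::vector<double> h_iter, h_loss, h_acc;
  // validation point at iteration 0: the initial weights are a candidate
  double best_acc = top1_accuracy(layers, p, Xval, yval);
  int best_iter = 0;
  Params best = p;
  h_iter.push_back(0); h_loss.push_back(NA_REAL); h_acc.push_back(best_acc);

  Cache cc(layers.size());
  double loss_sum = 0.0; int loss_n = 0;
  const int B = std::min(batch_size, Ntr);

  for (int iter = 1; iter <= iterations; ++iter) {
    // draw a minibatch without replacement (partial Fisher-Yates)
    for (int j = 0; j < B; ++j) {
      std::uniform_int_distribution<int> pick(j, Ntr - 1);
      std::swap(order[j], order[pick(rng)]);
    }
    for (size_t i = 0; i < layers.size(); ++i) {
      if (grad.W[i].n_elem > 0) { grad.W[i].zeros(); grad.b[i].zeros(); }
    }
    for (int j = 0; j < B; ++j) {
      const int idx = order[j];
      forward_one(layers, p, Xtr.slice(idx), cc, true, rng);
      loss_sum += -std::log(std::max(cc.probs[ytr[idx]], 1e-12));
      ++loss_n;
      backward_one(layers, p, cc, ytr[idx], true, grad);
    }
    const double lr = lr0 * std::pow(lr_decay, (iter - 1) / lr_step);
    for (size_t i = 0; i < layers.size(); ++i) {
      if (p.W[i].n_elem == 0) continue;
      vel.W[i] = momentum * vel.W[i] -
                 lr * (grad.W[i] / B + weight_decay * p.W[i]);
      vel.b[i] = momentum * vel.b[i] - lr * (grad.b[i] / B);
      p.W[i] += vel.W[i];
      p.b[i] += vel.b[i];
    }
    if (iter % val_interval == 0 || iter == iterations) {
      const double acc = top1_accuracy(layers, p, Xval, yval);
      h_iter.push_back(iter);
      h_loss.push_back(loss_n > 0 ? loss_sum / loss_n : NA_REAL);
      h_acc.push_back(acc);
      loss_sum = 0.0; loss_n = 0;
      if (!ISNAN(acc) && acc > best_acc) {  // strict: ties keep the earliest
        best_acc = acc; best_iter = iter; best = p;
      }
    }
  }

  arma::mat history(h_iter.size(), 3);
  for (size_t i = 0; i < h_iter.size(); ++i) {
    history(i, 0) = h_iter[i];
    history(i, 1) = h_loss[i];
    history(i, 2) = h_acc[i];
  }
  return List::create(
      Named("best_weights") = params_to_r(best),
      Named("final_weights") = params_to_r(p),
      Named("history") = history,
      Named("best_iteration") = best_iter,
      Named("best_accuracy") = best_acc);
}
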