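// Compact stacked-LSTM sequence regressor: full BPTT, Adam, per-sequence
// updates, masked losses so one forward pass serves both the training
// windows (chronological head) and the validation windows (tail).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LayerCache {
  mat in;   // (D_l + H) x T stacked [x_t; h_{t-1}]
  mat i, f, g, o, c, tc; // H x T gate activations, cell, tanh(cell)
};

inline vec sigmoid(const vec& z) { return 1.0 / (1.0 + exp(-z)); }

struct Net {
  std::vector<mat> W;  // per layer: 4H x (D_l + H)
  std::vector<vec> b;  // per layer: 4H
  vec w_out;           // H
  double b_out;
  int H, L;
};

Net unpack(const Rcpp::List& weights) {
  Net net;
  Rcpp::List layers = weights["layers"];
  net.L = layers.size();
  for (int l = 0; l < net.L; ++l) {
    Rcpp::List ly = layers[l];
    net.W.push_back(Rcpp::as<mat>(ly["W"]));
    net.b.push_back(Rcpp::as<vec>(ly["b"]));
  }
  net.w_out = Rcpp::as<vec>(weights["w_out"]);
  net.b_out = Rcpp::as<double>(weights["b_out"]);
  net.H = net.w_out.n_elem;
  return net;
}

Rcpp::List pack(const Net& net) {
  Rcpp::List layers(net.L);
  for (int l = 0; l < net.L; ++l)
    layers[l] = Rcpp::List::create(Rcpp::Named("W") = net.W[l],
                                   Rcpp::Named("b") = net.b[l]);
  return Rcpp::List::create(Rcpp::Named("layers") = layers,
                            Rcpp::Named("w_out") = net.w_out,
                            Rcpp::Named("b_out") = net.b_out);
}

// Forward pass over one sequence; fills caches when requested.
vec forward_seq(const Net& net, const mat& x, std::vector<LayerCache>* caches) {
  const int T = x.n_cols;
  const int H = net.H;
  vec y(T);
  mat h_prev(H, net.L, fill::zeros), c_prev(H, net.L, fill::zeros);
  if (caches) {
    caches->resize(net.L);
    for (int l = 0; l < net.L; ++l) {
      int Dl = net.W[l].n_cols - H;
      (*caches)[l].in.set_size(Dl + H, T);
      (*caches)[l].i.set_size(H, T); (*caches)[l].f.set_size(H, T);
      (*caches)[l].g.set_size(H, T); (*caches)[l].o.set_size(H, T);
      (*caches)[l].c.set_size(H, T); (*caches)[l].tc.set_size(H, T);
    }
  }
  vec xin;
  for (int t = 0; t < T; ++t) {
    xin = x.col(t);
    for (int l = 0; l < net.L; ++l) {
      vec in = join_cols(xin, h_prev.col(l));
      vec z = net.W[l] * in + net.b[l];
      vec iz = sigmoid(z.rows(0, H - 1));
      vec fz = sigmoid(z.rows(H, 2 * H - 1));
      vec gz = tanh(z.rows(2 * H, 3 * H - 1));
      vec oz = sigmoid(z.rows(3 * H, 4 * H - 1));
      vec ct = fz % c_prev.col(l) + iz % gz;
      vec tct = tanh(ct);
      vec ht = oz % tct;
      if (caches) {
        LayerCache& lc = (*caches)[l];
        lc.in.col(t) = in; lc.i.col(t) = iz; lc.f.col(t) = fz;
        lc.g.col(t) = gz; lc.o.col(t) = oz; lc.c.col(t) = ct;
        lc.tc.col(t) = tct;
      }
      h_prev.col(l) = ht;
      c_prev.col(l) = ct;
      xin = ht;
    }
    y(t) = dot(net.w_out, xin) + net.b_out;
  }
  return y;
}

struct Grads {
  std::vector<mat> dW;
  std::vector<vec> db;
  vec dw_out;
  double db_out;
  Grads(const Net& net) {
    for (int l = 0; l < net.L; ++l) {
      dW.push_back(mat(size(net.W[l]), fill::zeros));
      db.push_back(vec(size(net.b[l]), fill::zeros));
    }
    dw_out = vec(net.H, fill::zeros);
    db_out = 0.0;
  }
};

// BPTT for one sequence. dy: T-vector of dLoss/dy_t.
void backward_seq(const Net& net, const std::vector<LayerCache>& caches,
                  const vec& dy, Grads& gr) {
  const int T = dy.n_elem;
  const int H = net.H;
  mat carry_dh(H, net.L, fill::zeros), carry_dc(H, net.L, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec dx;  // gradient flowing down from the layer above at this t
    for (int l = net.L - 1; l >= 0; --l) {
      const LayerCache& lc = caches[l];
      vec dh = carry_dh.col(l);
      if (l == net.L - 1) {
        double d = dy(t);
        if (d != 0.0) {
          // h of top layer at t is lc.o % lc.tc
          gr.dw_out += d * (lc.o.col(t) % lc.tc.col(t));
          gr.db_out += d;
          dh += d * net.w_out;
        }
      } else {
        dh += dx;
      }
      vec tct = lc.tc.col(t);
      vec dc = carry_dc.col(l) + dh % lc.o.col(t) % (1.0 - tct % tct);
      vec c_prev_t = (t > 0) ? vec(lc.c.col(t - 1))
                             : vec(H, fill::zeros);
      vec di = dc % lc.g.col(t);
      vec df = dc % c_prev_t;
      vec dg = dc % lc.i.col(t);
      vec do_ = dh % tct;
      vec dz = join_cols(
          join_cols(di % lc.i.col(t) % (1.0 - lc.i.col(t)),
                    df % lc.f.col(t) % (1.0 - lc.f.col(t))),
          join_cols(dg % (1.0 - lc.g.col(t) % lc.g.col(t)),
                    do_ % lc.o.col(t) % (1.0 - lc.o.col(t))));
      gr.dW[l] += dz * lc.in.col(t).t();
      gr.db[l] += dz;
      vec din = net.W[l].t() * dz;
      int Dl = net.W[l].n_cols - H;
      dx = din.rows(0, Dl - 1);          // to layer below (or input: discarded)
      carry_dh.col(l) = din.rows(Dl, Dl + H - 1);
      carry_dc.col(l) = dc % lc.f.col(t);
    }
  }
}

struct AdamState {
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  vec m_out, v_out;
  double m_b, v_b;
  long step;
  AdamState(const Net& net) : m_b(0), v_b(0), step(0) {
    for (int l = 0; l < net.L; ++l) {
      mW.push_back(mat(size(net.W[l]), fill::zeros));
      vW.push_back(mat(size(net.W[l]), fill::zeros));
      mb.push_back(vec(size(net.b[l]), fill::zeros));
      vb.push_back(vec(size(net.b[l]), fill::zeros));
    }
    m_out = vec(net.H, fill::zeros);
    v_out = vec(net.H, fill::zeros);
  }
};

inline void adam_update_mat(mat& w, mat& m, mat& v, const mat& g,
                            double lr, double b1, double b2, double eps,
                            double bc1, double bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
}
inline void adam_update_vec(vec& w, vec& m, vec& v, const vec& g,
                            double lr, double b1, double b2, double eps,
                            double bc1, double bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
}

double grad_global_norm(const Grads& gr) {
  double s = gr.db_out * gr.db_out + dot(gr.dw_out, gr.dw_out);
  for (size_t l = 0; l < gr.dW.size(); ++l) {
    s += accu(gr.dW[l] % gr.dW[l]);
    s += dot(gr.db[l], gr.db[l]);
  }
  return std::sqrt(s);
}

void scale_grads(Grads& gr, double s) {
  gr.db_out *= s; gr.dw_out *= s;
  for (size_t l = 0; l < gr.dW.size(); ++l) { gr.dW[l] *= s; gr.db[l] *= s; }
}

double masked_mse(const vec& y, const vec& target, const vec& mask) {
  double n = accu(mask);
  if (n == 0) return NA_REAL;
  return accu(mask % square(y - target)) / n;
}

} // namespace

// [[Rcpp::export(name = ".lstm_fit")]]
Rcpp::List lstm_fit(Rcpp::List seqs_x, Rcpp::List seqs_y,
                    Rcpp::List train_mask, Rcpp::List val_mask,
                    Rcpp::List init_weights,
                    double lr, int max_epochs, int patience,
                    double clip_norm) {
  Net net = unpack(init_weights);
  AdamState adam(net);
  const int N = seqs_x.size();
  std::vector<mat> X(N);
  std::vector<vec> Y(N), TM(N), VM(N);
  for (int s = 0; s < N; ++s) {
    X[s] = Rcpp::as<mat>(seqs_x[s]).t();  // features x T
    Y[s] = Rcpp::as<vec>(seqs_y[s]);
    TM[s] = Rcpp::as<vec>(train_mask[s]);
    VM[s] = Rcpp::as<vec>(val_mask[s]);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  std::vector<double> train_hist, val_hist;
  double best_val = datum::inf;
  Net best = net;
  int best_epoch = -1, wait = 0;
  bool diverged = false;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double tr_sse = 0.0, tr_n = 0.0;
    for (int s = 0; s < N; ++s) {
      double n_tr = accu(TM[s]);
      if (n_tr == 0) continue;
      std::vector<LayerCache> caches;
      vec y = forward_seq(net, X[s], &caches);
      vec err = y - Y[s];
      tr_sse += accu(TM[s] % square(err));
      tr_n += n_tr;
      vec dy = 2.0 * (TM[s] % err) / n_tr;
      Grads gr(net);
      backward_seq(net, caches, dy, gr);
      double gn = grad_global_norm(gr);
      if (!std::isfinite(gn)) { diverged = true; break; }
      if (clip_norm > 0 && gn > clip_norm) scale_grads(gr, clip_norm / gn);
      adam.step += 1;
      double bc1 = 1.0 - std::pow(b1, (double)adam.step);
      double bc2 = 1.0 - std::pow(b2, (double)adam.step);
      for (int l = 0; l < net.L; ++l) {
        adam_update_mat(net.W[l], adam.mW[l], adam.vW[l], gr.dW[l],
                        lr, b1, b2, eps, bc1, bc2);
        adam_update_vec(net.b[l], adam.mb[l], adam.vb[l], gr.db[l],
                        lr, b1, b2, eps, bc1, bc2);
      }
      adam_update_vec(net.w_out, adam.m_out, adam.v_out, gr.dw_out,
                      lr, b1, b2, eps, bc1, bc2);
      // scalar Adam for the output bias
      adam.m_b = b1 * adam.m_b + (1 - b1) * gr.db_out;
      adam.v_b = b2 * adam.v_b + (1 - b2) * gr.db_out * gr.db_out;
      net.b_out -= lr * (adam.m_b / bc1) / (std::sqrt(adam.v_b / bc2) + eps);
    }
    if (diverged) break;
    double tr_loss = tr_n > 0 ? tr_sse / tr_n : NA_REAL;
    if (!std::isfinite(tr_loss)) { diverged = true; break; }
    // validation pass (no caches)
    double v_sse = 0.0, v_n = 0.0;
    for (int s = 0; s < N; ++s) {
      if (accu(VM[s]) == 0) continue;
      vec y = forward_seq(net, X[s], nullptr);
      v_sse += accu(VM[s] % square(y - Y[s]));
      v_n += accu(VM[s]);
    }
    double v_loss = v_n > 0 ? v_sse / v_n : tr_loss;
    train_hist.push_back(tr_loss);
    val_hist.push_back(v_loss);
    if (v_loss < best_val - 1e-12) {
      best_val = v_loss;
      best = net;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (best_epoch < 0) best = net;  // never improved (e.g. diverged at once)
  return Rcpp::List::create(
      Rcpp::Named("weights") = pack(best),
      Rcpp::Named("train_loss") = train_hist,
      Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("best_epoch") = best_epoch + 1,
      Rcpp::Named("best_val_loss") = best_val,
      Rcpp::Named("diverged") = diverged);
}

// [[Rcpp::export(name = ".lstm_forward")]]
arma::vec lstm_forward(Rcpp::List weights, const arma::mat& x) {
  Net net = unpack(weights);
  if (x.n_rows == 0) return vec();
  return forward_seq(net, x.t(), nullptr);
}
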