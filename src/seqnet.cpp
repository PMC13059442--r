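// Hybrid convolutional + recurrent sequence-to-PSI network.
//
// Trunk: B blocks of (same-padded 1-D convolution -> ReLU -> max pooling),
// then a GRU scanning the downsampled positions, then one dense sigmoid
// output per head. Trained with Adam on binary cross-entropy against
// continuous PSI targets. Written directly in Armadillo: forward,
// backpropagation (including BPTT through the GRU) and the in-silico
// mutagenesis fast path live here.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct NetConfig {
  int C = 0, L = 0, B = 0, H = 0, n_heads = 1;
  std::vector<int> filters, kernel, pool;
};

static NetConfig parse_config(const Rcpp::List& cfg) {
  NetConfig c;
  c.C = Rcpp::as<int>(cfg["channels"]);
  c.L = Rcpp::as<int>(cfg["window"]);
  c.H = Rcpp::as<int>(cfg["hidden"]);
  c.n_heads = Rcpp::as<int>(cfg["n_heads"]);
  c.filters = Rcpp::as<std::vector<int>>(cfg["filters"]);
  c.kernel = Rcpp::as<std::vector<int>>(cfg["kernel"]);
  c.pool = Rcpp::as<std::vector<int>>(cfg["pool"]);
  c.B = (int)c.filters.size();
  return c;
}

struct Params {
  std::vector<mat> Wc;  // (F_b, Cin_b * K_b)
  std::vector<vec> bc;
  mat Wz, Wr, Wh, Uz, Ur, Uh;
  vec bz, br, bh;
  mat Wout;  // (n_heads, H)
  vec bout;
};

static Rcpp::List params_to_list(const Params& p) {
  Rcpp::List conv_w(p.Wc.size()), conv_b(p.bc.size());
  for (size_t i = 0; i < p.Wc.size(); ++i) {
    conv_w[i] = p.Wc[i];
    conv_b[i] = p.bc[i];
  }
  return Rcpp::List::create(
      Rcpp::Named("conv_w") = conv_w, Rcpp::Named("conv_b") = conv_b,
      Rcpp::Named("Wz") = p.Wz, Rcpp::Named("Wr") = p.Wr,
      Rcpp::Named("Wh") = p.Wh, Rcpp::Named("Uz") = p.Uz,
      Rcpp::Named("Ur") = p.Ur, Rcpp::Named("Uh") = p.Uh,
      Rcpp::Named("bz") = p.bz, Rcpp::Named("br") = p.br,
      Rcpp::Named("bh") = p.bh, Rcpp::Named("Wout") = p.Wout,
      Rcpp::Named("bout") = p.bout);
}

static Params list_to_params(const Rcpp::List& lst) {
  Params p;
  Rcpp::List conv_w = lst["conv_w"], conv_b = lst["conv_b"];
  for (int i = 0; i < conv_w.size(); ++i) {
    p.Wc.push_back(Rcpp::as<mat>(conv_w[i]));
    p.bc.push_back(Rcpp::as<vec>(conv_b[i]));
  }
  p.Wz = Rcpp::as<mat>(lst["Wz"]); p.Wr = Rcpp::as<mat>(lst["Wr"]);
  p.Wh = Rcpp::as<mat>(lst["Wh"]); p.Uz = Rcpp::as<mat>(lst["Uz"]);
  p.Ur = Rcpp::as<mat>(lst["Ur"]); p.Uh = Rcpp::as<mat>(lst["Uh"]);
  p.bz = Rcpp::as<vec>(lst["bz"]); p.br = Rcpp::as<vec>(lst["br"]);
  p.bh = Rcpp::as<vec>(lst["bh"]);
  p.Wout = Rcpp::as<mat>(lst["Wout"]);
  p.bout = Rcpp::as<vec>(lst["bout"]);
  return p;
}

static Params init_params(const NetConfig& c, std::mt19937& rng) {
  std::normal_distribution<double> gauss(0.0, 1.0);
  auto randmat = [&](int r, int cc, double sd) {
    mat m(r, cc);
    for (uword i = 0; i < m.n_elem; ++i) m(i) = gauss(rng) * sd;
    return m;
  };
  Params p;
  int cin = c.C;
  for (int b = 0; b < c.B; ++b) {
    int fan_in = cin * c.kernel[b];
    mat W = randmat(c.filters[b], fan_in, std::sqrt(2.0 / fan_in));
    if (b > 0 && c.filters[b] == cin) {
      // deeper blocks start near the identity (center tap), so the
      // detections of the first block survive a randomly initialized
      // stack; the perturbation keeps filters distinguishable
      W *= 0.1;
      int center = (c.kernel[b] / 2) * cin;
      for (int f = 0; f < c.filters[b]; ++f) W(f, center + f) += 1.0;
    }
    p.Wc.push_back(W);
    p.bc.push_back(vec(c.filters[b], fill::zeros));
    cin = c.filters[b];
  }
  int D = cin;
  double sd_in = 1.0 / std::sqrt((double)D);
  double sd_h = 1.0 / std::sqrt((double)c.H);
  p.Wz = randmat(c.H, D, sd_in); p.Wr = randmat(c.H, D, sd_in);
  p.Wh = randmat(c.H, D, sd_in);
  p.Uz = randmat(c.H, c.H, sd_h); p.Ur = randmat(c.H, c.H, sd_h);
  p.Uh = randmat(c.H, c.H, sd_h);
  p.bz = vec(c.H, fill::zeros); p.br = vec(c.H, fill::zeros);
  p.bh = vec(c.H, fill::zeros);
  p.Wout = randmat(c.n_heads, c.H, sd_h);  // nonzero: lets gradient reach
  p.bout = vec(c.n_heads, fill::zeros);    // the trunk from step one
  return p;
}

static inline mat sigmoid_m(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct BlockCache {
  mat M;               // im2col input (Cin*K, L*nb)
  mat Zrelu;           // post-ReLU activations (F, L*nb)
  Cube<uword> argmax;  // (F, Lp, nb) source column (0..P-1) of each max
  int Lin = 0, Lp = 0, Cin = 0;
};

struct GruCache {
  std::vector<mat> x, z, r, cdd, h;  // per time step (dims x: D x nb)
};

struct ForwardCache {
  std::vector<BlockCache> blocks;
  cube conv_out;  // (D, T, nb) input to the GRU
  GruCache gru;
  mat hT;          // head input: elementwise max over time of the states
  umat hargmax;    // time step attaining the max, per (unit, sample)
  vec yhat;
};

// im2col with zero padding for same-length convolution
static mat im2col(const cube& X, int K) {
  const int C = X.n_rows, L = X.n_cols, nb = X.n_slices;
  const int pad = (K - 1) / 2;
  mat M(C * K, (size_t)L * nb, fill::zeros);
  for (int j = 0; j < nb; ++j) {
    const mat& S = X.slice(j);
    for (int k = 0; k < K; ++k) {
      int src_lo = std::max(0, pad - k);
      int src_hi = std::min(L, L + pad - k);
      // window position t reads input column t + k - pad
      for (int t = src_lo; t < src_hi; ++t) {
        M.submat(k * C, (size_t)j * L + t, k * C + C - 1,
                 (size_t)j * L + t) = S.col(t + k - pad);
      }
    }
  }
  return M;
}

static void col2im_add(cube& dX, const mat& dM, int K) {
  const int C = dX.n_rows, L = dX.n_cols, nb = dX.n_slices;
  const int pad = (K - 1) / 2;
  for (int j = 0; j < nb; ++j) {
    mat& S = dX.slice(j);
    for (int k = 0; k < K; ++k) {
      int src_lo = std::max(0, pad - k);
      int src_hi = std::min(L, L + pad - k);
      for (int t = src_lo; t < src_hi; ++t) {
        S.col(t + k - pad) +=
            dM.submat(k * C, (size_t)j * L + t, k * C + C - 1,
                      (size_t)j * L + t);
      }
    }
  }
}

static vec forward(const Params& p, const NetConfig& c, const cube& X,
                   const uvec& heads, ForwardCache* cache) {
  const int nb = X.n_slices;
  cube cur = X;
  if (cache) cache->blocks.resize(c.B);
  for (int b = 0; b < c.B; ++b) {
    const int K = c.kernel[b], F = c.filters[b], P = c.pool[b];
    const int Lin = cur.n_cols, Lp = Lin / P;
    mat M = im2col(cur, K);
    mat Z = p.Wc[b] * M;
    Z.each_col() += p.bc[b];
    Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    cube pooled(F, Lp, nb);
    Cube<uword> amax(F, Lp, nb);
    for (int j = 0; j < nb; ++j) {
      for (int tp = 0; tp < Lp; ++tp) {
        size_t base = (size_t)j * Lin + (size_t)tp * P;
        vec best = Z.col(base);
        uvec arg(F, fill::zeros);
        for (int q = 1; q < P; ++q) {
          vec candv = Z.col(base + q);
          for (int f = 0; f < F; ++f) {
            if (candv(f) > best(f)) { best(f) = candv(f); arg(f) = q; }
          }
        }
        pooled.slice(j).col(tp) = best;
        amax.slice(j).col(tp) = arg;
      }
    }
    if (cache) {
      cache->blocks[b].M = std::move(M);
      cache->blocks[b].Zrelu = std::move(Z);
      cache->blocks[b].argmax = std::move(amax);
      cache->blocks[b].Lin = Lin;
      cache->blocks[b].Lp = Lp;
      cache->blocks[b].Cin = cur.n_rows;
    }
    cur = std::move(pooled);
  }
  const int T = cur.n_cols, H = c.H;
  if (cache) cache->conv_out = cur;
  mat h(H, nb, fill::zeros);
  if (cache) {
    cache->gru.x.resize(T); cache->gru.z.resize(T);
    cache->gru.r.resize(T); cache->gru.cdd.resize(T);
    cache->gru.h.resize(T);
  }
  // head input: per-unit max over time (detector pooling); ties go to
  // the earliest step
  mat hmax(H, nb);
  hmax.fill(-datum::inf);
  umat hargmax(H, nb, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat xt = cur.col_as_mat(t);  // (D, nb)
    mat z = sigmoid_m(p.Wz * xt + p.Uz * h +
                      repmat(p.bz, 1, nb));
    mat r = sigmoid_m(p.Wr * xt + p.Ur * h + repmat(p.br, 1, nb));
    mat cd = tanh(p.Wh * xt + p.Uh * (r % h) + repmat(p.bh, 1, nb));
    mat hnew = (1.0 - z) % h + z % cd;
    if (cache) {
      cache->gru.x[t] = xt; cache->gru.z[t] = z; cache->gru.r[t] = r;
      cache->gru.cdd[t] = cd; cache->gru.h[t] = hnew;
    }
    h = std::move(hnew);
    uvec upd = find(h > hmax);
    hmax.elem(upd) = h.elem(upd);
    for (uword u = 0; u < upd.n_elem; ++u) hargmax(upd(u)) = t;
  }
  vec yhat(nb);
  for (int j = 0; j < nb; ++j) {
    int hd = heads(j);
    yhat(j) = 1.0 / (1.0 + std::exp(-(dot(p.Wout.row(hd), hmax.col(j)) +
                                      p.bout(hd))));
  }
  if (cache) {
    cache->hT = hmax;
    cache->hargmax = hargmax;
    cache->yhat = yhat;
  }
  return yhat;
}

static double bce(const vec& y, const vec& yhat) {
  vec p = clamp(yhat, 1e-12, 1.0 - 1e-12);
  return as_scalar(-mean(y % log(p) + (1.0 - y) % log(1.0 - p)));
}

// gradients of mean BCE wrt all parameters, for one batch
static Params backward(const Params& p, const NetConfig& c, const cube& X,
                       const vec& y, const uvec& heads,
                       ForwardCache& fc, double* loss_out) {
  const int nb = X.n_slices, H = c.H;
  Params g;
  g.Wc.resize(c.B); g.bc.resize(c.B);
  int cin = c.C;
  for (int b = 0; b < c.B; ++b) {
    g.Wc[b] = mat(size(p.Wc[b]), fill::zeros);
    g.bc[b] = vec(size(p.bc[b]), fill::zeros);
    cin = c.filters[b];
  }
  g.Wz = mat(size(p.Wz), fill::zeros); g.Wr = mat(size(p.Wr), fill::zeros);
  g.Wh = mat(size(p.Wh), fill::zeros); g.Uz = mat(size(p.Uz), fill::zeros);
  g.Ur = mat(size(p.Ur), fill::zeros); g.Uh = mat(size(p.Uh), fill::zeros);
  g.bz = vec(H, fill::zeros); g.br = vec(H, fill::zeros);
  g.bh = vec(H, fill::zeros);
  g.Wout = mat(size(p.Wout), fill::zeros);
  g.bout = vec(size(p.bout), fill::zeros);

  if (loss_out) *loss_out = bce(y, fc.yhat);

  // output layer: d(mean BCE)/d(logit) = (yhat - y)/nb for the sigmoid+BCE;
  // the head reads the per-unit max over time, so its gradient is routed
  // to the time step that attained each unit's max
  const int T = (int)fc.gru.x.size();
  mat dh(H, nb, fill::zeros);
  mat dhead(H, nb, fill::zeros);
  for (int j = 0; j < nb; ++j) {
    int hd = heads(j);
    double dlogit = (fc.yhat(j) - y(j)) / nb;
    g.Wout.row(hd) += dlogit * fc.hT.col(j).t();
    g.bout(hd) += dlogit;
    dhead.col(j) = p.Wout.row(hd).t() * dlogit;
  }

  // BPTT through the GRU
  cube dconv(fc.conv_out.n_rows, T, nb, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    dh += dhead % conv_to<mat>::from(fc.hargmax == (uword)t);
    const mat& z = fc.gru.z[t];
    const mat& r = fc.gru.r[t];
    const mat& cd = fc.gru.cdd[t];
    const mat& xt = fc.gru.x[t];
    mat h_prev = (t == 0) ? mat(H, nb, fill::zeros) : fc.gru.h[t - 1];
    mat dz = dh % (cd - h_prev);
    mat dcd = dh % z;
    mat da_z = dz % z % (1.0 - z);
    mat da_c = dcd % (1.0 - cd % cd);
    mat drh = p.Uh.t() * da_c;            // gradient wrt (r % h_prev)
    mat dr = drh % h_prev;
    mat da_r = dr % r % (1.0 - r);
    g.Wz += da_z * xt.t(); g.Uz += da_z * h_prev.t();
    g.bz += sum(da_z, 1);
    g.Wr += da_r * xt.t(); g.Ur += da_r * h_prev.t();
    g.br += sum(da_r, 1);
    g.Wh += da_c * xt.t(); g.Uh += da_c * (r % h_prev).t();
    g.bh += sum(da_c, 1);
    mat dxt = p.Wz.t() * da_z + p.Wr.t() * da_r + p.Wh.t() * da_c;
    for (int j = 0; j < nb; ++j) dconv.slice(j).col(t) = dxt.col(j);
    dh = dh % (1.0 - z) + p.Uz.t() * da_z + p.Ur.t() * da_r + drh % r;
  }

  // conv blocks in reverse
  cube dcur = std::move(dconv);
  for (int b = c.B - 1; b >= 0; --b) {
    const BlockCache& bc_ = fc.blocks[b];
    const int K = c.kernel[b], F = c.filters[b], P = c.pool[b];
    const int Lin = bc_.Lin, Lp = bc_.Lp;
    // unpool into post-ReLU position grid
    mat dZ(F, (size_t)Lin * nb, fill::zeros);
    for (int j = 0; j < nb; ++j) {
      for (int tp = 0; tp < Lp; ++tp) {
        size_t base = (size_t)j * Lin + (size_t)tp * P;
        for (int f = 0; f < F; ++f) {
          dZ(f, base + bc_.argmax(f, tp, j)) += dcur.slice(j)(f, tp);
        }
      }
    }
    // ReLU gate
    dZ.elem(find(bc_.Zrelu == 0.0)).zeros();
    g.Wc[b] = dZ * bc_.M.t();
    g.bc[b] = sum(dZ, 1);
    if (b > 0) {
      mat dM = p.Wc[b].t() * dZ;
      cube dX(bc_.Cin, Lin, nb, fill::zeros);
      col2im_add(dX, dM, K);
      dcur = std::move(dX);
    }
  }
  return g;
}

// ---- Adam ----------------------------------------------------------------

struct Adam {
  Params m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  explicit Adam(const Params& p) {
    auto zl = [](const Params& q) {
      Params z = q;
      for (auto& w : z.Wc) w.zeros();
      for (auto& w : z.bc) w.zeros();
      z.Wz.zeros(); z.Wr.zeros(); z.Wh.zeros();
      z.Uz.zeros(); z.Ur.zeros(); z.Uh.zeros();
      z.bz.zeros(); z.br.zeros(); z.bh.zeros();
      z.Wout.zeros(); z.bout.zeros();
      return z;
    };
    m = zl(p); v = zl(p);
  }
  double wd = 0.0;
  template <typename T>
  void upd1(T& w, T& mw, T& vw, const T& gw, double lr) {
    mw = b1 * mw + (1.0 - b1) * gw;
    vw = b2 * vw + (1.0 - b2) * (gw % gw);
    double c1 = 1.0 - std::pow(b1, (double)step);
    double c2 = 1.0 - std::pow(b2, (double)step);
    w -= lr * (mw / c1) / (sqrt(vw / c2) + eps) + lr * wd * w;
  }
  void update(Params& p, const Params& g, double lr) {
    ++step;
    for (size_t i = 0; i < p.Wc.size(); ++i) {
      upd1(p.Wc[i], m.Wc[i], v.Wc[i], g.Wc[i], lr);
      upd1(p.bc[i], m.bc[i], v.bc[i], g.bc[i], lr);
    }
    upd1(p.Wz, m.Wz, v.Wz, g.Wz, lr); upd1(p.Wr, m.Wr, v.Wr, g.Wr, lr);
    upd1(p.Wh, m.Wh, v.Wh, g.Wh, lr); upd1(p.Uz, m.Uz, v.Uz, g.Uz, lr);
    upd1(p.Ur, m.Ur, v.Ur, g.Ur, lr); upd1(p.Uh, m.Uh, v.Uh, g.Uh, lr);
    upd1(p.bz, m.bz, v.bz, g.bz, lr); upd1(p.br, m.br, v.br, g.br, lr);
    upd1(p.bh, m.bh, v.bh, g.bh, lr);
    upd1(p.Wout, m.Wout, v.Wout, g.Wout, lr);
    upd1(p.bout, m.bout, v.bout, g.bout, lr);
  }
};

static vec predict_all(const Params& p, const NetConfig& c, const cube& X,
                       const uvec& heads, int batch = 64) {
  const int n = X.n_slices;
  vec out(n);
  for (int s = 0; s < n; s += batch) {
    int e = std::min(n, s + batch);
    cube Xb = X.slices(s, e - 1);
    uvec hb = heads.subvec(s, e - 1);
    out.subvec(s, e - 1) = forward(p, c, Xb, hb, nullptr);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_seq_init(Rcpp::List config, int seed) {
  NetConfig c = parse_config(config);
  std::mt19937 rng((unsigned)seed);
  return params_to_list(init_params(c, rng));
}

// [[Rcpp::export]]
Rcpp::List cpp_seq_train(arma::cube X, arma::vec y,
                         arma::uvec heads, Rcpp::List config,
                         arma::uvec train_idx, arma::uvec val_idx,
                         double lr, double lr_decay, int batch_size,
                         int epochs, int patience, int seed,
                         double weight_decay, int augment_shift,
                         bool verbose) {
  NetConfig c = parse_config(config);
  std::mt19937 rng((unsigned)seed);
  Params p = init_params(c, rng);
  Adam opt(p);
  opt.wd = weight_decay;
  std::uniform_int_distribution<int> shift_d(-augment_shift, augment_shift);
  const int ntr = train_idx.n_elem;
  Params best = p;
  double best_loss = datum::inf;
  int wait = 0, best_epoch = 0;
  std::vector<double> hist;
  std::vector<uword> order(train_idx.begin(), train_idx.end());
  for (int epoch = 1; epoch <= epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int s = 0; s < ntr; s += batch_size) {
      int e = std::min(ntr, s + batch_size);
      uvec idx(e - s);
      for (int i = s; i < e; ++i) idx(i - s) = order[i];
      cube Xb(c.C, c.L, idx.n_elem);
      for (uword j = 0; j < idx.n_elem; ++j) {
        Xb.slice(j) = X.slice(idx(j));
        if (augment_shift > 0) {
          // random shift along the window (zero-filled edges): breaks
          // position-specific memorization, keeps motif content
          int sh = shift_d(rng);
          if (sh != 0) {
            mat& S = Xb.slice(j);
            mat out(S.n_rows, S.n_cols, fill::zeros);
            if (sh > 0) {
              out.cols(sh, S.n_cols - 1) = S.cols(0, S.n_cols - 1 - sh);
            } else {
              out.cols(0, S.n_cols - 1 + sh) = S.cols(-sh, S.n_cols - 1);
            }
            S = out;
          }
        }
      }
      vec yb = y.elem(idx);
      uvec hb = heads.elem(idx);
      ForwardCache fc;
      forward(p, c, Xb, hb, &fc);
      double loss;
      Params g = backward(p, c, Xb, yb, hb, fc, &loss);
      opt.update(p, g, lr);
    }
    lr *= lr_decay;
    double mon;
    if (val_idx.n_elem > 0) {
      cube Xv(c.C, c.L, val_idx.n_elem);
      for (uword j = 0; j < val_idx.n_elem; ++j)
        Xv.slice(j) = X.slice(val_idx(j));
      mon = bce(y.elem(val_idx),
                predict_all(p, c, Xv, heads.elem(val_idx)));
    } else {
      uvec ti = conv_to<uvec>::from(order);
      cube Xt(c.C, c.L, ti.n_elem);
      for (uword j = 0; j < ti.n_elem; ++j) Xt.slice(j) = X.slice(ti(j));
      mon = bce(y.elem(ti), predict_all(p, c, Xt, heads.elem(ti)));
    }
    hist.push_back(mon);
    if (verbose) Rcpp::Rcout << "epoch " << epoch << " val " << mon << "\n";
    if (mon < best_loss - 1e-5) {
      best_loss = mon; best = p; wait = 0; best_epoch = epoch;
    } else if (++wait >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  Rcpp::List out = params_to_list(best);
  out.attr("history") = hist;
  out.attr("best_epoch") = best_epoch;
  out.attr("val_loss") = best_loss;
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_seq_predict(Rcpp::List params, arma::cube X,
                          arma::uvec heads, Rcpp::List config) {
  NetConfig c = parse_config(config);
  Params p = list_to_params(params);
  return predict_all(p, c, X, heads);
}

// loss and gradients on one batch (for finite-difference checks)
// [[Rcpp::export]]
Rcpp::List cpp_seq_loss_grad(Rcpp::List params, arma::cube X, arma::vec y,
                             arma::uvec heads, Rcpp::List config) {
  NetConfig c = parse_config(config);
  Params p = list_to_params(params);
  ForwardCache fc;
  forward(p, c, X, heads, &fc);
  double loss;
  Params g = backward(p, c, X, y, heads, fc, &loss);
  Rcpp::List out = params_to_list(g);
  out.attr("loss") = loss;
  return out;
}

// [[Rcpp::export]]
double cpp_seq_loss(Rcpp::List params, arma::cube X, arma::vec y,
                    arma::uvec heads, Rcpp::List config) {
  NetConfig c = parse_config(config);
  Params p = list_to_params(params);
  vec yhat = forward(p, c, X, heads, nullptr);
  return bce(y, yhat);
}

// Saturation mutagenesis: predictions with every nucleotide substituted at
// every position. Sequence one-hot lives in channel rows 0..3; all other
// channels are held fixed. Returns an (L x 4) matrix of predictions.
// [[Rcpp::export]]
arma::mat cpp_seq_ism(Rcpp::List params, arma::mat window, int head,
                      Rcpp::List config, int chunk) {
  NetConfig c = parse_config(config);
  Params p = list_to_params(params);
  const int L = c.L;
  mat out(L, 4);
  int per = std::max(1, chunk / 4);
  for (int p0 = 0; p0 < L; p0 += per) {
    int p1 = std::min(L, p0 + per);
    int npos = p1 - p0;
    cube Xb(c.C, L, npos * 4);
    uvec hb(npos * 4, fill::zeros);
    hb.fill((uword)head);
    for (int i = 0; i < npos; ++i) {
      for (int n = 0; n < 4; ++n) {
        mat w = window;
        w.submat(0, p0 + i, 3, p0 + i).zeros();
        w(n, p0 + i) = 1.0;
        Xb.slice(i * 4 + n) = w;
      }
    }
    vec pr = predict_all(p, c, Xb, hb);
    for (int i = 0; i < npos; ++i)
      for (int n = 0; n < 4; ++n) out(p0 + i, n) = pr(i * 4 + n);
  }
  return out;
}
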