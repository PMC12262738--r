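// Bidirectional stacked LSTM slice labeler: forward pass, loss
// (binary cross-entropy + soft-Jaccard), and full backpropagation
// through time. The network maps a 1-D pixel-count sequence to a
// per-slice aneurysm probability via stacked bidirectional LSTM layers
// and a small fully connected stack shared across timesteps, ending in
// a sigmoid.
//
// Parameter layout (shared with the R side, see lstm.R):
//   for layer l = 1..L, direction in {forward, backward}:
//     Wx (d_l x 4h), Wh (h x 4h), b (1 x 4h)      gate order [i f g o]
//   then for each fully connected layer: W (in x out), b (1 x out);
//   the last FC layer has out = 1.
//
// All randomness (init, batching) lives on the R side; this file is
// deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmDirCache {
  cube I, F, G, O, C, Tc, H; // B x h x T each
};

// run one LSTM direction over the layer input (B x d x T)
static void run_direction(const cube& in, const mat& Wx, const mat& Wh,
                          const rowvec& b, bool reverse, LstmDirCache& cc) {
  const uword B = in.n_rows, T = in.n_slices, h = Wh.n_rows;
  cc.I.set_size(B, h, T); cc.F.set_size(B, h, T); cc.G.set_size(B, h, T);
  cc.O.set_size(B, h, T); cc.C.set_size(B, h, T); cc.Tc.set_size(B, h, T);
  cc.H.set_size(B, h, T);
  mat hprev(B, h, fill::zeros), cprev(B, h, fill::zeros);
  for (uword step = 0; step < T; ++step) {
    uword t = reverse ? (T - 1 - step) : step;
    mat A = in.slice(t) * Wx + hprev * Wh;
    A.each_row() += b;
    mat i = sigmoid(A.cols(0, h - 1));
    mat f = sigmoid(A.cols(h, 2 * h - 1));
    mat g = tanh(A.cols(2 * h, 3 * h - 1));
    mat o = sigmoid(A.cols(3 * h, 4 * h - 1));
    mat c = f % cprev + i % g;
    mat tc = tanh(c);
    mat hn = o % tc;
    cc.I.slice(t) = i; cc.F.slice(t) = f; cc.G.slice(t) = g;
    cc.O.slice(t) = o; cc.C.slice(t) = c; cc.Tc.slice(t) = tc;
    cc.H.slice(t) = hn;
    hprev = hn; cprev = c;
  }
}

// backward pass for one direction; fills gWx/gWh/gb and adds dIn
static void back_direction(const cube& in, const cube& dH, const mat& Wx,
                           const mat& Wh, bool reverse,
                           const LstmDirCache& cc, mat& gWx, mat& gWh,
                           rowvec& gb, cube& dIn) {
  const uword B = in.n_rows, T = in.n_slices, h = Wh.n_rows;
  gWx.zeros(Wx.n_rows, Wx.n_cols);
  gWh.zeros(Wh.n_rows, Wh.n_cols);
  gb.zeros(4 * h);
  mat dh_next(B, h, fill::zeros), dc(B, h, fill::zeros);
  for (uword step = 0; step < T; ++step) {
    // reverse of the forward time order
    uword t = reverse ? step : (T - 1 - step);
    bool first = (step == T - 1); // first step of the forward order
    mat hprev(B, h, fill::zeros), cprev(B, h, fill::zeros);
    if (!first) {
      uword tp = reverse ? (t + 1) : (t - 1);
      hprev = cc.H.slice(tp);
      cprev = cc.C.slice(tp);
    }
    mat dh = dH.slice(t) + dh_next;
    const mat& i = cc.I.slice(t); const mat& f = cc.F.slice(t);
    const mat& g = cc.G.slice(t); const mat& o = cc.O.slice(t);
    const mat& tc = cc.Tc.slice(t);
    mat do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    mat di = dc % g;
    mat df = dc % cprev;
    mat dg = dc % i;
    mat dA(B, 4 * h);
    dA.cols(0, h - 1)         = di % i % (1.0 - i);
    dA.cols(h, 2 * h - 1)     = df % f % (1.0 - f);
    dA.cols(2 * h, 3 * h - 1) = dg % (1.0 - g % g);
    dA.cols(3 * h, 4 * h - 1) = do_ % o % (1.0 - o);
    gWx += in.slice(t).t() * dA;
    gWh += hprev.t() * dA;
    gb += sum(dA, 0);
    dIn.slice(t) += dA * Wx.t();
    dh_next = dA * Wh.t();
    dc = dc % f;
  }
}

// Forward (and optionally backward) pass over a batch.
// X, Y: B x T. Returns loss components, probabilities (B x T) and, when
// want_grad, gradients in the same order as `params`.
// [[Rcpp::export(name = ".lstm_core")]]
Rcpp::List lstm_core(const arma::mat& X, const arma::mat& Y,
                     Rcpp::List params, int n_layers, int hidden,
                     double jaccard_weight, bool want_grad,
                     double clip_eps = 1e-7) {
  const uword B = X.n_rows, T = X.n_cols, h = (uword)hidden;
  const uword L = (uword)n_layers;
  const uword n_lstm_par = L * 2 * 3;
  const uword n_fc = (params.size() - n_lstm_par) / 2;

  // ---------- forward: LSTM stack ----------
  std::vector<LstmDirCache> caches(2 * L);
  std::vector<cube> inputs(L + 1); // layer inputs; inputs[L] = top output
  inputs[0].set_size(B, 1, T);
  for (uword t = 0; t < T; ++t) inputs[0].slice(t) = X.col(t);

  for (uword l = 0; l < L; ++l) {
    cube out(B, 2 * h, T);
    for (int dir = 0; dir < 2; ++dir) {
      uword base = (l * 2 + dir) * 3;
      mat Wx = Rcpp::as<mat>(params[base]);
      mat Wh = Rcpp::as<mat>(params[base + 1]);
      rowvec b = Rcpp::as<mat>(params[base + 2]).row(0);
      LstmDirCache& cc = caches[l * 2 + dir];
      run_direction(inputs[l], Wx, Wh, b, dir == 1, cc);
      for (uword t = 0; t < T; ++t)
        out.slice(t).cols(dir * h, (dir + 1) * h - 1) = cc.H.slice(t);
    }
    inputs[l + 1] = out;
  }

  // ---------- forward: shared FC head ----------
  mat Z(B * T, 2 * h);
  for (uword t = 0; t < T; ++t)
    Z.rows(t * B, t * B + B - 1) = inputs[L].slice(t);
  std::vector<mat> fc_acts(n_fc + 1);
  fc_acts[0] = Z;
  for (uword j = 0; j < n_fc; ++j) {
    mat W = Rcpp::as<mat>(params[n_lstm_par + 2 * j]);
    rowvec b = Rcpp::as<mat>(params[n_lstm_par + 2 * j + 1]).row(0);
    mat A = fc_acts[j] * W;
    A.each_row() += b;
    if (j + 1 < n_fc) A = clamp(A, 0.0, datum::inf); // ReLU
    fc_acts[j + 1] = A;
  }
  vec logits = fc_acts[n_fc].col(0);
  vec p = 1.0 / (1.0 + exp(-logits));

  // ---------- loss ----------
  vec y = vectorise(Y); // column-major: matches Z row ordering
  vec pc = clamp(p, clip_eps, 1.0 - clip_eps);
  double bce = -mean(y % log(pc) + (1.0 - y) % log(1.0 - pc));

  mat P(p.memptr(), B, T); // same layout as Y
  vec inter = sum(P % Y, 1);
  vec uni = sum(P + Y - P % Y, 1);
  vec J(B);
  for (uword bb = 0; bb < B; ++bb)
    J(bb) = (uni(bb) > 0) ? inter(bb) / uni(bb) : 1.0;
  double jac = mean(1.0 - J);
  double loss = bce + jaccard_weight * jac;

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("bce") = bce,
      Rcpp::Named("jaccard") = jac,
      Rcpp::Named("probs") = Rcpp::wrap(P));
  if (!want_grad) return out;

  // ---------- backward: loss -> logits ----------
  const double N = (double)(B * T);
  vec dlogit = (p - y) / N; // BCE part
  if (jaccard_weight != 0) {
    mat dJdP(B, T);
    for (uword bb = 0; bb < B; ++bb) {
      if (uni(bb) > 0) {
        double u2 = uni(bb) * uni(bb);
        for (uword t = 0; t < T; ++t) {
          double yy = Y(bb, t);
          dJdP(bb, t) = (yy * uni(bb) - inter(bb) * (1.0 - yy)) / u2;
        }
      } else {
        dJdP.row(bb).zeros();
      }
    }
    vec djac = vectorise(dJdP);
    dlogit += jaccard_weight * (-djac / (double)B) % (p % (1.0 - p));
  }

  // ---------- backward: FC head ----------
  std::vector<mat> gW_fc(n_fc);
  std::vector<rowvec> gb_fc(n_fc);
  mat dA = mat(dlogit);
  for (uword j = n_fc; j-- > 0;) {
    gW_fc[j] = fc_acts[j].t() * dA;
    gb_fc[j] = sum(dA, 0);
    mat W = Rcpp::as<mat>(params[n_lstm_par + 2 * j]);
    mat dprev = dA * W.t();
    // fc_acts[j] (j >= 1) is post-ReLU, so mask where it was clipped
    if (j > 0) dprev %= conv_to<mat>::from(fc_acts[j] > 0.0);
    dA = dprev;
  }
  // dA is now the gradient w.r.t. Z (B*T x 2h)
  cube dTop(B, 2 * h, T);
  for (uword t = 0; t < T; ++t)
    dTop.slice(t) = dA.rows(t * B, t * B + B - 1);

  // ---------- backward: LSTM stack ----------
  std::vector<mat> gWx(2 * L), gWh(2 * L);
  std::vector<rowvec> gb(2 * L);
  cube dOut = dTop;
  for (uword l = L; l-- > 0;) {
    cube dIn(B, inputs[l].n_cols, T, fill::zeros);
    for (int dir = 0; dir < 2; ++dir) {
      uword base = (l * 2 + dir) * 3;
      mat Wx = Rcpp::as<mat>(params[base]);
      mat Wh = Rcpp::as<mat>(params[base + 1]);
      cube dH(B, h, T);
      for (uword t = 0; t < T; ++t)
        dH.slice(t) = dOut.slice(t).cols(dir * h, (dir + 1) * h - 1);
      back_direction(inputs[l], dH, Wx, Wh, dir == 1, caches[l * 2 + dir],
                     gWx[l * 2 + dir], gWh[l * 2 + dir], gb[l * 2 + dir],
                     dIn);
    }
    dOut = dIn;
  }

  Rcpp::List grads(params.size());
  for (uword k = 0; k < 2 * L; ++k) {
    grads[3 * k] = Rcpp::wrap(gWx[k]);
    grads[3 * k + 1] = Rcpp::wrap(gWh[k]);
    grads[3 * k + 2] = Rcpp::wrap(mat(gb[k]));
  }
  for (uword j = 0; j < n_fc; ++j) {
    grads[n_lstm_par + 2 * j] = Rcpp::wrap(gW_fc[j]);
    grads[n_lstm_par + 2 * j + 1] = Rcpp::wrap(mat(gb_fc[j]));
  }
  out["grads"] = grads;
  return out;
}
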