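// Stacked-LSTM sequence-to-sequence autoencoder core.
//
// Encoder: token sequence -> stacked LSTM layers -> concatenated final
// (hidden, cell) states -> dense tanh bottleneck = latent vector.
// Decoder: latent -> 2*L dense tanh heads giving initial (h, c) per layer ->
// stacked LSTM fed the previous token (teacher-forced in training, greedy at
// inference) -> dense softmax over the token vocabulary.
// Property heads: latent -> ReLU MLP stacks -> scalar targets (MSE).
//
// The encoder carry-masks past each sequence's true length, so trailing pad
// steps are exact no-ops and encodings do not depend on padding width or
// batch composition.  All gradients are computed analytically (BPTT) and are
// verified against numerical differentiation in the test suite.
//
// Convention: every parameter is an R matrix (biases are 1 x n); token
// matrices arrive 1-based from R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
using namespace Rcpp;

namespace {

typedef std::map<std::string, arma::mat> GradMap;

struct Dims {
  int L, U, V, D, P;
  bool bottleneck_all;
  std::vector<int> widths;  // property-head widths, last entry 1
  int start, end, pad;      // 0-based special token indices
};

Dims read_dims(const List& dims) {
  Dims d;
  d.L = as<int>(dims["L"]);
  d.U = as<int>(dims["U"]);
  d.V = as<int>(dims["V"]);
  d.D = as<int>(dims["D"]);
  d.P = as<int>(dims["P"]);
  d.bottleneck_all = as<bool>(dims["bottleneck_all"]);
  d.widths = as<std::vector<int>>(dims["widths"]);
  d.start = as<int>(dims["start"]) - 1;
  d.end = as<int>(dims["end"]) - 1;
  d.pad = as<int>(dims["pad"]) - 1;
  return d;
}

arma::mat getm(const List& p, const std::string& name) {
  return as<arma::mat>(p[name]);
}

arma::rowvec getb(const List& p, const std::string& name) {
  return arma::rowvec(as<arma::mat>(p[name]).row(0));
}

std::string nm(const char* stem, int i) {
  return std::string(stem) + std::to_string(i);
}
std::string nm2(const char* stem, int p, int k) {
  return std::string(stem) + std::to_string(p) + "_" + std::to_string(k);
}

List gradmap_to_list(const GradMap& g) {
  List out(g.size());
  CharacterVector names(g.size());
  int i = 0;
  for (GradMap::const_iterator it = g.begin(); it != g.end(); ++it, ++i) {
    out[i] = wrap(it->second);
    names[i] = it->first;
  }
  out.attr("names") = names;
  return out;
}

inline arma::mat sigm(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Per-layer unrolled cache.  Slice t of c/h is the state AFTER step t
// (slice 0 = initial state); gates slice t-1 holds [i f g o] of step t.
struct LstmCache {
  arma::cube gates;  // B x 4U x T
  arma::cube c, h;   // B x U x (T+1)
  arma::mat xall;    // (B*T) x in, stacked inputs (layers above the first)
};

// One stacked-LSTM forward pass.  Layer 0 input is the token's one-hot,
// realised as a row lookup of W; higher layers read the h cube below.
// mask: B x T (1 while t <= true length, 0 after); empty => no masking.
void lstm_stack_forward(const List& params, const char* prefix, const Dims& d,
                        const arma::imat& tok, const arma::mat& mask,
                        const arma::mat& h0, const arma::mat& c0,
                        std::vector<LstmCache>& caches,
                        std::vector<arma::mat>& Ws, std::vector<arma::mat>& Us,
                        std::vector<arma::rowvec>& bs) {
  const int B = tok.n_rows, T = tok.n_cols;
  const bool masked = mask.n_elem > 0;
  caches.resize(d.L);
  Ws.resize(d.L); Us.resize(d.L); bs.resize(d.L);
  for (int l = 0; l < d.L; ++l) {
    Ws[l] = getm(params, nm(prefix, l + 1) + "_W");
    Us[l] = getm(params, nm(prefix, l + 1) + "_U");
    bs[l] = getb(params, nm(prefix, l + 1) + "_b");
    LstmCache& cc = caches[l];
    cc.gates.set_size(B, 4 * d.U, T);
    cc.c.set_size(B, d.U, T + 1);
    cc.h.set_size(B, d.U, T + 1);
    if (h0.n_elem > 0) {
      cc.h.slice(0) = h0.cols(l * d.U, (l + 1) * d.U - 1);
      cc.c.slice(0) = c0.cols(l * d.U, (l + 1) * d.U - 1);
    } else {
      cc.h.slice(0).zeros();
      cc.c.slice(0).zeros();
    }
    // input projection for all timesteps in one multiply (layer 0 is a
    // one-hot row lookup instead)
    arma::mat a_in;
    if (l == 0) {
      a_in.set_size(B * T, 4 * d.U);
      for (int t = 0; t < T; ++t)
        for (int b = 0; b < B; ++b)
          a_in.row(t * B + b) = Ws[l].row(tok(b, t));
    } else {
      cc.xall.set_size(B * T, d.U);
      for (int t = 0; t < T; ++t)
        cc.xall.rows(t * B, (t + 1) * B - 1) = caches[l - 1].h.slice(t + 1);
      a_in = cc.xall * Ws[l];
    }
    for (int t = 0; t < T; ++t) {
      arma::mat a = a_in.rows(t * B, (t + 1) * B - 1);
      a += cc.h.slice(t) * Us[l];
      a.each_row() += bs[l];
      arma::mat gi = sigm(a.cols(0, d.U - 1));
      arma::mat gf = sigm(a.cols(d.U, 2 * d.U - 1));
      arma::mat gg = arma::tanh(a.cols(2 * d.U, 3 * d.U - 1));
      arma::mat go = sigm(a.cols(3 * d.U, 4 * d.U - 1));
      cc.gates.slice(t).cols(0, d.U - 1) = gi;
      cc.gates.slice(t).cols(d.U, 2 * d.U - 1) = gf;
      cc.gates.slice(t).cols(2 * d.U, 3 * d.U - 1) = gg;
      cc.gates.slice(t).cols(3 * d.U, 4 * d.U - 1) = go;
      arma::mat cnew = gf % cc.c.slice(t) + gi % gg;
      arma::mat hnew = go % arma::tanh(cnew);
      if (masked) {
        arma::vec m = mask.col(t);
        cc.c.slice(t + 1) = cnew.each_col() % m +
                            cc.c.slice(t).each_col() % (1.0 - m);
        cc.h.slice(t + 1) = hnew.each_col() % m +
                            cc.h.slice(t).each_col() % (1.0 - m);
      } else {
        cc.c.slice(t + 1) = cnew;
        cc.h.slice(t + 1) = hnew;
      }
    }
  }
}

// Backward through a stacked LSTM.  dh_top: B x U x T gradient w.r.t. the
// top layer's h at every step; dh_fin/dc_fin: extra gradient injected into
// every layer's final state (encoder bottleneck), may be empty.  Fills
// parameter gradients into `grads`; optionally returns gradients w.r.t. the
// initial states (B x L*U) through dh0/dc0.
void lstm_stack_backward(GradMap& grads, const char* prefix, const Dims& d,
                         const arma::imat& tok, const arma::mat& mask,
                         const std::vector<LstmCache>& caches,
                         const std::vector<arma::mat>& Ws,
                         const std::vector<arma::mat>& Us,
                         const arma::cube& dh_top,
                         const arma::mat& dh_fin, const arma::mat& dc_fin,
                         arma::mat* dh0, arma::mat* dc0) {
  const int B = tok.n_rows, T = tok.n_cols;
  const bool masked = mask.n_elem > 0;
  if (dh0) { dh0->set_size(B, d.L * d.U); dc0->set_size(B, d.L * d.U); }
  arma::cube dh_above = dh_top;  // dx of the layer above, per step
  for (int l = d.L - 1; l >= 0; --l) {
    const LstmCache& cc = caches[l];
    arma::mat dW(arma::size(Ws[l]), arma::fill::zeros);
    arma::rowvec db(4 * d.U, arma::fill::zeros);
    arma::mat da_all(B * T, 4 * d.U);  // per-step dA, batched for the GEMMs
    arma::cube dx;
    if (l > 0) dx.zeros(B, d.U, T);
    arma::mat dh_next(B, d.U, arma::fill::zeros);
    arma::mat dc_next(B, d.U, arma::fill::zeros);
    if (dh_fin.n_elem > 0) {
      dh_next = dh_fin.cols(l * d.U, (l + 1) * d.U - 1);
      dc_next = dc_fin.cols(l * d.U, (l + 1) * d.U - 1);
    }
    for (int t = T - 1; t >= 0; --t) {
      arma::mat dh_tot = dh_next + dh_above.slice(t);
      arma::mat dc_tot = dc_next;
      arma::mat dh_t, dc_t, carry_h, carry_c;
      if (masked) {
        arma::vec m = mask.col(t);
        dh_t = dh_tot.each_col() % m;
        dc_t = dc_tot.each_col() % m;
        carry_h = dh_tot.each_col() % (1.0 - m);
        carry_c = dc_tot.each_col() % (1.0 - m);
      } else {
        dh_t = dh_tot; dc_t = dc_tot;
      }
      arma::mat gi = cc.gates.slice(t).cols(0, d.U - 1);
      arma::mat gf = cc.gates.slice(t).cols(d.U, 2 * d.U - 1);
      arma::mat gg = cc.gates.slice(t).cols(2 * d.U, 3 * d.U - 1);
      arma::mat go = cc.gates.slice(t).cols(3 * d.U, 4 * d.U - 1);
      // On unmasked rows the candidate state equals the stored blend; on
      // masked rows dh_t/dc_t are zero, so recomputing tanh(c~) is exact.
      arma::mat tc = arma::tanh(gf % cc.c.slice(t) + gi % gg);
      arma::mat dct = dc_t + dh_t % go % (1.0 - tc % tc);
      arma::mat dA(B, 4 * d.U);
      dA.cols(0, d.U - 1) = (dct % gg) % gi % (1.0 - gi);
      dA.cols(d.U, 2 * d.U - 1) = (dct % cc.c.slice(t)) % gf % (1.0 - gf);
      dA.cols(2 * d.U, 3 * d.U - 1) = (dct % gi) % (1.0 - gg % gg);
      dA.cols(3 * d.U, 4 * d.U - 1) = (dh_t % tc) % go % (1.0 - go);
      da_all.rows(t * B, (t + 1) * B - 1) = dA;
      db += arma::sum(dA, 0);
      dh_next = dA * Us[l].t();
      dc_next = dct % gf;
      if (masked) { dh_next += carry_h; dc_next += carry_c; }
    }
    // batched parameter/input gradients over all timesteps
    arma::mat hprev(B * T, d.U);
    for (int t = 0; t < T; ++t)
      hprev.rows(t * B, (t + 1) * B - 1) = cc.h.slice(t);
    arma::mat dU = hprev.t() * da_all;
    if (l == 0) {
      for (int t = 0; t < T; ++t)
        for (int b = 0; b < B; ++b)
          dW.row(tok(b, t)) += da_all.row(t * B + b);
    } else {
      dW = cc.xall.t() * da_all;
      arma::mat dx_all = da_all * Ws[l].t();
      for (int t = 0; t < T; ++t)
        dx.slice(t) = dx_all.rows(t * B, (t + 1) * B - 1);
    }
    grads[nm(prefix, l + 1) + "_W"] = dW;
    grads[nm(prefix, l + 1) + "_U"] = dU;
    grads[nm(prefix, l + 1) + "_b"] = arma::mat(db);
    if (dh0) {
      dh0->cols(l * d.U, (l + 1) * d.U - 1) = dh_next;
      dc0->cols(l * d.U, (l + 1) * d.U - 1) = dc_next;
    }
    if (l > 0) dh_above = dx;
  }
}

struct EncoderState {
  std::vector<LstmCache> caches;
  std::vector<arma::mat> Ws, Us;
  std::vector<arma::rowvec> bs;
  arma::mat mask;     // B x T
  arma::mat concat;   // B x (2*L*U or 2*U)
  arma::mat latent;   // B x D (tanh output, pre-noise)
};

void encoder_forward(const List& params, const Dims& d, const arma::imat& tok,
                     const arma::ivec& len, EncoderState& st) {
  const int B = tok.n_rows, T = tok.n_cols;
  st.mask.set_size(B, T);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) st.mask(b, t) = (t < len(b)) ? 1.0 : 0.0;
  lstm_stack_forward(params, "enc", d, tok, st.mask, arma::mat(), arma::mat(),
                     st.caches, st.Ws, st.Us, st.bs);
  const int nl = d.bottleneck_all ? d.L : 1;
  st.concat.set_size(B, 2 * nl * d.U);
  for (int k = 0; k < nl; ++k) {
    int l = d.bottleneck_all ? k : d.L - 1;
    st.concat.cols(2 * k * d.U, (2 * k + 1) * d.U - 1) =
        st.caches[l].h.slice(T);
    st.concat.cols((2 * k + 1) * d.U, (2 * k + 2) * d.U - 1) =
        st.caches[l].c.slice(T);
  }
  arma::mat bott_W = getm(params, "bott_W");
  arma::rowvec bott_b = getb(params, "bott_b");
  arma::mat pre = st.concat * bott_W;
  pre.each_row() += bott_b;
  st.latent = arma::tanh(pre);
}

// Decoder initial states; init head 2l+1 gives h of layer l+1, head 2l+2
// its c (1-based head numbering).
void decoder_init(const List& params, const Dims& d, const arma::mat& z,
                  arma::mat& h0, arma::mat& c0) {
  const int B = z.n_rows;
  h0.set_size(B, d.L * d.U);
  c0.set_size(B, d.L * d.U);
  for (int l = 0; l < d.L; ++l) {
    arma::mat Wh = getm(params, nm("init_W", 2 * l + 1));
    arma::rowvec bh = getb(params, nm("init_b", 2 * l + 1));
    arma::mat Wc = getm(params, nm("init_W", 2 * l + 2));
    arma::rowvec bc = getb(params, nm("init_b", 2 * l + 2));
    arma::mat ph = z * Wh;
    ph.each_row() += bh;
    arma::mat pc = z * Wc;
    pc.each_row() += bc;
    h0.cols(l * d.U, (l + 1) * d.U - 1) = arma::tanh(ph);
    c0.cols(l * d.U, (l + 1) * d.U - 1) = arma::tanh(pc);
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_ae_encode(Rcpp::List params, Rcpp::IntegerMatrix enc_tok,
                                  Rcpp::IntegerVector enc_len, Rcpp::List dims) {
  Dims d = read_dims(dims);
  arma::imat tok = as<arma::imat>(enc_tok) - 1;
  arma::ivec len = as<arma::ivec>(enc_len);
  EncoderState st;
  encoder_forward(params, d, tok, len, st);
  return wrap(st.latent);
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_ae_decode(Rcpp::List params, Rcpp::NumericMatrix latent,
                                  int max_steps, Rcpp::List dims) {
  Dims d = read_dims(dims);
  arma::mat z = as<arma::mat>(latent);
  const int B = z.n_rows;
  arma::mat h0, c0;
  decoder_init(params, d, z, h0, c0);
  std::vector<arma::mat> h(d.L), c(d.L), Ws(d.L), Us(d.L);
  std::vector<arma::rowvec> bs(d.L);
  for (int l = 0; l < d.L; ++l) {
    h[l] = h0.cols(l * d.U, (l + 1) * d.U - 1);
    c[l] = c0.cols(l * d.U, (l + 1) * d.U - 1);
    Ws[l] = getm(params, nm("dec", l + 1) + "_W");
    Us[l] = getm(params, nm("dec", l + 1) + "_U");
    bs[l] = getb(params, nm("dec", l + 1) + "_b");
  }
  arma::mat out_W = getm(params, "out_W");
  arma::rowvec out_b = getb(params, "out_b");
  IntegerMatrix tokens(B, max_steps);
  std::fill(tokens.begin(), tokens.end(), d.pad + 1);
  arma::ivec prev(B, arma::fill::value(d.start));
  std::vector<bool> done(B, false);
  for (int t = 0; t < max_steps; ++t) {
    arma::mat x;
    for (int l = 0; l < d.L; ++l) {
      arma::mat a(B, 4 * d.U);
      if (l == 0) {
        for (int b = 0; b < B; ++b) a.row(b) = Ws[0].row(prev(b));
      } else {
        a = x * Ws[l];
      }
      a += h[l] * Us[l];
      a.each_row() += bs[l];
      arma::mat gi = sigm(a.cols(0, d.U - 1));
      arma::mat gf = sigm(a.cols(d.U, 2 * d.U - 1));
      arma::mat gg = arma::tanh(a.cols(2 * d.U, 3 * d.U - 1));
      arma::mat go = sigm(a.cols(3 * d.U, 4 * d.U - 1));
      c[l] = gf % c[l] + gi % gg;
      h[l] = go % arma::tanh(c[l]);
      x = h[l];
    }
    arma::mat logits = h[d.L - 1] * out_W;
    logits.each_row() += out_b;
    bool all_done = true;
    for (int b = 0; b < B; ++b) {
      if (done[b]) continue;
      int best = logits.row(b).index_max();
      tokens(b, t) = best + 1;
      prev(b) = best;
      if (best == d.end) done[b] = true; else all_done = false;
    }
    if (all_done) break;
  }
  return tokens;
}

// [[Rcpp::export]]
Rcpp::List cpp_ae_grad(Rcpp::List params, Rcpp::IntegerMatrix enc_tok,
                       Rcpp::IntegerVector enc_len, Rcpp::IntegerMatrix dec_in,
                       Rcpp::IntegerMatrix dec_tgt, Rcpp::NumericMatrix noise,
                       Rcpp::NumericMatrix prop_targets, double lambda,
                       Rcpp::List dims) {
  Dims d = read_dims(dims);
  arma::imat etok = as<arma::imat>(enc_tok) - 1;
  arma::ivec len = as<arma::ivec>(enc_len);
  arma::imat din = as<arma::imat>(dec_in) - 1;
  arma::imat dtgt = as<arma::imat>(dec_tgt) - 1;
  arma::mat eps = as<arma::mat>(noise);
  arma::mat ptgt = as<arma::mat>(prop_targets);
  const int B = etok.n_rows, Td = din.n_cols;

  // ---- forward ----
  EncoderState est;
  encoder_forward(params, d, etok, len, est);
  arma::mat z = est.latent + eps;  // training-time latent noise

  arma::mat h0, c0;
  decoder_init(params, d, z, h0, c0);
  std::vector<LstmCache> dcache;
  std::vector<arma::mat> dWs, dUs;
  std::vector<arma::rowvec> dbs;
  lstm_stack_forward(params, "dec", d, din, arma::mat(), h0, c0,
                     dcache, dWs, dUs, dbs);

  arma::mat out_W = getm(params, "out_W");
  arma::rowvec out_b = getb(params, "out_b");
  double ce = 0.0;
  long n_tok = 0, n_correct = 0;
  arma::cube dh_top(B, d.U, Td, arma::fill::zeros);
  arma::mat dout_W(arma::size(out_W), arma::fill::zeros);
  arma::rowvec dout_b(d.V, arma::fill::zeros);
  for (int t = 0; t < Td; ++t)
    for (int b = 0; b < B; ++b) if (dtgt(b, t) != d.pad) ++n_tok;
  const double inv_n = n_tok > 0 ? 1.0 / n_tok : 0.0;
  for (int t = 0; t < Td; ++t) {
    arma::mat hT = dcache[d.L - 1].h.slice(t + 1);
    arma::mat logits = hT * out_W;
    logits.each_row() += out_b;
    arma::vec mx = arma::max(logits, 1);
    logits.each_col() -= mx;
    arma::mat ex = arma::exp(logits);
    arma::vec zsum = arma::sum(ex, 1);
    arma::mat probs = ex.each_col() / zsum;
    arma::mat dlogits(B, d.V, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      int y = dtgt(b, t);
      if (y == d.pad) continue;
      ce -= std::log(std::max(probs(b, y), 1e-300)) * inv_n;
      if ((int)logits.row(b).index_max() == y) ++n_correct;
      dlogits.row(b) = probs.row(b) * inv_n;
      dlogits(b, y) -= inv_n;
    }
    dout_W += hT.t() * dlogits;
    dout_b += arma::sum(dlogits, 0);
    dh_top.slice(t) = dlogits * out_W.t();
  }

  GradMap grads;
  grads["out_W"] = dout_W;
  grads["out_b"] = arma::mat(dout_b);

  // property heads forward/backward on the noisy latent
  arma::mat dz(B, d.D, arma::fill::zeros);
  arma::vec prop_loss(std::max(d.P, 1), arma::fill::zeros);
  if (d.P > 0) {
    const int K = (int)d.widths.size();
    for (int p = 0; p < d.P; ++p) {
      std::vector<arma::mat> acts(K + 1);
      acts[0] = z;
      for (int k = 0; k < K; ++k) {
        arma::mat W = getm(params, nm2("prop_W", p + 1, k + 1));
        arma::rowvec b = getb(params, nm2("prop_b", p + 1, k + 1));
        arma::mat a = acts[k] * W;
        a.each_row() += b;
        if (k < K - 1) a = arma::clamp(a, 0.0, arma::datum::inf);  // ReLU
        acts[k + 1] = a;
      }
      arma::vec resid = acts[K].col(0) - ptgt.col(p);
      prop_loss(p) = arma::mean(arma::square(resid));
      arma::mat da = arma::mat(resid) * (2.0 * lambda / B);  // B x 1
      for (int k = K - 1; k >= 0; --k) {
        arma::mat W = getm(params, nm2("prop_W", p + 1, k + 1));
        if (k < K - 1) da %= arma::conv_to<arma::mat>::from(acts[k + 1] > 0);
        grads[nm2("prop_W", p + 1, k + 1)] = acts[k].t() * da;
        grads[nm2("prop_b", p + 1, k + 1)] = arma::mat(arma::sum(da, 0));
        da = da * W.t();
      }
      dz += da;
    }
  }

  // decoder backward
  arma::mat ddec_h0, ddec_c0;
  lstm_stack_backward(grads, "dec", d, din, arma::mat(), dcache, dWs, dUs,
                      dh_top, arma::mat(), arma::mat(), &ddec_h0, &ddec_c0);

  // init-head backward: h0/c0 = tanh(z W + b)
  for (int l = 0; l < d.L; ++l) {
    arma::mat hcols = h0.cols(l * d.U, (l + 1) * d.U - 1);
    arma::mat ccols = c0.cols(l * d.U, (l + 1) * d.U - 1);
    arma::mat dpre_h = ddec_h0.cols(l * d.U, (l + 1) * d.U - 1) %
                       (1.0 - hcols % hcols);
    arma::mat dpre_c = ddec_c0.cols(l * d.U, (l + 1) * d.U - 1) %
                       (1.0 - ccols % ccols);
    arma::mat Wh = getm(params, nm("init_W", 2 * l + 1));
    arma::mat Wc = getm(params, nm("init_W", 2 * l + 2));
    grads[nm("init_W", 2 * l + 1)] = z.t() * dpre_h;
    grads[nm("init_b", 2 * l + 1)] = arma::mat(arma::sum(dpre_h, 0));
    grads[nm("init_W", 2 * l + 2)] = z.t() * dpre_c;
    grads[nm("init_b", 2 * l + 2)] = arma::mat(arma::sum(dpre_c, 0));
    dz += dpre_h * Wh.t() + dpre_c * Wc.t();
  }

  // bottleneck backward (noise is additive, so d latent = dz)
  arma::mat dpre = dz % (1.0 - est.latent % est.latent);
  arma::mat bott_W = getm(params, "bott_W");
  grads["bott_W"] = est.concat.t() * dpre;
  grads["bott_b"] = arma::mat(arma::sum(dpre, 0));
  arma::mat dconcat = dpre * bott_W.t();
  const int nl = d.bottleneck_all ? d.L : 1;
  arma::mat dh_fin(B, d.L * d.U, arma::fill::zeros);
  arma::mat dc_fin(B, d.L * d.U, arma::fill::zeros);
  for (int k = 0; k < nl; ++k) {
    int l = d.bottleneck_all ? k : d.L - 1;
    dh_fin.cols(l * d.U, (l + 1) * d.U - 1) =
        dconcat.cols(2 * k * d.U, (2 * k + 1) * d.U - 1);
    dc_fin.cols(l * d.U, (l + 1) * d.U - 1) =
        dconcat.cols((2 * k + 1) * d.U, (2 * k + 2) * d.U - 1);
  }

  // encoder backward
  arma::cube zero_top(B, d.U, etok.n_cols, arma::fill::zeros);
  lstm_stack_backward(grads, "enc", d, etok, est.mask, est.caches, est.Ws,
                      est.Us, zero_top, dh_fin, dc_fin, NULL, NULL);

  double total = ce;
  for (int p = 0; p < d.P; ++p) total += lambda * prop_loss(p);
  return List::create(
      _["grads"] = gradmap_to_list(grads), _["loss"] = total,
      _["loss_decoder"] = ce,
      _["loss_property"] = wrap(d.P > 0 ? prop_loss : arma::vec()),
      _["token_accuracy"] = n_tok > 0 ? (double)n_correct / n_tok : NA_REAL,
      _["n_tokens"] = (double)n_tok);
}
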