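// AdaptiveNet core: two fully-connected encoders projecting visit (21-dim)
// and medication (18-dim) event vectors into a shared latent space (the
// second encoder layer's weights are one shared parameter block), an LSTM
// pooling the date-sorted latent sequence into a fixed-length history
// encoding, and a fully-connected head consuming [history ; general
// features].  Forward and analytic backward passes are batched over ragged
// sequences: encoders run as single large matrix products over all events
// in the minibatch, the LSTM runs timestep-wise over instances sorted by
// sequence length (so each step is one dense product over the still-active
// instances).  Parameters live in one flat vector; gradients are returned
// in the same layout, which makes the optimizer and finite-difference
// checks trivial on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Dims {
  int Dv, Dm, H1, L, H, G, Hh;
  Dims(const Rcpp::IntegerVector& d)
      : Dv(d["Dv"]), Dm(d["Dm"]), H1(d["H1"]), L(d["L"]), H(d["H"]),
        G(d["G"]), Hh(d["Hh"]) {}
  int n_params() const {
    return H1 * Dv + H1 + H1 * Dm + H1 + L * H1 + L + 4 * H * L + 4 * H * H +
           4 * H + Hh * (H + G) + Hh + Hh + 1;
  }
};

// Flat-vector offsets for the fixed parameter layout.
struct Off {
  int w1v, b1v, w1m, b1m, w2, b2, wx, wh, bl, wd1, bd1, wo, bo;
  Off(const Dims& d) {
    w1v = 0;
    b1v = w1v + d.H1 * d.Dv;
    w1m = b1v + d.H1;
    b1m = w1m + d.H1 * d.Dm;
    w2 = b1m + d.H1;
    b2 = w2 + d.L * d.H1;
    wx = b2 + d.L;
    wh = wx + 4 * d.H * d.L;
    bl = wh + 4 * d.H * d.H;
    wd1 = bl + 4 * d.H;
    bd1 = wd1 + d.Hh * (d.H + d.G);
    wo = bd1 + d.Hh;
    bo = wo + d.Hh;
  }
};

// Writable views into the flat parameter vector (no copies: gradient
// accumulation through these views lands in the caller's buffer).
struct Params {
  mat W1v, b1v, W1m, b1m, W2, b2, Wx, Wh, bl, Wd1, bd1, Wo;
  double* bo;
  Params(double* p, const Dims& d, const Off& o)
      : W1v(p + o.w1v, d.H1, d.Dv, false, true),
        b1v(p + o.b1v, d.H1, 1, false, true),
        W1m(p + o.w1m, d.H1, d.Dm, false, true),
        b1m(p + o.b1m, d.H1, 1, false, true),
        W2(p + o.w2, d.L, d.H1, false, true),
        b2(p + o.b2, d.L, 1, false, true),
        Wx(p + o.wx, 4 * d.H, d.L, false, true),
        Wh(p + o.wh, 4 * d.H, d.H, false, true),
        bl(p + o.bl, 4 * d.H, 1, false, true),
        Wd1(p + o.wd1, d.Hh, d.H + d.G, false, true),
        bd1(p + o.bd1, d.Hh, 1, false, true),
        Wo(p + o.wo, 1, d.Hh, false, true),
        bo(p + o.bo) {}
};

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }
inline mat relu(const mat& x) { return x % conv_to<mat>::from(x > 0); }

// Per-batch assembled event data.
struct BatchData {
  int B = 0, T = 0;
  std::vector<int> lens;        // per (sorted) instance sequence length
  std::vector<int> orig;        // sorted position -> batch position
  std::vector<int> nt;          // active instances at each timestep
  // event source: for sorted instance j, event t: type (0 visit, 1 med) and
  // column in Xv / Xm
  Mat<int> src_type, src_col;   // T x B, -1 where absent
  mat Xv, Xm;                   // Dv x NV, Dm x NM (batch event features)
};

BatchData assemble(const Rcpp::List& data, const Rcpp::IntegerVector& idx,
                   const Dims& d) {
  Rcpp::List ev = data["events"];
  Rcpp::NumericMatrix XvAll = data["xv"];
  Rcpp::NumericMatrix XmAll = data["xm"];
  const mat XvA(XvAll.begin(), XvAll.nrow(), XvAll.ncol(), false);
  const mat XmA(XmAll.begin(), XmAll.nrow(), XmAll.ncol(), false);

  BatchData bd;
  bd.B = idx.size();
  std::vector<Rcpp::IntegerMatrix> evs(bd.B);
  bd.lens.resize(bd.B);
  int NV = 0, NM = 0;
  for (int b = 0; b < bd.B; ++b) {
    evs[b] = Rcpp::as<Rcpp::IntegerMatrix>(ev[idx[b] - 1]);
    bd.lens[b] = evs[b].ncol();
    for (int t = 0; t < bd.lens[b]; ++t)
      (evs[b](0, t) == 0 ? NV : NM)++;
  }
  // sort by length descending (stable)
  bd.orig.resize(bd.B);
  std::iota(bd.orig.begin(), bd.orig.end(), 0);
  std::stable_sort(bd.orig.begin(), bd.orig.end(),
                   [&](int a, int b2) { return bd.lens[a] > bd.lens[b2]; });
  std::vector<int> slen(bd.B);
  for (int j = 0; j < bd.B; ++j) slen[j] = bd.lens[bd.orig[j]];
  bd.T = bd.B > 0 ? slen[0] : 0;
  bd.nt.resize(bd.T);
  for (int t = 0; t < bd.T; ++t) {
    int n = 0;
    while (n < bd.B && slen[n] >= t + 1) ++n;
    bd.nt[t] = n;
  }
  bd.lens = slen;

  bd.Xv.set_size(d.Dv, NV);
  bd.Xm.set_size(d.Dm, NM);
  bd.src_type.set_size(std::max(bd.T, 1), bd.B);
  bd.src_col.set_size(std::max(bd.T, 1), bd.B);
  bd.src_type.fill(-1);
  bd.src_col.fill(-1);
  int cv = 0, cm = 0;
  for (int j = 0; j < bd.B; ++j) {
    const Rcpp::IntegerMatrix& e = evs[bd.orig[j]];
    for (int t = 0; t < e.ncol(); ++t) {
      int type = e(0, t);
      int srcc = e(1, t); // 0-based column in the full event matrix
      if (type == 0) {
        bd.Xv.col(cv) = XvA.col(srcc);
        bd.src_type(t, j) = 0;
        bd.src_col(t, j) = cv++;
      } else {
        bd.Xm.col(cm) = XmA.col(srcc);
        bd.src_type(t, j) = 1;
        bd.src_col(t, j) = cm++;
      }
    }
  }
  return bd;
}

} // namespace

// Forward (and optionally backward) pass over the instances `idx` of the
// prepared dataset.  task: 0 = regression (MSE on the delta target),
// 1 = classification (binary cross-entropy with logits).
// [[Rcpp::export]]
Rcpp::List anet_pass(Rcpp::NumericVector params, Rcpp::IntegerVector dims,
                     Rcpp::List data, Rcpp::IntegerVector idx, int task,
                     bool compute_grad) {
  Dims d(dims);
  if ((int)params.size() != d.n_params())
    Rcpp::stop("parameter vector has length %d, expected %d",
               (int)params.size(), d.n_params());
  Off off(d);
  Params P(params.begin(), d, off);

  BatchData bd = assemble(data, idx, d);
  const int B = bd.B, T = bd.T, H = d.H;

  Rcpp::NumericMatrix genAll = data["general"];
  const mat genA(genAll.begin(), genAll.nrow(), genAll.ncol(), false);
  Rcpp::NumericVector tgtAll = data["target"];
  mat Gb(d.G, B);
  vec tgt(B);
  for (int b = 0; b < B; ++b) {
    Gb.col(b) = genA.col(idx[b] - 1);
    tgt(b) = tgtAll[idx[b] - 1];
  }

  // ---- encoders (shared second layer) ----
  mat P1v = P.W1v * bd.Xv; P1v.each_col() += P.b1v.col(0);
  mat Z1v = relu(P1v); // relu
  mat P2v = P.W2 * Z1v; P2v.each_col() += P.b2.col(0);
  mat Ev = relu(P2v);

  mat P1m = P.W1m * bd.Xm; P1m.each_col() += P.b1m.col(0);
  mat Z1m = relu(P1m);
  mat P2m = P.W2 * Z1m; P2m.each_col() += P.b2.col(0);
  mat Em = relu(P2m);

  // ---- LSTM over sorted ragged sequences ----
  std::vector<mat> Es(T), Ig(T), Fg(T), Gg(T), Og(T), Cs(T), Th(T), Hs(T);
  for (int t = 0; t < T; ++t) {
    int n = bd.nt[t];
    mat Et(d.L, n);
    for (int j = 0; j < n; ++j)
      Et.col(j) = (bd.src_type(t, j) == 0) ? Ev.col(bd.src_col(t, j))
                                           : Em.col(bd.src_col(t, j));
    mat A = P.Wx * Et;
    A.each_col() += P.bl.col(0);
    if (t > 0) A += P.Wh * Hs[t - 1].cols(0, n - 1);
    Ig[t] = sigmoid(A.rows(0, H - 1));
    Fg[t] = sigmoid(A.rows(H, 2 * H - 1));
    Gg[t] = tanh(A.rows(2 * H, 3 * H - 1));
    Og[t] = sigmoid(A.rows(3 * H, 4 * H - 1));
    Cs[t] = Ig[t] % Gg[t];
    if (t > 0) Cs[t] += Fg[t] % Cs[t - 1].cols(0, n - 1);
    Th[t] = tanh(Cs[t]);
    Hs[t] = Og[t] % Th[t];
    Es[t] = Et;
  }

  // final hidden state per instance (zero for empty histories)
  mat hf(H, B, fill::zeros);
  for (int j = 0; j < B; ++j)
    if (bd.lens[j] > 0) hf.col(bd.orig[j]) = Hs[bd.lens[j] - 1].col(j);

  // ---- head ----
  mat Z = join_cols(hf, Gb);
  mat Pd1 = P.Wd1 * Z; Pd1.each_col() += P.bd1.col(0);
  mat U = relu(Pd1);
  rowvec y = P.Wo * U + *P.bo;

  // ---- loss ----
  double loss = 0.0;
  rowvec dy(B);
  if (task == 1) {
    for (int b = 0; b < B; ++b) {
      double z = y(b), t1 = tgt(b);
      loss += std::max(z, 0.0) - z * t1 + std::log1p(std::exp(-std::abs(z)));
      dy(b) = (1.0 / (1.0 + std::exp(-z)) - t1) / B;
    }
    loss /= B;
  } else {
    for (int b = 0; b < B; ++b) {
      double e = y(b) - tgt(b);
      loss += e * e;
      dy(b) = 2.0 * e / B;
    }
    loss /= B;
  }

  Rcpp::NumericVector yout(B);
  for (int b = 0; b < B; ++b) yout[b] = y(b);
  if (!compute_grad)
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("pred") = yout);

  // ---- backward ----
  Rcpp::NumericVector grad(d.n_params());
  Params Gp(grad.begin(), d, off);

  // head
  Gp.Wo += dy * U.t();
  *Gp.bo += accu(dy);
  mat dU = P.Wo.t() * dy;
  mat dPd1 = dU % conv_to<mat>::from(Pd1 > 0);
  Gp.Wd1 += dPd1 * Z.t();
  Gp.bd1.col(0) += sum(dPd1, 1);
  mat dZ = P.Wd1.t() * dPd1;
  mat dhf = dZ.rows(0, H - 1);

  // LSTM backward through time
  mat dEv(size(Ev), fill::zeros), dEm(size(Em), fill::zeros);
  mat dHc, dCc; // carries from step t+1 (width nt[t+1])
  for (int t = T - 1; t >= 0; --t) {
    int n = bd.nt[t];
    int n_next = (t + 1 < T) ? bd.nt[t + 1] : 0;
    mat dH(H, n, fill::zeros), dC(H, n, fill::zeros);
    if (n_next > 0) {
      dH.cols(0, n_next - 1) = dHc;
      dC.cols(0, n_next - 1) = dCc;
    }
    for (int j = n_next; j < n; ++j) // instances ending exactly at step t+1
      dH.col(j) += dhf.col(bd.orig[j]);

    mat dO = dH % Th[t];
    dC += dH % Og[t] % (1.0 - square(Th[t]));
    mat dI = dC % Gg[t];
    mat dG = dC % Ig[t];
    mat dF(H, n, fill::zeros);
    if (t > 0) dF = dC % Cs[t - 1].cols(0, n - 1);

    mat dA(4 * H, n);
    dA.rows(0, H - 1) = dI % Ig[t] % (1.0 - Ig[t]);
    dA.rows(H, 2 * H - 1) = dF % Fg[t] % (1.0 - Fg[t]);
    dA.rows(2 * H, 3 * H - 1) = dG % (1.0 - square(Gg[t]));
    dA.rows(3 * H, 4 * H - 1) = dO % Og[t] % (1.0 - Og[t]);

    Gp.Wx += dA * Es[t].t();
    Gp.bl.col(0) += sum(dA, 1);
    if (t > 0) Gp.Wh += dA * Hs[t - 1].cols(0, n - 1).t();

    mat dEt = P.Wx.t() * dA;
    for (int j = 0; j < n; ++j) {
      if (bd.src_type(t, j) == 0)
        dEv.col(bd.src_col(t, j)) += dEt.col(j);
      else
        dEm.col(bd.src_col(t, j)) += dEt.col(j);
    }
    if (t > 0) {
      mat dHprev = P.Wh.t() * dA; // H x n
      dHc = dHprev;
      dCc = dC % Fg[t];
    }
  }

  // encoders (W2/b2 gradients accumulate from both branches: shared layer)
  mat dP2v = dEv % conv_to<mat>::from(P2v > 0);
  Gp.W2 += dP2v * Z1v.t();
  Gp.b2.col(0) += sum(dP2v, 1);
  mat dZ1v = P.W2.t() * dP2v;
  mat dP1v = dZ1v % conv_to<mat>::from(P1v > 0);
  Gp.W1v += dP1v * bd.Xv.t();
  Gp.b1v.col(0) += sum(dP1v, 1);

  mat dP2m = dEm % conv_to<mat>::from(P2m > 0);
  Gp.W2 += dP2m * Z1m.t();
  Gp.b2.col(0) += sum(dP2m, 1);
  mat dZ1m = P.W2.t() * dP2m;
  mat dP1m = dZ1m % conv_to<mat>::from(P1m > 0);
  Gp.W1m += dP1m * bd.Xm.t();
  Gp.b1m.col(0) += sum(dP1m, 1);

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("pred") = yout,
                            Rcpp::Named("grad") = grad);
}
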