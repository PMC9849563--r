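// Conv-LSTM phase-regression network: forward pass and exact
// backpropagation-through-time gradients, with all trainable layers using a
// sigmoid output activation (Conv1D 'same' padding; LSTM candidate and cell
// output also sigmoid; recurrent gates standard sigmoid).
//
// Parameters travel as one flat vector in a fixed layout (mirrored by the R
// packing code in R/nn.R):
//   conv kernels W[j] (C x F) for j = 0..K-1, conv bias (F),
//   lstm Wx (F x 4U), lstm Wh (U x 4U), lstm bias (4U)  [gate order i,f,g,o],
//   then per dense layer: W (in x out), bias (out).
// cfg = (T, C, F, K, U, d1, ..., dL) with dL the output size.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct NetCfg {
  uword T, C, F, K, U;
  std::vector<uword> dense;
  explicit NetCfg(const Rcpp::IntegerVector& cfg) {
    if (cfg.size() < 6) Rcpp::stop("cfg must be (T,C,F,K,U,d1,...)");
    T = cfg[0]; C = cfg[1]; F = cfg[2]; K = cfg[3]; U = cfg[4];
    for (int i = 5; i < cfg.size(); ++i) dense.push_back(cfg[i]);
  }
  uword n_params() const {
    uword n = K * C * F + F;                 // conv
    n += F * 4 * U + U * 4 * U + 4 * U;      // lstm
    uword in = U;
    for (uword d : dense) { n += in * d + d; in = d; }
    return n;
  }
};

struct NetParams {
  std::vector<mat> convW;  // K matrices C x F
  rowvec convb;
  mat Wx, Wh;
  rowvec lstmb;
  std::vector<mat> denseW;
  std::vector<rowvec> denseb;
};

static NetParams unpack(const vec& p, const NetCfg& cf) {
  if (p.n_elem != cf.n_params()) Rcpp::stop("parameter vector has wrong length");
  NetParams np;
  uword off = 0;
  for (uword j = 0; j < cf.K; ++j) {
    np.convW.emplace_back(mat(&p[off], cf.C, cf.F));
    off += cf.C * cf.F;
  }
  np.convb = rowvec(&p[off], cf.F); off += cf.F;
  np.Wx = mat(&p[off], cf.F, 4 * cf.U); off += cf.F * 4 * cf.U;
  np.Wh = mat(&p[off], cf.U, 4 * cf.U); off += cf.U * 4 * cf.U;
  np.lstmb = rowvec(&p[off], 4 * cf.U); off += 4 * cf.U;
  uword in = cf.U;
  for (uword d : cf.dense) {
    np.denseW.emplace_back(mat(&p[off], in, d)); off += in * d;
    np.denseb.emplace_back(rowvec(&p[off], d)); off += d;
    in = d;
  }
  return np;
}

// restructure the (N, T, C) input array into per-timestep N x C matrices
static std::vector<mat> split_steps(const cube& X, const NetCfg& cf) {
  uword N = X.n_rows;
  std::vector<mat> Xt(cf.T, mat(N, cf.C));
  for (uword t = 0; t < cf.T; ++t)
    for (uword c = 0; c < cf.C; ++c)
      Xt[t].col(c) = X.slice(c).col(t);
  return Xt;
}

struct Cache {
  std::vector<mat> A;                    // conv activations, T of N x F
  std::vector<mat> gi, gf, gg, go;       // gates, T of N x U
  std::vector<mat> Cs, Hs, Hp;           // cell state, sigm(cell), prev hidden
  std::vector<mat> dact;                 // dense activations (incl. output)
  mat Hlast;
};

static mat forward_pass(const NetParams& np, const std::vector<mat>& Xt,
                        const NetCfg& cf, Cache* cache) {
  uword N = Xt[0].n_rows;
  uword padL = (cf.K - 1) / 2;           // 'same' padding, even-kernel split
  std::vector<mat> A(cf.T);
  for (uword t = 0; t < cf.T; ++t) {
    mat P(N, cf.F);
    P.each_row() = np.convb;
    for (uword j = 0; j < cf.K; ++j) {
      sword idx = (sword)t + (sword)j - (sword)padL;
      if (idx >= 0 && idx < (sword)cf.T) P += Xt[idx] * np.convW[j];
    }
    A[t] = sigm(P);
  }

  mat H(N, cf.U, fill::zeros), Cc(N, cf.U, fill::zeros);
  if (cache) {
    cache->gi.resize(cf.T); cache->gf.resize(cf.T); cache->gg.resize(cf.T);
    cache->go.resize(cf.T); cache->Cs.resize(cf.T); cache->Hs.resize(cf.T);
    cache->Hp.resize(cf.T);
  }
  for (uword t = 0; t < cf.T; ++t) {
    mat Z = A[t] * np.Wx + H * np.Wh;
    Z.each_row() += np.lstmb;
    mat i = sigm(Z.cols(0, cf.U - 1));
    mat f = sigm(Z.cols(cf.U, 2 * cf.U - 1));
    mat g = sigm(Z.cols(2 * cf.U, 3 * cf.U - 1));
    mat o = sigm(Z.cols(3 * cf.U, 4 * cf.U - 1));
    if (cache) cache->Hp[t] = H;
    mat Cprev = Cc;
    Cc = f % Cprev + i % g;
    mat hs = sigm(Cc);
    H = o % hs;
    if (cache) {
      cache->gi[t] = i; cache->gf[t] = f; cache->gg[t] = g; cache->go[t] = o;
      cache->Cs[t] = Cc; cache->Hs[t] = hs;
    }
  }

  mat D = H;
  if (cache) { cache->A = A; cache->Hlast = H; cache->dact.clear(); }
  for (size_t l = 0; l < np.denseW.size(); ++l) {
    mat Zl = D * np.denseW[l];
    Zl.each_row() += np.denseb[l];
    D = sigm(Zl);
    if (cache) cache->dact.push_back(D);
  }
  return D;
}

// [[Rcpp::export(name = ".nn_forward_cpp")]]
arma::mat nn_forward_cpp(const arma::vec& params, const arma::cube& X,
                         const Rcpp::IntegerVector& cfg) {
  NetCfg cf(cfg);
  if (X.n_cols != cf.T || X.n_slices != cf.C)
    Rcpp::stop("input must be N x %d x %d", (int)cf.T, (int)cf.C);
  NetParams np = unpack(params, cf);
  std::vector<mat> Xt = split_steps(X, cf);
  return forward_pass(np, Xt, cf, nullptr);
}

// [[Rcpp::export(name = ".nn_loss_grad_cpp")]]
Rcpp::List nn_loss_grad_cpp(const arma::vec& params, const arma::cube& X,
                            const arma::mat& Y,
                            const Rcpp::IntegerVector& cfg) {
  NetCfg cf(cfg);
  if (X.n_cols != cf.T || X.n_slices != cf.C)
    Rcpp::stop("input must be N x %d x %d", (int)cf.T, (int)cf.C);
  uword N = X.n_rows;
  if (Y.n_rows != N || Y.n_cols != cf.dense.back())
    Rcpp::stop("target matrix has wrong shape");
  NetParams np = unpack(params, cf);
  std::vector<mat> Xt = split_steps(X, cf);
  Cache cc;
  mat Yhat = forward_pass(np, Xt, cf, &cc);

  double loss = accu(square(Yhat - Y)) / (double)(N * cf.dense.back());

  // gradient accumulators, same layout
  std::vector<mat> dConvW(cf.K, mat(cf.C, cf.F, fill::zeros));
  rowvec dConvb(cf.F, fill::zeros);
  mat dWx(cf.F, 4 * cf.U, fill::zeros), dWh(cf.U, 4 * cf.U, fill::zeros);
  rowvec dLstmb(4 * cf.U, fill::zeros);
  size_t L = np.denseW.size();
  std::vector<mat> dDW(L);
  std::vector<rowvec> dDb(L);

  // dense backward
  mat dOut = 2.0 * (Yhat - Y) / (double)(N * cf.dense.back());
  for (size_t l = L; l-- > 0; ) {
    const mat& act = cc.dact[l];
    mat dZ = dOut % act % (1.0 - act);
    const mat& in = (l == 0) ? cc.Hlast : cc.dact[l - 1];
    dDW[l] = in.t() * dZ;
    dDb[l] = sum(dZ, 0);
    dOut = dZ * np.denseW[l].t();
  }

  // BPTT
  mat dH = dOut;                        // gradient w.r.t. last hidden state
  mat dC(N, cf.U, fill::zeros);
  std::vector<mat> dA(cf.T);
  for (uword tt = cf.T; tt-- > 0; ) {
    const mat &i = cc.gi[tt], &f = cc.gf[tt], &g = cc.gg[tt], &o = cc.go[tt];
    const mat &hs = cc.Hs[tt];
    mat Cprev = (tt == 0) ? mat(N, cf.U, fill::zeros)
                          : cc.Cs[tt - 1];
    mat dO = dH % hs;
    dC += dH % o % hs % (1.0 - hs);
    mat dI = dC % g;
    mat dF = dC % Cprev;
    mat dG = dC % i;
    mat dZ(N, 4 * cf.U);
    dZ.cols(0, cf.U - 1)              = dI % i % (1.0 - i);
    dZ.cols(cf.U, 2 * cf.U - 1)       = dF % f % (1.0 - f);
    dZ.cols(2 * cf.U, 3 * cf.U - 1)   = dG % g % (1.0 - g);
    dZ.cols(3 * cf.U, 4 * cf.U - 1)   = dO % o % (1.0 - o);
    dWx += cc.A[tt].t() * dZ;
    dWh += cc.Hp[tt].t() * dZ;
    dLstmb += sum(dZ, 0);
    dA[tt] = dZ * np.Wx.t();
    dH = dZ * np.Wh.t();
    dC = dC % f;
  }

  // conv backward (input gradients not needed)
  uword padL = (cf.K - 1) / 2;
  for (uword t = 0; t < cf.T; ++t) {
    const mat& a = cc.A[t];
    mat dP = dA[t] % a % (1.0 - a);
    dConvb += sum(dP, 0);
    for (uword j = 0; j < cf.K; ++j) {
      sword idx = (sword)t + (sword)j - (sword)padL;
      if (idx >= 0 && idx < (sword)cf.T) dConvW[j] += Xt[idx].t() * dP;
    }
  }

  // pack
  vec grad(params.n_elem);
  uword off = 0;
  for (uword j = 0; j < cf.K; ++j) {
    std::copy(dConvW[j].begin(), dConvW[j].end(), grad.begin() + off);
    off += cf.C * cf.F;
  }
  std::copy(dConvb.begin(), dConvb.end(), grad.begin() + off); off += cf.F;
  std::copy(dWx.begin(), dWx.end(), grad.begin() + off); off += cf.F * 4 * cf.U;
  std::copy(dWh.begin(), dWh.end(), grad.begin() + off); off += cf.U * 4 * cf.U;
  std::copy(dLstmb.begin(), dLstmb.end(), grad.begin() + off); off += 4 * cf.U;
  for (size_t l = 0; l < L; ++l) {
    std::copy(dDW[l].begin(), dDW[l].end(), grad.begin() + off);
    off += dDW[l].n_elem;
    std::copy(dDb[l].begin(), dDb[l].end(), grad.begin() + off);
    off += dDb[l].n_elem;
  }

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}
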