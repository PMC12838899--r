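// Stacked bidirectional LSTM sequence classifier: forward pass, per-timestep
// softmax cross-entropy, and full backpropagation through time.
//
// Parameters live in one flat vector (column-major, matching R's matrix
// layout) in the order: for each layer l, for direction d in {forward,
// backward}: W (4H x D), U (4H x H), b (4H); then the output projection
// Wo (2 x 2H_last), bo (2). Gate order inside the 4H block: input, forget,
// cell candidate, output.
//
// The "causal" forward variant never carries backward-direction state across
// time steps: each step's backward contribution is a single cell update from
// the zero state, so the decision at step t uses no input beyond t. The
// streaming harness on the R side implements identical arithmetic
// incrementally.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct LayerPar { mat W, U; vec b; };

static int input_dim_of(int l, int D0, const IntegerVector& hidden) {
  return l == 0 ? D0 : 2 * hidden[l - 1];
}

static void unpack(const NumericVector& theta, int D0,
                   const IntegerVector& hidden,
                   std::vector<std::array<LayerPar, 2>>& layers,
                   mat& Wo, vec& bo) {
  const int L = hidden.size();
  layers.resize(L);
  size_t off = 0;
  const double* p = theta.begin();
  for (int l = 0; l < L; ++l) {
    const int D = input_dim_of(l, D0, hidden), H = hidden[l];
    for (int d = 0; d < 2; ++d) {
      layers[l][d].W = mat(p + off, 4 * H, D); off += 4 * (size_t)H * D;
      layers[l][d].U = mat(p + off, 4 * H, H); off += 4 * (size_t)H * H;
      layers[l][d].b = vec(p + off, 4 * H);    off += 4 * (size_t)H;
    }
  }
  const int HL = hidden[L - 1];
  Wo = mat(p + off, 2, 2 * HL); off += 4 * (size_t)HL;
  bo = vec(p + off, 2);         off += 2;
  if (off != (size_t)theta.size())
    stop("parameter vector has length %d, expected %d",
         (int)theta.size(), (int)off);
}

// [[Rcpp::export]]
int cpp_bilstm_nparams(int input_dim, IntegerVector hidden) {
  size_t n = 0;
  for (int l = 0; l < hidden.size(); ++l) {
    int D = input_dim_of(l, input_dim, hidden), H = hidden[l];
    n += 2 * (4 * (size_t)H * D + 4 * (size_t)H * H + 4 * (size_t)H);
  }
  n += 4 * (size_t)hidden[hidden.size() - 1] + 2;
  return (int)n;
}

struct DirCache { mat I, F, G, O, C, Tc, H; };

// Run one direction of one layer over the whole sequence.
// backward = process in reverse time order; causal = reset state every step.
static mat dir_forward(const LayerPar& P, const mat& X, bool backward,
                       bool causal, DirCache* cache) {
  const int T = X.n_rows, H = P.b.n_elem / 4;
  mat Pm = X * P.W.t();  // T x 4H input projection
  mat Hs(H, T), Cs(H, T), Is(H, T), Fs(H, T), Gs(H, T), Os(H, T), Tcs(H, T);
  vec h(H, fill::zeros), c(H, fill::zeros);
  for (int s = 0; s < T; ++s) {
    const int t = backward ? T - 1 - s : s;
    if (causal) { h.zeros(); c.zeros(); }
    vec a = Pm.row(t).t() + P.U * h + P.b;
    vec i = 1.0 / (1.0 + exp(-a.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + exp(-a.subvec(H, 2 * H - 1)));
    vec g = tanh(a.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + exp(-a.subvec(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    vec tc = tanh(c);
    h = o % tc;
    Is.col(t) = i; Fs.col(t) = f; Gs.col(t) = g; Os.col(t) = o;
    Cs.col(t) = c; Tcs.col(t) = tc; Hs.col(t) = h;
  }
  if (cache) {
    cache->I = std::move(Is); cache->F = std::move(Fs);
    cache->G = std::move(Gs); cache->O = std::move(Os);
    cache->C = std::move(Cs); cache->Tc = std::move(Tcs);
    cache->H = Hs;
  }
  return Hs;
}

// BPTT through one direction. dH: H x T gradient w.r.t. this direction's
// outputs. Accumulates parameter grads into G and input grads into dX.
static void dir_backward(const LayerPar& P, const mat& X, bool backward,
                         const DirCache& c_, const mat& dH,
                         LayerPar& G, mat& dX) {
  const int T = X.n_rows, H = P.b.n_elem / 4;
  vec dh_carry(H, fill::zeros), dc_carry(H, fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    const int t = backward ? T - 1 - s : s;
    vec dh = dH.col(t) + dh_carry;
    vec i = c_.I.col(t), f = c_.F.col(t), g = c_.G.col(t), o = c_.O.col(t);
    vec tc = c_.Tc.col(t);
    vec dc = dh % o % (1.0 - tc % tc) + dc_carry;
    vec c_prev(H, fill::zeros), h_prev(H, fill::zeros);
    if (s > 0) {
      const int tp = backward ? T - s : s - 1;
      c_prev = c_.C.col(tp);
      h_prev = c_.H.col(tp);
    }
    vec da(4 * H);
    da.subvec(0, H - 1)         = (dc % g) % i % (1.0 - i);
    da.subvec(H, 2 * H - 1)     = (dc % c_prev) % f % (1.0 - f);
    da.subvec(2 * H, 3 * H - 1) = (dc % i) % (1.0 - g % g);
    da.subvec(3 * H, 4 * H - 1) = (dh % tc) % o % (1.0 - o);
    G.W += da * X.row(t);
    G.U += da * h_prev.t();
    G.b += da;
    dX.row(t) += (P.W.t() * da).t();
    dh_carry = P.U.t() * da;
    dc_carry = dc % f;
  }
}

static mat stack_forward(const std::vector<std::array<LayerPar, 2>>& layers,
                         const mat& X, bool causal,
                         std::vector<std::array<DirCache, 2>>* caches,
                         std::vector<mat>* inputs) {
  mat cur = X;
  for (size_t l = 0; l < layers.size(); ++l) {
    if (inputs) (*inputs)[l] = cur;
    DirCache *cf = caches ? &(*caches)[l][0] : nullptr;
    DirCache *cb = caches ? &(*caches)[l][1] : nullptr;
    // causal mode: the forward direction still carries state; only the
    // backward direction is restricted to a single step from zero state.
    mat Hf = dir_forward(layers[l][0], cur, false, false, cf);
    mat Hb = dir_forward(layers[l][1], cur, true, causal, cb);
    cur = join_rows(Hf.t(), Hb.t());  // T x 2H
  }
  return cur;
}

// [[Rcpp::export]]
arma::mat cpp_bilstm_forward(NumericVector theta, int input_dim,
                             IntegerVector hidden, arma::mat X,
                             bool causal = false) {
  std::vector<std::array<LayerPar, 2>> layers;
  mat Wo; vec bo;
  unpack(theta, input_dim, hidden, layers, Wo, bo);
  if ((int)X.n_cols != input_dim)
    stop("feature dimension mismatch: input has %d, model expects %d",
         (int)X.n_cols, input_dim);
  mat H2 = stack_forward(layers, X, causal, nullptr, nullptr);
  mat Z = H2 * Wo.t();
  Z.each_row() += bo.t();
  // row-wise softmax, numerically stabilized
  vec m = max(Z, 1);
  Z.each_col() -= m;
  mat E = exp(Z);
  vec s = sum(E, 1);
  E.each_col() /= s;
  return E;  // T x 2 class probabilities
}

// [[Rcpp::export]]
List cpp_bilstm_loss_grad(NumericVector theta, int input_dim,
                          IntegerVector hidden, arma::mat X,
                          arma::ivec y) {
  const int L = hidden.size(), T = X.n_rows;
  if ((int)y.n_elem != T) stop("label length %d != sequence length %d",
                               (int)y.n_elem, T);
  std::vector<std::array<LayerPar, 2>> layers;
  mat Wo; vec bo;
  unpack(theta, input_dim, hidden, layers, Wo, bo);
  if ((int)X.n_cols != input_dim)
    stop("feature dimension mismatch: input has %d, model expects %d",
         (int)X.n_cols, input_dim);

  std::vector<std::array<DirCache, 2>> caches(L);
  std::vector<mat> inputs(L);
  mat H2 = stack_forward(layers, X, false, &caches, &inputs);

  mat Z = H2 * Wo.t();
  Z.each_row() += bo.t();
  vec m = max(Z, 1);
  Z.each_col() -= m;
  mat E = exp(Z);
  vec s = sum(E, 1);
  mat Pr = E.each_col() / s;

  double loss = 0.0;
  mat dZ = Pr;
  for (int t = 0; t < T; ++t) {
    const int cls = (int)y[t];
    loss -= std::log(std::max(Pr(t, cls), 1e-12));
    dZ(t, cls) -= 1.0;
  }
  loss /= T;
  dZ /= T;

  mat gWo = dZ.t() * H2;
  vec gbo = sum(dZ, 0).t();
  mat dH2 = dZ * Wo;  // T x 2H_last

  // gradient containers mirroring the layer structure
  std::vector<std::array<LayerPar, 2>> grads(L);
  for (int l = 0; l < L; ++l) {
    const int D = input_dim_of(l, input_dim, hidden), H = hidden[l];
    for (int d = 0; d < 2; ++d) {
      grads[l][d].W = mat(4 * H, D, fill::zeros);
      grads[l][d].U = mat(4 * H, H, fill::zeros);
      grads[l][d].b = vec(4 * H, fill::zeros);
    }
  }

  mat dCur = dH2;
  for (int l = L - 1; l >= 0; --l) {
    const int H = hidden[l];
    mat dHf = dCur.cols(0, H - 1).t();        // H x T
    mat dHb = dCur.cols(H, 2 * H - 1).t();
    mat dX(inputs[l].n_rows, inputs[l].n_cols, fill::zeros);
    dir_backward(layers[l][0], inputs[l], false, caches[l][0], dHf,
                 grads[l][0], dX);
    dir_backward(layers[l][1], inputs[l], true, caches[l][1], dHb,
                 grads[l][1], dX);
    dCur = dX;
  }

  NumericVector grad(theta.size());
  double* gp = grad.begin();
  size_t off = 0;
  for (int l = 0; l < L; ++l) {
    for (int d = 0; d < 2; ++d) {
      const LayerPar& g = grads[l][d];
      std::memcpy(gp + off, g.W.memptr(), g.W.n_elem * sizeof(double));
      off += g.W.n_elem;
      std::memcpy(gp + off, g.U.memptr(), g.U.n_elem * sizeof(double));
      off += g.U.n_elem;
      std::memcpy(gp + off, g.b.memptr(), g.b.n_elem * sizeof(double));
      off += g.b.n_elem;
    }
  }
  std::memcpy(gp + off, gWo.memptr(), gWo.n_elem * sizeof(double));
  off += gWo.n_elem;
  std::memcpy(gp + off, gbo.memptr(), gbo.n_elem * sizeof(double));

  return List::create(_["loss"] = loss, _["grad"] = grad);
}
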