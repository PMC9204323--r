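// Twin-tower GIN kernels.
//
// Dense activations are (features x nodes); adjacency is a 0-based
// directed edge list (both directions of every bond); pooling segments
// are contiguous node runs per graph.  towerForwardCpp/towerBackwardCpp
// expose the per-tower passes for inference and verification;
// gnnTrainStepCpp fuses the full training step (both towers, projection,
// dropout, MLP head, MSE gradient, reverse pass) so layer caches never
// cross the R boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

struct GinLayer {
  mat W1, W2;
  vec b1, b2, gamma, beta, rm, rv;
};

struct TowerCache {
  std::vector<mat> Z, L1, R1, L2, xhat;
  std::vector<vec> invstd;
  mat pvec;   // pooled GIN output (hidden x graphs)
  mat H;      // final node embeddings
};

struct GinGrads {
  mat W1, W2;
  vec b1, b2, gamma, beta;
};

static std::vector<GinLayer> unpackLayers(List layers) {
  std::vector<GinLayer> out(layers.size());
  for (int l = 0; l < layers.size(); ++l) {
    List ly = layers[l];
    out[l].W1 = as<mat>(ly["W1"]);
    out[l].b1 = as<vec>(ly["b1"]);
    out[l].W2 = as<mat>(ly["W2"]);
    out[l].b2 = as<vec>(ly["b2"]);
    out[l].gamma = as<vec>(ly["gamma"]);
    out[l].beta = as<vec>(ly["beta"]);
    out[l].rm = as<vec>(ly["rm"]);
    out[l].rv = as<vec>(ly["rv"]);
  }
  return out;
}

// Z = H + H * S for the symmetric adjacency S given as directed edges.
static mat aggregate(const mat& H, const uvec& esrc, const uvec& edst) {
  mat Z = H;
  for (arma::uword k = 0; k < esrc.n_elem; ++k)
    Z.col(edst[k]) += H.col(esrc[k]);
  return Z;
}

// Forward through one tower's GIN stack and mean pooling; updates the
// layers' running statistics in place when training.
static TowerCache towerFwd(const mat& X, const uvec& esrc, const uvec& edst,
                           const uvec& poolSizes,
                           std::vector<GinLayer>& layers, bool training,
                           double momentum, double eps) {
  TowerCache c;
  const int L = layers.size();
  c.Z.resize(L); c.L1.resize(L); c.R1.resize(L); c.L2.resize(L);
  c.xhat.resize(L); c.invstd.resize(L);
  mat H = X;
  for (int l = 0; l < L; ++l) {
    GinLayer& ly = layers[l];
    c.Z[l] = aggregate(H, esrc, edst);
    c.L1[l] = ly.W1.t() * c.Z[l];
    c.L1[l].each_col() += ly.b1;
    c.R1[l] = c.L1[l] % (c.L1[l] > 0);
    c.L2[l] = ly.W2.t() * c.R1[l];
    c.L2[l].each_col() += ly.b2;
    mat R2 = c.L2[l] % (c.L2[l] > 0);
    vec mu, va;
    if (training) {
      mu = arma::mean(R2, 1);
      va = arma::var(R2, 1, 1);   // biased (population) variance
      ly.rm = (1 - momentum) * ly.rm + momentum * mu;
      ly.rv = (1 - momentum) * ly.rv + momentum * va;
    } else {
      mu = ly.rm;
      va = ly.rv;
    }
    c.invstd[l] = 1.0 / arma::sqrt(va + eps);
    c.xhat[l] = R2;
    c.xhat[l].each_col() -= mu;
    c.xhat[l].each_col() %= c.invstd[l];
    H = c.xhat[l];
    H.each_col() %= ly.gamma;
    H.each_col() += ly.beta;
  }
  const int G = poolSizes.n_elem;
  c.pvec.set_size(H.n_rows, G);
  arma::uword off = 0;
  for (int g = 0; g < G; ++g) {
    c.pvec.col(g) = arma::mean(H.cols(off, off + poolSizes[g] - 1), 1);
    off += poolSizes[g];
  }
  c.H = H;
  return c;
}

// Reverse pass through one tower from d(loss)/d(pvec).
static std::vector<GinGrads> towerBwd(const mat& dpvec, const uvec& esrc,
                                      const uvec& edst,
                                      const uvec& poolSizes,
                                      const std::vector<GinLayer>& layers,
                                      const TowerCache& c) {
  const int G = poolSizes.n_elem;
  arma::uword N = arma::accu(poolSizes);
  mat dH(dpvec.n_rows, N);
  arma::uword off = 0;
  for (int g = 0; g < G; ++g) {     // mean-pooling backward
    vec v = dpvec.col(g) / static_cast<double>(poolSizes[g]);
    for (arma::uword j = 0; j < poolSizes[g]; ++j) dH.col(off + j) = v;
    off += poolSizes[g];
  }
  const int L = layers.size();
  std::vector<GinGrads> grads(L);
  for (int l = L - 1; l >= 0; --l) {
    const GinLayer& ly = layers[l];
    const double n = static_cast<double>(dH.n_cols);
    mat dxhat = dH;
    dxhat.each_col() %= ly.gamma;
    grads[l].gamma = arma::sum(dH % c.xhat[l], 1);
    grads[l].beta = arma::sum(dH, 1);
    vec sx = arma::sum(dxhat, 1);
    vec sxx = arma::sum(dxhat % c.xhat[l], 1);
    mat dR2 = dxhat;
    dR2.each_col() -= sx / n;
    mat tmp = c.xhat[l];
    tmp.each_col() %= sxx / n;
    dR2 -= tmp;
    dR2.each_col() %= c.invstd[l];
    mat dL2 = dR2 % (c.L2[l] > 0);
    grads[l].W2 = c.R1[l] * dL2.t();
    grads[l].b2 = arma::sum(dL2, 1);
    mat dL1 = (ly.W2 * dL2) % (c.L1[l] > 0);
    grads[l].W1 = c.Z[l] * dL1.t();
    grads[l].b1 = arma::sum(dL1, 1);
    dH = aggregate(ly.W1 * dL1, esrc, edst);
  }
  return grads;
}

static List packStats(const std::vector<GinLayer>& layers) {
  List out(layers.size());
  for (size_t l = 0; l < layers.size(); ++l)
    out[l] = List::create(_["rm"] = layers[l].rm, _["rv"] = layers[l].rv);
  return out;
}

static List packGrads(const std::vector<GinGrads>& g) {
  List out(g.size());
  for (size_t l = 0; l < g.size(); ++l)
    out[l] = List::create(_["W1"] = g[l].W1, _["b1"] = g[l].b1,
                          _["W2"] = g[l].W2, _["b2"] = g[l].b2,
                          _["gamma"] = g[l].gamma, _["beta"] = g[l].beta);
  return out;
}

// [[Rcpp::export]]
List towerForwardCpp(const arma::mat& X, const arma::uvec& esrc,
                     const arma::uvec& edst, const arma::uvec& poolSizes,
                     List layers, bool training, double momentum,
                     double eps) {
  std::vector<GinLayer> lys = unpackLayers(layers);
  TowerCache c = towerFwd(X, esrc, edst, poolSizes, lys, training,
                          momentum, eps);
  const int L = lys.size();
  List caches(L);
  for (int l = 0; l < L; ++l)
    caches[l] = List::create(_["Z"] = c.Z[l], _["L1"] = c.L1[l],
                             _["R1"] = c.R1[l], _["L2"] = c.L2[l],
                             _["xhat"] = c.xhat[l],
                             _["invstd"] = c.invstd[l]);
  return List::create(_["pvec"] = c.pvec, _["caches"] = caches,
                      _["stats"] = packStats(lys));
}

// [[Rcpp::export]]
List towerBackwardCpp(const arma::mat& dpvec, const arma::uvec& esrc,
                      const arma::uvec& edst, const arma::uvec& poolSizes,
                      List layers, List caches) {
  std::vector<GinLayer> lys = unpackLayers(layers);
  TowerCache c;
  const int L = lys.size();
  c.Z.resize(L); c.L1.resize(L); c.R1.resize(L); c.L2.resize(L);
  c.xhat.resize(L); c.invstd.resize(L);
  for (int l = 0; l < L; ++l) {
    List cc = caches[l];
    c.Z[l] = as<mat>(cc["Z"]);
    c.L1[l] = as<mat>(cc["L1"]);
    c.R1[l] = as<mat>(cc["R1"]);
    c.L2[l] = as<mat>(cc["L2"]);
    c.xhat[l] = as<mat>(cc["xhat"]);
    c.invstd[l] = as<vec>(cc["invstd"]);
  }
  return packGrads(towerBwd(dpvec, esrc, edst, poolSizes, lys, c));
}

// One full training step: forward through both towers, projections,
// dropout mask, MLP head; MSE loss against refs; full reverse pass.
// mask has size (2*pooledDim x graphs) or 0x0 when dropout is off.
// [[Rcpp::export]]
List gnnTrainStepCpp(const arma::mat& Xp, const arma::uvec& esrcP,
                     const arma::uvec& edstP, const arma::uvec& nsP,
                     const arma::mat& Xd, const arma::uvec& esrcD,
                     const arma::uvec& edstD, const arma::uvec& nsD,
                     List pLayers, List dLayers,
                     const arma::mat& projWp, const arma::vec& projbp,
                     const arma::mat& projWd, const arma::vec& projbd,
                     List mlp, const arma::mat& mask,
                     const arma::vec& refs, bool sharedTowers,
                     double momentum, double eps) {
  std::vector<GinLayer> pl = unpackLayers(pLayers);
  std::vector<GinLayer> dl = unpackLayers(dLayers);
  TowerCache cp = towerFwd(Xp, esrcP, edstP, nsP, pl, true, momentum, eps);
  // with shared towers the second pass must see the stats the first one
  // already updated
  if (sharedTowers)
    for (size_t l = 0; l < pl.size(); ++l) {
      dl[l].rm = pl[l].rm;
      dl[l].rv = pl[l].rv;
    }
  TowerCache cd = towerFwd(Xd, esrcD, edstD, nsD, dl, true, momentum, eps);
  mat pooledP = projWp.t() * cp.pvec;
  pooledP.each_col() += projbp;
  mat pooledD = projWd.t() * cd.pvec;
  pooledD.each_col() += projbd;
  mat C = arma::join_cols(pooledP, pooledD);
  mat Cd = (mask.n_elem > 0) ? mat(C % mask) : C;
  const int ML = mlp.size();
  std::vector<mat> Wm(ML), inputs(ML), lins(ML), xhats(ML), bns(ML);
  std::vector<vec> bm(ML), gammas(ML), betas(ML), rms(ML), rvs(ML),
      invstds(ML);
  mat H = Cd;
  for (int l = 0; l < ML; ++l) {
    List ly = mlp[l];
    Wm[l] = as<mat>(ly["W"]);
    bm[l] = as<vec>(ly["b"]);
    inputs[l] = H;
    lins[l] = Wm[l].t() * H;
    lins[l].each_col() += bm[l];
    if (l == ML - 1) {
      H = lins[l];
    } else if (!ly.containsElementNamed("gamma")) {
      H = lins[l] % (lins[l] > 0);   // head normalization disabled
    } else {
      // hidden layers: batch norm over the graphs of the batch
      // (pre-activation), then ReLU
      gammas[l] = as<vec>(ly["gamma"]);
      betas[l] = as<vec>(ly["beta"]);
      rms[l] = as<vec>(ly["rm"]);
      rvs[l] = as<vec>(ly["rv"]);
      vec mu = arma::mean(lins[l], 1);
      vec va = arma::var(lins[l], 1, 1);
      rms[l] = (1 - momentum) * rms[l] + momentum * mu;
      rvs[l] = (1 - momentum) * rvs[l] + momentum * va;
      invstds[l] = 1.0 / arma::sqrt(va + eps);
      xhats[l] = lins[l];
      xhats[l].each_col() -= mu;
      xhats[l].each_col() %= invstds[l];
      bns[l] = xhats[l];
      bns[l].each_col() %= gammas[l];
      bns[l].each_col() += betas[l];
      H = bns[l] % (bns[l] > 0);
    }
  }
  arma::rowvec pred = H.row(0);
  const double G = static_cast<double>(pred.n_elem);
  arma::rowvec resid = pred - refs.t();
  double loss = arma::accu(arma::square(resid)) / G;
  // reverse
  mat dH = 2.0 * resid / G;
  List mlpGrads(ML), mlpStats(ML);
  for (int l = ML - 1; l >= 0; --l) {
    mat dlin;
    if (l == ML - 1) {
      dlin = dH;
      mlpGrads[l] = List::create(_["W"] = mat(inputs[l] * dlin.t()),
                                 _["b"] = vec(arma::sum(dlin, 1)));
    } else if (gammas[l].n_elem == 0) {
      dlin = dH % (lins[l] > 0);
      mlpGrads[l] = List::create(_["W"] = mat(inputs[l] * dlin.t()),
                                 _["b"] = vec(arma::sum(dlin, 1)));
    } else {
      mat dbn = dH % (bns[l] > 0);
      mat dxhat = dbn;
      dxhat.each_col() %= gammas[l];
      vec dgamma = arma::sum(dbn % xhats[l], 1);
      vec dbeta = arma::sum(dbn, 1);
      const double n = static_cast<double>(dbn.n_cols);
      vec sx = arma::sum(dxhat, 1);
      vec sxx = arma::sum(dxhat % xhats[l], 1);
      dlin = dxhat;
      dlin.each_col() -= sx / n;
      mat tmp = xhats[l];
      tmp.each_col() %= sxx / n;
      dlin -= tmp;
      dlin.each_col() %= invstds[l];
      mlpGrads[l] = List::create(_["W"] = mat(inputs[l] * dlin.t()),
                                 _["b"] = vec(arma::sum(dlin, 1)),
                                 _["gamma"] = dgamma, _["beta"] = dbeta);
      mlpStats[l] = List::create(_["rm"] = rms[l], _["rv"] = rvs[l]);
    }
    dH = Wm[l] * dlin;
  }
  mat dC = (mask.n_elem > 0) ? mat(dH % mask) : dH;
  const arma::uword pd = pooledP.n_rows;
  mat dPooledP = dC.rows(0, pd - 1);
  mat dPooledD = dC.rows(pd, 2 * pd - 1);
  mat gProjWp = cp.pvec * dPooledP.t();
  vec gProjbp = arma::sum(dPooledP, 1);
  mat gProjWd = cd.pvec * dPooledD.t();
  vec gProjbd = arma::sum(dPooledD, 1);
  mat dpvecP = projWp * dPooledP;
  mat dpvecD = projWd * dPooledD;
  std::vector<GinGrads> gp = towerBwd(dpvecP, esrcP, edstP, nsP, pl, cp);
  std::vector<GinGrads> gd = towerBwd(dpvecD, esrcD, edstD, nsD, dl, cd);
  return List::create(
      _["pred"] = pred, _["loss"] = loss,
      _["pStats"] = packStats(pl), _["dStats"] = packStats(dl),
      _["pGrads"] = packGrads(gp), _["dGrads"] = packGrads(gd),
      _["projWp"] = gProjWp, _["projbp"] = gProjbp,
      _["projWd"] = gProjWd, _["projbd"] = gProjbd,
      _["mlpGrads"] = mlpGrads, _["mlpStats"] = mlpStats);
}
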