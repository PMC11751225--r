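// Batched training/inference engine. Activations are (n*T) x C matrices,
// rows ordered time-fastest within sample (row = p + s*T), so each sample
// occupies a contiguous block of T rows and per-channel columns are
// contiguous in memory. Matrix products go through BLAS; elementwise layer
// chains (batch norm + activation, soft thresholding against per-sample
// thresholds) are fused single-pass column loops to stay memory-lean. All
// randomness (dropout, batch shuffling) is drawn from R's RNG, so runs are
// reproducible from the R seed. Mirrors the plain-R reference
// implementation used as an oracle in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uword;

namespace {

const double BN_EPS = 1e-5;
const double BN_MOM = 0.1;

struct Config {
  int inputLen, nFilters, convKernel, convStride, convPad, seRed, nClasses;
  double lambda, dropoutP;
  bool cw;
  int T() const {
    return (inputLen + 2 * convPad - convKernel) / convStride + 1;
  }
};

Config parseConfig(const List& cfg) {
  Config c;
  c.inputLen = as<int>(cfg["inputLen"]);
  c.nFilters = as<int>(cfg["nFilters"]);
  c.convKernel = as<int>(cfg["convKernel"]);
  c.convStride = as<int>(cfg["convStride"]);
  c.convPad = as<int>(cfg["convPad"]);
  c.seRed = as<int>(cfg["seReduction"]);
  c.nClasses = as<int>(cfg["nClasses"]);
  c.lambda = as<double>(cfg["softshrinkLambda"]);
  c.dropoutP = as<double>(cfg["dropoutP"]);
  c.cw = as<std::string>(cfg["thresholdMode"]) == "CW";
  return c;
}

struct Params {
  mat conv_w, conv1_w, conv2_w, se1_w, se2_w, head_w;
  rowvec conv_b, conv1_b, conv2_b, se1_b, se2_b, head_b;
  rowvec bn1_g, bn1_b, bn1_rm, bn1_rv;
  rowvec bn2_g, bn2_b, bn2_rm, bn2_rv;
  rowvec bn3_g, bn3_b, bn3_rm, bn3_rv;
  rowvec sebn_g, sebn_b, sebn_rm, sebn_rv;
};

mat getMat(const List& p, const char* nm) { return as<mat>(p[nm]); }
rowvec getVec(const List& p, const char* nm) {
  return as<rowvec>(as<NumericVector>(p[nm]));
}

Params parseParams(const List& p) {
  Params q;
  q.conv_w = getMat(p, "conv_w");   q.conv_b = getVec(p, "conv_b");
  q.conv1_w = getMat(p, "conv1_w"); q.conv1_b = getVec(p, "conv1_b");
  q.conv2_w = getMat(p, "conv2_w"); q.conv2_b = getVec(p, "conv2_b");
  q.se1_w = getMat(p, "se1_w");     q.se1_b = getVec(p, "se1_b");
  q.se2_w = getMat(p, "se2_w");     q.se2_b = getVec(p, "se2_b");
  q.head_w = getMat(p, "head_w");   q.head_b = getVec(p, "head_b");
  q.bn1_g = getVec(p, "bn1_g"); q.bn1_b = getVec(p, "bn1_b");
  q.bn1_rm = getVec(p, "bn1_rm"); q.bn1_rv = getVec(p, "bn1_rv");
  q.bn2_g = getVec(p, "bn2_g"); q.bn2_b = getVec(p, "bn2_b");
  q.bn2_rm = getVec(p, "bn2_rm"); q.bn2_rv = getVec(p, "bn2_rv");
  q.bn3_g = getVec(p, "bn3_g"); q.bn3_b = getVec(p, "bn3_b");
  q.bn3_rm = getVec(p, "bn3_rm"); q.bn3_rv = getVec(p, "bn3_rv");
  q.sebn_g = getVec(p, "sebn_g"); q.sebn_b = getVec(p, "sebn_b");
  q.sebn_rm = getVec(p, "sebn_rm"); q.sebn_rv = getVec(p, "sebn_rv");
  return q;
}

NumericVector rv(const rowvec& x) {
  return NumericVector(x.begin(), x.end());
}

List exportParams(const Params& q) {
  return List::create(
      _["conv_w"] = q.conv_w, _["conv_b"] = rv(q.conv_b),
      _["bn1_g"] = rv(q.bn1_g), _["bn1_b"] = rv(q.bn1_b),
      _["bn1_rm"] = rv(q.bn1_rm), _["bn1_rv"] = rv(q.bn1_rv),
      _["bn2_g"] = rv(q.bn2_g), _["bn2_b"] = rv(q.bn2_b),
      _["bn2_rm"] = rv(q.bn2_rm), _["bn2_rv"] = rv(q.bn2_rv),
      _["conv1_w"] = q.conv1_w, _["conv1_b"] = rv(q.conv1_b),
      _["bn3_g"] = rv(q.bn3_g), _["bn3_b"] = rv(q.bn3_b),
      _["bn3_rm"] = rv(q.bn3_rm), _["bn3_rv"] = rv(q.bn3_rv),
      _["conv2_w"] = q.conv2_w, _["conv2_b"] = rv(q.conv2_b),
      _["se1_w"] = q.se1_w, _["se1_b"] = rv(q.se1_b),
      _["sebn_g"] = rv(q.sebn_g), _["sebn_b"] = rv(q.sebn_b),
      _["sebn_rm"] = rv(q.sebn_rm), _["sebn_rv"] = rv(q.sebn_rv),
      _["se2_w"] = q.se2_w, _["se2_b"] = rv(q.se2_b),
      _["head_w"] = q.head_w, _["head_b"] = rv(q.head_b));
}

// ---- fused batch norm + activation -------------------------------------

enum Post { IDENT, RELU, SHRINK };

struct BNCache {
  mat xhat;           // normalized pre-affine activations
  rowvec invstd, g, b;
};

// out = post(g * xhat + b); keeps xhat for the backward pass
mat bnPostForward(const mat& A, const rowvec& g, const rowvec& b, rowvec& rm,
                  rowvec& rv, bool training, Post post, double lambda,
                  BNCache& cache) {
  uword m = A.n_rows, C = A.n_cols;
  rowvec mu(C), v(C);
  if (training) {
    for (uword j = 0; j < C; ++j) {
      const double* a = A.colptr(j);
      double s = 0, s2 = 0;
      for (uword i = 0; i < m; ++i) { s += a[i]; s2 += a[i] * a[i]; }
      mu[j] = s / m;
      double var = s2 / m - mu[j] * mu[j];
      v[j] = var > 0 ? var : 0.0;
    }
    rm = (1 - BN_MOM) * rm + BN_MOM * mu;
    rv = (1 - BN_MOM) * rv + BN_MOM * v * (m > 1 ? (double)m / (m - 1) : 1.0);
  } else {
    mu = rm;
    v = rv;
  }
  cache.invstd = 1.0 / arma::sqrt(v + BN_EPS);
  cache.g = g;
  cache.b = b;
  cache.xhat.set_size(m, C);
  mat out(m, C);
  for (uword j = 0; j < C; ++j) {
    const double* a = A.colptr(j);
    double* xh = cache.xhat.colptr(j);
    double* o = out.colptr(j);
    double mj = mu[j], ij = cache.invstd[j], gj = g[j], bj = b[j];
    for (uword i = 0; i < m; ++i) {
      double x = (a[i] - mj) * ij;
      xh[i] = x;
      double y = gj * x + bj;
      if (post == RELU) y = y > 0 ? y : 0.0;
      else if (post == SHRINK)
        y = y > lambda ? y - lambda : (y < -lambda ? y + lambda : 0.0);
      o[i] = y;
    }
  }
  return out;
}

// dY (gradient wrt post output) is consumed in place and becomes dA;
// the activation mask is recomputed from xhat and the affine scalars
void bnPostBackward(mat& dY, const BNCache& c, bool training, Post post,
                    double lambda, rowvec& dg, rowvec& db) {
  uword m = dY.n_rows, C = dY.n_cols;
  dg.set_size(C);
  db.set_size(C);
  for (uword j = 0; j < C; ++j) {
    double* d = dY.colptr(j);
    const double* xh = c.xhat.colptr(j);
    double gj = c.g[j], bj = c.b[j], ij = c.invstd[j];
    double sdg = 0, sdb = 0, s1 = 0, s2 = 0;
    for (uword i = 0; i < m; ++i) {
      double pre = gj * xh[i] + bj;
      bool on = post == IDENT || (post == RELU ? pre > 0
                                : std::abs(pre) > lambda);
      double dpre = on ? d[i] : 0.0;
      sdg += dpre * xh[i];
      sdb += dpre;
      double dxh = dpre * gj;
      s1 += dxh;
      s2 += dxh * xh[i];
      d[i] = dxh;  // now holds dxhat
    }
    dg[j] = sdg;
    db[j] = sdb;
    if (!training) {
      for (uword i = 0; i < m; ++i) d[i] *= ij;
    } else {
      double a1 = s1 / m, a2 = s2 / m;
      for (uword i = 0; i < m; ++i)
        d[i] = ij * (d[i] - a1 - xh[i] * a2);
    }
  }
}

// ---- im2col -------------------------------------------------------------

// gather an inputLen x n (transposed) signal matrix into (n*T) x K
mat im2col(const mat& Xt, const Config& c) {
  int n = Xt.n_cols, T = c.T(), L = c.inputLen;
  mat out(n * T, c.convKernel);
  for (int k = 0; k < c.convKernel; ++k) {
    double* o = out.colptr(k);
    for (int s = 0; s < n; ++s) {
      const double* x = Xt.colptr(s);
      double* os = o + s * T;
      for (int p = 0; p < T; ++p) {
        int src = p * c.convStride + k - c.convPad;
        os[p] = (src < 0 || src >= L) ? 0.0 : x[src];
      }
    }
  }
  return out;
}

// per-sample temporal mean over contiguous T-row blocks -> n x C
mat blockMeanAbs(const mat& A, int n, int T, bool useAbs) {
  mat out(n, A.n_cols);
  for (uword j = 0; j < A.n_cols; ++j) {
    const double* a = A.colptr(j);
    for (int s = 0; s < n; ++s) {
      double acc = 0;
      const double* as = a + s * T;
      if (useAbs) for (int p = 0; p < T; ++p) acc += std::abs(as[p]);
      else for (int p = 0; p < T; ++p) acc += as[p];
      out(s, j) = acc / T;
    }
  }
  return out;
}

struct Cache {
  int n;
  mat Xcol, dropMask, I, Z1, Z2, U, a, z1se, sig, tau, P, g, logits, probs;
  BNCache bn1, bn2, bn3, sebn;
  bool hasDrop;
};

// threshold for sample s, channel j (tau is n x C for CW, n x 1 for CS)
inline double tauAt(const mat& tau, int s, uword j, bool cw) {
  return cw ? tau(s, j) : tau(s, 0);
}

void forwardPass(const mat& Xt, Params& q, const Config& c, bool training,
                 Cache& f) {
  int n = Xt.n_cols, T = c.T();
  f.n = n;
  f.Xcol = im2col(Xt, c);
  mat H0 = f.Xcol * q.conv_w;
  H0.each_row() += q.conv_b;
  mat S = bnPostForward(H0, q.bn1_g, q.bn1_b, q.bn1_rm, q.bn1_rv, training,
                        SHRINK, c.lambda, f.bn1);
  f.hasDrop = training && c.dropoutP > 0;
  if (f.hasDrop) {
    NumericVector u = runif(S.n_elem);
    f.dropMask.set_size(S.n_rows, S.n_cols);
    double keep = 1.0 - c.dropoutP;
    for (uword i = 0; i < S.n_elem; ++i)
      f.dropMask(i) = u[i] >= c.dropoutP ? 1.0 / keep : 0.0;
    f.I = S % f.dropMask;
  } else {
    f.I = std::move(S);
  }
  f.Z1 = bnPostForward(f.I, q.bn2_g, q.bn2_b, q.bn2_rm, q.bn2_rv, training,
                       RELU, 0, f.bn2);
  mat U1 = f.Z1 * q.conv1_w;
  U1.each_row() += q.conv1_b;
  f.Z2 = bnPostForward(U1, q.bn3_g, q.bn3_b, q.bn3_rm, q.bn3_rv, training,
                       RELU, 0, f.bn3);
  f.U = f.Z2 * q.conv2_w;
  f.U.each_row() += q.conv2_b;

  // squeeze: per-sample mean |U|; excite: bottleneck -> logistic
  f.a = blockMeanAbs(f.U, n, T, true);
  mat s1 = f.a * q.se1_w;
  s1.each_row() += q.se1_b;
  mat Bse = bnPostForward(s1, q.sebn_g, q.sebn_b, q.sebn_rm, q.sebn_rv,
                          training, RELU, 0, f.sebn);
  f.z1se = std::move(Bse);
  mat s2 = f.z1se * q.se2_w;
  s2.each_row() += q.se2_b;
  f.sig = 1.0 / (1.0 + arma::exp(-s2));
  f.tau = c.cw ? mat(f.sig % f.a) : mat(f.sig % arma::mean(f.a, 1));

  // soft thresholding + identity shortcut, fused per (sample, channel)
  f.P.set_size(f.U.n_rows, f.U.n_cols);
  for (uword j = 0; j < f.U.n_cols; ++j) {
    const double* u = f.U.colptr(j);
    const double* ii = f.I.colptr(j);
    double* pp = f.P.colptr(j);
    for (int s = 0; s < n; ++s) {
      double t = tauAt(f.tau, s, j, c.cw);
      for (int p = s * T; p < (s + 1) * T; ++p) {
        double v = u[p];
        double o = v > t ? v - t : (v < -t ? v + t : 0.0);
        pp[p] = ii[p] + o;
      }
    }
  }
  f.g = blockMeanAbs(f.P, n, T, false);
  mat logits = f.g * q.head_w;
  logits.each_row() += q.head_b;
  arma::colvec zmax = arma::max(logits, 1);
  mat e = arma::exp(logits.each_col() - zmax);
  f.probs = e.each_col() / arma::sum(e, 1);
  f.logits = std::move(logits);
}

void backwardPass(const Cache& f, const Params& q, const Config& c,
                  const mat& dLogits, bool training, Params& gr) {
  int n = f.n, T = c.T(), C = c.nFilters;
  gr.head_w = f.g.t() * dLogits;
  gr.head_b = arma::sum(dLogits, 0);
  mat dgap = (dLogits * q.head_w.t()) / T;  // n x C, block-constant over time

  // through soft thresholding: dU direct part + per-sample tau gradient
  mat dU(f.U.n_rows, C);
  mat dtau(n, f.tau.n_cols, arma::fill::zeros);
  for (uword j = 0; j < (uword)C; ++j) {
    const double* u = f.U.colptr(j);
    double* du = dU.colptr(j);
    for (int s = 0; s < n; ++s) {
      double t = tauAt(f.tau, s, j, c.cw);
      double dp = dgap(s, j);
      double acc = 0;
      for (int p = s * T; p < (s + 1) * T; ++p) {
        double v = u[p];
        if (v > t) { du[p] = dp; acc -= dp; }
        else if (v < -t) { du[p] = dp; acc += dp; }
        else du[p] = 0.0;
      }
      if (c.cw) dtau(s, j) += acc;
      else dtau(s, 0) += acc;
    }
  }
  mat dsig, da;
  if (c.cw) {
    dsig = dtau % f.a;
    da = dtau % f.sig;
  } else {
    dsig = dtau % arma::mean(f.a, 1);
    da = arma::repmat((dtau % f.sig) / C, 1, C);
  }
  mat ds2 = dsig % f.sig % (1.0 - f.sig);
  mat dz1 = ds2 * q.se2_w.t();
  gr.se2_w = f.z1se.t() * ds2;
  gr.se2_b = arma::sum(ds2, 0);
  bnPostBackward(dz1, f.sebn, training, RELU, 0, gr.sebn_g, gr.sebn_b);
  da += dz1 * q.se1_w.t();
  gr.se1_w = f.a.t() * dz1;
  gr.se1_b = arma::sum(dz1, 0);
  // a = blockMean(|U|): dU += sign(U) * da / T
  for (uword j = 0; j < (uword)C; ++j) {
    const double* u = f.U.colptr(j);
    double* du = dU.colptr(j);
    for (int s = 0; s < n; ++s) {
      double d = da(s, j) / T;
      for (int p = s * T; p < (s + 1) * T; ++p)
        du[p] += u[p] > 0 ? d : (u[p] < 0 ? -d : 0.0);
    }
  }

  mat dZ2 = dU * q.conv2_w.t();
  gr.conv2_w = f.Z2.t() * dU;
  gr.conv2_b = arma::sum(dU, 0);
  bnPostBackward(dZ2, f.bn3, training, RELU, 0, gr.bn3_g, gr.bn3_b);
  mat dZ1 = dZ2 * q.conv1_w.t();
  gr.conv1_w = f.Z1.t() * dZ2;
  gr.conv1_b = arma::sum(dZ2, 0);
  bnPostBackward(dZ1, f.bn2, training, RELU, 0, gr.bn2_g, gr.bn2_b);

  // dI = shortcut (block-constant dgap) + residual-branch contribution
  mat& dI = dZ1;
  for (uword j = 0; j < (uword)C; ++j) {
    double* di = dI.colptr(j);
    for (int s = 0; s < n; ++s) {
      double d = dgap(s, j);
      for (int p = s * T; p < (s + 1) * T; ++p) di[p] += d;
    }
  }
  if (f.hasDrop) dI %= f.dropMask;
  bnPostBackward(dI, f.bn1, training, SHRINK, c.lambda, gr.bn1_g, gr.bn1_b);
  gr.conv_w = f.Xcol.t() * dI;
  gr.conv_b = arma::sum(dI, 0);
}

// ---- Adam ---------------------------------------------------------------

struct AdamState {
  Params m, v;
  long t = 0;
};

void zeroLike(const Params& q, Params& z) {
  z = q;
  z.conv_w.zeros(); z.conv_b.zeros();
  z.conv1_w.zeros(); z.conv1_b.zeros();
  z.conv2_w.zeros(); z.conv2_b.zeros();
  z.se1_w.zeros(); z.se1_b.zeros();
  z.se2_w.zeros(); z.se2_b.zeros();
  z.head_w.zeros(); z.head_b.zeros();
  z.bn1_g.zeros(); z.bn1_b.zeros();
  z.bn2_g.zeros(); z.bn2_b.zeros();
  z.bn3_g.zeros(); z.bn3_b.zeros();
  z.sebn_g.zeros(); z.sebn_b.zeros();
}

template <typename T1>
void adamOne(T1& p, const T1& g, T1& m, T1& v, double lr, double c1,
             double c2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  p -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8);
}

void adamUpdate(Params& q, const Params& g, AdamState& st, double lr) {
  st.t += 1;
  double c1 = 1.0 - std::pow(0.9, (double)st.t);
  double c2 = 1.0 - std::pow(0.999, (double)st.t);
  adamOne(q.conv_w, g.conv_w, st.m.conv_w, st.v.conv_w, lr, c1, c2);
  adamOne(q.conv_b, g.conv_b, st.m.conv_b, st.v.conv_b, lr, c1, c2);
  adamOne(q.bn1_g, g.bn1_g, st.m.bn1_g, st.v.bn1_g, lr, c1, c2);
  adamOne(q.bn1_b, g.bn1_b, st.m.bn1_b, st.v.bn1_b, lr, c1, c2);
  adamOne(q.bn2_g, g.bn2_g, st.m.bn2_g, st.v.bn2_g, lr, c1, c2);
  adamOne(q.bn2_b, g.bn2_b, st.m.bn2_b, st.v.bn2_b, lr, c1, c2);
  adamOne(q.conv1_w, g.conv1_w, st.m.conv1_w, st.v.conv1_w, lr, c1, c2);
  adamOne(q.conv1_b, g.conv1_b, st.m.conv1_b, st.v.conv1_b, lr, c1, c2);
  adamOne(q.bn3_g, g.bn3_g, st.m.bn3_g, st.v.bn3_g, lr, c1, c2);
  adamOne(q.bn3_b, g.bn3_b, st.m.bn3_b, st.v.bn3_b, lr, c1, c2);
  adamOne(q.conv2_w, g.conv2_w, st.m.conv2_w, st.v.conv2_w, lr, c1, c2);
  adamOne(q.conv2_b, g.conv2_b, st.m.conv2_b, st.v.conv2_b, lr, c1, c2);
  adamOne(q.se1_w, g.se1_w, st.m.se1_w, st.v.se1_w, lr, c1, c2);
  adamOne(q.se1_b, g.se1_b, st.m.se1_b, st.v.se1_b, lr, c1, c2);
  adamOne(q.sebn_g, g.sebn_g, st.m.sebn_g, st.v.sebn_g, lr, c1, c2);
  adamOne(q.sebn_b, g.sebn_b, st.m.sebn_b, st.v.sebn_b, lr, c1, c2);
  adamOne(q.se2_w, g.se2_w, st.m.se2_w, st.v.se2_w, lr, c1, c2);
  adamOne(q.se2_b, g.se2_b, st.m.se2_b, st.v.se2_b, lr, c1, c2);
  adamOne(q.head_w, g.head_w, st.m.head_w, st.v.head_w, lr, c1, c2);
  adamOne(q.head_b, g.head_b, st.m.head_b, st.v.head_b, lr, c1, c2);
}

void checkInput(const mat& X, const Config& c) {
  if ((int)X.n_cols != c.inputLen)
    stop("epoch length %d does not match config inputLen %d", (int)X.n_cols,
         c.inputLen);
  if (!X.is_finite()) stop("non-finite values in input");
}

}  // namespace

// [[Rcpp::export(name = "cppForward")]]
List cppForward(const arma::mat& X, List params, List config, bool training,
                bool trace) {
  Config c = parseConfig(config);
  checkInput(X, c);
  Params q = parseParams(params);
  Cache f;
  mat Xt = X.t();
  forwardPass(Xt, q, c, training, f);
  if (!trace)
    return List::create(_["probs"] = f.probs, _["logits"] = f.logits);
  mat O = f.P - f.I;  // exact: P was formed as I + O elementwise
  return List::create(
      _["probs"] = f.probs, _["logits"] = f.logits, _["g"] = f.g,
      _["P"] = f.P, _["I"] = f.I, _["U"] = f.U, _["O"] = O,
      _["sigma"] = f.sig, _["tau"] = f.tau, _["T"] = c.T());
}

// [[Rcpp::export(name = "cppGrads")]]
List cppGrads(const arma::mat& X, const arma::ivec& y, List params,
              List config, double alpha, bool training) {
  // single forward/backward pass (no update); exposed for gradient checks
  Config c = parseConfig(config);
  checkInput(X, c);
  Params q = parseParams(params);
  Cache f;
  mat Xt = X.t();
  forwardPass(Xt, q, c, training, f);
  int n = X.n_rows;
  mat Q(n, c.nClasses, arma::fill::value(alpha / c.nClasses));
  for (int i = 0; i < n; ++i) Q(i, y[i]) += 1.0 - alpha;
  mat lp = arma::log(arma::clamp(f.probs, 1e-12, 1.0));
  double loss = -arma::mean(arma::sum(Q % lp, 1));
  mat dLogits = (f.probs - Q) / n;
  Params gr;
  backwardPass(f, q, c, dLogits, training, gr);
  List out = exportParams(gr);
  out["loss"] = loss;
  return out;
}

// [[Rcpp::export(name = "cppTrain")]]
List cppTrain(const arma::mat& X, const arma::ivec& y, List params,
              List config, List tconf, const arma::mat& mask) {
  Config c = parseConfig(config);
  checkInput(X, c);
  Params q = parseParams(params);
  double lr = as<double>(tconf["learningRate"]);
  double alpha = as<double>(tconf["labelSmoothing"]);
  int L = as<int>(tconf["batchSize"]);
  int nEpochs = as<int>(tconf["nEpochs"]);
  int n = X.n_rows, C2 = c.nClasses;
  mat Xt = X.t();
  AdamState st;
  zeroLike(q, st.m);
  zeroLike(q, st.v);
  NumericVector history(nEpochs);

  for (int ep = 0; ep < nEpochs; ++ep) {
    // permutation via uniform sort keys from R's RNG: deterministic per seed
    NumericVector keys = runif(n);
    arma::uvec perm =
        arma::stable_sort_index(arma::vec(keys.begin(), n, false));
    double lossSum = 0.0;
    int nBatches = 0;
    for (int s0 = 0; s0 < n; s0 += L) {
      int s1 = std::min(s0 + L - 1, n - 1);
      int nb = s1 - s0 + 1;
      if (nb < 2) continue;  // batch norm needs >= 2 samples
      arma::uvec take = perm.subvec(s0, s1);
      mat Xb = Xt.cols(take);
      Cache f;
      forwardPass(Xb, q, c, true, f);
      mat Q(nb, C2, arma::fill::value(alpha / C2));
      for (int i = 0; i < nb; ++i) Q(i, y[take[i]]) += 1.0 - alpha;
      mat lp = arma::log(arma::clamp(f.probs, 1e-12, 1.0));
      lossSum += -arma::mean(arma::sum(Q % lp, 1));
      nBatches += 1;
      mat dLogits = (f.probs - Q) / nb;
      Params gr;
      backwardPass(f, q, c, dLogits, true, gr);
      gr.head_w %= mask;
      adamUpdate(q, gr, st, lr);
    }
    history[ep] = nBatches ? lossSum / nBatches : NA_REAL;
  }
  return List::create(_["params"] = exportParams(q), _["history"] = history);
}
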