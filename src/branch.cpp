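// Forward and backward passes of one EEGNet-style branch.
//
// The whole branch runs in compiled code: the time-axis convolutions are
// banded (Toeplitz) gemms, batch-norm + ELU are fused single-pass loops,
// and every intermediate needed by the backward pass lives in a cache
// object handed back to R as an external pointer, so a training step does
// not shuttle large activation tensors through the R heap.
//
// Internal layout is channel-major: the [n, C, T] input batch is permuted
// once to rows (c, n) so that all later reshapes between gemm layouts are
// pointer reinterpretations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

struct BranchCache {
  int n, C, T, T1, T2, f1, D, f2, k, sepk, p1, p2;
  bool train;
  arma::mat M;        // (C*n) x T channel-major input
  arma::mat Aall;     // T x (T*f1) banded temporal filters
  arma::mat xhat1, E1;          // (C*n*T) x f1
  arma::mat xhat2, E2, mask2;   // (n*T) x f2
  arma::mat P2;                 // n x (T1*f2)
  arma::mat S;                  // n x (T1*f2) after separable depthwise
  arma::mat xhat3, E3, mask3;   // (n*T1) x f2
  arma::vec si1, si2, si3;      // 1/sd per stage
  // scratch buffers reused across steps
  arma::mat Y1, Z2, D2, U, D3, Fout, dE1, dY1;
};

// Fill tap j of kernel w onto diagonal j - pad of the len x len band matrix
// ("same" padding, left pad floor((k-1)/2)).
static void band_fill(arma::mat& A, const double* w, int k, int len,
                      int row0, int col0) {
  const int pad = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    const int d = j - pad;
    const int lo = std::max(0, -d), hi = std::min(len - 1, len - 1 - d);
    for (int t = lo; t <= hi; ++t) A(row0 + t + d, col0 + t) = w[j];
  }
}

static void band_grad(const arma::mat& dA, int k, int row0, int col0, int len,
                      double* out) {
  const int pad = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    const int d = j - pad;
    const int lo = std::max(0, -d), hi = std::min(len - 1, len - 1 - d);
    double s = 0.0;
    for (int t = lo; t <= hi; ++t) s += dA(row0 + t + d, col0 + t);
    out[j] = s;
  }
}

// Batch statistics, fused normalise + affine + ELU. x viewed (m x f).
static void bn_stats(const arma::mat& x, arma::vec& mu, arma::vec& v) {
  const int m = x.n_rows, f = x.n_cols;
  mu.set_size(f); v.set_size(f);
  for (int j = 0; j < f; ++j) {
    const double* xc = x.colptr(j);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < m; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double mj = s / m;
    double vj = s2 / m - mj * mj;
    mu[j] = mj;
    v[j] = vj > 0 ? vj : 0.0;
  }
}

static void bn_elu_apply(const arma::mat& x, arma::mat& xhat, arma::mat& y,
                         const arma::vec& mu, const arma::vec& si,
                         const arma::vec& g, const arma::vec& b) {
  const int m = x.n_rows, f = x.n_cols;
  xhat.set_size(m, f);
  y.set_size(m, f);
  for (int j = 0; j < f; ++j) {
    const double mj = mu[j], sj = si[j], gj = g[j], bj = b[j];
    const double* xc = x.colptr(j);
    double* xh = xhat.colptr(j);
    double* yc = y.colptr(j);
    for (int i = 0; i < m; ++i) {
      const double h = (xc[i] - mj) * sj;
      xh[i] = h;
      const double z = h * gj + bj;
      yc[i] = z > 0 ? z : std::expm1(z);
    }
  }
}

// Backward through ELU (derivative via the output y) then batch-norm.
static void bn_elu_backward(const arma::mat& dy, const arma::mat& y,
                            const arma::mat& xhat, const arma::vec& g,
                            const arma::vec& si, bool train,
                            arma::mat& dx, arma::vec& dgamma, arma::vec& dbeta) {
  const int m = dy.n_rows, f = dy.n_cols;
  dx.set_size(m, f);
  dgamma.set_size(f);
  dbeta.set_size(f);
  for (int j = 0; j < f; ++j) {
    const double gs = g[j] * si[j];
    const double* dyc = dy.colptr(j);
    const double* yc = y.colptr(j);
    const double* xh = xhat.colptr(j);
    double* dxc = dx.colptr(j);
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < m; ++i) {
      const double der = yc[i] > 0 ? 1.0 : yc[i] + 1.0;
      const double d = dyc[i] * der;
      dxc[i] = d;
      s1 += d;
      s2 += d * xh[i];
    }
    dgamma[j] = s2;
    dbeta[j] = s1;
    if (train) {
      const double a1 = s1 / m, a2 = s2 / m;
      for (int i = 0; i < m; ++i) dxc[i] = (dxc[i] - a1 - xh[i] * a2) * gs;
    } else {
      for (int i = 0; i < m; ++i) dxc[i] *= gs;
    }
  }
}

// Inverted dropout using the R RNG stream (deterministic under set.seed).
static void dropout_apply(const arma::mat& x, double p, arma::mat& mask,
                          arma::mat& out) {
  const int m = x.n_rows, f = x.n_cols;
  mask.set_size(m, f);
  out.set_size(m, f);
  const double scale = 1.0 / (1.0 - p);
  const double* xc = x.memptr();
  double* mk = mask.memptr();
  double* oc = out.memptr();
  const int ntot = m * f;
  for (int i = 0; i < ntot; ++i) {
    const double u = unif_rand();
    const double mv = (u >= p) ? scale : 0.0;
    mk[i] = mv;
    oc[i] = xc[i] * mv;
  }
}

// Non-overlapping mean pooling along time. in: n x (T*f) per-map blocks.
static void avgpool(const arma::mat& in, int T_in, int f, int size, arma::mat& out) {
  const int T_out = T_in / size;
  const int n = in.n_rows;
  out.zeros(n, T_out * f);
  for (int m = 0; m < f; ++m) {
    for (int t = 0; t < T_out; ++t) {
      arma::vec acc = in.col(m * T_in + t * size);
      for (int u = 1; u < size; ++u) acc += in.col(m * T_in + t * size + u);
      out.col(m * T_out + t) = acc / size;
    }
  }
}

static void avgpool_back(const arma::mat& dout, int T_in, int f, int size,
                         arma::mat& din) {
  const int T_out = T_in / size;
  const int n = dout.n_rows;
  din.zeros(n, T_in * f);
  for (int m = 0; m < f; ++m) {
    for (int t = 0; t < T_out; ++t) {
      const arma::vec g = dout.col(m * T_out + t) / size;
      for (int u = 0; u < size; ++u) din.col(m * T_in + t * size + u) = g;
    }
  }
}

// [[Rcpp::export]]
List branch_fwd_cpp(NumericVector X, List params, List state, bool train,
                    double dropout_p, SEXP reuse = R_NilValue) {
  IntegerVector dims = X.attr("dim");
  const int n = dims[0], C = dims[1], T = dims[2];
  arma::mat W_temp = as<arma::mat>(params["W_temp"]);   // f1 x k
  arma::cube W_dw = as<arma::cube>(params["W_dw"]);     // D x C x f1
  arma::mat W_sepd = as<arma::mat>(params["W_sepd"]);   // f2 x sepk
  arma::mat W_sepp = as<arma::mat>(params["W_sepp"]);   // f2 x f2
  arma::vec g1 = as<arma::vec>(params["bn1_gamma"]), b1 = as<arma::vec>(params["bn1_beta"]);
  arma::vec g2 = as<arma::vec>(params["bn2_gamma"]), b2 = as<arma::vec>(params["bn2_beta"]);
  arma::vec g3 = as<arma::vec>(params["bn3_gamma"]), b3 = as<arma::vec>(params["bn3_beta"]);
  const int f1 = W_temp.n_rows, k = W_temp.n_cols;
  const int D = W_dw.n_rows, f2 = W_sepd.n_rows, sepk = W_sepd.n_cols;
  const int p1 = as<int>(params["pool1"]), p2 = as<int>(params["pool2"]);
  const int T1 = T / p1, T2 = T1 / p2;

  // Reuse the previous step's cache when shapes match, so the large
  // activation buffers are allocated once per fold rather than once per
  // batch (they are invisible to R's garbage collector).
  XPtr<BranchCache> cp = [&]() {
    if (TYPEOF(reuse) == EXTPTRSXP) {
      XPtr<BranchCache> prev(reuse);
      BranchCache* q = prev.get();
      if (q != nullptr && q->n == n && q->C == C && q->T == T &&
          q->f1 == f1 && q->D == D && q->f2 == f2 && q->k == k &&
          q->sepk == sepk && q->p1 == p1 && q->p2 == p2) {
        return prev;
      }
    }
    return XPtr<BranchCache>(new BranchCache(), true);
  }();
  BranchCache& cc = *cp;
  cc.n = n; cc.C = C; cc.T = T; cc.T1 = T1; cc.T2 = T2;
  cc.f1 = f1; cc.D = D; cc.f2 = f2; cc.k = k; cc.sepk = sepk;
  cc.p1 = p1; cc.p2 = p2; cc.train = train;

  // channel-major copy of the input
  const double* xp = X.begin();
  cc.M.set_size(C * n, T);
  for (int t = 0; t < T; ++t) {
    double* mcol = cc.M.colptr(t);
    const double* xsl = xp + (size_t)n * C * t;
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < C; ++c) mcol[c + C * i] = xsl[i + n * c];
    }
  }

  // temporal convolution
  cc.Aall.zeros(T, T * f1);
  for (int f = 0; f < f1; ++f) {
    arma::rowvec w = W_temp.row(f);
    band_fill(cc.Aall, w.memptr(), k, T, 0, f * T);
  }
  cc.Y1 = cc.M * cc.Aall;                              // (C*n) x (T*f1)
  arma::mat Y1v(cc.Y1.memptr(), (size_t)C * n * T, f1, false, true);

  arma::vec mu1, v1;
  arma::vec rm1 = as<arma::vec>(state["mean1"]), rv1 = as<arma::vec>(state["var1"]);
  if (train) {
    bn_stats(Y1v, mu1, v1);
    rm1 = (1 - BN_MOMENTUM) * rm1 + BN_MOMENTUM * mu1;
    rv1 = (1 - BN_MOMENTUM) * rv1 + BN_MOMENTUM * v1;
  } else { mu1 = rm1; v1 = rv1; }
  cc.si1 = 1.0 / arma::sqrt(v1 + BN_EPS);
  bn_elu_apply(Y1v, cc.xhat1, cc.E1, mu1, cc.si1, g1, b1);

  // depthwise spatial convolution: contract over channels per filter
  cc.Z2.set_size((size_t)n * T, f2);
  arma::mat& Z2 = cc.Z2;
  for (int f = 0; f < f1; ++f) {
    arma::mat Mp(const_cast<double*>(cc.E1.colptr(f)), C, (size_t)n * T, false, true);
    arma::mat Wf = W_dw.slice(f);                      // D x C
    arma::mat Zf = Wf * Mp;                            // D x (n*T)
    for (int d = 0; d < D; ++d) {
      double* zcol = Z2.colptr(f * D + d);
      const double* zr = Zf.memptr() + d;
      const size_t nt = (size_t)n * T;
      for (size_t j = 0; j < nt; ++j) zcol[j] = zr[j * D];
    }
  }
  arma::vec mu2, v2;
  arma::vec rm2 = as<arma::vec>(state["mean2"]), rv2 = as<arma::vec>(state["var2"]);
  if (train) {
    bn_stats(Z2, mu2, v2);
    rm2 = (1 - BN_MOMENTUM) * rm2 + BN_MOMENTUM * mu2;
    rv2 = (1 - BN_MOMENTUM) * rv2 + BN_MOMENTUM * v2;
  } else { mu2 = rm2; v2 = rv2; }
  cc.si2 = 1.0 / arma::sqrt(v2 + BN_EPS);
  bn_elu_apply(Z2, cc.xhat2, cc.E2, mu2, cc.si2, g2, b2);

  if (train && dropout_p > 0) {
    dropout_apply(cc.E2, dropout_p, cc.mask2, cc.D2);
  } else {
    cc.D2 = cc.E2;
  }
  arma::mat D2v(cc.D2.memptr(), n, (size_t)T * f2, false, true);
  avgpool(D2v, T, f2, p1, cc.P2);                      // n x (T1*f2)

  // separable convolution: per-map temporal kernel, then pointwise mixing
  cc.S.set_size(n, (size_t)T1 * f2);
  for (int m = 0; m < f2; ++m) {
    arma::mat Am(T1, T1, arma::fill::zeros);
    arma::rowvec w = W_sepd.row(m);
    band_fill(Am, w.memptr(), sepk, T1, 0, 0);
    cc.S.cols((size_t)m * T1, (size_t)(m + 1) * T1 - 1) =
      cc.P2.cols((size_t)m * T1, (size_t)(m + 1) * T1 - 1) * Am;
  }
  arma::mat Vs(cc.S.memptr(), (size_t)n * T1, f2, false, true);
  cc.U = Vs * W_sepp.t();                              // (n*T1) x f2
  arma::mat& U = cc.U;

  arma::vec mu3, v3;
  arma::vec rm3 = as<arma::vec>(state["mean3"]), rv3 = as<arma::vec>(state["var3"]);
  if (train) {
    bn_stats(U, mu3, v3);
    rm3 = (1 - BN_MOMENTUM) * rm3 + BN_MOMENTUM * mu3;
    rv3 = (1 - BN_MOMENTUM) * rv3 + BN_MOMENTUM * v3;
  } else { mu3 = rm3; v3 = rv3; }
  cc.si3 = 1.0 / arma::sqrt(v3 + BN_EPS);
  bn_elu_apply(U, cc.xhat3, cc.E3, mu3, cc.si3, g3, b3);

  if (train && dropout_p > 0) {
    dropout_apply(cc.E3, dropout_p, cc.mask3, cc.D3);
  } else {
    cc.D3 = cc.E3;
  }
  arma::mat D3v(cc.D3.memptr(), n, (size_t)T1 * f2, false, true);
  avgpool(D3v, T1, f2, p2, cc.Fout);                   // n x (T2*f2)

  return List::create(
    _["out"] = wrap(cc.Fout),
    _["state"] = List::create(
      _["mean1"] = wrap(rm1), _["var1"] = wrap(rv1),
      _["mean2"] = wrap(rm2), _["var2"] = wrap(rv2),
      _["mean3"] = wrap(rm3), _["var3"] = wrap(rv3)),
    _["cache"] = cp);
}

// [[Rcpp::export]]
List branch_bwd_cpp(SEXP cache, List params, NumericMatrix dF,
                    bool need_input_grad) {
  XPtr<BranchCache> cp(cache);
  BranchCache& cc = *cp;
  const int n = cc.n, C = cc.C, T = cc.T, T1 = cc.T1;
  const int f1 = cc.f1, D = cc.D, f2 = cc.f2;
  arma::cube W_dw = as<arma::cube>(params["W_dw"]);
  arma::mat W_sepd = as<arma::mat>(params["W_sepd"]);
  arma::mat W_sepp = as<arma::mat>(params["W_sepp"]);
  arma::vec g1 = as<arma::vec>(params["bn1_gamma"]);
  arma::vec g2 = as<arma::vec>(params["bn2_gamma"]);
  arma::vec g3 = as<arma::vec>(params["bn3_gamma"]);

  arma::mat dFm = as<arma::mat>(dF);
  arma::mat dD3;
  avgpool_back(dFm, T1, f2, cc.p2, dD3);
  arma::mat dD3v(dD3.memptr(), (size_t)n * T1, f2, false, true);
  if (cc.train && cc.mask3.n_elem > 0) dD3v %= cc.mask3;
  arma::mat dU;
  arma::vec dg3, db3;
  bn_elu_backward(dD3v, cc.E3, cc.xhat3, g3, cc.si3, cc.train, dU, dg3, db3);

  arma::mat Vs(cc.S.memptr(), (size_t)n * T1, f2, false, true);
  arma::mat dW_sepp = dU.t() * Vs;
  arma::mat dVs = dU * W_sepp;
  arma::mat dSv(dVs.memptr(), n, (size_t)T1 * f2, false, true);

  arma::mat dP2(n, (size_t)T1 * f2);
  arma::mat dW_sepd(f2, cc.sepk);
  std::vector<double> gw(std::max(cc.sepk, cc.k));
  for (int m = 0; m < f2; ++m) {
    arma::mat Am(T1, T1, arma::fill::zeros);
    arma::rowvec w = W_sepd.row(m);
    band_fill(Am, w.memptr(), cc.sepk, T1, 0, 0);
    const arma::mat dSm = dSv.cols((size_t)m * T1, (size_t)(m + 1) * T1 - 1);
    const arma::mat P2m = cc.P2.cols((size_t)m * T1, (size_t)(m + 1) * T1 - 1);
    dP2.cols((size_t)m * T1, (size_t)(m + 1) * T1 - 1) = dSm * Am.t();
    arma::mat dAm = P2m.t() * dSm;
    band_grad(dAm, cc.sepk, 0, 0, T1, gw.data());
    for (int j = 0; j < cc.sepk; ++j) dW_sepd(m, j) = gw[j];
  }

  arma::mat dD2;
  avgpool_back(dP2, T, f2, cc.p1, dD2);
  arma::mat dD2v(dD2.memptr(), (size_t)n * T, f2, false, true);
  if (cc.train && cc.mask2.n_elem > 0) dD2v %= cc.mask2;
  arma::mat dZ2;
  arma::vec dg2, db2;
  bn_elu_backward(dD2v, cc.E2, cc.xhat2, g2, cc.si2, cc.train, dZ2, dg2, db2);

  cc.dE1.set_size((size_t)C * n * T, f1);
  arma::mat& dE1 = cc.dE1;
  arma::cube dW_dw(D, C, f1);
  for (int f = 0; f < f1; ++f) {
    arma::mat dZf(D, (size_t)n * T);
    for (int d = 0; d < D; ++d) {
      const double* zcol = dZ2.colptr(f * D + d);
      double* zr = dZf.memptr() + d;
      const size_t nt = (size_t)n * T;
      for (size_t j = 0; j < nt; ++j) zr[j * D] = zcol[j];
    }
    arma::mat Mp(const_cast<double*>(cc.E1.colptr(f)), C, (size_t)n * T, false, true);
    dW_dw.slice(f) = dZf * Mp.t();
    arma::mat Wf = W_dw.slice(f);
    arma::mat dMp(dE1.colptr(f), C, (size_t)n * T, false, true);
    dMp = Wf.t() * dZf;
  }
  arma::vec dg1, db1;
  bn_elu_backward(dE1, cc.E1, cc.xhat1, g1, cc.si1, cc.train, cc.dY1, dg1, db1);
  arma::mat dY1v(cc.dY1.memptr(), (size_t)C * n, (size_t)T * f1, false, true);

  arma::mat dAall = cc.M.t() * dY1v;                   // T x (T*f1)
  arma::mat dW_temp(f1, cc.k);
  for (int f = 0; f < f1; ++f) {
    band_grad(dAall, cc.k, 0, f * T, T, gw.data());
    for (int j = 0; j < cc.k; ++j) dW_temp(f, j) = gw[j];
  }

  List grads = List::create(
    _["W_temp"] = wrap(dW_temp),
    _["bn1_gamma"] = wrap(dg1), _["bn1_beta"] = wrap(db1),
    _["W_dw"] = wrap(dW_dw),
    _["bn2_gamma"] = wrap(dg2), _["bn2_beta"] = wrap(db2),
    _["W_sepd"] = wrap(dW_sepd), _["W_sepp"] = wrap(dW_sepp),
    _["bn3_gamma"] = wrap(dg3), _["bn3_beta"] = wrap(db3));

  List out = List::create(_["grads"] = grads);
  if (need_input_grad) {
    arma::mat dM = dY1v * cc.Aall.t();                 // (C*n) x T
    NumericVector dX((size_t)n * C * T);
    dX.attr("dim") = IntegerVector::create(n, C, T);
    double* dxp = dX.begin();
    for (int t = 0; t < T; ++t) {
      const double* mcol = dM.colptr(t);
      double* xsl = dxp + (size_t)n * C * t;
      for (int i = 0; i < n; ++i) {
        for (int c = 0; c < C; ++c) xsl[i + n * c] = mcol[c + C * i];
      }
    }
    out["dX"] = dX;
  }
  return out;
}
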