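// Quasi-Poisson deviance kernels for the multisensory response model.
// Per-neuron data arrive as one matrix M with fixed columns:
//   0 Robs, 1 theta, 2 w (= 2 Robs / theta), 3 wz (= 2 / theta),
//   4 zero flag, 5 I_V, 6 I_A, 7 phi_V, 8 phi_A, 9 vnum, 10 anum,
//   11 vidx (1-based), 12 aidx (1-based),
//   13 ivu (1-based index into unique I_V levels), 14 iau,
//   15 phiVu (index into unique visual azimuths), 16 phiAu.
// Unique level vectors ride along as matrix attributes "uiv", "uia",
// "uphiV", "uphiA". The factorial design has only a handful of unique
// intensity and azimuth levels, so all sigmoid / Gaussian evaluations are
// cached per level instead of per row.
// Parameter layout per neuron: F_V[0..nv-1], I_V50, n_V, F_A[0..na-1],
// I_A50, n_A, alpha, phi_eff. Global: A_e, sig_e, I50_e, n_e, A_i,
// sig_i, I50_i, n_i. variant: 0 = L, 1 = AM, 2 = VM.
#include <Rcpp.h>
using namespace Rcpp;

static inline double sig(double I, double I50, double n) {
  if (I <= 0.0) return n == 0.0 ? 0.5 : 0.0;
  double r = std::pow(I / I50, n);
  if (!std::isfinite(r)) return 1.0;
  return r / (1.0 + r);
}

static inline double gau(double x, double s) {
  double z = x / s;
  return std::exp(-0.5 * z * z);
}

static double neuron_devgrad(const NumericMatrix& M, double b, int nv,
                             const double* p, int npar,
                             const double* g, int variant,
                             double floor_, bool want_grad, bool wantg,
                             double* grad, double* gglob) {
  int m = M.nrow();
  int na = npar - nv - 6;
  double IV50 = p[nv], nV = p[nv + 1];
  double IA50 = p[nv + 2 + na], nA = p[nv + 3 + na];
  double alpha = p[npar - 2], phi_eff = p[npar - 1];
  double la = (variant == 0) ? 0.0 : std::log(alpha);
  double Ae = g[0], se = g[1], I50e = g[2], ne = g[3];
  double Ai = g[4], si = g[5], I50i = g[6], ni = g[7];
  const double* Robs = &M(0, 0);
  const double* theta = &M(0, 1);
  const double* w = &M(0, 2);
  const double* wz = &M(0, 3);
  const double* zero = &M(0, 4);
  const double* iv = &M(0, 5);
  const double* ia = &M(0, 6);
  const double* phiV = &M(0, 7);
  const double* phiA = &M(0, 8);
  const double* vnum = &M(0, 9);
  const double* anum = &M(0, 10);
  const double* vidx = &M(0, 11);
  const double* aidx = &M(0, 12);
  const double* ivu = &M(0, 13);
  const double* iau = &M(0, 14);
  const double* phiVu = &M(0, 15);
  const double* phiAu = &M(0, 16);
  NumericVector uiv = M.attr("uiv"), uia = M.attr("uia"),
    uphiV = M.attr("uphiV"), uphiA = M.attr("uphiA");

  // per-level caches for the unisensory sigmoids
  int KV = uiv.size(), KA = uia.size();
  std::vector<double> Svu(KV), s1vu(KV), lvu(KV), Sau(KA), s1au(KA), lau(KA);
  for (int k = 0; k < KV; ++k) {
    Svu[k] = sig(uiv[k], IV50, nV);
    s1vu[k] = Svu[k] * (1.0 - Svu[k]);
    lvu[k] = uiv[k] > 0 ? std::log(uiv[k] / IV50) : 0.0;
  }
  for (int k = 0; k < KA; ++k) {
    Sau[k] = sig(uia[k], IA50, nA);
    s1au[k] = Sau[k] * (1.0 - Sau[k]);
    lau[k] = uia[k] > 0 ? std::log(uia[k] / IA50) : 0.0;
  }

  // per-level caches for the modulation function (modulating modality)
  const double* mphiu_row = nullptr; const double* miu_row = nullptr;
  const double* mnum_v = nullptr; const double* mIrow = nullptr;
  int KP = 0, KI = 0;
  std::vector<double> Geu, Giu, Seu, Siu, s1eu, s1iu, leu, liu, mIu;
  if (variant != 0) {
    NumericVector uphi = (variant == 1) ? uphiA : uphiV;
    NumericVector uI = (variant == 1) ? uia : uiv;
    mphiu_row = (variant == 1) ? phiAu : phiVu;
    miu_row = (variant == 1) ? iau : ivu;
    mnum_v = (variant == 1) ? anum : vnum;
    mIrow = (variant == 1) ? ia : iv;
    KP = uphi.size(); KI = uI.size();
    Geu.resize(KP); Giu.resize(KP);
    Seu.resize(KI); Siu.resize(KI);
    s1eu.resize(KI); s1iu.resize(KI); leu.resize(KI); liu.resize(KI);
    mIu.resize(KI);
    for (int k = 0; k < KP; ++k) {
      Geu[k] = gau(phi_eff - uphi[k], se);
      Giu[k] = gau(phi_eff - uphi[k], si);
    }
    for (int k = 0; k < KI; ++k) {
      mIu[k] = uI[k];
      Seu[k] = sig(uI[k], I50e, ne);
      Siu[k] = sig(uI[k], I50i, ni);
      s1eu[k] = Seu[k] * (1.0 - Seu[k]);
      s1iu[k] = Siu[k] * (1.0 - Siu[k]);
      leu[k] = uI[k] > 0 ? std::log(uI[k] / I50e) : 0.0;
      liu[k] = uI[k] > 0 ? std::log(uI[k] / I50i) : 0.0;
    }
  }
  // modulation coefficient per (azimuth level, intensity level)
  std::vector<double> deltau(KP * KI), coefu(KP * KI);
  if (variant != 0) {
    for (int a = 0; a < KP; ++a) for (int i = 0; i < KI; ++i) {
      double d = Ae * Geu[a] * Seu[i] - Ai * Giu[a] * Siu[i];
      deltau[a * KI + i] = d;
      coefu[a * KI + i] = std::exp(d * la);
    }
  }

  double dev = 0.0;
  for (int j = 0; j < m; ++j) {
    double Sv = vnum[j] > 0 ? Svu[(int)ivu[j] - 1] : 0.0;
    double Sa = anum[j] > 0 ? Sau[(int)iau[j] - 1] : 0.0;
    int vj = (int)vidx[j] - 1, aj = nv + 2 + (int)aidx[j] - 1;
    double Fv = p[vj], Fa = p[aj];
    double lin = b + Fv * Sv + Fa * Sa;
    double delta = 0.0, coef = 1.0;
    int ap = 0, ii = 0;
    bool modded = false;
    if (variant != 0 && mnum_v[j] > 0) {
      modded = true;
      ap = (int)mphiu_row[j] - 1;
      ii = (int)miu_row[j] - 1;
      delta = deltau[ap * KI + ii];
      coef = coefu[ap * KI + ii];
    }
    double Rraw = coef * lin;
    bool active = Rraw > floor_;
    double R = active ? Rraw : floor_;
    if (zero[j] > 0) dev += wz[j] * R;
    else {
      double r = R / Robs[j];
      dev += w[j] * (r - 1.0 - std::log(r));
    }
    if (!want_grad || !active) continue;
    double gR = (2.0 / theta[j]) * (1.0 - Robs[j] / R);
    double gc = gR * coef;
    grad[vj] += gc * Sv;
    if (vnum[j] > 0 && iv[j] > 0) {
      int k = (int)ivu[j] - 1;
      grad[nv] += gc * Fv * (-nV / IV50) * s1vu[k];
      grad[nv + 1] += gc * Fv * s1vu[k] * lvu[k];
    }
    grad[aj] += gc * Sa;
    if (anum[j] > 0 && ia[j] > 0) {
      int k = (int)iau[j] - 1;
      grad[nv + 2 + na] += gc * Fa * (-nA / IA50) * s1au[k];
      grad[nv + 3 + na] += gc * Fa * s1au[k] * lau[k];
    }
    if (modded) {
      double gRr = gR * Rraw;
      double dphi = phi_eff - ((variant == 1) ? phiA[j] : phiV[j]);
      double Ge = Geu[ap], Gi = Giu[ap], Se = Seu[ii], Si = Siu[ii];
      grad[npar - 2] += gRr * delta / alpha;
      double dde = Ae * Se * Ge * (-dphi / (se * se)) -
        Ai * Si * Gi * (-dphi / (si * si));
      grad[npar - 1] += gRr * la * dde;
      if (wantg) {
        double t0 = gRr * la;
        gglob[0] += t0 * Ge * Se;
        gglob[1] += t0 * Ae * Se * Ge * (dphi * dphi / (se * se * se));
        gglob[2] += t0 * Ae * Ge * (-ne / I50e) * s1eu[ii];
        gglob[3] += t0 * Ae * Ge * s1eu[ii] * leu[ii];
        gglob[4] -= t0 * Gi * Si;
        gglob[5] -= t0 * Ai * Si * Gi * (dphi * dphi / (si * si * si));
        gglob[6] -= t0 * Ai * Gi * (-ni / I50i) * s1iu[ii];
        gglob[7] -= t0 * Ai * Gi * s1iu[ii] * liu[ii];
      }
    }
  }
  return dev;
}

// [[Rcpp::export]]
double cpp_neuron_dev(NumericMatrix M, double b, int nv, NumericVector p,
                      NumericVector g, int variant, double floor_) {
  return neuron_devgrad(M, b, nv, REAL(p), p.size(), REAL(g), variant,
                        floor_, false, false, nullptr, nullptr);
}

// [[Rcpp::export]]
NumericVector cpp_neuron_grad(NumericMatrix M, double b, int nv,
                              NumericVector p, NumericVector g,
                              int variant, double floor_, bool wantg) {
  NumericVector grad(p.size());
  NumericVector gg(8);
  neuron_devgrad(M, b, nv, REAL(p), p.size(), REAL(g), variant, floor_,
                 true, wantg, REAL(grad), REAL(gg));
  if (wantg) grad.attr("global") = gg;
  return grad;
}

// [[Rcpp::export]]
double cpp_total_dev(List Ms, NumericVector bs, int nv, List plist,
                     NumericVector g, int variant, double floor_) {
  double dev = 0.0;
  for (int i = 0; i < Ms.size(); ++i) {
    NumericMatrix M = Ms[i];
    NumericVector p = plist[i];
    dev += neuron_devgrad(M, bs[i], nv, REAL(p), p.size(), REAL(g),
                          variant, floor_, false, false, nullptr, nullptr);
  }
  return dev;
}

// full gradient of the total deviance: per-neuron blocks concatenated,
// then the 8 shared parameters (zeros for the linear model)
// [[Rcpp::export]]
NumericVector cpp_total_grad(List Ms, NumericVector bs, int nv, List plist,
                             NumericVector g, int variant, double floor_) {
  int N = Ms.size();
  NumericVector p0 = plist[0];
  int npar = p0.size();
  NumericVector out(N * npar + 8);
  double* gg = REAL(out) + N * npar;
  for (int i = 0; i < N; ++i) {
    NumericMatrix M = Ms[i];
    NumericVector p = plist[i];
    neuron_devgrad(M, bs[i], nv, REAL(p), npar, REAL(g), variant, floor_,
                   true, variant != 0, REAL(out) + i * npar, gg);
  }
  return out;
}
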