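// Adaptive Metropolis-within-Gibbs sampler for the response-time-based
// latent response mixture IRT model of faking, over the likelihood with the
// discrete person-by-item strategy classes marginalized out (3-term
// log-sum-exp per cell). Also handles the reduced comparison models:
// person-level mixture (constant class per person, flat Dirichlet prior on
// the mixing proportions) and the single-class non-mixture response models.
//
// Per-cell per-class log-likelihood slices are cached; every Metropolis
// block recomputes only the slice it touches. All randomness comes from
// R's RNG so set.seed() in R gives bit-reproducible fits.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdio>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// ---- small dense linear algebra (P <= ~8) --------------------------------

// Cholesky, lower triangular; returns false if not PD
static bool chol_pd(const std::vector<double>& S, int P,
                    std::vector<double>& L) {
  L.assign(P * P, 0.0);
  for (int j = 0; j < P; ++j) {
    double d = S[j * P + j];
    for (int k = 0; k < j; ++k) d -= L[j * P + k] * L[j * P + k];
    if (d <= 1e-12) return false;
    L[j * P + j] = std::sqrt(d);
    for (int i = j + 1; i < P; ++i) {
      double s = S[i * P + j];
      for (int k = 0; k < j; ++k) s -= L[i * P + k] * L[j * P + k];
      L[i * P + j] = s / L[j * P + j];
    }
  }
  return true;
}

static double chol_logdet(const std::vector<double>& L, int P) {
  double s = 0.0;
  for (int j = 0; j < P; ++j) s += std::log(L[j * P + j]);
  return 2.0 * s;
}

// inverse from Cholesky
static void chol_inverse(const std::vector<double>& L, int P,
                         std::vector<double>& Inv) {
  // invert L (lower), then Inv = L^-T L^-1
  std::vector<double> Li(P * P, 0.0);
  for (int j = 0; j < P; ++j) {
    Li[j * P + j] = 1.0 / L[j * P + j];
    for (int i = j + 1; i < P; ++i) {
      double s = 0.0;
      for (int k = j; k < i; ++k) s += L[i * P + k] * Li[k * P + j];
      Li[i * P + j] = -s / L[i * P + i];
    }
  }
  Inv.assign(P * P, 0.0);
  for (int i = 0; i < P; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int k = i; k < P; ++k) s += Li[k * P + i] * Li[k * P + j];
      Inv[i * P + j] = Inv[j * P + i] = s;
    }
}

static inline double lse3(double a, double b, double c) {
  double m = a > b ? (a > c ? a : c) : (b > c ? b : c);
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

// ---- sampler state --------------------------------------------------------

struct Model {
  int N, I, D, K1, P;
  int mixture;        // 0 none, 1 person, 2 person-by-item
  bool rt;
  int resp_class;     // active class when mixture == 0
  bool use_theta, use_eta, use_phi, use_psi;
  int col_theta0, col_eta, col_phi, col_psi;   // -1 if absent

  const int* y;                 // N x I (column-major from R)
  std::vector<double> lt;       // log response times
  const double* ws;             // I x D x K1
  const double* wf;             // I x K1

  // which trait dims each item loads on, and items per trait dim
  std::vector<std::vector<int>> item_dims;    // per item
  std::vector<std::vector<int>> trait_items;  // per dim

  // parameters
  std::vector<double> x;        // N x P person scores (row-major n*P+p)
  std::vector<double> aS;       // I x D (row-major i*D+d)
  std::vector<double> aF;       // I
  std::vector<double> gS, gSF, gF;  // I x K1 (i*K1+k), col 0 fixed 0
  std::vector<double> beta;     // I x 3 (i*3+c), col 0 fixed 0
  std::vector<double> dS, dF;   // I
  double nphi, npsi, lam, sig[3];
  std::vector<double> Sig, Sinv, Lchol;  // P x P
  double logdetS;
  double lpi[3];                // log mixing proportions (mixture == 1)

  // priors
  double slope_sd, intercept_sd, delta_mean, delta_sd, lambda_sd, cauchy_scale;

  // caches
  std::vector<double> respLL, rtLL, clsLP;  // N*I*3, idx (n*I+i)*3+c
  std::vector<double> proY;   // propensity of the observed category, same idx
  std::vector<double> cellM;  // N*I marginal cell loglik (mixture == 2)
  std::vector<double> Snc;                  // N*3 person-class sums (mix==1)
  std::vector<double> Sx;                   // P x P sum of x x^T

  inline int cix(int n, int i, int c) const { return (n * I + i) * 3 + c; }
  inline double w_trait(int i, int d, int k) const {
    return ws[i + I * (d + D * k)];
  }
  inline double w_fake(int i, int k) const { return wf[i + I * k]; }

  bool class_active(int c) const {
    if (mixture > 0) return true;
    return c == resp_class;
  }

  // response log-likelihood of cell (n,i) in class c, with overridable
  // item-side parameters (pass current values for the usual case);
  // also returns the observed-category propensity so that scalar
  // intercept updates can adjust the normalizer incrementally
  double resp_ll(int n, int i, int c, const double* aS_row, double aF_i,
                 const double* gamma_row, const double* xrow,
                 double* pro_obs) const {
    double pro[16];
    double eta = use_eta ? xrow[col_eta] : 0.0;
    double mx = -1e300;
    for (int k = 0; k < K1; ++k) {
      double v = gamma_row[k];
      if (c != 2 && use_theta) {
        for (size_t j = 0; j < item_dims[i].size(); ++j) {
          int d = item_dims[i][j];
          v += aS_row[d] * w_trait(i, d, k) * xrow[col_theta0 + d];
        }
      }
      if (c != 0 && use_eta) v += aF_i * w_fake(i, k) * eta;
      pro[k] = v;
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int k = 0; k < K1; ++k) s += std::exp(pro[k] - mx);
    double po = pro[y[n + N * i]];
    if (pro_obs) *pro_obs = po;
    return po - mx - std::log(s);
  }

  double resp_ll_cur(int n, int i, int c, double* pro_obs) {
    const double* g = (c == 0) ? &gS[i * K1] : (c == 1) ? &gSF[i * K1]
                                             : &gF[i * K1];
    return resp_ll(n, i, c, &aS[i * D], aF[i], g, &x[n * P], pro_obs);
  }

  // propensity of one category k for cell (n,i), class c (current params)
  double pro_cat(int n, int i, int c, int k) const {
    double v = (c == 0) ? gS[i * K1 + k] : (c == 1) ? gSF[i * K1 + k]
                                                    : gF[i * K1 + k];
    if (c != 2 && use_theta)
      for (size_t j = 0; j < item_dims[i].size(); ++j) {
        int d = item_dims[i][j];
        v += aS[i * D + d] * w_trait(i, d, k) * x[n * P + col_theta0 + d];
      }
    if (c != 0 && use_eta)
      v += aF[i] * w_fake(i, k) * x[n * P + col_eta];
    return v;
  }

  // log-normal RT log-density for cell (n,i), class c, overridable pieces
  double rt_ll(int n, int i, int c, double dS_i, double dF_i, double nphi_,
               double lam_, double sig_c, double phi_n) const {
    double m = (c == 0) ? dS_i : (c == 1) ? dS_i + lam_ * dF_i : dF_i;
    m -= nphi_ * phi_n;
    double z = (lt[n + (size_t)N * i] - m) / sig_c;
    return -std::log(sig_c) - 0.5 * LOG2PI - 0.5 * z * z -
           lt[n + (size_t)N * i];
  }

  double rt_ll_cur(int n, int i, int c) const {
    return rt_ll(n, i, c, dS[i], dF[i], nphi, lam, sig[c],
                 use_phi ? x[n * P + col_phi] : 0.0);
  }

  void class_lp(int n, int i, double npsi_, double b1, double b2,
                double* out) const {
    double psi = use_psi ? x[n * P + col_psi] : 0.0;
    double z1 = npsi_ * psi + b1, z2 = 2.0 * npsi_ * psi + b2;
    double l = lse3(0.0, z1, z2);
    out[0] = -l; out[1] = z1 - l; out[2] = z2 - l;
  }

  // marginal cell log-likelihood from caches (mixture 0 or 2)
  double cell_ll(int n, int i) const {
    if (mixture == 0) {
      double v = respLL[cix(n, i, resp_class)];
      if (rt) v += rtLL[cix(n, i, resp_class)];
      return v;
    }
    int b = cix(n, i, 0);
    double a0 = clsLP[b] + respLL[b], a1 = clsLP[b + 1] + respLL[b + 1],
           a2 = clsLP[b + 2] + respLL[b + 2];
    if (rt) { a0 += rtLL[b]; a1 += rtLL[b + 1]; a2 += rtLL[b + 2]; }
    return lse3(a0, a1, a2);
  }

  // person-level log-likelihood (mixture == 1) from Snc
  double person_ll(int n) const {
    return lse3(lpi[0] + Snc[n * 3], lpi[1] + Snc[n * 3 + 1],
                lpi[2] + Snc[n * 3 + 2]);
  }

  void refresh_caches() {
    for (int n = 0; n < N; ++n)
      for (int i = 0; i < I; ++i)
        for (int c = 0; c < 3; ++c) {
          if (!class_active(c)) continue;
          respLL[cix(n, i, c)] = resp_ll_cur(n, i, c, &proY[cix(n, i, c)]);
          if (rt) rtLL[cix(n, i, c)] = rt_ll_cur(n, i, c);
        }
    if (mixture == 2) {
      for (int n = 0; n < N; ++n)
        for (int i = 0; i < I; ++i)
          class_lp(n, i, npsi, beta[i * 3 + 1], beta[i * 3 + 2],
                   &clsLP[cix(n, i, 0)]);
    }
    if (mixture != 1) {
      for (int n = 0; n < N; ++n)
        for (int i = 0; i < I; ++i) cellM[n * I + i] = cell_ll(n, i);
    }
    if (mixture == 1) {
      std::fill(Snc.begin(), Snc.end(), 0.0);
      for (int n = 0; n < N; ++n)
        for (int i = 0; i < I; ++i)
          for (int c = 0; c < 3; ++c) {
            double v = respLL[cix(n, i, c)];
            if (rt) v += rtLL[cix(n, i, c)];
            Snc[n * 3 + c] += v;
          }
    }
    // person scatter matrix for Sigma updates
    std::fill(Sx.begin(), Sx.end(), 0.0);
    for (int n = 0; n < N; ++n)
      for (int a = 0; a < P; ++a)
        for (int b = 0; b < P; ++b)
          Sx[a * P + b] += x[n * P + a] * x[n * P + b];
  }

  double total_loglik(bool with_rt) const {
    double s = 0.0;
    if (mixture == 1) {
      for (int n = 0; n < N; ++n) {
        if (with_rt || !rt) {
          if (!with_rt && rt) break;
          s += person_ll(n);
        }
      }
      if (!with_rt && rt) {
        // response-only: rebuild person sums without RT factors
        for (int n = 0; n < N; ++n) {
          double t0 = 0, t1 = 0, t2 = 0;
          for (int i = 0; i < I; ++i) {
            t0 += respLL[cix(n, i, 0)];
            t1 += respLL[cix(n, i, 1)];
            t2 += respLL[cix(n, i, 2)];
          }
          s += lse3(lpi[0] + t0, lpi[1] + t1, lpi[2] + t2);
        }
      }
      return s;
    }
    for (int n = 0; n < N; ++n)
      for (int i = 0; i < I; ++i) {
        if (mixture == 0) {
          double v = respLL[cix(n, i, resp_class)];
          if (rt && with_rt) v += rtLL[cix(n, i, resp_class)];
          s += v;
        } else if (with_rt || !rt) {
          s += cell_ll(n, i);
        } else {
          int b = cix(n, i, 0);
          s += lse3(clsLP[b] + respLL[b], clsLP[b + 1] + respLL[b + 1],
                    clsLP[b + 2] + respLL[b + 2]);
        }
      }
    return s;
  }
};

// adaptation helper: Robbins-Monro on the log step size
struct Adapt {
  std::vector<double> ls;
  double target;
  explicit Adapt(int n = 0, double init = -0.7, double target_ = 0.44)
      : ls(n, init), target(target_) {}
  void tune(int k, double acc, double gain) {
    ls[k] += gain * (acc - target);
    if (ls[k] > 3.0) ls[k] = 3.0;
    if (ls[k] < -8.0) ls[k] = -8.0;
  }
};

static inline double half_normal_lp(double v, double sd) {
  return -0.5 * v * v / (sd * sd);   // v > 0 enforced by caller
}
static inline double normal_lp(double v, double m, double sd) {
  double z = (v - m) / sd;
  return -0.5 * z * z;
}
static inline double half_cauchy_lp(double v, double s) {
  return -std::log(1.0 + (v / s) * (v / s));
}

// [[Rcpp::export]]
List fit_sampler_cpp(IntegerMatrix y, NumericMatrix logt, NumericVector ws,
                     NumericMatrix wf, List config, List priors, List mcmc,
                     List inits) {
  Model M;
  M.N = y.nrow(); M.I = y.ncol();
  IntegerVector wdim = as<IntegerVector>(
      as<RObject>(ws.attr("dim")));
  M.D = wdim[1]; M.K1 = wdim[2];
  if (M.K1 > 16) stop("At most 16 response categories supported.");
  M.mixture = as<int>(config["mixture"]);
  M.rt = as<bool>(config["include_rt"]);
  M.resp_class = as<int>(config["resp_class"]);
  M.y = INTEGER(y);
  M.ws = REAL(ws); M.wf = REAL(wf);
  M.lt.assign(M.N * (size_t)M.I, 0.0);
  if (M.rt) {
    for (R_xlen_t j = 0; j < logt.size(); ++j) M.lt[j] = logt[j];
  }

  // active person dimensions
  bool sf_class = M.mixture > 0;
  M.use_theta = sf_class || M.resp_class == 0 || M.resp_class == 1;
  M.use_eta = sf_class || M.resp_class == 1 || M.resp_class == 2;
  M.use_phi = M.rt;
  M.use_psi = M.mixture == 2;
  int p = 0;
  M.col_theta0 = M.use_theta ? p : -1; if (M.use_theta) p += M.D;
  M.col_eta = M.use_eta ? p++ : -1;
  M.col_phi = M.use_phi ? p++ : -1;
  M.col_psi = M.use_psi ? p++ : -1;
  M.P = p;

  M.item_dims.resize(M.I);
  M.trait_items.assign(M.D, {});
  for (int i = 0; i < M.I; ++i)
    for (int d = 0; d < M.D; ++d) {
      bool nz = false;
      for (int k = 0; k < M.K1; ++k)
        if (M.w_trait(i, d, k) != 0.0) { nz = true; break; }
      if (nz) { M.item_dims[i].push_back(d); M.trait_items[d].push_back(i); }
    }

  M.slope_sd = as<double>(priors["slope_sd"]);
  M.intercept_sd = as<double>(priors["intercept_sd"]);
  M.delta_mean = as<double>(priors["delta_mean"]);
  M.delta_sd = as<double>(priors["delta_sd"]);
  M.lambda_sd = as<double>(priors["lambda_sd"]);
  M.cauchy_scale = as<double>(priors["cauchy_scale"]);

  int n_chains = as<int>(mcmc["chains"]);
  int n_warm = as<int>(mcmc["warmup"]);
  int n_iter = as<int>(mcmc["iter"]);
  int thin = as<int>(mcmc["thin"]);
  double jitter = as<double>(mcmc["init_jitter"]);

  const int N = M.N, I = M.I, D = M.D, K1 = M.K1;
  const int P = M.P, K = K1 - 1;
  bool use_lam = M.rt && M.mixture > 0;

  // parameter layout for stored draws (persons stored separately)
  std::vector<std::string> names;
  char buf[64];
  for (int i = 0; i < I; ++i)
    if (M.use_theta)
      for (size_t j = 0; j < M.item_dims[i].size(); ++j) {
        std::snprintf(buf, 64, "alpha_s[%d,%d]", i + 1,
                      M.item_dims[i][j] + 1);
        names.push_back(buf);
      }
  if (M.use_eta)
    for (int i = 0; i < I; ++i) {
      std::snprintf(buf, 64, "alpha_f[%d]", i + 1); names.push_back(buf);
    }
  const char* gnames[3] = {"gamma_s", "gamma_sf", "gamma_f"};
  for (int c = 0; c < 3; ++c) {
    if (!M.class_active(c)) continue;
    for (int i = 0; i < I; ++i)
      for (int k = 1; k < K1; ++k) {
        std::snprintf(buf, 64, "%s[%d,%d]", gnames[c], i + 1, k);
        names.push_back(buf);
      }
  }
  if (M.mixture == 2)
    for (int i = 0; i < I; ++i)
      for (int c = 1; c < 3; ++c) {
        std::snprintf(buf, 64, "beta[%d,%d]", i + 1, c); names.push_back(buf);
      }
  if (M.rt) {
    for (int i = 0; i < I; ++i) {
      std::snprintf(buf, 64, "delta_s[%d]", i + 1); names.push_back(buf);
    }
    for (int i = 0; i < I; ++i) {
      std::snprintf(buf, 64, "delta_f[%d]", i + 1); names.push_back(buf);
    }
    names.push_back("nu_phi");
    names.push_back("sigma_s"); names.push_back("sigma_sf");
    names.push_back("sigma_f");
    if (use_lam) names.push_back("lambda");
  }
  if (M.mixture == 2) names.push_back("nu_psi");
  for (int a = 0; a < P; ++a)
    for (int b = a + 1; b < P; ++b) {
      std::snprintf(buf, 64, "Sigma[%d,%d]", a + 1, b + 1);
      names.push_back(buf);
    }
  if (M.mixture == 1)
    for (int c = 0; c < 3; ++c) {
      std::snprintf(buf, 64, "pi[%d]", c + 1); names.push_back(buf);
    }
  int n_par = (int)names.size();

  int n_save = n_chains * n_iter;
  NumericMatrix draws(n_save, n_par);
  NumericVector person_draws(Dimension(n_save, N, P));
  NumericVector ll_joint(n_save), ll_resp(n_save);
  IntegerVector chain_id(n_save);

  double mlt = 0.0, sdlt = 1.0;
  if (M.rt) {
    double s1 = 0, s2 = 0;
    for (size_t j = 0; j < M.lt.size(); ++j) { s1 += M.lt[j]; }
    mlt = s1 / M.lt.size();
    for (size_t j = 0; j < M.lt.size(); ++j) {
      s2 += (M.lt[j] - mlt) * (M.lt[j] - mlt);
    }
    sdlt = std::sqrt(s2 / (M.lt.size() - 1));
  }

  NumericMatrix init_gamma = as<NumericMatrix>(inits["gamma"]);
  NumericVector init_delta = as<NumericVector>(inits["delta"]);
  NumericMatrix init_theta = as<NumericMatrix>(inits["theta"]);
  NumericVector init_phi = as<NumericVector>(inits["phi"]);
  double init_sigma = as<double>(inits["sigma"]);

  GetRNGstate();
  int save_row = 0;
  for (int ch = 0; ch < n_chains; ++ch) {
    // ---- initialize (data-informed, jittered across chains) ----
    M.x.assign((size_t)N * P, 0.0);
    for (size_t j = 0; j < M.x.size(); ++j) M.x[j] = norm_rand() * 0.5;
    if (M.use_theta)
      for (int n = 0; n < N; ++n)
        for (int d = 0; d < D; ++d)
          M.x[n * P + M.col_theta0 + d] =
              init_theta(n, d) + norm_rand() * 0.5;
    if (M.use_phi)
      for (int n = 0; n < N; ++n)
        M.x[n * P + M.col_phi] = init_phi[n] + norm_rand() * 0.3;
    M.aS.assign((size_t)I * D, 0.0);
    for (int i = 0; i < I; ++i)
      for (size_t j = 0; j < M.item_dims[i].size(); ++j)
        M.aS[i * D + M.item_dims[i][j]] =
            std::exp(norm_rand() * jitter) * 0.8;
    M.aF.assign(I, 0.0);
    for (int i = 0; i < I; ++i)
      M.aF[i] = std::exp(norm_rand() * jitter) * 0.5;
    M.gS.assign((size_t)I * K1, 0.0);
    M.gSF.assign((size_t)I * K1, 0.0);
    M.gF.assign((size_t)I * K1, 0.0);
    for (int i = 0; i < I; ++i)
      for (int k = 1; k < K1; ++k) {
        M.gS[i * K1 + k] = init_gamma(i, k) + norm_rand() * jitter;
        M.gSF[i * K1 + k] = init_gamma(i, k) + norm_rand() * jitter;
        M.gF[i * K1 + k] = init_gamma(i, k) + norm_rand() * jitter;
      }
    M.beta.assign((size_t)I * 3, 0.0);
    for (int i = 0; i < I; ++i) {
      M.beta[i * 3 + 1] = -0.5 + norm_rand() * jitter;
      M.beta[i * 3 + 2] = -1.0 + norm_rand() * jitter;
    }
    M.dS.assign(I, 0.0); M.dF.assign(I, 0.0);
    for (int i = 0; i < I; ++i) {
      M.dS[i] = init_delta[i] + norm_rand() * jitter;
      M.dF[i] = init_delta[i] + norm_rand() * jitter;
    }
    M.nphi = std::exp(norm_rand() * jitter) * 0.8;
    M.npsi = std::exp(norm_rand() * jitter) * 1.0;
    M.lam = std::exp(norm_rand() * jitter) * 0.2;
    M.sig[0] = init_sigma * std::exp(norm_rand() * jitter);
    M.sig[1] = init_sigma * std::exp(norm_rand() * jitter);
    M.sig[2] = init_sigma * std::exp(norm_rand() * jitter);
    M.Sig.assign(P * P, 0.0);
    for (int a = 0; a < P; ++a) M.Sig[a * P + a] = 1.0;
    chol_pd(M.Sig, P, M.Lchol);
    M.logdetS = chol_logdet(M.Lchol, P);
    chol_inverse(M.Lchol, P, M.Sinv);
    double pa = 1.0 / 3.0;
    M.lpi[0] = M.lpi[1] = M.lpi[2] = std::log(pa);

    M.respLL.assign((size_t)N * I * 3, 0.0);
    M.proY.assign((size_t)N * I * 3, 0.0);
    M.cellM.assign((size_t)N * I, 0.0);
    M.rtLL.assign((size_t)N * I * 3, 0.0);
    M.clsLP.assign((size_t)N * I * 3, 0.0);
    M.Snc.assign((size_t)N * 3, 0.0);
    M.Sx.assign(P * P, 0.0);
    M.refresh_caches();

    // ---- adaptation state ----
    Adapt ad_person(N * P, std::log(0.4), 0.44);
    Adapt ad_aS(I * D, std::log(0.15), 0.44);
    Adapt ad_aF(I, std::log(0.15), 0.44);
    Adapt ad_gS(I * K1, std::log(0.3), 0.44),
        ad_gSF(I * K1, std::log(0.3), 0.44),
        ad_gF(I * K1, std::log(0.3), 0.44);
    Adapt ad_beta(I * 2, std::log(0.3), 0.44);
    Adapt ad_dS(I, std::log(0.1), 0.44), ad_dF(I, std::log(0.1), 0.44);
    Adapt ad_glob(8, std::log(0.05), 0.44);  // nphi,npsi,lam,3 sig
    Adapt ad_Sig(P * P, std::log(0.1), 0.44);
    Adapt ad_pi(2, std::log(0.2), 0.44);
    Adapt ad_scale(M.D + 3, std::log(0.1), 0.44);

    int total_sweeps = n_warm * thin + n_iter * thin;
    int warm_sweeps = n_warm * thin;
    std::vector<double> xprop(P), scr(7 * (size_t)(N > I ? N : I) + 16);

    for (int sweep = 0; sweep < total_sweeps; ++sweep) {
      bool adapting = sweep < warm_sweeps;
      double gain = adapting ? 2.0 / std::sqrt((double)sweep + 10.0) : 0.0;

      // ================= person updates =================
      for (int n = 0; n < N; ++n) {
        for (int pc = 0; pc < P; ++pc) {
          double step = std::exp(ad_person.ls[n * P + pc]);
          for (int a = 0; a < P; ++a) xprop[a] = M.x[n * P + a];
          xprop[pc] += step * norm_rand();
          // prior: MVN(0, Sigma) quadratic form
          double q_old = 0, q_new = 0;
          for (int a = 0; a < P; ++a)
            for (int b = 0; b < P; ++b) {
              q_old += M.x[n * P + a] * M.Sinv[a * P + b] * M.x[n * P + b];
              q_new += xprop[a] * M.Sinv[a * P + b] * xprop[b];
            }
          double delta = -0.5 * (q_new - q_old);

          // likelihood slices touched by this coordinate
          int kind = (M.use_theta && pc < M.col_theta0 + M.D &&
                      pc >= M.col_theta0) ? 0
                     : (pc == M.col_eta) ? 1
                     : (pc == M.col_phi) ? 2 : 3;
          const std::vector<int>* items_aff;
          std::vector<int> all_items;
          if (kind == 0) {
            items_aff = &M.trait_items[pc - M.col_theta0];
          } else {
            all_items.resize(I);
            for (int i = 0; i < I; ++i) all_items[i] = i;
            items_aff = &all_items;
          }
          int nit = (int)items_aff->size();
          double* nv = scr.data();  // new class-values, 3 per affected item
          double* nvP = nv + 3 * nit;   // proposed observed propensities
          double* ncell = nvP + 3 * nit;  // proposed cell marginals
          for (int j = 0; j < nit; ++j) {
            int i = (*items_aff)[j];
            double v0, v1, v2;
            int b = M.cix(n, i, 0);
            if (M.mixture == 2) {
              v0 = M.clsLP[b] + M.respLL[b];
              v1 = M.clsLP[b + 1] + M.respLL[b + 1];
              v2 = M.clsLP[b + 2] + M.respLL[b + 2];
              if (M.rt) { v0 += M.rtLL[b]; v1 += M.rtLL[b + 1];
                          v2 += M.rtLL[b + 2]; }
              if (kind == 0 || kind == 1) {
                int c_lo = (kind == 0) ? 0 : 1, c_hi = (kind == 0) ? 1 : 2;
                for (int c = c_lo; c <= c_hi; ++c) {
                  const double* g = (c == 0) ? &M.gS[i * K1]
                                  : (c == 1) ? &M.gSF[i * K1]
                                             : &M.gF[i * K1];
                  double po;
                  double r = M.resp_ll(n, i, c, &M.aS[i * D], M.aF[i], g,
                                       xprop.data(), &po);
                  nv[j * 3 + c] = r;
                  nvP[j * 3 + c] = po;
                  double add = M.clsLP[b + c] + r;
                  if (M.rt) add += M.rtLL[b + c];
                  if (c == 0) v0 = add; else if (c == 1) v1 = add;
                  else v2 = add;
                }
              } else if (kind == 2) {
                for (int c = 0; c < 3; ++c) {
                  double r = M.rt_ll(n, i, c, M.dS[i], M.dF[i], M.nphi,
                                     M.lam, M.sig[c], xprop[M.col_phi]);
                  nv[j * 3 + c] = r;
                  double add = M.clsLP[b + c] + M.respLL[b + c] + r;
                  if (c == 0) v0 = add; else if (c == 1) v1 = add;
                  else v2 = add;
                }
              } else {  // psi -> class propensities
                double lp[3];
                double psi_save = M.x[n * P + M.col_psi];
                M.x[n * P + M.col_psi] = xprop[M.col_psi];
                M.class_lp(n, i, M.npsi, M.beta[i * 3 + 1],
                           M.beta[i * 3 + 2], lp);
                M.x[n * P + M.col_psi] = psi_save;
                for (int c = 0; c < 3; ++c) {
                  nv[j * 3 + c] = lp[c];
                  double add = lp[c] + M.respLL[b + c];
                  if (M.rt) add += M.rtLL[b + c];
                  if (c == 0) v0 = add; else if (c == 1) v1 = add;
                  else v2 = add;
                }
              }
              ncell[j] = lse3(v0, v1, v2);
              delta += ncell[j] - M.cellM[n * I + i];
            } else if (M.mixture == 1) {
              // accumulate into proposed per-class sums below
            } else {  // mixture == 0
              int c = M.resp_class;
              double oldv = M.respLL[b + c];
              double newv = oldv;
              if (kind == 0 || kind == 1) {
                const double* g = (c == 0) ? &M.gS[i * K1]
                                : (c == 1) ? &M.gSF[i * K1]
                                           : &M.gF[i * K1];
                double po;
                newv = M.resp_ll(n, i, c, &M.aS[i * D], M.aF[i], g,
                                 xprop.data(), &po);
                nvP[j * 3 + c] = po;
              }
              nv[j * 3 + c] = newv;
              delta += newv - oldv;
            }
          }
          if (M.mixture == 1) {
            double Sn_new[3] = {M.Snc[n * 3], M.Snc[n * 3 + 1],
                                M.Snc[n * 3 + 2]};
            for (int j = 0; j < nit; ++j) {
              int i = (*items_aff)[j];
              int b = M.cix(n, i, 0);
              if (kind == 0 || kind == 1) {
                int c_lo = (kind == 0) ? 0 : 1, c_hi = (kind == 0) ? 1 : 2;
                for (int c = c_lo; c <= c_hi; ++c) {
                  const double* g = (c == 0) ? &M.gS[i * K1]
                                  : (c == 1) ? &M.gSF[i * K1]
                                             : &M.gF[i * K1];
                  double po;
                  double r = M.resp_ll(n, i, c, &M.aS[i * D], M.aF[i], g,
                                       xprop.data(), &po);
                  nv[j * 3 + c] = r;
                  nvP[j * 3 + c] = po;
                  Sn_new[c] += r - M.respLL[b + c];
                }
              } else if (kind == 2) {
                for (int c = 0; c < 3; ++c) {
                  double r = M.rt_ll(n, i, c, M.dS[i], M.dF[i], M.nphi,
                                     M.lam, M.sig[c], xprop[M.col_phi]);
                  nv[j * 3 + c] = r;
                  Sn_new[c] += r - M.rtLL[b + c];
                }
              }
            }
            double old_ll = M.person_ll(n);
            double new_ll = lse3(M.lpi[0] + Sn_new[0], M.lpi[1] + Sn_new[1],
                                 M.lpi[2] + Sn_new[2]);
            delta += new_ll - old_ll;
            if (std::log(unif_rand()) < delta) {
              double oldx = M.x[n * P + pc];
              for (int b2 = 0; b2 < P; ++b2) {
                if (b2 == pc) continue;
                double d2 = (xprop[pc] - oldx) * M.x[n * P + b2];
                M.Sx[pc * P + b2] += d2;
                M.Sx[b2 * P + pc] += d2;
              }
              M.Sx[pc * P + pc] += xprop[pc] * xprop[pc] - oldx * oldx;
              M.x[n * P + pc] = xprop[pc];
              for (int j = 0; j < nit; ++j) {
                int i = (*items_aff)[j];
                int b = M.cix(n, i, 0);
                if (kind == 0 || kind == 1) {
                  int c_lo = (kind == 0) ? 0 : 1, c_hi = (kind == 0) ? 1 : 2;
                  for (int c = c_lo; c <= c_hi; ++c) {
                    M.respLL[b + c] = nv[j * 3 + c];
                    M.proY[b + c] = nvP[j * 3 + c];
                  }
                } else if (kind == 2) {
                  for (int c = 0; c < 3; ++c) M.rtLL[b + c] = nv[j * 3 + c];
                }
              }
              for (int c = 0; c < 3; ++c) M.Snc[n * 3 + c] = Sn_new[c];
            }
            if (adapting)
              ad_person.tune(n * P + pc,
                             std::fmin(1.0, std::exp(delta)), gain);
            continue;
          }

          // mixture 0 / 2 accept step
          if (std::log(unif_rand()) < delta) {
            double oldx = M.x[n * P + pc];
            for (int b2 = 0; b2 < P; ++b2) {
              if (b2 == pc) continue;
              double d2 = (xprop[pc] - oldx) * M.x[n * P + b2];
              M.Sx[pc * P + b2] += d2;
              M.Sx[b2 * P + pc] += d2;
            }
            M.Sx[pc * P + pc] += xprop[pc] * xprop[pc] - oldx * oldx;
            M.x[n * P + pc] = xprop[pc];
            for (int j = 0; j < nit; ++j) {
              int i = (*items_aff)[j];
              int b = M.cix(n, i, 0);
              if (M.mixture == 2) {
                if (kind == 0 || kind == 1) {
                  int c_lo = (kind == 0) ? 0 : 1, c_hi = (kind == 0) ? 1 : 2;
                  for (int c = c_lo; c <= c_hi; ++c) {
                    M.respLL[b + c] = nv[j * 3 + c];
                    M.proY[b + c] = nvP[j * 3 + c];
                  }
                } else if (kind == 2) {
                  for (int c = 0; c < 3; ++c) M.rtLL[b + c] = nv[j * 3 + c];
                } else {
                  for (int c = 0; c < 3; ++c) M.clsLP[b + c] = nv[j * 3 + c];
                }
                M.cellM[n * I + i] = ncell[j];
              } else {
                int c = M.resp_class;
                if (kind == 0 || kind == 1) {
                  M.respLL[b + c] = nv[j * 3 + c];
                  M.proY[b + c] = nvP[j * 3 + c];
                }
              }
            }
          }
          if (adapting)
            ad_person.tune(n * P + pc, std::fmin(1.0, std::exp(delta)),
                           gain);
        }
      }

      // ================= item updates =================
      // generic lambda: recompute resp slice for classes [c_lo, c_hi] of
      // item i under proposed item-side values, return lik delta and fill
      // newvals (N x 3 slots used for touched classes)
      std::vector<double> newvals((size_t)N * 3), newvalsP((size_t)N * 3);
      std::vector<double> newcell((size_t)N);
      auto item_resp_delta = [&](int i, int c_lo, int c_hi,
                                 const double* aS_row, double aF_i,
                                 const double* g0, const double* g1,
                                 const double* g2) {
        double delta = 0.0;
        for (int n = 0; n < N; ++n) {
          int b = M.cix(n, i, 0);
          if (M.mixture == 2) {
            double v0 = M.clsLP[b] + M.respLL[b],
                   v1 = M.clsLP[b + 1] + M.respLL[b + 1],
                   v2 = M.clsLP[b + 2] + M.respLL[b + 2];
            if (M.rt) { v0 += M.rtLL[b]; v1 += M.rtLL[b + 1];
                        v2 += M.rtLL[b + 2]; }
            for (int c = c_lo; c <= c_hi; ++c) {
              const double* g = (c == 0) ? g0 : (c == 1) ? g1 : g2;
              double po;
              double r = M.resp_ll(n, i, c, aS_row, aF_i, g, &M.x[n * P],
                                   &po);
              newvals[n * 3 + c] = r;
              newvalsP[n * 3 + c] = po;
              double add = M.clsLP[b + c] + r;
              if (M.rt) add += M.rtLL[b + c];
              if (c == 0) v0 = add; else if (c == 1) v1 = add; else v2 = add;
            }
            newcell[n] = lse3(v0, v1, v2);
            delta += newcell[n] - M.cellM[n * I + i];
          } else if (M.mixture == 1) {
            double Sn_new[3] = {M.Snc[n * 3], M.Snc[n * 3 + 1],
                                M.Snc[n * 3 + 2]};
            for (int c = c_lo; c <= c_hi; ++c) {
              const double* g = (c == 0) ? g0 : (c == 1) ? g1 : g2;
              double po;
              double r = M.resp_ll(n, i, c, aS_row, aF_i, g, &M.x[n * P],
                                   &po);
              newvals[n * 3 + c] = r;
              newvalsP[n * 3 + c] = po;
              Sn_new[c] += r - M.respLL[b + c];
            }
            delta += lse3(M.lpi[0] + Sn_new[0], M.lpi[1] + Sn_new[1],
                          M.lpi[2] + Sn_new[2]) - M.person_ll(n);
          } else {
            int c = M.resp_class;
            if (c < c_lo || c > c_hi) continue;
            const double* g = (c == 0) ? g0 : (c == 1) ? g1 : g2;
            double po;
            double r = M.resp_ll(n, i, c, aS_row, aF_i, g, &M.x[n * P],
                                 &po);
            newvals[n * 3 + c] = r;
            newvalsP[n * 3 + c] = po;
            delta += r - M.respLL[b + c];
          }
        }
        return delta;
      };
      auto item_resp_accept = [&](int i, int c_lo, int c_hi) {
        for (int n = 0; n < N; ++n) {
          int b = M.cix(n, i, 0);
          for (int c = c_lo; c <= c_hi; ++c) {
            if (M.mixture == 0 && c != M.resp_class) continue;
            if (M.mixture == 1)
              M.Snc[n * 3 + c] += newvals[n * 3 + c] - M.respLL[b + c];
            M.respLL[b + c] = newvals[n * 3 + c];
            M.proY[b + c] = newvalsP[n * 3 + c];
          }
          if (M.mixture == 2) M.cellM[n * I + i] = newcell[n];
        }
      };

      for (int i = 0; i < I; ++i) {
        // trait slopes
        if (M.use_theta)
          for (size_t j = 0; j < M.item_dims[i].size(); ++j) {
            int d = M.item_dims[i][j];
            double cur = M.aS[i * D + d];
            double prop = cur +
                std::exp(ad_aS.ls[i * D + d]) * norm_rand();
            double delta;
            if (prop <= 0) {
              delta = -1e300;
            } else {
              std::vector<double> arow(&M.aS[i * D], &M.aS[i * D] + D);
              arow[d] = prop;
              int c_lo = (M.mixture > 0) ? 0
                         : (M.resp_class == 0 ? 0 : 1);
              int c_hi = (M.mixture > 0) ? 1 : c_lo;
              delta = half_normal_lp(prop, M.slope_sd) -
                      half_normal_lp(cur, M.slope_sd) +
                      item_resp_delta(i, c_lo, c_hi, arow.data(), M.aF[i],
                                      &M.gS[i * K1], &M.gSF[i * K1],
                                      &M.gF[i * K1]);
              if (std::log(unif_rand()) < delta) {
                item_resp_accept(i, c_lo, c_hi);
                M.aS[i * D + d] = prop;
              }
            }
            if (adapting)
              ad_aS.tune(i * D + d, std::fmin(1.0, std::exp(delta)), gain);
          }
        // faking slope
        if (M.use_eta) {
          double cur = M.aF[i];
          double prop = cur + std::exp(ad_aF.ls[i]) * norm_rand();
          double delta;
          if (prop <= 0) {
            delta = -1e300;
          } else {
            int c_lo = (M.mixture > 0) ? 1 : M.resp_class;
            int c_hi = (M.mixture > 0) ? 2 : M.resp_class;
            delta = half_normal_lp(prop, M.slope_sd) -
                    half_normal_lp(cur, M.slope_sd) +
                    item_resp_delta(i, c_lo, c_hi, &M.aS[i * D], prop,
                                    &M.gS[i * K1], &M.gSF[i * K1],
                                    &M.gF[i * K1]);
            if (std::log(unif_rand()) < delta) {
              item_resp_accept(i, c_lo, c_hi);
              M.aF[i] = prop;
            }
          }
          if (adapting) ad_aF.tune(i, std::fmin(1.0, std::exp(delta)), gain);
        }
        // class-specific category intercepts: scalar updates with an
        // incremental softmax-normalizer adjustment (only category k's
        // propensity changes, so the per-cell update is O(1))
        for (int c = 0; c < 3; ++c) {
          if (!M.class_active(c)) continue;
          std::vector<double>& g = (c == 0) ? M.gS : (c == 1) ? M.gSF : M.gF;
          Adapt& ad = (c == 0) ? ad_gS : (c == 1) ? ad_gSF : ad_gF;
          for (int k = 1; k < K1; ++k) {
            int slot = i * K1 + k;
            double cur = g[slot];
            double step = std::exp(ad.ls[slot]);
            double dstep = step * norm_rand();
            double prop = cur + dstep;
            double em1 = std::expm1(dstep);
            double delta = normal_lp(prop, 0.0, M.intercept_sd) -
                           normal_lp(cur, 0.0, M.intercept_sd);
            int yk = k;  // category whose propensity shifts
            for (int n = 0; n < N; ++n) {
              int b = M.cix(n, i, 0);
              double lse_old = M.proY[b + c] - M.respLL[b + c];
              double pk = M.pro_cat(n, i, c, yk);
              double r = std::exp(pk - lse_old);
              double lse_new = lse_old + std::log1p(r * em1);
              double poY_new = M.proY[b + c] +
                               (M.y[n + N * i] == yk ? dstep : 0.0);
              double r_new = poY_new - lse_new;
              newvals[n * 3 + c] = r_new;
              newvalsP[n * 3 + c] = poY_new;
              if (M.mixture == 2) {
                double v0 = M.clsLP[b] + M.respLL[b],
                       v1 = M.clsLP[b + 1] + M.respLL[b + 1],
                       v2 = M.clsLP[b + 2] + M.respLL[b + 2];
                if (M.rt) { v0 += M.rtLL[b]; v1 += M.rtLL[b + 1];
                            v2 += M.rtLL[b + 2]; }
                double add = M.clsLP[b + c] + r_new;
                if (M.rt) add += M.rtLL[b + c];
                if (c == 0) v0 = add; else if (c == 1) v1 = add;
                else v2 = add;
                newcell[n] = lse3(v0, v1, v2);
                delta += newcell[n] - M.cellM[n * I + i];
              } else if (M.mixture == 1) {
                double Sn_new[3] = {M.Snc[n * 3], M.Snc[n * 3 + 1],
                                    M.Snc[n * 3 + 2]};
                Sn_new[c] += r_new - M.respLL[b + c];
                delta += lse3(M.lpi[0] + Sn_new[0], M.lpi[1] + Sn_new[1],
                              M.lpi[2] + Sn_new[2]) - M.person_ll(n);
              } else {
                delta += r_new - M.respLL[b + c];
              }
            }
            if (std::log(unif_rand()) < delta) {
              item_resp_accept(i, c, c);
              g[slot] = prop;
            }
            if (adapting)
              ad.tune(slot, std::fmin(1.0, std::exp(delta)), gain);
          }
        }
        // latent response model intercepts
        if (M.mixture == 2)
          for (int c = 1; c < 3; ++c) {
            double cur = M.beta[i * 3 + c];
            double prop = cur +
                std::exp(ad_beta.ls[i * 2 + (c - 1)]) * norm_rand();
            double b1 = (c == 1) ? prop : M.beta[i * 3 + 1];
            double b2 = (c == 2) ? prop : M.beta[i * 3 + 2];
            double delta = normal_lp(prop, 0, M.intercept_sd) -
                           normal_lp(cur, 0, M.intercept_sd);
            for (int n = 0; n < N; ++n) {
              int b = M.cix(n, i, 0);
              double lp[3];
              M.class_lp(n, i, M.npsi, b1, b2, lp);
              double v0 = lp[0] + M.respLL[b],
                     v1 = lp[1] + M.respLL[b + 1],
                     v2 = lp[2] + M.respLL[b + 2];
              if (M.rt) {
                v0 += M.rtLL[b]; v1 += M.rtLL[b + 1]; v2 += M.rtLL[b + 2];
              }
              newcell[n] = lse3(v0, v1, v2);
              delta += newcell[n] - M.cellM[n * I + i];
              newvals[n * 3] = lp[0]; newvals[n * 3 + 1] = lp[1];
              newvals[n * 3 + 2] = lp[2];
            }
            if (std::log(unif_rand()) < delta) {
              M.beta[i * 3 + c] = prop;
              for (int n = 0; n < N; ++n) {
                int b = M.cix(n, i, 0);
                for (int cc = 0; cc < 3; ++cc)
                  M.clsLP[b + cc] = newvals[n * 3 + cc];
                M.cellM[n * I + i] = newcell[n];
              }
            }
            if (adapting)
              ad_beta.tune(i * 2 + (c - 1), std::fmin(1.0, std::exp(delta)),
                           gain);
          }
        // time intensities
        if (M.rt) {
          for (int which = 0; which < 2; ++which) {
            Adapt& ad = which == 0 ? ad_dS : ad_dF;
            double cur = which == 0 ? M.dS[i] : M.dF[i];
            double prop = cur + std::exp(ad.ls[i]) * norm_rand();
            double dS_i = which == 0 ? prop : M.dS[i];
            double dF_i = which == 1 ? prop : M.dF[i];
            // affected classes: dS -> {0,1}; dF -> {1,2} (or all if lam)
            int c_lo = which == 0 ? 0 : 1;
            int c_hi = which == 0 ? (use_lam ? 1 : 0) : 2;
            if (M.mixture == 0) { c_lo = M.resp_class; c_hi = M.resp_class; }
            double delta = normal_lp(prop, M.delta_mean, M.delta_sd) -
                           normal_lp(cur, M.delta_mean, M.delta_sd);
            for (int n = 0; n < N; ++n) {
              int b = M.cix(n, i, 0);
              double phi_n = M.use_phi ? M.x[n * P + M.col_phi] : 0.0;
              if (M.mixture == 2) {
                double v0 = M.clsLP[b] + M.respLL[b] + M.rtLL[b],
                       v1 = M.clsLP[b + 1] + M.respLL[b + 1] + M.rtLL[b + 1],
                       v2 = M.clsLP[b + 2] + M.respLL[b + 2] + M.rtLL[b + 2];
                for (int c = c_lo; c <= c_hi; ++c) {
                  double r = M.rt_ll(n, i, c, dS_i, dF_i, M.nphi, M.lam,
                                     M.sig[c], phi_n);
                  newvals[n * 3 + c] = r;
                  double add = M.clsLP[b + c] + M.respLL[b + c] + r;
                  if (c == 0) v0 = add; else if (c == 1) v1 = add;
                  else v2 = add;
                }
                newcell[n] = lse3(v0, v1, v2);
                delta += newcell[n] - M.cellM[n * I + i];
              } else if (M.mixture == 1) {
                double Sn_new[3] = {M.Snc[n * 3], M.Snc[n * 3 + 1],
                                    M.Snc[n * 3 + 2]};
                for (int c = c_lo; c <= c_hi; ++c) {
                  double r = M.rt_ll(n, i, c, dS_i, dF_i, M.nphi, M.lam,
                                     M.sig[c], phi_n);
                  newvals[n * 3 + c] = r;
                  Sn_new[c] += r - M.rtLL[b + c];
                }
                delta += lse3(M.lpi[0] + Sn_new[0], M.lpi[1] + Sn_new[1],
                              M.lpi[2] + Sn_new[2]) - M.person_ll(n);
              }
            }
            if (std::log(unif_rand()) < delta) {
              for (int n = 0; n < N; ++n) {
                int b = M.cix(n, i, 0);
                for (int c = c_lo; c <= c_hi; ++c) {
                  if (M.mixture == 1)
                    M.Snc[n * 3 + c] += newvals[n * 3 + c] - M.rtLL[b + c];
                  M.rtLL[b + c] = newvals[n * 3 + c];
                }
                if (M.mixture == 2) M.cellM[n * I + i] = newcell[n];
              }
              if (which == 0) M.dS[i] = prop; else M.dF[i] = prop;
            }
            if (adapting)
              ad.tune(i, std::fmin(1.0, std::exp(delta)), gain);
          }
        }
      }

      // ---- prior-refresh pass: independence proposals from the prior for
      // item-side parameters. For parameters the data barely identify
      // (e.g. intercepts of a class an item rarely uses) the random walk
      // crawls through wide tails; a prior draw traverses them in one step
      // (acceptance ratio reduces to the likelihood ratio), while for
      // well-identified parameters it is a cheap rejection. Alternated with
      // the mode-jump pass below to keep the sweep cost down.
      if (sweep % 2 == 0) {
        std::vector<double> gprop(K1, 0.0);
        for (int i = 0; i < I; ++i) {
          for (int c = 0; c < 3; ++c) {
            if (!M.class_active(c)) continue;
            std::vector<double>& g = (c == 0) ? M.gS : (c == 1) ? M.gSF
                                                                : M.gF;
            for (int k = 1; k < K1; ++k)
              gprop[k] = norm_rand() * M.intercept_sd;
            double delta =
                item_resp_delta(i, c, c, &M.aS[i * D], M.aF[i],
                                (c == 0) ? gprop.data() : &M.gS[i * K1],
                                (c == 1) ? gprop.data() : &M.gSF[i * K1],
                                (c == 2) ? gprop.data() : &M.gF[i * K1]);
            if (std::log(unif_rand()) < delta) {
              item_resp_accept(i, c, c);
              for (int k = 1; k < K1; ++k) g[i * K1 + k] = gprop[k];
            }
          }
          if (M.use_eta) {
            double prop = std::fabs(norm_rand()) * M.slope_sd;
            int c_lo = (M.mixture > 0) ? 1 : M.resp_class;
            int c_hi = (M.mixture > 0) ? 2 : M.resp_class;
            double delta = item_resp_delta(i, c_lo, c_hi, &M.aS[i * D],
                                           prop, &M.gS[i * K1],
                                           &M.gSF[i * K1], &M.gF[i * K1]);
            if (std::log(unif_rand()) < delta) {
              item_resp_accept(i, c_lo, c_hi);
              M.aF[i] = prop;
            }
          }
          if (M.mixture == 2) {
            for (int c = 1; c < 3; ++c) {
              double prop = norm_rand() * M.intercept_sd;
              double b1 = (c == 1) ? prop : M.beta[i * 3 + 1];
              double b2 = (c == 2) ? prop : M.beta[i * 3 + 2];
              double delta = 0.0;
              for (int n = 0; n < N; ++n) {
                int b = M.cix(n, i, 0);
                double lp[3];
                M.class_lp(n, i, M.npsi, b1, b2, lp);
                double v0 = lp[0] + M.respLL[b],
                       v1 = lp[1] + M.respLL[b + 1],
                       v2 = lp[2] + M.respLL[b + 2];
                if (M.rt) {
                  v0 += M.rtLL[b]; v1 += M.rtLL[b + 1]; v2 += M.rtLL[b + 2];
                }
                newcell[n] = lse3(v0, v1, v2);
                delta += newcell[n] - M.cellM[n * I + i];
                newvals[n * 3] = lp[0]; newvals[n * 3 + 1] = lp[1];
                newvals[n * 3 + 2] = lp[2];
              }
              if (std::log(unif_rand()) < delta) {
                M.beta[i * 3 + c] = prop;
                for (int n = 0; n < N; ++n) {
                  int b = M.cix(n, i, 0);
                  for (int cc = 0; cc < 3; ++cc)
                    M.clsLP[b + cc] = newvals[n * 3 + cc];
                  M.cellM[n * I + i] = newcell[n];
                }
              }
            }
          }
        }
      }

      // ---- mode-jumping move: swap the trait-only and faking-only
      // measurement roles of one item (gamma_s <-> gamma_f,
      // delta_s <-> delta_f, class intercepts reflected so the class
      // ordering reverses at psi = 0). Items whose trait and desirability
      // weights are nearly collinear have two posterior modes that
      // random-walk updates cannot traverse; this involution proposal
      // jumps between them and is corrected by the usual MH ratio.
      if (M.mixture > 0 && sweep % 2 == 1) {
        std::vector<double> r_new((size_t)N * 2), p_new((size_t)N * 2);
        std::vector<double> rt_new((size_t)N * 3), lp_new((size_t)N * 3);
        // which: 0 swaps classes 0<->2 (with an exact delta swap), 1 swaps
        // 1<->2, 2 swaps 0<->1 (delta involutions that exchange the two RT
        // means exactly while the third follows the linear constraint)
        auto item_swap_move = [&](int i, int which) {
          int ca = (which == 2) ? 0 : (which == 1) ? 1 : 0;
          int cb = (which == 2) ? 1 : 2;
          double b1 = M.beta[i * 3 + 1], b2 = M.beta[i * 3 + 2];
          double b1p, b2p;
          if (which == 0) { b1p = b1 - b2; b2p = -b2; }
          else if (which == 1) { b1p = b2; b2p = b1; }
          else { b1p = -b1; b2p = b2 - b1; }
          // proposed time intensities: exchange the RT means of the two
          // swapped classes; each map is a unit-Jacobian involution
          double dSp = M.dS[i], dFp = M.dF[i];
          if (M.rt) {
            double l = M.lam;
            if (which == 0) { dSp = M.dF[i]; dFp = M.dS[i]; }
            else if (which == 1) {
              dFp = M.dS[i] + l * M.dF[i];
              dSp = (1 - l * l) * M.dF[i] - l * M.dS[i];
            } else {
              dSp = M.dS[i] + l * M.dF[i];
              dFp = -M.dF[i];
            }
          }
          const double* ga = (ca == 0) ? &M.gS[i * K1] : &M.gSF[i * K1];
          const double* gb = (cb == 1) ? &M.gSF[i * K1] : &M.gF[i * K1];
          double delta = 0.0;
          if (M.mixture == 2) {
            delta += normal_lp(b1p, 0, M.intercept_sd) +
                     normal_lp(b2p, 0, M.intercept_sd) -
                     normal_lp(b1, 0, M.intercept_sd) -
                     normal_lp(b2, 0, M.intercept_sd);
          }
          if (M.rt) {
            delta += normal_lp(dSp, M.delta_mean, M.delta_sd) +
                     normal_lp(dFp, M.delta_mean, M.delta_sd) -
                     normal_lp(M.dS[i], M.delta_mean, M.delta_sd) -
                     normal_lp(M.dF[i], M.delta_mean, M.delta_sd);
          }
          for (int n = 0; n < N; ++n) {
            int b = M.cix(n, i, 0);
            double poa, pob;
            // intercepts of the two classes exchange; slopes stay with
            // their class
            double ra = M.resp_ll(n, i, ca, &M.aS[i * D], M.aF[i], gb,
                                  &M.x[n * P], &poa);
            double rb = M.resp_ll(n, i, cb, &M.aS[i * D], M.aF[i], ga,
                                  &M.x[n * P], &pob);
            r_new[n * 2] = ra; r_new[n * 2 + 1] = rb;
            p_new[n * 2] = poa; p_new[n * 2 + 1] = pob;
            double rtv[3] = {0, 0, 0};
            if (M.rt) {
              double phi_n = M.use_phi ? M.x[n * P + M.col_phi] : 0.0;
              for (int c = 0; c < 3; ++c)
                rtv[c] = M.rt_ll(n, i, c, dSp, dFp, M.nphi, M.lam,
                                 M.sig[c], phi_n);
            }
            rt_new[n * 3] = rtv[0]; rt_new[n * 3 + 1] = rtv[1];
            rt_new[n * 3 + 2] = rtv[2];
            double rr[3] = {M.respLL[b], M.respLL[b + 1], M.respLL[b + 2]};
            rr[ca] = ra; rr[cb] = rb;
            if (M.mixture == 2) {
              double lp[3];
              M.class_lp(n, i, M.npsi, b1p, b2p, lp);
              lp_new[n * 3] = lp[0]; lp_new[n * 3 + 1] = lp[1];
              lp_new[n * 3 + 2] = lp[2];
              double v0 = lp[0] + rr[0], v1 = lp[1] + rr[1],
                     v2 = lp[2] + rr[2];
              if (M.rt) { v0 += rtv[0]; v1 += rtv[1]; v2 += rtv[2]; }
              newcell[n] = lse3(v0, v1, v2);
              delta += newcell[n] - M.cellM[n * I + i];
            } else {
              double Sn_new[3];
              for (int c = 0; c < 3; ++c) {
                Sn_new[c] = M.Snc[n * 3 + c] + rr[c] - M.respLL[b + c];
                if (M.rt) Sn_new[c] += rtv[c] - M.rtLL[b + c];
              }
              newvals[n * 3] = Sn_new[0]; newvals[n * 3 + 1] = Sn_new[1];
              newvals[n * 3 + 2] = Sn_new[2];
              delta += lse3(M.lpi[0] + Sn_new[0], M.lpi[1] + Sn_new[1],
                            M.lpi[2] + Sn_new[2]) - M.person_ll(n);
            }
          }
          if (std::log(unif_rand()) < delta) {
            double* gav = (ca == 0) ? &M.gS[i * K1] : &M.gSF[i * K1];
            double* gbv = (cb == 1) ? &M.gSF[i * K1] : &M.gF[i * K1];
            for (int k = 0; k < K1; ++k) std::swap(gav[k], gbv[k]);
            if (M.rt) { M.dS[i] = dSp; M.dF[i] = dFp; }
            if (M.mixture == 2) {
              M.beta[i * 3 + 1] = b1p; M.beta[i * 3 + 2] = b2p;
            }
            for (int n = 0; n < N; ++n) {
              int b = M.cix(n, i, 0);
              M.respLL[b + ca] = r_new[n * 2];
              M.respLL[b + cb] = r_new[n * 2 + 1];
              M.proY[b + ca] = p_new[n * 2];
              M.proY[b + cb] = p_new[n * 2 + 1];
              if (M.rt)
                for (int c = 0; c < 3; ++c)
                  M.rtLL[b + c] = rt_new[n * 3 + c];
              if (M.mixture == 2) {
                for (int c = 0; c < 3; ++c)
                  M.clsLP[b + c] = lp_new[n * 3 + c];
                M.cellM[n * I + i] = newcell[n];
              } else {
                for (int c = 0; c < 3; ++c)
                  M.Snc[n * 3 + c] = newvals[n * 3 + c];
              }
            }
          }
        };
        if (M.mixture == 2) {
          for (int i = 0; i < I; ++i)
            for (int which = 0; which < 3; ++which) item_swap_move(i, which);
        } else {
          // person mixture: classes can only be relabeled test-wide, so the
          // involution swaps every item's intercepts/intensities and the
          // mixing proportions together
          std::vector<double> rG((size_t)N * I * 2), pG((size_t)N * I * 2);
          std::vector<double> rtG((size_t)N * I * 3), SnG((size_t)N * 3);
          for (int which = 0; which < 3; ++which) {
            int ca = (which == 2) ? 0 : (which == 1) ? 1 : 0;
            int cb = (which == 2) ? 1 : 2;
            double lpi_new[3] = {M.lpi[0], M.lpi[1], M.lpi[2]};
            std::swap(lpi_new[ca], lpi_new[cb]);
            double delta = 0.0;
            std::vector<double> dSp(M.dS), dFp(M.dF);
            if (M.rt) {
              double l = M.lam;
              for (int i = 0; i < I; ++i) {
                if (which == 0) { dSp[i] = M.dF[i]; dFp[i] = M.dS[i]; }
                else if (which == 1) {
                  dFp[i] = M.dS[i] + l * M.dF[i];
                  dSp[i] = (1 - l * l) * M.dF[i] - l * M.dS[i];
                } else {
                  dSp[i] = M.dS[i] + l * M.dF[i];
                  dFp[i] = -M.dF[i];
                }
                delta += normal_lp(dSp[i], M.delta_mean, M.delta_sd) +
                         normal_lp(dFp[i], M.delta_mean, M.delta_sd) -
                         normal_lp(M.dS[i], M.delta_mean, M.delta_sd) -
                         normal_lp(M.dF[i], M.delta_mean, M.delta_sd);
              }
            }
            for (int n = 0; n < N; ++n) {
              double Sn_new[3] = {M.Snc[n * 3], M.Snc[n * 3 + 1],
                                  M.Snc[n * 3 + 2]};
              for (int i = 0; i < I; ++i) {
                int b = M.cix(n, i, 0);
                const double* ga = (ca == 0) ? &M.gS[i * K1]
                                             : &M.gSF[i * K1];
                const double* gb = (cb == 1) ? &M.gSF[i * K1]
                                             : &M.gF[i * K1];
                double poa, pob;
                double ra = M.resp_ll(n, i, ca, &M.aS[i * D], M.aF[i], gb,
                                      &M.x[n * P], &poa);
                double rb = M.resp_ll(n, i, cb, &M.aS[i * D], M.aF[i], ga,
                                      &M.x[n * P], &pob);
                size_t q = ((size_t)n * I + i) * 2;
                rG[q] = ra; rG[q + 1] = rb;
                pG[q] = poa; pG[q + 1] = pob;
                Sn_new[ca] += ra - M.respLL[b + ca];
                Sn_new[cb] += rb - M.respLL[b + cb];
                if (M.rt) {
                  double phi_n = M.use_phi ? M.x[n * P + M.col_phi] : 0.0;
                  for (int c = 0; c < 3; ++c) {
                    double r = M.rt_ll(n, i, c, dSp[i], dFp[i], M.nphi,
                                       M.lam, M.sig[c], phi_n);
                    rtG[((size_t)n * I + i) * 3 + c] = r;
                    Sn_new[c] += r - M.rtLL[b + c];
                  }
                }
              }
              for (int c = 0; c < 3; ++c) SnG[n * 3 + c] = Sn_new[c];
              delta += lse3(lpi_new[0] + Sn_new[0], lpi_new[1] + Sn_new[1],
                            lpi_new[2] + Sn_new[2]) - M.person_ll(n);
            }
            if (std::log(unif_rand()) < delta) {
              for (int i = 0; i < I; ++i) {
                double* gav = (ca == 0) ? &M.gS[i * K1] : &M.gSF[i * K1];
                double* gbv = (cb == 1) ? &M.gSF[i * K1] : &M.gF[i * K1];
                for (int k = 0; k < K1; ++k) std::swap(gav[k], gbv[k]);
              }
              if (M.rt) { M.dS = dSp; M.dF = dFp; }
              M.lpi[0] = lpi_new[0]; M.lpi[1] = lpi_new[1];
              M.lpi[2] = lpi_new[2];
              for (int n = 0; n < N; ++n) {
                for (int i = 0; i < I; ++i) {
                  int b = M.cix(n, i, 0);
                  size_t q = ((size_t)n * I + i) * 2;
                  M.respLL[b + ca] = rG[q]; M.respLL[b + cb] = rG[q + 1];
                  M.proY[b + ca] = pG[q]; M.proY[b + cb] = pG[q + 1];
                  if (M.rt)
                    for (int c = 0; c < 3; ++c)
                      M.rtLL[b + c] = rtG[((size_t)n * I + i) * 3 + c];
                  M.clsLP[b] = lpi_new[0]; M.clsLP[b + 1] = lpi_new[1];
                  M.clsLP[b + 2] = lpi_new[2];
                }
                for (int c = 0; c < 3; ++c) M.Snc[n * 3 + c] = SnG[n * 3 + c];
              }
            }
          }
        }
      }

      // ================= global updates =================
      // RT-side globals: full rtLL slice recomputation under proposal
      auto rt_global_update = [&](int which) {
        // which: 0 nphi, 1 lambda, 2..4 sig[c]
        double cur = which == 0 ? M.nphi : which == 1 ? M.lam
                     : M.sig[which - 2];
        double step = std::exp(ad_glob.ls[which]);
        double prop = cur + step * norm_rand();
        double delta;
        if (prop <= 0) {
          delta = -1e300;
        } else {
          double nphi_ = which == 0 ? prop : M.nphi;
          double lam_ = which == 1 ? prop : M.lam;
          double sgv[3] = {M.sig[0], M.sig[1], M.sig[2]};
          if (which >= 2) sgv[which - 2] = prop;
          int c_lo = 0, c_hi = 2;
          if (which == 1) { c_lo = 1; c_hi = 1; }
          if (which >= 2) { c_lo = which - 2; c_hi = which - 2; }
          if (M.mixture == 0) {
            if (M.resp_class < c_lo || M.resp_class > c_hi) return;
            c_lo = c_hi = M.resp_class;
          }
          delta = which == 0 ? (half_normal_lp(prop, M.slope_sd) -
                                half_normal_lp(cur, M.slope_sd))
                  : which == 1 ? (half_normal_lp(prop, M.lambda_sd) -
                                  half_normal_lp(cur, M.lambda_sd))
                  : (half_cauchy_lp(prop, M.cauchy_scale) -
                     half_cauchy_lp(cur, M.cauchy_scale));
          std::vector<double> nvals((size_t)N * I * (c_hi - c_lo + 1));
          std::vector<double> ncellv((size_t)N * I);
          size_t q = 0;
          for (int n = 0; n < N; ++n) {
            double phi_n = M.use_phi ? M.x[n * P + M.col_phi] : 0.0;
            if (M.mixture == 1) {
              double Sn_new[3] = {M.Snc[n * 3], M.Snc[n * 3 + 1],
                                  M.Snc[n * 3 + 2]};
              for (int i = 0; i < I; ++i)
                for (int c = c_lo; c <= c_hi; ++c) {
                  double r = M.rt_ll(n, i, c, M.dS[i], M.dF[i], nphi_, lam_,
                                     sgv[c], phi_n);
                  nvals[q++] = r;
                  Sn_new[c] += r - M.rtLL[M.cix(n, i, c)];
                }
              delta += lse3(M.lpi[0] + Sn_new[0], M.lpi[1] + Sn_new[1],
                            M.lpi[2] + Sn_new[2]) - M.person_ll(n);
            } else {
              for (int i = 0; i < I; ++i) {
                int b = M.cix(n, i, 0);
                if (M.mixture == 2) {
                  double v0 = M.clsLP[b] + M.respLL[b] + M.rtLL[b],
                         v1 = M.clsLP[b + 1] + M.respLL[b + 1] +
                              M.rtLL[b + 1],
                         v2 = M.clsLP[b + 2] + M.respLL[b + 2] +
                              M.rtLL[b + 2];
                  for (int c = c_lo; c <= c_hi; ++c) {
                    double r = M.rt_ll(n, i, c, M.dS[i], M.dF[i], nphi_,
                                       lam_, sgv[c], phi_n);
                    nvals[q++] = r;
                    double add = M.clsLP[b + c] + M.respLL[b + c] + r;
                    if (c == 0) v0 = add; else if (c == 1) v1 = add;
                    else v2 = add;
                  }
                  ncellv[n * I + i] = lse3(v0, v1, v2);
                  delta += ncellv[n * I + i] - M.cellM[n * I + i];
                } else {
                  int c = M.resp_class;
                  double r = M.rt_ll(n, i, c, M.dS[i], M.dF[i], nphi_, lam_,
                                     sgv[c], phi_n);
                  nvals[q++] = r;
                  delta += r - M.rtLL[b + c];
                }
              }
            }
          }
          if (std::log(unif_rand()) < delta) {
            q = 0;
            for (int n = 0; n < N; ++n)
              for (int i = 0; i < I; ++i) {
                for (int c = c_lo; c <= c_hi; ++c) {
                  int b = M.cix(n, i, c);
                  if (M.mixture == 1)
                    M.Snc[n * 3 + c] += nvals[q] - M.rtLL[b];
                  M.rtLL[b] = nvals[q++];
                }
                if (M.mixture == 2) M.cellM[n * I + i] = ncellv[n * I + i];
              }
            if (which == 0) M.nphi = prop;
            else if (which == 1) M.lam = prop;
            else M.sig[which - 2] = prop;
          }
        }
        if (adapting)
          ad_glob.tune(which, std::fmin(1.0, std::exp(delta)), gain);
      };
      if (M.rt) {
        rt_global_update(0);
        if (use_lam) rt_global_update(1);
        for (int c = 0; c < 3; ++c)
          if (M.mixture > 0 || M.resp_class == c) rt_global_update(2 + c);
      }

      // strategy-inclination slope
      if (M.mixture == 2) {
        double cur = M.npsi;
        double prop = cur + std::exp(ad_glob.ls[5]) * norm_rand();
        double delta;
        if (prop <= 0) {
          delta = -1e300;
        } else {
          delta = half_normal_lp(prop, M.slope_sd) -
                  half_normal_lp(cur, M.slope_sd);
          std::vector<double> nvals((size_t)N * I * 3);
          std::vector<double> ncellv((size_t)N * I);
          size_t q = 0;
          for (int n = 0; n < N; ++n)
            for (int i = 0; i < I; ++i) {
              int b = M.cix(n, i, 0);
              double lp[3];
              M.class_lp(n, i, prop, M.beta[i * 3 + 1], M.beta[i * 3 + 2],
                         lp);
              double v0 = lp[0] + M.respLL[b],
                     v1 = lp[1] + M.respLL[b + 1],
                     v2 = lp[2] + M.respLL[b + 2];
              if (M.rt) {
                v0 += M.rtLL[b]; v1 += M.rtLL[b + 1]; v2 += M.rtLL[b + 2];
              }
              ncellv[n * I + i] = lse3(v0, v1, v2);
              delta += ncellv[n * I + i] - M.cellM[n * I + i];
              nvals[q++] = lp[0]; nvals[q++] = lp[1]; nvals[q++] = lp[2];
            }
          if (std::log(unif_rand()) < delta) {
            M.npsi = prop;
            std::copy(nvals.begin(), nvals.end(), M.clsLP.begin());
            std::copy(ncellv.begin(), ncellv.end(), M.cellM.begin());
          }
        }
        if (adapting)
          ad_glob.tune(5, std::fmin(1.0, std::exp(delta)), gain);
      }

      // latent correlations (flat prior over the PD region)
      if (P > 1) {
        for (int a = 0; a < P; ++a)
          for (int b = a + 1; b < P; ++b) {
            double cur = M.Sig[a * P + b];
            double prop = cur +
                std::exp(ad_Sig.ls[a * P + b]) * norm_rand();
            double delta = -1e300;
            if (prop > -1 && prop < 1) {
              std::vector<double> Sp(M.Sig);
              Sp[a * P + b] = Sp[b * P + a] = prop;
              std::vector<double> Lp;
              if (chol_pd(Sp, P, Lp)) {
                double ld_new = chol_logdet(Lp, P);
                std::vector<double> Sinv_new;
                chol_inverse(Lp, P, Sinv_new);
                double q_old = 0, q_new = 0;
                for (int u = 0; u < P; ++u)
                  for (int v = 0; v < P; ++v) {
                    q_old += M.Sinv[u * P + v] * M.Sx[u * P + v];
                    q_new += Sinv_new[u * P + v] * M.Sx[u * P + v];
                  }
                delta = -0.5 * N * (ld_new - M.logdetS) -
                        0.5 * (q_new - q_old);
                if (std::log(unif_rand()) < delta) {
                  M.Sig = Sp; M.Lchol = Lp; M.Sinv = Sinv_new;
                  M.logdetS = ld_new;
                }
              }
            }
            if (adapting)
              ad_Sig.tune(a * P + b, std::fmin(1.0, std::exp(delta)), gain);
          }
      }

      // mixing proportions (person mixture)
      if (M.mixture == 1) {
        // additive log-ratio walk with flat-Dirichlet prior
        double a1 = M.lpi[1] - M.lpi[0], a2 = M.lpi[2] - M.lpi[0];
        double p1 = a1 + std::exp(ad_pi.ls[0]) * norm_rand();
        double p2 = a2 + std::exp(ad_pi.ls[1]) * norm_rand();
        double l = lse3(0.0, p1, p2);
        double lpi_new[3] = {-l, p1 - l, p2 - l};
        // Jacobian of alr^-1: prod pi_c
        double delta = (lpi_new[0] + lpi_new[1] + lpi_new[2]) -
                       (M.lpi[0] + M.lpi[1] + M.lpi[2]);
        for (int n = 0; n < N; ++n)
          delta += lse3(lpi_new[0] + M.Snc[n * 3],
                        lpi_new[1] + M.Snc[n * 3 + 1],
                        lpi_new[2] + M.Snc[n * 3 + 2]) - M.person_ll(n);
        if (std::log(unif_rand()) < delta) {
          M.lpi[0] = lpi_new[0]; M.lpi[1] = lpi_new[1];
          M.lpi[2] = lpi_new[2];
        }
        if (adapting) {
          double ap = std::fmin(1.0, std::exp(delta));
          ad_pi.tune(0, ap, gain); ad_pi.tune(1, ap, gain);
        }
      }

      // ---- likelihood-invariant scale moves along identification ridges:
      // (theta_d, alpha_sd), (eta, alpha_f), (phi, nu_phi), (psi, nu_psi).
      // The products entering the likelihood are unchanged, so only the
      // priors and the Jacobian c^(N - n_scaled_down) enter the ratio;
      // all likelihood caches stay valid on acceptance.
      {
        int n_moves = M.D + 3;
        for (int mv = 0; mv < n_moves; ++mv) {
          int pc; double lc = std::exp(ad_scale.ls[mv]) * norm_rand();
          double c = std::exp(lc);
          double delta = 0.0; int d_down = 0;
          if (mv < M.D) {
            if (!M.use_theta || M.trait_items[mv].empty()) continue;
            pc = M.col_theta0 + mv;
            for (size_t j = 0; j < M.trait_items[mv].size(); ++j) {
              int i = M.trait_items[mv][j];
              double a = M.aS[i * D + mv];
              delta += half_normal_lp(a / c, M.slope_sd) -
                       half_normal_lp(a, M.slope_sd);
              ++d_down;
            }
          } else if (mv == M.D) {
            if (!M.use_eta) continue;
            pc = M.col_eta;
            for (int i = 0; i < I; ++i) {
              delta += half_normal_lp(M.aF[i] / c, M.slope_sd) -
                       half_normal_lp(M.aF[i], M.slope_sd);
              ++d_down;
            }
          } else if (mv == M.D + 1) {
            if (!M.use_phi) continue;
            pc = M.col_phi;
            delta += half_normal_lp(M.nphi / c, M.slope_sd) -
                     half_normal_lp(M.nphi, M.slope_sd);
            d_down = 1;
          } else {
            if (!M.use_psi) continue;
            pc = M.col_psi;
            delta += half_normal_lp(M.npsi / c, M.slope_sd) -
                     half_normal_lp(M.npsi, M.slope_sd);
            d_down = 1;
          }
          // person prior change: coordinate pc of every person scaled by c
          double q_old = 0.0, q_new = 0.0;
          for (int u = 0; u < P; ++u)
            for (int v = 0; v < P; ++v) {
              double fac = 1.0;
              if (u == pc) fac *= c;
              if (v == pc) fac *= c;
              q_old += M.Sinv[u * P + v] * M.Sx[u * P + v];
              q_new += M.Sinv[u * P + v] * M.Sx[u * P + v] * fac;
            }
          delta += -0.5 * (q_new - q_old) + (N - d_down) * lc;
          if (std::log(unif_rand()) < delta) {
            for (int n = 0; n < N; ++n) M.x[n * P + pc] *= c;
            for (int u = 0; u < P; ++u) {
              M.Sx[u * P + pc] *= c;
              M.Sx[pc * P + u] *= c;
            }
            if (mv < M.D) {
              for (size_t j = 0; j < M.trait_items[mv].size(); ++j)
                M.aS[M.trait_items[mv][j] * D + mv] /= c;
            } else if (mv == M.D) {
              for (int i = 0; i < I; ++i) M.aF[i] /= c;
            } else if (mv == M.D + 1) {
              M.nphi /= c;
            } else {
              M.npsi /= c;
            }
          }
          if (adapting)
            ad_scale.tune(mv, std::fmin(1.0, std::exp(delta)), gain);
        }
      }

      // periodic full cache refresh guards against drift in the
      // incrementally maintained sums
      if ((sweep + 1) % 500 == 0) M.refresh_caches();

      // ---- save ----
      if (sweep >= warm_sweeps && (sweep - warm_sweeps + 1) % thin == 0) {
        int col = 0;
        for (int i = 0; i < I; ++i)
          if (M.use_theta)
            for (size_t j = 0; j < M.item_dims[i].size(); ++j)
              draws(save_row, col++) = M.aS[i * D + M.item_dims[i][j]];
        if (M.use_eta)
          for (int i = 0; i < I; ++i) draws(save_row, col++) = M.aF[i];
        for (int c = 0; c < 3; ++c) {
          if (!M.class_active(c)) continue;
          std::vector<double>& g = (c == 0) ? M.gS : (c == 1) ? M.gSF : M.gF;
          for (int i = 0; i < I; ++i)
            for (int k = 1; k < K1; ++k)
              draws(save_row, col++) = g[i * K1 + k];
        }
        if (M.mixture == 2)
          for (int i = 0; i < I; ++i)
            for (int c = 1; c < 3; ++c)
              draws(save_row, col++) = M.beta[i * 3 + c];
        if (M.rt) {
          for (int i = 0; i < I; ++i) draws(save_row, col++) = M.dS[i];
          for (int i = 0; i < I; ++i) draws(save_row, col++) = M.dF[i];
          draws(save_row, col++) = M.nphi;
          draws(save_row, col++) = M.sig[0];
          draws(save_row, col++) = M.sig[1];
          draws(save_row, col++) = M.sig[2];
          if (use_lam) draws(save_row, col++) = M.lam;
        }
        if (M.mixture == 2) draws(save_row, col++) = M.npsi;
        for (int a = 0; a < P; ++a)
          for (int b = a + 1; b < P; ++b)
            draws(save_row, col++) = M.Sig[a * P + b];
        if (M.mixture == 1)
          for (int c = 0; c < 3; ++c)
            draws(save_row, col++) = std::exp(M.lpi[c]);
        for (int n = 0; n < N; ++n)
          for (int a = 0; a < P; ++a)
            person_draws[save_row + (size_t)n_save * (n + (size_t)N * a)] =
                M.x[n * P + a];
        ll_joint[save_row] = M.total_loglik(true);
        ll_resp[save_row] = M.total_loglik(false);
        chain_id[save_row] = ch + 1;
        ++save_row;
      }
      if (sweep % 50 == 0) Rcpp::checkUserInterrupt();
    }
  }
  PutRNGstate();

  colnames(draws) = wrap(names);
  List person_dims = List::create(_["P"] = P, _["col_theta0"] = M.col_theta0,
                                  _["col_eta"] = M.col_eta,
                                  _["col_phi"] = M.col_phi,
                                  _["col_psi"] = M.col_psi);
  return List::create(_["draws"] = draws, _["person_draws"] = person_draws,
                      _["chain_id"] = chain_id, _["ll_joint"] = ll_joint,
                      _["ll_resp"] = ll_resp, _["person_layout"] = person_dims);
}

// Per-draw per-cell log mixture terms, used for pointwise likelihoods
// (WAIC / PSIS-LOO), conditional class responsibilities, and posterior
// predictive simulation. Parameters arrive unpacked from R.
// [[Rcpp::export]]
List cell_terms_cpp(IntegerMatrix y, NumericMatrix logt, NumericVector ws,
                    NumericMatrix wf, List config, NumericMatrix aS,
                    NumericVector aF, NumericMatrix gS, NumericMatrix gSF,
                    NumericMatrix gF, NumericMatrix beta, NumericVector dS,
                    NumericVector dF, NumericVector globals,
                    NumericMatrix persons, NumericVector lpi) {
  // globals: nphi, npsi, lambda, sig_s, sig_sf, sig_f
  int N = y.nrow(), I = y.ncol();
  IntegerVector wdim = as<IntegerVector>(as<RObject>(ws.attr("dim")));
  int D = wdim[1], K1 = wdim[2];
  int mixture = as<int>(config["mixture"]);
  bool rt = as<bool>(config["include_rt"]);
  int resp_class = as<int>(config["resp_class"]);
  int Pp = persons.ncol();
  int col_theta0 = as<int>(config["col_theta0"]);
  int col_eta = as<int>(config["col_eta"]);
  int col_phi = as<int>(config["col_phi"]);
  int col_psi = as<int>(config["col_psi"]);

  NumericVector resp_terms(Dimension(N, I, 3)), rt_terms(Dimension(N, I, 3)),
      cls_terms(Dimension(N, I, 3));
  std::fill(resp_terms.begin(), resp_terms.end(), R_NegInf);
  std::fill(rt_terms.begin(), rt_terms.end(), 0.0);
  std::fill(cls_terms.begin(), cls_terms.end(), R_NegInf);

  double nphi = globals[0], npsi = globals[1], lam = globals[2];
  double sg[3] = {globals[3], globals[4], globals[5]};
  double pro[16];
  for (int n = 0; n < N; ++n) {
    double eta = col_eta >= 0 ? persons(n, col_eta) : 0.0;
    double phi = col_phi >= 0 ? persons(n, col_phi) : 0.0;
    double psi = col_psi >= 0 ? persons(n, col_psi) : 0.0;
    (void)Pp;
    for (int i = 0; i < I; ++i) {
      for (int c = 0; c < 3; ++c) {
        bool active = mixture > 0 ? true : (c == resp_class);
        if (!active) continue;
        double mx = -1e300;
        for (int k = 0; k < K1; ++k) {
          double v = (c == 0) ? gS(i, k) : (c == 1) ? gSF(i, k) : gF(i, k);
          if (c != 2 && col_theta0 >= 0)
            for (int d = 0; d < D; ++d)
              v += aS(i, d) * ws[i + I * (d + D * k)] *
                   persons(n, col_theta0 + d);
          if (c != 0 && col_eta >= 0) v += aF[i] * wf(i, k) * eta;
          pro[k] = v;
          if (v > mx) mx = v;
        }
        double s = 0.0;
        for (int k = 0; k < K1; ++k) s += std::exp(pro[k] - mx);
        resp_terms[n + N * (i + I * c)] =
            pro[y(n, i)] - mx - std::log(s);
        if (rt) {
          double m = (c == 0) ? dS[i] : (c == 1) ? dS[i] + lam * dF[i]
                                                 : dF[i];
          m -= nphi * phi;
          double z = (logt(n, i) - m) / sg[c];
          rt_terms[n + N * (i + I * c)] =
              -std::log(sg[c]) - 0.5 * LOG2PI - 0.5 * z * z - logt(n, i);
        }
        if (mixture == 2) {
          double z1 = npsi * psi + beta(i, 1),
                 z2 = 2.0 * npsi * psi + beta(i, 2);
          double l = lse3(0.0, z1, z2);
          cls_terms[n + N * (i + I * c)] =
              (c == 0) ? -l : (c == 1) ? z1 - l : z2 - l;
        } else if (mixture == 1) {
          cls_terms[n + N * (i + I * c)] = lpi[c];
        } else {
          cls_terms[n + N * (i + I * c)] = 0.0;
        }
      }
    }
  }
  return List::create(_["resp"] = resp_terms, _["rt"] = rt_terms,
                      _["cls"] = cls_terms);
}
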