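// Block Gibbs sampler for multivariate GLMMs with unstructured covariance
// matrices at the individual, year and residual levels, parameter-expanded
// (redundant multiplier) priors on the random-effect covariances, scalar
// assay batch effects, and slice-sampled latent values for count
// (Poisson-lognormal) and binary (logit/probit latent) traits. Binary-trait
// residual variances are held at exactly 1 via a conditional inverse-Wishart
// draw with that diagonal block fixed.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

static arma::mat rnorm_mat(int r, int c) {
  arma::mat z(r, c);
  for (int j = 0; j < c; ++j)
    for (int i = 0; i < r; ++i) z(i, j) = R::norm_rand();
  return z;
}

// Wishart(scale = Lambda, df = nu) via the Bartlett decomposition.
static arma::mat rwishart(const arma::mat& Lambda, double nu) {
  int p = Lambda.n_rows;
  arma::mat L = arma::chol(arma::symmatu(Lambda), "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Inverse-Wishart(S, nu): Sigma^{-1} ~ Wishart(S^{-1}, nu).
static arma::mat riwishart(const arma::mat& S, double nu) {
  arma::mat Om = rwishart(arma::inv_sympd(arma::symmatu(S)), nu);
  return arma::inv_sympd(arma::symmatu(Om));
}

// Inverse-Wishart(S, nu) conditional on the trailing block of Sigma being
// fixed at C. Uses the Wishart block factorization of Omega = Sigma^{-1}:
// with Lambda = S^{-1} partitioned conformably, Omega_11 ~ W(Lambda_11, nu),
// T = Omega_11^{-1} Omega_12 | Omega_11 ~ N(Lambda_11^{-1} Lambda_12,
// Omega_11^{-1} (x) Lambda_22.1), and Omega_22.1 (independent of both) is
// pinned at C^{-1} so that Sigma_22 = C exactly.
static arma::mat riwishart_fixed(const arma::mat& S, double nu,
                                 const arma::uvec& free_idx,
                                 const arma::uvec& fix_idx,
                                 const arma::mat& C) {
  int p = S.n_rows, p1 = free_idx.n_elem, p2 = fix_idx.n_elem;
  if (p2 == 0) return riwishart(S, nu);
  arma::mat Lambda = arma::inv_sympd(arma::symmatu(S));
  arma::mat L11 = Lambda.submat(free_idx, free_idx);
  arma::mat L12 = Lambda.submat(free_idx, fix_idx);
  arma::mat L22 = Lambda.submat(fix_idx, fix_idx);
  arma::mat L11i = arma::inv_sympd(arma::symmatu(L11));
  arma::mat L221 = arma::symmatu(L22 - L12.t() * L11i * L12);

  arma::mat Om11 = rwishart(L11, nu);
  arma::mat Om11i = arma::inv_sympd(arma::symmatu(Om11));
  arma::mat rowc = arma::chol(arma::symmatu(Om11i), "lower");
  arma::mat colc = arma::chol(L221, "lower");
  arma::mat T = L11i * L12 + rowc * rnorm_mat(p1, p2) * colc.t();
  arma::mat Om12 = Om11 * T;
  arma::mat Om22 = arma::inv_sympd(arma::symmatu(C)) + T.t() * Om11 * T;

  arma::mat Om(p, p, arma::fill::zeros);
  Om.submat(free_idx, free_idx) = Om11;
  Om.submat(free_idx, fix_idx) = Om12;
  Om.submat(fix_idx, free_idx) = Om12.t();
  Om.submat(fix_idx, fix_idx) = Om22;
  return arma::inv_sympd(arma::symmatu(Om));
}

// Observation log-likelihood of one latent value. fam: 1 = count with log
// link (Poisson around the lognormal latent mean), 2 = binary logit,
// 3 = binary probit.
static inline double loglik_obs(int fam, double y, double l) {
  switch (fam) {
  case 1:
    if (l > 500.0) return -arma::datum::inf;
    return y * l - std::exp(l);
  case 2:
    return y * l - (l > 35.0 ? l : std::log1p(std::exp(l)));
  case 3:
    return R::pnorm(l, 0.0, 1.0, y > 0.5, 1);
  }
  return 0.0;
}

// Univariate slice sampler (stepping out, Neal 2003) for one latent value
// with Gaussian conditional prior N(cmean, cvar) and observation likelihood.
static double slice_latent(double x0, int fam, double y, double cmean,
                           double cvar, double w = 1.0, int mmax = 50) {
  auto logf = [&](double x) {
    double d = x - cmean;
    return -0.5 * d * d / cvar + loglik_obs(fam, y, x);
  };
  double f0 = logf(x0);
  double z = f0 - R::exp_rand();
  double u = R::unif_rand();
  double lower = x0 - w * u, upper = lower + w;
  int j = std::floor(mmax * R::unif_rand()), k = mmax - 1 - j;
  while (j-- > 0 && logf(lower) > z) lower -= w;
  while (k-- > 0 && logf(upper) > z) upper += w;
  for (int it = 0; it < 200; ++it) {
    double x1 = lower + R::unif_rand() * (upper - lower);
    if (logf(x1) > z) return x1;
    if (x1 < x0) lower = x1; else upper = x1;
  }
  return x0;
}

// Sample from N(P^{-1} b, P^{-1}) given precision P and linear term b.
static arma::vec rmvn_precision(const arma::mat& P, const arma::vec& b) {
  arma::mat U = arma::chol(arma::symmatu(P));  // P = U' U
  arma::vec mean = arma::solve(arma::trimatu(U),
                               arma::solve(arma::trimatl(U.t()), b));
  return mean + arma::solve(arma::trimatu(U), rnorm_vec(P.n_rows));
}

struct RandomLevel {
  bool active = false;
  int nlev = 0;
  arma::uvec idx;                  // record -> level (0-based)
  std::vector<arma::uvec> groups;  // level -> record rows
  arma::vec counts;
  arma::mat eta;                   // nlev x K working effects
  arma::vec alpha;                 // K redundant multipliers
  arma::mat Psi;                   // working covariance
  bool update = true;
};

struct AssayEffect {
  int trait = 0;
  int nlev = 0;
  arma::uvec idx;
  std::vector<arma::uvec> groups;
  arma::vec xi;
  double alpha = 1.0, psi = 0.01;
};

static void init_level(RandomLevel& lv, const arma::ivec& idx_in, int K,
                       const arma::mat& Psi0) {
  if (idx_in.n_elem == 0) { lv.active = false; return; }
  lv.active = true;
  lv.idx = arma::conv_to<arma::uvec>::from(idx_in);
  lv.nlev = lv.idx.max() + 1;
  lv.groups.resize(lv.nlev);
  lv.counts.set_size(lv.nlev);
  for (int g = 0; g < lv.nlev; ++g) {
    lv.groups[g] = arma::find(lv.idx == (unsigned int)g);
    lv.counts(g) = lv.groups[g].n_elem;
  }
  lv.eta = arma::mat(lv.nlev, K, arma::fill::zeros);
  lv.alpha = arma::vec(K, arma::fill::ones);
  lv.Psi = Psi0;
}

static arma::mat level_contribution(const RandomLevel& lv, int n, int K) {
  arma::mat out(n, K, arma::fill::zeros);
  if (!lv.active) return out;
  arma::mat scaled = lv.eta;
  scaled.each_row() %= lv.alpha.t();
  return scaled.rows(lv.idx);
}

// Update (eta, Psi, alpha) of one K-variate random level given the residual
// target Tm (= latent minus every other model component) and Rinv.
static void update_level(RandomLevel& lv, const arma::mat& Tm,
                         const arma::mat& Rinv, double px_nu,
                         const arma::mat& px_V, double alpha_var, int K) {
  arma::mat Dalpha = arma::diagmat(lv.alpha);
  arma::mat B = Dalpha * Rinv * Dalpha;
  arma::mat Psii = arma::inv_sympd(arma::symmatu(lv.Psi));
  arma::mat DR = Dalpha * Rinv;
  std::map<int, arma::mat> chols;
  for (int g = 0; g < lv.nlev; ++g) {
    int ng = (int)lv.counts(g);
    auto it = chols.find(ng);
    if (it == chols.end()) {
      arma::mat U = arma::chol(arma::symmatu(Psii + ng * B));
      it = chols.emplace(ng, U).first;
    }
    const arma::mat& U = it->second;
    arma::vec s(K, arma::fill::zeros);
    for (unsigned int r = 0; r < lv.groups[g].n_elem; ++r)
      s += Tm.row(lv.groups[g](r)).t();
    arma::vec b = DR * s;
    arma::vec mean = arma::solve(arma::trimatu(U),
                                 arma::solve(arma::trimatl(U.t()), b));
    lv.eta.row(g) = (mean + arma::solve(arma::trimatu(U), rnorm_vec(K))).t();
  }
  if (lv.update) {
    arma::mat Spost = px_V + lv.eta.t() * lv.eta;
    lv.Psi = riwishart(Spost, px_nu + lv.nlev);
    arma::mat EtaRec = lv.eta.rows(lv.idx);
    arma::mat M = EtaRec.t() * EtaRec;
    arma::mat W = EtaRec.t() * Tm;
    arma::mat A = Rinv % M;
    A.diag() += 1.0 / alpha_var;
    arma::vec b = arma::sum(Rinv % W, 1);
    lv.alpha = rmvn_precision(A, b);
  }
}

// [[Rcpp::export(name = ".gibbs_glmm_cpp")]]
List gibbs_glmm_cpp(arma::mat Y, arma::ivec fam, List Xlist,
                    arma::ivec id_idx, arma::ivec year_idx, List assays,
                    List prior, int niter, int nburn, int nthin,
                    List control) {
  int n = Y.n_rows, K = Y.n_cols;
  if ((int)fam.n_elem != K || Xlist.size() != K)
    stop("family/design dimensions do not match the trait count");

  std::vector<arma::mat> X(K);
  arma::ivec pk(K);
  int P = 0;
  for (int k = 0; k < K; ++k) {
    X[k] = as<arma::mat>(Xlist[k]);
    pk(k) = X[k].n_cols;
    P += pk(k);
  }
  arma::ivec off(K);
  for (int k = 0, o = 0; k < K; ++k) { off(k) = o; o += pk(k); }
  std::vector<std::vector<arma::mat>> XtX(K, std::vector<arma::mat>(K));
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < K; ++j) XtX[k][j] = X[k].t() * X[j];

  arma::mat V_R = as<arma::mat>(prior["V_R"]);
  double nu_R = as<double>(prior["nu_R"]);
  arma::mat px_V = as<arma::mat>(prior["px_V"]);
  double px_nu = as<double>(prior["px_nu"]);
  double alpha_var = as<double>(prior["alpha_variance"]);
  double beta_var = as<double>(prior["beta_variance"]);

  bool upd_res = as<bool>(control["update_sigma_res"]);
  double eigen_floor = as<double>(control["eigen_floor"]);
  bool mh_sweep = as<bool>(control["mh_sweep"]);
  arma::mat SigmaR = as<arma::mat>(control["sigma_res_init"]);
  arma::uvec fix_idx = arma::find(fam >= 2);    // binary: latent variance 1
  arma::uvec free_idx = arma::find(fam < 2);
  arma::mat Cfix = arma::eye(fix_idx.n_elem, fix_idx.n_elem);
  for (unsigned int b = 0; b < fix_idx.n_elem; ++b)
    SigmaR(fix_idx(b), fix_idx(b)) = 1.0;

  RandomLevel ind, yearl;
  init_level(ind, id_idx, K, as<arma::mat>(control["sigma_ind_init"]));
  init_level(yearl, year_idx, K, as<arma::mat>(control["sigma_year_init"]));
  ind.update = as<bool>(control["update_sigma_ind"]);
  yearl.update = as<bool>(control["update_sigma_year"]);

  std::vector<AssayEffect> asy;
  for (int a = 0; a < assays.size(); ++a) {
    List one = assays[a];
    AssayEffect e;
    e.trait = as<int>(one["trait"]);
    arma::ivec ai = as<arma::ivec>(one["idx"]);
    e.idx = arma::conv_to<arma::uvec>::from(ai);
    e.nlev = e.idx.max() + 1;
    e.groups.resize(e.nlev);
    for (int g = 0; g < e.nlev; ++g)
      e.groups[g] = arma::find(e.idx == (unsigned int)g);
    e.xi = arma::vec(e.nlev, arma::fill::zeros);
    asy.push_back(e);
  }

  // latent initialisation
  arma::mat L = Y;
  for (int k = 0; k < K; ++k) {
    if (fam(k) == 1)
      for (int r = 0; r < n; ++r) L(r, k) = std::log(Y(r, k) + 0.5);
    if (fam(k) >= 2)
      for (int r = 0; r < n; ++r) L(r, k) = Y(r, k) > 0.5 ? 1.0 : -1.0;
  }
  arma::vec beta = as<arma::vec>(control["beta_init"]);
  arma::mat fx(n, K);
  for (int k = 0; k < K; ++k)
    fx.col(k) = X[k] * beta.subvec(off(k), off(k) + pk(k) - 1);
  arma::mat uu = level_contribution(ind, n, K);
  arma::mat vv = level_contribution(yearl, n, K);
  arma::mat aa(n, K, arma::fill::zeros);

  int nstore = (niter - nburn) / nthin;
  arma::mat beta_store(nstore, P);
  arma::cube si_store(K, K, nstore, arma::fill::zeros);
  arma::cube sy_store(K, K, nstore, arma::fill::zeros);
  arma::cube sr_store(K, K, nstore);
  arma::mat assay_store(nstore, std::max((int)asy.size(), 1),
                        arma::fill::zeros);
  int s = 0;

  arma::uvec nongauss = arma::find(fam > 0);

  for (int iter = 0; iter < niter; ++iter) {
    arma::mat Rinv = arma::inv_sympd(arma::symmatu(SigmaR));

    // --- latent values of non-Gaussian traits (slice within Gibbs) ---
    if (nongauss.n_elem > 0) {
      arma::mat mu = fx + uu + vv + aa;
      arma::mat E = L - mu;
      for (unsigned int q = 0; q < nongauss.n_elem; ++q) {
        int k = nongauss(q);
        // conditional prior of residual k given the other traits' residuals
        arma::uvec others(K - 1);
        for (int j = 0, c = 0; j < K; ++j) if (j != k) others(c++) = j;
        double cvar; arma::vec bvec;
        if (K > 1) {
          arma::mat Roo = SigmaR.submat(others, others);
          arma::vec rok = SigmaR.submat(others, arma::uvec{(unsigned)k});
          bvec = arma::solve(arma::symmatu(Roo), rok);
          cvar = SigmaR(k, k) - arma::dot(rok, bvec);
        } else { cvar = SigmaR(0, 0); bvec = arma::vec(); }
        for (int r = 0; r < n; ++r) {
          double cmean = mu(r, k);
          if (K > 1) {
            for (int j = 0; j < K - 1; ++j) cmean += bvec(j) * E(r, others(j));
          }
          double lnew = slice_latent(L(r, k), fam(k), Y(r, k), cmean, cvar);
          L(r, k) = lnew;
          E(r, k) = lnew - mu(r, k);
        }
      }
    }

    // --- fixed effects (joint GLS draw across traits) ---
    {
      arma::mat Tm = L - uu - vv - aa;
      arma::mat Q(P, P);
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < K; ++j)
          Q.submat(off(k), off(j), off(k) + pk(k) - 1, off(j) + pk(j) - 1) =
            Rinv(k, j) * XtX[k][j];
      Q.diag() += 1.0 / beta_var;
      arma::mat Wm = Tm * Rinv;
      arma::vec b(P);
      for (int k = 0; k < K; ++k)
        b.subvec(off(k), off(k) + pk(k) - 1) = X[k].t() * Wm.col(k);
      beta = rmvn_precision(Q, b);
      for (int k = 0; k < K; ++k)
        fx.col(k) = X[k] * beta.subvec(off(k), off(k) + pk(k) - 1);
    }

    // --- individual and year levels (parameter-expanded) ---
    if (ind.active) {
      arma::mat Tm = L - fx - vv - aa;
      update_level(ind, Tm, Rinv, px_nu, px_V, alpha_var, K);
      uu = level_contribution(ind, n, K);
    }
    if (yearl.active) {
      arma::mat Tm = L - fx - uu - aa;
      update_level(yearl, Tm, Rinv, px_nu, px_V, alpha_var, K);
      vv = level_contribution(yearl, n, K);
    }

    // --- scalar assay batch effects (parameter-expanded) ---
    for (size_t a = 0; a < asy.size(); ++a) {
      AssayEffect& e = asy[a];
      int k = e.trait;
      // remove this assay's own contribution from the target
      arma::mat Tm = L - fx - uu - vv - aa;
      for (int r = 0; r < n; ++r) Tm(r, k) += e.alpha * e.xi(e.idx(r));
      arma::mat WT = Tm * Rinv;
      double rkk = Rinv(k, k);
      for (int g = 0; g < e.nlev; ++g) {
        double prec = 1.0 / e.psi +
          e.alpha * e.alpha * e.groups[g].n_elem * rkk;
        double rhs = 0.0;
        for (unsigned int r = 0; r < e.groups[g].n_elem; ++r)
          rhs += WT(e.groups[g](r), k);
        rhs *= e.alpha;
        double mean = rhs / prec;
        e.xi(g) = mean + R::norm_rand() / std::sqrt(prec);
      }
      double Spost = px_V(0, 0) + arma::dot(e.xi, e.xi);
      e.psi = Spost / R::rchisq(px_nu + e.nlev);
      double aprec = 1.0 / alpha_var, arhs = 0.0;
      for (int r = 0; r < n; ++r) {
        double xr = e.xi(e.idx(r));
        aprec += xr * xr * rkk;
        arhs += xr * WT(r, k);
      }
      e.alpha = arhs / aprec + R::norm_rand() / std::sqrt(aprec);
      // rebuild the pooled assay contribution so later assays condition on
      // this assay's refreshed values
      aa.zeros();
      for (size_t a2 = 0; a2 < asy.size(); ++a2) {
        AssayEffect& e2 = asy[a2];
        for (int r = 0; r < n; ++r)
          aa(r, e2.trait) += e2.alpha * e2.xi(e2.idx(r));
      }
    }

    // --- residual covariance ---
    // The prior is truncated away from the singular boundary: draws whose
    // residual *correlation* matrix has an eigenvalue below eigen_floor are
    // rejected. Without this, latent (count/binary) trait pairs can enter a
    // quasi-absorbing state where their residuals become deterministic
    // copies: the scatter matrix goes singular, the next inverse-Wishart
    // draw has a near-zero eigenvalue (~scale/n), and the conditional latent
    // updates then reproduce the singular scatter indefinitely.
    if (upd_res) {
      arma::mat E = L - fx - uu - vv - aa;
      arma::mat Spost = V_R + E.t() * E;
      double nup = nu_R + n;
      for (int attempt = 0; attempt < 200; ++attempt) {
        arma::mat cand = (fix_idx.n_elem > 0)
          ? riwishart_fixed(Spost, nup, free_idx, fix_idx, Cfix)
          : riwishart(Spost, nup);
        if (K == 1) { SigmaR = cand; break; }
        arma::vec d = 1.0 / arma::sqrt(cand.diag());
        arma::mat corr = arma::diagmat(d) * cand * arma::diagmat(d);
        arma::vec ev = arma::eig_sym(arma::symmatu(corr));
        if (ev.min() >= eigen_floor) { SigmaR = cand; break; }
      }
    }

    // --- non-centered Metropolis sweep on the latent-trait residual block.
    // With count/binary traits, both residuals of a trait pair are latent and
    // the plain augmented Gibbs chain has almost no restoring force on their
    // correlation (it random-walks and sticks near the singular boundary).
    // Proposing a perturbed Sigma_R entry together with the matching linear
    // transform of the latent residuals makes the Gaussian prior terms cancel
    // exactly, so acceptance is driven by the observation likelihood: the
    // marginal information about the correlation.
    if (mh_sweep && upd_res && nongauss.n_elem > 0 && K > 1) {
      arma::uvec gidx = arma::find(fam == 0);
      arma::mat mu = fx + uu + vv + aa;
      arma::mat E = L - mu;
      // parameter list: (row k in NG, col j != k) cross entries + NG variances
      std::vector<std::pair<int,int>> pars;
      for (unsigned int a = 0; a < nongauss.n_elem; ++a) {
        int k = nongauss(a);
        if (fam(k) == 1) pars.push_back({k, k});       // free count variance
        for (int j = 0; j < K; ++j)
          if (j != k && !(fam(j) > 0 && j < k)) pars.push_back({k, j});
      }
      for (size_t q = 0; q < pars.size(); ++q) {
        int k = pars[q].first, j = pars[q].second;
        arma::mat Snew = SigmaR;
        double logjac = 0.0;
        if (k == j) {
          double f = std::exp(0.25 * R::norm_rand());
          Snew(k, k) *= f;
          logjac = std::log(f);                         // log-scale proposal
        } else {
          double step = 0.1 * std::sqrt(SigmaR(k, k) * SigmaR(j, j));
          double d = step * R::norm_rand();
          Snew(k, j) += d; Snew(j, k) += d;
        }
        // validity: positive definite and away from the singular boundary
        arma::vec dg = 1.0 / arma::sqrt(Snew.diag());
        arma::mat corr = arma::diagmat(dg) * Snew * arma::diagmat(dg);
        arma::vec evc;
        if (!arma::eig_sym(evc, arma::symmatu(corr))) continue;
        if (evc.min() < eigen_floor) continue;
        // conditional maps of the latent block given the Gaussian block
        arma::mat Bold, Bnew, Cold, Cnew;
        if (gidx.n_elem > 0) {
          arma::mat Ggi = arma::inv_sympd(
            arma::symmatu(SigmaR.submat(gidx, gidx)));
          Bold = SigmaR.submat(nongauss, gidx) * Ggi;
          Cold = arma::symmatu(SigmaR.submat(nongauss, nongauss) -
                               Bold * SigmaR.submat(gidx, nongauss));
          // Gaussian block untouched by the proposal, so Ggi is shared
          Bnew = Snew.submat(nongauss, gidx) * Ggi;
          Cnew = arma::symmatu(Snew.submat(nongauss, nongauss) -
                               Bnew * Snew.submat(gidx, nongauss));
        } else {
          Cold = arma::symmatu(SigmaR.submat(nongauss, nongauss));
          Cnew = arma::symmatu(Snew.submat(nongauss, nongauss));
        }
        arma::mat Lco, Lcn;
        if (!arma::chol(Lco, Cold, "lower")) continue;
        if (!arma::chol(Lcn, Cnew, "lower")) continue;
        arma::mat M = Lcn * arma::inv(arma::trimatl(Lco));  // p2 x p2
        // inverse-Wishart prior ratio
        double sold, snew, ld_old, ld_new;
        arma::log_det(ld_old, sold, SigmaR);
        arma::log_det(ld_new, snew, Snew);
        arma::mat Sold_i = arma::inv_sympd(arma::symmatu(SigmaR));
        arma::mat Snew_i = arma::inv_sympd(arma::symmatu(Snew));
        double logacc = -(nu_R + K + 1) / 2.0 * (ld_new - ld_old) -
          0.5 * (arma::trace(V_R * Snew_i) - arma::trace(V_R * Sold_i)) +
          logjac;
        // transformed latent residuals and observation likelihood ratio
        int p2 = nongauss.n_elem;
        arma::mat Eng(n, p2), Engnew(n, p2);
        for (int c = 0; c < p2; ++c) Eng.col(c) = E.col(nongauss(c));
        arma::mat shift(n, p2, arma::fill::zeros);
        if (gidx.n_elem > 0) {
          arma::mat Eg(n, gidx.n_elem);
          for (unsigned int c = 0; c < gidx.n_elem; ++c)
            Eg.col(c) = E.col(gidx(c));
          Engnew = Eg * Bnew.t() + (Eng - Eg * Bold.t()) * M.t();
        } else {
          Engnew = Eng * M.t();
        }
        for (int c = 0; c < p2; ++c) {
          int kk = nongauss(c);
          for (int r = 0; r < n; ++r) {
            logacc += loglik_obs(fam(kk), Y(r, kk), mu(r, kk) + Engnew(r, c)) -
                      loglik_obs(fam(kk), Y(r, kk), mu(r, kk) + Eng(r, c));
          }
        }
        if (std::log(R::unif_rand()) < logacc) {
          SigmaR = arma::symmatu(Snew);
          for (int c = 0; c < p2; ++c) {
            int kk = nongauss(c);
            E.col(kk) = Engnew.col(c);
            L.col(kk) = mu.col(kk) + Engnew.col(c);
          }
        }
      }
    }

    // --- store ---
    if (iter >= nburn && ((iter - nburn) % nthin == 0) && s < nstore) {
      beta_store.row(s) = beta.t();
      if (ind.active) {
        arma::mat D = arma::diagmat(ind.alpha);
        si_store.slice(s) = D * ind.Psi * D;
      }
      if (yearl.active) {
        arma::mat D = arma::diagmat(yearl.alpha);
        sy_store.slice(s) = D * yearl.Psi * D;
      }
      sr_store.slice(s) = SigmaR;
      for (size_t a = 0; a < asy.size(); ++a)
        assay_store(s, a) = asy[a].alpha * asy[a].alpha * asy[a].psi;
      ++s;
    }
  }

  return List::create(
    _["beta"] = beta_store, _["sigma_ind"] = si_store,
    _["sigma_year"] = sy_store, _["sigma_res"] = sr_store,
    _["assay_var"] = assay_store, _["n_stored"] = s);
}

// [[Rcpp::export(name = ".riwish_fixed_cpp")]]
arma::mat riwish_fixed_cpp(arma::mat S, double nu, arma::uvec free_idx,
                           arma::uvec fix_idx, arma::mat C) {
  return riwishart_fixed(S, nu, free_idx, fix_idx, C);
}

// [[Rcpp::export(name = ".riwish_cpp")]]
arma::mat riwish_cpp(arma::mat S, double nu) { return riwishart(S, nu); }
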