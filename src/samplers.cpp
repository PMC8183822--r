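#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// All random draws go through R's RNG so that set.seed() in R makes every
// chain bit-reproducible.

static inline double r_scinvchisq(double df, double S) {
  // draw from scaled-inverse-chi-square(df, S): df*S / chisq(df)
  return df * S / R::rchisq(df);
}

static inline double r_invgauss(double mu, double lambda) {
  // Michael-Schucany-Haas
  double z = R::rnorm(0.0, 1.0);
  double w = z * z;
  double x = mu + mu * mu * w / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * w + mu * mu * w * w);
  if (x <= 0.0) x = 1e-10;
  if (R::runif(0.0, 1.0) <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Gibbs sampler for whole-genome marker regression.
// model: 0 = BayesA (scaled-t via per-marker variances),
//        1 = BayesB (spike at zero + per-marker slab variance),
//        2 = Bayesian LASSO (double-exponential via exponential mixture).
// y is assumed centred/standardised upstream; X standardised marker matrix.
// [[Rcpp::export]]
List wgr_gibbs(const arma::vec& y, const arma::mat& X, const int model,
               const int niter, const int burnin, const int thin,
               const double dfb, const double Sb,
               const double dfe, const double Se,
               const double probIn,
               const double lshape, const double lrate) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec xx(p);
  for (int k = 0; k < p; ++k) xx[k] = arma::dot(X.col(k), X.col(k));

  double mu = arma::mean(y);
  arma::vec b(p, arma::fill::zeros);
  arma::vec s2b(p); s2b.fill(Sb);          // per-marker variances (BayesA/B)
  arma::vec tau2(p, arma::fill::ones);     // BL mixing variances
  arma::ivec delta(p, arma::fill::ones);   // BayesB inclusion indicators
  double lambda2 = (lrate > 0.0) ? lshape / lrate : 1.0;
  double ve = Se;
  if (!(ve > 0.0)) ve = 1.0;

  arma::vec e = y - mu;

  arma::vec bbar(p, arma::fill::zeros), dbar(p, arma::fill::zeros);
  double mubar = 0.0;
  int nkeep = 0;
  const int nstore = (niter - burnin + thin - 1) / thin;
  arma::mat chain(nstore, 3, arma::fill::zeros); // ve, var(Xb), lambda2

  for (int it = 1; it <= niter; ++it) {
    // intercept (flat prior)
    double m = arma::mean(e) + mu;
    double mu_new = R::rnorm(m, std::sqrt(ve / n));
    e -= (mu_new - mu);
    mu = mu_new;

    for (int k = 0; k < p; ++k) {
      const double bk = b[k];
      if (model == 2) { // Bayesian LASSO, prior b_k ~ N(0, tau2_k * ve)
        double c = arma::dot(X.col(k), e) + xx[k] * bk;
        double denom = xx[k] + 1.0 / tau2[k];
        double bnew = R::rnorm(c / denom, std::sqrt(ve / denom));
        if (bnew != bk) { e -= X.col(k) * (bnew - bk); b[k] = bnew; }
        double b2 = b[k] * b[k];
        if (b2 < 1e-12) b2 = 1e-12;
        double itau = r_invgauss(std::sqrt(lambda2 * ve / b2), lambda2);
        tau2[k] = 1.0 / itau;
      } else {
        double s2k = s2b[k];
        bool was_in = (model == 0) || (delta[k] == 1);
        // residuals with marker k removed
        double c = arma::dot(X.col(k), e) + (was_in ? xx[k] * bk : 0.0);
        bool now_in = true;
        if (model == 1) { // spike-and-slab inclusion draw
          double v1 = ve + xx[k] * s2k;
          double logodds = std::log(probIn / (1.0 - probIn)) +
            0.5 * (std::log(ve) - std::log(v1)) +
            0.5 * c * c * s2k / (ve * v1);
          double pr = 1.0 / (1.0 + std::exp(-logodds));
          now_in = (R::runif(0.0, 1.0) < pr);
          delta[k] = now_in ? 1 : 0;
        }
        double bnew = 0.0;
        if (now_in) {
          double prec = xx[k] / ve + 1.0 / s2k;
          double mean = (c / ve) / prec;
          bnew = R::rnorm(mean, std::sqrt(1.0 / prec));
        }
        double old_contrib = was_in ? bk : 0.0;
        if (bnew != old_contrib) e -= X.col(k) * (bnew - old_contrib);
        b[k] = bnew;
        // per-marker variance
        if (now_in) {
          s2b[k] = r_scinvchisq(dfb + 1.0,
                                (dfb * Sb + b[k] * b[k]) / (dfb + 1.0));
        } else {
          s2b[k] = r_scinvchisq(dfb, Sb);
        }
      }
    }

    if (model == 2) { // update lambda^2 | tau2
      double rate = lrate + 0.5 * arma::accu(tau2);
      lambda2 = R::rgamma(lshape + p, 1.0 / rate);
    }

    // residual variance
    if (model == 2) {
      double ss = arma::dot(e, e);
      for (int k = 0; k < p; ++k) ss += b[k] * b[k] / tau2[k];
      ve = (ss + dfe * Se) / R::rchisq(dfe + n + p);
    } else {
      ve = (arma::dot(e, e) + dfe * Se) / R::rchisq(dfe + n);
    }
    if (ve < 1e-10) ve = 1e-10;

    if (it > burnin && ((it - burnin) % thin == 0)) {
      bbar += b;
      mubar += mu;
      for (int k = 0; k < p; ++k) dbar[k] += (model == 1) ? delta[k] : 1.0;
      arma::vec g = X * b;
      chain(nkeep, 0) = ve;
      chain(nkeep, 1) = arma::var(g);
      chain(nkeep, 2) = lambda2;
      ++nkeep;
    }
    if (!e.is_finite())
      stop("divergent chain: non-finite residuals at iteration %d", it);
  }

  bbar /= nkeep; dbar /= nkeep; mubar /= nkeep;
  return List::create(_["mu"] = mubar, _["b"] = bbar, _["d"] = dbar,
                      _["chain"] = chain.rows(0, nkeep - 1),
                      _["nSamples"] = nkeep);
}

// Gibbs sampler for Gaussian-process (kernel) models with an arbitrary set of
// random components, each expressed in the eigenbasis of its kernel:
//   y = W beta + sum_r Z_r U_r a_r + e,  a_rk ~ N(0, s2_{g(r)} d_rk)
// Fixed effects beta get a flat prior; variance components are
// scaled-inverse-chi-square; components may share a variance group (MDs).
// 'map' per component gives, for each observation, the 1-based level index it
// loads on (0 = no contribution, e.g. environment-specific terms).
// [[Rcpp::export]]
List kernel_gibbs(const arma::vec& y, const arma::mat& W,
                  const List& comps,
                  const int ngroups,
                  const arma::vec& dfg, const arma::vec& Sg,
                  const double dfe, const double Se,
                  const int niter, const int burnin, const int thin) {
  const int n = y.n_elem;
  const int f = W.n_cols;
  const int R = comps.size();

  std::vector<arma::mat> U(R), Uo(R);
  std::vector<arma::vec> d(R), zz(R), a(R), abar(R);
  std::vector<arma::uvec> obs(R);
  std::vector<int> grp(R);

  for (int r = 0; r < R; ++r) {
    List cp = comps[r];
    U[r] = as<arma::mat>(cp["U"]);
    d[r] = as<arma::vec>(cp["d"]);
    grp[r] = as<int>(cp["group"]) - 1;
    IntegerVector mp = cp["map"];
    std::vector<unsigned int> oi, li;
    for (int i = 0; i < n; ++i)
      if (mp[i] > 0) { oi.push_back(i); li.push_back(mp[i] - 1); }
    obs[r] = arma::uvec(oi);
    arma::uvec lev = arma::uvec(li);
    // observation-expanded eigenvectors: row j = U[level(obs j), ]
    Uo[r] = U[r].rows(lev);
    const int q = U[r].n_cols;
    a[r] = arma::vec(q, arma::fill::zeros);
    abar[r] = arma::vec(q, arma::fill::zeros);
    zz[r] = arma::vec(q);
    for (int k = 0; k < q; ++k) zz[r][k] = arma::dot(Uo[r].col(k),
                                                     Uo[r].col(k));
  }

  arma::mat WtW = W.t() * W;
  arma::mat L = arma::chol(WtW, "lower");
  arma::vec beta(f, arma::fill::zeros), betabar(f, arma::fill::zeros);
  arma::vec s2(ngroups); s2.fill(1.0);
  for (int g = 0; g < ngroups; ++g) if (Sg[g] > 0) s2[g] = Sg[g];
  double ve = (Se > 0.0) ? Se : 1.0;
  arma::vec e = y - W * beta;

  const int nstore = (niter - burnin + thin - 1) / thin;
  arma::mat chain(nstore, ngroups + 1, arma::fill::zeros);
  int nkeep = 0;

  for (int it = 1; it <= niter; ++it) {
    // fixed effects, flat prior: beta ~ N((W'W)^-1 W'(e + W beta), ve (W'W)^-1)
    arma::vec rhs = W.t() * (e + W * beta);
    arma::vec mean = arma::solve(WtW, rhs);
    arma::vec z(f);
    for (int j = 0; j < f; ++j) z[j] = R::rnorm(0.0, 1.0);
    arma::vec beta_new = mean + std::sqrt(ve) * arma::solve(arma::trimatu(L.t()), z);
    e -= W * (beta_new - beta);
    beta = beta_new;

    // eigen-coefficients of each random component (contiguous gather /
    // scatter of the residuals this component touches)
    for (int r = 0; r < R; ++r) {
      const int q = a[r].n_elem;
      const double s2g = s2[grp[r]];
      const arma::uvec& oi = obs[r];
      arma::vec esub = e.elem(oi);
      for (int k = 0; k < q; ++k) {
        const double ak = a[r][k];
        double c = arma::dot(Uo[r].col(k), esub) + zz[r][k] * ak;
        double prec = zz[r][k] / ve + 1.0 / (s2g * d[r][k]);
        double mn = (c / ve) / prec;
        double anew = R::rnorm(mn, std::sqrt(1.0 / prec));
        double delta = anew - ak;
        if (delta != 0.0) esub -= Uo[r].col(k) * delta;
        a[r][k] = anew;
      }
      e.elem(oi) = esub;
    }

    // variance components by group
    for (int g = 0; g < ngroups; ++g) {
      double ss = 0.0; int mtot = 0;
      for (int r = 0; r < R; ++r) if (grp[r] == g) {
        for (arma::uword k = 0; k < a[r].n_elem; ++k)
          ss += a[r][k] * a[r][k] / d[r][k];
        mtot += a[r].n_elem;
      }
      s2[g] = (ss + dfg[g] * Sg[g]) / R::rchisq(dfg[g] + mtot);
      if (s2[g] < 1e-10) s2[g] = 1e-10;
    }

    ve = (arma::dot(e, e) + dfe * Se) / R::rchisq(dfe + n);
    if (ve < 1e-10) ve = 1e-10;

    if (it > burnin && ((it - burnin) % thin == 0)) {
      for (int r = 0; r < R; ++r) abar[r] += a[r];
      betabar += beta;
      for (int g = 0; g < ngroups; ++g) chain(nkeep, g) = s2[g];
      chain(nkeep, ngroups) = ve;
      ++nkeep;
    }
    if (!e.is_finite())
      stop("divergent chain: non-finite residuals at iteration %d", it);
  }

  betabar /= nkeep;
  List gmeans(R);
  for (int r = 0; r < R; ++r) {
    abar[r] /= nkeep;
    gmeans[r] = U[r] * abar[r]; // posterior-mean effect per level
  }
  return List::create(_["beta"] = betabar, _["g"] = gmeans,
                      _["chain"] = chain.rows(0, nkeep - 1),
                      _["nSamples"] = nkeep);
}
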