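// Gibbs sampler for the crossed-random-effects hierarchical model:
//   lognormal family: log y ~ Normal(eta, sigma), Exponential prior on sigma
//   bernoulli family: y ~ Bernoulli(logit^-1(eta)), Polya-Gamma augmentation
//   eta = U beta + U (diag(tau_b) L_b z_bi) + V (diag(tau_c) L_c z_cj)
// Priors: Normal on beta, Exponential on tau, LKJ(eta) on the random-effect
// correlation matrices (sampled in tanh canonical-partial-correlation space
// by adaptive random-walk Metropolis), standard normal on the non-centred z.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PG_TRUNC = 0.64;

// ---- Polya-Gamma PG(1, psi) sampler (Devroye-type alternating series) ----

static double pg_a_coef(int n, double x) {
  double np = n + 0.5;
  if (x > PG_TRUNC)
    return M_PI * np * std::exp(-np * np * M_PI * M_PI * 0.5 * x);
  return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np * np / x);
}

// CDF of inverse-Gaussian(mean 1/z, shape 1) at x
static double pg_pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double b = rx * (x * z - 1.0);
  double a = -rx * (x * z + 1.0);
  return R::pnorm(b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z + R::pnorm(a, 0.0, 1.0, 1, 1));
}

// inverse-Gaussian(1/z, 1) truncated to (0, t)
static double pg_rtigauss(double z, double t) {
  double x = t + 1.0;
  if (1.0 / z > t) {
    double alpha = 0.0;
    while (R::runif(0.0, 1.0) > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = R::norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (R::runif(0.0, 1.0) > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

static double rpg1(double psi) {
  double z = std::fabs(psi) * 0.5;
  double K = M_PI * M_PI * 0.125 + z * z * 0.5;
  double p = 0.5 * M_PI / K * std::exp(-K * PG_TRUNC);
  double q = 2.0 * std::exp(-z) * pg_pigauss(PG_TRUNC, z);
  double ratio = p / (p + q);
  for (;;) {
    double X;
    if (R::runif(0.0, 1.0) < ratio) {
      X = PG_TRUNC + R::exp_rand() / K;
    } else {
      X = pg_rtigauss(z, PG_TRUNC);
    }
    double S = pg_a_coef(0, X);
    double Y = R::runif(0.0, 1.0) * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= pg_a_coef(n, X);
        if (Y <= S) return X * 0.25;
      } else {
        S += pg_a_coef(n, X);
        if (Y > S) break;
      }
      if (n > 1000) return X * 0.25;  // series converged numerically
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector rpg_vec(Rcpp::NumericVector psi) {
  int n = psi.size();
  Rcpp::NumericVector out(n);
  GetRNGstate();
  for (int i = 0; i < n; ++i) out[i] = rpg1(psi[i]);
  PutRNGstate();
  return out;
}

// ---- truncated normal on (0, inf), mean m, sd s (Robert's method) ----
static double rtnorm_pos(double m, double s) {
  double a = -m / s;  // standardized lower bound
  double x;
  if (a < 0.4) {
    do {
      x = R::norm_rand();
    } while (x < a);
  } else {
    double lam = 0.5 * (a + std::sqrt(a * a + 4.0));
    for (;;) {
      x = a + R::exp_rand() / lam;
      double rho = std::exp(-0.5 * (x - lam) * (x - lam));
      if (R::runif(0.0, 1.0) <= rho) break;
    }
  }
  return m + s * x;
}

// ---- canonical partial correlations -> Cholesky factor ----
static arma::mat cpc_to_chol(const arma::vec& y, int q) {
  arma::mat L(q, q, arma::fill::zeros);
  L(0, 0) = 1.0;
  int idx = 0;
  for (int i = 1; i < q; ++i) {
    double sumsq = 0.0;
    for (int j = 0; j < i; ++j) {
      double r = std::tanh(y(idx++));
      L(i, j) = r * std::sqrt(1.0 - sumsq);
      sumsq += L(i, j) * L(i, j);
    }
    L(i, i) = std::sqrt(std::max(1.0 - sumsq, 1e-12));
  }
  return L;
}

// log prior of unconstrained CPC vector under LKJ(eta): the C-vine
// construction makes the CPCs independent scaled Betas whose shape depends
// on the column index; the tanh Jacobian contributes one extra power.
static double cpc_log_prior(const arma::vec& y, int q, double eta) {
  double lp = 0.0;
  int idx = 0;
  for (int i = 1; i < q; ++i) {
    for (int j = 0; j < i; ++j) {
      double alpha = eta + 0.5 * (q - 2 - j);
      double th = std::tanh(y(idx++));
      lp += alpha * std::log1p(-th * th);
    }
  }
  return lp;
}

struct Fam {
  int family;  // 0 gaussian (on log response), 1 bernoulli
};

// conditional log-likelihood of eta given weights/pseudo-response
static double loglik_eta(const arma::vec& eta, const arma::vec& r,
                         const arma::vec& w, int family,
                         const arma::vec& kappa) {
  if (family == 0) {
    arma::vec d = r - eta;
    return -0.5 * arma::dot(w % d, d);
  }
  // PG-augmented bernoulli: kappa*eta - omega*eta^2/2
  return arma::dot(kappa, eta) - 0.5 * arma::dot(w, eta % eta);
}

// [[Rcpp::export]]
Rcpp::List gibbs_hier(const arma::vec& y, int family,
                      const arma::mat& U, const arma::mat& V,
                      const arma::uvec& pid, const arma::uvec& iid,
                      int n_part, int n_item,
                      const arma::vec& beta_mean, const arma::vec& beta_sd,
                      double sd_rate, double lkj_eta, double sigma_rate,
                      const arma::uvec& vcols,
                      int n_iter, int n_warmup, int thin, bool store_z,
                      int lkj_steps = 1) {
  const int n = y.n_elem;
  const int qb = U.n_cols;
  const int qc = V.n_cols;
  const int mb = qb * (qb - 1) / 2;
  const int mc = qc * (qc - 1) / 2;

  // row index groups
  std::vector<arma::uvec> prow(n_part), irow(n_item);
  {
    std::vector<std::vector<arma::uword>> tmpp(n_part), tmpi(n_item);
    for (int k = 0; k < n; ++k) {
      tmpp[pid(k)].push_back(k);
      tmpi[iid(k)].push_back(k);
    }
    for (int i = 0; i < n_part; ++i) prow[i] = arma::uvec(tmpp[i]);
    for (int j = 0; j < n_item; ++j) irow[j] = arma::uvec(tmpi[j]);
  }

  // state
  arma::vec beta = beta_mean;
  arma::mat zb(qb, n_part, arma::fill::zeros);
  arma::mat zc(qc, n_item, arma::fill::zeros);
  arma::vec tau_b(qb, arma::fill::value(0.1));
  arma::vec tau_c(qc, arma::fill::value(0.1));
  arma::vec yb(std::max(mb, 1), arma::fill::zeros);
  arma::vec yc(std::max(mc, 1), arma::fill::zeros);
  double sigma = 0.5;
  arma::mat Lb = cpc_to_chol(yb, qb);
  arma::mat Lc = (qc > 1) ? cpc_to_chol(yc, qc) : arma::eye(qc, qc);

  arma::vec r = y;                       // working response
  arma::vec kappa(n, arma::fill::zeros); // bernoulli only
  if (family == 1) kappa = y - 0.5;
  arma::vec w(n, arma::fill::ones);

  arma::vec eta_f = U * beta;
  arma::vec eta_b(n, arma::fill::zeros);
  arma::vec eta_c(n, arma::fill::zeros);

  double step_b = 0.1, step_c = 0.1;
  double acc_b = 0.0, acc_c = 0.0;
  int n_mh = 0;

  const int n_keep = (n_iter - n_warmup) / thin;
  arma::mat out_beta(n_keep, qb), out_tau_b(n_keep, qb),
      out_tau_c(n_keep, qc), out_yb(n_keep, std::max(mb, 1)),
      out_yc(n_keep, std::max(mc, 1));
  arma::vec out_sigma(n_keep, arma::fill::zeros);
  arma::mat out_zb, out_zc;
  if (store_z) {
    out_zb.set_size(n_keep, qb * n_part);
    out_zc.set_size(n_keep, qc * n_item);
  }

  const arma::vec beta_prec = 1.0 / (beta_sd % beta_sd);

  GetRNGstate();
  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    // --- family-specific weights ---
    if (family == 0) {
      w.fill(1.0 / (sigma * sigma));
      r = y;
    } else {
      arma::vec eta = eta_f + eta_b + eta_c;
      for (int k = 0; k < n; ++k) {
        w(k) = rpg1(eta(k));
        r(k) = kappa(k) / w(k);
      }
    }

    // --- beta | rest ---
    {
      arma::vec resid = r - eta_b - eta_c;
      arma::mat Uw = U.each_col() % w;
      arma::mat A = U.t() * Uw;
      A.diag() += beta_prec;
      arma::vec rhs = U.t() * (w % resid) + beta_prec % beta_mean;
      arma::mat R = arma::chol(A);
      arma::vec mu = arma::solve(arma::trimatu(R),
                                 arma::solve(arma::trimatl(R.t()), rhs));
      arma::vec zdraw(qb);
      for (int k = 0; k < qb; ++k) zdraw(k) = R::norm_rand();
      beta = mu + arma::solve(arma::trimatu(R), zdraw);
      eta_f = U * beta;
    }

    // --- z_b | rest (per participant) ---
    {
      arma::mat Ab = Lb.each_col() % tau_b;  // diag(tau_b) * Lb
      for (int i = 0; i < n_part; ++i) {
        const arma::uvec& rows = prow[i];
        if (rows.n_elem == 0) { // prior draw
          for (int k = 0; k < qb; ++k) zb(k, i) = R::norm_rand();
          continue;
        }
        arma::mat M = U.rows(rows) * Ab;  // m_i x qb
        arma::vec resid = r.elem(rows) - eta_f.elem(rows) - eta_c.elem(rows);
        arma::vec wi = w.elem(rows);
        arma::mat P = M.t() * (M.each_col() % wi);
        P.diag() += 1.0;
        arma::vec rhs = M.t() * (wi % resid);
        arma::mat R = arma::chol(P);
        arma::vec mu = arma::solve(arma::trimatu(R),
                                   arma::solve(arma::trimatl(R.t()), rhs));
        arma::vec zdraw(qb);
        for (int k = 0; k < qb; ++k) zdraw(k) = R::norm_rand();
        zb.col(i) = mu + arma::solve(arma::trimatu(R), zdraw);
        eta_b.elem(rows) = M * zb.col(i);
      }
    }

    // --- z_c | rest (per item) ---
    {
      arma::mat Ac = Lc.each_col() % tau_c;
      for (int j = 0; j < n_item; ++j) {
        const arma::uvec& rows = irow[j];
        if (rows.n_elem == 0) {
          for (int k = 0; k < qc; ++k) zc(k, j) = R::norm_rand();
          continue;
        }
        arma::mat M = V.rows(rows) * Ac;
        arma::vec resid = r.elem(rows) - eta_f.elem(rows) - eta_b.elem(rows);
        arma::vec wj = w.elem(rows);
        arma::mat P = M.t() * (M.each_col() % wj);
        P.diag() += 1.0;
        arma::vec rhs = M.t() * (wj % resid);
        arma::mat R = arma::chol(P);
        arma::vec mu = arma::solve(arma::trimatu(R),
                                   arma::solve(arma::trimatl(R.t()), rhs));
        arma::vec zdraw(qc);
        for (int k = 0; k < qc; ++k) zdraw(k) = R::norm_rand();
        zc.col(j) = mu + arma::solve(arma::trimatu(R), zdraw);
        eta_c.elem(rows) = M * zc.col(j);
      }
    }

    // --- tau_b | rest (scalar truncated normals; eta linear in tau) ---
    {
      arma::mat sb = Lb * zb;  // qb x n_part
      for (int k = 0; k < qb; ++k) {
        arma::vec d(n);
        for (int t = 0; t < n; ++t) d(t) = U(t, k) * sb(k, pid(t));
        arma::vec resid_k = r - eta_f - eta_c - eta_b + tau_b(k) * d;
        double qq = arma::dot(w % d, d);
        double S = arma::dot(w % d, resid_k) - sd_rate;
        if (qq < 1e-12) {
          // likelihood carries no information: draw from the prior
          double newt = R::exp_rand() / sd_rate;
          eta_b += (newt - tau_b(k)) * d;
          tau_b(k) = newt;
          continue;
        }
        double m = S / qq, s = 1.0 / std::sqrt(qq);
        double newt = rtnorm_pos(m, s);
        eta_b += (newt - tau_b(k)) * d;
        tau_b(k) = newt;
      }
    }

    // --- tau_c | rest ---
    {
      arma::mat sc = Lc * zc;
      for (int k = 0; k < qc; ++k) {
        arma::vec d(n);
        for (int t = 0; t < n; ++t) d(t) = V(t, k) * sc(k, iid(t));
        arma::vec resid_k = r - eta_f - eta_b - eta_c + tau_c(k) * d;
        double qq = arma::dot(w % d, d);
        double S = arma::dot(w % d, resid_k) - sd_rate;
        if (qq < 1e-12) {
          double newt = R::exp_rand() / sd_rate;
          eta_c += (newt - tau_c(k)) * d;
          tau_c(k) = newt;
          continue;
        }
        double m = S / qq, s = 1.0 / std::sqrt(qq);
        double newt = rtnorm_pos(m, s);
        eta_c += (newt - tau_c(k)) * d;
        tau_c(k) = newt;
      }
    }

    // --- sweep updates: translate beta along likelihood-invariant
    // directions against the random effects (fixes slow mixing of the
    // shared location between fixed and random intercepts/slopes) ---
    {
      arma::mat Ab = Lb; Ab.each_col() %= tau_b;         // lower triangular
      arma::mat Mb = arma::solve(arma::trimatl(Ab), arma::eye(qb, qb));
      arma::mat P = Mb.t() * Mb * (double)n_part;
      P.diag() += beta_prec;
      arma::vec bvec = beta_prec % (beta_mean - beta) +
                       Mb.t() * arma::sum(zb, 1);
      arma::mat R = arma::chol(P);
      arma::vec mu = arma::solve(arma::trimatu(R),
                                 arma::solve(arma::trimatl(R.t()), bvec));
      arma::vec zdraw(qb);
      for (int k = 0; k < qb; ++k) zdraw(k) = R::norm_rand();
      arma::vec delta = mu + arma::solve(arma::trimatu(R), zdraw);
      beta += delta;
      zb.each_col() -= Mb * delta;
      arma::vec shift = U * delta;
      eta_f += shift;
      eta_b -= shift;
    }
    {
      arma::mat Ac = Lc; Ac.each_col() %= tau_c;
      arma::mat Mc = arma::solve(arma::trimatl(Ac), arma::eye(qc, qc));
      arma::mat P = Mc.t() * Mc * (double)n_item;
      arma::vec prec_sub = beta_prec.elem(vcols);
      P.diag() += prec_sub;
      arma::vec bvec = prec_sub % (beta_mean.elem(vcols) - beta.elem(vcols)) +
                       Mc.t() * arma::sum(zc, 1);
      arma::mat R = arma::chol(P);
      arma::vec mu = arma::solve(arma::trimatu(R),
                                 arma::solve(arma::trimatl(R.t()), bvec));
      arma::vec zdraw(qc);
      for (int k = 0; k < qc; ++k) zdraw(k) = R::norm_rand();
      arma::vec delta = mu + arma::solve(arma::trimatu(R), zdraw);
      beta.elem(vcols) += delta;
      zc.each_col() -= Mc * delta;
      arma::vec shift = V * delta;
      eta_f += shift;
      eta_c -= shift;
    }

    // --- correlation Cholesky factors: independence-MH proposal from the
    // LKJ prior (prior and proposal densities cancel, acceptance is the
    // likelihood ratio; near-perfect mixing wherever the correlations are
    // weakly identified), followed by a random-walk refinement ---
    if (mb > 0) {
      arma::vec prop(mb);
      int idx = 0;
      for (int i = 1; i < qb; ++i)
        for (int j = 0; j < i; ++j) {
          double a = lkj_eta + 0.5 * (qb - 2 - j);
          double rr = 2.0 * R::rbeta(a, a) - 1.0;
          prop(idx++) = std::atanh(std::min(std::max(rr, -0.999999), 0.999999));
        }
      arma::mat Lp = cpc_to_chol(prop, qb);
      arma::mat Bp = Lp * zb; Bp.each_col() %= tau_b;
      arma::vec eta_bp(n);
      for (int t = 0; t < n; ++t)
        eta_bp(t) = arma::dot(U.row(t).t(), Bp.col(pid(t)));
      double cur = loglik_eta(eta_f + eta_b + eta_c, r, w, family, kappa);
      double prp = loglik_eta(eta_f + eta_bp + eta_c, r, w, family, kappa);
      if (R::unif_rand() < std::exp(std::min(0.0, prp - cur))) {
        yb = prop; Lb = Lp; eta_b = eta_bp;
      }
    }
    if (mc > 0) {
      arma::vec prop(mc);
      int idx = 0;
      for (int i = 1; i < qc; ++i)
        for (int j = 0; j < i; ++j) {
          double a = lkj_eta + 0.5 * (qc - 2 - j);
          double rr = 2.0 * R::rbeta(a, a) - 1.0;
          prop(idx++) = std::atanh(std::min(std::max(rr, -0.999999), 0.999999));
        }
      arma::mat Lp = cpc_to_chol(prop, qc);
      arma::mat Cp = Lp * zc; Cp.each_col() %= tau_c;
      arma::vec eta_cp(n);
      for (int t = 0; t < n; ++t)
        eta_cp(t) = arma::dot(V.row(t).t(), Cp.col(iid(t)));
      double cur = loglik_eta(eta_f + eta_b + eta_c, r, w, family, kappa);
      double prp = loglik_eta(eta_f + eta_b + eta_cp, r, w, family, kappa);
      if (R::unif_rand() < std::exp(std::min(0.0, prp - cur))) {
        yc = prop; Lc = Lp; eta_c = eta_cp;
      }
    }

    if (mb > 0) {
      for (int rep = 0; rep < lkj_steps; ++rep) {
        arma::vec prop = yb;
        for (int k = 0; k < mb; ++k) prop(k) += step_b * R::norm_rand();
        arma::mat Lp = cpc_to_chol(prop, qb);
        arma::mat Bp = Lp * zb; Bp.each_col() %= tau_b;  // qb x n_part
        arma::vec eta_bp(n);
        for (int t = 0; t < n; ++t)
          eta_bp(t) = arma::dot(U.row(t).t(), Bp.col(pid(t)));
        double cur = loglik_eta(eta_f + eta_b + eta_c, r, w, family, kappa) +
                     cpc_log_prior(yb, qb, lkj_eta);
        double prp = loglik_eta(eta_f + eta_bp + eta_c, r, w, family, kappa) +
                     cpc_log_prior(prop, qb, lkj_eta);
        double a = std::exp(std::min(0.0, prp - cur));
        if (R::unif_rand() < a) {
          yb = prop; Lb = Lp; eta_b = eta_bp;
        }
        if (it < n_warmup) step_b *= std::exp((a - 0.25) / std::sqrt(it + 1.0));
        else acc_b += a;
      }
    }
    if (mc > 0) {
      for (int rep = 0; rep < lkj_steps; ++rep) {
        arma::vec prop = yc;
        for (int k = 0; k < mc; ++k) prop(k) += step_c * R::norm_rand();
        arma::mat Lp = cpc_to_chol(prop, qc);
        arma::mat Cp = Lp * zc; Cp.each_col() %= tau_c;
        arma::vec eta_cp(n);
        for (int t = 0; t < n; ++t)
          eta_cp(t) = arma::dot(V.row(t).t(), Cp.col(iid(t)));
        double cur = loglik_eta(eta_f + eta_b + eta_c, r, w, family, kappa) +
                     cpc_log_prior(yc, qc, lkj_eta);
        double prp = loglik_eta(eta_f + eta_b + eta_cp, r, w, family, kappa) +
                     cpc_log_prior(prop, qc, lkj_eta);
        double a = std::exp(std::min(0.0, prp - cur));
        if (R::unif_rand() < a) {
          yc = prop; Lc = Lp; eta_c = eta_cp;
        }
        if (it < n_warmup) step_c *= std::exp((a - 0.25) / std::sqrt(it + 1.0));
        else acc_c += a;
      }
    }
    if (it >= n_warmup) ++n_mh;

    // --- sigma | rest (gaussian family): slice sampler on log sigma ---
    if (family == 0) {
      arma::vec d = y - eta_f - eta_b - eta_c;
      double sse = arma::dot(d, d);
      auto logf = [&](double ls) {
        double s2 = std::exp(2.0 * ls);
        return -(n - 1.0) * ls - 0.5 * sse / s2 - sigma_rate * std::exp(ls);
      };
      double x0 = std::log(sigma);
      double logy = logf(x0) + std::log(R::unif_rand());
      double wslice = 0.5;
      double L = x0 - wslice * R::unif_rand();
      double Rr = L + wslice;
      int mexp = 50;
      while (mexp-- > 0 && logf(L) > logy) L -= wslice;
      mexp = 50;
      while (mexp-- > 0 && logf(Rr) > logy) Rr += wslice;
      for (;;) {
        double x1 = L + (Rr - L) * R::unif_rand();
        if (logf(x1) >= logy) { sigma = std::exp(x1); break; }
        if (x1 < x0) L = x1; else Rr = x1;
      }
    }

    // --- store ---
    if (it >= n_warmup && (it - n_warmup) % thin == 0) {
      out_beta.row(keep) = beta.t();
      out_tau_b.row(keep) = tau_b.t();
      out_tau_c.row(keep) = tau_c.t();
      out_yb.row(keep) = yb.t();
      out_yc.row(keep) = yc.t();
      out_sigma(keep) = sigma;
      if (store_z) {
        out_zb.row(keep) = arma::vectorise(zb).t();
        out_zc.row(keep) = arma::vectorise(zc).t();
      }
      ++keep;
    }
  }
  PutRNGstate();

  double denom = std::max(1, n_mh * lkj_steps);
  List out = List::create(
      _["beta"] = out_beta, _["tau_b"] = out_tau_b, _["tau_c"] = out_tau_c,
      _["cpc_b"] = out_yb, _["cpc_c"] = out_yc, _["sigma"] = out_sigma,
      _["accept_b"] = acc_b / denom, _["accept_c"] = acc_c / denom,
      _["step_b"] = step_b, _["step_c"] = step_c);
  if (store_z) {
    out["zb"] = out_zb;
    out["zc"] = out_zc;
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpc_to_chol_cpp(const arma::vec& y, int q) {
  if (q <= 1) return arma::eye(q, q);
  return cpc_to_chol(y, q);
}
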