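#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for joint Poisson disease mapping.
//
// Model: O_ij ~ Poisson(mu_ij), log mu_ij = log e_ij + alpha_j +
// delta_j * phi_i + eps_ij, with flat alpha_j, log delta_j ~
// N(0, 1/ldelta_prec), phi either exchangeable N(0, 1/prec_phi) or
// intrinsic CAR on the area graph, eps_ij exchangeable N(0, 1/prec_eps_j),
// and Gamma(hyper_shape, hyper_rate) hyperpriors on the precisions.
//
// The same engine serves the single-condition comparators: with J = 1,
// delta fixed at 1, phi ICAR and eps exchangeable it is the BYM model;
// dropping phi gives the non-spatial exchangeable model.
//
// Random-walk Metropolis steps are adapted during burn-in only
// (Robbins-Monro on the log step size, target acceptance 0.44).

static inline double rm_gamma(int iter) {
  double g = 1.0 / std::sqrt((double)(iter + 1));
  return g < 0.05 ? g : 0.05;
}

// [[Rcpp::export]]
List scm_chain_cpp(IntegerMatrix O, NumericMatrix E,
                   IntegerVector adj, IntegerVector adj_start,
                   LogicalVector isolated,
                   bool shared_icar, double phi_df,
                   bool include_phi, bool include_eps, bool update_delta,
                   bool gm_one,
                   double ldelta_prec,
                   double hyper_shape, double hyper_rate,
                   double fixed_prec_phi,
                   NumericVector alpha0, NumericVector ldelta0,
                   NumericVector phi0, NumericMatrix eps0,
                   double prec_phi0, NumericVector prec_eps0,
                   int n_iter, int burn_in, int thin) {
  const int N = O.nrow(), J = O.ncol();
  if (n_iter <= burn_in) stop("iterations must exceed burn_in");
  const int n_keep = (n_iter - burn_in) / thin;

  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  std::vector<double> ldelta(ldelta0.begin(), ldelta0.end());
  std::vector<double> delta(J);
  for (int j = 0; j < J; ++j) delta[j] = std::exp(ldelta[j]);
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> eps(N * J);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i) eps[i + N * j] = eps0(i, j);
  double prec_phi = fixed_prec_phi > 0 ? fixed_prec_phi : prec_phi0;
  std::vector<double> prec_eps(prec_eps0.begin(), prec_eps0.end());

  if (!include_phi) std::fill(phi.begin(), phi.end(), 0.0);
  if (!include_eps) std::fill(eps.begin(), eps.end(), 0.0);

  // current cell means
  std::vector<double> mu(N * J);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i)
      mu[i + N * j] = E(i, j) *
        std::exp(alpha[j] + delta[j] * phi[i] + eps[i + N * j]);

  double lgamma_sum = 0.0;
  std::vector<double> Osum(J, 0.0);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i) {
      lgamma_sum += R::lgammafn((double)O(i, j) + 1.0);
      Osum[j] += O(i, j);
    }

  // adaptive log step sizes
  std::vector<double> ls_alpha(J, std::log(0.1));
  std::vector<double> ls_ldelta(J, std::log(0.1));
  std::vector<double> ls_phi(N, std::log(0.1));
  std::vector<double> ls_eps(N * J, std::log(0.1));
  std::vector<double> ls_swapd(J, std::log(0.1));
  std::vector<double> ls_swapp(N, std::log(0.1));

  // post-burn-in acceptance tracking per block type
  double acc_alpha = 0, try_alpha = 0, acc_delta = 0, try_delta = 0;
  double acc_phi = 0, try_phi = 0, acc_eps = 0, try_eps = 0;
  double acc_swapd = 0, try_swapd = 0, acc_swapp = 0, try_swapp = 0;

  NumericMatrix out_alpha(n_keep, J), out_ldelta(n_keep, J);
  NumericMatrix out_phi(n_keep, include_phi ? N : 0);
  NumericMatrix out_eps(n_keep, include_eps ? N * J : 0);
  NumericVector out_prec_phi(n_keep), out_dev(n_keep);
  NumericMatrix out_prec_eps(n_keep, J);

  std::vector<double> fac(N);  // scratch for column updates
  RNGScope scope;
  int keep = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    const bool adapting = iter < burn_in;
    const bool tracking = !adapting;

    // --- alpha_j: random-walk, flat prior --------------------------------
    for (int j = 0; j < J; ++j) {
      double step = std::exp(ls_alpha[j]);
      double d = R::norm_rand() * step;
      double musum = 0.0;
      for (int i = 0; i < N; ++i) musum += mu[i + N * j];
      double dll = d * Osum[j] - (std::exp(d) - 1.0) * musum;
      bool acc = std::log(R::unif_rand()) < dll;
      if (acc) {
        double f = std::exp(d);
        alpha[j] += d;
        for (int i = 0; i < N; ++i) mu[i + N * j] *= f;
      }
      if (adapting)
        ls_alpha[j] += rm_gamma(iter) * ((acc ? 1.0 : 0.0) - 0.44);
      if (tracking) { try_alpha++; if (acc) acc_alpha++; }
    }

    // --- log delta_j ------------------------------------------------------
    if (include_phi && update_delta) {
      for (int j = 0; j < J; ++j) {
        double step = std::exp(ls_ldelta[j]);
        double d = R::norm_rand() * step;
        double ld_new = ldelta[j] + d;
        double ddelta = std::exp(ld_new) - delta[j];
        double dll = 0.0;
        for (int i = 0; i < N; ++i) {
          double f = std::exp(phi[i] * ddelta);
          fac[i] = f;
          dll += O(i, j) * phi[i] * ddelta - mu[i + N * j] * (f - 1.0);
        }
        dll += -0.5 * ldelta_prec * (ld_new * ld_new - ldelta[j] * ldelta[j]);
        bool acc = std::log(R::unif_rand()) < dll;
        if (acc) {
          ldelta[j] = ld_new;
          delta[j] = std::exp(ld_new);
          for (int i = 0; i < N; ++i) mu[i + N * j] *= fac[i];
        }
        if (adapting)
          ls_ldelta[j] += rm_gamma(iter) * ((acc ? 1.0 : 0.0) - 0.44);
        if (tracking) { try_delta++; if (acc) acc_delta++; }
      }
    }

    // --- phi_i ------------------------------------------------------------
    if (include_phi) {
      for (int i = 0; i < N; ++i) {
        double step = std::exp(ls_phi[i]);
        double d = R::norm_rand() * step;
        double dll = 0.0;
        for (int j = 0; j < J; ++j) {
          double f = std::exp(delta[j] * d);
          dll += O(i, j) * delta[j] * d - mu[i + N * j] * (f - 1.0);
        }
        // prior contribution
        if (shared_icar && !isolated[i]) {
          double diff_sum = 0.0;
          int deg = adj_start[i + 1] - adj_start[i];
          for (int a = adj_start[i]; a < adj_start[i + 1]; ++a)
            diff_sum += phi[i] - phi[adj[a]];
          dll += -0.5 * prec_phi * (deg * d * d + 2.0 * d * diff_sum);
        } else {
          dll += -0.5 * prec_phi *
            ((phi[i] + d) * (phi[i] + d) - phi[i] * phi[i]);
        }
        bool acc = std::log(R::unif_rand()) < dll;
        if (acc) {
          phi[i] += d;
          for (int j = 0; j < J; ++j)
            mu[i + N * j] *= std::exp(delta[j] * d);
        }
        if (adapting)
          ls_phi[i] += rm_gamma(iter) * ((acc ? 1.0 : 0.0) - 0.44);
        if (tracking) { try_phi++; if (acc) acc_phi++; }
      }
    }

    // --- eps_ij -----------------------------------------------------------
    if (include_eps) {
      for (int j = 0; j < J; ++j) {
        double pe = prec_eps[j];
        for (int i = 0; i < N; ++i) {
          int c = i + N * j;
          double step = std::exp(ls_eps[c]);
          double d = R::norm_rand() * step;
          double f = std::exp(d);
          double dll = O(i, j) * d - mu[c] * (f - 1.0)
            - 0.5 * pe * ((eps[c] + d) * (eps[c] + d) - eps[c] * eps[c]);
          bool acc = std::log(R::unif_rand()) < dll;
          if (acc) { eps[c] += d; mu[c] *= f; }
          if (adapting)
            ls_eps[c] += rm_gamma(iter) * ((acc ? 1.0 : 0.0) - 0.44);
          if (tracking) { try_eps++; if (acc) acc_eps++; }
        }
      }
    }

    // --- likelihood-invariant swap moves ---------------------------------
    // These keep every eta_ij (hence mu) fixed and move mass between the
    // shared and specific components, which single-site walks mix poorly.
    // (a) loading swap: ldelta_j += d, eps_ij -= (e^d - 1) delta_j phi_i;
    //     unit Jacobian, acceptance ratio = prior ratio only.
    if (include_phi && include_eps && update_delta) {
      for (int j = 0; j < J; ++j) {
        double step = std::exp(ls_swapd[j]);
        double d = R::norm_rand() * step;
        double ld_new = ldelta[j] + d;
        double c = std::exp(ld_new) - delta[j];
        double dlp = -0.5 * ldelta_prec *
          (ld_new * ld_new - ldelta[j] * ldelta[j]);
        double pe = prec_eps[j];
        double dS = 0.0;
        for (int i = 0; i < N; ++i) {
          double e_old = eps[i + N * j];
          double e_new = e_old - c * phi[i];
          dS += e_new * e_new - e_old * e_old;
        }
        dlp += -0.5 * pe * dS;
        bool acc = std::log(R::unif_rand()) < dlp;
        if (acc) {
          for (int i = 0; i < N; ++i) eps[i + N * j] -= c * phi[i];
          ldelta[j] = ld_new;
          delta[j] = std::exp(ld_new);
        }
        if (adapting)
          ls_swapd[j] += rm_gamma(iter) * ((acc ? 1.0 : 0.0) - 0.44);
        if (tracking) { try_swapd++; if (acc) acc_swapd++; }
      }
    }
    // (b) field swap: phi_i += d, eps_ij -= delta_j d; unit Jacobian.
    if (include_phi && include_eps) {
      for (int i = 0; i < N; ++i) {
        double step = std::exp(ls_swapp[i]);
        double d = R::norm_rand() * step;
        double dlp = 0.0;
        if (shared_icar && !isolated[i]) {
          double diff_sum = 0.0;
          int deg = adj_start[i + 1] - adj_start[i];
          for (int a = adj_start[i]; a < adj_start[i + 1]; ++a)
            diff_sum += phi[i] - phi[adj[a]];
          dlp += -0.5 * prec_phi * (deg * d * d + 2.0 * d * diff_sum);
        } else {
          dlp += -0.5 * prec_phi *
            ((phi[i] + d) * (phi[i] + d) - phi[i] * phi[i]);
        }
        for (int j = 0; j < J; ++j) {
          double e_old = eps[i + N * j];
          double e_new = e_old - delta[j] * d;
          dlp += -0.5 * prec_eps[j] * (e_new * e_new - e_old * e_old);
        }
        bool acc = std::log(R::unif_rand()) < dlp;
        if (acc) {
          phi[i] += d;
          for (int j = 0; j < J; ++j) eps[i + N * j] -= delta[j] * d;
        }
        if (adapting)
          ls_swapp[i] += rm_gamma(iter) * ((acc ? 1.0 : 0.0) - 0.44);
        if (tracking) { try_swapp++; if (acc) acc_swapp++; }
      }
    }

    // --- Gibbs for precisions --------------------------------------------
    if (include_phi && fixed_prec_phi <= 0) {
      double S = 0.0;
      if (shared_icar) {
        for (int i = 0; i < N; ++i) {
          if (isolated[i]) { S += phi[i] * phi[i]; continue; }
          for (int a = adj_start[i]; a < adj_start[i + 1]; ++a) {
            int k = adj[a];
            if (k > i) { double dd = phi[i] - phi[k]; S += dd * dd; }
          }
        }
      } else {
        for (int i = 0; i < N; ++i) S += phi[i] * phi[i];
      }
      prec_phi = R::rgamma(hyper_shape + 0.5 * phi_df,
                           1.0 / (hyper_rate + 0.5 * S));
    }
    if (include_eps) {
      for (int j = 0; j < J; ++j) {
        double S = 0.0;
        for (int i = 0; i < N; ++i) S += eps[i + N * j] * eps[i + N * j];
        prec_eps[j] = R::rgamma(hyper_shape + 0.5 * N,
                                1.0 / (hyper_rate + 0.5 * S));
      }
    }

    // --- identifiability transforms (leave mu invariant) -----------------
    if (include_phi) {
      double m = 0.0;
      for (int i = 0; i < N; ++i) m += phi[i];
      m /= N;
      for (int i = 0; i < N; ++i) phi[i] -= m;
      for (int j = 0; j < J; ++j) alpha[j] += delta[j] * m;
    }
    if (include_eps) {
      for (int j = 0; j < J; ++j) {
        double m = 0.0;
        for (int i = 0; i < N; ++i) m += eps[i + N * j];
        m /= N;
        for (int i = 0; i < N; ++i) eps[i + N * j] -= m;
        alpha[j] += m;
      }
    }
    if (include_phi && update_delta && gm_one && J > 1) {
      double lm = 0.0;
      for (int j = 0; j < J; ++j) lm += ldelta[j];
      lm /= J;
      double g = std::exp(lm);
      for (int j = 0; j < J; ++j) {
        ldelta[j] -= lm;
        delta[j] = std::exp(ldelta[j]);
      }
      for (int i = 0; i < N; ++i) phi[i] *= g;
    }

    // --- retain -----------------------------------------------------------
    if (iter >= burn_in && (iter - burn_in) % thin == 0 && keep < n_keep) {
      double dev = 0.0;
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < N; ++i) {
          int c = i + N * j;
          dev += O(i, j) * std::log(mu[c]) - mu[c];
        }
      dev = -2.0 * (dev - lgamma_sum);
      if (!std::isfinite(dev))
        stop("non-finite log-posterior at iteration %d", iter + 1);
      for (int j = 0; j < J; ++j) {
        out_alpha(keep, j) = alpha[j];
        out_ldelta(keep, j) = ldelta[j];
        out_prec_eps(keep, j) = prec_eps[j];
      }
      if (include_phi)
        for (int i = 0; i < N; ++i) out_phi(keep, i) = phi[i];
      if (include_eps)
        for (int c = 0; c < N * J; ++c) out_eps(keep, c) = eps[c];
      out_prec_phi[keep] = prec_phi;
      out_dev[keep] = dev;
      ++keep;
    }
  }

  return List::create(
    _["alpha"] = out_alpha, _["log_delta"] = out_ldelta,
    _["phi"] = out_phi, _["eps"] = out_eps,
    _["prec_phi"] = out_prec_phi, _["prec_eps"] = out_prec_eps,
    _["deviance"] = out_dev,
    _["accept"] = List::create(
      _["alpha"] = try_alpha > 0 ? acc_alpha / try_alpha : NA_REAL,
      _["delta"] = try_delta > 0 ? acc_delta / try_delta : NA_REAL,
      _["phi"] = try_phi > 0 ? acc_phi / try_phi : NA_REAL,
      _["eps"] = try_eps > 0 ? acc_eps / try_eps : NA_REAL,
      _["swap_delta"] = try_swapd > 0 ? acc_swapd / try_swapd : NA_REAL,
      _["swap_phi"] = try_swapp > 0 ? acc_swapp / try_swapp : NA_REAL));
}
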