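#' Shared Component Model specification
#'
#' Prior and identifiability choices for the joint model
#' \deqn{O_{ij} \sim Poisson(\mu_{ij}), \quad
#'   \log \mu_{ij} = \log e_{ij} + \alpha_j + \delta_j \varphi_i +
#'   \epsilon_{ij}}
#' with flat intercepts \eqn{\alpha_j}, factor loadings with
#' \eqn{\log\delta_j \sim N(0, 1/\lambda)} (\eqn{\lambda} =
#' `logdelta_prior_precision`, the WinBUGS precision convention), a shared
#' spatial field \eqn{\varphi} that is either exchangeable or intrinsic
#' CAR, exchangeable condition-specific effects \eqn{\epsilon_{ij}}, and
#' Gamma hyperpriors on all precisions.
#'
#' @param shared_prior `"exchangeable"` or `"icar"` for the shared field.
#' @param logdelta_prior_precision prior precision of `log(delta_j)`,
#'   default 5.9. Set `logdelta_prior_is_variance = TRUE` to read the same
#'   number as a variance instead (sensitivity analysis).
#' @param logdelta_prior_is_variance see above; default `FALSE`.
#' @param variance_hyperprior length-2 vector `(shape, rate)` of the Gamma
#'   hyperprior on each precision, default `c(0.5, 0.0005)`.
#' @param delta_identifiability `"geometric-mean-one"` (default; delta and
#'   the shared field are rescaled each sweep so the loadings have unit
#'   geometric mean) or `"none"` (identification left to the log-delta
#'   prior).
#' @return an object of class `scm_spec`.
#' @export
scm_spec <- function(shared_prior = c("exchangeable", "icar"),
                     logdelta_prior_precision = 5.9,
                     logdelta_prior_is_variance = FALSE,
                     variance_hyperprior = c(0.5, 0.0005),
                     delta_identifiability = c("geometric-mean-one",
                                               "none")) {
  shared_prior <- match.arg(shared_prior)
  delta_identifiability <- match.arg(delta_identifiability)
  if (logdelta_prior_precision <= 0) stop("prior precision must be > 0")
  if (length(variance_hyperprior) != 2 || any(variance_hyperprior <= 0)) {
    stop("variance_hyperprior must be positive (shape, rate)")
  }
  prec <- if (logdelta_prior_is_variance) {
    1 / logdelta_prior_precision
  } else {
    logdelta_prior_precision
  }
  structure(list(shared_prior = shared_prior,
                 logdelta_precision = prec,
                 variance_hyperprior = as.numeric(variance_hyperprior),
                 delta_identifiability = delta_identifiability),
            class = "scm_spec")
}

# flatten adjacency into 0-based CSR arrays for the C++ sampler
graph_csr <- function(graph) {
  idx <- seq_along(graph$area_ids)
  names(idx) <- graph$area_ids
  nb_idx <- lapply(graph$neighbors, function(v) unname(idx[v]) - 1L)
  deg <- vapply(nb_idx, length, 1L)
  list(adj = as.integer(unlist(nb_idx, use.names = FALSE)),
       adj_start = as.integer(c(0L, cumsum(deg))),
       isolated = deg == 0L)
}

# degrees of freedom of the shared-field Gaussian (for the precision Gibbs
# step): exchangeable fields count every area; an intrinsic CAR field loses
# one flat direction per connected component, while isolated areas fall
# back to an exchangeable conditional and count fully.
phi_degrees_of_freedom <- function(graph, shared_prior) {
  n <- length(graph$area_ids)
  if (shared_prior == "exchangeable") return(n)
  deg <- vapply(graph$neighbors, length, 1L)
  n_iso <- sum(deg == 0L)
  comp <- graph_components(graph)
  n_comp_noniso <- length(unique(comp[deg > 0L]))
  (n - n_iso - n_comp_noniso) + n_iso
}

chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) * 1000003 + chain * 7919) %% 2147483629)
}

run_chains <- function(data, spec, n_chains, iterations, burn_in, thin,
                       seed, include_phi, include_eps, update_delta,
                       fixed_prec_phi = -1) {
  O <- data$observed
  E <- data$expected
  N <- nrow(O); J <- ncol(O)
  if (any(colSums(O) < 1)) {
    stop("every condition needs at least one admission for the flat ",
         "intercept posterior to be proper; offending: ",
         paste(colnames(O)[colSums(O) < 1], collapse = ", "))
  }
  if (any(E <= 0)) stop("expected counts must be positive")
  icar <- spec$shared_prior == "icar"
  if (icar && any(vapply(data$graph$neighbors, length, 1L) == 0L)) {
    warning("isolated areas present: their shared-field conditional is ",
            "exchangeable with the shared precision")
  }
  csr <- graph_csr(data$graph)
  dfphi <- phi_degrees_of_freedom(data$graph, spec$shared_prior)
  hyper <- spec$variance_hyperprior
  gm1 <- spec$delta_identifiability == "geometric-mean-one"
  alpha_base <- log(pmax(colSums(O), 0.5) / colSums(E))

  chains <- vector("list", n_chains)
  seeds <- integer(n_chains)
  for (ch in seq_len(n_chains)) {
    seeds[ch] <- chain_seed(seed, ch)
    set.seed(seeds[ch])
    alpha0 <- alpha_base + stats::rnorm(J, 0, 0.05 * ch)
    phi0 <- if (include_phi) stats::rnorm(N, 0, 0.1) else numeric(N)
    eps0 <- if (include_eps) {
      matrix(stats::rnorm(N * J, 0, 0.1), N, J)
    } else {
      matrix(0, N, J)
    }
    res <- scm_chain_cpp(O, E, csr$adj, csr$adj_start, csr$isolated,
                         icar, dfphi,
                         include_phi, include_eps, update_delta, gm1,
                         spec$logdelta_precision, hyper[1], hyper[2],
                         fixed_prec_phi,
                         alpha0, rep(0, J), phi0, eps0,
                         10, rep(10, J),
                         as.integer(iterations), as.integer(burn_in),
                         as.integer(thin))
    colnames(res$alpha) <- colnames(res$log_delta) <-
      colnames(res$prec_eps) <- data$conditions
    if (include_phi) colnames(res$phi) <- data$graph$area_ids
    if (include_eps) {
      colnames(res$eps) <- paste(rep(data$graph$area_ids, J),
                                 rep(data$conditions, each = N),
                                 sep = ":")
    }
    chains[[ch]] <- res
  }
  list(chains = chains, seeds = seeds)
}

#' Fit the Shared Component Model by MCMC
#'
#' Metropolis-within-Gibbs sampling of the joint model described in
#' [scm_spec()]: conjugate Gamma updates for the precisions, adaptive
#' random-walk Metropolis (adaptation during burn-in only) for the
#' intercepts, log loadings, shared field and specific effects. After
#' every sweep the shared field and each column of specific effects are
#' centered (the shift absorbed into the intercepts) and, under the
#' default identifiability rule, the loadings are rescaled to unit
#' geometric mean with the inverse scale applied to the shared field.
#' Runs are exactly reproducible for a given `seed`: each chain uses a
#' seed derived from the master seed.
#'
#' @param data an `area_condition_data` from [assemble()] or
#'   [generate_pph_data()].
#' @param spec an [scm_spec()].
#' @param n_chains number of chains, default 3.
#' @param iterations,burn_in,thin MCMC schedule; the defaults (49,500
#'   iterations, 12,000 burn-in, keep every 75th) retain 500 draws per
#'   chain.
#' @param seed master integer seed.
#' @return an object of class `pph_draws`: `chains` (per chain, matrices
#'   of retained draws for `alpha`, `log_delta`, `phi`, `eps`, `prec_phi`,
#'   `prec_eps`, the per-draw `deviance`, and post-burn-in Metropolis
#'   acceptance rates) and `meta` (model tag, schedule, seeds, area and
#'   condition names).
#' @export
fit_scm <- function(data, spec = scm_spec(), n_chains = 3,
                    iterations = 49500, burn_in = 12000, thin = 75,
                    seed = 1) {
  stopifnot(inherits(data, "area_condition_data"),
            inherits(spec, "scm_spec"))
  run <- run_chains(data, spec, n_chains, iterations, burn_in, thin, seed,
                    include_phi = TRUE, include_eps = TRUE,
                    update_delta = TRUE)
  new_pph_draws(run,
                model = paste0("scm-",
                               if (spec$shared_prior == "icar") "car"
                               else "exch"),
                data = data, spec = spec, n_chains = n_chains,
                iterations = iterations, burn_in = burn_in, thin = thin,
                seed = seed)
}

#' Fit single-condition comparator models
#'
#' `fit_bym()` fits the Besag-York-Mollie model to one condition:
#' \eqn{\log \mu_i = \log e_i + \alpha + u_i + v_i} with an intrinsic CAR
#' structured effect \eqn{u} and an exchangeable unstructured effect
#' \eqn{v}. `fit_indep()` drops the structured effect, giving the
#' non-spatial exchangeable model used as the independent-modelling
#' baseline. Both share [fit_scm()]'s engineering contracts (adaptation,
#' centering, determinism under `seed`).
#'
#' In the returned draws the structured effect is stored under `phi` and
#' the unstructured effect under `eps`, mirroring the shared-model layout.
#'
#' @param data an `area_condition_data`; if it has several conditions,
#'   `condition` selects one.
#' @param condition condition name (defaults to the only condition).
#' @param spec an [scm_spec()]; only the hyperprior field is used
#'   (`shared_prior` is forced to `"icar"` for the structured effect).
#' @inheritParams fit_scm
#' @return a `pph_draws` object (see [fit_scm()]).
#' @export
fit_bym <- function(data, condition = NULL, spec = scm_spec(),
                    n_chains = 3, iterations = 49500, burn_in = 12000,
                    thin = 75, seed = 1) {
  data1 <- if (is.null(condition)) {
    if (length(data$conditions) != 1) {
      stop("data has several conditions; pass `condition`")
    }
    data
  } else {
    slice_condition(data, condition)
  }
  spec1 <- spec
  spec1$shared_prior <- "icar"
  run <- run_chains(data1, spec1, n_chains, iterations, burn_in, thin,
                    seed, include_phi = TRUE, include_eps = TRUE,
                    update_delta = FALSE)
  new_pph_draws(run, model = "bym", data = data1, spec = spec1,
                n_chains = n_chains, iterations = iterations,
                burn_in = burn_in, thin = thin, seed = seed)
}

#' @rdname fit_bym
#' @export
fit_indep <- function(data, condition = NULL, spec = scm_spec(),
                      n_chains = 3, iterations = 49500, burn_in = 12000,
                      thin = 75, seed = 1) {
  data1 <- if (is.null(condition)) {
    if (length(data$conditions) != 1) {
      stop("data has several conditions; pass `condition`")
    }
    data
  } else {
    slice_condition(data, condition)
  }
  spec1 <- spec
  spec1$shared_prior <- "exchangeable"
  run <- run_chains(data1, spec1, n_chains, iterations, burn_in, thin,
                    seed, include_phi = FALSE, include_eps = TRUE,
                    update_delta = FALSE)
  new_pph_draws(run, model = "indep", data = data1, spec = spec1,
                n_chains = n_chains, iterations = iterations,
                burn_in = burn_in, thin = thin, seed = seed)
}

#' Fit a shared-field-only model
#'
#' Reduced model \eqn{\log \mu_{ij} = \log e_{ij} + \alpha_j + \varphi_i}
#' (loadings fixed at 1, no condition-specific effects), mainly useful for
#' sampler validation: with `fixed_sigma` the shared-field standard
#' deviation is held constant so the posterior is low-dimensional and can
#' be checked against numerical integration.
#'
#' @inheritParams fit_scm
#' @param fixed_sigma if non-`NULL`, the shared field's standard deviation
#'   is fixed at this value instead of being sampled.
#' @return a `pph_draws` object.
#' @export
fit_shared_only <- function(data, spec = scm_spec(), n_chains = 3,
                            iterations = 49500, burn_in = 12000,
                            thin = 75, seed = 1, fixed_sigma = NULL) {
  fixed_prec <- if (is.null(fixed_sigma)) -1 else 1 / fixed_sigma^2
  run <- run_chains(data, spec, n_chains, iterations, burn_in, thin,
                    seed, include_phi = TRUE, include_eps = FALSE,
                    update_delta = FALSE, fixed_prec_phi = fixed_prec)
  new_pph_draws(run, model = "shared-only", data = data, spec = spec,
                n_chains = n_chains, iterations = iterations,
                burn_in = burn_in, thin = thin, seed = seed)
}

#' Fit any of the supported models by tag
#'
#' @param data an `area_condition_data`.
#' @param model `"scm-exch"`, `"scm-car"`, `"bym"` or `"indep"` (the two
#'   single-condition models require `condition` on multi-condition data).
#' @param condition condition name for single-condition models.
#' @param ... passed to the underlying fit function.
#' @return a `pph_draws` object.
#' @export
fit_model <- function(data, model = c("scm-exch", "scm-car", "bym",
                                      "indep"),
                      condition = NULL, ...) {
  model <- match.arg(model)
  switch(model,
         "scm-exch" = fit_scm(data, spec = scm_spec("exchangeable"), ...),
         "scm-car" = fit_scm(data, spec = scm_spec("icar"), ...),
         "bym" = fit_bym(data, condition = condition, ...),
         "indep" = fit_indep(data, condition = condition, ...))
}

new_pph_draws <- function(run, model, data, spec, n_chains, iterations,
                          burn_in, thin, seed) {
  structure(list(
    chains = run$chains,
    meta = list(model = model,
                shared_prior = spec$shared_prior,
                n_chains = n_chains,
                iterations = iterations, burn_in = burn_in, thin = thin,
                n_retained = (iterations - burn_in) %/% thin,
                seed = seed, chain_seeds = run$seeds,
                area_ids = data$graph$area_ids,
                conditions = data$conditions)),
    class = "pph_draws")
}

#' @export
print.pph_draws <- function(x, ...) {
  m <- x$meta
  cat("pph_draws [", m$model, "]: ", m$n_chains, " chains x ",
      m$n_retained, " retained draws (", m$iterations, " iterations, ",
      m$burn_in, " burn-in, thin ", m$thin, ")\n", sep = "")
  cat("  ", length(m$area_ids), " areas, conditions: ",
      paste(m$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Poisson log-likelihood of the joint model
#'
#' \eqn{\sum_{ij} [O_{ij} \log \mu_{ij} - \mu_{ij} - \log O_{ij}!]} with
#' \eqn{\mu_{ij} = e_{ij} \exp(\alpha_j + \delta_j \varphi_i +
#' \epsilon_{ij})}.
#'
#' @param data an `area_condition_data`.
#' @param params list with `alpha` (length J), `log_delta` (length J),
#'   `phi` (length N), `eps` (N x J matrix); missing components default
#'   to zero.
#' @return the log-likelihood (a scalar).
#' @export
poisson_log_lik <- function(data, params) {
  O <- data$observed
  E <- data$expected
  N <- nrow(O); J <- ncol(O)
  alpha <- if (is.null(params$alpha)) rep(0, J) else params$alpha
  ldelta <- if (is.null(params$log_delta)) rep(0, J) else params$log_delta
  phi <- if (is.null(params$phi)) rep(0, N) else params$phi
  eps <- if (is.null(params$eps)) matrix(0, N, J) else params$eps
  eta <- outer(phi, exp(ldelta)) +
    matrix(alpha, N, J, byrow = TRUE) + eps
  mu <- E * exp(eta)
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    bad <- which(!is.finite(mu) | mu <= 0, arr.ind = TRUE)[1, ]
    stop("non-finite or non-positive mean at area ", rownames(O)[bad[1]],
         ", condition ", colnames(O)[bad[2]])
  }
  sum(O * log(mu) - mu - lgamma(O + 1))
}

#' Intrinsic CAR quadratic form
#'
#' \eqn{\sum_{(i,k) \in E} (\varphi_i - \varphi_k)^2} over the undirected
#' edges of the area graph (each edge once). The intrinsic CAR log-density
#' is `-(prec/2)` times this, up to a constant.
#'
#' @param phi numeric vector, one value per area.
#' @param graph an [area_graph()].
#' @return the non-negative quadratic form.
#' @export
icar_quadratic <- function(phi, graph) {
  if (length(phi) != length(graph$area_ids)) {
    stop("phi length does not match number of areas")
  }
  em <- edge_matrix(graph)
  if (nrow(em) == 0) return(0)
  sum((phi[em[, 1]] - phi[em[, 2]])^2)
}
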