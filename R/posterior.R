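# pooled draw matrix for one named component across chains
pool_component <- function(draws, what) {
  do.call(rbind, lapply(draws$chains, `[[`, what))
}

#' Extract one scalar parameter as a draws-by-chains matrix
#'
#' Parameter names follow the draw layout: `"alpha[j]"`, `"log_delta[j]"`,
#' `"phi[i]"`, `"eps[i,j]"` (1-based indices), `"prec_phi"`,
#' `"prec_eps[j]"`, `"deviance"`, or the derived scales `"sigma_phi"` /
#' `"sigma_eps[j]"`.
#'
#' @param draws a `pph_draws` object.
#' @param parameter parameter name as above.
#' @return numeric matrix, retained draws x chains.
#' @export
extract_parameter <- function(draws, parameter) {
  m <- regmatches(parameter,
                  regexec("^([a-z_]+)(\\[([0-9]+)(,([0-9]+))?\\])?$",
                          parameter))[[1]]
  if (length(m) == 0) stop("unparseable parameter name: ", parameter)
  base <- m[2]
  i <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  j <- if (nzchar(m[6])) as.integer(m[6]) else NA_integer_
  N <- length(draws$meta$area_ids)
  get_col <- function(what, col) {
    vapply(draws$chains, function(ch) {
      x <- ch[[what]]
      if (is.matrix(x)) x[, col] else x
    }, numeric(draws$meta$n_retained))
  }
  switch(base,
         alpha = get_col("alpha", i),
         log_delta = get_col("log_delta", i),
         phi = get_col("phi", i),
         eps = get_col("eps", i + N * (j - 1L)),
         prec_phi = get_col("prec_phi", 1L),
         prec_eps = get_col("prec_eps", i),
         deviance = get_col("deviance", 1L),
         sigma_phi = 1 / sqrt(get_col("prec_phi", 1L)),
         sigma_eps = 1 / sqrt(get_col("prec_eps", i)),
         stop("unknown parameter: ", parameter))
}

#' Deviance information criterion
#'
#' \eqn{D(\theta) = -2 \log L(\theta)}; `dbar` is the posterior mean
#' deviance over retained draws, `d_at_mean` the deviance at the posterior
#' mean of every parameter on its sampled (log) scale, `pd = dbar -
#' d_at_mean` the effective number of parameters, and `dic = dbar + pd`.
#' `pd` can come out negative for strongly non-normal posteriors; it is
#' flagged but reported as computed, and the identity `dic = dbar + pd`
#' always holds.
#'
#' @param draws a `pph_draws` object.
#' @param data the `area_condition_data` the model was fitted to.
#' @return object of class `pph_model_fit`: list with `dbar`, `d_at_mean`,
#'   `pd`, `dic`, `model`, `pd_negative`.
#' @export
dic <- function(draws, data) {
  stopifnot(inherits(draws, "pph_draws"))
  dev <- pool_component(draws, "deviance")
  if (length(dev) < 2) stop("need at least 2 retained draws")
  dbar <- mean(dev)
  N <- length(draws$meta$area_ids)
  J <- length(draws$meta$conditions)
  mean_mat <- function(what) {
    x <- pool_component(draws, what)
    if (is.null(x) || ncol(x) == 0) return(NULL)
    colMeans(x)
  }
  alpha_m <- mean_mat("alpha")
  ldelta_m <- mean_mat("log_delta")
  phi_m <- mean_mat("phi")
  eps_m <- mean_mat("eps")
  params <- list(alpha = alpha_m, log_delta = ldelta_m, phi = phi_m,
                 eps = if (!is.null(eps_m)) matrix(eps_m, N, J))
  d_at_mean <- -2 * poisson_log_lik(data, params)
  pd <- dbar - d_at_mean
  if (pd < 0) warning("negative pD (", format(pd), "): plug-in deviance ",
                      "exceeds the posterior mean deviance")
  structure(list(dbar = dbar, d_at_mean = d_at_mean, pd = pd,
                 dic = dbar + pd, model = draws$meta$model,
                 pd_negative = pd < 0),
            class = "pph_model_fit")
}

#' @export
print.pph_model_fit <- function(x, ...) {
  cat(sprintf("%s: DIC = %.1f (pD = %.1f, Dbar = %.1f)\n",
              x$model, x$dic, x$pd, x$dbar))
  invisible(x)
}

#' Posterior decomposition into shared and specific spatial variance
#'
#' For each retained draw \eqn{t} and condition \eqn{j} the fraction of
#' log-relative-risk variance across areas carried by the shared
#' component,
#' \deqn{f_j^{(t)} = \frac{Var_i(\delta_j^{(t)} \varphi_i^{(t)})}
#'   {Var_i(\delta_j^{(t)} \varphi_i^{(t)}) + Var_i(\epsilon_{ij}^{(t)})}}
#' with empirical variances over areas, is computed and then summarized
#' over the posterior. Draws with zero total variance contribute a
#' fraction of 0 (with a warning counted). Scale summaries
#' (`sigma_shared`, per-condition `sigma_specific`, loadings) use
#' posterior medians and central 95% credible intervals.
#'
#' @param draws a `pph_draws` object from [fit_scm()].
#' @return object of class `pph_decomposition`: data frame `conditions`
#'   with per-condition sigma_specific / delta / pct_shared summaries, and
#'   a `sigma_shared` summary vector.
#' @export
variance_explained <- function(draws) {
  stopifnot(inherits(draws, "pph_draws"))
  if (!startsWith(draws$meta$model, "scm")) {
    stop("variance decomposition is defined for shared-component fits")
  }
  N <- length(draws$meta$area_ids)
  J <- length(draws$meta$conditions)
  phi <- pool_component(draws, "phi")
  eps <- pool_component(draws, "eps")
  ldelta <- pool_component(draws, "log_delta")
  ndraw <- nrow(phi)
  var_phi <- apply(phi, 1, stats::var)
  frac <- matrix(NA_real_, ndraw, J)
  zero_draws <- 0L
  for (j in seq_len(J)) {
    var_eps_j <- apply(eps[, (j - 1) * N + seq_len(N), drop = FALSE], 1,
                       stats::var)
    shared_j <- exp(2 * ldelta[, j]) * var_phi
    tot <- shared_j + var_eps_j
    zero <- tot == 0
    zero_draws <- zero_draws + sum(zero)
    frac[, j] <- ifelse(zero, 0, shared_j / tot)
  }
  if (zero_draws > 0) {
    warning(zero_draws, " draw/condition cells had zero total variance; ",
            "their shared fraction is 0")
  }
  qs <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  sig_eps <- 1 / sqrt(pool_component(draws, "prec_eps"))
  delta <- exp(ldelta)
  conditions <- data.frame(
    condition = draws$meta$conditions,
    sigma_specific = apply(sig_eps, 2, stats::median),
    sigma_specific_lo = apply(sig_eps, 2, stats::quantile, 0.025),
    sigma_specific_hi = apply(sig_eps, 2, stats::quantile, 0.975),
    delta = apply(delta, 2, stats::median),
    delta_lo = apply(delta, 2, stats::quantile, 0.025),
    delta_hi = apply(delta, 2, stats::quantile, 0.975),
    pct_shared = 100 * colMeans(frac),
    pct_shared_lo = 100 * apply(frac, 2, stats::quantile, 0.025),
    pct_shared_hi = 100 * apply(frac, 2, stats::quantile, 0.975),
    row.names = NULL)
  sig_phi <- 1 / sqrt(pool_component(draws, "prec_phi"))
  structure(list(conditions = conditions,
                 sigma_shared = qs(sig_phi)),
            class = "pph_decomposition")
}

#' @export
print.pph_decomposition <- function(x, ...) {
  cat(sprintf("sigma_shared = %.3f (%.3f - %.3f)\n",
              x$sigma_shared[1], x$sigma_shared[2], x$sigma_shared[3]))
  df <- x$conditions
  cat(sprintf("%-12s %-22s %-20s %s\n", "condition", "sigma_specific",
              "delta", "% shared"))
  for (k in seq_len(nrow(df))) {
    cat(sprintf("%-12s %.3f (%.3f - %.3f)  %.2f (%.2f - %.2f)  %.1f (%.1f - %.1f)\n",
                df$condition[k], df$sigma_specific[k],
                df$sigma_specific_lo[k], df$sigma_specific_hi[k],
                df$delta[k], df$delta_lo[k], df$delta_hi[k],
                df$pct_shared[k], df$pct_shared_lo[k],
                df$pct_shared_hi[k]))
  }
  invisible(x)
}

#' Exceedance-probability map surface
#'
#' Per area (and, for condition-level terms, per condition), the fraction
#' of retained draws in which a relative-risk term exceeds `threshold`,
#' with the mapping categories: `high` when the probability is above 0.8,
#' `low` below 0.2, otherwise `indeterminate`.
#'
#' Terms: `"shared"` is the shared-pattern relative risk
#' \eqn{\exp(\varphi_i)}; `"condition_rr"` is each condition's area
#' relative risk about its regional level,
#' \eqn{\exp(\delta_j \varphi_i + \epsilon_{ij})}; `"specific"` is the
#' discrepant component \eqn{\exp(\epsilon_{ij})}.
#'
#' @param draws a `pph_draws` object.
#' @param term one of `"shared"`, `"condition_rr"`, `"specific"`.
#' @param threshold exceedance threshold on the risk scale, default 1.
#' @param high,low category cutpoints on the probability, defaults 0.8
#'   and 0.2.
#' @return data frame with columns `area_id`, (`condition`,) `prob`,
#'   `category`.
#' @export
exceedance <- function(draws, term = c("shared", "condition_rr",
                                       "specific"),
                       threshold = 1, high = 0.8, low = 0.2) {
  stopifnot(inherits(draws, "pph_draws"))
  term <- match.arg(term)
  N <- length(draws$meta$area_ids)
  J <- length(draws$meta$conditions)
  categorize <- function(p) {
    ifelse(p > high, "high", ifelse(p < low, "low", "indeterminate"))
  }
  lt <- log(threshold)
  if (term == "shared") {
    phi <- pool_component(draws, "phi")
    if (is.null(phi) || ncol(phi) == 0) {
      stop("model '", draws$meta$model, "' has no shared/structured field")
    }
    p <- colMeans(phi > lt)
    return(data.frame(area_id = draws$meta$area_ids, prob = p,
                      category = categorize(p), row.names = NULL))
  }
  eps <- pool_component(draws, "eps")
  if (is.null(eps) || ncol(eps) == 0) {
    stop("model '", draws$meta$model, "' has no specific effects")
  }
  out <- vector("list", J)
  for (j in seq_len(J)) {
    eps_j <- eps[, (j - 1) * N + seq_len(N), drop = FALSE]
    val <- if (term == "specific") {
      eps_j
    } else {
      phi <- pool_component(draws, "phi")
      if (is.null(phi) || ncol(phi) == 0) phi <- matrix(0, nrow(eps_j), N)
      phi * exp(pool_component(draws, "log_delta")[, j]) + eps_j
    }
    p <- colMeans(val > lt)
    out[[j]] <- data.frame(area_id = draws$meta$area_ids,
                           condition = draws$meta$conditions[j],
                           prob = p, category = categorize(p),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Potential scale reduction factor (split chains)
#'
#' Plain Gelman-Rubin \eqn{\hat R} on split chains: each chain is halved,
#' the between- and within-half variances combined as
#' \eqn{\hat R = \sqrt{(\frac{n-1}{n} W + \frac{1}{n} B) / W}}. A
#' parameter that is constant across all chains returns 1 with a
#' `zero_variance` attribute.
#'
#' @param draws a `pph_draws` object with at least 2 chains and 4 retained
#'   draws per chain.
#' @param parameter parameter name, see [extract_parameter()].
#' @return \eqn{\hat R} (scalar); attribute `zero_variance` when
#'   degenerate.
#' @export
rhat <- function(draws, parameter) {
  x <- extract_parameter(draws, parameter)
  rhat_matrix(x)
}

# split-chain PSRF on a draws x chains matrix
rhat_matrix <- function(x) {
  if (ncol(x) < 2) stop("need at least 2 chains")
  if (nrow(x) < 4) stop("need at least 4 retained draws per chain")
  n2 <- nrow(x) %/% 2
  halves <- cbind(x[seq_len(n2), , drop = FALSE],
                  x[n2 + seq_len(n2), , drop = FALSE])
  if (stats::var(as.vector(halves)) == 0) {
    return(structure(1, zero_variance = TRUE))
  }
  m <- ncol(halves); n <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(structure(Inf, zero_variance = FALSE))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence summary across key parameters
#'
#' \eqn{\hat R} for every intercept, loading, precision and the deviance.
#'
#' @param draws a `pph_draws` object.
#' @return data frame with `parameter`, `rhat`.
#' @export
rhat_table <- function(draws) {
  J <- length(draws$meta$conditions)
  pars <- c(paste0("alpha[", seq_len(J), "]"),
            if (startsWith(draws$meta$model, "scm"))
              paste0("log_delta[", seq_len(J), "]"),
            if (ncol(draws$chains[[1]]$phi) > 0) "prec_phi",
            if (ncol(draws$chains[[1]]$eps) > 0)
              paste0("prec_eps[", seq_len(J), "]"),
            "deviance")
  data.frame(parameter = pars,
             rhat = vapply(pars, function(p) as.numeric(rhat(draws, p)),
                           0),
             row.names = NULL)
}

#' Sample autocorrelation of a parameter's chain
#'
#' Per-chain sample autocorrelations at lags `0..max_lag`, averaged over
#' chains; lag 0 is 1 by definition.
#'
#' @param draws a `pph_draws` object.
#' @param parameter parameter name, see [extract_parameter()].
#' @param max_lag largest lag, default 50 (draw count must exceed it by 2).
#' @return numeric vector of length `max_lag + 1`.
#' @export
autocorrelation <- function(draws, parameter, max_lag = 50) {
  x <- extract_parameter(draws, parameter)
  if (nrow(x) < max_lag + 2) stop("need at least max_lag + 2 draws")
  if (any(apply(x, 2, stats::sd) == 0)) stop("zero-variance parameter")
  ac <- vapply(seq_len(ncol(x)), function(ch) {
    as.numeric(stats::acf(x[, ch], lag.max = max_lag,
                          plot = FALSE, demean = TRUE)$acf)
  }, numeric(max_lag + 1))
  rowMeans(ac)
}

#' Post-burn-in Metropolis acceptance rates
#'
#' @param draws a `pph_draws` object.
#' @return data frame with one row per chain and one column per adapted
#'   block type (`alpha`, `delta`, `phi`, `eps`; `NA` when the block is
#'   absent from the model).
#' @export
acceptance_rates <- function(draws) {
  do.call(rbind, lapply(seq_along(draws$chains), function(ch) {
    a <- draws$chains[[ch]]$accept
    data.frame(chain = ch, alpha = a$alpha, delta = a$delta,
               phi = a$phi, eps = a$eps,
               swap_delta = if (is.null(a$swap_delta)) NA else a$swap_delta,
               swap_phi = if (is.null(a$swap_phi)) NA else a$swap_phi,
               row.names = NULL)
  }))
}
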