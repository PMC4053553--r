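# hand-built pph_draws with full control over every component
manual_draws <- function(chains, area_ids, conditions, model = "scm-exch") {
  n <- nrow(chains[[1]]$alpha)
  structure(list(chains = chains,
                 meta = list(model = model, n_chains = length(chains),
                             n_retained = n, iterations = NA,
                             burn_in = NA, thin = NA, seed = NA,
                             area_ids = area_ids,
                             conditions = conditions)),
            class = "pph_draws")
}

chain_of <- function(alpha, log_delta = NULL, phi = NULL, eps = NULL,
                     prec_phi = NULL, prec_eps = NULL, deviance = NULL) {
  n <- nrow(alpha)
  J <- ncol(alpha)
  list(alpha = alpha,
       log_delta = if (is.null(log_delta)) matrix(0, n, J) else log_delta,
       phi = if (is.null(phi)) matrix(0, n, 0) else phi,
       eps = if (is.null(eps)) matrix(0, n, 0) else eps,
       prec_phi = if (is.null(prec_phi)) rep(1, n) else prec_phi,
       prec_eps = if (is.null(prec_eps)) matrix(1, n, J) else prec_eps,
       deviance = if (is.null(deviance)) rep(0, n) else deviance,
       accept = list(alpha = NA, delta = NA, phi = NA, eps = NA))
}

test_that("DIC follows its definition and identity", {
  # single cell O = 3, e = 1, two draws of alpha: the definition gives
  # dbar = mean of per-draw deviances, d_at_mean = deviance at the mean
  # alpha, pd = dbar - d_at_mean, dic = dbar + pd
  g1 <- suppressWarnings(area_graph("a", list(a = character(0))))
  acd <- manual_acd(matrix(3L), matrix(1), graph = g1)
  dev_at <- function(a) -2 * (3 * a - exp(a) - lgamma(4))
  a_draws <- c(0, 0.4)
  ch <- chain_of(alpha = cbind(a_draws),
                 deviance = vapply(a_draws, dev_at, 0))
  d <- dic(manual_draws(list(ch), "a", "c1"), acd)
  expect_equal(d$dbar, (dev_at(0) + dev_at(0.4)) / 2)
  expect_equal(d$d_at_mean, dev_at(0.2))
  expect_equal(d$pd, d$dbar - dev_at(0.2))
  expect_equal(d$dic, d$dbar + d$pd)

  # degenerate posterior: identical draws give pd = 0, dic = dbar
  ch0 <- chain_of(alpha = cbind(c(0.4, 0.4)),
                  deviance = rep(dev_at(0.4), 2))
  d0 <- dic(manual_draws(list(ch0), "a", "c1"), acd)
  expect_equal(d0$pd, 0)
  expect_equal(d0$dic, d0$dbar)
  expect_error(dic(manual_draws(list(chain_of(alpha = cbind(0))),
                                "a", "c1"), acd), "2 retained")
})

test_that("stored deviances agree with the likelihood recomputed in R", {
  acd <- small_sim()$acd
  f <- small_fit()
  ch <- f$chains[[1]]
  N <- length(f$meta$area_ids); J <- length(f$meta$conditions)
  for (k in c(1, 250, 500)) {
    params <- list(alpha = ch$alpha[k, ], log_delta = ch$log_delta[k, ],
                   phi = ch$phi[k, ], eps = matrix(ch$eps[k, ], N, J))
    expect_equal(ch$deviance[k], -2 * poisson_log_lik(acd, params),
                 tolerance = 1e-8)
  }
  # DIC identity on the real fit
  d <- dic(f, acd)
  expect_equal(d$dic, d$dbar + d$pd)
})

test_that("exceedance probabilities are exact draw counts", {
  # 7 of 10 shared-field draws above log(1) for area 1
  phi <- cbind(c(rep(0.5, 7), rep(-0.5, 3)), rep(1, 10), rep(-1, 10))
  ch <- chain_of(alpha = matrix(0, 10, 1), phi = phi,
                 eps = matrix(0.1, 10, 3), prec_eps = matrix(1, 10, 1))
  dr <- manual_draws(list(ch), c("x", "y", "z"), "c1")
  ex <- exceedance(dr, "shared")
  expect_equal(ex$prob, c(0.7, 1, 0))
  expect_equal(ex$category, c("indeterminate", "high", "low"))

  # symmetric draws: probability one half
  phi2 <- cbind(c(rep(1, 5), rep(-1, 5)))
  ch2 <- chain_of(alpha = matrix(0, 10, 1), phi = phi2)
  ex2 <- exceedance(manual_draws(list(ch2), "x", "c1"), "shared")
  expect_equal(ex2$prob, 0.5)
  expect_equal(ex2$category, "indeterminate")

  expect_error(exceedance(dr, "nope"))
})

test_that("exceedance on fitted draws equals the brute-force count", {
  f <- small_fit()
  N <- length(f$meta$area_ids)
  phi <- do.call(rbind, lapply(f$chains, `[[`, "phi"))
  eps <- do.call(rbind, lapply(f$chains, `[[`, "eps"))
  ldel <- do.call(rbind, lapply(f$chains, `[[`, "log_delta"))

  ex <- exceedance(f, "shared")
  expect_equal(ex$prob, unname(colMeans(exp(phi) > 1)))

  ex_s <- exceedance(f, "specific")
  j <- 3
  block <- eps[, (j - 1) * N + seq_len(N)]
  expect_equal(ex_s$prob[ex_s$condition == f$meta$conditions[j]],
               unname(colMeans(exp(block) > 1)))

  ex_r <- exceedance(f, "condition_rr")
  rr <- exp(phi * exp(ldel[, j]) + block)
  expect_equal(ex_r$prob[ex_r$condition == f$meta$conditions[j]],
               unname(colMeans(rr > 1)))
})

test_that("variance decomposition honors its limiting cases", {
  n <- 50; N <- 4; J <- 2
  set.seed(2)
  phi <- matrix(rnorm(n * N), n, N)
  ldel <- matrix(0, n, J)
  # eps identically zero: all variance is shared -> 100% with flat CrI
  ch <- chain_of(alpha = matrix(0, n, J), log_delta = ldel, phi = phi,
                 eps = matrix(0, n, N * J),
                 prec_eps = matrix(1, n, J), prec_phi = rep(1, n))
  dr <- manual_draws(list(ch), paste0("a", 1:N), c("c1", "c2"))
  v <- variance_explained(dr)
  expect_equal(v$conditions$pct_shared, c(100, 100))
  expect_equal(v$conditions$pct_shared_lo, c(100, 100))

  # vanishing loadings: nothing is shared
  ch2 <- chain_of(alpha = matrix(0, n, J),
                  log_delta = matrix(-400, n, J), phi = phi,
                  eps = matrix(rnorm(n * N * J), n, N * J),
                  prec_eps = matrix(1, n, J), prec_phi = rep(1, n))
  v2 <- variance_explained(manual_draws(list(ch2), paste0("a", 1:N),
                                        c("c1", "c2")))
  expect_equal(v2$conditions$pct_shared, c(0, 0))

  # relabeling areas leaves the decomposition unchanged
  perm <- c(3, 1, 4, 2)
  eps3 <- matrix(rnorm(n * N * J), n, N * J)
  ch3 <- chain_of(alpha = matrix(0, n, J), log_delta = ldel, phi = phi,
                  eps = eps3, prec_eps = matrix(1, n, J))
  eps3p <- cbind(eps3[, perm], eps3[, N + perm])
  ch3p <- chain_of(alpha = matrix(0, n, J), log_delta = ldel,
                   phi = phi[, perm], eps = eps3p,
                   prec_eps = matrix(1, n, J))
  v3 <- variance_explained(manual_draws(list(ch3), paste0("a", 1:N),
                                        c("c1", "c2")))
  v3p <- variance_explained(manual_draws(list(ch3p),
                                         paste0("a", perm),
                                         c("c1", "c2")))
  expect_equal(v3$conditions$pct_shared, v3p$conditions$pct_shared)
  expect_true(all(v3$conditions$pct_shared >= 0 &
                    v3$conditions$pct_shared <= 100))
})

test_that("split-chain rhat flags separation and passes mixed chains", {
  set.seed(6)
  mk <- function(shift = 0) {
    chain_of(alpha = cbind(rnorm(1000) + shift))
  }
  mixed <- manual_draws(list(mk(), mk(), mk(), mk()), "a", "c1",
                        model = "indep")
  expect_gte(rhat(mixed, "alpha[1]"), 0.99)
  expect_lte(rhat(mixed, "alpha[1]"), 1.02)

  apart <- manual_draws(list(mk(), mk(10)), "a", "c1", model = "indep")
  expect_gt(rhat(apart, "alpha[1]"), 1.5)

  const <- manual_draws(list(chain_of(alpha = cbind(rep(2, 100))),
                             chain_of(alpha = cbind(rep(2, 100)))),
                        "a", "c1", model = "indep")
  r <- rhat(const, "alpha[1]")
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "zero_variance"))

  single <- manual_draws(list(mk()), "a", "c1", model = "indep")
  expect_error(rhat(single, "alpha[1]"), "2 chains")
})

test_that("autocorrelation estimates match known processes", {
  set.seed(8)
  white <- manual_draws(list(chain_of(alpha = cbind(rnorm(1000)))),
                        "a", "c1", model = "indep")
  ac <- autocorrelation(white, "alpha[1]", max_lag = 50)
  expect_equal(ac[1], 1)
  expect_gte(mean(abs(ac[-1]) < 3 / sqrt(1000)), 0.9)

  n <- 10000
  x <- numeric(n); x[1] <- rnorm(1)
  for (t in 2:n) x[t] <- 0.9 * x[t - 1] + rnorm(1)
  ar <- manual_draws(list(chain_of(alpha = cbind(x))), "a", "c1",
                     model = "indep")
  ac1 <- autocorrelation(ar, "alpha[1]", max_lag = 5)
  expect_equal(ac1[2], 0.9, tolerance = 0.05)

  expect_error(autocorrelation(white, "alpha[1]", max_lag = 2000),
               "max_lag")
  constant <- manual_draws(list(chain_of(alpha = cbind(rep(1, 100)))),
                           "a", "c1", model = "indep")
  expect_error(autocorrelation(constant, "alpha[1]"), "zero-variance")
})

test_that("rhat_table covers the monitored parameters on a real fit", {
  f <- small_fit()
  rt <- rhat_table(f)
  expect_true(all(c("prec_phi", "deviance") %in% rt$parameter))
  expect_equal(nrow(rt), 6 + 6 + 1 + 6 + 1)
  expect_true(all(is.finite(rt$rhat)))
})
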