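test_that("poisson log-likelihood matches hand arithmetic", {
  g1 <- suppressWarnings(area_graph("a", list(a = character(0))))
  acd <- manual_acd(matrix(0L), matrix(2), graph = g1)
  # O = 0, mu = 2: only the -mu term
  expect_equal(poisson_log_lik(acd, list(alpha = 0)), -2)
  # O = 2, mu = 2: 2 ln 2 - 2 - ln 2 = ln 2 - 2
  acd2 <- manual_acd(matrix(2L), matrix(2), graph = g1)
  expect_equal(poisson_log_lik(acd2, list(alpha = 0)), log(2) - 2)
  # for fixed O the likelihood is maximized at mu = O
  acd3 <- manual_acd(matrix(7L), matrix(1), graph = g1)
  ll <- vapply(seq(0.5, 3, by = 0.01),
               function(a) poisson_log_lik(acd3, list(alpha = a)), 0)
  expect_equal(seq(0.5, 3, by = 0.01)[which.max(ll)], log(7),
               tolerance = 0.01)
  # non-finite mean is reported with its cell
  expect_error(poisson_log_lik(acd3, list(alpha = Inf)), "condition")
})

test_that("icar quadratic equals the per-edge loop", {
  g <- make_lattice(2, 3)
  expect_equal(icar_quadratic(rep(3, 6), g), 0)
  # path a-b-c with phi = (0,1,3): (0-1)^2 + (1-3)^2 = 5
  path <- make_lattice(1, 3)
  expect_equal(icar_quadratic(c(0, 1, 3), path), 5)
  set.seed(13)
  g5 <- make_lattice(4, 5, "queen")
  for (k in 1:3) {
    phi <- rnorm(20)
    oracle <- 0
    em <- edge_matrix(g5)
    for (e in seq_len(nrow(em))) {
      oracle <- oracle + (phi[em[e, 1]] - phi[em[e, 2]])^2
    }
    expect_equal(icar_quadratic(phi, g5), oracle, tolerance = 1e-12)
  }
})

test_that("fits are bit-reproducible under a fixed seed", {
  acd <- small_sim()$acd
  f1 <- fit_scm(acd, n_chains = 2, iterations = 600, burn_in = 200,
                thin = 2, seed = 3)
  f2 <- fit_scm(acd, n_chains = 2, iterations = 600, burn_in = 200,
                thin = 2, seed = 3)
  expect_identical(f1$chains, f2$chains)
  f3 <- fit_scm(acd, n_chains = 2, iterations = 600, burn_in = 200,
                thin = 2, seed = 4)
  expect_false(identical(f1$chains[[1]]$alpha, f3$chains[[1]]$alpha))
  # retained count contract
  expect_equal(nrow(f1$chains[[1]]$alpha), (600 - 200) %/% 2)
  expect_true(all(is.finite(f1$chains[[1]]$deviance)))
})

test_that("the icar shared field is centered in every retained draw", {
  acd <- small_sim()$acd
  f <- fit_scm(acd, scm_spec("icar"), n_chains = 1, iterations = 800,
               burn_in = 200, thin = 3, seed = 5)
  sums <- rowSums(f$chains[[1]]$phi)
  expect_lt(max(abs(sums)), 1e-10)
})

test_that("adapted Metropolis blocks settle in the target window", {
  acc <- acceptance_rates(small_fit())
  for (col in c("alpha", "delta", "phi", "eps", "swap_delta",
                "swap_phi")) {
    expect_true(all(acc[[col]] >= 0.15 & acc[[col]] <= 0.6),
                info = col)
  }
})

test_that("a shared-only exchangeable fit shrinks SHRs toward one", {
  cfg <- pph_sim_config(n_areas = 64, conditions = "c1",
                        baseline_rates = 50, delta = 1,
                        sigma_shared = 0.3, sigma_specific = 1e-6)
  sim <- generate_pph_data(cfg, seed = 9)
  acd <- assemble(sim$stratum_table, sim$graph)
  f <- fit_shared_only(acd, n_chains = 2, iterations = 6000,
                       burn_in = 2000, thin = 4, seed = 2)
  phi <- do.call(rbind, lapply(f$chains, `[[`, "phi"))
  alpha <- unlist(lapply(f$chains, `[[`, "alpha"))
  rr <- colMeans(exp(phi + mean(alpha)))
  s <- acd$observed[, 1] / acd$expected[, 1]
  shrunk <- abs(rr - 1) <= abs(s - 1) + 1e-9
  expect_gte(mean(shrunk), 0.95)
})

test_that("every condition must carry at least one admission", {
  acd <- manual_acd(cbind(c(0L, 0L)), cbind(c(5, 5)))
  expect_error(fit_scm(acd, n_chains = 1, iterations = 100,
                       burn_in = 50, thin = 1, seed = 1), "admission")
})

test_that("BYM separates structured from unstructured variation", {
  # strongly spatial, almost noiseless data: sigma_u dominates sigma_v
  wins <- 0
  for (s in 1:3) {
    cfg <- pph_sim_config(n_areas = 100, conditions = "c1",
                          baseline_rates = 150, delta = 1,
                          sigma_shared = 0.4, sigma_specific = 0.01,
                          shared_family = "icar")
    sim <- generate_pph_data(cfg, seed = 40 + s)
    acd <- assemble(sim$stratum_table, sim$graph)
    f <- fit_bym(acd, n_chains = 2, iterations = 2000, burn_in = 500,
                 thin = 3, seed = s)
    su <- median(extract_parameter(f, "sigma_phi"))
    sv <- median(extract_parameter(f, "sigma_eps[1]"))
    if (su / sv > 2) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("BYM variance posteriors collapse on flat data", {
  # SHR ~ 1 everywhere with large expected counts
  g <- make_lattice(6, 6)
  e <- rep(400, 36)
  set.seed(77)
  o <- rpois(36, e)
  acd <- manual_acd(cbind(o), cbind(e * sum(o) / sum(e)), graph = g)
  f <- fit_bym(acd, n_chains = 2, iterations = 2000, burn_in = 500,
               thin = 3, seed = 8)
  expect_lt(median(extract_parameter(f, "sigma_phi")), 0.1)
  expect_lt(median(extract_parameter(f, "sigma_eps[1]")), 0.1)
})

test_that("the log-delta prior precision convention is switchable", {
  s1 <- scm_spec(logdelta_prior_precision = 5.9)
  s2 <- scm_spec(logdelta_prior_precision = 5.9,
                 logdelta_prior_is_variance = TRUE)
  expect_equal(s1$logdelta_precision, 5.9)
  expect_equal(s2$logdelta_precision, 1 / 5.9)
  expect_error(scm_spec(logdelta_prior_precision = -1),
               "prior precision")
})
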