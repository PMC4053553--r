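#' Regular lattice area graph
#'
#' Grid of `n_rows` x `n_cols` areas with rook (shared edge) or queen
#' (shared edge or corner) contiguity; a convenient stand-in for an
#' administrative neighbor map.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param contiguity `"rook"` or `"queen"`.
#' @return an [area_graph()] with ids `a001, a002, ...` in row-major
#'   order.
#' @export
make_lattice <- function(n_rows, n_cols, contiguity = c("rook", "queen")) {
  contiguity <- match.arg(contiguity)
  stopifnot(n_rows >= 1, n_cols >= 1)
  n <- n_rows * n_cols
  ids <- sprintf("a%03d", seq_len(n))
  at <- function(r, c) ids[(r - 1) * n_cols + c]
  offsets <- if (contiguity == "rook") {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  nb <- vector("list", n)
  names(nb) <- ids
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      here <- character(0)
      for (o in offsets) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr >= 1 && rr <= n_rows && cc >= 1 && cc <= n_cols) {
          here <- c(here, at(rr, cc))
        }
      }
      nb[[at(r, c)]] <- here
    }
  }
  if (n == 1) {
    suppressWarnings(area_graph(ids, nb))
  } else {
    area_graph(ids, nb)
  }
}

#' Sample a shared spatial field
#'
#' Draws the latent field \eqn{\varphi} either as exchangeable
#' i.i.d. \eqn{N(0, \sigma^2)} noise or as an intrinsic CAR realization:
#' a zero-mean draw from the pairwise-difference Gaussian on the graph
#' (via the spectrum of the graph Laplacian), centered within each
#' connected component and rescaled so the empirical standard deviation
#' equals `sigma`. Isolated areas under the CAR family carry no spatial
#' information and are set to 0.
#'
#' @param graph an [area_graph()].
#' @param family `"exchangeable"` or `"icar"`.
#' @param sigma positive scale.
#' @param seed optional integer seed.
#' @return numeric vector of length `n areas`.
#' @export
sample_shared_field <- function(graph, family = c("exchangeable", "icar"),
                                sigma, seed = NULL) {
  family <- match.arg(family)
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(graph$area_ids)
  if (family == "exchangeable") {
    return(stats::rnorm(n, 0, sigma))
  }
  comp <- graph_components(graph)
  if (length(unique(comp)) > 1) {
    warning("graph is disconnected: the intrinsic field is centered ",
            "within each component")
  }
  em <- edge_matrix(graph)
  if (nrow(em) == 0) stop("icar field needs at least one edge")
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(em))) {
    i <- em[k, 1]; j <- em[k, 2]
    L[i, j] <- L[i, j] - 1
    L[j, i] <- L[j, i] - 1
    L[i, i] <- L[i, i] + 1
    L[j, j] <- L[j, j] + 1
  }
  ev <- eigen(L, symmetric = TRUE)
  pos <- ev$values > 1e-8 * max(ev$values)
  coef <- stats::rnorm(sum(pos), 0, 1 / sqrt(ev$values[pos]))
  phi <- as.numeric(ev$vectors[, pos, drop = FALSE] %*% coef)
  for (cc in unique(comp)) {
    sel <- comp == cc
    phi[sel] <- if (sum(sel) == 1) 0 else phi[sel] - mean(phi[sel])
  }
  s <- stats::sd(phi)
  if (s > 0) phi <- phi * (sigma / s)
  phi
}

#' Synthetic-data generator configuration
#'
#' Defaults emulate the study conditions of a three-year regional
#' admission registry: 240 small areas, annual person-years log-uniform
#' between 4,065 and 250,616, six conditions with regional rates 11.3,
#' 155.0, 88.9, 3.9, 23.9 and 21.2 per 100,000 person-years, a shared
#' spatial field of scale 0.121 with loadings (0.92, 1.12, 0.74, 1.42,
#' 1.11, 1.09), and condition-specific exchangeable noise of scale
#' (0.243, 0.112, 0.079, 0.673, 0.489, 0.353).
#'
#' @param n_areas number of areas (a near-square rook lattice is built
#'   unless `graph` is supplied).
#' @param graph optional [area_graph()] overriding the lattice.
#' @param conditions condition names.
#' @param baseline_rates regional rates per `1e5` person-years.
#' @param delta factor loadings of the shared field.
#' @param sigma_shared scale of the shared field.
#' @param sigma_specific per-condition scale of the specific effects.
#' @param shared_family `"exchangeable"` or `"icar"`.
#' @param py_range annual person-years range (log-uniform).
#' @param years number of years aggregated.
#' @param n_age_bands 5-year age bands starting at 15-19 (default 18,
#'   i.e. up to 100+), crossed with two sexes.
#' @param age_rate_gradient log-linear increase of admission rates per
#'   age band (fixed shape; only its existence matters for
#'   standardization).
#' @return a list of class `pph_sim_config`.
#' @export
pph_sim_config <- function(n_areas = 240,
                           graph = NULL,
                           conditions = c("diabetes", "copd", "chf",
                                          "dehydration", "angina",
                                          "asthma"),
                           baseline_rates = c(11.3, 155.0, 88.9, 3.9,
                                              23.9, 21.2),
                           delta = c(0.92, 1.12, 0.74, 1.42, 1.11, 1.09),
                           sigma_shared = 0.121,
                           sigma_specific = c(0.243, 0.112, 0.079, 0.673,
                                              0.489, 0.353),
                           shared_family = c("exchangeable", "icar"),
                           py_range = c(4065, 250616),
                           years = 3,
                           n_age_bands = 18,
                           age_rate_gradient = 0.3) {
  shared_family <- match.arg(shared_family)
  J <- length(conditions)
  stopifnot(length(baseline_rates) == J, length(delta) == J,
            length(sigma_specific) == J,
            sigma_shared > 0, all(sigma_specific > 0), all(delta > 0),
            all(baseline_rates > 0), py_range[1] > 0,
            py_range[2] >= py_range[1], years > 0, n_age_bands >= 1)
  structure(list(n_areas = n_areas, graph = graph,
                 conditions = conditions,
                 baseline_rates = baseline_rates, delta = delta,
                 sigma_shared = sigma_shared,
                 sigma_specific = sigma_specific,
                 shared_family = shared_family,
                 py_range = py_range, years = years,
                 n_age_bands = n_age_bands,
                 age_rate_gradient = age_rate_gradient),
            class = "pph_sim_config")
}

stratum_ids <- function(n_age_bands) {
  ages <- 15 + 5 * (seq_len(n_age_bands) - 1)
  bands <- sprintf("%02d_%02d", ages, ages + 4)
  bands[n_age_bands] <- sprintf("%02dplus", ages[n_age_bands])
  as.vector(outer(c("M", "F"), bands, paste, sep = ""))
}

#' Generate synthetic stratified areal admission data
#'
#' Simulates exactly from the shared-component data-generating process:
#' person-years are drawn log-uniformly over the configured annual range
#' (times `years`) and split across age-sex strata by a fixed population
#' profile; the shared field \eqn{\varphi} and specific effects
#' \eqn{\epsilon_{ij}} are drawn at the configured scales; intercepts are
#' set so each condition's expected regional rate matches its baseline
#' (\eqn{\alpha_j = -[(\delta_j\sigma_{sh})^2 + \sigma_{sp,j}^2]/2}
#' cancels the log-normal mean); stratum-level means apply a fixed
#' age-rate gradient, and every stratum cell is Poisson.
#'
#' @param config a [pph_sim_config()].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `stratum_table` (see [validate_stratum_table()]),
#'   `graph`, and `truth`: the generating `alpha`, `delta`, `phi`, `eps`,
#'   scales, and the per-condition true shared-variance fraction
#'   `shared_fraction` (empirical across areas).
#' @export
generate_pph_data <- function(config = pph_sim_config(), seed = 1) {
  stopifnot(inherits(config, "pph_sim_config"))
  graph <- config$graph
  if (is.null(graph)) {
    nr <- floor(sqrt(config$n_areas))
    while (config$n_areas %% nr != 0) nr <- nr - 1
    graph <- make_lattice(nr, config$n_areas %/% nr)
  }
  n <- length(graph$area_ids)
  J <- length(config$conditions)
  set.seed(seed)

  # area person-years: log-uniform annual size, heavy right skew
  py_area <- exp(stats::runif(n, log(config$py_range[1]),
                              log(config$py_range[2]))) * config$years

  # fixed age-sex population profile (shares per 5-year band, both sexes
  # equal): roughly flat through middle age, declining in old age
  nb <- config$n_age_bands
  band_share <- exp(-0.18 * pmax(0, seq_len(nb) - 8))
  band_share <- band_share / sum(band_share)
  strata <- stratum_ids(nb)
  py_share <- rep(band_share / 2, each = 2)      # M, F within each band
  py_as <- outer(py_area, py_share)              # n x 2*nb

  # age-rate gradient, normalized so the regional rate equals baseline
  grad <- exp(config$age_rate_gradient * (seq_len(nb) - 1))
  grad_s <- rep(grad, each = 2)
  grad_s <- grad_s / sum(py_share * grad_s)      # sum_s w_s g_s = 1

  phi <- sample_shared_field(graph, config$shared_family,
                             config$sigma_shared)
  eps <- matrix(stats::rnorm(n * J, 0,
                             rep(config$sigma_specific, each = n)), n, J)
  alpha <- -((config$delta * config$sigma_shared)^2 +
               config$sigma_specific^2) / 2
  rho <- exp(matrix(alpha, n, J, byrow = TRUE) +
               outer(phi, config$delta) + eps)

  base <- config$baseline_rates / 1e5
  rows <- vector("list", J)
  for (j in seq_len(J)) {
    mu_as <- py_as * matrix(grad_s * base[j], n, length(strata),
                            byrow = TRUE) * rho[, j]
    if (all(rowSums(mu_as) < 0.001)) {
      warning("condition ", config$conditions[j],
              ": expected counts below 0.001 in every area (sparse ",
              "regime)")
    }
    counts <- matrix(stats::rpois(length(mu_as), mu_as), n)
    rows[[j]] <- data.frame(
      area_id = rep(graph$area_ids, times = length(strata)),
      condition = config$conditions[j],
      stratum_id = rep(strata, each = n),
      person_years = as.vector(py_as),
      count = as.integer(counts))
  }
  tab <- validate_stratum_table(do.call(rbind, rows))

  shared_var <- config$delta^2 * stats::var(phi)
  spec_var <- apply(eps, 2, stats::var)
  truth <- list(alpha = alpha, delta = config$delta, phi = phi, eps = eps,
                sigma_shared = config$sigma_shared,
                sigma_specific = config$sigma_specific,
                shared_fraction = shared_var / (shared_var + spec_var),
                conditions = config$conditions, seed = seed)
  list(stratum_table = tab, graph = graph, truth = truth)
}
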