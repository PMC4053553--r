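#' Crude admission rate
#'
#' @param count non-negative admission count.
#' @param person_years person-years at risk (must be positive).
#' @param per reporting scale, default per 100,000 person-years.
#' @return `count / person_years * per`.
#' @examples
#' crude_rate(20357, 13131836)  # 155.0 per 100,000 py
#' @export
crude_rate <- function(count, person_years, per = 1e5) {
  if (any(person_years <= 0)) stop("person_years must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count / person_years * per
}

#' Directly age-standardized rate
#'
#' Weighted average of stratum-specific rates, with weights proportional to
#' a standard population's stratum person-years. When the standard
#' population is the area's own population this reduces to the area's crude
#' rate.
#'
#' @param stratum_rates vector of stratum-specific rates for one area.
#' @param standard_weights non-negative weights (standard-population
#'   person-years); normalized internally to sum to 1.
#' @return the standardized rate.
#' @export
direct_standardized_rate <- function(stratum_rates, standard_weights) {
  if (length(stratum_rates) != length(standard_weights)) {
    stop("rates and weights differ in length")
  }
  if (any(standard_weights < 0)) stop("negative standard weights")
  tot <- sum(standard_weights)
  if (tot <= 0) stop("standard weights sum to zero")
  sum(stratum_rates * standard_weights) / tot
}

#' Standardized hospitalization ratio
#'
#' Ratio of observed to expected admissions for an area; expected counts
#' come from indirect standardization (region-wide stratum rates applied to
#' the area's population), see [assemble()].
#'
#' @param observed non-negative count(s).
#' @param expected positive expected count(s).
#' @return observed / expected.
#' @export
shr <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected must be positive")
  if (any(observed < 0)) stop("observed must be non-negative")
  observed / expected
}

#' Extremal quotient over the central 90% of areas (EQ5-95)
#'
#' Ratio of the 95th to the 5th percentile of area rates, using linear
#' interpolation quantiles (type 7). Undefined — returned as `NA` — when
#' fewer than `min_areas` areas are available or when the lower percentile
#' is zero (as happens for rare conditions with many zero-rate areas).
#'
#' @param rates vector of area-level rates.
#' @param lower,upper percentile bounds, defaults 0.05 and 0.95.
#' @param min_areas minimum number of areas for the statistic to be
#'   defined, default 20.
#' @return the quotient, or `NA_real_` when undefined.
#' @export
eq_quantile <- function(rates, lower = 0.05, upper = 0.95, min_areas = 20) {
  if (length(rates) == 0) stop("empty rates vector")
  if (any(!is.finite(rates))) stop("non-finite rates")
  if (length(rates) < min_areas) return(NA_real_)
  q <- stats::quantile(rates, c(lower, upper), names = FALSE, type = 7)
  if (q[1] <= 0) return(NA_real_)
  q[2] / q[1]
}

#' Empirical-Bayes estimate of between-area relative-risk variance
#'
#' Moment estimator of the variance \eqn{\tau^2} of area relative risks
#' beyond Poisson noise, under \eqn{o_i \sim Poisson(e_i \rho_i)} with
#' \eqn{E\rho = 1}, \eqn{Var(\rho) = \tau^2}. Since
#' \eqn{Var(o_i/e_i) = \tau^2 + 1/e_i} (at \eqn{E\rho_i = 1}), the
#' estimator averages \eqn{(o_i/e_i - 1)^2 - 1/e_i} over areas and
#' truncates at zero.
#'
#' @param observed vector of observed counts.
#' @param expected vector of positive expected counts.
#' @param weighted if `TRUE`, average with weights proportional to
#'   `expected` (precision-weighted variant); default `FALSE` (simple
#'   mean).
#' @return non-negative estimate of \eqn{\tau^2}.
#' @export
eb_variance <- function(observed, expected, weighted = FALSE) {
  if (any(expected <= 0)) stop("expected must be positive")
  contrib <- (observed / expected - 1)^2 - 1 / expected
  est <- if (weighted) {
    sum(expected * contrib) / sum(expected)
  } else {
    mean(contrib)
  }
  max(0, est)
}

#' Pairwise correlations between per-condition SHR vectors
#'
#' Pearson correlations across areas between each pair of conditions'
#' standardized hospitalization ratios, with two-sided t-test p-values
#' (unadjusted). A zero-variance column yields `NA` for its pairs.
#'
#' @param shr_matrix numeric area x condition matrix.
#' @return list with matrices `r` (correlations, unit diagonal) and
#'   `p_value` (`NA` on the diagonal).
#' @export
shr_correlations <- function(shr_matrix) {
  shr_matrix <- as.matrix(shr_matrix)
  n <- nrow(shr_matrix)
  if (n < 3) stop("need at least 3 areas")
  J <- ncol(shr_matrix)
  cn <- colnames(shr_matrix)
  r <- matrix(NA_real_, J, J, dimnames = list(cn, cn))
  p <- matrix(NA_real_, J, J, dimnames = list(cn, cn))
  sds <- apply(shr_matrix, 2, stats::sd)
  for (a in seq_len(J)) {
    r[a, a] <- 1
    for (b in seq_len(J)) {
      if (b <= a) next
      if (sds[a] == 0 || sds[b] == 0) next
      ct <- stats::cor.test(shr_matrix[, a], shr_matrix[, b],
                            method = "pearson", alternative = "two.sided")
      r[a, b] <- r[b, a] <- unname(ct$estimate)
      p[a, b] <- p[b, a] <- ct$p.value
    }
  }
  list(r = r, p_value = p)
}

#' Moran's I with a permutation test
#'
#' Spatial autocorrelation of an area-level variable on the adjacency
#' graph, with binary symmetric (non-row-standardized) weights:
#' \deqn{I = \frac{N}{\sum_{ij} w_{ij}} \cdot
#'       \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z} the centered values. Significance is assessed by random
#' relabeling: the two-sided p-value is
#' `(1 + #permutations with |I*| >= |I|) / (n_permutations + 1)`.
#' Isolated areas carry no weight and are dropped with a warning.
#'
#' @param values numeric vector, one per area, with positive variance.
#' @param graph an [area_graph()] with at least one edge.
#' @param n_permutations number of random relabelings, default 999.
#' @param seed optional integer seed for the permutation draw.
#' @return list with `i_statistic`, `p_value`, `n_permutations`.
#' @export
morans_i <- function(values, graph, n_permutations = 999, seed = NULL) {
  stopifnot(inherits(graph, "area_graph"))
  if (length(values) != length(graph$area_ids)) {
    stop("values length does not match number of areas")
  }
  deg <- vapply(graph$neighbors, length, 1L)
  keep <- deg > 0L
  if (!all(keep)) {
    warning(sum(!keep), " isolated area(s) excluded from Moran's I")
  }
  em <- edge_matrix(graph)
  if (nrow(em) == 0) stop("graph has no edges")
  values <- values[keep]
  # re-index edges onto the kept areas
  map <- cumsum(keep)
  em <- cbind(map[em[, 1]], map[em[, 2]])
  n <- length(values)
  if (stats::sd(values) == 0) stop("values are constant")
  w_sum <- 2 * nrow(em)

  stat <- function(z) {
    z <- z - mean(z)
    cross <- 2 * sum(z[em[, 1]] * z[em[, 2]])
    (n / w_sum) * cross / sum(z^2)
  }
  i_obs <- stat(values)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    if (abs(stat(sample(values))) >= abs(i_obs)) exceed <- exceed + 1L
  }
  list(i_statistic = i_obs,
       p_value = (1 + exceed) / (n_permutations + 1),
       n_permutations = as.integer(n_permutations))
}

#' Condition-level summary table of rates and small-area variation
#'
#' One row per condition: total admissions, crude regional rate per
#' `per` person-years, the extremal quotient EQ5-95 of directly
#' age-standardized area rates, and the empirical-Bayes between-area
#' variance of the standardized hospitalization ratios.
#'
#' @param stratum_table a stratum table (see [validate_stratum_table()]).
#' @param graph an [area_graph()].
#' @param per rate scale, default 100,000.
#' @return data frame with columns `condition`, `n`, `rate`, `eq_5_95`,
#'   `eb_variance`.
#' @export
variation_stats <- function(stratum_table, graph, per = 1e5) {
  tab <- validate_stratum_table(stratum_table)
  acd <- assemble(tab, graph)
  conditions <- acd$conditions
  areas <- graph$area_ids
  strata <- sort(unique(tab$stratum_id))
  a <- factor(tab$area_id, levels = areas)
  s <- factor(tab$stratum_id, levels = strata)
  j <- factor(tab$condition, levels = conditions)
  py_as <- tapply(tab$person_years, list(a, s), function(v) v[1])
  py_as[is.na(py_as)] <- 0
  cnt_asj <- tapply(tab$count, list(a, s, j), sum)
  cnt_asj[is.na(cnt_asj)] <- 0
  std_w <- colSums(py_as)  # regional population as the standard

  out <- lapply(seq_along(conditions), function(jj) {
    n_j <- sum(cnt_asj[, , jj])
    rate_j <- crude_rate(n_j, sum(py_as), per = per)
    # per-area directly standardized rates
    area_rates <- vapply(seq_along(areas), function(ii) {
      nys <- py_as[ii, ]
      rts <- ifelse(nys > 0, cnt_asj[ii, , jj] / nys, 0)
      direct_standardized_rate(rts, std_w) * per
    }, 0)
    data.frame(condition = conditions[jj],
               n = n_j,
               rate = rate_j,
               eq_5_95 = eq_quantile(area_rates),
               eb_variance = eb_variance(acd$observed[, jj],
                                         acd$expected[, jj]))
  })
  do.call(rbind, out)
}
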