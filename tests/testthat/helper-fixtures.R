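# shared fixtures, built in code and cached across test files

.fixtures <- new.env(parent = emptyenv())

# 2x2 rook lattice graph: areas a001..a004 row-major, 4 undirected edges
tiny_lattice <- function() make_lattice(2, 2)

# two-area graph (one edge); isolated-area warnings suppressed upstream
pair_graph <- function() {
  suppressWarnings(area_graph(c("a", "b"), list(a = "b", b = "a")))
}

# hand-built area_condition_data without going through assemble()
manual_acd <- function(observed, expected, graph = NULL,
                       conditions = NULL) {
  observed <- as.matrix(observed)
  expected <- as.matrix(expected)
  n <- nrow(observed)
  if (is.null(graph)) {
    graph <- if (n == 2) pair_graph() else
      make_lattice(1, n)  # path graph
  }
  if (is.null(conditions)) conditions <- paste0("c", seq_len(ncol(observed)))
  dimnames(observed) <- dimnames(expected) <-
    list(graph$area_ids, conditions)
  structure(list(graph = graph, conditions = conditions,
                 observed = matrix(as.integer(observed), n,
                                   dimnames = dimnames(observed)),
                 expected = expected,
                 person_years = stats::setNames(rep(1e5, n),
                                                graph$area_ids)),
            class = "area_condition_data")
}

# small assembled synthetic dataset reused by several files
small_sim <- function() {
  if (is.null(.fixtures$small_sim)) {
    sim <- generate_pph_data(pph_sim_config(n_areas = 48), seed = 7)
    .fixtures$small_sim <- list(sim = sim,
                                acd = assemble(sim$stratum_table,
                                               sim$graph))
  }
  .fixtures$small_sim
}

# short-schedule fit on the small dataset
small_fit <- function() {
  if (is.null(.fixtures$small_fit)) {
    .fixtures$small_fit <- fit_scm(small_sim()$acd,
                                   scm_spec("exchangeable"),
                                   n_chains = 2, iterations = 3000,
                                   burn_in = 1000, thin = 4, seed = 11)
  }
  .fixtures$small_fit
}

# random stratum table over a given graph (for property loops)
random_stratum_table <- function(graph, n_strata = 3, n_conditions = 2,
                                 seed = 1) {
  set.seed(seed)
  areas <- graph$area_ids
  strata <- paste0("s", seq_len(n_strata))
  conds <- paste0("c", seq_len(n_conditions))
  grid <- expand.grid(area_id = areas, stratum_id = strata,
                      condition = conds, stringsAsFactors = FALSE)
  grid$person_years <- round(stats::runif(nrow(grid), 500, 5000))
  # person-years must agree across conditions within (area, stratum)
  py <- tapply(grid$person_years,
               paste(grid$area_id, grid$stratum_id), max)
  grid$person_years <- py[paste(grid$area_id, grid$stratum_id)]
  grid$count <- stats::rpois(nrow(grid), grid$person_years * 2e-3)
  validate_stratum_table(grid)
}
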