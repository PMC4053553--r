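#' Area adjacency graph
#'
#' Construct the spatial support of all models: an ordered set of area
#' identifiers together with a symmetric neighbor structure. Adjacency must
#' be symmetric with no self-loops; isolated areas (no neighbors) are legal
#' but flagged with a warning because the intrinsic CAR prior treats them
#' specially.
#'
#' @param area_ids character vector of unique area identifiers. Their order
#'   fixes matrix row order everywhere downstream.
#' @param neighbors named list mapping each area id to a character vector of
#'   neighboring area ids.
#' @return An object of class `area_graph` with elements `area_ids` and
#'   `neighbors` (a named list of character vectors, in `area_ids` order).
#' @examples
#' g <- area_graph(c("a", "b"), list(a = "b", b = "a"))
#' n_edges(g)
#' @export
area_graph <- function(area_ids, neighbors) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stop("duplicate area ids: ",
         paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "))
  }
  nb <- lapply(area_ids, function(id) {
    v <- neighbors[[id]]
    if (is.null(v)) character(0) else sort(unique(as.character(v)))
  })
  names(nb) <- area_ids
  unknown <- setdiff(unlist(nb), area_ids)
  if (length(unknown) > 0) {
    stop("neighbor ids not present among areas: ",
         paste(unknown, collapse = ", "))
  }
  for (id in area_ids) {
    if (id %in% nb[[id]]) stop("self-loop at area ", id)
  }
  bad <- list()
  for (id in area_ids) {
    for (k in nb[[id]]) {
      if (!(id %in% nb[[k]])) bad[[length(bad) + 1L]] <- c(id, k)
    }
  }
  if (length(bad) > 0) {
    stop("asymmetric adjacency: ",
         paste(vapply(bad, function(p) paste0(p[1], "->", p[2]), ""),
               collapse = ", "))
  }
  iso <- area_ids[vapply(nb, length, 1L) == 0L]
  if (length(iso) > 0) {
    warning("isolated areas (no neighbors): ", paste(iso, collapse = ", "))
  }
  structure(list(area_ids = area_ids, neighbors = nb),
            class = "area_graph")
}

#' @export
print.area_graph <- function(x, ...) {
  cat("area_graph:", length(x$area_ids), "areas,", n_edges(x),
      "undirected edges\n")
  invisible(x)
}

#' Number of undirected edges in an area graph
#' @param graph an [area_graph()].
#' @return integer edge count (each adjacent pair counted once).
#' @export
n_edges <- function(graph) {
  sum(vapply(graph$neighbors, length, 1L)) %/% 2L
}

#' Edge list of an area graph
#'
#' @param graph an [area_graph()].
#' @return two-column integer matrix of 1-based area indices, one row per
#'   undirected edge, with `[,1] < [,2]`.
#' @export
edge_matrix <- function(graph) {
  idx <- seq_along(graph$area_ids)
  names(idx) <- graph$area_ids
  rows <- lapply(graph$area_ids, function(id) {
    i <- idx[[id]]
    k <- idx[graph$neighbors[[id]]]
    k <- k[k > i]
    if (length(k) == 0) return(NULL)
    cbind(i, as.integer(k))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  dimnames(out) <- NULL
  out
}

#' Connected components of an area graph
#' @param graph an [area_graph()].
#' @return integer vector of component labels, one per area.
#' @export
graph_components <- function(graph) {
  em <- edge_matrix(graph)
  ig <- igraph::make_empty_graph(n = length(graph$area_ids),
                                 directed = FALSE)
  if (nrow(em) > 0) ig <- igraph::add_edges(ig, t(em))
  as.integer(igraph::components(ig)$membership)
}

# ---- stratified count table -------------------------------------------------

stratum_cols <- c("area_id", "condition", "stratum_id", "person_years",
                  "count")

#' Validate a stratified count table
#'
#' A stratum table holds one row per (area, condition, age-sex stratum)
#' with the person-years at risk and the admission count. Keys must be
#' unique, counts non-negative integers, and any row with zero person-years
#' must have a zero count.
#'
#' @param tab data frame with columns `area_id`, `condition`, `stratum_id`,
#'   `person_years`, `count`.
#' @return the validated data frame (invisibly the same object), with key
#'   columns coerced to character.
#' @export
validate_stratum_table <- function(tab) {
  missing_cols <- setdiff(stratum_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("stratum table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- as.data.frame(tab)[stratum_cols]
  for (col in c("area_id", "condition", "stratum_id")) {
    tab[[col]] <- as.character(tab[[col]])
  }
  tab$person_years <- as.numeric(tab$person_years)
  tab$count <- as.numeric(tab$count)
  bad <- which(!is.finite(tab$person_years) | tab$person_years < 0 |
                 !is.finite(tab$count) | tab$count < 0 |
                 tab$count != round(tab$count))
  if (length(bad) > 0) {
    stop("malformed stratum rows (negative/non-integer count or bad ",
         "person-years) at row(s): ", paste(utils::head(bad, 5),
                                            collapse = ", "))
  }
  key <- paste(tab$area_id, tab$condition, tab$stratum_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    d <- dup[1]
    stop("duplicate (area_id, condition, stratum_id) key: (",
         tab$area_id[d], ", ", tab$condition[d], ", ", tab$stratum_id[d],
         ") at row ", d)
  }
  zero_py <- which(tab$person_years == 0 & tab$count > 0)
  if (length(zero_py) > 0) {
    stop("positive count with zero person-years at row(s): ",
         paste(utils::head(zero_py, 5), collapse = ", "))
  }
  tab$count <- as.integer(tab$count)
  tab
}

#' Read / write a stratified count table (CSV)
#'
#' CSV dialect: comma-separated, UTF-8, header required with at least the
#' columns `area_id,condition,stratum_id,person_years,count`; unknown
#' columns are ignored and row order is preserved.
#'
#' @param path file path.
#' @return `read_stratum_table()` returns a validated data frame.
#' @export
read_stratum_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  validate_stratum_table(tab)
}

#' @rdname read_stratum_table
#' @param tab a stratum table.
#' @export
write_stratum_table <- function(tab, path) {
  tab <- validate_stratum_table(tab)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# ---- GAL adjacency ----------------------------------------------------------

#' Read / write a GAL neighbor-list file
#'
#' The GAL format starts with a header line carrying the number of areas
#' (either a single integer, or the common 4-token `0 n shapefile key`
#' variant, in which case the second token is used). Each area then
#' contributes two records: `id n_neighbors` and a line with the neighbor
#' ids (absent when `n_neighbors` is 0). Symmetry is validated, not
#' silently repaired.
#'
#' @param path file path.
#' @return `read_adjacency_gal()` returns an [area_graph()]; area order is
#'   the file order.
#' @export
read_adjacency_gal <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) stop("empty GAL file: ", path)
  head_tok <- strsplit(lines[1], "[[:space:]]+")[[1]]
  n <- if (length(head_tok) == 1) {
    as.integer(head_tok[1])
  } else {
    as.integer(head_tok[2])
  }
  if (is.na(n) || n < 0) stop("unreadable GAL header: ", lines[1])
  area_ids <- character(n)
  nb <- vector("list", n)
  pos <- 2L
  for (i in seq_len(n)) {
    if (pos > length(lines)) {
      stop("GAL file truncated: header declares ", n,
           " areas but records end at area ", i - 1L)
    }
    rec <- strsplit(lines[pos], "[[:space:]]+")[[1]]
    if (length(rec) != 2) stop("malformed GAL area record: '", lines[pos], "'")
    area_ids[i] <- rec[1]
    k <- as.integer(rec[2])
    if (is.na(k) || k < 0) stop("bad neighbor count in: '", lines[pos], "'")
    pos <- pos + 1L
    if (k > 0) {
      if (pos > length(lines)) stop("GAL file truncated in neighbor list of ",
                                    rec[1])
      ids <- strsplit(lines[pos], "[[:space:]]+")[[1]]
      if (length(ids) != k) {
        stop("area ", rec[1], " declares ", k, " neighbors but lists ",
             length(ids))
      }
      nb[[i]] <- ids
      pos <- pos + 1L
    } else {
      nb[[i]] <- character(0)
    }
  }
  if (pos <= length(lines)) {
    stop("GAL file has trailing records beyond the declared ", n, " areas")
  }
  names(nb) <- area_ids
  area_graph(area_ids, nb)
}

#' @rdname read_adjacency_gal
#' @param graph an [area_graph()].
#' @export
write_adjacency_gal <- function(graph, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(as.character(length(graph$area_ids)), con)
  for (id in graph$area_ids) {
    nbr <- graph$neighbors[[id]]
    writeLines(paste(id, length(nbr)), con)
    if (length(nbr) > 0) writeLines(paste(nbr, collapse = " "), con)
  }
  invisible(path)
}

# ---- assembled area x condition data ---------------------------------------

#' Assemble area-by-condition counts with indirectly standardized expecteds
#'
#' Collapses an age-sex stratified count table over strata: observed counts
#' are summed, and expected counts come from indirect standardization —
#' the region-wide stratum rate for each condition,
#' \eqn{r_{sj} = \sum_i c_{isj} / \sum_i n_{is}}, applied to each area's
#' stratum person-years, \eqn{e_{ij} = \sum_s n_{is} r_{sj}}. By
#' construction the expected counts conserve the regional total for every
#' condition: \eqn{\sum_i e_{ij} = \sum_i O_{ij}}.
#'
#' A region-wide stratum with zero person-years has an undefined rate; its
#' contribution is defined as zero with a warning (it cannot arise from a
#' valid table, where a zero-person-year stratum must have zero count).
#'
#' @param stratum_table a stratum table (see [validate_stratum_table()]).
#' @param graph an [area_graph()] whose areas must coincide with the
#'   table's areas.
#' @return An object of class `area_condition_data`: list with `graph`,
#'   `conditions` (sorted unique condition names), `observed` and
#'   `expected` (area x condition matrices, rows in graph order) and
#'   `person_years` (total per area).
#' @export
assemble <- function(stratum_table, graph) {
  tab <- validate_stratum_table(stratum_table)
  areas <- graph$area_ids
  only_tab <- setdiff(unique(tab$area_id), areas)
  only_graph <- setdiff(areas, unique(tab$area_id))
  if (length(only_tab) > 0 || length(only_graph) > 0) {
    stop("area mismatch between table and graph; only in table: ",
         paste(only_tab, collapse = ", "), "; only in graph: ",
         paste(only_graph, collapse = ", "))
  }
  conditions <- sort(unique(tab$condition))
  strata <- sort(unique(tab$stratum_id))
  a <- factor(tab$area_id, levels = areas)
  s <- factor(tab$stratum_id, levels = strata)
  j <- factor(tab$condition, levels = conditions)

  # person-years per (area, stratum): may be repeated across conditions;
  # take the value from any one condition but require consistency
  py_as <- tapply(tab$person_years, list(a, s), function(v) {
    if (length(unique(v)) > 1) NA_real_ else v[1]
  })
  if (anyNA(py_as[tapply(tab$person_years, list(a, s), length) > 0])) {
    stop("inconsistent person-years for the same (area, stratum) across ",
         "conditions")
  }
  py_as[is.na(py_as)] <- 0

  obs_asj <- tapply(tab$count, list(a, s, j), sum)
  obs_asj[is.na(obs_asj)] <- 0

  observed <- apply(obs_asj, c(1, 3), sum)
  py_s <- colSums(py_as)                       # regional person-years/stratum
  rate_sj <- matrix(0, length(strata), length(conditions),
                    dimnames = list(strata, conditions))
  tot_sj <- apply(obs_asj, c(2, 3), sum)
  pos <- py_s > 0
  rate_sj[pos, ] <- tot_sj[pos, , drop = FALSE] / py_s[pos]
  if (any(!pos & rowSums(tot_sj) == 0) && any(!pos)) {
    # zero-person-year strata contribute nothing; warn only if present
    warning("region-wide stratum with zero person-years; its rate is ",
            "defined as 0")
  }
  expected <- py_as %*% rate_sj
  person_years <- rowSums(py_as)

  structure(list(graph = graph,
                 conditions = conditions,
                 observed = matrix(as.integer(round(observed)),
                                   nrow = length(areas),
                                   dimnames = list(areas, conditions)),
                 expected = matrix(as.numeric(expected),
                                   nrow = length(areas),
                                   dimnames = list(areas, conditions)),
                 person_years = stats::setNames(as.numeric(person_years),
                                                areas)),
            class = "area_condition_data")
}

#' @export
print.area_condition_data <- function(x, ...) {
  cat("area_condition_data:", nrow(x$observed), "areas x",
      ncol(x$observed), "conditions;", sum(x$observed), "admissions over",
      format(sum(x$person_years), big.mark = ","), "person-years\n")
  invisible(x)
}

#' Keep a single condition of an assembled dataset
#'
#' @param data an `area_condition_data`.
#' @param condition condition name.
#' @return an `area_condition_data` with one condition column.
#' @export
slice_condition <- function(data, condition) {
  stopifnot(inherits(data, "area_condition_data"))
  if (!condition %in% data$conditions) {
    stop("unknown condition: ", condition)
  }
  out <- data
  out$conditions <- condition
  out$observed <- data$observed[, condition, drop = FALSE]
  out$expected <- data$expected[, condition, drop = FALSE]
  out
}
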