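#' Published regional admission totals
#'
#' Regional totals for the six chronic potentially preventable
#' hospitalization conditions in the Valencia Community, 2007-2009
#' (adults 15+): admissions over the three-year window and the total
#' person-years at risk. These published figures calibrate the synthetic
#' generator's baseline rates and let the rate arithmetic be checked
#' against the published per-100,000 values.
#'
#' @return data frame with columns `condition`, `admissions`,
#'   `person_years`.
#' @export
region_totals <- function() {
  path <- system.file("extdata", "region_totals.csv", package = "pphmap")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize retained draws to long-format CSV
#'
#' One row per (chain, draw, parameter); a JSON sidecar (same path with
#' `.json` appended) records the run metadata (model, schedule, seeds).
#'
#' @param draws a `pph_draws` object.
#' @param path output CSV path.
#' @param parameters which draw components to write, default the scalar
#'   summaries (`alpha`, `log_delta`, `prec_phi`, `prec_eps`,
#'   `deviance`); add `"phi"`/`"eps"` for the full fields.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path,
                            parameters = c("alpha", "log_delta",
                                           "prec_phi", "prec_eps",
                                           "deviance")) {
  stopifnot(inherits(draws, "pph_draws"))
  rows <- list()
  for (ch in seq_along(draws$chains)) {
    for (what in parameters) {
      x <- draws$chains[[ch]][[what]]
      if (is.null(x)) next
      x <- as.matrix(x)
      if (ncol(x) == 0) next
      cn <- colnames(x)
      if (is.null(cn)) {
        cn <- if (ncol(x) == 1) what else paste0(what, "[", seq_len(ncol(x)), "]")
      } else {
        cn <- paste0(what, "[", cn, "]")
      }
      for (k in seq_len(ncol(x))) {
        rows[[length(rows) + 1]] <- data.frame(
          chain = ch, draw = seq_len(nrow(x)), parameter = cn[k],
          value = x[, k])
      }
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(draws$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Merge exceedance surfaces into GeoJSON properties
#'
#' Reads a GeoJSON FeatureCollection, matches features to areas on a
#' property key, and writes a copy whose features carry `prob` and
#' `category` properties for mapping.
#'
#' @param surface data frame from [exceedance()] (single-condition rows:
#'   filter beforehand for condition-level terms).
#' @param geojson_path input GeoJSON path.
#' @param out_path output path.
#' @param id_property feature property holding the area id, default
#'   `"area_id"`.
#' @return `out_path`, invisibly.
#' @export
export_map_geojson <- function(surface, geojson_path, out_path,
                               id_property = "area_id") {
  gj <- jsonlite::read_json(geojson_path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  ids <- as.character(surface$area_id)
  matched <- 0L
  gj$features <- lapply(gj$features, function(f) {
    id <- f$properties[[id_property]]
    k <- if (is.null(id)) NA_integer_ else match(as.character(id), ids)
    if (!is.na(k)) {
      f$properties$prob <- surface$prob[k]
      f$properties$category <- surface$category[k]
      matched <<- matched + 1L
    }
    f
  })
  if (matched == 0L) {
    warning("no GeoJSON feature matched an area id via property '",
            id_property, "'")
  }
  jsonlite::write_json(gj, out_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(out_path)
}

#' Write a reproducibility manifest
#'
#' Records what a pipeline stage ran: configuration values, seeds,
#' package version and timestamp, as JSON.
#'
#' @param path output path.
#' @param ... named fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  fields <- list(...)
  fields$package_version <-
    as.character(utils::packageVersion("pphmap"))
  fields$r_version <- as.character(getRversion())
  fields$timestamp <- format(Sys.time(), tz = "UTC",
                             "%Y-%m-%dT%H:%M:%SZ")
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
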