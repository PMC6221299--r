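#' Read and write telemetry fixes as CSV
#'
#' Columns: `individual_id`, `timestamp` (ISO-8601, UTC), `x`, `y`,
#' `altitude`. Extra columns (e.g. generator truth flags) round-trip
#' unchanged.
#'
#' @param fixes data.frame of fixes
#' @param path file path
#' @return `write_fixes_csv` returns `path` invisibly; `read_fixes_csv`
#'   returns the fixes data.frame with a parsed `timestamp`
#' @export
write_fixes_csv <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes_csv
#' @export
read_fixes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  d
}

#' Persist a strata set as CSV plus a JSON sidecar
#'
#' The flat CSV holds `stratum_id`, `cluster_id`, `is_used` and the
#' covariates; the sidecar records the design metadata a refit needs (the
#' matched ratio, availability radius, seed, covariate names and any
#' standardization constants).
#'
#' @param strata a `strata_set`
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`
#' @return `path`, invisibly
#' @export
write_strata_csv <- function(strata, path) {
  utils::write.csv(as.data.frame(strata), path, row.names = FALSE)
  std <- attr(strata, "standardization")
  jsonlite::write_json(
    list(
      covariates = attr(strata, "covariates"),
      M = attr(strata, "M"),
      radius_m = attr(strata, "radius_m"),
      seed = attr(strata, "seed"),
      standardization = if (is.null(std)) NULL else lapply(std, as.list)
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Write points or a polygon as GeoJSON
#'
#' Minimal GeoJSON FeatureCollection output (coordinates in the projected
#' meter grid of the analysis).
#'
#' @param coords matrix or data.frame with columns x, y
#' @param path file path
#' @param type `"points"` (one feature per row) or `"polygon"` (one closed
#'   ring)
#' @return `path`, invisibly
#' @export
write_geojson <- function(coords, path, type = c("points", "polygon")) {
  type <- match.arg(type)
  coords <- as.matrix(coords)
  features <- if (type == "points") {
    lapply(seq_len(nrow(coords)), function(i) {
      list(
        type = "Feature", properties = stats::setNames(list(), character(0)),
        geometry = list(type = "Point",
                        coordinates = c(coords[i, 1], coords[i, 2]))
      )
    })
  } else {
    ring <- rbind(coords, coords[1L, ])
    list(list(
      type = "Feature", properties = stats::setNames(list(), character(0)),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) c(ring[i, 1], ring[i, 2])))
      )
    ))
  }
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
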