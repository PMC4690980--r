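# Station colour-map export: GeoJSON (RFC 7946) point features plus a
# sidecar CSV, so campaign FUI maps can be drawn in any GIS tool.

#' Export a station FUI map as GeoJSON
#'
#' Writes one point feature per station with properties `station`, `fui`
#' (echoed to one decimal) and `source` (`handheld`, `rrs_derived` or
#' `corrected`), in longitude/latitude order per RFC 7946, plus a sidecar
#' CSV next to the GeoJSON. Records with invalid coordinates are reported
#' with a warning and skipped; the valid records are still written.
#'
#' @param records Data frame with columns `station`, `lat`, `lon`, `fui`,
#'   `source`.
#' @param path Output path for the GeoJSON file; the sidecar CSV gets the
#'   same name with a `.csv` extension.
#' @return Invisibly, a list with `path`, `csv_path`, `n_written`,
#'   `n_skipped`.
#' @export
export_station_map <- function(records, path) {
  need <- c("station", "lat", "lon", "fui", "source")
  if (!is.data.frame(records) || nrow(records) == 0 ||
      !all(need %in% names(records)))
    fu_stop(sprintf("records must be a non-empty data frame with columns %s",
                    paste(need, collapse = ", ")),
            "forelule_bad_columns")
  ok_src <- records$source %in% c("handheld", "rrs_derived", "corrected")
  ok_coord <- is.finite(records$lat) & is.finite(records$lon) &
    abs(records$lat) <= 90 & abs(records$lon) <= 180
  bad <- !(ok_src & ok_coord)
  if (any(bad))
    warning(sprintf("skipping %d record(s) with invalid coordinates or source: %s",
                    sum(bad), paste(records$station[bad], collapse = ", ")))
  recs <- records[!bad, , drop = FALSE]
  if (nrow(recs) == 0)
    fu_stop("no record with valid coordinates to write", "forelule_empty_map")
  features <- lapply(seq_len(nrow(recs)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(recs$lon[i], recs$lat[i])),
         properties = list(station = recs$station[i],
                           fui = round(recs$fui[i], 1),
                           source = recs$source[i]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  csv_path <- paste0(sub("\\.[^./]*$", "", path), ".csv")
  out <- data.frame(station = recs$station, lat = recs$lat, lon = recs$lon,
                    fui = round(recs$fui, 1), source = recs$source)
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  invisible(list(path = path, csv_path = csv_path,
                 n_written = nrow(recs), n_skipped = sum(bad)))
}

#' Read a station map back from GeoJSON
#'
#' Inverse of [export_station_map()]; round-trips station identifiers,
#' coordinates and FUI values exactly.
#'
#' @param path Path to a GeoJSON file written by [export_station_map()].
#' @return Data frame with columns `station`, `lat`, `lon`, `fui`, `source`.
#' @export
read_station_map <- function(path) {
  if (!file.exists(path))
    fu_stop(sprintf("map file not found: %s", path), "forelule_missing_file")
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    fu_stop("not a GeoJSON FeatureCollection", "forelule_bad_geojson")
  rows <- lapply(fc$features, function(f) {
    data.frame(station = f$properties$station,
               lat = as.numeric(f$geometry$coordinates[[2]]),
               lon = as.numeric(f$geometry$coordinates[[1]]),
               fui = as.numeric(f$properties$fui),
               source = f$properties$source)
  })
  do.call(rbind, rows)
}
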