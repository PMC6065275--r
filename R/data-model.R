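#' Core record types for tagged-fish data
#'
#' `depth_series()`, `geo_track()`, `fish_metadata()` and `movement_path()`
#' construct and validate the records the pipeline consumes: the 10-minute
#' depth log of a data storage tag, the daily geolocation track, release
#' metadata, and the derived daily bivariate log-movement path.
#'
#' @param fish_id single string identifying the fish.
#' @param timestamp `POSIXct` vector (UTC), nominally at 10-minute spacing.
#' @param depth numeric vector of depths in metres, non-negative.
#' @return An object of class `depth_series`: a list with `fish_id` and a
#'   `data` frame of `timestamp` and `depth`, sorted by time. Gaps in the
#'   10-minute raster are recorded in the `"gaps"` attribute.
#' @export
depth_series <- function(fish_id, timestamp, depth) {
  stopifnot(is.character(fish_id), length(fish_id) == 1L)
  if (length(timestamp) != length(depth)) {
    stop_usage("timestamp and depth must have equal length")
  }
  if (any(!is.finite(depth)) || any(depth < 0)) {
    bad <- which(!is.finite(depth) | depth < 0)[1L]
    stop_data("fish ", fish_id, ": negative or non-finite depth at row ", bad)
  }
  ord <- order(timestamp)
  timestamp <- timestamp[ord]
  depth <- depth[ord]
  dt <- diff(as.numeric(timestamp))
  if (any(dt == 0)) {
    stop_data("fish ", fish_id, ": duplicated (non-monotone) timestamps")
  }
  out <- list(fish_id = fish_id,
              data = data.frame(timestamp = timestamp, depth = depth))
  attr(out, "gaps") <- sum(dt != 600)
  class(out) <- "depth_series"
  out
}

#' @rdname depth_series
#' @param date `Date` vector, one position per day.
#' @param lat,lon decimal degrees (WGS84).
#' @return `geo_track()`: an object of class `geo_track`, a list with
#'   `fish_id` and a `data` frame of `date`, `lat`, `lon` sorted by date.
#' @export
geo_track <- function(fish_id, date, lat, lon) {
  stopifnot(is.character(fish_id), length(fish_id) == 1L)
  if (length(date) != length(lat) || length(lat) != length(lon)) {
    stop_usage("date, lat and lon must have equal length")
  }
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90)) {
    stop_data("fish ", fish_id, ": latitude outside [-90, 90]")
  }
  if (any(!is.finite(lon)) || any(lon < -180) || any(lon > 180)) {
    stop_data("fish ", fish_id, ": longitude outside [-180, 180]")
  }
  ord <- order(date)
  date <- date[ord]
  if (anyDuplicated(date)) {
    stop_data("fish ", fish_id, ": duplicate dates in geolocation track")
  }
  out <- list(fish_id = fish_id,
              data = data.frame(date = date, lat = lat[ord], lon = lon[ord]))
  class(out) <- "geo_track"
  out
}

#' @rdname depth_series
#' @param species `"cod"` or `"plaice"`.
#' @param substock substock label (release-location grouping).
#' @param release_date,end_date `Date`s with `release_date < end_date`.
#' @return `fish_metadata()`: an object of class `fish_metadata`.
#' @export
fish_metadata <- function(fish_id, species, substock, release_date, end_date) {
  species <- match.arg(species, c("cod", "plaice"))
  if (!(release_date < end_date)) {
    stop_data("fish ", fish_id, ": release_date must precede end_date")
  }
  structure(list(fish_id = fish_id, species = species, substock = substock,
                 release_date = release_date, end_date = end_date),
            class = "fish_metadata")
}

#' @rdname depth_series
#' @param h,v natural-log daily horizontal / vertical movement (log m/day).
#' @return `movement_path()`: an object of class `movement_path`, a list with
#'   `fish_id`, `species`, `substock` and per-day vectors `date`, `lat`,
#'   `lon`, `h`, `v` of common length `T`.
#' @export
movement_path <- function(fish_id, species, substock, date, lat, lon, h, v) {
  n <- length(date)
  if (!all(lengths(list(lat, lon, h, v)) == n)) {
    stop_usage("per-day vectors must share one length")
  }
  if (any(!is.finite(h)) || any(!is.finite(v))) {
    stop_data("fish ", fish_id, ": non-finite log-movement values")
  }
  structure(list(fish_id = fish_id, species = species, substock = substock,
                 date = date, lat = lat, lon = lon, h = h, v = v),
            class = "movement_path")
}

#' @export
print.movement_path <- function(x, ...) {
  cat(sprintf("<movement_path %s (%s/%s): T = %d days, %s .. %s>\n",
              x$fish_id, x$species, x$substock, length(x$date),
              format(min(x$date)), format(max(x$date))))
  invisible(x)
}

path_length <- function(path) length(path$date)

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_format(path, ": missing column(s) ", paste(miss, collapse = ", "))
  }
}

#' Read tag CSV files
#'
#' Readers for the three plain-text input formats: 10-minute depth logs
#' (`fish_id,timestamp,depth_m`, ISO-8601 UTC timestamps), daily geolocation
#' tracks (`fish_id,date,lat,lon`) and release metadata
#' (`fish_id,species,substock,release_date,end_date`). Rows may arrive in any
#' order; records are returned sorted by time. Malformed rows raise errors
#' that name the offending data line.
#'
#' @param path CSV file path.
#' @return `read_depth_csv()`: named list of [depth_series()] objects, one
#'   per `fish_id`.
#' @export
read_depth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("fish_id", "timestamp", "depth_m"), path)
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (anyNA(ts)) {
    stop_data(path, ": unparseable timestamp on data row(s) ",
              paste(which(is.na(ts)), collapse = ", "))
  }
  if (any(!is.finite(df$depth_m) | df$depth_m < 0)) {
    bad <- which(!is.finite(df$depth_m) | df$depth_m < 0)
    stop_data(path, ": negative or missing depth on data row(s) ",
              paste(bad, collapse = ", "))
  }
  ids <- unique(df$fish_id)
  out <- lapply(ids, function(id) {
    i <- df$fish_id == id
    depth_series(id, ts[i], df$depth_m[i])
  })
  setNames(out, ids)
}

#' @rdname read_depth_csv
#' @return `read_track_csv()`: named list of [geo_track()] objects.
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("fish_id", "date", "lat", "lon"), path)
  d <- as.Date(df$date)
  if (anyNA(d)) {
    stop_data(path, ": unparseable date on data row(s) ",
              paste(which(is.na(d)), collapse = ", "))
  }
  ids <- unique(df$fish_id)
  out <- lapply(ids, function(id) {
    i <- df$fish_id == id
    geo_track(id, d[i], df$lat[i], df$lon[i])
  })
  setNames(out, ids)
}

#' @rdname read_depth_csv
#' @return `read_metadata_csv()`: named list of [fish_metadata()] objects.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("fish_id", "species", "substock", "release_date",
                      "end_date"), path)
  out <- lapply(seq_len(nrow(df)), function(i) {
    fish_metadata(df$fish_id[i], df$species[i], df$substock[i],
                  as.Date(df$release_date[i]), as.Date(df$end_date[i]))
  })
  setNames(out, df$fish_id)
}

#' Write and read decoded state sequences
#'
#' `write_state_csv()` exports one row per fish-day with columns
#' `fish_id,date,lat,lon,p_resident,state,uncertain`, the package's analogue
#' of a deposited state-sequence table. A day is `uncertain` when the
#' winning state's smoothed probability falls below the classification
#' threshold (0.85 by default in [allocate_states()]). `read_state_csv()`
#' reads the same format back.
#'
#' @param fits list of fitted models from [fit_map()] / [run_two_stage()].
#' @param path output CSV path.
#' @return `write_state_csv()` invisibly returns the written data frame.
#' @export
write_state_csv <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    if (is.null(f$states)) {
      stop_state("fit for fish ", f$fish_id, " has no decoded states")
    }
    data.frame(fish_id = f$fish_id,
               date = as.character(f$path$date),
               lat = f$path$lat, lon = f$path$lon,
               p_resident = f$smoothed[, "R"],
               state = f$states,
               uncertain = f$uncertain)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @rdname write_state_csv
#' @return `read_state_csv()`: data frame with typed columns.
#' @export
read_state_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("fish_id", "date", "lat", "lon", "p_resident", "state",
                      "uncertain"), path)
  df$date <- as.Date(df$date)
  df$uncertain <- as.logical(df$uncertain)
  df
}

#' Write a run manifest sidecar
#'
#' Records the package version, seed and a hash of the configuration next to
#' pipeline outputs so any result file can be traced to the run that made it.
#'
#' @param path file to write.
#' @param config configuration list (hashed into the manifest).
#' @param seed integer seed of the run.
#' @return invisibly, the manifest lines.
#' @export
write_manifest <- function(path, config, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  lines <- c(paste0("package: fishHMM ",
                    as.character(utils::packageVersion("fishHMM"))),
             paste0("seed: ", seed),
             paste0("config_md5: ", unname(tools::md5sum(tmp))))
  writeLines(lines, path)
  invisible(lines)
}

#' Write and read movement-path CSV files
#'
#' Columns `fish_id,species,substock,date,lat,lon,h_log,v_log`; one row per
#' fish-day of the preprocessed bivariate log-movement series.
#'
#' @param paths list of [movement_path()] objects.
#' @param path CSV file path.
#' @return `write_movement_csv()` invisibly returns the data frame written.
#' @export
write_movement_csv <- function(paths, path) {
  rows <- lapply(paths, function(p) {
    data.frame(fish_id = p$fish_id, species = p$species,
               substock = p$substock, date = as.character(p$date),
               lat = p$lat, lon = p$lon, h_log = p$h, v_log = p$v)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @rdname write_movement_csv
#' @return `read_movement_csv()`: named list of [movement_path()] objects.
#' @export
read_movement_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("fish_id", "species", "substock", "date", "lat", "lon",
                      "h_log", "v_log"), path)
  df$date <- as.Date(df$date)
  ids <- unique(df$fish_id)
  out <- lapply(ids, function(id) {
    i <- which(df$fish_id == id)
    i <- i[order(df$date[i])]
    movement_path(id, df$species[i[1]], df$substock[i[1]], df$date[i],
                  df$lat[i], df$lon[i], df$h_log[i], df$v_log[i])
  })
  setNames(out, ids)
}
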