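#' Preprocessing configuration
#'
#' Settings used to turn raw tag records into analysis-ready movement paths:
#' the first `trim_head_days` and last `trim_tail_days` of each series are
#' discarded (release and recapture artefacts), fish with fewer than
#' `min_days` remaining days are rejected, and raw daily movements below
#' `zero_floor` metres/day are raised to the floor before the natural-log
#' transform so logs stay finite.
#'
#' @param trim_head_days days dropped at the start (default 14).
#' @param trim_tail_days days dropped at the end (default 1).
#' @param min_days minimum accepted path length after trimming (default 40).
#' @param zero_floor floor on raw daily movement, m/day (default 1).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(trim_head_days = 14L, trim_tail_days = 1L,
                              min_days = 40L, zero_floor = 1) {
  stopifnot(trim_head_days >= 0, trim_tail_days >= 0, min_days >= 1,
            zero_floor > 0)
  structure(list(trim_head_days = as.integer(trim_head_days),
                 trim_tail_days = as.integer(trim_tail_days),
                 min_days = as.integer(min_days),
                 zero_floor = zero_floor),
            class = "preprocess_config")
}

#' Daily net vertical movement from a depth series
#'
#' For each complete day (all `samples_per_day` 10-minute records present)
#' sums the absolute differences between consecutive within-day depth
#' samples, giving net vertical movement in metres per day. Incomplete days
#' are excluded from the output and reported in the `"incomplete_days"`
#' attribute.
#'
#' @param d a [depth_series()].
#' @param samples_per_day expected samples per UTC day (default 144).
#' @return data frame with columns `date` and `vertical_m`, one row per
#'   complete day; attribute `incomplete_days` lists excluded dates.
#' @export
daily_vertical_movement <- function(d, samples_per_day = 144L) {
  stopifnot(inherits(d, "depth_series"))
  day <- as.Date(d$data$timestamp, tz = "UTC")
  sp <- split(d$data$depth, day)
  n <- lengths(sp)
  complete <- n == samples_per_day
  vals <- vapply(sp[complete], function(z) sum(abs(diff(z))), numeric(1))
  out <- data.frame(date = as.Date(names(sp)[complete]),
                    vertical_m = unname(vals))
  attr(out, "incomplete_days") <- as.Date(names(sp)[!complete])
  out
}

#' Great-circle distance in metres
#'
#' Haversine distance on a sphere of radius 6,371 km, vectorised over
#' coordinate vectors.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (WGS84).
#' @return distances in metres.
#' @export
great_circle_m <- function(lat1, lon1, lat2, lon2) {
  for (z in list(lat1, lat2)) {
    if (any(!is.finite(z)) || any(abs(z) > 90)) {
      stop_data("latitude outside [-90, 90]")
    }
  }
  for (z in list(lon1, lon2)) {
    if (any(!is.finite(z)) || any(abs(z) > 180)) {
      stop_data("longitude outside [-180, 180]")
    }
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

#' Daily step lengths from a geolocation track
#'
#' Great-circle distance between consecutive daily positions; each step is
#' stamped to the earlier of the two days, so day *k*'s step describes the
#' same 24 h as day *k*'s vertical movement. Steps across date gaps larger
#' than one day are excluded and reported in the `"gap_dates"` attribute.
#'
#' @param t a [geo_track()].
#' @return data frame with columns `date` and `step_m`.
#' @export
daily_step_lengths <- function(t) {
  stopifnot(inherits(t, "geo_track"))
  df <- t$data
  n <- nrow(df)
  if (n < 2) stop_usage("track needs at least two daily positions")
  gap <- as.integer(diff(df$date))
  keep <- gap == 1L
  step <- great_circle_m(df$lat[-n], df$lon[-n], df$lat[-1], df$lon[-1])
  out <- data.frame(date = df$date[-n][keep], step_m = step[keep])
  attr(out, "gap_dates") <- df$date[-n][!keep]
  out
}

#' Build a bivariate log-movement path for one fish
#'
#' Aligns the complete-depth days with the step-length days, trims the head
#' and tail of the series, floors raw values at `cfg$zero_floor` m/day and
#' takes natural logs, producing the daily bivariate series (h, v) the HMM
#' consumes. Fish whose depth record contains incomplete days, or whose
#' aligned trimmed series is shorter than `cfg$min_days`, are rejected.
#'
#' @param d a [depth_series()].
#' @param t a [geo_track()] for the same fish.
#' @param meta a [fish_metadata()] for the same fish.
#' @param cfg a [preprocess_config()].
#' @return a [movement_path()], or a `path_rejection` object with fields
#'   `fish_id` and `reason` (`"too_short"` or `"incomplete_depth"`).
#' @export
build_movement_path <- function(d, t, meta, cfg = preprocess_config()) {
  if (d$fish_id != t$fish_id || d$fish_id != meta$fish_id) {
    stop_usage("fish ids disagree: ", d$fish_id, " / ", t$fish_id, " / ",
               meta$fish_id)
  }
  vert <- daily_vertical_movement(d)
  if (length(attr(vert, "incomplete_days")) > 0) {
    return(structure(list(fish_id = d$fish_id, reason = "incomplete_depth"),
                     class = "path_rejection"))
  }
  steps <- daily_step_lengths(t)
  df <- merge(vert, steps, by = "date")
  df <- df[order(df$date), , drop = FALSE]
  n <- nrow(df)
  keep <- seq_len(n) > cfg$trim_head_days & seq_len(n) <= n - cfg$trim_tail_days
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < cfg$min_days) {
    return(structure(list(fish_id = d$fish_id, reason = "too_short"),
                     class = "path_rejection"))
  }
  pos <- t$data[match(df$date, t$data$date), ]
  movement_path(d$fish_id, meta$species, meta$substock, df$date,
                pos$lat, pos$lon,
                h = log(pmax(df$step_m, cfg$zero_floor)),
                v = log(pmax(df$vertical_m, cfg$zero_floor)))
}

#' @export
print.path_rejection <- function(x, ...) {
  cat(sprintf("<path_rejection %s: %s>\n", x$fish_id, x$reason))
  invisible(x)
}
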