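#' Week of year
#'
#' Week w = floor((day_of_year - 1) / 7) + 1, counted from the 1st of
#' January and capped at 52 (days 365/366 join week 52). Independent of
#' year.
#'
#' @param dates a `Date` vector.
#' @return integer weeks in 1..52.
#' @export
week_of_year <- function(dates) {
  yd <- as.POSIXlt(dates)$yday + 1L
  pmin((yd - 1L) %/% 7L + 1L, 52L)
}

fit_day_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(fish_id = f$fish_id, species = f$species,
               substock = f$substock, date = f$path$date,
               week = week_of_year(f$path$date),
               lat = f$path$lat, lon = f$path$lon,
               p_R = f$smoothed[, "R"], state = f$states,
               h = f$path$h, v = f$path$v)
  }))
}

#' Weekly state timing across the cohort
#'
#' For every week of the year: the mean over all fish-days of the smoothed
#' resident probability, its standard error (across-fish SE of per-fish
#' weekly means; 0 when at most one fish contributes), the proportion of
#' fish-days allocated to the resident state, and the number of fish at
#' liberty. Weeks with no fish are emitted with `n_fish = 0` and `NA`
#' summaries.
#'
#' @param fits list of decoded `fitted_hmm` objects.
#' @return data frame with one row per week 1..52: `week`,
#'   `mean_p_resident`, `se`, `prop_resident`, `n_fish`, `n_days`.
#' @export
weekly_state_summary <- function(fits) {
  days <- fit_day_table(fits)
  out <- data.frame(week = 1:52, mean_p_resident = NA_real_, se = NA_real_,
                    prop_resident = NA_real_, n_fish = 0L, n_days = 0L)
  for (w in 1:52) {
    d <- days[days$week == w, ]
    if (nrow(d) == 0) next
    out$mean_p_resident[w] <- mean(d$p_R)
    out$prop_resident[w] <- mean(d$state == "R")
    fish_means <- tapply(d$p_R, d$fish_id, mean)
    nf <- length(fish_means)
    out$n_fish[w] <- nf
    out$n_days[w] <- nrow(d)
    out$se[w] <- if (nf > 1) sd(fish_means) / sqrt(nf) else 0
  }
  out
}

#' State-dominant seasonal windows
#'
#' Maximal runs of consecutive weeks whose cohort-mean probability of the
#' requested state strictly exceeds `threshold` (default 0.5). Runs may
#' wrap across the year boundary (week 52 into week 1), as winter migration
#' windows do.
#'
#' @param summary output of [weekly_state_summary()].
#' @param state `"R"` or `"M"`.
#' @param threshold dominance threshold (strict inequality).
#' @return data frame of windows: `start_week`, `end_week`, `n_weeks`.
#'   `start_week > end_week` marks a wrapped window. Zero rows when no week
#'   qualifies.
#' @export
state_dominant_windows <- function(summary, state = c("R", "M"),
                                   threshold = 0.5) {
  state <- match.arg(state)
  p <- summary$mean_p_resident[order(summary$week)]
  if (state == "M") p <- 1 - p
  ok <- !is.na(p) & p > threshold
  empty <- data.frame(start_week = integer(0), end_week = integer(0),
                      n_weeks = integer(0))
  if (!any(ok)) return(empty)
  if (all(ok)) {
    return(data.frame(start_week = 1L, end_week = 52L, n_weeks = 52L))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  win <- data.frame(start_week = starts[r$values],
                    end_week = ends[r$values])
  # merge a run touching week 52 with one starting at week 1
  if (nrow(win) > 1 && win$start_week[1] == 1L &&
      win$end_week[nrow(win)] == 52L) {
    win$end_week[nrow(win)] <- win$end_week[1]
    win <- win[-1, , drop = FALSE]
  }
  win$n_weeks <- ifelse(win$end_week >= win$start_week,
                        win$end_week - win$start_week + 1L,
                        52L - win$start_week + 1L + win$end_week)
  rownames(win) <- NULL
  win
}

weeks_in_window <- function(start_week, end_week) {
  if (end_week >= start_week) start_week:end_week
  else c(start_week:52L, 1L:end_week)
}

# ---- equal-area projection -------------------------------------------------
# Lambert azimuthal equal-area, spherical form, centred on (lat0, lon0).

laea_project <- function(lat, lon, lat0, lon0, R = 6371000) {
  phi <- lat * pi / 180; lam <- lon * pi / 180
  phi0 <- lat0 * pi / 180; lam0 <- lon0 * pi / 180
  dl <- lam - lam0
  kp <- sqrt(2 / (1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)))
  list(x = R * kp * cos(phi) * sin(dl),
       y = R * kp * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl)))
}

laea_inverse <- function(x, y, lat0, lon0, R = 6371000) {
  phi0 <- lat0 * pi / 180; lam0 <- lon0 * pi / 180
  rho <- sqrt(x^2 + y^2)
  cc <- 2 * asin(pmin(1, rho / (2 * R)))
  phi <- ifelse(rho == 0, phi0,
                asin(cos(cc) * sin(phi0) + y * sin(cc) * cos(phi0) / rho))
  lam <- lam0 + atan2(x * sin(cc),
                      rho * cos(phi0) * cos(cc) - y * sin(phi0) * sin(cc))
  list(lat = phi * 180 / pi, lon = lam * 180 / pi)
}

#' Utilization grid of state-classified fish-days
#'
#' Pools the daily geolocations of all fish-days whose week falls in
#' `weeks` and whose allocated state equals `state`, projects them with a
#' Lambert azimuthal equal-area projection centred on their centroid, and
#' bins them into square grid cells of side `cell_km`. Counts are
#' conserved: the grid total equals the number of matching fish-days.
#'
#' @param fits list of decoded `fitted_hmm` objects.
#' @param weeks integer vector of weeks of the year defining the window
#'   (see [weeks_in_window()] / [state_dominant_windows()]).
#' @param state `"R"` or `"M"`.
#' @param cell_km cell side in km (default 5; set
#'   `sqrt(5)` for a literal 5 km^2 cell area).
#' @return a `utilization_grid`: data frame of `cell_x`, `cell_y` (cell
#'   indices), `lon_center`, `lat_center`, `count`; attributes `cell_km`,
#'   `lat0`, `lon0`, `total`, `state`, `weeks`.
#' @export
utilization_grid <- function(fits, weeks, state = c("R", "M"), cell_km = 5) {
  state <- match.arg(state)
  if (length(weeks) == 0) stop_usage("empty week window")
  days <- fit_day_table(fits)
  days <- days[days$week %in% weeks & days$state == state, ]
  if (nrow(days) == 0) {
    out <- data.frame(cell_x = integer(0), cell_y = integer(0),
                      lon_center = numeric(0), lat_center = numeric(0),
                      count = integer(0))
    attr(out, "total") <- 0L
    class(out) <- c("utilization_grid", "data.frame")
    return(out)
  }
  lat0 <- mean(days$lat); lon0 <- mean(days$lon)
  xy <- laea_project(days$lat, days$lon, lat0, lon0)
  cell_m <- cell_km * 1000
  ix <- floor(xy$x / cell_m)
  iy <- floor(xy$y / cell_m)
  key <- paste(ix, iy)
  tab <- table(key)
  first <- !duplicated(key)
  cells <- data.frame(cell_x = ix[first], cell_y = iy[first],
                      key = key[first])
  cells$count <- as.integer(tab[cells$key])
  ctr <- laea_inverse((cells$cell_x + 0.5) * cell_m,
                      (cells$cell_y + 0.5) * cell_m, lat0, lon0)
  out <- data.frame(cell_x = cells$cell_x, cell_y = cells$cell_y,
                    lon_center = ctr$lon, lat_center = ctr$lat,
                    count = cells$count)
  out <- out[order(out$cell_x, out$cell_y), ]
  rownames(out) <- NULL
  attr(out, "cell_km") <- cell_km
  attr(out, "lat0") <- lat0
  attr(out, "lon0") <- lon0
  attr(out, "total") <- sum(out$count)
  attr(out, "state") <- state
  attr(out, "weeks") <- weeks
  class(out) <- c("utilization_grid", "data.frame")
  out
}

#' State-dependent movement rates by substock
#'
#' For each fish and state, the arithmetic mean of the raw (back-
#' transformed) daily movement over the days allocated to that state; then
#' the unweighted mean across fish within each species x substock.
#' Horizontal rates are reported in km/day, vertical in m/day. A fish with
#' no days in a state contributes nothing to that cell.
#'
#' @param fits list of decoded `fitted_hmm` objects.
#' @return data frame: `species`, `substock`, `state`,
#'   `horizontal_km_day`, `vertical_m_day`, `n_fish`.
#' @export
substock_rates <- function(fits) {
  per_fish <- do.call(rbind, lapply(fits, function(f) {
    do.call(rbind, lapply(c("R", "M"), function(s) {
      i <- f$states == s
      if (!any(i)) return(NULL)
      data.frame(species = f$species, substock = f$substock,
                 fish_id = f$fish_id, state = s,
                 h_m_day = mean(exp(f$path$h[i])),
                 v_m_day = mean(exp(f$path$v[i])))
    }))
  }))
  if (is.null(per_fish)) stop_state("no decoded days to summarise")
  key <- interaction(per_fish$species, per_fish$substock, per_fish$state,
                     drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    d <- per_fish[key == k, ]
    data.frame(species = d$species[1], substock = d$substock[1],
               state = d$state[1],
               horizontal_km_day = mean(d$h_m_day) / 1000,
               vertical_m_day = mean(d$v_m_day),
               n_fish = nrow(d))
  }))
  out[order(out$species, out$substock, out$state), ]
}

#' Dwell-time extraction and geometric goodness of fit
#'
#' Extracts per-state run lengths from the decoded sequences, flags runs
#' touching either end of a series as censored, fits a geometric
#' distribution to the uncensored runs of each state
#' (`p_hat = 1/mean(run length)`), and reports a chi-square goodness-of-fit
#' test on run lengths binned so that every expected count is at least 5.
#' Under a first-order Markov chain the dwell times are necessarily
#' geometric, so a non-rejecting test says the decoded dynamics are
#' consistent with the model.
#'
#' @param fits list of decoded `fitted_hmm` objects.
#' @return list with `runs` (data frame `fish_id`, `state`, `length`,
#'   `censored`) and `fit` (per state: `n_runs`, `n_uncensored`,
#'   `mean_dwell`, `p_hat`, `chisq`, `df`, `p_value`, `degenerate`).
#' @export
dwell_time_analysis <- function(fits) {
  runs <- do.call(rbind, lapply(fits, function(f) {
    r <- rle(f$states)
    n <- length(r$lengths)
    cens <- rep(FALSE, n)
    cens[c(1L, n)] <- TRUE    # touches a series end
    data.frame(fish_id = f$fish_id, state = r$values,
               length = r$lengths, censored = cens)
  }))
  fit <- do.call(rbind, lapply(c("R", "M"), function(s) {
    d <- runs[runs$state == s, ]
    u <- d$length[!d$censored]
    row <- data.frame(state = s, n_runs = nrow(d), n_uncensored = length(u),
                      mean_dwell = NA_real_, p_hat = NA_real_,
                      chisq = NA_real_, df = NA_integer_,
                      p_value = NA_real_, degenerate = TRUE)
    if (length(u) == 0) return(row)
    row$mean_dwell <- mean(u)
    row$p_hat <- 1 / mean(u)
    gof <- geometric_gof(u, row$p_hat)
    if (!is.null(gof)) {
      row$chisq <- gof$chisq; row$df <- gof$df; row$p_value <- gof$p_value
      row$degenerate <- FALSE
    }
    row
  }))
  list(runs = runs, fit = fit)
}

# chi-square GOF of run lengths against Geometric(p) (support 1, 2, ...),
# greedily binning consecutive lengths until each expected count >= 5.
geometric_gof <- function(lengths, p, min_expected = 5) {
  n <- length(lengths)
  kmax <- max(lengths)
  probs <- p * (1 - p)^(seq_len(kmax) - 1)
  probs <- c(probs, 1 - sum(probs))          # tail bin > kmax
  obs <- c(tabulate(lengths, nbins = kmax), 0)
  exp_counts <- n * probs
  # greedy merge from the left, then fold remaining small tail into last bin
  bins_o <- numeric(0); bins_e <- numeric(0)
  co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + exp_counts[i]
    if (ce >= min_expected) {
      bins_o <- c(bins_o, co); bins_e <- c(bins_e, ce)
      co <- 0; ce <- 0
    }
  }
  if (ce > 0) {
    bins_o[length(bins_o)] <- bins_o[length(bins_o)] + co
    bins_e[length(bins_e)] <- bins_e[length(bins_e)] + ce
  }
  df <- length(bins_o) - 2L   # one constraint for n, one for estimated p
  if (df < 1) return(NULL)
  chisq <- sum((bins_o - bins_e)^2 / bins_e)
  list(chisq = chisq, df = df, p_value = pchisq(chisq, df, lower.tail = FALSE))
}
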