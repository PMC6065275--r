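#' Species specification for synthetic cohorts
#'
#' Hyper-distributions from which each simulated fish draws its own HMM
#' parameters: state means mu_jd are Gaussian around `mu_mean` with
#' between-fish standard deviation `mu_sd`; emission standard deviations
#' and correlations are uniform on `sigma_range` / `rho_range`; self-
#' transition probabilities are Beta(`gamma_alpha`, `gamma_beta`) draws
#' (or fixed at `gamma_fixed`). Default mean movement rates are anchored
#' to the scale of published state-dependent rates for North Sea cod and
#' plaice (resident horizontal of order 6.5-9 km/day, migrating 13-14
#' km/day; vertical tens vs. low hundreds of m/day).
#'
#' With `seasonal = TRUE` the transition matrix is calendar-driven: inside
#' `resident_weeks` the chain strongly favours R
#' (`gamma_seasonal["in_RR"]`, `gamma_seasonal["in_MM"]`), outside it
#' favours M — the simplest mechanism that produces annual state cycles.
#'
#' @param species `"cod"` or `"plaice"` (sets default movement scales).
#' @param mu_mean list with elements `R` and `M`, each `c(H, V)` on the
#'   log m/day scale; `NULL` for the species default.
#' @param mu_sd between-fish SD of the state means (log scale).
#' @param sigma_range,rho_range uniform ranges for emission SDs and
#'   correlations.
#' @param gamma_alpha,gamma_beta Beta hyper-parameters for self-transitions.
#' @param gamma_fixed optional fixed self-transition probability (overrides
#'   the Beta draw; scalar or `c(RR, MM)`).
#' @param seasonal logical; calendar-driven transition matrices.
#' @param resident_weeks weeks of the year in which residency is favoured
#'   (default: cod 22-44, roughly June-October; plaice 13-39, roughly
#'   April-September).
#' @param gamma_seasonal named vector `in_RR`, `in_MM`, `out_RR`, `out_MM`.
#' @return a `species_spec` object.
#' @export
species_spec <- function(species = c("cod", "plaice"), mu_mean = NULL,
                         mu_sd = 0.15, sigma_range = c(0.4, 0.6),
                         rho_range = c(0, 0.3), gamma_alpha = 99,
                         gamma_beta = 1, gamma_fixed = NULL,
                         seasonal = FALSE, resident_weeks = NULL,
                         gamma_seasonal = c(in_RR = 0.995, in_MM = 0.95,
                                            out_RR = 0.95, out_MM = 0.995)) {
  species <- match.arg(species)
  if (is.null(mu_mean)) {
    mu_mean <- if (species == "cod") {
      list(R = c(log(9200), log(31.5)), M = c(log(13900), log(158.3)))
    } else {
      list(R = c(log(6500), log(23)), M = c(log(13900), log(120)))
    }
  }
  if (!(mu_mean$R[1] < mu_mean$M[1])) {
    stop_usage("resident horizontal hyper-mean must be below migrating")
  }
  if (is.null(resident_weeks)) {
    resident_weeks <- if (species == "cod") 22:44 else 13:39
  }
  structure(list(species = species, mu_mean = mu_mean, mu_sd = mu_sd,
                 sigma_range = sigma_range, rho_range = rho_range,
                 gamma_alpha = gamma_alpha, gamma_beta = gamma_beta,
                 gamma_fixed = gamma_fixed, seasonal = isTRUE(seasonal),
                 resident_weeks = as.integer(resident_weeks),
                 gamma_seasonal = gamma_seasonal),
            class = "species_spec")
}

#' Cohort specification
#'
#' Sizes and track-length ranges of a simulated cohort, mixing data-rich
#' (long) and data-poor (short) individuals. Defaults mirror a cohort of
#' 34 data-rich and 73 data-poor fish.
#'
#' @param n_rich,n_poor numbers of long and short tracks.
#' @param t_rich,t_poor `c(min, max)` path lengths in days.
#' @param seed cohort seed; every fish derives its own seed from it.
#' @param start_dates `c(earliest, latest)` release window (`Date`).
#' @param origin `c(lat, lon)` centre of the release region.
#' @param origin_jitter_deg half-width of the release box in degrees.
#' @param substocks substock labels assigned round-robin.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_rich = 34L, n_poor = 73L, t_rich = c(200L, 600L),
                        t_poor = c(40L, 80L), seed = 1L,
                        start_dates = as.Date(c("2003-01-01", "2004-12-31")),
                        origin = c(54, 2), origin_jitter_deg = 1,
                        substocks = "sim") {
  stopifnot(n_rich + n_poor >= 1, t_poor[1] >= 40, t_rich[2] <= 1000)
  structure(list(n_rich = as.integer(n_rich), n_poor = as.integer(n_poor),
                 t_rich = as.integer(t_rich), t_poor = as.integer(t_poor),
                 seed = as.integer(seed), start_dates = start_dates,
                 origin = origin, origin_jitter_deg = origin_jitter_deg,
                 substocks = substocks),
            class = "cohort_spec")
}

draw_fish_params <- function(sp) {
  mu <- matrix(c(rnorm(2, sp$mu_mean$R, sp$mu_sd),
                 rnorm(2, sp$mu_mean$M, sp$mu_sd)), 2, 2, byrow = TRUE)
  if (mu[1, 1] >= mu[2, 1]) {   # keep resident slower on H
    mid <- (mu[1, 1] + mu[2, 1]) / 2
    mu[1, 1] <- mid - sp$mu_sd / 2
    mu[2, 1] <- mid + sp$mu_sd / 2
  }
  sg <- matrix(runif(4, sp$sigma_range[1], sp$sigma_range[2]), 2, 2)
  rho <- runif(2, sp$rho_range[1], sp$rho_range[2])
  g <- if (!is.null(sp$gamma_fixed)) {
    rep(sp$gamma_fixed, length.out = 2)
  } else {
    pmax(pmin(rbeta(2, sp$gamma_alpha, sp$gamma_beta), 0.9995), 1e-4)
  }
  hmm_parameters(g[1], g[2], mu, sg, rho)
}

sim_states <- function(p, dates, sp, s1 = NULL) {
  T <- length(dates)
  s <- integer(T)
  s[1] <- if (is.null(s1)) sample(1:2, 1) else match(s1, c("R", "M"))
  if (sp$seasonal) {
    wk <- week_of_year(dates)
    inres <- wk %in% sp$resident_weeks
    gRR <- ifelse(inres, sp$gamma_seasonal[["in_RR"]],
                  sp$gamma_seasonal[["out_RR"]])
    gMM <- ifelse(inres, sp$gamma_seasonal[["in_MM"]],
                  sp$gamma_seasonal[["out_MM"]])
  } else {
    gRR <- rep(p$gamma_RR, T)
    gMM <- rep(p$gamma_MM, T)
  }
  if (T >= 2) {
    u <- runif(T - 1)
    for (t in 2:T) {
      stay <- if (s[t - 1] == 1) gRR[t - 1] else gMM[t - 1]
      s[t] <- if (u[t - 1] < stay) s[t - 1] else 3L - s[t - 1]
    }
  }
  c("R", "M")[s]
}

sim_emissions <- function(p, states) {
  T <- length(states)
  z1 <- rnorm(T); z2 <- rnorm(T)
  j <- match(states, c("R", "M"))
  rho <- unname(p$rho[j])
  h <- p$mu[cbind(j, 1)] + p$sigma[cbind(j, 1)] * z1
  v <- p$mu[cbind(j, 2)] +
    p$sigma[cbind(j, 2)] * (rho * z1 + sqrt(1 - rho^2) * z2)
  list(h = h, v = v)
}

sim_positions <- function(h, states, origin) {
  T <- length(h)
  step <- exp(h)
  lat <- numeric(T + 1); lon <- numeric(T + 1)
  lat[1] <- origin[1]; lon[1] <- origin[2]
  theta <- runif(1, 0, 2 * pi)
  dtheta <- rnorm(T, 0, 0.3)
  utheta <- runif(T, 0, 2 * pi)
  for (t in 1:T) {
    theta <- if (states[t] == "R") utheta[t] else theta + dtheta[t]
    # exact great-circle displacement so step lengths invert to exp(h)
    p <- geosphere::destPoint(c(lon[t], lat[t]), theta * 180 / pi, step[t],
                              r = 6371000)
    lon[t + 1] <- p[1, 1]
    lat[t + 1] <- p[1, 2]
  }
  list(lat = lat, lon = lon)
}

#' Simulate one tagged fish
#'
#' Draws per-fish parameters from the species hyper-distributions,
#' simulates the latent state chain (S_1 uniform unless `s1` is given) and
#' the state-dependent bivariate log-movements, and dead-reckons a daily
#' geolocation track whose step lengths reproduce exp(h) exactly to within
#' the tangent-plane approximation. Fully deterministic given `seed`.
#'
#' @param sp a [species_spec()].
#' @param T path length in days.
#' @param seed integer seed for this fish.
#' @param start_date first day of the path.
#' @param origin `c(lat, lon)` of the first position.
#' @param substock substock label for the fish.
#' @param fish_id identifier (default derived from the seed).
#' @param s1 optional forced initial state (`"R"` or `"M"`).
#' @return a `simulated_fish`: list with `path` (a [movement_path()]),
#'   true `states`, true `params` ([hmm_parameters()]), and `track`
#'   (a [geo_track()] with T + 1 daily positions).
#' @export
simulate_individual <- function(sp, T, seed,
                                start_date = as.Date("2004-01-01"),
                                origin = c(54, 2), substock = "sim",
                                fish_id = sprintf("sim%06d", seed),
                                s1 = NULL) {
  stopifnot(T >= 1)
  dates <- start_date + seq_len(T) - 1L
  with_seed(seed, {
    p <- draw_fish_params(sp)
    states <- sim_states(p, dates, sp, s1 = s1)
    em <- sim_emissions(p, states)
    pos <- sim_positions(em$h, states, origin)
    path <- movement_path(fish_id, sp$species, substock, dates,
                          pos$lat[seq_len(T)], pos$lon[seq_len(T)],
                          em$h, em$v)
    track <- geo_track(fish_id, c(dates, dates[T] + 1L), pos$lat, pos$lon)
    structure(list(path = path, states = states, params = p, track = track,
                   seed = seed),
              class = "simulated_fish")
  })
}

#' Re-simulate a geolocation track for a simulated fish
#'
#' Dead-reckons daily positions from `origin` so that the great-circle step
#' of day t equals exp(h_t) metres: headings are drawn uniformly on
#' resident days and as a correlated random walk on migrating days.
#'
#' @param fish a `simulated_fish`.
#' @param origin `c(lat, lon)` start position.
#' @param seed seed for the heading draws.
#' @return a [geo_track()] with T + 1 daily positions.
#' @export
simulate_track <- function(fish, origin = c(54, 2), seed = fish$seed + 1L) {
  if (abs(origin[1]) > 90 || abs(origin[2]) > 180) {
    stop_usage("origin outside valid lat/lon")
  }
  T <- length(fish$path$h)
  with_seed(seed, {
    pos <- sim_positions(fish$path$h, fish$states, origin)
    geo_track(fish$path$fish_id, c(fish$path$date, fish$path$date[T] + 1L),
              pos$lat, pos$lon)
  })
}

#' Simulate a 10-minute depth series for a simulated fish
#'
#' Generates `samples_per_day` depth samples per day as a random walk with
#' boundary-respecting signs on \[0, seabed\], whose within-day sum of
#' absolute 10-minute depth changes equals exp(v_t) exactly, so
#' [daily_vertical_movement()] inverts it.
#'
#' @param fish a `simulated_fish`.
#' @param seed seed for the walk.
#' @param seabed maximum depth in metres.
#' @param samples_per_day records per day (default 144 = 10-minute).
#' @return a [depth_series()].
#' @export
simulate_depth <- function(fish, seed = fish$seed + 2L, seabed = 100,
                           samples_per_day = 144L) {
  v_target <- exp(fish$path$v)
  T <- length(v_target)
  ns <- samples_per_day - 1L
  with_seed(seed, {
    depth_all <- numeric(T * samples_per_day)
    d <- seabed / 2
    k <- 1L
    for (t in seq_len(T)) {
      mag <- abs(rnorm(ns))
      mag <- mag * v_target[t] / sum(mag)
      sgn <- sample(c(-1, 1), ns, replace = TRUE)
      depth_all[k] <- d
      for (i in seq_len(ns)) {
        nxt <- d + sgn[i] * mag[i]
        if (nxt < 0 || nxt > seabed) nxt <- d - sgn[i] * mag[i]
        nxt <- min(max(nxt, 0), seabed)   # guard: mag larger than seabed
        depth_all[k + i] <- nxt
        d <- nxt
      }
      k <- k + samples_per_day
    }
    # timestamps laid out day by day on the 10-min raster
    ts <- as.POSIXct(rep(fish$path$date, each = samples_per_day),
                     tz = "UTC") + 600 * rep(0:(samples_per_day - 1L), T)
    depth_series(fish$path$fish_id, ts, depth_all)
  })
}

#' Simulate a cohort of tagged fish
#'
#' Generates `n_rich` long and `n_poor` short tracks with per-fish
#' parameter heterogeneity, reproducibly from the cohort seed.
#'
#' @param cs a [cohort_spec()].
#' @param sp a [species_spec()].
#' @return a `simulated_cohort`: list of `simulated_fish`, with the specs
#'   stored in attributes.
#' @export
simulate_cohort <- function(cs = cohort_spec(), sp = species_spec()) {
  n <- cs$n_rich + cs$n_poor
  draws <- with_seed(cs$seed, {
    list(T = c(if (cs$n_rich > 0)
                 sample(cs$t_rich[1]:cs$t_rich[2], cs$n_rich, replace = TRUE),
               if (cs$n_poor > 0)
                 sample(cs$t_poor[1]:cs$t_poor[2], cs$n_poor, replace = TRUE)),
         start = cs$start_dates[1] +
           sample.int(max(1L, as.integer(diff(cs$start_dates))), n,
                      replace = TRUE) - 1L,
         lat = runif(n, cs$origin[1] - cs$origin_jitter_deg,
                     cs$origin[1] + cs$origin_jitter_deg),
         lon = runif(n, cs$origin[2] - cs$origin_jitter_deg,
                     cs$origin[2] + cs$origin_jitter_deg))
  })
  fish <- lapply(seq_len(n), function(i) {
    simulate_individual(sp, draws$T[i], seed = cs$seed + 7919L * i,
                        start_date = draws$start[i],
                        origin = c(draws$lat[i], draws$lon[i]),
                        substock = cs$substocks[(i - 1L) %%
                                                  length(cs$substocks) + 1L],
                        fish_id = sprintf("%s%03d", sp$species, i))
  })
  structure(fish, class = "simulated_cohort", cohort_spec = cs,
            species_spec = sp,
            rich = c(rep(TRUE, cs$n_rich), rep(FALSE, cs$n_poor)))
}

#' Extract the movement paths of a simulated cohort
#'
#' @param cohort a `simulated_cohort`.
#' @return named list of [movement_path()] objects.
#' @export
cohort_paths <- function(cohort) {
  setNames(lapply(cohort, `[[`, "path"),
           vapply(cohort, function(f) f$path$fish_id, character(1)))
}

#' Write a simulated cohort to CSV files
#'
#' Emits the pipeline's input formats plus ground truth: `paths.csv`
#' (preprocessed movement paths), `tracks.csv` (daily geolocations),
#' `metadata.csv`, `truth_states.csv` (fish_id, date, true_state) and
#' `truth_params.csv`; optionally `depth.csv` with full 10-minute depth
#' series (large, off by default).
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if missing).
#' @param depth also write 10-minute depth series.
#' @return invisibly, the vector of files written.
#' @export
write_cohort_csvs <- function(cohort, dir, depth = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "paths.csv")
  write_movement_csv(cohort_paths(cohort), f)
  files <- c(files, f)

  tr <- do.call(rbind, lapply(cohort, function(x) {
    data.frame(fish_id = x$track$fish_id, date = as.character(x$track$data$date),
               lat = x$track$data$lat, lon = x$track$data$lon)
  }))
  f <- file.path(dir, "tracks.csv")
  utils::write.csv(tr, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  md <- do.call(rbind, lapply(cohort, function(x) {
    data.frame(fish_id = x$path$fish_id, species = x$path$species,
               substock = x$path$substock,
               release_date = as.character(min(x$path$date)),
               end_date = as.character(max(x$path$date) + 1L))
  }))
  f <- file.path(dir, "metadata.csv")
  utils::write.csv(md, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  ts <- do.call(rbind, lapply(cohort, function(x) {
    data.frame(fish_id = x$path$fish_id, date = as.character(x$path$date),
               true_state = x$states)
  }))
  f <- file.path(dir, "truth_states.csv")
  utils::write.csv(ts, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  tp <- do.call(rbind, lapply(cohort, function(x) {
    p <- x$params
    data.frame(fish_id = x$path$fish_id, gamma_RR = p$gamma_RR,
               gamma_MM = p$gamma_MM,
               mu_RH = p$mu["R", "H"], mu_RV = p$mu["R", "V"],
               mu_MH = p$mu["M", "H"], mu_MV = p$mu["M", "V"],
               sigma_RH = p$sigma["R", "H"], sigma_RV = p$sigma["R", "V"],
               sigma_MH = p$sigma["M", "H"], sigma_MV = p$sigma["M", "V"],
               rho_R = p$rho[["R"]], rho_M = p$rho[["M"]])
  }))
  f <- file.path(dir, "truth_params.csv")
  utils::write.csv(tp, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  if (depth) {
    dd <- do.call(rbind, lapply(cohort, function(x) {
      ds <- simulate_depth(x)
      data.frame(fish_id = ds$fish_id,
                 timestamp = format(ds$data$timestamp, "%Y-%m-%dT%H:%M:%S"),
                 depth_m = ds$data$depth)
    }))
    f <- file.path(dir, "depth.csv")
    utils::write.csv(dd, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
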