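# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written without the package's C++ recursions.

# hand-coded haversine on a 6371 km sphere
haversine_oracle <- function(lat1, lon1, lat2, lon2, R = 6371000) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# log-likelihood by exhaustive enumeration of all 2^T state sequences
enum_loglik <- function(h, v, p) {
  T <- length(h)
  G <- matrix(c(p$gamma_RR, 1 - p$gamma_RR, 1 - p$gamma_MM, p$gamma_MM),
              2, byrow = TRUE)
  ld <- cbind(emission_logdensity(cbind(h, v), "R", p),
              emission_logdensity(cbind(h, v), "M", p))
  seqs <- as.matrix(expand.grid(rep(list(1:2), T)))
  lls <- apply(seqs, 1, function(s) {
    ll <- log(p$omega[s[1]]) + ld[1, s[1]]
    if (T > 1) for (t in 2:T) ll <- ll + log(G[s[t - 1], s[t]]) + ld[t, s[t]]
    ll
  })
  m <- max(lls)
  m + log(sum(exp(lls - m)))
}

# smoothed marginals by the same enumeration
enum_smoothed <- function(h, v, p) {
  T <- length(h)
  G <- matrix(c(p$gamma_RR, 1 - p$gamma_RR, 1 - p$gamma_MM, p$gamma_MM),
              2, byrow = TRUE)
  ld <- cbind(emission_logdensity(cbind(h, v), "R", p),
              emission_logdensity(cbind(h, v), "M", p))
  seqs <- as.matrix(expand.grid(rep(list(1:2), T)))
  lls <- apply(seqs, 1, function(s) {
    ll <- log(p$omega[s[1]]) + ld[1, s[1]]
    if (T > 1) for (t in 2:T) ll <- ll + log(G[s[t - 1], s[t]]) + ld[t, s[t]]
    ll
  })
  w <- exp(lls - max(lls))
  w <- w / sum(w)
  out <- matrix(0, T, 2, dimnames = list(NULL, c("R", "M")))
  for (t in 1:T) for (j in 1:2) out[t, j] <- sum(w[seqs[, t] == j])
  out
}

random_params <- function() {
  hmm_parameters(runif(1, 0.05, 0.98), runif(1, 0.05, 0.98),
                 mu = matrix(rnorm(4, 3, 1.5), 2, 2),
                 sigma = matrix(runif(4, 0.3, 1.5), 2, 2),
                 rho = runif(2, -0.8, 0.8))
}

# a species with strong, fixed state separation for fast fitting tests
well_sep_spec <- function(gamma_fixed = 0.99, seasonal = FALSE) {
  species_spec("cod", mu_mean = list(R = c(2, 2), M = c(4, 4)), mu_sd = 0.05,
               sigma_range = c(0.5, 0.5), rho_range = c(0, 0),
               gamma_fixed = gamma_fixed, seasonal = seasonal)
}

# a minimal decoded-fit stub for population-level functions
make_fit_stub <- function(fish_id, dates, p_R, states,
                          species = "cod", substock = "sim",
                          lat = rep(54, length(dates)),
                          lon = rep(2, length(dates)),
                          h = rep(log(9000), length(dates)),
                          v = rep(log(30), length(dates)),
                          converged = TRUE) {
  path <- movement_path(fish_id, species, substock, dates, lat, lon, h, v)
  sm <- cbind(R = p_R, M = 1 - p_R)
  structure(list(fish_id = fish_id, species = species, substock = substock,
                 params = NULL, log_posterior = NA_real_, smoothed = sm,
                 states = states, uncertain = pmax(p_R, 1 - p_R) < 0.85,
                 converged = converged, prior_anchored = FALSE, path = path),
            class = "fitted_hmm")
}

# a complete one-day (or multi-day) 10-minute depth fixture
make_depth <- function(fish_id, dates, depth_fun) {
  ts <- as.POSIXct(rep(dates, each = 144), tz = "UTC") +
    600 * rep(0:143, length(dates))
  depth_series(fish_id, ts, depth_fun(length(ts)))
}
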