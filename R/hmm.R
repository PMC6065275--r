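#' Parameters of the two-state bivariate-normal HMM
#'
#' The latent process is a first-order Markov chain on states R (resident)
#' and M (migrating) with self-transition probabilities `gamma_RR` and
#' `gamma_MM` (off-diagonals implied). Given state j, the day's observation
#' (h, v) — log horizontal and log vertical movement — is bivariate normal
#' with mean `mu[j, ]`, standard deviations `sigma[j, ]` and correlation
#' `rho[j]`. The initial distribution `omega` is fixed uniform. Twelve free
#' parameters in total: 2 transition + 2 x 5 emission.
#'
#' @param gamma_RR,gamma_MM self-transition probabilities in (0, 1).
#' @param mu 2 x 2 matrix of state means, rows `R`,`M`, columns `H`,`V`
#'   (log m/day scale).
#' @param sigma 2 x 2 matrix of state standard deviations, same layout,
#'   all positive.
#' @param rho length-2 vector of within-day H-V correlations in (-1, 1),
#'   named or ordered `R`,`M`.
#' @param omega initial state distribution (default uniform; the model
#'   never estimates it).
#' @return an `hmm_parameters` object.
#' @export
hmm_parameters <- function(gamma_RR, gamma_MM, mu, sigma, rho,
                           omega = c(0.5, 0.5)) {
  stopifnot(gamma_RR > 0, gamma_RR < 1, gamma_MM > 0, gamma_MM < 1,
            is.matrix(mu), all(dim(mu) == c(2, 2)),
            is.matrix(sigma), all(dim(sigma) == c(2, 2)), all(sigma > 0),
            length(rho) == 2, all(abs(rho) < 1),
            length(omega) == 2, all(omega >= 0), abs(sum(omega) - 1) < 1e-8)
  dimnames(mu) <- dimnames(sigma) <- list(c("R", "M"), c("H", "V"))
  structure(list(gamma_RR = gamma_RR, gamma_MM = gamma_MM, mu = mu,
                 sigma = sigma, rho = setNames(rho, c("R", "M")),
                 omega = omega),
            class = "hmm_parameters")
}

#' @export
print.hmm_parameters <- function(x, ...) {
  cat(sprintf("<hmm_parameters: gamma_RR = %.4f, gamma_MM = %.4f>\n",
              x$gamma_RR, x$gamma_MM))
  cat("mu (log m/day):\n"); print(round(x$mu, 3))
  cat("sigma:\n"); print(round(x$sigma, 3))
  cat("rho:", round(x$rho, 3), "\n")
  invisible(x)
}

gamma_matrix <- function(p) {
  matrix(c(p$gamma_RR, 1 - p$gamma_RR, 1 - p$gamma_MM, p$gamma_MM),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("R", "M"), c("R", "M")))
}

#' Transition-probability prior
#'
#' Independent Beta(alpha, beta) priors on both self-transition
#' probabilities. The default Beta(99, 1) has mean 0.99, i.e. an expected
#' state dwell time of 100 days, which keeps the decoded states tracking
#' seasonal shifts rather than day-to-day flicker.
#'
#' @param alpha,beta positive Beta shape parameters.
#' @return a `transition_prior` object.
#' @export
transition_prior <- function(alpha = 99, beta = 1) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "transition_prior")
}

#' Expected dwell time implied by a transition prior
#'
#' At the prior mean self-transition probability alpha/(alpha + beta), the
#' dwell time in a state is geometric with expectation
#' 1 / (1 - alpha/(alpha + beta)) days.
#'
#' @param tp a [transition_prior()].
#' @return expected dwell in days.
#' @export
expected_dwell <- function(tp) {
  # 1 / (1 - alpha/(alpha+beta)), simplified for exactness
  (tp$alpha + tp$beta) / tp$beta
}

#' Fitting configuration
#'
#' @param n_restarts number of optimiser restarts with jittered initial
#'   values (default 10; the first restart is unjittered).
#' @param seed integer seed controlling restart jitter.
#' @param max_iter optimiser iteration cap per restart.
#' @param sigma_floor lower bound on emission standard deviations; an
#'   estimate on the floor flags the fit as degenerate.
#' @param min_occupancy minimum expected days in each state for an unprimed
#'   fit to count as converged (see [fit_map()]).
#' @return a `fit_config` object.
#' @export
fit_config <- function(n_restarts = 10L, seed = 1L, max_iter = 500L,
                       sigma_floor = 1e-3, min_occupancy = 2) {
  stopifnot(n_restarts >= 1)
  structure(list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 max_iter = as.integer(max_iter), sigma_floor = sigma_floor,
                 min_occupancy = min_occupancy),
            class = "fit_config")
}

# ---- parameter transforms -------------------------------------------------
# Working scale: logit(gamma_RR), logit(gamma_MM), mu_RH, mu_RV, mu_MH,
# mu_MV, log sigma_RH, log sigma_RV, log sigma_MH, log sigma_MV,
# atanh(rho_R), atanh(rho_M).

par_to_vec <- function(p) {
  c(qlogis(p$gamma_RR), qlogis(p$gamma_MM),
    p$mu["R", ], p$mu["M", ],
    log(p$sigma["R", ]), log(p$sigma["M", ]),
    atanh(p$rho))
}

vec_to_par <- function(vec) {
  hmm_parameters(gamma_RR = plogis(vec[1]), gamma_MM = plogis(vec[2]),
                 mu = matrix(vec[3:6], 2, 2, byrow = TRUE),
                 sigma = matrix(exp(vec[7:10]), 2, 2, byrow = TRUE),
                 rho = tanh(vec[11:12]))
}

swap_state_labels <- function(p) {
  hmm_parameters(gamma_RR = p$gamma_MM, gamma_MM = p$gamma_RR,
                 mu = p$mu[2:1, , drop = FALSE],
                 sigma = p$sigma[2:1, , drop = FALSE],
                 rho = unname(p$rho[2:1]), omega = p$omega[2:1])
}

# ---- densities ------------------------------------------------------------

bvn_logdens <- function(h, v, mu, sg, rho) {
  zh <- (h - mu[[1]]) / sg[[1]]
  zv <- (v - mu[[2]]) / sg[[2]]
  om <- 1 - rho^2
  unname(-log(2 * pi) - log(sg[[1]]) - log(sg[[2]]) - 0.5 * log(om) -
           (zh^2 - 2 * rho * zh * zv + zv^2) / (2 * om))
}

logdens_matrix <- function(h, v, p) {
  cbind(R = bvn_logdens(h, v, p$mu["R", ], p$sigma["R", ], p$rho[["R"]]),
        M = bvn_logdens(h, v, p$mu["M", ], p$sigma["M", ], p$rho[["M"]]))
}

get_hv <- function(path) {
  if (inherits(path, "movement_path") || (is.list(path) &&
      !is.null(path$h) && !is.null(path$v))) {
    list(h = path$h, v = path$v)
  } else {
    stop_usage("path must be a movement_path or a list with h and v")
  }
}

#' State-dependent emission log-density
#'
#' Log of the bivariate normal density of a day's (h, v) observation under
#' state `state`.
#'
#' @param x numeric vector `c(h, v)` or a two-column matrix of observations.
#' @param state `"R"` or `"M"`.
#' @param p an [hmm_parameters()].
#' @return log-density, one value per observation row.
#' @export
emission_logdensity <- function(x, state, p) {
  state <- match.arg(state, c("R", "M"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  if (any(!is.finite(x))) stop_usage("non-finite observation")
  bvn_logdens(x[, 1], x[, 2], p$mu[state, ], p$sigma[state, ],
              p$rho[[state]])
}

#' Forward-algorithm log-likelihood
#'
#' Log marginal likelihood of a bivariate movement path under the two-state
#' HMM, integrating over all latent state sequences with the scaled forward
#' recursion.
#'
#' @param path a [movement_path()] (or any list with `h` and `v`).
#' @param p an [hmm_parameters()].
#' @return log-likelihood (scalar).
#' @export
forward_loglik <- function(path, p) {
  xy <- get_hv(path)
  if (any(!is.finite(xy$h)) || any(!is.finite(xy$v))) {
    stop_usage("non-finite observations in path")
  }
  fwd_loglik_cpp(logdens_matrix(xy$h, xy$v, p), gamma_matrix(p), p$omega)
}

prior_logdens <- function(p, tp, mp = NULL) {
  lp <- dbeta(p$gamma_RR, tp$alpha, tp$beta, log = TRUE) +
    dbeta(p$gamma_MM, tp$alpha, tp$beta, log = TRUE)
  if (!is.null(mp)) {
    lp <- lp + sum(dnorm(as.vector(p$mu), as.vector(mp$m),
                         sqrt(as.vector(mp$delta)), log = TRUE))
  }
  lp
}

#' Log posterior density
#'
#' Forward log-likelihood plus the log Beta prior on each self-transition
#' probability and, when a movement-parameter prior is supplied, the log
#' Gaussian prior N(m, delta) on each state mean (delta is a variance).
#'
#' @inheritParams forward_loglik
#' @param tp a [transition_prior()].
#' @param mp optional [mean_prior_set()] (or any list with 2 x 2 matrices
#'   `m` and `delta`).
#' @return log posterior density (scalar, unnormalised).
#' @export
log_posterior <- function(path, p, tp, mp = NULL) {
  forward_loglik(path, p) + prior_logdens(p, tp, mp)
}

# ---- fitting --------------------------------------------------------------

initial_vectors <- function(h, v, mp, cfg) {
  qh <- quantile(h, c(0.25, 0.75), names = FALSE)
  qv <- quantile(v, c(0.25, 0.75), names = FALSE)
  sh <- max(sd(h), 0.1)
  sv <- max(sd(v), 0.1)
  mu0 <- if (is.null(mp)) {
    matrix(c(qh[1], qv[1], qh[2], qv[2]), 2, 2, byrow = TRUE)
  } else {
    mp$m
  }
  base <- c(qlogis(0.95), qlogis(0.95), mu0[1, ], mu0[2, ],
            log(c(sh, sv, sh, sv) * 0.75), 0, 0)
  if (cfg$n_restarts == 1L) return(list(base))
  jitters <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_restarts - 1L), function(i) {
      base + c(rnorm(2, 0, 1), rnorm(4, 0, 0.5), rnorm(4, 0, 0.3),
               rnorm(2, 0, 0.3))
    })
  })
  c(list(base), jitters)
}

.vec_bounds <- function(cfg) {
  list(lower = c(rep(qlogis(1e-6), 2), rep(-50, 4),
                 rep(log(cfg$sigma_floor), 4), rep(atanh(-0.999), 2)),
       upper = c(rep(qlogis(1 - 1e-6), 2), rep(50, 4),
                 rep(log(1e3), 4), rep(atanh(0.999), 2)))
}

#' Fit the HMM to one fish by maximum a posteriori estimation
#'
#' Maximises the log posterior (forward log-likelihood plus priors) over the
#' 12 parameters on an unconstrained working scale (logit for transition
#' probabilities, log for standard deviations, Fisher-z for correlations)
#' with `L-BFGS-B`, using `cfg$n_restarts` jittered initialisations; the
#' best restart wins. State means are initialised at the 25th/75th
#' percentiles of h and v (or at the prior means when `mp` is given).
#'
#' Without mean priors, states are relabelled after fitting so that R has
#' the smaller horizontal mean (resident = slow); with mean priors the
#' labels are anchored by the priors and never reordered. A fit is flagged
#' `converged = FALSE` when the optimiser fails, when any estimated sigma
#' sits on its lower bound, or — for unprimed fits only — when either
#' state's expected occupancy falls below `cfg$min_occupancy` days (with
#' informative mean priors a state may legitimately be empty on short
#' tracks).
#'
#' @inheritParams log_posterior
#' @param cfg a [fit_config()].
#' @param extra_inits optional list of working-scale parameter vectors to
#'   add to the restart pool (used by sensitivity refits).
#' @return a `fitted_hmm` object: `params`, `log_posterior`, `loglik`,
#'   smoothed state probabilities (`smoothed`, columns R and M), decoded
#'   `states`, `uncertain` flags, `converged`, and the `path`.
#' @export
fit_map <- function(path, tp = transition_prior(), mp = NULL,
                    cfg = fit_config(), extra_inits = NULL) {
  xy <- get_hv(path)
  h <- xy$h; v <- xy$v
  if (length(h) < 2) stop_usage("need at least two days to fit")
  pm <- if (is.null(mp)) matrix(0, 2, 2) else mp$m
  pdelta <- if (is.null(mp)) matrix(1, 2, 2) else mp$delta
  obj <- function(vec) {
    nll_bivariate_cpp(vec, h, v, tp$alpha, tp$beta, pm, pdelta, !is.null(mp))
  }
  inits <- c(initial_vectors(h, v, mp, cfg), extra_inits)
  b <- .vec_bounds(cfg)
  runs <- lapply(inits, function(ini) {
    tryCatch(optim(ini, obj, method = "L-BFGS-B", lower = b$lower,
                   upper = b$upper,
                   control = list(maxit = cfg$max_iter, factr = 1e7)),
             error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  ok[ok] <- vapply(runs[ok], function(r) is.finite(r$value) &&
                     r$value < 1e10, logical(1))
  if (!any(ok)) {
    return(structure(list(fish_id = path$fish_id, species = path$species,
                          substock = path$substock, params = NULL,
                          log_posterior = NA_real_, loglik = NA_real_,
                          smoothed = NULL, states = NULL, uncertain = NULL,
                          converged = FALSE, prior_anchored = !is.null(mp),
                          path = path),
                     class = "fitted_hmm"))
  }
  best <- runs[ok][[which.min(vapply(runs[ok], `[[`, numeric(1), "value"))]]
  p <- vec_to_par(best$par)
  if (is.null(mp) && p$mu["R", "H"] > p$mu["M", "H"]) {
    p <- swap_state_labels(p)
  }
  sm <- smooth_states(path, p)
  alloc <- allocate_states(sm)
  occ <- colSums(sm)
  degenerate <- any(p$sigma <= cfg$sigma_floor * (1 + 1e-6)) ||
    (is.null(mp) && min(occ) < cfg$min_occupancy)
  structure(list(fish_id = path$fish_id, species = path$species,
                 substock = path$substock, params = p,
                 log_posterior = -best$value,
                 loglik = forward_loglik(path, p),
                 smoothed = sm, states = alloc$state,
                 uncertain = alloc$uncertain,
                 converged = best$convergence == 0 && !degenerate,
                 prior_anchored = !is.null(mp), path = path),
            class = "fitted_hmm")
}

#' @export
print.fitted_hmm <- function(x, ...) {
  cat(sprintf("<fitted_hmm %s: T = %d, converged = %s, logpost = %.2f>\n",
              x$fish_id %||% "?", length(x$path$h), x$converged,
              x$log_posterior))
  if (!is.null(x$states)) {
    cat(sprintf("  days R: %d, days M: %d, uncertain: %d\n",
                sum(x$states == "R"), sum(x$states == "M"),
                sum(x$uncertain)))
  }
  invisible(x)
}

#' Smoothed state probabilities
#'
#' Forward-backward smoothed probabilities P(S_t = j | x_1..x_T) for every
#' day of the path.
#'
#' @inheritParams forward_loglik
#' @return T x 2 matrix with columns `R` and `M`; rows sum to 1.
#' @export
smooth_states <- function(path, p) {
  xy <- get_hv(path)
  sm <- fwd_bwd_cpp(logdens_matrix(xy$h, xy$v, p), gamma_matrix(p), p$omega)
  colnames(sm) <- c("R", "M")
  sm
}

#' Allocate states from smoothed probabilities
#'
#' Assigns each day the most probable state (ties to R) and flags days as
#' uncertain when the winning probability is below `threshold`.
#'
#' @param smoothed T x 2 matrix from [smooth_states()].
#' @param threshold classification-uncertainty threshold (default 0.85).
#' @return list with character vector `state` and logical `uncertain`.
#' @export
allocate_states <- function(smoothed, threshold = 0.85) {
  pR <- smoothed[, "R"]
  state <- ifelse(pR >= smoothed[, "M"], "R", "M")
  list(state = state, uncertain = pmax(pR, smoothed[, "M"]) < threshold)
}

#' One-step-ahead forecast pseudo-residuals
#'
#' For each day and dimension, the forecast CDF of the observation under
#' the predictive state mixture is mapped through the standard normal
#' quantile function. Under a well-specified model the residuals are
#' approximately iid standard normal in each dimension.
#'
#' @inheritParams forward_loglik
#' @return data frame with columns `r_h` and `r_v` (and `date` when the
#'   path carries dates).
#' @export
pseudo_residuals <- function(path, p) {
  xy <- get_hv(path)
  ld <- logdens_matrix(xy$h, xy$v, p)
  w <- fwd_predict_cpp(ld, gamma_matrix(p), p$omega)
  u_h <- w[, 1] * pnorm(xy$h, p$mu["R", "H"], p$sigma["R", "H"]) +
    w[, 2] * pnorm(xy$h, p$mu["M", "H"], p$sigma["M", "H"])
  u_v <- w[, 1] * pnorm(xy$v, p$mu["R", "V"], p$sigma["R", "V"]) +
    w[, 2] * pnorm(xy$v, p$mu["M", "V"], p$sigma["M", "V"])
  out <- data.frame(r_h = qnorm(u_h), r_v = qnorm(u_v))
  if (!is.null(path$date)) out <- cbind(date = path$date, out)
  out
}

# ---- univariate comparison model ------------------------------------------

uni_logdens_matrix <- function(h, mu, sg) {
  cbind(R = dnorm(h, mu[1], sg[1], log = TRUE),
        M = dnorm(h, mu[2], sg[2], log = TRUE))
}

#' Fit the univariate (horizontal-only) comparison model
#'
#' A two-state HMM with univariate normal emissions on log horizontal
#' movement only, sharing the transition-probability prior with the
#' bivariate model. Used to quantify what the vertical dimension adds to
#' state allocation.
#'
#' @inheritParams fit_map
#' @return a `fitted_hmm` object with `univariate = TRUE`; `params` holds
#'   length-2 `mu` and `sigma` vectors.
#' @export
fit_univariate_h <- function(path, tp = transition_prior(),
                             cfg = fit_config()) {
  h <- get_hv(path)$h
  obj <- function(vec) nll_univariate_cpp(vec, h, tp$alpha, tp$beta)
  qh <- quantile(h, c(0.25, 0.75), names = FALSE)
  sh <- max(sd(h), 0.1)
  base <- c(qlogis(0.95), qlogis(0.95), qh, log(c(sh, sh) * 0.75))
  inits <- if (cfg$n_restarts == 1L) list(base) else {
    c(list(base), with_seed(cfg$seed, {
      lapply(seq_len(cfg$n_restarts - 1L), function(i) {
        base + c(rnorm(2, 0, 1), rnorm(2, 0, 0.5), rnorm(2, 0, 0.3))
      })
    }))
  }
  lower <- c(rep(qlogis(1e-6), 2), rep(-50, 2), rep(log(cfg$sigma_floor), 2))
  upper <- c(rep(qlogis(1 - 1e-6), 2), rep(50, 2), rep(log(1e3), 2))
  runs <- lapply(inits, function(ini) {
    tryCatch(optim(ini, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = cfg$max_iter, factr = 1e7)),
             error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop_state("all univariate restarts failed")
  best <- runs[ok][[which.min(vapply(runs[ok], `[[`, numeric(1), "value"))]]
  g <- plogis(best$par[1:2]); mu <- best$par[3:4]; sg <- exp(best$par[5:6])
  if (mu[1] > mu[2]) {   # R = slower horizontal state
    g <- g[2:1]; mu <- mu[2:1]; sg <- sg[2:1]
  }
  G <- matrix(c(g[1], 1 - g[1], 1 - g[2], g[2]), 2, byrow = TRUE)
  sm <- fwd_bwd_cpp(uni_logdens_matrix(h, mu, sg), G, c(0.5, 0.5))
  colnames(sm) <- c("R", "M")
  alloc <- allocate_states(sm)
  structure(list(fish_id = path$fish_id, species = path$species,
                 substock = path$substock,
                 params = list(gamma_RR = g[1], gamma_MM = g[2],
                               mu = setNames(mu, c("R", "M")),
                               sigma = setNames(sg, c("R", "M"))),
                 log_posterior = -best$value, smoothed = sm,
                 states = alloc$state, uncertain = alloc$uncertain,
                 converged = best$convergence == 0, univariate = TRUE,
                 prior_anchored = FALSE, path = path),
            class = "fitted_hmm")
}
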