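#' Percent change between two state sequences
#'
#' 100 x (number of days with differing labels) / T. A metric on label
#' sequences: symmetric, zero iff identical, at most 100.
#'
#' @param a,b character state sequences of equal length.
#' @return percentage in \[0, 100\].
#' @export
percent_state_change <- function(a, b) {
  if (length(a) != length(b)) {
    stop_usage("state sequences differ in length (", length(a), " vs ",
               length(b), ")")
  }
  100 * mean(a != b)
}

#' Named prior-sensitivity scenarios
#'
#' `test1` (alpha = 49.5, beta = 0.5) keeps the prior mean self-transition
#' at 0.99 — still an expected switch every 100 days — but roughly doubles
#' the prior variance. `test2` (alpha = 49, beta = 1) halves the expected
#' dwell to 50 days (prior mean 49/50 = 0.98).
#'
#' @return named list of [transition_prior()] objects.
#' @export
sensitivity_scenarios <- function() {
  list(test1 = transition_prior(49.5, 0.5),
       test2 = transition_prior(49, 1))
}

new_sensitivity_result <- function(scenario, per_fish, n_failed = 0L) {
  structure(list(scenario = scenario, per_fish = per_fish,
                 mean_percent_change = mean(per_fish$percent_change),
                 n_failed = n_failed),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result %s: mean change %.2f%% over %d fish%s>\n",
              x$scenario, x$mean_percent_change, nrow(x$per_fish),
              if (x$n_failed > 0) sprintf(" (%d refits failed)", x$n_failed)
              else ""))
  invisible(x)
}

baseline_by_id <- function(baseline_fits) {
  setNames(baseline_fits,
           vapply(baseline_fits, `[[`, character(1), "fish_id"))
}

#' Sensitivity of state allocation to the transition prior
#'
#' Refits every fish with the scenario's Beta(alpha, beta) prior on the
#' self-transitions (any movement-parameter prior unchanged), decodes, and
#' reports the per-fish and mean percentage of days whose state label
#' changed relative to the baseline fits. Each refit adds the baseline
#' estimate to its restart pool, so comparing a scenario with the
#' baseline's own prior returns exactly 0%.
#'
#' @param paths list of [movement_path()] objects.
#' @param baseline_fits their baseline `fitted_hmm` objects (same order or
#'   matched by `fish_id`).
#' @param tp the scenario [transition_prior()].
#' @param mp optional [mean_prior_set()] (or per-species named list) kept
#'   constant across the refit.
#' @param cfg a [fit_config()].
#' @param scenario label carried into the result.
#' @return a `sensitivity_result`.
#' @export
transition_prior_sensitivity <- function(paths, baseline_fits, tp,
                                         mp = NULL, cfg = fit_config(),
                                         scenario = "scenario") {
  base <- baseline_by_id(baseline_fits)
  rows <- list(); failed <- 0L
  for (p in paths) {
    b <- base[[p$fish_id]]
    if (is.null(b) || is.null(b$states)) {
      stop_usage("no baseline fit for fish ", p$fish_id)
    }
    mpi <- if (inherits(mp, "mean_prior_set") || is.null(mp)) mp
           else mp[[p$species]]
    f <- fit_map(p, tp = tp, mp = mpi, cfg = cfg,
                 extra_inits = list(par_to_vec(b$params)))
    if (is.null(f$states)) {
      failed <- failed + 1L
      next
    }
    rows[[p$fish_id]] <- data.frame(
      fish_id = p$fish_id, species = p$species,
      percent_change = percent_state_change(b$states, f$states))
  }
  new_sensitivity_result(scenario, do.call(rbind, rows), failed)
}

#' Sensitivity of state allocation to the movement-parameter priors
#'
#' Scales every prior variance delta by `factor` (1.10 for "test A", 0.90
#' for "test B"), keeps the prior means and the transition prior fixed,
#' refits the prior-informed fish, and reports the percent state change
#' against their baseline adapted fits.
#'
#' @inheritParams transition_prior_sensitivity
#' @param mp a [mean_prior_set()] or per-species named list of them
#'   (the baseline priors before scaling).
#' @param factor multiplicative change to all delta values.
#' @param tp the (constant) transition prior.
#' @return a `sensitivity_result`.
#' @export
mean_prior_sensitivity <- function(paths, baseline_fits, mp, factor,
                                   tp = transition_prior(),
                                   cfg = fit_config(),
                                   scenario = sprintf("delta_x%.2f", factor)) {
  scale1 <- function(x) scale_mean_prior_delta(x, factor)
  mp_scaled <- if (inherits(mp, "mean_prior_set")) scale1(mp)
               else lapply(mp, scale1)
  base <- baseline_by_id(baseline_fits)
  rows <- list(); failed <- 0L
  for (p in paths) {
    b <- base[[p$fish_id]]
    if (is.null(b) || is.null(b$states)) {
      stop_usage("no baseline fit for fish ", p$fish_id)
    }
    mpi <- if (inherits(mp_scaled, "mean_prior_set")) mp_scaled
           else mp_scaled[[p$species]]
    f <- fit_adapted(p, tp = tp, mp = mpi, cfg = cfg,
                     extra_inits = list(par_to_vec(b$params)))
    if (is.null(f$states)) {
      failed <- failed + 1L
      next
    }
    rows[[p$fish_id]] <- data.frame(
      fish_id = p$fish_id, species = p$species,
      percent_change = percent_state_change(b$states, f$states))
  }
  new_sensitivity_result(scenario, do.call(rbind, rows), failed)
}

#' Bivariate vs univariate state allocation
#'
#' Fits the horizontal-only univariate model ([fit_univariate_h()]) to each
#' fish with the same transition prior and reports the percentage of days
#' on which its decoding disagrees with the bivariate baseline.
#'
#' @inheritParams transition_prior_sensitivity
#' @return a `sensitivity_result` with scenario `"univariate"`.
#' @export
univariate_comparison <- function(paths, baseline_fits,
                                  tp = transition_prior(),
                                  cfg = fit_config()) {
  base <- baseline_by_id(baseline_fits)
  rows <- list(); failed <- 0L
  for (p in paths) {
    b <- base[[p$fish_id]]
    if (is.null(b) || is.null(b$states)) {
      stop_usage("no baseline fit for fish ", p$fish_id)
    }
    f <- tryCatch(fit_univariate_h(p, tp = tp, cfg = cfg),
                  error = function(e) NULL)
    if (is.null(f) || is.null(f$states)) {
      failed <- failed + 1L
      next
    }
    rows[[p$fish_id]] <- data.frame(
      fish_id = p$fish_id, species = p$species,
      percent_change = percent_state_change(b$states, f$states))
  }
  new_sensitivity_result("univariate", do.call(rbind, rows), failed)
}
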