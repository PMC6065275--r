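#' Data-rich selection criteria
#'
#' Rules deciding which unprimed (stage-1) fits are informative enough to
#' feed the movement-parameter priors: the fit must have converged, the path
#' must span at least `min_T` days, and both states must occupy at least a
#' fraction `min_state_fraction` of the decoded days.
#'
#' @param min_T minimum path length in days (default 150).
#' @param min_state_fraction minimum per-state share of decoded days
#'   (default 0.10; must lie in (0, 0.5)).
#' @param require_converged drop non-converged fits (default TRUE).
#' @return a `selection_criteria` object.
#' @export
selection_criteria <- function(min_T = 150L, min_state_fraction = 0.10,
                               require_converged = TRUE) {
  stopifnot(min_state_fraction > 0, min_state_fraction < 0.5)
  structure(list(min_T = as.integer(min_T),
                 min_state_fraction = min_state_fraction,
                 require_converged = isTRUE(require_converged)),
            class = "selection_criteria")
}

#' Select data-rich fits
#'
#' @param fits list of `fitted_hmm` objects (stage-1, unprimed).
#' @param criteria a [selection_criteria()].
#' @return list with `selected` (the passing fits) and `report`, a data
#'   frame with one row per fish (`fish_id`, `converged`, `T`, `frac_R`,
#'   `frac_M`, `pass`, `reason`).
#' @export
select_data_rich <- function(fits, criteria = selection_criteria()) {
  rows <- lapply(fits, function(f) {
    Tn <- length(f$path$h)
    fr <- if (is.null(f$states)) NA_real_ else mean(f$states == "R")
    data.frame(fish_id = f$fish_id, converged = isTRUE(f$converged),
               T = Tn, frac_R = fr, frac_M = 1 - fr)
  })
  rep <- do.call(rbind, rows)
  reason <- character(nrow(rep))
  pass <- rep(TRUE, nrow(rep))
  if (criteria$require_converged) {
    i <- !rep$converged
    pass[i] <- FALSE; reason[i] <- "not_converged"
  }
  i <- pass & rep$T < criteria$min_T
  pass[i] <- FALSE; reason[i] <- "too_short"
  i <- pass & (is.na(rep$frac_R) |
                 pmin(rep$frac_R, rep$frac_M) < criteria$min_state_fraction)
  pass[i] <- FALSE; reason[i] <- "state_occupancy"
  rep$pass <- pass
  rep$reason <- ifelse(pass, "", reason)
  if (!any(pass)) {
    stop_state("no fits pass the data-rich criteria; relax selection_criteria()")
  }
  list(selected = fits[pass], report = rep)
}

#' Movement-parameter priors for one species
#'
#' Gaussian priors N(m, delta) on each state mean, one per state x
#' dimension (4 per species). `mean_prior_set()` builds one from explicit
#' matrices; [build_mean_priors()] estimates one from data-rich fits.
#'
#' @param species species label the priors apply to.
#' @param m 2 x 2 matrix of prior means (rows `R`,`M`, columns `H`,`V`,
#'   log m/day scale), with `m["R","H"] < m["M","H"]` (resident slower).
#' @param delta 2 x 2 matrix of prior variances, all positive.
#' @return a `mean_prior_set` object.
#' @export
mean_prior_set <- function(species, m, delta) {
  stopifnot(is.matrix(m), all(dim(m) == c(2, 2)),
            is.matrix(delta), all(dim(delta) == c(2, 2)), all(delta > 0))
  if (!(m[1, 1] < m[2, 1])) {
    stop_usage("prior means must order resident below migrating on H")
  }
  dimnames(m) <- dimnames(delta) <- list(c("R", "M"), c("H", "V"))
  structure(list(species = species, m = m, delta = delta),
            class = "mean_prior_set")
}

#' @export
print.mean_prior_set <- function(x, ...) {
  cat(sprintf("<mean_prior_set %s>\nm:\n", x$species))
  print(round(x$m, 3))
  cat("delta (variance):\n")
  print(signif(x$delta, 3))
  invisible(x)
}

#' Build movement-parameter priors from data-rich fits
#'
#' Prior mean `m` is the across-fish mean of the fitted state means; prior
#' variance `delta` is the unbiased across-fish variance, floored at
#' `delta_floor` to avoid degenerate point priors.
#'
#' @param selected list of `fitted_hmm` objects passing selection.
#' @param species species whose fits to use.
#' @param delta_floor lower bound on prior variances (default 1e-4).
#' @return a [mean_prior_set()].
#' @export
build_mean_priors <- function(selected, species, delta_floor = 1e-4) {
  fits <- Filter(function(f) identical(f$species, species), selected)
  if (length(fits) < 2) {
    stop_usage("need at least 2 selected fits for species ", species)
  }
  mus <- lapply(fits, function(f) f$params$mu)
  m <- Reduce(`+`, mus) / length(mus)
  delta <- apply(simplify2array(mus), c(1, 2), var)
  delta <- pmax(delta, delta_floor)
  mean_prior_set(species, m, delta)
}

#' Scale prior variances
#'
#' Multiplies every delta by `factor`, leaving the prior means untouched
#' (used by the prior-sensitivity tests).
#'
#' @param mp a [mean_prior_set()].
#' @param factor positive scale factor.
#' @return a new [mean_prior_set()].
#' @export
scale_mean_prior_delta <- function(mp, factor) {
  stopifnot(factor > 0)
  mean_prior_set(mp$species, mp$m, mp$delta * factor)
}

#' Fit a fish with the adapted (prior-informed) HMM
#'
#' Delegates to [fit_map()] with the species' movement-parameter priors
#' active; state labels are anchored by the priors rather than reordered
#' after fitting.
#'
#' @inheritParams fit_map
#' @param mp a [mean_prior_set()] matching the fish's species.
#' @return a `fitted_hmm`.
#' @export
fit_adapted <- function(path, tp = transition_prior(), mp,
                        cfg = fit_config(), extra_inits = NULL) {
  if (!is.null(path$species) && !identical(mp$species, path$species)) {
    stop_usage("prior set is for ", mp$species, " but fish ", path$fish_id,
               " is ", path$species)
  }
  fit_map(path, tp = tp, mp = mp, cfg = cfg, extra_inits = extra_inits)
}

#' Two-stage classification of a cohort
#'
#' Stage 1 fits every fish unprimed. Data-rich fits are then selected and
#' summarised into species-level movement-parameter priors, and every
#' remaining fish is refitted with the adapted, prior-informed model
#' (stage 2). Selected fish keep their stage-1 fits, so no fish's data
#' enters its own prior.
#'
#' @param paths list of [movement_path()] objects (at least 2 per species).
#' @param tp a [transition_prior()].
#' @param criteria a [selection_criteria()].
#' @param cfg a [fit_config()].
#' @return list with `fits` (one `fitted_hmm` per fish, stage-1 for
#'   selected fish, stage-2 otherwise), `priors` (named list of
#'   [mean_prior_set()] per species), `report` (per-fish data frame with
#'   `stage`, `converged`, `T`, `frac_R`, `frac_M`) and `selection` (the
#'   selection report).
#' @export
run_two_stage <- function(paths, tp = transition_prior(),
                          criteria = selection_criteria(),
                          cfg = fit_config()) {
  stage1 <- lapply(paths, fit_map, tp = tp, cfg = cfg)
  sel <- select_data_rich(stage1, criteria)
  selected_ids <- vapply(sel$selected, `[[`, character(1), "fish_id")
  species <- unique(vapply(paths, `[[`, character(1), "species"))
  priors <- setNames(
    lapply(species, function(sp) build_mean_priors(sel$selected, sp)),
    species)
  fits <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (p$fish_id %in% selected_ids) {
      stage1[[i]]
    } else {
      fit_adapted(p, tp = tp, mp = priors[[p$species]], cfg = cfg)
    }
  })
  report <- do.call(rbind, lapply(fits, function(f) {
    fr <- if (is.null(f$states)) NA_real_ else mean(f$states == "R")
    data.frame(fish_id = f$fish_id, species = f$species,
               substock = f$substock,
               stage = if (f$prior_anchored) 2L else 1L,
               converged = isTRUE(f$converged), T = length(f$path$h),
               frac_R = fr, frac_M = 1 - fr)
  }))
  list(fits = setNames(fits, vapply(fits, `[[`, character(1), "fish_id")),
       priors = priors, report = report, selection = sel$report)
}
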