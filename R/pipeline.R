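#' Run the full classification pipeline
#'
#' Single entry point tying the stages together: obtain movement paths
#' (either simulated from a `simulate:` block or read and preprocessed from
#' `inputs:` CSV paths), run the two-stage prior-informed classification,
#' write decoded states and per-fish reports, compute population summaries
#' (weekly state timing, state-dominant windows, utilization grids,
#' substock rates, dwell-time diagnostics) and any requested sensitivity
#' scenarios, and leave a run manifest beside the outputs. Deterministic
#' given the seed.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Must contain exactly one of `simulate` (fields of
#'   [cohort_spec()] plus `species`) or `inputs` (paths `depth`, `tracks`,
#'   `metadata`). Optional blocks: `preprocess`, `transition_prior`,
#'   `selection`, `fit`, `population` (`cell_km`, `threshold`),
#'   `sensitivity` (any of `"test1"`, `"test2"`, `"testA"`, `"testB"`,
#'   `"univariate"`), `seed`, `outdir`.
#' @param outdir output directory; overrides `config$outdir`.
#' @param seed integer; overrides `config$seed`.
#' @param verbose print progress lines.
#' @return invisibly, a list with `paths`, `two_stage`, `weekly`,
#'   `windows`, `grids`, `rates`, `dwell`, `sensitivity`, and the vector
#'   of `files` written.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_usage("config must be a list or a YAML path")
  has_sim <- !is.null(config$simulate)
  has_in <- !is.null(config$inputs)
  if (has_sim == has_in) {
    stop_usage("config must contain exactly one of 'simulate' or 'inputs'")
  }
  seed <- as.integer(seed %||% config$seed %||% 1L)
  outdir <- outdir %||% config$outdir %||% stop_usage("config: no 'outdir'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  files <- character(0)
  emit <- function(df, name) {
    f <- file.path(outdir, name)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
    f
  }

  # ---- movement paths ----
  if (has_sim) {
    sb <- config$simulate
    sp <- species_spec(species = sb$species %||% "cod",
                       seasonal = isTRUE(sb$seasonal))
    cs <- cohort_spec(n_rich = sb$n_rich %||% 34L,
                      n_poor = sb$n_poor %||% 73L,
                      t_rich = unlist(sb$t_rich %||% c(200L, 600L)),
                      t_poor = unlist(sb$t_poor %||% c(40L, 80L)),
                      seed = seed,
                      substocks = unlist(sb$substocks %||% "sim"))
    say("simulating cohort of ", cs$n_rich + cs$n_poor, " fish")
    cohort <- simulate_cohort(cs, sp)
    write_cohort_csvs(cohort, outdir)
    paths <- cohort_paths(cohort)
  } else {
    pc <- do.call(preprocess_config, config$preprocess %||% list())
    say("reading inputs")
    depth <- read_depth_csv(config$inputs$depth)
    tracks <- read_track_csv(config$inputs$tracks)
    meta <- read_metadata_csv(config$inputs$metadata)
    ids <- intersect(names(depth), intersect(names(tracks), names(meta)))
    built <- lapply(ids, function(id) {
      build_movement_path(depth[[id]], tracks[[id]], meta[[id]], pc)
    })
    rej <- Filter(function(x) inherits(x, "path_rejection"), built)
    for (r in rej) say("rejected ", r$fish_id, ": ", r$reason)
    paths <- Filter(function(x) inherits(x, "movement_path"), built)
    paths <- setNames(paths, vapply(paths, `[[`, character(1), "fish_id"))
    emit(do.call(rbind, lapply(built, function(x) {
      data.frame(fish_id = x$fish_id,
                 accepted = inherits(x, "movement_path"),
                 reason = if (inherits(x, "path_rejection")) x$reason else "")
    })), "preprocess_report.csv")
    write_movement_csv(paths, file.path(outdir, "paths.csv"))
  }

  # ---- two-stage classification ----
  tp <- do.call(transition_prior, config$transition_prior %||% list())
  crit <- do.call(selection_criteria, config$selection %||% list())
  cfg <- do.call(fit_config, c(config$fit %||% list(), list(seed = seed)))
  say("two-stage classification of ", length(paths), " fish")
  ts <- run_two_stage(paths, tp = tp, criteria = crit, cfg = cfg)
  emit(ts$report, "fit_report.csv")
  emit(ts$selection, "selection_report.csv")
  write_state_csv(ts$fits, file.path(outdir, "states.csv"))
  files <- c(files, file.path(outdir, "states.csv"))
  prior_file <- file.path(outdir, "priors.yaml")
  yaml::write_yaml(lapply(ts$priors, function(mp) {
    list(species = mp$species,
         m = as.list(as.data.frame(mp$m)),
         delta = as.list(as.data.frame(mp$delta)))
  }), prior_file)
  files <- c(files, prior_file)

  # ---- population summaries ----
  pop <- config$population %||% list()
  cell_km <- pop$cell_km %||% 5
  threshold <- pop$threshold %||% 0.5
  species <- unique(vapply(ts$fits, `[[`, character(1), "species"))
  weekly <- list(); windows <- list(); grids <- list()
  for (spn in species) {
    fsp <- Filter(function(f) identical(f$species, spn), ts$fits)
    wk <- weekly_state_summary(fsp)
    weekly[[spn]] <- wk
    emit(wk, paste0("weekly_", spn, ".csv"))
    wins <- do.call(rbind, lapply(c("R", "M"), function(s) {
      w <- state_dominant_windows(wk, s, threshold)
      if (nrow(w)) cbind(state = s, w) else NULL
    }))
    if (!is.null(wins)) {
      windows[[spn]] <- wins
      emit(wins, paste0("windows_", spn, ".csv"))
      for (i in seq_len(nrow(wins))) {
        s <- wins$state[i]
        g <- utilization_grid(fsp,
                              weeks_in_window(wins$start_week[i],
                                              wins$end_week[i]),
                              s, cell_km)
        grids[[paste(spn, s, i, sep = "_")]] <- g
        emit(as.data.frame(g), sprintf("grid_%s_%s_w%02d.csv", spn, s,
                                       wins$start_week[i]))
      }
    }
  }
  rates <- substock_rates(ts$fits)
  emit(rates, "substock_rates.csv")
  dw <- dwell_time_analysis(ts$fits)
  emit(dw$runs, "dwell_runs.csv")
  emit(dw$fit, "dwell_fit.csv")

  # ---- sensitivity scenarios ----
  sens <- list()
  scen <- unlist(config$sensitivity %||% character(0))
  if (length(scen)) {
    sel_ids <- ts$selection$fish_id[ts$selection$pass]
    rich_paths <- paths[names(paths) %in% sel_ids]
    rich_fits <- ts$fits[names(ts$fits) %in% sel_ids]
    poor_paths <- paths[!names(paths) %in% sel_ids]
    poor_fits <- ts$fits[!names(ts$fits) %in% sel_ids]
    for (sc in scen) {
      say("sensitivity scenario ", sc)
      res <- switch(sc,
        test1 = transition_prior_sensitivity(
          rich_paths, rich_fits, sensitivity_scenarios()$test1,
          cfg = cfg, scenario = "test1"),
        test2 = transition_prior_sensitivity(
          rich_paths, rich_fits, sensitivity_scenarios()$test2,
          cfg = cfg, scenario = "test2"),
        testA = if (length(poor_paths)) mean_prior_sensitivity(
          poor_paths, poor_fits, ts$priors, 1.10, tp = tp, cfg = cfg,
          scenario = "testA"),
        testB = if (length(poor_paths)) mean_prior_sensitivity(
          poor_paths, poor_fits, ts$priors, 0.90, tp = tp, cfg = cfg,
          scenario = "testB"),
        univariate = univariate_comparison(rich_paths, rich_fits, tp = tp,
                                           cfg = cfg),
        stop_usage("unknown sensitivity scenario: ", sc))
      if (!is.null(res)) sens[[sc]] <- res
    }
    if (length(sens)) {
      emit(do.call(rbind, lapply(sens, function(r) {
        cbind(scenario = r$scenario, r$per_fish)
      })), "sensitivity.csv")
    }
  }

  write_manifest(file.path(outdir, "manifest.txt"), config, seed)
  files <- c(files, file.path(outdir, "manifest.txt"))
  say("done: ", length(files), " output files in ", outdir)
  invisible(list(paths = paths, two_stage = ts, weekly = weekly,
                 windows = windows, grids = grids, rates = rates,
                 dwell = dw, sensitivity = sens, files = files))
}
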