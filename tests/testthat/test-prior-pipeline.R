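stub_with <- function(id, T, frac_R, converged = TRUE, species = "cod",
                      mu = matrix(c(2, 2, 4, 4), 2, byrow = TRUE)) {
  dates <- as.Date("2004-01-01") + seq_len(T) - 1
  nR <- round(T * frac_R)
  st <- c(rep("R", nR), rep("M", T - nR))
  s <- make_fit_stub(id, dates, p_R = as.numeric(st == "R"), states = st,
                     species = species, converged = converged)
  dimnames(mu) <- list(c("R", "M"), c("H", "V"))
  s$params <- list(mu = mu)
  s
}

test_that("data-rich selection applies length, convergence and occupancy rules", {
  fits <- list(stub_with("short", 45, 0.5),
               stub_with("onestate", 300, 0),
               stub_with("failed", 300, 0.5, converged = FALSE),
               stub_with("rich1", 300, 0.5),
               stub_with("rich2", 200, 0.3))
  sel <- select_data_rich(fits, selection_criteria())
  expect_equal(vapply(sel$selected, `[[`, character(1), "fish_id"),
               c("rich1", "rich2"))
  rep <- sel$report
  expect_equal(rep$reason[rep$fish_id == "short"], "too_short")
  expect_equal(rep$reason[rep$fish_id == "onestate"], "state_occupancy")
  expect_equal(rep$reason[rep$fish_id == "failed"], "not_converged")
  expect_error(select_data_rich(fits[1:2], selection_criteria()),
               class = "fishHMM_state_error")
})

test_that("selection separates a generated rich/poor cohort by length", {
  # 8 long + 8 short tracks; fake fits carrying the true lengths
  co <- simulate_cohort(cohort_spec(n_rich = 8, n_poor = 8, seed = 31,
                                    t_rich = c(200, 400), t_poor = c(40, 80)),
                        well_sep_spec())
  fits <- lapply(co, function(f) {
    T <- length(f$path$date)
    stub_with(f$path$fish_id, T, 0.4)
  })
  sel <- select_data_rich(fits, selection_criteria())
  expect_equal(sort(vapply(sel$selected, `[[`, character(1), "fish_id")),
               sort(vapply(co[attr(co, "rich")],
                           function(f) f$path$fish_id, character(1))))
})

test_that("mean priors are across-fish moments of the fitted state means", {
  f1 <- stub_with("a", 200, 0.5, mu = matrix(c(2.0, 3.0, 4.0, 5.0), 2,
                                             byrow = TRUE))
  f2 <- stub_with("b", 200, 0.5, mu = matrix(c(2.2, 3.2, 4.4, 5.4), 2,
                                             byrow = TRUE))
  mp <- build_mean_priors(list(f1, f2), "cod")
  expect_equal(mp$m["R", "H"], 2.1)
  expect_equal(mp$delta["R", "H"], var(c(2.0, 2.2)))
  expect_equal(mp$m["M", "V"], 5.2)

  # identical fits floor delta rather than collapsing to zero
  mp2 <- build_mean_priors(list(f1, f1), "cod")
  expect_equal(unname(mp2$delta), matrix(1e-4, 2, 2))

  expect_error(build_mean_priors(list(f1), "cod"),
               class = "fishHMM_usage_error")
  expect_error(build_mean_priors(list(f1, f2), "plaice"),
               class = "fishHMM_usage_error")
})

test_that("hyper-means are recovered from a generated cohort of fitted fish", {
  sp <- well_sep_spec()
  fits <- lapply(1:10, function(i) {
    f <- simulate_individual(sp, 300, seed = 300 + i)
    fit_map(f$path, cfg = fit_config(n_restarts = 3))
  })
  mp <- build_mean_priors(fits, "cod")
  expect_lt(max(abs(mp$m - matrix(c(2, 2, 4, 4), 2, byrow = TRUE))), 0.1)
})

test_that("prior limits: vanishing delta pins the means, huge delta frees them", {
  # a switching chain keeps both states occupied, so the posterior is
  # unimodal and the limit comparison is about the prior, not local optima
  sp <- well_sep_spec(gamma_fixed = 0.9)
  f <- simulate_individual(sp, 120, seed = 41)
  anchor <- matrix(c(1.9, 2.1, 4.1, 3.9), 2, byrow = TRUE)
  tiny <- mean_prior_set("cod", anchor, matrix(1e-8, 2, 2))
  fit <- fit_adapted(f$path, mp = tiny, cfg = fit_config(n_restarts = 3))
  expect_lt(max(abs(fit$params$mu - anchor)), 1e-3)

  huge <- mean_prior_set("cod", anchor, matrix(1e12, 2, 2))
  fit_free <- fit_adapted(f$path, mp = huge, cfg = fit_config(n_restarts = 3))
  fit_unprimed <- fit_map(f$path, cfg = fit_config(n_restarts = 3))
  # compare posteriors with the (constant) diffuse prior terms removed
  lp_free <- fit_free$log_posterior -
    sum(dnorm(as.vector(fit_free$params$mu), as.vector(anchor),
              sqrt(1e12), log = TRUE))
  expect_equal(lp_free, fit_unprimed$log_posterior, tolerance = 1e-4)
})

test_that("adapted fits refuse a species-mismatched prior set", {
  sp <- well_sep_spec()
  f <- simulate_individual(sp, 60, seed = 43)
  mp <- mean_prior_set("plaice", matrix(c(2, 2, 4, 4), 2, byrow = TRUE),
                       matrix(0.05, 2, 2))
  expect_error(fit_adapted(f$path, mp = mp), class = "fishHMM_usage_error")
})

test_that("two-stage run classifies every fish with coherent labels", {
  # gamma 0.9 keeps both states well occupied on every track, so the
  # rich/poor split maps exactly onto the selection outcome
  co <- simulate_cohort(cohort_spec(n_rich = 5, n_poor = 6, seed = 51,
                                    t_rich = c(200, 350)),
                        well_sep_spec(gamma_fixed = 0.9))
  ts <- run_two_stage(cohort_paths(co), cfg = fit_config(n_restarts = 4))
  expect_equal(sum(ts$report$stage == 1), 5)
  expect_equal(sum(ts$report$stage == 2), 6)
  expect_true(all(ts$report$converged))
  for (f in ts$fits) {
    hR <- f$path$h[f$states == "R"]
    hM <- f$path$h[f$states == "M"]
    if (length(hR) && length(hM)) expect_gt(mean(hM), mean(hR))
  }
  # decoded states track the generator truth
  acc <- mapply(function(f, s) mean(f$states == s),
                ts$fits, lapply(co, `[[`, "states"))
  expect_gt(median(acc), 0.9)

  # all-rich cohort leaves stage 2 empty
  co2 <- simulate_cohort(cohort_spec(n_rich = 4, n_poor = 0, seed = 52,
                                     t_rich = c(200, 300)),
                         well_sep_spec(gamma_fixed = 0.9))
  ts2 <- run_two_stage(cohort_paths(co2), cfg = fit_config(n_restarts = 3))
  expect_true(all(ts2$report$stage == 1))
})
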