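test_that("weeks of the year start on 1 January and cap at 52", {
  expect_equal(week_of_year(as.Date("2004-01-01")), 1L)
  expect_equal(week_of_year(as.Date("2004-01-07")), 1L)
  expect_equal(week_of_year(as.Date("2004-01-08")), 2L)
  expect_equal(week_of_year(as.Date("2004-12-31")), 52L)  # day 366
  expect_equal(week_of_year(as.Date("2003-12-31")), 52L)  # day 365
})

test_that("weekly summary averages fish-days and fish-level SE correctly", {
  dates <- as.Date("2004-01-01") + 0:6   # week 1
  f1 <- make_fit_stub("a", dates, p_R = rep(1, 7), states = rep("R", 7))
  f2 <- make_fit_stub("b", dates, p_R = rep(1, 7), states = rep("R", 7))
  wk <- weekly_state_summary(list(f1, f2))
  expect_equal(nrow(wk), 52)
  expect_equal(wk$mean_p_resident[1], 1)
  expect_equal(wk$se[1], 0)
  expect_equal(wk$prop_resident[1], 1)
  expect_equal(wk$n_fish[1], 2)
  expect_equal(wk$n_fish[2], 0)
  expect_true(is.na(wk$mean_p_resident[2]))

  f3 <- make_fit_stub("a", dates, p_R = rep(0.2, 7), states = rep("M", 7))
  f4 <- make_fit_stub("b", dates, p_R = rep(0.8, 7), states = rep("R", 7))
  wk <- weekly_state_summary(list(f3, f4))
  expect_equal(wk$mean_p_resident[1], 0.5)
  expect_equal(wk$prop_resident[1], 0.5)
  expect_equal(wk$se[1], sd(c(0.2, 0.8)) / sqrt(2))
  # conservation: weekly day counts sum to total decoded days
  expect_equal(sum(wk$n_days), 14)
})

test_that("state-dominant windows group consecutive weeks and wrap the year end", {
  base <- data.frame(week = 1:52, mean_p_resident = 0.2)
  base$mean_p_resident[22:44] <- 0.8    # summer residency
  wR <- state_dominant_windows(base, "R")
  expect_equal(wR, data.frame(start_week = 22L, end_week = 44L,
                              n_weeks = 23L))
  wM <- state_dominant_windows(base, "M")
  expect_equal(wM$start_week, 45L)      # wraps 45..52 and 1..21
  expect_equal(wM$end_week, 21L)
  expect_equal(wM$n_weeks, 29L)
  expect_equal(weeks_in_window(45L, 21L), c(45:52, 1:21))

  # exactly at the threshold: strict inequality, no window
  flat <- data.frame(week = 1:52, mean_p_resident = 0.5)
  expect_equal(nrow(state_dominant_windows(flat, "R")), 0)
  expect_equal(nrow(state_dominant_windows(flat, "M")), 0)
})

test_that("utilization grids count matching fish-days and conserve totals", {
  dates <- as.Date("2004-01-01") + 0:9   # weeks 1-2
  f1 <- make_fit_stub("a", dates, p_R = rep(1, 10), states = rep("R", 10),
                      lat = rep(54, 10), lon = rep(2, 10))
  g <- utilization_grid(list(f1), weeks = 1:2, state = "R")
  expect_equal(nrow(g), 1)
  expect_equal(g$count, 10)
  expect_equal(attr(g, "total"), 10)
  expect_equal(g$lat_center, 54, tolerance = 0.05)
  expect_equal(g$lon_center, 2, tolerance = 0.05)

  # a migrating day inside a resident window is excluded
  st <- c(rep("R", 9), "M")
  f2 <- make_fit_stub("a", dates, p_R = as.numeric(st == "R"), states = st,
                      lat = rep(54, 10), lon = rep(2, 10))
  g2 <- utilization_grid(list(f2), weeks = 1:2, state = "R")
  expect_equal(attr(g2, "total"), 9)

  # positions straddling cells split but conserve the total
  lats <- 54 + c(rep(0, 5), rep(0.2, 5))
  f3 <- make_fit_stub("a", dates, p_R = rep(1, 10), states = rep("R", 10),
                      lat = lats, lon = rep(2, 10))
  f4 <- make_fit_stub("b", dates, p_R = rep(1, 10), states = rep("R", 10),
                      lat = lats + 0.1, lon = rep(2.3, 10))
  g3 <- utilization_grid(list(f3, f4), weeks = 1:2, state = "R")
  expect_gt(nrow(g3), 1)
  expect_equal(sum(g3$count), 20)
  expect_equal(attr(g3, "total"), 20)
  expect_error(utilization_grid(list(f3), weeks = integer(0), state = "R"),
               class = "fishHMM_usage_error")
})

test_that("the equal-area projection round-trips coordinates", {
  set.seed(61)
  lat <- runif(50, 50, 60); lon <- runif(50, -4, 8)
  xy <- fishHMM:::laea_project(lat, lon, 54, 2)
  back <- fishHMM:::laea_inverse(xy$x, xy$y, 54, 2)
  expect_equal(back$lat, lat, tolerance = 1e-9)
  expect_equal(back$lon, lon, tolerance = 1e-9)
})

test_that("substock rates average raw daily movements per fish and state", {
  dates <- as.Date("2004-01-01") + 0:9
  st <- c(rep("R", 6), rep("M", 4))
  f <- make_fit_stub("a", dates, p_R = as.numeric(st == "R"), states = st,
                     substock = "SNS",
                     h = log(c(rep(9200, 6), rep(13900, 4))),
                     v = log(c(rep(31.5, 6), rep(158.3, 4))))
  rt <- substock_rates(list(f))
  expect_equal(rt$horizontal_km_day[rt$state == "R"], 9.2)
  expect_equal(rt$vertical_m_day[rt$state == "R"], 31.5)
  expect_equal(rt$horizontal_km_day[rt$state == "M"], 13.9)
  expect_equal(rt$vertical_m_day[rt$state == "M"], 158.3)

  # a fish with zero days in a state contributes nothing to that cell
  fR <- make_fit_stub("b", dates, p_R = rep(1, 10), states = rep("R", 10),
                      substock = "SNS", h = rep(log(1000), 10))
  rt2 <- substock_rates(list(f, fR))
  expect_equal(rt2$n_fish[rt2$state == "M"], 1)
  expect_equal(rt2$horizontal_km_day[rt2$state == "M"], 13.9)
  expect_equal(rt2$horizontal_km_day[rt2$state == "R"], mean(c(9.2, 1)))
})

test_that("generated substock rates recover the emission scale", {
  sp <- species_spec("plaice", mu_sd = 0.05)
  co <- simulate_cohort(cohort_spec(n_rich = 12, n_poor = 0, seed = 63,
                                    t_rich = c(150, 250), substocks = "GB"),
                        sp)
  # decode with the true parameters; this isolates the summary arithmetic
  fits <- lapply(co, function(f) {
    sm <- smooth_states(f$path, f$params)
    al <- allocate_states(sm)
    make_fit_stub(f$path$fish_id, f$path$date, sm[, "R"], al$state,
                  species = "plaice", substock = "GB",
                  h = f$path$h, v = f$path$v)
  })
  rt <- substock_rates(fits)
  hR <- rt$horizontal_km_day[rt$state == "R"]
  # lognormal mean exp(mu + sigma^2/2) with mu = log 6500, sigma ~ 0.4-0.6
  expect_gt(hR, 6.5)
  expect_lt(hR, 6.5 * exp(0.6^2 / 2) * 1.25)
})

test_that("dwell-time extraction censors end runs and fits the geometric", {
  dates <- as.Date("2004-01-01") + 0:5
  st <- c("R", "R", "R", "M", "M", "R")
  f <- make_fit_stub("a", dates, p_R = as.numeric(st == "R"), states = st)
  dw <- dwell_time_analysis(list(f))
  expect_equal(dw$runs$length, c(3, 2, 1))
  expect_equal(dw$runs$censored, c(TRUE, FALSE, TRUE))
  # only the M run of length 2 is uncensored
  expect_equal(dw$fit$n_uncensored[dw$fit$state == "M"], 1)
  expect_equal(dw$fit$mean_dwell[dw$fit$state == "M"], 2)
  expect_true(dw$fit$degenerate[dw$fit$state == "M"])  # too few for a GOF

  # alternating states: every interior run has length 1, p_hat = 1
  st2 <- rep(c("R", "M"), 10)
  f2 <- make_fit_stub("b", as.Date("2004-01-01") + 0:19,
                      p_R = as.numeric(st2 == "R"), states = st2)
  dw2 <- dwell_time_analysis(list(f2))
  expect_equal(dw2$fit$p_hat[dw2$fit$state == "R"], 1)
  expect_true(all(dw2$runs$length == 1))
})
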