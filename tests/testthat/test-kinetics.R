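# Hysteresis state machine, event extraction with censoring, rate and
# duration statistics.

test_that("hysteresis state machine follows the hand-traced example", {
  counts <- matrix(c(0L, 3L, 4L, 2L, 0L, 0L, 1L, 4L), ncol = 1)
  ser <- state_series_from_counts(counts, n_heavy = 4L, dt = 1)
  expect_equal(as.integer(ser$states), c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L))
  ev <- detect_events(ser)
  comp <- ev[!ev$censored, ]
  expect_equal(comp$duration[comp$state == "adsorbed"], 3)
  expect_equal(comp$duration[comp$state == "free"], 3)
  expect_true(ev$censored[1] && ev$censored[nrow(ev)])
  # constant-state series produce no completed events
  ser0 <- state_series_from_counts(matrix(0L, 10, 1), 4L, dt = 1)
  ev0 <- detect_events(ser0)
  expect_equal(nrow(ev0[!ev0$censored, ]), 0L)
  sern <- state_series_from_counts(matrix(4L, 10, 1), 4L, dt = 1)
  evn <- detect_events(sern)
  expect_equal(attr(evn, "n_desorption_events"), 0L)
})

test_that("'more than half' means count > floor(n/2) for even chains", {
  # a 4-atom chain needs >= 3 atoms within the cutoff to adsorb
  counts <- matrix(c(0L, 2L, 3L, 0L), ncol = 1)
  ser <- state_series_from_counts(counts, 4L, dt = 1)
  expect_equal(as.integer(ser$states), c(0L, 0L, 1L, 0L))
  # and hysteresis: dropping to 1 atom does not desorb
  counts2 <- matrix(c(4L, 1L, 1L, 0L), ncol = 1)
  ser2 <- state_series_from_counts(counts2, 4L, dt = 1)
  expect_equal(as.integer(ser2$states), c(1L, 1L, 1L, 0L))
})

test_that("event rates normalize by the analyzed time", {
  st <- matrix(0L, 101, 1)
  st[c(11:15, 31:35, 51:55, 71:75, 91:95)] <- 1L   # 5 adsorption events
  ser <- state_series_from_counts(st * 4L, 4L, dt = 1)
  ev <- detect_events(ser)
  r <- event_rates(ev, ser)
  expect_equal(r$adsorption_rate, 5 / 101)
  expect_equal(r$desorption_rate, 5 / 101)
  expect_equal(r$mean_adsorbed, 25 / 101)
  ser_none <- state_series_from_counts(matrix(0L, 50, 2), c(4L, 4L), dt = 1)
  r0 <- event_rates(detect_events(ser_none))
  expect_equal(r0$adsorption_rate, 0)
})

test_that("lognormal summaries use the geometric mean and 16/84 interval", {
  s <- lognormal_summary(c(1, 10, 100))
  expect_equal(s$gm, 10)
  s2 <- lognormal_summary(rep(3.5, 10))
  expect_equal(s2$gm, 3.5)
  expect_equal(s2$plus, 0)
  expect_equal(s2$minus, 0)
  set.seed(99)
  x <- exp(rnorm(1e5))
  s3 <- lognormal_summary(x)
  expect_lt(abs(s3$gm - 1), 0.02)
  expect_lt(abs(s3$lower - exp(-1)) / exp(-1), 0.02)
  expect_lt(abs(s3$upper - exp(1)) / exp(1), 0.02)
  expect_error(lognormal_summary(c(1, -2)), "positive|> 0")
})

test_that("duration histograms conserve events and handle edge cases", {
  set.seed(4)
  d <- rexp(500, 2)
  h <- duration_histogram(d, n_logbins = 15, total_time = 50)
  expect_equal(sum(h$count), 500)
  expect_equal(sum(h$rate) * 50, 500)
  h1 <- duration_histogram(3.3, n_logbins = 5)
  expect_equal(sum(h1$count > 0), 1L)
  expect_equal(nrow(duration_histogram(numeric(0))), 0L)
})

test_that("free durations from the Markov generator are exponential(k_on)", {
  g <- generate_markov_trajectory(markov_params(
    n_chains = 40, n_frames = 8000, dt = 0.02, k_on = 0.5, k_off = 2,
    water_density = 0, seed = 61, n_protein_points = 100))
  ser <- state_series_from_counts(g$truth$states * 4L, rep(4L, 40), 0.02)
  ev <- detect_events(ser)
  dur <- ev$duration[ev$state == "free" & !ev$censored]
  expect_gt(length(dur), 500)
  # chi-square against the discrete-sampling mean-matched exponential
  lam <- 0.5 + 2
  mean_dur <- 0.02 / ((0.5 / lam) * (1 - exp(-lam * 0.02)))
  qs <- stats::qexp(seq(0, 1, by = 0.1), 1 / mean_dur)
  obs <- table(cut(dur, qs, include.lowest = TRUE))
  chi <- stats::chisq.test(as.integer(obs))
  expect_gt(chi$p.value, 0.01)
})

test_that("stationary flux balance holds on long runs", {
  g <- generate_markov_trajectory(markov_params(
    n_chains = 50, n_frames = 10000, dt = 0.02, k_on = 0.3, k_off = 1.0,
    water_density = 0, seed = 62, n_protein_points = 100))
  ser <- state_series_from_counts(g$truth$states * 4L, rep(4L, 50), 0.02)
  ev <- detect_events(ser)
  comp <- ev[!ev$censored, ]
  mean_ads_dur <- mean(comp$duration[comp$state == "adsorbed"])
  mean_free_dur <- mean(comp$duration[comp$state == "free"])
  occ <- mean(g$truth$states)
  # occupancy ratio = duration ratio at stationarity
  expect_lt(abs((occ / (1 - occ)) / (mean_ads_dur / mean_free_dur) - 1), 0.1)
})

test_that("shortening a trajectory never creates new completed events", {
  g <- small_markov()
  ser <- chain_state_series(g$traj, g$system)
  ev_full <- detect_events(ser)
  comp_full <- ev_full[!ev_full$censored, ]
  short <- ser
  short$states <- ser$states[1:200, , drop = FALSE]
  short$counts <- ser$counts[1:200, , drop = FALSE]
  ev_short <- detect_events(short)
  comp_short <- ev_short[!ev_short$censored, ]
  expect_lte(nrow(comp_short), nrow(comp_full))
  key <- function(d) paste(d$chain, d$state, d$start, d$duration)
  expect_true(all(key(comp_short) %in% key(comp_full)))
})

test_that("adsorbed-atom distributions are restricted to adsorbed frames and
          conserve counts", {
  g <- small_markov()
  ser <- chain_state_series(g$traj, g$system)
  ad <- adsorbed_atoms_distribution(ser)
  expect_equal(sum(ad$count), sum(ser$states))
  # generator places whole chains in the shell: all mass at n
  expect_equal(ad$probability[ad$n_atoms == 4], 1)
})
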