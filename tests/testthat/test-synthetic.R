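# Generators: analytic ground truth of the Markov tier, physical sanity of
# the Brownian-dynamics tier, and isotherm data generation.

test_that("Markov limits: k_on = 0 never adsorbs, k_off = 0 never desorbs", {
  g0 <- generate_markov_trajectory(markov_params(
    n_chains = 10, n_frames = 300, k_on = 0, k_off = 1,
    water_density = 0, seed = 21, n_protein_points = 100))
  expect_true(all(g0$truth$states == 0L))
  ser <- chain_state_series(g0$traj, g0$system)
  ev <- detect_events(ser)
  expect_equal(attr(ev, "n_adsorption_events"), 0L)
  sf <- suppressWarnings(shell_fraction(g0$traj, g0$system))
  expect_equal(sum(sf$n_poly_shell), 0L)

  g1 <- generate_markov_trajectory(markov_params(
    n_chains = 10, n_frames = 300, k_on = 0.5, k_off = 0, init = "free",
    water_density = 0, seed = 22, n_protein_points = 100))
  # absorbing state: once adsorbed, never free again
  for (c in 1:10) {
    s <- g1$truth$states[, c]
    first <- match(1L, s)
    if (!is.na(first)) expect_true(all(s[first:length(s)] == 1L))
  }
})

test_that("Markov equilibrium occupancy matches k_on/(k_on+k_off)", {
  g <- generate_markov_trajectory(markov_params(
    n_chains = 100, n_frames = 5000, dt = 0.1, k_on = 1, k_off = 1,
    water_density = 0, seed = 23, n_protein_points = 100))
  frac <- mean(g$truth$states)
  # 100 chains x 500 ns; correlation time 1/(k_on+k_off) = 0.5 ns
  n_eff <- 100 * 500 / (2 * 0.5)
  se <- sqrt(0.25 / n_eff)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("Markov per-frame transition frequencies match the propagator and
          adsorbed durations are exponential(k_off)", {
  k_on <- 0.4; k_off <- 1.0; dt <- 0.02
  g <- generate_markov_trajectory(markov_params(
    n_chains = 50, n_frames = 10000, dt = dt, k_on = k_on, k_off = k_off,
    water_density = 0, seed = 24, n_protein_points = 100))
  st <- g$truth$states
  lam <- k_on + k_off; p <- k_on / lam
  p_fa <- p * (1 - exp(-lam * dt))
  p_af <- (1 - p) * (1 - exp(-lam * dt))
  from_f <- st[-nrow(st), ] == 0L
  trans_fa <- mean(st[-1, ][from_f] == 1L)
  trans_af <- mean(st[-1, ][!from_f] == 0L)
  n_f <- sum(from_f); n_a <- sum(!from_f)
  expect_lt(abs(trans_fa - p_fa), 3 * sqrt(p_fa * (1 - p_fa) / n_f))
  expect_lt(abs(trans_af - p_af), 3 * sqrt(p_af * (1 - p_af) / n_a))
  # completed adsorbed durations: geometric run lengths whose continuous
  # limit is exponential with mean 1/k_off; KS against the exact geometric
  # mean-matched exponential at n >= 1000
  ser <- state_series_from_counts(st * 4L, rep(4L, 50), dt)
  ev <- detect_events(ser)
  dur <- ev$duration[ev$state == "adsorbed" & !ev$censored]
  expect_gt(length(dur), 1000)
  mean_dur <- dt / ((1 - p) * (1 - exp(-lam * dt)))
  ks <- suppressWarnings(stats::ks.test(dur, "pexp", 1 / mean_dur))
  expect_gt(ks$p.value, 0.01)
})

test_that("generator geometry is exactly recoverable by the detector", {
  g <- small_markov()
  ser <- chain_state_series(g$traj, g$system)
  expect_identical(ser$states, g$truth$states)
  # all-in / all-out placement: counts are 0 or the full chain
  expect_true(all(ser$counts %in% c(0L, ser$n_heavy[1])))
})

test_that("isotherm generator lies on the curve without noise and saturates", {
  As <- c(0.01, 0.05, 0.1, 0.3)
  d0 <- generate_isotherm_data(0.32, 5.66, As, noise_sd = 0)
  expect_equal(d0$AP, 0.32 * 5.66 * As / (1 + 5.66 * As), tolerance = 1e-12)
  expect_equal(generate_isotherm_data(0.32, 5.66, 1e-12)$AP, 0,
               tolerance = 1e-9)
  expect_equal(generate_isotherm_data(0.32, 5.66, 0.9999,
                                      noise_sd = 0)$AP / 0.32,
               1, tolerance = 0.2)  # As >> 1/Ka approaches Ps_max
  expect_error(generate_isotherm_data(0.32, 5.66, 0.1, noise_sd = -1),
               "noise_sd")
})

test_that("BD free beads recover the input diffusion coefficient", {
  g <- generate_bd_trajectory(bd_params(
    n_chains = 300, n_beads = 1, radius = 0, D = 40, a_rep = 0,
    n_frames = 600, save_every = 20, n_equil = 0, seed = 31))
  d <- diffusion_coefficient(g$traj, heavy_atoms(g$system, "polymer"),
                             fit_window = c(0.1, 1.2))
  expect_lt(abs(d$D - 40) / 40, 0.10)
})

test_that("BD chains without surface attraction show no shell enrichment", {
  # BD frames are autocorrelated (a chain takes ~1 ns to diffuse a shell
  # width), so per-bin errors come from ~1 ns block averages, not
  # per-sample binomial counts
  g <- generate_bd_trajectory(bd_params(
    n_chains = 100, n_beads = 3, eps_surf = 0, a_rep = 0,
    n_frames = 500, save_every = 100, n_equil = 5000, seed = 32,
    box = 50, radius = 10, n_protein_points = 300))
  n_blocks <- 10
  idx <- split(seq_len(g$traj$n_frames),
               cut(seq_len(g$traj$n_frames), n_blocks, labels = FALSE))
  gmat <- sapply(idx, function(ii) {
    sub <- trajectory(g$traj$coords[, , ii, drop = FALSE],
                      g$traj$box[ii[1], ], dt = g$traj$dt)
    polymer_rdf(sub, g$system, bin_width = 2, r_max = 12,
                n_ref_samples = 1e5)$g
  })
  gbar <- rowMeans(gmat)
  gse <- apply(gmat, 1, sd) / sqrt(n_blocks)
  z <- abs(gbar - 1) / gse
  expect_gt(mean(z < 3, na.rm = TRUE), 0.8)
  expect_lt(abs(mean(gbar, na.rm = TRUE) - 1), 0.15)
})

test_that("BD detailed balance: 1-bead shell occupancy matches the
          Boltzmann weight of the surface well", {
  eps <- 1.0; sigma <- 2.5; Rp <- 12; box <- 50
  g <- generate_bd_trajectory(bd_params(
    n_chains = 60, n_beads = 1, eps_surf = eps, sigma_surf = sigma,
    n_frames = 2500, save_every = 10, n_equil = 5000, seed = 33,
    box = box, radius = Rp, n_protein_points = 400, a_rep = 0))
  kBT <- 1.9872e-3 * 300
  # radial distance of every bead from the sphere center, each frame
  ctr <- rep(box / 2, 3)
  sel <- heavy_atoms(g$system, "polymer")
  shell_cut <- Rp + 2 * sigma
  inshell <- ninside <- 0
  for (f in seq_len(g$traj$n_frames)) {
    X <- frame_coords(g$traj, f)[sel, , drop = FALSE]
    d <- sweep(X, 2, ctr)
    d <- d - box * round(d / box)
    r <- sqrt(rowSums(d^2))
    inshell <- inshell + sum(r > Rp & r <= shell_cut)
    ninside <- ninside + sum(r > shell_cut)
  }
  p_obs <- inshell / (inshell + ninside)
  # Boltzmann expectation: radial integral of exp(-U/kT) r^2 dr over the
  # shell vs the remaining accessible volume (well tail truncated there)
  rgrid <- seq(Rp, shell_cut, length.out = 400)
  w <- exp(eps / kBT * exp(-(rgrid - Rp)^2 / (2 * sigma^2)))
  vol_shell_w <- 4 * pi * sum(w * rgrid^2) * diff(rgrid[1:2])
  vol_out <- box^3 - 4 * pi / 3 * shell_cut^3
  p_exp <- vol_shell_w / (vol_shell_w + vol_out)
  expect_lt(abs(p_obs - p_exp) / p_exp, 0.15)
})

test_that("BD bond fluctuations stay within the stability bound", {
  g <- generate_bd_trajectory(bd_params(
    n_chains = 5, n_beads = 4, n_frames = 200, n_equil = 1000, seed = 34,
    radius = 0))
  expect_lt(g$diagnostics$bond_rel_fluct, 0.3)
})

test_that("chain-chain attraction strictly increases aggregation", {
  largest <- sapply(c(0, 2), function(ecc) {
    mean(sapply(1:3, function(s) {
      g <- generate_bd_trajectory(bd_params(
        n_chains = 15, n_beads = 4, eps_cc = ecc, radius = 0,
        n_frames = 150, n_equil = 3000, seed = 40 + s, box = 45))
      mean(cluster_report(g$traj, g$system)$largest)
    }))
  })
  expect_gt(largest[2], largest[1])
})
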