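# Hydration structure, hydrogen bonds, aggregation clusters, diffusion.

test_that("cumulative water RDF matches the uniform closed form", {
  # single probe atom in uniform 'water' at density rho: N(r) = rho 4/3 pi r^3
  box <- rep(40, 3)
  rho <- 0.0334 / 10
  n_w <- round(rho * prod(box))
  tmpl <- build_polymer_topology("generic", 1)
  sys <- assemble_system(NULL, tmpl, 1, n_w, box = box)
  set.seed(12)
  nf <- 60
  coords <- array(NA_real_, c(1 + n_w, 3, nf))
  coords[1, , ] <- box / 2
  for (f in seq_len(nf))
    coords[2:(1 + n_w), , f] <- matrix(runif(3 * n_w), ncol = 3) %*% diag(box)
  traj <- trajectory(coords, box, dt = 0.01)
  cr <- cumulative_water_rdf(traj, sys, r_max = 10, dr = 0.5)
  expect_equal(cr$n[1], 0)
  expect_true(all(diff(cr$n) >= 0))
  expected10 <- rho * 4 / 3 * pi * 1000
  got10 <- cr$n[cr$r == 10]
  se <- sqrt(expected10 / nf)
  expect_lt(abs(got10 - expected10), 3 * se)
  # no water -> identically zero
  sys0 <- assemble_system(NULL, tmpl, 1, 0, box = box)
  traj0 <- trajectory(coords[1, , , drop = FALSE], box, dt = 0.01)
  expect_true(all(cumulative_water_rdf(traj0, sys0, r_max = 10)$n == 0))
  expect_error(cumulative_water_rdf(traj, sys, r_max = 30), "half")
})

test_that("hydrogen bonds follow the distance/angle criterion", {
  # O-H...O with d(O..O) = 2.8 A and 5 degree deviation -> one bond
  frame <- rbind(c(0, 0, 0),                      # donor O
                 c(0.96, 0, 0),                   # H on donor
                 c(2.8 * cos(5 * pi / 180), 2.8 * sin(5 * pi / 180), 0))
  donors <- data.frame(d = 1L, h = 2L)
  box <- rep(50, 3)
  hb <- count_hbonds(frame, donors, acceptors = 3L, box = box)
  expect_equal(nrow(hb), 1L)
  expect_lt(hb$deviation, 10)
  # same geometry stretched to 3.6 A -> none
  frame2 <- frame; frame2[3, ] <- frame[3, ] * (3.6 / 2.8)
  expect_equal(nrow(count_hbonds(frame2, donors, 3L, box)), 0L)
  # bent to 40 degrees -> none
  frame3 <- frame
  frame3[3, ] <- c(2.8 * cos(40 * pi / 180), 2.8 * sin(40 * pi / 180), 0)
  expect_equal(nrow(count_hbonds(frame3, donors, 3L, box)), 0L)
  expect_error(count_hbonds(frame, NULL, 3L, box), "donor")
})

test_that("h-bond counts equal a brute-force triple loop on a random
          fixture", {
  set.seed(13)
  box <- rep(25, 3)
  nd <- 15; na_ <- 20
  don_o <- matrix(runif(3 * nd) * 25, ncol = 3)
  don_h <- don_o + matrix(rnorm(3 * nd, sd = 0.4), ncol = 3)
  acc <- matrix(runif(3 * na_) * 25, ncol = 3)
  frame <- rbind(don_o, don_h, acc)
  donors <- data.frame(d = 1:nd, h = nd + 1:nd)
  acceptors <- 2 * nd + seq_len(na_)
  got <- count_hbonds(frame, donors, acceptors, box)
  brute <- 0L
  for (i in 1:nd) for (j in seq_len(na_)) {
    a <- acc[j, ]
    dv <- a - don_o[i, ]; dv <- dv - box * round(dv / box)
    if (sqrt(sum(dv^2)) > 3.5) next
    v1 <- don_h[i, ] - don_o[i, ]
    va <- a - don_h[i, ]; va <- va - box * round(va / box)
    ang <- acos(max(-1, min(1, -sum(v1 * va) /
                              sqrt(sum(v1^2) * sum(va^2))))) * 180 / pi
    if (180 - ang <= 30) brute <- brute + 1L
  }
  expect_equal(nrow(got), brute)
})

test_that("cluster partitions cover all chains and shrink with cutoff", {
  # 3 chains: A and B close, C far
  tmpl <- build_polymer_topology("generic", 2)
  sys <- assemble_system(NULL, tmpl, 3, 0, box = rep(60, 3))
  frame <- rbind(c(5, 5, 5), c(8, 5, 5),      # chain A
                 c(11, 5, 5), c(14, 5, 5),    # chain B (3 A from A's end)
                 c(40, 40, 40), c(43, 40, 40))  # chain C
  cl <- polymer_clusters(frame, sys, cutoff = 4.5)
  expect_equal(sort(cl$sizes), c(1L, 2L))
  expect_equal(sum(cl$sizes), 3L)
  cl_tight <- polymer_clusters(frame, sys, cutoff = 2)
  expect_equal(cl_tight$sizes, c(1L, 1L, 1L))
  expect_gte(cl_tight$n_clusters, cl$n_clusters)
  # mutually distant chains are all singletons
  frame2 <- frame; frame2[3:4, 1] <- frame2[3:4, 1] + 20
  expect_equal(polymer_clusters(frame2, sys, 4.5)$largest, 1L)
})

test_that("diffusion: immobile atoms give D = 0 and MSD starts at zero", {
  box <- rep(30, 3)
  tmpl <- build_polymer_topology("generic", 1)
  sys <- assemble_system(NULL, tmpl, 2, 0, box = box)
  coords <- array(5, c(2, 3, 50))
  traj <- trajectory(coords, box, dt = 0.1)
  d <- suppressWarnings(diffusion_coefficient(traj, 1:2,
                                              fit_window = c(0.2, 2)))
  expect_equal(d$D, 0, tolerance = 1e-12)
  expect_equal(d$msd$msd[1], 0)
})

test_that("aggregating chains dry their hydration shell and slow down", {
  run <- function(ecc, s) generate_bd_trajectory(bd_params(
    n_chains = 15, n_beads = 4, eps_cc = ecc, radius = 0, box = 45,
    n_frames = 400, n_equil = 4000, water_density = 0.004, seed = s))
  n0 <- n2 <- cl0 <- cl2 <- d0 <- d2 <- c()
  for (s in 91:93) {
    g0 <- run(0, s); g2 <- run(3, s)
    n0 <- c(n0, tail(cumulative_water_rdf(g0$traj, g0$system,
                                          r_max = 10)$n, 1))
    n2 <- c(n2, tail(cumulative_water_rdf(g2$traj, g2$system,
                                          r_max = 10)$n, 1))
    cl0 <- c(cl0, mean(cluster_report(g0$traj, g0$system)$largest))
    cl2 <- c(cl2, mean(cluster_report(g2$traj, g2$system)$largest))
    d0 <- c(d0, diffusion_coefficient(g0$traj,
                                      heavy_atoms(g0$system, "polymer"))$D)
    d2 <- c(d2, diffusion_coefficient(g2$traj,
                                      heavy_atoms(g2$system, "polymer"))$D)
  }
  expect_lt(mean(n2), mean(n0))
  expect_gt(mean(cl2), mean(cl0))
  expect_lt(mean(d2), mean(d0))
})
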