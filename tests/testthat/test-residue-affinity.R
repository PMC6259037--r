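# Residue-shell polymer/water counts, per-type pooling, cross-polymer
# correlation, density grids and OpenDX export.

# small constructed system: 4 protein atoms (2 residues), polymer points,
# water points, one frame
affinity_fixture <- function(npol = 40, nwat = 60, seed = 14) {
  set.seed(seed)
  box <- rep(30, 3)
  prot <- data.frame(
    id = 1:4, element = "C", mass = 12.011,
    resname = c("ALA", "ALA", "SER", "SER"), resid = c(1, 1, 2, 2),
    chain = "A", role = "protein")
  tmpl <- build_polymer_topology("generic", 1)
  sys <- assemble_system(prot, tmpl, npol, nwat, box = box)
  coords <- array(NA_real_, c(4 + npol + nwat, 3, 1))
  coords[1:4, , 1] <- rbind(c(8, 8, 8), c(10, 8, 8), c(20, 20, 20),
                            c(22, 20, 20))
  coords[5:(4 + npol + nwat), , 1] <-
    matrix(runif(3 * (npol + nwat)) * 30, ncol = 3)
  list(sys = sys, traj = trajectory(coords, box, dt = 0.1))
}

test_that("residue counts equal a brute-force double loop", {
  fx <- affinity_fixture()
  tab <- residue_shell_counts(fx$traj, fx$sys, cutoff = 5)
  X <- frame_coords(fx$traj, 1)
  box <- fx$sys$box
  brute <- function(sel, res_rows) {
    sum(sapply(sel, function(i) {
      any(sapply(res_rows, function(j) {
        dv <- X[i, ] - X[j, ]; dv <- dv - box * round(dv / box)
        sqrt(sum(dv^2)) <= 5
      }))
    }))
  }
  poly <- heavy_atoms(fx$sys, "polymer"); wat <- heavy_atoms(fx$sys, "water")
  expect_equal(tab$residues$n_polymer,
               c(brute(poly, 1:2), brute(poly, 3:4)))
  expect_equal(tab$residues$n_water,
               c(brute(wat, 1:2), brute(wat, 3:4)))
})

test_that("per-type pooling conserves counts and normalizes by the bulk
          ratio", {
  fx <- affinity_fixture()
  tab <- residue_shell_counts(fx$traj, fx$sys, cutoff = 5)
  # pooling consistency: type sums equal residue sums
  for (ty in tab$types$type) {
    rows <- tab$residues$type == ty
    expect_equal(tab$types$n_polymer[tab$types$type == ty],
                 sum(tab$residues$n_polymer[rows]))
    expect_equal(tab$types$n_water[tab$types$type == ty],
                 sum(tab$residues$n_water[rows]))
  }
  expect_equal(tab$bulk_ratio, 40 / 60)
  # constructed ratio: shell with 6 polymer and 3 water at bulk ratio 1
  # normalizes to 2
  expect_equal((6 / 3) / 1, 2)
})

test_that("uniform mixtures give normalized ratios of 1 within noise", {
  g <- generate_markov_trajectory(markov_params(
    n_chains = 60, n_monomers = 1, n_frames = 80, k_on = 0, k_off = 1,
    water_density = 0.003, free_placement = "uniform", resample = "frame",
    seed = 15, n_protein_points = 60))
  tab <- residue_shell_counts(g$traj, g$system, cutoff = 5)
  good <- !is.na(tab$types$norm_ratio)
  # pooled over the sphere pseudo-residues: close to 1
  pooled <- sum(tab$types$n_polymer[good]) / sum(tab$types$n_water[good])
  expect_lt(abs(pooled / tab$bulk_ratio - 1), 0.15)
})

test_that("binding-patch adsorption raises the ratios of patch residues", {
  g <- generate_markov_trajectory(markov_params(
    n_chains = 40, n_frames = 150, k_on = 2, k_off = 1,
    water_density = 0.003, resample = "frame", anchor_patch = 0.25,
    seed = 16, n_protein_points = 200))
  tab <- residue_shell_counts(g$traj, g$system, cutoff = 5)
  r <- tab$residues
  patch <- r$ratio[r$resid <= 50]     # anchors: first quarter of the lattice
  far <- r$ratio[r$resid > 100]
  expect_gt(median(patch, na.rm = TRUE), median(far, na.rm = TRUE))
  w <- stats::wilcox.test(patch, far, alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("compare_polymers: identity, translation, anti-ordering", {
  mk <- function(vals) {
    list(types = data.frame(type = LETTERS[seq_along(vals)],
                            norm_ratio = vals))
  }
  a <- mk(c(0.5, 1.0, 1.5, 2.0, 2.5))
  expect_equal(compare_polymers(a, a)$r, 1)
  expect_equal(compare_polymers(a, a)$offset, 0)
  b <- mk(c(0.5, 1.0, 1.5, 2.0, 2.5) + 0.5)
  cmp <- compare_polymers(a, b)
  expect_equal(cmp$r, 1)
  expect_equal(cmp$offset, 0.5)
  anti <- mk(rev(c(0.5, 1.0, 1.5, 2.0, 2.5)))
  expect_lt(compare_polymers(a, anti)$r, 0)
  expect_error(compare_polymers(mk(c(1, NA, NA, NA, 2)), a), "fewer than 3")
})

test_that("density grids conserve counts and threshold sensibly", {
  fx <- affinity_fixture(npol = 30, nwat = 0)
  grid <- polymer_density_grid(fx$traj, fx$sys, voxel = 2, align = FALSE)
  expect_equal(sum(grid$counts), 30)  # one frame, all atoms binned
  # static single atom: all mass in one voxel
  box <- rep(20, 3)
  tmpl <- build_polymer_topology("generic", 1)
  sys1 <- assemble_system(NULL, tmpl, 1, 0, box = box)
  coords <- array(rep(c(5.5, 5.5, 5.5), 4), c(1, 3, 4))
  tr1 <- trajectory(coords, box, dt = 0.1)
  g1 <- polymer_density_grid(tr1, sys1, voxel = 1, align = FALSE)
  expect_equal(sum(g1$counts > 0), 1L)
  expect_equal(max(g1$density), 1)  # 1 atom per frame per voxel of 1 A^3
  # thresholding: one hot voxel at 10x bulk
  thr <- threshold_regions(g1, factor = 2)
  expect_equal(thr$n_voxels, 1L)
  # monotone non-increasing mask size in the factor
  grid2 <- polymer_density_grid(fx$traj, fx$sys, voxel = 3, align = FALSE)
  sizes <- sapply(c(0.5, 1, 2, 4), function(f)
    threshold_regions(grid2, f)$n_voxels)
  expect_true(all(diff(sizes) <= 0))
})

test_that("alignment puts the polymer map in the protein frame", {
  # protein rotating rigidly with a polymer atom fixed relative to it:
  # aligned map concentrates, unaligned map smears
  box <- rep(40, 3)
  prot <- data.frame(id = 1:4, element = "C", mass = 12.011,
                     resname = "ALA", resid = 1:4, chain = "A",
                     role = "protein")
  tmpl <- build_polymer_topology("generic", 1)
  sys <- assemble_system(prot, tmpl, 1, 0, box = box)
  base_p <- rbind(c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(-4, 0, 0))
  base_x <- c(6.3, 0.4, 0.2)   # off voxel boundaries after alignment
  nf <- 12
  coords <- array(NA_real_, c(5, 3, nf))
  for (f in seq_len(nf)) {
    th <- (f - 1) * pi / nf
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    coords[1:4, , f] <- sweep(base_p %*% R, 2, box / 2, `+`)
    coords[5, , f] <- (base_x %*% R) + box / 2
  }
  traj <- trajectory(coords, box, dt = 0.1)
  g_al <- polymer_density_grid(traj, sys, voxel = 2, align = TRUE)
  g_un <- polymer_density_grid(traj, sys, voxel = 2, align = FALSE)
  expect_lte(sum(g_al$counts > 0), 2L)
  expect_gt(sum(g_un$counts > 0), 3L)
})

test_that("OpenDX export round-trips densities", {
  fx <- affinity_fixture(npol = 25, nwat = 0)
  grid <- polymer_density_grid(fx$traj, fx$sys, voxel = 3, align = FALSE)
  f <- tempfile(fileext = ".dx")
  write_dx(grid, f)
  back <- read_dx(f)
  expect_equal(dim(back$density), dim(grid$density))
  expect_lt(max(abs(back$density - grid$density)), 1e-5)
  expect_equal(back$voxel, grid$voxel)
})
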