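# Topology data model, chain builder, selections, bookkeeping, geometry.

test_that("polymer templates reproduce the published heavy-atom counts", {
  expect_equal(template_n_heavy(build_polymer_topology("PEG", 7)), 22L)
  expect_equal(template_n_heavy(build_polymer_topology("PSar", 4)), 26L)
  expect_equal(template_n_heavy(build_polymer_topology("PAla", 4)), 26L)
  # PSar and PAla are constitutional isomers at every length
  for (n in c(1, 4, 7))
    expect_equal(template_n_heavy(build_polymer_topology("PSar", n)),
                 template_n_heavy(build_polymer_topology("PAla", n)))
  expect_equal(build_polymer_topology("PSar", 4)$mass,
               build_polymer_topology("PAla", 4)$mass)
  # diol PEG n-mer has 3n+1 heavy atoms; dimethyl-capped 3n+3
  expect_equal(template_n_heavy(build_polymer_topology("PEG", 4)), 13L)
  expect_equal(template_n_heavy(
    build_polymer_topology("PEG", 7, peg_cap = "dimethyl")), 24L)
  # dimethyl-capped PEG 7-mer formula C16H34O8
  expect_equal(build_polymer_topology("PEG", 7, peg_cap = "dimethyl")$mass,
               16 * 12.011 + 34 * 1.008 + 8 * 15.999, tolerance = 1e-6)
  expect_error(build_polymer_topology("PXX", 4), "unknown polymer kind")
  expect_error(build_polymer_topology("PEG", 0), "n_monomers")
})

test_that("template molecular weights match the molecular formulas", {
  # H-(OCH2CH2)7-OH = C14H30O8
  expect_equal(build_polymer_topology("PEG", 7)$mass,
               14 * 12.011 + 30 * 1.008 + 8 * 15.999, tolerance = 1e-6)
  # CH3CO-[N(CH3)CH2CO]4-N(CH3)2 = C16H29N5O5
  expect_equal(build_polymer_topology("PSar", 4)$mass,
               16 * 12.011 + 29 * 1.008 + 5 * 14.007 + 5 * 15.999,
               tolerance = 1e-6)
})

test_that("heavy_atoms excludes hydrogens and respects chain selections", {
  atoms <- data.frame(
    id = 1:6, element = c("O", "H", "H", "C", "H", "N"),
    mass = c(15.999, 1.008, 1.008, 12.011, 1.008, 14.007),
    resname = c("HOH", "HOH", "HOH", "ALA", "ALA", "ALA"),
    resid = c(1, 1, 1, 2, 2, 2), chain = "A",
    role = c("water", "water", "water", "protein", "protein", "protein"))
  sys <- molecular_system(atoms, list(), box = c(50, 50, 50))
  expect_equal(as.integer(heavy_atoms(sys, "water")), 1L)   # the water O
  expect_equal(as.integer(heavy_atoms(sys, "protein")), c(4L, 6L))
  expect_warning(heavy_atoms(sys, "polymer"), "empty")
})

test_that("mass concentration does the unit arithmetic and scales linearly", {
  # one molecule of MW 602.2 g/mol in a (100 A)^3 box is 1e-3 g/ml
  tmpl <- build_polymer_topology("generic", 1)
  sys1 <- assemble_system(NULL, tmpl, 1, 0, box = rep(100, 3))
  sys1$chains[[1]]$mass <- 602.2
  expect_equal(mass_concentration(sys1), 602.2 / 6.02214076e23 / 1e-18,
               tolerance = 1e-6)
  expect_equal(mass_concentration(sys1), 1.0e-3, tolerance = 1e-3)
  # doubling the chain count doubles the concentration
  peg <- build_polymer_topology("PEG", 7)
  s44 <- assemble_system(NULL, peg, 44, 0, box = rep(109, 3))
  s88 <- assemble_system(NULL, peg, 88, 0, box = rep(109, 3))
  expect_equal(2 * mass_concentration(s44), mass_concentration(s88))
  # inverse-cubic in the box edge
  s2 <- assemble_system(NULL, peg, 44, 0, box = rep(218, 3))
  expect_equal(mass_concentration(s44) / 8, mass_concentration(s2))
  expect_warning(
    expect_equal(mass_concentration(
      molecular_system(s44$atoms[s44$atoms$role != "polymer", , drop = FALSE],
                       list(), rep(109, 3))), 0),
    "no polymer")
})

test_that("minimum-image distance matches 27-image brute force", {
  box <- c(100, 80, 60)
  expect_equal(min_image_distance(c(1, 5, 5), c(99, 5, 5), c(100, 100, 100)),
               2.0)
  expect_equal(min_image_distance(c(3, 4, 5), c(3, 4, 5), box), 0)
  set.seed(7)
  for (i in 1:1000) {
    a <- runif(3) * box; b <- runif(3) * box
    expect_equal(min_image_distance(a, b, box), brute_min_image(a, b, box),
                 tolerance = 1e-12)
  }
})

test_that("Kabsch RMSD is zero for self and rigid copies, and matches a
          quaternion-grid minimizer", {
  set.seed(11)
  X <- matrix(rnorm(30, sd = 5), 10, 3)
  expect_equal(kabsch_rmsd(X, X), 0, tolerance = 1e-12)
  Y <- rigid_transform(X, seed = 3)
  expect_lt(kabsch_rmsd(Y, X), 1e-7)   # nm
  # grid-search oracle on two fixed 4-point sets: exhaustive search over
  # rotations (axis-angle grid) after centroid removal
  A <- matrix(c(0, 0, 0, 3, 0, 0, 3, 3, 0, 0, 3, 1), 4, 3, byrow = TRUE)
  B <- matrix(c(0, 0, 0, 2.8, 0.4, 0, 3.1, 3, 0.2, -0.2, 2.9, 1.2),
              4, 3, byrow = TRUE)
  grid_rmsd <- function(A, B, n_axis = 80, n_ang = 160) {
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    rot <- function(v) {   # axis-angle (Rodrigues) rotation matrix
      ang <- sqrt(sum(v^2))
      if (ang < 1e-12) return(diag(3))
      ax <- v / ang
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    }
    obj <- function(v) sqrt(mean(rowSums((Ac %*% rot(v) - Bc)^2)))
    best <- Inf; best_v <- c(0, 0, 0)
    gold <- pi * (3 - sqrt(5))
    for (i in seq_len(n_axis)) {
      z <- 1 - 2 * (i - 0.5) / n_axis
      r <- sqrt(1 - z^2); th <- gold * i
      ax <- c(r * cos(th), r * sin(th), z)
      for (ang in seq(0.01, 2 * pi, length.out = n_ang)) {
        v <- obj(ax * ang)
        if (v < best) { best <- v; best_v <- ax * ang }
      }
    }
    # derivative-free polish of the best grid rotation
    best <- optim(best_v, obj, method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 2000))$value
    best / 10  # nm
  }
  expect_lt(abs(kabsch_rmsd(A, B) - grid_rmsd(A, B)), 1e-4)
  # degenerate: collinear points
  L <- cbind(0:3, 0, 0)
  expect_error(kabsch_rmsd(L, L + 1), "degenerate|collinear")
})

test_that("PDB parsing assigns roles and counts the HSA-scale census", {
  path <- system.file("extdata", "hsa_ca_synthetic.pdb",
                      package = "coronadsorb")
  sys <- load_topology(path)
  cen <- system_census(sys)
  expect_equal(cen$n_protein_residues, 578L)
  expect_equal(sum(sys$atoms$role == "protein"), 578L)
  expect_equal(length(sys$chains), 0L)
  expect_equal(sys$box, c(100, 100, 100))
})

test_that("water-only and unknown-residue files are handled per config", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   30.000   30.000   30.000  90.00  90.00  90.00 P 1           1",
    sprintf("ATOM  %5d  OW  HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            1:3, 1:3, c(1, 5, 9), c(1, 5, 9), c(1, 5, 9)), "END"), f)
  sys <- load_topology(f)
  expect_equal(unname(table(sys$atoms$role)[c("water")]), 3L)
  expect_equal(sum(sys$atoms$role == "protein"), 0L)
  expect_equal(sum(sys$atoms$role == "polymer"), 0L)
  # unknown residue name: error when requested, protein fallback otherwise
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  C1  XYZ A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1L, 1L, 1, 1, 1), "END"), f2)
  expect_error(load_topology(f2, unknown = "error"), "XYZ")
  expect_equal(load_topology(f2)$atoms$role, "protein")
})

test_that("builder-written topology round-trips through PDB", {
  gen <- generate_markov_trajectory(markov_params(
    n_chains = 2, n_monomers = 4, n_frames = 2,
    water_density = 50 / 60^3, seed = 5, n_protein_points = 100))
  f <- tempfile(fileext = ".pdb")
  write_topology(gen$system, frame_coords(gen$traj, 1), f)
  back <- load_topology(f)
  expect_equal(length(back$chains), 2L)
  expect_equal(vapply(back$chains, function(ch) length(ch$atom_ids),
                      integer(1)), c(4L, 4L))
  expect_equal(sum(back$atoms$role == "water"), 50L)
  expect_equal(as.character(table(back$atoms$role)[c("protein")]), "100")
})
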