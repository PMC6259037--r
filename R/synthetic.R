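## Synthetic-trajectory generators. Two tiers:
##  * a two-state Markov placement model with exact analytic ground truth
##    (adsorbed probability, exponential residence times), used to validate
##    the kinetics / isotherm / energetics machinery;
##  * an overdamped Brownian-dynamics bead-spring simulator with a protein
##    surface well, used where physically realistic conformational and
##    aggregation behaviour is needed.

#' Idealized spherical protein as a surface point lattice
#'
#' Realizes a rigid sphere as near-uniform surface points (Fibonacci
#' lattice), so distance-to-nearest-protein-atom analyses work unchanged.
#' Each point is its own residue.
#'
#' @param radius sphere radius (Angstrom).
#' @param n_points number of surface points; spacing is
#'   `sqrt(4 pi R^2 / n)`, which bounds the surface-distance discretization
#'   error.
#' @param box length-3 box (Angstrom); the sphere sits at the box center.
#' @return List with `atoms` (data.frame in [molecular_system()] format),
#'   `coords` (`n x 3`), and `model` (`list(type="sphere", center, radius)`).
#' @export
make_sphere_protein <- function(radius, n_points = 800, box) {
  center <- box / 2
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  coords <- cbind(center[1] + radius * sin(phi) * cos(theta),
                  center[2] + radius * sin(phi) * sin(theta),
                  center[3] + radius * cos(phi))
  atoms <- data.frame(
    id = seq_len(n_points), element = "C", mass = 12.011,
    resname = "SPH", resid = seq_len(n_points), chain = "S",
    role = "protein")
  list(atoms = atoms, coords = coords,
       model = list(type = "sphere", center = center, radius = radius))
}

#' Parameters for the Markov placement generator
#'
#' Each chain is an independent two-state continuous-time Markov chain
#' (free <-> adsorbed) propagated exactly over the frame spacing. When
#' adsorbed, every bead is placed at surface distance in `(0, cutoff -
#' delta]`; when free, every bead beyond `cutoff + delta`. The margin
#' `delta` guarantees the hysteresis detector recovers the true state of
#' every frame exactly.
#'
#' Defaults mirror the study conditions this generator stands in for at desk
#' scale: 4-mer chains, a 0.5 nm shell cutoff, per-chain rates of the order
#' of the measured adsorption/desorption rates (mean residence ~1 ns), and
#' water represented as a uniform, non-interacting count reference.
#'
#' @param n_chains number of polymer chains.
#' @param n_monomers beads per chain.
#' @param k_on,k_off transition rates free->adsorbed / adsorbed->free
#'   (1/ns).
#' @param dt frame spacing (ns).
#' @param n_frames number of frames.
#' @param box box edge(s), Angstrom (scalar = cubic).
#' @param radius protein sphere radius (Angstrom).
#' @param n_protein_points sphere surface lattice size.
#' @param cutoff shell cutoff (Angstrom).
#' @param delta placement margin (Angstrom).
#' @param bond bead spacing of the placement random walk (Angstrom).
#' @param water_density water-oxygen number density (1/A^3). The default is
#'   a tenth of bulk water; water enters only as a count reference, so the
#'   scale cancels in ratio statistics.
#' @param resample how often positions are redrawn: `"transition"` (only
#'   when the state flips; cheap, right for kinetics) or `"frame"` (every
#'   frame; right for density statistics).
#' @param free_placement `"bulk"` keeps free chains beyond `cutoff + delta`;
#'   `"uniform"` places them anywhere outside the protein (ideal-gas
#'   reference for RDF validation).
#' @param init initial state distribution: `"stationary"` or `"free"`.
#' @param anchor_patch fraction of sphere points (by lattice order) usable
#'   as adsorption anchors; < 1 concentrates adsorption on part of the
#'   surface ("binding patch") for residue-affinity validation.
#' @param protein optional pre-built protein (result of
#'   [make_sphere_protein()]); overrides `radius`/`n_protein_points`.
#' @param seed RNG seed.
#' @return List of parameters (class `markov_params`).
#' @export
markov_params <- function(n_chains = 30, n_monomers = 4, k_on = 0.2,
                          k_off = 1.0, dt = 0.01, n_frames = 2000,
                          box = 60, radius = 15, n_protein_points = 800,
                          cutoff = 5.0, delta = 1.0, bond = 1.5,
                          water_density = 0.00334,
                          resample = c("transition", "frame"),
                          free_placement = c("bulk", "uniform"),
                          init = c("stationary", "free"),
                          anchor_patch = 1.0, protein = NULL, seed = 1L) {
  if (k_on < 0 || k_off < 0) stop("rates must be >= 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (delta <= 0) stop("placement margin delta must be > 0", call. = FALSE)
  if (dt * max(k_on, k_off) > 0.1)
    warning("dt * max(k_on, k_off) > 0.1: frame spacing is coarse for the ",
            "requested rates", call. = FALSE)
  if (cutoff - delta < bond)
    stop("shell too thin for the chain: cutoff - delta < bead spacing",
         call. = FALSE)
  structure(list(
    n_chains = n_chains, n_monomers = n_monomers, k_on = k_on, k_off = k_off,
    dt = dt, n_frames = n_frames, box = rep(box, length.out = 3),
    radius = radius, n_protein_points = n_protein_points, cutoff = cutoff,
    delta = delta, bond = bond, water_density = water_density,
    resample = match.arg(resample),
    free_placement = match.arg(free_placement), init = match.arg(init),
    anchor_patch = anchor_patch, protein = protein, seed = seed),
    class = "markov_params")
}

#' Generate a trajectory from the Markov placement model
#'
#' @param params a [markov_params()].
#' @return List with `system` (a [molecular_system()]), `traj` (a
#'   [trajectory()]) and `truth` (list: `p` the stationary adsorbed
#'   probability `k_on/(k_on+k_off)`, `mean_adsorbed = 1/k_off`,
#'   `mean_free = 1/k_on`, and `states`, the realized `n_frames x n_chains`
#'   adsorbed indicator matrix).
#' @export
generate_markov_trajectory <- function(params) {
  p <- params
  set.seed(p$seed)
  prot <- if (is.null(p$protein))
    make_sphere_protein(p$radius, p$n_protein_points, p$box) else p$protein

  lambda <- p$k_on + p$k_off
  peq <- if (lambda > 0) p$k_on / lambda else 0
  E <- exp(-lambda * p$dt)
  p_fa <- peq * (1 - E)            # free -> adsorbed over one frame
  p_af <- (1 - peq) * (1 - E)      # adsorbed -> free over one frame

  states <- matrix(0L, p$n_frames, p$n_chains)
  s <- if (p$init == "stationary") as.integer(runif(p$n_chains) < peq)
       else integer(p$n_chains)
  states[1, ] <- s
  if (p$n_frames > 1) {
    for (f in 2:p$n_frames) {
      u <- runif(p$n_chains)
      s <- ifelse(s == 1L, ifelse(u < p_af, 0L, 1L),
                           ifelse(u < p_fa, 1L, 0L))
      states[f, ] <- s
    }
  }

  n_anchor <- max(1L, round(p$anchor_patch * nrow(prot$coords)))
  poly <- cpp_markov_place(
    states, prot$coords, n_anchor, p$box,
    p$cutoff, p$delta, p$n_monomers, p$bond,
    has_sphere = identical(prot$model$type, "sphere"),
    center = if (!is.null(prot$model$center)) prot$model$center else p$box / 2,
    Rp = if (!is.null(prot$model$radius)) prot$model$radius else 0,
    r_excl = 2.0,
    resample_all = (p$resample == "frame"),
    free_uniform = (p$free_placement == "uniform"))
  npoly <- p$n_chains * p$n_monomers
  dim(poly) <- c(npoly, 3, p$n_frames)

  n_w <- round(p$water_density * prod(p$box))
  m <- nrow(prot$coords)
  natoms <- m + npoly + n_w
  coords <- array(NA_real_, c(natoms, 3, p$n_frames))
  coords[seq_len(m), , ] <- prot$coords
  coords[m + seq_len(npoly), , ] <- poly
  if (n_w > 0) {
    center <- prot$model$center; R2 <- prot$model$radius^2
    for (f in seq_len(p$n_frames)) {
      W <- matrix(runif(3 * n_w), ncol = 3) %*% diag(p$box)
      inside <- rowSums(sweep(W, 2, center)^2) < R2
      while (any(inside)) {
        W[inside, ] <- matrix(runif(3 * sum(inside)), ncol = 3) %*% diag(p$box)
        inside <- rowSums(sweep(W, 2, center)^2) < R2
      }
      coords[m + npoly + seq_len(n_w), , f] <- W
    }
  }

  tmpl <- build_polymer_topology("generic", p$n_monomers)
  system <- assemble_system(prot$atoms, tmpl, p$n_chains, n_w, p$box,
                            protein_model = prot$model)
  traj <- trajectory(coords, p$box, dt = p$dt, discard = 0)
  truth <- list(p = peq,
                mean_adsorbed = if (p$k_off > 0) 1 / p$k_off else Inf,
                mean_free = if (p$k_on > 0) 1 / p$k_on else Inf,
                states = states, k_on = p$k_on, k_off = p$k_off)
  list(system = system, traj = traj, truth = truth)
}

#' Parameters for the Brownian-dynamics generator
#'
#' Overdamped Langevin dynamics of bead-spring chains in a periodic box
#' around a rigid spherical protein: harmonic bonds, optional cosine angle
#' stiffness (stiff chains mimic the reduced flexibility of peptoid/peptide
#' backbones relative to PEG), a Gaussian surface attraction well, and an
#' optional inter-chain attraction well driving self-aggregation
#' (poly-alanine-like behaviour).
#'
#' @param n_chains,n_beads chains and beads per chain.
#' @param bond_r0 bond rest length (Angstrom).
#' @param bond_k bond stiffness (kcal/mol/A^2).
#' @param angle_k cosine angle stiffness (kcal/mol); 0 = fully flexible.
#' @param eps_surf surface well depth (kcal/mol); 0 = no adsorption.
#' @param sigma_surf surface well range (Angstrom).
#' @param eps_cc inter-chain well depth (kcal/mol); 0 = no aggregation.
#' @param sigma_cc,cc_d0 inter-chain well width and location (Angstrom).
#' @param a_rep,sigma_rep soft excluded-volume repulsion between chains.
#' @param D bead diffusion coefficient (A^2/ns).
#' @param temperature Kelvin (sets kT = R T).
#' @param dt integration timestep (ns).
#' @param n_frames saved frames; `save_every` steps between saves.
#' @param save_every steps per saved frame (frame spacing = dt * save_every).
#' @param box box edge(s), Angstrom.
#' @param radius protein sphere radius; 0 disables the protein entirely.
#' @param n_protein_points sphere lattice size.
#' @param k_wall harmonic wall stiffness inside the sphere.
#' @param water_density per-frame resampled water-oxygen density (1/A^3);
#'   waters are excluded from the protein interior and from within
#'   `water_excl` of any polymer bead, so aggregation dries the polymer's
#'   hydration shell. 0 = no water.
#' @param water_excl water exclusion radius around beads (Angstrom).
#' @param n_equil equilibration steps discarded before saving.
#' @param seed RNG seed.
#' @return List of parameters (class `bd_params`).
#' @export
bd_params <- function(n_chains = 10, n_beads = 4, bond_r0 = 3.0,
                      bond_k = 10, angle_k = 0, eps_surf = 0,
                      sigma_surf = 2.5, eps_cc = 0, sigma_cc = 1.5,
                      cc_d0 = 3.0, a_rep = 3, sigma_rep = 1.5, D = 40,
                      temperature = 300, dt = 2e-4, n_frames = 500,
                      save_every = 25, box = 60, radius = 15,
                      n_protein_points = 800, k_wall = 50,
                      water_density = 0, water_excl = 2.5,
                      n_equil = 2000, seed = 1L) {
  if (sigma_surf <= 0 || (eps_surf < 0))
    stop("surface well parameters must be positive", call. = FALSE)
  kBT <- .GAS_CONSTANT_KCAL * temperature
  # Euler stability heuristic for the stiffest spring
  if ((D / kBT) * bond_k * dt > 0.25)
    warning("timestep is large for the bond stiffness; expect inflated ",
            "bond fluctuations", call. = FALSE)
  structure(list(
    n_chains = n_chains, n_beads = n_beads, bond_r0 = bond_r0,
    bond_k = bond_k, angle_k = angle_k, eps_surf = eps_surf,
    sigma_surf = sigma_surf, eps_cc = eps_cc, sigma_cc = sigma_cc,
    cc_d0 = cc_d0, a_rep = a_rep, sigma_rep = sigma_rep, D = D,
    temperature = temperature, kBT = kBT, dt = dt, n_frames = n_frames,
    save_every = save_every, box = rep(box, length.out = 3), radius = radius,
    n_protein_points = n_protein_points, k_wall = k_wall,
    water_density = water_density, water_excl = water_excl,
    n_equil = n_equil, seed = seed), class = "bd_params")
}

#' Generate a trajectory with the Brownian-dynamics generator
#'
#' @param params a [bd_params()].
#' @return List with `system`, `traj` (frame spacing `dt * save_every` ns)
#'   and `diagnostics` (bond-length RMS fluctuation relative to the rest
#'   length; a warning is raised above 0.3).
#' @export
generate_bd_trajectory <- function(params) {
  p <- params
  set.seed(p$seed)
  has_prot <- p$radius > 0
  prot <- if (has_prot) make_sphere_protein(p$radius, p$n_protein_points,
                                            p$box) else NULL
  n <- p$n_chains * p$n_beads
  chain_of <- rep(seq_len(p$n_chains) - 1L, each = p$n_beads)
  ## bonds / angles (0-based for the integrator)
  bonds <- do.call(rbind, lapply(seq_len(p$n_chains), function(c) {
    o <- (c - 1L) * p$n_beads
    if (p$n_beads > 1) cbind(o + seq_len(p$n_beads - 1L) - 1L,
                             o + seq_len(p$n_beads - 1L)) else NULL
  }))
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  angles <- if (p$angle_k > 0 && p$n_beads >= 3)
    do.call(rbind, lapply(seq_len(p$n_chains), function(c) {
      o <- (c - 1L) * p$n_beads
      cbind(o + seq_len(p$n_beads - 2L) - 1L, o + seq_len(p$n_beads - 2L),
            o + seq_len(p$n_beads - 2L) + 1L)
    })) else matrix(integer(0), ncol = 3)

  ## initial placement: straight chains at random positions outside sphere
  X0 <- matrix(NA_real_, n, 3)
  center <- p$box / 2
  for (c in seq_len(p$n_chains)) {
    repeat {
      a <- runif(3) * p$box
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      pos <- t(a + outer(u, (seq_len(p$n_beads) - 1) * p$bond_r0))
      if (!has_prot ||
          all(sqrt(rowSums(sweep(pos, 2, center)^2)) > p$radius + 2)) break
    }
    X0[(c - 1L) * p$n_beads + seq_len(p$n_beads), ] <- pos
  }

  run <- function(X, nsteps, save_every) {
    cpp_bd_run(X, bonds, p$bond_k, p$bond_r0, angles, p$angle_k, chain_of,
               if (has_prot) p$eps_surf else 0, p$sigma_surf, center,
               p$radius, if (has_prot) p$k_wall else 0,
               p$eps_cc, p$sigma_cc, p$cc_d0, p$a_rep, p$sigma_rep,
               p$D, p$kBT, p$dt, nsteps, save_every, p$box)
  }
  if (p$n_equil > 0) {
    eq <- run(X0, p$n_equil, p$n_equil)
    X0 <- matrix(eq, n, 3)
  }
  out <- run(X0, p$n_frames * p$save_every, p$save_every)
  dim(out) <- c(n, 3, p$n_frames)

  n_w <- round(p$water_density * prod(p$box))
  m <- if (has_prot) nrow(prot$coords) else 0L
  natoms <- m + n + n_w
  coords <- array(NA_real_, c(natoms, 3, p$n_frames))
  if (has_prot) coords[seq_len(m), , ] <- prot$coords
  coords[m + seq_len(n), , ] <- out
  if (n_w > 0) {
    for (f in seq_len(p$n_frames)) {
      beads <- out[, , f, drop = TRUE]
      beads <- beads - floor(beads / matrix(p$box, n, 3, byrow = TRUE)) *
        matrix(p$box, n, 3, byrow = TRUE)
      W <- matrix(NA_real_, 0, 3)
      while (nrow(W) < n_w) {
        cand <- matrix(runif(3 * (n_w - nrow(W) + 16)), ncol = 3) %*% diag(p$box)
        bad <- cpp_within_any(cand, beads, p$box, p$water_excl) == 1L
        if (has_prot)
          bad <- bad | rowSums(sweep(cand, 2, center)^2) < p$radius^2
        W <- rbind(W, cand[!bad, , drop = FALSE])
      }
      coords[m + n + seq_len(n_w), , f] <- W[seq_len(n_w), ]
    }
  }

  tmpl <- build_polymer_topology("generic", p$n_beads)
  system <- assemble_system(if (has_prot) prot$atoms else NULL, tmpl,
                            p$n_chains, n_w, p$box,
                            protein_model = if (has_prot) prot$model else NULL)
  traj <- trajectory(coords, p$box, dt = p$dt * p$save_every, discard = 0)

  ## post-hoc bond fluctuation check
  rel_fluct <- NA_real_
  if (nrow(bonds) > 0) {
    i <- bonds[, 1] + 1L; j <- bonds[, 2] + 1L
    dl <- vapply(seq_len(p$n_frames), function(f) {
      d <- matrix(out[i, , f] - out[j, , f], ncol = 3)
      bb <- matrix(p$box, nrow(d), 3, byrow = TRUE)
      d <- d - bb * round(d / bb)
      sqrt(rowSums(d^2))
    }, numeric(length(i)))
    rel_fluct <- sd(as.numeric(dl)) / p$bond_r0
    if (is.finite(rel_fluct) && rel_fluct > 0.3)
      warning("bond-length RMS fluctuation exceeds 0.3 r0; ",
              "reduce the timestep", call. = FALSE)
  }
  list(system = system, traj = traj,
       diagnostics = list(bond_rel_fluct = rel_fluct))
}

#' Generate synthetic Langmuir isotherm data
#'
#' Points on the Langmuir curve `AP = Ps_max Ka As / (1 + Ka As)` with
#' additive Gaussian noise truncated at zero.
#'
#' @param Ps_max,Ka true parameters (> 0).
#' @param As bulk polymer heavy-atom fractions, in (0, 1).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @param form isotherm denominator convention, see [langmuir_ap()].
#' @return data.frame of class `isotherm_data` with columns `As`, `AP`,
#'   `sd`.
#' @export
generate_isotherm_data <- function(Ps_max, Ka, As, noise_sd = 0, seed = 1L,
                                   form = c("standard", "literal")) {
  form <- match.arg(form)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (Ps_max <= 0 || Ka <= 0) stop("Ps_max and Ka must be > 0", call. = FALSE)
  set.seed(seed)
  ap <- langmuir_ap(Ps_max, Ka, As, form = form)
  if (noise_sd > 0) ap <- pmax(0, ap + rnorm(length(As), 0, noise_sd))
  out <- data.frame(As = As, AP = ap,
                    sd = rep(noise_sd, length(As)))
  class(out) <- c("isotherm_data", "data.frame")
  out
}
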