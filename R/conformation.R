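## Polymer shape descriptors: end-to-end distance, radius of gyration, and
## the inertia-tensor aspect ratio sqrt(lambda_max / lambda_min). Chains are
## unwrapped across periodic boundaries (bond-following) before any
## measurement. The inertia tensor uses unit masses by default so the
## descriptors are pure shape measures; a mass-weighted variant sits behind
## a flag.

## unwrapped heavy-atom coordinates of one chain in one frame
.chain_coords <- function(frame, system, chain) {
  ch <- system$chains[[chain]]
  ids <- suppressWarnings(heavy_atoms(system, chain = chain))
  X <- frame[ids, , drop = FALSE]
  bonds <- ch$bonds
  if (!is.null(bonds) && nrow(bonds)) {
    local <- matrix(match(bonds, ids), ncol = 2)
    keep <- stats::complete.cases(local)
    X <- unwrap_chain(X, local[keep, , drop = FALSE], system$box)
  }
  list(coords = X, ids = ids, ends = ch$ends)
}

#' End-to-end distance of a chain
#'
#' Distance between the first and last backbone heavy atoms of the chain
#' template (caps excluded), after unwrapping.
#'
#' @param frame `n_atoms x 3` coordinates.
#' @param system the [molecular_system()].
#' @param chain chain index.
#' @return Distance in Angstrom.
#' @export
end_to_end <- function(frame, system, chain) {
  cc <- .chain_coords(frame, system, chain)
  if (length(cc$ids) < 2) stop("chain has fewer than 2 heavy atoms",
                               call. = FALSE)
  e <- match(cc$ends, cc$ids)
  if (anyNA(e)) e <- c(1L, length(cc$ids))
  sqrt(sum((cc$coords[e[1], ] - cc$coords[e[2], ])^2))
}

#' Radius of gyration of a chain
#'
#' `sqrt(mean |r_i - rbar|^2)` over heavy atoms with unit masses.
#'
#' @inheritParams end_to_end
#' @return Rg in Angstrom.
#' @export
gyration_radius <- function(frame, system, chain) {
  X <- .chain_coords(frame, system, chain)$coords
  rg_of(X)
}

rg_of <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sqrt(mean(rowSums(Xc^2)))
}

#' Inertia-tensor aspect ratio of a chain
#'
#' Square root of the ratio between the largest and smallest eigenvalue of
#' the moment-of-inertia tensor `I = sum(|r|^2 delta - r (x) r)` about the
#' centroid (unit masses by default). Collinear chains have a vanishing
#' smallest eigenvalue and are reported as `Inf`.
#'
#' @inheritParams end_to_end
#' @param mass_weighted use atomic masses instead of unit masses.
#' @return Dimensionless aspect ratio >= 1 (or `Inf` for collinear chains).
#' @export
aspect_ratio <- function(frame, system, chain, mass_weighted = FALSE) {
  cc <- .chain_coords(frame, system, chain)
  if (length(cc$ids) < 3)
    stop("aspect ratio undefined for chains with fewer than 3 atoms",
         call. = FALSE)
  w <- if (mass_weighted)
    system$atoms$mass[match(cc$ids, system$atoms$id)] else NULL
  aspect_of(cc$coords, w)
}

aspect_of <- function(X, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(X))
  ctr <- colSums(X * w) / sum(w)
  Xc <- sweep(X, 2, ctr)
  r2 <- rowSums(Xc^2)
  I <- diag(sum(w * r2), 3) - crossprod(Xc * w, Xc)
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[1] < 1e-9 * max(ev[3], 1e-300)) return(Inf)
  sqrt(ev[3] / ev[1])
}

#' Per-chain-frame shape samples and their distributions
#'
#' Computes Ree, Rg and aspect ratio for every chain and analysis frame,
#' flags each sample with the chain's adsorbed state, and returns the
#' sample table plus per-population summaries.
#'
#' @param traj,system as elsewhere.
#' @param state_series optional `adsorption_state_series` aligned to the
#'   trajectory (for the adsorbed-conditioned population).
#' @param chains chain indices (default all).
#' @param discard discard prefix override (ns).
#' @return List of class `shape_distributions`: `samples` (data.frame:
#'   chain, frame, ree, rg, aspect, adsorbed), `summary` (means and sds per
#'   population: all / adsorbed).
#' @export
shape_distributions <- function(traj, system, state_series = NULL,
                                chains = NULL, discard = NULL) {
  if (is.null(chains)) chains <- seq_along(system$chains)
  frames <- analysis_frames(traj, discard)
  rows <- vector("list", length(chains) * length(frames))
  i <- 0L
  for (f in frames) {
    X <- frame_coords(traj, f)
    for (c in chains) {
      cc <- .chain_coords(X, system, c)
      e <- match(cc$ends, cc$ids)
      if (anyNA(e)) e <- c(1L, length(cc$ids))
      i <- i + 1L
      rows[[i]] <- c(chain = c, frame = f,
                     ree = sqrt(sum((cc$coords[e[1], ] - cc$coords[e[2], ])^2)),
                     rg = rg_of(cc$coords),
                     aspect = if (length(cc$ids) >= 3) aspect_of(cc$coords)
                              else NA_real_)
    }
  }
  samples <- as.data.frame(do.call(rbind, rows))
  samples$adsorbed <- if (!is.null(state_series))
    state_series$states[cbind(samples$frame,
                              match(samples$chain, state_series$chains))] == 1L
  else NA
  summarize <- function(d) {
    if (!nrow(d)) return(c(ree_mean = NA, ree_sd = NA, rg_mean = NA,
                           rg_sd = NA, aspect_mean = NA, aspect_sd = NA))
    fin <- is.finite(d$aspect)
    c(ree_mean = mean(d$ree), ree_sd = sd(d$ree),
      rg_mean = mean(d$rg), rg_sd = sd(d$rg),
      aspect_mean = mean(d$aspect[fin]), aspect_sd = sd(d$aspect[fin]))
  }
  summ <- rbind(all = summarize(samples),
                adsorbed = summarize(samples[isTRUE_vec(samples$adsorbed), ]))
  if (!is.null(state_series) && !any(isTRUE_vec(samples$adsorbed)))
    warning("no adsorbed chain-frames; adsorbed-population summary is empty",
            call. = FALSE)
  structure(list(samples = samples, summary = summ),
            class = "shape_distributions")
}

isTRUE_vec <- function(x) !is.na(x) & x
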