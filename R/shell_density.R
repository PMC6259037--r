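## Distance-to-protein-surface densities: polymer RDF around the protein,
## shell/bulk polymer heavy-atom fractions, and enrichment-decay extent.
## "Distance from the protein" always means distance to the nearest protein
## heavy atom (surface distance), under the minimum image.

#' Surface distances of selected atoms in one frame
#'
#' Minimum-image distance of each selected atom to its nearest protein
#' heavy atom.
#'
#' @param frame `n_atoms x 3` coordinates (e.g. [frame_coords()]).
#' @param system the [molecular_system()].
#' @param selection atom ids to measure (e.g. [heavy_atoms()]).
#' @return Numeric vector of distances (Angstrom), in selection order.
#' @export
surface_distances <- function(frame, system, selection) {
  prot <- heavy_atoms(system, "protein")
  if (!length(prot)) stop("system has no protein heavy atoms", call. = FALSE)
  cpp_nearest_dist(frame[selection, , drop = FALSE],
                   frame[prot, , drop = FALSE], system$box)
}

## surface distances of a selection over analysis frames: nf x nsel matrix
.surface_dist_matrix <- function(traj, system, selection, discard = NULL) {
  prot <- heavy_atoms(system, "protein")
  if (!length(prot)) stop("system has no protein heavy atoms", call. = FALSE)
  frames <- analysis_frames(traj, discard)
  cpp_surface_dist_traj(as.numeric(traj$coords), dim(traj$coords)[1],
                        as.integer(selection - 1L), as.integer(prot - 1L),
                        traj$box, as.integer(frames - 1L))
}

#' Radial distribution function of polymer around the protein surface
#'
#' Histogram of polymer-heavy-atom surface distances, normalized by the
#' per-bin count expected for uniformly distributed points at the same
#' overall density. The uniform reference (the volume of each distance
#' stratum around the non-spherical protein) is estimated by seeded
#' Monte-Carlo sampling of the box.
#'
#' @param traj a [trajectory()].
#' @param system the [molecular_system()].
#' @param bin_width histogram bin width (Angstrom).
#' @param r_max largest surface distance (Angstrom); should not exceed half
#'   the smallest box edge.
#' @param selection atom ids; default all polymer heavy atoms.
#' @param n_ref_samples Monte-Carlo sample count for the stratum volumes.
#' @param discard discard prefix override (ns).
#' @param ref_seed seed of the Monte-Carlo reference stream.
#' @return data.frame of class `rdf_curve`: `r` (bin centers), `g`, `se`
#'   (binomial standard error of g), `count`; attributes `bin_width`,
#'   `n_frames`, `volume_fraction`.
#' @export
polymer_rdf <- function(traj, system, bin_width = 0.25, r_max = 15,
                        selection = NULL, n_ref_samples = 2e5,
                        discard = NULL, ref_seed = 42L) {
  if (is.null(selection)) selection <- heavy_atoms(system, "polymer")
  if (!length(selection)) stop("empty polymer selection", call. = FALSE)
  if (r_max > min(system$box) / 2)
    stop("r_max exceeds half the smallest box edge", call. = FALSE)
  D <- .surface_dist_matrix(traj, system, selection, discard)
  breaks <- seq(0, r_max, by = bin_width)
  nb <- length(breaks) - 1L
  obs <- tabulate(findInterval(D[D <= r_max], breaks,
                               rightmost.closed = TRUE), nbins = nb)
  n_tot <- length(D)  # atoms x frames
  ## Monte-Carlo stratum volume fractions over the protein-accessible
  ## volume (the reference is an ideal gas that, like the polymer, cannot
  ## occupy the protein interior)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(ref_seed)
  prot <- heavy_atoms(system, "protein")
  ref_frame <- frame_coords(traj, analysis_frames(traj, discard)[1])
  P <- ref_frame[prot, , drop = FALSE]
  U <- matrix(runif(3 * n_ref_samples), ncol = 3) %*% diag(system$box)
  keep <- !protein_interior(U, system, P = P,
                            candidates = which(cpp_within_any(
                              U, P, system$box, 3) == 1L))
  U <- U[keep, , drop = FALSE]
  dref <- cpp_nearest_dist(U, P, system$box)
  vol_frac <- tabulate(findInterval(dref[dref <= r_max], breaks,
                                    rightmost.closed = TRUE),
                       nbins = nb) / nrow(U)
  p_obs <- obs / n_tot
  g <- ifelse(vol_frac > 0, p_obs / vol_frac, NA_real_)
  se <- ifelse(vol_frac > 0,
               sqrt(pmax(p_obs, 1 / n_tot) * (1 - p_obs) / n_tot) / vol_frac,
               NA_real_)
  out <- data.frame(r = breaks[-1] - bin_width / 2, g = g, se = se,
                    count = obs)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- nrow(D)
  attr(out, "volume_fraction") <- vol_frac
  class(out) <- c("rdf_curve", "data.frame")
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Shell and bulk polymer heavy-atom fractions
#'
#' Per frame, the fraction of solvent heavy atoms (polymer heavy atoms plus
#' water oxygens) within the shell cutoff of the protein surface that are
#' polymer; plus the same fraction over the whole solvent (the bulk
#' fraction).
#'
#' @param traj,system as elsewhere.
#' @param cutoff shell thickness (Angstrom); 5.0 = the 0.5 nm layer.
#' @param discard discard prefix override (ns).
#' @return List of class `shell_fraction_series`: `ap` (per-frame shell
#'   fractions), `mean`, `sd`, `as_bulk` (bulk fraction over all frames),
#'   `cutoff`, `n_excluded` (frames with an empty shell), and per-frame
#'   counts `n_poly_shell`, `n_water_shell`.
#' @export
shell_fraction <- function(traj, system, cutoff = 5.0, discard = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  poly <- heavy_atoms(system, "polymer")
  wat <- suppressWarnings(heavy_atoms(system, "water"))
  np_tot <- length(poly); nw_tot <- length(wat)
  Dp <- if (np_tot) .surface_dist_matrix(traj, system, poly, discard) else NULL
  Dw <- if (nw_tot) .surface_dist_matrix(traj, system, wat, discard) else NULL
  nf <- max(nrow(Dp), nrow(Dw), 0L)
  n_poly_shell <- if (np_tot) rowSums(Dp <= cutoff) else rep(0L, nf)
  n_water_shell <- if (nw_tot) rowSums(Dw <= cutoff) else rep(0L, nf)
  denom <- n_poly_shell + n_water_shell
  ok <- denom > 0
  ap <- ifelse(ok, n_poly_shell / denom, NA_real_)
  if (any(!ok))
    warning(sum(!ok), " frame(s) had an empty shell and were excluded",
            call. = FALSE)
  as_bulk <- if (np_tot + nw_tot > 0) np_tot / (np_tot + nw_tot) else NA_real_
  structure(list(ap = ap, mean = mean(ap, na.rm = TRUE),
                 sd = sd(ap, na.rm = TRUE), as_bulk = as_bulk,
                 cutoff = cutoff, n_excluded = sum(!ok),
                 n_poly_shell = n_poly_shell,
                 n_water_shell = n_water_shell),
            class = "shell_fraction_series")
}

#' @export
print.shell_fraction_series <- function(x, ...) {
  cat(sprintf(
    "shell_fraction_series: [A_P] = %.4f +- %.4f (cutoff %.1f A), [A_s] = %.4f\n",
    x$mean, x$sd, x$cutoff, x$as_bulk))
  invisible(x)
}

#' Extent of the enrichment decay of an RDF curve
#'
#' Largest bin center at which the curve still deviates from 1 by more than
#' `tol`, i.e. the distance out to which surface enrichment (or depletion)
#' remains detectable.
#'
#' @param curve a [polymer_rdf()] result.
#' @param tol deviation tolerance on |g - 1|.
#' @return Distance in Angstrom; 0 when the curve never leaves the `1 +-
#'   tol` band. When the curve has not relaxed to 1 by its last bin a
#'   warning is raised and `max(r)` returned.
#' @export
decay_extent <- function(curve, tol = 0.05) {
  if (!nrow(curve)) stop("empty RDF curve", call. = FALSE)
  dev <- abs(curve$g - 1) > tol
  dev[is.na(dev)] <- FALSE
  if (!any(dev)) return(0)
  last <- max(which(dev))
  if (last == nrow(curve)) {
    warning("RDF has not relaxed to 1 within r_max; extent unresolved",
            call. = FALSE)
  }
  curve$r[last]
}
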