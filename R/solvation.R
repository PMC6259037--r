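## Water structure around the polymers, hydrogen-bond counting, chain
## aggregation clusters, and diffusion from mean-square displacements.

#' Cumulative radial distribution of water around polymer atoms
#'
#' Mean number of water oxygens within radius r of a polymer heavy atom,
#' calculated per heavy atom and averaged over all heavy atoms and frames.
#' Being a per-atom average, the curve is sensitive to molecule size and
#' shape: atoms in aggregated or bulky molecules "see" fewer waters.
#'
#' @param traj,system as elsewhere.
#' @param r_max largest radius (Angstrom); must be below half the box edge.
#' @param dr radial step (Angstrom).
#' @param selection polymer heavy-atom ids (default all).
#' @param discard discard prefix override (ns).
#' @return data.frame of class `cumulative_rdf`: `r`, `n` (mean cumulative
#'   water count, non-decreasing, `n(0) = 0`).
#' @export
cumulative_water_rdf <- function(traj, system, r_max = 10, dr = 0.25,
                                 selection = NULL, discard = NULL) {
  if (r_max > min(system$box) / 2)
    stop("r_max exceeds half the smallest box edge", call. = FALSE)
  if (is.null(selection)) selection <- heavy_atoms(system, "polymer")
  wat <- suppressWarnings(heavy_atoms(system, "water"))
  frames <- analysis_frames(traj, discard)
  nb <- ceiling(r_max / dr)
  acc <- numeric(nb)
  for (f in frames) {
    X <- frame_coords(traj, f)
    if (length(wat))
      acc <- acc + cpp_cross_dist_counts(X[selection, , drop = FALSE],
                                         X[wat, , drop = FALSE],
                                         traj$box[f, ], r_max, dr)
  }
  ncum <- cumsum(acc) / (length(selection) * length(frames))
  out <- data.frame(r = seq_len(nb) * dr, n = ncum)
  out <- rbind(data.frame(r = 0, n = 0), out)
  class(out) <- c("cumulative_rdf", "data.frame")
  out
}

#' Count hydrogen bonds by the geometric criterion
#'
#' A bond is counted when the donor-acceptor distance is at most `d_max`
#' and the donor-H-acceptor angle deviates from linearity by at most
#' `angle_max`. Donor/acceptor typing comes from the caller (real-data
#' path); heavy-atom-only synthetic systems have no hydrogens and must
#' supply explicit donor geometry.
#'
#' @param frame `n_atoms x 3` coordinates.
#' @param donors data.frame with columns `d` (donor heavy atom id) and `h`
#'   (its hydrogen id).
#' @param acceptors acceptor heavy-atom ids.
#' @param box length-3 box (Angstrom).
#' @param d_max donor-acceptor distance cutoff (Angstrom).
#' @param angle_max allowed deviation from linearity (degrees).
#' @return data.frame of bonds: `donor`, `h`, `acceptor`, `dist`,
#'   `deviation` (degrees).
#' @export
count_hbonds <- function(frame, donors, acceptors, box, d_max = 3.5,
                         angle_max = 30) {
  if (is.null(donors) || !nrow(donors))
    stop("no donors supplied: hydrogen positions (or explicit donor ",
         "geometry) are required for h-bond counting", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(donors))) {
    dpos <- frame[donors$d[i], ]; hpos <- frame[donors$h[i], ]
    for (a in acceptors) {
      if (a == donors$d[i]) next
      dv <- min_image_displacement(frame[a, ], dpos, box)
      dist <- sqrt(sum(dv^2))
      if (dist > d_max) next
      v1 <- min_image_displacement(hpos, dpos, box)
      va <- min_image_displacement(frame[a, ], hpos, box)
      # donor-H-acceptor angle; 180 deg = linear
      cosang <- -sum(v1 * va) / sqrt(sum(v1^2) * sum(va^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      dev <- 180 - ang
      if (dev <= angle_max)
        out[[length(out) + 1L]] <- data.frame(
          donor = donors$d[i], h = donors$h[i], acceptor = a,
          dist = dist, deviation = dev)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), h = integer(0),
                      acceptor = integer(0), dist = numeric(0),
                      deviation = numeric(0)))
  do.call(rbind, out)
}

#' Polymer aggregation clusters in one frame
#'
#' Connected components of the chain contact graph: two chains are linked
#' when any inter-chain heavy-atom pair is within the cutoff (minimum
#' image).
#'
#' @param frame `n_atoms x 3` coordinates.
#' @param system the [molecular_system()].
#' @param cutoff contact cutoff between heavy atoms (Angstrom).
#' @return List: `membership` (cluster id per chain), `sizes`, `largest`,
#'   `mean_size`, `n_clusters`.
#' @export
polymer_clusters <- function(frame, system, cutoff = 4.5) {
  nc <- length(system$chains)
  if (!nc) stop("system has no polymer chains", call. = FALSE)
  sel <- integer(0); chain_of <- integer(0)
  for (k in seq_len(nc)) {
    ids <- suppressWarnings(heavy_atoms(system, chain = k))
    sel <- c(sel, ids); chain_of <- c(chain_of, rep(k - 1L, length(ids)))
  }
  edges <- cpp_chain_edges(frame[sel, , drop = FALSE],
                           as.integer(chain_of), nc, system$box, cutoff)
  g <- igraph::make_empty_graph(n = nc, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  list(membership = as.integer(comp$membership), sizes = sizes,
       largest = max(sizes), mean_size = mean(sizes),
       n_clusters = comp$no)
}

#' Cluster-size report over a trajectory
#'
#' @param traj,system as elsewhere.
#' @param cutoff see [polymer_clusters()].
#' @param discard discard prefix override (ns).
#' @return data.frame per frame: `frame`, `largest`, `mean_size`,
#'   `n_clusters`.
#' @export
cluster_report <- function(traj, system, cutoff = 4.5, discard = NULL) {
  frames <- analysis_frames(traj, discard)
  do.call(rbind, lapply(frames, function(f) {
    cl <- polymer_clusters(frame_coords(traj, f), system, cutoff)
    data.frame(frame = f, largest = cl$largest, mean_size = cl$mean_size,
               n_clusters = cl$n_clusters)
  }))
}

#' Diffusion coefficient from the mean-square displacement
#'
#' MSD over lag times with all time origins; `D = slope / 6` from a least
#' squares line over the fit window. Coordinates must be continuous
#' (unwrapped); the Brownian-dynamics generator emits unwrapped
#' coordinates directly.
#'
#' @param traj a [trajectory()] with unwrapped coordinates.
#' @param selection atom ids whose MSD is averaged.
#' @param fit_window lag-time window (ns, length 2) for the linear fit;
#'   default the middle 10-50% of the trajectory length.
#' @param discard discard prefix override (ns).
#' @return List of class `diffusion_result`: `D` (A^2/ns), `D_se`, `msd`
#'   (data.frame lag/msd), `fit_window`, `r_squared`.
#' @export
diffusion_coefficient <- function(traj, selection, fit_window = NULL,
                                  discard = NULL) {
  frames <- analysis_frames(traj, discard)
  sub <- traj$coords[, , frames, drop = FALSE]
  nf <- length(frames)
  lags <- unique(round(seq(1, nf - 1, length.out = min(60, nf - 1))))
  msd <- cpp_msd(as.numeric(sub), dim(sub)[1], nf,
                 as.integer(selection - 1L), as.integer(lags))
  tau <- lags * traj$dt
  curve <- data.frame(lag = c(0, tau), msd = c(0, msd))
  if (is.null(fit_window)) {
    tmax <- nf * traj$dt
    fit_window <- c(0.1, 0.5) * tmax
  }
  sel_fit <- curve$lag >= fit_window[1] & curve$lag <= fit_window[2] &
    curve$lag > 0
  if (sum(sel_fit) < 2)
    stop("fit window contains fewer than 2 MSD points", call. = FALSE)
  fit <- lm(msd ~ lag, data = curve[sel_fit, ])
  r2 <- summary(fit)$r.squared
  if (is.finite(r2) && r2 < 0.9)
    warning("MSD is poorly linear over the fit window (R^2 = ",
            round(r2, 3), "); the window may be in the ballistic or ",
            "plateau regime", call. = FALSE)
  structure(list(D = unname(coef(fit)[2]) / 6,
                 D_se = summary(fit)$coefficients[2, 2] / 6,
                 msd = curve, fit_window = fit_window, r_squared = r2),
            class = "diffusion_result")
}
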