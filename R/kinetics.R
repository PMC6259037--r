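## Adsorption/desorption kinetics with a dual-threshold (hysteresis) state
## machine: a free chain adsorbs when more than half of its heavy atoms come
## within the cutoff of any protein heavy atom; an adsorbed chain desorbs
## only when every atom has left the cutoff. The threshold separation
## suppresses recrossing noise.

#' Per-chain adsorbed/free state series
#'
#' Computes per-frame in-cutoff heavy-atom counts for every polymer chain
#' and runs the hysteresis state machine. The initial state of each chain is
#' assigned by the adsorption criterion at the first frame.
#'
#' @param traj,system as elsewhere.
#' @param cutoff contact cutoff (Angstrom); 5.0 = 0.5 nm.
#' @param chains chain indices to analyze (default all).
#' @return List of class `adsorption_state_series`: `states` (`n_frames x
#'   n_chains`, 1 = adsorbed), `counts` (in-cutoff heavy-atom counts),
#'   `n_heavy` (per chain), `cutoff`, `dt`.
#' @export
chain_state_series <- function(traj, system, cutoff = 5.0, chains = NULL) {
  if (is.null(chains)) chains <- seq_along(system$chains)
  if (!length(chains)) stop("system has no polymer chains", call. = FALSE)
  prot <- heavy_atoms(system, "protein")
  sel <- integer(0); chain_of <- integer(0); n_heavy <- integer(0)
  for (k in seq_along(chains)) {
    ids <- suppressWarnings(heavy_atoms(system, chain = chains[k]))
    if (!length(ids)) stop("chain ", chains[k], " has no heavy atoms",
                           call. = FALSE)
    sel <- c(sel, ids)
    chain_of <- c(chain_of, rep(k - 1L, length(ids)))
    n_heavy <- c(n_heavy, length(ids))
  }
  counts <- cpp_contact_counts(as.numeric(traj$coords), dim(traj$coords)[1],
                               as.integer(sel - 1L), as.integer(chain_of),
                               length(chains), as.integer(prot - 1L),
                               traj$box, cutoff)
  states <- cpp_hysteresis(counts, as.integer(n_heavy))
  structure(list(states = states, counts = counts, n_heavy = n_heavy,
                 cutoff = cutoff, dt = traj$dt, chains = chains),
            class = "adsorption_state_series")
}

#' Build a state series from a precomputed count matrix
#'
#' Lower-level entry for the hysteresis machine when in-cutoff counts are
#' already available.
#'
#' @param counts `n_frames x n_chains` in-cutoff heavy-atom counts.
#' @param n_heavy per-chain heavy-atom totals.
#' @param dt frame spacing (ns).
#' @param cutoff cutoff used to build `counts` (Angstrom), for bookkeeping.
#' @return An `adsorption_state_series`.
#' @export
state_series_from_counts <- function(counts, n_heavy, dt, cutoff = NA_real_) {
  counts <- as.matrix(counts)
  states <- cpp_hysteresis(counts, as.integer(n_heavy))
  structure(list(states = states, counts = counts,
                 n_heavy = as.integer(n_heavy), cutoff = cutoff, dt = dt,
                 chains = seq_len(ncol(counts))),
            class = "adsorption_state_series")
}

#' Extract adsorption/desorption events from a state series
#'
#' Maximal constant-state runs become events. Runs touching either end of
#' the trajectory are censored: excluded from duration statistics but kept
#' for occupancy bookkeeping.
#'
#' @param series an `adsorption_state_series`.
#' @param dt frame spacing override (ns).
#' @return data.frame of class `event_table`: `chain`, `state`
#'   (`"adsorbed"`/`"free"`), `start` (ns), `duration` (ns), `censored`;
#'   attributes `total_time` (analyzed time in ns, all chains),
#'   `n_adsorption_events`, `n_desorption_events` (completed entries into
#'   each state, i.e. transitions observed).
#' @export
detect_events <- function(series, dt = NULL) {
  if (is.null(dt)) dt <- series$dt
  if (is.null(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  st <- series$states
  nf <- nrow(st); nc <- ncol(st)
  rows <- vector("list", nc)
  n_ads <- 0L; n_des <- 0L
  for (c in seq_len(nc)) {
    r <- rle(st[, c])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    censored <- (starts == 1L) | (ends == nf)
    n_ads <- n_ads + sum(r$values == 1L & starts > 1L)
    n_des <- n_des + sum(r$values == 0L & starts > 1L)
    rows[[c]] <- data.frame(
      chain = series$chains[c],
      state = ifelse(r$values == 1L, "adsorbed", "free"),
      start = (starts - 1L) * dt,
      duration = r$lengths * dt,
      censored = censored)
  }
  out <- do.call(rbind, rows)
  attr(out, "total_time") <- nf * dt * nc
  attr(out, "n_adsorption_events") <- n_ads
  attr(out, "n_desorption_events") <- n_des
  class(out) <- c("event_table", "data.frame")
  out
}

#' Event rates and mean adsorbed-molecule count
#'
#' Pools one or more event tables (independent runs are analyzed separately
#' and pooled here): adsorption rate = completed transitions into the
#' adsorbed state per analyzed time, desorption likewise; the mean and sd of
#' the per-frame adsorbed-molecule count come from the state series.
#'
#' @param tables an `event_table` or list of them.
#' @param series optional matching `adsorption_state_series` (or list) for
#'   the occupancy statistics.
#' @return List: `adsorption_rate`, `desorption_rate` (1/ns),
#'   `mean_adsorbed`, `sd_adsorbed`, `total_time` (ns).
#' @export
event_rates <- function(tables, series = NULL) {
  if (inherits(tables, "event_table")) tables <- list(tables)
  tt <- sum(vapply(tables, attr, numeric(1), "total_time"))
  if (tt <= 0) stop("total analyzed time must be > 0", call. = FALSE)
  n_ads <- sum(vapply(tables, attr, numeric(1), "n_adsorption_events"))
  n_des <- sum(vapply(tables, attr, numeric(1), "n_desorption_events"))
  mean_ads <- sd_ads <- NA_real_
  if (!is.null(series)) {
    if (inherits(series, "adsorption_state_series")) series <- list(series)
    occ <- unlist(lapply(series, function(s) rowSums(s$states)))
    mean_ads <- mean(occ); sd_ads <- sd(occ)
  }
  list(adsorption_rate = n_ads / tt, desorption_rate = n_des / tt,
       mean_adsorbed = mean_ads, sd_adsorbed = sd_ads, total_time = tt)
}

#' Geometric mean and 68% confidence interval of event durations
#'
#' The standard summary for (multi-)lognormally distributed residence
#' times: geometric mean with the empirical 16th/84th percentiles as the
#' asymmetric 68% interval (a GM */ GSD variant is available).
#'
#' @param durations positive event durations (ns).
#' @param method `"percentile"` (16/84 empirical percentiles, default) or
#'   `"gsd"` (GM times/divided-by geometric standard deviation).
#' @return List: `gm`, `lower`, `upper`, `plus` (= upper - gm), `minus`
#'   (= gm - lower), `n`.
#' @export
lognormal_summary <- function(durations, method = c("percentile", "gsd")) {
  method <- match.arg(method)
  if (!length(durations)) stop("no durations supplied", call. = FALSE)
  if (any(durations <= 0)) stop("durations must be > 0", call. = FALSE)
  lg <- log(durations)
  gm <- exp(mean(lg))
  if (method == "percentile") {
    q <- quantile(durations, c(0.16, 0.84), names = FALSE, type = 7)
    lower <- q[1]; upper <- q[2]
  } else {
    gsd <- exp(sd(lg))
    if (is.na(gsd)) gsd <- 1
    lower <- gm / gsd; upper <- gm * gsd
  }
  list(gm = gm, lower = lower, upper = upper,
       plus = upper - gm, minus = gm - lower, n = length(durations))
}

#' Events per unit time in log-spaced duration bins
#'
#' @param durations positive completed-event durations (ns).
#' @param n_logbins number of log-spaced bins spanning the data range.
#' @param total_time total analyzed time (ns) used to normalize counts to
#'   events per ns.
#' @return data.frame: `mid` (geometric bin center, ns), `lo`, `hi`,
#'   `count`, `rate` (events per ns of trajectory).
#' @export
duration_histogram <- function(durations, n_logbins = 20, total_time = 1) {
  if (!length(durations))
    return(data.frame(mid = numeric(0), lo = numeric(0), hi = numeric(0),
                      count = numeric(0), rate = numeric(0)))
  if (any(durations <= 0)) stop("durations must be > 0", call. = FALSE)
  rng <- range(durations)
  if (rng[1] == rng[2]) rng <- rng * c(0.99, 1.01)
  breaks <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_logbins + 1))
  breaks[1] <- breaks[1] * (1 - 1e-9); breaks[length(breaks)] <- breaks[length(breaks)] * (1 + 1e-9)
  cnt <- tabulate(findInterval(durations, breaks, rightmost.closed = TRUE),
                  nbins = n_logbins)
  data.frame(mid = sqrt(breaks[-1] * breaks[-length(breaks)]),
             lo = breaks[-length(breaks)], hi = breaks[-1],
             count = cnt, rate = cnt / total_time)
}

#' Distribution of adsorbed atoms per molecule
#'
#' Histogram of per-chain in-cutoff heavy-atom counts over the frames in
#' which the chain is adsorbed (hysteresis definition).
#'
#' @param series an `adsorption_state_series` (carries counts and states).
#' @param chains chains to pool (default all).
#' @return data.frame: `n_atoms` (0..max heavy atoms), `count`,
#'   `probability` (normalized over adsorbed chain-frames).
#' @export
adsorbed_atoms_distribution <- function(series, chains = NULL) {
  nc <- ncol(series$states)
  if (is.null(chains)) chains <- seq_len(nc)
  nmax <- max(series$n_heavy[chains])
  acc <- integer(nmax + 1L)
  for (c in chains) {
    k <- series$counts[series$states[, c] == 1L, c]
    if (length(k)) acc <- acc + tabulate(k + 1L, nbins = nmax + 1L)
  }
  tot <- sum(acc)
  data.frame(n_atoms = 0:nmax, count = acc,
             probability = if (tot > 0) acc / tot else rep(NA_real_, nmax + 1))
}
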