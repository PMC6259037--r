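## Adsorption free energy from adsorbed/free molecule densities:
## dG = -RT ln(rho_ads / rho_free), with the shell and bulk volumes
## estimated by seeded Monte-Carlo integration around the (non-spherical)
## protein. "log" is the natural log (statistical-mechanics convention);
## base 10 sits behind a flag.

#' Monte-Carlo shell, protein and bulk volumes
#'
#' Samples points uniformly in the box and classifies them as protein
#' interior, adsorption shell (surface distance in `(0, cutoff]`, interior
#' excluded) or bulk. The interior test uses the analytic sphere when the
#' system carries a sphere protein model, otherwise a per-atom van der
#' Waals radius test (C 1.7, N 1.55, O 1.52, S 1.8, default 1.7 Angstrom).
#'
#' @param system a [molecular_system()]; protein coordinates are taken from
#'   `system$coords` or must be passed via `frame`.
#' @param cutoff shell thickness (Angstrom).
#' @param n_samples Monte-Carlo samples (>= 1e5 recommended).
#' @param seed RNG seed of the volume estimate.
#' @param frame optional `n_atoms x 3` coordinate matrix.
#' @return List: `shell` (A^3), `protein`, `bulk`, `box`, standard errors
#'   `shell_se`, `bulk_se`, and the sample fractions.
#' @export
shell_volume <- function(system, cutoff = 5.0, n_samples = 2e5, seed = 1L,
                         frame = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (is.null(frame)) frame <- system$coords
  if (is.null(frame)) stop("no coordinates: pass frame=", call. = FALSE)
  prot <- heavy_atoms(system, "protein")
  if (!length(prot)) stop("system has no protein heavy atoms", call. = FALSE)
  P <- frame[prot, , drop = FALSE]
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  U <- matrix(runif(3 * n_samples), ncol = 3) %*% diag(system$box)
  near <- cpp_within_any(U, P, system$box, cutoff) == 1L
  inside <- protein_interior(U, system, P = P, candidates = which(near))
  in_shell <- !inside & near
  vol_box <- prod(system$box)
  f_shell <- mean(in_shell); f_prot <- mean(inside)
  f_bulk <- 1 - f_shell - f_prot
  se <- function(f) sqrt(f * (1 - f) / n_samples) * vol_box
  list(shell = f_shell * vol_box, protein = f_prot * vol_box,
       bulk = f_bulk * vol_box, box = vol_box,
       shell_se = se(f_shell), bulk_se = se(f_bulk),
       fractions = c(shell = f_shell, protein = f_prot, bulk = f_bulk))
}

## TRUE for points inside the protein body: analytic test when the system
## carries a sphere model, else a per-atom van der Waals radius test
## (C 1.7, N 1.55, O 1.52, S/P 1.8, default 1.7 Angstrom). `candidates`
## restricts the expensive per-atom test to plausible rows.
protein_interior <- function(U, system, P = NULL, candidates = NULL) {
  if (!is.null(system$protein_model) &&
      identical(system$protein_model$type, "sphere")) {
    ctr <- system$protein_model$center
    d <- sweep(U, 2, ctr)
    d <- d - matrix(system$box, nrow(U), 3, byrow = TRUE) *
      round(d / matrix(system$box, nrow(U), 3, byrow = TRUE))
    return(rowSums(d^2) < system$protein_model$radius^2)
  }
  prot <- heavy_atoms(system, "protein")
  if (is.null(P)) {
    if (is.null(system$coords)) stop("no protein coordinates available",
                                     call. = FALSE)
    P <- system$coords[prot, , drop = FALSE]
  }
  vdw <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)
  el <- system$atoms$element[match(prot, system$atoms$id)]
  r_at <- unname(vdw[el]); r_at[is.na(r_at)] <- 1.7
  inside <- logical(nrow(U))
  if (is.null(candidates)) candidates <- seq_len(nrow(U))
  for (r_e in unique(r_at)) {
    sub <- P[r_at == r_e, , drop = FALSE]
    if (length(candidates))
      inside[candidates] <- inside[candidates] |
        cpp_within_any(U[candidates, , drop = FALSE], sub, system$box,
                       r_e) == 1L
  }
  inside
}

#' Adsorption free energy from occupancy
#'
#' `dG_ads = -RT log(rho_ads / rho_free)`, where `rho_ads` is the mean
#' number of adsorbed molecules per shell volume and `rho_free` the mean
#' number of free molecules per bulk volume (box minus protein minus
#' shell). The uncertainty comes from block averaging of the per-frame
#' density ratio.
#'
#' @param series an `adsorption_state_series` (from [chain_state_series()]).
#' @param shell_vol,bulk_vol volumes in A^3 (see [shell_volume()]).
#' @param temperature Kelvin.
#' @param n_blocks blocks for the error estimate (>= 5).
#' @param log_base `"natural"` (default) or `"ten"`.
#' @return List of class `energetics_result`: `dG` (kcal/mol), `dG_se`,
#'   `rho_ads`, `rho_free` (molecules/A^3), `p_adsorbed`, `RT`.
#' @export
adsorption_free_energy <- function(series, shell_vol, bulk_vol,
                                   temperature = 300, n_blocks = 5,
                                   log_base = c("natural", "ten")) {
  log_base <- match.arg(log_base)
  if (shell_vol <= 0 || bulk_vol <= 0) stop("volumes must be > 0",
                                            call. = FALSE)
  st <- series$states
  n_ads <- rowSums(st); n_free <- ncol(st) - n_ads
  RT <- .GAS_CONSTANT_KCAL * temperature
  lg <- function(x) if (log_base == "natural") log(x) else log10(x)
  mean_ads <- mean(n_ads); mean_free <- mean(n_free)
  if (mean_ads == 0 || mean_free == 0) {
    warning("no adsorbed or no free molecules in any frame; dG is infinite",
            call. = FALSE)
    return(structure(list(
      dG = ifelse(mean_ads == 0, Inf, -Inf), dG_se = NA_real_,
      rho_ads = mean_ads / shell_vol, rho_free = mean_free / bulk_vol,
      p_adsorbed = mean_ads / ncol(st), RT = RT),
      class = "energetics_result"))
  }
  rho_ads <- mean_ads / shell_vol
  rho_free <- mean_free / bulk_vol
  dG <- -RT * lg(rho_ads / rho_free)
  ## block averaging over the frame axis
  nf <- nrow(st)
  n_blocks <- max(2L, min(n_blocks, nf))
  idx <- split(seq_len(nf), cut(seq_len(nf), n_blocks, labels = FALSE))
  bvals <- vapply(idx, function(ii) {
    ma <- mean(n_ads[ii]); mf <- mean(n_free[ii])
    if (ma == 0 || mf == 0) NA_real_
    else -RT * lg((ma / shell_vol) / (mf / bulk_vol))
  }, numeric(1))
  bvals <- bvals[is.finite(bvals)]
  dG_se <- if (length(bvals) >= 2) sd(bvals) / sqrt(length(bvals)) else NA_real_
  structure(list(dG = dG, dG_se = dG_se, rho_ads = rho_ads,
                 rho_free = rho_free, p_adsorbed = mean_ads / ncol(st),
                 RT = RT),
            class = "energetics_result")
}

#' @export
print.energetics_result <- function(x, ...) {
  cat(sprintf(
    "energetics_result: dG_ads = %.3f +- %.3f kcal/mol (rho_ads/rho_free = %.3g)\n",
    x$dG, x$dG_se, x$rho_ads / x$rho_free))
  invisible(x)
}
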