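# Shared fixtures: small synthetic datasets built once per test run.

# a compact Markov dataset with water, reused across analysis tests
small_markov <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_markov_trajectory(markov_params(
        n_chains = 20, n_frames = 400, k_on = 0.5, k_off = 1.0,
        water_density = 0.002, resample = "frame", seed = 101,
        n_protein_points = 300))
    cache
  }
})

# unit square in the xy plane, side 2
square_coords <- function(side = 2) {
  rbind(c(0, 0, 0), c(side, 0, 0), c(side, side, 0), c(0, side, 0))
}

# brute-force minimum-image distance over all 27 periodic images
brute_min_image <- function(a, b, box) {
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% diag(box)
  min(sqrt(rowSums((matrix(a, 27, 3, byrow = TRUE) + shifts -
                      matrix(b, 27, 3, byrow = TRUE))^2)))
}

# random rigid transform (rotation + translation)
rigid_transform <- function(X, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(X %*% R, 2, runif(3, -20, 20), `+`)
}
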