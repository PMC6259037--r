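## Periodic-boundary geometry and rigid-body superposition.

#' Minimum-image distance between two points
#'
#' Euclidean distance under the minimum-image convention for an orthorhombic
#' periodic box.
#'
#' @param a,b numeric length-3 points (Angstrom).
#' @param box numeric length-3 box edge lengths (Angstrom).
#' @return Distance in Angstrom; never exceeds half the box diagonal.
#' @export
min_image_distance <- function(a, b, box) {
  d <- min_image_displacement(a, b, box)
  sqrt(sum(d * d))
}

#' Minimum-image displacement vector a - b
#' @inheritParams min_image_distance
#' @return Length-3 displacement, each component in `(-L/2, L/2]`.
#' @export
min_image_displacement <- function(a, b, box) {
  d <- as.numeric(a) - as.numeric(b)
  d - box * round(d / box)
}

#' Optimal-superposition (Kabsch) RMSD
#'
#' Root-mean-square deviation after removing rotation and translation by
#' least-squares superposition of the selected atoms.
#'
#' @param frame `n x 3` coordinate matrix (Angstrom), e.g. [frame_coords()].
#' @param reference `n x 3` reference coordinates (same atoms).
#' @param selection atom ids (rows) to superpose and measure; default all.
#' @return RMSD in nm (trajectory coordinates are Angstrom internally; the
#'   conventional reporting unit for backbone drift is nm).
#' @export
kabsch_rmsd <- function(frame, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(frame))
  A <- frame[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selections differ in size", call. = FALSE)
  if (nrow(A) < 3) stop("need at least 3 atoms to superpose", call. = FALSE)
  fit <- kabsch_fit(A, B)
  if (fit$degenerate)
    stop("degenerate (collinear) selection: superposition undefined",
         call. = FALSE)
  Afit <- sweep(A, 2, fit$center_a) %*% fit$rotation
  Afit <- sweep(Afit, 2, fit$center_b, `+`)
  sqrt(mean(rowSums((Afit - B)^2))) / 10
}

## Kabsch rotation via SVD; returns rotation matrix mapping centered A onto
## centered B, plus both centroids.
kabsch_fit <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Dm <- diag(c(1, 1, d))
  R <- sv$u %*% Dm %*% t(sv$v)
  degenerate <- sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)
  list(rotation = R, center_a = ca, center_b = cb, degenerate = degenerate)
}

## Apply a kabsch_fit to arbitrary coordinates (rigid transform that maps
## the fitted selection of A onto B).
apply_fit <- function(X, fit) {
  sweep(sweep(X, 2, fit$center_a) %*% fit$rotation, 2, fit$center_b, `+`)
}

#' Unwrap a bonded chain across periodic boundaries
#'
#' Rebuilds continuous chain coordinates by walking the bond graph from the
#' first atom and accumulating minimum-image displacements, so shape
#' descriptors see the molecule whole.
#'
#' @param coords `n x 3` wrapped coordinates of the chain atoms (rows in the
#'   chain's atom order).
#' @param bonds 2-column matrix of 1-based row indices into `coords`.
#' @param box length-3 box (Angstrom).
#' @return `n x 3` unwrapped coordinates.
#' @export
unwrap_chain <- function(coords, bonds, box) {
  n <- nrow(coords)
  if (n == 1L || is.null(bonds) || nrow(bonds) == 0L) return(coords)
  out <- coords
  seen <- logical(n)
  adj <- vector("list", n)
  for (e in seq_len(nrow(bonds))) {
    i <- bonds[e, 1]; j <- bonds[e, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (j in adj[[i]]) {
      if (!seen[j]) {
        out[j, ] <- out[i, ] + min_image_displacement(coords[j, ], coords[i, ], box)
        ## keep using original wrapped coords for displacement reference of
        ## neighbours further out
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  if (!all(seen))
    stop("bond graph does not connect all chain atoms", call. = FALSE)
  span <- apply(out, 2, function(v) diff(range(v)))
  if (any(span > box / 2 + 1e-9))
    warning("unwrapped chain spans more than half the box; ",
            "periodic image assignment may be ambiguous", call. = FALSE)
  out
}
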