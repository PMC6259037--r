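## Core data model: MolecularSystem (static topology), Trajectory (frames),
## atom selections. Internal units: Angstrom, ns, g/mol, kcal/mol.

#' Standard atomic masses (g/mol) by element symbol
#'
#' Masses for the elements that occur in protein/polymer/water/ion systems.
#' Builder atoms carry united-atom masses (implicit hydrogens folded in) so
#' that chain masses sum to the full molecular weight; this table is used for
#' atoms read from PDB files.
#'
#' @return Named numeric vector of masses in g/mol.
#' @export
atomic_masses <- function() {
  c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
    S = 32.06, P = 30.974, NA. = 22.990, CL = 35.45, K = 39.098,
    MG = 24.305, CA. = 40.078, ZN = 65.38, FE = 55.845)
}

.mass_of_element <- function(el) {
  m <- atomic_masses()
  key <- toupper(el)
  key[key == "NA"] <- "NA."
  key[key == "CA"] <- "CA."
  out <- unname(m[key])
  if (anyNA(out)) {
    bad <- unique(el[is.na(out)])
    stop("no mass known for element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Construct a MolecularSystem
#'
#' The static topology of a simulated system: an atom table, the list of
#' polymer chains, and an orthorhombic periodic box.
#'
#' @param atoms data.frame with columns `id` (integer, 1..n), `element`
#'   (symbol, e.g. "C"), `mass` (g/mol), `resname`, `resid` (integer),
#'   `chain` (chain identifier) and `role` (one of `"protein"`, `"polymer"`,
#'   `"water"`, `"ion"`).
#' @param chains list of polymer chain descriptors, each a list with fields
#'   `atom_ids` (ordered integer ids), `kind` (`"PEG"`, `"PSar"`, `"PAla"` or
#'   `"generic"`), `n_monomers`, and optionally `bonds` (2-column integer
#'   matrix of within-chain atom ids), `ends` (the two backbone end atom ids)
#'   and `mass` (full molecular weight, g/mol).
#' @param box numeric length-3, box edge lengths in Angstrom.
#' @param protein_model optional list describing an idealized protein, e.g.
#'   `list(type = "sphere", center = c(x,y,z), radius = R)`; used by
#'   Monte-Carlo volume routines to exclude the protein interior analytically.
#' @return An object of class `MolecularSystem`.
#' @export
molecular_system <- function(atoms, chains = list(), box, protein_model = NULL) {
  required <- c("id", "element", "mass", "resname", "resid", "chain", "role")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  atoms$role <- as.character(atoms$role)
  bad_role <- setdiff(unique(atoms$role), c("protein", "polymer", "water", "ion"))
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  if (any(atoms$mass <= 0)) stop("all atom masses must be > 0", call. = FALSE)
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive edge lengths (Angstrom)", call. = FALSE)
  poly_ids <- atoms$id[atoms$role == "polymer"]
  in_chain <- unlist(lapply(chains, `[[`, "atom_ids"))
  if (anyDuplicated(in_chain))
    stop("an atom belongs to more than one polymer chain", call. = FALSE)
  if (!setequal(poly_ids, in_chain))
    stop("polymer atoms and chain membership disagree: ",
         length(poly_ids), " polymer atoms vs ",
         length(in_chain), " atoms in chains", call. = FALSE)
  structure(
    list(atoms = atoms, chains = chains, box = box,
         protein_model = protein_model),
    class = "MolecularSystem")
}

#' @export
print.MolecularSystem <- function(x, ...) {
  tab <- table(factor(x$atoms$role,
                      levels = c("protein", "polymer", "water", "ion")))
  cat("MolecularSystem:", nrow(x$atoms), "atoms,",
      length(x$chains), "polymer chain(s)\n")
  cat(sprintf("  box: %.2f x %.2f x %.2f A\n", x$box[1], x$box[2], x$box[3]))
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(x$chains)) {
    kinds <- table(vapply(x$chains, `[[`, "", "kind"))
    cat("  chain kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

n_atoms <- function(system) nrow(system$atoms)

#' Construct a Trajectory
#'
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`,
#'   coordinates in Angstrom.
#' @param box per-frame box: either a length-3 vector (constant box) or an
#'   `n_frames x 3` matrix.
#' @param dt frame spacing in ns.
#' @param discard leading time (ns) to drop from equilibrium averages;
#'   analysis functions use this as their default discard prefix.
#' @return Object of class `Trajectory`.
#' @export
trajectory <- function(coords, box, dt, discard = 0) {
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive frame spacing in ns", call. = FALSE)
  nf <- d[3]
  if (is.null(dim(box))) {
    box <- matrix(as.numeric(box), nrow = nf, ncol = 3, byrow = TRUE)
  } else {
    box <- as.matrix(box)
    if (nrow(box) != nf || ncol(box) != 3)
      stop("per-frame box must be n_frames x 3", call. = FALSE)
  }
  if (any(box <= 0)) stop("box edges must be > 0", call. = FALSE)
  structure(list(coords = coords, box = box, dt = dt, discard = discard,
                 n_frames = nf),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[1], "atoms,", x$n_frames, "frames, dt =",
      x$dt, "ns (", x$n_frames * x$dt, "ns total; discard prefix",
      x$discard, "ns )\n")
  invisible(x)
}

#' Coordinates of one frame
#'
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @return `n_atoms x 3` numeric matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  X <- traj$coords[, , i, drop = FALSE]
  dim(X) <- dim(X)[1:2]
  X
}

#' Frame indices entering equilibrium averages
#'
#' Frames whose time (frame index times `dt`, with frame 1 at t = dt) exceeds
#' the discard prefix.
#'
#' @param traj a [trajectory()].
#' @param discard override of the trajectory's discard prefix (ns).
#' @return Integer vector of frame indices.
#' @export
analysis_frames <- function(traj, discard = NULL) {
  if (is.null(discard)) discard <- traj$discard
  times <- seq_len(traj$n_frames) * traj$dt
  which(times > discard)
}

#' Select heavy (non-hydrogen) atoms
#'
#' Heavy atoms of a role, polymer chain, or explicit atom subset. Hydrogen
#' and deuterium are excluded by element.
#'
#' @param system a [molecular_system()].
#' @param role one of `"protein"`, `"polymer"`, `"water"`, `"ion"`, or `"all"`.
#' @param chain polymer chain index (1-based); overrides `role`.
#' @param ids explicit atom ids to filter; overrides `role` and `chain`.
#' @return Integer vector of atom ids (an atom selection), ordered by id,
#'   with attribute `label`. Empty selections are returned with a warning.
#' @export
heavy_atoms <- function(system, role = "all", chain = NULL, ids = NULL) {
  at <- system$atoms
  if (!is.null(ids)) {
    pool <- ids
    label <- "ids"
  } else if (!is.null(chain)) {
    if (chain < 1 || chain > length(system$chains))
      stop("chain index out of range: ", chain, call. = FALSE)
    pool <- system$chains[[chain]]$atom_ids
    label <- paste0("chain:", chain)
  } else {
    role <- match.arg(role, c("all", "protein", "polymer", "water", "ion"))
    pool <- if (role == "all") at$id else at$id[at$role == role]
    label <- role
  }
  el <- toupper(at$element[match(pool, at$id)])
  sel <- sort(pool[!el %in% c("H", "D")])
  if (!length(sel))
    warning("heavy-atom selection '", label, "' is empty", call. = FALSE)
  attr(sel, "label") <- label
  sel
}

#' Polymer mass concentration of a system
#'
#' Total polymer chain mass divided by box volume, in g/ml, matching the
#' concentration bookkeeping of simulation composition tables.
#'
#' @param system a [molecular_system()]; chains must carry full molecular
#'   weights (the builder provides united-atom masses so heavy-atom sums
#'   equal full molecular weights).
#' @return Concentration in g/ml.
#' @export
mass_concentration <- function(system) {
  if (!length(system$chains)) {
    warning("system has no polymer chains; concentration is 0", call. = FALSE)
    return(0)
  }
  chain_mass <- vapply(system$chains, function(ch) {
    if (!is.null(ch$mass)) ch$mass
    else sum(system$atoms$mass[match(ch$atom_ids, system$atoms$id)])
  }, numeric(1))
  grams <- sum(chain_mass) / .AVOGADRO
  vol_ml <- prod(system$box) * 1e-24   # A^3 -> cm^3 == ml
  grams / vol_ml
}

#' Census of a system (atoms, roles, residues, chains)
#'
#' @param system a [molecular_system()].
#' @return A list with per-role atom counts, protein residue count, polymer
#'   chain count and the mass concentration in g/ml.
#' @export
system_census <- function(system) {
  at <- system$atoms
  prot <- at[at$role == "protein", ]
  list(
    n_atoms = nrow(at),
    atoms_by_role = table(factor(at$role, levels = c("protein", "polymer",
                                                     "water", "ion"))),
    n_protein_residues = length(unique(paste(prot$chain, prot$resid))),
    n_water = length(unique(paste(at$chain, at$resid)[at$role == "water"])),
    n_chains = length(system$chains),
    concentration_g_ml = if (length(system$chains)) mass_concentration(system) else 0)
}
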