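## Standard-format I/O: PDB topologies (via bio3d), XYZ and DCD coordinate
## trajectories, and small CSV/JSON report helpers.

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET",
                  "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Default residue-name to role mapping
#'
#' PDB dialects differ in water/ion naming; the mapping is config-driven
#' with these defaults. Polymer residue names must be declared (the builder
#' emits `PEG`, `SAR`, `PAL`, `BEA` plus `ACE`/`NME` caps).
#'
#' @return List with `water`, `ion` and `polymer` residue-name vectors.
#' @export
default_role_map <- function() {
  list(water = c("HOH", "TIP3", "TIP3P", "TIP", "WAT", "SOL", "SPC"),
       ion = c("NA", "CL", "SOD", "CLA", "K", "POT", "MG", "CAL", "ZN"),
       polymer = c("PEG", "SAR", "PAL", "BEA", "ACE", "NME"))
}

#' Load a PDB topology as a MolecularSystem
#'
#' Parses a PDB file (via `bio3d::read.pdb`), assigns each atom a role
#' (protein / polymer / water / ion) from its residue name, and rebuilds the
#' polymer chain list from chain/segment labels.
#'
#' @param path PDB file.
#' @param box length-3 box edges in Angstrom (PDB `CRYST1` is used when
#'   present; an explicit `box` overrides it).
#' @param role_map list as [default_role_map()]; entries are merged over the
#'   defaults.
#' @param chain_source column used to group polymer chains: `"auto"` prefers
#'   the segment id when present, else the chain id.
#' @param unknown what to do with residue names that are neither mapped nor
#'   standard amino acids: `"protein"` tags them protein, `"error"` stops
#'   listing the offending names.
#' @return A [molecular_system()] with an additional `coords` element
#'   (`n x 3` matrix, the PDB coordinates).
#' @export
load_topology <- function(path, box = NULL, role_map = list(),
                          chain_source = c("auto", "chain", "segid"),
                          unknown = c("protein", "error")) {
  unknown <- match.arg(unknown)
  chain_source <- match.arg(chain_source)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("malformed PDB '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  rm0 <- default_role_map()
  for (nm in names(role_map)) rm0[[nm]] <- role_map[[nm]]
  resname <- toupper(trimws(at$resid))
  element <- toupper(trimws(at$elesy))
  noel <- is.na(element) | element == ""
  if (any(noel)) {
    # fall back to the first alphabetic character of the atom name, with
    # two-letter ion symbols resolved through the residue name
    nm1 <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(at$elety[noel])))
    el <- substr(nm1, 1, 1)
    two <- toupper(nm1) %in% c("NA", "CL", "MG", "FE", "ZN") &
      resname[noel] %in% rm0$ion
    el[two] <- toupper(nm1)[two]
    element[noel] <- toupper(el)
  }
  role <- rep(NA_character_, nrow(at))
  role[resname %in% rm0$water] <- "water"
  role[resname %in% rm0$ion] <- "ion"
  role[resname %in% rm0$polymer] <- "polymer"
  role[is.na(role) & resname %in% .STANDARD_AA] <- "protein"
  if (anyNA(role)) {
    leftovers <- unique(resname[is.na(role)])
    if (unknown == "error")
      stop("residue name(s) with no role mapping: ",
           paste(leftovers, collapse = ", "), call. = FALSE)
    role[is.na(role)] <- "protein"
  }
  segid <- if ("segid" %in% names(at)) trimws(at$segid) else ""
  chain <- trimws(ifelse(is.na(at$chain), "", at$chain))
  lab <- switch(chain_source,
    segid = segid,
    chain = chain,
    auto = ifelse(!is.na(segid) & segid != "", segid, chain))
  lab[is.na(lab) | lab == ""] <- "A"
  atoms <- data.frame(
    id = seq_len(nrow(at)), element = element,
    mass = .mass_of_element(element),
    resname = resname, resid = at$resno, chain = lab, role = role)
  chains <- .rebuild_polymer_chains(atoms)
  if (is.null(box)) {
    cr <- grep("^CRYST1", readLines(path, n = 500), value = TRUE)
    if (length(cr)) {
      box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                          substr(cr[1], 25, 33)))
    }
  }
  if (is.null(box) || any(is.na(box)) || any(box <= 0)) {
    span <- apply(cbind(at$x, at$y, at$z), 2, function(v) diff(range(v)))
    box <- pmax(span + 20, 1)  # generous non-periodic fallback
  }
  sys <- molecular_system(atoms, chains, box)
  sys$coords <- unname(cbind(at$x, at$y, at$z))
  sys
}

## group polymer atoms into chains by their chain label and infer kind and
## bond topology from the builder templates where the atom count matches
.rebuild_polymer_chains <- function(atoms) {
  poly <- atoms[atoms$role == "polymer", ]
  if (!nrow(poly)) return(list())
  chains <- list()
  for (lab in unique(poly$chain)) {
    sub <- poly[poly$chain == lab, ]
    main <- setdiff(unique(sub$resname), c("ACE", "NME"))
    kind <- switch(main[1], PEG = "PEG", SAR = "PSar", PAL = "PAla",
                   BEA = "generic", "generic")
    n_mon <- length(unique(sub$resid[sub$resname %in% main]))
    tmpl <- tryCatch(build_polymer_topology(kind, n_mon),
                     error = function(e) NULL)
    ids <- sub$id
    if (!is.null(tmpl) && nrow(tmpl$atoms) == length(ids)) {
      bonds <- matrix(ids[tmpl$bonds], ncol = 2)
      ends <- ids[tmpl$ends]; mass <- tmpl$mass
    } else {
      bonds <- if (length(ids) > 1)
        cbind(ids[-length(ids)], ids[-1]) else matrix(integer(0), ncol = 2)
      ends <- c(ids[1], ids[length(ids)])
      mass <- sum(sub$mass)
    }
    chains[[length(chains) + 1L]] <- list(
      atom_ids = ids, kind = kind, n_monomers = n_mon,
      bonds = bonds, ends = ends, mass = mass)
  }
  chains
}

#' Write a MolecularSystem + coordinates as PDB
#'
#' @param system a [molecular_system()].
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology <- function(system, coords, path) {
  at <- system$atoms
  stopifnot(nrow(coords) == nrow(at))
  chain1 <- substr(at$chain, 1, 1)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords)),
                   resno = at$resid, resid = at$resname,
                   eleno = at$id, elety = .atom_names(system),
                   chain = chain1, segid = at$chain,
                   elesy = at$element, print.segid = TRUE)
  # prepend a CRYST1 record so the box round-trips
  lines <- readLines(path)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   system$box[1], system$box[2], system$box[3], 90, 90, 90)
  writeLines(c(cryst, lines), path)
  invisible(path)
}

## best-effort atom names: template names for builder chains, element
## otherwise
.atom_names <- function(system) {
  at <- system$atoms
  nm <- at$element
  for (ch in system$chains) {
    kind <- ch$kind
    tmpl <- tryCatch(build_polymer_topology(kind, ch$n_monomers),
                     error = function(e) NULL)
    if (!is.null(tmpl) && nrow(tmpl$atoms) == length(ch$atom_ids))
      nm[match(ch$atom_ids, at$id)] <- tmpl$atoms$name
  }
  nm[at$role == "water"] <- "OW"
  nm
}

#' Write a trajectory in (extended) XYZ format
#'
#' Multi-frame XYZ; the comment line carries the box and frame time as
#' `box="lx ly lz" time=<ns>`.
#'
#' @param traj a [trajectory()].
#' @param system the matching [molecular_system()] (for element symbols).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, system, path) {
  n <- dim(traj$coords)[1]
  stopifnot(n == n_atoms(system))
  el <- system$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    X <- frame_coords(traj, f)
    writeLines(c(
      as.character(n),
      sprintf('box="%.6f %.6f %.6f" time=%.6f', traj$box[f, 1],
              traj$box[f, 2], traj$box[f, 3], f * traj$dt),
      sprintf("%-2s %12.6f %12.6f %12.6f", el, X[, 1], X[, 2], X[, 3])), con)
  }
  invisible(path)
}

#' Read an (extended) XYZ trajectory
#'
#' @param path XYZ file (frames concatenated).
#' @param system the [molecular_system()] the file must match; atom counts
#'   are checked.
#' @param dt frame spacing in ns.
#' @param box fallback box if the comment lines carry none.
#' @param discard discard prefix (ns) stored on the trajectory.
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(path, system, dt, box = NULL, discard = 0) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("not an XYZ file: first line must be an atom count",
                     call. = FALSE)
  if (n != n_atoms(system))
    stop("atom-count mismatch: file has ", n, " atoms, system has ",
         n_atoms(system), call. = FALSE)
  per <- n + 2L
  if (length(lines) %% per != 0L)
    stop("truncated XYZ file: ", length(lines), " lines is not a multiple of ",
         per, call. = FALSE)
  nf <- length(lines) %/% per
  coords <- array(NA_real_, c(n, 3, nf))
  boxes <- matrix(NA_real_, nf, 3)
  for (f in seq_len(nf)) {
    off <- (f - 1L) * per
    m <- regmatches(lines[off + 2L],
                    regexec('box="([-0-9.eE+ ]+)"', lines[off + 2L]))[[1]]
    if (length(m) == 2) boxes[f, ] <- scan(text = m[2], quiet = TRUE)
    body <- lines[off + 2L + seq_len(n)]
    vals <- matrix(scan(text = sub("^\\s*\\S+", "", body), quiet = TRUE),
                   ncol = 3, byrow = TRUE)
    coords[, , f] <- vals
  }
  if (anyNA(boxes)) {
    if (is.null(box))
      stop("XYZ file carries no box and none was supplied; periodic ",
           "analyses need one", call. = FALSE)
    boxes[] <- matrix(box, nf, 3, byrow = TRUE)
  }
  trajectory(coords, boxes, dt = dt, discard = discard)
}

#' Write a trajectory in (CHARMM-style) DCD format
#'
#' Minimal single-segment DCD writer with a crystal record per frame;
#' readable by `bio3d::read.dcd` and standard MD tools.
#'
#' @inheritParams write_xyz_trajectory
#' @return `path`, invisibly.
#' @export
write_dcd_trajectory <- function(traj, system, path) {
  n <- dim(traj$coords)[1]
  stopifnot(n == n_atoms(system))
  con <- file(path, "wb")
  on.exit(close(con))
  endian <- "little"
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = endian)
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = endian)
  }
  icntrl <- integer(20)
  icntrl[1] <- traj$n_frames
  icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- traj$n_frames
  icntrl[11] <- 1L   # crystal record present
  icntrl[20] <- 24L  # CHARMM version stamp
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl[1:9], con, size = 4, endian = endian)
    writeBin(as.numeric(traj$dt), con, size = 4, endian = endian)  # AKMA-ish dt slot
    writeBin(icntrl[11:20], con, size = 4, endian = endian)
  }, 84)
  title <- sprintf("%-80s", "written by coronadsorb")
  rec(function() {
    writeBin(1L, con, size = 4, endian = endian)
    writeChar(title, con, 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(n), con, size = 4, endian = endian), 4)
  for (f in seq_len(traj$n_frames)) {
    b <- traj$box[f, ]
    # XTLABC lower-triangle order: a, cos(gamma), b, cos(beta), cos(alpha), c
    rec(function() writeBin(as.numeric(c(b[1], 0, b[2], 0, 0, b[3])), con,
                            size = 8, endian = endian), 48)
    X <- frame_coords(traj, f)
    for (k in 1:3)
      rec(function() writeBin(as.numeric(X[, k]), con, size = 4,
                              endian = endian), 4 * n)
  }
  invisible(path)
}

#' Read a DCD trajectory
#'
#' Wraps `bio3d::read.dcd`; the crystal record supplies the per-frame box
#' when present.
#'
#' @inheritParams read_xyz_trajectory
#' @param path DCD file.
#' @return A [trajectory()].
#' @export
read_dcd_trajectory <- function(path, system, dt, box = NULL, discard = 0) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  n <- ncol(xyz) / 3
  if (n != n_atoms(system))
    stop("atom-count mismatch: file has ", n, " atoms, system has ",
         n_atoms(system), call. = FALSE)
  nf <- nrow(xyz)
  cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                   error = function(e) NULL)
  boxes <- if (!is.null(cell)) as.matrix(cell[, 1:3, drop = FALSE])
  else if (!is.null(box)) matrix(box, nf, 3, byrow = TRUE)
  else stop("DCD carries no unit cell and no box was supplied", call. = FALSE)
  coords <- array(NA_real_, c(n, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(coords, boxes, dt = dt, discard = discard)
}

#' Load a trajectory, dispatching on file extension
#'
#' @inheritParams read_xyz_trajectory
#' @param path `.xyz` or `.dcd` file.
#' @return A [trajectory()].
#' @export
load_trajectory <- function(path, system, dt, box = NULL, discard = 0) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    xyz = read_xyz_trajectory(path, system, dt, box = box, discard = discard),
    dcd = read_dcd_trajectory(path, system, dt, box = box, discard = discard),
    stop("unknown trajectory format: .", ext, " (expected .xyz or .dcd)",
         call. = FALSE))
}
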