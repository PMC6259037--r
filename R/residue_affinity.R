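## Per-residue and per-amino-acid-type polymer/water ratios, and voxelized
## polymer density grids with bulk-relative thresholding and OpenDX export.

.AA_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", HSD = "H",
             HSE = "H", HSP = "H", ILE = "I", LEU = "L", LYS = "K",
             MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T",
             TRP = "W", TYR = "Y", VAL = "V")

#' Time-summed polymer and water counts in residue shells
#'
#' For every protein residue, counts polymer heavy atoms and water oxygens
#' within the cutoff of any of the residue's heavy atoms, summed over
#' frames (an atom inside two residue shells counts once for each).
#' Per-amino-acid-type ratios pool the counts of all residues of the type
#' and are normalized by the whole-box polymer/water ratio.
#'
#' @param traj,system as elsewhere.
#' @param cutoff residue shell radius (Angstrom); 5.0 = 0.5 nm.
#' @param discard discard prefix override (ns).
#' @return List of class `residue_affinity_table`: `residues` (data.frame:
#'   chain, resid, resname, type, n_polymer, n_water, ratio), `types`
#'   (data.frame: type, n_polymer, n_water, ratio, norm_ratio), and
#'   `bulk_ratio`.
#' @export
residue_shell_counts <- function(traj, system, cutoff = 5.0, discard = NULL) {
  at <- system$atoms
  prot <- heavy_atoms(system, "protein")
  if (!length(prot)) stop("no protein residues present", call. = FALSE)
  poly <- suppressWarnings(heavy_atoms(system, "polymer"))
  wat <- suppressWarnings(heavy_atoms(system, "water"))
  key <- paste(at$chain[match(prot, at$id)], at$resid[match(prot, at$id)])
  res_keys <- unique(key)
  resid0 <- match(key, res_keys) - 1L
  nres <- length(res_keys)
  frames <- analysis_frames(traj, discard)
  npol <- nwat <- numeric(nres)
  for (f in frames) {
    X <- frame_coords(traj, f)
    P <- X[prot, , drop = FALSE]
    if (length(poly))
      npol <- npol + cpp_residue_counts(X[poly, , drop = FALSE], P, resid0,
                                        nres, traj$box[f, ], cutoff)
    if (length(wat))
      nwat <- nwat + cpp_residue_counts(X[wat, , drop = FALSE], P, resid0,
                                        nres, traj$box[f, ], cutoff)
  }
  first <- match(res_keys, key)
  resname <- at$resname[match(prot, at$id)][first]
  type <- unname(.AA_ONE[resname])
  type[is.na(type)] <- resname[is.na(type)]  # non-standard: keep the name
  residues <- data.frame(
    chain = at$chain[match(prot, at$id)][first],
    resid = at$resid[match(prot, at$id)][first],
    resname = resname, type = type,
    n_polymer = npol, n_water = nwat,
    ratio = ifelse(nwat > 0, npol / nwat, NA_real_))
  agg_p <- tapply(residues$n_polymer, residues$type, sum)
  agg_w <- tapply(residues$n_water, residues$type, sum)
  bulk_ratio <- if (length(wat))
    (length(poly) * length(frames)) / (length(wat) * length(frames))
  else NA_real_
  types <- data.frame(
    type = names(agg_p),
    n_polymer = as.numeric(agg_p), n_water = as.numeric(agg_w),
    ratio = ifelse(agg_w > 0, as.numeric(agg_p) / as.numeric(agg_w),
                   NA_real_))
  types$norm_ratio <- types$ratio / bulk_ratio
  undef <- is.na(types$ratio)
  if (any(undef))
    warning("type(s) with zero water counts flagged undefined: ",
            paste(types$type[undef], collapse = ", "), call. = FALSE)
  structure(list(residues = residues, types = types,
                 bulk_ratio = bulk_ratio, cutoff = cutoff),
            class = "residue_affinity_table")
}

#' Correlate the residue-type affinities of two polymers
#'
#' Pearson correlation of normalized polymer/water ratios over the shared
#' amino-acid types, plus the mean signed offset (a systematically more
#' adsorbing polymer shows a positive offset at equal correlation).
#'
#' @param tableA,tableB `residue_affinity_table`s for the two polymers.
#' @return List: `r`, `offset` (mean of B - A), `n_types`, `types`.
#' @export
compare_polymers <- function(tableA, tableB) {
  a <- tableA$types; b <- tableB$types
  shared <- intersect(a$type[!is.na(a$norm_ratio)],
                      b$type[!is.na(b$norm_ratio)])
  if (length(shared) < 3)
    stop("fewer than 3 shared residue types with defined ratios",
         call. = FALSE)
  va <- a$norm_ratio[match(shared, a$type)]
  vb <- b$norm_ratio[match(shared, b$type)]
  list(r = cor(va, vb), offset = mean(vb - va), n_types = length(shared),
       types = shared)
}

#' Voxelized time-averaged polymer density grid
#'
#' Bins polymer heavy atoms into voxels over all analysis frames, after
#' optionally aligning every frame onto the protein heavy atoms of the
#' first frame (rigid-body Kabsch superposition, so the map is in the
#' protein's frame of reference).
#'
#' @param traj,system as elsewhere.
#' @param voxel voxel edge (Angstrom).
#' @param align superpose frames on the protein before binning.
#' @param discard discard prefix override (ns).
#' @return List of class `density_grid`: `counts` (3-D array), `density`
#'   (counts / (frames * voxel^3), 1/A^3), `origin`, `voxel`, `n_frames`,
#'   `bulk_density` (total polymer heavy atoms / box volume).
#' @export
polymer_density_grid <- function(traj, system, voxel = 1.0, align = TRUE,
                                 discard = NULL) {
  if (voxel <= 0) stop("voxel must be > 0", call. = FALSE)
  if (any(voxel > system$box)) stop("voxel larger than the box", call. = FALSE)
  poly <- heavy_atoms(system, "polymer")
  if (!length(poly)) stop("no polymer heavy atoms", call. = FALSE)
  prot <- suppressWarnings(heavy_atoms(system, "protein"))
  frames <- analysis_frames(traj, discard)
  dims <- pmax(1L, as.integer(ceiling(system$box / voxel)))
  counts <- array(0, dims)
  ref <- if (align && length(prot))
    frame_coords(traj, frames[1])[prot, , drop = FALSE] else NULL
  for (f in frames) {
    X <- frame_coords(traj, f)
    pts <- X[poly, , drop = FALSE]
    if (!is.null(ref)) {
      fit <- kabsch_fit(X[prot, , drop = FALSE], ref)
      pts <- apply_fit(pts, fit)
    }
    # wrap into the box, then bin
    pts <- pts - floor(pts / matrix(system$box, nrow(pts), 3, byrow = TRUE)) *
      matrix(system$box, nrow(pts), 3, byrow = TRUE)
    ijk <- pmin(floor(pts / voxel), matrix(dims - 1L, nrow(pts), 3,
                                           byrow = TRUE))
    lin <- 1 + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- counts + array(tab, dims)
  }
  density <- counts / (length(frames) * voxel^3)
  structure(list(counts = counts, density = density,
                 origin = c(0, 0, 0), voxel = voxel,
                 n_frames = length(frames),
                 bulk_density = length(poly) / prod(system$box)),
            class = "density_grid")
}

#' Threshold a density grid at a multiple of the bulk density
#'
#' @param grid a [polymer_density_grid()] result.
#' @param factor threshold as a multiple of the overall (bulk) polymer
#'   density; the conventional map uses twice the bulk density.
#' @return List: `mask` (logical 3-D array, density > factor * bulk),
#'   `n_voxels`, `threshold` (1/A^3).
#' @export
threshold_regions <- function(grid, factor = 2.0) {
  if (grid$bulk_density <= 0) stop("bulk density must be > 0", call. = FALSE)
  thr <- factor * grid$bulk_density
  mask <- grid$density > thr
  list(mask = mask, n_voxels = sum(mask), threshold = thr)
}

#' Write a density grid in OpenDX format
#'
#' Standard `.dx` volumetric layout readable by common molecular viewers.
#'
#' @param grid a [polymer_density_grid()] result.
#' @param path output file.
#' @param per_nm3 write densities per nm^3 instead of per A^3 (display
#'   convention for polymer density maps).
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path, per_nm3 = FALSE) {
  d <- dim(grid$density)
  vals <- as.numeric(aperm(grid$density, c(3, 2, 1)))  # z fastest in file
  if (per_nm3) vals <- vals * 1000
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$voxel),
    sprintf("delta 0 %.6f 0", grid$voxel),
    sprintf("delta 0 0 %.6f", grid$voxel),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))), con)
  full <- length(vals) %/% 3
  if (full > 0)
    writeLines(sprintf("%.8g %.8g %.8g",
                       vals[3 * seq_len(full) - 2],
                       vals[3 * seq_len(full) - 1],
                       vals[3 * seq_len(full)]), con)
  rest <- length(vals) - 3 * full
  if (rest > 0)
    writeLines(paste(sprintf("%.8g", vals[(3 * full + 1):length(vals)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field'), con)
  invisible(path)
}

#' Read an OpenDX density grid
#'
#' @param path `.dx` file written by [write_dx()] (or compatible).
#' @return List of class `density_grid` with `density`, `origin`, `voxel`.
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  gp <- grep("gridpositions", lines, value = TRUE)[1]
  d <- as.integer(tail(strsplit(gp, "\\s+")[[1]], 3))
  origin <- as.numeric(strsplit(trimws(sub("origin", "",
    grep("^origin", lines, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dvals <- vapply(deltas, function(l)
    max(abs(as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]]))),
    numeric(1), USE.NAMES = FALSE)
  voxel <- dvals[1]
  start <- grep("data follows", lines)[1] + 1L
  end <- grep("attribute", lines)[1] - 1L
  vals <- scan(text = paste(lines[start:end], collapse = " "), quiet = TRUE)
  density <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  structure(list(density = density, counts = NULL, origin = origin,
                 voxel = voxel, n_frames = NA_integer_,
                 bulk_density = NA_real_),
            class = "density_grid")
}
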