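## Heavy-atom chain templates for the three polymer chemistries plus a
## generic bead polymer. Atoms carry united-atom masses (implicit hydrogens
## folded into the bonded heavy atom) so template masses sum to the full
## molecular weight, which is what mass-concentration bookkeeping needs.

#' Build a heavy-atom polymer chain template
#'
#' Constructs the ordered heavy-atom list, bonds, masses and backbone ends of
#' one polymer chain.
#'
#' Chemistries and end caps:
#' * `PEG`: poly(ethylene glycol). Default `peg_cap = "diol"` gives the
#'   hydroxyl-terminated chain H-(O-CH2-CH2)n-OH with `3n + 1` heavy atoms
#'   (22 for the 7-mer). `peg_cap = "dimethyl"` gives the methyl-ether capped
#'   CH3-(O-CH2-CH2)n-O-CH3 with `3n + 3` heavy atoms (24 for the 7-mer).
#' * `PSar`: poly-sarcosine (N-methyl glycine peptoid), acetyl N-cap and
#'   N,N-dimethylamide C-cap: `5n + 6` heavy atoms (26 for the 4-mer).
#' * `PAla`: poly-alanine with the same caps; constitutional isomer of PSar,
#'   identical heavy-atom count and molecular weight.
#' * `generic`: n CH2-like beads in a linear chain (used by the synthetic
#'   generators).
#'
#' @param kind `"PEG"`, `"PSar"`, `"PAla"` or `"generic"`.
#' @param n_monomers number of repeat units (>= 1).
#' @param peg_cap PEG end-group convention, `"diol"` (default) or
#'   `"dimethyl"`.
#' @return A list of class `polymer_template` with fields `kind`,
#'   `n_monomers`, `atoms` (data.frame: name, element, mass, resname, resid,
#'   backbone flag), `bonds` (2-column matrix of 1-based template indices),
#'   `ends` (indices of first/last backbone heavy atoms, caps excluded) and
#'   `mass` (full molecular weight, g/mol).
#' @export
build_polymer_topology <- function(kind, n_monomers,
                                   peg_cap = c("diol", "dimethyl")) {
  if (!is.numeric(n_monomers) || n_monomers < 1)
    stop("n_monomers must be >= 1", call. = FALSE)
  n <- as.integer(n_monomers)
  kind <- as.character(kind)
  if (!kind %in% c("PEG", "PSar", "PAla", "generic"))
    stop("unknown polymer kind: '", kind,
         "' (expected PEG, PSar, PAla or generic)", call. = FALSE)
  peg_cap <- match.arg(peg_cap)

  # united-atom masses
  m <- c(C = 12.011, CH = 13.019, CH2 = 14.027, CH3 = 15.035,
         O = 15.999, OH = 17.007, N = 14.007, NH = 15.015)

  if (kind == "PEG") {
    atoms <- list()
    for (i in seq_len(n)) {
      o_mass <- if (i == 1 && peg_cap == "diol") m[["OH"]] else m[["O"]]
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = c("O", "C1", "C2"), element = c("O", "C", "C"),
        mass = c(o_mass, m[["CH2"]], m[["CH2"]]),
        resname = "PEG", resid = i, backbone = TRUE)
    }
    if (peg_cap == "diol") {
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = "OT", element = "O", mass = m[["OH"]],
        resname = "PEG", resid = n, backbone = FALSE)
    } else {
      atoms[[1]]$mass[1] <- m[["O"]]
      atoms <- c(list(data.frame(
        name = "CM1", element = "C", mass = m[["CH3"]],
        resname = "PEG", resid = 1L, backbone = FALSE)), atoms)
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = "OT", element = "O", mass = m[["O"]],
        resname = "PEG", resid = n, backbone = FALSE)
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = "CM2", element = "C", mass = m[["CH3"]],
        resname = "PEG", resid = n, backbone = FALSE)
    }
    atoms <- do.call(rbind, atoms)
    # linear chain: every atom bonded to the previous one
    bonds <- cbind(seq_len(nrow(atoms) - 1L), seq_len(nrow(atoms) - 1L) + 1L)
    ends <- range(which(atoms$backbone))
  } else if (kind %in% c("PSar", "PAla")) {
    resname <- if (kind == "PSar") "SAR" else "PAL"
    # acetyl cap: CH3-C(=O)-
    atoms <- data.frame(
      name = c("CAY", "CY", "OY"), element = c("C", "C", "O"),
      mass = c(m[["CH3"]], m[["C"]], m[["O"]]),
      resname = "ACE", resid = 0L, backbone = FALSE)
    bonds <- rbind(c(1L, 2L), c(2L, 3L))
    prev_c <- 2L  # carbonyl carbon the next amide N bonds to
    for (i in seq_len(n)) {
      base <- nrow(atoms)
      if (kind == "PSar") {
        # peptoid: side methyl on the backbone nitrogen, CA is CH2
        res <- data.frame(
          name = c("N", "CN", "CA", "C", "O"),
          element = c("N", "C", "C", "C", "O"),
          mass = c(m[["N"]], m[["CH3"]], m[["CH2"]], m[["C"]], m[["O"]]),
          resname = resname, resid = i,
          backbone = c(TRUE, FALSE, TRUE, TRUE, FALSE))
        res_bonds <- rbind(c(base + 1L, base + 2L),  # N-CN
                           c(base + 1L, base + 3L),  # N-CA
                           c(base + 3L, base + 4L),  # CA-C
                           c(base + 4L, base + 5L))  # C=O
      } else {
        # peptide: NH backbone, CH side methyl on CA
        res <- data.frame(
          name = c("N", "CA", "CB", "C", "O"),
          element = c("N", "C", "C", "C", "O"),
          mass = c(m[["NH"]], m[["CH"]], m[["CH3"]], m[["C"]], m[["O"]]),
          resname = resname, resid = i,
          backbone = c(TRUE, TRUE, FALSE, TRUE, FALSE))
        res_bonds <- rbind(c(base + 1L, base + 2L),  # N-CA
                           c(base + 2L, base + 3L),  # CA-CB
                           c(base + 2L, base + 4L),  # CA-C
                           c(base + 4L, base + 5L))  # C=O
      }
      atoms <- rbind(atoms, res)
      bonds <- rbind(bonds, c(prev_c, base + 1L), res_bonds)
      prev_c <- base + 4L
    }
    # N,N-dimethylamide cap: -N(CH3)2
    base <- nrow(atoms)
    atoms <- rbind(atoms, data.frame(
      name = c("NT", "CT1", "CT2"), element = c("N", "C", "C"),
      mass = c(m[["N"]], m[["CH3"]], m[["CH3"]]),
      resname = "NME", resid = n + 1L, backbone = FALSE))
    bonds <- rbind(bonds, c(prev_c, base + 1L), c(base + 1L, base + 2L),
                   c(base + 1L, base + 3L))
    bb <- which(atoms$backbone)
    ends <- c(min(bb), max(bb))
  } else {  # generic bead chain
    atoms <- data.frame(
      name = paste0("B", seq_len(n)), element = "C", mass = m[["CH2"]],
      resname = "BEA", resid = seq_len(n), backbone = TRUE)
    bonds <- if (n > 1) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
             else matrix(integer(0), ncol = 2)
    ends <- c(1L, n)
  }
  rownames(atoms) <- NULL
  structure(list(kind = kind, n_monomers = n, atoms = atoms,
                 bonds = bonds, ends = as.integer(ends),
                 mass = sum(atoms$mass)),
            class = "polymer_template")
}

#' @export
print.polymer_template <- function(x, ...) {
  cat(sprintf("polymer_template: %s %d-mer, %d heavy atoms, MW %.2f g/mol\n",
              x$kind, x$n_monomers, nrow(x$atoms), x$mass))
  invisible(x)
}

#' Number of heavy atoms in a template
#' @param template a [build_polymer_topology()] result.
#' @return Integer heavy-atom count.
#' @export
template_n_heavy <- function(template) nrow(template$atoms)

#' Assemble a MolecularSystem from building blocks
#'
#' Builds the atom table of a system from optional protein atoms, `n_chains`
#' replicas of a polymer chain template, and water oxygens (each water is
#' represented by its oxygen carrying the full 18.015 g/mol). Used by the
#' synthetic generators and for composition bookkeeping (e.g. the mass
#' concentration of a polymer solution of known box size).
#'
#' @param protein_atoms optional data.frame of protein atoms in
#'   [molecular_system()] format (id column is renumbered).
#' @param template a [build_polymer_topology()] chain template.
#' @param n_chains number of polymer chains.
#' @param n_water number of waters.
#' @param box length-3 box edges (Angstrom).
#' @param protein_model optional idealized protein descriptor (see
#'   [molecular_system()]).
#' @return A [molecular_system()].
#' @export
assemble_system <- function(protein_atoms = NULL, template = NULL,
                            n_chains = 0, n_water = 0, box,
                            protein_model = NULL) {
  rows <- list(); chains <- list(); id0 <- 0L
  if (!is.null(protein_atoms)) {
    pa <- protein_atoms
    pa$id <- id0 + seq_len(nrow(pa))
    rows[[length(rows) + 1L]] <- pa
    id0 <- id0 + nrow(pa)
  }
  if (n_chains > 0) {
    stopifnot(!is.null(template))
    npa <- nrow(template$atoms)
    for (k in seq_len(n_chains)) {
      ids <- id0 + seq_len(npa)
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids, element = template$atoms$element,
        mass = template$atoms$mass, resname = template$atoms$resname,
        resid = template$atoms$resid, chain = paste0("P", k),
        role = "polymer")
      chains[[k]] <- list(atom_ids = ids, kind = template$kind,
                          n_monomers = template$n_monomers,
                          bonds = matrix(ids[template$bonds], ncol = 2),
                          ends = ids[template$ends], mass = template$mass)
      id0 <- id0 + npa
    }
  }
  if (n_water > 0) {
    ids <- id0 + seq_len(n_water)
    rows[[length(rows) + 1L]] <- data.frame(
      id = ids, element = "O", mass = 18.015,  # whole water on its oxygen
      resname = "HOH", resid = seq_len(n_water), chain = "W", role = "water")
    id0 <- id0 + n_water
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  molecular_system(atoms, chains, box, protein_model = protein_model)
}
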