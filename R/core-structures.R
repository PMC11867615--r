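#' @importFrom stats cor rnorm runif sd prcomp setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Chain roles recognised throughout the package.  CRBN is the substrate
# receptor, BRD4 the target protein, E2/UB the conjugating enzyme and
# ubiquitin, PROTAC the degrader atoms.
.ROLES <- c("CRBN", "BRD4", "DDB1", "CUL4A", "RBX1", "NEDD8",
            "E2", "UB", "PROTAC", "OTHER")

.ATOM_COLS <- c("chain_id", "residue_index", "residue_name", "atom_name",
                "element", "x", "y", "z", "charge", "lj_sigma", "lj_epsilon")

#' Build an atom table
#'
#' Constructs the atom `data.frame` used by [molecular_system()] and
#' [trajectory()]. One row per atom; coordinates in Angstrom. Partial charges
#' (elementary units) and Lennard-Jones parameters (`lj_sigma` in Angstrom,
#' `lj_epsilon` in kcal/mol) default to zero, i.e. no nonbonded interaction.
#'
#' @param chain_id single-character chain labels.
#' @param residue_index 1-based integer residue numbers, kept verbatim from
#'   the source numbering (never renumbered).
#' @param residue_name 3-letter residue codes.
#' @param atom_name PDB atom labels (e.g. `"NZ"`, `"CA"`, `"O"`).
#' @param x,y,z coordinates in Angstrom.
#' @param element element symbols; derived from the first letter of
#'   `atom_name` when missing.
#' @param charge,lj_sigma,lj_epsilon optional nonbonded parameters.
#' @return a `data.frame` with one row per atom.
#' @export
atom_table <- function(chain_id, residue_index, residue_name, atom_name,
                       x, y, z, element = NULL,
                       charge = 0, lj_sigma = 0, lj_epsilon = 0) {
  n <- max(lengths(list(chain_id, residue_index, residue_name, atom_name,
                        x, y, z)))
  if (is.null(element)) element <- substr(toupper(atom_name), 1, 1)
  df <- data.frame(
    chain_id = rep_len(as.character(chain_id), n),
    residue_index = rep_len(as.integer(residue_index), n),
    residue_name = rep_len(as.character(residue_name), n),
    atom_name = rep_len(as.character(atom_name), n),
    element = rep_len(as.character(element), n),
    x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
    z = rep_len(as.numeric(z), n),
    charge = rep_len(as.numeric(charge), n),
    lj_sigma = rep_len(as.numeric(lj_sigma), n),
    lj_epsilon = rep_len(as.numeric(lj_epsilon), n),
    stringsAsFactors = FALSE
  )
  df
}

.validate_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  miss <- setdiff(.ATOM_COLS, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("atom positions must be finite")
  key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain_id, residue_index, atom_name) in atom table: ",
         key[duplicated(key)][1])
  invisible(atoms)
}

#' Create a molecular system
#'
#' A `molecular_system` bundles an atom table with a role map assigning each
#' chain one of the degradation-machinery roles (`CRBN`, `BRD4`, `DDB1`,
#' `CUL4A`, `RBX1`, `NEDD8`, `E2`, `UB`, `PROTAC`, `OTHER`). Chains without an
#' explicit role default to `OTHER`. A chain carrying role `UB` must contain a
#' glycine residue: its highest-numbered Gly is taken as the C-terminal
#' glycine (the Gly75 analogue) whose backbone C/O atoms enter every
#' ubiquitination-distance criterion.
#'
#' @param atoms atom table as built by [atom_table()].
#' @param roles named character vector mapping chain ids to roles.
#' @return an object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, roles = character()) {
  .validate_atoms(atoms)
  chains <- unique(atoms$chain_id)
  roles <- vapply(roles, as.character, character(1))
  bad <- setdiff(roles, .ROLES)
  if (length(bad) > 0)
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         " (must be one of ", paste(.ROLES, collapse = ", "), ")")
  unknown <- setdiff(names(roles), chains)
  if (length(unknown) > 0)
    stop("role map names chains absent from the atom table: ",
         paste(unknown, collapse = ", "))
  full <- setNames(rep("OTHER", length(chains)), chains)
  full[names(roles)] <- roles
  ub_chains <- names(full)[full == "UB"]
  for (ch in ub_chains) {
    sel <- atoms$chain_id == ch & atoms$residue_name == "GLY"
    if (!any(sel))
      stop("chain ", ch, " has role UB but no Gly residue ",
           "(a C-terminal Gly analogue is required)")
  }
  structure(list(atoms = atoms, roles = full), class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular_system:", nrow(x$atoms), "atoms,",
      length(x$roles), "chains\n")
  for (ch in names(x$roles))
    cat(sprintf("  chain %s [%s]: %d atoms\n", ch, x$roles[[ch]],
                sum(x$atoms$chain_id == ch)))
  invisible(x)
}

#' Create a trajectory
#'
#' Frames-by-atoms-by-3 coordinate array over a fixed atom table, with a
#' constant sampling interval `dt` in picoseconds.
#'
#' @param frames numeric array of dimension `F x N x 3` (Angstrom), or an
#'   `N x 3` matrix for a single frame.
#' @param atoms atom table of the `N` atoms (shared by all frames).
#' @param dt sampling interval in ps (> 0).
#' @param roles optional chain role map, as in [molecular_system()].
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(frames, atoms, dt = 1, roles = character()) {
  .validate_atoms(atoms)
  if (is.matrix(frames)) frames <- array(frames, dim = c(1, dim(frames)))
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 3)
  if (dim(frames)[2] != nrow(atoms))
    stop("frame atom count (", dim(frames)[2],
         ") does not match atom table (", nrow(atoms), ")")
  if (dim(frames)[1] < 1) stop("trajectory needs at least one frame")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be a positive ps interval")
  sys <- molecular_system(atoms, roles)
  structure(list(frames = frames, atoms = atoms, roles = sys$roles, dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$frames)[1], "frames x", dim(x$frames)[2],
      "atoms, dt =", x$dt, "ps\n")
  invisible(x)
}

#' Number of frames
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

# Coordinates of one frame as an N x 3 matrix.
frame_coords <- function(traj, i) {
  m <- traj$frames[i, , , drop = FALSE]
  dim(m) <- dim(traj$frames)[2:3]
  m
}

# System snapshot of frame i (keeps roles and parameters).
frame_system <- function(traj, i) {
  atoms <- traj$atoms
  co <- frame_coords(traj, i)
  atoms$x <- co[, 1]; atoms$y <- co[, 2]; atoms$z <- co[, 3]
  molecular_system(atoms, traj$roles)
}

coords_matrix <- function(x) {
  if (inherits(x, "molecular_system")) x <- x$atoms
  cbind(x$x, x$y, x$z)
}

#' Atom keys
#'
#' A single string `"chain:residue:atom"` identifying one atom, used by the
#' series extractors, e.g. `"B:99:NZ"` for the NZ of Lys99 on chain B.
#'
#' @param chain_id chain label.
#' @param residue_index residue number.
#' @param atom_name atom label.
#' @return character key.
#' @export
atom_key <- function(chain_id, residue_index, atom_name) {
  paste(chain_id, residue_index, atom_name, sep = ":")
}

# Resolve a key (or vector of keys) to row indices in an atom table.
atom_index <- function(atoms, key) {
  all_keys <- atom_key(atoms$chain_id, atoms$residue_index, atoms$atom_name)
  idx <- match(key, all_keys)
  if (anyNA(idx))
    stop("atom key(s) not found: ", paste(key[is.na(idx)], collapse = ", "))
  idx
}

#' Select atoms by role/chain, residue range and atom name
#'
#' Order-preserving filter over a system's atom table. `chain` may be a
#' chain id or a role name (e.g. `"UB"`); a role selects every chain mapped
#' to it. An empty selection is allowed and returns a zero-row table.
#'
#' @param system a [molecular_system()] or [trajectory()].
#' @param chain chain id or role name; `NULL` selects all chains.
#' @param residue_range length-2 integer vector `c(lo, hi)` (inclusive), or
#'   a vector of explicit residue indices; `NULL` for all.
#' @param atom_names character vector of atom labels to keep; `NULL` for all.
#' @return the filtered atom `data.frame`.
#' @export
select_atoms <- function(system, chain = NULL, residue_range = NULL,
                         atom_names = NULL) {
  atoms <- system$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) {
    if (chain %in% system$roles) {            # role selection
      chains <- names(system$roles)[system$roles == chain]
    } else if (chain %in% names(system$roles)) {
      chains <- chain
    } else if (chain %in% .ROLES) {
      chains <- character()                   # known role, no such chain
    } else {
      stop("unknown chain or role: ", chain)
    }
    keep <- keep & atoms$chain_id %in% chains
  }
  if (!is.null(residue_range)) {
    if (length(residue_range) == 2)
      keep <- keep & atoms$residue_index >= residue_range[1] &
        atoms$residue_index <= residue_range[2]
    else
      keep <- keep & atoms$residue_index %in% residue_range
  }
  if (!is.null(atom_names))
    keep <- keep & atoms$atom_name %in% atom_names
  atoms[keep, , drop = FALSE]
}

#' Subset a system to whole chains by role
#'
#' @param system a [molecular_system()].
#' @param roles character vector of roles to keep.
#' @return a [molecular_system()] containing only chains with those roles.
#' @export
subset_system <- function(system, roles) {
  keep_chains <- names(system$roles)[system$roles %in% roles]
  if (length(keep_chains) == 0) stop("no chain carries role(s): ",
                                     paste(roles, collapse = ", "))
  atoms <- system$atoms[system$atoms$chain_id %in% keep_chains, , drop = FALSE]
  molecular_system(atoms, system$roles[keep_chains])
}

#' Locate the C-terminal glycine of ubiquitin
#'
#' Returns keys of the backbone C and O atoms of the highest-numbered Gly on
#' the chain with role `UB` (the Gly75 analogue that reacts with the target
#' lysine during ubiquitination).
#'
#' @param system a [molecular_system()] or [trajectory()].
#' @return list with `chain`, `residue`, `c_key`, `o_key`.
#' @export
ub_cterm_gly <- function(system) {
  ub <- names(system$roles)[system$roles == "UB"]
  if (length(ub) == 0) stop("system has no chain with role UB")
  gly <- select_atoms(system, chain = "UB")
  gly <- gly[gly$residue_name == "GLY", , drop = FALSE]
  if (nrow(gly) == 0) stop("UB chain has no Gly residue")
  res <- max(gly$residue_index)
  ch <- gly$chain_id[gly$residue_index == res][1]
  list(chain = ch, residue = res,
       c_key = atom_key(ch, res, "C"),
       o_key = atom_key(ch, res, "O"))
}
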