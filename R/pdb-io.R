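# PDB v3.3 fixed-column reading/writing, layered on bio3d with strict
# pre-validation: bio3d tolerates malformed records silently, but downstream
# geometry must fail loudly instead of guessing.

.pdb_validate_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("PDB format error at line ", i,
           ": ATOM/HETATM record shorter than 54 columns")
    resno <- substr(ln, 23, 26)
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    vals <- suppressWarnings(as.numeric(c(resno, xyz)))
    if (anyNA(vals))
      stop("PDB format error at line ", i,
           ": non-numeric residue number or coordinate field")
    icode <- substr(ln, 27, 27)
    if (icode != " ")
      stop("PDB format error at line ", i,
           ": insertion codes are not supported (found '", icode, "')")
  }
  # per-MODEL atom-count consistency
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    model_of <- findInterval(which(is_atom), model_starts)
    counts <- table(model_of[model_of > 0])
    if (length(unique(as.integer(counts))) > 1)
      stop("PDB structural error: inconsistent atom counts across MODEL ",
           "blocks (", paste(as.integer(counts), collapse = ", "), ")")
  }
  invisible(length(model_starts))
}

#' Read a PDB file
#'
#' Parses a PDB v3.3 fixed-column file into a [molecular_system()] (or a
#' [trajectory()] when `multi_model = TRUE` and the file carries `MODEL`
#' blocks). `ATOM` and `HETATM` records are treated identically, so degrader
#' (PROTAC) atoms stored as HETATM become first-class atoms; assign them a
#' role via `roles`. For alternate locations only the first altloc is kept;
#' insertion codes are rejected with an error.
#'
#' @param path path to the PDB file.
#' @param multi_model if `TRUE`, read `MODEL` blocks as trajectory frames.
#' @param roles named character role map passed to the constructor.
#' @param dt frame interval in ps for multi-model input.
#' @return a [molecular_system()] or [trajectory()].
#' @export
read_pdb <- function(path, multi_model = FALSE, roles = character(), dt = 1) {
  lines <- readLines(path, warn = FALSE)
  n_models <- .pdb_validate_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = multi_model, verbose = FALSE)
  at <- pdb$atom
  # keep first altloc per atom identity
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    at_keep <- !duplicated(key)
  } else {
    at_keep <- rep(TRUE, nrow(at))
  }
  at <- at[at_keep, , drop = FALSE]
  elesy <- trimws(at$elesy)
  no_el <- is.na(elesy) | elesy == ""
  elesy[no_el] <- substr(gsub("[0-9]", "", toupper(at$elety[no_el])), 1, 1)
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- atom_table(chain_id = chain, residue_index = at$resno,
                      residue_name = trimws(at$resid),
                      atom_name = trimws(at$elety),
                      x = at$x, y = at$y, z = at$z, element = elesy)
  if (multi_model && n_models >= 1) {
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    f <- nrow(xyz)
    n <- ncol(xyz) / 3
    frames <- array(NA_real_, dim = c(f, n, 3))
    for (i in seq_len(f))
      frames[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    frames <- frames[, which(at_keep), , drop = FALSE]
    return(trajectory(frames, atoms, dt = dt, roles = roles))
  }
  molecular_system(atoms, roles)
}

#' Write a PDB file
#'
#' Writes a [molecular_system()] as fixed-column `ATOM` records, or a
#' [trajectory()] as `MODEL`/`ENDMDL` blocks. Coordinates are printed in the
#' standard 8.3 field, so `read_pdb(write_pdb(x))` reproduces coordinates to
#' 1e-3 Angstrom. Nonbonded parameters (charge, LJ) are not representable in
#' PDB and are not written.
#'
#' @param x a [molecular_system()] or [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "trajectory")) {
    atoms <- x$atoms
    f <- n_frames(x)
    xyz <- matrix(NA_real_, nrow = f, ncol = nrow(atoms) * 3)
    for (i in seq_len(f))
      xyz[i, ] <- as.vector(t(frame_coords(x, i)))
  } else if (inherits(x, "molecular_system")) {
    atoms <- x$atoms
    xyz <- matrix(as.vector(t(coords_matrix(atoms))), nrow = 1)
  } else stop("x must be a molecular_system or trajectory")
  if (nrow(atoms) == 0) {
    writeLines("END", path)
    return(invisible(path))
  }
  if (any(atoms$residue_index > 9999) || any(atoms$residue_index < -999))
    stop("residue_index outside the 4-digit PDB field (max 9999)")
  if (any(abs(xyz) >= 1e4))
    stop("coordinate outside the 8.3 PDB field")
  if (!all(is.finite(xyz))) stop("all positions must be finite")
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = atoms$residue_index,
                   resid = atoms$residue_name,
                   eleno = seq_len(nrow(atoms)),
                   elety = atoms$atom_name,
                   chain = atoms$chain_id,
                   elesy = atoms$element)
  invisible(path)
}
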