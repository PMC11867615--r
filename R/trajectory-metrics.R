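# Per-frame geometric observables on trajectories: pseudo-dihedral and
# distance series, the two-distance ubiquitination-competence criteria, the
# fraction-of-frames statistic, and the windowed circular histogram shift.

#' IUPAC-signed torsion angle of four points
#'
#' `phi = atan2((n1 x n2) . b2_hat, n1 . n2)` with `b_i` the bond vectors and
#' `n_i` the plane normals; degrees in `[-180, 180)` (a trans arrangement
#' maps to -180). Used both for chemical dihedrals and for pseudo-dihedrals
#' over non-bonded landmark atoms that summarise inter-domain motion.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors in Angstrom.
#' @return torsion in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  .dihedral_vec(matrix(b1, 1), matrix(b2, 1), matrix(b3, 1))
}

# vectorised torsion over rows of bond-vector matrices
.dihedral_vec <- function(b1, b2, b3) {
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  if (any(nb2 < 1e-12) || any(rowSums(n1^2) < 1e-24) ||
      any(rowSums(n2^2) < 1e-24))
    stop("geometry error: degenerate (coincident or collinear) points")
  m <- cross(n1, n2)
  x <- rowSums(n1 * n2)
  y <- rowSums(m * b2) / nb2
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Pseudo-dihedral series over a trajectory
#'
#' Evaluates the torsion defined by four landmark atoms in every frame. The
#' canonical choice links the PROTAC linker to hinge residues across the
#' machinery (e.g. linker N3, two hinge C-alphas, and a distal C-alpha) to
#' capture the essential swinging motion of the complex.
#'
#' @param traj a [trajectory()].
#' @param selectors character vector of 4 atom keys (see [atom_key()]).
#' @return an [angle_series()] of length `n_frames(traj)`.
#' @export
pseudo_dihedral_series <- function(traj, selectors) {
  stopifnot(length(selectors) == 4)
  idx <- atom_index(traj$atoms, selectors)
  P <- lapply(1:4, function(k) traj$frames[, idx[k], , drop = FALSE])
  P <- lapply(P, function(a) { dim(a) <- dim(traj$frames)[c(1, 3)]; a })
  vals <- .dihedral_vec(P[[2]] - P[[1]], P[[3]] - P[[2]], P[[4]] - P[[3]])
  angle_series(vals, dt = traj$dt, label = paste(selectors, collapse = "-"))
}

#' Inter-atom distance series over a trajectory
#'
#' @param traj a [trajectory()].
#' @param atom_a,atom_b atom keys (see [atom_key()]).
#' @return a [dist_series()] of per-frame Euclidean distances.
#' @export
distance_series <- function(traj, atom_a, atom_b) {
  ia <- atom_index(traj$atoms, atom_a)
  ib <- atom_index(traj$atoms, atom_b)
  d <- sqrt(rowSums((traj$frames[, ia, ] - traj$frames[, ib, ])^2))
  dist_series(d, dt = traj$dt, atom_pair = c(atom_a, atom_b))
}

#' Ubiquitination-competence configuration
#'
#' The geometric thresholds for isopeptide-bond chemistry: target Lys NZ
#' within `lys_gly_max` of ubiquitin's C-terminal Gly C (strictly less
#' than), an E2 Asp carboxylate O within `asp_gly_max` of the same Gly's O
#' (strictly less than), and the assembly-stage retention threshold
#' `retain_max` on Lys NZ to Gly O (inclusive).
#'
#' @param lys_gly_max Lys(NZ)-Gly(C) criterion in Angstrom (default 10).
#' @param asp_gly_max Asp(O)-Gly(O) criterion in Angstrom (default 6).
#' @param retain_max retention threshold in Angstrom (default 16).
#' @return list of class `competence_config`.
#' @export
competence_config <- function(lys_gly_max = 10, asp_gly_max = 6,
                              retain_max = 16) {
  stopifnot(lys_gly_max > 0, asp_gly_max > 0, retain_max > 0)
  structure(list(lys_gly_max = lys_gly_max, asp_gly_max = asp_gly_max,
                 retain_max = retain_max),
            class = "competence_config")
}

#' Per-frame ubiquitination-competence flags
#'
#' A frame is competent when, for at least one candidate lysine, the Lys NZ
#' to Gly C distance is under `lys_gly_max` AND the closest E2 Asp
#' carboxylate oxygen (min over OD1/OD2) to the Gly O is under `asp_gly_max`
#' (both strict, as the criteria are stated). Flags for multiple candidate
#' lysines are OR-ed: any one lysine reaching the catalytic pocket suffices.
#'
#' @param traj a [trajectory()] whose atom table carries roles BRD4, E2, UB.
#' @param lys_residues integer vector of candidate Lys residue indices on the
#'   BRD4 chain; `NULL` means every Lys with an NZ atom.
#' @param asp_residue Asp residue index on the E2 chain.
#' @param config a [competence_config()].
#' @return logical vector of length `n_frames(traj)`.
#' @export
competence_flags <- function(traj, lys_residues = NULL, asp_residue,
                             config = competence_config()) {
  gly <- ub_cterm_gly(traj)
  gc_i <- atom_index(traj$atoms, gly$c_key)
  go_i <- atom_index(traj$atoms, gly$o_key)
  nz <- select_atoms(traj, chain = "BRD4", atom_names = "NZ")
  nz <- nz[nz$residue_name == "LYS", , drop = FALSE]
  if (!is.null(lys_residues))
    nz <- nz[nz$residue_index %in% lys_residues, , drop = FALSE]
  if (nrow(nz) == 0) stop("criteria error: no candidate Lys NZ atoms")
  asp_o <- select_atoms(traj, chain = "E2", residue_range = asp_residue,
                        atom_names = c("OD1", "OD2"))
  if (nrow(asp_o) == 0)
    stop("criteria error: Asp ", asp_residue, " has no carboxylate O atoms")
  nz_idx <- atom_index(traj$atoms,
                       atom_key(nz$chain_id, nz$residue_index, nz$atom_name))
  asp_idx <- atom_index(traj$atoms, atom_key(asp_o$chain_id,
                                             asp_o$residue_index,
                                             asp_o$atom_name))
  f <- n_frames(traj)
  d_lys <- sapply(nz_idx, function(i)
    sqrt(rowSums((traj$frames[, i, , drop = FALSE] -
                  traj$frames[, gc_i, , drop = FALSE])^2, dims = 1)))
  d_asp <- sapply(asp_idx, function(i)
    sqrt(rowSums((traj$frames[, i, , drop = FALSE] -
                  traj$frames[, go_i, , drop = FALSE])^2, dims = 1)))
  d_lys <- matrix(d_lys, nrow = f)
  d_asp <- matrix(d_asp, nrow = f)
  lys_ok <- apply(d_lys < config$lys_gly_max, 1, any)
  asp_ok <- apply(d_asp, 1, min) < config$asp_gly_max
  lys_ok & asp_ok
}

#' Fraction of competent frames
#'
#' The probability-of-ubiquitination statistic: the mean of the per-frame
#' competence flags, optionally from `start_frame` onward (the averaging
#' window defaults to the full series).
#'
#' @param flags logical vector from [competence_flags()].
#' @param start_frame first frame included (default 1).
#' @return fraction in `[0, 1]`.
#' @export
competence_fraction <- function(flags, start_frame = 1) {
  if (length(flags) == 0 || start_frame > length(flags))
    stop("empty flag vector")
  mean(flags[seq(start_frame, length(flags))])
}

#' Circular shift between the first and last window of an angle series
#'
#' The shortest signed arc between the circular mean of the first `window`
#' frames and that of the last `window` frames, in degrees in `[-180, 180)`.
#' Quantifies the population shift of a pseudo-dihedral histogram between the
#' start and the end of a run (e.g. first vs last 100 ns).
#'
#' @param series an [angle_series()].
#' @param window window length in frames (`2*window <= length`).
#' @return signed shift in degrees.
#' @export
window_shift <- function(series, window) {
  x <- .series_values(series)
  n <- length(x)
  if (2 * window > n) stop("window too large: need 2*window <= length")
  m1 <- circ_mean(x[seq_len(window)])
  m2 <- circ_mean(x[seq(n - window + 1, n)])
  circ_dev(m2, m1)
}
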