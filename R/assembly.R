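# Rigid-body machinery assembly: Kabsch superposition, clash screening,
# interface-gap scaffold classification, and the Lys-Gly retention filter.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between paired atom sets, mapping `mobile` onto `reference` as
#' `x -> R x + t`. The SVD determinant is corrected so a reflection is never
#' returned.
#'
#' @param mobile,reference `n x 3` coordinate matrices or atom tables with
#'   matching row order; `n >= 3`, not all collinear.
#' @return list of class `rigid_transform` with elements `rotation` (3x3),
#'   `translation` (length 3) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, reference) {
  A <- if (is.data.frame(mobile)) coords_matrix(mobile) else as.matrix(mobile)
  B <- if (is.data.frame(reference)) coords_matrix(reference) else as.matrix(reference)
  if (!all(dim(A) == dim(B))) stop("alignment error: atom sets differ in size")
  n <- nrow(A)
  if (n < 3) stop("alignment error: need at least 3 paired atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(A0, B0))          # 3x3 covariance
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("alignment error: degenerate (collinear) geometry")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(cb - R %*% ca)
  fitted <- sweep(A %*% t(R), 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform` (rmsd carried over unchanged).
#' @export
invert_transform <- function(transform) {
  R <- t(transform$rotation)
  structure(list(rotation = R,
                 translation = as.numeric(-R %*% transform$translation),
                 rmsd = transform$rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to (a subset of) a system
#'
#' Maps the coordinates of the listed chains through `x -> R x + t`; other
#' chains are untouched.
#'
#' @param system a [molecular_system()].
#' @param transform a `rigid_transform` from [superpose()].
#' @param chains chain ids to move; `NULL` moves every chain.
#' @return the transformed [molecular_system()].
#' @export
apply_transform <- function(system, transform, chains = NULL) {
  atoms <- system$atoms
  if (is.null(chains)) chains <- names(system$roles)
  missing <- setdiff(chains, names(system$roles))
  if (length(missing) > 0)
    stop("no such chain(s): ", paste(missing, collapse = ", "))
  sel <- atoms$chain_id %in% chains
  if (any(sel)) {
    co <- cbind(atoms$x[sel], atoms$y[sel], atoms$z[sel])
    co <- sweep(co %*% t(transform$rotation), 2, transform$translation, "+")
    atoms$x[sel] <- co[, 1]; atoms$y[sel] <- co[, 2]; atoms$z[sel] <- co[, 3]
  }
  molecular_system(atoms, system$roles)
}

#' Count inter-chain steric clashes
#'
#' Counts heavy-atom pairs closer than `cutoff` (default 2.0 Angstrom, below
#' any physical heavy-atom contact). Pairs are counted once; by default only
#' pairs from different chains count.
#'
#' A cell-list spatial grid keeps the scan linear in atom count for the small
#' cutoff used here.
#'
#' @param system a [molecular_system()].
#' @param cutoff clash distance in Angstrom (> 0).
#' @param inter_chain_only count only pairs on different chains.
#' @return integer clash count.
#' @export
detect_clashes <- function(system, cutoff = 2.0, inter_chain_only = TRUE) {
  stopifnot(cutoff > 0)
  atoms <- system$atoms
  n <- nrow(atoms)
  if (n < 2) return(0L)
  co <- coords_matrix(atoms)
  chain <- atoms$chain_id
  # cell list: bin atoms into cubes of edge `cutoff`; a clashing pair can
  # only sit in the same or an adjacent cell
  cell <- floor(sweep(co, 2, apply(co, 2, min)) / cutoff)
  cid <- paste(cell[, 1], cell[, 2], cell[, 3])
  by_cell <- split(seq_len(n), cid)
  cells <- do.call(rbind, lapply(strsplit(names(by_cell), " "), as.numeric))
  count <- 0L
  cut2 <- cutoff^2
  for (k in seq_along(by_cell)) {
    # neighbours with lexicographically >= cell index to count each pair once
    neigh_ids <- which(abs(cells[, 1] - cells[k, 1]) <= 1 &
                       abs(cells[, 2] - cells[k, 2]) <= 1 &
                       abs(cells[, 3] - cells[k, 3]) <= 1 & seq_along(by_cell) >= k)
    i_idx <- by_cell[[k]]
    for (m in neigh_ids) {
      j_idx <- by_cell[[m]]
      dx <- outer(co[i_idx, 1], co[j_idx, 1], "-")
      dy <- outer(co[i_idx, 2], co[j_idx, 2], "-")
      dz <- outer(co[i_idx, 3], co[j_idx, 3], "-")
      d2 <- dx * dx + dy * dy + dz * dz
      hit <- d2 < cut2
      if (m == k) hit[!upper.tri(hit)] <- FALSE
      else if (any(i_idx %in% j_idx)) stop("internal: overlapping cells")
      if (inter_chain_only)
        hit <- hit & outer(chain[i_idx], chain[j_idx], "!=")
      count <- count + sum(hit)
    }
  }
  as.integer(count)
}

#' CRBN-to-E2 interface gap
#'
#' Fits a total-least-squares plane through the E2 interface atoms and
#' returns the minimum signed point-plane distance over the CRBN probe
#' atoms. The sign is positive on the side of the plane opposite the E2 body
#' centroid, so a negative gap means CRBN penetrates into the E2 side
#' (overlap).
#'
#' @param system a [molecular_system()] (used for the E2 body centroid).
#' @param e2_interface atom table (>= 3 non-collinear atoms) defining the
#'   interface plane.
#' @param crbn_probe atom table of CRBN probe atoms.
#' @return signed gap distance in Angstrom.
#' @export
interface_gap <- function(system, e2_interface, crbn_probe) {
  P <- coords_matrix(e2_interface)
  if (nrow(P) < 3) stop("geometry error: need >= 3 interface atoms")
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("geometry error: collinear interface atoms")
  normal <- sv$v[, 3]
  e2_atoms <- select_atoms(system, chain = "E2")
  body_ctr <- if (nrow(e2_atoms) > 0) colMeans(coords_matrix(e2_atoms)) else ctr
  # orient the normal away from the E2 body
  if (sum((body_ctr - ctr) * normal) > 0) normal <- -normal
  Q <- coords_matrix(crbn_probe)
  d <- as.numeric(sweep(Q, 2, ctr) %*% normal)
  min(d)
}

#' Classify a ligase scaffold by interface gap
#'
#' Cluster `A` is ring-forming (gap below 10 Angstrom, no clash), `B` is
#' ring-open (gap of 10 Angstrom or more), and `C` is clashing/overlapping
#' (negative gap or any clash) and is discarded from assembly.
#'
#' @param gap signed CRBN-to-E2 gap in Angstrom from [interface_gap()].
#' @param clash_count inter-chain clash count from [detect_clashes()].
#' @return one of `"A"`, `"B"`, `"C"`.
#' @export
classify_scaffold <- function(gap, clash_count = 0L) {
  stopifnot(length(gap) == 1, length(clash_count) == 1)
  if (gap < 0 || clash_count > 0) return("C")
  if (gap < 10) "A" else "B"
}

#' Assemble a ternary complex onto a ligase scaffold
#'
#' Superposes the ternary complex's CRBN C-alpha set onto the scaffold's CRBN
#' (the common component), applies the transform to the whole ternary, and
#' merges the scaffold chains with the transformed target (BRD4) and PROTAC
#' chains. The scaffold's CRBN copy is kept, so CRBN appears exactly once.
#'
#' @param ternary [molecular_system()] with roles CRBN + BRD4 (+ PROTAC).
#' @param scaffold [molecular_system()] with role CRBN among its chains.
#' @return the merged [molecular_system()].
#' @export
assemble <- function(ternary, scaffold) {
  t_ca <- select_atoms(ternary, chain = "CRBN", atom_names = "CA")
  s_ca <- select_atoms(scaffold, chain = "CRBN", atom_names = "CA")
  if (nrow(t_ca) == 0 || nrow(s_ca) == 0)
    stop("alignment error: both systems need a CRBN chain with CA atoms")
  t_ca <- t_ca[order(t_ca$residue_index), , drop = FALSE]
  s_ca <- s_ca[order(s_ca$residue_index), , drop = FALSE]
  if (nrow(t_ca) != nrow(s_ca) ||
      !all(t_ca$residue_index == s_ca$residue_index))
    stop("alignment error: CRBN CA residue sets do not match")
  tr <- superpose(t_ca, s_ca)
  moved <- apply_transform(ternary, tr)
  crbn_chains <- names(moved$roles)[moved$roles == "CRBN"]
  keep <- setdiff(names(moved$roles), crbn_chains)
  clash_names <- intersect(keep, names(scaffold$roles))
  if (length(clash_names) > 0)
    stop("chain id collision between ternary and scaffold: ",
         paste(clash_names, collapse = ", "))
  atoms <- rbind(scaffold$atoms,
                 moved$atoms[moved$atoms$chain_id %in% keep, , drop = FALSE])
  molecular_system(atoms, c(scaffold$roles, moved$roles[keep]))
}

#' Minimum surface-Lys NZ to ubiquitin Gly distance
#'
#' Scans every lysine NZ on the target (role `BRD4`) against one atom of the
#' C-terminal Gly of ubiquitin and returns the argmin residue with its
#' distance. The retention filter measures against the Gly backbone O
#' (default); the ubiquitination-competence criterion uses the Gly C, so the
#' atom is a parameter.
#'
#' @param system a [molecular_system()] with roles BRD4 and UB.
#' @param gly_atom `"O"` (retention stage) or `"C"` (competence stage).
#' @param lys_residues optional residue indices restricting the candidate
#'   surface lysines (default: all Lys on BRD4).
#' @return list with `residue` (argmin Lys index) and `distance` (Angstrom).
#' @export
min_lys_gly_distance <- function(system, gly_atom = "O", lys_residues = NULL) {
  gly <- ub_cterm_gly(system)
  g_idx <- atom_index(system$atoms,
                      atom_key(gly$chain, gly$residue, gly_atom))
  g <- as.numeric(system$atoms[g_idx, c("x", "y", "z")])
  nz <- select_atoms(system, chain = "BRD4", atom_names = "NZ")
  nz <- nz[nz$residue_name == "LYS", , drop = FALSE]
  if (!is.null(lys_residues))
    nz <- nz[nz$residue_index %in% lys_residues, , drop = FALSE]
  if (nrow(nz) == 0)
    stop("criteria error: no surface Lys NZ atoms on the BRD4 chain")
  d <- sqrt(rowSums(sweep(coords_matrix(nz), 2, g)^2))
  i <- which.min(d)
  list(residue = nz$residue_index[i], distance = d[i])
}

#' Build the ternary x scaffold assembly grid
#'
#' Enumerates every pairing of ternary-conformation ids with scaffold ids,
#' the combinatorial space from which machinery models are built and then
#' filtered.
#'
#' @param ternary_ids character vector of ternary-conformation labels.
#' @param scaffold_ids character vector of scaffold labels (e.g. A1..B4).
#' @return data.frame with columns `ternary_id`, `scaffold_id`.
#' @export
assembly_grid <- function(ternary_ids, scaffold_ids) {
  g <- expand.grid(scaffold_id = scaffold_ids, ternary_id = ternary_ids,
                   stringsAsFactors = FALSE)
  g <- g[, c("ternary_id", "scaffold_id")]
  rownames(g) <- NULL
  g
}

#' Retention filter over assembly records
#'
#' Keeps assemblies with no inter-chain clash and a minimum Lys-Gly distance
#' at or under `retain_max` (default 16 Angstrom; the boundary is inclusive,
#' reading "less than or close to" permissively). Order is preserved.
#'
#' @param records data.frame with columns `clash_count` and `min_lys_gly`
#'   (and typically `ternary_id`, `scaffold_id`, `cluster`,
#'   `min_lys_residue`).
#' @param retain_max retention threshold in Angstrom.
#' @return the retained rows, with a logical `retained` column added to
#'   reflect the decision.
#' @export
filter_assemblies <- function(records, retain_max = 16.0) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    records$retained <- logical(0)
    return(records)
  }
  keep <- records$clash_count == 0 & records$min_lys_gly <= retain_max
  out <- records[keep, , drop = FALSE]
  out$retained <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
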