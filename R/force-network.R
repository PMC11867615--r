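# Pairwise nonbonded residue forces (Lennard-Jones + cutoff Coulomb), the
# thresholded interaction network with shortest-path extraction, and the
# interaction-energy difference over the same toy energy model.

.KE <- 332.0637        # Coulomb constant, kcal A / (mol e^2)
.KCAL_PER_A_TO_PN <- 69.4786   # 1 kcal/(mol A) in pN

# Vectorised scalar radial force -dU/dr in kcal/(mol A), for
# U = 4 eps [ (sig/r)^12 - (sig/r)^6 ] + ke q1 q2 / r, zero beyond cutoff.
# Negative = attractive.
.pair_force_kcal <- function(r, qq, sigma, epsilon, cutoff) {
  out <- numeric(length(r))
  if (any(r <= 0)) stop("singularity error: zero inter-atom distance")
  inside <- r <= cutoff
  if (any(inside)) {
    ri <- r[inside]
    f <- .KE * qq[inside] / ri^2
    lj <- epsilon[inside] > 0 & sigma[inside] > 0
    if (any(lj)) {
      sr6 <- (sigma[inside][lj] / ri[lj])^6
      f[lj] <- f[lj] + 4 * epsilon[inside][lj] *
        (12 * sr6^2 - 6 * sr6) / ri[lj]
    }
    out[inside] <- f
  }
  out
}

# Vectorised pair energy U in kcal/mol, zero beyond cutoff.
.pair_energy_kcal <- function(r, qq, sigma, epsilon, cutoff) {
  out <- numeric(length(r))
  if (any(r <= 0)) stop("singularity error: zero inter-atom distance")
  inside <- r <= cutoff
  if (any(inside)) {
    ri <- r[inside]
    u <- .KE * qq[inside] / ri
    lj <- epsilon[inside] > 0 & sigma[inside] > 0
    if (any(lj)) {
      sr6 <- (sigma[inside][lj] / ri[lj])^6
      u[lj] <- u[lj] + 4 * epsilon[inside][lj] * (sr6^2 - sr6)
    }
    out[inside] <- u
  }
  out
}

#' Scalar nonbonded force between two atoms
#'
#' Radial force `-dU/dr` for the nonbonded pair potential
#' `U = 4 eps [(sigma/r)^12 - (sigma/r)^6] + ke q_i q_j / r`
#' (`ke = 332.0637 kcal A / (mol e^2)`), converted to piconewtons
#' (`1 kcal/(mol A) = 69.4786 pN`). Negative values are attractive. The force
#' is zero beyond the short-range `cutoff` (plain truncation; no Ewald
#' summation). Lorentz-Berthelot combination: `sigma = (s_i + s_j)/2`,
#' `eps = sqrt(e_i e_j)`.
#'
#' @param atom_i,atom_j one-row atom tables (or lists) with fields `x,y,z`,
#'   `charge`, `lj_sigma`, `lj_epsilon`.
#' @param cutoff short-range cutoff in Angstrom (default 10).
#' @return signed force in pN.
#' @export
pair_force <- function(atom_i, atom_j, cutoff = 10) {
  r <- sqrt(sum((c(atom_i$x, atom_i$y, atom_i$z) -
                 c(atom_j$x, atom_j$y, atom_j$z))^2))
  qq <- atom_i$charge * atom_j$charge
  sigma <- (atom_i$lj_sigma + atom_j$lj_sigma) / 2
  epsilon <- sqrt(atom_i$lj_epsilon * atom_j$lj_epsilon)
  .pair_force_kcal(r, qq, sigma, epsilon, cutoff) * .KCAL_PER_A_TO_PN
}

#' Nonbonded pair energy between two atoms
#'
#' The potential underlying [pair_force()], in kcal/mol, zero beyond the
#' cutoff.
#'
#' @inheritParams pair_force
#' @return energy in kcal/mol.
#' @export
pair_energy <- function(atom_i, atom_j, cutoff = 10) {
  r <- sqrt(sum((c(atom_i$x, atom_i$y, atom_i$z) -
                 c(atom_j$x, atom_j$y, atom_j$z))^2))
  qq <- atom_i$charge * atom_j$charge
  sigma <- (atom_i$lj_sigma + atom_j$lj_sigma) / 2
  epsilon <- sqrt(atom_i$lj_epsilon * atom_j$lj_epsilon)
  .pair_energy_kcal(r, qq, sigma, epsilon, cutoff)
}

# residue-pair force matrix of a single N x 3 coordinate snapshot
.frame_force_matrix <- function(co, atoms, res_fac, cutoff) {
  n <- nrow(co)
  dx <- outer(co[, 1], co[, 1], "-")
  dy <- outer(co[, 2], co[, 2], "-")
  dz <- outer(co[, 3], co[, 3], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  qq <- outer(atoms$charge, atoms$charge)
  sigma <- outer(atoms$lj_sigma, atoms$lj_sigma, "+") / 2
  epsilon <- sqrt(outer(atoms$lj_epsilon, atoms$lj_epsilon))
  same_res <- outer(as.integer(res_fac), as.integer(res_fac), "==")
  r[same_res] <- Inf                       # intra-residue pairs excluded
  diag(r) <- Inf
  f <- .pair_force_kcal(as.vector(r), as.vector(qq), as.vector(sigma),
                        as.vector(epsilon), cutoff)
  fm <- matrix(f, n, n)
  m <- rowsum(t(rowsum(fm, res_fac)), res_fac)   # aggregate atoms -> residues
  (m + t(m)) / 2                                  # enforce exact symmetry
}

#' Residue-pair force matrix
#'
#' Sums the scalar nonbonded atom-pair forces between every pair of residues
#' and, for a trajectory, time-averages over the production frames. By
#' default the first 10% of frames are discarded as equilibration
#' (configurable via `start_frame`). Intra-residue pairs are excluded, so the
#' diagonal is zero; the matrix is exactly symmetric.
#'
#' @param x a [molecular_system()] or [trajectory()].
#' @param start_frame first production frame; `NULL` means 10% discard for
#'   trajectories, frame 1 for a single system.
#' @param cutoff short-range cutoff in Angstrom.
#' @return object of class `force_matrix`: list with `residue_keys`
#'   (data.frame `chain`, `residue_index`) and `forces` (symmetric pN
#'   matrix).
#' @export
residue_force_matrix <- function(x, start_frame = NULL, cutoff = 10) {
  if (inherits(x, "trajectory")) {
    atoms <- x$atoms
    f <- n_frames(x)
    if (is.null(start_frame)) start_frame <- floor(f * 0.1) + 1
    frames <- seq(start_frame, f)
  } else {
    atoms <- x$atoms
    frames <- 1L
  }
  rid <- paste(atoms$chain_id, atoms$residue_index, sep = ":")
  res_fac <- factor(rid, levels = unique(rid))
  acc <- NULL
  for (i in frames) {
    co <- if (inherits(x, "trajectory")) frame_coords(x, i) else
      coords_matrix(atoms)
    m <- .frame_force_matrix(co, atoms, res_fac, cutoff)
    acc <- if (is.null(acc)) m else acc + m
  }
  m <- acc / length(frames) * .KCAL_PER_A_TO_PN
  diag(m) <- 0
  keys <- do.call(rbind, strsplit(levels(res_fac), ":"))
  residue_keys <- data.frame(chain = keys[, 1],
                             residue_index = as.integer(keys[, 2]),
                             stringsAsFactors = FALSE)
  dimnames(m) <- list(levels(res_fac), levels(res_fac))
  structure(list(residue_keys = residue_keys, forces = m),
            class = "force_matrix")
}

#' Threshold a force matrix into an interaction network
#'
#' Builds the undirected residue-interaction graph keeping exactly the pairs
#' whose force magnitude exceeds `threshold` (pN): minor attractions or
#' repulsions within the band are eliminated. Edge weight is `1/|force|`, so
#' strongly coupled pairs are "short" and shortest paths trace the strongest
#' mechanical coupling routes.
#'
#' @param matrix a `force_matrix` (from [residue_force_matrix()] or
#'   [make_force_matrix()]).
#' @param threshold elimination band half-width in pN (default 10).
#' @return an `igraph` graph with vertex name `chain:residue`, edge
#'   attributes `force_pN` and `weight`, and graph attribute `threshold`.
#' @export
threshold_graph <- function(matrix, threshold = 10) {
  stopifnot(threshold >= 0)
  m <- matrix$forces
  keys <- rownames(m)
  g <- igraph::make_empty_graph(n = nrow(m), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = keys)
  idx <- which(abs(m) > threshold & upper.tri(m), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    edges <- rbind(keys[idx[, 1]], keys[idx[, 2]])
    f <- m[idx]
    g <- igraph::add_edges(g, as.vector(edges))
    g <- igraph::set_edge_attr(g, "force_pN", value = f)
    g <- igraph::set_edge_attr(g, "weight", value = 1 / abs(f))
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Strongest-coupling shortest path through the interaction network
#'
#' Minimum-total-weight path (weight `1/|force|`) between two residues. When
#' several paths tie, the lexicographically smallest vertex-name sequence is
#' returned, making the output deterministic.
#'
#' @param graph graph from [threshold_graph()].
#' @param source,target vertex names (`"chain:residue"`).
#' @return character vector of vertex names along the path.
#' @export
shortest_force_path <- function(graph, source, target) {
  vn <- igraph::V(graph)$name
  if (!(source %in% vn) || !(target %in% vn))
    stop("source/target not in graph: ",
         paste(setdiff(c(source, target), vn), collapse = ", "))
  if (source == target) return(source)
  comp <- igraph::components(graph)
  if (comp$membership[source] != comp$membership[target])
    stop("disconnected error: ", source, " (component ",
         comp$membership[source], ") and ", target, " (component ",
         comp$membership[target], ") are not connected")
  ap <- suppressWarnings(
    igraph::all_shortest_paths(graph, from = source, to = target,
                               weights = igraph::E(graph)$weight))
  vpaths <- if (!is.null(ap$vpaths)) ap$vpaths else ap$res
  paths <- lapply(vpaths, igraph::as_ids)
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths[[order(keys)[1]]]
}

#' Interaction energy across a chain partition
#'
#' `dE = E_complex - E_part1 - E_part2` over the toy nonbonded energy model;
#' internal terms cancel by construction, so this equals the sum of pair
#' energies over inter-partition atom pairs within the cutoff.
#'
#' @param system a [molecular_system()].
#' @param partition list of two character vectors of chain ids (or role
#'   names), together covering all chains exactly once.
#' @param cutoff short-range cutoff in Angstrom.
#' @return interaction energy in kcal/mol.
#' @export
interaction_energy <- function(system, partition, cutoff = 10) {
  stopifnot(is.list(partition), length(partition) == 2)
  expand <- function(p) {
    out <- unlist(lapply(p, function(x)
      if (x %in% system$roles) names(system$roles)[system$roles == x] else x))
    unique(out)
  }
  g1 <- expand(partition[[1]]); g2 <- expand(partition[[2]])
  if (length(intersect(g1, g2)) > 0)
    stop("overlapping partition: ",
         paste(intersect(g1, g2), collapse = ", "))
  all_chains <- names(system$roles)
  uncovered <- setdiff(all_chains, c(g1, g2))
  if (length(uncovered) > 0)
    stop("partition must cover all chains; missing: ",
         paste(uncovered, collapse = ", "))
  bad <- setdiff(c(g1, g2), all_chains)
  if (length(bad) > 0) stop("no such chain(s): ", paste(bad, collapse = ", "))
  atoms <- system$atoms
  a1 <- atoms[atoms$chain_id %in% g1, , drop = FALSE]
  a2 <- atoms[atoms$chain_id %in% g2, , drop = FALSE]
  if (nrow(a1) == 0 || nrow(a2) == 0) return(0)
  dx <- outer(a1$x, a2$x, "-"); dy <- outer(a1$y, a2$y, "-")
  dz <- outer(a1$z, a2$z, "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  qq <- outer(a1$charge, a2$charge)
  sigma <- outer(a1$lj_sigma, a2$lj_sigma, "+") / 2
  epsilon <- sqrt(outer(a1$lj_epsilon, a2$lj_epsilon))
  sum(.pair_energy_kcal(as.vector(r), as.vector(qq), as.vector(sigma),
                        as.vector(epsilon), cutoff))
}
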