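# Backbone-coordinate PCA of trajectories: Kabsch alignment onto an
# iterative mean reference, covariance eigendecomposition (via SVD),
# variance fractions, and mode projections.

# indices of the PCA atom selection; default backbone N/CA/C
.pca_selection <- function(traj, selection = NULL,
                           atom_names = c("N", "CA", "C")) {
  if (!is.null(selection)) return(as.integer(selection))
  idx <- which(traj$atoms$atom_name %in% atom_names)
  if (length(idx) == 0) idx <- seq_len(nrow(traj$atoms))
  idx
}

#' Align a trajectory onto a reference
#'
#' Superposes every frame (Kabsch, via [superpose()]) onto a reference over
#' the selected atoms, removing global rigid-body motion. With
#' `reference = "mean"` the reference is refined iteratively: frames are
#' aligned, the mean structure recomputed, and the loop repeats until the
#' mean shifts by less than 1e-6 Angstrom (RMS).
#'
#' @param traj a [trajectory()].
#' @param selection integer atom indices used for the fit; default backbone
#'   (N, CA, C) atoms, falling back to all atoms when none match.
#' @param reference `"mean"` or a frame index.
#' @param max_iter iteration cap for the mean-reference loop.
#' @return the aligned [trajectory()].
#' @export
align_trajectory <- function(traj, selection = NULL, reference = "mean",
                             max_iter = 20) {
  idx <- .pca_selection(traj, selection)
  if (length(idx) < 3) stop("alignment error: selection needs >= 3 atoms")
  f <- n_frames(traj)
  if (f == 1) return(traj)
  frames <- traj$frames
  align_all <- function(frames, ref_sel) {
    for (i in seq_len(f)) {
      co <- frames[i, , ]
      tr <- superpose(co[idx, , drop = FALSE], ref_sel)
      frames[i, , ] <- sweep(co %*% t(tr$rotation), 2, tr$translation, "+")
    }
    frames
  }
  if (identical(reference, "mean")) {
    ref_sel <- frames[1, idx, ]
    for (it in seq_len(max_iter)) {
      frames <- align_all(frames, ref_sel)
      new_ref <- apply(frames[, idx, , drop = FALSE], c(2, 3), mean)
      shift <- sqrt(mean((new_ref - ref_sel)^2))
      ref_sel <- new_ref
      if (shift < 1e-6) break
    }
  } else {
    ref_sel <- frames[as.integer(reference), idx, ]
    frames <- align_all(frames, ref_sel)
  }
  out <- traj
  out$frames <- frames
  out
}

#' Principal component analysis of trajectory coordinates
#'
#' Eigendecomposition of the `3N x 3N` covariance (unbiased, `F - 1`
#' denominator) of the aligned selected coordinates, computed through the
#' SVD route of [stats::prcomp()]. Modes are orthonormal 3N displacement
#' fields with a deterministic sign convention (largest-magnitude component
#' positive); eigenvalues are in square Angstrom, sorted descending.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection integer atom indices; default backbone N/CA/C.
#' @param align align the trajectory first (default `TRUE`).
#' @return object of class `pca_result`: `mean_coords` (N_sel x 3),
#'   `eigenvalues`, `modes` (3N_sel x k orthonormal), `variance_fraction`,
#'   `selection`.
#' @export
pca_trajectory <- function(traj, selection = NULL, align = TRUE) {
  idx <- .pca_selection(traj, selection)
  f <- n_frames(traj)
  if (f < 2) stop("input error: PCA needs at least 2 frames")
  if (align) traj <- align_trajectory(traj, selection = idx)
  X <- matrix(NA_real_, nrow = f, ncol = 3 * length(idx))
  for (i in seq_len(f))
    X[i, ] <- as.vector(t(traj$frames[i, idx, ]))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  modes <- pc$rotation
  # deterministic sign: largest-|component| positive
  for (j in seq_len(ncol(modes))) {
    mj <- modes[, j]
    if (mj[which.max(abs(mj))] < 0) modes[, j] <- -mj
  }
  total <- sum(ev)
  vf <- if (total > 0) ev / total else rep(0, length(ev))
  structure(list(mean_coords = matrix(pc$center, ncol = 3, byrow = TRUE),
                 eigenvalues = ev, modes = modes,
                 variance_fraction = vf, selection = idx),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat("pca_result:", length(x$eigenvalues), "modes over",
      length(x$selection), "atoms\n")
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(k)]),
            collapse = " "), "\n")
  invisible(x)
}

#' Cumulative variance fraction of the leading modes
#'
#' @param result a `pca_result`.
#' @param k number of leading modes (default 2, the "essential motion"
#'   summary).
#' @return sum of the first `k` variance fractions.
#' @export
variance_fraction <- function(result, k = 2) {
  if (k <= 0) stop("input error: k must be positive")
  if (k > length(result$variance_fraction))
    stop("input error: k exceeds the number of modes")
  sum(result$variance_fraction[seq_len(k)])
}

#' Project a trajectory onto a principal mode
#'
#' Per-frame scalar projection of the centred selected coordinates onto one
#' mode, in Angstrom.
#'
#' @param traj the (aligned) [trajectory()] the PCA was computed from.
#' @param result a `pca_result`.
#' @param mode_index mode number.
#' @param align re-align the trajectory over the PCA selection first.
#' @return numeric vector of length `n_frames(traj)`.
#' @export
project_mode <- function(traj, result, mode_index, align = TRUE) {
  if (mode_index < 1 || mode_index > ncol(result$modes))
    stop("invalid mode index")
  idx <- result$selection
  if (align) traj <- align_trajectory(traj, selection = idx)
  f <- n_frames(traj)
  ctr <- as.vector(t(result$mean_coords))
  out <- numeric(f)
  for (i in seq_len(f))
    out[i] <- sum((as.vector(t(traj$frames[i, idx, ])) - ctr) *
                    result$modes[, mode_index])
  out
}
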