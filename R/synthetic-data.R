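# Synthetic-data generators with planted, known ground truth: toy machinery
# complexes, trajectories with planted low-rank collective motion, coupled
# angle/distance series with a planted time lag, and force matrices with a
# planted strong-interaction path.  All generators are pure functions of
# (spec, seed): identical inputs give identical outputs, and the caller's
# RNG state is left untouched.

# run expr with a locally seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic-data specification
#'
#' Bundles the parameters shared by the generators. The defaults emulate the
#' study conditions this package targets: 8000 samples at 50-ps spacing
#' (400 ns of production), a planted angle-to-distance lag of 65 samples,
#' moderate coupling, and Angstrom-scale noise.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical outputs.
#' @param n_frames number of frames/samples (>= 2; default 8000).
#' @param dt sampling interval in ps (default 50).
#' @param planted_lag planted angle-to-distance lag in samples (default 65).
#' @param coupling coupling strength in `[0, 1]` (default 0.6).
#' @param angle_concentration dimensionless concentration of the circular
#'   walk; the stationary spread is `60/sqrt(angle_concentration)` degrees.
#' @param noise_sd additive noise, Angstrom (default 0.5).
#' @param mode_amplitudes planted collective-mode amplitudes in Angstrom.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_frames = 8000, dt = 50,
                           planted_lag = 65, coupling = 0.6,
                           angle_concentration = 1, noise_sd = 0.5,
                           mode_amplitudes = c(2, 1)) {
  stopifnot(n_frames >= 2, dt > 0, coupling >= 0, coupling <= 1,
            angle_concentration > 0, noise_sd >= 0)
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 dt = dt, planted_lag = as.integer(planted_lag),
                 coupling = coupling,
                 angle_concentration = angle_concentration,
                 noise_sd = noise_sd, mode_amplitudes = mode_amplitudes),
            class = "synthetic_spec")
}

# deterministic well-spread unit directions (spherical Fibonacci lattice)
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# default 12 surface lysines of the toy target (labels follow the
# BRD4-BD1-like numbering; K72/76/99/102/111 are the catalytically relevant
# ones) with NZ-to-Gly-C distances in Angstrom
.DEFAULT_LYS <- c(K57 = 22, K60 = 25, K62 = 28, K72 = 14, K76 = 15.5,
                  K91 = 24, K99 = 8, K102 = 11, K111 = 13, K112 = 19,
                  K141 = 30, K155 = 33)

#' Build a toy degradation-machinery complex
#'
#' A bead-level (C-alpha) multi-chain model carrying the reactive atoms of
#' the ubiquitination criteria explicitly: the target chain (role `BRD4`)
#' has 12 surface lysines with NZ atoms at controllable distances from the
#' C-terminal Gly C of ubiquitin (role `UB`, Gly with CA/C/O atoms); the E2
#' chain carries an Asp with both carboxylate oxygens at a controllable
#' OD1-to-Gly-O distance; roles `CRBN` and `PROTAC` (with an N3 linker atom)
#' complete the complex. Requested distances are realised exactly (to
#' 1e-6 Angstrom) by construction. Reactive atoms carry partial charges and
#' all atoms small LJ parameters, so force and energy analyses are
#' non-trivial.
#'
#' @param spec a [synthetic_spec()] (its seed fixes the bead jitter).
#' @param lys_gly named numeric vector of Lys NZ to Gly C distances in
#'   Angstrom, names like `"K99"`; default plants 12 surface lysines.
#' @param asp_gly Asp OD1 to Gly O distance in Angstrom.
#' @param asp_residue residue index of the E2 Asp.
#' @return a [molecular_system()] with roles CRBN, BRD4, E2, UB, PROTAC.
#' @export
make_toy_complex <- function(spec = synthetic_spec(),
                             lys_gly = .DEFAULT_LYS,
                             asp_gly = 5, asp_residue = 117) {
  if (any(lys_gly < 1) || asp_gly < 1)
    stop("construction error: requested reactive distances must be >= 1 A")
  with_seed(spec$seed, {
    rows <- list()
    add <- function(chain, res, resname, atom, pos, charge = 0,
                    sigma = 3.4, eps = 0.1) {
      rows[[length(rows) + 1]] <<- atom_table(chain, res, resname, atom,
                                              pos[1], pos[2], pos[3],
                                              charge = charge,
                                              lj_sigma = sigma,
                                              lj_epsilon = eps)
    }
    # --- ubiquitin: 8 bead tail + C-terminal Gly75 with CA/C/O
    gly_c <- c(0, 0, 0)
    gly_o <- gly_c + c(0, 0, 1.23)
    gly_ca <- gly_c + c(-1.52, 0, 0)
    for (i in 1:8)
      add("U", 66 + i, "UBQ", "CA", gly_ca + c(-3.8 * (9 - i), 0, 6))
    add("U", 75, "GLY", "CA", gly_ca)
    add("U", 75, "GLY", "C", gly_c, charge = 0.5)
    add("U", 75, "GLY", "O", gly_o, charge = -0.5)
    # --- E2: bead arm + catalytic Asp (OD1 at the requested Gly-O distance)
    od1 <- gly_o + asp_gly * c(0, 1, 0)
    od2 <- od1 + c(0, 0.76, 1.0)            # ~1.25 A away, farther from Gly O
    cg <- od1 + c(0, 1.3, -0.4)
    for (i in 1:10)
      add("E", 100 + i, "E2B", "CA", cg + c(3.8 * i, 2.5, 2))
    add("E", asp_residue, "ASP", "CA", cg + c(0, 2.4, 0))
    add("E", asp_residue, "ASP", "CG", cg)
    add("E", asp_residue, "ASP", "OD1", od1, charge = -0.5)
    add("E", asp_residue, "ASP", "OD2", od2, charge = -0.5)
    # --- target (BRD4-like): backbone arc + surface lysines with NZ atoms
    # NZ atoms sit at the requested distances from Gly C along well-spread
    # directions; each Lys CA sits 1.5 A outward from its NZ.
    dirs <- .fib_sphere(length(lys_gly))
    # keep NZ directions clear of the E2/UB construction axis (+y, +z)
    dirs <- sweep(dirs, 2, c(0.3, -1.2, -0.6))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    lys_res <- as.integer(sub("^K", "", names(lys_gly)))
    for (k in seq_along(lys_gly)) {
      nz <- gly_c + lys_gly[[k]] * dirs[k, ]
      add("B", lys_res[k], "LYS", "NZ", nz, charge = 1)
      add("B", lys_res[k], "LYS", "CA", nz + 1.5 * dirs[k, ])
    }
    arc0 <- gly_c + 40 * c(-0.5, -0.7, -0.5)
    for (i in 1:20)
      add("B", 160 + i, "GLY", "CA",
          arc0 + c(3.8 * i, 4 * sin(i / 3), 4 * cos(i / 3)))
    # --- CRBN: helical bead chain off to one side
    crbn0 <- gly_c + c(-30, -25, -20)
    for (i in 1:20)
      add("C", 300 + i, "ALA", "CA",
          crbn0 + c(1.5 * i, 5 * sin(i * 100 * pi / 180),
                    5 * cos(i * 100 * pi / 180)))
    # --- PROTAC: small linker between CRBN and target regions
    p0 <- (crbn0 + arc0) / 2
    add("P", 1, "LIG", "N3", p0, charge = -0.2, sigma = 3.2, eps = 0.15)
    add("P", 1, "LIG", "C1", p0 + c(1.5, 0, 0), sigma = 3.2, eps = 0.15)
    add("P", 1, "LIG", "C2", p0 + c(2.9, 0.8, 0), sigma = 3.2, eps = 0.15)
    add("P", 1, "LIG", "C3", p0 + c(4.3, 0.8, 0.9), sigma = 3.2, eps = 0.15)
    atoms <- do.call(rbind, rows)
    molecular_system(atoms, c(U = "UB", E = "E2", B = "BRD4",
                              C = "CRBN", P = "PROTAC"))
  })
}

#' Simulate a coupled angle/distance series pair
#'
#' The angle series is a wrapped autocorrelated walk: circular deviations
#' follow an AR(1) (Ornstein-Uhlenbeck) process with correlation time 20
#' samples and stationary spread `60/sqrt(angle_concentration)` degrees,
#' wrapped around a random centre so the +/-180 discontinuity is exercised.
#' The distance series responds to the angle after the planted lag:
#' `y(t) = 10 + coupling * 6 * dev(x(t - lag))/180 + N(0, noise_sd)`
#' (Angstrom), a monotone map of the circular deviation. The planted lag is
#' recoverable by [lagged_correlation()].
#'
#' @param spec a [synthetic_spec()]; uses `seed`, `n_frames`, `dt`,
#'   `planted_lag`, `coupling`, `angle_concentration`, `noise_sd`.
#' @return list with elements `angle` ([angle_series()]) and `distance`
#'   ([dist_series()]).
#' @export
simulate_coupled_series <- function(spec = synthetic_spec()) {
  n <- spec$n_frames
  lag <- spec$planted_lag
  if (lag >= n / 2) stop("planted_lag must be below n_frames/2")
  with_seed(spec$seed, {
    rho <- exp(-1 / 20)
    sd_st <- 60 / sqrt(spec$angle_concentration)
    sd_step <- sd_st * sqrt(1 - rho^2)
    total <- n + lag
    dev <- numeric(total)
    dev[1] <- rnorm(1, 0, sd_st)
    steps <- rnorm(total - 1, 0, sd_step)
    for (t in 2:total) dev[t] <- rho * dev[t - 1] + steps[t - 1]
    dev <- wrap_angle(dev)
    mu <- runif(1, -180, 180)
    x <- wrap_angle(mu + dev[(lag + 1):(lag + n)])
    y <- 10 + spec$coupling * 6 * dev[1:n] / 180 +
      rnorm(n, 0, spec$noise_sd)
    y[y < 0] <- 0
    list(angle = angle_series(x, dt = spec$dt, label = "planted_walk"),
         distance = dist_series(y, dt = spec$dt))
  })
}

#' Simulate a trajectory with planted collective modes
#'
#' `frames(t) = reference + sum_k amplitude_k sin(2 pi c_k t / F) mode_k +
#' noise`, with mutually orthonormal random displacement fields `mode_k` and
#' distinct integer cycle counts `c_k` (so the planted temporal signals are
#' exactly orthogonal and each mode contributes variance `amplitude_k^2/2`).
#' Optional per-frame rigid-body jitter exercises trajectory alignment.
#'
#' @param system reference [molecular_system()].
#' @param spec a [synthetic_spec()]; uses `seed`, `n_frames`, `dt`,
#'   `mode_amplitudes`, `noise_sd`.
#' @param rigid_jitter apply a random rigid rotation + translation per frame.
#' @param noise_sd overrides `spec$noise_sd` for the isotropic coordinate
#'   noise (Angstrom) if not `NULL`.
#' @return a [trajectory()]; the planted modes are attached as attribute
#'   `"modes"` (3N x k orthonormal matrix) and the temporal signals as
#'   `"signals"` (F x k).
#' @export
simulate_trajectory <- function(system, spec = synthetic_spec(),
                                rigid_jitter = FALSE, noise_sd = NULL) {
  amps <- spec$mode_amplitudes
  if (length(amps) < 1) stop("need at least one mode amplitude")
  if (is.null(noise_sd)) noise_sd <- spec$noise_sd
  atoms <- system$atoms
  n <- nrow(atoms)
  f <- spec$n_frames
  ref <- as.vector(t(coords_matrix(atoms)))     # length 3N, atom-major
  k <- length(amps)
  with_seed(spec$seed, {
    M <- matrix(rnorm(3 * n * k), ncol = k)
    modes <- qr.Q(qr(M))[, seq_len(k), drop = FALSE]
    cycles <- 2 + 3 * (seq_len(k) - 1)           # distinct integer cycles
    tgrid <- seq_len(f)
    signals <- sapply(seq_len(k), function(j)
      amps[j] * sin(2 * pi * cycles[j] * tgrid / f))
    signals <- matrix(signals, nrow = f)
    flat <- matrix(rep(ref, each = f), nrow = f) + signals %*% t(modes)
    if (noise_sd > 0)
      flat <- flat + matrix(rnorm(f * 3 * n, 0, noise_sd), nrow = f)
    frames <- array(NA_real_, dim = c(f, n, 3))
    for (i in seq_len(f))
      frames[i, , ] <- matrix(flat[i, ], ncol = 3, byrow = TRUE)
    if (rigid_jitter) {
      for (i in seq_len(f)) {
        ang <- runif(3, -10, 10) * pi / 180
        Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                    c(0, sin(ang[1]), cos(ang[1])))
        Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
                    c(-sin(ang[2]), 0, cos(ang[2])))
        Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                    c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
        shift <- runif(3, -5, 5)
        frames[i, , ] <- sweep(frames[i, , ] %*% t(Rz %*% Ry %*% Rx),
                               2, shift, "+")
      }
    }
    out <- trajectory(frames, atoms, dt = spec$dt, roles = system$roles)
    attr(out, "modes") <- modes
    attr(out, "signals") <- signals
    out
  })
}

#' Build a force matrix with a planted strong-interaction path
#'
#' Symmetric residue-pair force matrix whose background entries lie strictly
#' inside the (-10, 10) pN elimination band, with consecutive pairs along
#' `planted_path` set to a strong attractive force `-|strong|`. Thresholding
#' at 10 pN therefore keeps exactly the planted edges, and the planted path
#' is the unique shortest path between its endpoints.
#'
#' @param n_residues number of residues (matrix dimension).
#' @param planted_path integer vector of distinct residue indices.
#' @param strong planted force magnitude in pN (`|strong| > 10`).
#' @param background_sd background force sd in pN (values are resampled to
#'   stay inside the band).
#' @param seed RNG seed.
#' @return a `force_matrix` with residue keys `X:1 .. X:n`.
#' @export
make_force_matrix <- function(n_residues, planted_path = integer(),
                              strong = 50, background_sd = 3, seed = 1) {
  if (abs(strong) <= 10)
    stop("planted force magnitude must exceed the 10 pN band")
  if (anyDuplicated(planted_path))
    stop("input error: planted path repeats a residue")
  if (length(planted_path) > 0 &&
      (min(planted_path) < 1 || max(planted_path) > n_residues))
    stop("planted path indices out of range")
  with_seed(seed, {
    n <- n_residues
    m <- matrix(0, n, n)
    vals <- rnorm(n * (n - 1) / 2, 0, background_sd)
    bad <- abs(vals) >= 10
    while (any(bad)) {                       # keep background sub-threshold
      vals[bad] <- rnorm(sum(bad), 0, background_sd)
      bad <- abs(vals) >= 10
    }
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    if (length(planted_path) > 1) {
      for (i in seq_len(length(planted_path) - 1)) {
        a <- planted_path[i]; b <- planted_path[i + 1]
        m[a, b] <- m[b, a] <- -abs(strong)
      }
    }
    diag(m) <- 0
    keys <- paste0("X:", seq_len(n))
    dimnames(m) <- list(keys, keys)
    structure(list(residue_keys = data.frame(chain = "X",
                                             residue_index = seq_len(n),
                                             stringsAsFactors = FALSE),
                   forces = m),
              class = "force_matrix")
  })
}
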