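# Circular statistics for dihedral-angle series: resultant-vector means,
# shortest-arc deviations, wrap-safe Pearson correlation, dihedral Gibbs
# entropy, and time-lagged correlation between an angle and a distance
# series.  All angles are degrees in [-180, 180).

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# wrap any angle into [-180, 180)
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Angle / distance series constructors
#'
#' Lightweight containers pairing a per-frame series with its sampling
#' interval. Angle values are wrapped into `[-180, 180)` degrees; distances
#' must be nonnegative Angstrom.
#'
#' @param values numeric vector.
#' @param dt sampling interval in ps.
#' @param label descriptive label (angle) .
#' @param atom_pair length-2 character vector of atom keys (distance).
#' @return object of class `angle_series` / `distance_series`.
#' @export
angle_series <- function(values, dt = 1, label = "") {
  stopifnot(is.numeric(values), dt > 0)
  structure(list(values = wrap_angle(as.numeric(values)), dt = dt,
                 label = label),
            class = "angle_series")
}

#' @rdname angle_series
#' @export
dist_series <- function(values, dt = 1, atom_pair = c(NA, NA)) {
  stopifnot(is.numeric(values), dt > 0)
  if (any(values < 0)) stop("distances must be nonnegative")
  structure(list(values = as.numeric(values), dt = dt,
                 atom_pair = atom_pair),
            class = "distance_series")
}

.series_values <- function(x) if (is.list(x) && !is.null(x$values)) x$values else as.numeric(x)

#' Circular mean of angles
#'
#' Resultant-vector mean: `atan2(sum(sin), sum(cos))`, returned in degrees in
#' `[-180, 180)`. Errors when the resultant vector vanishes (e.g. exactly
#' antipodal mass), where the mean is undefined.
#'
#' @param angles numeric vector of degrees, or an [angle_series()].
#' @return circular mean in degrees.
#' @export
circ_mean <- function(angles) {
  x <- .deg2rad(.series_values(angles))
  if (length(x) == 0) stop("empty angle vector")
  s <- sum(sin(x)); c <- sum(cos(x))
  if (sqrt(s^2 + c^2) / length(x) < 1e-12)
    stop("undefined circular mean: zero resultant vector")
  wrap_angle(.rad2deg(atan2(s, c)))
}

#' Shortest-arc deviation from a circular mean
#'
#' `atan2(sin(x - m), cos(x - m))`: the signed shortest arc from `mean` to
#' `x`, in degrees in `[-180, 180)`. This is the quantity correlated in the
#' wrap-safe Pearson correlation, avoiding the discontinuity at +/-180.
#'
#' @param x angle(s) in degrees.
#' @param mean reference angle in degrees.
#' @return deviation(s) in degrees.
#' @export
circ_dev <- function(x, mean) {
  xr <- .deg2rad(.series_values(x)); mr <- .deg2rad(mean)
  wrap_angle(.rad2deg(atan2(sin(xr - mr), cos(xr - mr))))
}

#' Wrap-safe Pearson correlation of two angle series
#'
#' Pearson correlation of the shortest-arc deviations of each series from its
#' own circular mean. For series confined away from the wrap point this
#' equals the ordinary linear Pearson correlation; for series straddling
#' +/-180 it remains continuous.
#'
#' @param x_series,y_series [angle_series()] or numeric degree vectors of
#'   equal length (>= 3).
#' @return correlation in `[-1, 1]`.
#' @export
circ_pearson <- function(x_series, y_series) {
  x <- .series_values(x_series); y <- .series_values(y_series)
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3) stop("need at least 3 paired angles")
  dx <- circ_dev(x, circ_mean(x))
  dy <- circ_dev(y, circ_mean(y))
  if (sd(dx) < 1e-12 || sd(dy) < 1e-12)
    stop("undefined correlation: zero circular variance")
  r <- cor(dx, dy)
  max(-1, min(1, r))
}

#' Dihedral Gibbs entropy of an angle series
#'
#' Bins the angles into `n_bins` uniform bins over `[-180, 180)`, forms the
#' occupancy distribution `p`, and returns the Gibbs entropy scaled to energy
#' units: `T*S = R*T*(-sum p ln p)` in kcal/mol with
#' `R = 0.0019872 kcal/(mol K)`. A delta distribution gives 0; the uniform
#' distribution is maximal (`R*T*ln(n_bins)`). Larger values mean a more
#' flexible torsion. The raw plug-in entropy in nats is attached as attribute
#' `"nats"`.
#'
#' @param series [angle_series()] or numeric degrees.
#' @param n_bins number of uniform bins (default 36, i.e. 10-degree bins).
#' @param temperature_K temperature for the `R*T` scale (default 300 K).
#' @return entropy as `T*S` in kcal/mol, with attribute `nats`.
#' @export
dihedral_entropy <- function(series, n_bins = 36, temperature_K = 300) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  x <- wrap_angle(.series_values(series))
  if (length(x) < n_bins)
    warning("fewer samples than bins; entropy estimate will be biased low")
  bin <- floor((x + 180) / (360 / n_bins)) + 1
  bin[bin > n_bins] <- n_bins        # guard x == 180 after numerical wrap
  p <- tabulate(bin, nbins = n_bins) / length(x)
  nz <- p > 0
  s_nats <- -sum(p[nz] * log(p[nz]))       # 0*log(0) := 0
  R <- 0.0019872                            # kcal/(mol K)
  out <- R * temperature_K * s_nats
  attr(out, "nats") <- s_nats
  out
}

#' Time-lagged correlation between an angle and a distance series
#'
#' For each lag `l` in `0..max_lag` computes the Pearson correlation between
#' the circular deviations of the angle series at time `t` and the distance
#' series at `t + l`, over the overlapping window. Positive lags only by
#' default (the angle leads the distance, the causal reading of a torsion
#' driving a contact); `symmetric = TRUE` also scans negative lags. Lags with
#' degenerate overlap variance are recorded as `NA` and excluded from the
#' peak.
#'
#' @param x an [angle_series()] (or degrees vector).
#' @param y a [distance_series()] (or numeric vector) of the same length.
#' @param max_lag maximum lag in frames (`< length/2`).
#' @param symmetric also scan negative lags.
#' @return object of class `lag_correlation`: list with `lags`, `r_values`,
#'   `peak_lag`, `peak_r`, `dt` (`lag * dt / 1000` converts to ns).
#' @export
lagged_correlation <- function(x, y, max_lag, symmetric = FALSE) {
  xv <- .series_values(x); yv <- .series_values(y)
  n <- length(xv)
  if (length(yv) != n) stop("series lengths differ")
  if (max_lag >= n / 2) stop("max_lag must be below half the series length")
  dt <- if (is.list(x) && !is.null(x$dt)) x$dt else 1
  dx <- circ_dev(xv, circ_mean(xv))
  lags <- if (symmetric) seq(-max_lag, max_lag) else 0:max_lag
  r <- vapply(lags, function(l) {
    if (l >= 0) { a <- dx[seq_len(n - l)]; b <- yv[seq_len(n - l) + l] }
    else        { a <- dx[seq_len(n + l) - l]; b <- yv[seq_len(n + l)] }
    if (sd(a) < 1e-12 || sd(b) < 1e-12) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  if (all(is.na(r))) stop("no lag with defined correlation")
  i <- which.max(r)
  structure(list(lags = lags, r_values = r,
                 peak_lag = lags[i], peak_r = r[i], dt = dt),
            class = "lag_correlation")
}

#' @export
print.lag_correlation <- function(x, ...) {
  cat(sprintf("lag_correlation: peak r = %.3f at lag %d frames (%.2f ns)\n",
              x$peak_r, x$peak_lag, x$peak_lag * x$dt / 1000))
  invisible(x)
}
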