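#' Regular source grid inside the phantom sphere
#'
#' Cubic lattice with the given spacing, clipped to 95% of the conductor
#' radius (the forward model is singular at the surface).
#'
#' @param sensors A [make_sensor_array()].
#' @param spacing Grid spacing in metres (5 mm default).
#' @return A list of class `source_grid` with `points` (voxels x 3,
#'   metres), `spacing`, and `inside_mask` over the candidate cube.
#' @export
build_grid <- function(sensors, spacing = 5e-3) {
  stopifnot(spacing > 0)
  r_max <- 0.95 * sensors$sphere_radius
  ax <- seq(-r_max, r_max, by = spacing)
  cand <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  colnames(cand) <- NULL
  inside <- sqrt(rowSums(cand^2)) < r_max
  structure(
    list(points = sweep(cand[inside, , drop = FALSE], 2,
                        sensors$sphere_center, "+"),
         spacing = spacing, inside_mask = inside),
    class = "source_grid"
  )
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d voxels, %g mm spacing\n",
              nrow(x$points), x$spacing * 1e3))
  invisible(x)
}

#' Leadfield matrix on a source grid
#'
#' Three orthogonal unit-dipole field columns per voxel through the same
#' closed-form conducting-sphere model used by the simulator, so forward
#' simulation and inverse modelling share one physics.
#'
#' @param grid A [build_grid()].
#' @param sensors A [make_sensor_array()].
#' @return A list of class `leadfield` with `matrix` (channels x
#'   `3 * voxels`, Tesla per A m; columns voxel-major x,y,z) and `grid`.
#' @export
compute_leadfield <- function(grid, sensors) {
  nv <- nrow(grid$points)
  L <- matrix(0, n_sensors(sensors), 3 * nv)
  ctr <- sensors$sphere_center
  for (v in seq_len(nv)) {
    p <- grid$points[v, ] - ctr
    for (ax in 1:3) {
      m <- numeric(3)
      m[ax] <- 1
      L[, 3 * (v - 1) + ax] <- dipole_field(p, m, sensors)
    }
  }
  structure(list(matrix = L, grid = grid), class = "leadfield")
}

#' Median-eigenvalue covariance regularization
#'
#' Eigen-decomposes a symmetric PSD covariance and raises every
#' eigenvalue below the median eigenvalue to the median, bounding the
#' condition number by max-eigenvalue / median-eigenvalue.
#'
#' @param C Symmetric covariance matrix.
#' @return The regularized covariance.
#' @export
regularize_cov <- function(C) {
  if (!isSymmetric(unname(C), tol = 1e-8)) {
    stop("covariance matrix must be symmetric")
  }
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, stats::median(eg$values))
  eg$vectors %*% (vals * t(eg$vectors))
}

#' Unit-gain vector LCMV beamformer weights
#'
#' Sensors are whitened by the (regularized) noise covariance via its
#' symmetric inverse square root; per voxel the vector (free-orientation)
#' unit-gain LCMV weights `W = (L' C^-1 L)^+ L' C^-1` are formed with
#' the whitened leadfield and whitened regularized data covariance. For
#' a spherical conductor the radial source orientation is silent, so
#' `L' C^-1 L` always has (numerical) rank 2; its eigeninverse is
#' truncated at `rank_rtol` of the leading eigenvalue, which makes the
#' beamformer unit-gain on the voxel's visible (tangential) moment
#' subspace: `W L` equals the orthogonal projector onto that subspace.
#' Voxels whose visible subspace degenerates below rank 2 are flagged
#' and excluded from maps.
#'
#' @param data_cov Channels x channels data covariance (regularize with
#'   [regularize_cov()] first).
#' @param noise_cov Noise covariance (typically from the empty-room
#'   recording), regularized likewise.
#' @param lf A [compute_leadfield()].
#' @param rank_rtol Relative eigenvalue cutoff of the per-voxel
#'   `L' C^-1 L` inverse.
#' @return A list of class `lcmv_weights`: `weights` (`3*voxels` x
#'   channels, acting on raw sensor data), `gain` (`3*voxels` x 3,
#'   the per-voxel `W L` projector), `ok` (logical per voxel), `grid`.
#' @export
lcmv_weights <- function(data_cov, noise_cov, lf, rank_rtol = 1e-8) {
  W_n <- sym_inv_sqrt(noise_cov)
  Lw <- W_n %*% lf$matrix
  Cw <- W_n %*% data_cov %*% W_n
  Cw <- (Cw + t(Cw)) / 2
  Ci <- robust_inverse(Cw)
  CiL <- Ci %*% Lw
  nv <- ncol(Lw) / 3
  W <- matrix(0, 3 * nv, nrow(Cw))
  gain <- matrix(0, 3 * nv, 3)
  ok <- rep(TRUE, nv)
  for (v in seq_len(nv)) {
    cols <- 3 * (v - 1) + 1:3
    G <- crossprod(Lw[, cols], CiL[, cols])
    G <- (G + t(G)) / 2
    eg <- eigen(G, symmetric = TRUE)
    keep <- eg$values > rank_rtol * eg$values[1]
    if (sum(keep) < 2) {
      ok[v] <- FALSE
      next
    }
    V <- eg$vectors[, keep, drop = FALSE]
    Ginv <- V %*% (t(V) / eg$values[keep])
    W[cols, ] <- Ginv %*% t(CiL[, cols, drop = FALSE])
    gain[cols, ] <- tcrossprod(V)
  }
  noise_gain <- rowSums(W^2)
  noise_gain <- noise_gain[seq(1, 3 * nv, by = 3)] +
    noise_gain[seq(2, 3 * nv, by = 3)] + noise_gain[seq(3, 3 * nv, by = 3)]
  structure(list(weights = W %*% W_n, weights_whitened = W, gain = gain,
                 noise_gain = noise_gain, ok = ok, grid = lf$grid,
                 whitener = W_n),
            class = "lcmv_weights")
}

sym_inv_sqrt <- function(C) {
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-12 * max(eg$values))
  eg$vectors %*% (t(eg$vectors) / sqrt(vals))
}

# Inverse with a diagonal-loading fallback for (near-)singular
# covariances, e.g. noiseless simulations.
robust_inverse <- function(C) {
  if (rcond(C) > 1e-12) return(solve(C))
  solve(C + diag(1e-8 * mean(diag(C)), nrow(C)))
}

#' Per-voxel source power at a target frequency
#'
#' For each 4 s Hamming window, the sensor Fourier coefficient vector at
#' the bin nearest `frequency` is passed through the beamformer; the
#' per-window source power is the squared norm of the resulting
#' 3-vector divided by the voxel's noise gain (the squared Frobenius
#' norm of its whitened weights), and `power` is its mean over windows
#' (per-window values are retained for the bootstrap threshold). The
#' noise-gain normalization (the neural-activity-index family) is what
#' makes activation maps interpretable for a unit-gain beamformer:
#' without it, deep voxels with weak leadfields amplify sensor noise
#' quadratically and the map peaks at the sphere centre regardless of
#' the sources.
#'
#' @param rec A [recording()].
#' @param weights An [lcmv_weights()].
#' @param frequency Target frequency, Hz (below Nyquist).
#' @param window_length,overlap Welch windowing convention.
#' @return A list of class `source_map`: `power` (per voxel), `frequency`,
#'   `per_window_power` (voxels x windows), `active` (unset), `threshold`
#'   (unset), `ok`, `grid`.
#' @export
source_power_at <- function(rec, weights, frequency,
                            window_length = 4, overlap = 0.5) {
  if (frequency >= rec$fs / 2) stop("frequency must be below Nyquist")
  nwin <- round(window_length * rec$fs)
  hop <- round(nwin * (1 - overlap))
  starts <- seq(1, ncol(rec$data) - nwin + 1, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  bin <- round(frequency * window_length) + 1
  freq_used <- (bin - 1) / window_length
  phasor <- exp(-2i * pi * (bin - 1) * seq(0, nwin - 1) / nwin)
  basis <- w * phasor
  co <- matrix(0i, nrow(rec$data), length(starts))
  for (j in seq_along(starts)) {
    seg <- rec$data[, seq(starts[j], starts[j] + nwin - 1), drop = FALSE]
    co[, j] <- seg %*% basis
  }
  proj <- weights$weights %*% co          # (3*voxels) x windows, complex
  nv <- length(weights$ok)
  pw <- matrix(0, nv, length(starts))
  for (ax in 1:3) {
    pw <- pw + Mod(proj[seq(ax, 3 * nv, by = 3), , drop = FALSE])^2
  }
  pw <- pw / weights$noise_gain
  pw[!weights$ok, ] <- NA_real_
  structure(
    list(power = rowMeans(pw), frequency = freq_used,
         per_window_power = pw, active = NULL, threshold = NULL,
         ok = weights$ok, grid = weights$grid),
    class = "source_map"
  )
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("<source_map> %d voxels @ %g Hz, %d windows%s\n",
              length(x$power), x$frequency, ncol(x$per_window_power),
              if (!is.null(x$active)) {
                sprintf(", %d active (threshold %.3g)", sum(x$active),
                        x$threshold)
              } else ""))
  invisible(x)
}

#' Bootstrap activation threshold for a source map
#'
#' Each iteration draws the map's windows with replacement and averages
#' per voxel; the threshold is the given percentile of the pooled
#' (voxel, iteration) mean-power values, optionally excluding voxels
#' (e.g. those already active in the reference map) from the pool.
#'
#' @param map A [source_power_at()] map with per-window power.
#' @param n_iter Bootstrap iterations.
#' @param percentile Pool percentile defining the threshold.
#' @param exclude Logical per voxel: `TRUE` removes the voxel from the
#'   percentile pool (it can still be declared active later).
#' @param seed RNG seed.
#' @return The power threshold (numeric scalar).
#' @export
bootstrap_threshold <- function(map, n_iter = 1000, percentile = 95,
                                exclude = NULL, seed = 1) {
  P <- map$per_window_power
  if (is.null(P)) stop("map has no per-window power")
  nw <- ncol(P)
  if (nw < 8) stop("bootstrap needs at least 8 windows")
  keep <- map$ok
  if (!is.null(exclude)) keep <- keep & !exclude
  if (!any(keep)) stop("all voxels excluded from the bootstrap pool")
  P <- P[keep, , drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- matrix(0, nw, n_iter)
  for (i in seq_len(n_iter)) {
    counts[, i] <- tabulate(sample.int(nw, nw, replace = TRUE), nbins = nw)
  }
  means <- (P %*% counts) / nw
  unname(stats::quantile(means, percentile / 100))
}

#' Apply an activation threshold to a source map
#'
#' @param map A [source_power_at()] map.
#' @param threshold Power threshold; voxels with `power > threshold`
#'   become active.
#' @return The map with `active` and `threshold` set.
#' @export
active_map <- function(map, threshold) {
  map$active <- !is.na(map$power) & map$power > threshold
  map$threshold <- threshold
  map
}

#' Spatial overlap D between two activation maps
#'
#' Intersection-over-union of the active voxel sets; 1 means perfect
#' overlap. Undefined (error) when both maps are empty.
#'
#' @param a,b [active_map()] results on the same grid.
#' @return A list of class `d_result` with `d`, `n_intersection`,
#'   `n_union`.
#' @export
overlap_D <- function(a, b) {
  if (length(a$power) != length(b$power) ||
      max(abs(a$grid$points - b$grid$points)) > 1e-12) {
    stop("maps are not on the same grid")
  }
  if (is.null(a$active) || is.null(b$active)) {
    stop("both maps must be thresholded first (see active_map)")
  }
  ni <- sum(a$active & b$active)
  nu <- sum(a$active | b$active)
  if (nu == 0) stop("both maps are empty; D is undefined (0/0)")
  structure(list(d = ni / nu, n_intersection = ni, n_union = nu),
            class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("D = %.4f (%d / %d voxels)\n", x$d, x$n_intersection,
              x$n_union))
  invisible(x)
}
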