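#' Signal space separation multipole basis
#'
#' Columns are magnetic fields of interior (`r^-(l+1)`-type potentials,
#' sources inside the helmet) and exterior (`r^l`-type, sources outside)
#' multipoles, evaluated at the sensor positions and projected on the
#' sensor orientations. Fields are obtained as gradients of the real
#' spherical-harmonic scalar potentials by high-accuracy central
#' differences; columns are normalized to unit Euclidean norm. The inner
#' basis has `L_in (L_in + 2)` columns (80 at order 8), the outer
#' `L_out (L_out + 2)` (15 at order 3).
#'
#' @param sensors A [make_sensor_array()].
#' @param L_in,L_out Inner and outer expansion orders.
#' @param origin Expansion origin (defaults to the sphere centre).
#' @param basis_rtol Relative tolerance used to warn about
#'   ill-conditioning of the joint column-normalized basis.
#' @return A channels x (n_in + n_out) matrix with attributes `n_in`,
#'   `n_out`.
#' @export
sss_basis <- function(sensors, L_in = 8, L_out = 3,
                      origin = sensors$sphere_center, basis_rtol = 1e-8) {
  pos <- sweep(sensors$positions, 2, origin)
  ori <- sensors$orientations
  nch <- nrow(pos)
  n_in <- L_in * (L_in + 2)
  n_out <- L_out * (L_out + 2)
  if (nch <= n_in + n_out) {
    stop("fewer channels than inner + outer basis dimensions")
  }
  h <- 1e-5
  cols_at <- function(pts, L, kind) {
    # potentials for all (l, m) at the given points
    r <- sqrt(rowSums(pts^2))
    ct <- pts[, 3] / r
    phi <- atan2(pts[, 2], pts[, 1])
    out <- matrix(0, nrow(pts), L * (L + 2))
    j <- 0
    for (l in seq_len(L)) {
      Plm <- pracma::legendre(l, ct)     # (l+1) x npts, m = 0..l
      radial <- if (kind == "in") r^(-(l + 1)) else r^l
      j <- j + 1
      out[, j] <- radial * Plm[1, ]
      for (m in seq_len(l)) {
        j <- j + 1
        out[, j] <- radial * Plm[m + 1, ] * cos(m * phi)
        j <- j + 1
        out[, j] <- radial * Plm[m + 1, ] * sin(m * phi)
      }
    }
    out
  }
  grad_basis <- function(L, kind) {
    B <- matrix(0, nch, L * (L + 2))
    for (ax in 1:3) {
      e <- numeric(3)
      e[ax] <- h
      dpsi <- (cols_at(sweep(pos, 2, e, "+"), L, kind) -
                 cols_at(sweep(pos, 2, e, "-"), L, kind)) / (2 * h)
      B <- B + dpsi * ori[, ax]          # -grad psi . ori, sign irrelevant
    }
    B
  }
  S <- cbind(grad_basis(L_in, "in"), grad_basis(L_out, "out"))
  S <- sweep(S, 2, sqrt(colSums(S^2)), "/")
  sv <- svd(S, nu = 0, nv = 0)$d
  if (sv[length(sv)] < basis_rtol * sv[1]) {
    warning("SSS basis is ill-conditioned; truncated pseudoinverse engaged")
  }
  attr(S, "n_in") <- n_in
  attr(S, "n_out") <- n_out
  S
}

#' Parameters for temporal signal space separation
#'
#' @param CL Correlation limit in (0, 1]: temporal directions whose
#'   canonical correlation between the inner reconstruction and the
#'   residual exceeds `CL` are projected out of the inner part. `CL = 1`
#'   reduces tSSS to plain SSS inner reconstruction.
#' @param segment_length Segment length in seconds (non-overlapping).
#' @param L_in,L_out Spherical-harmonic orders of the expansion.
#' @param basis_rtol Relative singular-value cutoff of the basis
#'   pseudoinverse.
#' @param res_floor Residual temporal directions participate in the
#'   subspace intersection only if their singular value exceeds this
#'   fraction of the segment's leading singular value. Weaker residual
#'   directions are indistinguishable from basis-truncation leakage of
#'   the signal itself and must not be projected out (a noiseless
#'   interior source would otherwise be destroyed).
#' @return A list of class `tsss_params`.
#' @export
tsss_params <- function(CL = 0.95, segment_length = 10, L_in = 8,
                        L_out = 3, basis_rtol = 1e-8, res_floor = 0.01) {
  stopifnot(CL > 0, CL <= 1)
  structure(list(CL = CL, segment_length = segment_length, L_in = L_in,
                 L_out = L_out, basis_rtol = basis_rtol,
                 res_floor = res_floor),
            class = "tsss_params")
}

#' Temporal signal space separation cleaning
#'
#' Per non-overlapping segment: least-squares fit of the joint
#' inner+outer multipole basis (truncated-SVD pseudoinverse); the segment
#' splits into an inner reconstruction, an outer reconstruction and a
#' residual. Orthonormal temporal bases of the inner part and the
#' residual are intersected by canonical correlation; temporal directions
#' correlated above `CL` (artefact leakage across the separation) are
#' projected out of the inner part. The output is the concatenated
#' cleaned inner reconstruction; a trailing partial segment is processed
#' as its own shorter segment.
#'
#' @param rec A [recording()].
#' @param p A [tsss_params()].
#' @param sensors Sensor array (defaults to the recording's).
#' @return The cleaned [recording()].
#' @export
tsss_clean <- function(rec, p = tsss_params(), sensors = rec$sensors) {
  S <- sss_basis(sensors, p$L_in, p$L_out, basis_rtol = p$basis_rtol)
  n_in <- attr(S, "n_in")
  sv <- svd(S)
  keep <- sv$d > p$basis_rtol * sv$d[1]
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  S_in <- S[, seq_len(n_in), drop = FALSE]

  n <- ncol(rec$data)
  seg_n <- round(p$segment_length * rec$fs)
  if (seg_n > n) seg_n <- n
  starts <- seq(1, n, by = seg_n)
  out <- matrix(0, nrow(rec$data), n)
  for (s0 in starts) {
    idx <- seq(s0, min(n, s0 + seg_n - 1))
    X <- rec$data[, idx, drop = FALSE]
    A <- pinv %*% X
    B_in <- S_in %*% A[seq_len(n_in), , drop = FALSE]
    B_res <- X - S %*% A
    out[, idx] <- tsss_segment(B_in, B_res, p$CL,
                               p$res_floor * svd(X, nu = 0, nv = 0)$d[1])
  }
  rec$data <- out
  rec
}

# Project temporal directions shared (correlation > CL) between the inner
# reconstruction and the residual out of the inner part. `res_sv_floor`
# suppresses residual directions too weak to be genuine artefacts.
tsss_segment <- function(B_in, B_res, CL, res_sv_floor = 0) {
  if (CL >= 1) return(B_in)
  V_in <- temporal_basis(B_in)
  V_res <- temporal_basis(B_res, res_sv_floor)
  if (ncol(V_in) == 0 || ncol(V_res) == 0) return(B_in)
  cc <- svd(crossprod(V_in, V_res))
  corr <- pmin(cc$d, 1)
  sel <- corr > CL
  if (!any(sel)) return(B_in)
  Q <- V_in %*% cc$u[, sel, drop = FALSE]  # time x s, orthonormal
  B_in - (B_in %*% Q) %*% t(Q)
}

# Orthonormal basis of the row space (temporal subspace) of a
# channels x time matrix, retaining directions with singular value above
# 1e-10 of the leading one and above an optional absolute floor.
temporal_basis <- function(B, sv_floor = 0) {
  sv <- svd(B, nu = 0)
  keep <- sv$d > max(1e-10 * sv$d[1], sv_floor)
  sv$v[, keep, drop = FALSE]
}

#' Channel-wise baseline correction of a cleaned spectrum
#'
#' For each channel, the mean difference in log10 power between the
#' cleaned and reference spectra over 15-125 Hz (excluding 49-51 and
#' 99-101 Hz line-noise bands) is computed and subtracted from the
#' cleaned spectrum at all frequencies. This removes the uniform
#' baseline power shift that tSSS introduces, without touching spectral
#' structure.
#'
#' @param clean_spec,ref_spec [welch_psd()] estimates on identical
#'   frequency axes.
#' @param band Averaging band (Hz) used to estimate the offset.
#' @param exclude Intervals excluded from the averaging band.
#' @return A corrected `spectrum_estimate` (per-window power, if present,
#'   is rescaled consistently).
#' @export
baseline_correct <- function(clean_spec, ref_spec,
                             band = c(15, 125),
                             exclude = rbind(c(49, 51), c(99, 101))) {
  if (length(clean_spec$freqs) != length(ref_spec$freqs) ||
      max(abs(clean_spec$freqs - ref_spec$freqs)) > 1e-9) {
    stop("frequency axes of the two spectra do not match")
  }
  sel <- band_bins(clean_spec$freqs, band_spec(band, exclude))
  delta <- rowMeans(log10(clean_spec$power[, sel, drop = FALSE]) -
                      log10(ref_spec$power[, sel, drop = FALSE]))
  fac <- 10^(-delta)
  clean_spec$power <- clean_spec$power * fac
  if (!is.null(clean_spec$per_window_power)) {
    clean_spec$per_window_power <- clean_spec$per_window_power *
      array(fac, dim(clean_spec$per_window_power))
  }
  clean_spec
}
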