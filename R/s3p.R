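#' Parameters for spectral signal space projection (S3P)
#'
#' @param k Noise-subspace dimension removed at each frequency in scope
#'   (constant across frequencies); `k = 0` is the identity.
#' @param window_length STFT window length, seconds (0.25 Hz resolution at
#'   the default 4 s, matching the ~0.2 Hz artefact width).
#' @param overlap Window overlap fraction.
#' @param kaiser_beta Kaiser window shape (strong side-lobe suppression
#'   keeps the narrow bins independent).
#' @param mode `"dbs_band"` projects only at frequencies inside
#'   `dbs_bands`; `"wide_band"` projects at all frequencies.
#' @param dbs_bands 2-column matrix of Hz intervals, or `NULL` for
#'   `f_stim` harmonics +/- `band_halfwidth`.
#' @param f_stim,band_halfwidth Defaults for the harmonic bands.
#' @return A list of class `s3p_params`.
#' @export
s3p_params <- function(k = 1, window_length = 4, overlap = 0.5,
                       kaiser_beta = 14,
                       mode = c("dbs_band", "wide_band"),
                       dbs_bands = NULL, f_stim = 130, band_halfwidth = 3) {
  stopifnot(k >= 0)
  structure(list(k = k, window_length = window_length, overlap = overlap,
                 kaiser_beta = kaiser_beta, mode = match.arg(mode),
                 dbs_bands = dbs_bands, f_stim = f_stim,
                 band_halfwidth = band_halfwidth),
            class = "s3p_params")
}

# Short-time Fourier transform of a channels x samples matrix with the
# S3P conventions. The signal is zero-padded by one hop on both sides so
# every original sample is covered by at least two windows, which keeps
# the overlap-add denominator well away from zero.
stft <- function(x, fs, window_length = 4, overlap = 0.5,
                 kaiser_beta = 14) {
  nwin <- round(window_length * fs)
  hop <- round(nwin * (1 - overlap))
  if (ncol(x) < nwin) stop("recording shorter than one STFT window")
  npad <- hop
  xp <- cbind(matrix(0, nrow(x), npad), x, matrix(0, nrow(x), npad))
  starts <- seq(1, ncol(xp) - nwin + 1, by = hop)
  w <- kaiser_window(nwin, kaiser_beta)
  nfreq <- nwin %/% 2 + 1
  coefs <- array(0i, c(nrow(x), nfreq, length(starts)))
  for (j in seq_along(starts)) {
    seg <- xp[, seq(starts[j], starts[j] + nwin - 1), drop = FALSE] *
      matrix(w, nrow(x), nwin, byrow = TRUE)
    coefs[, , j] <- t(stats::mvfft(t(seg)))[, seq_len(nfreq)]
  }
  list(coefs = coefs, freqs = (seq_len(nfreq) - 1) / window_length,
       window = w, hop = hop, nwin = nwin, npad = npad,
       n_orig = ncol(x), fs = fs)
}

# Inverse STFT by weighted overlap-add with window-sum-of-squares
# normalization; rejects window/hop combinations whose denominator falls
# below 1e-6 of its maximum anywhere over the original samples.
istft <- function(tf) {
  nwin <- tf$nwin
  hop <- tf$hop
  nw <- dim(tf$coefs)[3]
  nch <- dim(tf$coefs)[1]
  ntot <- (nw - 1) * hop + nwin
  acc <- matrix(0, nch, ntot)
  den <- numeric(ntot)
  w <- tf$window
  nfreq <- dim(tf$coefs)[2]
  even <- nwin %% 2 == 0
  for (j in seq_len(nw)) {
    os <- tf$coefs[, , j, drop = FALSE]
    dim(os) <- c(nch, nfreq)
    full <- matrix(0i, nch, nwin)
    full[, seq_len(nfreq)] <- os
    mir <- Conj(os[, seq(2, nfreq - as.integer(even)), drop = FALSE])
    full[, seq(nwin, nwin - ncol(mir) + 1)] <- mir
    seg <- Re(t(stats::mvfft(t(full), inverse = TRUE))) / nwin
    idx <- seq((j - 1) * hop + 1, (j - 1) * hop + nwin)
    acc[, idx] <- acc[, idx] + seg * matrix(w, nch, nwin, byrow = TRUE)
    den[idx] <- den[idx] + w^2
  }
  keep <- seq(tf$npad + 1, tf$npad + tf$n_orig)
  if (min(den[keep]) < 1e-6 * max(den)) {
    stop("overlap-add denominator below tolerance; bad window/hop combination")
  }
  acc[, keep, drop = FALSE] / matrix(den[keep], nch, tf$n_orig, byrow = TRUE)
}

#' Per-frequency spatial projectors from cross-spectral density
#'
#' For each requested frequency, the CSD matrix is averaged over STFT
#' windows (outer products of the coefficient vectors), its Hermitian
#' eigen-decomposition taken with eigenvalues descending, and the
#' projector `P = I - U_k U_k^H` formed from the leading `k` eigenvectors
#' spanning the artefact subspace.
#'
#' @param tf An STFT as produced internally ([s3p_clean()] exposes it via
#'   this function for diagnostic use): list with a `coefs`
#'   channels x freqs x windows complex array.
#' @param k Number of leading eigenvectors to project out; must be below
#'   the channel count, and at most `windows - 1` windows... at least
#'   `k + 1` windows are required for a rank-sufficient CSD.
#' @param freq_idx Indices of frequencies to process (default: all).
#' @return A list of `freq_projector` objects with elements `frequency`,
#'   `P` (Hermitian, idempotent), `U_k` and `eigenvalues`.
#' @export
s3p_projectors <- function(tf, k, freq_idx = NULL) {
  nch <- dim(tf$coefs)[1]
  nw <- dim(tf$coefs)[3]
  if (k >= nch) stop("k must be smaller than the number of channels")
  if (nw < k + 1) stop("need at least k + 1 STFT windows")
  if (is.null(freq_idx)) freq_idx <- seq_along(tf$freqs)
  lapply(freq_idx, function(fi) {
    V <- tf$coefs[, fi, , drop = FALSE]
    dim(V) <- c(nch, nw)
    csd <- tcrossprod(V, Conj(V)) / nw
    csd <- (csd + Conj(t(csd))) / 2
    eg <- eigen(csd, symmetric = TRUE)
    if (k > 0) {
      U <- eg$vectors[, seq_len(k), drop = FALSE]
      P <- diag(nch) - tcrossprod(U, Conj(U))
    } else {
      U <- matrix(0i, nch, 0)
      P <- diag(nch) + 0i
    }
    structure(list(frequency = tf$freqs[fi], P = P, U_k = U,
                   eigenvalues = eg$values),
              class = "freq_projector")
  })
}

#' Spectral signal space projection cleaning
#'
#' STFT with Kaiser windows, per-frequency projection of the leading
#' `k`-dimensional CSD eigenspace out of every window's coefficient
#' vector (at all frequencies in `wide_band` mode, only inside the DBS
#' harmonic bands otherwise), and inverse transform by weighted
#' overlap-add. With `k = 0` the analysis-synthesis chain is the identity
#' to numerical precision.
#'
#' @param rec A [recording()].
#' @param p An [s3p_params()].
#' @return The cleaned [recording()].
#' @export
s3p_clean <- function(rec, p = s3p_params()) {
  tf <- stft(rec$data, rec$fs, p$window_length, p$overlap, p$kaiser_beta)
  if (p$mode == "wide_band") {
    scope <- seq_along(tf$freqs)
  } else {
    bands <- p$dbs_bands
    if (is.null(bands)) {
      bands <- dbs_harmonic_bands(p$f_stim, rec$fs / 2, p$band_halfwidth)
    }
    scope <- which(band_bins(tf$freqs, band_spec(bands)))
  }
  if (p$k > 0 && length(scope) > 0) {
    projs <- s3p_projectors(tf, p$k, scope)
    nch <- dim(tf$coefs)[1]
    nw <- dim(tf$coefs)[3]
    for (i in seq_along(scope)) {
      fi <- scope[i]
      V <- tf$coefs[, fi, , drop = FALSE]
      dim(V) <- c(nch, nw)
      tf$coefs[, fi, ] <- projs[[i]]$P %*% V
    }
  }
  rec$data <- istft(tf)
  rec
}
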