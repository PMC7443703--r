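#' Parameters for the frequency-domain Hampel filter
#'
#' @param C Threshold in robust-SD units; higher is less sensitive.
#' @param window_hz Sliding-window width in Hz (at least twice the ~0.2 Hz
#'   artefact width).
#' @param mode `"dbs_band"` runs the identifier only on bins inside
#'   `dbs_bands`; `"wide_band"` runs it on the whole one-sided spectrum.
#' @param dbs_bands 2-column matrix of Hz intervals, or `NULL` to use
#'   `f_stim` harmonics +/- `band_halfwidth` up to Nyquist.
#' @param f_stim Stimulation frequency used to build default DBS bands.
#' @param band_halfwidth Half-width (Hz) of each default harmonic band.
#' @param scale `"mad"` (1.4826 x median absolute deviation, the classic
#'   Hampel identifier) or `"sd"` (plain window standard deviation).
#' @return A list of class `hampel_params`.
#' @export
hampel_params <- function(C = 5, window_hz = 6,
                          mode = c("dbs_band", "wide_band"),
                          dbs_bands = NULL, f_stim = 130,
                          band_halfwidth = 3,
                          scale = c("mad", "sd")) {
  stopifnot(C > 0, window_hz >= 0.4)
  structure(list(C = C, window_hz = window_hz, mode = match.arg(mode),
                 dbs_bands = dbs_bands, f_stim = f_stim,
                 band_halfwidth = band_halfwidth,
                 scale = match.arg(scale)),
            class = "hampel_params")
}

#' Harmonic DBS frequency bands below Nyquist
#'
#' @param f_stim Stimulation frequency, Hz.
#' @param nyquist Nyquist frequency, Hz.
#' @param halfwidth Half-width of each band, Hz.
#' @return 2-column matrix of intervals `[k*f_stim - halfwidth,
#'   k*f_stim + halfwidth]`.
#' @export
dbs_harmonic_bands <- function(f_stim, nyquist, halfwidth = 3) {
  ks <- seq_len(floor((nyquist - halfwidth) / f_stim))
  cbind(ks * f_stim - halfwidth, ks * f_stim + halfwidth)
}

#' Frequency-domain Hampel filtering of narrow spectral peaks
#'
#' Each channel is Fourier transformed over its full length (no
#' windowing); a Hampel identifier slides bin-by-bin over the one-sided
#' spectrum and flags a bin as an outlier in the real (resp. imaginary)
#' part when it deviates from the window median by more than
#' `C * 1.4826 * MAD` (or `C` window SDs). Outliers are replaced by the
#' window median of that part, conjugate symmetry is restored and the
#' inverse FFT returns a real signal of the original length. In
#' `dbs_band` mode only bins inside the DBS harmonic bands are eligible,
#' so the filter is exactly the identity elsewhere.
#'
#' @param rec A [recording()].
#' @param p A [hampel_params()].
#' @return The cleaned [recording()].
#' @export
hampel_clean <- function(rec, p = hampel_params()) {
  n <- ncol(rec$data)
  df <- rec$fs / n
  wbins <- round(p$window_hz / df)
  if (wbins < 3) stop("Hampel window shorter than 3 frequency bins")
  half <- wbins %/% 2
  n_os <- n %/% 2 + 1
  freqs <- (seq_len(n_os) - 1) * df
  eval_mask <- if (p$mode == "wide_band") {
    rep(TRUE, n_os)
  } else {
    bands <- p$dbs_bands
    if (is.null(bands)) {
      bands <- dbs_harmonic_bands(p$f_stim, rec$fs / 2, p$band_halfwidth)
    }
    band_bins(freqs, band_spec(bands))
  }
  use_mad <- p$scale == "mad"
  clean1 <- function(x) {
    X <- stats::fft(x)
    os <- X[seq_len(n_os)]
    re <- hampel_identify_cpp(Re(os), half, p$C, eval_mask, use_mad)
    im <- hampel_identify_cpp(Im(os), half, p$C, eval_mask, use_mad)
    im[1] <- 0
    if (n %% 2 == 0) im[n_os] <- 0
    os <- complex(real = re, imaginary = im)
    full <- X
    full[seq_len(n_os)] <- os
    if (n_os > 2) {
      mirror <- Conj(os[seq(2, n_os - 1 + (n %% 2))])
      full[seq(n, n - length(mirror) + 1)] <- mirror
    }
    Re(stats::fft(full, inverse = TRUE)) / n
  }
  rec$data <- t(apply(rec$data, 1, clean1))
  rec
}
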