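#' Zero-phase notch filtering of power-line harmonics
#'
#' Applies second-order IIR notches at `base`, `2*base`, ... up to
#' `max_harmonic`, forward-backward (zero phase), to every channel.
#' Each notch has a fixed -3 dB bandwidth (default 0.5 Hz) independent of
#' the harmonic, which keeps the passband ripple below 0.5 dB outside
#' +/- 1 Hz of every notch centre while attenuating the centre itself by
#' far more than 30 dB. Harmonics at or above the Nyquist frequency are
#' skipped with a message.
#'
#' @param rec A [recording()], or a plain numeric vector (then `fs` is
#'   required). The vector form is used, e.g., to notch the DBS reference
#'   channel at the dipole frequency before mutual-information ranking.
#' @param base Fundamental notch frequency, Hz; must be below Nyquist.
#' @param max_harmonic Highest harmonic frequency to notch, Hz.
#' @param fs Sampling rate, Hz; only for the vector form.
#' @param bandwidth -3 dB width of each notch, Hz.
#' @return Same type as `rec`, filtered.
#' @export
notch_filter <- function(rec, base = 50, max_harmonic = base, fs = NULL,
                         bandwidth = 0.5) {
  is_rec <- inherits(rec, "recording")
  if (is_rec) fs <- rec$fs
  if (is.null(fs)) stop("fs is required when filtering a plain vector")
  if (base >= fs / 2) stop("base notch frequency must be below Nyquist")
  freqs <- seq(base, max_harmonic, by = base)
  keep <- freqs < fs / 2
  if (any(!keep)) {
    message(sprintf("skipping %d notch harmonic(s) at or above Nyquist",
                    sum(!keep)))
    freqs <- freqs[keep]
  }
  filt <- function(x) {
    for (f0 in freqs) {
      ba <- biquad_notch(f0, fs, bandwidth)
      x <- filtfilt_reflect(ba$b, ba$a, x)
    }
    x
  }
  if (is_rec) {
    rec$data <- t(apply(rec$data, 1, filt))
    rec
  } else {
    filt(rec)
  }
}

# RBJ biquad notch with a fixed absolute -3 dB bandwidth.
biquad_notch <- function(f0, fs, bandwidth) {
  w0 <- 2 * pi * f0 / fs
  Q <- f0 / bandwidth
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Forward-backward filtering with odd-reflection edge padding long enough
# for the filter's impulse response to decay (8 time constants of the
# slowest pole), which keeps edge transients of narrow notches negligible
# for quasi-stationary input.
filtfilt_reflect <- function(b, a, x, npad = NULL) {
  n <- length(x)
  if (is.null(npad)) {
    r <- suppressWarnings(max(Mod(polyroot(rev(a)))))
    npad <- if (is.finite(r) && r < 1) ceiling(8 / (1 - r)) else 5000L
  }
  npad <- min(n - 1, max(npad, 3 * (length(a) + length(b))))
  head_pad <- 2 * x[1] - x[seq(npad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[seq(npad + 1, npad + n)]
}

#' Anti-aliased integer-ratio downsampling
#'
#' Polyphase-style decimation: a linear-phase Kaiser-windowed FIR low-pass
#' (cutoff at the new Nyquist, ~60 dB stopband) is applied via FFT
#' convolution with exact group-delay compensation, and every `fs/fs_new`-th
#' sample is kept.
#'
#' @param rec A [recording()] or a numeric vector (then `fs` is required).
#' @param fs_new Target sampling rate; `fs` must be an integer multiple.
#' @param fs Sampling rate of the vector form.
#' @return Same type as `rec`, resampled to `fs_new`; length is
#'   `floor(samples * fs_new / fs)`.
#' @export
downsample <- function(rec, fs_new, fs = NULL) {
  is_rec <- inherits(rec, "recording")
  if (is_rec) fs <- rec$fs
  if (is.null(fs)) stop("fs is required when downsampling a plain vector")
  q <- fs / fs_new
  if (abs(q - round(q)) > 1e-9) {
    stop("fs must be an integer multiple of fs_new")
  }
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  h <- decim_fir(q)
  dec <- function(x) {
    y <- fft_filt_linphase(h, x)
    y[seq(1, length(x), by = q)][seq_len(length(x) %/% q)]
  }
  if (is_rec) {
    rec$data <- t(apply(rec$data, 1, dec))
    rec$fs <- fs_new
    rec
  } else {
    dec(rec)
  }
}

# Kaiser low-pass for decimation by q: passband edge 0.42/q, stopband 0.5/q
# (normalized to the old rate), ~62 dB attenuation.
decim_fir <- function(q) {
  atten <- 62
  d_omega <- 2 * pi * (0.5 - 0.42) / q
  n <- ceiling((atten - 8) / (2.285 * d_omega))
  n <- n + (n %% 2)                      # even order -> odd length, type I
  beta <- 0.1102 * (atten - 8.7)
  k <- 0:n
  fc <- 0.46 / q                          # cycles/sample
  hd <- 2 * fc * sinc_fn(2 * fc * (k - n / 2))
  w <- besselI(beta * sqrt(pmax(0, 1 - (2 * k / n - 1)^2)), 0) /
    besselI(beta, 0)
  h <- hd * w
  h / sum(h)
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Linear convolution with a symmetric FIR via FFT, trimmed to compensate
# the (N-1)/2 group delay, output length = input length.
fft_filt_linphase <- function(h, x) {
  n <- length(x)
  m <- length(h)
  nfft <- stats::nextn(n + m - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(h, numeric(nfft - m))), inverse = TRUE)) / nfft
  d <- (m - 1) / 2
  y[seq(d + 1, d + n)]
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with the study's conventions: 4 s windows,
#' 50% overlap, Hamming taper, one-sided density scaling in T^2/Hz. The
#' per-window power estimates can be retained; the bootstrap activation
#' threshold at the source level resamples exactly these windows.
#'
#' @param rec A [recording()] or a numeric vector (then `fs` required).
#' @param window_length Window length in seconds; the frequency spacing of
#'   the estimate is `1/window_length`.
#' @param overlap Window overlap fraction.
#' @param window Taper: `"hamming"` or `"kaiser"`.
#' @param keep_windows Keep per-window power (channels x freqs x windows)?
#' @param kaiser_beta Kaiser shape, used when `window = "kaiser"`.
#' @param fs Sampling rate of the vector form.
#' @return An object of class `spectrum_estimate`: `freqs` (Hz), `power`
#'   (channels x freqs, T^2/Hz), window metadata, `n_windows`, and
#'   optionally `per_window_power`.
#' @export
welch_psd <- function(rec, window_length = 4, overlap = 0.5,
                      window = c("hamming", "kaiser"), keep_windows = FALSE,
                      kaiser_beta = 14, fs = NULL) {
  window <- match.arg(window)
  x <- if (inherits(rec, "recording")) rec$data else
    matrix(rec, nrow = 1)
  if (inherits(rec, "recording")) fs <- rec$fs
  if (is.null(fs)) stop("fs is required for the vector form")
  nwin <- round(window_length * fs)
  if (ncol(x) < nwin) stop("recording shorter than one Welch window")
  hop <- round(nwin * (1 - overlap))
  starts <- seq(1, ncol(x) - nwin + 1, by = hop)
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1)),
    kaiser = kaiser_window(nwin, kaiser_beta)
  )
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nwin %/% 2 + 1
  freqs <- (seq_len(nfreq) - 1) / window_length
  acc <- matrix(0, nrow(x), nfreq)
  per_win <- if (keep_windows) {
    array(NA_real_, c(nrow(x), nfreq, length(starts)))
  }
  for (j in seq_along(starts)) {
    seg <- x[, seq(starts[j], starts[j] + nwin - 1), drop = FALSE]
    seg <- seg * matrix(w, nrow(seg), nwin, byrow = TRUE)
    co <- t(stats::mvfft(t(seg)))[, seq_len(nfreq), drop = FALSE]
    p <- (Mod(co)^2) * scale
    p[, -1] <- 2 * p[, -1]
    if (nwin %% 2 == 0) p[, nfreq] <- p[, nfreq] / 2
    acc <- acc + p
    if (keep_windows) per_win[, , j] <- p
  }
  structure(
    list(freqs = freqs, power = acc / length(starts),
         window_length = window_length, overlap = overlap,
         window_kind = window, n_windows = length(starts),
         per_window_power = per_win, fs = fs),
    class = "spectrum_estimate"
  )
}

kaiser_window <- function(n, beta) {
  k <- seq(0, n - 1)
  besselI(beta * sqrt(pmax(0, 1 - (2 * k / (n - 1) - 1)^2)), 0) /
    besselI(beta, 0)
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectrum_estimate> %d ch x %d freqs (0-%g Hz, df %g Hz), %d windows (%s)\n",
    nrow(x$power), length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1],
    x$n_windows, x$window_kind))
  invisible(x)
}

#' Band-averaged log power per channel
#'
#' For each channel, the mean of `log10(power)` over the frequency bins
#' inside the band. Bands may be unions of intervals with exclusions, e.g.
#' the movement band 1-15 Hz excluding 11.5-12.5 Hz; see [band_spec()].
#'
#' @param spec A [welch_psd()] estimate.
#' @param band A [band_spec()], or a length-2 numeric interval.
#' @return A list of class `band_power` with `band`, `pi` (per-channel
#'   averaged log power), `n_channels` and the bin count used.
#' @export
band_log_power <- function(spec, band) {
  band <- as_band_spec(band)
  sel <- band_bins(spec$freqs, band)
  if (!any(sel)) stop("band does not overlap the frequency axis")
  lp <- log10(spec$power[, sel, drop = FALSE])
  structure(
    list(band = band, pi = rowMeans(lp), n_channels = nrow(spec$power),
         n_bins = sum(sel)),
    class = "band_power"
  )
}

#' Frequency band with optional exclusions
#'
#' @param include Numeric vector `c(lo, hi)` or 2-column matrix of included
#'   intervals (Hz, inclusive).
#' @param exclude Optional interval(s) removed from the band.
#' @param label Optional label.
#' @return A `band_spec` object.
#' @export
band_spec <- function(include, exclude = NULL, label = NULL) {
  as_mat <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) x else matrix(x, ncol = 2, byrow = TRUE)
  }
  structure(list(include = as_mat(include), exclude = as_mat(exclude),
                 label = label),
            class = "band_spec")
}

as_band_spec <- function(band) {
  if (inherits(band, "band_spec")) band else band_spec(band)
}

band_bins <- function(freqs, band) {
  in_any <- function(intervals) {
    if (is.null(intervals)) return(rep(FALSE, length(freqs)))
    sel <- rep(FALSE, length(freqs))
    for (r in seq_len(nrow(intervals))) {
      sel <- sel | (freqs >= intervals[r, 1] & freqs <= intervals[r, 2])
    }
    sel
  }
  in_any(band$include) & !in_any(band$exclude)
}

# Channel-mean log10 Welch spectrum; the canonical quantity used both for
# stimulation-gain calibration and for spectrum figures.
channel_mean_log_spectrum <- function(spec) {
  list(freqs = spec$freqs, logp = log10(colMeans(spec$power)))
}
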