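#' Biphasic DBS pulse train at the internal rendering rate
#'
#' Renders the "analog" stimulation waveform: a charge-balanced biphasic
#' rectangular pulse train at `f_stim` with the configured single-phase
#' width, at `fs_internal`. Because the pulse period is not an integer
#' number of output samples, later decimation samples the pulses
#' inconsistently, which is what creates aliased spectral peaks.
#'
#' @param config A [sim_config()].
#' @return Numeric waveform (arbitrary units) of length
#'   `round(duration * fs_internal)`.
#' @export
simulate_dbs_train <- function(config) {
  fs <- config$fs_internal
  n <- round(config$duration * fs)
  w <- max(1L, round(config$pulse_width * fs))
  train <- numeric(n)
  onsets <- round(seq(0, config$duration, by = 1 / config$f_stim) * fs) + 1
  onsets <- onsets[onsets + 2 * w - 1 <= n]
  for (o in onsets) {
    train[o:(o + w - 1)] <- 1
    train[(o + w):(o + 2 * w - 1)] <- -1
  }
  train
}

#' Movement (pneumatic tube) displacement waveform
#'
#' Periodic events every `move_period` seconds: a raised-cosine rise over
#' `move_rise` to `move_amplitude`, then an exponential-like decay whose
#' duration is drawn uniformly from `move_jitter` (seeded). The resulting
#' spectrum is concentrated below 15 Hz and strongest below 5 Hz.
#'
#' @param config A [sim_config()].
#' @return Displacement waveform in metres at `fs_out`.
#' @export
simulate_movement_waveform <- function(config) {
  fs <- config$fs_out
  n <- round(config$duration * fs)
  if (config$duration < config$move_period) {
    stop("duration must cover at least one movement period")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream(config$seed, 4))
  onsets <- seq(0, config$duration - 1e-9, by = config$move_period)
  durs <- stats::runif(length(onsets), config$move_jitter[1],
                       config$move_jitter[2])
  wave <- numeric(n)
  A <- config$move_amplitude
  for (k in seq_along(onsets)) {
    i0 <- round(onsets[k] * fs)
    nr <- max(2L, round(config$move_rise * fs))
    nd <- round(durs[k] * fs)
    tr <- seq_len(nr) / nr
    rise <- A * 0.5 * (1 - cos(pi * tr))
    td <- seq_len(nd) / nd
    decay <- A * exp(-5 * td) * 0.5 * (1 + cos(pi * td))
    ev <- c(rise, decay)
    idx <- i0 + seq_along(ev)
    keep <- idx <= n
    wave[idx[keep]] <- wave[idx[keep]] + ev[keep]
  }
  wave
}

# The stimulation waveform as seen at fs_out: analog train -> weak
# 4th-order Butterworth anti-alias low-pass at 0.4*fs_intermediate ->
# subsample to fs_intermediate (this stage folds high pulse harmonics into
# the band) -> sharp polyphase decimation to fs_out.
stim_waveform_fs_out <- function(config) {
  train <- simulate_dbs_train(config)
  ba <- signal::butter(4, 0.4 * config$fs_intermediate /
                         (config$fs_internal / 2))
  filt <- filtfilt_reflect(ba$b, ba$a, train)
  q1 <- config$fs_internal / config$fs_intermediate
  acq <- filt[seq(1, length(filt), by = q1)]
  downsample(acq, config$fs_out, fs = config$fs_intermediate)
}

# Fixed spatial patterns and seeded noise streams shared by all conditions
# of one configuration. Streams are drawn in a fixed order from substreams
# of the master seed, so that every condition built from the same config
# sees bit-identical noise, line phases, wire topography and movement
# jitter (this is what makes the condition-set linearity exact).
sim_components <- function(config, sensors, include_stim = TRUE) {
  n <- round(config$duration * config$fs_out)
  nch <- n_sensors(sensors)
  t <- seq_len(n) / config$fs_out

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  set.seed(substream(config$seed, 1))
  noise <- matrix(
    stats::rnorm(nch * n, sd = config$sensor_noise_asd *
                   sqrt(config$fs_out / 2)),
    nch, n)

  set.seed(substream(config$seed, 2))
  harmonics <- seq(config$line_freq,
                   min(config$line_max, 0.999 * config$fs_out / 2),
                   by = config$line_freq)
  line_topo <- matrix(stats::rnorm(nch * length(harmonics)), nch)
  line_topo <- sweep(line_topo, 2, sqrt(colSums(line_topo^2)), "/")
  phases <- stats::runif(length(harmonics), 0, 2 * pi)
  amps <- config$line_amp / seq_along(harmonics)
  line_waves <- matrix(0, length(harmonics), n)
  for (k in seq_along(harmonics)) {
    line_waves[k, ] <- amps[k] * sin(2 * pi * harmonics[k] * t + phases[k])
  }
  ambient <- noise + line_topo %*% line_waves

  set.seed(substream(config$seed, 3))
  wire_topo <- smooth_posterior_topography(sensors)

  move <- simulate_movement_waveform(config)

  R <- sensors$sphere_radius
  dip_pos <- c(0, 0, config$dipole_rel_depth * R)
  dip_topo <- dipole_field(dip_pos, config$dipole_moment * c(1, 0, 0),
                           sensors)
  dip_wave <- sin(2 * pi * config$f_dipole * t)

  stim <- NULL
  if (include_stim) {
    elec_pos <- 0.45 * R * c(0.8, -0.4, 0.45) /
      sqrt(sum(c(0.8, -0.4, 0.45)^2))
    elec_field <- dipole_field(elec_pos, c(0, 1e-8, 1e-8), sensors)
    elec_field <- elec_field / sqrt(sum(elec_field^2))
    topo <- (1 - config$wire_stim_mix) * elec_field +
      config$wire_stim_mix * wire_topo
    stim <- list(topo = topo / sqrt(sum(topo^2)),
                 wave = stim_waveform_fs_out(config))
  }

  list(t = t, ambient = ambient, wire_topo = wire_topo, move = move,
       dip_pos = dip_pos, dip_topo = dip_topo, dip_wave = dip_wave,
       stim = stim)
}

# Smooth random topography concentrated on the posterior-most sensors
# (where the extension wires are taped). Must be called with the RNG
# already seeded.
smooth_posterior_topography <- function(sensors) {
  pos <- sensors$positions
  raw <- stats::rnorm(nrow(pos))
  d2 <- as.matrix(stats::dist(pos))^2
  sm <- drop(exp(-d2 / (2 * 0.03^2)) %*% raw)
  y <- pos[, 2]
  w <- exp(-3 * (y - min(y)) / (max(y) - min(y)))
  topo <- sm * w
  topo / sqrt(sum(topo^2))
}

#' Simulate one phantom recording
#'
#' Sums the enabled source terms projected through the spherical forward
#' model: the 12 Hz dipole, the stimulation term (under-sampled DBS pulse
#' train through a fixed electrode + wire topography), and the
#' movement-coupled wire artefact. White sensor noise and fixed-topography
#' line-noise harmonics are always present. When both stimulation and
#' movement are enabled the stimulation term is additionally modulated by
#' `(1 + displacement / move_amplitude)`, coupling the two artefacts.
#'
#' @param config A [sim_config()]. `stim_gain` must be set (or stimulation
#'   disabled); [make_condition_set()] calibrates it automatically.
#' @param sensors A [make_sensor_array()]; defaults to the array implied by
#'   `config`.
#' @param include Character subset of `c("dipole", "stim",
#'   "movement_wire")`; empty means an empty-room recording.
#' @return A [recording()] whose condition label reflects the enabled
#'   sources.
#' @export
acquire <- function(config, sensors = NULL,
                    include = c("dipole", "stim", "movement_wire")) {
  if (is.null(sensors)) sensors <- config_sensors(config)
  stopifnot(all(include %in% c("dipole", "stim", "movement_wire")))
  want_stim <- "stim" %in% include
  comp <- sim_components(config, sensors, include_stim = want_stim)
  data <- comp$ambient
  if ("dipole" %in% include) {
    data <- data + tcrossprod(comp$dip_topo, comp$dip_wave)
  }
  if ("movement_wire" %in% include) {
    data <- data + config$wire_gain * tcrossprod(comp$wire_topo, comp$move)
  }
  if (want_stim) {
    g <- config$stim_gain
    if (is.null(g)) stop("config$stim_gain is not set; run calibrate_stim_gain")
    wave <- comp$stim$wave
    if ("movement_wire" %in% include) {
      wave <- wave * (1 + comp$move / config$move_amplitude)
    }
    data <- data + g * tcrossprod(comp$stim$topo, wave)
  }
  condition <- if (length(include) == 0) "empty_room"
  else if (setequal(include, c("dipole", "stim", "movement_wire"))) "dsmw"
  else if (setequal(include, c("dipole", "movement_wire"))) "dmw"
  else "reference"
  recording(data, config$fs_out, sensors, condition)
}

config_sensors <- function(config) {
  make_sensor_array(config$n_channels, config$helmet_radius,
                    seed = substream(config$seed, 0),
                    sphere_radius = config$sphere_radius)
}

#' Calibrate the stimulation gain against the dipole peak
#'
#' Finds the stimulation gain at which, in the channel-mean Welch log10
#' spectrum of a DSMW simulation, the DBS peak exceeds the 12 Hz dipole
#' peak by `target_log_ratio` (default 1.75 log10-power units, the ratio
#' observed between DBS and alpha peaks in patient recordings). The search
#' starts from a closed-form guess based on the component spectra and is
#' refined by bisection on log-gain against the fully recombined
#' recording's measured ratio.
#'
#' @param config A [sim_config()].
#' @param sensors Optional sensor array (defaults to the config's).
#' @param tol Acceptable deviation of the realized ratio from the target.
#' @return The gain (Tesla), with the realized ratio attached as attribute
#'   `"realized_ratio"`.
#' @export
calibrate_stim_gain <- function(config, sensors = NULL, tol = 0.02) {
  if (is.null(sensors)) sensors <- config_sensors(config)
  comp <- sim_components(config, sensors, include_stim = TRUE)
  base <- comp$ambient + tcrossprod(comp$dip_topo, comp$dip_wave) +
    config$wire_gain * tcrossprod(comp$wire_topo, comp$move)
  wave_c <- comp$stim$wave * (1 + comp$move / config$move_amplitude)

  spec_base <- welch_psd(recording(base, config$fs_out, sensors, "dsmw"))
  p_base <- colMeans(spec_base$power)
  spec_wave <- welch_psd(wave_c, fs = config$fs_out)
  # rank-1 stim term with unit-norm topography: channel-mean PSD is
  # PSD(wave)/n_channels
  p_stim1 <- drop(spec_wave$power) / n_sensors(sensors)
  freqs <- spec_base$freqs

  dip_sel <- freqs >= config$f_dipole - 0.5 & freqs <= config$f_dipole + 0.5
  dbs_sel <- freqs >= config$f_stim - 5 & freqs <= config$f_stim + 5
  p_dip <- max(p_base[dip_sel])
  i_dbs <- which(dbs_sel)[which.max(p_stim1[dbs_sel])]
  target_p <- p_dip * 10^config$target_log_ratio
  g2 <- (target_p - p_base[i_dbs]) / p_stim1[i_dbs]
  if (!is.finite(g2) || g2 <= 0) {
    stop("calibration target is not bracketed: the DSMW background at the ",
         "DBS peak already exceeds the target power (p_base = ",
         signif(p_base[i_dbs], 3), ", target = ", signif(target_p, 3), ")")
  }
  g <- sqrt(g2)

  measured <- function(gain) {
    rec <- recording(base + gain * tcrossprod(comp$stim$topo, wave_c),
                     config$fs_out, sensors, "dsmw")
    stim_dipole_log_ratio(rec, f_dipole = config$f_dipole,
                          search = c(config$f_stim - 5, config$f_stim + 5))
  }
  r <- measured(g)
  if (abs(r - config$target_log_ratio) > tol) {
    lo <- g / 4; hi <- g * 4
    r_lo <- measured(lo); r_hi <- measured(hi)
    if ((r_lo - config$target_log_ratio) * (r_hi - config$target_log_ratio) > 0) {
      stop("bisection bracket failed: ratio(", signif(lo, 3), ") = ",
           round(r_lo, 3), ", ratio(", signif(hi, 3), ") = ", round(r_hi, 3))
    }
    for (it in 1:40) {
      g <- sqrt(lo * hi)
      r <- measured(g)
      if (abs(r - config$target_log_ratio) <= tol) break
      if (r < config$target_log_ratio) lo <- g else hi <- g
    }
  }
  attr(g, "realized_ratio") <- r
  g
}

#' Measured DBS-to-dipole log-power ratio of a recording
#'
#' Channel-mean Welch log10 spectrum; returns (peak log power in the DBS
#' search interval) minus (peak log power within +/- 0.5 Hz of the dipole
#' frequency).
#'
#' @param rec A [recording()].
#' @param f_dipole Dipole frequency, Hz.
#' @param search DBS peak search interval, Hz.
#' @return Dimensionless log10-power difference.
#' @export
stim_dipole_log_ratio <- function(rec, f_dipole = 12,
                                  search = c(125, 135)) {
  sp <- channel_mean_log_spectrum(welch_psd(rec))
  dip <- max(sp$logp[sp$freqs >= f_dipole - 0.5 & sp$freqs <= f_dipole + 0.5])
  dbs <- max(sp$logp[sp$freqs >= search[1] & sp$freqs <= search[2]])
  dbs - dip
}

#' Generate the four linked phantom conditions
#'
#' Builds Reference (dipole only), DMW (dipole + movement + wires), DSMW
#' (all artefact sources) and empty-room recordings from shared
#' seed-derived noise streams, so that exactly
#' `dsmw = reference + stim + movement + coupling` holds sample for
#' sample, plus the DBS reference channel (the movement-coupled
#' stimulation waveform with a small 12 Hz dipole leakage).
#'
#' @param config A [sim_config()]. If `stim_gain` is `NULL` it is
#'   calibrated first.
#' @return An object of class `condition_set` with elements `reference`,
#'   `dmw`, `dsmw`, `empty_room` (recordings), `dbs_reference_channel`,
#'   `sensors`, `stim_gain` and `config`.
#' @export
make_condition_set <- function(config) {
  sensors <- config_sensors(config)
  if (is.null(config$stim_gain)) {
    config$stim_gain <- as.numeric(calibrate_stim_gain(config, sensors))
  }
  comp <- sim_components(config, sensors, include_stim = TRUE)

  empty <- comp$ambient
  ref <- empty + tcrossprod(comp$dip_topo, comp$dip_wave)
  dmw <- ref + config$wire_gain * tcrossprod(comp$wire_topo, comp$move)
  wave_c <- comp$stim$wave * (1 + comp$move / config$move_amplitude)
  dsmw <- dmw + config$stim_gain * tcrossprod(comp$stim$topo, wave_c)

  leak <- config$dipole_leak * stats::sd(wave_c) * sqrt(2) * comp$dip_wave
  ref_chan <- wave_c + leak

  structure(
    list(
      reference = recording(ref, config$fs_out, sensors, "reference"),
      dmw = recording(dmw, config$fs_out, sensors, "dmw"),
      dsmw = recording(dsmw, config$fs_out, sensors, "dsmw"),
      empty_room = recording(empty, config$fs_out, sensors, "empty_room"),
      dbs_reference_channel = ref_chan,
      sensors = sensors,
      stim_gain = config$stim_gain,
      config = config
    ),
    class = "condition_set"
  )
}

#' @export
print.condition_set <- function(x, ...) {
  cat(sprintf(
    "<condition_set> %d ch x %d samples @ %g Hz, stim gain %.3g T, seed %d\n",
    nrow(x$dsmw$data), ncol(x$dsmw$data), x$config$fs_out, x$stim_gain,
    x$config$seed))
  invisible(x)
}
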