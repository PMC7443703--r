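#' Simulation configuration for the phantom study
#'
#' Bundles every tunable of the synthetic phantom: the 12 Hz dipole, the
#' DBS pulse train (130 Hz bipolar, 140 us pulses) with its deliberately
#' under-sampled acquisition chain, the pneumatic movement events (every
#' 2.5 s, ~40 ms rise to ~3 mm, 0.5-1 s decay), wire artefact coupling,
#' line noise and sensor noise. Defaults reproduce the study conditions at
#' a 128-channel, 120 s, 2400 Hz desk scale.
#'
#' @param n_channels Sensors in the simulated helmet array.
#' @param helmet_radius Sensor shell radius, metres.
#' @param sphere_radius Conducting phantom sphere radius, metres.
#' @param f_dipole Dipole oscillation frequency, Hz.
#' @param dipole_rel_depth Dipole distance from the sphere centre as a
#'   fraction of `sphere_radius` (placed on the z axis, tangential moment).
#' @param dipole_moment Dipole moment amplitude, ampere-metres.
#' @param f_stim DBS stimulation frequency, Hz.
#' @param pulse_width Single-phase pulse width, seconds.
#' @param move_period Movement event period, seconds.
#' @param move_rise Rise time of a movement event, seconds.
#' @param move_jitter Range (seconds) of the uniformly drawn per-event
#'   decay duration.
#' @param move_amplitude Peak vertical displacement, metres.
#' @param duration Recording length, seconds.
#' @param fs_internal Rate at which the analog pulse train is rendered, Hz.
#' @param fs_intermediate Acquisition rate of the simulated electronics,
#'   Hz; the 4th-order anti-alias filter of the acquisition chain cuts at
#'   0.4 times this rate, so pulse harmonics above Nyquist fold back and
#'   produce aliased peaks.
#' @param fs_out Output (post-decimation) sampling rate, Hz.
#' @param target_log_ratio Calibration target: channel-mean log10 power at
#'   the DBS peak minus at the dipole peak in the DSMW condition.
#' @param line_freq Power-line fundamental, Hz.
#' @param line_max Highest line harmonic simulated, Hz.
#' @param line_amp Line-noise amplitude at the fundamental, Tesla.
#' @param sensor_noise_asd White sensor noise amplitude spectral density,
#'   Tesla per sqrt(Hz).
#' @param wire_gain Wire-artefact field per metre of displacement, Tesla/m.
#'   The default makes DMW channel-mean power below 5 Hz roughly 10x the
#'   Reference level.
#' @param wire_stim_mix Fraction of the stimulation topography contributed
#'   by the extension-wire path (the remainder is the intracranial bipolar
#'   electrode dipole).
#' @param stim_gain Stimulation field gain, Tesla; `NULL` means calibrate
#'   with [calibrate_stim_gain()] when a condition set is built.
#' @param dipole_leak Fractional 12 Hz leakage into the DBS reference
#'   channel.
#' @param seed Integer master seed; every random component draws from a
#'   substream derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 128,
                       helmet_radius = 0.12,
                       sphere_radius = 0.075,
                       f_dipole = 12,
                       dipole_rel_depth = 0.6,
                       dipole_moment = 2e-8,
                       f_stim = 130,
                       pulse_width = 140e-6,
                       move_period = 2.5,
                       move_rise = 0.040,
                       move_jitter = c(0.5, 1.0),
                       move_amplitude = 3e-3,
                       duration = 120,
                       fs_internal = 192000,
                       fs_intermediate = 19200,
                       fs_out = 2400,
                       target_log_ratio = 1.75,
                       line_freq = 50,
                       line_max = 550,
                       line_amp = 1.2e-13,
                       sensor_noise_asd = 1e-14,
                       wire_gain = 1.8e-9,
                       wire_stim_mix = 0.5,
                       stim_gain = NULL,
                       dipole_leak = 0.05,
                       seed = 1) {
  cfg <- as.list(environment())
  if (cfg$fs_internal %% cfg$fs_intermediate != 0) {
    stop("fs_internal must be an integer multiple of fs_intermediate")
  }
  if (cfg$fs_intermediate %% cfg$fs_out != 0) {
    stop("fs_intermediate must be an integer multiple of fs_out")
  }
  if (cfg$pulse_width >= 1 / cfg$f_stim) {
    stop("pulse_width must be shorter than the stimulation period")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d ch, %g s @ %g Hz | dipole %g Hz, stim %g Hz (%g us), move every %g s, seed %d\n",
    x$n_channels, x$duration, x$fs_out, x$f_dipole, x$f_stim,
    x$pulse_width * 1e6, x$move_period, x$seed))
  invisible(x)
}
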