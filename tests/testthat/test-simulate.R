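test_that("DBS pulse train has the configured rate, bipolar symmetry and harmonics", {
  cfg <- sim_config(n_channels = 32, duration = 2, seed = 1)
  tr <- simulate_dbs_train(cfg)
  onsets <- sum(diff(tr[seq_len(cfg$fs_internal)] > 0.5) == 1) +
    (tr[1] > 0.5)
  expect_equal(onsets, 130)
  expect_equal(mean(tr), 0)

  # FFT oracle: spectral peaks of the analytic train sit at k * 130 Hz
  n <- length(tr)
  P <- Mod(stats::fft(tr)[seq_len(n %/% 2)])^2
  f <- (seq_len(n %/% 2) - 1) * cfg$fs_internal / n
  sel <- f > 50 & f < 2000
  pk <- which(P[sel] > 0.25 * max(P[sel]))
  expect_true(all(abs((f[sel][pk] + 65) %% 130 - 65) < 1.5))
})

test_that("movement waveform: event count, amplitude and low-frequency content", {
  cfg <- sim_config(n_channels = 32, duration = 120, seed = 4)
  mv <- simulate_movement_waveform(cfg)
  expect_equal(sum(diff(mv > 0.5 * cfg$move_amplitude) == 1), 48)
  expect_equal(max(mv), cfg$move_amplitude, tolerance = 1e-6)
  sp <- welch_psd(mv - mean(mv), fs = cfg$fs_out)
  p <- drop(sp$power)
  expect_gt(sum(p[sp$freqs <= 5]) / sum(p), 0.6)
  expect_gt(sum(p[sp$freqs <= 15]) / sum(p), 0.95)
  expect_error(simulate_movement_waveform(
    sim_config(duration = 1, seed = 1)), "movement period")
})

test_that("acquisition chain aliases the pulse train unless f_stim divides fs", {
  cfg <- sim_config(n_channels = 32, duration = 10, seed = 1)
  aliased_peaks <- function(f_stim) {
    cfg$f_stim <- f_stim
    sw <- megdbs:::stim_waveform_fs_out(cfg)
    sp <- welch_psd(sw, fs = cfg$fs_out)
    p <- drop(sp$power)
    pk <- which(p > 50 * stats::median(p) &
                  p > c(0, utils::head(p, -1)) &
                  p > c(utils::tail(p, -1), 0))
    fp <- sp$freqs[pk]
    half <- f_stim / 2
    sum(abs((fp + half) %% f_stim - half) > 2)
  }
  expect_gt(aliased_peaks(130), 0)    # 19200 / 130 is not an integer
  expect_equal(aliased_peaks(150), 0) # 19200 / 150 = 128 exactly
})

test_that("condition set: construction identities and spectra", {
  cfg <- small_config()
  set <- small_set()
  comp <- megdbs:::sim_components(cfg, set$sensors, include_stim = TRUE)

  # reference = empty room + dipole term, exactly (shared noise streams)
  dip <- tcrossprod(comp$dip_topo, comp$dip_wave)
  expect_lt(max(abs(set$reference$data - set$empty_room$data - dip)),
            1e-12 * max(abs(set$reference$data)))

  # linearity: dsmw = reference + movement + stim + coupling, exactly
  wave_c <- comp$stim$wave * (1 + comp$move / cfg$move_amplitude)
  recon <- set$reference$data +
    cfg$wire_gain * tcrossprod(comp$wire_topo, comp$move) +
    cfg$stim_gain * tcrossprod(comp$stim$topo, wave_c)
  expect_lt(max(abs(recon - set$dsmw$data)),
            1e-12 * max(abs(set$dsmw$data)))

  # all conditions share length, fs, sensors
  for (cond in c("dmw", "dsmw", "empty_room")) {
    expect_equal(dim(set[[cond]]$data), dim(set$reference$data))
    expect_equal(set[[cond]]$fs, set$reference$fs)
  }
  expect_equal(length(set$dbs_reference_channel), ncol(set$dsmw$data))

  # reproducibility: identical config => bit-identical set
  set2 <- make_condition_set(cfg)
  expect_identical(set$dsmw$data, set2$dsmw$data)
  expect_identical(set$dbs_reference_channel, set2$dbs_reference_channel)
})

test_that("condition spectra show the study's features", {
  set <- small_set()
  sp_ref <- mean_log_spec(set$reference)
  sp_dmw <- mean_log_spec(set$dmw)
  sp_dsmw <- mean_log_spec(set$dsmw)
  sp_emp <- mean_log_spec(set$empty_room)
  f <- sp_ref$freqs

  # empty room: flat except line harmonics (compare two line-free bands)
  flat1 <- mean(sp_emp$logp[f > 20 & f < 45])
  flat2 <- mean(sp_emp$logp[f > 200 & f < 245 & abs(f %% 50) > 5])
  expect_lt(abs(flat1 - flat2), 0.1)
  i50 <- which(f == 50)
  expect_gt(sp_emp$logp[i50], flat1 + 0.5)

  # reference: single clear peak at 12 Hz
  local_bg <- stats::median(sp_ref$logp[f > 8 & f < 16 & abs(f - 12) > 1])
  expect_gt(sp_ref$logp[f == 12], local_bg + 1)

  # DMW: low-frequency power elevated ~10x below 5 Hz, strongest there
  lo <- f >= 1 & f <= 5
  ratio <- 10^(mean(sp_dmw$logp[lo]) - mean(sp_ref$logp[lo]))
  expect_gt(ratio, 3)
  expect_lt(ratio, 40)

  # DSMW: 12 Hz peak, elevated low frequencies, 130 Hz peak, and at
  # least one aliased peak away from the stimulation harmonics
  expect_gt(sp_dsmw$logp[f == 12],
            stats::median(sp_dsmw$logp[f > 8 & f < 16 & abs(f - 12) > 1]) + 1)
  expect_gt(mean(sp_dsmw$logp[lo]),
            mean(sp_dsmw$logp[f > 5 & f <= 15 & abs(f - 12) > 1]) + 0.3)
  expect_gt(sp_dsmw$logp[f == 130], stats::median(sp_dsmw$logp) + 1)
  bg <- stats::median(sp_dsmw$logp)
  alias <- f > 20 & f < 1100 & abs((f + 65) %% 130 - 65) > 3 &
    pmin(f %% 50, 50 - f %% 50) > 2 & sp_dsmw$logp > bg + 1
  expect_gt(sum(alias), 0)
})

test_that("stimulation gain calibration hits its target ratio", {
  cfg <- small_config()
  expect_equal(attr(calibrate_stim_gain(cfg), "realized_ratio"), 1.75,
               tolerance = 0.06)
  # target 0: DBS and dipole peaks equal within tolerance
  cfg0 <- cfg
  cfg0$target_log_ratio <- 0
  cfg0$stim_gain <- NULL
  g0 <- calibrate_stim_gain(cfg0)
  expect_lt(abs(attr(g0, "realized_ratio")), 0.1)
})

test_that("DBS reference channel carries 12 Hz leakage until notched", {
  set <- small_set()
  fs <- set$config$fs_out
  # central segment (zero-phase notch edge transients excluded)
  mid <- seq(round(5 * fs), length(set$dbs_reference_channel) - round(5 * fs))
  prom <- function(x) {
    sp <- welch_psd(x[mid], fs = fs)
    l <- log10(drop(sp$power))
    nb <- abs(sp$freqs - 12) > 0.3 & abs(sp$freqs - 12) <= 1.5
    l[sp$freqs == 12] - stats::median(l[nb])
  }
  before <- prom(set$dbs_reference_channel)
  after <- prom(notch_filter(set$dbs_reference_channel, 12, 12, fs = fs))
  expect_gt(before, 2)
  expect_lt(after, 1)
})
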