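# Shared fixtures, built once per test run and memoized. The small
# condition set is a reduced-scale version of the study conditions
# (fewer channels, shorter duration) used by the module tests; the
# acceptance tests build their own sets at the scales they state.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_config <- function() {
  memo("small_config", {
    cfg <- sim_config(n_channels = 32, duration = 30, seed = 7)
    cfg$stim_gain <- as.numeric(calibrate_stim_gain(cfg))
    cfg
  })
}

small_set <- function() {
  memo("small_set", make_condition_set(small_config()))
}

small_arr <- function() memo("small_arr", make_sensor_array(32, seed = 1))

# Free-space magnetic field of a current dipole (Biot-Savart law); the
# oracle for the radial field component of the conducting-sphere model,
# whose volume currents contribute no radial field.
biot_savart_dipole <- function(r, r0, Q) {
  a <- r - r0
  1e-7 * cross3_oracle(Q, a) / sum(a^2)^1.5
}

cross3_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Magnetic scalar potential of a dipole in a conducting sphere; the full
# vector field oracle is its numerical gradient, B = -mu0 * grad(U) with
# U(r) = -(Q x r0 . r) / (4 pi F).
sphere_potential_field <- function(r, r0, Q, h = 1e-7) {
  U <- function(p) {
    a <- p - r0
    an <- sqrt(sum(a^2))
    rn <- sqrt(sum(p^2))
    F <- an * (rn * an + rn^2 - sum(r0 * p))
    -sum(cross3_oracle(Q, r0) * p) / (4 * pi * F)
  }
  g <- vapply(1:3, function(k) {
    e <- numeric(3)
    e[k] <- h
    (U(r + e) - U(r - e)) / (2 * h)
  }, numeric(1))
  -4 * pi * 1e-7 * g
}

# Welch of a numeric vector, channel-mean log10 spectrum of a recording.
mean_log_spec <- function(rec) {
  sp <- welch_psd(rec)
  list(freqs = sp$freqs, logp = log10(colMeans(sp$power)))
}

tsss_arr <- function() memo("tsss_arr", make_sensor_array(128, seed = 5))

source_fixture <- function() {
  memo("source_fixture", {
    arr <- make_sensor_array(64, seed = 3)
    grid <- build_grid(arr, 7.5e-3)
    lf <- compute_leadfield(grid, arr)
    fs <- 600
    t <- seq(1 / fs, 40, by = 1 / fs)
    v <- which.min(colSums((t(grid$points) - c(0.01, -0.005, 0.03))^2))
    set.seed(51)
    sig <- tcrossprod(dipole_field(grid$points[v, ], c(0, 2e-8, 0), arr),
                      sin(2 * pi * 12 * t)) +
      matrix(rnorm(64 * length(t), sd = 2e-14), 64)
    rec <- recording(sig, fs, arr, "reference")
    dc <- regularize_cov(tcrossprod(sig) / ncol(sig))
    nc <- regularize_cov(diag(2e-14^2 * fs / 2, 64))
    w <- lcmv_weights(dc, nc, lf)
    list(arr = arr, grid = grid, lf = lf, rec = rec, v = v, w = w)
  })
}

hampel_fixture <- function() {
  memo("hampel_fixture", {
    fs <- 1200
    arr <- small_arr()
    t <- seq(1 / fs, 40, by = 1 / fs)
    set.seed(21)
    dat <- matrix(rnorm(32 * length(t), sd = 1e-13), 32)
    dat[5, ] <- dat[5, ] + 3e-12 * sin(2 * pi * 130 * t)
    recording(dat, fs, arr, "dsmw")
  })
}

s3p_fixture <- function() {
  memo("s3p_fixture", {
    fs <- 1200
    arr <- small_arr()
    t <- seq(1 / fs, 40, by = 1 / fs)
    set.seed(31)
    topo <- rnorm(32)
    topo <- topo / sqrt(sum(topo^2))
    dat <- matrix(rnorm(32 * length(t), sd = 1e-15), 32) +
      tcrossprod(topo, 3e-12 * sin(2 * pi * 130 * t))
    list(rec = recording(dat, fs, arr, "dsmw"), topo = topo)
  })
}

ica_fixture <- function() {
  memo("ica_fixture", {
    fs <- 600
    arr <- make_sensor_array(32, seed = 2)
    t <- seq(1 / fs, 60, by = 1 / fs)
    set.seed(42)
    # spiky pulse-train-like reference, as a DBS reference channel is
    ref <- ifelse((t %% 0.5) < 0.02, 1, 0) * sign(sin(2 * pi * 3 * t)) +
      0.05 * rnorm(length(t))
    S_true <- matrix(rnorm(32 * length(t)), 32)
    S_true[7, ] <- 3 * as.numeric(scale(ref))
    A <- matrix(rnorm(32 * 32), 32)
    list(rec = recording((A %*% S_true) * 1e-13, fs, arr, "dsmw"),
         ref = ref)
  })
}
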