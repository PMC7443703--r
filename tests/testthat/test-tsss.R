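test_that("multipole basis dimensions and source-separation fits", {
  arr <- tsss_arr()
  S <- sss_basis(arr, 8, 3)
  expect_equal(attr(S, "n_in"), 80)
  expect_equal(attr(S, "n_out"), 15)
  expect_equal(dim(S), c(128, 95))

  # interior dipole: inner basis alone fits to < 1%
  b <- dipole_field(c(0, 0, 0.045), c(1e-8, 0, 0), arr)
  res_in <- qr.resid(qr(S[, 1:80]), b)
  expect_lt(sqrt(sum(res_in^2) / sum(b^2)), 0.01)
  # joint fit keeps the interior field in the inner part
  co <- qr.coef(qr(S), b)
  B_out <- S[, 81:95] %*% co[81:95]
  expect_lt(sqrt(sum(B_out^2) / sum(b^2)), 0.05)

  # distant exterior dipole (>= 5 helmet radii): outer fit < 5%,
  # inner field contribution small after the joint fit
  r_ext <- c(0.9, 0.3, 0.2)
  bx <- vapply(seq_len(128), function(i) {
    sum(biot_savart_dipole(arr$positions[i, ], r_ext,
                           c(1e-6, 2e-6, -1e-6)) * arr$orientations[i, ])
  }, numeric(1))
  expect_lt(sqrt(sum(qr.resid(qr(S[, 81:95]), bx)^2) / sum(bx^2)), 0.05)
  co2 <- qr.coef(qr(S), bx)
  B_in2 <- S[, 1:80] %*% co2[1:80]
  expect_lt(sqrt(sum(B_in2^2) / sum(bx^2)), 0.15)

  expect_error(sss_basis(make_sensor_array(64, seed = 1), 8, 3),
               "fewer channels")
})

test_that("tSSS reproduces a noiseless interior dipole for any correlation limit", {
  arr <- tsss_arr()
  fs <- 300
  t <- seq(1 / fs, 30, by = 1 / fs)
  topo <- dipole_field(c(0.01, 0, 0.045), c(2e-8, 0, 0), arr)
  rec <- recording(tcrossprod(topo, sin(2 * pi * 12 * t)), fs, arr,
                   "reference")
  for (CL in c(1, 0.95, 0.6)) {
    cl <- tsss_clean(rec, tsss_params(CL = CL))
    expect_lt(sqrt(mean((cl$data - rec$data)^2) / mean(rec$data^2)), 0.01)
  }
  # CL = 1 is exactly the plain SSS inner reconstruction
  cl1 <- tsss_clean(rec, tsss_params(CL = 1))
  S <- sss_basis(arr, 8, 3)
  sv <- svd(S)
  keep <- sv$d > 1e-8 * sv$d[1]
  pinv <- sv$v[, keep] %*% (t(sv$u[, keep]) / sv$d[keep])
  seg <- rec$data[, 1:(10 * fs)]
  A <- pinv %*% seg
  expect_equal(cl1$data[, 1:(10 * fs)], S[, 1:80] %*% A[1:80, ],
               tolerance = 1e-10)
})

test_that("a planted inner-residual intersection artefact is projected out", {
  arr <- tsss_arr()
  fs <- 300
  t <- seq(1 / fs, 30, by = 1 / fs)
  topo <- dipole_field(c(0.01, 0, 0.045), c(2e-8, 0, 0), arr)
  set.seed(61)
  noise <- matrix(rnorm(128 * length(t), sd = 1e-13), 128)
  art_wave <- ifelse((t %% 1) < 0.1, 1, 0) * 5e-12
  art_in <- dipole_field(c(-0.02, 0.01, 0.03), c(0, 2e-8, 0), arr)
  art_in <- art_in / sqrt(sum(art_in^2))
  antopo <- rnorm(128)
  S <- sss_basis(arr, 8, 3)
  art_res <- antopo - S %*% qr.coef(qr(S), antopo)
  art_res <- art_res / sqrt(sum(art_res^2))
  dat <- tcrossprod(topo, sin(2 * pi * 12 * t)) + noise +
    (art_in + art_res) %*% t(art_wave)
  rec <- recording(dat, fs, arr, "dsmw")
  cl <- tsss_clean(rec, tsss_params(CL = 0.9))
  pow_art <- function(d) sum(drop(d %*% art_wave)^2)
  expect_gt(1 - pow_art(cl$data) / pow_art(rec$data), 0.9)

  # near-idempotency on the cleaned output
  cl2 <- tsss_clean(cl, tsss_params(CL = 0.9))
  expect_lt(sqrt(mean((cl2$data - cl$data)^2) / mean(cl$data^2)), 0.05)
})

test_that("spectrum baseline correction removes the channel-wise offset", {
  set <- small_set()
  ref_spec <- welch_psd(set$reference)
  # a cleaned spectrum that is the reference shifted by 1 decade: the
  # correction must restore it exactly
  shifted <- ref_spec
  shifted$power <- shifted$power * 10
  fixed <- baseline_correct(shifted, ref_spec)
  expect_equal(fixed$power, ref_spec$power, tolerance = 1e-12)
  # identity when already matching
  same <- baseline_correct(ref_spec, ref_spec)
  expect_equal(same$power, ref_spec$power, tolerance = 1e-12)
  # after correction, the 15-125 Hz mean log-power difference is 0
  other <- welch_psd(set$dsmw)
  corr <- baseline_correct(other, ref_spec)
  sel <- megdbs:::band_bins(ref_spec$freqs,
                            band_spec(c(15, 125),
                                      rbind(c(49, 51), c(99, 101))))
  delta <- rowMeans(log10(corr$power[, sel]) - log10(ref_spec$power[, sel]))
  expect_lt(max(abs(delta)), 1e-10)
  bad <- ref_spec
  bad$freqs <- bad$freqs + 0.1
  expect_error(baseline_correct(bad, ref_spec), "axes")
})
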