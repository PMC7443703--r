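test_that("DBS peak detection finds injected peaks and rejects flat spectra", {
  set <- small_set()
  expect_equal(detect_dbs_peak(welch_psd(set$dsmw)), 130, tolerance = 0.3)
  expect_error(detect_dbs_peak(welch_psd(set$reference)), "no DBS peak")
  # a pure 127.75 Hz line is located to within the bin width
  fs <- 1200
  t <- seq(1 / fs, 30, by = 1 / fs)
  dat <- matrix(rep(1e-13 * sin(2 * pi * 127.75 * t), 32), 32,
                byrow = TRUE) +
    matrix(rnorm(32 * length(t), sd = 1e-14), 32)
  rec <- recording(dat, fs, small_arr(), "dsmw")
  expect_equal(detect_dbs_peak(welch_psd(rec)), 127.75, tolerance = 0.25)
})

test_that("band RMSE formula on hand-computed cases", {
  bp <- function(pi_vals) {
    structure(list(band = band_spec(c(1, 2), label = "x"), pi = pi_vals,
                   n_channels = length(pi_vals)),
              class = "band_power")
  }
  expect_equal(rmse_band(bp(3), bp(2))$value, 0.5)
  expect_equal(rmse_band(bp(c(3, 4)), bp(c(2, 4)))$value,
               sqrt((0.25 + 0) / 2), tolerance = 1e-12)
  expect_equal(rmse_band(bp(c(3, 4)), bp(c(2, 4)))$value, 0.35355,
               tolerance = 1e-4)
  expect_equal(rmse_band(bp(c(2, 4)), bp(c(2, 4)))$value, 0)
  expect_error(rmse_band(bp(1), bp(0)), "undefined")
  expect_error(rmse_band(bp(1), bp(c(1, 2))), "channel counts")
})

test_that("evaluate_cleaning: perfect cleaning, identity cleaning, out-of-band identity", {
  set <- small_set()
  bands <- band_set(detect_dbs_peak(welch_psd(set$dsmw)))
  perfect <- evaluate_cleaning(set, set$reference, bands)
  expect_equal(perfect$rmse$value, rep(0, 3))
  identity <- evaluate_cleaning(set, set$dsmw, bands)
  expect_equal(identity$rmse$value, identity$rmse$baseline)
  # dbs_band Hampel: dipole and movement bands stay at the baseline
  ev <- evaluate_cleaning(set, clean_with("hampel", set, 5), bands)
  expect_equal(ev$rmse$value[1], ev$rmse$baseline[1], tolerance = 1e-4)
  expect_lt(ev$rmse$value[3], ev$rmse$baseline[3])
})

test_that("sweeps collect per-value RMSE, are reproducible and tolerate failures", {
  set <- small_set()
  bands <- band_set(detect_dbs_peak(welch_psd(set$dsmw)))
  sw <- sweep_method("hampel", c(2, 8), set, bands)
  expect_equal(dim(sw$rmse), c(3, 2))
  expect_equal(sw$parameter_name, "C")
  # stronger cleaning (smaller C) removes at least as much DBS artefact
  expect_lte(sw$rmse["dbs", "2"], sw$rmse["dbs", "8"] + 1e-12)
  sw2 <- sweep_method("hampel", c(2, 8), set, bands)
  expect_identical(sw$rmse, sw2$rmse)
  # an invalid value is recorded, the sweep continues
  sw3 <- sweep_method("hampel", c(-1, 5), set, bands)
  expect_length(sw3$errors, 1)
  expect_false(anyNA(sw3$rmse[, "5"]))
  expect_error(sweep_method("unknown_method", 1, set, bands), "unknown")
})

test_that("robustness pools the method-appropriate bands with sample SD", {
  sw <- structure(
    list(method = "hampel", parameter_name = "C", values = c(1, 2),
         rmse = matrix(c(0.3, 0.2, 0.1, 0.3, 0.2, 0.2), 3,
                       dimnames = list(c("dipole", "movement", "dbs"),
                                       c("1", "2"))),
         baseline = c(1, 1, 1)),
    class = "sweep_result")
  r <- robustness(sw)
  expect_equal(r$bands_used, "dbs")
  expect_equal(r$mean, 0.15)
  expect_equal(r$sd, stats::sd(c(0.1, 0.2)))
  expect_equal(r$sd, 0.0707, tolerance = 1e-3)
  sw$method <- "icami"
  r2 <- robustness(sw)
  expect_equal(r2$n, 6)
  sw$rmse <- sw$rmse[, 1, drop = FALSE]
  sw$method <- "hampel"
  expect_error(robustness(sw), "at least 2")
  # constant values give SD 0
  sw$rmse <- matrix(0.2, 3, 2,
                    dimnames = list(c("dipole", "movement", "dbs"), 1:2))
  expect_equal(robustness(sw)$sd, 0)
})

test_that("optimal sensor parameter minimizes the average RMSE with weak-end ties", {
  mk <- function(method, values, rmse) {
    structure(list(method = method, parameter_name = "p", values = values,
                   rmse = matrix(rmse, 3, length(values),
                                 dimnames = list(c("dipole", "movement",
                                                   "dbs"), values))),
              class = "sweep_result")
  }
  expect_equal(select_optimal_sensor(mk("hampel", 5, c(1, 1, 1))), 5)
  sw <- mk("s3p", c(1, 3, 5), c(rep(0.2, 3), rep(0.1, 3), rep(0.3, 3)))
  expect_equal(select_optimal_sensor(sw), 3)
  # exhaustive re-check by enumeration
  expect_equal(mean(sw$rmse[, "3"]), min(colMeans(sw$rmse)))
  # tie breaks toward weaker cleaning: larger C, smaller k
  tie_h <- mk("hampel", c(2, 6), rep(0.1, 6))
  expect_equal(select_optimal_sensor(tie_h), 6)
  tie_s <- mk("s3p", c(1, 4), rep(0.1, 6))
  expect_equal(select_optimal_sensor(tie_s), 1)
})

test_that("source-level selection walks while D improves by more than 0.01", {
  expect_equal(select_optimal_source(c("1" = 0.50, "2" = 0.60,
                                       "3" = 0.605)), 2)
  expect_equal(select_optimal_source(c("1" = 0.5, "2" = 0.4,
                                       "3" = 0.3)), 1)
  expect_equal(select_optimal_source(c("1" = 0.5, "2" = 0.52,
                                       "3" = 0.54)), 3)
  expect_error(select_optimal_source(numeric(0)), "empty")
})

test_that("study report collects RMSE, robustness, optima and spectra", {
  set <- small_set()
  bands <- band_set(detect_dbs_peak(welch_psd(set$dsmw)))
  sw <- sweep_method("hampel", c(2, 8), set, bands)
  rep <- study_report(set, list(hampel = sw))
  expect_equal(nrow(rep$rmse), 6)          # 2 values x 3 bands
  expect_equal(rep$optimal$best_sensor_value, sw$best_sensor_value)
  expect_setequal(unique(rep$spectra$condition),
                  c("reference", "dmw", "dsmw", "empty_room"))
  expect_output(print(rep), "Robustness")
  # serialization round trip is lossless
  f <- tempfile(fileext = ".rds")
  write_container(rep, f)
  expect_equal(read_container(f, "megdbs_report"), rep)
  unlink(f)
})

test_that("plot helpers return ggplot objects", {
  set <- small_set()
  bands <- band_set(detect_dbs_peak(welch_psd(set$dsmw)))
  sw <- sweep_method("hampel", c(2, 8), set, bands)
  rep <- study_report(set, list(hampel = sw))
  expect_s3_class(plot_condition_spectra(rep), "ggplot")
  expect_s3_class(plot_rmse_sweep(sw), "ggplot")
})
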