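#' The study's three evaluation bands
#'
#' Dipole band 11.5-12.5 Hz, movement band 1-15 Hz excluding the dipole
#' band, and DBS band `f_peak` +/- 1 Hz around the *detected* stimulation
#' peak (which need not sit exactly at the nominal stimulation frequency).
#'
#' @param f_peak Detected DBS peak frequency, Hz (see
#'   [detect_dbs_peak()]).
#' @return A list of class `band_set` with `dipole`, `movement`, `dbs`
#'   ([band_spec()] objects) and `f_peak`.
#' @export
band_set <- function(f_peak) {
  structure(
    list(
      dipole = band_spec(c(11.5, 12.5), label = "dipole"),
      movement = band_spec(c(1, 15), exclude = c(11.5, 12.5),
                           label = "movement"),
      dbs = band_spec(c(f_peak - 1, f_peak + 1), label = "dbs"),
      f_peak = f_peak
    ),
    class = "band_set"
  )
}

#' Detect the DBS spectral peak
#'
#' Frequency of maximum channel-mean power inside the search interval;
#' errors if no clear peak (at least twice the interval's median power)
#' exists, e.g. on the reference condition.
#'
#' @param spec A [welch_psd()] estimate.
#' @param search Search interval, Hz.
#' @return The peak frequency, Hz.
#' @export
detect_dbs_peak <- function(spec, search = c(120, 140)) {
  sel <- which(spec$freqs >= search[1] & spec$freqs <= search[2])
  if (length(sel) == 0) stop("search interval outside the frequency axis")
  p <- colMeans(spec$power[, sel, drop = FALSE])
  if (max(p) < 2 * stats::median(p)) {
    stop("no DBS peak in ", search[1], "-", search[2], " Hz")
  }
  spec$freqs[sel[which.max(p)]]
}

#' Band-wise relative RMSE of log power against the reference
#'
#' `sqrt(mean(((pi_clean - pi_ref) / pi_ref)^2))` over channels, where
#' `pi` is the band-averaged log10 power of each channel.
#'
#' @param clean,ref [band_log_power()] summaries over the same band and
#'   channels.
#' @return A list of class `rmse_result` with `band`, `value`,
#'   `n_channels`.
#' @export
rmse_band <- function(clean, ref) {
  if (clean$n_channels != ref$n_channels) {
    stop("band power summaries have different channel counts")
  }
  if (any(ref$pi == 0)) {
    stop("reference band log power of exactly 0 makes the relative RMSE undefined")
  }
  structure(
    list(band = clean$band$label,
         value = sqrt(mean(((clean$pi - ref$pi) / ref$pi)^2)),
         n_channels = clean$n_channels),
    class = "rmse_result"
  )
}

#' Evaluate a cleaned recording against the reference condition
#'
#' Welch-transforms the reference and the cleaned data and reports the
#' three band RMSEs together with the uncleaned DSMW baseline.
#'
#' @param set A [make_condition_set()].
#' @param cleaned A cleaned [recording()] derived from `set$dsmw`, or a
#'   [welch_psd()] spectrum of one (the spectrum form is used for
#'   baseline-corrected tSSS, which operates on spectra).
#' @param bands A [band_set()]; `NULL` detects the DBS peak from the DSMW
#'   spectrum.
#' @return A list of class `cleaning_evaluation` with tibble `rmse`
#'   (band, value, baseline, n_channels) and the `bands` used.
#' @export
evaluate_cleaning <- function(set, cleaned, bands = NULL) {
  ref_spec <- welch_psd(set$reference)
  dsmw_spec <- welch_psd(set$dsmw)
  clean_spec <- if (inherits(cleaned, "spectrum_estimate")) cleaned
    else welch_psd(cleaned)
  if (is.null(bands)) bands <- band_set(detect_dbs_peak(dsmw_spec))
  one <- function(band) {
    ref_bp <- band_log_power(ref_spec, band)
    val <- rmse_band(band_log_power(clean_spec, band), ref_bp)$value
    base <- rmse_band(band_log_power(dsmw_spec, band), ref_bp)$value
    c(value = val, baseline = base)
  }
  rows <- vapply(list(bands$dipole, bands$movement, bands$dbs), one,
                 numeric(2))
  structure(
    list(rmse = tibble::tibble(
      band = c("dipole", "movement", "dbs"),
      value = rows["value", ],
      baseline = rows["baseline", ],
      n_channels = nrow(ref_spec$power)
    ), bands = bands),
    class = "cleaning_evaluation"
  )
}

#' Run one cleaning method at one strength value
#'
#' Applies one of the four artefact-rejection methods to the DSMW
#' recording of a condition set, with the method's strength parameter
#' (C, k, R or CL) set to `value`. `params` carries method options other
#' than the swept strength (e.g. `mode = "wide_band"`, seeds).
#'
#' @param method `"hampel"`, `"s3p"`, `"icami"` or `"tsss"`.
#' @param set A [make_condition_set()].
#' @param value The strength parameter value.
#' @param params Named list of extra method parameters.
#' @return The cleaned [recording()].
#' @export
clean_with <- function(method, set, value, params = list()) {
  f_stim <- set$config$f_stim
  switch(method,
    hampel = {
      p <- do.call(hampel_params,
                   utils::modifyList(list(C = value, f_stim = f_stim),
                                     params))
      hampel_clean(set$dsmw, p)
    },
    s3p = {
      p <- do.call(s3p_params,
                   utils::modifyList(list(k = value, f_stim = f_stim),
                                     params))
      s3p_clean(set$dsmw, p)
    },
    icami = {
      p <- do.call(ica_mi_params,
                   utils::modifyList(list(R = value,
                                          notch_freq = set$config$f_dipole),
                                     params))
      ica_mi_clean(set$dsmw, set$dbs_reference_channel, p)
    },
    tsss = {
      p <- do.call(tsss_params, utils::modifyList(list(CL = value), params))
      tsss_clean(set$dsmw, p)
    },
    stop("unknown cleaning method: ", method)
  )
}

sweep_parameter_name <- function(method) {
  switch(method, hampel = "C", s3p = "k", icami = "R", tsss = "CL")
}

# Direction of weaker cleaning for tie-breaks in optimal selection.
weaker_is_larger <- function(method) {
  switch(method, hampel = TRUE, s3p = FALSE, icami = FALSE, tsss = TRUE)
}

#' Parameter sweep of a cleaning method
#'
#' Runs one method across its strength values on the DSMW condition,
#' collecting the three band RMSEs per value (and reusing fixed seeds for
#' the stochastic methods so the sweep is reproducible). Single-value
#' failures are recorded and the sweep continues.
#'
#' @param method `"hampel"`, `"s3p"`, `"icami"` or `"tsss"`.
#' @param values Strength values (C, k, R or CL respectively).
#' @param set A [make_condition_set()].
#' @param bands A [band_set()]; `NULL` detects the peak from DSMW.
#' @param params Extra method parameters (e.g. `mode = "wide_band"`).
#' @return A list of class `sweep_result`: `method`, `parameter_name`,
#'   `values`, `rmse` (3 x values matrix, rows dipole/movement/dbs),
#'   `baseline` (3-vector), `errors`, `best_sensor_value`.
#' @export
sweep_method <- function(method, values, set, bands = NULL,
                         params = list()) {
  if (!method %in% c("hampel", "s3p", "icami", "tsss")) {
    stop("unknown cleaning method: ", method)
  }
  dsmw_spec <- welch_psd(set$dsmw)
  if (is.null(bands)) bands <- band_set(detect_dbs_peak(dsmw_spec))
  rmse <- matrix(NA_real_, 3, length(values),
                 dimnames = list(c("dipole", "movement", "dbs"),
                                 as.character(values)))
  baseline <- NULL
  errors <- character(0)
  for (i in seq_along(values)) {
    ev <- tryCatch({
      cleaned <- clean_with(method, set, values[i], params)
      evaluate_cleaning(set, cleaned, bands)
    }, error = function(e) e)
    if (inherits(ev, "error")) {
      errors <- c(errors, sprintf("%s=%g: %s", sweep_parameter_name(method),
                                  values[i], conditionMessage(ev)))
      next
    }
    rmse[, i] <- ev$rmse$value
    baseline <- ev$rmse$baseline
  }
  res <- structure(
    list(method = method, parameter_name = sweep_parameter_name(method),
         values = values, rmse = rmse, baseline = baseline,
         errors = errors, bands = bands),
    class = "sweep_result"
  )
  res$best_sensor_value <- if (all(is.na(rmse))) NA_real_ else
    select_optimal_sensor(res)
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over %s = {%s}; best (avg RMSE) %s = %g\n",
              x$method, x$parameter_name,
              paste(x$values, collapse = ", "), x$parameter_name,
              x$best_sensor_value))
  print(round(x$rmse, 5))
  invisible(x)
}

#' Robustness of a method over its parameter range
#'
#' Mean and sample standard deviation of the RMSE across the sweep: over
#' the DBS band only for Hampel and S3P (which in their recommended mode
#' act only there), pooled over all three bands for ICA-MI and tSSS.
#'
#' @param sweep A [sweep_method()] result.
#' @param bands_used Override of the pooled bands (character subset of
#'   dipole/movement/dbs).
#' @return A list with `mean`, `sd`, `n`, `bands_used`.
#' @export
robustness <- function(sweep, bands_used = NULL) {
  if (is.null(bands_used)) {
    bands_used <- if (sweep$method %in% c("hampel", "s3p")) "dbs"
      else c("dipole", "movement", "dbs")
  }
  vals <- as.vector(sweep$rmse[bands_used, , drop = FALSE])
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2) stop("robustness needs at least 2 RMSE values")
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals),
       bands_used = bands_used)
}

#' Optimal parameter at the sensor level
#'
#' The swept value minimizing the unweighted mean of the three band
#' RMSEs; ties (within 1e-12) break toward the weaker-cleaning end of the
#' range (larger C, smaller k, smaller R, larger CL).
#'
#' @param sweep A [sweep_method()] result.
#' @return The selected parameter value.
#' @export
select_optimal_sensor <- function(sweep) {
  avg <- colMeans(sweep$rmse)
  ok <- which(!is.na(avg))
  if (length(ok) == 0) stop("sweep contains no successful values")
  best <- min(avg[ok])
  cand <- ok[avg[ok] <= best + 1e-12]
  vals <- sweep$values[cand]
  if (weaker_is_larger(sweep$method)) vals[which.max(vals)] else
    vals[which.min(vals)]
}

#' Optimal parameter at the source level
#'
#' Walks the parameter values in sweep order (from each method's initial
#' value towards stronger cleaning) and keeps increasing the strength as
#' long as the D overlap improves by more than `min_improvement`;
#' returns the last accepted value.
#'
#' @param d_by_value Named numeric vector of D values in sweep order.
#' @param min_improvement Required D gain per step.
#' @return The selected parameter value (names preserved as numeric).
#' @export
select_optimal_source <- function(d_by_value, min_improvement = 0.01) {
  if (length(d_by_value) == 0) stop("empty D map")
  vals <- as.numeric(names(d_by_value))
  if (anyNA(vals)) vals <- seq_along(d_by_value)
  best <- vals[1]
  for (i in seq_along(d_by_value)[-1]) {
    if (d_by_value[i] - d_by_value[i - 1] > min_improvement) {
      best <- vals[i]
    } else {
      break
    }
  }
  best
}

#' Structured study report
#'
#' Collects the sensor-level RMSE tables, robustness summaries and
#' optimal parameters for a set of method sweeps, optionally source-level
#' D values, and the channel-mean condition spectra, as plain tibbles
#' ready for printing, plotting or serialization.
#'
#' @param set A [make_condition_set()].
#' @param sweeps Named list of [sweep_method()] results.
#' @param source_results Optional tibble (or named list coerced) of
#'   source-level D per method.
#' @param spectra_fmax Upper frequency bound of the stored channel-mean
#'   spectra.
#' @return A list of class `megdbs_report` with tibbles `rmse`,
#'   `robustness`, `optimal`, `d`, `spectra`.
#' @export
study_report <- function(set, sweeps, source_results = NULL,
                         spectra_fmax = 140) {
  rmse <- do.call(rbind, lapply(sweeps, function(s) {
    tibble::tibble(
      method = s$method,
      parameter = s$parameter_name,
      value = rep(s$values, each = 3),
      band = rep(rownames(s$rmse), length(s$values)),
      rmse = as.vector(s$rmse),
      baseline = rep(s$baseline, length(s$values))
    )
  }))
  rob <- do.call(rbind, lapply(sweeps, function(s) {
    r <- tryCatch(robustness(s), error = function(e) NULL)
    if (is.null(r)) {
      return(tibble::tibble(method = s$method, mean = NA_real_,
                            sd = NA_real_, n = NA_integer_, bands = NA))
    }
    tibble::tibble(method = s$method, mean = r$mean, sd = r$sd, n = r$n,
                   bands = paste(r$bands_used, collapse = "+"))
  }))
  opt <- do.call(rbind, lapply(sweeps, function(s) {
    tibble::tibble(method = s$method, parameter = s$parameter_name,
                   best_sensor_value = s$best_sensor_value)
  }))
  spectra <- do.call(rbind, lapply(
    c("reference", "dmw", "dsmw", "empty_room"),
    function(cond) {
      sp <- channel_mean_log_spectrum(welch_psd(set[[cond]]))
      keep <- sp$freqs <= spectra_fmax
      tibble::tibble(condition = cond, freq = sp$freqs[keep],
                     log10_power = sp$logp[keep])
    }))
  d_tbl <- NULL
  if (!is.null(source_results)) {
    d_tbl <- if (tibble::is_tibble(source_results)) source_results
      else tibble::tibble(method = names(source_results),
                          d = as.numeric(source_results))
  }
  structure(list(rmse = rmse, robustness = rob, optimal = opt, d = d_tbl,
                 spectra = spectra, config = set$config),
            class = "megdbs_report")
}

#' @export
print.megdbs_report <- function(x, ...) {
  cat("== DBS artefact rejection study report ==\n\nRMSE by method/parameter/band:\n")
  print(x$rmse, n = 20)
  cat("\nRobustness (mean +/- SD of RMSE over the parameter range):\n")
  print(x$robustness)
  cat("\nOptimal sensor-level parameters (lowest average RMSE):\n")
  print(x$optimal)
  if (!is.null(x$d)) {
    cat("\nSource-level D overlap:\n")
    print(x$d)
  }
  invisible(x)
}
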