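container_kinds <- c(
  condition_set = "condition_set",
  recording = "recording",
  spectrum_estimate = "spectrum_estimate",
  source_map = "source_map",
  sweep_result = "sweep_result",
  megdbs_report = "megdbs_report"
)

container_version <- "1.0"

#' Write a pipeline object to a container file
#'
#' Serializes any of the pipeline's native objects (condition sets,
#' recordings, spectra, source maps, sweeps, reports) with an embedded
#' kind tag and format version so that [read_container()] can dispatch
#' and validate on load. The round trip is lossless.
#'
#' @param x The object to store.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(x, path) {
  kind <- intersect(class(x), container_kinds)[1]
  if (is.na(kind)) {
    stop("cannot store objects of class ", paste(class(x), collapse = "/"))
  }
  saveRDS(list(format = "megdbs-container", version = container_version,
               kind = kind, object = x),
          path)
  invisible(path)
}

#' Read a pipeline object from a container file
#'
#' @param path File written by [write_container()].
#' @param expect Optional kind (e.g. `"condition_set"`); reading a file of
#'   a different kind is refused.
#' @return The stored object.
#' @export
read_container <- function(path, expect = NULL) {
  if (!file.exists(path)) stop("no such container file: ", path)
  env <- readRDS(path)
  if (!is.list(env) || !identical(env$format, "megdbs-container")) {
    stop("not a megdbs container: ", path)
  }
  if (!identical(env$version, container_version)) {
    stop("unsupported container version '", env$version,
         "' (this build reads version ", container_version, ")")
  }
  if (!is.character(env$kind) || !(env$kind %in% container_kinds)) {
    stop("container has an unknown kind tag: ",
         deparse(env$kind))
  }
  if (!is.null(expect) && !identical(env$kind, expect)) {
    stop("container holds a '", env$kind, "', not the expected '",
         expect, "'")
  }
  env$object
}

#' Run the full phantom study pipeline
#'
#' simulate -> preprocess -> sweep the cleaning methods -> sensor report
#' -> source maps and D at the dipole frequency. Every stage's outcome,
#' parameters and output-file digest are recorded in a manifest; a failed
#' stage is recorded and the remaining dependent stages are skipped. The
#' run is deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Directory receiving the container files.
#' @param methods Cleaning methods to sweep.
#' @param sweep_values Named list of strength grids per method (defaults
#'   to the study grids).
#' @param source_freq Frequency of the source-level comparison, Hz.
#' @param grid_spacing Source grid spacing, metres.
#' @param run_source Run the source-level stage?
#' @return A list of class `run_manifest`.
#' @export
run_pipeline <- function(config, out_dir,
                         methods = c("hampel", "s3p", "icami", "tsss"),
                         sweep_values = NULL,
                         source_freq = config$f_dipole,
                         grid_spacing = 5e-3,
                         run_source = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  defaults <- list(hampel = 1:8, s3p = 1:9, icami = seq(5, 40, by = 5),
                   tsss = seq(0.95, 0.60, by = -0.05))
  if (is.null(sweep_values)) sweep_values <- defaults
  manifest <- list(config = config, seed = config$seed,
                   package_version = as.character(utils::packageVersion("megdbs")),
                   stages = list(), outputs = character(0))
  note <- function(stage, status, detail = NULL, file = NULL) {
    digest <- if (!is.null(file)) unname(tools::md5sum(file)) else NULL
    manifest$stages[[stage]] <<- list(status = status, detail = detail,
                                      file = file, md5 = digest)
    if (!is.null(file)) manifest$outputs <<- c(manifest$outputs, file)
    message(sprintf("[%s] %s", stage, status))
  }

  set <- tryCatch(make_condition_set(config), error = function(e) e)
  if (inherits(set, "error")) {
    note("simulate", "error", conditionMessage(set))
    class(manifest) <- "run_manifest"
    return(manifest)
  }
  f_set <- file.path(out_dir, "condition_set.rds")
  write_container(set, f_set)
  note("simulate", "ok",
       sprintf("stim gain %.3g", set$stim_gain), f_set)

  sweeps <- list()
  for (m in methods) {
    sw <- tryCatch(sweep_method(m, sweep_values[[m]], set),
                   error = function(e) e)
    if (inherits(sw, "error")) {
      note(paste0("sweep_", m), "error", conditionMessage(sw))
    } else {
      f <- file.path(out_dir, sprintf("sweep_%s.rds", m))
      write_container(sw, f)
      note(paste0("sweep_", m), "ok",
           sprintf("best %s = %g", sw$parameter_name, sw$best_sensor_value),
           f)
      sweeps[[m]] <- sw
    }
  }

  if (length(sweeps) > 0) {
    rep <- study_report(set, sweeps)
    f_rep <- file.path(out_dir, "report.rds")
    write_container(rep, f_rep)
    note("report", "ok", NULL, f_rep)
  } else {
    note("report", "skipped", "no successful sweeps")
  }

  if (run_source) {
    src <- tryCatch({
      grid <- build_grid(set$sensors, grid_spacing)
      lf <- compute_leadfield(grid, set$sensors)
      noise_cov <- regularize_cov(tcrossprod(set$empty_room$data) /
                                    ncol(set$empty_room$data))
      maps <- lapply(list(reference = set$reference, dsmw = set$dsmw),
                     function(rec) {
        dc <- regularize_cov(tcrossprod(rec$data) / ncol(rec$data))
        w <- lcmv_weights(dc, noise_cov, lf)
        source_power_at(rec, w, source_freq)
      })
      thr_ref <- bootstrap_threshold(maps$reference,
                                     seed = substream(config$seed, 11))
      maps$reference <- active_map(maps$reference, thr_ref)
      thr_dsmw <- bootstrap_threshold(maps$dsmw,
                                      exclude = maps$reference$active,
                                      seed = substream(config$seed, 12))
      maps$dsmw <- active_map(maps$dsmw, thr_dsmw)
      list(maps = maps, d = overlap_D(maps$reference, maps$dsmw))
    }, error = function(e) e)
    if (inherits(src, "error")) {
      note("source", "error", conditionMessage(src))
    } else {
      f_ref <- file.path(out_dir, "source_map_reference.rds")
      f_dsmw <- file.path(out_dir, "source_map_dsmw.rds")
      write_container(src$maps$reference, f_ref)
      write_container(src$maps$dsmw, f_dsmw)
      note("source", "ok",
           sprintf("D(reference, dsmw) = %.3f", src$d$d), f_dsmw)
      manifest$d_reference_dsmw <- src$d$d
    }
  } else {
    note("source", "skipped", "disabled")
  }

  class(manifest) <- "run_manifest"
  manifest
}

#' Import a recording from a vendor MEG format
#'
#' Best-effort bridge to real acquisitions in FIF (Elekta/MEGIN) or CTF
#' formats. Reading these binary formats requires an MEG I/O backend,
#' which this package does not bundle; without one installed this
#' function stops with an actionable error naming it.
#'
#' @param path Path to a `.fif` file or CTF `.ds` directory.
#' @param format `"fif"` or `"ctf"`.
#' @return A [recording()] (magnetometer-type channels only), when a
#'   backend is available.
#' @export
import_standard <- function(path, format = c("fif", "ctf")) {
  format <- match.arg(format)
  backend <- "mne.io"
  stop("importing ", format, " recordings requires an MEG I/O backend (",
       backend, " via a Python bridge such as 'reticulate'), which is ",
       "not installed; generate synthetic recordings with ",
       "make_condition_set() instead")
}
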