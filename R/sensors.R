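#' Construct a synthetic MEG sensor array
#'
#' Places `n_channels` radial-pointing point magnetometers quasi-uniformly
#' on the upper portion of a sphere of radius `helmet_radius`, mimicking a
#' whole-head MEG helmet over a spherical conductor phantom. The layout uses
#' a Fibonacci spiral over the spherical cap covering roughly the upper 60%
#' of the sphere's surface, followed by a small seeded jitter and a seeded
#' azimuthal rotation so that distinct seeds give distinct (but equally
#' uniform) arrays.
#'
#' @param n_channels Number of magnetometers; at least 32. Arrays intended
#'   for signal space separation at inner order 8 need more than 95
#'   channels (see [sss_basis()]).
#' @param helmet_radius Radius of the sensor shell in metres.
#' @param seed Integer seed controlling jitter, rotation and orientation
#'   tilt; the same seed always yields a bit-identical array.
#' @param sphere_radius Radius of the conducting phantom sphere in metres.
#'   Must be smaller than `helmet_radius`.
#' @param tilt_sd Spread of the random tangential orientation tilt
#'   (radians-like; 0.12 gives ~10 degree typical deviations from
#'   radial). A strictly zero tilt would make the interior/exterior
#'   multipole separation of [sss_basis()] singular.
#' @return An object of class `sensor_array`: a list with `positions`
#'   (`n_channels` x 3, metres), `orientations` (`n_channels` x 3 unit
#'   vectors, quasi-radial), `names`, `sphere_center` (3-vector, metres)
#'   and `sphere_radius` (metres).
#' @examples
#' arr <- make_sensor_array(64, 0.12, seed = 1)
#' range(sqrt(rowSums(arr$positions^2)))
#' @export
make_sensor_array <- function(n_channels, helmet_radius = 0.12, seed = 1,
                              sphere_radius = 0.075, tilt_sd = 0.12) {
  if (n_channels < 32) {
    stop("n_channels must be >= 32 (fewer sensors cannot support the ",
         "order-8 inner SSS basis)")
  }
  if (sphere_radius >= helmet_radius) {
    stop("sphere_radius must be smaller than helmet_radius")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # Fibonacci spiral over the cap z/r in [z_min, 1]; cap area fraction 0.6.
  z_min <- 1 - 2 * 0.6
  i <- seq_len(n_channels)
  z <- z_min + (1 - z_min) * (i - 0.5) / n_channels
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden + stats::runif(1, 0, 2 * pi)
  # jitter keeps determinism per seed but breaks the exact spiral lattice
  z <- pmin(1 - 1e-6, pmax(z_min, z + stats::rnorm(n_channels, 0, 0.004)))
  phi <- phi + stats::rnorm(n_channels, 0, 0.004)
  s <- sqrt(1 - z^2)
  u <- cbind(s * cos(phi), s * sin(phi), z)
  u <- u / sqrt(rowSums(u^2))
  positions <- helmet_radius * u
  # Quasi-radial orientations: a small seeded tangential tilt (~10 deg).
  # Exactly radial sensors on a single shell cannot separate interior from
  # exterior multipoles (the two have identical angular patterns at one
  # radius), so a perfect-radial array would make SSS singular; real
  # helmets are never perfectly radial either.
  tilt <- matrix(stats::rnorm(3 * n_channels, 0, tilt_sd), n_channels)
  tilt <- tilt - u * rowSums(tilt * u)    # tangential component only
  orientations <- u + tilt
  orientations <- orientations / sqrt(rowSums(orientations^2))

  structure(
    list(
      positions = positions,
      orientations = orientations,
      names = sprintf("MEG%03d", i),
      sphere_center = c(0, 0, 0),
      sphere_radius = sphere_radius
    ),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf(
    "<sensor_array> %d radial magnetometers, helmet radius %.3f m, sphere radius %.3f m\n",
    nrow(x$positions), sqrt(sum(x$positions[1, ]^2)), x$sphere_radius
  ))
  invisible(x)
}

n_sensors <- function(sensors) nrow(sensors$positions)

# Save/restore .Random.seed so seeded constructors do not disturb the
# caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic substream seed derived from a base seed and a stream id,
# kept below 2^31 - 1.
substream <- function(seed, id) {
  as.integer((as.numeric(seed) * 69069 + 12345 * (id + 1)) %% 2147483647)
}
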