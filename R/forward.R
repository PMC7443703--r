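#' Magnetic field of a current dipole in a conducting sphere
#'
#' Closed-form (Sarvas) magnetic field of a current dipole inside a
#' homogeneous conducting sphere, evaluated at each sensor and projected on
#' the sensor orientation. For a spherical phantom this forward model is
#' exact; the same code path is used both by the simulator and by the
#' beamformer leadfield so that simulation and source analysis share one
#' physics.
#'
#' Two classic sphere properties follow from the formula and are relied on
#' throughout: the radial component of the dipole moment produces exactly
#' zero external field (a "silent source"), and the field is linear in the
#' moment.
#'
#' @param dipole_pos 3-vector, metres, relative to the sphere centre; must
#'   be strictly inside the sphere.
#' @param dipole_moment 3-vector, ampere-metres.
#' @param sensors A [make_sensor_array()] object.
#' @return Numeric vector, one Tesla value per channel.
#' @export
dipole_field <- function(dipole_pos, dipole_moment, sensors) {
  r0 <- as.numeric(dipole_pos)
  if (sqrt(sum(r0^2)) >= sensors$sphere_radius) {
    stop("dipole must lie strictly inside the conducting sphere")
  }
  B <- sarvas_field(sensors$positions, r0, as.numeric(dipole_moment))
  rowSums(B * sensors$orientations)
}

# Vector Sarvas field at points `rs` (n x 3, relative to sphere centre) for
# a dipole with moment Q at r0. mu0 = 4*pi*1e-7.
sarvas_field <- function(rs, r0, Q) {
  mu0 <- 4 * pi * 1e-7
  a_vec <- sweep(rs, 2, r0)               # a = r - r0
  a <- sqrt(rowSums(a_vec^2))
  r <- sqrt(rowSums(rs^2))
  r0dotr <- drop(rs %*% r0)
  adotr <- rowSums(a_vec * rs)
  F <- a * (r * a + r^2 - r0dotr)
  # grad F = (a^2/r + a.r/a + 2a + 2r) r  -  (a + 2r + a.r/a) r0
  c1 <- a^2 / r + adotr / a + 2 * a + 2 * r
  c2 <- a + 2 * r + adotr / a
  gradF <- rs * c1 - matrix(r0, nrow(rs), 3, byrow = TRUE) * c2
  Qxr0 <- cross3(Q, r0)
  Qxr0dotr <- drop(rs %*% Qxr0)
  (mu0 / (4 * pi)) *
    (matrix(Qxr0, nrow(rs), 3, byrow = TRUE) * F - gradF * Qxr0dotr) / F^2
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
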