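test_that("sensor arrays are on-shell, unit-oriented and deterministic", {
  arr <- make_sensor_array(128, 0.12, seed = 1)
  expect_equal(nrow(arr$positions), 128)
  expect_lt(max(abs(sqrt(rowSums(arr$positions^2)) - 0.12)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(arr$orientations^2)) - 1)), 1e-9)
  expect_true(all(sqrt(rowSums(arr$positions^2)) > arr$sphere_radius))
  expect_identical(arr, make_sensor_array(128, 0.12, seed = 1))
  expect_false(identical(arr$positions,
                         make_sensor_array(128, 0.12, seed = 2)$positions))
  expect_error(make_sensor_array(16, 0.12, seed = 1), "32")
})

test_that("sphere dipole field: silent radial source and linearity", {
  arr <- small_arr()
  p <- c(0.013, -0.021, 0.032)
  b_rad <- dipole_field(p, 1e-8 * p / sqrt(sum(p^2)), arr)
  b_tan <- dipole_field(p, c(1e-8, 0, 0), arr)
  expect_lt(max(abs(b_rad)), 1e-9 * max(abs(b_tan)))
  expect_equal(dipole_field(p, c(2e-8, 0, 0), arr), 2 * b_tan,
               tolerance = 1e-12)
  expect_error(dipole_field(c(0.1, 0, 0), c(1e-8, 0, 0), arr), "inside")
})

test_that("sphere dipole field matches two independent oracles within 1%", {
  arr <- make_sensor_array(48, 0.12, seed = 3)
  r0 <- c(0.012, -0.02, 0.035)
  Q <- c(3e-8, 1e-8, -2e-8)
  measured <- dipole_field(r0, Q, arr)

  # oracle 1: the radial component equals the free-space Biot-Savart
  # dipole field (volume currents of a sphere are purely tangential)
  for (i in c(1, 13, 30, 48)) {
    r <- arr$positions[i, ]
    rhat <- r / sqrt(sum(r^2))
    b_full <- megdbs:::sarvas_field(matrix(r, 1), r0, Q)
    expect_equal(sum(b_full * rhat),
                 sum(biot_savart_dipole(r, r0, Q) * rhat),
                 tolerance = 1e-10)
  }

  # oracle 2: the full vector equals the numerical gradient of the
  # closed-form magnetic scalar potential
  for (i in c(2, 20, 41)) {
    r <- arr$positions[i, ]
    b_num <- sphere_potential_field(r, r0, Q)
    b_ana <- drop(megdbs:::sarvas_field(matrix(r, 1), r0, Q))
    expect_lt(max(abs(b_num - b_ana)) / max(abs(b_ana)), 0.01)
  }
})
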