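test_that("default sector fast axes map input linear light onto the local radius", {
  ax <- sector_axes(8, input_axis = 0)
  expect_equal(ax, c(0, 45, 90, 135, 180, 225, 270, 315) / 2)
  # HWP at each axis maps horizontal input to linear light along the sector azimuth
  for (k in c(1, 2, 3)) {
    phi <- (k - 1) * 45
    out <- apply_mueller(mueller_retarder(pi, ax[k]), c(1, 1, 0, 0))
    expect_equal(out, c(1, cos(2 * phi * pi / 180), sin(2 * phi * pi / 180), 0),
                 tolerance = 1e-12)
  }
})

test_that("transmit produces per-sector radial states, conserves intensity, keeps s3 = 0", {
  cfg <- svr_config()
  m <- svr_transmit(stokes(1, 1, 0, 0), cfg, c(64, 64), pixel_pitch = 6)
  inap <- !is.na(m$mask) & m$mask > 0
  expect_true(any(inap))
  # lossless half-wave sectors
  expect_equal(m$s[, , 1][inap], rep(1, sum(inap)))
  # half-wave plates cannot create circularity
  expect_equal(max(abs(m$s[, , 4][inap])), 0, tolerance = 1e-12)
  # each in-sector pixel is the linear state along its sector azimuth
  for (k in c(1, 3, 6)) {
    sel <- !is.na(m$mask) & m$mask == k
    phi <- (k - 1) * 45 * pi / 180
    expect_equal(unique(round(m$s[, , 2][sel], 12)), round(cos(2 * phi), 12))
    expect_equal(unique(round(m$s[, , 3][sel], 12)), round(sin(2 * phi), 12))
  }
  # outside the aperture: dark
  outside <- is.na(m$mask)
  expect_true(all(m$s[, , 1][outside] == 0))
})

test_that("gap pixels pass the input state through unmodified", {
  cfg <- svr_config(gap_angular_width = 6)
  m <- svr_transmit(stokes(1, 1, 0, 0), cfg, c(64, 64))
  gap <- !is.na(m$mask) & m$mask == 0L
  expect_true(any(gap))
  expect_equal(unique(m$s[, , 2][gap]), 1)
  expect_equal(unique(m$s[, , 3][gap]), 0)
})

test_that("zero-retardance sectors act as the identity", {
  cfg <- svr_config(retardance = 0)
  m <- svr_transmit(stokes(1, 1, 0, 0), cfg, c(32, 32))
  inap <- !is.na(m$mask)
  expect_equal(m$s[, , 2][inap], rep(1, sum(inap)), tolerance = 1e-12)
  expect_equal(m$s[, , 3][inap], rep(0, sum(inap)), tolerance = 1e-12)
})

test_that("ideal radial map holds (1, cos 2phi, sin 2phi, 0) at each azimuth", {
  m <- ideal_radial_map(c(65, 65), pixel_pitch = 6)
  # pixels on the +x axis (phi = 0), +y axis (phi = 90), and diagonal (phi = 45)
  ctr <- 33
  expect_equal(m$s[ctr, ctr + 10, ], c(1, 1, 0, 0), tolerance = 1e-12)
  expect_equal(m$s[ctr - 10, ctr, ], c(1, -1, 0, 0), tolerance = 1e-12)
  expect_equal(m$s[ctr - 10, ctr + 10, ], c(1, 0, 1, 0), tolerance = 1e-12)
  inap <- !is.na(m$mask)
  expect_true(all(is_physical_stokes(matrix(m$s, 65 * 65, 4)[inap, ])))
})

test_that("map agreement matches its definition and a brute-force oracle", {
  ref <- ideal_radial_map(c(48, 48))
  expect_equal(unname(map_agreement(ref, ref)), rep(100, 4))
  # uniform s1 offset of 0.02 * s0 gives exactly 98% on S1
  off <- ref
  off$s[, , 2] <- off$s[, , 2] + 0.02 * off$s[, , 1]
  acc <- map_agreement(off, ref)
  expect_equal(unname(acc["S1"]), 98)
  expect_equal(unname(acc["S0"]), 100)

  # 8-sector device vs continuous limit: brute-force average over the grid
  cfg <- svr_config()
  meas <- svr_transmit(stokes(1, 1, 0, 0), cfg, c(48, 48))
  acc2 <- map_agreement(meas, ref)
  keep <- !is.na(meas$mask) & meas$mask > 0 & !is.na(ref$mask)
  phi <- atan2(ref$s[, , 3], ref$s[, , 2])[keep] / 2   # pixel azimuth (mod 180)
  phik <- (meas$mask[keep] - 1) * 45 * pi / 180
  oracle_s1 <- 100 * (1 - mean(abs(cos(2 * phik) - cos(2 * phi))))
  expect_equal(unname(acc2["S1"]), oracle_s1, tolerance = 1e-10)
  expect_error(map_agreement(meas, ideal_radial_map(c(32, 32))), "geometry")
})

test_that("rotating the sector layout with the input frame leaves agreement unchanged", {
  ref <- ideal_radial_map(c(48, 48))
  base <- map_agreement(svr_transmit(stokes(1, 1, 0, 0), svr_config(input_axis = 0),
                                     c(48, 48)), ref)
  rot <- map_agreement(svr_transmit(
    apply_mueller(mueller_rotator(-30), c(1, 1, 0, 0)),  # linear at 30 deg
    svr_config(input_axis = 30), c(48, 48)), ref)
  expect_equal(rot, base, tolerance = 1e-10)
})

test_that("polarization maps roundtrip through TIFF + JSON sidecar", {
  dir <- withr::local_tempdir()
  m <- svr_transmit(stokes(1, 1, 0, 0), svr_config(gap_angular_width = 4), c(40, 40))
  prefix <- file.path(dir, "map")
  write_polarization_map(m, prefix)
  back <- read_polarization_map(prefix)
  # 16-bit fixed point over the plane range (here [-1, 1])
  expect_lt(max(abs(back$s - m$s)), 2 / 65535)
  expect_identical(back$mask, m$mask)
  expect_equal(back$pixel_pitch, m$pixel_pitch)
  # a re-write of the read map is byte-identical
  prefix2 <- file.path(dir, "map2")
  write_polarization_map(back, prefix2)
  expect_identical(readBin(paste0(prefix, ".tif"), "raw", 1e6),
                   readBin(paste0(prefix2, ".tif"), "raw", 1e6))
})

test_that("per-sector axis jitter is reproducible and perturbs the layout", {
  j1 <- svr_config(axis_jitter_sd = 2, jitter_seed = 5)
  j2 <- svr_config(axis_jitter_sd = 2, jitter_seed = 5)
  j3 <- svr_config(axis_jitter_sd = 2, jitter_seed = 6)
  expect_identical(j1$sector_fast_axes, j2$sector_fast_axes)
  expect_false(identical(j1$sector_fast_axes, j3$sector_fast_axes))
  expect_false(identical(j1$sector_fast_axes, svr_config()$sector_fast_axes))
  # jittered device is less radial than the ideal one
  ref <- ideal_radial_map(c(48, 48))
  acc_ideal <- map_agreement(svr_transmit(stokes(1, 1, 0, 0), svr_config(), c(48, 48)), ref)
  acc_jit <- map_agreement(svr_transmit(stokes(1, 1, 0, 0),
                                        svr_config(axis_jitter_sd = 5), c(48, 48)), ref)
  expect_lt(mean(acc_jit[2:3]), mean(acc_ideal[2:3]))
})
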