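test_that("retardation is linear in path length and hits the half-wave path", {
  expect_equal(retardation(0), 0)
  # delta * x = lambda / 2  =>  d = pi  (0.415 um / 0.007 = 59.2857 um)
  expect_equal(retardation(0.415 / 0.007, delta = 0.007, wavelength = 0.83), pi,
               tolerance = 1e-12)
  x <- c(3.7, 21, 80)
  expect_equal(retardation(2 * x), 2 * retardation(x))
  expect_error(retardation(-1), ">= 0")
})

test_that("depth-dependent degree of polarization decays exponentially", {
  expect_equal(depth_dop(0), 1)
  expect_equal(depth_dop(100, depol_length = 100), exp(-1))
  expect_equal(depth_dop(1e6), 0, tolerance = 1e-12)
  x <- seq(0, 200, by = 10)
  expect_true(all(diff(depth_dop(x)) < 0))
  expect_error(depth_dop(1, depol_length = 0), "> 0")
})

test_that("Mueller-chain intensities equal the closed forms on 1000 random tuples", {
  set.seed(77)
  n <- 1000
  th <- stats::runif(n, -180, 180)
  ps <- stats::runif(n, -180, 180)
  d <- stats::runif(n, 0, 2 * pi)
  p <- stats::runif(n)
  b <- stats::runif(n, 0, 0.2)
  for (i in seq_len(n)) {
    rel <- (th[i] - ps[i]) * pi / 180
    lin <- crossed_intensity(illumination_linear(th[i]), ps[i], d[i], p[i], b[i])
    expect_lt(abs(lin - (p[i] * sin(2 * rel)^2 * sin(d[i] / 2)^2 + b[i])), 1e-10)
    circ <- crossed_intensity(illumination_circular(1), ps[i], d[i], p[i], b[i])
    expect_lt(abs(circ - (p[i] * sin(d[i] / 2)^2 + b[i])), 1e-10)
    rad <- crossed_intensity(illumination_radial(8), ps[i], d[i], p[i], b[i])
    expect_lt(abs(rad - (0.5 * p[i] * sin(d[i] / 2)^2 + b[i])), 1e-10)
  }
})

test_that("circular and radial responses are independent of fiber orientation", {
  d <- 1.3; p <- 0.8
  base_c <- crossed_intensity(illumination_circular(1), 0, d, p)
  base_r8 <- crossed_intensity(illumination_radial(8), 0, d, p)
  base_r <- crossed_intensity(illumination_radial(360), 0, d, p)
  for (ps in c(13, 45, 90, 137.5)) {
    expect_lt(abs(crossed_intensity(illumination_circular(1), ps, d, p) - base_c), 1e-12)
    expect_lt(abs(crossed_intensity(illumination_radial(8), ps, d, p) - base_r8), 1e-12)
    expect_lt(abs(crossed_intensity(illumination_radial(360), ps, d, p) - base_r), 1e-12)
  }
  # the 8-sector discrete average already equals the continuous pupil average
  expect_lt(abs(base_r8 - base_r), 1e-12)
})

test_that("linear response has 90-degree period, minima at 0/90 and maximum at 45", {
  d <- 2.0; p <- 1
  ang <- seq(-180, 180, by = 7.5)
  i1 <- vapply(ang, function(a) crossed_intensity(illumination_linear(a), 0, d, p),
               numeric(1))
  i2 <- vapply(ang + 90, function(a) crossed_intensity(illumination_linear(a), 0, d, p),
               numeric(1))
  expect_equal(i1, i2, tolerance = 1e-12)
  expect_equal(crossed_intensity(illumination_linear(0), 0, d, p), 0, tolerance = 1e-12)
  expect_equal(crossed_intensity(illumination_linear(90), 0, d, p), 0, tolerance = 1e-12)
  i45 <- crossed_intensity(illumination_linear(45), 0, d, p)
  expect_equal(i45, sin(d / 2)^2, tolerance = 1e-12)
  fine <- seq(0, 180, by = 1)
  vals <- vapply(fine, function(a) crossed_intensity(illumination_linear(a), 0, d, p),
                 numeric(1))
  expect_equal(fine[which.max(vals)] %% 90, 45)
})

test_that("all illumination modes converge to the background as p -> 0", {
  b <- 0.05
  for (ill in list(illumination_linear(30), illumination_circular(1),
                   illumination_radial(8))) {
    expect_equal(crossed_intensity(ill, 10, 1.7, p = 0, b = b), b, tolerance = 1e-12)
  }
})

test_that("a non-birefringent fiber is indistinguishable from its background", {
  sc <- fiber_scene(delta = 0, background = "air", b = 1e-3, floor = 1e-3)
  img <- render_image(sc, illumination_linear(45), small_instrument(), depth = 20)
  expect_equal(max(img$intensity), min(img$intensity), tolerance = 1e-12)
})

test_that("rotating fiber and polarization together leaves the image unchanged", {
  ins <- instrument_config(fov = c(150, 150), pixels = c(180, 180))  # square px
  img0 <- render_image(fiber_scene(psi = 0, background = "air"),
                       illumination_linear(30), ins, depth = 15)
  img90 <- render_image(fiber_scene(psi = 90, background = "air"),
                        illumination_linear(120), ins, depth = 15)
  # 90-degree joint rotation maps the pixel grid onto itself (transpose)
  expect_equal(img90$intensity, t(img0$intensity), tolerance = 1e-12)
})

test_that("45-degree incidence is brighter than along-axis incidence over the fiber", {
  sc <- fiber_scene(background = "skin")
  ins <- small_instrument()
  fm <- fiber_mask(sc, ins)
  m0 <- render_image(sc, illumination_linear(0), ins, depth = 20, seed = 1)
  m45 <- render_image(sc, illumination_linear(45), ins, depth = 20, seed = 1)
  expect_gt(mean(m45$intensity[fm]), mean(m0$intensity[fm]))
})

test_that("depth series lose polarization monotonically and orientations converge", {
  sc <- fiber_scene(background = "skin", depol_length = 6)
  ins <- small_instrument()
  # central band only: edge pixels keep short chords at every depth and would
  # pin the orientation gap at a constant floor
  fm <- fiber_mask(sc, ins, erode_um = 15)
  depths <- c(25, 40, 60, 80)
  s0 <- render_depth_series(sc, illumination_linear(0), ins, depths, seed = 2)
  s45 <- render_depth_series(sc, illumination_linear(45), ins, depths, seed = 2)
  gap <- vapply(seq_along(depths), function(i) {
    abs(mean(s45[[i]]$intensity[fm]) - mean(s0[[i]]$intensity[fm]))
  }, numeric(1))
  # with depol_length << depth range, the orientation difference dies away
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[length(gap)] / gap[1], 0.1)
})

test_that("confocal images roundtrip through disk", {
  dir <- withr::local_tempdir()
  sc <- fiber_scene(background = "skin")
  img <- render_image(sc, illumination_circular(1), small_instrument(),
                      depth = 20, seed = 4)
  p <- file.path(dir, "img")
  write_confocal_image(img, p)
  back <- read_confocal_image(p)
  expect_equal(back$intensity, img$intensity, tolerance = 2e-7)
  expect_equal(back$metadata$depth, 20)
  # 8-bit variant quantizes but preserves scale
  write_confocal_image(img, paste0(p, "_8"), bit_depth = 8L)
  back8 <- read_confocal_image(paste0(p, "_8"))
  expect_lt(max(abs(back8$intensity - img$intensity)), max(img$intensity) / 255)
})

test_that("a fiber outside the field of view triggers an empty-footprint warning", {
  ins <- instrument_config(fov = c(100, 100), pixels = c(60, 60))
  # a vanishingly thin fiber misses every pixel centre
  sc <- fiber_scene(diameter = 1e-9)
  expect_warning(render_image(sc, illumination_circular(1), ins, depth = 5),
                 "outside the field of view")
})
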