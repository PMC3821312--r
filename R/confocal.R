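# Forward model of cross-polarized confocal imaging of a birefringent fiber
# (hair cortex) in a non-birefringent background, under linear, circular and
# radial illumination.
#
# Detection model: the illumination state, attenuated in its polarized part by
# the depth-dependent degree of polarization p, traverses the fiber section as
# a linear retarder with retardance d and fast axis along the fiber, and is
# analyzed by the crossed counterpart of the illumination (orthogonal linear,
# opposite circular, or per-azimuth crossed linear for radial light). The
# depolarized fraction is multiply-scattered light that the confocal pinhole
# rejects, so the analyzer's unpolarized throughput (1-p)/2 is removed from the
# detected signal. This makes the Mueller chain reproduce the closed forms
#   linear:   I = I0 * p * sin^2(2(theta - psi)) * sin^2(d/2) + b
#   circular: I = I0 * p * sin^2(d/2) + b
#   radial:   I = I0 * p * sin^2(d/2) / 2 + b
# exactly (the radial 1/2 is the pupil average of sin^2, echoing the lower
# focal intensity of radial beams).

#' Phase retardation accumulated along a birefringent path
#'
#' `d = 2 * pi * delta * x / wavelength`.
#'
#' @param x Optical path length in the birefringent medium (micrometres).
#' @param delta Birefringence `n_e - n_o` (0.007 for hair cortex).
#' @param wavelength Wavelength in micrometres (0.83 for the instrument
#'   modelled).
#' @return Phase in radians (vectorized over `x`).
#' @export
retardation <- function(x, delta = 0.007, wavelength = 0.83) {
  if (any(x < 0)) stop("path length `x` must be >= 0", call. = FALSE)
  2 * pi * delta * x / wavelength
}

#' Depth-dependent degree of polarization
#'
#' Phenomenological single-exponential loss of polarization with optical path
#' from multiple scattering: `p = exp(-x / depol_length)`.
#'
#' @param x Optical path length (micrometres).
#' @param depol_length Depolarization length (micrometres); default 100.
#' @return Fraction in `(0, 1]` (vectorized over `x`).
#' @export
depth_dop <- function(x, depol_length = 100) {
  if (any(x < 0)) stop("path length `x` must be >= 0", call. = FALSE)
  if (depol_length <= 0) stop("`depol_length` must be > 0", call. = FALSE)
  exp(-x / depol_length)
}

#' Illumination states
#'
#' @param theta Linear polarization axis in degrees (image frame).
#' @param handedness `+1` (right) or `-1` (left) circular.
#' @param n_azimuths Number of equally spaced pupil azimuths used for the
#'   incoherent radial average: 8 matches the segmented retarder; large values
#'   approximate the continuous ideal (the equally spaced average of `sin^2` is
#'   exactly 1/2 for any `n >= 3`, so both limits agree analytically).
#' @return Object of class `illumination`.
#' @name illumination
NULL

#' @rdname illumination
#' @export
illumination_linear <- function(theta = 0) {
  structure(list(mode = "linear", theta = theta), class = "illumination")
}

#' @rdname illumination
#' @export
illumination_circular <- function(handedness = 1) {
  if (!handedness %in% c(-1, 1)) stop("`handedness` must be +1 or -1", call. = FALSE)
  structure(list(mode = "circular", handedness = handedness), class = "illumination")
}

#' @rdname illumination
#' @export
illumination_radial <- function(n_azimuths = 8) {
  if (n_azimuths < 3) stop("`n_azimuths` must be >= 3", call. = FALSE)
  structure(list(mode = "radial", n_azimuths = as.integer(n_azimuths)),
            class = "illumination")
}

# Crossed-analyzer detection row for a linear illumination at `theta`.
crossed_linear_row <- function(theta) mueller_polarizer(theta + 90)[1, ]

# Crossed circular analyzer (QWP + polarizer unit of the opposite handedness):
# transmits the opposite circular state, first row (1, 0, 0, -h)/2.
crossed_circular_row <- function(handedness) {
  (mueller_polarizer(0) %*% mueller_retarder(pi / 2, 45 * handedness))[1, ]
}

# Mueller chain for one linear pupil component: depolarize, retard in the
# fiber frame (vectorized over d), analyze crossed. Returns detected intensity
# with the pinhole-rejected unpolarized leak (1-p)/2 removed.
linear_chain <- function(theta, psi, d, p, i0) {
  s_in <- apply_mueller(mueller_rotator(-theta), c(1, 1, 0, 0))  # linear at theta
  n <- max(length(d), length(p))
  d <- rep_len(d, n); p <- rep_len(p, n)
  s_dep <- cbind(i0, i0 * p * s_in[2], i0 * p * s_in[3], i0 * p * s_in[4])
  s_f <- apply_mueller(mueller_rotator(psi), s_dep)    # into the fiber frame
  cd <- cos(d); sd_ <- sin(d)                          # retarder at axis 0
  s_ret <- cbind(s_f[, 1], s_f[, 2],
                 s_f[, 3] * cd + s_f[, 4] * sd_,
                 -s_f[, 3] * sd_ + s_f[, 4] * cd)
  s_lab <- apply_mueller(mueller_rotator(-psi), s_ret)
  drop(s_lab %*% crossed_linear_row(theta)) - 0.5 * (1 - p) * i0
}

circular_chain <- function(handedness, psi, d, p, i0) {
  n <- max(length(d), length(p))
  d <- rep_len(d, n); p <- rep_len(p, n)
  s_dep <- cbind(i0, 0, 0, i0 * p * handedness)
  s_f <- apply_mueller(mueller_rotator(psi), s_dep)
  cd <- cos(d); sd_ <- sin(d)
  s_ret <- cbind(s_f[, 1], s_f[, 2],
                 s_f[, 3] * cd + s_f[, 4] * sd_,
                 -s_f[, 3] * sd_ + s_f[, 4] * cd)
  s_lab <- apply_mueller(mueller_rotator(-psi), s_ret)
  drop(s_lab %*% crossed_circular_row(handedness)) - 0.5 * (1 - p) * i0
}

#' Cross-polarized detected intensity of a birefringent element
#'
#' Evaluates the full Mueller chain (partial depolarizer, linear retarder with
#' fast axis along the fiber, crossed analyzer matched to the illumination)
#' for linear, circular or radial illumination. Radial illumination is an
#' incoherent average of linear pupil components over equally spaced azimuths,
#' each analyzed by its own crossed linear analyzer.
#'
#' @param illumination An [illumination_linear()], [illumination_circular()] or
#'   [illumination_radial()] state.
#' @param psi Fiber axis angle in the image plane (degrees).
#' @param d Retardance(s) in radians (see [retardation()]).
#' @param p Degree(s) of polarization surviving to the focus (see
#'   [depth_dop()]); recycled against `d`.
#' @param b Background intensity added to the detected signal.
#' @param i0 Illumination intensity.
#' @param orientation Offset (degrees) applied to the illumination polarization
#'   frame; this is how the two measurement orientations P1/P2 (45 degrees
#'   apart) are realized. A no-op for circular and (exactly, by symmetry) for
#'   radial light.
#' @return Detected intensity, vectorized over `d`/`p`.
#' @export
crossed_intensity <- function(illumination, psi, d, p = 1, b = 0, i0 = 1,
                              orientation = 0) {
  if (any(p < 0 | p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
  sig <- switch(illumination$mode,
    linear = linear_chain(illumination$theta + orientation, psi, d, p, i0),
    circular = circular_chain(illumination$handedness, psi, d, p, i0),
    radial = {
      az <- (seq_len(illumination$n_azimuths) - 1) * 360 / illumination$n_azimuths
      acc <- 0
      for (a in az) acc <- acc + linear_chain(a + orientation, psi, d, p, i0)
      acc / illumination$n_azimuths
    },
    stop("unknown illumination mode", call. = FALSE))
  sig + b
}

#' Instrument configuration
#'
#' @param wavelength Wavelength in micrometres.
#' @param fov Field of view `c(width, height)` in micrometres.
#' @param pixels Image size `c(width, height)` in pixels. The default maps a
#'   25 x 25 um region to 35 x 30 pixels, matching the imaging scale used in
#'   the ROI analysis.
#' @param power Illumination power in arbitrary units (recorded for the
#'   power-normalization step of the contrast analysis).
#' @return Object of class `instrument_config`.
#' @export
instrument_config <- function(wavelength = 0.83, fov = c(450, 400),
                              pixels = c(630, 480), power = 1) {
  structure(list(wavelength = wavelength, fov = fov,
                 pixels = as.integer(pixels), power = power,
                 pixel_size = fov / pixels),
            class = "instrument_config")
}

#' Birefringent fiber scene
#'
#' A cylindrical fiber (hair) lying in the image plane against a
#' non-birefringent background.
#'
#' @param psi Fiber axis angle in the image plane (degrees).
#' @param diameter Fiber diameter in micrometres (80 = typical scalp hair).
#' @param n_o,n_e Ordinary/extraordinary refractive indices of the cortex.
#' @param delta Birefringence; defaults to `n_e - n_o`.
#' @param background `"air"` (near-zero floor) or `"skin"` (positive level
#'   with multiplicative speckle texture).
#' @param b Background intensity level; defaults to `0.001` (air) or `0.05`
#'   (skin) in units of the illumination intensity.
#' @param speckle_sd Log-normal sigma of the skin speckle texture.
#' @param depol_length Depolarization length in micrometres (see [depth_dop()]).
#' @param pass_factor 1 for single-pass retardation to the focus, 2 for
#'   double-pass (illumination + backscattered return).
#' @param floor Residual detected floor inside the fiber footprint (same role
#'   as `b` for the background: keeps ratios finite).
#' @return Object of class `fiber_scene`.
#' @export
fiber_scene <- function(psi = 0, diameter = 80, n_o = 1.541, n_e = 1.548,
                        delta = n_e - n_o, background = c("air", "skin"),
                        b = NULL, speckle_sd = 0.3, depol_length = 100,
                        pass_factor = 1, floor = 1e-3) {
  background <- match.arg(background)
  if (is.null(b)) b <- if (background == "air") 1e-3 else 0.05
  if (b < 0) stop("`b` must be >= 0", call. = FALSE)
  structure(list(psi = psi, diameter = diameter, n_o = n_o, n_e = n_e,
                 delta = delta, background = background, b = b,
                 speckle_sd = speckle_sd, depol_length = depol_length,
                 pass_factor = pass_factor, floor = floor),
            class = "fiber_scene")
}

# Signed in-plane distance from each pixel centre to the fiber axis (a line
# through the image centre at angle psi), in micrometres.
fiber_offsets <- function(scene, instrument) {
  nc <- instrument$pixels[1]; nr <- instrument$pixels[2]
  px <- instrument$pixel_size[1]; py <- instrument$pixel_size[2]
  xs <- (seq_len(nc) - (nc + 1) / 2) * px
  ys <- ((nr + 1) / 2 - seq_len(nr)) * py
  x <- matrix(xs, nr, nc, byrow = TRUE)
  y <- matrix(ys, nr, nc)
  a <- deg2rad(scene$psi)
  -sin(a) * x + cos(a) * y
}

#' Fiber footprint mask
#'
#' @param scene A [fiber_scene()].
#' @param instrument An [instrument_config()].
#' @param erode_um Shrink the footprint by this margin (um) on each side, e.g.
#'   to keep ROIs away from the fiber edge.
#' @return Logical matrix (`TRUE` inside the fiber).
#' @export
fiber_mask <- function(scene, instrument, erode_um = 0) {
  abs(fiber_offsets(scene, instrument)) < scene$diameter / 2 - erode_um
}

#' Background mask
#'
#' @param scene A [fiber_scene()].
#' @param instrument An [instrument_config()].
#' @param margin_um Clearance (um) kept between the fiber edge and the mask.
#' @return Logical matrix (`TRUE` in usable background).
#' @export
background_mask <- function(scene, instrument, margin_um = 10) {
  abs(fiber_offsets(scene, instrument)) > scene$diameter / 2 + margin_um
}

# Per-pixel optical path (um) within the fiber for a focal plane at
# `depth` um below the fiber top surface: the chord of the circular
# cross-section from the entry surface down to the focal plane.
fiber_path <- function(scene, instrument, depth) {
  a <- scene$diameter / 2
  r <- abs(fiber_offsets(scene, instrument))
  inside <- r < a
  path <- matrix(0, nrow(r), ncol(r))
  h <- sqrt(pmax(a^2 - r[inside]^2, 0))
  entry <- a - h
  exit <- a + h
  path[inside] <- pmax(0, pmin(depth, exit) - entry) * scene$pass_factor
  path
}

#' Render a cross-polarized confocal image
#'
#' Pixels in the fiber footprint receive the crossed-analyzer Mueller-chain
#' intensity with per-pixel retardance and degree of polarization set by the
#' chord path length down to the focal plane; background pixels receive the
#' scene background (a near-zero floor for air, a seeded multiplicative
#' speckle texture for skin). Everything is scaled by the instrument power.
#'
#' @param scene A [fiber_scene()].
#' @param illumination An illumination state (see [illumination_linear()]).
#' @param instrument An [instrument_config()].
#' @param depth Focal depth below the fiber top surface (micrometres).
#' @param orientation Rotation (degrees) of the illumination polarization
#'   frame; the P1/P2 measurement orientations differ by 45 degrees here.
#' @param seed Seed for the background texture (skin scenes).
#' @return Object of class `confocal_image`: `intensity` matrix plus metadata.
#' @export
render_image <- function(scene, illumination, instrument = instrument_config(),
                         depth = 0, orientation = 0, seed = NULL) {
  path <- fiber_path(scene, instrument, depth)
  inside <- abs(fiber_offsets(scene, instrument)) < scene$diameter / 2
  if (!any(inside)) warning("fiber footprint is empty: fiber lies outside the field of view")
  intensity <- matrix(0, instrument$pixels[2], instrument$pixels[1])
  # background
  if (scene$background == "skin") {
    tex <- with_seed(seed, {
      n <- sum(!inside)
      exp(stats::rnorm(n, -scene$speckle_sd^2 / 2, scene$speckle_sd))
    })
    intensity[!inside] <- scene$b * tex
  } else {
    intensity[!inside] <- scene$b
  }
  # fiber signal
  if (any(inside)) {
    d <- retardation(path[inside], scene$delta, instrument$wavelength)
    p <- depth_dop(path[inside], scene$depol_length)
    intensity[inside] <- crossed_intensity(illumination, scene$psi, d, p,
                                           b = scene$floor, i0 = 1,
                                           orientation = orientation)
  }
  structure(list(intensity = intensity * instrument$power,
                 metadata = list(mode = illumination$mode, depth = depth,
                                 orientation = orientation, psi = scene$psi,
                                 power = instrument$power,
                                 pixel_size = instrument$pixel_size,
                                 background = scene$background, seed = seed)),
            class = "confocal_image")
}

#' @export
print.confocal_image <- function(x, ...) {
  d <- dim(x$intensity)
  m <- x$metadata
  cat(sprintf("<confocal_image> %d x %d px, %s illumination, depth %g um, orientation %g deg\n",
              d[1], d[2], m$mode, m$depth, m$orientation))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
plot.confocal_image <- function(x, ...) {
  graphics::image(t(x$intensity[nrow(x$intensity):1, ]), axes = FALSE,
                  col = grDevices::gray.colors(256, 0, 1),
                  main = sprintf("%s, depth %g um", x$metadata$mode, x$metadata$depth),
                  ...)
  invisible(x)
}

#' Render a focal-depth series
#'
#' @inheritParams render_image
#' @param depths Focal depths (micrometres).
#' @param seed Base seed; the background texture of depth `i` uses `seed + i`
#'   so the series shares one texture family but varies realistically.
#' @return List of [render_image()] results, one per depth.
#' @export
render_depth_series <- function(scene, illumination,
                                instrument = instrument_config(), depths,
                                orientation = 0, seed = NULL) {
  lapply(seq_along(depths), function(i) {
    s <- if (is.null(seed)) NULL else seed + i
    render_image(scene, illumination, instrument, depths[i], orientation, s)
  })
}
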