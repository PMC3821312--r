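# Segmented half-wave spatially variable retarder (SVR) and polarization maps.

#' Configuration of a segmented half-wave retarder
#'
#' Describes the sector layout of a spatially variable retarder built from
#' `n_sectors` pieces of half-wave plate, each with its own fast axis, which
#' converts a homogeneous linear beam into a nearly radially polarized beam.
#' Sector `k` spans azimuths `[phi_k - span/2, phi_k + span/2)` with
#' `phi_k = (k - 1) * 360 / n_sectors`, minus half a gap on each side.
#'
#' @param n_sectors Number of wave-plate sectors (>= 2; 8 for the device
#'   modelled here).
#' @param input_axis Polarization axis of the incoming linear beam (degrees);
#'   determines the default fast axes via [sector_axes()].
#' @param sector_fast_axes Optional explicit fast axes (degrees), one per
#'   sector; defaults to the radial-converter layout.
#' @param gap_angular_width Angular width (degrees) of the air gap between
#'   adjacent sectors; gap light passes through unmodified.
#' @param retardance Retardance of every sector in radians (`pi` = half-wave).
#' @param aperture_radius Radius of the clear aperture in micrometres;
#'   `NULL` means "fit the grid" (half the smaller grid extent).
#' @param axis_jitter_sd Standard deviation (degrees) of random per-sector
#'   fast-axis misalignment, emulating cutting/mounting inaccuracy; 0 = ideal.
#' @param jitter_seed Seed used to draw the jitter (so imperfect devices are
#'   reproducible).
#' @return An object of class `svr_config`.
#' @export
svr_config <- function(n_sectors = 8, input_axis = 0, sector_fast_axes = NULL,
                       gap_angular_width = 0, retardance = pi,
                       aperture_radius = NULL, axis_jitter_sd = 0,
                       jitter_seed = 1L) {
  if (n_sectors < 2) stop("`n_sectors` must be >= 2", call. = FALSE)
  span <- 360 / n_sectors
  if (gap_angular_width < 0 || gap_angular_width >= span) {
    stop("`gap_angular_width` must be in [0, 360/n_sectors)", call. = FALSE)
  }
  if (is.null(sector_fast_axes)) {
    sector_fast_axes <- sector_axes(n_sectors, input_axis)
  }
  if (length(sector_fast_axes) != n_sectors) {
    stop("`sector_fast_axes` must have one angle per sector", call. = FALSE)
  }
  if (axis_jitter_sd > 0) {
    jit <- with_seed(jitter_seed, stats::rnorm(n_sectors, 0, axis_jitter_sd))
    sector_fast_axes <- sector_fast_axes + jit
  }
  structure(list(n_sectors = as.integer(n_sectors), input_axis = input_axis,
                 sector_fast_axes = sector_fast_axes,
                 gap_angular_width = gap_angular_width,
                 retardance = retardance,
                 aperture_radius = aperture_radius),
            class = "svr_config")
}

#' Default sector fast axes of a radial converter
#'
#' For a half-wave sector centred at azimuth `phi_k`, a fast axis at
#' `(phi_k + input_axis) / 2` maps linear input at `input_axis` onto linear
#' output along `phi_k` — the local radial direction.
#'
#' @param n_sectors Number of sectors.
#' @param input_axis Input polarization axis in degrees.
#' @return Numeric vector of fast-axis angles (degrees), one per sector.
#' @export
sector_axes <- function(n_sectors, input_axis = 0) {
  if (n_sectors < 2) stop("`n_sectors` must be >= 2", call. = FALSE)
  phi <- (seq_len(n_sectors) - 1) * 360 / n_sectors
  (phi + input_axis) / 2
}

#' Spatial map of Stokes vectors
#'
#' Container for per-pixel polarization states on a regular grid.
#'
#' @param s Numeric array `nrow x ncol x 4` holding S0..S3 planes.
#' @param pixel_pitch Pixel size in micrometres (square pixels).
#' @param mask Integer matrix, same grid: sector index `k >= 1` for pixels
#'   behind sector `k`, `0` for gap pixels, `NA` outside the aperture. `NULL`
#'   means all pixels valid (coded as sector 1).
#' @return Object of class `polarization_map`.
#' @export
polarization_map <- function(s, pixel_pitch = 6, mask = NULL) {
  stopifnot(length(dim(s)) == 3L, dim(s)[3] == 4L)
  if (is.null(mask)) mask <- matrix(1L, dim(s)[1], dim(s)[2])
  stopifnot(all(dim(mask) == dim(s)[1:2]))
  structure(list(s = s, pixel_pitch = pixel_pitch, mask = mask),
            class = "polarization_map")
}

#' @export
print.polarization_map <- function(x, ...) {
  d <- dim(x$s)
  n_in <- sum(!is.na(x$mask))
  cat(sprintf("<polarization_map> %d x %d px (pitch %g um), %d in-aperture px\n",
              d[1], d[2], x$pixel_pitch, n_in))
  s0 <- x$s[, , 1][!is.na(x$mask)]
  if (length(s0)) {
    cat(sprintf("  S0 range [%.4g, %.4g]; mean dop %.4f\n",
                min(s0), max(s0), mean(map_dop(x), na.rm = TRUE)))
  }
  invisible(x)
}

# Per-pixel degree of polarization of a map (NA outside aperture / dark pixels).
map_dop <- function(map) {
  s0 <- map$s[, , 1]
  num <- sqrt(map$s[, , 2]^2 + map$s[, , 3]^2 + map$s[, , 4]^2)
  out <- num / s0
  out[s0 <= 0 | is.na(map$mask)] <- NA_real_
  out
}

#' @export
plot.polarization_map <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (i in 1:4) {
    graphics::image(t(x$s[dim(x$s)[1]:1, , i]), axes = FALSE,
                    col = grDevices::hcl.colors(64, "Blue-Red 2"),
                    main = paste0("S", i - 1), ...)
  }
  invisible(x)
}

# Pixel-centre coordinates (um) and azimuth (deg, [0, 360)) for a grid, with
# the origin at the grid centre and y increasing upward (row 1 is the top).
grid_geometry <- function(grid_shape, pixel_pitch) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  xs <- (seq_len(nc) - (nc + 1) / 2) * pixel_pitch
  ys <- ((nr + 1) / 2 - seq_len(nr)) * pixel_pitch
  x <- matrix(xs, nr, nc, byrow = TRUE)
  y <- matrix(ys, nr, nc)
  phi <- (atan2(y, x) * 180 / pi) %% 360
  list(x = x, y = y, r = sqrt(x^2 + y^2), phi = phi)
}

# Sector / gap / aperture classification for every pixel of a grid.
classify_pixels <- function(config, grid_shape, pixel_pitch) {
  g <- grid_geometry(grid_shape, pixel_pitch)
  span <- 360 / config$n_sectors
  rel <- (g$phi + span / 2) %% 360
  k <- floor(rel / span) + 1L
  offset <- rel %% span - span / 2
  mask <- matrix(as.integer(k), grid_shape[1], grid_shape[2])
  if (config$gap_angular_width > 0) {
    half_open <- (span - config$gap_angular_width) / 2
    mask[abs(offset) > half_open] <- 0L
  }
  ap <- config$aperture_radius
  if (is.null(ap)) ap <- min(grid_shape) * pixel_pitch / 2
  mask[g$r > ap] <- NA_integer_
  list(mask = mask, phi = g$phi, r = g$r)
}

#' Transmit a beam through the segmented retarder
#'
#' Applies each sector's retarder Mueller matrix to the (homogeneous) input
#' state pixel by pixel. Gap pixels carry the unmodified input state (light
#' passing between the sectors is not transformed); pixels outside the clear
#' aperture carry zero intensity.
#'
#' @param input Stokes vector of the incoming beam. A fully polarized linear
#'   state is the intended use; anything else raises a warning.
#' @param config An [svr_config()].
#' @param grid_shape `c(nrow, ncol)` of the output map.
#' @param pixel_pitch Pixel size in micrometres.
#' @return A [polarization_map()] with sector/gap/aperture mask.
#' @export
svr_transmit <- function(input, config = svr_config(), grid_shape = c(128, 128),
                         pixel_pitch = 6) {
  if (abs(stokes_dop(input) - 1) > 1e-6 || abs(input[4]) > 1e-9 * input[1]) {
    warning("SVR input is not fully polarized linear light; model is intended for linear input")
  }
  cls <- classify_pixels(config, grid_shape, pixel_pitch)
  s <- array(0, c(grid_shape[1], grid_shape[2], 4))
  # one Mueller matrix per sector: output state is constant within a sector
  for (k in seq_len(config$n_sectors)) {
    m <- mueller_retarder(config$retardance, config$sector_fast_axes[k])
    out_k <- apply_mueller(m, input)
    sel <- !is.na(cls$mask) & cls$mask == k
    for (i in 1:4) {
      plane <- s[, , i]
      plane[sel] <- out_k[i]
      s[, , i] <- plane
    }
  }
  gap <- !is.na(cls$mask) & cls$mask == 0L
  if (any(gap)) {
    for (i in 1:4) {
      plane <- s[, , i]
      plane[gap] <- input[i]
      s[, , i] <- plane
    }
  }
  polarization_map(s, pixel_pitch, cls$mask)
}

#' Ideal continuous radially polarized map
#'
#' The continuous-limit reference the segmented device approximates: at pixel
#' azimuth `phi` the state is `(1, cos 2phi, sin 2phi, 0)` (unit intensity,
#' fully linear, polarized along the local radius).
#'
#' @param grid_shape `c(nrow, ncol)`.
#' @param pixel_pitch Pixel size in micrometres.
#' @param aperture_radius Clear-aperture radius (um); `NULL` fits the grid.
#' @return A [polarization_map()].
#' @export
ideal_radial_map <- function(grid_shape = c(128, 128), pixel_pitch = 6,
                             aperture_radius = NULL) {
  g <- grid_geometry(grid_shape, pixel_pitch)
  ap <- if (is.null(aperture_radius)) min(grid_shape) * pixel_pitch / 2 else aperture_radius
  a <- deg2rad(2 * g$phi)
  s <- array(0, c(grid_shape[1], grid_shape[2], 4))
  s[, , 1] <- 1
  s[, , 2] <- cos(a)
  s[, , 3] <- sin(a)
  mask <- matrix(1L, grid_shape[1], grid_shape[2])
  out <- g$r > ap
  mask[out] <- NA_integer_
  for (i in 1:4) {
    plane <- s[, , i]
    plane[out] <- 0
    s[, , i] <- plane
  }
  polarization_map(s, pixel_pitch, mask)
}

#' Per-component agreement between two polarization maps
#'
#' For each Stokes component `i`,
#' `accuracy_i = 100 * (1 - mean(|S_i,meas - S_i,ref| / S0,ref))`
#' averaged over included pixels. Gap pixels and pixels outside the aperture
#' can be excluded via the masks.
#'
#' @param measured,reference [polarization_map()]s on the same grid.
#' @param exclude_gaps Drop pixels flagged as gaps (mask == 0) in either map.
#' @param worst Also report the worst-pixel accuracy per component.
#' @return Named numeric vector `c(S0 =, S1 =, S2 =, S3 =)` in percent, with
#'   attribute `"worst"` when `worst = TRUE`.
#' @export
map_agreement <- function(measured, reference, exclude_gaps = TRUE, worst = FALSE) {
  if (!all(dim(measured$s) == dim(reference$s))) {
    stop("maps have different geometry", call. = FALSE)
  }
  keep <- !is.na(measured$mask) & !is.na(reference$mask)
  if (exclude_gaps) keep <- keep & measured$mask != 0L & reference$mask != 0L
  s0 <- reference$s[, , 1][keep]
  keep2 <- s0 > 0
  acc <- numeric(4); wst <- numeric(4)
  for (i in 1:4) {
    rel <- abs(measured$s[, , i][keep][keep2] - reference$s[, , i][keep][keep2]) / s0[keep2]
    acc[i] <- 100 * (1 - mean(rel))
    wst[i] <- 100 * (1 - max(rel))
  }
  names(acc) <- names(wst) <- paste0("S", 0:3)
  if (worst) attr(acc, "worst") <- wst
  acc
}
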