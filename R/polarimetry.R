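# Rotating circular-polarizer Stokes polarimeter: forward simulation of 8-bit
# averaged CCD frame stacks and per-pixel least-squares reconstruction.
#
# The analyzer is a rigid quarter-wave plate + linear polarizer unit with their
# axes 45 degrees apart. With the QWP facing the light ("normal") the unit is a
# circular analyzer: detected intensity = (S0 + S3)/2, independent of the unit
# rotation. Flipped by 180 degrees the polarizer faces the light and the unit
# acts as a linear analyzer at the polarizer axis: (S0 + S1 cos 2a + S2 sin 2a)/2.

#' One analyzer setting of the polarimeter
#'
#' @param orientation `"flipped"` (polarizer faces the light: linear analyzer)
#'   or `"normal"` (QWP faces the light: circular analyzer).
#' @param angle Rotation angle (degrees) of the rigid QWP+polarizer unit; in
#'   this model the polarizer transmission axis sits at `angle` and the QWP
#'   fast axis at `angle - 45`.
#' @return Object of class `analyzer_setting`.
#' @export
analyzer_setting <- function(orientation = c("flipped", "normal"), angle = 0) {
  orientation <- match.arg(orientation)
  structure(list(orientation = orientation, angle = angle),
            class = "analyzer_setting")
}

#' Detection row of an analyzer setting
#'
#' First row of the unit's Mueller matrix, built by composing
#' [mueller_polarizer()] and [mueller_retarder()] in the order the light
#' traverses them; detected intensity is the dot product with the incident
#' Stokes vector.
#'
#' @param setting An [analyzer_setting()].
#' @return Numeric length-4 vector `a` with `I = a . S`.
#' @export
analyzer_row <- function(setting) {
  p <- mueller_polarizer(setting$angle)
  q <- mueller_retarder(pi / 2, setting$angle - 45)
  m <- switch(setting$orientation,
              normal  = p %*% q,   # light meets the QWP first
              flipped = q %*% p)   # light meets the polarizer first
  m[1, ]
}

#' Default measurement protocol
#'
#' Four linear-analyzer (flipped) settings at 0, 45, 90, 135 degrees plus one
#' circular-analyzer (normal) setting: the minimal full-rank set that
#' separates S0..S2 from the rotation series and S3 from the flip.
#'
#' @param flipped_angles Rotation angles (degrees) used with the polarizer
#'   facing the light.
#' @param normal_angles Rotation angles used with the QWP facing the light.
#' @return List of [analyzer_setting()]s.
#' @export
default_protocol <- function(flipped_angles = c(0, 45, 90, 135),
                             normal_angles = 0) {
  c(lapply(flipped_angles, function(a) analyzer_setting("flipped", a)),
    lapply(normal_angles, function(a) analyzer_setting("normal", a)))
}

protocol_design <- function(protocol) {
  a <- t(vapply(protocol, analyzer_row, numeric(4)))
  rownames(a) <- vapply(protocol, function(s)
    sprintf("%s@%g", s$orientation, s$angle), character(1))
  a
}

check_protocol_rank <- function(protocol) {
  a <- protocol_design(protocol)
  r <- qr(a)$rank
  if (r < 4L) {
    has_normal <- any(vapply(protocol, function(s) s$orientation == "normal", logical(1)))
    hint <- if (!has_normal) {
      "no 'normal' (circular-analyzer) setting: S3 is unobservable"
    } else {
      "need >= 3 distinct flipped rotation angles to separate S0, S1, S2"
    }
    stop(sprintf("analyzer protocol is rank-deficient (rank %d < 4): %s", r, hint),
         call. = FALSE)
  }
  a
}

#' CCD camera model
#'
#' @param bit_depth Bits per recorded sample (8 for the frame grabber
#'   modelled); `Inf` disables quantization and clipping (an idealized
#'   continuous detector, useful for noise-free consistency checks).
#' @param full_scale Incident intensity that maps to the top digital count;
#'   `NULL` (default) auto-exposes so the brightest ideal pixel of a stack sits
#'   at 90 percent of full scale, avoiding saturation.
#' @param read_noise_sd Read noise standard deviation in digital counts per frame.
#' @param shot_noise Include photon shot noise (Gaussian, variance = mean counts)?
#' @param pixel_pitch Pixel size in micrometres.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(bit_depth = 8, full_scale = NULL, read_noise_sd = 1,
                         shot_noise = TRUE, pixel_pitch = 6) {
  structure(list(bit_depth = if (is.finite(bit_depth)) as.integer(bit_depth) else Inf,
                 full_scale = full_scale,
                 read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 pixel_pitch = pixel_pitch),
            class = "camera_model")
}

#' Quantized multi-frame camera acquisition
#'
#' Shared noise core: per frame adds shot noise (Gaussian approximation to
#' photon counting, variance = mean counts) and read noise to the ideal count
#' image, quantizes to the camera bit depth by rounding with clipping at full
#' scale, and averages `n_frames` frames.
#'
#' @param ideal_counts Numeric matrix/vector of noise-free mean counts.
#' @param camera A [camera_model()].
#' @param n_frames Number of frames averaged (>= 1).
#' @param seed Seed for the per-frame noise; `NULL` uses the current RNG state.
#' @return Averaged count image, same shape as `ideal_counts` (not rounded:
#'   the average of quantized frames).
#' @export
camera_digitize <- function(ideal_counts, camera = camera_model(), n_frames = 1,
                            seed = NULL) {
  if (n_frames < 1) stop("`n_frames` must be >= 1", call. = FALSE)
  maxc <- 2^camera$bit_depth - 1
  mu <- pmin(pmax(as.numeric(ideal_counts), 0), Inf)
  n <- length(mu)
  noisy <- camera$shot_noise || camera$read_noise_sd > 0
  acc <- with_seed(seed, {
    acc <- numeric(n)
    sd_frame <- if (camera$shot_noise) sqrt(mu + camera$read_noise_sd^2)
                else rep(camera$read_noise_sd, n)
    quantize <- is.finite(maxc)
    for (f in seq_len(n_frames)) {
      frame <- if (noisy) mu + stats::rnorm(n, 0, sd_frame) else mu
      acc <- acc + if (quantize) pmin(pmax(round(frame), 0), maxc) else frame
    }
    acc
  })
  out <- acc / n_frames
  if (is.matrix(ideal_counts)) dim(out) <- dim(ideal_counts)
  out
}

#' Simulate a polarimeter frame stack
#'
#' For every analyzer setting, forms the ideal detected intensity `a . S` per
#' pixel of the truth map, converts to camera counts with an auto- or fixed
#' exposure, applies per-frame shot/read noise with quantization, and averages
#' `n_averaged` frames.
#'
#' @param truth A [polarization_map()] of the incident beam.
#' @param protocol List of [analyzer_setting()]s; must be full rank.
#' @param camera A [camera_model()].
#' @param n_averaged Frames averaged per setting.
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @return Object of class `frame_stack`: averaged count images (one per
#'   setting), the protocol, camera with realized gain, and geometry.
#' @export
simulate_stack <- function(truth, protocol = default_protocol(),
                           camera = camera_model(), n_averaged = 256,
                           seed = NULL) {
  a <- check_protocol_rank(protocol)
  dims <- dim(truth$s)
  npx <- dims[1] * dims[2]
  smat <- matrix(truth$s, npx, 4)
  ideal <- smat %*% t(a)   # npx x n_settings ideal intensities
  maxc <- 2^camera$bit_depth - 1
  gain <- if (!is.finite(maxc)) {
    1
  } else if (is.null(camera$full_scale)) {
    0.9 * maxc / max(ideal)
  } else {
    maxc / camera$full_scale
  }
  frames <- with_seed(seed, {
    lapply(seq_along(protocol), function(j) {
      f <- camera_digitize(ideal[, j] * gain, camera, n_averaged, seed = NULL)
      matrix(f, dims[1], dims[2])
    })
  })
  structure(list(settings = protocol, frames = frames, n_averaged = n_averaged,
                 camera = camera, gain = gain, pixel_pitch = truth$pixel_pitch,
                 mask = truth$mask, seed = seed),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d settings, %d x %d px, %d frames averaged, gain %.4g counts/unit\n",
              length(x$settings), d[1], d[2], x$n_averaged, x$gain))
  for (s in x$settings) cat(sprintf("  %s @ %g deg\n", s$orientation, s$angle))
  invisible(x)
}

#' Reconstruct Stokes parameters from a frame stack
#'
#' Per-pixel ordinary least squares on `I_j = a_j . S` over all settings,
#' solved for the whole image with one normal-equation factorization. The
#' result is projected onto the physical cone (degree of polarization clipped
#' to 1, direction preserved); the raw pre-projection residual norm is
#' attached.
#'
#' @param stack A `frame_stack` from [simulate_stack()] or [read_frame_stack()].
#' @return A [polarization_map()] with attributes `residual` (pixel matrix of
#'   residual norms in intensity units) and `clipped` (fraction of pixels whose
#'   dop was clipped).
#' @export
reconstruct_stokes <- function(stack) {
  a <- check_protocol_rank(stack$settings)
  d <- dim(stack$frames[[1]])
  intens <- vapply(stack$frames, function(f) as.numeric(f) / stack$gain,
                   numeric(d[1] * d[2]))          # npx x n_settings
  # OLS: S-hat = (A'A)^{-1} A' I, all pixels at once
  sol <- solve(crossprod(a), t(a) %*% t(intens))  # 4 x npx
  fit <- a %*% sol
  resid <- sqrt(colSums((fit - t(intens))^2))
  s <- t(sol)
  # physical projection: radially clip (s1,s2,s3) into the cone |P| <= s0
  s0 <- pmax(s[, 1], 0)
  pnorm_ <- sqrt(rowSums(s[, 2:4, drop = FALSE]^2))
  over <- pnorm_ > s0 & pnorm_ > 0
  if (any(over)) {
    scale <- s0[over] / pnorm_[over]
    s[over, 2:4] <- s[over, 2:4, drop = FALSE] * scale
  }
  s[, 1] <- s0
  arr <- array(s, c(d[1], d[2], 4))
  out <- polarization_map(arr, stack$pixel_pitch, stack$mask)
  attr(out, "residual") <- matrix(resid, d[1], d[2])
  attr(out, "clipped") <- mean(over)
  out
}

#' Reconstruction accuracy report
#'
#' Delegates to [map_agreement()] and adds the worst-pixel accuracy per
#' component.
#'
#' @param measured,truth [polarization_map()]s on the same grid.
#' @param exclude_gaps Exclude gap-flagged pixels.
#' @return Named percent vector with `"worst"` attribute (see [map_agreement()]).
#' @export
accuracy_report <- function(measured, truth, exclude_gaps = TRUE) {
  map_agreement(measured, truth, exclude_gaps = exclude_gaps, worst = TRUE)
}

#' Uniform polarization map

#' @param s Stokes vector replicated at every pixel.
#' @param grid_shape `c(nrow, ncol)`.
#' @param pixel_pitch Pixel size (um).
#' @return A [polarization_map()].
#' @export
uniform_map <- function(s, grid_shape = c(128, 128), pixel_pitch = 6) {
  arr <- array(rep(s, each = grid_shape[1] * grid_shape[2]),
               c(grid_shape[1], grid_shape[2], 4))
  polarization_map(arr, pixel_pitch)
}
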