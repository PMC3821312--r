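# Shared generators for property-style tests.

# n points roughly uniform on the Poincare sphere (pure states, s0 = 1),
# via a Fibonacci lattice: deterministic, no RNG needed.
poincare_sphere <- function(n = 100) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(1 - z^2)
  cbind(1, r * cos(phi), r * sin(phi), z)
}

# Random physical (possibly partially polarized) Stokes vector.
random_stokes <- function() {
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  s0 <- stats::runif(1, 0.2, 2)
  p <- stats::runif(1)
  c(s0, s0 * p * dir)
}

# Noise-free idealized camera: continuous detector, no noise.
ideal_camera <- function() {
  camera_model(bit_depth = Inf, read_noise_sd = 0, shot_noise = FALSE)
}

# Small instrument for fast confocal tests (same 25 um -> 35 x 30 px scale).
small_instrument <- function(power = 1) {
  instrument_config(fov = c(150, 150), pixels = c(210, 180), power = power)
}
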