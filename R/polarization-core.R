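# Mueller/Stokes algebra: states, element matrices, composition, scalars.
#
# A Stokes vector is a plain numeric vector (s0, s1, s2, s3); a Mueller matrix
# is a plain 4x4 numeric matrix. Keeping these as base types lets whole image
# grids be processed as n x 4 matrices with one matrix product.

#' Construct a Stokes vector
#'
#' @param s0 Total intensity (arbitrary linear units, must be >= 0).
#' @param s1,s2 Linear polarization components (0/90 degree and +/-45 degree).
#' @param s3 Circular component; `s3 > 0` is right circular by convention.
#' @param check If `TRUE` (default) verify physicality:
#'   `s0^2 >= s1^2 + s2^2 + s3^2` up to rounding.
#' @return Numeric vector of length 4.
#' @examples
#' stokes(1, 1, 0, 0)          # horizontal linear
#' stokes(1, 0, 0, 0)          # unpolarized
#' @export
stokes <- function(s0, s1 = 0, s2 = 0, s3 = 0, check = TRUE) {
  s <- c(s0, s1, s2, s3)
  if (check && !is_physical_stokes(s)) {
    stop("non-physical Stokes vector: requires s0 >= 0 and s0^2 >= s1^2 + s2^2 + s3^2",
         call. = FALSE)
  }
  s
}

#' Test Stokes physicality
#'
#' @param s Stokes vector (length 4) or an n x 4 matrix of Stokes rows.
#' @param tol Relative slack on the polarized-fraction bound.
#' @return Logical (vector for matrix input).
#' @export
is_physical_stokes <- function(s, tol = 1e-9) {
  if (is.matrix(s)) {
    p2 <- rowSums(s[, 2:4, drop = FALSE]^2)
    return(s[, 1] >= -tol & p2 <= s[, 1]^2 * (1 + tol) + tol)
  }
  p2 <- sum(s[2:4]^2)
  s[1] >= -tol && p2 <= s[1]^2 * (1 + tol) + tol
}

#' Degree of polarization
#'
#' `sqrt(s1^2 + s2^2 + s3^2) / s0`, in `[0, 1]` for physical states.
#'
#' @param s Stokes vector or n x 4 matrix.
#' @return Numeric scalar (or vector for matrix input).
#' @examples
#' stokes_dop(stokes(1, 1, 0, 0))  # 1
#' stokes_dop(stokes(1, 0, 0, 0))  # 0
#' @export
stokes_dop <- function(s) {
  if (is.matrix(s)) {
    s0 <- s[, 1]
    if (any(s0 <= 0)) stop("dop undefined for s0 <= 0", call. = FALSE)
    return(sqrt(rowSums(s[, 2:4, drop = FALSE]^2)) / s0)
  }
  if (s[1] <= 0) stop("dop undefined for s0 <= 0", call. = FALSE)
  sqrt(sum(s[2:4]^2)) / s[1]
}

#' Mueller rotation matrix
#'
#' Rotates the Stokes frame by `theta` degrees (a rotation by `2*theta` in the
#' (s1, s2) plane). Satisfies `mueller_rotator(a) %*% mueller_rotator(b) ==
#' mueller_rotator(a + b)`.
#'
#' @param theta Rotation angle in degrees.
#' @return 4x4 Mueller matrix.
#' @export
mueller_rotator <- function(theta) {
  stopifnot_scalar(theta)
  a <- deg2rad(2 * theta)
  c2 <- cos(a); s2 <- sin(a)
  matrix(c(1, 0, 0, 0,
           0, c2, s2, 0,
           0, -s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Linear retarder Mueller matrix
#'
#' Textbook linear retarder with phase `retardance` (radians) and fast axis at
#' `fast_axis` degrees. `retardance = pi` is a half-wave plate, `pi/2` a
#' quarter-wave plate; `retardance = 0` gives the identity.
#'
#' @param retardance Phase delay in radians.
#' @param fast_axis Fast-axis angle in degrees.
#' @return 4x4 Mueller matrix.
#' @examples
#' # half-wave plate at 22.5 degrees rotates horizontal to +45 linear
#' apply_mueller(mueller_retarder(pi, 22.5), stokes(1, 1, 0, 0))
#' @export
mueller_retarder <- function(retardance, fast_axis = 0) {
  stopifnot_scalar(retardance)
  cd <- cos(retardance); sd <- sin(retardance)
  m0 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, cd, sd,
                 0, 0, -sd, cd), 4, 4, byrow = TRUE)
  rotate_element(m0, fast_axis)
}

#' Ideal linear polarizer Mueller matrix
#'
#' @param axis Transmission axis in degrees.
#' @return 4x4 Mueller matrix; idempotent (`P %*% P == P`).
#' @export
mueller_polarizer <- function(axis = 0) {
  stopifnot_scalar(axis)
  m0 <- 0.5 * matrix(c(1, 1, 0, 0,
                       1, 1, 0, 0,
                       0, 0, 0, 0,
                       0, 0, 0, 0), 4, 4, byrow = TRUE)
  rotate_element(m0, axis)
}

#' Isotropic partial depolarizer
#'
#' `diag(1, p, p, p)`: keeps total intensity, scales the polarized part by
#' `p`. `p = 1` is the identity, `p = 0` fully depolarizes.
#'
#' @param p Retained polarized fraction in `[0, 1]`.
#' @return 4x4 Mueller matrix.
#' @export
mueller_depolarizer <- function(p) {
  stopifnot_scalar(p)
  if (p < 0 || p > 1) stop("depolarizer fraction `p` must be in [0, 1]", call. = FALSE)
  diag(c(1, p, p, p))
}

# Express an element defined in its own frame at angle `axis` in the lab frame.
rotate_element <- function(m0, axis) {
  mueller_rotator(-axis) %*% m0 %*% mueller_rotator(axis)
}

#' Apply a Mueller matrix to Stokes states
#'
#' @param m 4x4 Mueller matrix.
#' @param s Stokes vector (length 4) or n x 4 matrix of Stokes rows.
#' @return Same shape as `s`.
#' @export
apply_mueller <- function(m, s) {
  if (is.matrix(s)) return(s %*% t(m))
  drop(m %*% s)
}
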