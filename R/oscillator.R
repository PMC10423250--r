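#' Normal-form oscillator parameters
#'
#' A single circadian oscillator in the normal form: a circular limit cycle
#' of radius `a` (so the peak-to-trough amplitude of each coordinate is
#' `2a`), traversed counterclockwise at constant angular velocity `omega`,
#' with radial attraction rate controlled by `epsilon`
#' (`dr/dt = epsilon * r * (a^2 - r^2)`).
#'
#' @param omega angular velocity in rad/h. The intrinsic period is
#'   `2*pi/omega`; the default gives exactly 24 h.
#' @param a limit-cycle radius in nM. See [nominal_oscillator()] for the
#'   calibrated default.
#' @param epsilon radial relaxation coefficient in 1/(h nM^2). Must be
#'   non-negative; zero gives a neutrally stable (conservative) radius and
#'   is allowed for diagnostic use.
#' @return An object of class `oscillator_params`.
#' @examples
#' p <- oscillator_params(a = 8.7)
#' 2 * pi / p$omega   # intrinsic period, hours
#' @export
oscillator_params <- function(omega = 2 * pi / 24, a, epsilon = 1e-4) {
  check_positive(omega, "omega")
  check_positive(a, "a")
  check_positive(epsilon, "epsilon", strict = FALSE)
  period <- 2 * pi / omega
  structure(list(omega = omega, a = a, epsilon = epsilon, period = period),
            class = "oscillator_params")
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat("<oscillator_params>\n")
  cat(sprintf("  omega   = %.6g rad/h  (period %.4g h)\n", x$omega, x$period))
  cat(sprintf("  a       = %.6g nM\n", x$a))
  cat(sprintf("  epsilon = %.6g 1/(h nM^2)\n", x$epsilon))
  invisible(x)
}

#' Nominal calibrated oscillator
#'
#' Returns the package's nominal single-cell parameters: `omega = 2*pi/24`,
#' `epsilon = 1e-4`, and the limit-cycle radius `a` calibrated by
#' [calibrate_radius()] so that the critical light pulse (3-hour
#' light-induced transcription starting at CT17, push 3 nM/h) drives an
#' on-cycle oscillator as close as possible to the singularity point at the
#' origin. The calibration result (about 8.65 nM) is cached per session.
#'
#' @param omega,epsilon as in [oscillator_params()].
#' @return An `oscillator_params` object.
#' @export
nominal_oscillator <- function(omega = 2 * pi / 24, epsilon = 1e-4) {
  key <- sprintf("nominal_%.12g_%.12g", omega, epsilon)
  hit <- .clockamp_cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- calibrate_radius(omega = omega, epsilon = epsilon)
  out <- oscillator_params(omega = omega, a = a, epsilon = epsilon)
  assign(key, out, envir = .clockamp_cache)
  out
}

#' Oscillator vector field in Cartesian coordinates
#'
#' Time derivative of the state `(x, y)` = (mRNA, protein) under the
#' normal-form dynamics with optional light pushes:
#' `dx/dt = -omega*y + epsilon*x*(a^2 - x^2 - y^2) + lit` and
#' `dy/dt =  omega*x + epsilon*y*(a^2 - x^2 - y^2) - lid`.
#' Rotation is counterclockwise, so the protein peak trails the mRNA peak
#' by a quarter cycle (6 h at the nominal period).
#'
#' @param state numeric length-2 vector `c(x, y)` in nM.
#' @param params an [oscillator_params()] object.
#' @param lit additive push on `dx/dt` (light-induced transcription), nM/h.
#' @param lid subtractive push on `dy/dt` (light-induced degradation), nM/h.
#' @return Numeric length-2 vector `c(dx, dy)` in nM/h.
#' @examples
#' p <- oscillator_params(a = 2)
#' vector_field(c(2, 0), p)        # on-cycle: purely tangential
#' vector_field(c(0, 0), p)        # the singularity point is fixed
#' @export
vector_field <- function(state, params, lit = 0, lid = 0) {
  if (!inherits(params, "oscillator_params"))
    stop_bad("`params` must be an oscillator_params object")
  if (!is.numeric(state) || length(state) != 2L)
    stop_bad("`state` must be a numeric vector c(x, y)")
  if (!is.finite(state[1L])) stop_bad("state field `x` is not finite")
  if (!is.finite(state[2L])) stop_bad("state field `y` is not finite")
  check_finite_scalar(lit, "lit")
  check_finite_scalar(lid, "lid")
  x <- state[1L]; y <- state[2L]
  s <- params$a^2 - x^2 - y^2
  c(-params$omega * y + params$epsilon * x * s + lit,
     params$omega * x + params$epsilon * y * s - lid)
}

#' Oscillator vector field in polar coordinates (unstimulated)
#'
#' The unstimulated normal form decouples in polar coordinates:
#' `dtheta/dt = omega` (independent of the radius) and
#' `dr/dt = epsilon * r * (a^2 - r^2)`.
#'
#' @param r radius in nM, must be >= 0.
#' @param theta angle in radians (does not enter the derivatives; retained
#'   for signature symmetry with the Cartesian form).
#' @param params an [oscillator_params()] object.
#' @return Numeric length-2 vector `c(dtheta, dr)` in (rad/h, nM/h).
#' @export
polar_vector_field <- function(r, theta = 0, params) {
  if (!inherits(params, "oscillator_params"))
    stop_bad("`params` must be an oscillator_params object")
  check_finite_scalar(r, "r")
  if (r < 0) stop_bad("`r` must be >= 0")
  c(params$omega, params$epsilon * r * (params$a^2 - r^2))
}

#' Circadian time to phase angle
#'
#' Maps circadian time to the geometric phase angle, measured in degrees
#' counterclockwise from the positive mRNA (`x`) axis. CT6 is the mRNA peak
#' and maps to 0 degrees; CT18 is the mRNA trough (180 degrees); CT12 is
#' the protein peak (90 degrees). One circadian hour is 15 degrees.
#'
#' @param ct circadian time in hours, interpreted modulo 24.
#' @return Angle in degrees in `[0, 360)`.
#' @examples
#' ct_to_angle(c(6, 12, 18))   # 0, 90, 180
#' @export
ct_to_angle <- function(ct) ((ct - 6) * 15) %% 360

#' Phase angle to circadian time
#'
#' Inverse of [ct_to_angle()].
#'
#' @param angle angle in degrees (any real number).
#' @return Circadian time in hours in `[0, 24)`.
#' @export
angle_to_ct <- function(angle) (angle / 15 + 6) %% 24

#' Place an oscillator on its limit cycle at a given circadian time
#'
#' @param ct circadian time in hours.
#' @param params an [oscillator_params()] object.
#' @return Numeric length-2 state `c(x, y)` on the cycle of radius `a`.
#' @export
ct_to_state <- function(ct, params) {
  if (!inherits(params, "oscillator_params"))
    stop_bad("`params` must be an oscillator_params object")
  alpha <- ct_to_angle(ct) * pi / 180
  c(params$a * cos(alpha), params$a * sin(alpha))
}
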