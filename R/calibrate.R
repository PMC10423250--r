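# radius of a single on-cycle oscillator at pulse offset
post_pulse_radius <- function(a, protocol, omega, epsilon,
                              solver = solver_settings()) {
  params <- oscillator_params(omega = omega, a = a, epsilon = epsilon)
  state <- ct_to_state(protocol$onset_ct, params)
  out <- integrate_segment(state, c(0, protocol$duration), single_p(params),
                           llit = protocol$l_lit, llid = protocol$l_lid,
                           solver = solver)
  last <- out[nrow(out), ]
  sqrt(last[2L]^2 + last[3L]^2)
}

#' Calibrate the limit-cycle radius against the critical pulse
#'
#' The nominal limit-cycle radius is not an observable of the unstimulated
#' clock alone; it is pinned by the singularity experiment: a 3-hour
#' light-induced transcription pulse starting at CT17 must drive an
#' on-cycle oscillator to the immediate vicinity of the unstable fixed
#' point at the origin. `calibrate_radius()` finds the radius `a` that
#' minimizes the post-pulse radius for that protocol by golden-section
#' search over `interval`, integrating the full nonlinear system.
#'
#' In the limit `epsilon -> 0` the calibration has a closed form: the pulse
#' accumulates a displacement of magnitude `(2*l_lit/omega) * sin(omega*T/2)`
#' in the corotating frame, and projecting it onto the onset direction gives
#' `a = (2*l_lit/omega) * sin(omega*T/2) * cos(omega*T/2 - dphi)` where
#' `dphi` is the angular offset of the onset from the exact annihilation
#' phase. For the default protocol this is about 8.70 nM; the full
#' integration at `epsilon = 1e-4` gives about 8.65 nM.
#'
#' @param protocol the critical pulse, a [stimulus_protocol()] with mode
#'   `"LIT"` and positive duration.
#' @param omega,epsilon remaining oscillator parameters.
#' @param interval search bracket for `a` in nM.
#' @param solver a [solver_settings()] object.
#' @return The calibrated radius `a` in nM.
#' @examples
#' \donttest{
#' calibrate_radius()   # about 8.65
#' }
#' @export
calibrate_radius <- function(protocol = stimulus_protocol("LIT", onset_ct = 17,
                                                          duration = 3),
                             omega = 2 * pi / 24, epsilon = 1e-4,
                             interval = c(1, 20),
                             solver = solver_settings()) {
  if (!inherits(protocol, "stimulus_protocol"))
    stop_bad("`protocol` must be a stimulus_protocol object")
  if (protocol$mode != "LIT")
    stop_bad("calibration requires a LIT protocol, got mode ", protocol$mode)
  if (protocol$duration <= 0)
    stop_bad("calibration requires duration > 0: a zero-length pulse has no ",
             "interior optimum")
  check_positive(omega, "omega")
  check_positive(epsilon, "epsilon", strict = FALSE)
  opt <- optimize(post_pulse_radius, interval = interval,
                  protocol = protocol, omega = omega, epsilon = epsilon,
                  solver = solver, tol = 1e-6)
  span <- diff(range(interval))
  if (min(opt$minimum - interval[1L], interval[2L] - opt$minimum) < 1e-3 * span)
    stop_bad("no interior minimum inside the bracket [", interval[1L], ", ",
             interval[2L], "]; widen `interval`")
  opt$minimum
}

#' Onset circadian time that minimizes the post-pulse radius
#'
#' Given calibrated oscillator parameters, scans pulse onset CT and returns
#' the onset that drives the oscillator closest to the singularity point.
#' Serves as a cross-check of the calibration: at the nominal parameters a
#' 3-hour LIT pulse is critical near CT16.5.
#'
#' @param params an [oscillator_params()] object.
#' @param duration pulse duration in hours.
#' @param mode `"LIT"` or `"LID"`.
#' @param l push magnitude in nM/h.
#' @param ct_grid onset circadian times to scan.
#' @param solver a [solver_settings()] object.
#' @return A list with the optimal `onset_ct`, the attained `radius`, and
#'   the scanned `profile` (data frame of ct and radius).
#' @export
critical_onset_ct <- function(params, duration = 3, mode = c("LIT", "LID"),
                              l = 3, ct_grid = seq(0, 23.75, by = 0.25),
                              solver = solver_settings()) {
  mode <- match.arg(mode)
  radius <- vapply(ct_grid, function(ct) {
    prot <- stimulus_protocol(mode, onset_ct = ct, duration = duration,
                              l_lit = if (mode == "LIT") l else 0,
                              l_lid = if (mode == "LID") l else 0)
    post_pulse_radius(params$a, prot, params$omega, params$epsilon, solver)
  }, numeric(1))
  i <- which.min(radius)
  list(onset_ct = ct_grid[i], radius = radius[i],
       profile = data.frame(ct = ct_grid, radius = radius))
}
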