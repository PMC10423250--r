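#' Solver settings
#'
#' Numerical settings shared by all simulations: an adaptive integrator
#' (`deSolve::lsoda`) with tight tolerances, sampled on a uniform output
#' grid. Pulses are handled by integrating the pre-, during- and
#' post-stimulus epochs separately so the rectangular discontinuity never
#' falls inside a solver step.
#'
#' @param dt output sampling interval in hours.
#' @param rtol,atol relative and absolute integration tolerances.
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(dt = 0.1, rtol = 1e-8, atol = 1e-10) {
  check_positive(dt, "dt")
  check_positive(rtol, "rtol")
  check_positive(atol, "atol")
  structure(list(dt = dt, rtol = rtol, atol = atol),
            class = "solver_settings")
}

# guard threshold for the saturating coupling denominator F + K_f (nM)
COUPLING_GUARD <- 0.5

# right-hand side of the (possibly coupled) population ODE.
# p: list(n, omega[n], a[n], epsilon, k_c, K_f, llit, llid)
rhs_population <- function(t, state, p) {
  n <- p$n
  x <- state[seq_len(n)]
  y <- state[n + seq_len(n)]
  s <- p$a^2 - x^2 - y^2
  if (p$k_c > 0) {
    f_mean <- sum(x) / n
    if (!is.finite(f_mean) || abs(f_mean + p$K_f) < COUPLING_GUARD)
      stop_bad("coupling singularity: mean field F = ", format(f_mean),
               " is within ", COUPLING_GUARD, " nM of -K_f = ", -p$K_f)
    coupling <- p$k_c * (f_mean - x) / (f_mean + p$K_f)
  } else {
    coupling <- 0
  }
  list(c(-p$omega * y + p$epsilon * x * s + p$llit + coupling,
          p$omega * x + p$epsilon * y * s - p$llid))
}

# integrate one epoch on a fixed output grid; returns deSolve matrix
integrate_segment <- function(state, times, p, llit = 0, llid = 0,
                              solver = solver_settings()) {
  p$llit <- llit
  p$llid <- llid
  out <- deSolve::ode(y = unname(state), times = times, func = rhs_population,
                      parms = p, method = "lsoda",
                      rtol = solver$rtol, atol = solver$atol)
  if (attr(out, "istate")[1L] < 0 || anyNA(out) || any(!is.finite(out)))
    stop_bad("ODE integration failed (non-finite state or step-size collapse) ",
             "on [", times[1L], ", ", times[length(times)], "] h")
  out
}

# output time grid for an epoch [t0, t1]; always contains both endpoints
epoch_times <- function(t0, t1, dt) {
  tt <- seq(t0, t1, by = dt)
  if (tt[length(tt)] < t1) tt <- c(tt, t1)
  tt
}

# single-oscillator parameter list for the integrator
single_p <- function(params) {
  list(n = 1L, omega = params$omega, a = params$a, epsilon = params$epsilon,
       k_c = 0, K_f = 1)
}
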