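# offset added to the population seed before drawing burn-in phases, so the
# phase draw does not reuse the random stream that produced (omega_i, a_i)
PHASE_SEED_OFFSET <- 499979L

# parameter list for the coupled-population integrator
population_p <- function(population, spec) {
  list(n = nrow(population), omega = population$omega, a = population$a,
       epsilon = spec$epsilon, k_c = spec$k_c, K_f = spec$K_f)
}

#' Burn in a coupled population to its synchronized steady state
#'
#' Samples (or accepts) a population, draws initial phases uniformly on an
#' arc of the limit cycle, integrates the unstimulated coupled system for
#' the burn-in period, and then records a long unstimulated reference
#' segment. The reference segment provides (i) the mean-field peak used to
#' anchor circadian time, (ii) the locked period, and (iii) the shared
#' pre-stimulus trajectory reused by every stimulated run, so that scans
#' over many protocols pay for the burn-in only once per seed.
#'
#' @param spec a [population_spec()] object.
#' @param population optionally a pre-sampled `clock_population`; by
#'   default sampled from `spec`.
#' @param ctrl_horizon length (h) of the unstimulated reference segment.
#' @param solver a [solver_settings()] object.
#' @return An object of class `clock_prep`.
#' @export
prepare_population <- function(spec, population = NULL, ctrl_horizon = 160,
                               solver = solver_settings()) {
  if (!inherits(spec, "population_spec"))
    stop_bad("`spec` must be a population_spec object")
  population <- population %||% sample_population(spec)
  n <- nrow(population)
  if (n < 1L) stop_bad("population is empty")
  p <- population_p(population, spec)

  set.seed(spec$seed + PHASE_SEED_OFFSET)
  theta0 <- runif(n, 0, max(spec$init_arc, 1e-9))
  state <- c(population$a * cos(theta0), population$a * sin(theta0))

  # burn-in: coarse output is enough, we only need the end state plus an
  # order-parameter series for the convergence diagnostic
  burn_len <- spec$burn_in * 2 * pi / spec$omega_mean
  drift <- NA_real_
  if (burn_len > 0) {
    bt <- epoch_times(0, burn_len, 1)
    burn <- integrate_segment(state, bt, p, solver = solver)
    state <- unname(burn[nrow(burn), -1L])
    ph <- atan2(burn[, n + 1L + seq_len(n), drop = FALSE],
                burn[, 1L + seq_len(n), drop = FALSE])
    op <- abs(rowMeans(exp(1i * ph)))
    period0 <- 2 * pi / spec$omega_mean
    if (burn_len > 2.5 * period0) {
      last <- mean(op[bt > burn_len - period0])
      prev <- mean(op[bt > burn_len - 2 * period0 & bt <= burn_len - period0])
      drift <- abs(last - prev)
      if (is.finite(drift) && drift > 1e-3)
        warning("burn-in may not have converged: order-parameter drift ",
                format(drift, digits = 3), " per cycle; increase `burn_in`",
                call. = FALSE)
    }
  }

  ct <- epoch_times(0, ctrl_horizon, solver$dt)
  ctrl <- integrate_segment(state, ct, p, solver = solver)
  x <- ctrl[, 1L + seq_len(n), drop = FALSE]
  y <- ctrl[, n + 1L + seq_len(n), drop = FALSE]
  dimnames(x) <- NULL
  dimnames(y) <- NULL
  mean_x <- rowMeans(x)

  pk <- find_peaks(ct, mean_x)
  if (length(pk) < 3L)
    stop_bad("mean field is arrhythmic during the reference segment; ",
             "cannot anchor circadian time")
  period <- mean(diff(pk))
  t_peak <- pk[pk >= 24 + solver$dt][1L]
  if (is.na(t_peak))
    stop_bad("no mean-field peak found after the 24 h pre-window")

  structure(list(spec = spec, population = population, p = p,
                 times = ct, x = x, y = y,
                 mean_x = mean_x, mean_y = rowMeans(y),
                 t_peak = t_peak, period = period,
                 ct0 = wrap_ct(6 - t_peak * 24 / period),
                 burn_drift = drift, solver = solver),
            class = "clock_prep")
}

#' @export
print.clock_prep <- function(x, ...) {
  cat(sprintf("<clock_prep> %d oscillators, seed %d\n",
              x$p$n, x$spec$seed))
  cat(sprintf("  locked period %.4g h; CT6 anchor (mean-field peak) at t = %.4g h\n",
              x$period, x$t_peak))
  if (is.finite(x$burn_drift))
    cat(sprintf("  burn-in order-parameter drift %.2g per cycle\n", x$burn_drift))
  invisible(x)
}

# build a clock_trace from assembled pieces
new_trace <- function(times, x, y, t_on, t_off, protocol, period, ct0,
                      spec = NULL, population = NULL, params = NULL) {
  dimnames(x) <- NULL
  dimnames(y) <- NULL
  names(times) <- NULL
  structure(list(times = times, x = x, y = y,
                 mean_x = rowMeans(x), mean_y = rowMeans(y),
                 n = ncol(x), t_on = t_on, t_off = t_off,
                 protocol = protocol, period = period, ct0 = ct0,
                 spec = spec, population = population, params = params),
            class = "clock_trace")
}

#' @export
print.clock_trace <- function(x, ...) {
  cat(sprintf("<clock_trace> %d oscillator%s, t in [%g, %g] h (dt %.3g)\n",
              x$n, if (x$n == 1L) "" else "s",
              min(x$times), max(x$times), x$times[2L] - x$times[1L]))
  print(x$protocol)
  cat(sprintf("  stimulus window [%g, %g] h; period %.4g h; CT(0) = %.3g\n",
              x$t_on, x$t_off, x$period, x$ct0))
  invisible(x)
}

#' Circadian time of a simulation time point
#'
#' Circadian time is anchored on the rhythm itself: CT6 is the peak of the
#' (mean-field) mRNA coordinate and one circadian hour is 1/24 of the
#' locked period.
#'
#' @param trace a `clock_trace` (or `clock_prep`).
#' @param t simulation time(s) in hours.
#' @return Circadian time(s) in `[0, 24)`.
#' @export
ct_of_t <- function(trace, t) wrap_ct(trace$ct0 + t * 24 / trace$period)

#' First simulation time at a circadian time
#'
#' @param trace a `clock_trace` or `clock_prep`.
#' @param ct target circadian time in hours.
#' @param not_before earliest admissible simulation time (h); the default
#'   leaves a full 24 h pre-stimulus window inside the trace.
#' @return Simulation time in hours.
#' @export
time_at_ct <- function(trace, ct, not_before = 24) {
  base <- ((ct - trace$ct0) %% 24) * trace$period / 24
  k <- ceiling((not_before - base) / trace$period)
  base + max(k, 0) * trace$period
}

# schedule a protocol against a prep: grid-snapped onset/offset times
schedule_pulse <- function(prep, protocol, solver) {
  t_on <- time_at_ct(prep, protocol$onset_ct,
                     not_before = 24 + 2 * solver$dt)
  t_on <- round(t_on / solver$dt) * solver$dt
  c(t_on = t_on, t_off = t_on + protocol$duration)
}

#' Simulate a coupled oscillator population through a light pulse
#'
#' Runs the coupled population model
#' `dx_i/dt = -omega_i y_i + epsilon x_i (a_i^2 - x_i^2 - y_i^2) + L_LIT +
#' k_c (F - x_i)/(F + K_f)` and the matching `dy_i/dt` with `-L_LID`,
#' where `F` is the population mean of `x`. The population is first burnt
#' in to its synchronized steady state (see [prepare_population()]); the
#' pulse is then timed against the circadian time of the mean-field rhythm,
#' with the push terms active only inside the stimulus window. The coupling
#' acts throughout, including during the pulse.
#'
#' @param spec a [population_spec()] object.
#' @param protocol a [stimulus_protocol()] object.
#' @param population optional pre-sampled `clock_population`.
#' @param prep optional [prepare_population()] result to reuse across runs
#'   with the same spec/seed.
#' @param post_horizon hours of recovery simulated after pulse offset (at
#'   least 24 to cover the after-window; the default also covers the two
#'   post-pulse cycles used by [phase_shift()]).
#' @param solver a [solver_settings()] object.
#' @return A `clock_trace`.
#' @export
simulate_population <- function(spec, protocol, population = NULL,
                                prep = NULL, post_horizon = 56,
                                solver = solver_settings()) {
  if (!inherits(protocol, "stimulus_protocol"))
    stop_bad("`protocol` must be a stimulus_protocol object")
  if (post_horizon < 24)
    stop_bad("`post_horizon` must be >= 24 to cover the after-window")
  prep <- prep %||% prepare_population(spec, population, solver = solver)
  sched <- schedule_pulse(prep, protocol, solver)
  t_on <- sched[["t_on"]]; t_off <- sched[["t_off"]]

  pre <- prep$times <= t_on + 1e-9
  times <- prep$times[pre]
  x <- prep$x[pre, , drop = FALSE]
  y <- prep$y[pre, , drop = FALSE]
  state <- c(x[nrow(x), ], y[nrow(y), ])

  if (protocol$duration > 0 && protocol$mode != "NONE") {
    tp <- epoch_times(t_on, t_off, solver$dt)
    seg <- integrate_segment(state, tp, prep$p,
                             llit = protocol$l_lit, llid = protocol$l_lid,
                             solver = solver)
    state <- unname(seg[nrow(seg), -1L])
    keep <- -1L  # drop duplicated boundary point
    times <- c(times, tp[keep])
    x <- rbind(x, seg[keep, 1L + seq_len(prep$p$n), drop = FALSE])
    y <- rbind(y, seg[keep, prep$p$n + 1L + seq_len(prep$p$n), drop = FALSE])
    ta <- epoch_times(t_off, t_off + post_horizon, solver$dt)
    seg <- integrate_segment(state, ta, prep$p, solver = solver)
    times <- c(times, ta[keep])
    x <- rbind(x, seg[keep, 1L + seq_len(prep$p$n), drop = FALSE])
    y <- rbind(y, seg[keep, prep$p$n + 1L + seq_len(prep$p$n), drop = FALSE])
  } else {
    # null stimulus: the trace is the shared unstimulated reference
    upto <- prep$times <= t_off + post_horizon + 1e-9
    times <- prep$times[upto]
    x <- prep$x[upto, , drop = FALSE]
    y <- prep$y[upto, , drop = FALSE]
  }
  new_trace(times, x, y, t_on, t_off, protocol, prep$period, prep$ct0,
            spec = spec, population = prep$population)
}

#' Unstimulated twin of a stimulated population run
#'
#' Returns the control trace sharing the burn-in (and hence every sample
#' before the pulse onset) with [simulate_population()] runs built from the
#' same prep/seed. Used as the reference for [phase_shift()] and for
#' null-stimulus checks of the indices.
#'
#' @inheritParams simulate_population
#' @param reference_protocol optional protocol whose onset/offset define
#'   the analysis windows of the control (so indices are computed over the
#'   same windows as the stimulated twin); by default a zero-duration pulse
#'   one period after the CT6 anchor.
#' @return A `clock_trace` with protocol `NONE`.
#' @export
control_trace <- function(spec, population = NULL, prep = NULL,
                          reference_protocol = NULL,
                          solver = solver_settings()) {
  prep <- prep %||% prepare_population(spec, population, solver = solver)
  ref <- reference_protocol %||% stimulus_protocol("NONE", onset_ct = 6)
  sched <- schedule_pulse(prep, ref, solver)
  new_trace(prep$times, prep$x, prep$y,
            sched[["t_on"]], sched[["t_on"]] + ref$duration,
            stimulus_protocol("NONE", onset_ct = ref$onset_ct),
            prep$period, prep$ct0,
            spec = spec, population = prep$population)
}

#' Simulate a single oscillator through a light pulse
#'
#' The oscillator starts on its limit cycle, positioned so that the pulse
#' onset falls at the requested circadian time after at least one full
#' unstimulated cycle (the single-cell burn-in convention); the push terms
#' are active only inside the stimulus window.
#'
#' @param params an [oscillator_params()] object.
#' @param protocol a [stimulus_protocol()] object.
#' @param post_horizon hours simulated after pulse offset (>= 24).
#' @param solver a [solver_settings()] object.
#' @return A `clock_trace` with `n = 1`.
#' @export
simulate_single <- function(params, protocol, post_horizon = 56,
                            solver = solver_settings()) {
  if (!inherits(params, "oscillator_params"))
    stop_bad("`params` must be an oscillator_params object")
  if (!inherits(protocol, "stimulus_protocol"))
    stop_bad("`protocol` must be a stimulus_protocol object")
  if (post_horizon < 24)
    stop_bad("`post_horizon` must be >= 24 to cover the after-window")
  p <- single_p(params)
  t_on <- max(24, params$period)
  t_on <- round(t_on / solver$dt) * solver$dt
  t_off <- t_on + protocol$duration
  alpha0 <- ct_to_angle(protocol$onset_ct) * pi / 180 - params$omega * t_on
  state <- c(params$a * cos(alpha0), params$a * sin(alpha0))
  ct0 <- wrap_ct(protocol$onset_ct - t_on * 24 / params$period)

  grab <- function(seg) list(x = seg[, 2L, drop = FALSE],
                             y = seg[, 3L, drop = FALSE])
  t1 <- epoch_times(0, t_on, solver$dt)
  seg <- integrate_segment(state, t1, p, solver = solver)
  times <- t1; xs <- grab(seg)$x; ys <- grab(seg)$y
  state <- unname(seg[nrow(seg), -1L])
  if (protocol$duration > 0 && protocol$mode != "NONE") {
    tp <- epoch_times(t_on, t_off, solver$dt)
    seg <- integrate_segment(state, tp, p, llit = protocol$l_lit,
                             llid = protocol$l_lid, solver = solver)
    times <- c(times, tp[-1L])
    xs <- rbind(xs, grab(seg)$x[-1L, , drop = FALSE])
    ys <- rbind(ys, grab(seg)$y[-1L, , drop = FALSE])
    state <- unname(seg[nrow(seg), -1L])
  }
  ta <- epoch_times(t_off, t_off + post_horizon, solver$dt)
  seg <- integrate_segment(state, ta, p, solver = solver)
  times <- c(times, ta[-1L])
  xs <- rbind(xs, grab(seg)$x[-1L, , drop = FALSE])
  ys <- rbind(ys, grab(seg)$y[-1L, , drop = FALSE])

  new_trace(times, xs, ys, t_on, t_off, protocol, params$period, ct0,
            params = params)
}

#' Population-average output of a trace
#'
#' @param trace a `clock_trace`.
#' @param observable `"x"` (mRNA) or `"y"` (protein).
#' @return A data frame with columns `time_h` and `value` (nM).
#' @export
mean_output <- function(trace, observable = c("x", "y")) {
  observable <- match.arg(observable)
  data.frame(time_h = trace$times,
             value = if (observable == "x") trace$mean_x else trace$mean_y)
}

#' @export
as.data.frame.clock_trace <- function(x, ...) {
  n <- x$n
  data.frame(time_h = rep(x$times, times = n),
             oscillator_id = rep(seq_len(n), each = length(x$times)),
             x = as.vector(x$x), y = as.vector(x$y))
}

#' Export a trace as CSV with a JSON provenance sidecar
#'
#' Writes the long-format per-oscillator trajectories plus the mean-field
#' series to `file`, and the protocol/population metadata (including a
#' content hash) to `paste0(file, ".json")`.
#'
#' @param trace a `clock_trace`.
#' @param file CSV output path.
#' @return Invisibly, the two file paths.
#' @export
write_trace <- function(trace, file) {
  df <- as.data.frame(trace)
  mf <- data.frame(time_h = trace$times, oscillator_id = NA_integer_,
                   x = trace$mean_x, y = trace$mean_y)
  write.csv(rbind(df, mf), file, row.names = FALSE)
  meta <- list(protocol = unclass(trace$protocol),
               n = trace$n, period_h = trace$period,
               t_on = trace$t_on, t_off = trace$t_off,
               spec = if (!is.null(trace$spec)) unclass(trace$spec),
               params = if (!is.null(trace$params))
                 trace$params[c("omega", "a", "epsilon")])
  meta$hash <- text_hash(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  sidecar <- paste0(file, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(file, sidecar))
}
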