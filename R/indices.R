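# floor below which a "before" quantity is considered degenerate
AMPLITUDE_FLOOR <- 1e-8
ORDER_PARAM_FLOOR <- 0.05

#' Peak-to-trough amplitude of a signal over a time window
#'
#' The amplitude of a trajectory is read directly from the observable: the
#' difference between its maximum and minimum over the window (one full
#' cycle, 24 h, in all standard uses).
#'
#' @param times sample times in hours.
#' @param values signal values at `times`.
#' @param window numeric length-2 `c(from, to)` in hours; must be covered
#'   by `times`.
#' @return `max - min` of the signal inside the window.
#' @examples
#' t <- seq(0, 24, 0.1)
#' window_amplitude(t, 8.7 * cos(2 * pi * t / 24), c(0, 24))  # 2 * 8.7
#' @export
window_amplitude <- function(times, values, window) {
  if (length(window) != 2L || window[2L] <= window[1L])
    stop_bad("`window` must be c(from, to) with to > from")
  eps <- 1e-9
  if (window[1L] < min(times) - eps || window[2L] > max(times) + eps)
    stop_bad("window [", window[1L], ", ", window[2L],
             "] h is outside the trace [", min(times), ", ", max(times), "] h")
  inside <- times >= window[1L] - eps & times <= window[2L] + eps
  v <- values[inside]
  max(v) - min(v)
}

#' Kuramoto order parameter of a set of phases
#'
#' @param phases numeric vector of phases in radians.
#' @return `|mean(exp(1i * phases))|`, a number in `[0, 1]`: 1 for perfect
#'   synchrony, 0 for balanced dispersion.
#' @examples
#' order_parameter(c(0, pi / 3))          # cos(pi/6)
#' order_parameter(c(0, 0.5, 1, 1.5) * pi)  # 0
#' @export
order_parameter <- function(phases) {
  if (length(phases) == 0L) stop_bad("`phases` must be non-empty")
  if (any(!is.finite(phases))) stop_bad("`phases` must be finite")
  Mod(mean(exp(1i * phases)))
}

# analysis windows of a trace: 24 h before onset, 24 h after offset
trace_windows <- function(trace) {
  list(before = c(trace$t_on - 24, trace$t_on),
       after = c(trace$t_off, trace$t_off + 24))
}

# window-averaged order parameter of per-oscillator geometric phases
window_order_parameter <- function(trace, window) {
  eps <- 1e-9
  inside <- trace$times >= window[1L] - eps & trace$times <= window[2L] + eps
  ph <- atan2(trace$y[inside, , drop = FALSE], trace$x[inside, , drop = FALSE])
  mean(abs(rowMeans(exp(1i * ph))))
}

#' Before/after response indices of a stimulated trace
#'
#' Computes the four amplitude/synchrony indices from a simulated trace,
#' comparing the 24 h window before pulse onset with the 24 h window after
#' pulse offset (the pulse itself is excluded). All ratios are
#' after/before, so 1 means no change and values below 1 mean suppression:
#' * `R_A`  -- single-oscillator amplitude ratio (only for `n = 1` traces);
#' * `R_AA` -- amplitude ratio of the population-average output;
#' * `R_IA` -- mean over oscillators of the per-oscillator amplitude ratios;
#' * `R_IS` -- synchronization ratio: window-averaged Kuramoto order
#'   parameter of the per-oscillator geometric phases (`atan2(y, x)`),
#'   after over before.
#'
#' @param trace a `clock_trace` from [simulate_single()] or
#'   [simulate_population()].
#' @param observable `"x"` (mRNA) or `"y"` (protein). Default: `"y"` for
#'   LID protocols, `"x"` otherwise.
#' @return An object of class `response_indices`: a list with the four
#'   ratios, the per-oscillator amplitudes (`A_bs`, `A_as`), the
#'   average-output amplitudes (`AA_bs`, `AA_as`), per-oscillator circular
#'   mean phases in each window (`theta_bs`, `theta_as`), the windows and
#'   the observable.
#' @examples
#' \donttest{
#' p <- nominal_oscillator()
#' tr <- simulate_single(p, stimulus_protocol("LIT", onset_ct = 9, duration = 3))
#' response_indices(tr)$R_A   # amplitude increase, about 1.4
#' }
#' @export
response_indices <- function(trace, observable = NULL) {
  if (!inherits(trace, "clock_trace"))
    stop_bad("`trace` must be a clock_trace")
  observable <- observable %||% default_observable(trace$protocol$mode)
  observable <- match.arg(observable, c("x", "y"))
  w <- trace_windows(trace)
  eps <- 1e-9
  ib <- trace$times >= w$before[1L] - eps & trace$times <= w$before[2L] + eps
  ia <- trace$times >= w$after[1L] - eps & trace$times <= w$after[2L] + eps
  if (!any(ib) || trace$times[1L] > w$before[1L] + eps)
    stop_bad("trace does not cover the 24 h window before pulse onset")
  if (max(trace$times) < w$after[2L] - eps)
    stop_bad("trace does not cover the 24 h window after pulse offset")

  sig <- if (observable == "x") trace$x else trace$y
  amp <- function(idx) apply(sig[idx, , drop = FALSE], 2L,
                             function(v) max(v) - min(v))
  A_bs <- amp(ib); A_as <- amp(ia)
  if (any(A_bs < AMPLITUDE_FLOOR))
    stop_bad("pre-stimulus amplitude below the positivity floor; ",
             "before/after ratios are undefined")
  msig <- if (observable == "x") trace$mean_x else trace$mean_y
  AA_bs <- window_amplitude(trace$times, msig, w$before)
  AA_as <- window_amplitude(trace$times, msig, w$after)
  if (AA_bs < AMPLITUDE_FLOOR)
    stop_bad("pre-stimulus average amplitude below the positivity floor")

  op_b <- window_order_parameter(trace, w$before)
  op_a <- window_order_parameter(trace, w$after)
  if (op_b < ORDER_PARAM_FLOOR)
    stop_bad("pre-stimulus order parameter below the floor (",
             ORDER_PARAM_FLOOR, "); population is not synchronized")

  circ_mean <- function(idx) {
    ph <- atan2(trace$y[idx, , drop = FALSE], trace$x[idx, , drop = FALSE])
    apply(ph, 2L, function(v) Arg(mean(exp(1i * v))))
  }
  structure(list(
    R_A = if (trace$n == 1L) unname(A_as / A_bs) else NA_real_,
    R_AA = AA_as / AA_bs,
    R_IA = mean(A_as / A_bs),
    R_IS = op_a / op_b,
    A_bs = A_bs, A_as = A_as, AA_bs = AA_bs, AA_as = AA_as,
    order_param_before = op_b, order_param_after = op_a,
    theta_bs = circ_mean(ib), theta_as = circ_mean(ia),
    observable = observable, windows = w, n = trace$n,
    protocol = trace$protocol
  ), class = "response_indices")
}

#' @export
print.response_indices <- function(x, ...) {
  cat("<response_indices>  (after/before, observable =", x$observable, ")\n")
  if (x$n == 1L) cat(sprintf("  R_A  = %.4g\n", x$R_A))
  cat(sprintf("  R_AA = %.4g   R_IA = %.4g   R_IS = %.4g\n",
              x$R_AA, x$R_IA, x$R_IS))
  cat(sprintf("  windows: before [%g, %g] h, after [%g, %g] h\n",
              x$windows$before[1L], x$windows$before[2L],
              x$windows$after[1L], x$windows$after[2L]))
  invisible(x)
}

#' Single-oscillator amplitude ratio R_A
#'
#' @param trace a single-oscillator `clock_trace`.
#' @param observable `"x"` or `"y"`; see [response_indices()].
#' @return The after/before amplitude ratio.
#' @export
amplitude_ratio <- function(trace, observable = NULL) {
  if (trace$n != 1L)
    stop_bad("R_A is defined for single-oscillator traces; use ",
             "average_amplitude_ratio() or individual_amplitude_ratio()")
  response_indices(trace, observable)$R_A
}

#' Average-amplitude ratio R_AA of a population trace
#'
#' @param trace a population `clock_trace`.
#' @inheritParams amplitude_ratio
#' @return Amplitude of the population-average output after the pulse over
#'   the amplitude before it.
#' @export
average_amplitude_ratio <- function(trace, observable = NULL) {
  response_indices(trace, observable)$R_AA
}

#' Mean individual amplitude ratio R_IA of a population trace
#'
#' @inheritParams average_amplitude_ratio
#' @return Mean over oscillators of the per-oscillator after/before ratios.
#' @export
individual_amplitude_ratio <- function(trace, observable = NULL) {
  response_indices(trace, observable)$R_IA
}

#' Synchronization ratio R_IS of a population trace
#'
#' @inheritParams average_amplitude_ratio
#' @return Window-averaged order parameter after the pulse over before.
#' @export
sync_ratio <- function(trace) {
  response_indices(trace)$R_IS
}

#' Phase shift of a stimulated run against its unstimulated control
#'
#' Compares mean-field peak times on the second cycle after pulse offset.
#' Positive values are phase advances (the stimulated rhythm peaks earlier
#' than the control), mapped circularly into (-12, 12] circadian hours.
#'
#' @param trace a stimulated `clock_trace`.
#' @param control the unstimulated twin from [control_trace()] (same
#'   prep/seed), or any reference trace sharing the burn-in.
#' @param observable `"x"` or `"y"`.
#' @return Phase shift in circadian hours.
#' @export
phase_shift <- function(trace, control, observable = c("x", "y")) {
  observable <- match.arg(observable)
  sig_s <- if (observable == "x") trace$mean_x else trace$mean_y
  sig_c <- if (observable == "x") control$mean_x else control$mean_y
  per <- control$period
  if (max(trace$times) < trace$t_off + 2 * per)
    stop_bad("trace must extend at least two cycles past pulse offset")
  after <- trace$times >= trace$t_off
  amp_post <- max(sig_s[after]) - min(sig_s[after])
  amp_ctrl <- window_amplitude(control$times, sig_c,
                               c(trace$t_on - 24, trace$t_on))
  if (amp_post < 0.01 * amp_ctrl)
    stop_bad("arrhythmic: post-stimulus mean field has no detectable peak")
  pk_s <- find_peaks(trace$times[after], sig_s[after])
  pk_s <- pk_s[pk_s >= trace$t_off + per]
  if (length(pk_s) == 0L)
    stop_bad("arrhythmic: no mean-field peak on the second cycle after offset")
  pk_c <- find_peaks(control$times, sig_c)
  if (length(pk_c) == 0L) stop_bad("control trace has no mean-field peaks")
  s2 <- pk_s[1L]
  d <- (pk_c - s2) %% per
  d <- ifelse(d > per / 2, d - per, d)
  d[which.min(abs(d))] * 24 / per
}

#' Export a response-indices record as JSON
#'
#' Writes a flat JSON record of the protocol, windows, observable and all
#' four indices; per-oscillator ratios are included when `per_oscillator`
#' is `TRUE`.
#'
#' @param indices a [response_indices()] object.
#' @param file output path.
#' @param per_oscillator include per-oscillator amplitude ratios.
#' @param extra named list merged into the record (e.g. seeds).
#' @return `file`, invisibly.
#' @export
export_indices <- function(indices, file, per_oscillator = FALSE,
                           extra = list()) {
  rec <- c(list(
    mode = indices$protocol$mode,
    onset_ct = indices$protocol$onset_ct,
    duration = indices$protocol$duration,
    l_lit = indices$protocol$l_lit,
    l_lid = indices$protocol$l_lid,
    observable = indices$observable,
    window_before = indices$windows$before,
    window_after = indices$windows$after,
    n = indices$n,
    R_A = indices$R_A, R_AA = indices$R_AA,
    R_IA = indices$R_IA, R_IS = indices$R_IS), extra)
  if (per_oscillator)
    rec$per_oscillator_ratio <- unname(indices$A_as / indices$A_bs)
  jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(file)
}
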