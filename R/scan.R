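#' Amplitude response curve (ARC)
#'
#' Response index as a function of pulse onset circadian time at fixed
#' duration. With `spec = NULL` the curve is the single-oscillator `R_A`
#' at the nominal (or supplied) parameters; with a [population_spec()] it
#' is the population `R_AA`, averaged over replicate seeds.
#'
#' @param mode `"LIT"`, `"LID"` or `"COMBINED"`.
#' @param duration pulse duration in hours (0 gives a flat curve at 1).
#' @param ct_grid onset circadian times in hours.
#' @param params single-oscillator parameters (used when `spec` is NULL);
#'   default [nominal_oscillator()].
#' @param spec optional [population_spec()] for a population ARC.
#' @param observable `"x"` or `"y"`; default depends on `mode` (protein
#'   for LID).
#' @param n_replicates,seeds replicate seeds for population curves.
#' @param solver a [solver_settings()] object.
#' @return A data frame with columns `ct` and `R` (plus attribute
#'   `"level"`, `"single"` or `"population"`).
#' @export
run_arc <- function(mode = c("LIT", "LID", "COMBINED"), duration = 3,
                    ct_grid = 0:23, params = NULL, spec = NULL,
                    observable = NULL, n_replicates = 1, seeds = NULL,
                    solver = solver_settings()) {
  mode <- match.arg(mode)
  if (length(ct_grid) < 1L) stop_bad("`ct_grid` must be non-empty")
  observable <- observable %||% default_observable(mode)
  if (is.null(spec)) {
    params <- params %||% nominal_oscillator()
    R <- vapply(ct_grid, function(ct) {
      prot <- make_protocol(mode, ct, duration)
      tr <- simulate_single(params, prot, post_horizon = 24, solver = solver)
      response_indices(tr, observable)$R_A
    }, numeric(1))
    level <- "single"
  } else {
    scan <- run_ars(spec, mode = mode, ct_grid = ct_grid,
                    duration_grid = duration, n_replicates = n_replicates,
                    seeds = seeds, observable = observable, solver = solver)
    R <- scan$R_AA[, 1L]
    level <- "population"
  }
  out <- data.frame(ct = ct_grid, R = unname(R))
  attr(out, "level") <- level
  attr(out, "mode") <- mode
  attr(out, "duration") <- duration
  attr(out, "observable") <- observable
  out
}

# protocol for a scan cell (zero duration maps to the null stimulus)
make_protocol <- function(mode, ct, duration) {
  if (duration <= 0) stimulus_protocol("NONE", onset_ct = ct)
  else stimulus_protocol(mode, onset_ct = ct, duration = duration)
}

#' Amplitude response surface (ARS)
#'
#' Runs the full phase-by-strength scan experiment for a coupled
#' population: for every combination of onset circadian time and pulse
#' duration, the population is stimulated and the three population indices
#' (`R_AA`, `R_IA`, `R_IS`) are recorded, averaged over replicate seeds.
#' The burn-in is shared across all cells of a replicate, so a full grid
#' costs one burn-in plus one short pulse-and-recovery integration per
#' cell.
#'
#' @param spec a [population_spec()]; its seed is the base of the
#'   replicate seeds.
#' @param mode `"LIT"`, `"LID"` or `"COMBINED"`.
#' @param ct_grid onset circadian times (h).
#' @param duration_grid pulse durations (h); may include 0.
#' @param n_replicates number of replicate populations.
#' @param seeds explicit replicate seeds (overrides `n_replicates`).
#' @param observable `"x"` or `"y"`; default depends on `mode`.
#' @param solver a [solver_settings()] object.
#' @return An object of class `clock_scan` with matrices `R_AA`, `R_IA`,
#'   `R_IS` (rows = onset CT, columns = duration), the grids, seeds and
#'   observable.
#' @export
run_ars <- function(spec, mode = c("LIT", "LID", "COMBINED"),
                    ct_grid = 0:23, duration_grid = 0:10,
                    n_replicates = 5, seeds = NULL, observable = NULL,
                    solver = solver_settings()) {
  mode <- match.arg(mode)
  if (!inherits(spec, "population_spec"))
    stop_bad("`spec` must be a population_spec object")
  if (length(ct_grid) < 1L) stop_bad("`ct_grid` must be non-empty")
  if (length(duration_grid) < 1L) stop_bad("`duration_grid` must be non-empty")
  seeds <- seeds %||% (spec$seed + seq_len(n_replicates) - 1L)
  observable <- observable %||% default_observable(mode)
  dims <- c(length(ct_grid), length(duration_grid))
  acc <- list(R_AA = 0, R_IA = 0, R_IS = 0)
  for (sd in seeds) {
    spec_i <- spec
    spec_i$seed <- as.integer(sd)
    prep <- prepare_population(spec_i, solver = solver)
    cell <- function(ct, dur) {
      tr <- simulate_population(spec_i, make_protocol(mode, ct, dur),
                                prep = prep, post_horizon = 24,
                                solver = solver)
      ind <- response_indices(tr, observable)
      c(ind$R_AA, ind$R_IA, ind$R_IS)
    }
    vals <- mapply(cell,
                   rep(ct_grid, times = dims[2L]),
                   rep(duration_grid, each = dims[1L]))
    acc$R_AA <- acc$R_AA + matrix(vals[1L, ], dims[1L], dims[2L])
    acc$R_IA <- acc$R_IA + matrix(vals[2L, ], dims[1L], dims[2L])
    acc$R_IS <- acc$R_IS + matrix(vals[3L, ], dims[1L], dims[2L])
  }
  dn <- list(format(ct_grid), format(duration_grid))
  out <- lapply(acc, function(m) {
    m <- m / length(seeds); dimnames(m) <- dn; m
  })
  structure(list(mode = mode, ct_grid = ct_grid,
                 duration_grid = duration_grid,
                 R_AA = out$R_AA, R_IA = out$R_IA, R_IS = out$R_IS,
                 n_replicates = length(seeds), seeds = as.integer(seeds),
                 observable = observable, spec = spec),
            class = "clock_scan")
}

#' @export
print.clock_scan <- function(x, ...) {
  cat(sprintf("<clock_scan> %s, %d onset CTs x %d durations, %d replicate%s\n",
              x$mode, length(x$ct_grid), length(x$duration_grid),
              x$n_replicates, if (x$n_replicates == 1L) "" else "s"))
  cat(sprintf("  observable %s; R_AA range [%.3g, %.3g]\n",
              x$observable, min(x$R_AA), max(x$R_AA)))
  s <- find_singularity(x)
  cat(sprintf("  minimum R_AA = %.3g at (CT%g, %g h)\n",
              s$R_AA_min, s$ct, s$duration))
  invisible(x)
}

#' Locate the singularity cell of a scan
#'
#' The singularity stimulus is the grid cell with the lowest average
#' amplitude response. Ties are broken toward the smallest duration, then
#' the smallest onset CT.
#'
#' @param scan a `clock_scan` from [run_ars()].
#' @return A list with `ct`, `duration` and `R_AA_min`.
#' @export
find_singularity <- function(scan) {
  if (!inherits(scan, "clock_scan")) stop_bad("`scan` must be a clock_scan")
  ct <- rep(scan$ct_grid, times = length(scan$duration_grid))
  dur <- rep(scan$duration_grid, each = length(scan$ct_grid))
  v <- as.vector(scan$R_AA)
  i <- order(v, dur, ct)[1L]
  list(ct = ct[i], duration = dur[i], R_AA_min = v[i])
}

#' Classify an amplitude response column
#'
#' Classifies the response-vs-strength profile at a fixed onset CT:
#' * `"monotonic_increasing"` -- nondecreasing within tolerance `delta`
#'   with all values at least `1 - delta`;
#' * `"nonmonotonic"` -- dips below `1 - delta` and later rises by more
#'   than `delta` above its minimum;
#' * `"other"` -- anything else.
#'
#' @param values response index values, ordered by increasing duration.
#' @param durations matching durations; must contain 0 and at least three
#'   values.
#' @param delta classification tolerance on the index.
#' @return A character scalar.
#' @examples
#' classify_response(c(1, 1.1, 1.3, 1.6), 0:3)
#' classify_response(c(1, 0.7, 0.2, 1.1), 0:3)
#' @export
classify_response <- function(values, durations, delta = 0.03) {
  if (length(values) != length(durations))
    stop_bad("`values` and `durations` must have equal length")
  if (length(values) < 3L)
    stop_bad("classification needs at least 3 durations")
  if (min(abs(durations)) > 1e-9)
    stop_bad("`durations` must include 0 (the null stimulus)")
  o <- order(durations)
  v <- values[o]
  if (all(diff(v) >= -delta) && all(v >= 1 - delta))
    return("monotonic_increasing")
  im <- which.min(v)
  if (v[im] < 1 - delta && any(v[im:length(v)] > v[im] + delta))
    return("nonmonotonic")
  "other"
}

#' Classify every onset-CT column of a scan
#'
#' @param scan a `clock_scan` whose duration grid includes 0.
#' @param index which index matrix to classify.
#' @param delta tolerance passed to [classify_response()].
#' @return Named character vector, one label per onset CT.
#' @export
classify_scan <- function(scan, index = c("R_AA", "R_IA", "R_IS"),
                          delta = 0.03) {
  index <- match.arg(index)
  m <- scan[[index]]
  out <- vapply(seq_along(scan$ct_grid), function(i)
    classify_response(m[i, ], scan$duration_grid, delta), character(1))
  names(out) <- as.character(scan$ct_grid)
  out
}

#' Width of the phase range with a suppressed response
#'
#' Total width, in hours of onset circadian time, of the CT set whose
#' replicate-mean index is below 1 at a given duration. CT is treated as
#' circular; the width is simply the grid step times the number of
#' suppressed cells, so it is exact for a uniform full-circle grid.
#'
#' @param scan a `clock_scan`.
#' @param duration which duration column to use (must be in the grid).
#' @param index which index to threshold.
#' @return Width in hours.
#' @export
reduction_phase_range <- function(scan, duration,
                                  index = c("R_AA", "R_IA", "R_IS")) {
  index <- match.arg(index)
  j <- which(abs(scan$duration_grid - duration) < 1e-9)
  if (length(j) != 1L)
    stop_bad("duration ", duration, " h is not a column of the scan")
  steps <- diff(sort(scan$ct_grid))
  step <- if (length(steps)) stats::median(steps) else 1
  if (step > 1 + 1e-9)
    stop_bad("CT grid resolution must be <= 1 h for a phase-range width")
  step * sum(scan[[index]][, j] < 1)
}

#' Evaluate a combined LIT+LID stimulus strategy
#'
#' Applies equal-magnitude transcription and degradation pushes at once
#' and reports both sides of the amplitude/phase trade-off: the average
#' amplitude ratio and the phase shift against the unstimulated control.
#'
#' @param spec a [population_spec()].
#' @param onset_ct pulse onset circadian time (h).
#' @param duration pulse duration (h).
#' @param l common push magnitude (nM/h) for both channels.
#' @param observable `"x"` or `"y"` for the amplitude readout.
#' @param prep optional shared [prepare_population()] result.
#' @param solver a [solver_settings()] object.
#' @return A list with `R_AA`, `phase_shift_h`, and the full
#'   `response_indices` object.
#' @export
combined_strategy_eval <- function(spec, onset_ct, duration, l = 3,
                                   observable = "x", prep = NULL,
                                   solver = solver_settings()) {
  prot <- stimulus_protocol("COMBINED", onset_ct = onset_ct,
                            duration = duration, l_lit = l, l_lid = l)
  prep <- prep %||% prepare_population(spec, solver = solver)
  tr <- simulate_population(spec, prot, prep = prep, post_horizon = 56,
                            solver = solver)
  ctrl <- control_trace(spec, prep = prep, reference_protocol = prot,
                        solver = solver)
  ind <- response_indices(tr, observable)
  list(R_AA = ind$R_AA,
       phase_shift_h = phase_shift(tr, ctrl),
       indices = ind)
}

#' Export a scan grid as CSV with a JSON metadata sidecar
#'
#' @param scan a `clock_scan`.
#' @param file CSV path for the index grid (rows = onset CT, columns =
#'   duration).
#' @param index which index matrix to write.
#' @return Invisibly, the two paths written.
#' @export
write_scan <- function(scan, file, index = c("R_AA", "R_IA", "R_IS")) {
  index <- match.arg(index)
  m <- scan[[index]]
  df <- data.frame(onset_ct = scan$ct_grid, m, check.names = FALSE)
  names(df) <- c("onset_ct", paste0("dur_", format(scan$duration_grid)))
  write.csv(df, file, row.names = FALSE)
  meta <- list(mode = scan$mode, index = index, ct_grid = scan$ct_grid,
               duration_grid = scan$duration_grid,
               n_replicates = scan$n_replicates, seeds = scan$seeds,
               observable = scan$observable,
               spec = unclass(scan$spec))
  meta$hash <- text_hash(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  sidecar <- paste0(file, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(file, sidecar))
}

#' Replicate-averaged population indices for one protocol
#'
#' Convenience wrapper running the same protocol on several independently
#' sampled populations (one per seed) and averaging the three population
#' indices, as done for every reported population value.
#'
#' @param spec a [population_spec()]; its seed is the base seed.
#' @param protocol a [stimulus_protocol()].
#' @param n_replicates,seeds replicate seeds (default `spec$seed + 0:4`).
#' @param observable `"x"` or `"y"`; default depends on the protocol mode.
#' @param preps optional list of [prepare_population()] results matching
#'   `seeds`, to share burn-ins across protocols.
#' @param solver a [solver_settings()] object.
#' @return A list with the averaged `R_AA`, `R_IA`, `R_IS` and a
#'   `per_seed` data frame.
#' @export
replicate_indices <- function(spec, protocol, n_replicates = 5, seeds = NULL,
                              observable = NULL, preps = NULL,
                              solver = solver_settings()) {
  seeds <- seeds %||% (spec$seed + seq_len(n_replicates) - 1L)
  observable <- observable %||% default_observable(protocol$mode)
  rows <- lapply(seq_along(seeds), function(i) {
    spec_i <- spec
    spec_i$seed <- as.integer(seeds[i])
    prep <- if (!is.null(preps)) preps[[i]] else
      prepare_population(spec_i, solver = solver)
    tr <- simulate_population(spec_i, protocol, prep = prep,
                              post_horizon = 24, solver = solver)
    ind <- response_indices(tr, observable)
    data.frame(seed = seeds[i], R_AA = ind$R_AA, R_IA = ind$R_IA,
               R_IS = ind$R_IS)
  })
  per_seed <- do.call(rbind, rows)
  list(R_AA = mean(per_seed$R_AA), R_IA = mean(per_seed$R_IA),
       R_IS = mean(per_seed$R_IS), per_seed = per_seed)
}
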