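#' Light-pulse stimulus protocol
#'
#' A rectangular light pulse, described by its mode, onset circadian time
#' and duration. "Strength" throughout the package means pulse duration in
#' hours at a fixed push magnitude (default 3 nM/h). Modes:
#' * `"LIT"`  -- light-induced transcription: push `+l_lit` on `dx/dt`;
#' * `"LID"`  -- light-induced degradation: push `-l_lid` on `dy/dt`;
#' * `"COMBINED"` -- both pushes at once;
#' * `"NONE"` -- no stimulus (control).
#'
#' @param mode one of `"LIT"`, `"LID"`, `"COMBINED"`, `"NONE"`.
#' @param onset_ct circadian time of pulse onset in hours, wrapped into
#'   `[0, 24)`.
#' @param duration pulse duration ("strength") in hours, `>= 0`.
#' @param l_lit,l_lid push magnitudes in nM/h. Defaults follow the mode:
#'   3 for the active push(es), 0 otherwise.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol("LIT", onset_ct = 17, duration = 3)
#' @export
stimulus_protocol <- function(mode = c("NONE", "LIT", "LID", "COMBINED"),
                              onset_ct = 0, duration = 0,
                              l_lit = NULL, l_lid = NULL) {
  mode <- match.arg(mode)
  check_finite_scalar(onset_ct, "onset_ct")
  check_positive(duration, "duration", strict = FALSE)
  l_lit <- l_lit %||% if (mode %in% c("LIT", "COMBINED")) 3 else 0
  l_lid <- l_lid %||% if (mode %in% c("LID", "COMBINED")) 3 else 0
  check_positive(l_lit, "l_lit", strict = FALSE)
  check_positive(l_lid, "l_lid", strict = FALSE)
  ok <- switch(mode,
    LIT      = l_lit > 0 && l_lid == 0,
    LID      = l_lit == 0 && l_lid > 0,
    COMBINED = l_lit > 0 && l_lid > 0,
    NONE     = l_lit == 0 && l_lid == 0)
  if (!ok)
    stop_bad("push magnitudes (l_lit = ", l_lit, ", l_lid = ", l_lid,
             ") are inconsistent with mode ", mode)
  structure(list(mode = mode, onset_ct = wrap_ct(onset_ct),
                 duration = duration, l_lit = l_lit, l_lid = l_lid),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  if (x$mode == "NONE") {
    cat("<stimulus_protocol> NONE (control)\n")
  } else {
    cat(sprintf("<stimulus_protocol> %s at CT%g for %g h (l_lit = %g, l_lid = %g nM/h)\n",
                x$mode, x$onset_ct, x$duration, x$l_lit, x$l_lid))
  }
  invisible(x)
}

# default observable for an index readout: protein for LID, mRNA otherwise
default_observable <- function(mode) if (identical(mode, "LID")) "y" else "x"
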