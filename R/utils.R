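# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)

check_finite_scalar <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop_bad("`", name, "` must be a finite numeric scalar")
  invisible(value)
}

check_positive <- function(value, name, strict = TRUE) {
  check_finite_scalar(value, name)
  if ((strict && value <= 0) || (!strict && value < 0))
    stop_bad("`", name, "` must be ", if (strict) "> 0" else ">= 0",
             " (got ", format(value), ")")
  invisible(value)
}

#' Wrap circadian time into [0, 24)
#'
#' @param ct circadian time in hours (any real number).
#' @return `ct` modulo 24.
#' @export
wrap_ct <- function(ct) ct %% 24

# wrap an hour difference to (-12, 12]
wrap_half_day <- function(dh) {
  out <- dh %% 24
  ifelse(out > 12, out - 24, out)
}

# local maxima of a sampled signal with parabolic refinement of peak times
find_peaks <- function(times, values) {
  stopifnot(length(times) == length(values))
  i <- which(diff(sign(diff(values))) < 0) + 1L
  if (length(i) == 0L) return(numeric(0))
  dt <- times[2L] - times[1L]
  vapply(i, function(j) {
    den <- values[j - 1L] - 2 * values[j] + values[j + 1L]
    if (den == 0) return(times[j])
    times[j] + dt * (values[j - 1L] - values[j + 1L]) / (2 * den)
  }, numeric(1))
}

# cheap deterministic checksum of a character scalar (config provenance)
text_hash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
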