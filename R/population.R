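#' Specification of a heterogeneous oscillator population
#'
#' Describes how a population of slightly different oscillators is drawn
#' and coupled. Per-oscillator angular velocities and radii are sampled
#' independently from Gaussian distributions around the nominal values,
#' truncated at a small positive floor; the relaxation coefficient and the
#' coupling constants are shared. Oscillators are coupled through a
#' saturating mean field of the mRNA coordinate (see
#' [simulate_population()]).
#'
#' @param n number of oscillators (default 100, the population size used
#'   throughout the scan experiments).
#' @param omega_mean mean angular velocity, rad/h.
#' @param omega_cv coefficient of variation of omega (SD / mean).
#' @param a_mean mean limit-cycle radius, nM; `NULL` uses the calibrated
#'   nominal radius from [nominal_oscillator()].
#' @param a_cv coefficient of variation of the radius.
#' @param epsilon shared radial relaxation coefficient, 1/(h nM^2).
#' @param k_c coupling magnitude, nM/h.
#' @param K_f coupling half-saturation constant, nM.
#' @param seed integer RNG seed; fixes the sampled population and the
#'   burn-in initial phases.
#' @param init_arc width (radians) of the arc over which burn-in initial
#'   phases are drawn uniformly.
#' @param burn_in burn-in length in intrinsic periods before any stimulus.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n = 100L, omega_mean = 2 * pi / 24,
                            omega_cv = 0.02, a_mean = NULL, a_cv = 0.05,
                            epsilon = 1e-4, k_c = 3, K_f = 20, seed = 1L,
                            init_arc = pi / 2, burn_in = 10) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_bad("`n` must be a positive integer")
  check_positive(omega_mean, "omega_mean")
  check_positive(omega_cv, "omega_cv", strict = FALSE)
  a_mean <- a_mean %||% nominal_oscillator()$a
  check_positive(a_mean, "a_mean")
  check_positive(a_cv, "a_cv", strict = FALSE)
  check_positive(epsilon, "epsilon", strict = FALSE)
  check_positive(k_c, "k_c", strict = FALSE)
  check_positive(K_f, "K_f")
  check_finite_scalar(seed, "seed")
  check_positive(init_arc, "init_arc", strict = FALSE)
  check_positive(burn_in, "burn_in", strict = FALSE)
  structure(list(n = as.integer(n), omega_mean = omega_mean,
                 omega_cv = omega_cv, a_mean = a_mean, a_cv = a_cv,
                 epsilon = epsilon, k_c = k_c, K_f = K_f,
                 seed = as.integer(seed), init_arc = init_arc,
                 burn_in = burn_in),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  cat(sprintf("  n = %d oscillators, seed = %d\n", x$n, x$seed))
  cat(sprintf("  omega ~ N(%.4g, cv %.3g) rad/h; a ~ N(%.4g, cv %.3g) nM\n",
              x$omega_mean, x$omega_cv, x$a_mean, x$a_cv))
  cat(sprintf("  epsilon = %.3g; coupling k_c = %.3g nM/h, K_f = %.3g nM\n",
              x$epsilon, x$k_c, x$K_f))
  cat(sprintf("  burn-in %.3g periods, initial arc %.3g rad\n",
              x$burn_in, x$init_arc))
  invisible(x)
}

#' Sample a heterogeneous oscillator population
#'
#' Draws per-oscillator `(omega_i, a_i)` from independent Gaussian
#' distributions `N(mean, cv * mean)` and truncates both at `1e-6` of the
#' mean to guarantee positivity. Sampling is reproducible: the spec's seed
#' fully determines the draw.
#'
#' @param spec a [population_spec()] object.
#' @return A data frame of class `clock_population` with columns
#'   `oscillator_id`, `omega`, `a`; the shared `epsilon` is attached as an
#'   attribute.
#' @examples
#' pop <- sample_population(population_spec(n = 5, a_mean = 8.7, seed = 42))
#' pop
#' @export
sample_population <- function(spec) {
  if (!inherits(spec, "population_spec"))
    stop_bad("`spec` must be a population_spec object")
  set.seed(spec$seed)
  floor_om <- 1e-6 * spec$omega_mean
  floor_a <- 1e-6 * spec$a_mean
  omega <- pmax(rnorm(spec$n, spec$omega_mean, spec$omega_cv * spec$omega_mean),
                floor_om)
  a <- pmax(rnorm(spec$n, spec$a_mean, spec$a_cv * spec$a_mean), floor_a)
  out <- data.frame(oscillator_id = seq_len(spec$n), omega = omega, a = a)
  attr(out, "epsilon") <- spec$epsilon
  class(out) <- c("clock_population", "data.frame")
  out
}

#' @export
print.clock_population <- function(x, ...) {
  cat(sprintf("<clock_population> %d oscillators\n", nrow(x)))
  cat(sprintf("  omega: mean %.5g rad/h (period %.4g h), sd %.3g\n",
              mean(x$omega), 2 * pi / mean(x$omega), stats::sd(x$omega)))
  cat(sprintf("  a:     mean %.5g nM, sd %.3g\n", mean(x$a), stats::sd(x$a)))
  invisible(x)
}

#' Write / read a population table
#'
#' Plain-CSV export of a sampled population with columns `oscillator_id`,
#' `omega`, `a` -- the package's stand-in format for per-oscillator
#' parameter tables.
#'
#' @param population a `clock_population` data frame.
#' @param file path to a CSV file.
#' @return `write_population()` returns `file` invisibly;
#'   `read_population()` returns a `clock_population`.
#' @export
write_population <- function(population, file) {
  stopifnot(inherits(population, "clock_population"))
  write.csv(as.data.frame(population)[c("oscillator_id", "omega", "a")],
            file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_population
#' @export
read_population <- function(file) {
  out <- read.csv(file)
  need <- c("oscillator_id", "omega", "a")
  if (!all(need %in% names(out)))
    stop_bad("population file must have columns ",
             paste(need, collapse = ", "))
  if (any(out$omega <= 0) || any(out$a <= 0))
    stop_bad("population file contains non-positive omega or a")
  class(out) <- c("clock_population", "data.frame")
  out
}
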