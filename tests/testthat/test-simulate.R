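test_that("an on-cycle oscillator stays on its cycle without stimulus", {
  p <- nominal()
  tr <- simulate_single(p, stimulus_protocol("NONE", onset_ct = 9),
                        post_horizon = 24)
  phi0 <- atan2(tr$y[1, 1], tr$x[1, 1])
  expect_equal(tr$x[, 1], p$a * cos(phi0 + p$omega * tr$times),
               tolerance = 1e-6)
  # CT bookkeeping: the labeled onset CT is hit at t_on
  expect_lt(abs(clockamp:::wrap_half_day(ct_of_t(tr, tr$t_on) - 9)), 0.01)
})

test_that("a zero-duration pulse is identical to the null protocol", {
  p <- nominal()
  tr0 <- simulate_single(p, stimulus_protocol("NONE", onset_ct = 17),
                         post_horizon = 24)
  trz <- simulate_single(p, stimulus_protocol("LIT", 17, duration = 0,
                                              l_lit = 3),
                         post_horizon = 24)
  expect_equal(trz$x, tr0$x)
  expect_equal(trz$y, tr0$y)
})

test_that("the critical pulse leaves the predicted residual radius", {
  # rotating-frame closed form: residual ~ |D| sin(7.5 deg) ~ 1.1 nM
  p <- nominal()
  tr <- simulate_single(p, stimulus_protocol("LIT", 17, 3), post_horizon = 24)
  i_off <- which.min(abs(tr$times - tr$t_off))
  resid <- sqrt(tr$x[i_off, 1]^2 + tr$y[i_off, 1]^2)
  D <- (2 * 3 / p$omega) * sin(p$omega * 3 / 2)
  expect_equal(resid, D * sin(7.5 * pi / 180), tolerance = 0.05)
})

test_that("a homogeneous coupled population stays identical and on-cycle", {
  spec <- population_spec(n = 8, omega_cv = 0, a_cv = 0, a_mean = 8.65,
                          seed = 5, init_arc = 0, burn_in = 2)
  prep <- prepare_population(spec, ctrl_horizon = 80)
  # diffusive mean-field coupling vanishes for identical oscillators
  expect_equal(apply(prep$x, 1, stats::sd), rep(0, nrow(prep$x)),
               tolerance = 1e-8)
  r <- sqrt(prep$x[, 1]^2 + prep$y[, 1]^2)
  expect_equal(r, rep(8.65, length(r)), tolerance = 1e-5)
  ph <- atan2(prep$y, prep$x)
  expect_equal(apply(ph, 1, function(v) order_parameter(v)),
               rep(1, nrow(ph)), tolerance = 1e-10)
})

test_that("uncoupled heterogeneous phases disperse at the analytic rate", {
  spec <- population_spec(n = 12, omega_cv = 0.03, a_cv = 0, a_mean = 8.65,
                          k_c = 0, seed = 9, init_arc = 0, burn_in = 0)
  pop <- sample_population(spec)
  prep <- prepare_population(spec, population = pop, ctrl_horizon = 96)
  ph_end <- atan2(prep$y[nrow(prep$y), ], prep$x[nrow(prep$x), ])
  ph_start <- atan2(prep$y[1, ], prep$x[1, ])
  drift <- ph_end - ph_start
  expected <- pop$omega * 96
  mismatch <- (drift - expected + pi) %% (2 * pi) - pi
  expect_equal(mismatch, rep(0, 12), tolerance = 1e-4)
})

test_that("coupling synchronizes a dispersed heterogeneous population", {
  prep <- small_prep()
  expect_lt(prep$burn_drift, 1e-3)
  ph <- atan2(prep$y, prep$x)
  op <- apply(ph, 1, order_parameter)
  expect_gt(min(op), 0.95)
  # locked period within 1% of the mean intrinsic period
  expect_equal(prep$period, 2 * pi / prep$spec$omega_mean, tolerance = 0.01)
})

test_that("stimulated and control traces share every pre-onset sample", {
  spec <- small_spec()
  prep <- small_prep()
  prot <- stimulus_protocol("LIT", 17, 3)
  tr <- simulate_population(spec, prot, prep = prep, post_horizon = 24)
  ctl <- control_trace(spec, prep = prep, reference_protocol = prot)
  pre <- tr$times <= tr$t_on
  expect_identical(tr$x[pre, ], ctl$x[seq_len(sum(pre)), ])
  # and the pulse is anchored at the requested mean-field circadian time
  expect_lt(abs(clockamp:::wrap_half_day(ct_of_t(tr, tr$t_on) - 17)), 0.2)
})

test_that("population runs are reproducible end-to-end from the seed", {
  spec <- small_spec(seed = 21)
  prot <- stimulus_protocol("LIT", 9, 3)
  t1 <- simulate_population(spec, prot, post_horizon = 24)
  t2 <- simulate_population(spec, prot, post_horizon = 24)
  expect_identical(t1$x, t2$x)
  expect_identical(response_indices(t1)$R_AA, response_indices(t2)$R_AA)
})

test_that("the coupling guard rejects a mean field approaching -K_f", {
  # radii comparable to K_f push the mean field into the guard band
  spec <- population_spec(n = 4, omega_cv = 0, a_cv = 0, a_mean = 19.8,
                          K_f = 20, seed = 1, init_arc = 0, burn_in = 1)
  expect_error(prepare_population(spec, ctrl_horizon = 30),
               "coupling singularity")
})

test_that("traces export to long CSV with a provenance sidecar", {
  spec <- small_spec()
  tr <- simulate_population(spec, stimulus_protocol("LIT", 9, 1),
                            prep = small_prep(), post_horizon = 24)
  f <- withr::local_tempfile(fileext = ".csv")
  paths <- write_trace(tr, f)
  expect_true(all(file.exists(paths)))
  df <- read.csv(f)
  expect_setequal(names(df), c("time_h", "oscillator_id", "x", "y"))
  meta <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(meta$protocol$mode, "LIT")
  expect_match(meta$hash, "^[0-9a-f]{8}$")
})
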