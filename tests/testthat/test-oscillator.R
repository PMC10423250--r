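test_that("Cartesian vector field matches the model on key states", {
  p <- oscillator_params(omega = 2 * pi / 24, a = 5, epsilon = 1e-4)
  # on-cycle state has zero radial component: purely tangential flow
  expect_equal(vector_field(c(5, 0), p), c(0, p$omega * 5))
  # the origin (singularity point) is a fixed point of the free system
  expect_equal(vector_field(c(0, 0), p), c(0, 0))
  # a transcription push moves the fixed point along +x at the push rate
  expect_equal(vector_field(c(0, 0), p, lit = 3), c(3, 0))
  # a degradation push acts along -y
  expect_equal(vector_field(c(0, 0), p, lid = 3), c(0, -3))
  # generic off-cycle state, against direct evaluation of the equations
  st <- c(1.5, -2)
  s <- p$a^2 - st[1]^2 - st[2]^2
  expect_equal(vector_field(st, p, lit = 1, lid = 2),
               c(-p$omega * st[2] + p$epsilon * st[1] * s + 1,
                  p$omega * st[1] + p$epsilon * st[2] * s - 2))
})

test_that("non-finite states are rejected with a named diagnostic", {
  p <- oscillator_params(a = 5)
  expect_error(vector_field(c(NaN, 0), p), "x")
  expect_error(vector_field(c(0, Inf), p), "y")
  expect_error(oscillator_params(a = -1), "a")
  expect_error(oscillator_params(a = 5, omega = 0), "omega")
})

test_that("polar vector field gives constant rotation and cubic radial flow", {
  p <- oscillator_params(a = 2, epsilon = 1e-4)
  expect_equal(polar_vector_field(2, 0, p), c(p$omega, 0))     # limit cycle
  expect_equal(polar_vector_field(0, 1, p), c(p$omega, 0))     # fixed point
  expect_equal(polar_vector_field(1, 0, p),                    # a/2, direct
               c(p$omega, 1e-4 * 1 * (4 - 1)))
  expect_error(polar_vector_field(-1, 0, p), "r")
})

test_that("circadian time and phase angle convert both ways", {
  expect_equal(ct_to_angle(6), 0)      # mRNA peak
  expect_equal(ct_to_angle(18), 180)   # mRNA trough
  expect_equal(ct_to_angle(12), 90)    # protein peak, 6 h after mRNA
  expect_equal(ct_to_angle(30), ct_to_angle(6))  # modulo 24
  ct <- seq(0, 23.5, by = 0.5)
  expect_equal(angle_to_ct(ct_to_angle(ct)), ct)
})

test_that("ct_to_state places the oscillator on the cycle and round-trips", {
  p <- oscillator_params(a = 8.7)
  expect_equal(ct_to_state(6, p), c(8.7, 0))
  expect_equal(ct_to_state(18, p), c(-8.7, 0))
  st <- ct_to_state(9, p)
  expect_equal(st, 8.7 * c(cos(pi / 4), sin(pi / 4)))
  # round trip through the geometric angle
  expect_equal(angle_to_ct(atan2(st[2], st[1]) * 180 / pi), 9)
})

test_that("free trajectories relax to the cycle with constant angular speed", {
  p <- oscillator_params(a = 6, epsilon = 5e-4)
  sp <- clockamp:::single_p(p)
  tt <- seq(0, 48, by = 0.1)
  for (r0 in c(1.5, 9)) {
    out <- clockamp:::integrate_segment(c(r0, 0), tt, sp)
    r <- sqrt(out[, 2]^2 + out[, 3]^2)
    if (r0 < p$a) expect_true(all(diff(r) > 0))   # monotone approach from inside
    else expect_true(all(diff(r) < 0))            # and from outside
    # unwrapped angle grows exactly linearly at omega, independent of r
    th <- atan2(out[, 3], out[, 2])
    th_unwrapped <- th + 2 * pi * cumsum(c(0, diff(th) < -pi))
    expect_equal(th_unwrapped, p$omega * tt, tolerance = 1e-6)
  }
})

test_that("integrating Cartesian equations matches the polar closed form", {
  # polar system solves exactly: theta = omega t, r^2 logistic in t
  p <- oscillator_params(a = 6, epsilon = 5e-4)
  r0 <- 2.5
  tt <- seq(0, 36, by = 0.5)
  out <- clockamp:::integrate_segment(c(r0, 0), tt, clockamp:::single_p(p))
  u0 <- r0^2; A <- p$a^2; g <- exp(2 * p$epsilon * A * tt)
  r_exact <- sqrt(A * u0 * g / (A - u0 + u0 * g))
  expect_equal(sqrt(out[, 2]^2 + out[, 3]^2), r_exact, tolerance = 1e-7)
})

test_that("the free flow is rotationally equivariant", {
  p <- oscillator_params(a = 6, epsilon = 5e-4)
  sp <- clockamp:::single_p(p)
  tt <- seq(0, 30, by = 0.5)
  beta <- 1.1
  rot <- matrix(c(cos(beta), sin(beta), -sin(beta), cos(beta)), 2)
  base <- clockamp:::integrate_segment(c(4, 1), tt, sp)
  rotated <- clockamp:::integrate_segment(as.vector(rot %*% c(4, 1)), tt, sp)
  expect_equal(unname(rotated[, 2:3]), unname(t(rot %*% t(base[, 2:3]))),
               tolerance = 1e-7)
})

test_that("with epsilon = 0 the radius is conserved", {
  p <- oscillator_params(a = 6, epsilon = 0)
  tt <- seq(0, 72, by = 0.5)
  out <- clockamp:::integrate_segment(c(2, 1), tt, clockamp:::single_p(p))
  r <- sqrt(out[, 2]^2 + out[, 3]^2)
  expect_equal(r, rep(r[1], length(tt)), tolerance = 1e-8)
})
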