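test_that("inertia matrix matches hand computation and is SPD in bounds", {
  p <- arm_params()
  expect_equal(p$k1, 0.169, tolerance = 1e-12)
  expect_equal(p$k2, 0.0528, tolerance = 1e-12)
  expect_equal(p$k3, 0.045, tolerance = 1e-12)
  expect_equal(compute_inertia(0, p),
               matrix(c(0.2746, 0.0978, 0.0978, 0.045), 2, 2),
               tolerance = 1e-12)
  expect_equal(compute_inertia(pi / 2, p),
               matrix(c(0.169, 0.045, 0.045, 0.045), 2, 2),
               tolerance = 1e-12)
  for (q2 in seq(p$q_lower[2], p$q_upper[2], length.out = 25)) {
    M <- compute_inertia(q2, p)
    expect_identical(M, t(M))
    expect_true(all(eigen(M, symmetric = TRUE)$values > 0))
  }
})

test_that("muscle torque map reproduces the printed moment arms and tensions", {
  p0 <- arm_params(kappa = 0)
  expect_equal(muscle_torque(c(1, 0, 0, 0, 0, 0), p0)$torque, c(28, 0),
               tolerance = 1e-12)
  expect_equal(muscle_torque(rep(1, 6), p0)$torque, c(6.042, -3.503),
               tolerance = 1e-10)
  # multiplicative noise: silence is noiseless
  p <- arm_params(kappa = 0.3)
  expect_equal(muscle_torque(rep(0, 6), p, noise = rnorm(6))$torque, c(0, 0))
  expect_error(muscle_torque(c(1.2, 0, 0, 0, 0, 0), p), "\\[0, 1\\]")
  expect_error(muscle_torque(rep(-0.1, 6), p), "\\[0, 1\\]")
})

test_that("signal-dependent noise is unbiased and clamped to the action box", {
  p <- arm_params(kappa = 0.3)
  set.seed(42)
  n <- 20000
  u <- rep(0.5, 6)
  draws <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) draws[i, ] <- muscle_torque(u, p)$u_noisy
  expect_true(all(draws >= 0 & draws <= 1))
  se <- sd(as.vector(draws)) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
})

test_that("Coriolis vector matches the closed form", {
  p <- arm_params()
  expect_equal(coriolis_vector(c(0, pi / 2), c(1, 0), p), c(0, 0.0528),
               tolerance = 1e-12)
  # at rest there is no Coriolis force
  expect_equal(coriolis_vector(c(0.3, 1.1), c(0, 0), p), c(0, 0))
})

test_that("passive frictionless arm conserves kinetic energy", {
  p <- arm_params(kappa = 0, dt = 1e-5,
                  B = matrix(0, 2, 2))
  st <- plant_state(c(0.8, 1.2), c(1.0, -0.5))
  kinetic <- function(s) 0.5 * drop(t(s$q_dot) %*% compute_inertia(s$q[2], p) %*% s$q_dot)
  e0 <- kinetic(st)
  for (i in seq_len(10000)) st <- arm_step(st, rep(0, 6), p)$state
  expect_lt(abs(kinetic(st) - e0) / e0, 1e-4)
})

test_that("damping dissipates energy in the passive arm", {
  p <- arm_params(kappa = 0, dt = 2e-3)
  st <- plant_state(c(0.8, 1.2), c(1.0, -0.5))
  kinetic <- function(s) 0.5 * drop(t(s$q_dot) %*% compute_inertia(s$q[2], p) %*% s$q_dot)
  e <- kinetic(st)
  for (i in seq_len(200)) {
    st <- arm_step(st, rep(0, 6), p)$state
    e_new <- kinetic(st)
    expect_lte(e_new, e + 1e-12)
    e <- e_new
  }
})

test_that("stationary arm with zero input stays put", {
  p <- arm_params(kappa = 0)
  st <- plant_state(c(1.0, 0.8), c(0, 0))
  nxt <- arm_step(st, rep(0, 6), p)$state
  expect_equal(nxt$q, st$q)
  expect_equal(nxt$q_dot, st$q_dot)
})

test_that("forward kinematics follows the shoulder-at-origin convention", {
  p <- arm_params()
  expect_equal(forward_kinematics(c(pi / 2, 0), p)$position, c(0, 0.65),
               tolerance = 1e-12)
  expect_equal(forward_kinematics(c(0, pi / 2), p)$position, c(0.3, 0.35),
               tolerance = 1e-12)
  fk <- forward_kinematics(c(0.7, 1.1), p)
  expect_equal(drop(fk$jacobian %*% c(0, 0)), c(0, 0))
})

test_that("inverse kinematics returns the elbow-positive branch and round-trips", {
  p <- arm_params()
  expect_equal(inverse_kinematics(c(0, 0.65), p), c(pi / 2, 0),
               tolerance = 1e-6)
  q <- inverse_kinematics(c(0, 0.6175), p)
  expect_equal(q[2], acos((0.6175^2 - p$l1^2 - p$l2^2) / (2 * p$l1 * p$l2)),
               tolerance = 1e-9)
  expect_equal(q[2], 0.637, tolerance = 1e-3)
  expect_error(inverse_kinematics(c(0, 0.7), p), "unreachable")
  set.seed(7)
  for (i in 1:100) {
    r <- runif(1, abs(p$l1 - p$l2) + 0.01, p$l1 + p$l2 - 0.01)
    th <- runif(1, 0, 2 * pi)
    pt <- r * c(cos(th), sin(th))
    qi <- inverse_kinematics(pt, p)
    expect_gte(qi[2], 0)
    expect_equal(forward_kinematics(qi, p)$position, pt, tolerance = 1e-9)
  }
})

test_that("parameter validation rejects unphysical arms", {
  expect_error(arm_params(m1 = -1), "positive")
  expect_error(arm_params(dt = 0), "dt")
  expect_error(arm_params(B = matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
  expect_error(arm_params(f_max = rep(1, 5)), "f_max")
})
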