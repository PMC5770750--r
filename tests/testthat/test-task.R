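test_that("task layout reproduces the three start arcs", {
  lay <- task_layout(0.01)
  sp <- lay$start_points
  expect_equal(nrow(sp), 15L)
  expect_equal(sort(unique(sp$distance)), c(0.0975, 0.24375, 0.39),
               tolerance = 1e-12)
  expect_equal(as.vector(table(sp$arc)), c(3L, 5L, 7L))
  expect_equal(lay$wall_y, 0.6175, tolerance = 1e-12)
  # distances are measured from the target centre
  d <- sqrt(sp$x^2 + (sp$y - lay$wall_y)^2)
  expect_equal(d, sp$distance, tolerance = 1e-12)
  # mirror symmetry about the target axis
  expect_equal(sort(round(sp$x, 10)), sort(round(-sp$x, 10)))
  expect_error(task_layout(0), "positive")
})

test_that("noise-free rollouts are exactly repeatable", {
  p <- arm_params(kappa = 0)
  lay <- task_layout(0.04, params = p)
  pol <- constant_policy()
  a <- rollout(pol, 2, lay)
  b <- rollout(pol, 2, lay)
  expect_identical(a$table, b$table)
  expect_identical(a$hit_x, b$hit_x)
})

test_that("a silent controller times out with negligible effort", {
  lay <- task_layout(0.04)
  pol <- constant_policy(rep(1e-12, 6))
  cc <- cost_config(timeout = 0.5)
  tr <- rollout(pol, 2, lay, cost_cfg = cc)
  expect_equal(tr$outcome, "timeout")
  expect_equal(tr$mt, 0.5)
  expect_lt(tr$effort, 1e-12)
  expect_equal(utility(tr, cc), -cost_config()$upsilon * tr$effort)
})

test_that("wall-crossing interpolation lies on the final segment", {
  p <- arm_params(kappa = 0)
  cfg <- estimator_config()
  lay <- task_layout(0.04, params = p)
  pol <- constant_policy(c(0.5, 0.05, 0, 0.45, 0, 0))
  ref <- reference_rollout(pol, c(0.05, 0.45), p, cfg, lay$wall_y, n_max = 2000)
  expect_equal(ref$status, 1L)
  n <- nrow(ref$table)
  x_pre <- ref$table[n, 12]; y_pre <- ref$table[n, 13]
  p_post <- forward_kinematics(ref$final_state$q, p)$position
  expect_lt(y_pre, lay$wall_y)
  expect_gte(p_post[2], lay$wall_y)
  expect_true(ref$hit_x >= min(x_pre, p_post[1]) - 1e-12 &&
                ref$hit_x <= max(x_pre, p_post[1]) + 1e-12)
  # movement time falls inside the crossing step
  expect_gte(ref$mt, ref$table[n, 1])
  expect_lte(ref$mt, ref$table[n, 1] + p$dt)
})

test_that("utility implements discounted reward minus effort and penalties", {
  cc <- cost_config(rho = 3000, upsilon = 1, gamma = 0.6, w_perp = 1)
  mk <- function(outcome, mt, effort = 0, vx = 0)
    structure(list(outcome = outcome, mt = mt, effort = effort,
                   v_cross = c(vx, 1)), class = "reach_trajectory")
  expect_equal(utility(mk("hit", 0.5), cc), 3000 * exp(-0.5 / 0.6))
  expect_equal(utility(mk("hit", 0.5), cc), 1303.76, tolerance = 1e-4)
  expect_equal(utility(mk("miss", 0.5), cc), 0)
  expect_equal(utility(mk("timeout", 4, effort = 2), cc), -2)
  # monotone in movement time
  mts <- seq(0.1, 1.5, by = 0.1)
  js <- vapply(mts, function(m) utility(mk("hit", m), cc), numeric(1))
  expect_true(all(diff(js) < 0))
  # perpendicularity penalty applies to any crossing
  expect_equal(utility(mk("miss", 0.5, vx = 2), cc), -4)
  expect_equal(utility(mk("hit", 0.5, effort = 1, vx = 2), cc),
               3000 * exp(-0.5 / 0.6) - 1 - 4)
})

test_that("effort is computed from commanded, not noisy, activations", {
  lay <- task_layout(0.04)
  pol <- constant_policy(c(0.5, 0.1, 0.4, 0.1, 0.2, 0.1))
  set.seed(21)
  tr <- rollout(pol, 2, lay)
  u_cols <- paste0("u", 1:6)
  recomputed <- sum(rowSums(as.matrix(tr$table[, u_cols])^2)) * arm_params()$dt
  expect_equal(tr$effort, recomputed, tolerance = 1e-12)
})

test_that("expected utility reduces to a single rollout when noise-free", {
  p <- arm_params(kappa = 0)
  lay <- task_layout(0.04, params = p)
  pol <- constant_policy()
  ev <- expected_utility(pol, 2, lay, n_rollouts = 5, seed = 4)
  tr <- rollout(pol, 2, lay, record = FALSE)
  expect_equal(ev$mean_utility, utility(tr))
  expect_equal(var(ev$utilities), 0)
})

test_that("Monte-Carlo error of the expected utility shrinks with rollouts", {
  lay <- task_layout(0.04)
  set.seed(5)
  pol <- init_policy()
  means_small <- vapply(1:12, function(r)
    expected_utility(pol, 2, lay, n_rollouts = 4, seed = 1000 + r)$mean_utility,
    numeric(1))
  means_large <- vapply(1:12, function(r)
    expected_utility(pol, 2, lay, n_rollouts = 36, seed = 2000 + r)$mean_utility,
    numeric(1))
  # nine-fold sample size should shrink the sd about three-fold
  expect_lt(sd(means_large), sd(means_small))
})
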