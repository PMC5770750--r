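tiny_opt <- optimizer_config(popsize = 6, max_iter = 10, repet = 2)

test_that("policy search improves on the random initial controller", {
  lay <- task_layout(0.04)
  fit <- optimize_policy(2, lay, opt_cfg = tiny_opt, seed = 1)
  expect_s3_class(fit, "reach_policy")
  tr <- fit$trace
  expect_true(all(diff(tr$J_best_so_far) >= 0))
  expect_gte(tr$J_best_so_far[nrow(tr)], tr$J_best_iter[1] - 1e-9)
  expect_equal(length(coef(fit)), 116L)
})

test_that("optimization runs are exactly reproducible from the master seed", {
  lay <- task_layout(0.04)
  f1 <- optimize_policy(2, lay, opt_cfg = tiny_opt, seed = 42)
  f2 <- optimize_policy(2, lay, opt_cfg = tiny_opt, seed = 42)
  expect_equal(f1$trace, f2$trace)
  expect_identical(coef(f1), coef(f2))
  f3 <- optimize_policy(2, lay, opt_cfg = tiny_opt, seed = 43)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("candidate rollout streams are independent of population size", {
  # the rollout stream of candidate (iter, idx) depends only on the master
  # seed and those labels, never on how many other candidates exist
  s_a <- derive_seed(5, 2001L, 3L, 2L)
  s_b <- derive_seed(5, 2001L, 3L, 2L)
  expect_identical(s_a, s_b)
  expect_false(derive_seed(5, 2001L, 3L, 2L) == derive_seed(5, 2001L, 3L, 3L))
  expect_false(derive_seed(5, 2001L, 3L, 2L) == derive_seed(6, 2001L, 3L, 2L))
  lay <- task_layout(0.04)
  set.seed(1); pol <- init_policy()
  e1 <- expected_utility(pol, 2, lay, n_rollouts = 3, seed = s_a)
  e2 <- expected_utility(pol, 2, lay, n_rollouts = 5, seed = s_a)
  expect_equal(e1$utilities, e2$utilities[1:3])
})

test_that("with no reward the search minimizes effort", {
  lay <- task_layout(0.04)
  cc <- cost_config(rho = 0, w_perp = 0, timeout = 0.3)
  fit <- optimize_policy(2, lay, cost_cfg = cc,
                         opt_cfg = optimizer_config(popsize = 8,
                                                    max_iter = 25, repet = 2),
                         seed = 9)
  set.seed(1)
  tr_init <- rollout(fit$initial_policy, 2, lay, cost_cfg = cc, record = FALSE)
  set.seed(1)
  tr_best <- rollout(fit$policy, 2, lay, cost_cfg = cc, record = FALSE)
  expect_lt(tr_best$effort, tr_init$effort)
})

test_that("campaign evaluation produces the full trial table", {
  camp <- optimize_campaign(widths = c(0.04), start_ids = c(2L, 12L),
                            opt_cfg = tiny_opt, n_eval = 8, seed = 2)
  expect_s3_class(camp, "reach_campaign")
  expect_equal(nrow(camp$trials), 16L)
  expect_setequal(unique(camp$trials$start_id), c(2L, 12L))
  expect_true(all(camp$trials$outcome %in% c("hit", "miss", "timeout")))
  done <- camp$trials[camp$trials$outcome != "timeout", ]
  expect_true(all(is.finite(done$mt)) && all(done$mt > 0))
  expect_true(all(is.finite(done$hit_x)))
})
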