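# Pure-R reference implementation of the closed-loop rollout, built from the
# exported primitives (arm_step / open_loop_update / closed_loop_update /
# combine_estimates / policy_forward). Used to cross-check the compiled
# rollout step for step, and to expose per-step estimator internals that the
# fast path does not record.
reference_rollout <- function(pol, start_xy, params, est_cfg,
                              wall_y, n_max = 2000, keep_estimates = FALSE) {
  q0 <- inverse_kinematics(start_xy, params)
  truth <- plant_state(q0, c(0, 0))
  est1 <- truth                      # open-loop term
  cmd_hist <- list()                 # efference copies u_0 ... u_{t-1}
  state_hist <- list(truth)          # true states x_0 ... x_t
  tab <- matrix(NA_real_, n_max, 13)
  est_err <- if (keep_estimates) matrix(NA_real_, n_max, 3) else NULL
  status <- 0L; hit_x <- NA; mt <- NA; v_cross <- c(NA, NA)
  effort <- 0
  p_old <- forward_kinematics(truth$q, params)$position

  for (t in seq_len(n_max) - 1L) {
    if (t == 0L) {
      est <- truth
      est2 <- truth
    } else {
      est1 <- open_loop_update(est1, cmd_hist[[t]], params)
      avail <- min(t, est_cfg$delay)
      delayed <- state_hist[[t - avail + 1L]]
      buf <- cmd_hist[seq.int(t - avail + 1L, t)]
      est2 <- closed_loop_update(delayed, buf, params, delay = avail)
      est <- combine_estimates(est1, est2, est_cfg)
    }
    u <- policy_forward(pol, est, params)
    tab[t + 1L, ] <- c(t * params$dt, truth$q, truth$q_dot, u, p_old)
    if (keep_estimates)
      est_err[t + 1L, ] <- c(sqrt(sum((est1$q - truth$q)^2)),
                             sqrt(sum((est2$q - truth$q)^2)),
                             sqrt(sum((est$q - truth$q)^2)))
    cmd_hist[[t + 1L]] <- u
    stp <- arm_step(truth, u, params)
    truth <- stp$state
    state_hist[[t + 2L]] <- truth
    effort <- effort + sum(u^2) * params$dt
    p_new <- forward_kinematics(truth$q, params)$position
    if (p_new[2] >= wall_y && p_old[2] < wall_y) {
      alpha <- (wall_y - p_old[2]) / (p_new[2] - p_old[2])
      hit_x <- p_old[1] + alpha * (p_new[1] - p_old[1])
      mt <- (t + alpha) * params$dt
      v_cross <- drop(forward_kinematics(truth$q, params)$jacobian %*% truth$q_dot)
      status <- 1L
      tab <- tab[seq_len(t + 1L), , drop = FALSE]
      if (keep_estimates) est_err <- est_err[seq_len(t + 1L), , drop = FALSE]
      break
    }
    p_old <- p_new
  }
  list(status = status, hit_x = hit_x, mt = mt, v_cross = v_cross,
       effort = effort, table = tab, est_err = est_err,
       final_state = truth)
}

# a hand-built controller that emits a fixed activation vector regardless of
# state; the default (shoulder flexor + elbow extensor) extends the arm
# toward the wall from the central start points
constant_policy <- function(u_target = c(0.5, 0, 0, 0.5, 0, 0), n_hidden = 10) {
  th <- numeric(n_policy_params(n_hidden))
  # zero hidden weights: hidden layer outputs tanh(0) = 0, so outputs are
  # logistic(b2); choose b2 = logit(u_target)
  eps <- 1e-9
  u <- pmin(pmax(u_target, eps), 1 - eps)
  th[(5 * n_hidden + 6 * n_hidden) + 1:6] <- log(u / (1 - u))
  policy(th, n_hidden = n_hidden)
}

smoke_layouts <- function(widths = c(0.005, 0.04)) {
  lapply(widths, task_layout)
}
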