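#' Reaching task geometry
#'
#' The target is an interval of width `target_width` centred on
#' `(0, wall_y)` on a wall line parallel to the x axis; the shoulder is at
#' the origin and the wall sits at 95% of full arm length. Movements begin
#' at rest from one of 15 start points arranged on three arcs centred on the
#' target, at 15%, 37.5% and 60% of arm length, holding 3, 5 and 7 points
#' spread evenly over +-45 degrees about the target-to-shoulder axis.
#'
#' @param target_width width of the target interval (m). The four task
#'   conditions use 0.005, 0.01, 0.02 and 0.04 m.
#' @param params an [arm_params()] object (fixes arm length, hence the wall
#'   position and arc radii).
#' @param wall_y wall line position (m); default 95% of `l1 + l2`.
#' @param arc_fractions arc radii as fractions of arm length.
#' @param points_per_arc number of start points on each arc.
#' @param angular_span half-width of the angular spread (rad).
#' @return An object of class `task_layout`: target geometry plus a
#'   data.frame `start_points` with columns `id`, `arc`, `distance`, `x`,
#'   `y`.
#' @export
task_layout <- function(target_width = 0.01, params = arm_params(),
                        wall_y = 0.95 * (params$l1 + params$l2),
                        arc_fractions = c(0.15, 0.375, 0.60),
                        points_per_arc = c(3L, 5L, 7L),
                        angular_span = pi / 4) {
  if (target_width <= 0) stop("target_width must be positive")
  arm_len <- params$l1 + params$l2
  radii <- arc_fractions * arm_len
  pts <- do.call(rbind, lapply(seq_along(radii), function(k) {
    n <- points_per_arc[k]
    phi <- seq(-angular_span, angular_span, length.out = n)
    # arcs are centred on the target; phi = 0 points back toward the shoulder
    data.frame(arc = k, distance = radii[k],
               x = radii[k] * sin(phi),
               y = wall_y - radii[k] * cos(phi))
  }))
  pts <- cbind(id = seq_len(nrow(pts)), pts)
  for (i in seq_len(nrow(pts))) {
    r <- sqrt(pts$x[i]^2 + pts$y[i]^2)
    if (r >= arm_len || r <= abs(params$l1 - params$l2))
      stop(sprintf("start point %d at radius %.3f m lies outside the workspace", i, r))
  }
  structure(list(wall_y = wall_y, target_center_x = 0,
                 target_width = target_width,
                 start_points = pts, params = params),
            class = "task_layout")
}

#' Cost-function configuration
#'
#' The objective of a movement is its expected utility: on a hit the agent
#' collects a reward `rho` discounted exponentially in movement time with
#' time constant `gamma`; every movement pays the integrated squared
#' activation (weight `upsilon`) and, whenever the wall is crossed, a
#' penalty `w_perp` times the squared tangential (along-wall) end-effector
#' speed, which favours perpendicular hits.
#'
#' @param rho immediate reward factor (default 3000).
#' @param upsilon effort weight (default 1).
#' @param gamma discount time constant in seconds (default 0.6).
#' @param w_perp perpendicularity-penalty weight (default 1).
#' @param timeout maximum simulated movement duration in seconds
#'   (default 4).
#' @return An object of class `cost_config`.
#' @export
cost_config <- function(rho = 3000, upsilon = 1, gamma = 0.6,
                        w_perp = 1, timeout = 4) {
  if (gamma <= 0) stop("gamma must be positive")
  if (rho < 0 || upsilon < 0 || w_perp < 0) stop("weights must be non-negative")
  if (timeout <= 0) stop("timeout must be positive")
  structure(list(rho = rho, upsilon = upsilon, gamma = gamma,
                 w_perp = w_perp, timeout = timeout),
            class = "cost_config")
}

#' Simulate one reaching movement in closed loop
#'
#' Runs the full control loop from a start point at rest: at each step the
#' delayed-feedback estimator produces a state estimate, the controller maps
#' it to six activations, and the plant integrates one step under
#' signal-dependent motor noise. The movement ends when the end effector
#' crosses the wall line (the crossing point is obtained by linear
#' interpolation within the crossing step) or when the timeout elapses.
#'
#' @param pol a [policy()].
#' @param start start-point id (row of `layout$start_points`) or a numeric
#'   `(x, y)` position.
#' @param layout a [task_layout()].
#' @param cost_cfg a [cost_config()] (supplies the timeout).
#' @param est_cfg an [estimator_config()].
#' @param record if `FALSE`, per-step time series are omitted (faster;
#'   used inside optimization).
#' @return An object of class `reach_trajectory`: `outcome` (`"hit"`,
#'   `"miss"` or `"timeout"`), `hit_x`, `mt` (movement time, s), `effort`
#'   (integral of squared activation norm), `v_cross` (Cartesian
#'   end-effector velocity at crossing), and — when recorded — a data.frame
#'   `table` with columns `t`, `q1`, `q2`, `qd1`, `qd2`, `u1..u6`, `x`, `y`.
#' @export
rollout <- function(pol, start, layout, cost_cfg = cost_config(),
                    est_cfg = estimator_config(), record = TRUE) {
  params <- layout$params
  if (length(start) == 1) {
    sp <- layout$start_points
    if (!start %in% sp$id) stop("unknown start point id")
    start <- c(sp$x[sp$id == start], sp$y[sp$id == start])
  }
  q0 <- inverse_kinematics(start, params)
  n_max <- as.integer(ceiling(cost_cfg$timeout / params$dt))
  res <- rollout_cpp(pol$theta, pol$n_hidden, pol$vel_scale,
                     q0, c(0, 0),
                     params$k1, params$k2, params$k3,
                     params$B, params$A, params$f_max,
                     params$kappa, params$dt,
                     params$q_lower, params$q_upper,
                     params$l1, params$l2,
                     layout$wall_y, n_max,
                     est_cfg$delay, est_cfg$k1, est_cfg$k2,
                     isTRUE(record))
  out <- list(outcome = c("timeout", "miss", "hit")[res$status + 1L],
              hit_x = if (res$status > 0) res$hit_x else NA_real_,
              mt = if (res$status > 0) res$mt else cost_cfg$timeout,
              effort = res$effort,
              v_cross = if (res$status > 0) c(res$vx, res$vy) else c(NA, NA),
              start = start,
              target_width = layout$target_width,
              wall_y = layout$wall_y,
              l1 = params$l1, l2 = params$l2)
  # hit/miss is decided here so the same simulation serves every width
  if (res$status > 0) {
    hit <- abs(res$hit_x - layout$target_center_x) <= layout$target_width / 2
    out$outcome <- if (hit) "hit" else "miss"
  }
  if (isTRUE(record)) {
    tab <- as.data.frame(res$table)
    names(tab) <- c("t", "q1", "q2", "qd1", "qd2",
                    paste0("u", 1:6), "x", "y")
    out$table <- tab
  }
  structure(out, class = "reach_trajectory")
}

#' Utility of one movement
#'
#' `J = hit * rho * exp(-mt / gamma) - upsilon * sum(||u_t||^2) * dt -
#' w_perp * vx_cross^2`. The reward term is zero on a miss or timeout; the
#' perpendicularity penalty applies whenever the wall was crossed; effort is
#' computed from the commanded (pre-noise) activations.
#'
#' @param traj a [rollout()] result.
#' @param cost_cfg a [cost_config()].
#' @return scalar utility.
#' @export
utility <- function(traj, cost_cfg = cost_config()) {
  J <- -cost_cfg$upsilon * traj$effort
  if (traj$outcome == "hit")
    J <- J + cost_cfg$rho * exp(-traj$mt / cost_cfg$gamma)
  if (traj$outcome != "timeout" && is.finite(traj$v_cross[1]))
    J <- J - cost_cfg$w_perp * traj$v_cross[1]^2
  J
}

#' Monte-Carlo expected utility of a controller
#'
#' Averages [utility()] over independently seeded rollouts, reporting the
#' hit rate and mean movement time alongside.
#'
#' @inheritParams rollout
#' @param n_rollouts number of rollouts (the optimizer default is 50).
#' @param seed integer seed for the first rollout; rollout `i` uses a
#'   deterministic stream derived from `seed` and `i`.
#' @return list with `mean_utility`, `hit_rate`, `mean_mt`, `utilities`.
#' @export
expected_utility <- function(pol, start, layout, cost_cfg = cost_config(),
                             est_cfg = estimator_config(),
                             n_rollouts = 50, seed = 1) {
  J <- numeric(n_rollouts); hit <- logical(n_rollouts); mt <- numeric(n_rollouts)
  for (i in seq_len(n_rollouts)) {
    set.seed(derive_seed(seed, 7001L, i))
    tr <- rollout(pol, start, layout, cost_cfg, est_cfg, record = FALSE)
    J[i] <- utility(tr, cost_cfg)
    hit[i] <- tr$outcome == "hit"
    mt[i] <- tr$mt
  }
  list(mean_utility = mean(J), hit_rate = mean(hit), mean_mt = mean(mt),
       utilities = J)
}

#' @export
print.reach_trajectory <- function(x, ...) {
  cat(sprintf("reaching movement: %s", x$outcome))
  if (x$outcome != "timeout")
    cat(sprintf(" at x = %+.4f m (target half-width %.4f m), MT = %.3f s",
                x$hit_x, x$target_width / 2, x$mt))
  cat(sprintf(", effort = %.3f\n", x$effort))
  invisible(x)
}

#' @export
plot.reach_trajectory <- function(x, ...) {
  if (is.null(x$table)) stop("trajectory was not recorded; rerun rollout() with record = TRUE")
  tab <- x$table
  graphics::par(mfrow = c(1, 2))
  graphics::plot(tab$x, tab$y, type = "l", asp = 1, xlab = "x (m)", ylab = "y (m)",
                 main = "end-effector path", ...)
  graphics::abline(h = x$wall_y, col = "grey")
  vp <- velocity_profile(x)
  graphics::plot(tab$t, vp$speed, type = "l", xlab = "t (s)",
                 ylab = "speed (m/s)", main = "velocity profile")
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}
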