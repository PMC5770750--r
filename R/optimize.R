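#' Optimizer configuration
#'
#' Meta-parameters of the CMA-ES policy search. Defaults are the full-budget
#' study settings; scaled-down smoke settings are available through
#' [reproduce()].
#'
#' @param sigma0 initial covariance factor (the CMA-ES step size starts at
#'   `sqrt(sigma0)` would be another convention; here `sigma0` is used
#'   directly as the initial global step size, default 0.01).
#' @param popsize population size (default 30).
#' @param max_iter maximum number of iterations (default 5000).
#' @param repet rollouts per candidate evaluation (default 50).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(sigma0 = 0.01, popsize = 30,
                             max_iter = 5000, repet = 50) {
  if (sigma0 <= 0) stop("sigma0 must be positive")
  if (popsize < 2) stop("popsize must be >= 2")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (repet < 1) stop("repet must be >= 1")
  structure(list(sigma0 = sigma0, popsize = as.integer(popsize),
                 max_iter = as.integer(max_iter), repet = as.integer(repet)),
            class = "optimizer_config")
}

#' Fit a reaching controller by CMA-ES policy search
#'
#' The central fitting function of the package: finds, for one start point
#' and one target width, the feed-forward controller that maximizes the
#' Monte-Carlo expected utility of the reaching movement (discounted hit
#' reward minus integrated effort minus the perpendicularity penalty).
#' Candidate controllers are evaluated on `repet` independently seeded
#' noisy rollouts; candidate rollout streams depend only on the master
#' seed, the iteration and the candidate index, so runs are exactly
#' reproducible and unaffected by population-size changes elsewhere.
#'
#' @param start start-point id (row of `layout$start_points`).
#' @param layout a [task_layout()] (fixes the target width).
#' @param cost_cfg a [cost_config()].
#' @param est_cfg an [estimator_config()].
#' @param opt_cfg an [optimizer_config()].
#' @param n_hidden hidden-layer size of the controller.
#' @param seed master seed.
#' @param verbose print per-iteration progress.
#' @return An object of class `reach_policy` with components `policy` (the
#'   best evaluated controller), `initial_policy`, `trace` (per-iteration
#'   best/mean objective, hit rate, mean movement time), `eval` (final
#'   fresh-seed evaluation of the best controller), and the configurations.
#'   Supports `print`, `summary`, `coef`, `plot`, `predict` and
#'   `simulate`.
#' @examples
#' \donttest{
#' lay <- task_layout(target_width = 0.04)
#' fit <- optimize_policy(1, lay, opt_cfg = optimizer_config(
#'   popsize = 6, max_iter = 5, repet = 2), seed = 1)
#' print(fit)
#' }
#' @export
optimize_policy <- function(start, layout, cost_cfg = cost_config(),
                            est_cfg = estimator_config(),
                            opt_cfg = optimizer_config(),
                            n_hidden = 10, seed = 1, verbose = FALSE) {
  stopifnot(inherits(layout, "task_layout"))
  set.seed(derive_seed(seed, 11L))
  pol0 <- init_policy(n_hidden)

  evaluate <- function(theta, it, idx) {
    pol <- policy(theta, n_hidden)
    ev <- expected_utility(pol, start, layout, cost_cfg, est_cfg,
                           n_rollouts = opt_cfg$repet,
                           seed = derive_seed(seed, 2001L, it, idx))
    # CMA-ES minimizes; utilities are maximized
    structure(-ev$mean_utility, hit_rate = ev$hit_rate, mean_mt = ev$mean_mt)
  }

  aux <- new.env()
  aux$rows <- list()
  res <- cma_es(function(x, it, idx) {
    f <- evaluate(x, it, idx)
    aux$last_hit <- c(aux$last_hit, attr(f, "hit_rate"))
    aux$last_mt <- c(aux$last_mt, attr(f, "mean_mt"))
    as.numeric(f)
  }, x0 = pol0$theta, sigma0 = opt_cfg$sigma0,
  popsize = opt_cfg$popsize, max_iter = opt_cfg$max_iter, seed = seed,
  callback = function(row) {
    aux$rows[[row$iter]] <- data.frame(
      iter = row$iter, J_best_iter = -row$f_best_iter,
      J_mean = -row$f_mean, J_best_so_far = -row$f_best_so_far,
      sigma = row$sigma,
      hit_rate = mean(aux$last_hit), mean_mt = mean(aux$last_mt))
    aux$last_hit <- NULL; aux$last_mt <- NULL
    if (verbose)
      message(sprintf("iter %4d  best J %10.2f  hit %4.2f  MT %5.3f s",
                      row$iter, -row$f_best_so_far,
                      utils::tail(aux$rows, 1)[[1]]$hit_rate,
                      utils::tail(aux$rows, 1)[[1]]$mean_mt))
  })

  best <- policy(res$x_best, n_hidden)
  ev0 <- expected_utility(pol0, start, layout, cost_cfg, est_cfg,
                          n_rollouts = opt_cfg$repet,
                          seed = derive_seed(seed, 3001L))
  ev1 <- expected_utility(best, start, layout, cost_cfg, est_cfg,
                          n_rollouts = opt_cfg$repet,
                          seed = derive_seed(seed, 3002L))

  structure(list(policy = best, initial_policy = pol0,
                 trace = do.call(rbind, aux$rows),
                 eval = ev1, eval_initial = ev0,
                 start = start, layout = layout,
                 cost_cfg = cost_cfg, est_cfg = est_cfg, opt_cfg = opt_cfg,
                 n_hidden = n_hidden, seed = seed),
            class = "reach_policy")
}

#' @export
print.reach_policy <- function(x, ...) {
  cat(sprintf("Optimized reaching controller (start %s, target width %.3f m)\n",
              x$start, x$layout$target_width))
  cat(sprintf("  CMA-ES: popsize %d, %d iterations, %d rollouts/candidate, seed %d\n",
              x$opt_cfg$popsize, nrow(x$trace), x$opt_cfg$repet, x$seed))
  cat(sprintf("  expected utility %.1f (initial %.1f), hit rate %.2f, mean MT %.3f s\n",
              x$eval$mean_utility, x$eval_initial$mean_utility,
              x$eval$hit_rate, x$eval$mean_mt))
  invisible(x)
}

#' @export
summary.reach_policy <- function(object, ...) {
  structure(list(fit = object), class = "summary.reach_policy")
}

#' @export
print.summary.reach_policy <- function(x, ...) {
  f <- x$fit
  print(f)
  tr <- f$trace
  cat(sprintf("  best-so-far J: start %.1f -> end %.1f over %d iterations\n",
              tr$J_best_so_far[1], tr$J_best_so_far[nrow(tr)], nrow(tr)))
  cat(sprintf("  final-iteration population mean J: %.1f\n", tr$J_mean[nrow(tr)]))
  invisible(x)
}

#' @export
coef.reach_policy <- function(object, ...) object$policy$theta

#' Activations predicted by a fitted controller
#'
#' @param object a [optimize_policy()] fit.
#' @param state a [plant_state()]; defaults to the start state of the fit.
#' @param ... unused.
#' @return length-6 activation vector.
#' @export
predict.reach_policy <- function(object, state = NULL, ...) {
  if (is.null(state)) {
    sp <- object$layout$start_points
    p <- c(sp$x[sp$id == object$start], sp$y[sp$id == object$start])
    state <- plant_state(inverse_kinematics(p, object$layout$params))
  }
  policy_forward(object$policy, state, object$layout$params)
}

#' Simulate movements from a fitted controller
#'
#' @param object a [optimize_policy()] fit.
#' @param nsim number of rollouts.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of [rollout()] trajectories.
#' @export
simulate.reach_policy <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim), function(i) {
    set.seed(derive_seed(seed, 4001L, i))
    rollout(object$policy, object$start, object$layout,
            object$cost_cfg, object$est_cfg, record = TRUE)
  })
}

#' @export
plot.reach_policy <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$iter, tr$J_best_so_far, type = "l", lwd = 2,
                 xlab = "CMA-ES iteration", ylab = "expected utility J",
                 main = "policy search progress", ...)
  graphics::lines(tr$iter, tr$J_mean, col = "grey")
  graphics::legend("bottomright", c("best so far", "population mean"),
                   col = c("black", "grey"), lwd = c(2, 1), bty = "n")
  invisible(x)
}

#' Run a campaign of policy optimizations
#'
#' Optimizes one controller per (target width, start point) pair and then
#' evaluates each optimized controller on `n_eval` fresh rollouts,
#' producing the trial table consumed by the analysis functions
#' ([fitts_fit()], [dispersion_summary()], [normalized_tables()]). The
#' study layout uses 4 widths x 15 starts with 100 evaluation rollouts per
#' start (1500 trajectories per width).
#'
#' @param widths target widths (m).
#' @param start_ids start-point ids to optimize (default: all 15).
#' @param params an [arm_params()] object.
#' @param cost_cfg,est_cfg,opt_cfg configurations.
#' @param n_eval evaluation rollouts per (width, start) pair (default 100).
#' @param n_hidden hidden-layer size.
#' @param seed master seed; each (width, start) run derives its own stream.
#' @param verbose print progress.
#' @return An object of class `reach_campaign` with `trials` (one row per
#'   evaluation rollout: width, start id, distance, outcome, mt, hit_x,
#'   effort, J, peak speed and its time, crossing speed) and `fits`
#'   (the per-pair `reach_policy` objects).
#' @export
optimize_campaign <- function(widths = c(0.005, 0.01, 0.02, 0.04),
                              start_ids = NULL,
                              params = arm_params(),
                              cost_cfg = cost_config(),
                              est_cfg = estimator_config(),
                              opt_cfg = optimizer_config(),
                              n_eval = 100, n_hidden = 10,
                              seed = 1, verbose = FALSE) {
  fits <- list(); rows <- list()
  for (wi in seq_along(widths)) {
    lay <- task_layout(target_width = widths[wi], params = params)
    ids <- if (is.null(start_ids)) lay$start_points$id else start_ids
    for (sid in ids) {
      if (verbose)
        message(sprintf("optimizing width %.3f m, start %d", widths[wi], sid))
      fit <- optimize_policy(sid, lay, cost_cfg, est_cfg, opt_cfg,
                             n_hidden = n_hidden,
                             seed = derive_seed(seed, 5001L, wi, sid))
      key <- sprintf("W%.3f_S%d", widths[wi], sid)
      fits[[key]] <- fit
      rows[[key]] <- evaluate_policy_trials(fit, n_eval = n_eval,
                                            seed = derive_seed(seed, 6001L, wi, sid))
    }
  }
  structure(list(trials = do.call(rbind, c(rows, make.row.names = FALSE)),
                 fits = fits, widths = widths, seed = seed,
                 params = params, cost_cfg = cost_cfg, est_cfg = est_cfg,
                 opt_cfg = opt_cfg, n_eval = n_eval),
            class = "reach_campaign")
}

#' Evaluate a fitted controller into trial-table rows
#'
#' @param fit a [optimize_policy()] object.
#' @param n_eval number of rollouts.
#' @param seed integer seed.
#' @return data.frame with one row per rollout.
#' @export
evaluate_policy_trials <- function(fit, n_eval = 100, seed = 1) {
  lay <- fit$layout
  sp <- lay$start_points
  dist <- sp$distance[sp$id == fit$start]
  arc <- sp$arc[sp$id == fit$start]
  out <- vector("list", n_eval)
  for (i in seq_len(n_eval)) {
    set.seed(derive_seed(seed, 8001L, i))
    tr <- rollout(fit$policy, fit$start, lay, fit$cost_cfg, fit$est_cfg,
                  record = TRUE)
    vp <- if (tr$outcome != "timeout") velocity_profile(tr) else
      list(peak_speed = NA_real_, t_peak = NA_real_, terminal_speed = NA_real_,
           asymmetry = NA_real_)
    out[[i]] <- data.frame(
      width = lay$target_width, start_id = fit$start, arc = arc,
      distance = dist, outcome = tr$outcome, mt = tr$mt,
      hit_x = tr$hit_x, effort = tr$effort,
      J = utility(tr, fit$cost_cfg),
      peak_speed = vp$peak_speed, t_peak = vp$t_peak,
      terminal_speed = vp$terminal_speed, asymmetry = vp$asymmetry)
  }
  do.call(rbind, out)
}

#' @export
print.reach_campaign <- function(x, ...) {
  cat(sprintf("Reaching campaign: %d optimized controllers, %d evaluation trials\n",
              length(x$fits), nrow(x$trials)))
  agg <- stats::aggregate(cbind(mt, hit = outcome == "hit") ~ width,
                          data = x$trials, FUN = mean)
  cat("  per target width: mean MT (s) / hit rate\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("    W = %.3f m: %.3f s / %.2f\n",
                agg$width[i], agg$mt[i], agg$hit[i]))
  invisible(x)
}
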