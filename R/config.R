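#' Assemble a full run configuration
#'
#' Bundles every configurable component of a simulation run — arm,
#' cost function, state estimator, optimizer, task — plus the master seed.
#' All defaults are the study settings (e.g. rho = 3000, upsilon = 1,
#' gamma = 0.6 s, kappa = 0.3, delay = 10 steps, k1 = 0.2, k2 = 1.0,
#' popsize = 30, repet = 50, n_hidden = 10).
#'
#' @param arm list of overrides for [arm_params()].
#' @param cost list of overrides for [cost_config()].
#' @param estimator list of overrides for [estimator_config()].
#' @param optimizer list of overrides for [optimizer_config()].
#' @param task list: `widths` (target widths, m) and `n_hidden`.
#' @param seed master seed.
#' @return An object of class `reach_config`.
#' @export
reach_config <- function(arm = list(), cost = list(), estimator = list(),
                         optimizer = list(), task = list(), seed = 1) {
  check_keys <- function(given, fn, what) {
    ok <- names(formals(fn))
    bad <- setdiff(names(given), ok)
    if (length(bad))
      stop(sprintf("unknown %s field(s): %s (allowed: %s)", what,
                   paste(bad, collapse = ", "), paste(ok, collapse = ", ")))
  }
  check_keys(arm, arm_params, "arm")
  check_keys(cost, cost_config, "cost")
  check_keys(estimator, estimator_config, "estimator")
  check_keys(optimizer, optimizer_config, "optimizer")
  bad <- setdiff(names(task), c("widths", "n_hidden"))
  if (length(bad))
    stop(sprintf("unknown task field(s): %s", paste(bad, collapse = ", ")))
  task <- utils::modifyList(list(widths = c(0.005, 0.01, 0.02, 0.04),
                                 n_hidden = 10L), task)
  if (any(task$widths <= 0)) stop("task widths must be positive")
  structure(list(arm = do.call(arm_params, arm),
                 cost = do.call(cost_config, cost),
                 estimator = do.call(estimator_config, estimator),
                 optimizer = do.call(optimizer_config, optimizer),
                 task = task,
                 seed = as.integer(seed),
                 overrides = list(arm = arm, cost = cost,
                                  estimator = estimator,
                                  optimizer = optimizer, task = task,
                                  seed = seed)),
            class = "reach_config")
}

#' Load a run configuration from YAML
#'
#' An empty file yields the full study defaults; any present key overrides
#' the default; unknown keys are rejected with the offending name.
#'
#' @param path path to a YAML file with (optional) sections `arm`, `cost`,
#'   `estimator`, `optimizer`, `task`, `seed`.
#' @return a [reach_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("arm", "cost", "estimator", "optimizer",
                               "task", "seed"))
  if (length(bad))
    stop(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")))
  # matrices arrive from YAML as nested lists; rebuild them
  if (!is.null(raw$arm$B)) raw$arm$B <- matrix(unlist(raw$arm$B), 2, 2)
  if (!is.null(raw$arm$A))
    raw$arm$A <- matrix(unlist(raw$arm$A), ncol = 2, byrow = TRUE)
  reach_config(arm = raw$arm %||% list(), cost = raw$cost %||% list(),
               estimator = raw$estimator %||% list(),
               optimizer = raw$optimizer %||% list(),
               task = raw$task %||% list(), seed = raw$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration to YAML
#'
#' Writes only the explicit overrides plus the seed, so a round trip
#' through [load_config()] reproduces the configuration exactly.
#'
#' @param config a [reach_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "reach_config"))
  ov <- config$overrides
  out <- list()
  for (s in c("arm", "cost", "estimator", "optimizer")) {
    if (length(ov[[s]])) {
      sec <- ov[[s]]
      if (!is.null(sec$B)) sec$B <- as.list(as.data.frame(sec$B))
      if (!is.null(sec$A)) sec$A <- lapply(seq_len(nrow(sec$A)),
                                           function(i) sec$A[i, ])
      out[[s]] <- sec
    }
  }
  out$task <- ov$task
  out$seed <- config$seed
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.reach_config <- function(x, ...) {
  cat("Reaching-simulation run configuration\n")
  cat(sprintf("  cost: rho = %g, upsilon = %g, gamma = %g s, w_perp = %g\n",
              x$cost$rho, x$cost$upsilon, x$cost$gamma, x$cost$w_perp))
  cat(sprintf("  noise kappa = %g; estimator: delay %d steps, k1 = %g, k2 = %g\n",
              x$arm$kappa, x$estimator$delay, x$estimator$k1, x$estimator$k2))
  cat(sprintf("  CMA-ES: sigma0 = %g, popsize %d, max_iter %d, repet %d\n",
              x$optimizer$sigma0, x$optimizer$popsize, x$optimizer$max_iter,
              x$optimizer$repet))
  cat(sprintf("  task: widths %s m, n_hidden %d, seed %d\n",
              paste(x$task$widths, collapse = "/"), x$task$n_hidden, x$seed))
  invisible(x)
}
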