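#' State-estimator configuration
#'
#' The controller never sees the true arm state directly: sensory feedback
#' arrives with a delay of `delay` time steps, and the motor command applied
#' to the plant is noisier than the efference copy available internally. The
#' estimate combines (i) an open-loop term that integrates the noise-free
#' forward model from the previous open-loop estimate, and (ii) a
#' closed-loop term that rolls the delayed true state forward through the
#' buffered efference copies. The two are averaged with weights `k1`
#' (open loop) and `k2` (closed loop).
#'
#' @param delay sensory delay in integration steps (default 10, i.e. 20 ms
#'   at dt = 2 ms).
#' @param k1 open-loop weight (default 0.2).
#' @param k2 closed-loop weight (default 1.0).
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(delay = 10, k1 = 0.2, k2 = 1.0) {
  if (delay < 0 || delay != round(delay)) stop("delay must be a non-negative integer")
  if (k1 < 0 || k2 < 0 || k1 + k2 <= 0)
    stop("weights must be non-negative with k1 + k2 > 0")
  structure(list(delay = as.integer(delay), k1 = k1, k2 = k2),
            class = "estimator_config")
}

#' Noise-free forward model
#'
#' One deterministic integration step of the arm under the commanded
#' (pre-noise) activation: the internal model the estimator iterates.
#'
#' @param state a [plant_state()].
#' @param u commanded activations, length 6.
#' @param params an [arm_params()] object.
#' @return next [plant_state()].
#' @export
forward_model <- function(state, u, params) {
  arm_step(state, u, params, noise = rep(0, 6))$state
}

#' Open-loop estimate update
#'
#' `x1[t] = FM(x1[t-1], u[t-1])`: integrates the previous open-loop estimate
#' one step with the efference copy. Having no access to the realized motor
#' noise, this term drifts from the true trajectory during fast movement.
#'
#' @param prev_estimate previous open-loop estimate, a [plant_state()].
#' @inheritParams forward_model
#' @return updated open-loop estimate.
#' @export
open_loop_update <- function(prev_estimate, u, params) {
  forward_model(prev_estimate, u, params)
}

#' Closed-loop estimate from delayed feedback
#'
#' Rolls the delayed true state forward by applying the forward model once
#' per buffered efference copy (`u[t - delay] ... u[t - 1]`). Because the
#' starting point is ground truth, only the noise of the last `delay` steps
#' can accumulate, which re-anchors the estimate whenever the arm slows.
#'
#' @param delayed_state the true state `delay` steps ago, a [plant_state()].
#' @param command_buffer list (or 6-row matrix) of the efference copies
#'   issued since `delayed_state`, oldest first.
#' @inheritParams forward_model
#' @param delay expected buffer length; the call errors if the buffer is
#'   shorter.
#' @return estimate of the current state.
#' @export
closed_loop_update <- function(delayed_state, command_buffer, params,
                               delay = length(command_buffer)) {
  if (is.matrix(command_buffer))
    command_buffer <- lapply(seq_len(ncol(command_buffer)),
                             function(j) command_buffer[, j])
  if (length(command_buffer) < delay)
    stop(sprintf("command buffer holds %d commands; %d required",
                 length(command_buffer), delay))
  est <- delayed_state
  for (u in command_buffer) est <- forward_model(est, u, params)
  est
}

#' Combine open- and closed-loop estimates
#'
#' Weighted average `(k1 * x1 + k2 * x2) / (k1 + k2)`, applied component
#' wise to positions and velocities.
#'
#' @param x1 open-loop estimate, a [plant_state()].
#' @param x2 closed-loop estimate, a [plant_state()].
#' @param config an [estimator_config()].
#' @return combined [plant_state()].
#' @export
combine_estimates <- function(x1, x2, config) {
  s <- config$k1 + config$k2
  if (s <= 0) stop("k1 + k2 must be positive")
  plant_state((config$k1 * x1$q + config$k2 * x2$q) / s,
              (config$k1 * x1$q_dot + config$k2 * x2$q_dot) / s)
}
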