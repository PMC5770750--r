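#' Feed-forward reaching controller
#'
#' One controller per starting point: a single-hidden-layer network mapping
#' the (estimated) 4-D arm state to six muscle activations. The hidden layer
#' uses tanh units; the output layer uses logistic units so activations are
#' guaranteed to lie in `[0, 1]^6` without clipping. Inputs are normalized:
#' joint angles are mapped affinely to `[-1, 1]` using the joint limits, and
#' joint velocities are divided by a fixed scale (`vel_scale`, default
#' 20 rad/s) so the units stay in their sensitive range.
#'
#' @param theta flat parameter vector: hidden weights (4 x n_hidden, column
#'   major), hidden biases (n_hidden), output weights (n_hidden x 6), output
#'   biases (6). Length `5 * n_hidden + 6 * (n_hidden + 1)`.
#' @param n_hidden number of hidden units (default 10, giving 116
#'   parameters).
#' @param vel_scale velocity normalization scale (rad/s).
#' @return An object of class `reach_policy_net`.
#' @export
policy <- function(theta, n_hidden = 10, vel_scale = 20) {
  theta <- as.numeric(theta)
  if (length(theta) != n_policy_params(n_hidden))
    stop(sprintf("theta must have length %d for n_hidden = %d",
                 n_policy_params(n_hidden), n_hidden))
  if (!all(is.finite(theta))) stop("non-finite policy parameters")
  structure(list(theta = theta, n_hidden = n_hidden, vel_scale = vel_scale),
            class = "reach_policy_net")
}

#' Number of free parameters of a controller
#'
#' `4 * n_hidden + n_hidden + n_hidden * 6 + 6`.
#'
#' @inheritParams policy
#' @return integer parameter count (116 for the default `n_hidden = 10`).
#' @export
n_policy_params <- function(n_hidden = 10) {
  4L * n_hidden + n_hidden + n_hidden * 6L + 6L
}

#' Random controller initialization
#'
#' All weights and biases drawn uniformly from `[0, 0.1]`.
#'
#' @inheritParams policy
#' @return a `reach_policy_net`.
#' @export
init_policy <- function(n_hidden = 10, vel_scale = 20) {
  policy(stats::runif(n_policy_params(n_hidden), 0, 0.1),
         n_hidden = n_hidden, vel_scale = vel_scale)
}

unpack_policy <- function(pol) {
  nh <- pol$n_hidden
  th <- pol$theta
  i <- 0L
  W1 <- matrix(th[seq_len(4 * nh)], nrow = nh, ncol = 4, byrow = FALSE)
  i <- 4L * nh
  b1 <- th[i + seq_len(nh)]; i <- i + nh
  W2 <- matrix(th[i + seq_len(nh * 6)], nrow = 6, ncol = nh, byrow = FALSE)
  i <- i + nh * 6L
  b2 <- th[i + seq_len(6)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

#' Evaluate a controller on an arm state
#'
#' Pure function: normalizes the state, applies the tanh hidden layer and
#' the logistic output layer, and returns six activations in `[0, 1]`.
#'
#' @param pol a [policy()].
#' @param state a [plant_state()] (typically the state estimate).
#' @param params an [arm_params()] object (supplies the joint limits used
#'   for input normalization).
#' @return length-6 activation vector in `[0, 1]`.
#' @export
policy_forward <- function(pol, state, params) {
  w <- unpack_policy(pol)
  qn <- 2 * (state$q - params$q_lower) /
    (params$q_upper - params$q_lower) - 1
  x <- c(qn, state$q_dot / pol$vel_scale)
  h <- tanh(drop(w$W1 %*% x) + w$b1)
  1 / (1 + exp(-(drop(w$W2 %*% h) + w$b2)))
}

#' @export
print.reach_policy_net <- function(x, ...) {
  cat(sprintf("reaching controller: 4 -> %d -> 6 network, %d parameters\n",
              x$n_hidden, length(x$theta)))
  invisible(x)
}
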