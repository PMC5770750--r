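#' Parameters of the two-joint, six-muscle planar arm
#'
#' Constructs and validates the parameter set of the rigid-body arm model:
#' segment masses, lengths, inertias and centre-of-mass offsets, the joint
#' damping matrix `B`, the constant moment-arm matrix `A` mapping the six
#' muscle tensions to shoulder and elbow torque, the maximum muscle tensions
#' `f_max`, the multiplicative motor-noise scale `kappa`, the integration
#' step `dt` and the joint limits. Defaults are the standard literature
#' values for a human arm restrained to the horizontal plane (gravity is
#' therefore absent from the dynamics).
#'
#' The six muscles are, in order: shoulder flexor, shoulder extensor, elbow
#' flexor, elbow extensor, biarticular flexor, biarticular extensor.
#'
#' @param m1,m2 segment masses (kg): upper arm, forearm.
#' @param l1,l2 segment lengths (m).
#' @param I1,I2 segment moments of inertia (kg m^2).
#' @param s1,s2 distance from each segment's proximal joint to its centre of
#'   mass (m).
#' @param B 2x2 joint damping matrix (N m s); lumps unmodelled dissipative
#'   effects.
#' @param A 6x2 moment-arm matrix (m); torque is `t(A) %*% (f_max * u)`.
#' @param f_max maximum tension of each muscle (N), length 6.
#' @param kappa multiplicative motor-noise scale (dimensionless): commanded
#'   activations are perturbed as `u * (1 + kappa * N(0, 1))`.
#' @param dt integration time step (s).
#' @param q_lower,q_upper joint-angle limits (rad), length 2: shoulder
#'   (measured from the +x axis), elbow flexion.
#'
#' @return An object of class `arm_params` (a validated list).
#' @examples
#' p <- arm_params()
#' compute_inertia(0, p)
#' @export
arm_params <- function(m1 = 1.4, m2 = 1.1,
                       l1 = 0.3, l2 = 0.35,
                       I1 = 0.025, I2 = 0.045,
                       s1 = 0.11, s2 = 0.16,
                       B = matrix(c(0.05, 0.025, 0.025, 0.05), 2, 2),
                       A = default_moment_arms(),
                       f_max = c(700, 382, 572, 445, 159, 318),
                       kappa = 0.3,
                       dt = 0.002,
                       q_lower = c(-0.6, -0.2),
                       q_upper = c(2.6, 3.0)) {
  p <- list(m1 = m1, m2 = m2, l1 = l1, l2 = l2, I1 = I1, I2 = I2,
            s1 = s1, s2 = s2, B = B, A = A, f_max = f_max,
            kappa = kappa, dt = dt,
            q_lower = q_lower, q_upper = q_upper)
  scalars <- c(m1, m2, l1, l2, I1, I2, s1, s2)
  if (!all(is.finite(scalars)) || any(scalars <= 0))
    stop("masses, lengths, inertias and centre-of-mass offsets must be strictly positive")
  if (!is.matrix(B) || !all(dim(B) == c(2, 2)) ||
      max(abs(B - t(B))) > 1e-12 || any(diag(B) < 0))
    stop("B must be a symmetric 2x2 matrix with non-negative diagonal")
  if (!is.matrix(A) || !all(dim(A) == c(6, 2)))
    stop("A must be a 6x2 moment-arm matrix")
  if (length(f_max) != 6 || any(f_max <= 0))
    stop("f_max must be 6 strictly positive maximum tensions")
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be >= 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (any(q_lower >= q_upper)) stop("joint bounds must satisfy lower < upper")
  # derived rigid-body constants
  p$k1 <- I1 + I2 + m2 * l1^2
  p$k2 <- m2 * l1 * s2
  p$k3 <- I2
  class(p) <- "arm_params"
  p
}

default_moment_arms <- function() {
  # rows: muscles (shoulder flex/ext, elbow flex/ext, biarticular flex/ext)
  matrix(c(0.040, 0.000,
           -0.040, 0.000,
           0.000, 0.025,
           0.000, -0.025,
           0.028, 0.028,
           -0.035, -0.035),
         nrow = 6, ncol = 2, byrow = TRUE)
}

#' Arm state
#'
#' Joint-space state of the plant: shoulder and elbow angle `q` (rad) and
#' joint velocities `q_dot` (rad/s).
#'
#' @param q joint angles (rad), length 2.
#' @param q_dot joint velocities (rad/s), length 2.
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(q = c(pi / 2, 0), q_dot = c(0, 0)) {
  stopifnot(length(q) == 2, length(q_dot) == 2)
  if (!all(is.finite(c(q, q_dot)))) stop("non-finite plant state")
  structure(list(q = as.numeric(q), q_dot = as.numeric(q_dot)),
            class = "plant_state")
}

#' Configuration-dependent inertia matrix
#'
#' `M(q) = [[k1 + 2 k2 cos(q2), k3 + k2 cos(q2)], [k3 + k2 cos(q2), k3]]`
#' with `k1 = I1 + I2 + m2 l1^2`, `k2 = m2 l1 s2`, `k3 = I2`. Only the elbow
#' angle enters.
#'
#' @param q2 elbow angle (rad).
#' @param params an [arm_params()] object.
#' @return symmetric positive-definite 2x2 matrix (kg m^2).
#' @export
compute_inertia <- function(q2, params) {
  c2 <- cos(q2)
  off <- params$k3 + params$k2 * c2
  matrix(c(params$k1 + 2 * params$k2 * c2, off, off, params$k3), 2, 2)
}

#' Coriolis / centripetal force vector
#'
#' `C(q, q_dot) = k2 sin(q2) * c(-q2d * (2 q1d + q2d), q1d^2)`.
#'
#' @param q joint angles (rad).
#' @param q_dot joint velocities (rad/s).
#' @inheritParams compute_inertia
#' @return length-2 torque vector (N m).
#' @export
coriolis_vector <- function(q, q_dot, params) {
  params$k2 * sin(q[2]) *
    c(-q_dot[2] * (2 * q_dot[1] + q_dot[2]), q_dot[1]^2)
}

#' Muscle activations to joint torque, with signal-dependent noise
#'
#' The commanded activation `u` in `[0,1]^6` is corrupted multiplicatively,
#' `u_noisy = clamp(u * (1 + kappa * z), 0, 1)` where `z` is a standard
#' normal draw per muscle, then converted to torque via the moment arms:
#' `tau = t(A) %*% (f_max * u_noisy)`. Noise scales with the signal, so a
#' silent muscle is noiseless.
#'
#' @param u commanded activations in `[0,1]`, length 6.
#' @param params an [arm_params()] object.
#' @param noise optional length-6 standard-normal draw; `NULL` draws from
#'   the session RNG. Pass `rep(0, 6)` (or set `kappa = 0`) for the
#'   deterministic map.
#' @return list with `torque` (length 2, N m) and `u_noisy` (length 6).
#' @export
muscle_torque <- function(u, params, noise = NULL) {
  if (length(u) != 6 || any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("u must be 6 activations in [0, 1]")
  if (params$kappa > 0) {
    if (is.null(noise)) noise <- stats::rnorm(6)
    u_noisy <- pmin(pmax(u * (1 + params$kappa * noise), 0), 1)
  } else {
    u_noisy <- u
  }
  list(torque = drop(crossprod(params$A, params$f_max * u_noisy)),
       u_noisy = u_noisy)
}

#' One integration step of the arm dynamics
#'
#' Advances the plant by `dt` under activation `u` using semi-implicit Euler
#' integration of `q_ddot = M(q)^{-1} (tau - C(q, q_dot) - B q_dot)`
#' (velocity first, then position with the updated velocity). Gravity is
#' absent: the arm moves in the horizontal plane. Joint limits are enforced
#' by clamping the violating coordinate and zeroing its velocity.
#'
#' @param state a [plant_state()].
#' @inheritParams muscle_torque
#' @return list with `state` (the next [plant_state()]) and `u_noisy`.
#' @export
arm_step <- function(state, u, params, noise = NULL) {
  q <- state$q; qd <- state$q_dot
  if (!all(is.finite(c(q, qd)))) stop("non-finite plant state")
  mt <- muscle_torque(u, params, noise)
  M <- compute_inertia(q[2], params)
  rhs <- mt$torque - coriolis_vector(q, qd, params) - drop(params$B %*% qd)
  qdd <- solve(M, rhs)
  qd <- qd + qdd * params$dt
  q <- q + qd * params$dt
  for (j in 1:2) {
    if (q[j] < params$q_lower[j]) { q[j] <- params$q_lower[j]; qd[j] <- 0 }
    if (q[j] > params$q_upper[j]) { q[j] <- params$q_upper[j]; qd[j] <- 0 }
  }
  list(state = plant_state(q, qd), u_noisy = mt$u_noisy)
}

#' Forward kinematics of the end effector
#'
#' The shoulder sits at the origin; `q1` is measured from the +x axis and
#' `q2` is relative elbow flexion, so the fully extended arm at
#' `q = (pi/2, 0)` points straight up the y axis.
#'
#' @param q joint angles (rad), length 2.
#' @inheritParams compute_inertia
#' @return list with `position` (x, y in m) and `jacobian` (2x2), which maps
#'   joint velocity to Cartesian end-effector velocity.
#' @export
forward_kinematics <- function(q, params) {
  a1 <- q[1]; a12 <- q[1] + q[2]
  x <- params$l1 * cos(a1) + params$l2 * cos(a12)
  y <- params$l1 * sin(a1) + params$l2 * sin(a12)
  J <- matrix(c(-params$l1 * sin(a1) - params$l2 * sin(a12),
                params$l1 * cos(a1) + params$l2 * cos(a12),
                -params$l2 * sin(a12),
                params$l2 * cos(a12)), 2, 2)
  list(position = c(x, y), jacobian = J)
}

#' Inverse kinematics (elbow-positive branch)
#'
#' Returns the joint configuration reaching Cartesian point `p` with
#' non-negative elbow flexion. Errors for unreachable points.
#'
#' @param p target point (x, y) in m.
#' @inheritParams compute_inertia
#' @return length-2 joint-angle vector (rad).
#' @export
inverse_kinematics <- function(p, params) {
  r2 <- sum(p^2); r <- sqrt(r2)
  l1 <- params$l1; l2 <- params$l2
  if (r > l1 + l2 + 1e-12 || r < abs(l1 - l2) - 1e-12)
    stop(sprintf("point at radius %.4f m unreachable (arm annulus [%.4f, %.4f] m)",
                 r, abs(l1 - l2), l1 + l2))
  cq2 <- (r2 - l1^2 - l2^2) / (2 * l1 * l2)
  q2 <- acos(pmin(pmax(cq2, -1), 1))            # elbow-positive branch
  q1 <- atan2(p[2], p[1]) - atan2(l2 * sin(q2), l1 + l2 * cos(q2))
  c(q1, q2)
}

#' @export
print.arm_params <- function(x, ...) {
  cat("Planar 2-joint / 6-muscle arm parameters\n")
  cat(sprintf("  segments: m = (%.2f, %.2f) kg, l = (%.2f, %.2f) m, I = (%.3f, %.3f) kg m^2\n",
              x$m1, x$m2, x$l1, x$l2, x$I1, x$I2))
  cat(sprintf("  noise kappa = %.2f, dt = %.3g s, reach = %.3f m\n",
              x$kappa, x$dt, x$l1 + x$l2))
  invisible(x)
}
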