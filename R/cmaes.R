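#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Minimal, dependency-free implementation of the standard
#' `(mu/mu_w, lambda)` CMA-ES with rank-one and rank-mu covariance updates
#' and cumulative step-size adaptation, following Hansen's reference
#' formulation. Written for noisy objectives: each candidate is evaluated
#' once per iteration and the returned optimum is the best candidate ever
#' evaluated, which makes the best-so-far trace non-increasing by
#' construction.
#'
#' Sampling is reseeded deterministically at every iteration from
#' `seed` via [derive_seed()], so the search path is reproducible even when
#' the objective function itself consumes and reseeds the session RNG.
#'
#' @param fn objective to minimize; called as `fn(x, iter, idx)` where
#'   `iter` is the iteration and `idx` the candidate index within the
#'   population, so the caller can derive per-candidate random streams.
#' @param x0 initial mean vector.
#' @param sigma0 initial global step size (the square root of the initial
#'   covariance factor).
#' @param popsize population size `lambda` (>= 2).
#' @param max_iter number of iterations.
#' @param seed master seed for the sampling streams.
#' @param callback optional function called after each iteration with the
#'   trace row (a list); return value ignored.
#' @return list with `x_best`, `f_best`, `x_mean` (final distribution
#'   mean), and `trace` (data.frame with `iter`, `f_best_iter`, `f_mean`,
#'   `f_best_so_far`, `sigma`).
#' @export
cma_es <- function(fn, x0, sigma0 = 0.1, popsize = 30, max_iter = 100,
                   seed = 1, callback = NULL) {
  n <- length(x0)
  if (popsize < 2) stop("popsize must be >= 2")
  if (max_iter < 1) stop("max_iter must be >= 1")
  lambda <- as.integer(popsize)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)

  c_sigma <- (mu_eff + 2) / (n + mu_eff + 5)
  d_sigma <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + c_sigma
  c_c <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  c_1 <- 2 / ((n + 1.3)^2 + mu_eff)
  c_mu <- min(1 - c_1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  chi_n <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- as.numeric(x0)
  sigma <- sigma0
  C <- diag(n)
  p_sigma <- numeric(n)
  p_c <- numeric(n)
  B <- diag(n); D <- rep(1, n)

  f_best <- Inf; x_best <- m
  trace <- vector("list", max_iter)

  for (it in seq_len(max_iter)) {
    ed <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(ed$values, .Machine$double.eps))
    B <- ed$vectors

    set.seed(derive_seed(seed, 1003L, it))
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                 # C^{1/2} z
    X <- m + sigma * Y

    f <- numeric(lambda)
    for (k in seq_len(lambda)) f[k] <- fn(X[, k], it, k)
    if (all(!is.finite(f)))
      stop(sprintf("all %d candidates non-finite at iteration %d", lambda, it))
    ord <- order(f)

    if (f[ord[1]] < f_best) {
      f_best <- f[ord[1]]
      x_best <- X[, ord[1]]
    }

    sel <- ord[seq_len(mu)]
    y_w <- drop(Y[, sel, drop = FALSE] %*% w)
    m <- m + sigma * y_w

    # C^{-1/2} (m_new - m_old) / sigma = B z_w
    z_w <- drop(Z[, sel, drop = FALSE] %*% w)
    p_sigma <- (1 - c_sigma) * p_sigma +
      sqrt(c_sigma * (2 - c_sigma) * mu_eff) * drop(B %*% z_w)
    h_sigma <- as.numeric(
      sqrt(sum(p_sigma^2)) / sqrt(1 - (1 - c_sigma)^(2 * it)) / chi_n <
        1.4 + 2 / (n + 1))
    p_c <- (1 - c_c) * p_c +
      h_sigma * sqrt(c_c * (2 - c_c) * mu_eff) * y_w

    rank_mu <- matrix(0, n, n)
    for (j in seq_len(mu))
      rank_mu <- rank_mu + w[j] * tcrossprod(Y[, sel[j]])
    C <- (1 - c_1 - c_mu) * C +
      c_1 * (tcrossprod(p_c) + (1 - h_sigma) * c_c * (2 - c_c) * C) +
      c_mu * rank_mu
    C <- (C + t(C)) / 2
    sigma <- sigma * exp((c_sigma / d_sigma) *
                           (sqrt(sum(p_sigma^2)) / chi_n - 1))

    row <- list(iter = it, f_best_iter = f[ord[1]],
                f_mean = mean(f[is.finite(f)]),
                f_best_so_far = f_best, sigma = sigma)
    trace[[it]] <- row
    if (!is.null(callback)) callback(row)
  }

  list(x_best = x_best, f_best = f_best, x_mean = m,
       trace = do.call(rbind.data.frame, trace))
}
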