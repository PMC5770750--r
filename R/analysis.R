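#' Fitts' law regression
#'
#' Regresses mean movement time on the index of difficulty
#' `ID = log2(D / W)` by ordinary least squares, one point per
#' (distance, width) cell. With three start-arc distances and four target
#' widths the design has 12 points. By default all completed movements
#' (hits and misses both cross the wall) contribute to the cell means;
#' set `hits_only = TRUE` to restrict to hits.
#'
#' @param trials trial table as produced by [optimize_campaign()] (columns
#'   `distance`, `width`, `mt`, `outcome`), or any data.frame with those
#'   columns.
#' @param hits_only restrict to trials with outcome `"hit"`.
#' @return An object of class `fitts_fit`: `points` (data.frame with
#'   `distance`, `width`, `id`, `mean_mt`, `n`), `a` (slope, s/bit), `b`
#'   (intercept, s), `r_squared`, and the underlying `lm` fit. Supports
#'   `print`, `summary`, `coef`, `predict` and `plot`.
#' @examples
#' trials <- expand.grid(distance = c(0.1, 0.24, 0.39),
#'                       width = c(0.005, 0.01, 0.02, 0.04))
#' trials$mt <- 0.1 * log2(trials$distance / trials$width) + 0.05
#' trials$outcome <- "hit"
#' fitts_fit(trials)
#' @export
fitts_fit <- function(trials, hits_only = FALSE) {
  stopifnot(all(c("distance", "width", "mt") %in% names(trials)))
  if ("outcome" %in% names(trials)) {
    keep <- if (hits_only) trials$outcome == "hit" else trials$outcome != "timeout"
    trials <- trials[keep, , drop = FALSE]
  }
  if (nrow(trials) == 0) stop("no completed movements to fit")
  pts <- stats::aggregate(mt ~ distance + width, data = trials, FUN = mean)
  pts$n <- stats::aggregate(mt ~ distance + width, data = trials,
                            FUN = length)$mt
  names(pts)[names(pts) == "mt"] <- "mean_mt"
  pts$id <- log2(pts$distance / pts$width)
  if (length(unique(round(pts$id, 12))) < 2)
    stop("degenerate design: at least two distinct index-of-difficulty values required")
  fit <- stats::lm(mean_mt ~ id, data = pts)
  structure(list(points = pts[, c("distance", "width", "id", "mean_mt", "n")],
                 a = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 lm = fit),
            class = "fitts_fit")
}

#' @export
print.fitts_fit <- function(x, ...) {
  cat(sprintf("Fitts' law fit over %d (distance, width) cells:\n",
              nrow(x$points)))
  cat(sprintf("  MT = %.4f * ID + %.4f  (s; ID in bits), r^2 = %.3f\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' @export
summary.fitts_fit <- function(object, ...) summary(object$lm, ...)

#' @export
coef.fitts_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.fitts_fit <- function(object, id = NULL, ...) {
  if (is.null(id)) id <- object$points$id
  object$a * id + object$b
}

#' @export
plot.fitts_fit <- function(x, ...) {
  graphics::plot(x$points$id, x$points$mean_mt, pch = 19,
                 xlab = "index of difficulty (bits)",
                 ylab = "mean movement time (s)",
                 main = sprintf("Fitts' law (r^2 = %.2f)", x$r_squared), ...)
  graphics::abline(x$b, x$a)
  invisible(x)
}

#' Hit-dispersion histogram and Gaussian fit
#'
#' Bins the wall-crossing x coordinates into fixed 0.5 mm bins centred on
#' the target centre and fits a Gaussian to the bin counts by least
#' squares (the histogram-fit reading of a dispersion diagram);
#' `method = "ml"` instead fits by maximum likelihood on the raw crossing
#' points. Also reports the hit rate and the offset of the fitted peak from
#' the target centre as a percentage of target width.
#'
#' @param hits numeric vector of wall-crossing x coordinates (m).
#' @param width target width (m).
#' @param center target centre (m), default 0.
#' @param bin_width histogram bin width (m), default 0.5 mm.
#' @param method `"histogram"` (least squares on bin counts) or `"ml"`.
#' @return An object of class `dispersion_summary`: `breaks`, `counts`,
#'   `gauss_mu`, `gauss_sigma` (m), `hit_rate`, `peak_offset_pct`.
#' @export
dispersion_summary <- function(hits, width, center = 0,
                               bin_width = 5e-4,
                               method = c("histogram", "ml")) {
  method <- match.arg(method)
  hits <- hits[is.finite(hits)]
  if (length(hits) == 0) stop("no wall crossings to summarize")
  # bin edges aligned so that one bin is centred on the target centre
  lo <- floor((min(hits) - center) / bin_width - 0.5)
  hi <- ceiling((max(hits) - center) / bin_width + 0.5)
  breaks <- center + (seq(lo, hi) - 0.5) * bin_width
  counts <- as.numeric(table(cut(hits, breaks, include.lowest = TRUE)))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2

  mu0 <- mean(hits); sd0 <- stats::sd(hits)
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- bin_width / 2
  if (method == "ml" || length(hits) < 10) {
    mu <- mu0; sigma <- sd0
  } else {
    fit <- tryCatch(
      stats::nls(counts ~ amp * exp(-(mids - mu)^2 / (2 * sigma^2)),
                 start = list(amp = max(counts), mu = mu0, sigma = sd0),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      mu <- mu0; sigma <- sd0
    } else {
      cf <- stats::coef(fit)
      mu <- unname(cf["mu"]); sigma <- abs(unname(cf["sigma"]))
    }
  }
  structure(list(breaks = breaks, counts = counts, mids = mids,
                 gauss_mu = mu, gauss_sigma = sigma,
                 hit_rate = mean(abs(hits - center) <= width / 2),
                 peak_offset_pct = 100 * (mu - center) / width,
                 n = length(hits), width = width, center = center),
            class = "dispersion_summary")
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat(sprintf("hit dispersion over %d crossings (target width %.3f m):\n",
              x$n, x$width))
  cat(sprintf("  Gaussian fit: mu = %+.2f mm, sigma = %.2f mm; peak offset %+.2f%% of width\n",
              1000 * x$gauss_mu, 1000 * x$gauss_sigma, x$peak_offset_pct))
  cat(sprintf("  hit rate %.2f\n", x$hit_rate))
  invisible(x)
}

#' @export
plot.dispersion_summary <- function(x, ...) {
  graphics::plot(1000 * x$mids, x$counts, type = "h", lwd = 3,
                 xlab = "crossing x (mm)", ylab = "count",
                 main = "hit dispersion", ...)
  xs <- seq(min(x$breaks), max(x$breaks), length.out = 200)
  amp <- max(x$counts)
  graphics::lines(1000 * xs,
                  amp * exp(-(xs - x$gauss_mu)^2 / (2 * x$gauss_sigma^2)),
                  col = "steelblue", lwd = 2)
  graphics::abline(v = 1000 * (x$center + c(-1, 1) * x$width / 2), col = "red")
  invisible(x)
}

#' Kullback-Leibler divergence between two Gaussians
#'
#' Closed form
#' `KL(p || q) = log(sq/sp) + (sp^2 + (mp - mq)^2) / (2 sq^2) - 1/2`,
#' used to compare fitted hit-dispersion Gaussians (direction: model as
#' `p`, reference as `q`).
#'
#' @param p_mu,p_sigma mean and sd of `p`.
#' @param q_mu,q_sigma mean and sd of `q`.
#' @return scalar divergence (nats), non-negative.
#' @export
kl_divergence <- function(p_mu, p_sigma, q_mu, q_sigma) {
  if (p_sigma <= 0 || q_sigma <= 0) stop("sigmas must be positive")
  log(q_sigma / p_sigma) +
    (p_sigma^2 + (p_mu - q_mu)^2) / (2 * q_sigma^2) - 0.5
}

#' End-effector velocity profile of one movement
#'
#' Computes the Cartesian end-effector speed at every recorded step (via
#' the kinematic Jacobian), the peak speed and its time, the speed at wall
#' crossing and the profile asymmetry `t_peak / MT` (< 0.5 means the peak
#' lies in the first half of the movement). A flat profile (constant
#' speed) reports asymmetry 0.5 by convention.
#'
#' @param traj a recorded [rollout()] trajectory that crossed the wall.
#' @return An object of class `velocity_profile`: `speed` (m/s per step),
#'   `peak_speed`, `t_peak`, `terminal_speed`, `asymmetry`.
#' @export
velocity_profile <- function(traj) {
  if (is.null(traj$table)) stop("trajectory was not recorded")
  if (traj$outcome == "timeout") stop("velocity profile undefined for a timed-out movement")
  tab <- traj$table
  # speeds from the recorded joint state via the Jacobian
  sp <- jacobian_speed(tab$q1, tab$q2, tab$qd1, tab$qd2, traj$l1, traj$l2)
  structure(sp_summary(sp, tab$t, traj), class = "velocity_profile")
}

jacobian_speed <- function(q1, q2, qd1, qd2, l1, l2) {
  vx <- (-l1 * sin(q1) - l2 * sin(q1 + q2)) * qd1 + (-l2 * sin(q1 + q2)) * qd2
  vy <- (l1 * cos(q1) + l2 * cos(q1 + q2)) * qd1 + (l2 * cos(q1 + q2)) * qd2
  sqrt(vx^2 + vy^2)
}

sp_summary <- function(speed, t, traj) {
  pk <- which.max(speed)
  flat <- diff(range(speed)) < 1e-12
  asym <- if (flat) 0.5 else t[pk] / traj$mt
  list(speed = speed, t = t,
       peak_speed = max(speed), t_peak = t[pk],
       terminal_speed = sqrt(sum(traj$v_cross^2)),
       asymmetry = asym)
}

#' Normalized peak-velocity and movement-time tables
#'
#' Builds the two 3 (distances) x 4 (widths) summary tables: cell means of
#' peak end-effector speed and of movement time, each normalized by the
#' (shortest distance, smallest width) reference cell, which is 1.00 by
#' construction.
#'
#' @param trials trial table (columns `distance`, `width`, `mt`,
#'   `peak_speed`, `outcome`).
#' @return list with matrices `peak_speed` and `mt` (rows: distances
#'   ascending; columns: widths ascending), plus the raw cell means.
#' @export
normalized_tables <- function(trials) {
  trials <- trials[trials$outcome != "timeout", , drop = FALSE]
  ds <- sort(unique(trials$distance)); ws <- sort(unique(trials$width))
  cell <- function(stat) {
    m <- matrix(NA_real_, length(ds), length(ws),
                dimnames = list(sprintf("D=%.4f", ds), sprintf("W=%.3f", ws)))
    for (i in seq_along(ds)) for (j in seq_along(ws)) {
      v <- trials[[stat]][trials$distance == ds[i] & trials$width == ws[j]]
      v <- v[is.finite(v)]
      if (length(v) == 0)
        stop(sprintf("empty cell: distance %.4f, width %.3f (%s)",
                     ds[i], ws[j], stat))
      m[i, j] <- mean(v)
    }
    m
  }
  pk <- cell("peak_speed"); mt <- cell("mt")
  list(peak_speed = pk / pk[1, 1], mt = mt / mt[1, 1],
       peak_speed_raw = pk, mt_raw = mt)
}

#' Full behavioural analysis of a campaign
#'
#' Convenience wrapper producing the Fitts regression, per-width dispersion
#' summaries and the normalized tables from a campaign's trial table.
#'
#' @param campaign a [optimize_campaign()] result, or its `trials` table.
#' @return list with `fitts` ([fitts_fit()]), `dispersion` (list per
#'   width), `tables` ([normalized_tables()]).
#' @export
analyze_campaign <- function(campaign) {
  trials <- if (inherits(campaign, "reach_campaign")) campaign$trials else campaign
  disp <- lapply(sort(unique(trials$width)), function(w) {
    sub <- trials[trials$width == w & trials$outcome != "timeout", ]
    dispersion_summary(sub$hit_x, width = w)
  })
  names(disp) <- sprintf("W=%.3f", sort(unique(trials$width)))
  list(fitts = fitts_fit(trials), dispersion = disp,
       tables = normalized_tables(trials))
}
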