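#' Reproduction driver
#'
#' Runs the simulation-plus-analysis pipeline end to end and reports the
#' qualitative signatures of the two trade-offs. `scale = "smoke"` runs a
#' reduced campaign (two target widths, the middle start point of each of
#' the three arcs, CMA-ES at popsize 8, 50 iterations, 6 rollouts per
#' candidate) and checks directional properties; `scale = "full"` runs the
#' complete study budget (4 widths x 15 starts, popsize 30, 5000
#' iterations, 50 rollouts) and computes the quantitative readouts — at
#' full budget this is a long multi-hour computation intended for batch
#' use.
#'
#' @param scale `"smoke"` or `"full"`.
#' @param seed master seed.
#' @param verbose print progress.
#' @return list with `campaign` (the [optimize_campaign()] result),
#'   `analysis` ([analyze_campaign()] output) and `checks` (data.frame of
#'   named qualitative properties with observed values and pass flags).
#' @export
reproduce <- function(scale = c("smoke", "full"), seed = 1, verbose = FALSE) {
  scale <- match.arg(scale)
  if (scale == "smoke") {
    widths <- c(0.005, 0.04)
    starts <- smoke_start_ids()
    opt <- optimizer_config(popsize = 8, max_iter = 50, repet = 6)
    n_eval <- 50
  } else {
    widths <- c(0.005, 0.01, 0.02, 0.04)
    starts <- NULL
    opt <- optimizer_config()
    n_eval <- 100
  }
  camp <- optimize_campaign(widths = widths, start_ids = starts,
                            opt_cfg = opt, n_eval = n_eval,
                            seed = seed, verbose = verbose)
  an <- analyze_campaign(camp)
  list(campaign = camp, analysis = an,
       checks = campaign_checks(camp, an))
}

# middle start point of each arc (ids follow task_layout row order)
smoke_start_ids <- function() c(2L, 6L, 12L)

#' Qualitative trade-off checks on a campaign
#'
#' Evaluates the directional signatures expected of the model on any
#' campaign's trial table: policy search improves on the random initial
#' controller; small targets take longer than large ones; dispersion grows
#' with target width; peak speed grows with distance; velocity profiles
#' peak in the first half of the movement.
#'
#' @param campaign a [optimize_campaign()] result.
#' @param analysis optional [analyze_campaign()] output (recomputed if
#'   missing).
#' @return data.frame with columns `check`, `value`, `pass`.
#' @export
campaign_checks <- function(campaign, analysis = NULL) {
  if (is.null(analysis)) analysis <- analyze_campaign(campaign)
  tr <- campaign$trials
  done <- tr[tr$outcome != "timeout", ]
  ws <- sort(unique(tr$width))
  w_small <- ws[1]; w_large <- ws[length(ws)]

  improved <- vapply(campaign$fits, function(f)
    f$eval$mean_utility > f$eval_initial$mean_utility, logical(1))

  mt_small <- mean(done$mt[done$width == w_small])
  mt_large <- mean(done$mt[done$width == w_large])

  sig <- vapply(analysis$dispersion, function(d) d$gauss_sigma, numeric(1))
  sig_small <- sig[[sprintf("W=%.3f", w_small)]]
  sig_large <- sig[[sprintf("W=%.3f", w_large)]]

  d_near <- min(done$distance); d_far <- max(done$distance)
  pk_near <- mean(done$peak_speed[done$distance == d_near], na.rm = TRUE)
  pk_far <- mean(done$peak_speed[done$distance == d_far], na.rm = TRUE)

  asym_frac <- mean(done$asymmetry < 0.5, na.rm = TRUE)

  data.frame(
    check = c("optimizer improves on initial policy (fraction of runs)",
              sprintf("mean MT larger for W = %.3f than W = %.3f", w_small, w_large),
              "dispersion sigma larger for the large target",
              "peak speed larger for the far arc than the near arc",
              "velocity peak in first half of movement (fraction of trials)"),
    value = c(mean(improved), mt_small - mt_large, sig_large - sig_small,
              pk_far - pk_near, asym_frac),
    pass = c(mean(improved) >= 0.9, mt_small > mt_large,
             sig_large > sig_small, pk_far > pk_near, asym_frac > 0.5),
    stringsAsFactors = FALSE)
}
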