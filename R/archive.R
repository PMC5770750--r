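#' Write a campaign archive
#'
#' Serializes a campaign to a directory of plain-text files: `trials.csv`
#' (the evaluation trial table), `policies.csv` (one row per optimized
#' controller: width, start id, seed, hidden size, then the flat parameter
#' vector) and `config.yaml` (arm / cost / estimator / optimizer overrides
#' and the master seed). Everything needed to re-evaluate any stored
#' controller bit-reproducibly is contained in the archive.
#'
#' @param campaign a [optimize_campaign()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "reach_campaign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(campaign$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  pol <- do.call(rbind, lapply(campaign$fits, function(f) {
    data.frame(width = f$layout$target_width, start_id = f$start,
               seed = f$seed, n_hidden = f$n_hidden,
               eval_J = f$eval$mean_utility,
               eval_hit_rate = f$eval$hit_rate,
               eval_mean_mt = f$eval$mean_mt,
               t(f$policy$theta))
  }))
  utils::write.csv(pol, file.path(dir, "policies.csv"), row.names = FALSE)
  cfg <- reach_config(optimizer = unclass_overrides(campaign$opt_cfg,
                                                    optimizer_config),
                      seed = campaign$seed)
  save_config(cfg, file.path(dir, "config.yaml"))
  writeLines(sprintf("reachsim %s",
                     as.character(utils::packageVersion("reachsim"))),
             file.path(dir, "VERSION"))
  invisible(dir)
}

unclass_overrides <- function(obj, fn) {
  defaults <- do.call(fn, list())
  keep <- names(unclass(defaults))
  ov <- unclass(obj)[keep]
  ov[!vapply(seq_along(ov), function(i) identical(ov[[i]], defaults[[i]]),
             logical(1))]
}

#' Read a campaign archive
#'
#' Restores the trial table and the stored controllers from a
#' [write_campaign()] directory. Each controller is rebuilt as a
#' `reach_policy`-like record sufficient for re-evaluation with
#' [evaluate_policy_trials()] or [rollout()].
#'
#' @param dir archive directory.
#' @return list with `trials`, `policies` (list with `policy`, `width`,
#'   `start_id`, `seed`, recorded evaluation statistics) and `config`.
#' @export
read_campaign <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  pol <- utils::read.csv(file.path(dir, "policies.csv"))
  cfg <- load_config(file.path(dir, "config.yaml"))
  theta_cols <- grep("^X", names(pol))
  policies <- lapply(seq_len(nrow(pol)), function(i) {
    list(policy = policy(as.numeric(pol[i, theta_cols]),
                         n_hidden = pol$n_hidden[i]),
         width = pol$width[i], start_id = pol$start_id[i],
         seed = pol$seed[i], eval_J = pol$eval_J[i],
         eval_hit_rate = pol$eval_hit_rate[i],
         eval_mean_mt = pol$eval_mean_mt[i])
  })
  list(trials = trials, policies = policies, config = cfg)
}
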