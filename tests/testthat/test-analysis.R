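test_that("Fitts regression recovers an exact linear law", {
  trials <- expand.grid(distance = c(0.0975, 0.24375, 0.39),
                        width = c(0.005, 0.01, 0.02, 0.04))
  trials$mt <- 0.1 * log2(trials$distance / trials$width) + 0.05
  trials$outcome <- "hit"
  fit <- suppressWarnings(fitts_fit(trials))  # lm warns on an exact fit
  expect_equal(fit$a, 0.1, tolerance = 1e-12)
  expect_equal(fit$b, 0.05, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(nrow(fit$points), 12L)
  # index of difficulty of the hardest cell
  expect_equal(max(fit$points$id), log2(0.39 / 0.005), tolerance = 1e-12)
  expect_equal(max(fit$points$id), 6.285, tolerance = 1e-3)
})

test_that("Fitts OLS matches the normal-equations oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    pts <- data.frame(distance = runif(n, 0.05, 0.5),
                      width = runif(n, 0.004, 0.05))
    pts$mt <- runif(n, 0.1, 1.5)
    pts$outcome <- "hit"
    fit <- fitts_fit(pts)
    id <- log2(pts$distance / pts$width)
    X <- cbind(1, id)
    beta <- solve(t(X) %*% X, t(X) %*% pts$mt)
    expect_equal(unname(c(fit$b, fit$a)), unname(drop(beta)),
                 tolerance = 1e-10)
  }
})

test_that("a single index of difficulty is a degenerate Fitts design", {
  trials <- data.frame(distance = 0.2, width = 0.02,
                       mt = runif(5), outcome = "hit")
  expect_error(fitts_fit(trials), "degenerate")
})

test_that("dispersion summary recovers known Gaussian parameters", {
  set.seed(17)
  hits <- rnorm(10000, mean = 0.001, sd = 0.003)
  ds <- dispersion_summary(hits, width = 0.01)
  expect_lt(abs(ds$gauss_mu - 0.001) / 0.001, 0.05)
  expect_lt(abs(ds$gauss_sigma - 0.003) / 0.003, 0.05)
  expect_equal(sum(ds$counts), length(hits))
  expect_equal(ds$peak_offset_pct, 100 * ds$gauss_mu / 0.01)
  # perfectly centred hits
  exact <- dispersion_summary(rep(0, 50), width = 0.01)
  expect_equal(exact$gauss_mu, 0)
  expect_equal(exact$peak_offset_pct, 0)
  expect_equal(exact$hit_rate, 1)
  expect_error(dispersion_summary(numeric(0), width = 0.01), "no wall crossings")
})

test_that("dispersion recovery holds across seeds and the ML option agrees", {
  mus <- sig <- numeric(20)
  for (i in 1:20) {
    set.seed(400 + i)
    hits <- rnorm(4000, 0.002, 0.004)
    ds <- dispersion_summary(hits, width = 0.02)
    mus[i] <- ds$gauss_mu; sig[i] <- ds$gauss_sigma
    ml <- dispersion_summary(hits, width = 0.02, method = "ml")
    expect_equal(ml$gauss_mu, mean(hits))
  }
  expect_lt(max(abs(mus - 0.002)), 0.05 * 0.004 + 3 * 0.004 / sqrt(4000))
  expect_lt(max(abs(sig - 0.004) / 0.004), 0.08)
})

test_that("Gaussian KL divergence closed form is exact", {
  expect_equal(kl_divergence(0, 1, 0, 1), 0)
  expect_equal(kl_divergence(0, 1, 1, 1), 0.5)
  expect_false(isTRUE(all.equal(kl_divergence(0, 1, 0, 2),
                                kl_divergence(0, 2, 0, 1))))
  set.seed(23)
  for (i in 1:10) {
    mp <- rnorm(1); sp <- runif(1, 0.3, 2)
    mq <- rnorm(1); sq <- runif(1, 0.3, 2)
    kl <- kl_divergence(mp, sp, mq, sq)
    expect_gte(kl, 0)
    num <- integrate(function(x) {
      p <- dnorm(x, mp, sp)
      ifelse(p > 0, p * (dnorm(x, mp, sp, log = TRUE) -
                           dnorm(x, mq, sq, log = TRUE)), 0)
    }, mp - 12 * sp, mp + 12 * sp, rel.tol = 1e-10)$value
    expect_equal(kl, num, tolerance = 1e-6)
  }
  expect_error(kl_divergence(0, 0, 0, 1), "positive")
})

test_that("velocity profile summarizes speed, peak time and asymmetry", {
  p <- arm_params(kappa = 0)
  lay <- task_layout(0.04, params = p)
  pol <- constant_policy()
  tr <- rollout(pol, 2, lay)
  expect_equal(tr$outcome %in% c("hit", "miss"), TRUE)
  vp <- velocity_profile(tr)
  expect_equal(length(vp$speed), nrow(tr$table))
  expect_equal(vp$peak_speed, max(vp$speed))
  expect_gt(vp$asymmetry, 0)
  expect_lte(vp$asymmetry, 1.001)
  # constant-velocity synthetic movement: flat profile reports 0.5
  fake <- structure(list(
    outcome = "hit", mt = 1, v_cross = c(0, 0.2), l1 = p$l1, l2 = p$l2,
    table = data.frame(t = seq(0, 0.998, by = 0.002),
                       q1 = seq(0, 0.998, by = 0.002), q2 = 1,
                       qd1 = 1, qd2 = 0)), class = "reach_trajectory")
  vpf <- velocity_profile(fake)
  expect_equal(vpf$asymmetry, 0.5)
  expect_error(velocity_profile(structure(list(outcome = "timeout",
                                               table = data.frame()),
                                          class = "reach_trajectory")),
               "timed-out")
})

test_that("normalized tables anchor at the reference cell and flag gaps", {
  grid <- expand.grid(distance = c(0.1, 0.24, 0.39),
                      width = c(0.005, 0.01, 0.02, 0.04))
  trials <- grid[rep(seq_len(nrow(grid)), each = 5), ]
  # construct means with known structure: speed grows with distance,
  # MT falls with width
  trials$peak_speed <- 2 * trials$distance + 0.1
  trials$mt <- 0.3 - 2 * trials$width
  trials$outcome <- "hit"
  tabs <- normalized_tables(trials)
  expect_equal(tabs$peak_speed[1, 1], 1)
  expect_equal(tabs$mt[1, 1], 1)
  expect_true(all(diff(tabs$peak_speed[, 1]) > 0))
  expect_true(all(apply(tabs$mt, 1, diff) < 0))
  expect_error(normalized_tables(trials[trials$width > 0.005 |
                                          trials$distance > 0.2, ]),
               "empty cell")
})
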