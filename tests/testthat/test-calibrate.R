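# shared small fixture: noise-free observations from the default truth
truth_obs <- local({
  gen <- rscm_generate(design = default_design(times = seq(0, 20, 2),
                                               noise = 0, seed = 1))
  gen$obs
})

test_that("residuals vanish on data generated from the same parameters", {
  res <- rscm_residuals(truth_obs)
  expect_lt(max(abs(res)), 1e-6)
  expect_equal(length(res), 6 * 11)
})

test_that("residuals follow the max-mean weighting definition", {
  # one observable, one time: residual = (model - obs) / obs
  traj <- rscm_simulate(horizon = 5, grid_step = 0.01)
  m <- traj$xNO3[match(5, traj$time)]
  obs <- observation_set(data.frame(time = 5, observable = "NO3",
                                    replicate = 1, value = 2 * m))
  res <- rscm_residuals(obs)
  expect_equal(unname(res), (m - 2 * m) / (2 * m), tolerance = 1e-6)
  # scaling: the divisor is the observable's maximum mean over time
  obs2 <- observation_set(data.frame(time = c(2, 5), observable = "NO3",
                                     replicate = 1, value = c(10, 5)))
  obs3 <- obs2; obs3$value <- 2 * obs2$value
  m2 <- traj$xNO3[match(c(2, 5), traj$time)]
  expect_equal(unname(rscm_residuals(obs2)), (m2 - c(10, 5)) / 10,
               tolerance = 1e-6)
  expect_equal(unname(rscm_residuals(obs3)), (m2 - c(20, 10)) / 20,
               tolerance = 1e-6)
})

test_that("the objective ignores observation record order", {
  set.seed(3)
  shuffled <- truth_obs[sample(nrow(truth_obs)), ]
  f1 <- rscm_fit(truth_obs, free = character(0))
  f2 <- rscm_fit(observation_set(shuffled), free = character(0))
  expect_equal(f1$objective, f2$objective)
})

test_that("an empty free set evaluates the objective without searching", {
  fit <- rscm_fit(truth_obs, free = character(0))
  expect_true(fit$converged)
  expect_equal(fit$objective, sum(rscm_residuals(truth_obs)^2))
  expect_equal(length(fit$par), 0)
})

test_that("a small perturbed fit recovers the generating parameters", {
  truth <- rscm_params()
  start <- c(k1 = truth$k1 * 1.3, f1 = truth$f1 * 1.3)
  fit <- rscm_fit(truth_obs, free = c("k1", "f1"), start = start)
  expect_true(fit$converged)
  expect_equal(fit$par[["k1"]], truth$k1, tolerance = 1e-3)
  expect_equal(fit$par[["f1"]], truth$f1, tolerance = 1e-3)
})

test_that("freezing a parameter at the wrong value raises the objective", {
  wrong <- rscm_params(f1 = 0.9)
  frozen <- rscm_fit(truth_obs, free = character(0), params = wrong)
  freed <- rscm_fit(truth_obs, free = "f1", params = wrong,
                    start = c(f1 = 0.9))
  expect_gt(frozen$objective, freed$objective)
})

test_that("only the model's fitted parameter set may be freed", {
  expect_error(rscm_fit(truth_obs, free = c("k1", "Kd1")), "fittable")
  expect_error(rscm_fit(truth_obs, free = "k1",
                        start = c(k1 = 6), upper = c(k1 = Inf)),
               "finite")
})

test_that("quantile trimming matches a brute-force enumeration oracle", {
  set.seed(11)
  mat <- cbind(a = rnorm(40, 10, 2), b = rlnorm(40), c = runif(40))
  trim <- bootstrap_trim(mat)
  # independent enumeration: per-parameter linear-interpolation quantiles,
  # drop rows with any coordinate strictly outside
  keep_oracle <- rep(TRUE, nrow(mat))
  for (j in seq_len(ncol(mat))) {
    qlo <- stats::quantile(mat[, j], 0.025, type = 7)
    qhi <- stats::quantile(mat[, j], 0.975, type = 7)
    for (i in seq_len(nrow(mat)))
      if (mat[i, j] < qlo || mat[i, j] > qhi) keep_oracle[i] <- FALSE
  }
  expect_equal(unname(trim$kept), keep_oracle)
  kept_rows <- mat[keep_oracle, , drop = FALSE]
  expect_equal(trim$ci[, "lower"], apply(kept_rows, 2, min))
  expect_equal(trim$ci[, "upper"], apply(kept_rows, 2, max))
  # trimming never widens: retained range inside the full range
  expect_true(all(trim$ci[, "lower"] >= apply(mat, 2, min)))
  expect_true(all(trim$ci[, "upper"] <= apply(mat, 2, max)))
})

test_that("zero-SD data collapse the bootstrap interval to a point", {
  fit <- rscm_bootstrap(truth_obs, free = "k1", n_sets = 3, seed = 4)
  expect_equal(fit$ci["k1", "lower"], fit$ci["k1", "upper"])
  expect_equal(fit$ci["k1", "lower"], fit$par[["k1"]], tolerance = 1e-6)
})

test_that("bootstrap runs are reproducible bit-for-bit given the seed", {
  gen <- rscm_generate(design = default_design(times = seq(0, 20, 4),
                                               noise = 0.05, seed = 2))
  a <- rscm_bootstrap(gen$obs, free = "k1", n_sets = 3, seed = 21)
  b <- rscm_bootstrap(gen$obs, free = "k1", n_sets = 3, seed = 21)
  expect_identical(a$ci, b$ci)
  expect_identical(a$boot$estimates, b$boot$estimates)
  expect_true(all(a$ci["k1", "lower"] <= a$par[["k1"]]),
              all(a$par[["k1"]] <= a$ci["k1", "upper"]))
  expect_error(rscm_bootstrap(gen$obs, free = "k1", n_sets = 1), "at least 2")
})
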