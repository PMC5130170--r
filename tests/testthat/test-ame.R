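test_that("Gaussian histogram fit agrees with the generating parameters", {
  set.seed(31)
  x <- rnorm(1e4, mean = 1, sd = 0.044)
  fit <- fit_gaussian_cv(x)
  expect_equal(fit$mean, 1, tolerance = 0.01)
  expect_equal(fit$cv, 0.044, tolerance = 0.003 / 0.044)
  # fit vs direct moment estimates
  expect_equal(fit$mean, mean(x), tolerance = 0.05)
  expect_equal(fit$cv, sd(x) / mean(x), tolerance = 0.05)

  expect_warning(f0 <- fit_gaussian_cv(rep(2, 100)), "degenerate")
  expect_identical(f0$cv, 0)
  expect_error(fit_gaussian_cv(rnorm(10)), ">= 50")
})

test_that("AME estimation composes CVs in quadrature", {
  g <- function(cv) structure(list(mean = 1, sd = cv, cv = cv),
                              class = "gaussian_fit")
  expect_identical(estimate_ame(g(0.02), g(0.02))$cv_ame, 0)
  expect_identical(estimate_ame(g(0), g(0.044))$cv_ame, 0.044)
  # the published basal CVs: sqrt(0.044^2 - 0.0035^2)
  ame <- estimate_ame(g(0.0035), g(0.044))
  expect_equal(ame$cv_ame, 0.04386057, tolerance = 1e-6)
  expect_error(estimate_ame(g(0.05), g(0.044)), "overpredicts")
})

test_that("applying AME adds variance independently", {
  x <- rep(1.2, 1000)
  ame0 <- structure(list(cv_ame = 0), class = "ame_model")
  expect_identical(apply_ame(x, ame0), x)

  set.seed(32)
  base <- rnorm(1e5, 1, 0.05)
  ame <- structure(list(cv_ame = 0.08), class = "ame_model")
  out <- apply_ame(base, ame, seed = 5)
  cv_out <- sd(out) / mean(out)
  expect_equal(cv_out^2, 0.05^2 + 0.08^2, tolerance = 0.02)
  # deterministic given the seed
  expect_identical(apply_ame(base, ame, seed = 5), out)
})

test_that("estimated AME reproduces the observed basal distribution", {
  set.seed(33)
  sim_basal <- rnorm(5000, 1, 0.0035)
  obs_basal <- rnorm(5000, 1, 0.044)
  ame <- estimate_ame(fit_gaussian_cv(sim_basal), fit_gaussian_cv(obs_basal))
  noisy <- apply_ame(sim_basal, ame, seed = 9)
  refit <- fit_gaussian_cv(noisy)
  expect_equal(refit$mean, 1, tolerance = 0.01)
  expect_equal(refit$cv, fit_gaussian_cv(obs_basal)$cv,
               tolerance = 0.1)
})

test_that("protein-CV recovery scores candidates by an RSS oracle", {
  net <- reduced_model()
  ame <- structure(list(cv_ame = 0.044), class = "ame_model")
  # pseudo-data generated at truth CV 10% on a coarse grid
  pseudo <- generate_pseudo_experiment(net, truth_cv = 0.10,
                                       truth_ame_cv = 0.044,
                                       doses = c(0, 0.05, 50), n_cells = 150,
                                       seed = 77, t_end = 1800, dt = 20)
  rec <- recover_protein_cv(net, pseudo, ame, cv_grid = c(0, 0.10, 0.25),
                            n_cells = 60, master_seed = 3,
                            t_end = 1800, dt = 20)
  expect_equal(rec$best_cv, 0.10)
  # independent re-summation of the RSS profile
  obs_cv <- vapply(split(pseudo$data$fold_change, pseudo$data$dose),
                   function(v) sd(v) / mean(v), numeric(1))
  obs_cv <- obs_cv[order(as.numeric(names(obs_cv)))]
  manual <- apply(rec$cv_curves, 1, function(row) sum((row - obs_cv)^2))
  expect_equal(unname(manual), rec$rss$rss, tolerance = 1e-12)
  expect_error(recover_protein_cv(net, pseudo, ame, cv_grid = c(0, 0.6)),
               "0, 0.5")
})

test_that("AME matters at low dose and cancels out at saturation", {
  net <- reduced_model()
  ame <- structure(list(cv_ame = 0.044), class = "ame_model")
  cv_at <- function(dose, with_ame, seed) {
    cfg <- noise_config(extrinsic_cv = 0.25, n_cells = 80, master_seed = 55)
    ens <- run_ensemble(net, dose, cfg, t_end = 1800, dt = 20)
    p <- if (with_ame) apply_ame(ens$peaks, ame, seed = seed) else ens$peaks
    sd(p) / mean(p)
  }
  delta_low <- abs(cv_at(0.001, TRUE, 1) - cv_at(0.001, FALSE, 1))
  delta_high <- abs(cv_at(50, TRUE, 2) - cv_at(50, FALSE, 2))
  expect_gt(delta_low, 0.03)   # dominates the near-flat basal response
  expect_lt(delta_high, delta_low)
})
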