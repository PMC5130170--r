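test_that("SSA mean of linear decay tracks the analytic solution", {
  net <- ab_network(a0 = 100, kf = 0.05)
  n_paths <- 2000
  seeds <- cell_seeds(101, n_paths)
  tgrid <- seq(0, 60, by = 20)
  b <- vapply(seeds, function(s)
    ssa_simulate(net, 0, t_end = 60, seed = s, dt = 20)$states[, "B"],
    numeric(length(tgrid)))
  for (i in 2:length(tgrid)) {
    t <- tgrid[i]
    p <- 1 - exp(-0.05 * t)
    mu <- 100 * p
    se <- sqrt(100 * p * (1 - p)) / sqrt(n_paths)  # binomial death process
    expect_lt(abs(mean(b[i, ]) - mu), 3 * se + 1e-9)
  }
})

test_that("birth-death process reaches its Poisson stationary law", {
  lambda <- 20; mu <- 1
  net <- birth_death_network(a0 = 20, lambda = lambda, mu = mu)
  n <- 5000
  seeds <- cell_seeds(202, n)
  finals <- vapply(seeds, function(s)
    ssa_simulate(net, 0, t_end = 12, seed = s, dt = 6)$states[3, "A"],
    numeric(1))
  # chi-square GOF against Poisson(lambda/mu), tail-pooled
  kmax <- max(finals)
  probs <- dpois(0:kmax, lambda / mu)
  probs[kmax + 1] <- probs[kmax + 1] + ppois(kmax, lambda / mu,
                                             lower.tail = FALSE)
  obs <- tabulate(finals + 1, nbins = kmax + 1)
  keep <- probs * n >= 5
  pooled_obs <- c(obs[keep], sum(obs[!keep]))
  pooled_p <- c(probs[keep], sum(probs[!keep]))
  gof <- suppressWarnings(chisq.test(pooled_obs, p = pooled_p))
  expect_gt(gof$p.value, 0.01)
  expect_equal(mean(finals), lambda / mu, tolerance = 0.05)
})

test_that("closed-system conservation is exact on every SSA path", {
  net <- ab_network(a0 = 50, b0 = 30, kf = 0.2, kr = 0.1)
  for (s in cell_seeds(7, 10)) {
    tr <- ssa_simulate(net, 0, t_end = 50, seed = s, dt = 5)
    expect_true(all(rowSums(tr$states) == 80))
    expect_true(all(tr$states >= 0))
    expect_true(all(tr$states == round(tr$states)))
  }
})

test_that("identical seeds reproduce identical paths; zero propensity holds", {
  net <- ab_network(a0 = 5, kf = 1)
  t1 <- ssa_simulate(net, 0, t_end = 100, seed = 33, dt = 10)
  t2 <- ssa_simulate(net, 0, t_end = 100, seed = 33, dt = 10)
  expect_identical(t1$states, t2$states)
  # all A consumed -> absorbing state held to the end, not an error
  expect_identical(unname(t1$states[nrow(t1$states), ]), c(0, 5))

  ens1 <- run_intrinsic_ensemble(reduced_model(), 0, n_cells = 3,
                                 master_seed = 5, t_end = 60, dt = 30)
  ens2 <- run_intrinsic_ensemble(reduced_model(), 0, n_cells = 3,
                                 master_seed = 5, t_end = 60, dt = 30)
  expect_identical(ens1$peaks, ens2$peaks)
})

test_that("SSA ensemble mean matches the ODE limit on a nonlinear toy", {
  net <- cascade_toy_network()
  ode <- integrate_network(net, 0, t_end = 200, dt = 100,
                           pre_equilibrate = FALSE)
  n_paths <- 2000
  finals <- vapply(cell_seeds(303, n_paths), function(s)
    ssa_simulate(net, 0, t_end = 200, seed = s, dt = 100)$states[3, "P"],
    numeric(1))
  expect_lt(abs(mean(finals) - ode$states[3, "P"]) / ode$states[3, "P"], 0.02)
})

test_that("intrinsic noise shrinks as 1/sqrt(molecule count)", {
  cv_at_scale <- function(scale, seed) {
    net <- cascade_toy_network(scale)
    finals <- vapply(cell_seeds(seed, 300), function(s)
      ssa_simulate(net, 0, t_end = 300, seed = s, dt = 150)$states[3, "P"],
      numeric(1))
    sd(finals) / mean(finals)
  }
  ratio <- cv_at_scale(1, 404) / cv_at_scale(100, 405)
  expect_gt(ratio, 6)   # expected ~10 under 1/sqrt(N) scaling
  expect_lt(ratio, 15)
})

test_that("tau-leaping agrees with the direct method in distribution", {
  net <- cascade_toy_network(10)
  stat <- function(method, seed0) {
    finals <- vapply(cell_seeds(seed0, 200), function(s)
      ssa_simulate(net, 0, t_end = 200, seed = s, dt = 100,
                   method = method)$states[3, "P"], numeric(1))
    c(mean(finals), sd(finals))
  }
  d <- stat("direct", 51); t <- stat("tau", 52)
  expect_lt(abs(d[1] - t[1]) / d[1], 0.02)
  expect_lt(abs(d[2] - t[2]) / d[2], 0.35)
})
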