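test_that("hill_fit recovers known parameters from noise-free curves", {
  fit <- hill_fit(noiseless_hill_curve(n = 2, K = 1))
  expect_equal(fit$n, 2, tolerance = 0.01 / 2)
  expect_equal(fit$K, 1, tolerance = 0.01)
  expect_equal(fit$R_min, 0, tolerance = 1e-6)
  expect_equal(fit$R_max, 1, tolerance = 1e-6)

  for (true in list(c(0.7, 0.05), c(1.46, 0.2), c(2.99, 0.06), c(4, 3))) {
    fit <- hill_fit(noiseless_hill_curve(n = true[1], K = true[2],
                                         rmin = 1, rmax = 2.4,
                                         doses = c(0, 10^seq(-3, 2, length.out = 24))))
    expect_equal(fit$n, true[1], tolerance = 1e-4)
    expect_equal(fit$K, true[2], tolerance = 1e-4)
  }
  expect_error(hill_fit(list(doses = c(0, 1, 2), responses = c(0, 1, 2))),
               "6 distinct")
})

test_that("fit minimum matches a brute-force grid-search oracle", {
  set.seed(21)
  cur <- noiseless_hill_curve(n = 1.8, K = 0.6, rmin = 0.2, rmax = 1.4)
  cur$responses <- cur$responses + rnorm(length(cur$responses), 0, 0.01)
  fit <- hill_fit(cur)
  # oracle: dense grid over (n, K), analytic least-squares for (rmin, rmax)
  rss_of <- function(n, K) {
    h <- ifelse(cur$doses > 0, cur$doses^n / (K^n + cur$doses^n), 0)
    X <- cbind(1 - h, h)
    sum(stats::lm.fit(X, cur$responses)$residuals^2)
  }
  grid <- expand.grid(n = seq(0.5, 4, by = 0.02),
                      K = 10^seq(-1.5, 0.5, by = 0.01))
  rss <- mapply(rss_of, grid$n, grid$K)
  best <- grid[which.min(rss), ]
  expect_lte(fit$residual, min(rss) + 1e-10)
  expect_equal(fit$n, best$n, tolerance = 0.02)
  expect_equal(fit$K, best$K, tolerance = 0.025)
})

test_that("effective concentrations follow the Hill algebra exactly", {
  fit <- structure(list(n = 2.5, K = 0.7, R_min = 1, R_max = 3),
                   class = "hill_fit")
  expect_identical(effective_concentration(fit, 0.5), 0.7)
  ec10 <- effective_concentration(fit, 0.1)
  ec90 <- effective_concentration(fit, 0.9)
  expect_equal(ec90 / ec10, 81^(1 / 2.5), tolerance = 1e-12)
  expect_error(effective_concentration(fit, 0), "strictly between")
  expect_error(effective_concentration(fit, 1), "strictly between")
})

test_that("hill_fit is scale-equivariant", {
  cur <- noiseless_hill_curve(n = 1.3, K = 0.4, rmin = 1, rmax = 2)
  f1 <- hill_fit(cur)
  cur2 <- list(doses = cur$doses, responses = 5 * cur$responses)
  f2 <- hill_fit(cur2)
  expect_equal(f2$n, f1$n, tolerance = 1e-6)
  expect_equal(f2$K, f1$K, tolerance = 1e-6)
  expect_equal(f2$R_min, 5 * f1$R_min, tolerance = 1e-6)
  expect_equal(f2$R_max, 5 * f1$R_max, tolerance = 1e-6)
})

test_that("model dose curves: graded pERK, switch-like nERK, knockout equalizes", {
  net <- reduced_model()
  grid <- default_dose_grid(16, 1e-3, 50)
  wt_perk <- build_dose_response(net, grid, "pERK", t_end = 3600, dt = 20)
  wt_nerk <- build_dose_response(net, grid, "nERK", t_end = 3600, dt = 20)
  ko <- knockout_npc_regulation(net)
  ko_perk <- build_dose_response(ko, grid, "pERK", t_end = 3600, dt = 20)
  ko_nerk <- build_dose_response(ko, grid, "nERK", t_end = 3600, dt = 20)

  expect_equal(wt_nerk$responses[1], 1, tolerance = 1e-6)  # dose 0 included
  # non-decreasing through the transition (tiny saturation-level wiggles
  # from feedback timing are tolerated at 0.1% of the response)
  expect_true(all(diff(wt_nerk$responses) >= -1e-3 * max(wt_nerk$responses)))
  expect_true(all(diff(ko_nerk$responses) >= -1e-3 * max(ko_nerk$responses)))

  f_wt_p <- hill_fit(wt_perk); f_wt_n <- hill_fit(wt_nerk)
  f_ko_p <- hill_fit(ko_perk); f_ko_n <- hill_fit(ko_nerk)

  # negative autoregulation of nuclear ERK makes nERK switch-like
  expect_gt(f_wt_n$n, 2 * f_wt_p$n)
  # removing it equalizes the Hill coefficients of nERK and pERK
  expect_equal(f_ko_n$n, f_ko_p$n, tolerance = 0.1)
  expect_lt(f_ko_n$n, 1.6)
  # autoregulation narrows the transition: knockout EC90 is larger,
  # EC10 nearly unchanged (export, not import, is regulated)
  ec90_wt <- effective_concentration(f_wt_n, 0.9)
  ec90_ko <- effective_concentration(f_ko_n, 0.9)
  expect_gt(ec90_ko / ec90_wt, 3)
  ec10_wt <- effective_concentration(f_wt_n, 0.1)
  ec10_ko <- effective_concentration(f_ko_n, 0.1)
  expect_lt(abs(log(ec10_ko / ec10_wt)), log(2.5))
  # autoregulation drastically reduces the maximal fold change
  expect_lt(f_wt_n$R_max, 0.7 * f_ko_n$R_max)
})

test_that("dose-response files round-trip through the CSV/JSON writers", {
  cur <- noiseless_hill_curve(n = 2, K = 1)
  cur <- structure(c(cur, list(observable = "nERK", variant = "wildtype")),
                   class = "dose_response_curve")
  fit <- hill_fit(cur)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_dose_response(cur, fit, csv, js)
  back <- read.csv(csv)
  expect_equal(back$response, cur$responses)
  jf <- jsonlite::fromJSON(js)
  expect_equal(jf$n, fit$n, tolerance = 1e-12)
})
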