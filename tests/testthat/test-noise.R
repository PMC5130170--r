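test_that("log-normal sampler is moment-matched at the configured CV", {
  net <- reduced_model()
  cfg0 <- noise_config(extrinsic_cv = 0, n_cells = 10, master_seed = 1)
  m0 <- sample_initials(net, cfg0)
  expect_true(all(t(m0) == net$species$initial_count))

  cfg <- noise_config(extrinsic_cv = 0.25, n_cells = 5000, master_seed = 2)
  m <- sample_initials(net, cfg)
  varied <- c("EGFR", "RasGDP", "Raf", "MEK", "ERK_cyt", "ERK_nuc",
              "Sos", "GAP", "Grb2", "Shc")
  nominal <- setNames(net$species$initial_count, net$species$id)
  for (s in varied) {
    expect_lt(abs(mean(m[, s]) / nominal[s] - 1), 0.01)
    cv <- sd(m[, s]) / mean(m[, s])
    expect_gte(cv, 0.24); expect_lte(cv, 0.26)
  }
  # unlabeled species (complexes, NPC) stay at nominal
  expect_true(all(m[, "NPC"] == nominal["NPC"]))
  expect_true(all(m[, "pEGFR"] == 0))
  # one protein, one factor: compartment split of ERK preserved per cell
  expect_equal(m[, "ERK_cyt"] / m[, "ERK_nuc"],
               rep(528000 / 72000, 5000), tolerance = 1e-12)
})

test_that("covariation shares one expression factor across proteins", {
  net <- reduced_model()
  cfg <- noise_config(extrinsic_cv = 0.25, covariation = "full",
                      n_cells = 2000, master_seed = 3)
  m <- sample_initials(net, cfg)
  expect_gt(cor(m[, "EGFR"], m[, "MEK"]), 0.99)
  expect_gt(cor(m[, "Raf"], m[, "ERK_cyt"]), 0.99)
  cfg_ind <- noise_config(extrinsic_cv = 0.25, n_cells = 2000, master_seed = 3)
  mi <- sample_initials(net, cfg_ind)
  expect_lt(abs(cor(mi[, "EGFR"], mi[, "MEK"])), 0.1)
})

test_that("a zero-abundance protein stays zero under extrinsic noise", {
  net <- build_network(toy_spec(
    list(toy_species("A", 0, protein = "A"), toy_species("B", 10)),
    list(toy_rxn(1, "A", "B", 1))))
  cfg <- noise_config(extrinsic_cv = 0.3, n_cells = 5, master_seed = 1)
  expect_warning(m <- sample_initials(net, cfg), "stays 0")
  expect_true(all(m[, "A"] == 0))
})

test_that("noise regimes behave as configured at the distribution level", {
  net <- reduced_model()
  # no noise: every cell identical, CV exactly 0
  ens0 <- run_ensemble(net, 0.5,
                       noise_config(n_cells = 5, master_seed = 1),
                       t_end = 1800, dt = 20)
  expect_identical(ens0$summary$cv, 0)
  expect_identical(ens0$regime, "none")

  # extrinsic-only at dose 0: fold-change normalization cancels abundance
  # scaling, every cell sits at its own steady state
  for (cov in c("none", "full")) {
    ens <- run_ensemble(net, 0,
                        noise_config(extrinsic_cv = 0.25, covariation = cov,
                                     n_cells = 12, master_seed = 4),
                        t_end = 900, dt = 30)
    expect_true(all(abs(ens$peaks - 1) < 1e-6))
  }
})

test_that("extrinsic noise dominates intrinsic noise at high dose", {
  net <- reduced_model()
  ens_ext <- run_ensemble(net, 50,
                          noise_config(extrinsic_cv = 0.30, n_cells = 40,
                                       master_seed = 6),
                          t_end = 1800, dt = 20)
  ens_int <- run_ensemble(net, 50,
                          noise_config(intrinsic = TRUE, n_cells = 8,
                                       master_seed = 6),
                          t_end = 1800, dt = 20, ssa_method = "tau")
  expect_gt(ens_ext$summary$cv, ens_int$summary$cv)
})

test_that("covariation suppresses nuclear-ERK heterogeneity at high dose", {
  net <- reduced_model()
  cv_of <- function(cov, seed) {
    run_ensemble(net, 50,
                 noise_config(extrinsic_cv = 0.25, covariation = cov,
                              n_cells = 60, master_seed = seed),
                 t_end = 1800, dt = 20)$summary$cv
  }
  # one-sided bootstrap over master seeds
  seeds <- 11:14
  cv_none <- vapply(seeds, function(s) cv_of("none", s), numeric(1))
  cv_full <- vapply(seeds, function(s) cv_of("full", s), numeric(1))
  expect_true(all(cv_full < cv_none))
})

test_that("sweep classification recovers planted heterogeneity patterns", {
  doses <- c(0.01, 0.03, 0.06, 0.1, 0.5, 5, 50)
  planted <- rbind(
    a = c(0.01, 0.09, 0.10, 0.08, 0.01, 0.01, 0.01),  # transition-elevated
    b = c(0.01, 0.01, 0.01, 0.02, 0.08, 0.09, 0.09),  # high-dose elevated
    c = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),  # flat
    d = c(0.01, 0.12, 0.11, 0.09, 0.02, 0.01, 0.01),
    e = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01))
  colnames(planted) <- doses
  types <- classify_sweep(planted, ec10 = 0.02, ec90 = 0.12)
  expect_identical(unname(types),
                   c("type1", "type2", "type3", "type1", "type3"))
  expect_error(classify_sweep(planted[, 1:3], 0.02, 0.12), "cover")
})

test_that("one-at-a-time sweep isolates the varied protein", {
  net <- reduced_model()
  sweep <- species_sensitivity_sweep(net, dose_grid = c(0.05, 50),
                                     proteins = c("EGFR", "Grb2"),
                                     cv = 0.25, n_cells = 25, master_seed = 9,
                                     t_end = 1800, dt = 20)
  expect_identical(dim(sweep), c(2L, 2L))
  # receptor variability drives transition-region heterogeneity;
  # the Grb2 adaptor does not
  expect_gt(sweep["EGFR", "0.05"], 2 * sweep["Grb2", "0.05"])
  expect_error(species_sensitivity_sweep(net, 1, proteins = "NotAProtein"),
               "unknown protein")
})
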