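#' Run a named figure-level analysis scenario
#'
#' Thin, seeded driver over the package's simulation and analysis functions;
#' each scenario writes its result tables (CSV/JSON) plus a run manifest into
#' `out_dir`. The numbered scripts under `analysis/` in the source repository
#' are narrative wrappers around these scenarios.
#'
#' Scenarios: `timecourse` (pERK/nERK time courses across doses),
#' `dose_response` (peak dose curves + Hill fits), `knockout` (wildtype vs
#' NPC-knockout Hill fits), `noise_compare` (CV table, four regimes x doses),
#' `ame_recovery` (pseudo-data, AME estimation, protein-CV recovery),
#' `covariation` (CV with vs without covaried abundances), `sensitivity`
#' (one-at-a-time protein sweep + classification), `mutual_info` (debiased
#' MI of simulated vs pseudo-experimental channels), `synth_data` (writes a
#' pseudo-experimental dataset).
#'
#' @param scenario Scenario name (see above).
#' @param config Named list of overrides (`seed`, `n_cells`, `doses`, `cv`,
#'   `truth_cv`, `truth_ame_cv`, `model_path`, `t_end`, `dt`, ...).
#' @param out_dir Output directory (created if needed).
#' @param smoke If TRUE, run at a reduced smoke scale (small ensembles,
#'   coarse dose grids) meant to finish in well under two minutes.
#' @return Invisibly, a list of the result objects written.
#' @export
run_scenario <- function(scenario, config = list(), out_dir, smoke = FALSE) {
  scenarios <- c("timecourse", "dose_response", "knockout", "noise_compare",
                 "ame_recovery", "covariation", "sensitivity", "mutual_info",
                 "synth_data")
  if (!scenario %in% scenarios)
    stop("unknown scenario '", scenario, "'; must be one of: ",
         paste(scenarios, collapse = ", "))
  cfg <- function(name, default) if (!is.null(config[[name]])) config[[name]] else default
  seed <- cfg("seed", 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  net <- load_network(cfg("model_path", reduced_egf_model_path()))
  t_end <- cfg("t_end", 3600); dt <- cfg("dt", 10)
  results <- list()
  out <- function(name) file.path(out_dir, name)

  if (scenario == "timecourse") {
    doses <- cfg("doses", c(0, 0.01, 0.05, 0.1, 0.5, 5, 50))
    x0 <- equilibrate_network(net)
    tab <- do.call(rbind, lapply(doses, function(d) {
      tr <- integrate_network(net, d, t_end = t_end, dt = dt, init = x0,
                              pre_equilibrate = FALSE)
      data.frame(dose = d, time = tr$times,
                 pERK = observable_series(tr, net, "pERK"),
                 nERK = observable_series(tr, net, "nERK"))
    }))
    write.csv(tab, out("timecourse.csv"), row.names = FALSE)
    results$timecourse <- tab
  }

  if (scenario %in% c("dose_response", "knockout")) {
    grid <- cfg("doses", default_dose_grid(if (smoke) 12 else 24))
    variants <- if (scenario == "knockout")
      list(wildtype = net, knockout = knockout_npc_regulation(net))
    else list(wildtype = net)
    fits <- list()
    for (vn in names(variants)) {
      for (obs in c("pERK", "nERK")) {
        curve <- build_dose_response(variants[[vn]], grid, obs,
                                     t_end = t_end, dt = dt)
        fit <- hill_fit(curve)
        write_dose_response(curve, fit,
                            out(paste0("curve_", vn, "_", obs, ".csv")),
                            out(paste0("hill_", vn, "_", obs, ".json")))
        fits[[paste(vn, obs, sep = "_")]] <-
          list(n = fit$n, K = fit$K,
               EC10 = effective_concentration(fit, 0.1),
               EC90 = effective_concentration(fit, 0.9))
      }
    }
    jsonlite::write_json(fits, out("hill_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    results$fits <- fits
  }

  if (scenario == "noise_compare") {
    doses <- cfg("doses", c(0, 0.05, 0.5, 50))
    n_cells <- cfg("n_cells", if (smoke) 20 else 100)
    cv <- cfg("cv", 0.30)  # representative extrinsic protein variability
    regimes <- list(
      none = noise_config(FALSE, 0, n_cells = n_cells, master_seed = seed),
      intrinsic = noise_config(TRUE, 0, n_cells = n_cells, master_seed = seed),
      extrinsic = noise_config(FALSE, cv, n_cells = n_cells, master_seed = seed),
      both = noise_config(TRUE, cv, n_cells = n_cells, master_seed = seed))
    tab <- do.call(rbind, lapply(names(regimes), function(rn) {
      do.call(rbind, lapply(doses, function(d) {
        ens <- run_ensemble(net, d, regimes[[rn]], t_end = t_end, dt = dt,
                            ssa_method = "tau")
        data.frame(regime = rn, dose = d, mean = ens$summary$mean,
                   sd = ens$summary$sd, cv = ens$summary$cv)
      }))
    }))
    write.csv(tab, out("noise_compare.csv"), row.names = FALSE)
    results$noise_compare <- tab
  }

  if (scenario %in% c("ame_recovery", "mutual_info", "synth_data")) {
    truth_cv <- cfg("truth_cv", 0.25)
    truth_ame <- cfg("truth_ame_cv", 0.044)
    doses <- cfg("doses", c(0, 0.01, 0.05, 0.1, 0.5, 50))
    n_cells <- cfg("n_cells", if (smoke) 100 else 1000)
    pseudo <- generate_pseudo_experiment(net, truth_cv, truth_ame,
                                         doses = doses, n_cells = n_cells,
                                         seed = seed, t_end = t_end, dt = dt)
    write_dataset(pseudo, out("pseudo_experiment.csv"))
    results$pseudo <- pseudo

    if (scenario == "ame_recovery") {
      obs_basal <- fit_gaussian_cv(
        pseudo$data$fold_change[pseudo$data$dose == 0])
      sim_basal <- structure(list(mean = 1, sd = 0.0035, cv = 0.0035),
                             class = "gaussian_fit")
      ame <- estimate_ame(sim_basal, obs_basal)
      rec <- recover_protein_cv(net, pseudo, ame,
                                cv_grid = cfg("cv_grid", seq(0, 0.5, 0.05)),
                                n_cells = cfg("rec_cells", if (smoke) 40 else 150),
                                master_seed = seed, t_end = t_end, dt = dt)
      write.csv(rec$rss, out("rss_profile.csv"), row.names = FALSE)
      write.csv(data.frame(dose = colnames(rec$cv_curves),
                           t(rec$cv_curves)), out("cv_curves.csv"),
                row.names = FALSE)
      jsonlite::write_json(list(cv_ame = ame$cv_ame, best_cv = rec$best_cv),
                           out("ame_recovery.json"), auto_unbox = TRUE,
                           digits = NA)
      results$ame <- ame; results$recovery <- rec
    }
    if (scenario == "mutual_info") {
      mi <- debiased_mi(pseudo$data, seed = seed)
      jsonlite::write_json(list(mi_bits = mi$mi, bin_count = mi$bin_count),
                           out("mutual_info.json"), auto_unbox = TRUE,
                           digits = NA)
      write.csv(mi$profile, out("mi_profile.csv"), row.names = FALSE)
      results$mi <- mi
    }
  }

  if (scenario == "covariation") {
    doses <- cfg("doses", c(0, 50))
    n_cells <- cfg("n_cells", if (smoke) 40 else 200)
    cv <- cfg("cv", 0.25)
    tab <- do.call(rbind, lapply(c("none", "full"), function(cov) {
      cfgn <- noise_config(FALSE, cv, covariation = cov, n_cells = n_cells,
                           master_seed = seed)
      do.call(rbind, lapply(doses, function(d) {
        ens <- run_ensemble(net, d, cfgn, t_end = t_end, dt = dt)
        data.frame(covariation = cov, dose = d, cv = ens$summary$cv)
      }))
    }))
    write.csv(tab, out("covariation.csv"), row.names = FALSE)
    results$covariation <- tab
  }

  if (scenario == "sensitivity") {
    doses <- cfg("doses", c(0.01, 0.02, 0.05, 0.08, 0.12, 0.5, 5, 50))
    n_cells <- cfg("n_cells", if (smoke) 25 else 100)
    sweep <- species_sensitivity_sweep(net, doses, cv = cfg("cv", 0.25),
                                       n_cells = n_cells, master_seed = seed,
                                       t_end = t_end, dt = dt)
    types <- classify_sweep(sweep, ec10 = cfg("ec10", 0.02),
                            ec90 = cfg("ec90", 0.12))
    write.csv(data.frame(protein = rownames(sweep), sweep,
                         type = types, check.names = FALSE),
              out("sensitivity_sweep.csv"), row.names = FALSE)
    results$sweep <- sweep; results$types <- types
  }

  manifest <- list(scenario = scenario, seed = seed, smoke = smoke,
                   config = config[setdiff(names(config), "")],
                   package_version = as.character(utils::packageVersion("erknoise")),
                   r_version = R.version.string,
                   wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(results)
}
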