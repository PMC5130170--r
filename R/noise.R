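#' Noise-regime configuration
#'
#' Intrinsic noise = stochastic reaction timing (simulated by exact SSA);
#' extrinsic noise = cell-to-cell protein variability (log-normal sampling of
#' initial abundances). Four regimes arise from the two flags: none,
#' intrinsic, extrinsic, both.
#'
#' @param intrinsic Logical: simulate reaction-event stochasticity.
#' @param extrinsic_cv Global protein-variability CV (fraction, e.g. 0.25);
#'   0 disables extrinsic noise.
#' @param per_protein_cv Optional named vector protein -> CV overriding
#'   `extrinsic_cv` for those proteins (proteins absent keep the global CV).
#' @param covariation `"none"` (independent log-normals per protein) or
#'   `"full"` (one shared log-normal factor per cell: perfectly correlated
#'   abundances, the modeled extreme of shared expression capacity).
#' @param rho Correlation parameter between 0 and 1 for intermediate covariation;
#'   ignored unless `covariation = "partial"`.
#' @param n_cells Ensemble size.
#' @param master_seed Integer master seed.
#' @return A `noise_config` list with a derived `regime` field.
#' @export
noise_config <- function(intrinsic = FALSE, extrinsic_cv = 0,
                         per_protein_cv = NULL,
                         covariation = c("none", "full", "partial"),
                         rho = 0, n_cells = 100, master_seed = 1) {
  covariation <- match.arg(covariation)
  if (extrinsic_cv < 0 || any(per_protein_cv < 0)) stop("cv must be >= 0")
  if (extrinsic_cv >= 3 || any(per_protein_cv >= 3))
    stop("cv must be < 3 for a valid moment-matched log-normal")
  rho <- switch(covariation, none = 0, full = 1, partial = rho)
  extrinsic <- extrinsic_cv > 0 || any(per_protein_cv > 0)
  regime <- if (intrinsic && extrinsic) "both"
            else if (intrinsic) "intrinsic"
            else if (extrinsic) "extrinsic" else "none"
  structure(list(intrinsic = intrinsic, extrinsic_cv = extrinsic_cv,
                 per_protein_cv = per_protein_cv, covariation = covariation,
                 rho = rho, n_cells = n_cells, master_seed = master_seed,
                 regime = regime),
            class = "noise_config")
}

#' Sample per-cell initial molecule counts under extrinsic noise
#'
#' Each varied protein is drawn from a moment-matched log-normal with mean
#' equal to its nominal abundance and the configured CV
#' (sigma^2 = log(1 + CV^2), mu = log(nominal) - sigma^2/2). A protein
#' distributed over several species (e.g. cytoplasmic and nuclear ERK) gets
#' one shared multiplicative factor, so its compartment split is preserved.
#' Under covariation, a per-cell standard-normal factor is shared across
#' proteins with correlation `rho` (1 = fully covaried).
#'
#' Only free, initial-condition proteins (species with a `protein` label in
#' the model file) are varied; complexes and unlabeled species stay nominal.
#'
#' @param network A `reaction_network`.
#' @param config A [noise_config()].
#' @return `n_cells` x species numeric matrix of initial counts (real-valued;
#'   rounded to integers only when fed to the SSA engine).
#' @export
sample_initials <- function(network, config) {
  sp <- network$species
  nominal <- sp$initial_count
  n_cells <- config$n_cells
  out <- matrix(rep(nominal, each = n_cells), nrow = n_cells,
                dimnames = list(NULL, sp$id))
  proteins <- unique(sp$protein[!is.na(sp$protein)])
  if (length(proteins) == 0 || config$regime %in% c("none", "intrinsic"))
    return(out)

  cv_of <- function(p) {
    if (!is.null(config$per_protein_cv) && p %in% names(config$per_protein_cv))
      config$per_protein_cv[[p]] else config$extrinsic_cv
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(.cpp_stream_seed(config$master_seed, 0)))
  z_shared <- rnorm(n_cells)
  rho <- config$rho
  for (p in proteins) {
    cv <- cv_of(p)
    if (cv == 0) next
    cols <- which(!is.na(sp$protein) & sp$protein == p)
    if (all(nominal[cols] == 0)) {
      warning("protein ", p, " has nominal count 0; stays 0 despite cv > 0")
      next
    }
    sigma <- sqrt(log(1 + cv^2))
    z <- sqrt(rho) * z_shared + sqrt(1 - rho) * rnorm(n_cells)
    factor <- exp(sigma * z - sigma^2 / 2)   # mean-1 multiplicative factor
    out[, cols] <- outer(factor, nominal[cols])
  }
  out
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a single-cell ensemble under a noise regime
#'
#' Runs `n_cells` cells at one EGF dose and returns each cell's peak nuclear
#' ERK fold change, normalized to that cell's own pre-stimulus steady-state
#' nuclear ERK (for dose 0, the fold change at the final readout time is
#' reported). Engine by regime: extrinsic-only and none use the ODE engine
#' per cell; intrinsic and both use SSA.
#'
#' @param network A `reaction_network`.
#' @param egf_dose EGF concentration (ng/mL).
#' @param config A [noise_config()].
#' @param t_end,dt Simulation horizon and output grid (s).
#' @param ssa_method `"direct"` or `"tau"`, see [ssa_simulate()].
#' @param engine `"auto"` (by regime) or force `"ode"`/`"ssa"`. Forcing
#'   `"ode"` for a `both` regime drops the intrinsic component, which is
#'   negligible at the packaged model's molecule counts (basal CV ~0.35%);
#'   used by the CV-recovery stage for speed.
#' @return An `ensemble_result`: per-cell `peaks`, sampled `initials`, dose,
#'   regime, and `summary` (mean, sd, cv).
#' @export
run_ensemble <- function(network, egf_dose, config, t_end = 3600, dt = 10,
                         ssa_method = c("direct", "tau"),
                         engine = c("auto", "ode", "ssa")) {
  ssa_method <- match.arg(ssa_method)
  engine <- match.arg(engine)
  if (engine == "auto")
    engine <- if (config$intrinsic) "ssa" else "ode"
  initials <- sample_initials(network, config)
  seeds <- cell_seeds(config$master_seed, config$n_cells)

  one_cell <- function(i) {
    x0 <- equilibrate_network(network, init = initials[i, ])
    if (engine == "ode") {
      tr <- integrate_network(network, egf_dose, t_end = t_end, dt = dt,
                              init = x0, pre_equilibrate = FALSE)
    } else {
      tr <- ssa_simulate(network, egf_dose, t_end = t_end, seed = seeds[i],
                         dt = dt, init = round(x0), method = ssa_method)
    }
    cell_peak_nerk(tr, network)
  }

  peaks <- rep(NA_real_, config$n_cells)
  failures <- character(0)
  if (config$regime %in% c("none", "intrinsic") && engine == "ode") {
    # identical cells: one solve suffices
    peaks[] <- one_cell(1)
  } else {
    for (i in seq_len(config$n_cells)) {
      peaks[i] <- tryCatch(one_cell(i), error = function(e) {
        failures <<- c(failures, paste0("cell ", i, ": ", conditionMessage(e)))
        NA_real_
      })
    }
  }
  if (length(failures) > 0.01 * config$n_cells)
    stop("ensemble aborted: >1% of cells failed\n",
         paste(head(failures, 5), collapse = "\n"))
  if (length(failures))
    message(length(failures), " cell(s) failed and were excluded")
  ok <- !is.na(peaks)
  m <- mean(peaks[ok]); s <- sd(peaks[ok])
  structure(list(peaks = peaks[ok], initials = initials, dose = egf_dose,
                 regime = config$regime, config = config,
                 summary = list(mean = m, sd = s,
                                cv = if (m > 0) s / m else NA_real_)),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("ensemble (", x$regime, "): ", length(x$peaks), " cells, EGF ",
      x$dose, " ng/mL; mean ", signif(x$summary$mean, 4), ", CV ",
      signif(100 * x$summary$cv, 3), "%\n", sep = "")
  invisible(x)
}

#' One-at-a-time protein-variability sweep across EGF doses
#'
#' Varies each listed protein alone (others held exactly at nominal) at the
#' given CV, and records the CV of peak nuclear ERK at each dose, using the
#' per-cell ODE engine.
#'
#' @param network A `reaction_network`.
#' @param dose_grid EGF doses (ng/mL).
#' @param proteins Protein labels to sweep (default: every labeled protein).
#' @param cv Protein-variability CV (default 0.25).
#' @param n_cells Cells per (protein, dose) ensemble.
#' @param master_seed Master seed.
#' @param t_end,dt Simulation horizon and grid (s).
#' @return Matrix of nERK CVs (proteins x doses), with dose colnames.
#' @export
species_sensitivity_sweep <- function(network, dose_grid, proteins = NULL,
                                      cv = 0.25, n_cells = 100,
                                      master_seed = 1, t_end = 3600, dt = 10) {
  all_p <- unique(network$species$protein[!is.na(network$species$protein)])
  if (is.null(proteins)) proteins <- all_p
  extra <- setdiff(proteins, all_p)
  if (length(extra))
    stop("unknown protein label(s): ", paste(extra, collapse = ", "))
  out <- matrix(NA_real_, length(proteins), length(dose_grid),
                dimnames = list(proteins, as.character(dose_grid)))
  for (pi in seq_along(proteins)) {
    pcv <- setNames(rep(0, length(all_p)), all_p)
    pcv[proteins[pi]] <- cv
    cfg <- noise_config(intrinsic = FALSE, extrinsic_cv = 0,
                        per_protein_cv = pcv, n_cells = n_cells,
                        master_seed = master_seed + pi)
    for (di in seq_along(dose_grid)) {
      ens <- run_ensemble(network, dose_grid[di], cfg, t_end = t_end, dt = dt)
      out[pi, di] <- ens$summary$cv
    }
  }
  out
}

#' Classify sweep rows into heterogeneity-contribution types
#'
#' Type 1: CV elevated inside the dose-response transition region
#' \[EC10, EC90\] (proteins that decide whether a cell responds);
#' type 2: CV elevated only above EC90 (heterogeneity among responders);
#' type 3: flat everywhere. "Elevated" in a region means the row's maximum
#' CV there exceeds `factor` times the all-protein median CV of that region.
#'
#' @param cv_matrix Proteins x doses CV matrix (dose colnames numeric).
#' @param ec10,ec90 Transition-region bounds (ng/mL).
#' @param factor Elevation multiplier over the regional median (default 2).
#' @return Named character vector protein -> "type1"/"type2"/"type3".
#' @export
classify_sweep <- function(cv_matrix, ec10, ec90, factor = 2) {
  doses <- as.numeric(colnames(cv_matrix))
  in_trans <- doses >= ec10 & doses <= ec90
  above <- doses > ec90
  if (!any(in_trans) || !any(above))
    stop("dose grid must cover both the transition region and doses above EC90")
  med_trans <- median(cv_matrix[, in_trans])
  med_above <- median(cv_matrix[, above])
  res <- apply(cv_matrix, 1, function(row) {
    hi_trans <- max(row[in_trans]) > factor * med_trans
    hi_above <- max(row[above]) > factor * med_above
    if (hi_trans) "type1" else if (hi_above) "type2" else "type3"
  })
  setNames(res, rownames(cv_matrix))
}
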