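#' Gaussian curve fit to a sample histogram
#'
#' Histograms the samples with Freedman-Diaconis bin widths and fits a
#' Gaussian density to the bin densities by least squares (mirroring curve
#' fitting of measured distributions, rather than plain moment estimation).
#'
#' @param samples Numeric vector (>= 50 values).
#' @return A `gaussian_fit`: `mean`, `sd`, `cv` (= sd/mean), and `rss`
#'   (residual sum of squares on bin densities).
#' @export
fit_gaussian_cv <- function(samples) {
  if (length(samples) < 50) stop("need >= 50 samples")
  if (diff(range(samples)) == 0) {
    warning("degenerate (all-equal) samples; cv = 0")
    return(structure(list(mean = samples[1], sd = 0, cv = 0, rss = 0),
                     class = "gaussian_fit"))
  }
  h <- graphics::hist(samples, breaks = "FD", plot = FALSE)
  mids <- h$mids; dens <- h$density
  m0 <- mean(samples); s0 <- sd(samples)
  fit <- tryCatch(
    minpack.lm::nlsLM(dens ~ dnorm(mids, mean = m, sd = s),
                      start = list(m = m0, s = s0),
                      lower = c(m = -Inf, s = .Machine$double.eps)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to moment estimates if the histogram fit is degenerate
    return(structure(list(mean = m0, sd = s0, cv = s0 / m0, rss = NA_real_),
                     class = "gaussian_fit"))
  }
  p <- coef(fit)
  structure(list(mean = unname(p["m"]), sd = unname(p["s"]),
                 cv = unname(p["s"] / p["m"]), rss = sum(resid(fit)^2)),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("gaussian_fit: mean = %.4g, cv = %.3g%%\n", x$mean, 100 * x$cv))
  invisible(x)
}

#' Estimate the Apparent Measurement Error (AME)
#'
#' AME is the measurement-derived noise that, composed with the simulated
#' basal (unstimulated) fold-change distribution, reproduces the observed
#' basal distribution. With independent multiplicative Gaussian errors the
#' CVs add in quadrature, so cv_ame = sqrt(cv_obs^2 - cv_sim^2).
#'
#' @param sim_basal_fit [fit_gaussian_cv()] of the simulated basal
#'   distribution (both-noise, dose 0).
#' @param obs_basal_fit Same for the observed (or pseudo-experimental) basal
#'   distribution.
#' @return An `ame_model` with `cv_ame` and the provenance CVs.
#' @export
estimate_ame <- function(sim_basal_fit, obs_basal_fit) {
  cv_sim <- sim_basal_fit$cv; cv_obs <- obs_basal_fit$cv
  if (cv_obs < cv_sim)
    stop("observed basal CV (", signif(100 * cv_obs, 3),
         "%) below simulated (", signif(100 * cv_sim, 3),
         "%): model overpredicts basal noise")
  structure(list(cv_ame = sqrt(cv_obs^2 - cv_sim^2),
                 cv_sim = cv_sim, cv_obs = cv_obs),
            class = "ame_model")
}

#' @export
print.ame_model <- function(x, ...) {
  cat(sprintf("ame_model: cv_ame = %.3g%% (obs %.3g%%, sim %.3g%%)\n",
              100 * x$cv_ame, 100 * x$cv_obs, 100 * x$cv_sim))
  invisible(x)
}

#' Apply AME to simulated fold-change samples
#'
#' Multiplies each sample by an independent Gaussian factor N(1, cv_ame^2).
#' Negative products (never expected at these CVs) are clipped at 0 with a
#' warning.
#'
#' @param samples Positive numeric vector (fold changes).
#' @param ame An `ame_model` (or a list with `cv_ame`).
#' @param seed Integer seed for the error draws.
#' @return Noisy samples, same length.
#' @export
apply_ame <- function(samples, ame, seed = 1) {
  if (ame$cv_ame == 0) return(samples)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  out <- samples * rnorm(length(samples), mean = 1, sd = ame$cv_ame)
  if (any(out < 0)) {
    warning(sum(out < 0), " sample(s) clipped at 0 after AME")
    out <- pmax(out, 0)
  }
  out
}

#' Recover protein-variability CV by matching noisy simulations to data
#'
#' For each candidate protein CV, simulates per-dose single-cell ensembles,
#' applies the AME, computes the CV of nuclear-ERK fold change per dose, and
#' scores the candidate by the residual sum of squares against the observed
#' per-dose CVs. The grid argmin is the recovered protein variability.
#'
#' Ensembles use the per-cell ODE engine (extrinsic noise only): at the
#' packaged model's molecule counts the intrinsic contribution to the peak CV
#' (basal ~0.35%) is negligible against the AME and extrinsic components.
#'
#' @param network A `reaction_network`.
#' @param observed A `synthetic_dataset`, a data.frame with columns `dose`
#'   and `fold_change`, or a named numeric vector of per-dose CVs (names =
#'   doses in ng/mL).
#' @param ame An `ame_model` applied to simulated peaks.
#' @param cv_grid Candidate protein CVs within 0 to 0.5 (default 0 to 50% by 5%).
#' @param n_cells Cells per (cv, dose) ensemble.
#' @param master_seed Master seed.
#' @param t_end,dt Simulation horizon and grid (s).
#' @return List: `best_cv`, `rss` (data.frame cv, rss), and `cv_curves`
#'   (matrix candidate CV x dose of simulated nERK CVs after AME).
#' @export
recover_protein_cv <- function(network, observed, ame,
                               cv_grid = seq(0, 0.5, by = 0.05),
                               n_cells = 150, master_seed = 1,
                               t_end = 3600, dt = 10) {
  if (any(cv_grid < 0 | cv_grid > 0.5))
    stop("cv_grid must lie within [0, 0.5]")
  obs_cv <- observed_dose_cvs(observed)
  doses <- as.numeric(names(obs_cv))

  cv_curves <- matrix(NA_real_, length(cv_grid), length(doses),
                      dimnames = list(as.character(cv_grid),
                                      as.character(doses)))
  for (gi in seq_along(cv_grid)) {
    cfg <- noise_config(intrinsic = FALSE, extrinsic_cv = cv_grid[gi],
                        n_cells = n_cells,
                        master_seed = master_seed + 1000L * gi)
    for (di in seq_along(doses)) {
      ens <- run_ensemble(network, doses[di], cfg, t_end = t_end, dt = dt)
      noisy <- apply_ame(ens$peaks, ame,
                         seed = .cpp_stream_seed(master_seed, gi * 101 + di))
      cv_curves[gi, di] <- sd(noisy) / mean(noisy)
    }
  }
  rss <- apply(cv_curves, 1, function(row) sum((row - obs_cv)^2))
  list(best_cv = cv_grid[which.min(rss)],
       rss = data.frame(cv = cv_grid, rss = as.numeric(rss)),
       cv_curves = cv_curves)
}

# per-dose CVs from any accepted "observed data" representation
observed_dose_cvs <- function(observed) {
  if (inherits(observed, "synthetic_dataset")) observed <- observed$data
  if (is.data.frame(observed)) {
    sp <- split(observed$fold_change, observed$dose)
    cvs <- vapply(sp, function(v) sd(v) / mean(v), numeric(1))
    return(cvs[order(as.numeric(names(cvs)))])
  }
  if (is.numeric(observed) && !is.null(names(observed)))
    return(observed[order(as.numeric(names(observed)))])
  stop("observed must be a synthetic_dataset, a (dose, fold_change) ",
       "data.frame, or a named per-dose CV vector")
}
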