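#' Default EGF dose grid
#'
#' Zero plus `n` log-spaced doses between `lo` and `hi` ng/mL.
#'
#' @param n Number of positive doses (default 24).
#' @param lo,hi Grid limits in ng/mL.
#' @return Sorted numeric dose vector including 0.
#' @export
default_dose_grid <- function(n = 24, lo = 1e-4, hi = 50) {
  c(0, 10^seq(log10(lo), log10(hi), length.out = n))
}

#' Deterministic peak-response dose curve
#'
#' One pre-equilibrated ODE solve per dose; the peak of the requested
#' observable is recorded.
#'
#' @param network A `reaction_network`.
#' @param dose_grid EGF doses (ng/mL), see [default_dose_grid()].
#' @param observable `"pERK"` or `"nERK"`.
#' @param t_end,dt Simulation horizon and output grid (s).
#' @return A `dose_response_curve`: data.frame-backed list with `doses`,
#'   `responses`, `observable`, and `variant` (from the network).
#' @export
build_dose_response <- function(network, dose_grid = default_dose_grid(),
                                observable = c("pERK", "nERK"),
                                t_end = 3600, dt = 10) {
  observable <- match.arg(observable)
  dose_grid <- sort(dose_grid)
  x0 <- equilibrate_network(network)
  responses <- vapply(dose_grid, function(d) {
    tr <- integrate_network(network, d, t_end = t_end, dt = dt, init = x0,
                            pre_equilibrate = FALSE)
    suppressWarnings(peak_response(tr, network, observable))
  }, numeric(1))
  variant <- attr(network, "variant")
  structure(list(doses = dose_grid, responses = responses,
                 observable = observable,
                 variant = if (is.null(variant)) "wildtype" else variant),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat("dose_response_curve (", x$observable, ", ", x$variant, "): ",
      length(x$doses), " doses in [", min(x$doses), ", ", max(x$doses),
      "] ng/mL\n", sep = "")
  invisible(x)
}

.hill <- function(d, rmin, rmax, k, n) rmin + (rmax - rmin) * d^n / (k^n + d^n)

#' Fit a four-parameter Hill function to a dose-response curve
#'
#' Least-squares fit of R(d) = R_min + (R_max - R_min) d^n / (K^n + d^n) by
#' Levenberg-Marquardt, multi-started over Hill coefficients
#' n in {0.5, 1, 2, 4}; the best converged fit is returned.
#'
#' @param curve A `dose_response_curve`, or a list/data.frame with `doses`
#'   and `responses`.
#' @return A `hill_fit`: `n` (Hill coefficient), `K` (half-max dose, ng/mL),
#'   `R_min`, `R_max`, `residual` (residual sum of squares), `converged`.
#' @export
hill_fit <- function(curve) {
  d <- curve$doses; r <- curve$responses
  pos <- d > 0
  if (length(unique(d[pos])) < 6)
    stop("need >= 6 distinct positive doses spanning the transition")
  rmin0 <- min(r); rmax0 <- max(r)
  if (rmax0 <= rmin0) stop("flat curve: no transition to fit")
  # starting K: dose nearest half-maximal response
  half <- rmin0 + 0.5 * (rmax0 - rmin0)
  k0 <- d[pos][which.min(abs(r[pos] - half))]
  if (k0 <= 0) k0 <- median(d[pos])

  best <- NULL
  diagnostics <- character(0)
  for (n0 in c(0.5, 1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ rmin + (rmax - rmin) * ifelse(d > 0, d^n / (k^n + d^n), 0),
        start = list(rmin = rmin0, rmax = rmax0, k = k0, n = n0),
        lower = c(rmin = -Inf, rmax = -Inf, k = 1e-12, n = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        diagnostics <<- c(diagnostics, paste0("start n=", n0, ": ",
                                              conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$residual) {
      p <- coef(fit)
      best <- list(n = unname(p["n"]), K = unname(p["k"]),
                   R_min = unname(p["rmin"]), R_max = unname(p["rmax"]),
                   residual = rss, converged = TRUE)
    }
  }
  if (is.null(best))
    stop("Hill fit failed from all starts:\n",
         paste(diagnostics, collapse = "\n"))
  if (best$R_max < best$R_min) { # re-express as an increasing curve
    tmp <- best$R_max; best$R_max <- best$R_min; best$R_min <- tmp
  }
  structure(best, class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit: n = %.2f, K = %.4g ng/mL, R in [%.4g, %.4g], RSS = %.3g\n",
              x$n, x$K, x$R_min, x$R_max, x$residual))
  invisible(x)
}

#' Effective concentration from a fitted Hill curve
#'
#' Dose at which the response reaches `R_min + fraction * (R_max - R_min)`,
#' from the Hill algebra EC_f = K * (f / (1 - f))^(1/n). EC50 = K exactly,
#' and EC90 / EC10 = 81^(1/n).
#'
#' @param fit A `hill_fit`.
#' @param fraction Response fraction strictly between 0 and 1 (0.5 for EC50).
#' @return Dose in ng/mL.
#' @export
effective_concentration <- function(fit, fraction) {
  if (any(fraction <= 0 | fraction >= 1))
    stop("fraction must be strictly between 0 and 1")
  fit$K * (fraction / (1 - fraction))^(1 / fit$n)
}

#' Write a dose-response curve and Hill fit to disk
#'
#' @param curve A `dose_response_curve`.
#' @param fit Optional `hill_fit` for the same curve.
#' @param csv_path Curve CSV path (dose, response).
#' @param json_path Optional fit JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_dose_response <- function(curve, fit = NULL, csv_path,
                                json_path = NULL) {
  write.csv(data.frame(dose = curve$doses, response = curve$responses,
                       observable = curve$observable, variant = curve$variant),
            csv_path, row.names = FALSE)
  if (!is.null(fit) && !is.null(json_path))
    jsonlite::write_json(unclass(fit), json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(csv_path)
}
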