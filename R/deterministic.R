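#' Relax a network to its unstimulated steady state
#'
#' Integrates the dose-0 system until the largest relative rate of change
#' falls below `rate_tol`, so that nuclear-ERK fold changes can be normalized
#' to a true pre-stimulus steady state. The packaged model's nominal initial
#' counts are already at (or on the manifold of) this steady state, in which
#' case this returns almost immediately.
#'
#' @param network A `reaction_network`.
#' @param init Optional initial counts (defaults to the model file's values).
#' @param rate_tol Convergence threshold on max_i |dx_i/dt| / max(|x_i|, 1).
#' @param max_time Give up (with a warning) beyond this simulated time (s).
#' @param rtol,atol Integrator tolerances.
#' @return Named steady-state count vector (dose 0).
#' @export
equilibrate_network <- function(network, init = NULL, rate_tol = 1e-9,
                                max_time = 1e7, rtol = 1e-8, atol = 1e-6) {
  x <- initial_state(network, egf_dose = 0, base_counts = init)
  k <- network$reactions$rate_value
  relrate <- function(y) {
    d <- .cpp_deriv(y, k, network$r1, network$r2, network$S)
    max(abs(d) / pmax(abs(y), 1))
  }
  t_win <- 1e4
  total <- 0
  while (relrate(x) >= rate_tol && total < max_time) {
    sol <- deSolve::lsoda(y = x, times = c(0, t_win), func = .ode_rhs,
                          parms = network, rtol = rtol, atol = atol,
                          maxsteps = 50000)
    x <- pmax(sol[nrow(sol), -1], 0)
    names(x) <- network$species$id
    total <- total + t_win
    t_win <- t_win * 4
  }
  if (relrate(x) >= rate_tol)
    warning("pre-equilibration did not converge within max_time")
  x
}

.ode_rhs <- function(t, y, parms) {
  list(.cpp_deriv(y, parms$reactions$rate_value, parms$r1, parms$r2, parms$S))
}

#' Deterministic (ODE) simulation of an EGF-stimulated network
#'
#' Solves the mass-action ODE system with a stiff integrator (lsoda). The
#' system is pre-equilibrated at dose 0, EGF is applied at t = 0 and held
#' constant (no ligand depletion), and the solution is reported on a regular
#' output grid in molecule-count units.
#'
#' @param network A `reaction_network`.
#' @param egf_dose EGF concentration (ng/mL, >= 0).
#' @param t_end End time in seconds (default 3600, safely covering the
#'   transient peak of the packaged model).
#' @param dt Output grid spacing in seconds (default 10).
#' @param init Optional initial counts used as the pre-equilibration start.
#' @param pre_equilibrate If FALSE, `init` (or nominal counts) is used as-is.
#' @param rtol,atol Integrator tolerances.
#' @return A `trajectory`: list with `times`, `states` (time x species matrix,
#'   clipped at 0), `dose`, `engine = "ode"`, `seed = NA`.
#' @export
integrate_network <- function(network, egf_dose, t_end = 3600, dt = 10,
                              init = NULL, pre_equilibrate = TRUE,
                              rtol = 1e-8, atol = 1e-6) {
  if (egf_dose < 0) stop("egf_dose must be >= 0")
  x0 <- if (pre_equilibrate) {
    equilibrate_network(network, init = init, rtol = rtol, atol = atol)
  } else {
    initial_state(network, egf_dose = 0, base_counts = init)
  }
  x0 <- initial_state(network, egf_dose = egf_dose, base_counts = x0)
  times <- seq(0, t_end, by = dt)
  sol <- tryCatch(
    deSolve::lsoda(y = x0, times = times, func = .ode_rhs, parms = network,
                   rtol = rtol, atol = atol, maxsteps = 50000),
    error = function(e) stop("integrator failure at dose ", egf_dose,
                             " ng/mL: ", conditionMessage(e))
  )
  got <- nrow(sol)
  if (got < length(times))
    stop("integrator failure at dose ", egf_dose, " ng/mL: stopped at t = ",
         sol[got, 1], " s of ", t_end, " s")
  states <- pmax(sol[, -1, drop = FALSE], 0)
  colnames(states) <- network$species$id
  structure(list(times = times, states = states, dose = egf_dose,
                 engine = "ode", seed = NA_real_),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory (", x$engine, "): ", length(x$times), " time points, ",
      ncol(x$states), " species, EGF ", x$dose, " ng/mL\n", sep = "")
  invisible(x)
}

#' Observable time series from a trajectory
#'
#' `pERK` is the total of singly and doubly phosphorylated ERK including
#' complexes (molecule counts); `nERK` is the fold change in total nuclear
#' ERK (all phospho-forms and NPC-bound complexes) relative to its value at
#' t = 0, so `nERK(0) = 1` exactly.
#'
#' @param trajectory A `trajectory`.
#' @param network The network it was simulated from (supplies the observable
#'   weights annotated on the species table).
#' @param observable `"pERK"` or `"nERK"`.
#' @return Numeric series on the trajectory's time grid.
#' @export
observable_series <- function(trajectory, network,
                              observable = c("pERK", "nERK")) {
  observable <- match.arg(observable)
  w <- switch(observable, pERK = network$species$perk_weight,
              nERK = network$species$nerk_weight)
  if (all(w == 0))
    stop("observable ", observable, " undefined for this network (no ",
         "annotated ERK species)")
  v <- as.numeric(trajectory$states[, network$species$id, drop = FALSE] %*% w)
  if (observable == "nERK") {
    if (v[1] <= 0) stop("nERK undefined: no nuclear ERK at t = 0")
    v <- v / v[1]
  }
  v
}

#' Peak value of an observable over a trajectory
#'
#' @inheritParams observable_series
#' @return Maximum of the observable over the output grid. If the maximum
#'   falls on the final time point the transient may be truncated and a
#'   warning is raised.
#' @export
peak_response <- function(trajectory, network,
                          observable = c("pERK", "nERK")) {
  v <- observable_series(trajectory, network, observable)
  i <- which.max(v)
  if (i == length(v) && length(v) > 1 && v[i] > v[1])
    warning("observable is maximal at the final time point; transient may be truncated")
  v[i]
}

#' Write a trajectory to tidy and wide CSV
#'
#' @param trajectory A `trajectory`.
#' @param path Output CSV path (wide format: time, one column per species).
#' @param tidy If TRUE write long format (time, species, count) instead.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, tidy = FALSE) {
  if (tidy) {
    df <- data.frame(
      time = rep(trajectory$times, times = ncol(trajectory$states)),
      species = rep(colnames(trajectory$states), each = length(trajectory$times)),
      count = as.numeric(trajectory$states)
    )
  } else {
    df <- data.frame(time = trajectory$times, trajectory$states,
                     check.names = FALSE)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
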