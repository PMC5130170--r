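#' Generate a pseudo-experimental single-cell dataset from the kinetic model
#'
#' Emulates measured per-dose distributions of single-cell nuclear-ERK
#' fold changes: an extrinsic-noise ensemble at the truth protein CV is run
#' per dose with the kinetic model, and every cell's peak fold change is
#' multiplied by an independent Gaussian measurement factor
#' N(1, truth_ame_cv^2). Generating parameters and the seed are recorded so
#' parameter-recovery tests can close the loop. Intrinsic reaction noise can
#' optionally be added via SSA; it is off by default because its basal
#' contribution (~0.35% CV) is far below the measurement error it stands in
#' for (~4.4%).
#'
#' @param network A `reaction_network`.
#' @param truth_cv Protein-variability CV used to generate the data.
#' @param truth_ame_cv Measurement-error CV applied on top.
#' @param doses Dose set (ng/mL); default mirrors a low/transition/high
#'   design: 0, 0.01, 0.05, 0.1, 0.5, 50.
#' @param n_cells Cells per dose (default 1000).
#' @param seed Master seed.
#' @param covariation Covariation mode for the extrinsic sampling.
#' @param intrinsic If TRUE, use SSA per cell (slow at full counts).
#' @param t_end,dt Simulation horizon and grid (s).
#' @return A `synthetic_dataset`: `data` (data.frame dose, cell_id,
#'   fold_change) and `provenance` (all generating parameters).
#' @export
generate_pseudo_experiment <- function(network, truth_cv, truth_ame_cv,
                                       doses = c(0, 0.01, 0.05, 0.1, 0.5, 50),
                                       n_cells = 1000, seed = 1,
                                       covariation = "none",
                                       intrinsic = FALSE,
                                       t_end = 3600, dt = 10) {
  ame <- structure(list(cv_ame = truth_ame_cv), class = "ame_model")
  rows <- vector("list", length(doses))
  for (di in seq_along(doses)) {
    cfg <- noise_config(intrinsic = intrinsic, extrinsic_cv = truth_cv,
                        covariation = covariation, n_cells = n_cells,
                        master_seed = seed + 7000L * di)
    ens <- run_ensemble(network, doses[di], cfg, t_end = t_end, dt = dt)
    fc <- apply_ame(ens$peaks, ame, seed = .cpp_stream_seed(seed, 90000 + di))
    rows[[di]] <- data.frame(dose = doses[di],
                             cell_id = seq_along(fc), fold_change = fc)
  }
  structure(list(
    data = do.call(rbind, rows),
    provenance = list(generator = "kinetic", truth_cv = truth_cv,
                      truth_ame_cv = truth_ame_cv, doses = doses,
                      n_cells = n_cells, seed = seed,
                      covariation = covariation, intrinsic = intrinsic,
                      t_end = t_end, dt = dt, network = network$name)
  ), class = "synthetic_dataset")
}

#' Model-free surrogate single-cell dataset from a Hill response
#'
#' A fast fixture generator for testing the measurement-error and
#' mutual-information stages without the kinetic model: each cell responds
#' with a Hill curve whose half-max dose K is scaled by a per-cell log-normal
#' factor (CV = `basal_cv`, emulating extrinsic variability), then multiplied
#' by a Gaussian measurement factor. This is NOT the pathway mechanism; it is
#' a test fixture with the right statistical shape.
#'
#' @param hill_params List with `n`, `K`, `R_min`, `R_max`.
#' @param basal_cv Per-cell log-normal CV on K.
#' @param ame_cv Measurement-error CV.
#' @param doses Dose set (ng/mL).
#' @param n_cells Cells per dose.
#' @param seed Seed.
#' @return A `synthetic_dataset` (provenance marks generator = "surrogate").
#' @export
fast_surrogate_generator <- function(hill_params, basal_cv, ame_cv,
                                     doses = c(0, 0.01, 0.05, 0.1, 0.5, 50),
                                     n_cells = 1000, seed = 1) {
  stopifnot(hill_params$n > 0, hill_params$K > 0,
            hill_params$R_max >= hill_params$R_min)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  rows <- vector("list", length(doses))
  for (di in seq_along(doses)) {
    kcell <- if (basal_cv > 0) {
      sigma <- sqrt(log(1 + basal_cv^2))
      hill_params$K * exp(sigma * rnorm(n_cells) - sigma^2 / 2)
    } else rep(hill_params$K, n_cells)
    r <- .hill(doses[di], hill_params$R_min, hill_params$R_max, kcell,
               hill_params$n)
    if (ame_cv > 0) r <- r * rnorm(n_cells, 1, ame_cv)
    rows[[di]] <- data.frame(dose = doses[di], cell_id = seq_len(n_cells),
                             fold_change = pmax(r, 0))
  }
  structure(list(
    data = do.call(rbind, rows),
    provenance = list(generator = "surrogate", hill_params = hill_params,
                      basal_cv = basal_cv, ame_cv = ame_cv, doses = doses,
                      n_cells = n_cells, seed = seed)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset (", x$provenance$generator, "): ",
      nrow(x$data), " cells over ", length(unique(x$data$dose)),
      " doses\n", sep = "")
  invisible(x)
}

#' Write a single-cell dataset to CSV with a JSON provenance sidecar
#'
#' @param dataset A `synthetic_dataset`.
#' @param csv_path Output CSV (dose, cell_id, fold_change); the provenance
#'   sidecar is written next to it with extension `.json`.
#' @return `csv_path`, invisibly.
#' @export
write_dataset <- function(dataset, csv_path) {
  write.csv(dataset$data, csv_path, row.names = FALSE)
  jsonlite::write_json(dataset$provenance,
                       paste0(sub("\\.csv$", "", csv_path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Read a single-cell dataset written by [write_dataset()]
#'
#' Also the entry point for importing real single-cell fold-change tables in
#' the same (dose, cell_id, fold_change) layout.
#'
#' @param csv_path Dataset CSV path.
#' @return A `synthetic_dataset` (provenance empty if no sidecar is found).
#' @export
read_dataset <- function(csv_path) {
  data <- read.csv(csv_path)
  stopifnot(all(c("dose", "fold_change") %in% names(data)))
  side <- paste0(sub("\\.csv$", "", csv_path), ".json")
  prov <- if (file.exists(side)) jsonlite::fromJSON(side) else list()
  structure(list(data = data, provenance = prov), class = "synthetic_dataset")
}
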