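#' Plug-in mutual information of a discretized joint distribution
#'
#' I(R;S) = sum_S sum_R P(R,S) log2( P(R,S) / (P(R) P(S)) ), with
#' 0 log 0 := 0. Counts or probabilities are accepted; the table is
#' normalized internally.
#'
#' @param joint S x R matrix of counts (or probabilities), rows = signal
#'   (dose) levels, columns = response bins.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < 0)) stop("counts must be >= 0")
  tot <- sum(joint)
  if (tot <= 0) stop("empty joint table")
  p <- joint / tot
  ps <- rowSums(p); pr <- colSums(p)
  terms <- p * log2(p / outer(ps, pr))
  sum(terms[p > 0])
}

# plug-in MI of (dose label, response) pairs at a given response bin count
.binned_mi <- function(dose, response, n_bins, breaks = NULL) {
  if (is.null(breaks)) {
    rng <- range(response)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  bin <- findInterval(response, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mutual_information(table(factor(dose), factor(bin, levels = seq_len(n_bins))))
}

#' Debiased mutual information between EGF dose and nuclear-ERK response
#'
#' The plug-in estimator is biased upward on finite data, increasingly so at
#' finer response binning. This estimator (a documented stand-in honoring
#' bin-size optimization plus jackknife sampling) removes the leading O(1/n)
#' bias by subsample extrapolation: the plug-in MI is computed on the full
#' data and on random subsamples of 1/2 and 1/4 of the cells, a line is fit
#' in 1/n, and its intercept (1/n -> 0) is the debiased estimate at that bin
#' count. The reported MI is taken at the smallest response bin count whose
#' debiased estimate changes by less than 2% (with a 0.01-bit absolute floor
#' absorbing the subsampling noise of the extrapolation)
#' when the bin count is doubled; the result is clipped at 0.
#'
#' @param samples Data.frame with columns `dose` (signal label) and
#'   `fold_change` (response), >= 50 cells per dose; the dose marginal is
#'   taken uniform over the tested doses.
#' @param bin_counts Candidate response bin counts (doubling ladder).
#' @param n_rep Random subsamples per fraction.
#' @param seed Seed for the subsampling.
#' @return List: `mi` (bits), `bin_count`, and `profile` (per-bin-count
#'   debiased estimates).
#' @export
debiased_mi <- function(samples, bin_counts = c(2, 4, 8, 16, 32, 64, 128),
                        n_rep = 6, seed = 1) {
  dose <- samples$dose; response <- samples$fold_change
  per_dose <- table(dose)
  if (any(per_dose < 50))
    stop("need >= 50 samples per dose (min observed: ", min(per_dose), ")")
  n <- length(response)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))

  extrapolated <- vapply(bin_counts, function(B) {
    rng <- range(response)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = B + 1)
    inv_n <- c(); mi <- c()
    for (frac in c(1, 1 / 2, 1 / 4)) {
      reps <- if (frac == 1) 1 else n_rep
      for (r in seq_len(reps)) {
        idx <- if (frac == 1) seq_len(n) else {
          # stratified subsample: keep the dose marginal uniform
          unlist(lapply(split(seq_len(n), dose), function(ix)
            sample(ix, max(2, round(length(ix) * frac)))))
        }
        inv_n <- c(inv_n, 1 / length(idx))
        mi <- c(mi, .binned_mi(dose[idx], response[idx], B, breaks = breaks))
      }
    }
    unname(coef(stats::lm(mi ~ inv_n))[1])
  }, numeric(1))

  chosen <- length(bin_counts)
  for (i in seq_len(length(bin_counts) - 1)) {
    tol <- max(0.02 * abs(extrapolated[i]), 0.01)
    if (abs(extrapolated[i + 1] - extrapolated[i]) < tol) { chosen <- i; break }
  }
  list(mi = max(extrapolated[chosen], 0), bin_count = bin_counts[chosen],
       profile = data.frame(bin_count = bin_counts,
                            mi_extrapolated = extrapolated))
}
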