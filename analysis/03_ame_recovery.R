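#!/usr/bin/env Rscript
# Apparent Measurement Error (AME) estimation and protein-variability
# recovery on pseudo-experimental data: generates a synthetic single-cell
# dataset at a known truth (protein CV 25%, AME CV 4.4%), estimates the AME
# from the basal distributions, and recovers the protein CV by the RSS grid
# search over noisy simulations.
# Usage: Rscript analysis/03_ame_recovery.R [--smoke]
suppressPackageStartupMessages(library(erknoise))
smoke <- "--smoke" %in% commandArgs(TRUE)
out <- "results/03_ame_recovery"

res <- run_scenario("ame_recovery", config = list(seed = 3), out_dir = out,
                    smoke = smoke)
cat(sprintf("\nEstimated AME CV: %.3f%%\n", 100 * res$ame$cv_ame))
cat("RSS profile over candidate protein CVs:\n")
print(transform(res$recovery$rss, cv_pct = 100 * cv, rss = signif(rss, 4))[,
      c("cv_pct", "rss")], row.names = FALSE)
cat(sprintf("\nFindings: the RSS grid search recovers %.0f%% protein
variability (truth: 25%%). AME dominates the response CV at doses below the
transition and has little effect at saturating EGF.\n",
            100 * res$recovery$best_cv))
cat("Tables written under", out, "\n")
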