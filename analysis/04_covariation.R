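#!/usr/bin/env Rscript
# Covariation of protein abundances (shared expression capacity): compares
# nuclear-ERK heterogeneity when per-cell abundances are sampled
# independently vs fully covaried (one shared log-normal factor per cell).
# Usage: Rscript analysis/04_covariation.R [--smoke]
suppressPackageStartupMessages(library(erknoise))
smoke <- "--smoke" %in% commandArgs(TRUE)
out <- "results/04_covariation"

res <- run_scenario("covariation",
                    config = list(seed = 4, doses = c(0, 50),
                                  n_cells = if (smoke) 20 else 120, cv = 0.25),
                    out_dir = out, smoke = smoke)
tab <- res$covariation
cat("\nCV of peak nERK fold change (%):\n")
print(transform(tab, cv_pct = round(100 * cv, 3))[, c("covariation", "dose", "cv_pct")],
      row.names = FALSE)
cat("\nFindings: at dose 0 the fold-change distribution is unaffected by
covariation (normalization to each cell's own steady state cancels shared
scaling), while at saturating EGF covariation suppresses heterogeneity:
kinase and phosphatase abundances rise and fall together, preserving the
balance that sets the peak response.\n")
cat("Tables written under", out, "\n")
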