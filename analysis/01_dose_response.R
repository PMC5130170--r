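#!/usr/bin/env Rscript
# Deterministic validation of the EGF->ERK->NPC model: time courses across
# doses, peak dose-response curves for pERK (total phospho-ERK) and nERK
# (nuclear-ERK fold change), Hill fits, and the NPC-regulation knockout that
# converts the switch-like nERK response back to the graded pERK shape.
# Usage: Rscript analysis/01_dose_response.R [--smoke]
suppressPackageStartupMessages(library(erknoise))
smoke <- "--smoke" %in% commandArgs(TRUE)
out <- "results/01_dose_response"

run_scenario("timecourse", config = list(seed = 1), out_dir = out,
             smoke = smoke)
res <- run_scenario("knockout", config = list(seed = 1), out_dir = out,
                    smoke = smoke)

f <- res$fits
cat("\nHill fits (peak responses, deterministic engine):\n")
for (nm in names(f))
  cat(sprintf("  %-16s n = %5.2f  K = %6.3f ng/mL  EC10 = %6.3f  EC90 = %6.3f\n",
              nm, f[[nm]]$n, f[[nm]]$K, f[[nm]]$EC10, f[[nm]]$EC90))
cat("\nFindings: pERK responds gradedly while nERK is switch-like",
    "(higher Hill n, narrow EC10-EC90 window); zeroing the ERK-mediated",
    "NPC-phosphorylation block (reactions 137-144) removes the negative",
    "autoregulation of nuclear ERK, raising the nERK EC90 several-fold and",
    "equalizing its Hill coefficient with pERK's.\n")
cat("Tables written under", out, "\n")
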