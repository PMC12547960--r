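#!/usr/bin/env Rscript

# Optional real-data reproduction on the Changing Cost of Living Study
# (CCLS) version 3 public deposit.  The deposit is NOT bundled with this
# package and this script is not part of the automated test suite: it
# requires a network download and a manual mapping step.
#
# 1. Download the CCLS v3 monthly data and codebook (publicly deposited
#    on OSF) and export the monthly reports to CSV.
# 2. Map the deposit's columns to the panel dialect this package reads:
#    person_id,country,month_index,income,currency,srh,gad7,phq8,age,gender
#    (incomes in the currency reported; currency column "GBP" or "EUR";
#    gender collapsed to woman/man/other).
# 3. Run:  Rscript scripts/reproduce_ccls.R path/to/ccls_panel.csv out_dir
#
# The full pipeline then reproduces the person-level coefficient tables,
# the concavity decomposition and its ratios, the multilevel volatility
# coefficients, and the zero-volatility counterfactual summaries
# (Hedges' g and GAD-7/PHQ-8 clinical-cutoff prevalences).

suppressPackageStartupMessages(library(volhealth))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: Rscript scripts/reproduce_ccls.R <panel.csv> [out_dir]")
}
panel <- read_panel(args[1], gbp_to_eur = 1.15)
out_dir <- if (length(args) >= 2) args[2] else "results/ccls"

report <- run_full_analysis(panel = panel, seed = 1, boot = 5000,
                            output_dir = out_dir)
print(report)
cat("\nStage outputs written to", out_dir, "\n")
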