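#!/usr/bin/env Rscript

# Optional validation against the source studies' supplementary compilations
# (not distributable with the package). Given rate tables in the package CSV
# schema — and optionally a metabolic table — this driver recomputes the
# published full-data statistics: per-group regressions with both dependent
# variables, hull-membership and nearest-line overlap matrices, the
# delta-AICc model-selection grid, the pairwise growth/metabolism R2 values,
# and the proportionality-test factor ranges.
#
# Usage:
#   Rscript scripts/validate-external.R --rates <rates.csv> \
#     [--metabolic <metabolic.csv>] [--dependent kC|kD] \
#     [--independent M|BMatMG] [--out <dir>]
#
# Expected rate-table columns: taxon, group, thermo, M_g, BMatMG_g,
# Gmax_g_per_day, kC_per_day, kD_per_day, weight, excluded (+ optional
# model). Expected metabolic columns: taxon, group, thermo, BMR_W, M_met_g,
# M_g, Gmax_g_per_day, kC_per_day.

suppressPackageStartupMessages({
  library(optparse)
  library(allomax)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--rates", type = "character"),
  make_option("--metabolic", type = "character", default = NULL),
  make_option("--dependent", type = "character", default = "kC"),
  make_option("--independent", type = "character", default = "M"),
  make_option("--out", type = "character", default = "results/validation"),
  make_option("--seed", type = "integer", default = 1L)
)))

if (is.null(opts$rates)) {
  stop("--rates is required (CSV in the package rate-table schema)")
}

rates <- read_rate_table(opts$rates)
metabolic <- if (!is.null(opts$metabolic)) read_metabolic(opts$metabolic) else NULL

bundle <- run_pipeline(
  rates,
  metabolic = metabolic,
  dependent = opts$dependent,
  independent = opts$independent,
  seed = opts$seed
)

write_report_bundle(bundle, opts$out)

cat("== per-group regressions ==\n")
print(bundle$regression_report, n = Inf)
cat("\n== hull membership (points in rows, hulls in columns) ==\n")
print(bundle$hulls$counts)
cat("\n== nearest-line classification ==\n")
print(bundle$nearest_line$counts)
cat("\n== delta-AICc model selection ==\n")
print(selection_wide(bundle$selection), n = Inf)
if (!is.null(bundle$metabolic)) {
  cat("\n== growth-metabolism tests ==\n")
  print(bundle$metabolic$transitivity)
  print(bundle$metabolic$direct)
  print(bundle$metabolic$direct_adjusted)
}
cat("\nfull reports written to", opts$out, "\n")
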