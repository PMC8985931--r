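#!/usr/bin/env Rscript

# Nonparametric group comparisons over the simulated herding results:
# Kruskal-Wallis omnibus tests with Dunn post-hoc pairwise z tests and
# bootstrap 95% confidence intervals of the medians, along the study's
# comparison axes (design label, fractal vs Euclidean, low vs high glial
# regime). Writes results/stats_*.csv.

suppressPackageStartupMessages(library(fractalherd))

res_file <- "results/herding_results.csv"
if (!file.exists(res_file)) {
  stop("run analysis/04_quantify_herding.R first", call. = FALSE)
}
rows <- read.csv(res_file)

report <- function(gc, file) {
  write.csv(gc$summary, file.path("results", paste0(file, "_medians.csv")),
            row.names = FALSE)
  if (!is.null(gc$dunn)) {
    write.csv(gc$dunn, file.path("results", paste0(file, "_dunn.csv")),
              row.names = FALSE)
  }
  print(gc)
  cat("\n")
}

cat("== G_Si by fractal design ==\n")
report(summarize_study(rows[rows$type == "fractal", ], "label", "G_Si"),
       "gsi_by_design")

cat("== N_Si by fractal design ==\n")
report(summarize_study(rows[rows$type == "fractal", ], "label", "N_Si"),
       "nsi_by_design")

cat("== Combined herding GN: fractal vs Euclidean ==\n")
report(summarize_study(rows, "type", "GN"), "gn_by_type")

rows$regime <- as.character(regime_split(rows$G))
cat("== G_CNT: low vs high glial regime ==\n")
report(summarize_study(rows, "regime", "G_CNT"), "gcnt_by_regime")
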