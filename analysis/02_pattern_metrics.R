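#!/usr/bin/env Rscript

# Map out how the geometric descriptors vary with the fractal dimension D
# and the number of repeating levels m, and along the simulated wide-gap
# Euclidean series. Proximity is measured on 2.5 um/px rasters via the
# exact Euclidean distance transform. Writes results/metric_trends.csv and
# results/euclidean_series.csv.

suppressPackageStartupMessages(library(fractalherd))
dir.create("results", showWarnings = FALSE)

trend <- NULL
for (m in c(4, 5, 6)) {
  for (D in seq(1.1, 2.0, by = 0.1)) {
    d <- fractal_design(D = D, m = m, w_cnt = 20, W = 6262)
    tr <- tryCatch(build_htree(d), error = function(e) NULL)
    if (is.null(tr)) next   # overlapping branch combinations are excluded
    cf <- closed_form_metrics(d)
    mk <- rasterize(tr, 2.5)
    trend <- rbind(trend, data.frame(
      D = D, m = m, E_n = cf$E_n, T = cf$T,
      P = mean_proximity(mk),
      A_r = cf$A_r, A_c_closed = cf$A_c,
      A_c_raster = connected_gap_area(mk)))
  }
  cat("finished m =", m, "\n")
}
write.csv(trend, "results/metric_trends.csv", row.names = FALSE)

ser <- euclidean_sim_series()
eu <- do.call(rbind, lapply(ser, function(d) {
  mk <- rasterize(build_euclidean(d), 2.5)
  data.frame(w_si = d$w_si, P = mean_proximity(mk),
             A_c = closed_form_metrics(d)$A_c)
}))
write.csv(eu, "results/euclidean_series.csv", row.names = FALSE)

cat("\nAt m = 4, raising D from 1.1 to 2.0 increases the normalized edge\n")
cat(sprintf("length %.1f -> %.1f, tortuosity %.2f -> %.2f and proximity %.4f -> %.4f 1/um,\n",
            trend$E_n[trend$m == 4][1], tail(trend$E_n[trend$m == 4], 1),
            trend$T[trend$m == 4][1], tail(trend$T[trend$m == 4], 1),
            trend$P[trend$m == 4][1], tail(trend$P[trend$m == 4], 1)))
cat("while the gap ratio A_r falls; at D = 2, adding repeating levels\n")
cat("shrinks the largest connected gap area:\n")
print(subset(trend, D == 2, c(m, A_c_closed, A_c_raster)), row.names = FALSE)
cat("\nAcross the simulated Euclidean series, widening the gap from 200 to\n")
cat(sprintf("1100 um lowers mean proximity from %.4f to %.4f 1/um while the\n",
            eu$P[1], tail(eu$P, 1)))
cat("connected gap area grows to match the most open fractal design.\n")
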