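signif_eq <- function(x, printed, digits) {
  expect_equal(signif(x, digits), printed)
}

test_that("closed forms reproduce the published geometry tables", {
  fd <- fractal_designs()
  m <- lapply(fd, closed_form_metrics)
  # minimum characteristic gap widths, um (one decimal / nearest um)
  expect_equal(round(m[["1.1-4"]]$W_Si_min, 1), 56.4)
  expect_equal(round(m[["1.5-4"]]$W_Si_min, 1), 101.0)
  expect_equal(round(m[["2-5"]]$W_Si_min, 1), 61.2)
  expect_equal(round(m[["2-6"]]$W_Si_min), 25)
  # branch areas at two significant figures
  signif_eq(m[["1.1-4"]]$A_CNT, 8e5, 1)
  signif_eq(m[["1.5-4"]]$A_CNT, 1.5e6, 2)
  signif_eq(m[["2-5"]]$A_CNT, 4.6e6, 2)
  signif_eq(m[["2-6"]]$A_CNT, 8.8e6, 2)
  # bounding areas and maximum gap widths
  signif_eq(m[["1.5-4"]]$A_bounding, 2.3e7, 2)
  signif_eq(m[["1.5-4"]]$W_Si_max, 3.7e3, 2)
  signif_eq(m[["2-6"]]$W_Si_max, 3.2e3, 2)

  ed <- lapply(euclidean_designs(), closed_form_metrics)
  printed <- list(
    S100C100 = c(1.8e7, 1.7e7, 3.5e7), S75C100 = c(2.0e7, 1.5e7, 3.5e7),
    S50C100 = c(2.4e7, 1.2e7, 3.6e7), S25C100 = c(2.9e7, 7.0e6, 3.6e7),
    S75C75 = c(1.8e7, 1.8e7, 3.6e7), S50C50 = c(1.8e7, 1.8e7, 3.6e7),
    S25C25 = c(1.8e7, 1.8e7, 3.6e7))
  for (nm in names(printed)) {
    signif_eq(ed[[nm]]$A_CNT, printed[[nm]][1], 2)
    signif_eq(ed[[nm]]$A_Si, printed[[nm]][2], 2)
    signif_eq(ed[[nm]]$A_bounding, printed[[nm]][3], 2)
  }
})

test_that("area conservation and limits hold in the closed forms", {
  for (d in c(fractal_designs(), euclidean_designs())) {
    m <- closed_form_metrics(d)
    expect_equal(m$A_CNT + m$A_Si, m$A_bounding)
    expect_equal(m$E_n, m$E / d$W)
    expect_gte(m$T, 1)
    expect_gte(m$A_r, 1)
    expect_gt(m$A_c, 0)
    expect_lte(m$A_c, m$A_Si)
  }
  # zero-width limit: L_b -> 2 L0 + 4 L1 and A_CNT -> 0 for one H
  d0 <- fractal_design(D = 2, m = 1, w_cnt = 1e-6, W = 2000)
  m0 <- closed_form_metrics(d0)
  expect_equal(m0$L_b, 2 * d0$L0 + 4 * d0$L0 / sqrt(2), tolerance = 1e-6)
  expect_lt(m0$A_CNT, 1)
})

test_that("tortuosity matches analytic values and endpoint enumeration", {
  expect_equal(tortuosity(tiny_rows()), 1)
  tr1 <- build_htree(fractal_design(D = 2, m = 1, w_cnt = 20, W = 2020))
  expect_equal(tortuosity(tr1), (1 + 2^(-1 / 2)) / sqrt(1 + 1 / 2),
               tolerance = 1e-12)
  # brute-force mean over all 256 endpoints of the built tree equals the
  # sign-enumeration closed form
  d <- fractal_designs()[["1.1-4"]]
  tr <- build_htree(d)
  expect_equal(sum(tr$segments$order == d$N), 256)
  expect_equal(tortuosity(tr), closed_form_metrics(d)$T, tolerance = 1e-9)
})

test_that("proximity maps are reciprocal distance transforms", {
  # gap strip of width 4 px between two branch faces:
  # per-pixel distances 1,2,2,1 -> mean reciprocal 0.75 (at 1 um/px)
  cnt <- matrix(TRUE, 8, 8)
  cnt[, 3:6] <- FALSE
  mk <- manual_mask(cnt)
  pm <- proximity_map(mk)
  expect_equal(unname(pm$values[1, 3:6]), c(1, 1 / 2, 1 / 2, 1))
  expect_equal(mean_proximity(pm), 0.75)
  expect_true(all(is.na(pm$values[cnt])))
  # resolution scales the units: value of an adjacent gap pixel is 1/res
  mk2 <- manual_mask(cnt, res = 2)
  expect_equal(unname(proximity_map(mk2)$values[1, 3]), 0.5)
  # degenerate masks
  expect_error(proximity_map(manual_mask(matrix(TRUE, 4, 4))), "gap")
  expect_error(proximity_map(manual_mask(matrix(FALSE, 4, 4))), "branch")
})

test_that("connected gap area uses 4-connectivity", {
  # each row gap is its own component of area W x w_si
  d <- euclidean_design(10, 10, W = 100)
  mk <- rasterize(build_euclidean(d), 1)
  expect_equal(connected_gap_area(mk), 100 * 10)
  # checkerboard of isolated 1-px gaps: diagonal touching does not connect
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2 == 0)
  expect_equal(connected_gap_area(manual_mask(cb, res = 2)), 4)
})

test_that("gap rectangle search agrees with the closed forms", {
  # single empty rectangle
  cnt <- matrix(TRUE, 10, 12)
  cnt[3:7, 4:9] <- FALSE
  gr <- gap_rectangles(manual_mask(cnt))
  expect_equal(gr$A_max, 5 * 6)
  # Euclidean rows are single-scaled
  d <- euclidean_design(10, 10, W = 100)
  expect_equal(closed_form_metrics(d)$A_r, 1)
  gr2 <- gap_rectangles(rasterize(build_euclidean(d), 1), d)
  expect_equal(gr2$A_r, 1, tolerance = 0.02)
  # raster maximal-empty-rectangle vs the analytic largest gap rectangle
  d3 <- fractal_designs()[["1.5-4"]]
  gr3 <- gap_rectangles(rasterize(build_htree(d3), 2), d3)
  expect_equal(gr3$A_max, closed_form_metrics(d3)$A_max, tolerance = 0.02)
})

test_that("characteristic and global gap widths are consistent", {
  fd <- fractal_designs()
  for (nm in c("1.1-4", "2-6")) {
    tr <- build_htree(fd[[nm]])
    expect_equal(min_gap_width(tr), closed_form_metrics(fd[[nm]])$W_Si_min)
    expect_equal(max_gap_width(tr), 2 * fd[[nm]]$L0 - 20)
  }
  # the labelled finest gap is a realized face-to-face clearance, so the
  # global minimum clearance cannot exceed it
  tr <- tiny_htree(D = 1.8, m = 3, w = 4, W = 200)
  expect_gt(min_clearance(tr), 0)
  expect_lte(min_clearance(tr), min_gap_width(tr) + 1e-9)
})

test_that("raster edge length and areas match vector values", {
  # solid block: perimeter 2(r + c)
  cnt <- matrix(FALSE, 30, 40)
  cnt[6:15, 11:30] <- TRUE
  expect_equal(edge_length_raster(manual_mask(cnt)), 2 * (10 + 20))
  ar <- area_raster(manual_mask(cnt))
  expect_equal(ar$A_CNT, 200)
  expect_equal(ar$A_CNT + ar$A_Si, ar$A_bounding)
  # fractal design at 2 um/px: raster within 1% of closed form
  d <- fractal_designs()[["1.5-4"]]
  mk <- rasterize(build_htree(d), 2)
  cfm <- closed_form_metrics(d)
  expect_equal(edge_length_raster(mk), cfm$E, tolerance = 0.01)
  expect_equal(area_raster(mk)$A_CNT, cfm$A_CNT, tolerance = 0.01)
})

test_that("simulated wide-gap Euclidean series is as specified", {
  ser <- euclidean_sim_series()
  expect_length(ser, 10)
  expect_equal(vapply(ser, function(d) d$w_si, 0), seq(200, 1100, 100))
  for (d in ser[c(1, 10)]) {
    expect_equal(closed_form_metrics(d)$A_c, 6000 * d$w_si)
  }
})
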