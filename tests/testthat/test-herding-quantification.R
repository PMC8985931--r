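test_that("stitching reassembles tiles at the fixed grid", {
  manifest <- list(tile = 20, overlap = 0.1, stride = 18,
                   grid = c(rows = 3, cols = 2),
                   full_dim = c(ny = 2 * 18 + 20, nx = 18 + 20),
                   excluded = list())
  tiles <- list()
  for (i in 1:3) for (j in 1:2) {
    tiles[[length(tiles) + 1]] <- list(neuron = matrix(5, 20, 20),
                                       row = i, col = j)
  }
  out <- stitch_tiles(tiles, manifest)
  expect_equal(dim(out), c(56, 38))
  expect_true(all(out == 5))  # averaging constant tiles is idempotent
  # missing tiles are reported by index
  expect_error(stitch_tiles(tiles[-2], manifest), "1 2")
})

test_that("stitching a rendered tile set recovers the full field", {
  cnt <- matrix(FALSE, 100, 140)
  cnt[40:60, ] <- TRUE
  mk <- manual_mask(cnt, res = 1)
  sc <- manual_scene(mk, processes = list(cbind(c(10, 130), c(30, 80))))
  full <- render_channels(sc, pixel_size = 1, noise = FALSE)
  ft <- render_fov_tiles(sc, pixel_size = 1, tile = 50, overlap = 0.1,
                         noise = FALSE)
  st <- stitch_tiles(ft$tiles, ft$manifest)
  expect_equal(st[1:100, 1:140], full$neuron, tolerance = 1e-12)
})

test_that("mask alignment resamples labels and adjusts edges", {
  d <- euclidean_design(100, 60, W = 420)   # 3 rows; middle row interior
  mk <- rasterize(build_euclidean(d), 1)
  # identity resampling preserves label counts
  am <- align_mask(mk, dim(mk$cnt), 1)
  expect_identical(am$cnt, mk$cnt)
  # dilation by 1 px widens the interior 100 px row to 102 px
  am2 <- align_mask(mk, dim(mk$cnt), 1, edge_adjust_px = 1)
  expect_equal(max(rle(am2$cnt[, 10])$lengths[rle(am2$cnt[, 10])$values]), 102)
  # resampling to a different grid preserves area within 0.5%
  d2 <- fractal_designs()[["1.5-4"]]
  mk2 <- rasterize(build_htree(d2), 4)
  am3 <- align_mask(mk2, round(dim(mk2$cnt) * 4 / 1.5), 1.5)
  expect_equal(area_raster(am3)$A_CNT, closed_form_metrics(d2)$A_CNT,
               tolerance = 0.005)
  # incompatible extents are refused
  expect_error(align_mask(mk, c(10, 10), 1), "extents")
})

test_that("process measurement handles blanks, bundles and somas", {
  cnt <- matrix(FALSE, 220, 600)
  mk <- manual_mask(cnt, res = 1)
  # blank channel
  blank <- matrix(0, 220, 600)
  mp0 <- measure_process_length(blank, mk)
  expect_equal(mp0$cnt_um, 0)
  expect_equal(mp0$gap_um, 0)
  # noise-free straight 500 um line fully in gap
  sc <- manual_scene(mk, processes = list(cbind(c(40, 540), c(100, 100))))
  ch <- render_channels(sc, pixel_size = 1, noise = FALSE)
  mp1 <- measure_process_length(ch$neuron, mk)
  expect_equal(mp1$gap_um, 500, tolerance = 0.02)
  expect_equal(mp1$cnt_um, 0)
  # two coincident polylines collapse onto one skeleton: counted once
  sc2 <- manual_scene(mk, processes = list(cbind(c(40, 540), c(100, 100)),
                                           cbind(c(40, 540), c(100, 100))))
  ch2 <- render_channels(sc2, pixel_size = 1, noise = FALSE)
  mp2 <- measure_process_length(ch2$neuron, mk)
  expect_equal(mp2$gap_um, 500, tolerance = 0.02)
  # an isolated soma blob contributes no process length
  gl <- data.frame(x = 300, y = 60, r = 8, on_cnt = FALSE)
  sc3 <- manual_scene(mk, processes = list(cbind(c(40, 540), c(100, 100))))
  sc3$clusters <- data.frame(x = 300, y = 60, n = 5, id = 1, r = 12)
  ch3 <- render_channels(sc3, pixel_size = 1, noise = FALSE)
  mp3 <- measure_process_length(ch3$neuron, mk)
  expect_equal(mp3$gap_um, 500, tolerance = 0.03)
})

test_that("glial area measurement recovers rendered coverage", {
  cnt <- matrix(FALSE, 200, 200)
  cnt[1:30, ] <- TRUE
  mk <- manual_mask(cnt, res = 1)
  # a glial region of ~10^4 um^2 in the gap, noise-free
  r <- sqrt(1e4 / pi)
  gl <- data.frame(x = 100, y = 120, r = r, on_cnt = FALSE)
  sc <- manual_scene(mk, glia = gl)
  ch <- render_channels(sc, pixel_size = 1, noise = FALSE)
  mg <- measure_glial_area(ch$glia, mk)
  expect_equal(mg$gap_um2, 1e4, tolerance = 0.03)
  expect_equal(mg$cnt_um2, 0, tolerance = 0.03)
  # blank channel -> zeros; constant non-zero channel -> threshold failure
  expect_equal(measure_glial_area(matrix(0, 200, 200), mk)$gap_um2, 0)
  expect_error(measure_glial_area(matrix(7, 200, 200), mk), "threshold")
  # full gap coverage normalizes to G_Si = 1
  full <- matrix(0, 200, 200); full[!cnt] <- 2000
  mgf <- measure_glial_area(full, mk, threshold = 1000, open_px = 1)
  ar <- area_raster(mk)
  hi <- herding_indices(0, 0, mgf$cnt_um2, mgf$gap_um2, ar$A_CNT, ar$A_Si)
  expect_equal(hi$G_Si, 1)
  expect_equal(hi$G, 1)
})

test_that("herding indices follow their defining ratios", {
  h <- herding_indices(100, 100, 10, 10, 1e4, 1e4)
  expect_equal(h$N, 0.5)   # symmetric densities
  expect_equal(h$G, 0.5)
  h2 <- herding_indices(200, 100, 0, 50, 1e4, 1e4)
  expect_equal(h2$N, 2 / 3)
  expect_equal(h2$G, 1)    # no glia on the branches
  h3 <- herding_indices(200, 100, 10, 90, 1e4, 1e4)
  expect_equal(h3$GN, h3$G * h3$N)
  expect_equal(herding_indices(100, 0, 0, 0, 1e4, 1e4)$N, 1)
  # degenerate: both numerators zero -> flagged NA, not NaN
  h4 <- herding_indices(0, 0, 0, 0, 1e4, 1e4)
  expect_true(is.na(h4$N) && is.na(h4$G))
  expect_length(attr(h4, "flags"), 2)
  expect_error(herding_indices(1, 1, 1, 1, 0, 1e4), "positive")
  # a worked example: N_CNT = 2 N_Si and G = 0.9 -> GN = 0.6
  h5 <- herding_indices(200, 100, 100 / 9, 100, 1e4, 1e4)
  expect_equal(h5$N, 2 / 3)
  expect_equal(h5$G, 0.9)
  expect_equal(h5$GN, 0.6)
})

test_that("profile sums localize glia in gaps and processes at edges", {
  # rows at known positions with edge-following processes and gap glia
  d <- suppressWarnings(euclidean_design(w_cnt = 40, w_si = 40, W = 400))
  tr <- build_euclidean(d)
  mk <- rasterize(tr, 1, keep_ids = TRUE)
  yc <- tr$segments$y0
  procs <- list()
  for (y in yc) {
    procs[[length(procs) + 1]] <- cbind(c(-180, 180), c(y + 19, y + 19))
    procs[[length(procs) + 1]] <- cbind(c(-180, 180), c(y - 19, y - 19))
  }
  gl <- data.frame(x = c(-100, 50, 150), y = rep(yc[1] + 40, 3), r = 15,
                   on_cnt = FALSE)
  sc <- manual_scene(mk, processes = procs, glia = gl)
  ch <- render_channels(sc, pixel_size = 1, noise = FALSE)
  mp <- measure_process_length(ch$neuron, mk)
  mg <- measure_glial_area(ch$glia, mk)
  pr <- profile_sums(mp, mg, mk, axis = "y")
  edges <- attr(pr, "edges")
  expect_gt(length(edges), 0)
  # the strongest process positions coincide with electrode edges (+-2 px)
  top <- pr$pos[order(-pr$N_l)][1:4]
  expect_true(all(vapply(top, function(p) min(abs(p - edges)) <= 2, TRUE)))
  # glial coverage peaks inside a gap
  gpos <- pr$pos[which.max(pr$G_a)]
  iy <- ceiling((gpos - mk$origin[["y"]]) / mk$res)
  expect_false(any(mk$cnt[iy, ]))
  # blank images give zero curves
  pr0 <- profile_sums(measure_process_length(matrix(0, nrow(mk$cnt), ncol(mk$cnt)), mk),
                      measure_glial_area(matrix(0, nrow(mk$cnt), ncol(mk$cnt)), mk),
                      mk)
  expect_true(all(pr0$G_a == 0) && all(pr0$N_l == 0))
})

test_that("regime split is inclusive-low at the threshold", {
  expect_equal(as.character(regime_split(c(0.95, 0.96, 0, 1))),
               c("low", "high", "low", "high"))
  expect_equal(as.character(regime_split(0.9, G_T = 0.8)), "high")
})

test_that("quantification is robust to a doubled image resolution", {
  d <- euclidean_designs()[["S50C50"]]
  ws <- window_scene(d, seed = 8, window = 600)
  ch1 <- render_channels(ws$scene, pixel_size = 1.5, noise = FALSE)
  r1 <- quantify_scene(ch1, ws$mask)
  ch2 <- render_channels(ws$scene, pixel_size = 0.75, noise = FALSE)
  r2 <- quantify_scene(ch2, ws$mask)
  expect_equal(r2$N_CNT, r1$N_CNT, tolerance = 0.02)
  expect_equal(r2$N_Si, r1$N_Si, tolerance = 0.02)
  expect_equal(r2$G_Si, r1$G_Si, tolerance = 0.02)
})
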