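test_that("seeding is homogeneous Poisson at the culture density", {
  # 1 mm^2 field at the study density
  d <- euclidean_design(100, 100, W = 2000)
  mk <- crop_mask(rasterize(build_euclidean(d), 2, keep_ids = TRUE), 1000)
  p <- culture_params(rng_seed = 42)
  sc <- seed_cells(mk, p)
  expect_lt(abs(nrow(sc$somas) - 9300), 3 * sqrt(9300))
  expect_true(all(sc$somas$x >= -500 & sc$somas$x <= 500))
  # neuron fraction
  expect_equal(mean(sc$somas$kind == "neuron"), 0.7, tolerance = 0.05)
  # zero density -> empty scene
  sc0 <- seed_cells(mk, culture_params(seed_density = 0, rng_seed = 1))
  expect_equal(nrow(sc0$somas), 0)
})

test_that("scene generation is deterministic under the seed", {
  d <- euclidean_designs()[["S50C50"]]
  ws1 <- window_scene(d, seed = 5, window = 600)
  ws2 <- window_scene(d, seed = 5, window = 600)
  expect_identical(ws1$scene$somas, ws2$scene$somas)
  expect_identical(ws1$scene$processes, ws2$scene$processes)
  expect_identical(ws1$scene$glial_regions, ws2$scene$glial_regions)
  ch1 <- render_channels(ws1$scene, pixel_size = 1.5)
  ch2 <- render_channels(ws2$scene, pixel_size = 1.5)
  expect_identical(ch1$neuron, ch2$neuron)
  # a different seed gives a different culture
  ws3 <- window_scene(d, seed = 6, window = 600)
  expect_false(identical(ws1$scene$somas, ws3$scene$somas))
})

test_that("ground truth splits are exact partitions", {
  d <- euclidean_designs()[["S75C75"]]
  ws <- window_scene(d, seed = 3, window = 800)
  sc <- ws$scene; mk <- ws$mask
  gt <- sc$ground_truth
  total <- sum(vapply(sc$processes, function(q)
    sum(sqrt(diff(q[, 1])^2 + diff(q[, 2])^2)), 0))
  expect_equal(gt$N_CNT * gt$A_CNT + gt$N_Si * gt$A_Si, total,
               tolerance = 1e-9)
  # independent clipping oracle: dense sampling of each polyline
  len_cnt <- 0; len_gap <- 0
  for (q in sc$processes) {
    for (i in seq_len(nrow(q) - 1)) {
      L <- sqrt(sum((q[i + 1, ] - q[i, ])^2))
      if (L == 0) next
      n <- max(2, ceiling(L / 0.05))
      t <- (seq_len(n) - 0.5) / n
      xs <- q[i, 1] + t * (q[i + 1, 1] - q[i, 1])
      ys <- q[i, 2] + t * (q[i + 1, 2] - q[i, 2])
      on <- fractalherd:::mask_label_at(mk, xs, ys)
      len_cnt <- len_cnt + sum(on) * L / n
      len_gap <- len_gap + sum(!on) * L / n
    }
  }
  expect_equal(gt$N_CNT * gt$A_CNT, len_cnt, tolerance = 0.005)
  expect_equal(gt$N_Si * gt$A_Si, len_gap, tolerance = 0.005)
  # every process vertex lies inside the field
  b <- sc$bounds
  for (q in sc$processes) {
    expect_true(all(q[, 1] >= b["xmin"] & q[, 1] <= b["xmax"] &
                      q[, 2] >= b["ymin"] & q[, 2] <= b["ymax"]))
  }
})

test_that("glial coverage toggles and confinement behave as modelled", {
  d <- fractal_designs()[["1.5-4"]]
  tr <- build_pattern(d)
  mk <- crop_mask(rasterize(tr, 1.5, keep_ids = TRUE), 800)
  p0 <- culture_params(glia_coverage_scale = 0, rng_seed = 2)
  sc0 <- simulate_development(seed_cells(mk, p0), mk, tr)
  expect_equal(sc0$ground_truth$G_CNT, 0)
  expect_equal(sc0$ground_truth$G_Si, 0)
  # default: glia herded into the gaps
  p1 <- culture_params(rng_seed = 2)
  sc1 <- simulate_development(seed_cells(mk, p1), mk, tr)
  expect_gt(sc1$ground_truth$G_Si, sc1$ground_truth$G_CNT)
  expect_gt(sc1$ground_truth$G, 0.8)
})

test_that("gap glia form boundary coverage near branches and deserts far away", {
  d <- fractal_designs()[["1.1-4"]]
  ws <- window_scene(d, seed = 4, window = 1200)
  sc <- ws$scene; mk <- ws$mask
  gimg <- fractalherd:::glia_coverage(sc$glial_regions, mk)
  dmap <- EBImage::imageData(EBImage::distmap(1 - mk$cnt * 1L)) * mk$res
  near <- !mk$cnt & dmap > 0 & dmap <= 100
  far <- !mk$cnt & dmap > 200
  expect_gt(sum(far), 0)
  expect_gt(mean(gimg[near]), mean(gimg[far]))
})

test_that("rendered process geometry survives re-measurement", {
  cnt <- matrix(FALSE, 200, 200)
  cnt[1:40, ] <- TRUE   # a branch band at the bottom
  mk <- manual_mask(cnt, res = 1, origin = c(x = 0, y = 0))
  # noise-free straight 100 um process entirely in the gap
  sc <- manual_scene(mk, processes = list(cbind(c(50, 150), c(120, 120))))
  ch <- render_channels(sc, pixel_size = 1, noise = FALSE)
  mp <- measure_process_length(ch$neuron, mk)
  expect_equal(mp$gap_um, 100, tolerance = 0.02)
  expect_equal(mp$cnt_um, 0, tolerance = 0.02)
})

test_that("field-of-view tiling covers the scene with the stated overlap", {
  cnt <- matrix(FALSE, 120, 160)
  mk <- manual_mask(cnt, res = 1)
  sc <- manual_scene(mk, processes = list(cbind(c(10, 150), c(60, 60))))
  ft <- render_fov_tiles(sc, pixel_size = 1, tile = 64, overlap = 0.10,
                         noise = FALSE)
  stride <- floor(64 * 0.9)
  expect_equal(ft$manifest$stride, stride)
  expect_equal(unname(ft$manifest$grid),
               c(ceiling((120 - 64) / stride) + 1, ceiling((160 - 64) / stride) + 1))
  # neighbouring tiles share the overlap strip exactly
  t11 <- ft$tiles[[1]]; t12 <- ft$tiles[[2]]
  expect_equal(t11$neuron[, (stride + 1):64], t12$neuron[, 1:(64 - stride)])
  # the study's full-field grid arithmetic: 6020 x 3216 um at 0.32 um/px
  ny <- round(3216 / 0.32); nx <- round(6020 / 0.32)
  s2 <- floor(2048 * 0.9)
  expect_equal(ceiling((nx - 2048) / s2) + 1, 11)
  expect_equal(ceiling((ny - 2048) / s2) + 1, 6)
})

test_that("total process length rises to 7 DIV and falls by 17 DIV", {
  d <- euclidean_designs()[["S75C75"]]
  tr <- build_pattern(d)
  mk <- crop_mask(rasterize(tr, 1.5, keep_ids = TRUE), 700)
  tot <- sapply(c(3, 7, 17), function(dv) {
    mean(sapply(1:5, function(s) {
      p <- culture_params(div = dv, rng_seed = s)
      g <- simulate_development(seed_cells(mk, p), mk, tr)$ground_truth
      g$N_CNT * g$A_CNT + g$N_Si * g$A_Si
    }))
  })
  expect_gt(tot[2], tot[1])
  expect_gt(tot[2], tot[3])
})
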