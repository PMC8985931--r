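test_that("base length solves the width constraint", {
  # one H: W = 2 L0 + w
  expect_equal(fractal_design(D = 2, m = 1, w_cnt = 20, W = 2020)$L0, 1000)
  # geometric series solutions for the fabricated widths
  expect_equal(fractal_design(D = 2, m = 6, w_cnt = 20, W = 6262)$L0,
               (6262 - 20) / (2 * (1 + 1/2 + 1/4 + 1/8 + 1/16 + 1/32)))
  expect_equal(fractal_design(D = 2, m = 6, w_cnt = 20, W = 6262)$L0,
               1585.27, tolerance = 1e-5)
  expect_equal(fractal_design(D = 1.1, m = 4, w_cnt = 20, W = 6020)$L0,
               (6020 - 20) / (2 * sum(2^(-2 * (0:3) / 1.1))))
  expect_equal(fractal_design(D = 1.1, m = 4, w_cnt = 20, W = 6020)$L0,
               2163.25, tolerance = 1e-4)
  # width closure holds exactly for every fabricated design
  for (d in fractal_designs()) {
    L <- segment_lengths(d)
    expect_equal(2 * sum(L[seq(1, d$N, by = 2)]) + d$w_cnt, d$W,
                 tolerance = 1e-9)
  }
})

test_that("invalid designs are rejected", {
  expect_error(fractal_design(D = 1, m = 4, w_cnt = 20, W = 6020), "1 < D")
  expect_error(fractal_design(D = 2.5, m = 4, w_cnt = 20, W = 6020), "1 < D")
  expect_error(fractal_design(D = 2, m = 2.5, w_cnt = 20, W = 6020), "integer")
  expect_error(fractal_design(D = 2, m = 4, w_cnt = 20, W = 10), "exceed")
  expect_error(euclidean_design(w_cnt = 6000, w_si = 0, W = 6000), "positive")
  expect_warning(euclidean_design(w_cnt = 3000, w_si = 2000, W = 6000),
                 "degenerate")
})

test_that("H-tree construction follows the recursive geometry", {
  tr <- build_htree(fractal_design(D = 2, m = 1, w_cnt = 20, W = 2020))
  expect_equal(nrow(tr$segments), 6)  # 2 horizontal + 4 vertical
  expect_equal(sum(tr$segments$orientation == "h"), 2)
  L0 <- tr$design$L0
  L1 <- L0 / sqrt(2)
  expect_equal(unname(tr$bounds[["xmax"]] - tr$bounds[["xmin"]]), 2 * L0 + 20)
  expect_equal(unname(tr$bounds[["ymax"]] - tr$bounds[["ymin"]]), 2 * L1 + 20)

  tr3 <- tiny_htree(D = 1.6, m = 3)
  # segment-count law: 2^(n+1) segments at order n
  expect_equal(as.vector(table(tr3$segments$order)),
               2^(sort(unique(tr3$segments$order)) + 1))
  # scaling law L_{n+1}/L_n = 2^(-1/D)
  L <- as.numeric(tapply(tr3$segments$length, tr3$segments$order, unique))
  expect_equal(L[-1] / L[-length(L)],
               rep(2^(-1 / 1.6), length(L) - 1), tolerance = 1e-12)
  # orientation alternates with order parity
  expect_true(all((tr3$segments$order %% 2 == 0) ==
                    (tr3$segments$orientation == "h")))
  # total count for the deepest fabricated tree
  tr6 <- build_htree(fractal_designs()[["2-6"]])
  expect_equal(nrow(tr6$segments), 2^13 - 2)
})

test_that("branch rectangles only overlap at junctions", {
  for (nm in c("1.1-4", "1.5-4", "2-4")) {
    expect_true(validate_tree(build_htree(fractal_designs()[[nm]])))
  }
  # a D/m combination whose finest branches collide is rejected outright
  expect_error(build_htree(fractal_design(D = 1.2, m = 6, w_cnt = 20, W = 6262)),
               "overlapping")
})

test_that("Euclidean rows pack to the fabricated dimensions", {
  d <- euclidean_design(100, 100, W = 6000)
  expect_equal(d$n_rows, 30L)
  expect_equal(d$height, 5900)
  d2 <- euclidean_design(25, 25, W = 6000)
  expect_equal(d2$n_rows, 120L)
  expect_equal(d2$height, 5975)
  tr <- build_euclidean(d)
  expect_equal(nrow(tr$segments), 30)
  expect_equal(unname(tr$bounds[["ymax"]] - tr$bounds[["ymin"]]), 5900)
  # packing invariant holds for the whole catalog
  for (dd in euclidean_designs()) {
    expect_lte(dd$n_rows * dd$w_cnt + (dd$n_rows - 1) * dd$w_si, dd$W)
    expect_gt((dd$n_rows + 1) * dd$w_cnt + dd$n_rows * dd$w_si, dd$W)
  }
})

test_that("rasterization samples pixel centres exactly", {
  # single 100 x 200 um rectangle at 1 um/px
  d <- suppressWarnings(euclidean_design(w_cnt = 100, w_si = 150, W = 200))
  tr <- build_euclidean(d)
  mk <- rasterize(tr, 1)
  expect_equal(sum(mk$cnt), 100 * 200)
  # resolution must resolve the branch width
  expect_error(rasterize(tr, 150), "coarse")
  # determinism
  expect_identical(mk$cnt, rasterize(tr, 1)$cnt)
  # cropping preserves resolution and centring
  tr2 <- tiny_rows()
  mk2 <- rasterize(tr2, 1, keep_ids = TRUE)
  win <- crop_mask(mk2, 40)
  expect_equal(dim(win$cnt), c(40, 40))
  expect_equal(unname(win$origin["x"]), -20)
})

test_that("design JSON round trip preserves parameters", {
  skip_if_not_installed("jsonlite")
  path <- withr::local_tempfile(fileext = ".json")
  d <- fractal_designs()[["1.5-4"]]
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(d2$L0, d$L0)
  expect_equal(d2$label, d$label)
  e <- euclidean_designs()[["S50C50"]]
  write_design(e, path)
  expect_equal(read_design(path)$n_rows, e$n_rows)
})
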