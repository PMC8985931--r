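# small fixtures shared across tests; everything is generated in code

tiny_htree <- function(D = 2, m = 2, w = 4, W = 100) {
  build_htree(fractal_design(D = D, m = m, w_cnt = w, W = W))
}

tiny_rows <- function(w_cnt = 10, w_si = 10, W = 100) {
  build_euclidean(euclidean_design(w_cnt = w_cnt, w_si = w_si, W = W))
}

# raster mask built directly from a logical matrix (rows = y)
manual_mask <- function(cnt, res = 1, origin = c(x = 0, y = 0)) {
  structure(list(cnt = cnt, seg = NULL, res = res, origin = origin,
                 dim = dim(cnt), label = "manual"),
            class = "raster_mask")
}

# minimal synthetic scene holding given polylines / glial disks on a mask
manual_scene <- function(mask, processes = list(), glia = NULL, seed = 1L) {
  b <- c(xmin = unname(mask$origin["x"]),
         xmax = unname(mask$origin["x"]) + ncol(mask$cnt) * mask$res,
         ymin = unname(mask$origin["y"]),
         ymax = unname(mask$origin["y"]) + nrow(mask$cnt) * mask$res)
  structure(
    list(somas = data.frame(x = numeric(), y = numeric(),
                            kind = character(), cluster = integer()),
         processes = processes, glial_regions = glia, clusters = NULL,
         branch_clusters = NULL, bounds = b, mask_res = mask$res,
         mask = mask, params = culture_params(rng_seed = seed),
         rng_seed = seed, div = 17, label = "manual"),
    class = "synthetic_scene")
}

# evolve a seeded culture on a central window of a design; cached per call
window_scene <- function(design, seed = 1L, window = 1024, res = 1.5,
                         div = 17) {
  tr <- build_pattern(design)
  mk <- rasterize(tr, res, keep_ids = TRUE)
  win <- crop_mask(mk, window)
  p <- culture_params(div = div, rng_seed = seed)
  sc <- simulate_development(seed_cells(win, p), win, tr)
  list(scene = sc, mask = win, tree = tr)
}
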