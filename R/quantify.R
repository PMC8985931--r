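#' Stitch field-of-view tiles into a full-field image
#'
#' Fixed-grid placement at stride `tile * (1 - overlap)` with averaging of
#' the overlap strips (placement is exact for tiles cut from one field, and
#' averaging is idempotent there).
#'
#' @param tiles list of tiles as produced by [render_fov_tiles()].
#' @param manifest the accompanying manifest.
#' @param channel which channel to stitch (`"neuron"`, `"glia"`, `"nuclei"`).
#' @return full-field matrix of size `manifest$full_dim`.
#' @export
stitch_tiles <- function(tiles, manifest, channel = "neuron") {
  nr <- manifest$grid[["rows"]]; nc <- manifest$grid[["cols"]]
  stride <- manifest$stride
  tile <- manifest$tile
  have <- vapply(tiles, function(t) paste(t$row, t$col), "")
  need <- as.vector(outer(seq_len(nr), seq_len(nc), paste))
  miss <- setdiff(need, have)
  if (length(miss)) {
    stop("missing tiles (row col): ", paste(miss, collapse = "; "), call. = FALSE)
  }
  acc <- matrix(0, manifest$full_dim[["ny"]], manifest$full_dim[["nx"]])
  cnt <- matrix(0L, manifest$full_dim[["ny"]], manifest$full_dim[["nx"]])
  for (t in tiles) {
    if (paste(t$row, t$col) %in% names(manifest$excluded)) next
    ri <- (t$row - 1) * stride + seq_len(tile)
    ci <- (t$col - 1) * stride + seq_len(tile)
    acc[ri, ci] <- acc[ri, ci] + t[[channel]]
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  acc / pmax(cnt, 1L)
}

#' Resample an electrode mask onto an image grid
#'
#' Nearest-label resampling of the binary mask to the image resolution and
#' dimensions, with an optional uniform dilation (positive
#' `edge_adjust_px`) or erosion (negative) of the branch regions to absorb
#' fabrication or registration slack.
#'
#' @param mask a `raster_mask`.
#' @param dim target dimensions `c(ny, nx)` in pixels.
#' @param pixel_size target pixel size (um).
#' @param edge_adjust_px integer; per-side branch growth in target pixels.
#' @return a `raster_mask` on the target grid.
#' @export
align_mask <- function(mask, dim, pixel_size, edge_adjust_px = 0) {
  ny <- dim[1]; nx <- dim[2]
  ext_x <- ncol(mask$cnt) * mask$res
  ext_y <- nrow(mask$cnt) * mask$res
  if (abs(nx * pixel_size - ext_x) > 2 * max(pixel_size, mask$res) ||
      abs(ny * pixel_size - ext_y) > 2 * max(pixel_size, mask$res)) {
    stop("mask and image extents disagree beyond rescaling tolerance", call. = FALSE)
  }
  sx <- pmin(pmax(ceiling(((seq_len(nx) - 0.5) * pixel_size) / mask$res), 1L),
             ncol(mask$cnt))
  sy <- pmin(pmax(ceiling(((seq_len(ny) - 0.5) * pixel_size) / mask$res), 1L),
             nrow(mask$cnt))
  cnt <- mask$cnt[sy, sx, drop = FALSE]
  if (edge_adjust_px != 0) {
    k <- EBImage::makeBrush(2 * abs(edge_adjust_px) + 1, shape = "box")
    cnt <- if (edge_adjust_px > 0) {
      EBImage::imageData(EBImage::dilate(cnt * 1, k)) > 0.5
    } else {
      EBImage::imageData(EBImage::erode(cnt * 1, k)) > 0.5
    }
  }
  structure(
    list(cnt = cnt, seg = NULL, res = pixel_size, origin = mask$origin,
         dim = c(ny = ny, nx = nx), label = mask$label),
    class = "raster_mask")
}

auto_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) {
    if (rng[1] == 0) return(Inf)   # blank channel: nothing above threshold
    stop("threshold failure: constant non-zero image, supply a manual threshold",
         call. = FALSE)
  }
  x <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  rng[1] + th * diff(rng)
}

#' Measure total neuronal process length per surface
#'
#' Binarize the neuron channel, remove soma blobs (compact regions thicker
#' than the process calibre, detected by morphological opening), skeletonize
#' to a 1 px centreline and measure its length by chord summation along the
#' traced skeleton paths, split by the surface label under each chord.
#' Overlapping or bundled processes collapse onto one skeleton line and are
#' counted once -- the same overlap-insensitive undercount as the reference
#' tracing algorithm.
#'
#' @param img neuron-channel matrix.
#' @param mask `raster_mask` aligned to the image grid (same dimensions).
#' @param threshold `NULL` for automatic (Otsu) or a numeric image value.
#' @param soma_area_um2,soma_solidity compact connected components larger
#'   than `soma_area_um2` with convex solidity above `soma_solidity` are
#'   treated as isolated soma blobs and removed; elongated components (and
#'   so components where processes attach to or cross a soma) are kept
#'   whole, letting the skeleton pass through the blob so the process length
#'   is preserved.
#' @param min_px connected components smaller than this many pixels are
#'   treated as noise speckle.
#' @return list with `cnt_um`, `gap_um` (lengths in um), the `skeleton`
#'   and the process `binary` mask.
#' @export
measure_process_length <- function(img, mask, threshold = NULL,
                                   soma_area_um2 = 80, soma_solidity = 0.8,
                                   min_px = 6) {
  stopifnot(all(dim(img) == dim(mask$cnt)))
  res <- mask$res
  th <- threshold %||% auto_threshold(img)
  bin <- img > th
  if (!any(bin)) {
    return(list(cnt_um = 0, gap_um = 0,
                skeleton = matrix(FALSE, nrow(img), ncol(img)), binary = bin))
  }
  # speckle removal
  lab <- EBImage::bwlabel(bin * 1L)
  sz <- tabulate(lab[lab > 0L])
  small <- which(sz < min_px)
  if (length(small)) bin[matrix(lab %in% small, nrow(bin))] <- FALSE
  # isolated soma blobs: large, compact (near-circular footprint, high
  # convex solidity) components without protruding processes
  lab <- EBImage::bwlabel(bin * 1L)
  n_comp <- max(lab)
  if (n_comp > 0) {
    idx <- which(lab > 0L)
    li <- lab[idx]
    rr <- (idx - 1L) %% nrow(bin) + 1L
    cc <- (idx - 1L) %/% nrow(bin) + 1L
    area <- tabulate(li, nbins = n_comp)
    dr <- tapply(rr, li, function(v) diff(range(v))) + 1
    dc <- tapply(cc, li, function(v) diff(range(v))) + 1
    maxdim2 <- dr^2 + dc^2
    cand <- which(area * res^2 > soma_area_um2 & maxdim2 / area < 3)
    drop <- integer()
    for (k in cand) {
      sel <- li == k
      pts <- cbind(cc[sel], rr[sel])
      h <- grDevices::chull(pts)
      hp <- pts[h, , drop = FALSE]
      ha <- abs(sum(hp[, 1] * hp[c(2:nrow(hp), 1), 2] -
                      hp[c(2:nrow(hp), 1), 1] * hp[, 2])) / 2
      hper <- sum(sqrt(rowSums((hp - hp[c(2:nrow(hp), 1), ])^2)))
      ha <- ha + hper / 2 + 1    # Minkowski correction for pixel extent
      if (area[k] / ha > soma_solidity) drop <- c(drop, k)
    }
    if (length(drop)) bin[matrix(lab %in% drop, nrow(bin))] <- FALSE
  }
  skel <- cpp_thin(bin)
  v <- cpp_skel_lengths(skel, matrix(as.integer(mask$cnt), nrow(mask$cnt)), 4L)
  list(cnt_um = unname(v[["cnt"]]) * res, gap_um = unname(v[["gap"]]) * res,
       skeleton = skel, binary = bin)
}

#' Measure glial coverage area per surface
#'
#' Global automatic (Otsu) or manual thresholding of the glia channel,
#' morphological opening to remove speckle, and pixel-area summation by
#' surface label.
#'
#' @param img glia-channel matrix.
#' @param mask aligned `raster_mask`.
#' @param threshold `"auto"` or a numeric image value.
#' @param open_px opening brush diameter in pixels.
#' @return list with `cnt_um2`, `gap_um2` and the thresholded `binary`.
#' @export
measure_glial_area <- function(img, mask, threshold = "auto", open_px = 3) {
  stopifnot(all(dim(img) == dim(mask$cnt)))
  th <- if (identical(threshold, "auto")) auto_threshold(img) else threshold
  bin <- img > th
  if (any(bin) && open_px > 1) {
    bin <- EBImage::imageData(
      EBImage::opening(bin * 1, EBImage::makeBrush(open_px, "disc"))) > 0.5
  }
  px <- mask$res^2
  list(cnt_um2 = sum(bin & mask$cnt) * px,
       gap_um2 = sum(bin & !mask$cnt) * px,
       binary = bin)
}

#' Normalized herding indices
#'
#' Normalized process lengths `N_CNT = len_cnt / A_CNT` and
#' `N_Si = len_gap / A_Si` (um per um^2), normalized glial coverages
#' `G_CNT = glia_cnt / A_CNT` and `G_Si = glia_gap / A_Si` (area
#' fractions), and the herding indices
#' `N = N_CNT / (N_CNT + N_Si)`, `G = G_Si / (G_CNT + G_Si)`,
#' `GN = G * N`. Values above 0.5 indicate successful guiding of processes
#' onto the branches and of glia into the gaps.
#'
#' @param len_cnt,len_gap total process length (um) on each surface.
#' @param glia_cnt,glia_gap glial coverage area (um^2) on each surface.
#' @param A_CNT,A_Si analyzed surface areas (um^2), both positive.
#' @param label,div optional metadata carried through.
#' @return object of class `herding_result` (a one-row data.frame with
#'   `N_CNT`, `N_Si`, `G_CNT`, `G_Si`, `N`, `G`, `GN`, areas and metadata);
#'   indices whose numerator and denominator are both zero are flagged in
#'   `attr(, "flags")` and set `NA`.
#' @export
herding_indices <- function(len_cnt, len_gap, glia_cnt, glia_gap,
                            A_CNT, A_Si, label = NA_character_, div = NA_real_) {
  if (!(A_CNT > 0) || !(A_Si > 0)) stop("analyzed areas must be positive", call. = FALSE)
  n_cnt <- len_cnt / A_CNT
  n_si <- len_gap / A_Si
  g_cnt <- glia_cnt / A_CNT
  g_si <- glia_gap / A_Si
  flags <- character()
  if (n_cnt + n_si > 0) nn <- n_cnt / (n_cnt + n_si)
  else { nn <- NA_real_; flags <- c(flags, "N undefined: no processes") }
  if (g_cnt + g_si > 0) gg <- g_si / (g_cnt + g_si)
  else { gg <- NA_real_; flags <- c(flags, "G undefined: no glia") }
  out <- data.frame(label = label, div = div,
                    N_CNT = n_cnt, N_Si = n_si, G_CNT = g_cnt, G_Si = g_si,
                    N = nn, G = gg, GN = gg * nn,
                    A_CNT = A_CNT, A_Si = A_Si)
  attr(out, "flags") <- flags
  class(out) <- c("herding_result", class(out))
  out
}

#' Quantify a rendered scene against its electrode mask
#'
#' Convenience pipeline: align the mask to the image grid, measure process
#' length and glial coverage, and form the herding indices.
#'
#' @param channels output of [render_channels()] (or stitched equivalents).
#' @param mask the design `raster_mask`.
#' @param edge_adjust_px passed to [align_mask()].
#' @param glia_threshold `"auto"` or numeric.
#' @return a `herding_result`; the aligned mask and measured layers are in
#'   `attr(, "layers")`.
#' @export
quantify_scene <- function(channels, mask, edge_adjust_px = 0,
                           glia_threshold = "auto") {
  am <- align_mask(mask, dim(channels$neuron), channels$pixel_size,
                   edge_adjust_px)
  mp <- measure_process_length(channels$neuron, am)
  mg <- measure_glial_area(channels$glia, am, threshold = glia_threshold)
  ar <- area_raster(am)
  out <- herding_indices(mp$cnt_um, mp$gap_um, mg$cnt_um2, mg$gap_um2,
                         ar$A_CNT, ar$A_Si,
                         label = channels$label %||% mask$label,
                         div = channels$div %||% NA_real_)
  attr(out, "layers") <- list(mask = am, process = mp, glia = mg)
  out
}

#' Positional profile sums across a row electrode
#'
#' Sums the measured glial coverage area and skeleton process length along
#' one axis to locate the peak glia and neuron positions along the other;
#' for row electrodes summed along the rows, glial coverage peaks inside
#' the gaps and process length at the electrode edges.
#'
#' @param process result of [measure_process_length()].
#' @param glia result of [measure_glial_area()].
#' @param mask aligned `raster_mask`.
#' @param axis `"y"` (profile across the rows; sums run along x) or `"x"`.
#' @return data.frame with `pos` (um, pattern coordinates), `G_a` (summed
#'   glial coverage area per position, um^2), `N_l` (summed process length
#'   per position, um); electrode edge positions in `attr(, "edges")`.
#' @export
profile_sums <- function(process, glia, mask, axis = c("y", "x")) {
  axis <- match.arg(axis)
  res <- mask$res
  f <- if (axis == "y") rowSums else colSums
  n <- if (axis == "y") nrow(mask$cnt) else ncol(mask$cnt)
  o <- if (axis == "y") mask$origin[["y"]] else mask$origin[["x"]]
  G_a <- f(glia$binary) * res^2
  N_l <- f(process$skeleton) * res
  frac <- f(mask$cnt) / (if (axis == "y") ncol(mask$cnt) else nrow(mask$cnt))
  on <- frac > 0.5
  edges <- o + which(abs(diff(on)) == 1) * res
  if (on[1]) edges <- c(o, edges)                 # electrode at the field edge
  if (on[n]) edges <- c(edges, o + n * res)
  out <- data.frame(pos = o + (seq_len(n) - 0.5) * res, G_a = G_a, N_l = N_l)
  attr(out, "edges") <- edges
  out
}

#' Split herding results into low/high glial-herding regimes
#'
#' @param G numeric vector of glial herding indices.
#' @param G_T regime threshold (default 0.95); `G <= G_T` is `"low"`
#'   (boundary inclusive).
#' @return factor with levels `low`, `high`.
#' @export
regime_split <- function(G, G_T = 0.95) {
  factor(ifelse(G <= G_T, "low", "high"), levels = c("low", "high"))
}
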