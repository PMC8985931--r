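#' Build the H-tree segment tree
#'
#' Recursive construction from the pattern centre: two horizontal order-0
#' segments extend to `+/- L_0`; at the free endpoint of every order-`n`
#' segment, two perpendicular order-`(n+1)` segments extend `+/- L_{n+1}`,
#' through order `N = 2m - 1`. Every segment is an axis-aligned rectangle of
#' width `w_cnt` centred on its centreline, running exactly `L_n` from the
#' parent junction centreline (free branch ends carry no extra half-width
#' cap; this is the reading that reproduces the fabricated minimum gap
#' widths).
#'
#' Coordinates are pattern-centred micrometres with y increasing upward.
#' Even orders are horizontal, odd orders vertical. Designs whose finest
#' branches would collide with their grandparent crossbars (negative minimum
#' gap) are rejected as overlapping.
#'
#' @param design a [fractal_design()].
#' @return An object of class `segment_tree`: a list with `segments` (a
#'   data.frame of junction/tip centreline coordinates, order, orientation,
#'   length, width and parent index), `rects` (branch rectangles, columns
#'   `x0,x1,y0,y1`), `bounds` (the nominal pattern rectangle, width `W` and
#'   height `2 * sum(L_n, n odd) + w_cnt`), and the design.
#' @export
#' @examples
#' tr <- build_htree(fractal_design(D = 2, m = 1, w_cnt = 20, W = 2020))
#' nrow(tr$segments)  # 2 horizontal + 4 vertical
build_htree <- function(design) {
  stopifnot(inherits(design, "fractal_design"))
  L <- segment_lengths(design)
  w <- design$w_cnt
  N <- design$N
  if (design$m >= 2) {
    gap <- L[N - 2 + 1] - L[N + 1] - w / 2
    if (gap <= 0) {
      stop("overlapping design: finest branches collide with their crossbars (D = ",
           design$D, ", m = ", design$m, ")", call. = FALSE)
    }
  }

  # level-by-level vectorized construction; each segment is (junction, dir)
  jx <- c(0, 0); jy <- c(0, 0); dx <- c(1, -1); dy <- c(0, 0)
  ord <- c(0L, 0L); parent <- c(NA_integer_, NA_integer_)
  tipx <- jx + dx * L[1]; tipy <- jy + dy * L[1]
  prev_idx <- 1:2
  for (n in seq_len(N)) {
    pj <- prev_idx
    px <- tipx[pj]; py <- tipy[pj]
    horiz <- ord[pj[1]] %% 2 == 0            # parent orientation
    k <- length(pj)
    njx <- rep(px, each = 2); njy <- rep(py, each = 2)
    if (horiz) { ndx <- rep(0, 2 * k); ndy <- rep(c(1, -1), k) }
    else       { ndx <- rep(c(1, -1), k); ndy <- rep(0, 2 * k) }
    idx0 <- length(jx)
    jx <- c(jx, njx); jy <- c(jy, njy); dx <- c(dx, ndx); dy <- c(dy, ndy)
    ord <- c(ord, rep.int(as.integer(n), 2 * k))
    parent <- c(parent, rep(pj, each = 2))
    new_idx <- idx0 + seq_len(2 * k)
    tipx <- c(tipx, njx + ndx * L[n + 1]); tipy <- c(tipy, njy + ndy * L[n + 1])
    prev_idx <- new_idx
  }

  segments <- data.frame(
    order = ord,
    orientation = ifelse(ord %% 2 == 0, "h", "v"),
    x0 = jx, y0 = jy, x1 = tipx, y1 = tipy,
    length = L[ord + 1], width = w, parent = parent)

  rects <- cbind(
    x0 = pmin(jx, tipx) - ifelse(ord %% 2 == 1, w / 2, 0),
    x1 = pmax(jx, tipx) + ifelse(ord %% 2 == 1, w / 2, 0),
    y0 = pmin(jy, tipy) - ifelse(ord %% 2 == 0, w / 2, 0),
    y1 = pmax(jy, tipy) + ifelse(ord %% 2 == 0, w / 2, 0))

  H <- 2 * sum(L[seq(2, N + 1, by = 2)]) + w
  structure(
    list(segments = segments, rects = rects, design = design, type = "htree",
         bounds = c(xmin = -design$W / 2, xmax = design$W / 2,
                    ymin = -H / 2, ymax = H / 2)),
    class = "segment_tree")
}

#' Build a Euclidean row pattern
#'
#' `n_rows` horizontal rectangles of size `W x w_cnt` separated by `w_si`,
#' vertically centred on the origin.
#'
#' @param design a [euclidean_design()].
#' @return A `segment_tree` of horizontal row rectangles.
#' @export
build_euclidean <- function(design) {
  stopifnot(inherits(design, "euclidean_design"))
  n <- design$n_rows
  w <- design$w_cnt
  H <- design$height
  yc <- -H / 2 + w / 2 + (seq_len(n) - 1) * (w + design$w_si)
  segments <- data.frame(
    order = 0L, orientation = "h",
    x0 = -design$W / 2, y0 = yc, x1 = design$W / 2, y1 = yc,
    length = design$W, width = w, parent = NA_integer_)
  rects <- cbind(x0 = rep(-design$W / 2, n), x1 = rep(design$W / 2, n),
                 y0 = yc - w / 2, y1 = yc + w / 2)
  structure(
    list(segments = segments, rects = rects, design = design, type = "rows",
         bounds = c(xmin = -design$W / 2, xmax = design$W / 2,
                    ymin = -H / 2, ymax = H / 2)),
    class = "segment_tree")
}

#' Build the segment tree for any design
#' @param design a fractal or Euclidean design.
#' @return a `segment_tree`.
#' @export
build_pattern <- function(design) {
  if (inherits(design, "fractal_design")) build_htree(design)
  else if (inherits(design, "euclidean_design")) build_euclidean(design)
  else stop("not an electrode design", call. = FALSE)
}

#' @export
print.segment_tree <- function(x, ...) {
  b <- x$bounds
  cat(sprintf("segment_tree (%s, %s): %d segments, bounds %.1f x %.1f um\n",
              x$type, x$design$label, nrow(x$segments),
              b["xmax"] - b["xmin"], b["ymax"] - b["ymin"]))
  invisible(x)
}

#' Check that branch rectangles only overlap at junctions
#'
#' Exhaustive pairwise rectangle-intersection test. Parent-child pairs are
#' allowed to share their junction overlap (at most half a branch width
#' deep); any other positive-area intersection marks the design as
#' overlapping. Quadratic in the number of segments, so intended for
#' validation of individual designs.
#'
#' @param tree a `segment_tree`.
#' @param chunk pair-block size used to bound memory.
#' @return `TRUE` invisibly, or an error describing the first offending pair.
#' @export
validate_tree <- function(tree, chunk = 2e6) {
  r <- tree$rects
  n <- nrow(r)
  seg <- tree$segments
  pr <- seg$parent
  pairs_total <- n * (n - 1) / 2
  ij <- function(k) {
    # map linear pair index k (1-based) to (i, j), i < j
    i <- n - 1 - floor((sqrt(8 * (pairs_total - k) + 1) - 1) / 2)
    base <- (i - 1) * n - (i - 1) * i / 2
    j <- i + (k - base)
    cbind(i, j)
  }
  eps <- 1e-9
  done <- 0
  while (done < pairs_total) {
    kk <- (done + 1):min(done + chunk, pairs_total)
    p <- ij(kk)
    i <- p[, 1]; j <- p[, 2]
    ox <- pmin(r[i, "x1"], r[j, "x1"]) - pmax(r[i, "x0"], r[j, "x0"])
    oy <- pmin(r[i, "y1"], r[j, "y1"]) - pmax(r[i, "y0"], r[j, "y0"])
    bad <- ox > eps & oy > eps
    if (any(bad)) {
      ib <- i[bad]; jb <- j[bad]
      related <- (!is.na(pr[jb]) & pr[jb] == ib) | (!is.na(pr[ib]) & pr[ib] == jb) |
        (!is.na(pr[ib]) & !is.na(pr[jb]) & pr[ib] == pr[jb] &
           seg$x0[ib] == seg$x0[jb] & seg$y0[ib] == seg$y0[jb])
      if (any(!related)) {
        k1 <- which(!related)[1]
        stop(sprintf("overlapping design: segments %d and %d intersect beyond their junction",
                     ib[k1], jb[k1]), call. = FALSE)
      }
    }
    done <- done + length(kk)
  }
  invisible(TRUE)
}

#' Rasterize a segment tree to a binary branch/gap mask
#'
#' A pixel is labelled branch (CNT) iff its centre lies inside the union of
#' branch rectangles. The grid covers the nominal pattern rectangle
#' (`tree$bounds`); rows index y from the bottom, columns index x.
#'
#' @param tree a `segment_tree`.
#' @param resolution pixel size in micrometres (must resolve the branch
#'   width: `resolution < w_cnt` is required).
#' @param keep_ids also store a segment-id matrix (`0` in gaps), used by the
#'   synthetic culture generator for edge following.
#' @return An object of class `raster_mask`: list with `cnt` (logical
#'   matrix), optional `seg` (integer matrix), `res`, `origin` (x,y of the
#'   lower-left corner of pixel `[1,1]`) and the design label.
#' @export
rasterize <- function(tree, resolution = 1, keep_ids = FALSE) {
  stopifnot(inherits(tree, "segment_tree"), resolution > 0)
  w <- min(tree$segments$width)
  if (resolution >= w) {
    stop("resolution (", resolution, " um/px) too coarse for branch width ",
         w, " um", call. = FALSE)
  }
  b <- tree$bounds
  nx <- max(1L, round((b["xmax"] - b["xmin"]) / resolution))
  ny <- max(1L, round((b["ymax"] - b["ymin"]) / resolution))
  cnt <- matrix(FALSE, nrow = ny, ncol = nx)
  seg <- if (keep_ids) matrix(0L, nrow = ny, ncol = nx) else NULL
  ox <- b[["xmin"]]; oy <- b[["ymin"]]
  r <- tree$rects
  for (k in seq_len(nrow(r))) {
    # pixel centres at ox + (i - 0.5) * res; inside iff strictly within rect
    c0 <- ceiling((r[k, "x0"] - ox) / resolution + 0.5)
    c1 <- ceiling((r[k, "x1"] - ox) / resolution - 0.5)
    r0 <- ceiling((r[k, "y0"] - oy) / resolution + 0.5)
    r1 <- ceiling((r[k, "y1"] - oy) / resolution - 0.5)
    c0 <- max(1L, c0); c1 <- min(nx, c1); r0 <- max(1L, r0); r1 <- min(ny, r1)
    if (c0 > c1 || r0 > r1) next
    cnt[r0:r1, c0:c1] <- TRUE
    if (keep_ids) seg[r0:r1, c0:c1] <- k
  }
  structure(
    list(cnt = cnt, seg = seg, res = resolution,
         origin = c(x = unname(ox), y = unname(oy)),
         dim = c(ny = ny, nx = nx), label = tree$design$label),
    class = "raster_mask")
}

#' @export
print.raster_mask <- function(x, ...) {
  cat(sprintf("raster_mask (%s): %d x %d px at %g um/px, %.1f%% branch\n",
              x$label %||% "?", x$dim[1], x$dim[2], x$res,
              100 * mean(x$cnt)))
  invisible(x)
}

#' Crop a central window out of a raster mask
#'
#' Used to run the measurement pipeline on a tractable sub-field while
#' keeping the design's local geometry; the window is centred on the
#' pattern centre.
#'
#' @param mask a `raster_mask`.
#' @param width,height window size in micrometres.
#' @return a `raster_mask` covering the window.
#' @export
crop_mask <- function(mask, width, height = width) {
  nx <- ncol(mask$cnt); ny <- nrow(mask$cnt)
  wx <- min(nx, round(width / mask$res)); wy <- min(ny, round(height / mask$res))
  c0 <- floor((nx - wx) / 2) + 1L; r0 <- floor((ny - wy) / 2) + 1L
  cols <- c0:(c0 + wx - 1L); rows <- r0:(r0 + wy - 1L)
  structure(
    list(cnt = mask$cnt[rows, cols, drop = FALSE],
         seg = if (!is.null(mask$seg)) mask$seg[rows, cols, drop = FALSE],
         res = mask$res,
         origin = c(x = unname(mask$origin["x"]) + (c0 - 1) * mask$res,
                    y = unname(mask$origin["y"]) + (r0 - 1) * mask$res),
         dim = c(ny = wy, nx = wx), label = mask$label),
    class = "raster_mask")
}

#' Export branch rectangles as an SVG drawing
#'
#' @param tree a `segment_tree`.
#' @param path output file.
#' @param scale drawing units per micrometre.
#' @export
write_pattern_svg <- function(tree, path, scale = 0.1) {
  b <- tree$bounds
  W <- (b["xmax"] - b["xmin"]) * scale
  H <- (b["ymax"] - b["ymin"]) * scale
  r <- tree$rects
  rect_tags <- sprintf(
    '  <rect x="%.3f" y="%.3f" width="%.3f" height="%.3f" fill="black"/>',
    (r[, "x0"] - b["xmin"]) * scale, (b["ymax"] - r[, "y1"]) * scale,
    (r[, "x1"] - r[, "x0"]) * scale, (r[, "y1"] - r[, "y0"]) * scale)
  writeLines(c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.1f" height="%.1f" viewBox="0 0 %.1f %.1f">',
            W, H, W, H),
    rect_tags, "</svg>"), path)
  invisible(path)
}
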