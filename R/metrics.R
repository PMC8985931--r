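#' Closed-form geometric metrics of an electrode design
#'
#' Computes the analytic geometry of a design from its parameters alone:
#' total centreline branch length `L_b`, branch area `A_CNT` (with the
#' junction double-count correction), total edge length `E` and its
#' width-normalized form `E_n = E / W`, mean tortuosity `T`, bounding and
#' gap areas, the smallest/largest branch-bounded gap rectangles
#' (`A_min`, `A_max`) with their ratio `A_r`, the largest connected gap area
#' `A_c`, and the characteristic gap widths `W_Si_min`, `W_Si_max`.
#'
#' For an H-tree with orders `0..N`:
#' \deqn{L_b = \sum_n 2^{n+1} L_n, \quad
#'       A_{CNT} = w L_b - \sum_{n=1}^{N} 2^n w^2/2, \quad
#'       E = 2 A_{CNT}/w + w\,2^{N+1} - \sum_{n=1}^{N} w\,2^n.}
#' Euclidean rows use the elementary row formulas (`T = 1`, `A_r = 1`).
#'
#' `W_Si_min` is the characteristic finest gap
#' `L_{N-2} - L_N - w/2` (the clearance between the end face of a
#' final-order branch and the facing side of its grandparent crossbar);
#' `W_Si_max = 2 L_0 - w` is the clear span between the inner faces of the
#' two order-1 branch pairs.
#'
#' @param design a [fractal_design()] or [euclidean_design()].
#' @return named list of metrics (micrometre units; areas in um^2,
#'   proximity not included -- see [mean_proximity()]).
#' @export
#' @examples
#' m <- closed_form_metrics(fractal_design(2, 6, 20, 6262))
#' signif(m$A_CNT, 2)  # 8.8e6 um^2
closed_form_metrics <- function(design) {
  if (inherits(design, "euclidean_design")) {
    n <- design$n_rows; w <- design$w_cnt; W <- design$W
    A_cnt <- n * w * W
    A_si <- (n - 1) * design$w_si * W
    A_bounding <- design$height * W
    E <- n * 2 * (W + w)
    gap_area <- W * design$w_si
    return(list(
      type = "rows", label = design$label,
      L_b = n * W, E = E, E_n = E / W, T = 1,
      A_CNT = A_cnt, A_Si = A_si, A_bounding = A_bounding,
      A_min = gap_area, A_max = gap_area, A_r = 1, A_c = gap_area,
      W_Si_min = design$w_si, W_Si_max = design$w_si))
  }
  stopifnot(inherits(design, "fractal_design"))
  D <- design$D; N <- design$N; w <- design$w_cnt; W <- design$W
  L <- segment_lengths(design)
  L0 <- design$L0
  L_b <- sum(2^(1:(N + 1)) * L)
  A_cnt <- w * L_b - sum(2^(1:N)) * w^2 / 2
  E <- 2 * A_cnt / w + w * 2^(N + 1) - sum(w * 2^(1:N))
  H <- 2 * sum(L[seq(2, N + 1, by = 2)]) + w
  A_bounding <- W * H
  A_si <- A_bounding - A_cnt

  # smallest branch-bounded gap rectangle, framed by the finest branches
  A_min <- (L[N - 2 + 1] - w) * (L[N - 1 + 1] - w)
  # largest branch-bounded gap rectangle
  ke <- 0:((N - 1) / 2)                     # even-order index n = 2k
  ko <- seq_len((N - 1) / 2)                # n = 1..(N-1)/2 of the odd sums
  s_odd_half <- sum(2^(-(2 * ke + 1) / D))  # sum over 2^-( (2n+1)/D )
  s_even_half <- sum(2^(-(2 * ko) / D))     # sum over 2^-( 2n/D ), n >= 1
  A_max <- 2 * L0^2 * (1 - s_even_half) * s_odd_half -
    L0 * w * (1 + s_odd_half - s_even_half) + (w / 2)^2
  # largest 4-connected gap area
  kk <- (N - 1) / 2
  s1 <- sum(2^(-(2 * (0:kk) + 1) / D))
  s2 <- 0
  if (kk >= 1) for (n in 1:kk) for (mm in n:kk) s2 <- s2 + 2^(-(2 * mm + 2 * n + 1) / D)
  s3 <- 0
  if (kk >= 1) for (n in 1:kk) {
    mm <- (2 * n + 1):N
    s3 <- s3 + sum(2^mm / 2^((2 * n + mm) / D))
  }
  s4 <- sum(2^(-(0:N) / D))
  A_c <- 2 * L0^2 * (s1 - s2) - L0 * w * (s3 + s4)

  list(
    type = "htree", label = design$label,
    L_b = L_b, E = E, E_n = E / W, T = tortuosity_closed(design),
    A_CNT = A_cnt, A_Si = A_si, A_bounding = A_bounding,
    A_min = A_min, A_max = A_max, A_r = A_max / A_min, A_c = A_c,
    W_Si_min = if (design$m >= 2) L[N - 2 + 1] - L[N + 1] - w / 2 else NA_real_,
    W_Si_max = 2 * L0 - w)
}

tortuosity_closed <- function(design) {
  # mean over all 2^(N+1) finest-branch endpoints of path length over
  # displacement; enumerate sign choices of the alternating axis sums
  L <- segment_lengths(design)
  N <- design$N
  path <- sum(L)
  ie <- seq(1, N + 1, by = 2)   # even orders -> x
  io <- seq(2, N + 1, by = 2)   # odd orders -> y
  # by symmetry restrict to positive signs on order 0 and average the rest
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), N + 1)))
  x <- signs[, ie, drop = FALSE] %*% L[ie]
  y <- signs[, io, drop = FALSE] %*% L[io]
  mean(path / sqrt(x^2 + y^2))
}

#' Mean tortuosity of a segment tree
#'
#' The along-branch path length from the pattern centre to a finest-branch
#' endpoint (identical for every endpoint) divided by the straight-line
#' displacement, averaged over all endpoints. Euclidean rows are straight
#' paths, so `T = 1`.
#'
#' @param tree a `segment_tree`.
#' @return mean tortuosity `T >= 1`.
#' @export
tortuosity <- function(tree) {
  if (tree$type == "rows") return(1)
  seg <- tree$segments
  tips <- seg[seg$order == max(seg$order), c("x1", "y1")]
  path <- sum(segment_lengths(tree$design))
  mean(path / sqrt(tips$x1^2 + tips$y1^2))
}

#' Proximity map of a raster mask
#'
#' For every gap pixel, the reciprocal of the Euclidean distance to the
#' nearest branch pixel (units 1/um at the mask's resolution); branch
#' pixels carry `NA`. A gap pixel face-adjacent to a branch has value
#' `1 / res`.
#'
#' @param mask a `raster_mask`.
#' @return object of class `proximity_map`: list with `values` (matrix),
#'   `res`.
#' @export
proximity_map <- function(mask) {
  cnt <- mask$cnt
  if (all(cnt)) stop("undefined proximity: mask has no gap pixels", call. = FALSE)
  if (!any(cnt)) stop("undefined proximity: mask has no branch pixels", call. = FALSE)
  d <- EBImage::imageData(EBImage::distmap(1 - cnt * 1L, metric = "euclidean"))
  d <- d * mask$res
  v <- 1 / d
  v[cnt] <- NA_real_
  structure(list(values = v, res = mask$res, label = mask$label),
            class = "proximity_map")
}

#' @rdname proximity_map
#' @param pm a `proximity_map`.
#' @return `mean_proximity`: the mean of the reciprocal distances over all
#'   gap pixels (1/um).
#' @export
mean_proximity <- function(pm) {
  if (inherits(pm, "raster_mask")) pm <- proximity_map(pm)
  mean(pm$values, na.rm = TRUE)
}

#' Largest connected gap area
#'
#' Area of the largest 4-connected gap component within the bounding
#' rectangle (diagonally touching gaps are not connected for cell
#' spreading).
#'
#' @param mask a `raster_mask`.
#' @return area in um^2.
#' @export
connected_gap_area <- function(mask) {
  gap <- !mask$cnt
  if (!any(gap)) return(0)
  lab <- EBImage::bwlabel(gap * 1L)
  max(tabulate(lab[lab > 0L])) * mask$res^2
}

#' Extremal gap rectangles
#'
#' `A_max` is found on the raster as the largest axis-aligned rectangle
#' contained entirely in the gaps (maximal-empty-rectangle search,
#' first-occurrence tie break in row-major order). `A_min` is the smallest
#' member of the family of branch-bounded gap rectangles and is taken from
#' the vector geometry (for H-trees, the rectangle framed by the two
#' finest branch orders); for row patterns every gap is the same rectangle.
#'
#' @param mask a `raster_mask`.
#' @param design the design the mask was built from (for the vector
#'   `A_min`); defaults to recomputing nothing and using the raster minimum
#'   if omitted.
#' @return list with `A_min`, `A_max`, `A_r` (um^2, um^2, ratio) and the
#'   raster rectangle `rect` (row/col/height/width in px).
#' @export
gap_rectangles <- function(mask, design = NULL) {
  gap <- !mask$cnt
  if (!any(gap)) stop("undefined: mask has no gap", call. = FALSE)
  mr <- cpp_max_rect(gap)
  A_max <- mr[1] * mask$res^2
  A_min <- if (!is.null(design)) closed_form_metrics(design)$A_min else A_max
  list(A_min = A_min, A_max = A_max, A_r = A_max / A_min,
       rect = stats::setNames(mr[2:5], c("row", "col", "height", "width")))
}

#' Characteristic gap widths of an H-tree
#'
#' `min_gap_width` is the labelled finest gap `L_{N-2} - L_N - w/2`; it is
#' the clearance between the end face of a final-order branch and the
#' facing side of its grandparent crossbar, and is the quantity the
#' fabricated designs control. `max_gap_width = 2 L_0 - w` is the clear
#' span between the inner faces of the two order-1 branch pairs. The global
#' minimum face-to-face clearance over all segment pairs is available
#' separately as [min_clearance()].
#'
#' @param tree a `segment_tree` (H-tree; `m >= 2` for the minimum width).
#' @return width in micrometres.
#' @export
min_gap_width <- function(tree) {
  d <- tree$design
  if (tree$type == "rows") return(d$w_si)
  if (d$m < 2) stop("min_gap_width needs m >= 2", call. = FALSE)
  L <- segment_lengths(d)
  v <- L[d$N - 2 + 1] - L[d$N + 1] - d$w_cnt / 2
  if (v <= 0) stop("branches collide: negative minimum gap", call. = FALSE)
  v
}

#' @rdname min_gap_width
#' @export
max_gap_width <- function(tree) {
  d <- tree$design
  if (tree$type == "rows") return(d$w_si)
  2 * d$L0 - d$w_cnt
}

#' Global minimum clearance between non-touching branch rectangles
#'
#' Smallest face-to-face distance over all segment pairs that do not share
#' a junction. Quadratic scan in blocks; exact for axis-aligned geometry.
#'
#' @param tree a `segment_tree`.
#' @param chunk pair-block size.
#' @return clearance in micrometres.
#' @export
min_clearance <- function(tree, chunk = 2e6) {
  r <- tree$rects
  n <- nrow(r)
  pr <- tree$segments$parent
  best <- Inf
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- sequence((n - 1):1) + ii
  for (start in seq(1, length(ii), by = chunk)) {
    k <- start:min(start + chunk - 1, length(ii))
    i <- ii[k]; j <- jj[k]
    dx <- pmax(0, pmax(r[i, "x0"], r[j, "x0"]) - pmin(r[i, "x1"], r[j, "x1"]))
    dy <- pmax(0, pmax(r[i, "y0"], r[j, "y0"]) - pmin(r[i, "y1"], r[j, "y1"]))
    d <- sqrt(dx^2 + dy^2)
    touch <- d == 0
    d[touch] <- Inf
    m <- min(d)
    if (m < best) best <- m
  }
  best
}

#' Raster edge length and areas
#'
#' `edge_length_raster` counts branch/gap (and branch/outside) pixel face
#' adjacencies and multiplies by the resolution -- exact for axis-aligned
#' geometry up to pixel-alignment error. `area_raster` returns label counts
#' times the pixel area.
#'
#' @param mask a `raster_mask`.
#' @return edge length in um, or list of areas in um^2.
#' @export
edge_length_raster <- function(mask) {
  cnt <- mask$cnt
  nr <- nrow(cnt); nc <- ncol(cnt)
  faces <- sum(cnt[1, ]) + sum(cnt[nr, ]) + sum(cnt[, 1]) + sum(cnt[, nc])
  faces <- faces + sum(cnt[-1, ] != cnt[-nr, ]) + sum(cnt[, -1] != cnt[, -nc])
  faces * mask$res
}

#' @rdname edge_length_raster
#' @export
area_raster <- function(mask) {
  n_cnt <- sum(mask$cnt)
  n_all <- length(mask$cnt)
  px <- mask$res^2
  list(A_CNT = n_cnt * px, A_Si = (n_all - n_cnt) * px, A_bounding = n_all * px)
}

#' Raster-side metric bundle
#'
#' Convenience wrapper computing the raster oracle values (areas, edge
#' length, proximity, largest connected gap, largest empty rectangle) for a
#' mask.
#'
#' @param mask a `raster_mask`.
#' @param design optional design for the vector `A_min`.
#' @param proximity compute the (relatively expensive) distance transform.
#' @return named list.
#' @export
raster_metrics <- function(mask, design = NULL, proximity = TRUE) {
  ar <- area_raster(mask)
  gr <- gap_rectangles(mask, design)
  out <- c(ar, list(E = edge_length_raster(mask),
                    A_c = connected_gap_area(mask),
                    A_max = gr$A_max, A_min = gr$A_min, A_r = gr$A_r))
  if (proximity) out$P <- mean_proximity(mask)
  out
}
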