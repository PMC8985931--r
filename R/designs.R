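#' Fractal (H-tree) electrode design
#'
#' Parametric description of an H-tree electrode: branches of constant width
#' `w_cnt` whose lengths shrink between repeating levels at a rate set by the
#' fractal dimension `D` (length of an order-`n` segment is
#' `L_n = L_0 / 2^(n/D)`). A design with `m` repeating levels of the H motif
#' contains segment orders `0..N` with `N = 2m - 1`. The base length `L_0` is
#' solved from the overall pattern width `W` so that
#' `W = 2 * sum(L_n, n even) + w_cnt`.
#'
#' @param D fractal dimension, `1 < D <= 2`. `D = 2` is space filling; lower
#'   values shrink the repeating levels faster.
#' @param m number of repeating H levels (integer `>= 1`).
#' @param w_cnt branch width in micrometres.
#' @param W overall pattern width in micrometres.
#' @param label optional text tag, e.g. `"1.1-4"`.
#' @return An object of class `fractal_design` with fields `D`, `m`, `N`,
#'   `w_cnt`, `W`, `L0` and `label`.
#' @seealso [solve_base_length()], [build_htree()], [closed_form_metrics()]
#' @export
#' @examples
#' d <- fractal_design(D = 2, m = 6, w_cnt = 20, W = 6262)
#' d$L0
fractal_design <- function(D, m, w_cnt = 20, W, label = NULL) {
  stopifnot(is.numeric(D), length(D) == 1L, is.numeric(m), length(m) == 1L)
  if (!(D > 1 && D <= 2)) stop("invalid design: need 1 < D <= 2", call. = FALSE)
  if (m < 1 || m != round(m)) stop("invalid design: m must be an integer >= 1", call. = FALSE)
  if (!(w_cnt > 0)) stop("invalid design: w_cnt must be positive", call. = FALSE)
  if (!(W > w_cnt)) stop("invalid design: W must exceed w_cnt", call. = FALSE)
  d <- structure(
    list(type = "htree", D = D, m = as.integer(m), N = as.integer(2 * m - 1),
         w_cnt = w_cnt, W = W,
         label = label %||% sprintf("%g-%d", D, as.integer(m))),
    class = "fractal_design")
  d$L0 <- solve_base_length(d)
  d
}

#' Euclidean row electrode design
#'
#' Rows of textured electrode material of width `w_cnt` separated by smooth
#' gaps of width `w_si`, packed into an overall width `W`. The number of rows
#' is the largest integer with
#' `n_rows * w_cnt + (n_rows - 1) * w_si <= W`.
#'
#' @param w_cnt row width (micrometres).
#' @param w_si gap width (micrometres).
#' @param W overall pattern width (micrometres); the rows run the full width.
#' @param label optional text tag, e.g. `"S75C75"`.
#' @return An object of class `euclidean_design` with derived `n_rows` and
#'   pattern `height`.
#' @export
#' @examples
#' euclidean_design(100, 100)$n_rows  # 30 rows
euclidean_design <- function(w_cnt, w_si, W = 6000, label = NULL) {
  if (!(w_cnt > 0) || !(w_si > 0)) {
    stop("invalid design: w_cnt and w_si must be positive", call. = FALSE)
  }
  if (w_cnt > W) stop("invalid design: w_cnt must not exceed W", call. = FALSE)
  n_rows <- floor((W + w_si) / (w_cnt + w_si))
  if (n_rows < 2) {
    warning("degenerate design: fewer than 2 rows fit into W", call. = FALSE)
  }
  structure(
    list(type = "rows", w_cnt = w_cnt, w_si = w_si, W = W,
         n_rows = as.integer(n_rows),
         height = n_rows * w_cnt + (n_rows - 1) * w_si,
         label = label %||% sprintf("S%gC%g", w_si, w_cnt)),
    class = "euclidean_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve the H-tree base segment length
#'
#' The base length satisfies the width constraint exactly:
#' `W = 2 * sum_{even n, 0 <= n <= N-1} L_0 / 2^(n/D) + w_cnt`
#' (the horizontal half-extents of the tree plus the width of the outermost
#' vertical branches).
#'
#' @param design a [fractal_design()].
#' @return `L_0` in micrometres.
#' @export
solve_base_length <- function(design) {
  stopifnot(inherits(design, "fractal_design"))
  denom <- 2 * sum(2^(-2 * (0:(design$m - 1)) / design$D))
  L0 <- (design$W - design$w_cnt) / denom
  if (!(L0 > 0)) stop("invalid design: W too small for a positive base length", call. = FALSE)
  L0
}

#' Branch segment lengths by order
#'
#' @param design a [fractal_design()].
#' @return numeric vector `L_n` for `n = 0..N` (micrometres).
#' @export
segment_lengths <- function(design) {
  stopifnot(inherits(design, "fractal_design"))
  design$L0 / 2^((0:design$N) / design$D)
}

#' Experimental fractal electrode catalog
#'
#' The five fabricated H-tree designs: branch width 20 micrometres
#' throughout; overall width 6020 micrometres for the m = 4 designs and
#' 6262 micrometres for the m = 5 and 6 designs (chosen so the smallest
#' branch-to-branch gap of the 2-6 design is 25 micrometres).
#'
#' @return named list of [fractal_design()] objects.
#' @export
fractal_designs <- function() {
  specs <- list(
    `1.1-4` = c(1.1, 4, 6020),
    `1.5-4` = c(1.5, 4, 6020),
    `2-4`   = c(2.0, 4, 6020),
    `2-5`   = c(2.0, 5, 6262),
    `2-6`   = c(2.0, 6, 6262))
  out <- lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    fractal_design(D = s[1], m = s[2], w_cnt = 20, W = s[3], label = nm)
  })
  names(out) <- names(specs)
  out
}

#' Experimental Euclidean electrode catalog
#'
#' The seven fabricated row designs, all with overall width 6000
#' micrometres: rows of width 100 micrometres with gaps of 25-100
#' micrometres, plus equal row/gap designs of 25, 50 and 75 micrometres.
#'
#' @return named list of [euclidean_design()] objects.
#' @export
euclidean_designs <- function() {
  specs <- list(
    S100C100 = c(100, 100), S75C100 = c(100, 75), S50C100 = c(100, 50),
    S25C100 = c(100, 25), S75C75 = c(75, 75), S50C50 = c(50, 50),
    S25C25 = c(25, 25))
  out <- lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    euclidean_design(w_cnt = s[1], w_si = s[2], W = 6000, label = nm)
  })
  names(out) <- names(specs)
  out
}

#' Simulated wide-gap Euclidean series
#'
#' Row designs with `W = 6000`, `w_cnt = 100` and gap widths from 200 to
#' 1100 micrometres in 100 micrometre steps, used to compare proximity
#' against connected gap area; the 1100 micrometre upper limit makes the
#' largest connected gap comparable to that of the most open fractal design.
#'
#' @return list of [euclidean_design()] objects (length 10).
#' @export
euclidean_sim_series <- function() {
  lapply(seq(200, 1100, by = 100), function(ws) {
    euclidean_design(w_cnt = 100, w_si = ws, W = 6000,
                     label = sprintf("S%dC100", ws))
  })
}

#' Simulated H-tree series over fractal dimension
#'
#' H-trees with `W = 6262`, branch width 20 micrometres and `D` from 1.1 to
#' 2.0 in 0.1 steps at a fixed number of repeating levels.
#'
#' @param m number of repeating levels (default 4).
#' @return list of [fractal_design()] objects.
#' @export
htree_sim_series <- function(m = 4) {
  lapply(seq(1.1, 2.0, by = 0.1), function(D) {
    fractal_design(D = D, m = m, w_cnt = 20, W = 6262)
  })
}

#' @export
print.fractal_design <- function(x, ...) {
  cat(sprintf("H-tree design %s: D = %g, m = %d (orders 0..%d), w_cnt = %g um, W = %g um, L0 = %.2f um\n",
              x$label, x$D, x$m, x$N, x$w_cnt, x$W, x$L0))
  invisible(x)
}

#' @export
print.euclidean_design <- function(x, ...) {
  cat(sprintf("Euclidean row design %s: w_cnt = %g um, w_si = %g um, W = %g um, %d rows, height = %g um\n",
              x$label, x$w_cnt, x$w_si, x$W, x$n_rows, x$height))
  invisible(x)
}

#' Read / write electrode designs as JSON
#'
#' Designs are stored as a flat JSON object with a `type` field
#' (`"htree"` or `"rows"`).
#'
#' @param path file path.
#' @return [fractal_design()] or [euclidean_design()].
#' @export
read_design <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to read design files", call. = FALSE)
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(j$type, "htree")) {
    fractal_design(D = j$D, m = j$m, w_cnt = j$w_cnt, W = j$W, label = j$label)
  } else if (identical(j$type, "rows")) {
    euclidean_design(w_cnt = j$w_cnt, w_si = j$w_si, W = j$W, label = j$label)
  } else {
    stop("unknown design type: ", j$type, call. = FALSE)
  }
}

#' @rdname read_design
#' @param design a design object.
#' @export
write_design <- function(design, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write design files", call. = FALSE)
  }
  keep <- intersect(names(design), c("type", "D", "m", "w_cnt", "w_si", "W", "label"))
  jsonlite::write_json(design[keep], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
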