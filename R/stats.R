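#' Kruskal-Wallis omnibus test over groups
#'
#' Rank-based H with tie correction and a chi-square reference distribution
#' with `k - 1` degrees of freedom (delegates to [stats::kruskal.test()]).
#' If every observation is identical the test is degenerate and returns
#' `H = 0`, `p = 1`.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @return list with `H`, `df`, `p`.
#' @export
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$H  # 7.2
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) < 2) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics from the pooled ranks with tie correction,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{n(n+1)}{12} - \frac{\sum_t (t^3 - t)}{12(n-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' with two-sided normal p-values, optionally adjusted for multiplicity.
#'
#' @param groups list of numeric vectors; names are used as group labels.
#' @param adjust `"none"` (the common report after a significant omnibus
#'   test), `"holm"` or `"bonferroni"`.
#' @return data.frame with one row per pair: `group1`, `group2`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_posthoc <- function(groups, adjust = c("none", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  labs <- names(groups) %||% as.character(seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(length(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(v0 * (1 / ni[i] + 1 / ni[j]))
    z[k] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]],
             z = z, p = p, p_adj = stats::p.adjust(p, method = adjust))
}

#' Bootstrap percentile confidence interval of the median
#'
#' @param values numeric sample (`n >= 3` for a meaningful interval).
#' @param conf confidence level.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed; the interval is deterministic given the seed.
#' @return list with `median`, `ci_low`, `ci_high`, `n`; for `n < 3` the
#'   interval is `NA` and `flag` explains why.
#' @export
median_ci <- function(values, conf = 0.95, n_boot = 1e4, seed = 1L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) {
    return(list(median = if (n) stats::median(values) else NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, n = n,
                flag = "interval undefined for n < 3"))
  }
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  meds <- apply(idx, 1, function(i) stats::median(values[i]))
  q <- stats::quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(median = stats::median(values), ci_low = q[1], ci_high = q[2], n = n,
       flag = NULL)
}

#' Significance stars
#'
#' `*` for p <= 0.05, `**` <= 0.01, `***` <= 0.001, `****` <= 0.0001.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", ""), right = TRUE) |> as.character()
}

#' Grouped medians, confidence intervals and nonparametric comparisons
#'
#' For each requested grouping key, summarizes a herding-results table with
#' per-group n, median and bootstrap 95% CI of `value`, plus the
#' Kruskal-Wallis omnibus test and Dunn's pairwise table across the groups.
#'
#' @param results data.frame of per-electrode results (e.g. rows of
#'   `herding_result`).
#' @param group_by name of the grouping column.
#' @param value name of the measured column to compare.
#' @param adjust multiplicity adjustment for the Dunn table.
#' @param alpha significance level recorded in the output.
#' @param seed seed for the bootstrap CIs.
#' @return object of class `group_comparison`: list with `summary`
#'   (data.frame), `kw`, `dunn` (or `NULL` for a single group), `group_by`,
#'   `value`, `alpha`.
#' @export
summarize_study <- function(results, group_by, value, adjust = "none",
                            alpha = 0.05, seed = 1L) {
  if (!group_by %in% names(results)) stop("unknown grouping key: ", group_by, call. = FALSE)
  if (!value %in% names(results)) stop("unknown value column: ", value, call. = FALSE)
  sp <- split(results[[value]], results[[group_by]])
  sp <- lapply(sp, function(v) v[!is.na(v)])
  sp <- sp[lengths(sp) > 0]
  summ <- do.call(rbind, lapply(names(sp), function(nm) {
    ci <- median_ci(sp[[nm]], seed = seed)
    data.frame(group = nm, n = ci$n, median = ci$median,
               ci_low = ci$ci_low, ci_high = ci$ci_high)
  }))
  if (length(sp) >= 2) {
    kw <- kruskal_wallis(sp)
    dn <- dunn_posthoc(sp, adjust = adjust)
    dn$stars <- p_stars(dn$p_adj)
  } else {
    kw <- NULL; dn <- NULL
  }
  structure(list(summary = summ, kw = kw, dunn = dn,
                 group_by = group_by, value = value, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Comparison of %s by %s\n", x$value, x$group_by))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$kw)) {
    cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g\n",
                x$kw$H, x$kw$df, x$kw$p))
    print(x$dunn, row.names = FALSE)
  }
  invisible(x)
}
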