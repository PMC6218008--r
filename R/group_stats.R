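#' Per-image total crack areas for one sample series
#'
#' @param series_name name of the series (subdirectory name).
#' @param totals_um2 per-image total crack areas in um^2 (one value per
#'   image; the sum of `area_um2` over that image's cracks).
#' @return A `series_areas` list.
#' @export
series_areas <- function(series_name, totals_um2) {
  stopifnot(is.character(series_name), length(series_name) == 1L)
  if (anyNA(totals_um2) || any(totals_um2 < 0)) {
    stop("total areas must be non-negative and non-missing", call. = FALSE)
  }
  structure(list(series_name = series_name,
                 totals_um2 = as.numeric(totals_um2)),
            class = "series_areas")
}

#' Compare crack burden between two sample series
#'
#' Routed two-sample comparison of per-image total crack areas. The test is
#' chosen by the data: Shapiro-Wilk normality on each series first; if
#' either rejects at `alpha`, a two-sided Wilcoxon rank-sum (Mann-Whitney)
#' test is run. If both pass, Bartlett's test compares variances: equal
#' variances route to Student's t (pooled variance), unequal to Welch's t.
#' Every intermediate p-value and the routing are recorded so the decision
#' can be audited.
#'
#' @param a,b [series_areas()] with at least 3 values each (the Shapiro-Wilk
#'   minimum).
#' @param alpha significance level used for the Shapiro and Bartlett gates
#'   (default 0.05); the final p-value is reported, not gated.
#' @return A `comparison_result` with `names`, `shapiro_p` (named pair),
#'   `bartlett_p` (NA when the route skipped it), `chosen_test` (one of
#'   `"student_t"`, `"welch_t"`, `"wilcoxon_rank_sum"`), `statistic`,
#'   `p_value`, `alpha`.
#' @export
compare_series <- function(a, b, alpha = 0.05) {
  stopifnot(inherits(a, "series_areas"), inherits(b, "series_areas"))
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)", call. = FALSE)
  for (s in list(a, b)) {
    if (length(s$totals_um2) < 3L) {
      stop(sprintf(
        "insufficient sample: series '%s' has %d image(s); Shapiro's test needs >= 3",
        s$series_name, length(s$totals_um2)), call. = FALSE)
    }
  }
  x <- a$totals_um2; y <- b$totals_um2
  sh <- c(shapiro.test(x)$p.value, shapiro.test(y)$p.value)
  names(sh) <- c(a$series_name, b$series_name)
  if (any(sh < alpha)) {
    chosen <- "wilcoxon_rank_sum"
    bart_p <- NA_real_
    ht <- wilcox.test(x, y, alternative = "two.sided",
                      exact = length(x) <= 20 && length(y) <= 20 &&
                        !any(duplicated(c(x, y))),
                      correct = TRUE)
  } else {
    bart_p <- bartlett.test(list(x, y))$p.value
    if (bart_p >= alpha) {
      chosen <- "student_t"
      ht <- t.test(x, y, var.equal = TRUE)
    } else {
      chosen <- "welch_t"
      ht <- t.test(x, y, var.equal = FALSE)
    }
  }
  structure(list(names = c(a$series_name, b$series_name),
                 shapiro_p = sh, bartlett_p = bart_p,
                 chosen_test = chosen,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s\n", x$names[1], x$names[2]))
  cat(sprintf("  Shapiro p: %.4g / %.4g; Bartlett p: %s\n",
              x$shapiro_p[1], x$shapiro_p[2],
              if (is.na(x$bartlett_p)) "n/a" else sprintf("%.4g", x$bartlett_p)))
  cat(sprintf("  chosen test: %s, statistic = %.4g, p = %.4g\n",
              x$chosen_test, x$statistic, x$p_value))
  invisible(x)
}

#' All pairwise series comparisons
#'
#' Runs [compare_series()] on every pair of series. No multiple-testing
#' correction is applied: each comparison is reported as a stand-alone
#' two-set comparison, which callers should keep in mind when more than two
#' series are configured.
#'
#' @param series_list list of [series_areas()], length >= 2.
#' @param alpha gate level passed to [compare_series()].
#' @return List of `comparison_result`s, one per unordered pair, in
#'   combination order.
#' @export
compare_all_series <- function(series_list, alpha = 0.05) {
  stopifnot(length(series_list) >= 2L)
  pairs <- utils::combn(length(series_list), 2)
  lapply(seq_len(ncol(pairs)), function(k) {
    compare_series(series_list[[pairs[1, k]]], series_list[[pairs[2, k]]],
                   alpha = alpha)
  })
}
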