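#' Incremental two-group significance scan
#'
#' Refines the threshold choice inside a candidate FIT window by asking at
#' which threshold the rise in urgent conversions first becomes — and stays —
#' statistically significant. Patients are split into a low-FIT reference
#' group (Group 1: FIT <= `g1_max`) and, at each candidate threshold t in
#' `[scan_lo, scan_hi]`, a rising-FIT group; urgent conversion is compared
#' between the groups by logistic regression (odds ratio, Wald 95% CI and
#' p-value per threshold).
#'
#' Two readings of "the group at threshold t" are supported:
#' `group2 = "cumulative"` (default) takes Group 2(t) = (`g1_max`, t], which
#' grows with t; `group2 = "tail"` takes Group 2(t) = \[t, `scan_hi`\].
#'
#' "Persistently significant" means significant at t and at every larger
#' evaluable threshold in the scan range; `first_sustained` is the smallest
#' such t, or `NA` if none. Thresholds with an empty group or a zero cell in
#' the 2x2 table are flagged and skipped by the sustained-run logic rather
#' than silently dropped.
#'
#' @param cohort A `cohort_table` (or data frame with `fit_value` and
#'   `urgent`).
#' @param g1_max Upper FIT bound of the low-FIT reference group (ug/g),
#'   default 10.
#' @param scan_lo,scan_hi Scan range bounds (ug/g), defaults 11 and 29.
#' @param alpha Significance level, default 0.05.
#' @param step Scan step in ug/g, default 1.
#' @param group2 `"cumulative"` or `"tail"` (see Details).
#' @return A `significance_scan` object: list with `rows` (tibble: `t`,
#'   `n1`, `n2`, `events1`, `events2`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `flagged`), `first_sustained`, and the settings.
#' @examples
#' cohort <- generate_cohort(synthetic_params(n = 2000, seed = 11))
#' incremental_significance_scan(cohort)$first_sustained
#' @export
incremental_significance_scan <- function(cohort, g1_max = 10,
                                          scan_lo = 11, scan_hi = 29,
                                          alpha = 0.05, step = 1,
                                          group2 = c("cumulative", "tail")) {
  group2 <- rlang::arg_match(group2)
  stopifnot(is.data.frame(cohort),
            all(c("fit_value", "urgent") %in% names(cohort)),
            g1_max > 0, scan_lo > g1_max, scan_hi >= scan_lo,
            alpha > 0, alpha < 1, step > 0)
  fit <- cohort$fit_value
  urgent <- as.logical(cohort$urgent)
  in_g1 <- fit <= g1_max
  if (!any(in_g1)) rlang::abort("Group 1 (low FIT) is empty")

  ts <- seq(scan_lo, scan_hi, by = step)
  rows <- purrr::map_dfr(ts, function(t) {
    in_g2 <- if (group2 == "cumulative") fit > g1_max & fit <= t
             else fit >= t & fit <= scan_hi
    n1 <- sum(in_g1); n2 <- sum(in_g2)
    e1 <- sum(urgent[in_g1]); e2 <- sum(urgent[in_g2])
    cells <- c(e1, n1 - e1, e2, n2 - e2)
    if (n2 == 0L || any(cells == 0)) {
      return(tibble::tibble(t = t, n1 = n1, n2 = n2, events1 = e1,
                            events2 = e2, odds_ratio = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p_value = NA_real_, flagged = TRUE))
    }
    d <- tibble::tibble(
      grp = rep(c(0L, 1L), c(n1, n2)),
      y = c(urgent[in_g1], urgent[in_g2])
    )
    m <- fit_logistic(d, "y", "grp")
    row <- m$terms[m$terms$term == "grp", ]
    tibble::tibble(t = t, n1 = n1, n2 = n2, events1 = e1, events2 = e2,
                   odds_ratio = row$odds_ratio, ci_low = row$ci_low,
                   ci_high = row$ci_high, p_value = row$p_value,
                   flagged = FALSE)
  })

  # smallest t significant at t and at every larger evaluable t
  ok <- !rows$flagged
  sig <- ok & rows$p_value < alpha
  first_sustained <- NA_real_
  if (any(ok)) {
    # among evaluable rows (right to left): all later evaluable rows significant
    sustained <- rev(cumprod(rev(ifelse(ok, sig, TRUE)))) == 1
    cand <- which(sustained & ok & sig)
    if (length(cand)) first_sustained <- rows$t[min(cand)]
  }

  structure(list(rows = rows, first_sustained = first_sustained,
                 g1_max = g1_max, scan_lo = scan_lo, scan_hi = scan_hi,
                 alpha = alpha, step = step, group2 = group2),
            class = "significance_scan")
}

#' @export
print.significance_scan <- function(x, ...) {
  cat(sprintf(
    "<significance_scan> Group 1: FIT <= %g; scan %g-%g by %g (%s); alpha %g\n",
    x$g1_max, x$scan_lo, x$scan_hi, x$step, x$group2, x$alpha))
  cat(if (is.na(x$first_sustained))
    " no sustained significant threshold in range\n"
    else sprintf(" first sustained significant threshold: %g ug/g\n",
                 x$first_sustained))
  invisible(x)
}

#' @rdname incremental_significance_scan
#' @param x,object A `significance_scan` object.
#' @param ... Unused.
#' @method tidy significance_scan
#' @export
tidy.significance_scan <- function(x, ...) x$rows

#' @rdname incremental_significance_scan
#' @method autoplot significance_scan
#' @export
autoplot.significance_scan <- function(object, ...) {
  d <- object$rows[!object$rows$flagged, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$p_value)) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "FIT threshold (ug/g)", y = "p-value",
                  title = "Evolution of significance across the scan range") +
    ggplot2::theme_minimal()
  if (!is.na(object$first_sustained)) {
    p <- p + ggplot2::geom_vline(xintercept = object$first_sustained,
                                 colour = "blue", linetype = "dotted")
  }
  p
}
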