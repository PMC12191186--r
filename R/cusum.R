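#' CUSUM cumulative-count scan over FIT thresholds
#'
#' Walks an ascending grid of FIT thresholds in exact 0.1 ug/g steps and, at
#' each threshold t, counts the patients with FIT <= t (the subgroup a
#' FIT-triage policy would send to capsule endoscopy) and how many of them
#' are urgent conversions. A one-step increase in the cumulative urgent
#' count of at least `min_jump` cases is a "jump point" — a candidate
#' inflection threshold. Detection-limit imputation stacks patients at the
#' assay limits, so jumps at those values reflect the assays, not biology.
#'
#' All grid arithmetic is integer, in deci-ug/g units (1 unit = 0.1 ug/g);
#' FIT values are matched to the grid by rounding to the same resolution, so
#' there is no floating-point drift along the scan.
#'
#' @param cohort A `cohort_table` (or data frame with `fit_value` and
#'   `urgent`).
#' @param step Grid step in ug/g; must be a positive multiple of 0.1.
#'   Default 0.1.
#' @param min_jump Minimum one-step increase in the cumulative urgent count
#'   that counts as a jump. Default 5 cases.
#' @param denominator `"triaged"` (default): conversion rate =
#'   cum_urgent / cum_total among patients with FIT <= t;
#'   `"cohort"`: divide by the full cohort size instead.
#' @return A `cusum_scan` object: list with `grid` (tibble: `threshold`,
#'   `threshold_deci`, `cum_urgent`, `cum_total`, `conversion_rate`,
#'   `jump_size`, `is_jump`), `jump_points` (tibble: `threshold`,
#'   `jump_size`, `cum_urgent`, `cum_total`, `conversion_rate`,
#'   `rate_diff` — absolute conversion-rate difference vs the previous jump
#'   point), and the scan settings. [tidy()] returns the grid,
#'   [autoplot()] the chart.
#' @examples
#' cohort <- generate_cohort(synthetic_params(n = 400, seed = 7))
#' scan <- cusum_scan(cohort)
#' scan$jump_points
#' @export
cusum_scan <- function(cohort, step = 0.1, min_jump = 5,
                       denominator = c("triaged", "cohort")) {
  denominator <- rlang::arg_match(denominator)
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L,
            all(c("fit_value", "urgent") %in% names(cohort)))
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    rlang::abort("step must be a positive number of ug/g")
  }
  step_deci <- as.integer(round(step * 10))
  if (step_deci < 1 || abs(step * 10 - step_deci) > 1e-9) {
    rlang::abort("step must be a positive multiple of 0.1 ug/g")
  }
  if (!is.numeric(min_jump) || length(min_jump) != 1L || min_jump < 1) {
    rlang::abort("min_jump must be a count >= 1")
  }

  fit_deci <- as.integer(round(cohort$fit_value * 10))
  urgent <- as.logical(cohort$urgent)
  n <- length(fit_deci)

  lo <- 10L * as.integer(floor(min(cohort$fit_value)))
  hi <- lo + as.integer(ceiling((max(fit_deci) - lo) / step_deci) * step_deci)
  grid_deci <- seq.int(lo, hi, by = step_deci)

  # cumulative counts at each grid point: #(fit <= t)
  cum_total <- findInterval(grid_deci, sort(fit_deci))
  cum_urgent <- findInterval(grid_deci, sort(fit_deci[urgent]))

  jump_size <- diff(c(0L, cum_urgent))
  is_jump <- jump_size >= min_jump
  denom <- if (denominator == "triaged") cum_total else rep(n, length(grid_deci))
  conversion_rate <- ifelse(denom > 0, cum_urgent / denom, 0)

  grid <- tibble::tibble(
    threshold = grid_deci / 10, threshold_deci = grid_deci,
    cum_urgent = cum_urgent, cum_total = cum_total,
    conversion_rate = conversion_rate,
    jump_size = jump_size, is_jump = is_jump
  )
  jp <- grid[grid$is_jump, c("threshold", "jump_size", "cum_urgent",
                             "cum_total", "conversion_rate")]
  jp$rate_diff <- c(NA_real_, abs(diff(jp$conversion_rate)))

  structure(list(grid = grid, jump_points = jp,
                 step = step, min_jump = min_jump,
                 denominator = denominator,
                 n = n, n_urgent = sum(urgent)),
            class = "cusum_scan")
}

#' Conversion rate at a grid threshold
#'
#' Looks up the colon-capsule-to-colonoscopy conversion rate at threshold
#' `t` of a [cusum_scan()]. `t` must lie exactly on the scan grid: there is
#' no silent snapping, because 0.1 ug/g neighbours can differ materially
#' when imputation stacks patients at one value.
#'
#' @param scan A `cusum_scan` object.
#' @param t Threshold in ug/g.
#' @return The conversion rate (proportion in `[0, 1]`).
#' @export
conversion_rate_at <- function(scan, t) {
  stopifnot(inherits(scan, "cusum_scan"), is.numeric(t), length(t) == 1L)
  t_deci <- round(t * 10)
  i <- match(t_deci, scan$grid$threshold_deci)
  if (abs(t * 10 - t_deci) > 1e-9) i <- NA_integer_
  if (is.na(i)) {
    nearest <- scan$grid$threshold[
      which.min(abs(scan$grid$threshold_deci - t * 10))]
    rlang::abort(sprintf(
      "threshold %g is not on the scan grid; nearest grid point is %g",
      t, nearest))
  }
  scan$grid$conversion_rate[i]
}

#' @export
print.cusum_scan <- function(x, ...) {
  cat(sprintf(
    "<cusum_scan> %d patients (%d urgent), grid %g-%g ug/g by %g; %d jump point(s) (>= %g cases)\n",
    x$n, x$n_urgent, min(x$grid$threshold), max(x$grid$threshold), x$step,
    nrow(x$jump_points), x$min_jump))
  if (nrow(x$jump_points)) {
    cat(" jumps at:", paste(x$jump_points$threshold, collapse = ", "),
        "ug/g\n")
  }
  invisible(x)
}

#' @rdname cusum_scan
#' @param x,object A `cusum_scan` object.
#' @param ... Unused.
#' @method tidy cusum_scan
#' @export
tidy.cusum_scan <- function(x, ...) x$grid

#' @rdname cusum_scan
#' @param type `"cusum"` for the cumulative urgent-count chart, `"rate"`
#'   for the conversion-rate chart.
#' @method autoplot cusum_scan
#' @export
autoplot.cusum_scan <- function(object, type = c("cusum", "rate"), ...) {
  type <- rlang::arg_match(type)
  g <- object$grid
  jp <- object$jump_points
  if (type == "cusum") {
    p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$threshold,
                                         y = .data$cum_urgent)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "FIT threshold (ug/g)",
                    y = "Cumulative urgent conversions",
                    title = sprintf("CUSUM scan: jump points at %s ug/g",
                                    paste(jp$threshold, collapse = ", ")))
    if (nrow(jp)) {
      p <- p + ggplot2::geom_point(data = jp,
                                   ggplot2::aes(y = .data$cum_urgent),
                                   colour = "red")
    }
  } else {
    p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$threshold,
                                         y = 100 * .data$conversion_rate)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "FIT threshold (ug/g)", y = "Conversion rate (%)",
                    title = "Conversion rate by FIT threshold")
    if (nrow(jp)) {
      p <- p + ggplot2::geom_point(
        data = jp, ggplot2::aes(y = 100 * .data$conversion_rate),
        colour = "red")
    }
  }
  p + ggplot2::scale_x_continuous(trans = "log10") + ggplot2::theme_minimal()
}
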