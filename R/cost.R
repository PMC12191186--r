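#' Monetary values of the four triage outcomes
#'
#' In a FIT-triage pathway, "positive" at a threshold means the patient goes
#' straight to colonoscopy; "negative" means capsule first. Against the
#' urgent label the four cells carry money:
#'
#' * true positive — saves the cost of a capsule that would only have
#'   converted anyway (`value_tp`, default the capsule cost);
#' * true negative — avoids a colonoscopy (`value_tn`, default the
#'   colonoscopy cost);
#' * false positive — a colonoscopy where a cheaper capsule would have
#'   sufficed (`loss_fp`, default the cost difference);
#' * false negative — a capsule that converts, so both procedures happen.
#'   Two accountings are supported: `fn_accounting = "incremental"`
#'   (default) charges the wasted capsule on top of the colonoscopy the
#'   patient needed anyway (`loss_fn` = capsule cost); `"absolute"` charges
#'   both procedures (`loss_fn` = capsule + colonoscopy).
#'
#' Costs default to a normalised scale (colonoscopy = 1) with the capsule
#' 17% cheaper; pass real tariffs in GBP for monetary curves in GBP.
#'
#' @param cost_colonoscopy Cost per conventional colonoscopy (default 1,
#'   i.e. normalised units).
#' @param cost_cce Cost per colon capsule procedure; default
#'   `0.83 * cost_colonoscopy`.
#' @param value_tp,value_tn Savings per true positive / true negative.
#' @param loss_fp,loss_fn Losses per false positive / false negative.
#' @param fn_accounting `"incremental"` or `"absolute"` (see Details);
#'   only used to pick the `loss_fn` default.
#' @return A `cost_model` object (a named list).
#' @export
cost_model <- function(cost_colonoscopy = 1,
                       cost_cce = 0.83 * cost_colonoscopy,
                       value_tp = cost_cce,
                       value_tn = cost_colonoscopy,
                       loss_fp = cost_colonoscopy - cost_cce,
                       loss_fn = NULL,
                       fn_accounting = c("incremental", "absolute")) {
  fn_accounting <- rlang::arg_match(fn_accounting)
  if (is.null(loss_fn)) {
    loss_fn <- if (fn_accounting == "incremental") cost_cce
               else cost_cce + cost_colonoscopy
  }
  vals <- c(cost_colonoscopy = cost_colonoscopy, cost_cce = cost_cce,
            value_tp = value_tp, value_tn = value_tn,
            loss_fp = loss_fp, loss_fn = loss_fn)
  if (any(vals < 0)) rlang::abort("cost magnitudes must be >= 0")
  structure(c(as.list(vals), list(fn_accounting = fn_accounting)),
            class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf(
    "<cost_model> colonoscopy %.4g, capsule %.4g | +TP %.4g +TN %.4g -FP %.4g -FN %.4g (%s FN accounting)\n",
    x$cost_colonoscopy, x$cost_cce, x$value_tp, x$value_tn, x$loss_fp,
    x$loss_fn, x$fn_accounting))
  invisible(x)
}

#' Monetary net benefit across FIT thresholds
#'
#' At each FIT threshold t, patients with FIT above t are sent straight to
#' colonoscopy (predicted positive) and the rest to capsule; the confusion
#' matrix against the urgent label is costed with a [cost_model()] and the
#' net benefit per patient is
#'
#'   (value_tp*TP + value_tn*TN - loss_fp*FP - loss_fn*FN) / n.
#'
#' The curve is linear in the cost vector, so scaling all costs rescales
#' the whole curve.
#'
#' @param cohort A `cohort_table` (or data frame with `fit_value` and
#'   `urgent`).
#' @param costs A [cost_model()].
#' @param fit_grid Ascending FIT thresholds (ug/g); default an integer grid
#'   spanning the observed FIT range.
#' @return A `monetary_curve` object: list with `curve` (tibble:
#'   `threshold`, `tp`, `fp`, `tn`, `fn`, `net_benefit_gbp`), `costs` and
#'   `n`. [tidy()] returns the curve; [steepest_declines()] ranks the
#'   drops.
#' @examples
#' cohort <- generate_cohort(synthetic_params(n = 500, seed = 3))
#' mc <- monetary_curve(cohort, cost_model(cost_colonoscopy = 1000))
#' steepest_declines(mc, k = 5)
#' @export
monetary_curve <- function(cohort, costs = cost_model(), fit_grid = NULL) {
  stopifnot(is.data.frame(cohort),
            all(c("fit_value", "urgent") %in% names(cohort)),
            inherits(costs, "cost_model"))
  fit <- cohort$fit_value
  y <- as.logical(cohort$urgent)
  n <- length(y)
  if (is.null(fit_grid)) {
    fit_grid <- seq(floor(min(fit)), ceiling(max(fit)), by = 1)
  }
  if (length(fit_grid) == 0L) rlang::abort("fit_grid is empty")
  if (is.unsorted(fit_grid, strictly = TRUE)) {
    rlang::abort("fit_grid must be strictly ascending")
  }

  counts <- purrr::map_dfr(fit_grid, function(t) {
    pos <- fit > t
    tibble::tibble(threshold = t,
                   tp = sum(pos & y), fp = sum(pos & !y),
                   tn = sum(!pos & !y), fn = sum(!pos & y))
  })
  counts$net_benefit_gbp <-
    (costs$value_tp * counts$tp + costs$value_tn * counts$tn -
       costs$loss_fp * counts$fp - costs$loss_fn * counts$fn) / n

  structure(list(curve = counts, costs = costs, n = n),
            class = "monetary_curve")
}

#' Steepest one-step declines of a monetary curve
#'
#' Ranks grid points by the size of the one-step drop in net benefit
#' relative to the previous grid point, `nb(t[i-1]) - nb(t[i])`; only
#' positive drops count as declines. Ties break toward the lower threshold.
#'
#' @param curve A [monetary_curve()] object.
#' @param k Number of decline points to return, default 5. Fewer are
#'   returned when the curve has fewer declines.
#' @return A tibble (`threshold`, `drop`, `net_benefit_before`,
#'   `net_benefit_after`), at most `k` rows, largest drop first.
#' @export
steepest_declines <- function(curve, k = 5) {
  stopifnot(inherits(curve, "monetary_curve"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    rlang::abort("k must be a count >= 1")
  }
  cv <- curve$curve
  if (nrow(cv) < 2L) rlang::abort("curve needs at least 2 grid points")
  drop <- -diff(cv$net_benefit_gbp)
  d <- tibble::tibble(threshold = cv$threshold[-1], drop = drop,
                      net_benefit_before = cv$net_benefit_gbp[-nrow(cv)],
                      net_benefit_after = cv$net_benefit_gbp[-1])
  d <- d[d$drop > 0, , drop = FALSE]
  d <- d[order(-d$drop, d$threshold), , drop = FALSE]
  utils::head(d, k)
}

#' @export
print.monetary_curve <- function(x, ...) {
  cat(sprintf(
    "<monetary_curve> n = %d, %d thresholds (%g-%g ug/g); net benefit %0.4g to %0.4g per patient\n",
    x$n, nrow(x$curve), min(x$curve$threshold), max(x$curve$threshold),
    min(x$curve$net_benefit_gbp), max(x$curve$net_benefit_gbp)))
  invisible(x)
}

#' @rdname monetary_curve
#' @param x,object A `monetary_curve` object.
#' @param ... Unused.
#' @method tidy monetary_curve
#' @export
tidy.monetary_curve <- function(x, ...) x$curve

#' @rdname monetary_curve
#' @param k Number of decline points to highlight.
#' @method autoplot monetary_curve
#' @export
autoplot.monetary_curve <- function(object, k = 5, ...) {
  dec <- steepest_declines(object, k = k)
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$threshold,
                                    y = .data$net_benefit_gbp)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "FIT threshold (ug/g)",
                  y = "Net benefit per patient",
                  title = "Cost-benefit curve across FIT thresholds") +
    ggplot2::theme_minimal()
  if (nrow(dec)) {
    p <- p + ggplot2::geom_point(
      data = dec, ggplot2::aes(y = .data$net_benefit_after), colour = "red")
  }
  p
}
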