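#' Decision curve analysis for FIT-based triage
#'
#' Fits the univariate logistic model of urgent conversion on continuous
#' FIT, then computes the net benefit of classifying patients high-risk at
#' each threshold probability p_t on a 0-1 grid (0.01 steps by default):
#'
#'   net benefit = TP/n - (FP/n) * p_t / (1 - p_t)
#'
#' in units of true positives per patient, alongside the treat-all and
#' treat-none reference policies. Because the model is monotone in FIT, each
#' p_t maps back to a FIT threshold via [prob_to_fit()], giving the curve a
#' clinical x-axis.
#'
#' Grid endpoints follow the limit conventions: at p_t = 0 the FP weight
#' vanishes (treat-all net benefit = event prevalence); at p_t = 1 no one is
#' classified positive and net benefit is 0.
#'
#' @param cohort A `cohort_table` (or data frame with `fit_value` and the
#'   outcome column).
#' @param outcome Name of the binary outcome column, default `"urgent"`.
#' @param grid_step Threshold-probability step, default 0.01.
#' @return A `dca_curve` object: list with `curve` (tibble: `threshold`
#'   (p_t), `net_benefit_model`, `net_benefit_all`, `net_benefit_none`,
#'   `fit_at_threshold`, `extrapolated`), `model` (the [fit_logistic()]
#'   fit), `prevalence`, `n` and `best` (one-row tibble with the
#'   net-benefit-maximising p_t and its FIT value).
#' @examples
#' cohort <- generate_cohort(synthetic_params(n = 500, seed = 3))
#' dca <- dca_curve(cohort)
#' dca$best
#' @export
dca_curve <- function(cohort, outcome = "urgent", grid_step = 0.01) {
  stopifnot(is.data.frame(cohort), "fit_value" %in% names(cohort),
            grid_step > 0, grid_step < 1)
  model <- fit_logistic(cohort, outcome = outcome, predictors = "fit_value")
  y <- as.logical(cohort[[outcome]])
  p <- model$predicted
  n <- length(y)
  prev <- mean(y)

  thresholds <- seq(0, 1, by = grid_step)
  w <- ifelse(thresholds < 1, thresholds / (1 - thresholds), Inf)

  nb_model <- vapply(seq_along(thresholds), function(i) {
    pt <- thresholds[i]
    if (pt >= 1) return(0)
    pos <- p >= pt
    tp <- sum(pos & y); fp <- sum(pos & !y)
    tp / n - (fp / n) * w[i]
  }, numeric(1))
  nb_all <- ifelse(thresholds < 1, prev - (1 - prev) * w, 0)

  b1 <- model$terms$estimate[model$terms$term == "fit_value"]
  interior <- thresholds > 0 & thresholds < 1
  fit_at <- rep(NA_real_, length(thresholds))
  extrap <- rep(NA, length(thresholds))
  if (b1 > 0) {
    mapped <- prob_to_fit(model, thresholds[interior])
    fit_at[interior] <- mapped$fit
    extrap[interior] <- mapped$extrapolated
  }

  curve <- tibble::tibble(
    threshold = thresholds,
    net_benefit_model = nb_model,
    net_benefit_all = nb_all,
    net_benefit_none = 0,
    fit_at_threshold = fit_at,
    extrapolated = extrap
  )
  ibest <- which.max(nb_model)
  best <- tibble::tibble(threshold = thresholds[ibest],
                         net_benefit = nb_model[ibest],
                         fit = fit_at[ibest])
  structure(list(curve = curve, model = model, prevalence = prev, n = n,
                 grid_step = grid_step, best = best),
            class = "dca_curve")
}

#' Map a threshold probability back to a FIT value
#'
#' Inverts the fitted univariate logistic model: for a threshold
#' probability p_t, the FIT value whose predicted probability equals p_t is
#' `(logit(p_t) - b0) / b1`. Only meaningful for a single-predictor model
#' with positive slope. Values outside the FIT range the model was fitted
#' on are flagged as extrapolated.
#'
#' @param fit_model A [fit_logistic()] object with exactly one (numeric)
#'   predictor and positive slope.
#' @param p_t Threshold probabilities, strictly inside (0, 1).
#' @return A tibble with columns `p_t`, `fit` (ug/g) and `extrapolated`.
#' @examples
#' # logit(p) = -2 + 0.01 * FIT  =>  p = 0.5 at FIT = 200
#' @export
prob_to_fit <- function(fit_model, p_t) {
  stopifnot(inherits(fit_model, "fit_logistic"), is.numeric(p_t))
  if (length(fit_model$predictors) != 1L) {
    rlang::abort("prob_to_fit() needs a single-predictor model")
  }
  if (any(p_t <= 0 | p_t >= 1)) {
    rlang::abort("threshold probabilities must lie strictly inside (0, 1)")
  }
  pred <- fit_model$predictors
  b0 <- fit_model$terms$estimate[fit_model$terms$term == "(Intercept)"]
  b1 <- fit_model$terms$estimate[fit_model$terms$term == pred]
  if (b1 <= 0) {
    rlang::abort("model slope must be positive for a monotone-increasing FIT mapping")
  }
  fit <- (stats::qlogis(p_t) - b0) / b1
  rng <- fit_model$data_ranges[[pred]]
  tibble::tibble(p_t = p_t, fit = fit,
                 extrapolated = fit < rng[1] | fit > rng[2])
}

#' Optimal triage band of a decision curve
#'
#' The maximal contiguous threshold-probability interval where the model's
#' net benefit strictly exceeds both the treat-all and treat-none reference
#' policies, together with its FIT image and the net-benefit-maximising
#' point. An empty result (no such interval) is a valid outcome.
#'
#' @param dca A [dca_curve()] object.
#' @return A one-row tibble (`p_lo`, `p_hi`, `fit_lo`, `fit_hi`, `p_best`,
#'   `fit_best`, `nb_best`) or a zero-row tibble when the model never beats
#'   both references.
#' @export
optimal_band <- function(dca) {
  stopifnot(inherits(dca, "dca_curve"))
  cv <- dca$curve
  above <- cv$net_benefit_model > cv$net_benefit_all &
    cv$net_benefit_model > cv$net_benefit_none
  empty <- tibble::tibble(p_lo = double(), p_hi = double(),
                          fit_lo = double(), fit_hi = double(),
                          p_best = double(), fit_best = double(),
                          nb_best = double())
  if (!any(above)) return(empty)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  true_runs <- which(runs$values)
  pick <- true_runs[which.max(runs$lengths[true_runs])]
  i0 <- starts[pick]; i1 <- ends[pick]
  nb <- cv$net_benefit_model
  ibest <- (i0:i1)[which.max(nb[i0:i1])]
  tibble::tibble(
    p_lo = cv$threshold[i0], p_hi = cv$threshold[i1],
    fit_lo = cv$fit_at_threshold[i0], fit_hi = cv$fit_at_threshold[i1],
    p_best = cv$threshold[ibest], fit_best = cv$fit_at_threshold[ibest],
    nb_best = nb[ibest]
  )
}

#' @export
print.dca_curve <- function(x, ...) {
  cat(sprintf(
    "<dca_curve> n = %d, prevalence %.3f; max net benefit %.4f at p_t = %.2f (FIT %.2f ug/g)\n",
    x$n, x$prevalence, x$best$net_benefit, x$best$threshold, x$best$fit))
  invisible(x)
}

#' @rdname dca_curve
#' @param x,object A `dca_curve` object.
#' @param ... Unused.
#' @method tidy dca_curve
#' @export
tidy.dca_curve <- function(x, ...) x$curve

#' @rdname dca_curve
#' @method autoplot dca_curve
#' @export
autoplot.dca_curve <- function(object, ...) {
  d <- tidyr::pivot_longer(object$curve,
                           c("net_benefit_model", "net_benefit_all",
                             "net_benefit_none"),
                           names_to = "policy", values_to = "net_benefit")
  d$policy <- c(net_benefit_model = "FIT model", net_benefit_all = "Treat all",
                net_benefit_none = "Treat none")[d$policy]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                                  colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, object$prevalence * 1.2)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  colour = NULL, title = "Decision curve analysis") +
    ggplot2::theme_minimal()
}
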