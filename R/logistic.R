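#' Univariate or multivariable logistic regression with OR reporting
#'
#' Maximum-likelihood logistic regression via [stats::glm()], reported the
#' way clinical studies report it: odds ratios with Wald 95% confidence
#' intervals and Wald p-values per term. Zero-variance predictors are
#' rejected by name; complete (or quasi-complete) separation is detected and
#' surfaced as an explicit diagnostic rather than silently divergent
#' estimates.
#'
#' @param data A data frame (e.g. a `cohort_table`).
#' @param outcome Name of the binary outcome column (logical or 0/1).
#' @param predictors Character vector of predictor column names.
#' @param conf_level Confidence level for the Wald intervals, default 0.95.
#' @return A `fit_logistic` object: list with `terms` (tibble: `term`,
#'   `estimate` on the log-odds scale, `std_error`, `odds_ratio`, `ci_low`,
#'   `ci_high` on the OR scale, `p_value`), `n`, `converged`, `separation`,
#'   `predicted` (in-sample event probabilities), `outcome`, `predictors`,
#'   `data_ranges` and the underlying `glm` object as `fit`.
#' @examples
#' d <- tibble::tibble(exposed = rep(c(1, 0), each = 100),
#'                     y = c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95)))
#' tidy(fit_logistic(d, "y", "exposed"))
#' @export
fit_logistic <- function(data, outcome, predictors, conf_level = 0.95) {
  stopifnot(is.data.frame(data), rlang::is_string(outcome),
            is.character(predictors), length(predictors) >= 1L)
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss)) {
    rlang::abort(paste0("column(s) not in data: ", paste(miss, collapse = ", ")))
  }
  df <- tibble::as_tibble(data)[, c(outcome, predictors)]
  y <- as.logical(df[[outcome]])
  if (anyNA(df)) rlang::abort("missing values in outcome or predictors")
  if (all(y) || !any(y)) {
    rlang::abort(sprintf("outcome '%s' has a single class; model undefined",
                         outcome))
  }
  for (p in predictors) {
    v <- df[[p]]
    if (length(unique(v)) < 2L) {
      rlang::abort(sprintf("predictor '%s' has zero variance", p))
    }
  }
  if (nrow(df) <= length(predictors) + 1L) {
    rlang::abort("fewer observations than model terms")
  }

  df[[outcome]] <- as.integer(y)
  form <- stats::reformulate(predictors, response = outcome)
  fit <- suppressWarnings(stats::glm(form, data = df,
                                     family = stats::binomial()))

  sm <- summary(fit)$coefficients
  # Separation heuristic: fitted probabilities numerically 0/1 together with
  # exploding coefficients/SEs.
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) &&
    (max(abs(stats::coef(fit))) > 10 || max(sm[, "Std. Error"]) > 100)
  if (separation) {
    rlang::warn("possible complete separation: coefficient estimates are unreliable")
  }
  if (!fit$converged) {
    rlang::warn("glm did not converge")
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- unname(sm[, "Estimate"])
  se <- unname(sm[, "Std. Error"])
  terms <- tibble::tibble(
    term = rownames(sm),
    estimate = est,
    std_error = se,
    odds_ratio = exp(est),
    ci_low = exp(est - z * se),
    ci_high = exp(est + z * se),
    p_value = unname(sm[, "Pr(>|z|)"])
  )

  num <- predictors[vapply(df[predictors], is.numeric, logical(1))]
  structure(list(terms = terms, n = nrow(df),
                 converged = fit$converged, separation = separation,
                 predicted = unname(fit$fitted.values),
                 outcome = outcome, predictors = predictors,
                 conf_level = conf_level,
                 data_ranges = lapply(df[num], range),
                 fit = fit),
            class = "fit_logistic")
}

#' @export
print.fit_logistic <- function(x, ...) {
  cat(sprintf("<fit_logistic> %s ~ %s  (n = %d%s%s)\n", x$outcome,
              paste(x$predictors, collapse = " + "), x$n,
              if (!x$converged) ", NOT converged" else "",
              if (x$separation) ", SEPARATION suspected" else ""))
  print(x$terms)
  invisible(x)
}

#' @rdname fit_logistic
#' @param x,object A `fit_logistic` object.
#' @param ... Unused.
#' @method tidy fit_logistic
#' @export
tidy.fit_logistic <- function(x, ...) x$terms

#' @rdname fit_logistic
#' @method glance fit_logistic
#' @export
glance.fit_logistic <- function(x, ...) {
  tibble::tibble(n = x$n, n_terms = nrow(x$terms),
                 aic = stats::AIC(x$fit),
                 deviance = stats::deviance(x$fit),
                 converged = x$converged, separation = x$separation)
}
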