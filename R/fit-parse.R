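#' Parse raw FIT strings into censoring class and imputed value
#'
#' Quantitative FIT results are reported by laboratories either as exact
#' faecal haemoglobin concentrations (micrograms Hb per gram of faeces) or as
#' censored strings at the assay detection limits, e.g. `"<7"`, `"<10"`,
#' `">400"`. For modelling, censored results are imputed at the limit itself:
#' `"<7"` becomes 7, `"<10"` becomes 10 and `">400"` becomes 400. Different
#' sites run assays with different lower limits, so the accepted lower limits
#' are configuration, not constants.
#'
#' @param raw Character vector of raw FIT strings as reported.
#' @param limits An [assay_limits()] object giving the recognised lower
#'   detection limits and the upper detection limit.
#' @return A tibble with one row per input and columns `raw`, `censoring`
#'   (one of `"exact"`, `"below_lower_limit"`, `"above_upper_limit"`) and
#'   `value` (the imputed numeric concentration, always positive and finite).
#' @examples
#' parse_fit(c("<7", "23.4", ">400"))
#' @seealso [censor_fit()] for the inverse operation.
#' @export
parse_fit <- function(raw, limits = assay_limits()) {
  stopifnot(is.character(raw))
  if (length(raw) == 0L) {
    return(tibble::tibble(raw = character(), censoring = character(),
                          value = double()))
  }
  bad <- is.na(raw) | !nzchar(trimws(raw))
  if (any(bad)) {
    rlang::abort(sprintf("empty or missing FIT string at position %d",
                         which(bad)[1L]))
  }
  x <- trimws(raw)
  censoring <- rep("exact", length(x))
  value <- rep(NA_real_, length(x))

  below <- startsWith(x, "<")
  above <- startsWith(x, ">")
  censoring[below] <- "below_lower_limit"
  censoring[above] <- "above_upper_limit"

  payload <- x
  payload[below | above] <- substring(x[below | above], 2L)
  num <- suppressWarnings(as.numeric(payload))

  if (anyNA(num)) {
    rlang::abort(sprintf("cannot parse FIT value '%s': not numeric",
                         raw[which(is.na(num))[1L]]))
  }
  nonpos <- num <= 0
  if (any(nonpos)) {
    rlang::abort(sprintf(
      "invalid FIT value '%s': concentrations must be positive",
      raw[which(nonpos)[1L]]))
  }
  bad_lower <- below & !(num %in% limits$lower)
  if (any(bad_lower)) {
    rlang::abort(sprintf(
      "censoring marker '%s' uses an unrecognised lower limit (accepted: %s)",
      raw[which(bad_lower)[1L]], paste(limits$lower, collapse = ", ")))
  }
  bad_upper <- above & num != limits$upper
  if (any(bad_upper)) {
    rlang::abort(sprintf(
      "censoring marker '%s' uses an unrecognised upper limit (accepted: %s)",
      raw[which(bad_upper)[1L]], format(limits$upper)))
  }
  value <- num
  tibble::tibble(raw = raw, censoring = censoring, value = value)
}

#' Render a true FIT concentration as the lab-reported string
#'
#' Applies assay detection-limit censoring: values below the site's lower
#' limit are reported `"<L"`, values above the upper limit `">U"`, and
#' everything in between as decimal text at 0.1 ug/g resolution (the assay
#' reporting resolution; keeping it fixed makes serialisation lossless for
#' the threshold-scan arithmetic).
#'
#' @param value Numeric vector of true concentrations, ug Hb / g faeces (> 0).
#' @param lower_limit Lower detection limit(s), recycled against `value`.
#' @param upper_limit Upper detection limit (scalar).
#' @return Character vector of raw strings, parseable by [parse_fit()].
#' @examples
#' censor_fit(c(3.2, 23.41, 512), lower_limit = 7)
#' @export
censor_fit <- function(value, lower_limit = 10, upper_limit = 400) {
  stopifnot(is.numeric(value), all(is.finite(value)), all(value > 0),
            all(lower_limit > 0), length(upper_limit) == 1L,
            upper_limit > max(lower_limit))
  lower_limit <- rep_len(lower_limit, length(value))
  out <- sprintf("%.1f", round(value, 1))
  out[value < lower_limit] <-
    sprintf("<%s", format(lower_limit[value < lower_limit], trim = TRUE))
  out[value > upper_limit] <- sprintf(">%s", format(upper_limit, trim = TRUE))
  out
}

#' Assay detection limits
#'
#' FIT assays in use across sites have lower detection limits of 7 or
#' 10 ug/g and a shared upper limit of 400 ug/g; censored results pile up at
#' these limits after imputation, which is why they surface as jump points in
#' the threshold scan.
#'
#' @param lower Numeric vector of recognised lower detection limits (ug/g).
#' @param upper Scalar upper detection limit (ug/g).
#' @return An object of class `assay_limits`.
#' @export
assay_limits <- function(lower = c(7, 10), upper = 400) {
  stopifnot(is.numeric(lower), length(lower) >= 1L, all(lower > 0),
            is.numeric(upper), length(upper) == 1L, upper > max(lower))
  structure(list(lower = sort(unique(lower)), upper = upper),
            class = "assay_limits")
}

#' @export
print.assay_limits <- function(x, ...) {
  cat("<assay_limits> lower:", paste(x$lower, collapse = "/"),
      "upper:", x$upper, "ug/g\n")
  invisible(x)
}
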