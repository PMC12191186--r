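#' Conversion criteria: when do colonic findings mandate colonoscopy?
#'
#' A colon-capsule examination converts to conventional colonoscopy when the
#' findings need tissue diagnosis or resection. National referral criteria
#' are not enumerated in one place, so the rule is explicit configuration.
#' The default mirrors common practice: colorectal cancer always converts, as
#' does any polyp of at least `size_threshold` mm (an "advanced polyp" at the
#' default 10 mm) or a polyp burden of at least `count_threshold` polyps.
#'
#' @param size_threshold Largest-polyp size (mm) at or above which a patient
#'   is labelled urgent. Default 10 (advanced polyp).
#' @param count_threshold Polyp count at or above which a patient is labelled
#'   urgent. Default 3.
#' @param crc_always_urgent Should colorectal cancer always convert? Default
#'   `TRUE`.
#' @param extra_urgent_findings Character vector of labels in the cohort's
#'   `other_findings` column that also trigger conversion (e.g. `"IBD"`).
#'   Default empty.
#' @return An object of class `conversion_criteria`.
#' @export
conversion_criteria <- function(size_threshold = 10, count_threshold = 3,
                                crc_always_urgent = TRUE,
                                extra_urgent_findings = character()) {
  stopifnot(is.numeric(size_threshold), length(size_threshold) == 1L,
            size_threshold > 0,
            is.numeric(count_threshold), length(count_threshold) == 1L,
            count_threshold >= 1,
            rlang::is_bool(crc_always_urgent),
            is.character(extra_urgent_findings))
  structure(list(size_threshold = size_threshold,
                 count_threshold = count_threshold,
                 crc_always_urgent = crc_always_urgent,
                 extra_urgent_findings = extra_urgent_findings),
            class = "conversion_criteria")
}

#' @export
print.conversion_criteria <- function(x, ...) {
  cat("<conversion_criteria>\n",
      " urgent iff:", if (x$crc_always_urgent) "CRC, or" else "",
      sprintf("polyp >= %g mm, or >= %g polyps", x$size_threshold,
              x$count_threshold),
      if (length(x$extra_urgent_findings))
        paste(", or finding in {", paste(x$extra_urgent_findings,
                                         collapse = ", "), "}") else "",
      "\n")
  invisible(x)
}

# Vectorised conversion rule on raw finding columns. `other` is a character
# vector of ";"-separated labels (or NA).
urgent_rule <- function(crc, polyp_count, max_polyp_size, other = NULL,
                        criteria = conversion_criteria()) {
  out <- (criteria$crc_always_urgent & crc) |
    max_polyp_size >= criteria$size_threshold |
    polyp_count >= criteria$count_threshold
  if (length(criteria$extra_urgent_findings) && !is.null(other)) {
    labs <- strsplit(ifelse(is.na(other), "", other), ";", fixed = TRUE)
    hit <- vapply(labs, function(l)
      any(trimws(l) %in% criteria$extra_urgent_findings), logical(1))
    out <- out | hit
  }
  out
}

#' Derive the urgent-conversion label from colonic findings
#'
#' Adds (or overwrites) the logical `urgent` column: `TRUE` when the
#' patient's findings meet the active [conversion_criteria()]. The label is a
#' pure function of the findings, so re-deriving it is idempotent.
#'
#' @param data A data frame with columns `crc` (logical or 0/1),
#'   `polyp_count` and `max_polyp_size_mm`; an optional `other_findings`
#'   column (";"-separated labels) is consulted when the criteria list extra
#'   urgent findings.
#' @param criteria A [conversion_criteria()] object.
#' @return `data` as a tibble with the `urgent` column set.
#' @examples
#' df <- tibble::tibble(crc = c(TRUE, FALSE, FALSE),
#'                      polyp_count = c(0, 1, 1),
#'                      max_polyp_size_mm = c(0, 12, 4))
#' label_urgent(df)$urgent
#' @export
label_urgent <- function(data, criteria = conversion_criteria()) {
  stopifnot(is.data.frame(data), inherits(criteria, "conversion_criteria"))
  need <- c("crc", "polyp_count", "max_polyp_size_mm")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    rlang::abort(paste0("label_urgent() needs column(s): ",
                        paste(miss, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  other <- if ("other_findings" %in% names(data)) data$other_findings else NULL
  data$urgent <- urgent_rule(as.logical(data$crc), data$polyp_count,
                             data$max_polyp_size_mm, other, criteria)
  data
}
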