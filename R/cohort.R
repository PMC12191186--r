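#' Load and validate a patient-level cohort CSV
#'
#' Reads a cohort table with the documented column schema, parses and imputes
#' censored FIT strings, derives the urgent-conversion label, and applies the
#' complete-case rule: rows missing a FIT result, the polyp count or the
#' largest-polyp size are excluded (and counted), as are rows failing
#' validation, each with a row-indexed diagnostic.
#'
#' Expected columns (UTF-8, comma-separated, header row):
#' `id`, `age`, `sex` (`M`/`F`), `haemoglobin_g_l`, `fit_raw`,
#' `crc` (0/1), `polyp_count`, `max_polyp_size_mm`,
#' `bowel_prep` (`adequate`/`poor`/empty = missing). An optional
#' `other_findings` column carries ";"-separated extra labels.
#'
#' Haemoglobin is in g/L; values outside 30-250 g/L are rejected as probable
#' unit errors (g/dL values would sit near 11, SI values near 112).
#'
#' @param path Path to the CSV file.
#' @param criteria [conversion_criteria()] used to derive `urgent`.
#' @param limits [assay_limits()] recognised when parsing `fit_raw`.
#' @return A `cohort_table`: a tibble with the input columns plus
#'   `fit_censoring`, `fit_value` and `urgent`, carrying attributes
#'   `criteria`, `limits`, `provenance` and `exclusions` (a tibble of
#'   excluded rows with `row` and `reason`; retrieve with
#'   [cohort_exclusions()]).
#' @export
load_cohort <- function(path, criteria = conversion_criteria(),
                        limits = assay_limits()) {
  stopifnot(file.exists(path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               progress = FALSE))
  mandatory <- c("id", "age", "sex", "haemoglobin_g_l", "fit_raw", "crc",
                 "polyp_count", "max_polyp_size_mm")
  miss <- setdiff(mandatory, hdr)
  if (length(miss)) {
    rlang::abort(paste0("cohort CSV is missing mandatory column(s): ",
                        paste(miss, collapse = ", ")))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    haemoglobin_g_l = readr::col_double(),
    fit_raw = readr::col_character(),
    crc = readr::col_double(),
    polyp_count = readr::col_double(),
    max_polyp_size_mm = readr::col_double(),
    bowel_prep = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  if (!"bowel_prep" %in% names(raw)) raw$bowel_prep <- NA_character_
  as_cohort(raw, criteria = criteria, limits = limits,
            provenance = list(source = "file", path = path))
}

#' Validate an in-memory cohort data frame
#'
#' The workhorse behind [load_cohort()] and [generate_cohort()]: validates
#' row by row, imputes censored FIT values, derives the urgent label and
#' attaches the completeness report. Row-level failures become exclusions
#' with diagnostics; structural failures (missing columns, duplicate ids,
#' zero valid rows) are errors.
#'
#' @param data Data frame in the [load_cohort()] schema.
#' @inheritParams load_cohort
#' @param provenance A list describing where the table came from.
#' @return A `cohort_table` tibble (see [load_cohort()]).
#' @export
as_cohort <- function(data, criteria = conversion_criteria(),
                      limits = assay_limits(),
                      provenance = list(source = "data.frame")) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  n_in <- nrow(data)
  if (n_in == 0L) rlang::abort("cohort has zero rows")

  dup <- data$id[duplicated(data$id)]
  if (length(dup)) {
    rlang::abort(sprintf("duplicate patient id(s): %s",
                         paste(unique(dup), collapse = ", ")))
  }

  reason <- rep(NA_character_, n_in)
  note <- function(idx, msg) {
    fill <- idx & is.na(reason)
    reason[fill] <<- msg
  }

  # Complete-case rule: FIT, polyp count and largest polyp size must all be
  # present; covariates are not imputed.
  note(is.na(data$fit_raw) | !nzchar(trimws(ifelse(is.na(data$fit_raw), "",
                                                   data$fit_raw))),
       "missing FIT result")
  note(is.na(data$polyp_count), "missing polyp count")
  note(is.na(data$max_polyp_size_mm), "missing largest polyp size")
  note(is.na(data$id) | !nzchar(data$id), "missing id")
  note(is.na(data$age) | data$age < 18, "age missing or < 18")
  note(!data$sex %in% c("M", "F"), "sex not M/F")
  note(is.na(data$haemoglobin_g_l) | data$haemoglobin_g_l <= 0,
       "missing haemoglobin")
  note(!is.na(data$haemoglobin_g_l) &
         (data$haemoglobin_g_l < 30 | data$haemoglobin_g_l > 250),
       "haemoglobin outside 30-250 g/L (unit error?)")
  note(!data$crc %in% c(0, 1, TRUE, FALSE), "crc not 0/1")
  note(!is.na(data$polyp_count) &
         (data$polyp_count < 0 | data$polyp_count != round(data$polyp_count)),
       "polyp count not a non-negative integer")
  note(!is.na(data$max_polyp_size_mm) & data$max_polyp_size_mm < 0,
       "negative polyp size")
  note(!is.na(data$polyp_count) & !is.na(data$max_polyp_size_mm) &
         data$polyp_count == 0 & data$max_polyp_size_mm != 0,
       "polyp size recorded with zero polyp count")
  note(!is.na(data$bowel_prep) & !data$bowel_prep %in% c("adequate", "poor"),
       "bowel_prep not adequate/poor/empty")

  # FIT strings that survived the missingness checks must parse; a parse
  # failure is a row-level exclusion, not a load failure.
  ok <- is.na(reason)
  fit_censoring <- rep(NA_character_, n_in)
  fit_value <- rep(NA_real_, n_in)
  batch <- tryCatch(parse_fit(data$fit_raw[ok], limits), error = identity)
  if (!rlang::is_condition(batch)) {
    fit_censoring[ok] <- batch$censoring
    fit_value[ok] <- batch$value
  } else {
    # at least one bad token: fall back to per-row parsing to attribute it
    for (i in which(ok)) {
      parsed <- tryCatch(parse_fit(data$fit_raw[i], limits),
                         error = identity)
      if (rlang::is_condition(parsed)) {
        reason[i] <- conditionMessage(parsed)
      } else {
        fit_censoring[i] <- parsed$censoring
        fit_value[i] <- parsed$value
      }
    }
  }

  keep <- is.na(reason)
  exclusions <- tibble::tibble(row = which(!keep), id = data$id[!keep],
                               reason = reason[!keep])
  if (!any(keep)) rlang::abort("cohort has zero valid rows after validation")

  out <- data[keep, , drop = FALSE]
  out$crc <- as.logical(out$crc)
  out$polyp_count <- as.integer(out$polyp_count)
  out$fit_censoring <- fit_censoring[keep]
  out$fit_value <- fit_value[keep]
  out <- label_urgent(out, criteria)

  first <- c("id", "age", "sex", "haemoglobin_g_l", "fit_raw",
             "fit_censoring", "fit_value", "crc", "polyp_count",
             "max_polyp_size_mm", "bowel_prep", "urgent")
  out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]

  structure(out,
            class = c("cohort_table", class(out)),
            criteria = criteria, limits = limits,
            provenance = provenance, exclusions = exclusions)
}

#' Completeness report of a loaded cohort
#'
#' @param cohort A `cohort_table`.
#' @return A tibble with one row per excluded input row: `row` (index in the
#'   source), `id` and `reason`.
#' @export
cohort_exclusions <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  attr(cohort, "exclusions")
}

#' Serialise a validated cohort back to CSV
#'
#' Writes the cohort with the derived columns (`fit_censoring`, `fit_value`,
#' `urgent`) included, so reloading with [load_cohort()] is idempotent.
#'
#' @param cohort A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- tibble::as_tibble(cohort)
  df$crc <- as.integer(df$crc)
  df$urgent <- as.integer(df$urgent)
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  excl <- attr(x, "exclusions")
  cat(sprintf("<cohort_table> %d patients (%d urgent, %.1f%%); %d row(s) excluded\n",
              nrow(x), sum(x$urgent), 100 * mean(x$urgent),
              if (is.null(excl)) 0L else nrow(excl)))
  NextMethod()
}
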