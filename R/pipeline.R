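#' Configuration of a full analysis run
#'
#' Bundles everything a run needs so that config + seed fully determine the
#' outputs: the input source (a cohort CSV path or [synthetic_params()]),
#' the conversion criteria and assay limits, threshold-scan settings, the
#' cost model and the DCA grid.
#'
#' @param input Path to a cohort CSV, or a [synthetic_params()] object to
#'   simulate the cohort.
#' @param criteria [conversion_criteria()].
#' @param limits [assay_limits()].
#' @param scan_step,min_jump CUSUM scan settings (see [cusum_scan()]).
#' @param g1_max,scan_lo,scan_hi,alpha Significance-scan settings (see
#'   [incremental_significance_scan()]).
#' @param costs [cost_model()].
#' @param dca_step DCA probability grid step, default 0.01.
#' @param seed Integer seed used when `input` is synthetic params (overrides
#'   the seed inside them) and recorded for provenance.
#' @return A `run_config` object.
#' @export
run_config <- function(input = synthetic_params(),
                       criteria = conversion_criteria(),
                       limits = assay_limits(),
                       scan_step = 0.1, min_jump = 5,
                       g1_max = 10, scan_lo = 11, scan_hi = 29,
                       alpha = 0.05,
                       costs = cost_model(),
                       dca_step = 0.01,
                       seed = 1L) {
  stopifnot(inherits(input, "synthetic_params") ||
              (rlang::is_string(input) && file.exists(input)))
  if (inherits(input, "synthetic_params")) input$seed <- as.integer(seed)
  structure(list(input = input, criteria = criteria, limits = limits,
                 scan_step = scan_step, min_jump = min_jump,
                 g1_max = g1_max, scan_lo = scan_lo, scan_hi = scan_hi,
                 alpha = alpha, costs = costs, dca_step = dca_step,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full FIT-threshold analysis
#'
#' Sequences the whole pipeline on one cohort: load or simulate, Table-1
#' style descriptives, ROC accuracy for colorectal cancer / polypoid
#' lesions / urgent conversion (each skipped with an explicit note when the
#' outcome has a single class), univariate and multivariable logistic
#' models with a paired AUC comparison, the CUSUM threshold scan with jump
#' points, the incremental significance scan, the decision curve and the
#' monetary cost-benefit curve. Results are written to `outdir` as CSV/JSON
#' with a machine-readable JSON index; the run is reproducible byte-for-byte
#' from config + seed.
#'
#' A stage failure aborts with the stage name after writing a
#' partial-results manifest (`manifest.json`) listing the stages completed.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @param save_plots Also render the standard charts as PNG files (default
#'   `FALSE`; the [autoplot()] methods are the interactive interface).
#' @return Invisibly, a `fittriage_report` list with elements `cohort`,
#'   `descriptives`, `roc` (named list), `models`, `auc_comparison`,
#'   `cusum`, `signif_scan`, `dca`, `monetary`, `index` and `outdir`.
#' @export
run_full_analysis <- function(config = run_config(), outdir = tempfile("fittriage_"),
                              save_plots = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  done <- character()
  index <- list(seed = config$seed, stages = list())
  report <- list(outdir = outdir)

  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest <- list(failed_stage = name, error = conditionMessage(e),
                       completed = as.list(done))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      rlang::abort(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
    done <<- c(done, name)
    res
  }

  cohort <- run_stage("cohort", {
    if (inherits(config$input, "synthetic_params")) {
      generate_cohort(config$input, config$criteria, config$limits)
    } else {
      load_cohort(config$input, config$criteria, config$limits)
    }
  })
  write_cohort(cohort, file.path(outdir, "cohort.csv"))
  index$n <- nrow(cohort)
  index$n_excluded <- nrow(cohort_exclusions(cohort))
  report$cohort <- cohort

  desc <- run_stage("descriptives", summarise_cohort(cohort))
  readr::write_csv(desc, file.path(outdir, "descriptives.csv"),
                   progress = FALSE)
  report$descriptives <- desc
  index$stages$descriptives <- "descriptives.csv"

  # ROC per outcome, skipping single-class outcomes gracefully
  cohort$polypoid <- cohort$crc | cohort$polyp_count > 0
  rocs <- list()
  roc_index <- list()
  for (oc in c("crc", "polypoid", "urgent")) {
    y <- as.logical(cohort[[oc]])
    if (all(y) || !any(y)) {
      rocs[[oc]] <- NULL
      roc_index[[oc]] <- list(skipped = "insufficient events")
      next
    }
    d_roc <- tibble::tibble(score = cohort$fit_value, y = y)
    r <- run_stage(paste0("roc_", oc), roc_with_ci(d_roc, score, y))
    rocs[[oc]] <- r
    readr::write_csv(r$curve, file.path(outdir, paste0("roc_", oc, ".csv")),
                     progress = FALSE)
    roc_index[[oc]] <- list(auc = round(r$auc, 6),
                            ci_low = round(r$ci_low, 6),
                            ci_high = round(r$ci_high, 6))
  }
  report$roc <- rocs
  index$stages$roc <- roc_index

  models <- run_stage("logistic_models", {
    uni <- fit_logistic(cohort, "urgent", "fit_value")
    multi <- fit_logistic(cohort, "urgent",
                          c("fit_value", "haemoglobin_g_l", "age", "sex"))
    list(univariate = uni, multivariable = multi)
  })
  readr::write_csv(dplyr::bind_rows(
    dplyr::mutate(models$univariate$terms, model = "univariate"),
    dplyr::mutate(models$multivariable$terms, model = "multivariable")),
    file.path(outdir, "logistic_models.csv"), progress = FALSE)
  report$models <- models

  cmp <- run_stage("auc_comparison", {
    d <- tibble::tibble(a = models$univariate$predicted,
                        b = models$multivariable$predicted,
                        y = cohort$urgent)
    compare_auc_paired(d, a, b, y)
  })
  report$auc_comparison <- cmp
  index$stages$auc_comparison <- list(delta_auc = round(cmp$delta_auc, 6),
                                      p_value = round(cmp$p_value, 6))

  cusum <- run_stage("cusum_scan",
                     cusum_scan(cohort, step = config$scan_step,
                                min_jump = config$min_jump))
  readr::write_csv(cusum$grid, file.path(outdir, "cusum_grid.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(jump_points = cusum$jump_points$threshold,
         conversion_rates = round(cusum$jump_points$conversion_rate, 6)),
    file.path(outdir, "jump_points.json"), auto_unbox = FALSE, digits = NA)
  report$cusum <- cusum
  index$stages$cusum <- list(jump_points = cusum$jump_points$threshold)

  sig <- run_stage("significance_scan",
                   incremental_significance_scan(
                     cohort, g1_max = config$g1_max,
                     scan_lo = config$scan_lo, scan_hi = config$scan_hi,
                     alpha = config$alpha))
  readr::write_csv(sig$rows, file.path(outdir, "significance_scan.csv"),
                   progress = FALSE)
  report$signif_scan <- sig
  index$stages$significance_scan <-
    list(first_sustained = if (is.na(sig$first_sustained)) NULL
         else sig$first_sustained)

  dca <- run_stage("dca", dca_curve(cohort, grid_step = config$dca_step))
  readr::write_csv(dca$curve, file.path(outdir, "dca_curve.csv"),
                   progress = FALSE)
  band <- optimal_band(dca)
  report$dca <- dca
  index$stages$dca <- list(
    best_p = dca$best$threshold, best_fit = round(dca$best$fit, 4),
    band = if (nrow(band)) list(p_lo = band$p_lo, p_hi = band$p_hi,
                                fit_lo = round(band$fit_lo, 4),
                                fit_hi = round(band$fit_hi, 4)) else NULL)

  monetary <- run_stage("monetary", monetary_curve(cohort, config$costs))
  readr::write_csv(monetary$curve, file.path(outdir, "monetary_curve.csv"),
                   progress = FALSE)
  declines <- steepest_declines(monetary, k = 5)
  readr::write_csv(declines, file.path(outdir, "decline_points.csv"),
                   progress = FALSE)
  report$monetary <- monetary
  report$declines <- declines
  index$stages$monetary <- list(
    decline_thresholds = declines$threshold,
    max_net_benefit = round(max(monetary$curve$net_benefit_gbp), 6))

  if (save_plots) {
    run_stage("plots", {
      ggplot2::ggsave(file.path(outdir, "roc_urgent.png"),
                      autoplot(rocs$urgent), width = 5, height = 5, dpi = 150)
      ggplot2::ggsave(file.path(outdir, "cusum.png"), autoplot(cusum),
                      width = 7, height = 4, dpi = 150)
      ggplot2::ggsave(file.path(outdir, "conversion_rate.png"),
                      autoplot(cusum, type = "rate"),
                      width = 7, height = 4, dpi = 150)
      ggplot2::ggsave(file.path(outdir, "dca.png"), autoplot(dca),
                      width = 7, height = 4, dpi = 150)
      ggplot2::ggsave(file.path(outdir, "monetary.png"), autoplot(monetary),
                      width = 7, height = 4, dpi = 150)
    })
  }

  jsonlite::write_json(index, file.path(outdir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$index <- index
  class(report) <- "fittriage_report"
  invisible(report)
}

#' @export
print.fittriage_report <- function(x, ...) {
  cat("<fittriage_report>\n outputs in:", x$outdir, "\n stages:",
      paste(names(x$index$stages), collapse = ", "), "\n")
  invisible(x)
}

#' Table-1 style cohort descriptives
#'
#' Counts with percentages (one decimal place) for categorical
#' characteristics, and mean, SD and median for the continuous ones (FIT,
#' age, haemoglobin). With a single record the SD is reported `NA` and the
#' row flagged.
#'
#' @param cohort A `cohort_table`.
#' @return A tibble with columns `variable`, `level`, `n`, `percent`,
#'   `mean`, `sd`, `median`, `formatted` (the "211 (13.8)" /
#'   "65.4 +/- 14.3" rendering) and `flag`.
#' @examples
#' summarise_cohort(generate_cohort(synthetic_params(n = 300, seed = 5)))
#' @export
summarise_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L)
  n <- nrow(cohort)
  pct <- function(k) round(100 * k / n, 1)
  cat_row <- function(variable, level, k) {
    tibble::tibble(variable = variable, level = level, n = k,
                   percent = pct(k), mean = NA_real_, sd = NA_real_,
                   median = NA_real_,
                   formatted = sprintf("%d (%.1f)", k, pct(k)),
                   flag = NA_character_)
  }
  num_row <- function(variable, x) {
    s <- if (n > 1) stats::sd(x) else NA_real_
    tibble::tibble(variable = variable, level = NA_character_, n = n,
                   percent = NA_real_, mean = mean(x), sd = s,
                   median = stats::median(x),
                   formatted = if (is.na(s)) sprintf("%.1f", mean(x))
                   else sprintf("%.1f ± %.1f", mean(x), s),
                   flag = if (is.na(s)) "sd undefined for n = 1"
                   else NA_character_)
  }
  advanced <- cohort$max_polyp_size_mm >= 10
  dplyr::bind_rows(
    cat_row("patients", "included", n),
    num_row("age", cohort$age),
    cat_row("sex", "male", sum(cohort$sex == "M")),
    cat_row("sex", "female", sum(cohort$sex == "F")),
    num_row("fit", cohort$fit_value),
    num_row("haemoglobin", cohort$haemoglobin_g_l),
    cat_row("bowel_prep", "adequate",
            sum(cohort$bowel_prep %in% "adequate")),
    cat_row("bowel_prep", "poor", sum(cohort$bowel_prep %in% "poor")),
    cat_row("bowel_prep", "missing", sum(is.na(cohort$bowel_prep))),
    cat_row("findings", "polyp", sum(cohort$polyp_count > 0)),
    cat_row("findings", "crc", sum(cohort$crc)),
    cat_row("findings", "advanced_polyp", sum(advanced)),
    cat_row("outcome", "urgent", sum(cohort$urgent))
  )
}
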