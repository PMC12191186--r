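# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths (no rank tricks, no findInterval):
# everything is recomputed by direct enumeration.

# AUC as explicit concordance over all positive x negative pairs.
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# CUSUM scan by independent recount at every grid point.
oracle_cusum <- function(fit, urgent, step = 0.1, min_jump = 5) {
  fd <- round(fit * 10)
  sd_ <- round(step * 10)
  lo <- 10 * floor(min(fit))
  hi <- lo + ceiling((max(fd) - lo) / sd_) * sd_
  grid <- seq(lo, hi, by = sd_)
  cum_total <- sapply(grid, function(t) sum(fd <= t))
  cum_urgent <- sapply(grid, function(t) sum(fd <= t & urgent))
  jump <- cum_urgent - c(0, cum_urgent[-length(cum_urgent)])
  list(threshold = grid / 10, cum_total = cum_total,
       cum_urgent = cum_urgent,
       rate = ifelse(cum_total > 0, cum_urgent / cum_total, 0),
       jumps = grid[jump >= min_jump] / 10)
}

# Net benefit by explicit confusion matrix at each threshold probability.
oracle_dca <- function(p, y, thresholds) {
  n <- length(y)
  sapply(thresholds, function(pt) {
    if (pt >= 1) return(0)
    pos <- p >= pt
    tp <- sum(pos & y)
    fp <- sum(pos & !y)
    tp / n - (fp / n) * pt / (1 - pt)
  })
}

# Monetary net benefit by explicit confusion matrix at each FIT threshold.
oracle_monetary <- function(fit, y, grid, vtp, vtn, lfp, lfn) {
  n <- length(y)
  sapply(grid, function(t) {
    pos <- fit > t
    (vtp * sum(pos & y) + vtn * sum(!pos & !y) -
       lfp * sum(pos & !y) - lfn * sum(!pos & y)) / n
  })
}

# Minimal analysis table: downstream scans only need fit_value + urgent.
make_scan_cohort <- function(fit_value, urgent) {
  tibble::tibble(fit_value = fit_value, urgent = as.logical(urgent))
}

# A small well-formed cohort data frame in the CSV schema.
make_cohort_df <- function(n = 5, fit_raw = NULL) {
  if (is.null(fit_raw)) {
    fit_raw <- rep(c("<7", "<10", "23.4", "150.0", ">400"), length.out = n)
  }
  tibble::tibble(
    id = sprintf("P%03d", seq_len(n)),
    age = seq(40, 40 + n - 1),
    sex = rep(c("M", "F"), length.out = n),
    haemoglobin_g_l = rep(c(95, 120, 108.5), length.out = n),
    fit_raw = fit_raw,
    crc = rep(c(0, 0, 0, 1, 0), length.out = n),
    polyp_count = rep(c(0L, 1L, 4L, 0L, 1L), length.out = n),
    max_polyp_size_mm = rep(c(0, 4, 6, 0, 12), length.out = n),
    bowel_prep = rep(c("adequate", "poor", NA), length.out = n)
  )
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, na = "", progress = FALSE)
  path
}
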