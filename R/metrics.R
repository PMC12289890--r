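#' Compare aggregated counts to the expert gold standard
#'
#' Sums expert and consensus counts over the matched images and decomposes
#' their difference into undercounted animals (summed per-image deficits)
#' and overcounted animals (summed per-image excesses), so that the exact
#' identity `cs_total = expert_total - undercounted + overcounted` holds on
#' every row. Percentages are relative to the expert total. The exact-match
#' rate is the fraction of images (blank images included) where the
#' consensus count equals the expert count.
#'
#' @param aggregates Output of [count_images()].
#' @param gold Gold-standard table.
#' @param method One of `"median"`, `"mode"`, `"dbscan"`, `"hdbscan"`.
#' @param scope `"all"` or a single phase number.
#' @param round_median Round fractional medians half-up before comparison
#'   (the comparison needs integer counts; the fractional medians stay
#'   available in `aggregates`).
#' @return One-row data frame with `method`, `scope`, `expert_total`,
#'   `cs_total`, `pct_agreement`, `undercounted`, `pct_under`,
#'   `overcounted`, `pct_over`, integer-rounded percentage columns,
#'   `n_images`, `n_exact_match`, `exact_match_rate`.
#' @export
compare_counts <- function(aggregates, gold,
                           method = c("median", "mode", "dbscan", "hdbscan"),
                           scope = "all", round_median = TRUE) {
  method <- match.arg(method)
  d <- merge(aggregates, gold, by = "image_id")
  if (nrow(d) == 0) stop("no images in common", call. = FALSE)
  if (!identical(scope, "all")) d <- d[d$phase == scope, , drop = FALSE]
  cs <- d[[paste0("count_", method)]]
  if (method == "median" && round_median) cs <- round_half_up(cs)
  expert <- d$expert_count
  under <- sum(pmax(0, expert - cs))
  over <- sum(pmax(0, cs - expert))
  expert_total <- sum(expert)
  cs_total <- sum(cs)
  if (expert_total == 0) {
    warning("expert total is 0 in scope '", scope,
            "'; percentages undefined", call. = FALSE)
    pct <- c(NA_real_, NA_real_, NA_real_)
  } else {
    pct <- 100 * c(cs_total, under, over) / expert_total
  }
  data.frame(method = method, scope = as.character(scope),
             expert_total = expert_total, cs_total = cs_total,
             pct_agreement = pct[1], undercounted = under,
             pct_under = pct[2], overcounted = over, pct_over = pct[3],
             pct_agreement_int = round(pct[1]),
             pct_under_int = round(pct[2]), pct_over_int = round(pct[3]),
             n_images = nrow(d), n_exact_match = sum(cs == expert),
             exact_match_rate = mean(cs == expert),
             stringsAsFactors = FALSE)
}

#' Per-phase summary of all aggregation methods
#'
#' One [compare_counts()] row per method and scope (each phase plus the
#' all-phases row), mirroring the layout of a method-by-phase validation
#' table: totals, percentage agreement, under/overcount decomposition and
#' exact-match rates.
#'
#' @inheritParams compare_counts
#' @param methods Methods to include.
#' @return Data frame of class `"phase_summary"`.
#' @export
phase_summary_table <- function(aggregates, gold,
                                methods = c("median", "mode", "hdbscan",
                                            "dbscan"),
                                round_median = TRUE) {
  scopes <- c("all", sort(unique(gold$phase)))
  rows <- list()
  for (sc in scopes) {
    for (m in methods) {
      rows[[length(rows) + 1L]] <-
        compare_counts(aggregates, gold, m, sc, round_median)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phase_summary", "data.frame")
  out
}

#' @export
print.phase_summary <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  pc <- c("pct_agreement", "pct_under", "pct_over", "exact_match_rate")
  y[pc] <- lapply(y[pc], round, digits + 2)
  y[c("pct_agreement", "pct_under", "pct_over")] <-
    lapply(y[c("pct_agreement", "pct_under", "pct_over")], round, digits)
  print(y[, c("method", "scope", "expert_total", "cs_total",
              "pct_agreement", "undercounted", "pct_under", "overcounted",
              "pct_over", "n_exact_match", "exact_match_rate")],
        row.names = FALSE, ...)
  invisible(x)
}

#' Accuracy stratified by an image factor
#'
#' Repeats the count comparison within each stratum of an image-level
#' factor from the gold standard: image quality, abundance category
#' (`low` 1-5, `medium` 6-10, `high` >10) or phase.
#'
#' @inheritParams compare_counts
#' @param stratifier `"quality"`, `"abundance_category"` or `"phase"`.
#' @return Data frame with one [compare_counts()] row per stratum, plus a
#'   `stratum` column.
#' @export
stratified_accuracy <- function(aggregates, gold,
                                method = c("median", "mode", "dbscan",
                                           "hdbscan"),
                                stratifier = c("quality",
                                               "abundance_category",
                                               "phase"),
                                round_median = TRUE) {
  method <- match.arg(method)
  stratifier <- match.arg(stratifier)
  strata <- unique(as.character(gold[[stratifier]]))
  strata <- strata[!is.na(strata)]
  rows <- lapply(sort(strata), function(s) {
    sub <- gold[as.character(gold[[stratifier]]) == s, , drop = FALSE]
    row <- compare_counts(aggregates, sub, method, "all", round_median)
    cbind(stratum = s, row)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
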