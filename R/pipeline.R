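#' End-to-end consensus analysis
#'
#' Runs the full aggregation and validation pipeline on one dataset:
#' presence tallies, minimum-threshold search against the gold standard,
#' consensus presence at the selected (or supplied) threshold, per-image
#' count aggregation by all methods, the method-by-phase comparison table
#' and the detection confusion summary.
#'
#' @param cls Classifications data frame.
#' @param gold Gold-standard table.
#' @param threshold Yes-vote threshold; `NULL` uses the threshold selected
#'   by [threshold_search()].
#' @param t_max,target_agreement Passed to [threshold_search()].
#' @param params Clustering parameters for the count methods.
#' @param methods Counting methods for the summary table.
#' @param include_zero_counts Passed to [count_images()].
#' @return Object of class `"consensus_analysis"` with components
#'   `tallies`, `search`, `threshold`, `consensus`, `aggregates`,
#'   `summary`, `confusion`, `gold`.
#' @export
consensus_analysis <- function(cls, gold, threshold = NULL, t_max = 11L,
                               target_agreement = 0.95,
                               params = clustering_params(),
                               methods = c("median", "mode", "hdbscan",
                                           "dbscan"),
                               include_zero_counts = FALSE) {
  tallies <- tally_presence(cls, images = gold$image_id)
  search <- threshold_search(tallies, gold, t_max = t_max,
                             target_agreement = target_agreement)
  if (is.null(threshold)) threshold <- search$selected_threshold
  consensus <- consensus_presence(tallies, threshold)
  aggregates <- count_images(cls, consensus, params = params,
                             include_zero_counts = include_zero_counts)
  summary_tab <- phase_summary_table(aggregates, gold, methods = methods)
  confusion <- detection_confusion(consensus, gold)
  structure(list(tallies = tallies, search = search,
                 threshold = as.integer(threshold), consensus = consensus,
                 aggregates = aggregates, summary = summary_tab,
                 confusion = confusion, gold = gold),
            class = "consensus_analysis")
}

#' @export
print.consensus_analysis <- function(x, ...) {
  cat(sprintf("Consensus analysis of %d images (%d classifications/image expected)\n",
              nrow(x$tallies),
              max(x$tallies$n_classifications)))
  cat(sprintf("  threshold in use: %d yes votes (search selected %d; target %.0f%% %s)\n",
              x$threshold, x$search$selected_threshold,
              100 * x$search$target_agreement,
              if (x$search$target_met) "met" else "not met"))
  cat(sprintf("  consensus-present images: %d (experts: %d)\n",
              sum(x$consensus$consensus_present),
              sum(x$gold$expert_present)))
  print(x$confusion)
  cat("\nCount aggregation vs experts:\n")
  print(x$summary)
  invisible(x)
}

#' @export
summary.consensus_analysis <- function(object, ...) {
  list(threshold = object$threshold,
       selected_threshold = object$search$selected_threshold,
       agreement = as.data.frame(object$search),
       confusion = object$confusion,
       counts = as.data.frame(object$summary))
}
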