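#' Per-volunteer animal counts
#'
#' Counts, for every classification, the marks in countable categories.
#' Partial-category marks (animals bisected by the tile edge) are excluded
#' by default so edge animals are not double counted across tiles. A
#' classification answering "no" has no marks and counts 0.
#'
#' @param cls Classifications data frame.
#' @param countable Categories that count as one animal each.
#' @return Data frame `classification_id`, `volunteer_id`, `image_id`,
#'   `count` (one row per classification).
#' @export
per_volunteer_count <- function(cls, countable = COUNTABLE_CATEGORIES) {
  one <- cls[!duplicated(cls$classification_id),
             c("classification_id", "volunteer_id", "image_id")]
  marked <- cls[!is.na(cls$mark_index) & cls$category %in% countable, ]
  tab <- table(factor(marked$classification_id,
                      levels = one$classification_id))
  one$count <- as.integer(tab[one$classification_id])
  rownames(one) <- NULL
  one
}

#' Median of per-volunteer counts
#'
#' Standard sample median; even-length samples give the mean of the two
#' central values, which may be a half-integer. Exact-match comparisons in
#' the metrics layer round such values half-up.
#'
#' @param counts Nonempty numeric vector of per-volunteer counts.
#' @return The median (possibly fractional).
#' @export
aggregate_median <- function(counts) {
  if (length(counts) == 0) stop("empty count vector", call. = FALSE)
  stats::median(counts)
}

#' Mode of per-volunteer counts, max tie-break
#'
#' The most frequent count; when several values tie for the highest
#' frequency the largest tied value is returned (the "mode (max)" rule).
#'
#' @param counts Nonempty numeric vector of per-volunteer counts.
#' @return Integer mode.
#' @export
aggregate_mode <- function(counts) {
  if (length(counts) == 0) stop("empty count vector", call. = FALSE)
  tab <- table(counts)
  tied <- as.numeric(names(tab)[tab == max(tab)])
  as.integer(max(tied))
}

#' Aggregate per-image counts by all methods
#'
#' For every image carrying a consensus-presence label, produces the
#' consensus count under each method: the median and mode of the
#' contributing volunteers' counts, and the DBSCAN/HDBSCAN cluster counts
#' of the pooled marks. Consensus-absent images receive 0 under every
#' method. Contributing volunteers are, by default, those reporting at
#' least one countable mark: with a threshold of 5 yes votes out of 20-30
#' classifications, most volunteers of a consensus-present image report
#' nothing, and including their zeros would drag the median to 0
#' (`include_zero_counts = TRUE` preserves the alternative).
#'
#' @param cls Classifications data frame.
#' @param consensus Data frame with `image_id` and logical
#'   `consensus_present` (from [consensus_presence()]).
#' @param params A [clustering_params()].
#' @param countable Categories that count as one animal each.
#' @param include_zero_counts Include zero-count volunteers among the
#'   contributors for median/mode.
#' @param keep_centroids Attach per-image cluster centroids as the
#'   `"centroids"` attribute.
#' @return Data frame `image_id`, `consensus_present`, `n_contributing`,
#'   `count_median`, `count_mode`, `count_dbscan`, `count_hdbscan`.
#' @export
count_images <- function(cls, consensus, params = clustering_params(),
                         countable = COUNTABLE_CATEGORIES,
                         include_zero_counts = FALSE,
                         keep_centroids = FALSE) {
  pvc <- per_volunteer_count(cls, countable)
  pvc_by_img <- split(pvc$count, pvc$image_id)
  marks <- cls[!is.na(cls$mark_index) & cls$category %in% countable,
               c("image_id", "x", "y")]
  marks_by_img <- split(marks[, c("x", "y")], marks$image_id)
  n <- nrow(consensus)
  out <- data.frame(image_id = consensus$image_id,
                    consensus_present = consensus$consensus_present,
                    n_contributing = 0L, count_median = 0,
                    count_mode = 0L, count_dbscan = 0L,
                    count_hdbscan = 0L, stringsAsFactors = FALSE)
  centroids <- if (keep_centroids) vector("list", n) else NULL
  for (i in seq_len(n)) {
    if (!consensus$consensus_present[i]) next
    img <- consensus$image_id[i]
    counts <- pvc_by_img[[img]]
    if (is.null(counts)) counts <- integer(0)
    contrib <- if (include_zero_counts) counts else counts[counts > 0]
    if (length(contrib) == 0) {
      warning("consensus-present image ", img,
              " has no contributing volunteers; counts set to 0",
              call. = FALSE)
      next
    }
    out$n_contributing[i] <- length(contrib)
    out$count_median[i] <- aggregate_median(contrib)
    out$count_mode[i] <- aggregate_mode(contrib)
    xy <- marks_by_img[[img]]
    if (is.null(xy)) xy <- data.frame(x = numeric(0), y = numeric(0))
    db <- cluster_count(xy, "dbscan", params)
    hdb <- cluster_count(xy, "hdbscan", params)
    out$count_dbscan[i] <- db$count
    out$count_hdbscan[i] <- hdb$count
    if (keep_centroids) {
      centroids[[i]] <- list(dbscan = db$centroids,
                             hdbscan = hdb$centroids)
    }
  }
  if (keep_centroids) {
    names(centroids) <- consensus$image_id
    attr(out, "centroids") <- centroids
  }
  out
}
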