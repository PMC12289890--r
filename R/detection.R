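#' Tally presence answers per image
#'
#' Counts, for every image, the number of classifications received and the
#' number answering "yes" to the presence question.
#'
#' @param cls Classifications data frame (see [read_classifications()]).
#' @param images Optional character vector of image ids that must appear in
#'   the output; images with no classifications are returned as (0, 0)
#'   tallies with a warning.
#' @return Data frame `image_id`, `n_classifications`, `yes_votes`.
#' @export
tally_presence <- function(cls, images = NULL) {
  one <- cls[!duplicated(cls$classification_id),
             c("image_id", "presence_answer")]
  tab <- table(factor(one$image_id))
  yes <- table(factor(one$image_id[one$presence_answer == "yes"],
                      levels = names(tab)))
  tallies <- data.frame(image_id = names(tab),
                        n_classifications = as.integer(tab),
                        yes_votes = as.integer(yes),
                        stringsAsFactors = FALSE)
  if (!is.null(images)) {
    missing <- setdiff(images, tallies$image_id)
    if (length(missing)) {
      warning(length(missing), " image(s) have no classifications",
              call. = FALSE)
      tallies <- rbind(tallies,
                       data.frame(image_id = missing,
                                  n_classifications = 0L, yes_votes = 0L,
                                  stringsAsFactors = FALSE))
    }
    tallies <- tallies[match(images, tallies$image_id), , drop = FALSE]
  }
  rownames(tallies) <- NULL
  tallies
}

#' Consensus presence under an absolute agreement threshold
#'
#' An image is consensus-present when at least `threshold` of its
#' classifications answered "yes". The threshold is absolute (not
#' proportional), so it applies unchanged to images with 20 or 30
#' classifications.
#'
#' @param tallies Output of [tally_presence()].
#' @param threshold Minimum number of yes votes (>= 1).
#' @return `tallies` with a logical `consensus_present` column.
#' @export
consensus_presence <- function(tallies, threshold) {
  stopifnot(threshold >= 1)
  if (nrow(tallies) && threshold > max(tallies$n_classifications)) {
    warning("threshold exceeds the number of classifications; ",
            "consensus is always absent", call. = FALSE)
  }
  tallies$consensus_present <- tallies$yes_votes >= threshold
  tallies
}

#' Majority-vote threshold
#'
#' The simple-plurality rule: the answer chosen by 50% plus one of the
#' classifiers, i.e. `floor(n/2) + 1` yes votes out of `n`.
#'
#' @param n_classifications Number of classifications per image.
#' @return Integer threshold(s).
#' @examples
#' majority_vote_threshold(c(20, 30)) # 11, 16
#' @export
majority_vote_threshold <- function(n_classifications) {
  stopifnot(all(n_classifications >= 1))
  as.integer(n_classifications %/% 2 + 1L)
}

#' Search for the minimum agreement threshold
#'
#' Evaluates consensus presence against the expert gold standard for every
#' threshold 1..`t_max` and selects the smallest threshold attaining the
#' maximal overall agreement (ties break toward the smallest threshold).
#' Agreement is also decomposed over expert-present and expert-absent
#' images; by construction the absent-image series is non-decreasing and
#' the present-image series non-increasing in the threshold.
#'
#' @param tallies Output of [tally_presence()].
#' @param gold Gold-standard table.
#' @param t_max Largest threshold to evaluate.
#' @param target_agreement Agreement level the study requires (a flag in
#'   the result reports whether it was met).
#' @return Object of class `"threshold_search"`.
#' @export
threshold_search <- function(tallies, gold, t_max = 11L,
                             target_agreement = 0.95) {
  stopifnot(t_max >= 1)
  d <- merge(tallies, gold[, c("image_id", "expert_present")],
             by = "image_id")
  if (nrow(d) == 0) {
    stop("no images in common between tallies and gold standard",
         call. = FALSE)
  }
  thresholds <- seq_len(t_max)
  pres <- d$expert_present
  agr_all <- agr_pres <- agr_abs <- numeric(t_max)
  for (t in thresholds) {
    cons <- d$yes_votes >= t
    ok <- cons == pres
    agr_all[t] <- mean(ok)
    agr_pres[t] <- if (any(pres)) mean(ok[pres]) else NA_real_
    agr_abs[t] <- if (any(!pres)) mean(ok[!pres]) else NA_real_
  }
  selected <- which.max(agr_all)  # smallest index attaining the max
  structure(list(thresholds = thresholds,
                 agreement_overall = agr_all,
                 agreement_present = agr_pres,
                 agreement_absent = agr_abs,
                 selected_threshold = as.integer(selected),
                 target_agreement = target_agreement,
                 target_met = agr_all[selected] >= target_agreement,
                 n_images = nrow(d),
                 n_present = sum(pres), n_absent = sum(!pres)),
            class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("Minimum-threshold search over %d images (%d expert-present, %d absent)\n",
              x$n_images, x$n_present, x$n_absent))
  tab <- as.data.frame(x)
  tab[-1] <- lapply(tab[-1], function(v) sprintf("%.3f", v))
  print(tab, row.names = FALSE)
  cat(sprintf("Selected threshold: %d (overall agreement %.1f%%; target %.0f%% %s)\n",
              x$selected_threshold,
              100 * x$agreement_overall[x$selected_threshold],
              100 * x$target_agreement,
              if (x$target_met) "met" else "not met"))
  invisible(x)
}

#' @export
as.data.frame.threshold_search <- function(x, ...) {
  data.frame(threshold = x$thresholds,
             agreement_overall = x$agreement_overall,
             agreement_present = x$agreement_present,
             agreement_absent = x$agreement_absent)
}

#' @export
plot.threshold_search <- function(x, ...) {
  graphics::matplot(x$thresholds,
                    cbind(x$agreement_overall, x$agreement_present,
                          x$agreement_absent),
                    type = "b", pch = c(19, 1, 2), lty = 1,
                    col = c("black", "firebrick", "steelblue"),
                    xlab = "yes-vote threshold", ylab = "agreement with experts",
                    ...)
  graphics::abline(v = x$selected_threshold, lty = 3)
  graphics::abline(h = x$target_agreement, lty = 3, col = "grey40")
  graphics::legend("bottomleft",
                   legend = c("overall", "expert-present", "expert-absent"),
                   pch = c(19, 1, 2),
                   col = c("black", "firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Filter classifications by volunteer identity and activity
#'
#' Removes classifications from anonymous volunteers and/or from volunteers
#' whose total activity (counted over the *full* input, before any
#' filtering) is at or below a cutoff. Images whose classification set is
#' emptied by the filter are dropped from the result and recorded in the
#' `"dropped_images"` attribute, so downstream agreement denominators
#' exclude them rather than treating them as consensus-absent.
#'
#' @param cls Classifications data frame.
#' @param exclude_anonymous Drop classifications from not-logged-in
#'   volunteers.
#' @param min_volunteer_activity Drop volunteers with `n_classifications <=`
#'   this value (0 keeps everyone).
#' @return Filtered classifications, with attribute `"dropped_images"`.
#' @export
filter_classifications <- function(cls, exclude_anonymous = FALSE,
                                   min_volunteer_activity = 0L) {
  prof <- profile_volunteers(cls)
  drop_vol <- prof$volunteer_id[
    (exclude_anonymous & prof$anonymous) |
      prof$n_classifications <= min_volunteer_activity]
  out <- cls[!(cls$volunteer_id %in% drop_vol), , drop = FALSE]
  dropped <- setdiff(unique(cls$image_id), unique(out$image_id))
  if (length(dropped)) {
    message(length(dropped),
            " image(s) lost all classifications and were dropped")
  }
  rownames(out) <- NULL
  attr(out, "dropped_images") <- dropped
  out
}

#' Confusion summary of consensus presence against the experts
#'
#' @param consensus Data frame with `image_id` and logical
#'   `consensus_present` (e.g. from [consensus_presence()]).
#' @param gold Gold-standard table.
#' @return Object of class `"detection_confusion"`: agreement overall and
#'   within expert-present / expert-absent images, false-positive and
#'   false-negative rates, each with its denominator, plus the 2x2 counts.
#' @export
detection_confusion <- function(consensus, gold) {
  d <- merge(consensus[, c("image_id", "consensus_present")],
             gold[, c("image_id", "expert_present")], by = "image_id")
  tp <- sum(d$consensus_present & d$expert_present)
  tn <- sum(!d$consensus_present & !d$expert_present)
  fp <- sum(d$consensus_present & !d$expert_present)
  fn <- sum(!d$consensus_present & d$expert_present)
  n_present <- tp + fn; n_absent <- tn + fp
  structure(list(
    n_images = nrow(d), n_present = n_present, n_absent = n_absent,
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
    agreement_overall = (tp + tn) / nrow(d),
    agreement_present = if (n_present) tp / n_present else NA_real_,
    agreement_absent = if (n_absent) tn / n_absent else NA_real_,
    false_positive_rate = if (n_absent) fp / n_absent else NA_real_,
    false_negative_rate = if (n_present) fn / n_present else NA_real_),
    class = "detection_confusion")
}

#' @export
print.detection_confusion <- function(x, ...) {
  cat(sprintf("Detection vs experts over %d images\n", x$n_images))
  cat(sprintf("  overall agreement:        %.1f%%\n",
              100 * x$agreement_overall))
  cat(sprintf("  expert-present agreement: %.1f%% (n = %d)\n",
              100 * x$agreement_present, x$n_present))
  cat(sprintf("  expert-absent agreement:  %.1f%% (n = %d)\n",
              100 * x$agreement_absent, x$n_absent))
  cat(sprintf("  false negatives %.1f%%, false positives %.1f%%\n",
              100 * x$false_negative_rate, 100 * x$false_positive_rate))
  invisible(x)
}
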