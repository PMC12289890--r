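make_aggregates <- function(image_id, counts, method = "hdbscan") {
  out <- data.frame(image_id = image_id, consensus_present = counts > 0,
                    n_contributing = ifelse(counts > 0, 5L, 0L),
                    count_median = counts, count_mode = counts,
                    count_dbscan = counts, count_hdbscan = counts,
                    stringsAsFactors = FALSE)
  out
}

test_that("under/overcount decomposition matches a hand count", {
  gold <- gold_row(c("i1", "i2", "i3"), 1, c(3L, 0L, 2L))
  agg <- make_aggregates(c("i1", "i2", "i3"), c(2, 1, 2))
  cmp <- compare_counts(agg, gold, "hdbscan")
  expect_equal(cmp$expert_total, 5)
  expect_equal(cmp$cs_total, 5)
  expect_equal(cmp$undercounted, 1)
  expect_equal(cmp$overcounted, 1)
  expect_equal(cmp$cs_total,
               cmp$expert_total - cmp$undercounted + cmp$overcounted)
  expect_equal(cmp$n_exact_match, 1)
  expect_equal(cmp$exact_match_rate, 1 / 3)
})

test_that("perfect agreement gives 100% and exact-match 1", {
  gold <- gold_row(c("i1", "i2"), 2, c(4L, 0L))
  agg <- make_aggregates(c("i1", "i2"), c(4, 0))
  cmp <- compare_counts(agg, gold, "median")
  expect_equal(cmp$pct_agreement, 100)
  expect_equal(cmp$undercounted + cmp$overcounted, 0)
  expect_equal(cmp$exact_match_rate, 1)
})

test_that("an all-blank scope reports undefined percentages with a warning", {
  gold <- gold_row(c("i1", "i2"), 1, c(0L, 0L))
  agg <- make_aggregates(c("i1", "i2"), c(0, 0))
  expect_warning(cmp <- compare_counts(agg, gold, "mode"), "undefined")
  expect_true(is.na(cmp$pct_agreement))
})

test_that("the printed all-phase benchmark row satisfies the identity", {
  # expert total 1410, 333 undercounted, 70 overcounted -> 1147 counted, 81%
  gold <- gold_row(c("a", "b"), 1, c(1000L, 410L))
  agg <- make_aggregates(c("a", "b"), c(1000 - 333, 410 + 70))
  cmp <- compare_counts(agg, gold, "hdbscan")
  expect_equal(cmp$cs_total, 1147)
  expect_equal(cmp$cs_total, 1410 - 333 + 70)
  expect_equal(cmp$pct_agreement_int, 81)
  expect_equal(cmp$pct_under_int, 24)
  expect_equal(cmp$pct_over_int, 5)
})

test_that("conservation identity holds on every simulated summary row", {
  st <- simulate_study(small_config(n_images = 200, seed = 18))
  an <- consensus_analysis(st$classifications, st$gold, threshold = 5)
  s <- an$summary
  expect_true(all(s$cs_total == s$expert_total - s$undercounted +
                    s$overcounted))
  # independent per-image loop for one method
  d <- merge(an$aggregates, st$gold, by = "image_id")
  cs <- crowdcount:::round_half_up(d$count_median)
  under <- over <- 0
  for (i in seq_len(nrow(d))) {
    under <- under + max(0, d$expert_count[i] - cs[i])
    over <- over + max(0, cs[i] - d$expert_count[i])
  }
  row <- s[s$method == "median" & s$scope == "all", ]
  expect_equal(row$undercounted, under)
  expect_equal(row$overcounted, over)
})

test_that("per-phase rows add up to the all-phases row", {
  st <- simulate_study(small_config(n_images = 200, seed = 19))
  an <- consensus_analysis(st$classifications, st$gold, threshold = 5)
  s <- an$summary
  for (m in unique(s$method)) {
    allrow <- s[s$method == m & s$scope == "all", ]
    phases <- s[s$method == m & s$scope != "all", ]
    for (col in c("expert_total", "cs_total", "undercounted",
                  "overcounted", "n_images", "n_exact_match")) {
      expect_equal(sum(phases[[col]]), allrow[[col]])
    }
  }
})

test_that("exact-match rate ignores image labelling", {
  gold <- gold_row(c("i1", "i2", "i3"), 1, c(2L, 1L, 0L))
  agg <- make_aggregates(c("i1", "i2", "i3"), c(2, 3, 0))
  a <- compare_counts(agg, gold, "mode")
  gold2 <- gold; gold2$image_id <- c("x1", "x2", "x3")
  agg2 <- agg; agg2$image_id <- c("x1", "x2", "x3")
  b <- compare_counts(agg2, gold2, "mode")
  expect_equal(a$exact_match_rate, b$exact_match_rate)
})

test_that("abundance strata follow the category boundaries", {
  gold <- gold_row(paste0("i", 1:5), 1, c(0L, 5L, 6L, 10L, 11L))
  agg <- make_aggregates(paste0("i", 1:5), c(0, 5, 6, 10, 11))
  suppressWarnings(
    out <- stratified_accuracy(agg, gold, "median", "abundance_category"))
  expect_setequal(out$stratum, c("absent", "low", "medium", "high"))
  expect_equal(out$expert_total[out$stratum == "low"], 5)
  expect_equal(out$expert_total[out$stratum == "medium"], 16)
  expect_equal(out$expert_total[out$stratum == "high"], 11)
})

test_that("an all-good-quality dataset collapses to the unstratified result", {
  st <- simulate_study(small_config(n_images = 80, seed = 20,
                                    bad_quality_fraction = c(0, 0, 0)))
  # small sets can leave a phase with no animals; those rows warn by design
  suppressWarnings(
    an <- consensus_analysis(st$classifications, st$gold, threshold = 5))
  strat <- stratified_accuracy(an$aggregates, st$gold, "hdbscan", "quality")
  expect_equal(nrow(strat), 1)
  whole <- compare_counts(an$aggregates, st$gold, "hdbscan")
  expect_equal(strat$cs_total, whole$cs_total)
  expect_equal(strat$exact_match_rate, whole$exact_match_rate)
})

test_that("bad image quality increases the undercount rate", {
  st <- simulate_study(sim_config(
    n_images = 1000, n_volunteers = 400, random_seed = 22,
    bad_quality_fraction = c(0.5, 0.5, 0.5), quality_penalty = 0.35,
    false_positive_rate = 0))
  an <- consensus_analysis(st$classifications, st$gold, threshold = 5)
  strat <- stratified_accuracy(an$aggregates, st$gold, "median", "quality")
  expect_gt(strat$pct_under[strat$stratum == "bad"],
            strat$pct_under[strat$stratum == "good"])
})
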