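test_that("presence tallies count yes votes per image", {
  cls <- rbind(
    do.call(rbind, lapply(1:6, function(i)
      cls_row(as.character(i), paste0("v", i), "imgA", "yes",
              marks = data.frame(category = "other", x = 1, y = 1)))),
    do.call(rbind, lapply(7:20, function(i)
      cls_row(as.character(i), paste0("v", i), "imgA", "no"))))
  tl <- tally_presence(cls)
  expect_equal(tl$n_classifications, 20)
  expect_equal(tl$yes_votes, 6)
  # gold image without classifications yields a (0, 0) tally and a warning
  expect_warning(tl2 <- tally_presence(cls, images = c("imgA", "imgB")),
                 "no classifications")
  expect_equal(tl2[tl2$image_id == "imgB", c("n_classifications", "yes_votes")],
               data.frame(n_classifications = 0L, yes_votes = 0L,
                          row.names = 2L))
})

test_that("threshold rule and majority vote behave as printed", {
  tl <- data.frame(image_id = c("a", "b", "c"),
                   n_classifications = c(20L, 20L, 30L),
                   yes_votes = c(5L, 4L, 0L))
  cons <- consensus_presence(tl, 5)
  expect_equal(cons$consensus_present, c(TRUE, FALSE, FALSE))
  expect_warning(consensus_presence(tl, 31), "always absent")
  expect_equal(majority_vote_threshold(c(20, 30, 1)), c(11L, 16L, 1L))
})

test_that("majority-vote threshold reproduces the 50%-plus-one rule", {
  set.seed(42)
  for (n in c(20L, 30L)) {
    votes <- sample(0:n, 50, replace = TRUE)
    tl <- data.frame(image_id = as.character(seq_along(votes)),
                     n_classifications = n, yes_votes = votes)
    cons <- consensus_presence(tl, majority_vote_threshold(n))
    expect_equal(cons$consensus_present, votes > n / 2)
  }
})

test_that("threshold search reproduces a hand-counted example", {
  tl <- data.frame(image_id = c("p", "a"), n_classifications = 20L,
                   yes_votes = c(6L, 3L))
  gold <- gold_row(c("p", "a"), 1, c(2L, 0L))
  ts <- threshold_search(tl, gold, t_max = 11)
  expect_equal(ts$agreement_overall[5], 1.0)
  expect_equal(ts$agreement_overall[7], 0.5)
  # smallest threshold attaining the maximum: agreement is 1.0 from t=4
  # (absent image has 3 yes votes) through t=6
  expect_equal(ts$selected_threshold, 4L)
  expect_true(ts$target_met)
})

test_that("threshold search is monotone where it must be, with exact decomposition", {
  st <- simulate_study(small_config(n_images = 250, seed = 14))
  tl <- tally_presence(st$classifications)
  ts <- threshold_search(tl, st$gold)
  expect_true(all(diff(ts$agreement_absent) >= 0))
  expect_true(all(diff(ts$agreement_present) <= 0))
  p_pres <- ts$n_present / ts$n_images
  expect_equal(ts$agreement_overall,
               p_pres * ts$agreement_present +
                 (1 - p_pres) * ts$agreement_absent,
               tolerance = 1e-12)
  # consensus-present set shrinks weakly as the threshold rises
  sets <- lapply(1:11, function(t) tl$image_id[tl$yes_votes >= t])
  for (t in 2:11) expect_true(all(sets[[t]] %in% sets[[t - 1]]))
})

test_that("an all-blank gold set pushes the search toward high thresholds", {
  tl <- data.frame(image_id = as.character(1:30), n_classifications = 20L,
                   yes_votes = rep(c(0L, 1L, 3L), 10))
  gold <- gold_row(as.character(1:30), 1, 0L)
  ts <- threshold_search(tl, gold)
  expect_true(all(diff(ts$agreement_overall) >= 0))
  expect_equal(ts$selected_threshold,
               min(which(ts$agreement_overall == max(ts$agreement_overall))))
  expect_error(threshold_search(tl, gold_row("zzz", 1, 0L)), "in common")
})

test_that("volunteer filters use pre-filter activity and flag emptied images", {
  cls <- rbind(
    do.call(rbind, lapply(1:8, function(i)
      cls_row(as.character(i), "busy", paste0("i", i), "no"))),
    do.call(rbind, lapply(9:10, function(i)
      cls_row(as.character(i), "not-logged-in:1", paste0("i", i - 8), "no",
              anonymous = TRUE))),
    cls_row("11", "solo", "lonely", "no"))
  out <- filter_classifications(cls, exclude_anonymous = TRUE)
  expect_equal(sum(out$volunteer_id == "not-logged-in:1"), 0)
  expect_equal(nrow(out), 9)
  # activity cutoff: a volunteer with exactly 10 classifications is removed,
  # one with 11 is kept
  cls2 <- rbind(
    do.call(rbind, lapply(1:10, function(i)
      cls_row(paste0("a", i), "ten", paste0("i", i), "no"))),
    do.call(rbind, lapply(1:11, function(i)
      cls_row(paste0("b", i), "eleven", paste0("j", i), "no"))))
  out2 <- filter_classifications(cls2, min_volunteer_activity = 10)
  expect_setequal(unique(out2$volunteer_id), "eleven")
  # images emptied by the filter are reported, not silently lost
  expect_message(
    out3 <- filter_classifications(cls, min_volunteer_activity = 1),
    "dropped")
  expect_true("lonely" %in% attr(out3, "dropped_images"))
  # a no-op filter is the identity
  expect_equal(nrow(filter_classifications(cls)), nrow(cls))
})

test_that("confusion summary equals a brute-force recount", {
  st <- simulate_study(small_config(n_images = 50, seed = 15))
  cons <- consensus_presence(tally_presence(st$classifications), 5)
  cf <- detection_confusion(cons, st$gold)
  # independent recount, image by image
  agree <- pres_ok <- abs_ok <- 0
  n_pres <- n_abs <- 0
  for (i in seq_len(nrow(st$gold))) {
    e <- st$gold$expert_present[i]
    c_ <- cons$consensus_present[cons$image_id == st$gold$image_id[i]]
    if (e) { n_pres <- n_pres + 1; pres_ok <- pres_ok + (c_ == e) }
    else { n_abs <- n_abs + 1; abs_ok <- abs_ok + (c_ == e) }
    agree <- agree + (c_ == e)
  }
  expect_equal(cf$agreement_overall, agree / nrow(st$gold))
  expect_equal(cf$agreement_present, pres_ok / n_pres)
  expect_equal(cf$agreement_absent, abs_ok / n_abs)
  expect_equal(cf$false_negative_rate, 1 - cf$agreement_present)
  # perfect consensus limit
  perfect <- data.frame(image_id = st$gold$image_id,
                        consensus_present = st$gold$expert_present)
  cfp <- detection_confusion(perfect, st$gold)
  expect_equal(cfp$agreement_overall, 1)
  expect_equal(cfp$agreement_present, 1)
  expect_equal(cfp$agreement_absent, 1)
})
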