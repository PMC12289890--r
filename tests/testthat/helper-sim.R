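# small, fast simulation configurations reused across tests

small_config <- function(n_images = 60, seed = 1, ...) {
  sim_config(n_images = n_images, n_volunteers = 200L, random_seed = seed,
             ...)
}

# deterministic observation model: everyone sees everything, no noise
noiseless_config <- function(n_images = 60, seed = 1, ...) {
  small_config(n_images = n_images, seed = seed,
               skill_p_detect = c(moderate = 1, skilled = 1),
               visibility_probs = c(1), visibility_levels = c(1),
               quality_penalty = 1, phase_detectability = c(1, 1, 1),
               false_positive_rate = 0, mark_jitter_sd = 0,
               partial_fraction = 0, ...)
}

# hand-built classification rows (one row per mark; NA mark for mark-less)
cls_row <- function(cid, vol, img, presence, marks = NULL,
                    anonymous = FALSE) {
  if (is.null(marks)) {
    return(data.frame(classification_id = cid, volunteer_id = vol,
                      anonymous = anonymous, image_id = img,
                      presence_answer = presence,
                      mark_index = NA_integer_, category = NA_character_,
                      x = NA_real_, y = NA_real_, stringsAsFactors = FALSE))
  }
  data.frame(classification_id = cid, volunteer_id = vol,
             anonymous = anonymous, image_id = img,
             presence_answer = presence,
             mark_index = seq_len(nrow(marks)), category = marks$category,
             x = marks$x, y = marks$y, stringsAsFactors = FALSE)
}

gold_row <- function(img, phase, count, quality = "good") {
  as_gold_standard(data.frame(image_id = img, phase = phase,
                              expert_count = count, quality = quality,
                              stringsAsFactors = FALSE))
}

# fixed 2-d point set whose cluster structure was verified against an
# independent reference implementation (counts frozen in the tests)
clustering_fixture <- function() {
  set.seed(424242)
  centers <- matrix(c(100, 100, 500, 500, 900, 200), ncol = 2, byrow = TRUE)
  sizes <- c(8, 6, 7)
  pts <- do.call(rbind, lapply(1:3, function(i)
    cbind(stats::rnorm(sizes[i], centers[i, 1], 5),
          stats::rnorm(sizes[i], centers[i, 2], 5))))
  noise <- matrix(c(50, 900, 700, 50, 300, 800), ncol = 2, byrow = TRUE)
  rbind(pts, noise)
}
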