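#' Simulation configuration
#'
#' Builds and validates the configuration for the volunteer simulator. The
#' defaults describe an aerial-survey citizen-science campaign over marine
#' iguana colonies: a gold-standard-sized set of 4,345 image tiles in three
#' phases (2,733 / 456 / 1,156), with 20 classifications per image in phases
#' 1-2 and 30 in phase 3; ~90% blank tiles overall, with per-phase colony
#' densities; occupied-tile counts following a
#' zero-truncated negative binomial calibrated so that 84% of occupied tiles
#' hold fewer than five animals, truncated at 35; a heavy-tailed volunteer
#' activity distribution with ~15% anonymous participants; a detection-skill
#' mixture (many moderate, few highly skilled volunteers); image-quality and
#' phase-level detectability effects; a low spurious-mark rate; and Gaussian
#' mark jitter around the true animal positions.
#'
#' @param n_images Total number of image tiles.
#' @param phase_proportions Length-3 proportions of images per phase.
#' @param classifications_per_phase Classifications required per image, by
#'   phase.
#' @param blank_fraction Probability an image holds no animals; a scalar,
#'   or one value per phase (the default mirrors a campaign whose phases
#'   covered colonies of very different density while ~90% of all tiles
#'   were blank).
#' @param count_p_lt5 Target P(count < 5) among occupied images; the
#'   negative-binomial mean is solved from this at construction time.
#' @param count_size Negative-binomial size (shape) parameter.
#' @param count_max Upper truncation of the occupied count.
#' @param n_volunteers Size of the volunteer pool.
#' @param activity_exponent Power-law exponent of volunteer activity
#'   weights (weight of rank r is r^-exponent).
#' @param anonymous_fraction Fraction of volunteers not logged in.
#' @param skill_probs,skill_p_detect Mixture weights and per-animal
#'   detection probabilities of the volunteer skill classes.
#' @param visibility_probs,visibility_levels Mixture weights and levels of
#'   per-animal visibility: most animals are conspicuous (visibility 1),
#'   some are cryptic against the substrate and are missed by almost
#'   everyone. A volunteer marks an animal with probability
#'   `p_detect * visibility` (times the quality/phase effects).
#' @param quality_penalty Multiplier on detection probability for
#'   bad-quality images.
#' @param bad_quality_fraction Per-phase fraction of bad-quality images.
#' @param phase_detectability Per-phase multiplier on detection probability
#'   (phase 1 imagery was poor; phase 3 animals are small and cryptic).
#' @param false_positive_rate Expected spurious marks per volunteer per
#'   image (Poisson).
#' @param mark_jitter_sd Isotropic Gaussian jitter of marks, in pixels.
#' @param partial_fraction Probability that an animal lying within
#'   `mark_jitter_sd` of the tile edge is marked `"partial"`.
#' @param adult_male_fraction Fraction of animals that are adult males.
#' @param min_separation Minimum distance between animals, in pixels
#'   (body-size exclusion).
#' @param image_width,image_height Tile dimensions in pixels.
#' @param random_seed Integer seed fixing the full output stream.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_images = 4345,
                       phase_proportions = c(2733, 456, 1156) / 4345,
                       classifications_per_phase = c(20L, 20L, 30L),
                       blank_fraction = c(0.945, 0.61, 0.90),
                       count_p_lt5 = 0.84,
                       count_size = 1,
                       count_max = 35L,
                       n_volunteers = 2000L,
                       activity_exponent = 1,
                       anonymous_fraction = 0.15,
                       skill_probs = c(moderate = 0.85, skilled = 0.15),
                       skill_p_detect = c(moderate = 0.85, skilled = 1.00),
                       visibility_probs = c(conspicuous = 0.72,
                                            difficult = 0.16,
                                            cryptic = 0.12),
                       visibility_levels = c(conspicuous = 1.00,
                                             difficult = 0.35,
                                             cryptic = 0.10),
                       quality_penalty = 0.5,
                       bad_quality_fraction = c(0.45, 0.10, 0.20),
                       phase_detectability = c(0.85, 1.0, 0.80),
                       false_positive_rate = 0.04,
                       mark_jitter_sd = 10,
                       partial_fraction = 0.5,
                       adult_male_fraction = 0.2,
                       min_separation = 40,
                       image_width = 1000,
                       image_height = 1000,
                       random_seed = 1L) {
  cfg <- list(n_images = as.integer(n_images),
              phase_proportions = phase_proportions,
              classifications_per_phase = as.integer(classifications_per_phase),
              blank_fraction = rep_len(blank_fraction, 3L),
              count_p_lt5 = count_p_lt5, count_size = count_size,
              count_max = as.integer(count_max),
              n_volunteers = as.integer(n_volunteers),
              activity_exponent = activity_exponent,
              anonymous_fraction = anonymous_fraction,
              skill_probs = skill_probs, skill_p_detect = skill_p_detect,
              visibility_probs = visibility_probs,
              visibility_levels = visibility_levels,
              quality_penalty = quality_penalty,
              bad_quality_fraction = bad_quality_fraction,
              phase_detectability = phase_detectability,
              false_positive_rate = false_positive_rate,
              mark_jitter_sd = mark_jitter_sd,
              partial_fraction = partial_fraction,
              adult_male_fraction = adult_male_fraction,
              min_separation = min_separation,
              image_width = image_width, image_height = image_height,
              random_seed = as.integer(random_seed))
  validate_sim_config(cfg)
  cfg$count_mu <- calibrate_count_mu(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid sim_config field '", field, "': ", msg,
                  call. = FALSE)
  }
  chk(length(cfg$blank_fraction) %in% c(1L, 3L) &&
        all(cfg$blank_fraction >= 0 & cfg$blank_fraction <= 1),
      "blank_fraction", "must be 1 or 3 probabilities in [0, 1]")
  probs <- c(anonymous_fraction = cfg$anonymous_fraction,
             quality_penalty = cfg$quality_penalty,
             partial_fraction = cfg$partial_fraction,
             adult_male_fraction = cfg$adult_male_fraction,
             count_p_lt5 = cfg$count_p_lt5)
  for (f in names(probs)) chk(probs[[f]] >= 0 && probs[[f]] <= 1, f,
                              "must be in [0, 1]")
  chk(cfg$n_images >= 1, "n_images", "must be positive")
  chk(length(cfg$phase_proportions) == 3 &&
        abs(sum(cfg$phase_proportions) - 1) < 1e-8 &&
        all(cfg$phase_proportions >= 0),
      "phase_proportions", "must be 3 non-negative values summing to 1")
  chk(length(cfg$classifications_per_phase) == 3 &&
        all(cfg$classifications_per_phase >= 1),
      "classifications_per_phase", "must be 3 positive integers")
  chk(cfg$n_volunteers >= max(cfg$classifications_per_phase), "n_volunteers",
      "must be at least the classifications required per image")
  chk(length(cfg$skill_probs) == length(cfg$skill_p_detect) &&
        abs(sum(cfg$skill_probs) - 1) < 1e-8 &&
        all(cfg$skill_p_detect >= 0 & cfg$skill_p_detect <= 1),
      "skill_mixture", "weights must sum to 1, probabilities lie in [0, 1]")
  chk(length(cfg$visibility_probs) == length(cfg$visibility_levels) &&
        abs(sum(cfg$visibility_probs) - 1) < 1e-8 &&
        all(cfg$visibility_levels >= 0 & cfg$visibility_levels <= 1),
      "visibility_mixture",
      "weights must sum to 1, levels lie in [0, 1]")
  chk(all(cfg$bad_quality_fraction >= 0 & cfg$bad_quality_fraction <= 1),
      "bad_quality_fraction", "must be in [0, 1]")
  chk(all(cfg$phase_detectability > 0), "phase_detectability",
      "must be positive")
  chk(cfg$false_positive_rate >= 0, "false_positive_rate",
      "must be non-negative")
  chk(cfg$mark_jitter_sd >= 0, "mark_jitter_sd", "must be non-negative")
  chk(cfg$count_max >= 1, "count_max", "must be positive")
  chk(cfg$min_separation >= 0, "min_separation", "must be non-negative")
  chk(cfg$image_width > 0 && cfg$image_height > 0, "image dimensions",
      "must be positive")
  chk(is.finite(cfg$random_seed) && abs(cfg$random_seed) < 2^30,
      "random_seed", "must be an integer below 2^30")
  invisible(cfg)
}

# solve the negative-binomial mean so that, truncated to 1..count_max,
# P(count < 5) equals the configured value
calibrate_count_mu <- function(cfg) {
  # the whole support lies below 5: any mean satisfies the constraint
  if (cfg$count_max < 5) return(1)
  k <- seq_len(cfg$count_max)
  f <- function(mu) {
    p <- stats::dnbinom(k, size = cfg$count_size, mu = mu)
    sum(p[k < 5]) / sum(p) - cfg$count_p_lt5
  }
  stats::uniroot(f, c(1e-3, 1e3))$root
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Volunteer-simulation configuration\n")
  cat(sprintf("  images: %d (phases %s), %s classifications per image\n",
              x$n_images,
              paste(round(x$n_images * x$phase_proportions), collapse = "/"),
              paste(x$classifications_per_phase, collapse = "/")))
  cat(sprintf("  blank fraction %s; occupied counts ~ ZTNB(size=%.3g, mu=%.3f) on 1..%d\n",
              paste(sprintf("%.2f", x$blank_fraction), collapse = "/"),
              x$count_size, x$count_mu, x$count_max))
  cat(sprintf("  %d volunteers, activity exponent %.2f, %.0f%% anonymous\n",
              x$n_volunteers, x$activity_exponent,
              100 * x$anonymous_fraction))
  cat(sprintf("  skill p_detect: %s; quality penalty %.2f; fp rate %.3f; jitter sd %.1f px\n",
              paste(sprintf("%s=%.2f (%.0f%%)", names(x$skill_p_detect),
                            x$skill_p_detect, 100 * x$skill_probs),
                    collapse = ", "),
              x$quality_penalty, x$false_positive_rate, x$mark_jitter_sd))
  invisible(x)
}

#' Generate ground-truth scenes
#'
#' Draws the true state of every image tile: phase, image quality, the
#' number of animals and their positions (with a minimum body-size
#' separation). The matching expert gold standard is exact truth.
#'
#' @param config A [sim_config()].
#' @return List of class `"scene_set"` with components `scenes` (one row
#'   per image: `image_id`, `phase`, `quality`, `true_count`), `positions`
#'   (one row per animal: `image_id`, `animal_id`, `x`, `y`, `category`,
#'   `near_edge`) and `gold` (gold-standard table, `expert_count` equal to
#'   the true count).
#' @export
generate_scenes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$random_seed)
  n <- config$n_images
  n_phase <- diff(round(cumsum(c(0, config$phase_proportions)) * n))
  phase <- rep(1:3, n_phase)
  if (length(phase) < n) phase <- c(phase, rep(3L, n - length(phase)))
  image_id <- sprintf("img%05d", seq_len(n))
  quality <- ifelse(stats::runif(n) < config$bad_quality_fraction[phase],
                    "bad", "good")
  occupied <- stats::runif(n) >= config$blank_fraction[phase]
  k <- seq_len(config$count_max)
  pmf <- stats::dnbinom(k, size = config$count_size, mu = config$count_mu)
  true_count <- integer(n)
  true_count[occupied] <- sample(k, sum(occupied), replace = TRUE,
                                 prob = pmf)
  pos <- place_animals(image_id, true_count, config)
  scenes <- data.frame(image_id = image_id, phase = phase,
                       quality = quality, true_count = true_count,
                       stringsAsFactors = FALSE)
  gold <- as_gold_standard(data.frame(
    image_id = image_id, phase = phase, expert_count = true_count,
    quality = quality, stringsAsFactors = FALSE))
  structure(list(scenes = scenes, positions = pos, gold = gold,
                 config = config),
            class = "scene_set")
}

# rejection sampling of animal positions with a minimum pairwise distance
place_animals <- function(image_id, true_count, config) {
  occ <- which(true_count > 0)
  out <- vector("list", length(occ))
  w <- config$image_width; h <- config$image_height
  sep2 <- config$min_separation^2
  edge <- config$mark_jitter_sd
  for (j in seq_along(occ)) {
    i <- occ[j]; m <- true_count[i]
    xs <- numeric(m); ys <- numeric(m)
    placed <- 0L
    while (placed < m) {
      px <- stats::runif(1, 0, w); py <- stats::runif(1, 0, h)
      if (placed == 0L ||
          all((xs[seq_len(placed)] - px)^2 +
                (ys[seq_len(placed)] - py)^2 >= sep2)) {
        placed <- placed + 1L
        xs[placed] <- px; ys[placed] <- py
      }
    }
    vis <- sample(length(config$visibility_probs), m, replace = TRUE,
                  prob = config$visibility_probs)
    out[[j]] <- data.frame(
      image_id = image_id[i], animal_id = seq_len(m), x = xs, y = ys,
      category = ifelse(stats::runif(m) < config$adult_male_fraction,
                        "adult_male", "other"),
      visibility = unname(config$visibility_levels[vis]),
      near_edge = xs < edge | xs > w - edge | ys < edge | ys > h - edge,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(image_id = character(), animal_id = integer(),
                      x = numeric(), y = numeric(), category = character(),
                      visibility = numeric(), near_edge = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.scene_set <- function(x, ...) {
  cat(sprintf("Scene set: %d images, %d occupied (%.1f%%), %d animals\n",
              nrow(x$scenes), sum(x$scenes$true_count > 0),
              100 * mean(x$scenes$true_count > 0),
              sum(x$scenes$true_count)))
  invisible(x)
}

#' Simulate volunteer classifications
#'
#' Draws, for every image, the required number of classifications from
#' distinct volunteers sampled proportionally to their activity weights.
#' Each volunteer marks each true animal independently with their personal
#' detection probability (scaled by phase detectability and, on bad-quality
#' images, the quality penalty); mark positions are the true positions plus
#' isotropic Gaussian jitter, clamped to the image bounds. Spurious marks
#' arrive as a Poisson stream placed uniformly. The presence answer is
#' "yes" exactly when the classification carries at least one mark.
#'
#' @param scenes A `"scene_set"` from [generate_scenes()].
#' @param config The same [sim_config()].
#' @return Classifications data frame (see [read_classifications()]).
#' @export
simulate_classifications <- function(scenes, config) {
  stopifnot(inherits(scenes, "scene_set"), inherits(config, "sim_config"))
  if (nrow(scenes$scenes) == 0) stop("scenes must be nonempty", call. = FALSE)
  set.seed(config$random_seed + 1L)
  pool <- volunteer_pool(config)
  sc <- scenes$scenes
  pos_by_img <- split(scenes$positions, scenes$positions$image_id)
  w <- config$image_width; h <- config$image_height
  n_img <- nrow(sc)
  col <- function(proto) vector("list", n_img)
  a_cid <- col(); a_vol <- col(); a_anon <- col(); a_img <- col()
  a_pres <- col(); a_idx <- col(); a_cat <- col(); a_x <- col(); a_y <- col()
  next_id <- 1L
  for (i in seq_len(n_img)) {
    n_cl <- config$classifications_per_phase[sc$phase[i]]
    vols <- sample(config$n_volunteers, n_cl, prob = pool$weight)
    pos <- pos_by_img[[sc$image_id[i]]]
    m <- if (is.null(pos)) 0L else nrow(pos)
    p_eff <- pmin(1, pool$p_detect[vols] *
                    config$phase_detectability[sc$phase[i]] *
                    if (sc$quality[i] == "bad") config$quality_penalty else 1)
    det <- if (m > 0) {
      p_mark <- rep(p_eff, each = m) * rep.int(pos$visibility, n_cl)
      matrix(stats::rbinom(n_cl * m, 1, p_mark) == 1,
             nrow = m, ncol = n_cl)
    } else matrix(FALSE, 0, n_cl)
    n_fp <- stats::rpois(n_cl, config$false_positive_rate)
    n_hit <- if (m > 0) colSums(det) else integer(n_cl)
    n_marks <- n_hit + n_fp
    rows_of <- pmax(n_marks, 1L)           # mark-less classifications: 1 row
    cids <- as.character(seq.int(next_id, length.out = n_cl))
    next_id <- next_id + n_cl
    rep_v <- rep.int(seq_len(n_cl), rows_of)
    # true-detection marks, in classification order
    xs <- ys <- numeric(0); cats <- character(0)
    if (m > 0 && any(n_hit > 0)) {
      hits <- which(det)                   # column-major: grouped by volunteer
      arow <- ((hits - 1L) %% m) + 1L
      xs0 <- pos$x[arow] + stats::rnorm(length(arow), 0, config$mark_jitter_sd)
      ys0 <- pos$y[arow] + stats::rnorm(length(arow), 0, config$mark_jitter_sd)
      cats0 <- ifelse(pos$near_edge[arow] &
                        stats::runif(length(arow)) < config$partial_fraction,
                      "partial", pos$category[arow])
    } else {
      arow <- integer(0); xs0 <- ys0 <- numeric(0); cats0 <- character(0)
    }
    # interleave detections and spurious marks per classification
    idx <- integer(sum(rows_of)); cat_i <- character(sum(rows_of))
    x_i <- rep(NA_real_, sum(rows_of)); y_i <- rep(NA_real_, sum(rows_of))
    off <- cumsum(c(0L, rows_of))          # row offsets per classification
    hoff <- cumsum(c(0L, n_hit))           # offsets into detection vectors
    for (v in seq_len(n_cl)) {
      r0 <- off[v]
      if (n_marks[v] == 0L) {
        idx[r0 + 1L] <- NA_integer_; cat_i[r0 + 1L] <- NA_character_
        next
      }
      kk <- n_marks[v]
      idx[r0 + seq_len(kk)] <- seq_len(kk)
      if (n_hit[v] > 0) {
        hr <- hoff[v] + seq_len(n_hit[v])
        x_i[r0 + seq_len(n_hit[v])] <- xs0[hr]
        y_i[r0 + seq_len(n_hit[v])] <- ys0[hr]
        cat_i[r0 + seq_len(n_hit[v])] <- cats0[hr]
      }
      if (n_fp[v] > 0) {
        fr <- r0 + n_hit[v] + seq_len(n_fp[v])
        x_i[fr] <- stats::runif(n_fp[v], 0, w)
        y_i[fr] <- stats::runif(n_fp[v], 0, h)
        cat_i[fr] <- "other"
      }
    }
    x_i <- pmin(pmax(x_i, 0), w); y_i <- pmin(pmax(y_i, 0), h)
    a_cid[[i]] <- cids[rep_v]
    a_vol[[i]] <- pool$volunteer_id[vols][rep_v]
    a_anon[[i]] <- pool$anonymous[vols][rep_v]
    a_img[[i]] <- rep.int(sc$image_id[i], length(rep_v))
    a_pres[[i]] <- ifelse(n_marks[rep_v] > 0, "yes", "no")
    a_idx[[i]] <- idx; a_cat[[i]] <- cat_i; a_x[[i]] <- x_i; a_y[[i]] <- y_i
  }
  out <- data.frame(
    classification_id = unlist(a_cid, use.names = FALSE),
    volunteer_id = unlist(a_vol, use.names = FALSE),
    anonymous = unlist(a_anon, use.names = FALSE),
    image_id = unlist(a_img, use.names = FALSE),
    presence_answer = unlist(a_pres, use.names = FALSE),
    mark_index = unlist(a_idx, use.names = FALSE),
    category = unlist(a_cat, use.names = FALSE),
    x = unlist(a_x, use.names = FALSE),
    y = unlist(a_y, use.names = FALSE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# volunteer pool: power-law activity weights by rank, skill mixture,
# anonymity assigned independently of rank
volunteer_pool <- function(config) {
  nv <- config$n_volunteers
  anon <- stats::runif(nv) < config$anonymous_fraction
  id <- ifelse(anon,
               sprintf("not-logged-in:%08d", seq_len(nv)),
               sprintf("vol%05d", seq_len(nv)))
  skill <- sample(length(config$skill_probs), nv, replace = TRUE,
                  prob = config$skill_probs)
  data.frame(volunteer_id = id, anonymous = anon,
             weight = seq_len(nv)^(-config$activity_exponent),
             p_detect = unname(config$skill_p_detect[skill]),
             stringsAsFactors = FALSE)
}

#' Simulate a full study
#'
#' Convenience wrapper: [generate_scenes()] then
#' [simulate_classifications()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `scenes` (a `"scene_set"`), `classifications` and
#'   `gold`.
#' @export
simulate_study <- function(config = sim_config()) {
  scenes <- generate_scenes(config)
  cls <- simulate_classifications(scenes, config)
  list(scenes = scenes, classifications = cls, gold = scenes$gold)
}
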