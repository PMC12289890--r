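sim_long <- function(n_img, rate_a, rate_b, seed) {
  set.seed(seed)
  data.frame(
    image_id = rep(sprintf("i%04d", seq_len(n_img)), 2),
    phase = 1L, quality = "good", abundance_category = "low",
    source = factor(rep(c("expert", "hdbscan"), each = n_img),
                    levels = c("expert", "hdbscan")),
    count = c(rpois(n_img, rate_a), rpois(n_img, rate_b)),
    stringsAsFactors = FALSE)
}

test_that("the long table is the image-by-source cross product", {
  gold <- gold_row(c("i1", "i2", "i3"), 1, c(2L, 1L, 3L))
  agg <- data.frame(image_id = c("i1", "i2", "i3"),
                    consensus_present = TRUE, n_contributing = 5L,
                    count_median = c(1.5, 1, 3), count_mode = c(2L, 1L, 3L),
                    count_dbscan = c(2L, 2L, 3L), count_hdbscan = c(2L, 1L, 2L))
  lt <- build_long_table(agg, gold)
  expect_equal(nrow(lt), 12)
  lt3 <- build_long_table(agg, gold, sources = c("expert", "median", "mode"))
  expect_equal(nrow(lt3), 9)
  # brute-force cross product
  expect_equal(nrow(lt), length(unique(lt$image_id)) * nlevels(lt$source))
  expect_equal(as.vector(table(lt$source)), rep(3, 4))
  # medians rounded half-up
  expect_equal(lt$count[lt$source == "median" & lt$image_id == "i1"], 2)
  # expert-present restriction
  gold0 <- gold_row(c("i1", "i2", "i3"), 1, c(2L, 0L, 3L))
  expect_equal(nrow(build_long_table(agg, gold0)), 8)
})

test_that("identical sources fit a null method effect", {
  lt <- sim_long(120, 4, 4, seed = 30)
  lt$count[lt$source == "hdbscan"] <- lt$count[lt$source == "expert"]
  fit <- fit_quasipoisson(lt)
  expect_equal(unname(coef(fit)[2]), 0, tolerance = 1e-10)
  p <- fit$anova_chisq[["Pr(>Chi)"]][2]
  expect_gt(p, 0.9)
  ctr <- pairwise_contrasts(fit)
  expect_gt(ctr$p_adjusted, 0.9)
})

test_that("constant counts give intercept log(c) and near-zero dispersion", {
  lt <- sim_long(40, 1, 1, seed = 31)
  lt$count <- 7L
  fit <- fit_quasipoisson(lt)
  expect_equal(unname(coef(fit)[1]), log(7), tolerance = 1e-8)
  expect_equal(unname(coef(fit)[2]), 0, tolerance = 1e-8)
  expect_lt(fit$dispersion, 1e-8)
})

test_that("the method coefficient is consistent for a known rate ratio", {
  lt <- sim_long(2000, 5, 4, seed = 32)
  fit <- fit_quasipoisson(lt)
  expect_equal(unname(coef(fit)["sourcehdbscan"]), log(0.8),
               tolerance = 0.06)
})

test_that("quasi-Poisson point estimates equal Poisson maximum likelihood", {
  lt <- sim_long(150, 5, 3, seed = 33)
  qfit <- fit_quasipoisson(lt)
  pfit <- glm(count ~ source, family = poisson(), data = lt)
  expect_equal(coef(qfit), coef(pfit), tolerance = 1e-12)
})

test_that("pairwise contrasts cover all pairs and adjustment never helps", {
  set.seed(34)
  n <- 80
  lt <- data.frame(
    image_id = rep(sprintf("i%03d", 1:n), 4),
    phase = 1L, quality = "good", abundance_category = "low",
    source = factor(rep(c("expert", "median", "mode", "hdbscan"), each = n),
                    levels = c("expert", "median", "mode", "hdbscan")),
    count = rpois(4 * n, rep(c(5, 3.5, 3.4, 4.5), each = n)))
  fit <- fit_quasipoisson(lt)
  adj <- pairwise_contrasts(fit, adjust = "tukey")
  raw <- pairwise_contrasts(fit, adjust = "none")
  expect_equal(nrow(adj), choose(4, 2))
  expect_equal(adj$contrast, raw$contrast)
  expect_true(all(adj$p_adjusted >= raw$p_adjusted - 1e-12))
  # z-ratios flip sign when the factor levels are reversed
  lt2 <- lt
  lt2$source <- factor(as.character(lt2$source),
                       levels = rev(levels(lt$source)))
  fit2 <- fit_quasipoisson(lt2)
  adj2 <- pairwise_contrasts(fit2, adjust = "tukey")
  pair_key <- function(d) {
    vapply(strsplit(d$contrast, " - "),
           function(p) paste(sort(p), collapse = "|"), "")
  }
  m <- match(pair_key(adj), pair_key(adj2))
  expect_equal(abs(adj$z_ratio), abs(adj2$z_ratio[m]), tolerance = 1e-8)
  expect_error(pairwise_contrasts(fit, factor = "quality"), "not in")
})

test_that("the nested-model test is calibrated under the null", {
  set.seed(35)
  reps <- 150
  p <- replicate(reps, {
    lt <- sim_long(60, 4, 4, seed = sample.int(1e6, 1))
    fit <- fit_quasipoisson(lt)
    fit$anova_chisq[["Pr(>Chi)"]][2]
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.13)
})

test_that("Nagelkerke R2 follows its closed form and limits", {
  expect_equal(nagelkerke_r2(-10, -10, 50), 0)
  expect_equal(nagelkerke_r2(0, -30, 50), 1)
  expect_error(nagelkerke_r2(-31, -30, 50), "below the null")
  # brute-force logistic check on a tiny non-separable sample: the
  # likelihood is maximised directly and fed through the formula
  y <- c(0, 1, 0, 1, 1); x <- c(1, 2, 3, 4, 2)
  loglik <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  opt <- optim(c(0, 0), function(b) -loglik(b[1], b[2]))
  ll1 <- -opt$value
  ll0 <- -optim(0, function(b) -loglik(b, 0), method = "BFGS")$value
  fit <- glm(y ~ x, family = binomial())
  null <- glm(y ~ 1, family = binomial())
  expect_equal(nagelkerke_r2(as.numeric(logLik(fit)),
                             as.numeric(logLik(null)), 5),
               nagelkerke_r2(ll1, ll0, 5), tolerance = 1e-4)
})

test_that("method ranking rewards counts that track expert presence", {
  st <- simulate_study(small_config(n_images = 250, seed = 36))
  an <- consensus_analysis(st$classifications, st$gold, threshold = 5)
  rk <- method_fit_ranking(an$aggregates, st$gold)
  expect_setequal(rk$method, c("median", "mode", "hdbscan"))
  expect_true(all(rk$r2_nagelkerke >= 0 & rk$r2_nagelkerke <= 1))
  expect_equal(rk$r2_nagelkerke, sort(rk$r2_nagelkerke, decreasing = TRUE))
})
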