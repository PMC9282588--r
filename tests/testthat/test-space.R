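test_that("rating normalization floors at 0.01 and detects the 0-100 dialect", {
  expect_equal(normalize_rating(1.0), 1.0)
  expect_equal(normalize_rating(0.0), 0.01)
  expect_equal(normalize_rating(c(97, 40, 0)), c(0.97, 0.40, 0.01))
  expect_error(normalize_rating(120), "100")
  expect_error(normalize_rating(-0.1), "non-negative")
})

test_that("non-normed counts follow the additive-margin odds formula", {
  expect_equal(estimate_nonnormed_count(0, 0, 10, 0), 0L)
  expect_equal(estimate_nonnormed_count(0.5, 0.5, 10, 0.5), 10L)
  # clipped proportion bounds the count at 19x the normed size
  expect_equal(estimate_nonnormed_count(0.9, 0.9, 10, 0), 190L)
  expect_error(estimate_nonnormed_count(0.2, 0.2, 0, 0.2), "no normed")
  expect_error(estimate_nonnormed_count(1.2, 0, 10), "cue_margin")
})

test_that("the frequency-to-strength map is isotonic with fixed points", {
  # already-monotone calibration pairs are reproduced at their knots
  f <- c(0.1, 0.2, 0.4, 0.6, 0.8)
  r <- c(0.2, 0.3, 0.5, 0.7, 0.9)
  expect_equal(strengths_for_unreported_normed(f, f, r), r)
  # constant ratings give a constant map
  expect_equal(strengths_for_unreported_normed(c(0.1, 0.5), f, rep(0.4, 5)),
               c(0.4, 0.4))
  # recovers strength = sqrt(frequency) from noisy ratings
  set.seed(20)
  cf <- runif(50, 0.01, 1)
  cr <- pmin(pmax(sqrt(cf) + rnorm(50, 0, 0.03), 0.01), 1)
  out <- strengths_for_unreported_normed(cf, cf, cr)
  expect_lt(mean(abs(out - sqrt(cf))), 0.05)
  # never outside (0.01, 1]
  expect_true(all(out > 0 & out <= 1))
})

test_that("non-normed slots follow the reweighted strength histogram", {
  expect_length(strengths_for_nonnormed(runif(20), 1, 0.1, 0), 0)
  # uniform weights over 10 occupied bins put one slot at each midpoint
  s <- seq(0.05, 0.95, by = 0.1)
  out <- strengths_for_nonnormed(s, rep(0.5, 10), 0.1, 10)
  expect_equal(sort(out), s)
  # doubling the bin width moves strengths by less than 0.1 on average
  set.seed(30)
  smooth <- rbeta(500, 2, 2)
  a <- sort(strengths_for_nonnormed(smooth, 0.5, 0.1, 50))
  b <- sort(strengths_for_nonnormed(smooth, 0.5, 0.2, 50))
  expect_lt(mean(abs(a - b)), 0.1)
  expect_error(strengths_for_nonnormed(s, 0, 0.1, 5), "zero")
})

test_that("spaces rebuilt from a synthetic cohort match the ground truth", {
  cfg <- cohort_config(n_per_group = 4, n_cues = 15, seed = 7)
  coh <- gen_cohort(cfg)
  tr <- coh$trials[!is.na(coh$trials$response), ]
  spaces <- build_spaces(tr, coh$norms)
  # reported associations always appear in the rebuilt space
  for (pid in names(spaces)) {
    ptr <- tr[tr$participant == pid, ]
    for (cu in unique(ptr$cue)) {
      sp <- spaces[[pid]][[tolower(cu)]]
      expect_true(all(tolower(ptr$response[ptr$cue == cu]) %in% sp$ids))
      expect_gte(length(sp$ids), 2)
      expect_true(all(sp$strengths > 0 & sp$strengths <= 1))
    }
  }
  # deterministic rebuild
  spaces2 <- build_spaces(tr, coh$norms)
  expect_identical(spaces, spaces2)
  # pooled strength correlation with the generating truth, per participant
  cors <- sapply(names(spaces), function(pid) {
    est_all <- tru_all <- c()
    for (cu in names(spaces[[pid]])) {
      est <- spaces[[pid]][[cu]]
      tru <- coh$truth$spaces[[pid]][[cu]]
      common <- intersect(tolower(est$ids), tolower(tru$ids))
      est_all <- c(est_all, est$strengths[match(common, tolower(est$ids))])
      tru_all <- c(tru_all, tru$strengths[match(common, tolower(tru$ids))])
    }
    cor(est_all, tru_all)
  })
  expect_gt(median(cors), 0.8)
  # median non-normed slot share tracks the configured rate within 5 points
  nn_share <- sapply(names(spaces), function(pid)
    median(sapply(spaces[[pid]], function(s) mean(!s$normed))))
  expect_lt(abs(median(nn_share) - cfg$space$nonnormed_rate), 0.05)
})

test_that("norm tables are validated", {
  bad <- data.frame(cue = c("a", "a"), association = c("x", "x"),
                    frequency = c(0.4, 0.4))
  expect_error(smpassoc:::validate_norms(bad), "duplicate")
  bad2 <- data.frame(cue = "a", association = "x", frequency = 1.4)
  expect_error(smpassoc:::validate_norms(bad2), "frequencies")
})
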