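test_that("norm generation is deterministic with unit-sum frequencies", {
  n1 <- gen_norms(5, seed = 3)
  n2 <- gen_norms(5, seed = 3)
  expect_identical(n1, n2)
  sums <- tapply(n1$frequency, n1$cue, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # frequencies sorted descending within cue
  for (cu in unique(n1$cue))
    expect_true(all(diff(n1$frequency[n1$cue == cu]) <= 0))
  n_small <- gen_norms(2, size_range = c(2, 2), concentration = 1e6,
                       seed = 1)
  expect_equal(n_small$frequency, rep(0.5, 4), tolerance = 1e-2)
})

test_that("cohort generation is a pure function of its configuration", {
  cfg <- cohort_config(n_per_group = 2, n_cues = 5, seed = 42)
  a <- gen_cohort(cfg)
  b <- gen_cohort(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth$params, b$truth$params)
  # minimal design: 1 participant per group, 1 cue, 1 presentation
  tiny <- gen_cohort(cohort_config(n_per_group = 1, n_cues = 1,
                                   presentations = 1, n_fast_guess = 0,
                                   seed = 1))
  expect_equal(nrow(tiny$trials), 2)
  expect_true(all(tiny$trials$presentation == 1))
})

test_that("reported associations exist in their ground-truth spaces", {
  coh <- gen_cohort(cohort_config(n_per_group = 3, n_cues = 8, seed = 9))
  tr <- coh$trials[!is.na(coh$trials$response), ]
  ok <- vapply(seq_len(nrow(tr)), function(i) {
    sp <- coh$truth$spaces[[tr$participant[i]]][[tr$cue[i]]]
    tr$response[i] %in% sp$ids
  }, logical(1))
  expect_true(all(ok))
  # injected fast guesses are flagged and counted
  expect_equal(sum(coh$trials$injected_fast), 16)
  expect_true(all(coh$trials$rt[coh$trials$injected_fast] < 0.1))
  expect_true(all(!coh$trials$valid[coh$trials$injected_fast]))
})

test_that("zero rating noise returns the base strengths exactly", {
  coh <- gen_cohort(cohort_config(n_per_group = 2, n_cues = 5,
                                  rating_noise_sd = 0, n_fast_guess = 0,
                                  seed = 10))
  tr <- coh$trials[!is.na(coh$trials$response), ]
  base <- vapply(seq_len(nrow(tr)), function(i) {
    sp <- coh$truth$spaces[[tr$participant[i]]][[tr$cue[i]]]
    sp$strengths[match(tr$response[i], sp$ids)]
  }, numeric(1))
  expect_equal(tr$rating, base)
})

test_that("cohorts survive a write/read round trip bit-for-bit", {
  coh <- gen_cohort(cohort_config(n_per_group = 2, n_cues = 4, seed = 11))
  dir <- file.path(tempdir(), "smpassoc-cohort-test")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$trials$rt, coh$trials$rt, tolerance = 1e-9)
  expect_equal(back$trials$response, coh$trials$response)
  expect_equal(back$norms$frequency, coh$norms$frequency)
  p1 <- names(coh$truth$params)[1]
  expect_equal(back$truth$params[[p1]]$rho, coh$truth$params[[p1]]$rho)
  expect_equal(back$truth$spaces[[p1]][[1]]$strengths,
               coh$truth$spaces[[p1]][[1]]$strengths)
  # identical writes produce identical files
  dir2 <- file.path(tempdir(), "smpassoc-cohort-test2")
  write_cohort(coh, dir2)
  expect_identical(readLines(file.path(dir, "trials.csv")),
                   readLines(file.path(dir2, "trials.csv")))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("suppress participants repeat less than controls at the defaults", {
  # cohort medians, averaged over seeds
  diffs <- sapply(1:3, function(sd) {
    coh <- gen_cohort(cohort_config(n_per_group = 4, n_cues = 15,
                                    seed = sd))
    cl <- classify_trials(coh$trials[coh$trials$valid, ])
    per <- tapply(cl$trial_type == "repeated/repeated",
                  list(cl$participant), mean)
    grp <- coh$truth$groups[names(per)]
    median(per[grp == "suppress"]) - median(per[grp == "control"])
  })
  expect_lt(mean(diffs), 0)
})
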