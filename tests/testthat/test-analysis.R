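test_that("trial classification crosses novelty with cue repetition", {
  tr <- data.frame(participant = "p1", cue = "table", presentation = 1:3,
                   response = c("A", "B", "A"), rt = 1)
  cl <- classify_trials(tr)
  expect_equal(cl$trial_type,
               c("new/new", "new/repeated", "repeated/repeated"))
  # all first presentations are new/new; case and whitespace fold
  tr2 <- data.frame(participant = "p1", cue = c("a", "b"), presentation = 1,
                    response = c("x", "y"), rt = 1)
  expect_true(all(classify_trials(tr2)$trial_type == "new/new"))
  tr3 <- data.frame(participant = "p1", cue = "a", presentation = 1:2,
                    response = c("Chair ", "chair"), rt = 1)
  expect_equal(classify_trials(tr3)$trial_type[2], "repeated/repeated")
  # missing responses are labelled, duplicates rejected
  tr4 <- data.frame(participant = "p1", cue = "a", presentation = 1:2,
                    response = c("x", NA), rt = 1)
  expect_equal(classify_trials(tr4)$trial_type[2], "missing")
  expect_error(classify_trials(rbind(tr2, tr2)), "duplicate")
  # order independence given presentation indices
  set.seed(2)
  tr5 <- data.frame(participant = rep(c("p1", "p2"), each = 6),
                    cue = rep(c("a", "b"), 6),
                    presentation = rep(rep(1:3, each = 2), 2),
                    response = sample(c("u", "v", "w"), 12, replace = TRUE),
                    rt = 1)
  cl_a <- classify_trials(tr5)
  perm <- sample(nrow(tr5))
  cl_b <- classify_trials(tr5[perm, ])
  expect_equal(cl_b$trial_type[order(perm)], cl_a$trial_type)
  # idempotence
  expect_equal(classify_trials(cl_a)$trial_type, cl_a$trial_type)
})

test_that("exclusions drop exactly the triggering trials and participants", {
  coh <- gen_cohort(cohort_config(n_per_group = 3, n_cues = 10, seed = 21))
  ex <- apply_exclusions(coh$trials)
  n_fast <- ex$report$n[ex$report$rule == "fast_guess_trials"]
  expect_equal(n_fast, sum(coh$trials$injected_fast))
  expect_equal(sum(ex$report$n), nrow(coh$trials) - nrow(ex$trials))
  # nothing to exclude leaves the table untouched
  clean <- coh$trials[coh$trials$valid, ]
  ex2 <- apply_exclusions(clean)
  expect_equal(nrow(ex2$trials), nrow(clean))
  expect_equal(sum(ex2$report$n), 0)
  # participant-level threshold semantics: > 30% missing drops, 29% keeps
  mk <- function(pid, n_miss, n_tot = 100) {
    data.frame(participant = pid, cue = "c", presentation = seq_len(n_tot),
               response = c(rep(NA_character_, n_miss),
                            rep("x", n_tot - n_miss)),
               rt = 1, rating = 0.5)
  }
  tr <- rbind(mk("p31", 31), mk("p29", 29))
  ex3 <- apply_exclusions(tr)
  expect_equal(ex3$excluded_participants, "p31")
  expect_true(all(ex3$trials$participant == "p29"))
  # degenerate ratings: > 90% of ratings above 0.97
  tr_deg <- data.frame(participant = "pd", cue = "c", presentation = 1:100,
                       response = "x", rt = 1,
                       rating = c(rep(0.99, 95), rep(0.5, 5)))
  expect_equal(apply_exclusions(tr_deg)$excluded_participants, "pd")
})

test_that("descriptives are symmetric for identical groups", {
  tr <- data.frame(participant = rep(c("s1", "s2", "c1", "c2"), each = 4),
                   group = rep(c("suppress", "control"), each = 8),
                   cue = "a", presentation = rep(1:4, 4),
                   response = rep(c("w", "x", "y", "x"), 4),
                   rt = rep(c(1, 1.5, 2, 1.2), 4))
  de <- descriptives(classify_trials(tr))
  expect_equal(de$contrasts$t, rep(0, nrow(de$contrasts)))
  expect_equal(de$contrasts$d, rep(0, nrow(de$contrasts)))
  # single-participant groups have zero-width IQRs
  expect_equal(de$groups$pct_repeated_q1, de$groups$pct_repeated_q3)
})

test_that("analytic power matches the noncentral-t benchmarks", {
  expect_equal(two_sample_power(0, 40), 0.05)
  expect_gte(two_sample_power(2.04, 40, 0.05), 0.99)
  expect_gte(two_sample_power(-2.04, 40, 0.05), 0.99)  # sign ignored
  # strictly increasing in |d| and n
  ds <- seq(0.2, 2, by = 0.3)
  expect_true(all(diff(sapply(ds, two_sample_power, n_per_group = 30)) > 0))
  ns <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(sapply(ns, function(n)
    two_sample_power(0.5, n))) > 0))
  expect_error(two_sample_power(1, 1), "n_per_group")
})

test_that("the absolute-fit table is well-formed even at one simulation", {
  coh <- gen_cohort(cohort_config(n_per_group = 1, n_cues = 8, seed = 31))
  pid <- names(coh$truth$params)[1]
  cl <- classify_trials(coh$trials[coh$trials$valid, ])
  fits <- setNames(list(structure(list(params = coh$truth$params[[pid]]),
                                  class = "smp_fit")), pid)
  af <- absolute_fit(fits, cl[cl$participant == pid, ], coh$truth$spaces,
                     n_sims = 1, seed = 2)
  expect_true(is.data.frame(af$repeated))
  expect_equal(af$repeated$participant, pid)
  expect_true(all(c("observed", "sim_mean") %in% names(af$repeated)))
})

test_that("the RT-difference table has one row per eligible participant-cue", {
  tr <- data.frame(participant = "p1", cue = rep(c("a", "b"), each = 3),
                   presentation = rep(1:3, 2),
                   response = c("x", "y", "x", "u", "u", "u"),
                   rt = c(1, 2, 1.5, 1, 1.2, 1.1), rating = 0.5)
  tab <- rt_difference_table(classify_trials(tr))
  # cue b never has a new/repeated trial, so only cue a appears
  expect_equal(nrow(tab), 1)
  expect_equal(tab$cue, "a")
  expect_equal(tab$dlog_nr_nn, log(2) - log(1))
  expect_equal(tab$n_prior_associations, 2)
})
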