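test_that("the inverted joint density matches the shifted-Gamma closed form", {
  sp <- association_space("c", c("a", "b"), c(0.5, 0.5))
  ctx <- trial_context(sp)
  pp <- smp_params("no_reject", rho = 0, s_mu = 0, e_mu = 1, lam = 1,
                   tau = 0.3)
  # mu = log 2 for both; f(a, tau + log 2) = 0.5 * (1/log 2) * exp(-1)
  expect_equal(trial_density(ctx, pp, "a", 0.3 + log(2)),
               0.5 * exp(-1) / log(2), tolerance = 1e-7)
  # general mixture component: p_j * dgamma(t; 1/lam^2, mu_j lam^2)
  pp2 <- smp_params("no_reject", rho = 0, s_mu = -0.4, e_mu = 1.3,
                    lam = 0.6, tau = 0.5)
  sp2 <- association_space("c", c("a", "b", "d"), c(0.6, 0.3, 0.1))
  ctx2 <- trial_context(sp2)
  p <- sampling_probs(sp2$strengths)
  mu <- mean_gen_time(p, -0.4, 1.3)
  for (j in 1:3) {
    f_cl <- p[j] * dgamma(1.7 - 0.5, shape = 1 / 0.36, scale = mu[j] * 0.36)
    expect_equal(trial_density(ctx2, pp2, sp2$ids[j], 1.7), f_cl,
                 tolerance = 1e-5)  # 48-node inversion floor ~ 4e-8 absolute
  }
})

test_that("density is zero at or below the non-decision time", {
  set.seed(5)
  for (v in smp_variants()) {
    ctx <- make_ctx(4, 2)
    pp <- rand_params(v)
    expect_equal(trial_density(ctx, pp, ctx$space$ids[1], pp$tau), 0)
    expect_equal(trial_density(ctx, pp, ctx$space$ids[1], pp$tau - 0.1), 0)
  }
})

test_that("report probabilities are transforms at zero and normalize", {
  set.seed(8)
  # no_reject: identical to normalized strengths
  ctx <- make_ctx(6, 2)
  pp <- smp_params("no_reject", rho = 1.2, s_mu = -0.5, e_mu = 1, lam = 0.7,
                   tau = 0.4)
  p_mod <- sampling_probs(modified_strengths(ctx$space, ctx$repeated_ids,
                                             1.2))
  expect_equal(unname(report_probs(ctx, pp)), unname(p_mod),
               tolerance = 1e-10)

  # geometric series: one new + one repeated at alpha ~ 1 puts all mass on new
  sp <- association_space("c", c("new1", "old1"), c(0.3, 0.7))
  ctx2 <- trial_context(sp, "old1")
  pp2 <- smp_params("reject", rho = 0, alpha = 1 - 1e-6, s_mu = 0, e_mu = 1,
                    lam = 1, tau = 0.3)
  rp <- report_probs(ctx2, pp2)
  expect_equal(unname(rp["new1"]), 1, tolerance = 1e-5)
  expect_lt(rp["old1"], 1e-5)

  # normalization across variants on randomized contexts
  for (v in smp_variants()) for (i in 1:8) {
    ctx <- make_ctx(sample(3:8, 1), sample(0:3, 1))
    pp <- rand_params(v, alpha_max = 0.99)
    expect_lt(abs(sum(report_probs(ctx, pp)) - 1), 1e-8)
  }
})

test_that("report probabilities match a simulation oracle", {
  set.seed(13)
  for (v in c("reject", "reject_rhow", "reject_noresample")) {
    ctx <- make_ctx(5, 2)
    pp <- rand_params(v)
    rp <- report_probs(ctx, pp)
    sims <- smpassoc:::sim_trials_batch(ctx, pp, 2e5, t_max = Inf)
    emp <- tabulate(sims$reported, length(rp)) / 2e5
    se <- sqrt(rp * (1 - rp) / 2e5)
    expect_true(all(abs(emp - rp) < 3.5 * pmax(se, 1e-6)),
                label = paste("report probs vs simulation,", v))
  }
})

test_that("the rejection variant at alpha = 0 collapses to no rejections", {
  set.seed(21)
  for (i in 1:5) {
    ctx <- make_ctx(5, 2)
    base <- rand_params("reject")
    pars0 <- smp_params("reject", rho = base$rho, alpha = 0,
                        s_mu = base$s_mu, e_mu = base$e_mu, lam = base$lam,
                        tau = base$tau)
    pars_nr <- smp_params("no_reject", rho = base$rho, s_mu = base$s_mu,
                          e_mu = base$e_mu, lam = base$lam, tau = base$tau)
    for (t0 in c(1, 2.5)) {
      j <- ctx$space$ids[sample(5, 1)]
      a <- trial_density(ctx, pars0, j, t0)
      b <- trial_density(ctx, pars_nr, j, t0)
      expect_equal(a, b, tolerance = 1e-6)
    }
  }
})

test_that("censoring probability matches closed form and simulation", {
  set.seed(34)
  ctx <- make_ctx(4, 0)
  pp <- smp_params("no_reject", rho = 0, s_mu = 0.2, e_mu = 1, lam = 0.8,
                   tau = 0.5)
  # essentially no mass beyond a huge window
  expect_lt(censoring_prob(ctx, pp, t_max = 500), 1e-6)
  # no_reject closed form: 1 - sum p_j GammaCDF(t_max - tau)
  p <- sampling_probs(ctx$space$strengths)
  mu <- pmax(mean_gen_time(p, 0.2, 1), 1e-4)
  t_max <- 2.5
  closed <- 1 - sum(p * pgamma(t_max - 0.5, shape = 1 / 0.64,
                               scale = mu * 0.64))
  expect_equal(censoring_prob(ctx, pp, t_max), closed, tolerance = 1e-6)

  # rejection variant vs simulated timeout frequency
  ctx2 <- make_ctx(4, 2)
  pp2 <- smp_params("reject_noresample", rho = 1.4, alpha = 0.7,
                    s_mu = 0.1, e_mu = 1, lam = 0.75, tau = 0.5)
  sims <- smpassoc:::sim_trials_batch(ctx2, pp2, 2e5, t_max = 4)
  emp <- mean(sims$timed_out)
  pr <- censoring_prob(ctx2, pp2, t_max = 4)
  se <- sqrt(pr * (1 - pr) / 2e5)
  expect_lt(abs(emp - pr), 3.5 * se)
})

test_that("session log-likelihood sums trial terms invariantly", {
  spaces <- make_spaces(8, seed = 2)
  pp <- smp_params("reject_noresample", rho = 1.4, alpha = 0.7, s_mu = -0.7,
                   e_mu = 0.8, lam = 0.75, tau = 0.6)
  set.seed(31)
  tr <- simulate_session(spaces, pp, presentations = 4, t_max = Inf)
  ll <- session_loglik(tr, spaces, pp)
  # permuting rows leaves the value unchanged (repeated sets come from
  # presentation indices, not row order)
  set.seed(1)
  tr_perm <- tr[sample(nrow(tr)), ]
  expect_equal(session_loglik(tr_perm, spaces, pp), ll)
  # single-trial reduction: log of the closed-form density
  one <- tr[tr$presentation == 1, ][1, ]
  pp_nr <- smp_params("no_reject", rho = 0, s_mu = -0.7, e_mu = 0.8,
                      lam = 0.75, tau = 0.6)
  f <- trial_density(trial_context(spaces[[one$cue]]), pp_nr, one$response,
                     one$rt)
  expect_equal(session_loglik(one, spaces, pp_nr), log(f), tolerance = 1e-6)
  # compiled and reference engines agree
  ll_r <- session_loglik(tr, spaces, pp, engine = "r")
  expect_equal(ll, ll_r, tolerance = 1e-6)
})

test_that("the generating parameters beat 2-sd-perturbed parameters", {
  spaces <- make_spaces(50, size_range = c(6, 14), seed = 3)
  truth <- smp_params("reject_noresample", rho = 1.41, alpha = 0.7,
                      s_mu = -0.7, e_mu = 0.7, lam = 0.75, tau = 0.7)
  pert <- smp_params("reject_noresample", rho = 1.41 + 2 * 0.54,
                     alpha = min(0.7 + 2 * 0.1, 0.95),
                     s_mu = -0.7 + 2 * 0.3, e_mu = 0.7 + 2 * 0.15,
                     lam = 0.75 + 2 * 0.15, tau = 0.7 + 2 * 0.15)
  wins <- 0
  set.seed(55)
  for (rep_i in 1:20) {
    tr <- simulate_session(spaces, truth, presentations = 5, t_max = 15)
    tr <- tr[!tr$timed_out, ]
    wins <- wins + (session_loglik(tr, spaces, truth) >=
                      session_loglik(tr, spaces, pert))
  }
  expect_gte(wins, 19)
})

test_that("Monte-Carlo joint density normalizes and is seed-reproducible", {
  ctx <- make_ctx(4, 1, seed = 9)
  pp <- smp_params("reject", rho = 1, alpha = 0.6, s_mu = -0.5, e_mu = 1,
                   lam = 0.7, tau = 0.5)
  breaks <- seq(0.5, 25, length.out = 60)
  set.seed(100)
  mc <- mc_joint_density(ctx, pp, 2e4, breaks)
  mass <- sum(mc$density %*% diff(breaks))
  expect_lt(abs(mass - 1), 1 / sqrt(2e4) + 1e-3)
  set.seed(100)
  mc2 <- mc_joint_density(ctx, pp, 2e4, breaks)
  expect_identical(mc$density, mc2$density)
  expect_error(mc_joint_density(ctx, pp, 100, breaks), "1e4")
})
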