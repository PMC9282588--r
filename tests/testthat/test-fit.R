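test_that("parameter transforms round-trip on the interior", {
  p <- smp_params("reject_rhow", rho = 1.2, alpha = 0.5, rho_w = -0.3,
                  s_mu = -0.6, e_mu = 1.4, lam = 0.8, tau = 0.55)
  x <- transform_params(p, tau_max = 1.0)
  q <- untransform_params(x, "reject_rhow", tau_max = 1.0)
  for (nm in c("rho", "alpha", "rho_w", "s_mu", "e_mu", "lam", "tau"))
    expect_equal(q[[nm]], p[[nm]], tolerance = 1e-10)
  # alpha = 0.5 maps near the logit origin, lam = 1 to log 0
  expect_equal(unname(transform_params(p)["lam"]), log(0.8))
  set.seed(4)
  for (i in 1:20) {
    pr <- rand_params("reject")
    x <- transform_params(pr)
    q <- untransform_params(x, "reject")
    expect_equal(params_to_vector_test <- q$alpha, pr$alpha,
                 tolerance = 1e-10)
    expect_equal(q$tau, pr$tau, tolerance = 1e-10)
    expect_equal(q$e_mu, pr$e_mu, tolerance = 1e-10)
  }
})

test_that("fitting with every parameter fixed is a likelihood evaluation", {
  spaces <- make_spaces(10, seed = 12)
  truth <- smp_params("reject", rho = 1.2, alpha = 0.6, s_mu = -0.7,
                      e_mu = 0.8, lam = 0.7, tau = 0.5)
  set.seed(66)
  tr <- simulate_session(spaces, truth, presentations = 4, t_max = Inf)
  fx <- list(rho = 1.2, alpha = 0.6, s_mu = -0.7, e_mu = 0.8, lam = 0.7,
             tau = 0.5)
  fit <- fit_participant(tr, spaces, "reject", fit_config(fixed = fx))
  expect_equal(fit$n_free_params, 0)
  expect_equal(fit$loglik, session_loglik(tr, spaces, truth,
                                          inv = inversion_config(n_nodes = 24)),
               tolerance = 1e-9)
  expect_equal(fit$bic, -2 * fit$loglik)
})

test_that("the BIC identity holds and fits are seed-deterministic", {
  spaces <- make_spaces(10, seed = 13)
  truth <- smp_params("no_reject", rho = 2.5, s_mu = -1.0, e_mu = 0.8,
                      lam = 0.7, tau = 0.55)
  set.seed(77)
  tr <- simulate_session(spaces, truth, presentations = 4, t_max = Inf)
  f1 <- fit_participant(tr, spaces, "no_reject", quick_cfg(seed = 3))
  f2 <- fit_participant(tr, spaces, "no_reject", quick_cfg(seed = 3))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
  expect_equal(f1$bic, f1$n_free_params * log(f1$n_trials) - 2 * f1$loglik)
  expect_equal(f1$n_trials, nrow(tr))
  # the rejection-free truth is recovered reasonably
  expect_lt(abs(f1$params$rho - 2.5), 0.8)
})

test_that("BIC tables rank variants and respect invariances", {
  mk_fit <- function(bic, np) structure(list(bic = bic, n_free_params = np),
                                        class = "smp_fit")
  single <- bic_table(list(no_reject = list(mk_fit(100, 5), mk_fit(90, 5))))
  expect_equal(single$delta_bic, 0)
  tab <- bic_table(list(no_reject = list(mk_fit(100, 5), mk_fit(90, 5)),
                        reject = list(mk_fit(101, 6), mk_fit(92, 6))))
  expect_equal(tab$delta_bic[tab$variant == "no_reject"], 0)
  expect_equal(tab$delta_bic[tab$variant == "reject"], 3)
  # shifting every participant's BIC by a constant preserves the ordering
  tab2 <- bic_table(list(no_reject = list(mk_fit(150, 5), mk_fit(140, 5)),
                         reject = list(mk_fit(151, 6), mk_fit(142, 6))))
  expect_equal(tab2$best, tab$best)
  # ties break toward fewer parameters
  tie <- bic_table(list(reject = list(mk_fit(100, 6)),
                        no_reject = list(mk_fit(100, 5))))
  expect_true(tie$best[tie$variant == "no_reject"])
  expect_error(bic_table(list(a = list(mk_fit(1, 2)),
                              b = list(mk_fit(1, 2), mk_fit(2, 2)))),
               "same participants")
})

test_that("Welch group statistics behave under symmetry and recover d", {
  a <- c(1, 2, 3, 4)
  st <- group_param_stats(a, a)
  expect_equal(st$t, 0)
  expect_equal(st$d, 0)
  set.seed(10)
  x <- rnorm(40, 0.7, 0.1); y <- rnorm(40, 0, 0.05)
  st <- group_param_stats(x, y)
  d_true <- 0.7 / sqrt((0.1^2 + 0.05^2) / 2)
  expect_lt(abs(st$d - d_true) / d_true, 0.15)
  st_sw <- group_param_stats(y, x)
  expect_equal(st_sw$t, -st$t)
  expect_equal(st_sw$d, -st$d)
  expect_error(group_param_stats(c(1), c(2, 3)), ">= 2")
})

test_that("the sensitivity refit frees only the thought-control parameters", {
  spaces <- make_spaces(10, seed = 14)
  truth <- smp_params("reject", rho = 1.3, alpha = 0.65, s_mu = -0.7,
                      e_mu = 0.8, lam = 0.7, tau = 0.5)
  set.seed(88)
  tr <- simulate_session(spaces, truth, presentations = 4, t_max = Inf)
  ref <- list(s_mu = -0.7, e_mu = 0.8, lam = 0.7, tau = 0.5)
  fit <- sensitivity_refit(tr, spaces, "reject", ref, quick_cfg())
  expect_equal(fit$n_free_params, 2)  # alpha and rho
  expect_equal(fit$params$s_mu, -0.7)
  expect_equal(fit$params$tau, 0.5)
  expect_lt(abs(fit$params$alpha - 0.65), 0.25)
  expect_error(sensitivity_refit(tr, spaces, "reject",
                                 list(s_mu = 0, e_mu = 1), quick_cfg()),
               "reference")
})

test_that("fit records serialize to JSON and read back", {
  f <- structure(list(params = smp_params("reject", rho = 1, alpha = 0.5,
                                          s_mu = -0.5, e_mu = 1, lam = 0.7,
                                          tau = 0.4),
                      loglik = -100.5, n_trials = 120, n_free_params = 6,
                      bic = 6 * log(120) + 201, converged = TRUE,
                      start_index = 1L, seed = 1L),
                 class = "smp_fit")
  path <- file.path(tempdir(), "fits.json")
  write_fits(list(P01 = f), path)
  back <- jsonlite::read_json(path)
  expect_equal(back$P01$params$alpha, 0.5)
  expect_equal(back$P01$n_trials, 120)
  expect_equal(back$P01$variant, "reject")
  unlink(path)
})
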