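# shared fixtures: random contexts, parameter draws, tiny cohorts

make_ctx <- function(n = 5, n_rep = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- association_space("cue", paste0("a", seq_len(n)),
                          runif(n, 0.05, 1))
  trial_context(sp, sample(sp$ids, n_rep))
}

rand_params <- function(variant, alpha_max = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  smp_params(variant,
             rho = rnorm(1, 1, 0.8),
             alpha = if (variant == "no_reject") 0 else
               runif(1, 0.05, alpha_max),
             rho_w = if (variant == "reject_rhow") rnorm(1, 0, 1) else NULL,
             s_mu = rnorm(1, -0.5, 0.4),
             e_mu = runif(1, 0.5, 1.8),
             lam = runif(1, 0.3, 1.1),
             tau = runif(1, 0.3, 0.8))
}

# small set of association spaces for session-level tests
make_spaces <- function(n_cues = 20, size_range = c(6, 14), seed = 1) {
  set.seed(seed)
  sp <- lapply(seq_len(n_cues), function(i) {
    m <- sample(seq(size_range[1], size_range[2]), 1)
    association_space(paste0("c", i), paste0("c", i, "_a", seq_len(m)),
                      runif(m, 0.05, 1))
  })
  names(sp) <- paste0("c", seq_len(n_cues))
  sp
}

# group spec with all between-participant sds set to 0 (exact group means)
fixed_mean_spec <- function(spec) {
  for (p in setdiff(names(spec), "variant")) spec[[p]][2] <- 0
  spec
}

# quick fit settings used across tests
quick_cfg <- function(seed = 1, ...) {
  fit_config(n_starts = 2, seed = seed, ...)
}
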