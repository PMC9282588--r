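#' Synthetic cohort configuration
#'
#' Defaults reproduce the study design this package models: two instruction
#' groups (suppress / control) of 40 participants, 60 cues presented five
#' times each in random order within a 15 s response window. Control
#' participants are generated from the rejection-free variant; suppress
#' participants from the rejections + no-resampling variant. The
#' thought-control parameter means are the reported group means
#' (`alpha = 0.7`, `rho = 1.41` suppress; `rho = 3.07` control); the
#' RT-controlling parameter settings are synthetic conventions chosen to
#' put median RTs in the 1-3 s range typical of the task.
#'
#' @param n_per_group Participants per group (default 40).
#' @param n_cues Number of cues (default 60).
#' @param presentations Presentations per cue (default 5).
#' @param t_max Response window in seconds (default 15).
#' @param suppress,control Per-group parameter distributions: named list of
#'   `c(mean, sd)` pairs plus a `variant` tag (sd 0 gives every participant
#'   the mean).
#' @param space Space-generator settings: `size_range` (normed set size,
#'   uniform), `concentration` (Dirichlet concentration of norm
#'   frequencies), `nonnormed_rate` (expected share of reports that are
#'   non-normed; default 0.48), `strength_jitter` (sd of the jitter on
#'   resampled non-normed strengths).
#' @param rating_noise_sd Additive Gaussian noise on ratings (default 0.05).
#' @param n_fast_guess Number of sub-100 ms fast-guess trials injected
#'   across the cohort to exercise exclusion logic (default 16).
#' @param seed Integer seed; the cohort is a pure function of the
#'   configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 40, n_cues = 60, presentations = 5,
                          t_max = 15,
                          suppress = list(variant = "reject_noresample",
                                          alpha = c(0.7, 0.1),
                                          rho = c(1.41, 0.54),
                                          s_mu = c(-0.7, 0.3),
                                          e_mu = c(0.7, 0.15),
                                          lam = c(0.75, 0.15),
                                          tau = c(0.7, 0.15)),
                          control = list(variant = "no_reject",
                                         rho = c(3.07, 1.09),
                                         s_mu = c(-1.1, 0.3),
                                         e_mu = c(0.7, 0.15),
                                         lam = c(0.75, 0.15),
                                         tau = c(0.6, 0.15)),
                          space = list(size_range = c(8, 20),
                                       concentration = 1,
                                       nonnormed_rate = 0.48,
                                       strength_jitter = 0.02),
                          rating_noise_sd = 0.05,
                          n_fast_guess = 16,
                          seed = 1) {
  stopifnot(n_per_group >= 1, n_cues >= 1, presentations >= 1, t_max > 0,
            rating_noise_sd >= 0, n_fast_guess >= 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_cues = as.integer(n_cues),
                 presentations = as.integer(presentations),
                 t_max = t_max, suppress = suppress, control = control,
                 space = space, rating_noise_sd = rating_noise_sd,
                 n_fast_guess = as.integer(n_fast_guess),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# truncated-normal draw by rejection (falls back to clipping after 100 tries)
rtnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in 1:100) {
    x <- rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

param_bounds <- list(rho = c(-10, 10), rho_w = c(-10, 10),
                     alpha = c(0.01, 0.99), s_mu = c(-5, 3),
                     e_mu = c(0.2, 5), lam = c(0.1, 3), tau = c(0.1, 2))

draw_group_params <- function(spec) {
  variant <- spec$variant
  nm <- setdiff(names(spec), "variant")
  vals <- lapply(setNames(nm, nm), function(p) {
    b <- param_bounds[[p]]
    rtnorm1(spec[[p]][1], spec[[p]][2], b[1], b[2])
  })
  smp_params(variant = variant,
             rho = vals$rho,
             alpha = if (variant == "no_reject") 0
                     else if (is.null(vals$alpha)) 0 else vals$alpha,
             rho_w = if (variant == "reject_rhow") vals$rho_w else NULL,
             s_mu = vals$s_mu, e_mu = vals$e_mu, lam = vals$lam,
             tau = vals$tau)
}

#' Generate a synthetic free-association norm table
#'
#' Stands in for published population norms: per cue, a normed set whose
#' size is uniform over `size_range` and whose frequencies are a sorted
#' symmetric Dirichlet draw (summing to 1).
#'
#' @param n_cues Number of cues.
#' @param size_range Integer range of per-cue set sizes (default 10-40).
#' @param concentration Dirichlet concentration (default 1).
#' @param seed Integer seed (deterministic output).
#' @return Data frame `cue`, `association`, `frequency`, sorted by cue and
#'   descending frequency.
#' @export
gen_norms <- function(n_cues, size_range = c(10, 40), concentration = 1,
                      seed = 1) {
  stopifnot(size_range[1] >= 2)
  with_seed(seed, {
    sizes <- seq(size_range[1], size_range[2])
    out <- lapply(seq_len(n_cues), function(ci) {
      m <- sizes[sample.int(length(sizes), 1)]
      f <- rgamma(m, shape = concentration)
      f <- sort(f / sum(f), decreasing = TRUE)
      data.frame(cue = sprintf("cue%03d", ci),
                 association = sprintf("cue%03d_w%02d", ci, seq_len(m)),
                 frequency = f)
    })
    do.call(rbind, out)
  })
}

# Ground-truth space for one (participant, cue): normed associations with
# strength sqrt(frequency), plus non-normed associations resampled from the
# normed strengths (so that the expected non-normed report share matches
# the configured rate).
gen_space <- function(cue, cue_norms, pid, space_cfg) {
  strengths_n <- pmin(pmax(sqrt(cue_norms$frequency),
                           .smp_const$strength_eps), 1)
  rate <- space_cfg$nonnormed_rate
  m <- nrow(cue_norms)
  n_nn <- round(m * rate / (1 - rate))
  ids <- cue_norms$association
  strengths <- strengths_n
  normed <- rep(TRUE, m)
  if (n_nn > 0) {
    s_nn <- sample(strengths_n, n_nn, replace = TRUE) +
      rnorm(n_nn, 0, space_cfg$strength_jitter)
    s_nn <- pmin(pmax(s_nn, .smp_const$strength_eps), 1)
    ids <- c(ids, sprintf("%s_p%s_nn%02d", cue, pid, seq_len(n_nn)))
    strengths <- c(strengths, s_nn)
    normed <- c(normed, rep(FALSE, n_nn))
  }
  association_space(cue, ids, strengths, normed)
}

#' Generate a two-group synthetic cohort with known ground truth
#'
#' Simulates the full design: norms, per-(participant, cue) association
#' spaces, per-participant parameters drawn from the configured group
#' distributions, and every trial of every session, plus post-task strength
#' ratings (base strength plus clipped Gaussian noise) and a configurable
#' number of injected sub-100 ms fast-guess trials.
#'
#' @param cfg A [cohort_config()].
#' @return A list with `trials` (data frame: `participant`, `group`, `cue`,
#'   `presentation`, `response`, `rt` seconds, `rating`, `valid`,
#'   `timed_out`, `injected_fast`), `norms`, and `truth` (per-participant
#'   `params`, per-participant `spaces`, injected-trial flags, seed).
#' @export
gen_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    norms <- gen_norms(cfg$n_cues, cfg$space$size_range,
                       cfg$space$concentration,
                       seed = sample.int(.Machine$integer.max, 1))
    cues <- unique(norms$cue)
    groups <- c(rep("suppress", cfg$n_per_group),
                rep("control", cfg$n_per_group))
    pids <- sprintf("P%02d", seq_along(groups))
    params_list <- list()
    spaces_list <- list()
    trial_rows <- list()
    for (i in seq_along(pids)) {
      pid <- pids[i]
      spec <- if (groups[i] == "suppress") cfg$suppress else cfg$control
      pars <- draw_group_params(spec)
      spaces <- lapply(setNames(cues, cues), function(cu)
        gen_space(cu, norms[norms$cue == cu, , drop = FALSE], pid,
                  cfg$space))
      sess <- simulate_session(spaces, pars,
                               presentations = cfg$presentations,
                               t_max = cfg$t_max)
      sess$participant <- pid
      sess$group <- groups[i]
      # ratings: base strength of the reported association + noise
      sess$rating <- NA_real_
      has <- !is.na(sess$response)
      base <- vapply(which(has), function(r) {
        sp <- spaces[[sess$cue[r]]]
        sp$strengths[match(sess$response[r], sp$ids)]
      }, numeric(1))
      sess$rating[has] <- pmin(pmax(base +
        rnorm(sum(has), 0, cfg$rating_noise_sd), 0), 1)
      params_list[[pid]] <- pars
      spaces_list[[pid]] <- spaces
      trial_rows[[pid]] <- sess
    }
    trials <- do.call(rbind, trial_rows)
    rownames(trials) <- NULL
    # inject fast guesses (rt < 100 ms) into randomly chosen answered trials
    trials$injected_fast <- FALSE
    cand <- which(!trials$timed_out)
    n_fast <- min(cfg$n_fast_guess, length(cand))
    if (n_fast > 0) {
      pick <- sample(cand, n_fast)
      trials$rt[pick] <- runif(n_fast, 0.02, 0.095)
      trials$injected_fast[pick] <- TRUE
    }
    trials$valid <- !trials$timed_out & !trials$injected_fast
    trials <- trials[, c("participant", "group", "cue", "presentation",
                         "response", "rt", "rating", "valid", "timed_out",
                         "injected_fast", "n_attempts")]
    # post-task rating table: one row per (participant, cue, association),
    # first report
    has <- !is.na(trials$response)
    first <- has & !duplicated(paste(trials$participant, trials$cue,
                                     tolower(trials$response)))
    ratings <- data.frame(participant = trials$participant[first],
                          cue = trials$cue[first],
                          association = trials$response[first],
                          rating = trials$rating[first])
    list(trials = trials, ratings = ratings, norms = norms,
         truth = list(params = params_list, spaces = spaces_list,
                      groups = setNames(groups, pids), seed = cfg$seed))
  })
}

#' Write / read a cohort as plain-text files
#'
#' Trials and norms go to CSV (RTs written in milliseconds at the file
#' boundary; seconds in memory), ground-truth parameters and spaces to
#' JSON. Output is bit-stable given identical input.
#'
#' @param cohort A cohort from [gen_cohort()].
#' @param dir Destination directory (created if needed).
#' @return `write_cohort`: the directory, invisibly. `read_cohort`: a
#'   cohort list (`trials`, `norms`, `truth`).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tr <- cohort$trials
  tr$rt_ms <- round(tr$rt * 1000, 6)
  tr$rt <- NULL
  write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  if (!is.null(cohort$ratings))
    write.csv(cohort$ratings, file.path(dir, "ratings.csv"),
              row.names = FALSE)
  write.csv(cohort$norms, file.path(dir, "norms.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth_json <- list(
    seed = truth$seed,
    groups = as.list(truth$groups),
    params = lapply(truth$params, function(p)
      p[c("variant", "rho", "alpha", "rho_w", "s_mu", "e_mu", "lam", "tau")]),
    spaces = lapply(truth$spaces, function(sps) lapply(sps, function(s)
      list(cue = s$cue_id, ids = s$ids, strengths = s$strengths,
           normed = s$normed))))
  jsonlite::write_json(truth_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tr <- read.csv(file.path(dir, "trials.csv"),
                 colClasses = c(response = "character"))
  tr$response[tr$response == ""] <- NA_character_
  tr$rt <- tr$rt_ms / 1000
  tr$rt_ms <- NULL
  norms <- read.csv(file.path(dir, "norms.csv"))
  ratings_path <- file.path(dir, "ratings.csv")
  ratings <- if (file.exists(ratings_path)) read.csv(ratings_path) else NULL
  tj <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  params <- lapply(tj$params, function(p)
    smp_params(variant = p$variant, rho = p$rho,
               alpha = if (is.null(p$alpha)) 0 else p$alpha,
               rho_w = p$rho_w, s_mu = p$s_mu, e_mu = p$e_mu,
               lam = p$lam, tau = p$tau))
  spaces <- lapply(tj$spaces, function(sps) lapply(sps, function(s)
    association_space(s$cue, unlist(s$ids), unlist(s$strengths),
                      unlist(s$normed))))
  list(trials = tr, ratings = ratings, norms = norms,
       truth = list(params = params, spaces = spaces,
                    groups = unlist(tj$groups), seed = tj$seed))
}
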