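#' Classify trials by response novelty and cue repetition
#'
#' A response is "repeated" iff it string-matches (case-folded, trimmed) a
#' response the same participant gave to an earlier presentation of the
#' same cue. Crossing response novelty with cue presentation gives the
#' trial types: `new/new` (first presentation), `new/repeated` (new
#' association to a repeated cue), `repeated/repeated`; missing responses
#' get `missing`, and a "repeated" response on a first presentation (only
#' possible with malformed input) gets `repeated_first`.
#'
#' @param trials Data frame with `participant`, `cue`, `presentation`,
#'   `response` (plus any other columns, preserved).
#' @return `trials` with a `trial_type` column added.
#' @export
classify_trials <- function(trials) {
  stopifnot(all(c("participant", "cue", "presentation", "response")
                %in% names(trials)))
  norm_str <- function(x) tolower(trimws(as.character(x)))
  key <- paste(trials$participant, trials$cue, trials$presentation)
  if (anyDuplicated(key))
    stop("duplicate (participant, cue, presentation) keys")
  ord <- order(trials$participant, trials$cue, trials$presentation)
  tt <- rep(NA_character_, nrow(trials))
  for (grp in split(ord, paste(trials$participant[ord], trials$cue[ord]))) {
    seen <- character(0)
    for (i in grp) {
      resp <- trials$response[i]
      if (is.na(resp)) { tt[i] <- "missing"; next }
      resp <- norm_str(resp)
      repeated <- resp %in% seen
      first_pres <- trials$presentation[i] == min(trials$presentation[grp])
      tt[i] <- if (repeated && first_pres) "repeated_first"
               else if (repeated) "repeated/repeated"
               else if (first_pres) "new/new"
               else "new/repeated"
      seen <- c(seen, resp)
    }
  }
  trials$trial_type <- tt
  trials
}

#' Exclusion rules
#'
#' Defaults follow the task's printed criteria: trials faster than 100 ms
#' are dropped, timeouts (missing responses) are dropped, participants
#' missing more than 30% of responses are excluded, and participants with
#' degenerate ratings (more than 90% of ratings above 0.97) are excluded.
#'
#' @param min_rt Trial-level minimum RT in seconds (default 0.1).
#' @param drop_timeouts Drop trials without a response (default TRUE).
#' @param max_missing_rate Participant-level missing-response threshold
#'   (default 0.30; strictly greater is excluded).
#' @param rating_ceiling,rating_ceiling_prop Participant-level degenerate
#'   rating rule: excluded if more than `rating_ceiling_prop` of ratings
#'   exceed `rating_ceiling` (defaults 0.97 and 0.90).
#' @return A list of rules for [apply_exclusions()].
#' @export
exclusion_rules <- function(min_rt = 0.1, drop_timeouts = TRUE,
                            max_missing_rate = 0.30,
                            rating_ceiling = 0.97,
                            rating_ceiling_prop = 0.90) {
  list(min_rt = min_rt, drop_timeouts = drop_timeouts,
       max_missing_rate = max_missing_rate,
       rating_ceiling = rating_ceiling,
       rating_ceiling_prop = rating_ceiling_prop)
}

#' Apply trial- and participant-level exclusions
#'
#' @param trials Trial table (`participant`, `response`, `rt`, optionally
#'   `rating`).
#' @param rules From [exclusion_rules()].
#' @return List with `trials` (filtered), `excluded_participants`
#'   (character vector) and `report` (data frame of per-rule counts;
#'   trial-level counts sum to the number of trials removed).
#' @export
apply_exclusions <- function(trials, rules = exclusion_rules()) {
  n0 <- nrow(trials)
  # participant-level rules evaluate on the raw data
  missing_rate <- tapply(is.na(trials$response), trials$participant, mean)
  bad_missing <- names(missing_rate)[missing_rate > rules$max_missing_rate]
  bad_rating <- character(0)
  if ("rating" %in% names(trials)) {
    ceiling_rate <- tapply(trials$rating > rules$rating_ceiling,
                           trials$participant,
                           function(x) mean(x, na.rm = TRUE))
    ceiling_rate[is.na(ceiling_rate)] <- 0
    bad_rating <- names(ceiling_rate)[ceiling_rate >
                                        rules$rating_ceiling_prop]
  }
  excluded <- union(bad_missing, bad_rating)
  keep_p <- !(trials$participant %in% excluded)
  n_part_trials <- sum(!keep_p)
  trials <- trials[keep_p, , drop = FALSE]

  is_timeout <- is.na(trials$response)
  n_timeout <- if (rules$drop_timeouts) sum(is_timeout) else 0L
  if (rules$drop_timeouts) trials <- trials[!is_timeout, , drop = FALSE]

  too_fast <- !is.na(trials$rt) & trials$rt < rules$min_rt
  n_fast <- sum(too_fast)
  trials <- trials[!too_fast, , drop = FALSE]

  report <- data.frame(
    rule = c("participant_excluded_trials", "timeout_trials",
             "fast_guess_trials"),
    n = c(n_part_trials, n_timeout, n_fast))
  stopifnot(sum(report$n) == n0 - nrow(trials))
  list(trials = trials, excluded_participants = excluded, report = report)
}

#' Descriptive group summaries and contrasts
#'
#' Computes, per participant, the share of repeated responses (among
#' answered trials of repeated cue presentations), and the median raw RT
#' and mean log RT per trial type; per group, medians and inter-quartile
#' ranges; and the group contrast (Welch t, Cohen's d) on the
#' new/repeated minus new/new RT difference (log and raw-median) and on
#' the repeated/repeated minus new/new log difference.
#'
#' @param trials Classified, filtered trial table (needs `participant`,
#'   `group`, `trial_type`, `rt`).
#' @return List: `participants` (per-participant stats), `groups`
#'   (medians/IQRs), `contrasts` (suppress vs control Welch tests).
#' @export
descriptives <- function(trials) {
  stopifnot("trial_type" %in% names(trials))
  per_p <- lapply(split(trials, trials$participant), function(d) {
    later <- d[d$trial_type %in% c("new/repeated", "repeated/repeated"), ]
    rep_frac <- if (nrow(later)) mean(later$trial_type ==
                                        "repeated/repeated") else NA_real_
    one_type <- function(type, fun) {
      x <- d$rt[d$trial_type == type]
      if (!length(x)) return(NA_real_)
      fun(x)
    }
    data.frame(
      participant = d$participant[1], group = d$group[1],
      pct_repeated = 100 * rep_frac,
      med_rt_nn = one_type("new/new", median),
      med_rt_nr = one_type("new/repeated", median),
      med_rt_rr = one_type("repeated/repeated", median),
      mlog_nn = one_type("new/new", function(x) mean(log(x))),
      mlog_nr = one_type("new/repeated", function(x) mean(log(x))),
      mlog_rr = one_type("repeated/repeated", function(x) mean(log(x))))
  })
  pp <- do.call(rbind, per_p)
  rownames(pp) <- NULL
  pp$dlog_nr_nn <- pp$mlog_nr - pp$mlog_nn
  pp$dmed_nr_nn <- pp$med_rt_nr - pp$med_rt_nn
  pp$dlog_rr_nn <- pp$mlog_rr - pp$mlog_nn

  groups <- do.call(rbind, lapply(split(pp, pp$group), function(g) {
    qs <- quantile(g$pct_repeated, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(group = g$group[1], n = nrow(g),
               pct_repeated_median = qs[2], pct_repeated_q1 = qs[1],
               pct_repeated_q3 = qs[3],
               dlog_nr_nn_mean = mean(g$dlog_nr_nn, na.rm = TRUE),
               dlog_rr_nn_mean = mean(g$dlog_rr_nn, na.rm = TRUE))
  }))
  rownames(groups) <- NULL

  contrasts <- NULL
  if (all(c("suppress", "control") %in% pp$group)) {
    sup <- pp[pp$group == "suppress", ]
    ctl <- pp[pp$group == "control", ]
    one <- function(var) {
      a <- sup[[var]][is.finite(sup[[var]])]
      b <- ctl[[var]][is.finite(ctl[[var]])]
      st <- group_param_stats(a, b)
      data.frame(measure = var, t = st$t, df = st$df, p = st$p, d = st$d,
                 mean_suppress = st$mean_a, mean_control = st$mean_b)
    }
    contrasts <- do.call(rbind, lapply(
      c("pct_repeated", "dlog_nr_nn", "dmed_nr_nn", "dlog_rr_nn"), one))
    rownames(contrasts) <- NULL
  }
  list(participants = pp, groups = groups, contrasts = contrasts)
}

#' Absolute (posterior-predictive style) fit check
#'
#' For each participant, simulates `n_sims` full sessions at the fitted
#' parameters and compares observed repeated-response counts and RT
#' quantiles (10th, 30th, 50th, 70th, 90th) per trial type against the
#' simulated distribution (mean and 95% interval).
#'
#' @param fits Named list of `smp_fit` per participant.
#' @param trials Classified trial table covering those participants.
#' @param spaces `spaces[[participant]][[cue]]` association spaces.
#' @param n_sims Simulated sessions per participant (default 20).
#' @param t_max Response window in seconds (default 15).
#' @param seed Integer seed.
#' @return List: `repeated` (per participant observed vs simulated repeated
#'   counts), `quantiles` (per participant x trial type x quantile).
#' @export
absolute_fit <- function(fits, trials, spaces, n_sims = 20, t_max = 15,
                         seed = 1) {
  qs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  with_seed(seed, {
    rep_rows <- list(); q_rows <- list()
    for (pid in names(fits)) {
      d <- trials[trials$participant == pid & !is.na(trials$response), ]
      obs_rep <- sum(d$trial_type == "repeated/repeated")
      sims <- lapply(seq_len(n_sims), function(s) {
        ss <- simulate_session(spaces[[pid]], fits[[pid]]$params,
                               presentations = max(d$presentation),
                               t_max = t_max)
        classify_trials(cbind(participant = pid, ss))
      })
      sim_rep <- vapply(sims, function(s)
        sum(s$trial_type == "repeated/repeated", na.rm = TRUE), numeric(1))
      rep_rows[[pid]] <- data.frame(
        participant = pid, observed = obs_rep, sim_mean = mean(sim_rep),
        sim_lo = unname(quantile(sim_rep, 0.025)),
        sim_hi = unname(quantile(sim_rep, 0.975)))
      for (type in c("new/new", "new/repeated", "repeated/repeated")) {
        x <- d$rt[d$trial_type == type & d$rt >= 0.1]
        if (length(x) < 5) next
        obs_q <- quantile(x, qs)
        sim_q <- vapply(sims, function(s) {
          y <- s$rt[!is.na(s$response) & s$trial_type == type & s$rt >= 0.1]
          if (length(y) < 5) return(rep(NA_real_, length(qs)))
          quantile(y, qs)
        }, numeric(length(qs)))
        q_rows[[paste(pid, type)]] <- data.frame(
          participant = pid, trial_type = type, q = qs,
          observed = unname(obs_q),
          sim_mean = apply(sim_q, 1, mean, na.rm = TRUE),
          sim_lo = apply(sim_q, 1, quantile, 0.025, na.rm = TRUE),
          sim_hi = apply(sim_q, 1, quantile, 0.975, na.rm = TRUE))
      }
    }
    list(repeated = do.call(rbind, c(rep_rows, list(make.row.names = FALSE))),
         quantiles = do.call(rbind, c(q_rows, list(make.row.names = FALSE))))
  })
}

#' Analytic power of the two-sided two-sample t test
#'
#' Exact noncentral-t power for a standardized group difference `d` with
#' `n_per_group` participants per group.
#'
#' @param d Standardized effect size (sign is ignored).
#' @param n_per_group Participants per group (>= 2).
#' @param alpha_level Two-sided significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
two_sample_power <- function(d, n_per_group, alpha_level = 0.05) {
  stopifnot(n_per_group >= 2, alpha_level > 0, alpha_level < 1)
  if (d == 0) return(alpha_level)
  power.t.test(n = n_per_group, delta = abs(d), sd = 1,
               sig.level = alpha_level, type = "two.sample",
               alternative = "two.sided")$power
}

#' Per-(participant, cue) RT difference table
#'
#' The tidy table consumed by regression analyses of the
#' new/repeated minus new/new log-RT difference: one row per participant
#' and cue with the difference, the number of prior (distinct reported)
#' associations, and the mean rating of those prior associations where
#' available.
#'
#' @param trials Classified trial table (needs `participant`, `cue`,
#'   `trial_type`, `rt`; `rating` used if present).
#' @return Data frame `participant`, `cue`, `dlog_nr_nn`,
#'   `n_prior_associations`, `mean_prior_rating`.
#' @export
rt_difference_table <- function(trials) {
  stopifnot("trial_type" %in% names(trials))
  has_rating <- "rating" %in% names(trials)
  rows <- lapply(split(trials, list(trials$participant, trials$cue),
                       drop = TRUE), function(d) {
    nn <- d$rt[d$trial_type == "new/new"]
    nr <- d$rt[d$trial_type == "new/repeated"]
    if (!length(nn) || !length(nr)) return(NULL)
    prior <- d[!is.na(d$response), ]
    data.frame(participant = d$participant[1], cue = d$cue[1],
               dlog_nr_nn = mean(log(nr)) - mean(log(nn)),
               n_prior_associations =
                 length(unique(tolower(trimws(prior$response)))),
               mean_prior_rating = if (has_rating)
                 mean(prior$rating, na.rm = TRUE) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
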