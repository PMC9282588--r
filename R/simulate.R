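# Internal: per-phase sampling distributions and Gamma scales for a context.
# Returns list(p, scale) for phase 1, phase 2 (reject_rhow only), and the
# exclusion-renormalized versions used by reject_noresample (one per
# repeated id, since only just-rejected -- hence repeated -- associations
# can be excluded).
trial_kernels <- function(ctx, params) {
  space <- ctx$space
  k <- 1 / params$lam^2
  mk <- function(strengths, exclude = NULL) {
    p <- sampling_probs(strengths, exclude = exclude)
    pos <- p > 0
    mu <- numeric(length(p))
    mu[pos] <- mean_gen_time(pmin(p[pos], 1), params$s_mu, params$e_mu)
    gtp <- gen_time_params(mu, params$lam)
    scale <- gtp$scale
    scale[!pos] <- NA_real_
    list(p = p, scale = scale)
  }
  s1 <- modified_strengths(space, ctx$repeated_ids, params$rho)
  out <- list(shape = k, phase1 = mk(s1))
  if (params$variant == "reject_rhow") {
    s2 <- modified_strengths(space, ctx$repeated_ids, params$rho,
                             phase = "post_rejection", rho_w = params$rho_w)
    out$phase2 <- mk(s2)
  }
  if (params$variant == "reject_noresample") {
    rep_idx <- which(repeated_mask(ctx))
    out$excluded <- lapply(setNames(rep_idx, space$ids[rep_idx]),
                           function(i) mk(s1, exclude = i))
  }
  out
}

#' Simulate a single free-association trial
#'
#' Runs the generative semi-Markov process: candidate associations are drawn
#' in proportion to their (modified) strength, each draw takes a
#' Gamma-distributed generation time, new associations are accepted, and
#' repeated associations are rejected with probability `alpha` (after which
#' sampling restarts, subject to the variant's rules). The response time is
#' the non-decision time `tau` plus the sum of all generation times;
#' rejection itself consumes no time.
#'
#' @param ctx A [trial_context()].
#' @param params An [smp_params()].
#' @param t_max Response window in seconds; if the cumulative time exceeds it
#'   before an association is accepted the trial times out (no report).
#' @return A list with `reported_id` (`NA` on timeout), `rt` (seconds, `NA`
#'   on timeout), `n_attempts`, `attempt_sequence` (ids in sampling order)
#'   and `timed_out`.
#' @export
simulate_trial <- function(ctx, params, t_max = 15) {
  stopifnot(inherits(ctx, "trial_context"), inherits(params, "smp_params"))
  if (t_max <= params$tau) stop("t_max must exceed tau")
  kern <- trial_kernels(ctx, params)
  space <- ctx$space
  rep_mask <- repeated_mask(ctx)
  n <- length(space$ids)
  cum <- 0
  attempts <- integer(0)
  last_rejected <- 0L
  phase2 <- FALSE
  repeat {
    if (length(attempts) >= 100000L)
      stop("trial did not absorb within 1e5 attempts")
    kn <- if (params$variant == "reject_noresample" && last_rejected > 0L) {
      kern$excluded[[space$ids[last_rejected]]]
    } else if (phase2) kern$phase2 else kern$phase1
    i <- sample.int(n, 1L, prob = kn$p)
    cum <- cum + rgamma(1L, shape = kern$shape, scale = kn$scale[i])
    attempts <- c(attempts, i)
    if (params$tau + cum > t_max) {
      return(list(reported_id = NA_character_, rt = NA_real_,
                  n_attempts = length(attempts),
                  attempt_sequence = space$ids[attempts], timed_out = TRUE))
    }
    accept <- !rep_mask[i] || runif(1L) >= params$alpha
    if (accept) {
      return(list(reported_id = space$ids[i], rt = params$tau + cum,
                  n_attempts = length(attempts),
                  attempt_sequence = space$ids[attempts], timed_out = FALSE))
    }
    if (params$variant == "reject_noresample") last_rejected <- i
    if (params$variant == "reject_rhow") phase2 <- TRUE
  }
}

# Internal vectorized batch simulator for one fixed context. Used as the
# Monte-Carlo oracle for the Laplace-transform likelihood and for
# absolute-fit simulations. Returns a data.frame with columns
# reported (index, NA on timeout), rt, n_attempts, timed_out.
sim_trials_batch <- function(ctx, params, n, t_max = Inf) {
  kern <- trial_kernels(ctx, params)
  space <- ctx$space
  rep_mask <- repeated_mask(ctx)
  n_assoc <- length(space$ids)
  reported <- rep(NA_integer_, n)
  cum <- numeric(n)
  n_att <- integer(n)
  timed_out <- logical(n)
  active <- seq_len(n)
  last_rej <- integer(n)       # 0 = none
  in_phase2 <- logical(n)
  round <- 0L
  while (length(active) > 0L) {
    round <- round + 1L
    if (round > 10000L) { timed_out[active] <- TRUE; break }
    # group by effective kernel
    key <- if (params$variant == "reject_noresample") last_rej[active]
           else if (params$variant == "reject_rhow") as.integer(in_phase2[active])
           else rep(0L, length(active))
    draws <- integer(length(active))
    times <- numeric(length(active))
    for (kv in unique(key)) {
      sel <- which(key == kv)
      kn <- if (params$variant == "reject_noresample" && kv > 0L)
              kern$excluded[[space$ids[kv]]]
            else if (params$variant == "reject_rhow" && kv == 1L) kern$phase2
            else kern$phase1
      d <- sample.int(n_assoc, length(sel), replace = TRUE, prob = kn$p)
      draws[sel] <- d
      times[sel] <- rgamma(length(sel), shape = kern$shape,
                           scale = kn$scale[d])
    }
    cum[active] <- cum[active] + times
    n_att[active] <- n_att[active] + 1L
    out_of_time <- params$tau + cum[active] > t_max
    accept <- !rep_mask[draws] | runif(length(active)) >= params$alpha
    done_ok <- accept & !out_of_time
    reported[active[done_ok]] <- draws[done_ok]
    timed_out[active[out_of_time]] <- TRUE
    keep <- !done_ok & !out_of_time
    if (params$variant == "reject_noresample")
      last_rej[active[keep]] <- draws[keep]
    if (params$variant == "reject_rhow")
      in_phase2[active[keep]] <- TRUE
    active <- active[keep]
  }
  data.frame(reported = reported,
             rt = ifelse(timed_out, NA_real_, params$tau + cum),
             n_attempts = n_att, timed_out = timed_out)
}

#' Simulate a full session for one participant
#'
#' Presents each cue `presentations` times in a randomized interleaved
#' order. The repeated set of each cue accumulates the associations reported
#' on its earlier presentations (timeouts add nothing), mirroring the task's
#' instruction history.
#'
#' @param spaces Named list of [association_space()] objects (names = cue
#'   ids); one space per cue.
#' @param params An [smp_params()].
#' @param presentations Number of presentations per cue (default 5).
#' @param t_max Response window in seconds (default 15).
#' @return A data.frame with one row per trial: `cue`, `presentation`
#'   (1-based occurrence index), `response` (id or `NA`), `rt` (seconds,
#'   `NA` on timeout), `n_attempts`, `timed_out`, in presentation order.
#' @export
simulate_session <- function(spaces, params, presentations = 5, t_max = 15) {
  stopifnot(length(spaces) >= 1, presentations >= 1)
  if (is.null(names(spaces)) || any(names(spaces) == ""))
    stop("`spaces` must be a named list keyed by cue id")
  cues <- rep(names(spaces), each = presentations)
  cues <- sample(cues)                      # randomized trial order
  pres <- stats::ave(seq_along(cues), cues, FUN = seq_along)
  history <- lapply(spaces, function(s) character(0))
  out <- vector("list", length(cues))
  for (t in seq_along(cues)) {
    cue <- cues[t]
    ctx <- trial_context(spaces[[cue]], history[[cue]])
    res <- simulate_trial(ctx, params, t_max = t_max)
    if (!res$timed_out)
      history[[cue]] <- unique(c(history[[cue]], res$reported_id))
    out[[t]] <- data.frame(cue = cue, presentation = pres[t],
                           response = res$reported_id, rt = res$rt,
                           n_attempts = res$n_attempts,
                           timed_out = res$timed_out)
  }
  do.call(rbind, out)
}
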