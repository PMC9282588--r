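# Laplace transform of a Gamma(shape k, scale theta) holding time,
# vectorized over complex s.
gamma_lt <- function(s, theta, k) exp(-k * log(1 + theta * s))

# Internal builder of the absorption transform F_j(s) for one context.
# target: index of the reported association, or NULL for the sum over all
# absorbing states (used for censoring probabilities). Time is measured
# from trial start minus tau. Returns a function of a complex vector s.
absorption_transform <- function(ctx, params, target = NULL) {
  kern <- trial_kernels(ctx, params)
  space <- ctx$space
  rep_mask <- repeated_mask(ctx)
  n <- length(space$ids)
  k <- kern$shape
  alpha <- params$alpha
  p1 <- kern$phase1$p
  th1 <- kern$phase1$scale
  q <- ifelse(rep_mask, 1 - alpha, 1)
  rep_idx <- which(rep_mask)

  # numerator-style term sum_{j in J} p_j q_j g_j(s) for one kernel
  accept_sum <- function(s, p, th, J) {
    out <- complex(length(s))
    for (j in J) if (p[j] > 0) out <- out + p[j] * q[j] * gamma_lt(s, th[j], k)
    out
  }
  # rejection loop term r(s) = alpha * sum_{i in R} p_i g_i(s)
  reject_sum <- function(s, p, th) {
    out <- complex(length(s))
    for (i in rep_idx) if (p[i] > 0)
      out <- out + alpha * p[i] * gamma_lt(s, th[i], k)
    out
  }
  J <- if (is.null(target)) seq_len(n) else target

  if (params$variant == "no_reject" || length(rep_idx) == 0L) {
    return(function(s) accept_sum(s, p1, th1, J))
  }
  if (params$variant == "reject") {
    return(function(s) accept_sum(s, p1, th1, J) / (1 - reject_sum(s, p1, th1)))
  }
  if (params$variant == "reject_rhow") {
    p2 <- kern$phase2$p
    th2 <- kern$phase2$scale
    return(function(s) {
      accept_sum(s, p1, th1, J) +
        reject_sum(s, p1, th1) * accept_sum(s, p2, th2, J) /
          (1 - reject_sum(s, p2, th2))
    })
  }
  # reject_noresample: states {fresh} + {just-rejected-i : i in R}; solve the
  # linear system (I - B(s)) x = a(s) over the rejected states per s value.
  m <- length(rep_idx)
  exc <- kern$excluded
  function(s) {
    out <- complex(length(s))
    for (u in seq_along(s)) {
      sv <- s[u]
      B <- matrix(0 + 0i, m, m)
      a <- complex(m)
      for (ai in seq_len(m)) {
        ke <- exc[[ai]]
        for (bi in seq_len(m)) {
          ib <- rep_idx[bi]
          if (bi != ai && ke$p[ib] > 0)
            B[ai, bi] <- alpha * ke$p[ib] * gamma_lt(sv, ke$scale[ib], k)
        }
        acc <- 0 + 0i
        for (j in J) if (j != rep_idx[ai] && ke$p[j] > 0)
          acc <- acc + ke$p[j] * q[j] * gamma_lt(sv, ke$scale[j], k)
        a[ai] <- acc
      }
      x <- solve(diag(m) - B, a)
      val <- accept_sum(sv, p1, th1, J)
      for (ai in seq_len(m)) {
        i <- rep_idx[ai]
        val <- val + alpha * p1[i] * gamma_lt(sv, th1[i], k) * x[ai]
      }
      out[u] <- val
    }
    out
  }
}

#' Laplace transform of the joint absorption sub-density for one report
#'
#' Returns the closed-form Laplace transform `F_j(s)` of the sub-density of
#' reporting association `reported_id` at time `t = rt - tau`: the
#' absorption transform of the semi-Markov sampling process under the
#' variant in `params`. `F_j(0)` is the probability that `reported_id` is
#' the reported association.
#'
#' @param ctx A [trial_context()].
#' @param params An [smp_params()].
#' @param reported_id Association id present in the context's space.
#' @return A list of class `trial_transform` with elements `reported_id`,
#'   `variant`, and `transform` (a function of a complex vector `s`).
#' @export
trial_transform <- function(ctx, params, reported_id) {
  j <- match(as.character(reported_id), ctx$space$ids)
  if (is.na(j)) stop("reported_id not present in the association space")
  if (params$alpha >= 1 && reported_id %in% ctx$repeated_ids)
    stop("reported association has acceptance probability 0 (alpha = 1)")
  structure(list(reported_id = as.character(reported_id),
                 variant = params$variant,
                 transform = absorption_transform(ctx, params, target = j)),
            class = "trial_transform")
}

#' Report probabilities for all associations in a context
#'
#' Evaluates every absorption transform at `s = 0`, giving the marginal
#' probability that each association is the one reported. Sums to 1
#' whenever absorption is almost sure.
#'
#' @inheritParams trial_transform
#' @return Named probability vector over the space's association ids.
#' @export
report_probs <- function(ctx, params) {
  n <- length(ctx$space$ids)
  rep_mask <- repeated_mask(ctx)
  out <- numeric(n)
  for (j in seq_len(n)) {
    if (params$alpha >= 1 && rep_mask[j]) { out[j] <- 0; next }
    f <- absorption_transform(ctx, params, target = j)
    out[j] <- Re(f(complex(real = 0)))
  }
  setNames(out, ctx$space$ids)
}

#' Joint density of (reported association, response time)
#'
#' Numerically inverts the absorption transform at `t = rt - tau`. Under
#' `no_reject` (or an empty repeated set) the density has the closed form
#' `p_j * dgamma(rt - tau; shape, scale_j)`, which the inversion reproduces;
#' the inversion path is used for all variants with rejections.
#'
#' @inheritParams trial_transform
#' @param rt Observed response time in seconds.
#' @param inv An [inversion_config()].
#' @return Non-negative density (per second); 0 when `rt <= tau`.
#' @export
trial_density <- function(ctx, params, reported_id, rt,
                          inv = inversion_config()) {
  t <- rt - params$tau
  if (!is.finite(t) || t <= 0) return(0)
  tt <- trial_transform(ctx, params, reported_id)
  val <- invert_laplace(tt$transform, t, inv)
  if (val < 0) {
    if (val < -inv$clip_negative_at)
      stop(sprintf("inversion produced a large negative density (%.3e)", val))
    val <- 0
  }
  val
}

#' Probability of exceeding the response window
#'
#' `P(RT > t_max)`, obtained by inverting the transform of the overall
#' absorption CDF, `sum_j F_j(s) / s`, at `t_max - tau`.
#'
#' @inheritParams trial_transform
#' @param t_max Response window in seconds (> tau).
#' @return Probability in `[0, 1]`.
#' @export
censoring_prob <- function(ctx, params, t_max, inv = inversion_config()) {
  if (t_max <= params$tau) stop("t_max must exceed tau")
  f_tot <- absorption_transform(ctx, params, target = NULL)
  cdf <- invert_laplace(function(s) f_tot(s) / s, t_max - params$tau, inv)
  min(max(1 - cdf, 0), 1)
}

#' Monte-Carlo estimate of the joint (association, RT) density
#'
#' Simulation oracle for the Laplace-transform likelihood: simulates
#' `n_sims` trials from the generative process and bins response times per
#' reported association, with binomial standard errors. Densities are per
#' second and integrate (sum over cells times bin width) to the probability
#' mass captured by the grid.
#'
#' @inheritParams trial_transform
#' @param n_sims Number of simulated trials (>= 1e4).
#' @param breaks Increasing numeric vector of RT bin edges (seconds).
#' @return A list with `breaks`, `density` (associations x bins matrix),
#'   `se` (same shape) and `n_sims`.
#' @export
mc_joint_density <- function(ctx, params, n_sims, breaks) {
  if (n_sims < 1e4) stop("n_sims must be >= 1e4")
  if (length(breaks) < 2L || any(diff(breaks) <= 0))
    stop("breaks must be strictly increasing")
  sims <- sim_trials_batch(ctx, params, n_sims, t_max = Inf)
  n_assoc <- length(ctx$space$ids)
  nb <- length(breaks) - 1L
  widths <- diff(breaks)
  bin <- findInterval(sims$rt, breaks, rightmost.closed = TRUE)
  ok <- !is.na(sims$reported) & !is.na(bin) & bin >= 1L & bin <= nb
  cell <- (bin[ok] - 1L) * n_assoc + sims$reported[ok]
  counts <- matrix(tabulate(cell, nbins = n_assoc * nb), n_assoc, nb,
                   dimnames = list(ctx$space$ids, NULL))
  phat <- counts / n_sims
  dens <- sweep(phat, 2, widths, "/")
  se <- sweep(sqrt(phat * (1 - phat) / n_sims), 2, widths, "/")
  list(breaks = breaks, density = dens, se = se, n_sims = n_sims)
}

# Internal: turn one participant's trial table into per-trial likelihood
# inputs. `trials` needs columns cue, presentation, response, rt (seconds).
# Responses are matched to space ids case-folded and trimmed. The repeated
# set of a trial is the set of earlier (lower presentation index) responses
# to the same cue.
prepare_session_data <- function(trials, spaces) {
  stopifnot(all(c("cue", "presentation", "response", "rt") %in% names(trials)))
  norm_str <- function(x) tolower(trimws(as.character(x)))
  out <- vector("list", nrow(trials))
  trials$cue <- as.character(trials$cue)
  for (idx in seq_len(nrow(trials))) {
    cue <- trials$cue[idx]
    space <- spaces[[cue]]
    if (is.null(space)) stop(sprintf("no association space for cue '%s'", cue))
    ids_n <- norm_str(space$ids)
    earlier <- trials$cue == cue &
      trials$presentation < trials$presentation[idx] &
      !is.na(trials$response)
    rep_ids <- match(unique(norm_str(trials$response[earlier])), ids_n)
    if (anyNA(rep_ids))
      stop(sprintf("earlier response to cue '%s' not in its space", cue))
    resp <- trials$response[idx]
    reported <- if (is.na(resp)) NA_integer_ else match(norm_str(resp), ids_n)
    if (!is.na(resp) && is.na(reported))
      stop(sprintf("response '%s' not in the space of cue '%s'", resp, cue))
    out[[idx]] <- list(strengths = space$strengths,
                       repeated = seq_along(ids_n) %in% rep_ids,
                       reported = reported,
                       rt = trials$rt[idx],
                       cue = cue)
  }
  out
}

#' Session log-likelihood for one participant
#'
#' Sums log joint densities of (reported association, RT) over the valid,
#' uncensored trials of a session, reconstructing each trial's repeated set
#' from the earlier presentations of its cue. Timed-out (missing-response)
#' trials are dropped by default; with `censored = "include"` they
#' contribute the log probability of exceeding the response window instead.
#' Per-trial densities are floored at `1e-300` before taking logs.
#'
#' @param trials Data frame with columns `cue`, `presentation`, `response`
#'   (`NA` for timeouts), `rt` (seconds) for one participant.
#' @param spaces Named list of [association_space()] objects keyed by cue.
#' @param params An [smp_params()].
#' @param inv An [inversion_config()].
#' @param engine `"cpp"` (compiled fixed-Talbot likelihood, default) or
#'   `"r"` (pure-R transform + inversion; reference implementation).
#' @param censored `"drop"` (default) or `"include"`.
#' @param t_max Response window (seconds), used only for censored terms.
#' @return Log-likelihood (finite; large negative under underflow).
#' @export
session_loglik <- function(trials, spaces, params,
                           inv = inversion_config(),
                           engine = c("cpp", "r"),
                           censored = c("drop", "include"),
                           t_max = 15) {
  engine <- match.arg(engine)
  censored <- match.arg(censored)
  data <- prepare_session_data(trials, spaces)
  obs <- Filter(function(d) !is.na(d$reported) && is.finite(d$rt) &&
                  d$rt > 0, data)
  ll <- if (engine == "cpp") {
    smp_session_loglik_cpp(lapply(obs, function(d)
        d[c("strengths", "repeated", "reported", "rt")]),
      par = params_to_list(params), variant = params$variant,
      n_nodes = inv$n_nodes)
  } else {
    floor_d <- .smp_const$density_floor
    sum(vapply(obs, function(d) {
      sp <- association_space("x", paste0("a", seq_along(d$strengths)),
                              d$strengths)
      ctx <- trial_context(sp, sp$ids[d$repeated])
      f <- trial_density(ctx, params, sp$ids[d$reported], d$rt, inv)
      log(max(f, floor_d))
    }, numeric(1)))
  }
  if (censored == "include") {
    cens <- Filter(function(d) is.na(d$reported), data)
    for (d in cens) {
      sp <- association_space("x", paste0("a", seq_along(d$strengths)),
                              d$strengths)
      ctx <- trial_context(sp, sp$ids[d$repeated])
      pr <- censoring_prob(ctx, params, t_max, inv)
      ll <- ll + log(max(pr, .smp_const$density_floor))
    }
  }
  ll
}

# params as plain list for the compiled code
params_to_list <- function(params) {
  list(rho = params$rho, alpha = params$alpha, rho_w = params$rho_w,
       s_mu = params$s_mu, e_mu = params$e_mu, lam = params$lam,
       tau = params$tau)
}
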