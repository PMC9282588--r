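# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Map parameters to an unconstrained vector and back
#'
#' Free parameters are optimized on an unconstrained scale: `rho`, `rho_w`
#' and `s_mu` are unbounded and kept as-is; `alpha` is logit-transformed on
#' `(0, 1 - 1e-6)`; `lam` and `e_mu` are log-transformed; `tau` is
#' logit-transformed on `(0, tau_max)` when a finite upper bound is imposed
#' (fitting bounds it at 0.95 x the smallest observed RT) and
#' log-transformed otherwise. The map is bijective on the interior of the
#' parameter space.
#'
#' @param params An [smp_params()] (or a named vector for `untransform_params`).
#' @param tau_max Upper bound for `tau` (default `Inf`: plain log transform).
#' @return `transform_params`: named numeric vector on the unconstrained
#'   scale. `untransform_params`: an [smp_params()].
#' @export
transform_params <- function(params, tau_max = Inf) {
  v <- params_to_vector(params)
  out <- c(rho = v[["rho"]],
           s_mu = v[["s_mu"]],
           e_mu = log(v[["e_mu"]]),
           lam = log(v[["lam"]]),
           tau = if (is.finite(tau_max)) qlogis(v[["tau"]] / tau_max)
                 else log(v[["tau"]]))
  if (params$variant != "no_reject")
    out <- c(out, alpha = qlogis(v[["alpha"]] / .smp_const$alpha_max))
  if (params$variant == "reject_rhow") out <- c(out, rho_w = v[["rho_w"]])
  out
}

#' @rdname transform_params
#' @param x Named numeric vector on the unconstrained scale.
#' @param variant Model variant for the reconstructed parameters.
#' @export
untransform_params <- function(x, variant, tau_max = Inf) {
  smp_params(variant = variant,
             rho = x[["rho"]],
             alpha = if (variant == "no_reject") 0
                     else .smp_const$alpha_max * plogis(x[["alpha"]]),
             rho_w = if (variant == "reject_rhow") x[["rho_w"]] else NULL,
             s_mu = x[["s_mu"]],
             e_mu = exp(x[["e_mu"]]),
             lam = exp(x[["lam"]]),
             tau = if (is.finite(tau_max)) tau_max * plogis(x[["tau"]])
                   else exp(x[["tau"]]))
}

#' Fitting configuration
#'
#' @param n_starts Number of multi-start local optimizations (>= 1;
#'   default 5). The first start is a warm start: for variants with
#'   rejections, the RT-controlling parameters are initialized at the
#'   estimates of a fast rejection-free pre-fit; further starts are
#'   jittered around it.
#' @param seed Integer seed controlling the start jitter (fits are
#'   deterministic given seed and data).
#' @param fixed Named list of parameters held fixed at given values (not
#'   counted as free; used by the sensitivity refit).
#' @param n_nodes Talbot nodes for the likelihood (default 24; in double
#'   precision more nodes add roundoff, not accuracy).
#' @param nm_maxit Max Nelder-Mead iterations per start.
#' @param refine Run a BFGS refinement after Nelder-Mead (default TRUE).
#' @param reltol Relative convergence tolerance.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 5, seed = 1, fixed = list(),
                       n_nodes = 24, nm_maxit = 500, refine = TRUE,
                       reltol = 1e-8) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 fixed = fixed, n_nodes = as.integer(n_nodes),
                 nm_maxit = as.integer(nm_maxit), refine = isTRUE(refine),
                 reltol = reltol),
            class = "fit_config")
}

# heuristic start point (natural scale) for a variant given observed RTs
default_start <- function(variant, rts, tau_max) {
  tau0 <- min(0.5 * min(rts), 0.9 * tau_max)
  med <- max(median(rts) - tau0, 0.2)
  c(rho = 1, alpha = 0.5, s_mu = log(med) - log(2), e_mu = 1.2, lam = 0.6,
    tau = tau0, rho_w = 1)
}

#' Per-participant maximum-likelihood fit
#'
#' Fits the free parameters of one model variant to one participant's valid
#' uncensored trials by multi-start Nelder-Mead (optionally refined by
#' BFGS) on the transformed scale. `tau` is bounded above by 0.95 x the
#' smallest observed RT. Returns the best start.
#'
#' @param trials One participant's trial data frame (`cue`, `presentation`,
#'   `response`, `rt` seconds). Trials with missing responses or `rt < 0.1`
#'   s are dropped.
#' @param spaces Named list of [association_space()]s keyed by cue.
#' @param variant One of [smp_variants()].
#' @param cfg A [fit_config()].
#' @return An object of class `smp_fit`: `params`, `loglik`, `n_trials`,
#'   `n_free_params`, `bic`, `converged`, `start_index`, `seed`.
#' @export
fit_participant <- function(trials, spaces, variant, cfg = fit_config()) {
  variant <- match.arg(variant, smp_variants())
  keep <- !is.na(trials$response) & is.finite(trials$rt) & trials$rt >= 0.1
  trials <- trials[keep, , drop = FALSE]
  n_trials <- nrow(trials)
  if (n_trials < 30) stop("need at least 30 valid trials to fit")
  data <- prepare_session_data(trials, spaces)
  data <- lapply(data, function(d) d[c("strengths", "repeated", "reported",
                                       "rt")])
  session <- smp_make_session_cpp(data)
  rts <- trials$rt
  tau_max <- 0.95 * min(rts)

  free_all <- free_param_names(variant)
  fixed <- cfg$fixed
  if (length(fixed) && !all(names(fixed) %in% free_all))
    stop("fixed parameters must be a subset of the variant's parameters")
  free <- setdiff(free_all, names(fixed))
  n_free <- length(free)

  to_natural <- function(nm, x) switch(nm,
    alpha = .smp_const$alpha_max * plogis(x),
    e_mu = exp(x), lam = exp(x),
    tau = tau_max * plogis(x),
    x)  # rho, rho_w, s_mu: identity
  to_transformed <- function(nm, v) switch(nm,
    alpha = qlogis(min(max(v / .smp_const$alpha_max, 1e-9), 1 - 1e-9)),
    e_mu = log(v), lam = log(v),
    tau = qlogis(min(max(v / tau_max, 1e-9), 1 - 1e-9)),
    v)

  par_list_from_x <- function(x_free, vnt, start_nat) {
    full <- as.list(start_nat)
    for (nm in names(fixed)) if (nm %in% free_param_names(vnt))
      full[[nm]] <- fixed[[nm]]
    for (nm in names(x_free)) full[[nm]] <- to_natural(nm, x_free[[nm]])
    if (vnt == "no_reject") full$alpha <- 0
    if (vnt != "reject_rhow") full$rho_w <- NULL
    full
  }
  make_negll <- function(vnt, vfree, start_nat) {
    function(x) {
      names(x) <- vfree
      pl <- par_list_from_x(as.list(x), vnt, start_nat)
      if (abs(pl$rho) > 25 || (!is.null(pl$rho_w) && abs(pl$rho_w) > 25) ||
          abs(pl$s_mu) > 25 || pl$e_mu > 25)
        return(1e10)
      ll <- smp_session_loglik_ptr_cpp(session, par = pl, variant = vnt,
                                       n_nodes = cfg$n_nodes)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  }
  run_starts <- function(vnt, vfree, starts, start_nat) {
    negll <- make_negll(vnt, vfree, start_nat)
    if (length(vfree) == 0)
      return(list(par = numeric(0), value = negll(numeric(0)),
                  convergence = 0L, start = 1L))
    best <- NULL
    for (i in seq_along(starts)) {
      o <- if (length(vfree) == 1) {
        optim(starts[[i]], negll, method = "BFGS",
              control = list(maxit = cfg$nm_maxit, reltol = cfg$reltol))
      } else {
        optim(starts[[i]], negll, method = "Nelder-Mead",
              control = list(maxit = cfg$nm_maxit, reltol = cfg$reltol))
      }
      if (cfg$refine) {
        o2 <- tryCatch(
          optim(o$par, negll, method = "BFGS",
                control = list(maxit = 60, reltol = cfg$reltol)),
          error = function(e) NULL)
        if (!is.null(o2) && is.finite(o2$value) && o2$value <= o$value) o <- o2
      }
      if (is.null(best) || o$value < best$value) {
        best <- o
        best$start <- i
      }
    }
    best
  }

  start_nat <- as.list(default_start(variant, rts, tau_max))
  jitter_sd <- c(rho = 1, alpha = 1.5, s_mu = 0.7, e_mu = 0.4, lam = 0.5,
                 tau = 1, rho_w = 1)
  center <- vapply(free, function(nm) to_transformed(nm, start_nat[[nm]]),
                   numeric(1))

  # Stage 1: rejection-free pre-fit (cheap closed-form likelihood) to anchor
  # the RT-controlling parameters. It is the full fit when variant is
  # no_reject; otherwise it provides the warm start.
  stage1_free <- setdiff(free_param_names("no_reject"), names(fixed))
  center1 <- center[intersect(free, stage1_free)]
  starts1 <- with_seed(cfg$seed, lapply(seq_len(cfg$n_starts), function(i) {
    x <- center1
    if (i > 1) x <- x + rnorm(length(x)) * jitter_sd[names(x)]
    x
  }))
  best1 <- run_starts("no_reject", names(center1), starts1, start_nat)

  if (variant == "no_reject") {
    best <- best1
  } else {
    warm <- center
    names(best1$par) <- names(center1)
    warm[names(center1)] <- best1$par
    starts2 <- with_seed(cfg$seed + 1L,
      lapply(seq_len(cfg$n_starts), function(i) {
        x <- warm
        # the post-rejection modification can plausibly sit on either side
        # of zero; alternate its start sign so one start covers each basin
        if ("rho_w" %in% free && i %% 2 == 0)
          x[["rho_w"]] <- -abs(x[["rho_w"]]) - 0.5
        if (i > 2) x <- x + rnorm(length(x)) * jitter_sd[free]
        x
      }))
    best <- run_starts(variant, free, starts2, start_nat)
  }

  names(best$par) <- free
  pl <- par_list_from_x(as.list(best$par), variant, start_nat)
  params <- smp_params(variant = variant, rho = pl$rho, alpha = pl$alpha,
                       rho_w = pl$rho_w, s_mu = pl$s_mu, e_mu = pl$e_mu,
                       lam = pl$lam, tau = pl$tau)
  loglik <- -best$value
  structure(list(params = params, loglik = loglik, n_trials = n_trials,
                 n_free_params = n_free,
                 bic = n_free * log(n_trials) - 2 * loglik,
                 converged = identical(best$convergence, 0L) ||
                   best$convergence == 0,
                 start_index = best$start, seed = cfg$seed),
            class = "smp_fit")
}

#' @export
print.smp_fit <- function(x, ...) {
  cat(sprintf("<smp_fit> %s: logLik = %.2f, BIC = %.2f (%d trials, %d free)\n",
              x$params$variant, x$loglik, x$bic, x$n_trials,
              x$n_free_params))
  print(x$params)
  invisible(x)
}

#' Sensitivity refit with fixed nuisance parameters
#'
#' Refits only the thought-control parameters (`alpha`, `rho`, and `rho_w`
#' where present) while the RT-controlling nuisance parameters (`s_mu`,
#' `e_mu`, `lam`, `tau`) are held fixed at supplied reference values (e.g.
#' the control-group means).
#'
#' @inheritParams fit_participant
#' @param reference Named list/vector with values for `s_mu`, `e_mu`,
#'   `lam`, `tau`.
#' @return An `smp_fit`.
#' @export
sensitivity_refit <- function(trials, spaces, variant, reference,
                              cfg = fit_config()) {
  need <- c("s_mu", "e_mu", "lam", "tau")
  if (!all(need %in% names(reference)))
    stop("reference must supply s_mu, e_mu, lam and tau")
  cfg$fixed <- c(cfg$fixed, as.list(reference[need]))
  fit_participant(trials, spaces, variant, cfg)
}

#' Group BIC comparison table
#'
#' Sums per-participant BICs within each variant and reports the difference
#' from the best (lowest-sum) variant, which gets 0. Ties are broken toward
#' the variant with fewer free parameters.
#'
#' @param fits_by_variant Named list: variant -> list of `smp_fit` objects,
#'   one per participant (same participants under every variant).
#' @return Data frame with `variant`, `n_free_params`, `total_bic`,
#'   `delta_bic`, `best`.
#' @export
bic_table <- function(fits_by_variant) {
  ns <- lengths(fits_by_variant)
  if (length(unique(ns)) != 1L)
    stop("every variant must be fitted to the same participants")
  total <- vapply(fits_by_variant, function(fits)
    sum(vapply(fits, function(f) f$bic, numeric(1))), numeric(1))
  npar <- vapply(fits_by_variant, function(fits) fits[[1]]$n_free_params,
                 numeric(1))
  ord <- order(total, npar)
  best_variant <- names(fits_by_variant)[ord[1]]
  data.frame(variant = names(fits_by_variant),
             n_free_params = npar,
             total_bic = total,
             delta_bic = total - total[[best_variant]],
             best = names(fits_by_variant) == best_variant,
             row.names = NULL)
}

#' Welch group contrast on a fitted parameter
#'
#' Welch unequal-variance t test (Welch-Satterthwaite df) plus Cohen's d
#' with pooled SD, comparing a parameter between two groups of fits.
#'
#' @param fits_a,fits_b Lists of `smp_fit` objects (or numeric vectors of
#'   parameter values).
#' @param param Parameter name (ignored when numeric vectors are given).
#' @return List with `t`, `df`, `p`, `d`, `mean_a`, `mean_b`.
#' @export
group_param_stats <- function(fits_a, fits_b, param = "alpha") {
  pull <- function(fits) {
    if (is.numeric(fits)) return(fits)
    vapply(fits, function(f) {
      v <- f$params[[param]]
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
  }
  a <- pull(fits_a)
  b <- pull(fits_b)
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 fits per group")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1, d = 0,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("zero variance in both groups with unequal means")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (mean(a) - mean(b)) / sp,
       mean_a = mean(a), mean_b = mean(b))
}

#' Serialize fit results to JSON
#'
#' Writes one JSON record per fit (participant x variant): fitted
#' parameters, log-likelihood, trial count, BIC and convergence metadata.
#'
#' @param fits Named list of `smp_fit` objects (names = participant ids).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  recs <- lapply(fits, function(f) {
    p <- f$params
    list(variant = p$variant,
         params = Filter(Negate(is.null),
                         list(rho = p$rho, alpha = p$alpha, rho_w = p$rho_w,
                              s_mu = p$s_mu, e_mu = p$e_mu, lam = p$lam,
                              tau = p$tau)),
         loglik = f$loglik, n_trials = f$n_trials,
         n_free_params = f$n_free_params, bic = f$bic,
         converged = f$converged, start_index = f$start_index,
         seed = f$seed)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
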