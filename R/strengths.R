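#' Modified associative strengths
#'
#' Repeated associations (those the participant already reported on earlier
#' presentations of the cue) have their base strength multiplied by
#' `exp(rho)`; new associations keep their base strength. Under the
#' `reject_rhow` variant, once the first rejection of a trial has occurred
#' the multiplier switches to `exp(rho_w)` (phase `"post_rejection"`).
#'
#' @param space An [association_space()].
#' @param repeated_ids Ids of repeated associations (subset of the space).
#' @param rho Log strength multiplier for repeated associations.
#' @param phase `"initial"` (default) or `"post_rejection"`.
#' @param rho_w Post-rejection multiplier; used only when
#'   `phase = "post_rejection"` and non-`NULL`, otherwise `rho` applies.
#' @return Numeric vector of modified strengths, aligned with `space$ids`.
#' @export
modified_strengths <- function(space, repeated_ids, rho,
                               phase = c("initial", "post_rejection"),
                               rho_w = NULL) {
  stopifnot(inherits(space, "association_space"))
  phase <- match.arg(phase)
  if (!is.finite(rho)) stop("rho must be finite")
  rho_eff <- if (phase == "post_rejection" && !is.null(rho_w)) {
    if (!is.finite(rho_w)) stop("rho_w must be finite")
    rho_w
  } else rho
  out <- space$strengths
  rep_mask <- space$ids %in% repeated_ids
  out[rep_mask] <- exp(rho_eff) * out[rep_mask]
  out
}

#' Sampling probabilities from strengths
#'
#' Normalizes a positive strength vector into the probability with which
#' each candidate association is sampled. Optionally excludes one entry
#' (used by the no-resampling variant, where the association rejected on the
#' previous attempt cannot be drawn) and renormalizes over the rest; the
#' excluded entry gets probability 0.
#'
#' @param strengths Positive numeric vector (possibly named by id).
#' @param exclude Index or name of an entry to exclude, or `NULL`.
#' @return Probability vector of the same length, summing to 1.
#' @export
sampling_probs <- function(strengths, exclude = NULL) {
  if (length(strengths) == 0L) stop("empty strength vector")
  if (any(!is.finite(strengths)) || any(strengths <= 0))
    stop("all strengths must be positive and finite")
  keep <- rep(TRUE, length(strengths))
  if (!is.null(exclude)) {
    idx <- if (is.character(exclude)) match(exclude, names(strengths))
           else as.integer(exclude)
    if (is.na(idx) || idx < 1L || idx > length(strengths))
      stop("exclude does not match an entry")
    keep[idx] <- FALSE
    if (!any(keep)) stop("cannot exclude every entry")
  }
  tot <- sum(strengths[keep])
  if (tot <= 0) stop("zero total strength")
  p <- numeric(length(strengths))
  p[keep] <- strengths[keep] / tot
  names(p) <- names(strengths)
  p
}

#' Mean generation time from sampling probability
#'
#' The mean time to generate a candidate association is a power function of
#' its surprisal: `mu = exp(s_mu) * (-log p)^e_mu` seconds. The function is
#' strictly decreasing in `p` and equals 0 at `p = 1` (a cue with a single
#' association would be reported instantly, before the non-decision time).
#' The raw value is returned; callers constructing time distributions floor
#' it at `1e-4` s (see [gen_time_params()]).
#'
#' @param p Sampling probability in (0, 1]. Vectorized.
#' @param s_mu Log time-scale.
#' @param e_mu Curvature exponent, > 0.
#' @return Mean generation time(s) in seconds (unfloored).
#' @export
mean_gen_time <- function(p, s_mu, e_mu) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p must lie in (0, 1]")
  if (!is.finite(e_mu) || e_mu <= 0) stop("e_mu must be > 0")
  exp(s_mu) * (-log(p))^e_mu
}

#' Gamma generation-time parameters
#'
#' Generation times are Gamma with mean `mu` and standard deviation
#' `lam * mu`, i.e. shape `1/lam^2` (common to all associations of a
#' parameter set) and scale `mu * lam^2`. The mean is floored at `1e-4` s so
#' that `p -> 1` does not produce a degenerate point mass.
#'
#' @param mu Mean generation time(s) in seconds, >= 0. Vectorized.
#' @param lam Coefficient of variation, > 0.
#' @return List with `shape` (scalar) and `scale` (vector, seconds).
#' @export
gen_time_params <- function(mu, lam) {
  if (!is.finite(lam) || lam <= 0) stop("lam must be > 0")
  if (any(!is.finite(mu)) || any(mu < 0)) stop("mu must be >= 0")
  mu <- pmax(mu, .smp_const$mu_min)
  list(shape = 1 / lam^2, scale = mu * lam^2)
}
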