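#' Model variants
#'
#' The four semi-Markov model variants differ in how repeated associations
#' are handled after sampling:
#' \describe{
#'   \item{`no_reject`}{every sampled association is reported (`alpha` fixed
#'     to 0).}
#'   \item{`reject`}{a repeated association is rejected with probability
#'     `alpha` and sampling restarts.}
#'   \item{`reject_rhow`}{as `reject`, but after the first rejection the
#'     strength modification applied to repeated associations switches from
#'     `rho` to `rho_w` (post-rejection preemption).}
#'   \item{`reject_noresample`}{as `reject`, but the association rejected on
#'     the immediately preceding attempt cannot be re-sampled on the next
#'     attempt (sampling probabilities renormalize over the rest).}
#' }
#' @export
smp_variants <- function() {
  c("no_reject", "reject", "reject_rhow", "reject_noresample")
}

# integer codes shared with the compiled likelihood
variant_code <- function(variant) {
  match(match.arg(variant, smp_variants()), smp_variants()) - 1L
}

#' Semi-Markov process parameters
#'
#' @param variant One of [smp_variants()].
#' @param rho Associative-strength modification: repeated associations have
#'   strength `exp(rho) * AS`. `rho > 0` is rehearsal strengthening,
#'   `rho < 0` proactive weakening.
#' @param alpha Probability of rejecting a sampled repeated association, in
#'   `[0, 1 - 1e-6]`. Forced to 0 for `no_reject`.
#' @param rho_w Post-rejection strength modification; only present (and
#'   required) for `reject_rhow`.
#' @param s_mu Log time-scale of the generation-time function: the mean
#'   generation time of an association with sampling probability `p` is
#'   `exp(s_mu) * (-log p)^e_mu` seconds.
#' @param e_mu Curvature (exponent) of the generation-time function, > 0.
#' @param lam Coefficient of variation of generation times (Gamma sd =
#'   `lam * mean`), > 0.
#' @param tau Non-decision time in seconds (cue encoding + response
#'   execution), >= 0.
#' @return An object of class `smp_params`.
#' @examples
#' smp_params("reject", rho = 1.4, alpha = 0.7,
#'            s_mu = -0.5, e_mu = 1.5, lam = 0.75, tau = 0.6)
#' @export
smp_params <- function(variant = c("no_reject", "reject", "reject_rhow",
                                   "reject_noresample"),
                       rho, alpha = 0, rho_w = NULL,
                       s_mu, e_mu, lam, tau) {
  variant <- match.arg(variant)
  if (variant == "no_reject") {
    if (!missing(alpha) && alpha != 0)
      stop("alpha must be 0 under the no_reject variant")
    alpha <- 0
  }
  if (variant == "reject_rhow") {
    if (is.null(rho_w)) stop("reject_rhow requires rho_w")
  } else if (!is.null(rho_w)) {
    stop("rho_w is only meaningful under reject_rhow")
  }
  num <- c(rho = rho, alpha = alpha, s_mu = s_mu, e_mu = e_mu,
           lam = lam, tau = tau)
  if (!is.null(rho_w)) num <- c(num, rho_w = rho_w)
  if (any(!is.finite(num))) stop("all parameters must be finite")
  if (alpha < 0 || alpha > .smp_const$alpha_max)
    stop("alpha must lie in [0, 1 - 1e-6]")
  if (e_mu <= 0) stop("e_mu must be > 0")
  if (lam <= 0) stop("lam must be > 0")
  if (tau < 0) stop("tau must be >= 0")
  structure(list(variant = variant, rho = rho, alpha = alpha,
                 rho_w = rho_w, s_mu = s_mu, e_mu = e_mu,
                 lam = lam, tau = tau),
            class = "smp_params")
}

#' @export
print.smp_params <- function(x, ...) {
  cat(sprintf("<smp_params> variant = %s\n", x$variant))
  cat(sprintf("  rho = %.3f%s, alpha = %.3f\n", x$rho,
              if (!is.null(x$rho_w)) sprintf(", rho_w = %.3f", x$rho_w) else "",
              x$alpha))
  cat(sprintf("  s_mu = %.3f, e_mu = %.3f, lam = %.3f, tau = %.3f s\n",
              x$s_mu, x$e_mu, x$lam, x$tau))
  invisible(x)
}

# Names of the free parameters of a variant (alpha is not free in no_reject).
free_param_names <- function(variant) {
  switch(variant,
         no_reject         = c("rho", "s_mu", "e_mu", "lam", "tau"),
         reject            = c("rho", "alpha", "s_mu", "e_mu", "lam", "tau"),
         reject_rhow       = c("rho", "rho_w", "alpha", "s_mu", "e_mu",
                               "lam", "tau"),
         reject_noresample = c("rho", "alpha", "s_mu", "e_mu", "lam", "tau"),
         stop("unknown variant"))
}

# params -> named numeric vector in canonical order (rho_w may be absent)
params_to_vector <- function(params) {
  v <- c(rho = params$rho, alpha = params$alpha, s_mu = params$s_mu,
         e_mu = params$e_mu, lam = params$lam, tau = params$tau)
  if (!is.null(params$rho_w)) v <- c(v, rho_w = params$rho_w)
  v
}

vector_to_params <- function(v, variant) {
  smp_params(variant = variant, rho = v[["rho"]],
             alpha = if (variant == "no_reject") 0 else v[["alpha"]],
             rho_w = if (variant == "reject_rhow") v[["rho_w"]] else NULL,
             s_mu = v[["s_mu"]], e_mu = v[["e_mu"]],
             lam = v[["lam"]], tau = v[["tau"]])
}
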