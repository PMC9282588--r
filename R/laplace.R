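#' Numerical Laplace inversion configuration
#'
#' @param method `"talbot"` (fixed-Talbot contour, default) or `"euler"`
#'   (Fourier-series with Euler summation); the two are independent
#'   algorithms and serve as cross-checks for one another.
#' @param n_nodes Number of contour nodes / series terms (>= 16).
#' @param clip_negative_at Negative inversion values no larger than this in
#'   magnitude are treated as numerical noise and clipped to 0; larger
#'   negative values raise an error.
#' @return An object of class `inversion_config`.
#' @export
inversion_config <- function(method = c("talbot", "euler"), n_nodes = 48,
                             clip_negative_at = 1e-8) {
  method <- match.arg(method)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 16L) stop("n_nodes must be >= 16")
  structure(list(method = method, n_nodes = n_nodes,
                 clip_negative_at = clip_negative_at),
            class = "inversion_config")
}

#' Invert a Laplace transform at a time point
#'
#' Fixed-Talbot inversion (Abate & Valko) deforms the Bromwich contour
#' around the negative real axis, where the transforms arising here (finite
#' mixtures/compositions of Gamma transforms) have all their singularities.
#' The Euler method evaluates the Bromwich integral on a vertical line by
#' the trapezoidal rule and accelerates the alternating series by Euler
#' (binomial) summation.
#'
#' @param Fs A function of one complex argument returning the transform
#'   value(s); must accept a complex vector.
#' @param t Positive time point (seconds).
#' @param inv An [inversion_config()].
#' @return The inverted value `f(t)` (may contain small negative noise; the
#'   caller clips).
#' @export
invert_laplace <- function(Fs, t, inv = inversion_config()) {
  stopifnot(t > 0)
  if (inv$method == "talbot") talbot_invert(Fs, t, inv$n_nodes)
  else euler_invert(Fs, t, inv$n_nodes)
}

talbot_invert <- function(Fs, t, M) {
  r <- 2 * M / (5 * t)
  k <- seq_len(M - 1)
  theta <- k * pi / M
  cot <- cos(theta) / sin(theta)
  s <- complex(real = r * theta * cot, imaginary = r * theta)
  sigma <- theta + (theta * cot - 1) * cot
  vals <- Fs(s)
  terms <- Re(exp(s * t) * vals * complex(real = 1, imaginary = sigma))
  head_term <- 0.5 * exp(r * t) * Re(Fs(complex(real = r)))
  (r / M) * (head_term + sum(terms))
}

euler_invert <- function(Fs, t, n) {
  # Abate-Whitt Euler algorithm with binomial averaging of the last m+1
  # partial sums; A controls the discretization error (~ exp(-A)).
  A <- 18.4
  m <- 11L
  n_sum <- n + m
  k <- 0:n_sum
  s <- complex(real = A / (2 * t), imaginary = k * pi / t)
  vals <- Re(Fs(s))
  terms <- (-1)^k * vals
  terms[1] <- terms[1] / 2
  partial <- cumsum(terms)[(n + 1):(n_sum + 1)]
  w <- choose(m, 0:m) / 2^m
  exp(A / 2) / t * sum(w * partial)
}
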