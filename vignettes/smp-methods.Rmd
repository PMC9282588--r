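---
title: "Modelling thought control in repeated free association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thought control in repeated free association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the question

In a repeated free-association task, participants see each of a set of cue
words several times (here 60 cues, five presentations each, in random
order, with a 15 s response window) and report the first association that
comes to mind. One group (*suppress*) is told not to repeat associations
they already gave to the same cue; the other (*control*) is not. The
scientific question is **how** people avoid repeats: *reactively*, by
rejecting a repeated association after it comes to mind and sampling
another (which costs time), or *proactively*, by lowering the strength of
repeated associations so they are less likely to come to mind at all
(which saves time). Raw response times cannot fully separate these
mechanisms; a generative model of the sampling process can.

## The semi-Markov sampling model

Each cue has an association space: candidate associations $i$ with latent
associative strengths $AS_i \in (0, 1]$. On a trial, repeated associations
(those already reported to this cue) have their strength multiplied by
$e^{\rho}$; $\rho > 0$ is rehearsal strengthening, $\rho < 0$ proactive
weakening. Candidates are sampled with probability

$$p_i = \frac{AS'_i}{\sum_j AS'_j},$$

and generating a candidate takes a Gamma-distributed time with mean

$$\mu_i = e^{S^{(\mu)}} \, (-\log p_i)^{E^{(\mu)}}, \qquad
\sigma_i = \lambda \, \mu_i,$$

so weaker (more surprising) associations are slower, and the mean is
exactly 0 in the limiting case of a cue with a single association
($p = 1$). A sampled *new* association is reported; a sampled *repeated*
association is rejected with probability $\alpha$ and sampling restarts.
The response time is the non-decision time $\tau$ plus the sum of all
generation times; rejection itself consumes no time (the task's RT is
defined as the accumulated generation time, and no separate rejection
duration is identified by the data).

Four variants differ in what happens around rejections:

* **`no_reject`** — $\alpha = 0$; every sample is reported.
* **`reject`** — repeated associations are rejected with probability
  $\alpha$; sampling probabilities are unchanged across attempts.
* **`reject_rhow`** — after the first rejection of a trial, the repeated
  multiplier switches from $\rho$ to a second parameter $\rho_w$ and stays
  there until the trial ends (post-rejection preemption).
* **`reject_noresample`** — the association rejected on the immediately
  preceding attempt cannot be re-sampled on the next one; probabilities
  renormalize over the remaining candidates.

## Exact likelihood via Laplace transforms

The process is a semi-Markov chain whose absorbing states are "report
association $j$". Because Gamma holding times have the simple transform
$\tilde g_i(s) = (1 + \theta_i s)^{-k}$ (with $k = 1/\lambda^2$,
$\theta_i = \mu_i \lambda^2$), the transform of the joint sub-density of
absorbing at $j$ at time $t = \mathrm{RT} - \tau$ is closed-form:

* `no_reject`: $\tilde F_j(s) = p_j \tilde g_j(s)$;
* `reject`: $\tilde F_j(s) = p_j q_j \tilde g_j(s) / (1 - r(s))$ with
  $r(s) = \alpha \sum_{i \in R} p_i \tilde g_i(s)$ and acceptance factor
  $q_j = 1$ for new, $1 - \alpha$ for repeated $j$;
* `reject_rhow`: a first-attempt term plus the phase-2 geometric series,
  $\tilde F_j = a^{(1)}_j + r^{(1)} a^{(2)}_j / (1 - r^{(2)})$, where
  phase-2 quantities use the $\rho_w$-modified strengths;
* `reject_noresample`: a linear system over the states
  $\{\text{fresh}\} \cup \{\text{just-rejected-}i : i \in R\}$ with
  exclusion-renormalized probabilities, solved per transform node (the
  repeated set has at most four members, so the systems are tiny).

Time-domain densities come from fixed-Talbot contour inversion, with an
independent Euler (Fourier-series) inverter as a cross-check and a
10⁶-draw simulation oracle validating both. On the fixed-Talbot contour
$s_k t$ is independent of $t$, so the contour and its exponential weights
are precomputed once; the rejection-free case short-circuits to the
closed-form shifted-Gamma mixture. Timed-out trials are excluded from the
likelihood by default (matching the study's treatment of non-responses);
censored-term handling via $1 - \sum_j \mathrm{CDF}_j(t_{\max} - \tau)$
is available as an option.

### Numerical choices

* Generation-time means are floored at $10^{-4}$ s before constructing
  Gamma distributions, so $p \to 1$ keeps densities proper.
* $\alpha$ is capped at $1 - 10^{-6}$ so absorption stays almost sure.
* The likelihood uses 24 Talbot nodes. In double precision the
  fixed-Talbot roundoff floor grows like $\varepsilon\, e^{2M/5}$, so more
  nodes are *less* accurate beyond $M \approx 32$ ($M = 48$ reaches only
  ${\sim}4 \times 10^{-8}$ absolute, $M = 24$ ${\sim}10^{-10}$); 24 nodes
  also halve the cost. The user-facing inversion configuration defaults to
  48 nodes, which is equally adequate for all statistical purposes.
* Negative inversion artifacts below $10^{-8}$ are clipped to zero; larger
  negatives raise an error (they indicate a genuine bug, not noise).
* Per-trial densities are floored at $10^{-300}$ before logging.
* Under `reject_noresample`, the generation-time mean of a candidate drawn
  from an exclusion-renormalized distribution uses the renormalized
  probability — surprisal under the distribution actually sampled from.
  The alternative reading (original probabilities) is not distinguishable
  from the main text and would change densities only slightly.
* Under `reject_rhow`, phase 2 begins at the second sampling attempt of a
  trial and persists to trial end (a literal reading of "after an initial
  rejection").

## Fitting and model comparison

Each participant is fitted separately by maximum likelihood over
transformed parameters: $\alpha$ by logit on $(0, 1-10^{-6})$, $\lambda$
and $E^{(\mu)}$ by log, $\tau$ by scaled logit on $(0,\,0.95 \times
\min \mathrm{RT})$ (a smooth way to keep the non-decision time below every
observed RT), and $\rho$, $\rho_w$, $S^{(\mu)}$ untransformed. The
optimizer is multi-start Nelder-Mead with a BFGS polish. The first start
is a *warm start*: a cheap rejection-free pre-fit (closed-form likelihood)
anchors the RT-controlling parameters; for `reject_rhow`, start signs of
$\rho_w$ alternate so both basins (post-rejection strengthening vs
preemption) are explored. Five starts by default; fits are deterministic
given the seed. BIC is $k \ln n - 2 \ln L$ with $n$ the number of valid
trials entering the likelihood, and group comparison sums BIC over
participants within each variant (ΔBIC relative to the best variant, ties
broken toward fewer parameters). $\alpha$ is not counted as a free
parameter under `no_reject`.

The sensitivity refit re-estimates only the thought-control parameters
($\alpha$, $\rho$, $\rho_w$ where present) with the four RT-controlling
parameters fixed at supplied reference values (e.g. control-group means),
mirroring the study's check that group differences in thought control do
not ride on group differences in RT parameters.

## Estimating covert association spaces

For likelihood evaluation, each (participant, cue) needs the candidate
set and strengths the participant could have sampled, not just what they
reported. The reconstruction assumes any normed association (one present
in population free-association norms) was available to every participant:

1. **Reported associations** enter with their own first-report rating,
   normalized to $(0.01, 1]$ (0–100 rating dialects are auto-detected).
2. **Unreported normed associations** get strengths from an isotonic
   (monotone) regression of the participant's own ratings on norm
   frequency — their personal mapping from population frequency to the
   rating scale — falling back to the pooled mapping below five
   calibration pairs.
3. **Non-normed associations** (idiosyncratic ones absent from norms) are
   counted via an additive-margin estimate: the combined proportion
   $\pi = \mathrm{clip}(\text{cue margin} + \text{participant margin} -
   \text{global margin},\, 0,\, 0.95)$ converts to
   $\mathrm{round}(n_{\text{normed}} \, \pi / (1 - \pi))$ slots. Their
   strengths resample the normed-strength histogram (bin width 0.1)
   reweighted by the observed per-bin share of non-normed reports, with
   largest-remainder rounding. The additive-margin combination is this
   package's design choice — simple, symmetric, anchored at the global
   rate; the multiplicative alternative behaves similarly at the observed
   margins. Bin widths of 0.05 and 0.2 are exercised in the test suite as
   a sensitivity check.

String matching for repetition detection is case-folded, trimmed, exact —
deterministic and conservative; no stemming.

## The synthetic cohort generator

The generator exists so the entire pipeline — exclusions, classification,
descriptives, space reconstruction, fitting, BIC comparison, recovery
studies — runs from known ground truth with no external data. Its
defaults are the study conditions: 40 participants per group, 60 cues ×
5 presentations, 15 s window; suppress participants generated from
`reject_noresample` with $\alpha \sim N(0.7, 0.1)$ and
$\rho \sim N(1.41, 0.54)$; control participants from `no_reject` with
$\rho \sim N(3.07, 1.09)$ (each truncated to its admissible range). A
configurable number of sub-100 ms fast guesses (default 16 per cohort) is
injected and flagged in ground truth so exclusion logic can be tested
exactly; timeouts arise naturally from the 15 s window.

The RT-controlling parameters and space geometry are **synthetic
conventions** (the study reports only that such parameters differed
between groups, with standardized differences above 1.4):

* suppress: $S^{(\mu)} \sim N(-0.7, 0.3)$, $\tau \sim N(0.7, 0.15)$;
  control: $S^{(\mu)} \sim N(-1.1, 0.3)$, $\tau \sim N(0.6, 0.15)$;
  both groups $E^{(\mu)} \sim N(0.7, 0.15)$, $\lambda \sim N(0.75, 0.15)$.
* Norm sets of 8–20 associations per cue with symmetric-Dirichlet
  frequencies; generative strength $= \sqrt{\text{frequency}}$; non-normed
  associations added at a 0.48 expected report share (the share observed
  in the real task) with strengths resampled from the cue's normed
  strengths; ratings are the base strength plus $N(0, 0.05)$ noise,
  clipped to $[0, 1]$.

These choices were calibrated once, jointly, to place median RTs in the
1–3 s range typical of the task and to reproduce the study's qualitative
pattern: with group-*identical* RT parameters the control group's
new/repeated trials are dominated by search-space dilution (under
$\rho = 3.07$, strengthened repeats crowd out new candidates, inflating
their surprisal), which overturns the empirically observed ordering of
the new/repeated − new/new contrast. A sublinear surprisal curvature
($E^{(\mu)} = 0.7$) tempers that dilution penalty, and small association
spaces make rejections frequent — consistent with the study's observation
that the suppression slowdown concentrates on cues with few possible
associations. None of these conventions is a fitted quantity; all are
overridable through `cohort_config()`.

**What the generator does not emulate:** real word strings, typing,
spelling variation, attention checks, semantic similarity between cues,
affective content, and any within-trial neural dynamics. Passing tests on
synthetic cohorts therefore validate the *inference machinery* (that the
pipeline recovers what generated the data), not the model's adequacy for
any particular empirical dataset.

## Validation surface and problem sizes

The test suite validates the chain end to end, at sizes chosen for a
single-CPU run:

* likelihood vs simulation: 10⁶-draw oracles on 20 randomized contexts
  per rejection variant, compared through analytic bin masses;
* parameter recovery: 40 participants × 300 trials under
  `reject_noresample`, requiring each fitted parameter to correlate more
  strongly with its own generating value than with any other (diagonal
  dominance);
* group-mean recovery: 8 participants per group at the reported group
  means, refitted with the group's winning variant;
* model recovery: 5 replicate cohorts of 4 participants × 300 trials per
  generating variant, group-summed BIC choosing the winner;
* directional checks: three replicate default cohorts of 10 + 10
  participants × 200 trials.

## Known limitations

* The likelihood treats the association space as known once
  reconstructed; uncertainty in the space estimate is not propagated.
* A variant in which rejected associations can *never* be re-sampled in
  the same trial is outside the semi-Markov framework (it would need an
  exponentially growing state space) and is not implemented.
* Only reported associations enter the repeated set; covert unreported
  generations are unobservable and unmodelled.
* Hierarchical (population-level) likelihoods, standard errors beyond
  between-participant dispersion, and the exploratory strength-control
  extension are out of scope.
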