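#' Normalize an associative-strength rating to a base strength
#'
#' Ratings arrive on a 0-1 visual-analog scale (or a 0-100 dialect, detected
#' automatically from the value range) and are floored at 0.01 so that base
#' strengths stay strictly positive.
#'
#' @param raw Numeric vector of ratings in `[0, 1]` or `[0, 100]`.
#' @return Strengths in `(0.01, 1]`.
#' @export
normalize_rating <- function(raw) {
  if (any(!is.finite(raw))) stop("ratings must be finite")
  if (any(raw < 0)) stop("ratings must be non-negative")
  if (any(raw > 1)) {           # 0-100 dialect
    if (any(raw > 100)) stop("ratings must lie in [0, 1] or [0, 100]")
    raw <- raw / 100
  }
  pmax(raw, .smp_const$strength_eps)
}

#' Estimated number of non-normed associations for a (participant, cue)
#'
#' Combines the cue's non-normed report proportion (across participants)
#' and the participant's (across cues) additively, anchored at the global
#' proportion, then converts the combined proportion into a count of
#' non-normed slots relative to the cue's normed set size.
#'
#' @param cue_margin Proportion of non-normed responses for this cue, in
#'   `[0, 1)`.
#' @param participant_margin Proportion of non-normed responses for this
#'   participant, in `[0, 1)`.
#' @param n_normed_cue Number of normed associations for the cue (> 0).
#' @param global_margin Overall non-normed proportion, in `[0, 1)`.
#' @return Integer count >= 0 (deterministic).
#' @export
estimate_nonnormed_count <- function(cue_margin, participant_margin,
                                     n_normed_cue, global_margin = 0) {
  stopifnot(cue_margin >= 0, cue_margin < 1,
            participant_margin >= 0, participant_margin < 1,
            global_margin >= 0, global_margin < 1)
  if (n_normed_cue == 0) stop("cue has no normed associations")
  pi_hat <- min(max(cue_margin + participant_margin - global_margin, 0), 0.95)
  as.integer(round(n_normed_cue * pi_hat / (1 - pi_hat)))
}

#' Strengths for unreported normed associations
#'
#' Maps norm population frequencies onto the rating scale with a monotone
#' (isotonic) regression calibrated on the participant's own reported
#' normed associations: pairs of (population frequency, normalized rating).
#' With fewer than 5 calibration pairs the caller should pool pairs across
#' participants (global calibration) before calling.
#'
#' @param freqs Population frequencies to map, each in `(0, 1]`.
#' @param calib_freqs,calib_ratings Calibration pairs (same length).
#' @return Strengths in `(0.01, 1]`, monotone in frequency.
#' @export
strengths_for_unreported_normed <- function(freqs, calib_freqs,
                                            calib_ratings) {
  if (length(freqs) == 0) return(numeric(0))
  if (length(calib_freqs) != length(calib_ratings) ||
      length(calib_freqs) < 2)
    stop("need at least 2 calibration pairs")
  ord <- order(calib_freqs)
  xs <- calib_freqs[ord]
  iso <- isoreg(xs, calib_ratings[ord])   # iso$yf aligned with sorted x
  ox <- unique(xs)
  oy <- as.numeric(tapply(iso$yf, match(xs, ox), mean))
  mapped <- if (length(ox) == 1) rep(oy, length(freqs))
            else approx(ox, oy, xout = freqs, rule = 2)$y
  pmin(pmax(mapped, .smp_const$strength_eps), 1)
}

#' Strengths for estimated non-normed association slots
#'
#' The strength distribution of non-normed associations is modelled as the
#' histogram of the participant's normed strengths reweighted by the
#' empirical proportion of non-normed reports observed at each strength
#' level (bin). The requested number of slots is apportioned to bins by
#' largest-remainder rounding and each slot gets its bin's midpoint.
#'
#' @param normed_strengths Strengths of the normed associations, in (0, 1].
#' @param nonnormed_props Per-bin proportion of reports that are non-normed
#'   (length = number of bins, recycled if scalar).
#' @param bin_width Histogram bin width in (0, 0.5] (default 0.1).
#' @param n_slots Number of non-normed slots to create (>= 0).
#' @return Numeric vector of `n_slots` strengths.
#' @export
strengths_for_nonnormed <- function(normed_strengths, nonnormed_props,
                                    bin_width = 0.1, n_slots) {
  stopifnot(bin_width > 0, bin_width <= 0.5, n_slots >= 0)
  if (n_slots == 0) return(numeric(0))
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  nb <- length(breaks) - 1L
  props <- rep_len(nonnormed_props, nb)
  bin <- pmin(pmax(findInterval(normed_strengths, breaks,
                                rightmost.closed = TRUE), 1L), nb)
  counts <- tabulate(bin, nbins = nb)
  w <- counts * props
  if (all(w == 0)) stop("all bin weights are zero")
  w <- w / sum(w)
  # largest-remainder apportionment
  raw <- w * n_slots
  base <- floor(raw)
  rem <- n_slots - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- rep(mids, times = base)
  pmin(pmax(out, .smp_const$strength_eps), 1)
}

# Cohort-level ingredients shared by every space build: non-normed margins,
# the pooled frequency->rating calibration, and per-bin non-normed report
# proportions. `trials` needs participant, cue, response, rating; `norms`
# needs cue, association, frequency.
space_build_stats <- function(trials, norms, bin_width = 0.1) {
  norm_str <- function(x) tolower(trimws(as.character(x)))
  trials <- trials[!is.na(trials$response), , drop = FALSE]
  key <- paste(norm_str(trials$cue), norm_str(trials$response))
  nkey <- paste(norm_str(norms$cue), norm_str(norms$association))
  is_normed <- key %in% nkey
  cue_margin <- tapply(!is_normed, norm_str(trials$cue), mean)
  part_margin <- tapply(!is_normed, as.character(trials$participant), mean)
  global_margin <- mean(!is_normed)

  has_rating <- !is.na(trials$rating)
  calib <- trials[is_normed & has_rating, , drop = FALSE]
  freq <- norms$frequency[match(paste(norm_str(calib$cue),
                                      norm_str(calib$response)), nkey)]
  calib_pairs <- data.frame(participant = as.character(calib$participant),
                            freq = freq,
                            rating = normalize_rating(calib$rating))

  # proportion of non-normed reports per strength bin (pooled)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  nb <- length(breaks) - 1L
  rated <- trials[has_rating, , drop = FALSE]
  rbin <- pmin(pmax(findInterval(normalize_rating(rated$rating), breaks,
                                 rightmost.closed = TRUE), 1L), nb)
  nn <- !(paste(norm_str(rated$cue), norm_str(rated$response)) %in% nkey)
  props <- vapply(seq_len(nb), function(b) {
    sel <- rbin == b
    if (!any(sel)) return(global_margin)
    mean(nn[sel])
  }, numeric(1))

  list(cue_margin = cue_margin, part_margin = part_margin,
       global_margin = global_margin, calib_pairs = calib_pairs,
       nonnormed_props = props, bin_width = bin_width)
}

#' Build the covert association space for one (participant, cue)
#'
#' The space is the union of (i) the participant's reported associations to
#' the cue, with their first-report normalized rating as base strength,
#' (ii) the unreported normed associations of the cue, with strengths
#' mapped from population frequency via [strengths_for_unreported_normed()],
#' and (iii) estimated non-normed slots ([estimate_nonnormed_count()],
#' [strengths_for_nonnormed()]).
#'
#' @param participant Participant identifier.
#' @param cue Cue word.
#' @param norms Norm table (`cue`, `association`, `frequency`).
#' @param reported Data frame of the participant's reports for this cue:
#'   columns `response`, `rating` (first report per distinct response is
#'   used).
#' @param stats Cohort-level statistics from the internal margin/calibration
#'   pass (see [build_spaces()], which computes them).
#' @return An [association_space()].
#' @export
build_space <- function(participant, cue, norms, reported, stats) {
  norm_str <- function(x) tolower(trimws(as.character(x)))
  cue_n <- norm_str(cue)
  nsel <- norm_str(norms$cue) == cue_n
  cue_norms <- norms[nsel, , drop = FALSE]
  reported <- reported[!is.na(reported$response), , drop = FALSE]
  if (nrow(cue_norms) == 0 && nrow(reported) == 0)
    stop(sprintf("cue '%s' absent from norms and never reported", cue))

  # (i) reported associations, first-report rating
  rep_ids <- norm_str(reported$response)
  first <- !duplicated(rep_ids)
  rep_ids <- rep_ids[first]
  rep_rating <- reported$rating[first]
  med_rating <- median(rep_rating, na.rm = TRUE)
  if (!is.finite(med_rating)) med_rating <- 0.5
  rep_rating[is.na(rep_rating)] <- med_rating
  rep_strength <- normalize_rating(rep_rating)
  rep_normed <- rep_ids %in% norm_str(cue_norms$association)

  # (ii) unreported normed associations
  unrep <- cue_norms[!(norm_str(cue_norms$association) %in% rep_ids), ,
                     drop = FALSE]
  cp <- stats$calib_pairs
  own <- cp[cp$participant == as.character(participant), , drop = FALSE]
  if (nrow(own) < 5) own <- cp   # global calibration fallback
  unrep_strength <- if (nrow(unrep) > 0) {
    strengths_for_unreported_normed(unrep$frequency, own$freq, own$rating)
  } else numeric(0)

  # (iii) non-normed slots
  cm <- stats$cue_margin[[cue_n]]
  if (is.null(cm) || is.na(cm)) cm <- stats$global_margin
  pm <- stats$part_margin[[as.character(participant)]]
  if (is.null(pm) || is.na(pm)) pm <- stats$global_margin
  n_normed_cue <- nrow(cue_norms)
  n_nn <- if (n_normed_cue > 0)
    estimate_nonnormed_count(cm, pm, n_normed_cue, stats$global_margin)
  else 0L
  n_nn_new <- max(0L, n_nn - sum(!rep_normed))
  nn_strength <- if (n_nn_new > 0) {
    normed_pool <- c(rep_strength[rep_normed], unrep_strength)
    if (length(normed_pool) == 0) normed_pool <- med_rating
    strengths_for_nonnormed(normed_pool, stats$nonnormed_props,
                            stats$bin_width, n_nn_new)
  } else numeric(0)

  ids <- c(rep_ids, norm_str(unrep$association),
           if (n_nn_new > 0) paste0(".nonnormed_", seq_len(n_nn_new)))
  strengths <- c(rep_strength, unrep_strength, nn_strength)
  normed <- c(rep_normed, rep(TRUE, nrow(unrep)), rep(FALSE, n_nn_new))
  if (length(ids) < 2) {  # degenerate cue: pad with one non-normed slot
    ids <- c(ids, ".nonnormed_pad")
    strengths <- c(strengths, max(med_rating, .smp_const$strength_eps))
    normed <- c(normed, FALSE)
  }
  association_space(cue, ids, strengths, normed)
}

#' Build association spaces for a whole cohort
#'
#' Runs the margin/calibration pass over the trial table, then builds one
#' space per (participant, cue): the deterministic reconstruction of the
#' covert spaces the semi-Markov model samples from.
#'
#' @param trials Trial table with columns `participant`, `cue`, `response`,
#'   `rating` (rating may be `NA` where unavailable).
#' @param norms Norm table (`cue`, `association`, `frequency` per-cue
#'   frequencies summing to at most 1).
#' @param bin_width Strength-histogram bin width for the non-normed
#'   estimation (default 0.1).
#' @return Nested named list: `spaces[[participant]][[cue]]`.
#' @export
build_spaces <- function(trials, norms, bin_width = 0.1) {
  stopifnot(all(c("participant", "cue", "response") %in% names(trials)))
  if (!"rating" %in% names(trials)) trials$rating <- NA_real_
  validate_norms(norms)
  stats <- space_build_stats(trials, norms, bin_width)
  out <- list()
  for (p in unique(as.character(trials$participant))) {
    ptr <- trials[as.character(trials$participant) == p, , drop = FALSE]
    cues <- unique(as.character(ptr$cue))
    out[[p]] <- lapply(setNames(cues, tolower(trimws(cues))), function(cu) {
      rep_rows <- ptr[as.character(ptr$cue) == cu, c("response", "rating")]
      build_space(p, cu, norms, rep_rows, stats)
    })
  }
  out
}

validate_norms <- function(norms) {
  stopifnot(all(c("cue", "association", "frequency") %in% names(norms)))
  if (any(norms$frequency <= 0) || any(norms$frequency > 1))
    stop("norm frequencies must lie in (0, 1]")
  key <- paste(tolower(trimws(norms$cue)), tolower(trimws(norms$association)))
  if (anyDuplicated(key)) stop("duplicate (cue, association) pairs in norms")
  sums <- tapply(norms$frequency, norms$cue, sum)
  if (any(sums > 1 + 1e-8)) stop("per-cue norm frequencies must sum to <= 1")
  invisible(TRUE)
}
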