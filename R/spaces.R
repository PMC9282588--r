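#' Association space for one cue
#'
#' An association space holds, for one (participant, cue) pair, the candidate
#' associations the participant could sample, each with a base associative
#' strength in (0, 1] and a flag recording whether the association appears in
#' published free-association norms. The space is the state set of the
#' semi-Markov sampling process: candidates are drawn with probability
#' proportional to (possibly modified) strength.
#'
#' @param cue_id Identifier of the cue (character scalar).
#' @param ids Character vector of association identifiers, unique.
#' @param strengths Numeric vector of base strengths, each in (0, 1].
#' @param normed Logical vector; `TRUE` where the association appears in the
#'   norms. Recycled if scalar.
#' @return An object of class `association_space`.
#' @examples
#' sp <- association_space("table", c("chair", "desk", "eat"),
#'                         c(0.8, 0.4, 0.2))
#' sp
#' @export
association_space <- function(cue_id, ids, strengths, normed = TRUE) {
  ids <- as.character(ids)
  strengths <- as.numeric(strengths)
  if (length(ids) < 2L)
    stop("an association space needs at least 2 entries")
  if (length(strengths) != length(ids))
    stop("`ids` and `strengths` must have equal length")
  if (anyDuplicated(ids))
    stop("association ids must be unique within a space")
  if (any(!is.finite(strengths)) || any(strengths <= 0) || any(strengths > 1))
    stop("base strengths must lie in (0, 1]")
  normed <- rep_len(as.logical(normed), length(ids))
  structure(list(cue_id = as.character(cue_id), ids = ids,
                 strengths = strengths, normed = normed),
            class = "association_space")
}

#' @export
print.association_space <- function(x, ...) {
  cat(sprintf("<association_space> cue '%s': %d associations (%d normed)\n",
              x$cue_id, length(x$ids), sum(x$normed)))
  cat(sprintf("  strength range [%.3f, %.3f]\n",
              min(x$strengths), max(x$strengths)))
  invisible(x)
}

#' @export
length.association_space <- function(x) length(x$ids)

#' Trial context: a space plus the participant's repetition history
#'
#' The repeated set contains the associations this participant already
#' reported on earlier presentations of the same cue; those are the
#' associations that may be strengthened/weakened (via `rho`) and rejected
#' (via `alpha`) on the current trial. It is empty on a cue's first
#' presentation.
#'
#' @param space An [association_space()].
#' @param repeated_ids Character vector of association ids previously
#'   reported for this cue (subset of the space's ids).
#' @return An object of class `trial_context`.
#' @export
trial_context <- function(space, repeated_ids = character()) {
  stopifnot(inherits(space, "association_space"))
  repeated_ids <- as.character(repeated_ids)
  if (!all(repeated_ids %in% space$ids))
    stop("repeated_ids must be a subset of the space's association ids")
  structure(list(space = space,
                 repeated_ids = unique(repeated_ids)),
            class = "trial_context")
}

# Logical mask of repeated associations, aligned with space$ids.
repeated_mask <- function(ctx) ctx$space$ids %in% ctx$repeated_ids
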