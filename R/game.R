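#' Minimum target-distractor distance for a given discriminative need
#'
#' The discrimination game only pairs a target with distractors at least a
#' minimum perceptual distance away; that minimum is parameterized as a
#' percentile of the list of pairwise distances between distinct chips.
#' The percentile is resolved by nearest rank on the sorted list of the
#' n(n-1)/2 unordered-pair distances (percentile 50 is the median of that
#' list, percentile 0 the smallest pairwise distance).
#'
#' @param palette a `color_palette` with >= 2 chips.
#' @param percentile number in \[0, 100\].
#' @return the distance threshold (same units as the palette coordinates).
#' @export
distance_threshold <- function(palette, percentile) {
  stopifnot_palette(palette)
  if (n_chips(palette) < 2) stop("palette needs at least 2 chips")
  if (percentile < 0 || percentile > 100) stop("percentile must be in [0, 100]")
  dd <- sort(palette$dist[lower.tri(palette$dist)])
  k <- max(1L, ceiling(percentile / 100 * length(dd)))
  dd[k]
}

#' Valid distractor sets under a distance threshold
#'
#' For each target chip, the indices of chips at distance >= `threshold`
#' that may serve as its distractor. Targets whose set is empty make the
#' game unplayable at that threshold (this is what caps the usable
#' percentile range on the 330-chip chart at about 80).
#'
#' @param palette a `color_palette`.
#' @param threshold minimum target-distractor distance (>= 0).
#' @param on_empty `"flag"` (default) records empty targets in the result,
#'   `"error"` raises.
#' @return a list with `sets` (list of integer index vectors, one per chip)
#'   and `empty_targets` (integer indices of chips with no valid distractor).
#' @export
valid_distractor_sets <- function(palette, threshold, on_empty = c("flag", "error")) {
  stopifnot_palette(palette)
  on_empty <- match.arg(on_empty)
  if (threshold < 0) stop("threshold must be nonnegative")
  n <- n_chips(palette)
  ok <- palette$dist >= threshold
  diag(ok) <- FALSE
  sets <- lapply(seq_len(n), function(i) which(ok[i, ]))
  empty <- which(lengths(sets) == 0L)
  if (length(empty) && on_empty == "error") {
    stop(sprintf("%d target(s) have no valid distractor at threshold %.3f",
                 length(empty), threshold))
  }
  list(sets = sets, empty_targets = empty)
}

#' Enumerate all valid game rounds with their sampling probabilities
#'
#' Lists every (target, distractor) pair the game can produce at the given
#' threshold together with its probability prior(target) / |valid(target)|.
#' Supports exact (non-Monte-Carlo) evaluation of success rates.
#'
#' @param palette a `color_palette`.
#' @param threshold minimum target-distractor distance.
#' @param drop_isolated_targets drop targets with empty valid sets and
#'   renormalize the prior over the rest (default errors instead).
#' @return data.frame with columns `target`, `distractor`, `weight`
#'   (weights sum to 1).
#' @export
enumerate_valid_rounds <- function(palette, threshold,
                                   drop_isolated_targets = FALSE) {
  vd <- valid_distractor_sets(palette, threshold)
  prior <- palette$prior
  if (length(vd$empty_targets)) {
    if (!drop_isolated_targets) {
      stop(sprintf(paste0("%d target(s) have no valid distractor; ",
                          "set drop_isolated_targets = TRUE to exclude them"),
                   length(vd$empty_targets)))
    }
    message(sprintf("dropping %d isolated target(s); prior renormalized",
                    length(vd$empty_targets)))
    prior[vd$empty_targets] <- 0
    prior <- prior / sum(prior)
  }
  counts <- lengths(vd$sets)
  tg <- rep.int(seq_along(vd$sets), counts)
  ds <- unlist(vd$sets, use.names = FALSE)
  data.frame(target = tg, distractor = ds,
             weight = prior[tg] / counts[tg])
}

#' Sample discrimination-game rounds
#'
#' Draws `n` rounds: the target from the palette prior, the distractor
#' uniformly from the target's valid set, and the target's display position
#' uniformly from \{1, 2\}. Uses R's global RNG stream.
#'
#' @param palette a `color_palette`.
#' @param threshold minimum target-distractor distance.
#' @param n number of rounds.
#' @param sets optional precomputed [valid_distractor_sets()] result.
#' @param drop_isolated_targets as in [enumerate_valid_rounds()].
#' @return data.frame with columns `target`, `distractor`, `position`.
#' @export
sample_rounds <- function(palette, threshold, n, sets = NULL,
                          drop_isolated_targets = FALSE) {
  stopifnot_palette(palette)
  if (is.null(sets)) sets <- valid_distractor_sets(palette, threshold)
  prior <- palette$prior
  if (length(sets$empty_targets)) {
    if (!drop_isolated_targets) {
      stop("some targets have no valid distractor")
    }
    prior[sets$empty_targets] <- 0
    prior <- prior / sum(prior)
  }
  tg <- sample.int(n_chips(palette), n, replace = TRUE, prob = prior)
  counts <- lengths(sets$sets)
  pick <- floor(stats::runif(n) * counts[tg]) + 1L
  flat <- unlist(sets$sets, use.names = FALSE)
  offset <- cumsum(counts) - counts
  data.frame(target = tg, distractor = flat[offset[tg] + pick],
             position = sample(c(1L, 2L), n, replace = TRUE))
}

#' @rdname sample_rounds
#' @return `sample_round` returns a single-round list with elements
#'   `target`, `distractor`, `position`.
#' @export
sample_round <- function(palette, threshold, sets = NULL,
                         drop_isolated_targets = FALSE) {
  r <- sample_rounds(palette, threshold, 1L, sets = sets,
                     drop_isolated_targets = drop_isolated_targets)
  list(target = r$target[1], distractor = r$distractor[1],
       position = r$position[1])
}
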