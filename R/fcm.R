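#' Fuzzy c-means clustering of a palette
#'
#' Soft-partitions the chip coordinates into `k` clusters with the fuzzy
#' c-means algorithm (via [e1071::cmeans()]), taking the best of several
#' seeded restarts by the within-cluster objective. Treating cluster labels
#' as color names, the membership rows serve directly as a baseline naming
#' system.
#'
#' @param palette a `color_palette`.
#' @param k number of clusters, 2 <= k <= n_chips.
#' @param fuzzifier fuzziness exponent m (> 1); 2 is the common default.
#' @param tol convergence tolerance on the objective.
#' @param restarts number of random restarts.
#' @param seed RNG seed driving the restarts.
#' @param max_iter iteration cap per restart.
#' @return object of class `fcm_result`: list with `k`, `fuzzifier`,
#'   `centers` (k x 3), `memberships` (chips x k, rows sum to 1),
#'   `objective`, `converged`.
#' @export
fcm_fit <- function(palette, k, fuzzifier = 2.0, tol = 1e-6, restarts = 10,
                    seed = 1L, max_iter = 1000L) {
  stopifnot_palette(palette)
  n <- n_chips(palette)
  if (k < 2 || k > n) stop("k must be in [2, n_chips]")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- palette$coords[sample.int(n, k), , drop = FALSE] +
        matrix(stats::rnorm(k * 3, sd = 1e-3), k, 3)  # break coincident chips
      fit <- e1071::cmeans(palette$coords, centers = init, m = fuzzifier,
                           iter.max = max_iter, method = "cmeans",
                           control = list(reltol = tol))
      if (is.null(best) || fit$withinerror < best$withinerror) best <- fit
    }
    memberships <- unname(best$membership)
    structure(list(k = k, fuzzifier = fuzzifier,
                   centers = unname(best$centers),
                   memberships = memberships / rowSums(memberships),
                   objective = best$withinerror,
                   converged = best$iter < max_iter),
              class = "fcm_result")
  })
}

#' Naming system from a fuzzy clustering
#'
#' Each chip's word distribution is its membership row: P(w | c) =
#' membership of chip c in cluster w.
#'
#' @param res an `fcm_result`.
#' @return a `naming_system` with provenance `"fcm"`.
#' @export
fcm_naming <- function(res) {
  naming_system(res$memberships, provenance = "fcm", tol = 1e-6)
}

#' Exact expected success of a naming system with a Bayesian listener
#'
#' Plays the discrimination game in closed form: the speaker emits a word
#' for the target chip, the Bayesian listener picks the candidate chip c
#' maximizing P(w | c), and exact ties contribute 1/2. The expectation runs
#' over every valid (target, distractor) pair with its sampling weight, so
#' the result is deterministic -- no Monte Carlo, no seed.
#'
#' Two speaker conventions are supported. With `speaker = "sample"` the
#' word is drawn from the full distribution P(w | target) (fuzzy naming)
#' and the expectation also runs over that draw. Note that a system whose
#' word distributions have full support can then never reach success
#' exactly 1: some sampled words are necessarily better evidence for the
#' distractor. With `speaker = "modal"` the speaker deterministically emits
#' the chip's most probable word; exact 100% success is attainable and
#' this is the convention under which "fully successful" cluster systems
#' are meaningful (see [fcm_sweep()]).
#'
#' @param ns a `naming_system`.
#' @param palette a `color_palette`.
#' @param threshold minimum target-distractor distance.
#' @param speaker `"sample"` (default) or `"modal"`, see Details.
#' @param drop_isolated_targets as in [enumerate_valid_rounds()].
#' @return expected success probability in \[0, 1\].
#' @export
bayesian_expected_success <- function(ns, palette, threshold,
                                      speaker = c("sample", "modal"),
                                      drop_isolated_targets = FALSE) {
  stopifnot_palette(palette)
  speaker <- match.arg(speaker)
  rounds <- enumerate_valid_rounds(palette, threshold,
                                   drop_isolated_targets = drop_isolated_targets)
  enc <- ns$enc
  if (speaker == "modal") {
    w <- max.col(enc, ties.method = "first")
    pt <- enc[cbind(rounds$target, w[rounds$target])]
    pd <- enc[cbind(rounds$distractor, w[rounds$target])]
    win <- (pt > pd) + 0.5 * (pt == pd)
  } else {
    pt <- enc[rounds$target, , drop = FALSE]
    pd <- enc[rounds$distractor, , drop = FALSE]
    win <- rowSums(pt * ((pt > pd) + 0.5 * (pt == pd)))
  }
  sum(rounds$weight * win)
}

#' Sweep fuzzy c-means cluster counts for the least complex fully
#' successful system
#'
#' Fits fuzzy c-means for every k in `k_range`, scores each resulting
#' naming system by exact Bayesian expected success and by complexity, and
#' returns the least complex system among those achieving full success.
#' This is the clustering baseline showing that perfect discrimination is
#' attainable at every percentile -- at the cost of complexity well above
#' what emergent neural systems settle on.
#'
#' Full success is tested at machine precision on the exact expectation,
#' which is only attainable when the speaker deterministically emits each
#' chip's modal word (see [bayesian_expected_success()]); `speaker =
#' "modal"` is therefore the default here. Complexity is scored on the
#' code the speaker actually transmits: the hard argmax naming in modal
#' mode, the fuzzy membership rows in sampling mode (the table reports
#' both).
#'
#' @param palette a `color_palette`.
#' @param threshold minimum target-distractor distance.
#' @param k_range integer vector of cluster counts to try (default 2:20).
#' @param success_tol slack below 1 still counted as full success (default
#'   1e-12, i.e. machine-exact full success).
#' @param speaker speaker convention for the success computation.
#' @param fuzzifier,restarts,seed passed to [fcm_fit()].
#' @param drop_isolated_targets as in [enumerate_valid_rounds()].
#' @return list with `best` (the least complex fully successful
#'   `naming_system`, or NULL if none), `best_k`, and `table` (data.frame
#'   k / complexity / success / fully_successful).
#' @export
fcm_sweep <- function(palette, threshold, k_range = 2:20,
                      success_tol = 1e-12, speaker = c("modal", "sample"),
                      fuzzifier = 2.0, restarts = 10,
                      seed = 1L, drop_isolated_targets = FALSE) {
  if (!length(k_range)) stop("k_range must be nonempty")
  speaker <- match.arg(speaker)
  rows <- list()
  systems <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    ns <- fcm_naming(fcm_fit(palette, k, fuzzifier = fuzzifier,
                             restarts = restarts, seed = seed + i))
    succ <- bayesian_expected_success(ns, palette, threshold, speaker = speaker,
                                      drop_isolated_targets = drop_isolated_targets)
    w <- max.col(ns$enc, ties.method = "first")
    modal_enc <- matrix(0, nrow(ns$enc), ncol(ns$enc))
    modal_enc[cbind(seq_len(nrow(ns$enc)), w)] <- 1
    modal_ns <- naming_system(modal_enc, provenance = "fcm")
    cx_fuzzy <- complexity(ns, palette)
    cx_modal <- complexity(modal_ns, palette)
    rows[[i]] <- data.frame(k = k,
                            complexity = if (speaker == "modal") cx_modal
                                         else cx_fuzzy,
                            complexity_fuzzy = cx_fuzzy,
                            complexity_modal = cx_modal,
                            success = succ,
                            fully_successful = succ >= 1 - success_tol)
    systems[[i]] <- if (speaker == "modal") modal_ns else ns
  }
  tab <- do.call(rbind, rows)
  ok <- which(tab$fully_successful)
  if (!length(ok)) {
    return(list(best = NULL, best_k = NA_integer_, table = tab))
  }
  best_i <- ok[which.min(tab$complexity[ok])]
  list(best = systems[[best_i]], best_k = tab$k[best_i], table = tab)
}
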