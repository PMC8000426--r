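#' Extract a naming system from a trained Speaker by sampling
#'
#' Estimates P(w | c) for every chip by drawing `n_samples` words with
#' replacement from the converged Speaker's categorical output and taking
#' empirical frequencies (all probabilities are multiples of 1/n_samples).
#' A Dirac speaker yields exactly one word per chip; a maximally uncertain
#' one up to `n_samples` distinct words. Words never sampled for any chip
#' are dropped and the remaining word ids relabeled in order of first use.
#'
#' @param speaker a `speaker_params` object (see [init_speaker()]).
#' @param palette a `color_palette`.
#' @param n_samples draws per chip (default 25).
#' @param seed RNG seed for the draws.
#' @return a `naming_system` with provenance `"nn"`.
#' @export
extract_naming <- function(speaker, palette, n_samples = 25, seed = 1L) {
  stopifnot_palette(palette)
  probs <- speaker_probs(speaker, palette$coords)
  n <- n_chips(palette)
  V <- ncol(probs)
  counts <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      draws <- sample.int(V, n_samples, replace = TRUE, prob = probs[i, ])
      tabulate(draws, nbins = V)
    }, numeric(V)))
  })
  used <- which(colSums(counts) > 0)
  # relabel in order of first use (scanning chips in order)
  first_use <- apply(counts[, used, drop = FALSE], 2,
                     function(x) which(x > 0)[1])
  used <- used[order(first_use, used)]
  enc <- counts[, used, drop = FALSE] / n_samples
  naming_system(enc, words = as.character(seq_along(used)), provenance = "nn")
}

#' Exact naming system from Speaker softmax outputs
#'
#' The infinite-sample limit of [extract_naming()]: P(w | c) is the
#' Speaker's exact categorical output, with words of negligible total mass
#' pruned. Used to quantify the finite-sample bias of the 25-draw estimate
#' (sampling inflates measured complexity).
#'
#' @param speaker a `speaker_params`.
#' @param palette a `color_palette`.
#' @param prune_tol marginal-probability threshold for dropping words.
#' @return a `naming_system` with provenance `"nn"`.
#' @export
naming_from_probs <- function(speaker, palette, prune_tol = 1e-12) {
  stopifnot_palette(palette)
  probs <- speaker_probs(speaker, palette$coords)
  ns <- naming_system(probs, words = as.character(seq_len(ncol(probs))),
                      provenance = "nn", tol = 1e-6)
  prune_words(ns, prior = palette$prior, tol = prune_tol)
}
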