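#' Construct a naming system
#'
#' A naming system is an encoder: the conditional distribution P(w | c) from
#' color chips to words, stored as a chips x words matrix whose rows sum to 1.
#'
#' @param enc numeric matrix, chips x words; each row is the word
#'   distribution of one chip and must sum to 1 (tolerance 1e-9 by default).
#' @param words word identifiers (default `1:ncol(enc)` as character).
#' @param provenance one of `"nn"`, `"fcm"`, `"human"`, `"synthetic"`.
#' @param tol row-sum tolerance for validation.
#' @return an object of class `naming_system`.
#' @export
naming_system <- function(enc, words = NULL, provenance = "synthetic",
                          tol = 1e-9) {
  enc <- as.matrix(enc)
  storage.mode(enc) <- "double"
  if (any(enc < 0)) stop("encoder probabilities must be nonnegative")
  rs <- rowSums(enc)
  if (any(abs(rs - 1) > tol)) {
    stop(sprintf("encoder rows must sum to 1 (max deviation %.3g)",
                 max(abs(rs - 1))))
  }
  if (is.null(words)) words <- as.character(seq_len(ncol(enc)))
  if (length(words) != ncol(enc)) stop("words length must match encoder columns")
  dimnames(enc) <- NULL
  structure(list(enc = enc, words = as.character(words),
                 provenance = match.arg(provenance,
                                        c("nn", "fcm", "human", "synthetic"))),
            class = "naming_system")
}

#' @export
print.naming_system <- function(x, ...) {
  cat(sprintf("<naming_system> %d chips x %d words (%s)\n",
              nrow(x$enc), ncol(x$enc), x$provenance))
  invisible(x)
}

#' Number of words carrying probability mass
#'
#' Counts the words of a naming system whose marginal probability (under a
#' uniform prior over chips unless one is supplied) is nonzero. Both human
#' and emergent systems typically settle on a handful of effective words out
#' of a much larger available vocabulary.
#'
#' @param ns a `naming_system`.
#' @param prior optional prior over chips; default uniform.
#' @return integer count of words with nonzero marginal.
#' @export
effective_vocab <- function(ns, prior = NULL) {
  if (is.null(prior)) prior <- rep(1 / nrow(ns$enc), nrow(ns$enc))
  sum(as.numeric(crossprod(ns$enc, prior)) > 0)
}

#' Drop words with (near-)zero marginal probability
#'
#' @param ns a `naming_system`.
#' @param prior prior over chips; default uniform.
#' @param tol marginal-probability threshold below which a word is dropped.
#' @return a pruned `naming_system` with rows renormalized.
#' @export
prune_words <- function(ns, prior = NULL, tol = 1e-12) {
  if (is.null(prior)) prior <- rep(1 / nrow(ns$enc), nrow(ns$enc))
  pw <- as.numeric(crossprod(ns$enc, prior))
  keep <- pw >= tol
  if (!any(keep)) stop("pruning removed all words")
  enc <- ns$enc[, keep, drop = FALSE]
  enc <- enc / rowSums(enc)
  naming_system(enc, words = ns$words[keep], provenance = ns$provenance)
}

#' Write / read a naming system as CSV
#'
#' Long format with columns chip_id, word_id, probability; zero entries are
#' omitted. Reading validates that probabilities per chip sum to 1 within
#' 1e-6, and the write/read round trip is exact to 1e-12.
#'
#' @param ns a `naming_system`.
#' @param path file path.
#' @param palette optional `color_palette` supplying chip ids; default ids
#'   are `1:nrow(enc)`.
#' @return `write_naming_csv` returns `path` invisibly; `read_naming_csv`
#'   returns a `naming_system`.
#' @export
write_naming_csv <- function(ns, path, palette = NULL) {
  if (!inherits(ns, "naming_system")) stop("expected a naming_system")
  chip_ids <- if (is.null(palette)) seq_len(nrow(ns$enc)) else palette$chip_id
  idx <- which(ns$enc > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(chip_id = chip_ids[idx[, 1]],
                   word_id = ns$words[idx[, 2]],
                   probability = ns$enc[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_naming_csv
#' @export
read_naming_csv <- function(path, palette = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(word_id = "character"))
  chip_ids <- sort(unique(df$chip_id))
  if (!is.null(palette)) {
    if (!all(df$chip_id %in% palette$chip_id)) {
      stop("naming file contains chip ids absent from palette")
    }
    chip_ids <- palette$chip_id
  }
  words <- unique(df$word_id)
  enc <- matrix(0, length(chip_ids), length(words))
  ci <- match(df$chip_id, chip_ids)
  wi <- match(df$word_id, words)
  enc[cbind(ci, wi)] <- df$probability
  rs <- rowSums(enc)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("probabilities per chip do not sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  naming_system(enc, words = words, tol = 1e-6)
}

#' Read WCS-style naming data
#'
#' Parses a World Color Survey term table (columns: language id, speaker id,
#' chip id, term) and turns it, per language, into a naming system by the
#' frequency of each term across speaker judgments for each chip. Languages
#' in which some chip was judged by only a single speaker carry too sparse
#' information and are excluded, as are languages in which some chip
#' received no judgment at all.
#'
#' @param path path to a whitespace/tab-separated term table; lines starting
#'   with `#` are skipped.
#' @param palette the `color_palette` the chip ids refer to.
#' @param columns named list with the column indices of `language`,
#'   `speaker`, `chip`, `term` (defaults 1:4).
#' @param normalize_terms lowercase and trim term strings before counting
#'   (distinct strings after normalization are distinct words).
#' @return a list with elements `systems` (named list of `naming_system`
#'   objects, one per retained language, words = term strings) and
#'   `exclusions` (data.frame language / reason).
#' @examples
#' pal <- load_wcs_palette(system.file("extdata", "synthetic_wcs_chips.tsv",
#'                                     package = "ibcolor"),
#'                         expected_chips = 10)
#' terms <- system.file("extdata", "synthetic_wcs_terms.tsv",
#'                      package = "ibcolor")
#' out <- load_wcs_naming(terms, pal)
#' names(out$systems)     # the sparsely judged language is excluded
#' out$exclusions
#' @export
load_wcs_naming <- function(path, palette,
                            columns = list(language = 1, speaker = 2,
                                           chip = 3, term = 4),
                            normalize_terms = TRUE) {
  stopifnot_palette(palette)
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  lang <- as.character(raw[[columns$language]])
  speaker <- as.character(raw[[columns$speaker]])
  chip <- as.integer(raw[[columns$chip]])
  term <- as.character(raw[[columns$term]])
  if (normalize_terms) term <- tolower(trimws(term))
  if (!all(chip %in% palette$chip_id)) {
    stop("term table contains chip ids absent from the palette: ",
         paste(utils::head(setdiff(chip, palette$chip_id)), collapse = ", "))
  }
  systems <- list()
  exclusions <- data.frame(language = character(), reason = character(),
                           stringsAsFactors = FALSE)
  for (lg in unique(lang)) {
    sel <- lang == lg
    cj <- chip[sel]
    judgments <- table(factor(cj, levels = palette$chip_id))
    if (any(judgments == 0)) {
      exclusions <- rbind(exclusions, data.frame(
        language = lg, reason = "chip with no judgment"))
      next
    }
    if (any(judgments == 1)) {
      exclusions <- rbind(exclusions, data.frame(
        language = lg, reason = "chip judged by a single speaker"))
      next
    }
    tj <- term[sel]
    words <- sort(unique(tj))
    counts <- table(factor(cj, levels = palette$chip_id),
                    factor(tj, levels = words))
    enc <- unclass(counts) / rowSums(counts)
    dimnames(enc) <- NULL
    systems[[lg]] <- naming_system(enc, words = words, provenance = "human")
  }
  list(systems = systems, exclusions = exclusions)
}
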