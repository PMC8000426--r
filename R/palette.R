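#' Construct a color palette
#'
#' A palette is the universe of the communication game: a set of color chips
#' with 3-D CIELAB coordinates, a prior distribution over chips, and the
#' matrix of pairwise Euclidean distances (CIELAB Euclidean distance is the
#' perceptual dissimilarity measure used throughout).
#'
#' @param coords numeric matrix, one row per chip, 3 columns (L*, a*, b*).
#' @param chip_id integer chip identifiers, unique; default `1:nrow(coords)`.
#' @param prior prior probability of each chip being the communication
#'   target; default uniform. Must be nonnegative and sum to 1.
#' @param lightness_row optional lightness-row labels (WCS rows A-J).
#' @param hue_col optional hue-column indices (WCS columns 0-40).
#' @param meta optional list of extra metadata (e.g. blob labels for
#'   synthetic cluster palettes).
#' @return An object of class `color_palette` with elements `chip_id`,
#'   `coords`, `prior`, `dist`, `lightness_row`, `hue_col`, `meta`.
#' @export
color_palette <- function(coords, chip_id = NULL, prior = NULL,
                          lightness_row = NULL, hue_col = NULL,
                          meta = list()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns (L, a, b)")
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords))) stop("chip coordinates must be finite")
  n <- nrow(coords)
  if (is.null(chip_id)) chip_id <- seq_len(n)
  chip_id <- as.integer(chip_id)
  if (anyDuplicated(chip_id)) stop("duplicate chip ids")
  if (any(chip_id < 1L)) stop("chip ids must be >= 1")
  # canonical ordering: chip_id ascending; all matrices follow this order
  ord <- order(chip_id)
  coords <- coords[ord, , drop = FALSE]
  chip_id <- chip_id[ord]
  if (!is.null(lightness_row)) lightness_row <- as.character(lightness_row)[ord]
  if (!is.null(hue_col)) hue_col <- as.integer(hue_col)[ord]
  if (is.null(prior)) {
    prior <- rep(1 / n, n)
  } else {
    prior <- as.numeric(prior)[ord]
    if (length(prior) != n) stop("prior length must equal number of chips")
    if (any(prior < 0)) stop("prior entries must be nonnegative")
    if (abs(sum(prior) - 1) > 1e-12) stop("prior must sum to 1")
  }
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  dimnames(coords) <- NULL
  structure(
    list(chip_id = chip_id, coords = coords, prior = prior, dist = d,
         lightness_row = lightness_row, hue_col = hue_col, meta = meta),
    class = "color_palette"
  )
}

#' @export
print.color_palette <- function(x, ...) {
  cat(sprintf("<color_palette> %d chips, prior %s\n", n_chips(x),
              if (max(abs(x$prior - 1 / n_chips(x))) < 1e-12) "uniform"
              else "nonuniform"))
  invisible(x)
}

#' Number of chips in a palette
#' @param palette a `color_palette`.
#' @return integer chip count.
#' @export
n_chips <- function(palette) length(palette$chip_id)

stopifnot_palette <- function(palette) {
  if (!inherits(palette, "color_palette")) stop("expected a color_palette")
  invisible(palette)
}

#' Read a WCS-style chip coordinate table
#'
#' Parses the World Color Survey chip table format: one row per chip with the
#' chip id, lightness row letter, hue column number and CIELAB coordinates.
#' Field positions vary between file dialects, so the column mapping is
#' configurable; the default matches `cnum-vhcm-lab-new.txt`-style files
#' (chip number, V row, H column, ..., L*, a*, b* in the last three columns).
#'
#' @param path path to a whitespace- or tab-separated table. Lines starting
#'   with `#` are treated as comments; a non-numeric first field on line 1 is
#'   treated as a header and skipped.
#' @param columns named list mapping the roles `chip_id`, `lightness_row`,
#'   `hue_col`, `L`, `a`, `b` to column indices. Negative indices count from
#'   the last column. Default: chip id in column 1, row in 2, column in 3,
#'   and L*, a*, b* in the last three columns.
#' @param expected_chips expected chip count (WCS has 330). A mismatch warns,
#'   or errors when `strict = TRUE`.
#' @param strict error (rather than warn) on unexpected chip counts.
#' @return a `color_palette` with uniform prior.
#' @examples
#' chips <- system.file("extdata", "synthetic_wcs_chips.tsv",
#'                      package = "ibcolor")
#' pal <- load_wcs_palette(chips, expected_chips = 10)
#' pal
#' @export
load_wcs_palette <- function(path,
                             columns = list(chip_id = 1, lightness_row = 2,
                                            hue_col = 3, L = -3, a = -2, b = -1),
                             expected_chips = 330L, strict = FALSE) {
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, fill = FALSE)
  if (nrow(raw) > 0 && is.na(suppressWarnings(as.numeric(raw[1, 1])))) {
    raw <- raw[-1, , drop = FALSE]  # header line
  }
  pick <- function(i) {
    i <- as.integer(i)
    if (i < 0) i <- ncol(raw) + 1L + i
    if (i < 1 || i > ncol(raw)) stop("column index out of range: ", i)
    raw[[i]]
  }
  chip_id <- suppressWarnings(as.integer(pick(columns$chip_id)))
  if (any(is.na(chip_id))) stop("non-integer chip ids")
  coords <- cbind(L = suppressWarnings(as.numeric(pick(columns$L))),
                  a = suppressWarnings(as.numeric(pick(columns$a))),
                  b = suppressWarnings(as.numeric(pick(columns$b))))
  if (any(is.na(coords))) stop("non-numeric coordinates")
  if (!is.null(expected_chips) && nrow(raw) != expected_chips) {
    msg <- sprintf("expected %d chips, found %d", expected_chips, nrow(raw))
    if (strict) stop(msg) else warning(msg)
  }
  color_palette(coords, chip_id = chip_id,
                lightness_row = pick(columns$lightness_row),
                hue_col = suppressWarnings(as.integer(pick(columns$hue_col))))
}

#' Write / read a palette as CSV
#'
#' Plain-text serialization with columns chip_id, row, col, L, a, b.
#'
#' @param palette a `color_palette`.
#' @param path file path.
#' @return `write_palette_csv` returns `path` invisibly; `read_palette_csv`
#'   returns a `color_palette`.
#' @export
write_palette_csv <- function(palette, path) {
  stopifnot_palette(palette)
  df <- data.frame(
    chip_id = palette$chip_id,
    row = if (is.null(palette$lightness_row)) NA_character_ else palette$lightness_row,
    col = if (is.null(palette$hue_col)) NA_integer_ else palette$hue_col,
    L = palette$coords[, 1], a = palette$coords[, 2], b = palette$coords[, 3]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_palette_csv
#' @export
read_palette_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  color_palette(as.matrix(df[, c("L", "a", "b")]), chip_id = df$chip_id,
                lightness_row = if (all(is.na(df$row))) NULL else df$row,
                hue_col = if (all(is.na(df$col))) NULL else df$col)
}
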