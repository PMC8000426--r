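#' Generate a hue x lightness grid palette
#'
#' Builds a synthetic palette with the geometry of the standard color-chip
#' chart: rows of equally spaced lightness values crossed with columns of
#' equally spaced hues at fixed chroma, laid out on a hue circle in the
#' (a*, b*) plane, plus an optional achromatic column on the L* axis.
#' All chips get a uniform prior.
#'
#' @param n_hues number of hue columns (>= 2).
#' @param n_lightness number of chromatic lightness rows (>= 1).
#' @param chroma radius of the hue circle in the (a*, b*) plane; must be > 0.
#' @param lightness_range length-2 numeric, lightness of the first and last
#'   chromatic row.
#' @param n_achromatic number of achromatic chips (a* = b* = 0) with
#'   lightness equally spaced over `achromatic_range`; 0 disables them.
#' @param achromatic_range lightness span of the achromatic chips.
#' @param jitter_sd standard deviation of optional Gaussian coordinate
#'   jitter; 0 (the default) gives a deterministic grid.
#' @param seed RNG seed for the jitter.
#' @return a `color_palette` with `n_hues * n_lightness + n_achromatic`
#'   chips. Grid metadata (hue angle, row) is kept in `lightness_row` /
#'   `hue_col` (achromatic chips get row `"A"` and column 0).
#' @export
make_grid_palette <- function(n_hues, n_lightness, chroma = 45,
                              lightness_range = c(25, 90),
                              n_achromatic = 0,
                              achromatic_range = c(15, 96),
                              jitter_sd = 0, seed = 1L) {
  if (n_hues < 2) stop("n_hues must be >= 2")
  if (n_lightness < 1) stop("n_lightness must be >= 1")
  if (chroma <= 0) stop("chroma must be positive")
  if (jitter_sd < 0) stop("jitter_sd must be nonnegative")
  theta <- 2 * pi * (seq_len(n_hues) - 1) / n_hues
  L <- if (n_lightness == 1) mean(lightness_range) else
    seq(lightness_range[1], lightness_range[2], length.out = n_lightness)
  grid <- expand.grid(hue = seq_len(n_hues), row = seq_len(n_lightness))
  coords <- cbind(L[grid$row],
                  chroma * cos(theta[grid$hue]),
                  chroma * sin(theta[grid$hue]))
  lightness_row <- LETTERS[grid$row + 1L]  # chromatic rows B, C, ...
  hue_col <- grid$hue
  if (n_achromatic > 0) {
    La <- if (n_achromatic == 1) mean(achromatic_range) else
      seq(achromatic_range[1], achromatic_range[2], length.out = n_achromatic)
    coords <- rbind(coords, cbind(La, 0, 0))
    lightness_row <- c(lightness_row, rep("A", n_achromatic))
    hue_col <- c(hue_col, rep(0L, n_achromatic))
  }
  if (jitter_sd > 0) {
    coords <- coords + with_seed(seed, matrix(
      stats::rnorm(length(coords), sd = jitter_sd), nrow(coords), 3))
  }
  color_palette(coords, lightness_row = lightness_row, hue_col = hue_col,
                meta = list(kind = "grid", n_hues = n_hues,
                            n_lightness = n_lightness, chroma = chroma))
}

#' The default 330-chip synthetic palette
#'
#' The package's standard stand-in for the 330-chip Munsell chart: 40 hues
#' x 8 chromatic lightness rows plus 10 achromatic chips, so counts and
#' bounds stated for the real chart (for instance the log2(330)-bit
#' complexity ceiling) transfer unchanged. Unlike the idealized cylinder of
#' [make_grid_palette()], the hue circle is displaced off the gray axis by
#' `hue_offset` in the a* direction, emulating the asymmetry of real
#' maximum-saturation gamuts (one side of the hue circle reaches much
#' higher chroma than the other). The offset pulls the cloud's centroid
#' away from the achromatic column, which gives the gray chips distant
#' partners; with the defaults the discrimination game is playable at
#' every discriminative-need percentile up to 80, and some targets become
#' isolated only above that -- the same usable percentile range as the
#' real chart.
#'
#' @param chroma radius of the hue circle.
#' @param hue_offset displacement of the hue-circle center along a*.
#' @param lightness_range lightness span of both the chromatic rows and
#'   the achromatic column.
#' @param jitter_sd,seed optional Gaussian coordinate jitter and its seed.
#' @return a 330-chip `color_palette`.
#' @export
wcs_stand_in_palette <- function(chroma = 45, hue_offset = 36,
                                 lightness_range = c(10, 96),
                                 jitter_sd = 2, seed = 1L) {
  n_hues <- 40L; n_lightness <- 8L; n_achromatic <- 10L
  L <- seq(lightness_range[1], lightness_range[2], length.out = n_lightness)
  theta <- 2 * pi * (seq_len(n_hues) - 1) / n_hues
  g <- expand.grid(hue = seq_len(n_hues), row = seq_len(n_lightness))
  coords <- cbind(L[g$row], hue_offset + chroma * cos(theta[g$hue]),
                  chroma * sin(theta[g$hue]))
  coords <- rbind(coords,
                  cbind(seq(lightness_range[1], lightness_range[2],
                            length.out = n_achromatic), 0, 0))
  if (jitter_sd > 0) {
    coords <- coords + with_seed(seed, matrix(
      stats::rnorm(length(coords), sd = jitter_sd), nrow(coords), 3))
  }
  color_palette(coords,
                lightness_row = c(LETTERS[g$row + 1L], rep("A", n_achromatic)),
                hue_col = c(g$hue, rep(0L, n_achromatic)),
                meta = list(kind = "wcs_stand_in"))
}

#' Generate a Gaussian-blob palette
#'
#' Places `k_blobs` well-separated Gaussian clusters of chips in 3-D color
#' space. Used for recovery tests and fast scaled-down communication games
#' where the intended category structure is known by construction; blob
#' labels are kept in `meta$blob`.
#'
#' @param k_blobs number of clusters.
#' @param n_per_blob chips per cluster.
#' @param separation distance scale between blob centers; must be > 0.
#' @param sd within-blob standard deviation per coordinate.
#' @param seed RNG seed.
#' @return a `color_palette` with `meta$blob` giving each chip's blob label.
#' @export
make_blob_palette <- function(k_blobs, n_per_blob, separation = 50, sd = 2,
                              seed = 1L) {
  if (k_blobs < 1) stop("k_blobs must be >= 1")
  if (n_per_blob < 1) stop("n_per_blob must be >= 1")
  if (separation <= 0) stop("separation must be positive")
  with_seed(seed, {
    # centers on a scaled simplex-ish random configuration, min distance
    # 'separation' enforced by rejection
    centers <- matrix(stats::rnorm(k_blobs * 3), k_blobs, 3)
    if (k_blobs > 1) {
      repeat {
        d <- stats::dist(centers)
        if (min(d) > 1e-6) break
        centers <- matrix(stats::rnorm(k_blobs * 3), k_blobs, 3)
      }
      centers <- centers / min(stats::dist(centers)) * separation
    }
    blob <- rep(seq_len(k_blobs), each = n_per_blob)
    coords <- centers[blob, , drop = FALSE] +
      matrix(stats::rnorm(k_blobs * n_per_blob * 3, sd = sd),
             k_blobs * n_per_blob, 3)
    color_palette(coords, meta = list(kind = "blob", blob = blob,
                                      centers = centers))
  })
}

#' Generate a synthetic naming system over a palette
#'
#' Picks `n_words` centroid chips by seeded farthest-point selection and
#' assigns each chip Gaussian responsibilities over the centroids:
#' P(w | c) proportional to exp(-dist(c, centroid_w)^2 / (2 softness^2)).
#' `softness = 0` gives the hard nearest-centroid partition.
#'
#' @param palette a `color_palette`.
#' @param n_words number of words (<= number of chips).
#' @param softness Gaussian kernel width in distance units; >= 0.
#' @param seed seed for the initial centroid pick.
#' @return a `naming_system` with provenance `"synthetic"`.
#' @export
make_synthetic_naming <- function(palette, n_words, softness = 0, seed = 1L) {
  stopifnot_palette(palette)
  n <- n_chips(palette)
  if (n_words < 1 || n_words > n) stop("n_words must be in [1, n_chips]")
  if (softness < 0) stop("softness must be nonnegative")
  centroids <- with_seed(seed, {
    first <- sample.int(n, 1)
    cs <- first
    while (length(cs) < n_words) {
      dmin <- apply(palette$dist[, cs, drop = FALSE], 1, min)
      dmin[cs] <- -1
      cs <- c(cs, which.max(dmin))
    }
    cs
  })
  d <- palette$dist[, centroids, drop = FALSE]  # chips x words
  if (softness == 0) {
    w <- max.col(-d, ties.method = "first")
    enc <- matrix(0, n, n_words)
    enc[cbind(seq_len(n), w)] <- 1
  } else {
    logw <- -d^2 / (2 * softness^2)
    logw <- logw - apply(logw, 1, max)
    enc <- exp(logw)
    enc <- enc / rowSums(enc)
  }
  naming_system(enc, provenance = "synthetic")
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
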