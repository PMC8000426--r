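# Independent brute-force oracles and shared fixtures.

# literal double-sum mutual information I(C;W) in bits
complexity_brute <- function(enc, prior) {
  pw <- numeric(ncol(enc))
  for (w in seq_len(ncol(enc))) {
    for (c in seq_len(nrow(enc))) pw[w] <- pw[w] + prior[c] * enc[c, w]
  }
  total <- 0
  for (c in seq_len(nrow(enc))) {
    for (w in seq_len(ncol(enc))) {
      if (enc[c, w] > 0) {
        total <- total + prior[c] * enc[c, w] * log2(enc[c, w] / pw[w])
      }
    }
  }
  total
}

# literal triple-sum I(U;W) in bits from the explicit joint
accuracy_brute <- function(enc, prior, M) {
  nw <- ncol(enc); nu <- ncol(M)
  joint <- matrix(0, nw, nu)
  for (w in seq_len(nw)) {
    for (u in seq_len(nu)) {
      for (c in seq_len(nrow(enc))) {
        joint[w, u] <- joint[w, u] + prior[c] * enc[c, w] * M[c, u]
      }
    }
  }
  pw <- rowSums(joint); pu <- colSums(joint)
  total <- 0
  for (w in seq_len(nw)) {
    for (u in seq_len(nu)) {
      if (joint[w, u] > 0) {
        total <- total + joint[w, u] * log2(joint[w, u] / (pw[w] * pu[u]))
      }
    }
  }
  total
}

# brute-force pairwise Euclidean distance matrix
dist_brute <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  d
}

# a small fixed 4-chip palette used across tests
toy_palette4 <- function() {
  color_palette(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 12, 0), c(5, 5, 9)))
}

random_row_stochastic <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}

# shared expensive fixtures, computed once per test run
.fixture_env <- new.env(parent = emptyenv())

std_palette <- function() {
  if (is.null(.fixture_env$pal)) .fixture_env$pal <- wcs_stand_in_palette()
  .fixture_env$pal
}

std_meanings <- function() {
  if (is.null(.fixture_env$me)) {
    .fixture_env$me <- build_meanings(std_palette())
  }
  .fixture_env$me
}

std_curve <- function() {
  if (is.null(.fixture_env$curve)) {
    .fixture_env$curve <- compute_ib_curve(std_meanings(), std_palette(),
                                           n_beta = 600)
  }
  .fixture_env$curve
}
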