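#' Gaussian meaning model over a palette
#'
#' The speaker is assumed to represent a target chip c not as a point but as
#' a belief m(c): a Gaussian-shaped distribution over all chips, centered at
#' c, with variance `sigma2` in squared perceptual-distance units, and
#' normalized over the discrete chip set. These meaning distributions are
#' what the complexity and accuracy measures are defined on; they play no
#' role in the discrimination game itself.
#'
#' @param palette a `color_palette`.
#' @param sigma2 variance of the Gaussian belief; default 64.
#' @return object of class `meaning_model`: list with `M` (chips x chips
#'   matrix, row c = distribution m(c) over chips u), `sigma2`.
#' @export
build_meanings <- function(palette, sigma2 = 64) {
  stopifnot_palette(palette)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  logM <- -palette$dist^2 / (2 * sigma2)
  M <- exp(logM)
  M <- M / rowSums(M)
  structure(list(M = M, sigma2 = sigma2), class = "meaning_model")
}

# mutual information (bits) of a joint distribution given as a matrix
mi_bits <- function(joint) {
  joint <- joint / sum(joint)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' Complexity of a naming system
#'
#' The informational cost of the code in bits: the mutual information
#' I(M; W) between speaker meanings and words. Because each chip determines
#' its meaning distribution, this equals I(C; W) computed from the encoder
#' P(w | c) and the chip prior, with the convention 0 log 0 = 0.
#'
#' @param ns a `naming_system` defined on `palette`.
#' @param palette a `color_palette` supplying the prior p(c).
#' @return complexity in bits (>= 0).
#' @export
complexity <- function(ns, palette) {
  stopifnot_palette(palette)
  if (nrow(ns$enc) != n_chips(palette)) stop("naming system / palette mismatch")
  mi_bits(ns$enc * palette$prior)
}

#' Accuracy of a naming system
#'
#' How much information the words carry about the world: I(U; W) under the
#' joint p(u, w) = sum_c p(c) P(w|c) m(c)(u). Equivalently the expected
#' Kullback-Leibler divergence between the listener's reconstructed meaning
#' for each word and the prior-mixture meaning; larger means a listener can
#' recover the speaker's belief more faithfully. Always <= complexity
#' (data-processing inequality along the chain W - C - U).
#'
#' @param ns a `naming_system`.
#' @param meanings a `meaning_model` from [build_meanings()].
#' @param palette a `color_palette`.
#' @return accuracy in bits (>= 0).
#' @export
accuracy <- function(ns, meanings, palette) {
  stopifnot_palette(palette)
  if (nrow(ns$enc) != n_chips(palette) || nrow(meanings$M) != n_chips(palette)) {
    stop("shape mismatch between naming system, meanings and palette")
  }
  joint <- crossprod(ns$enc * palette$prior, meanings$M)  # words x chips(u)
  mi_bits(joint)
}

# KL(m(c) || mhat_w) in nats for all chips x words.
# M: chips x u (rows strictly positive up to underflow), Mhat: words x u.
kl_to_listener <- function(M, Mhat) {
  logM <- log(pmax(M, .Machine$double.xmin))
  logMhat <- log(pmax(Mhat, .Machine$double.xmin))
  rowSums(M * logM) - M %*% t(logMhat)
}

#' One iterative-IB self-consistent update of an encoder
#'
#' Recomputes the word marginal P(w) and each word's listener meaning
#' (the posterior mixture of speaker meanings), then reassigns
#' P(w | c) proportional to P(w) exp(-beta KL\[m(c) || mhat_w\]),
#' row-normalized in log space. Iterating to a fixed point at fixed beta
#' solves the IB problem I(M;W) - beta I(U;W) locally; the objective is
#' nonincreasing across iterations.
#'
#' @param enc chips x words encoder matrix (rows sum to 1).
#' @param meanings a `meaning_model`.
#' @param palette a `color_palette`.
#' @param beta trade-off parameter, >= 1.
#' @return updated encoder matrix of the same shape.
#' @export
ib_step <- function(enc, meanings, palette, beta) {
  prior <- palette$prior
  pw <- as.numeric(crossprod(enc, prior))
  alive <- pw > 0
  joint <- crossprod(enc * prior, meanings$M)        # words x u
  Mhat <- joint
  Mhat[alive, ] <- joint[alive, , drop = FALSE] / pw[alive]
  d <- kl_to_listener(meanings$M, Mhat)              # chips x words (nats)
  logenc <- sweep(-beta * d, 2, log(pmax(pw, .Machine$double.xmin)), "+")
  logenc[, !alive] <- -Inf
  logenc <- logenc - apply(logenc, 1, max)
  out <- exp(logenc)
  out / rowSums(out)
}

ib_objective <- function(enc, meanings, palette, beta) {
  ns <- naming_system(enc, tol = 1e-6)
  complexity(ns, palette) - beta * accuracy(ns, meanings, palette)
}

# listener meanings per word: words x u
listener_meanings <- function(enc, meanings, palette) {
  pw <- as.numeric(crossprod(enc, palette$prior))
  joint <- crossprod(enc * palette$prior, meanings$M)
  joint / pmax(pw, .Machine$double.xmin)
}

# merge word groups given a grouping vector
merge_words <- function(enc, group) {
  if (max(group) == ncol(enc)) return(enc)
  do.call(cbind, lapply(seq_len(max(group)), function(g) {
    rowSums(enc[, group == g, drop = FALSE])
  }))
}

# candidate encoders that jump across merge transitions: single-linkage
# groupings of words by total-variation distance of their listener
# meanings, at progressively coarser cuts (from "just the closest pair"
# up to an absolute cut). Transitions often involve many pairs at once;
# the coarser candidates batch them.
merge_candidates <- function(enc, meanings, palette) {
  K <- ncol(enc)
  if (K < 2) return(list())
  Mhat <- listener_meanings(enc, meanings, palette)
  tv <- as.matrix(stats::dist(Mhat, method = "manhattan")) / 2
  diag(tv) <- Inf
  mn <- min(tv)
  if (!is.finite(mn)) return(list())
  close_groups <- function(cut) {
    # single-linkage components of the graph {tv < cut}
    group <- seq_len(K)
    idx <- which(tv < cut, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      a <- group[idx[r, 1]]; b <- group[idx[r, 2]]
      if (a != b) group[group == max(a, b)] <- min(a, b)
    }
    match(group, sort(unique(group)))
  }
  cuts <- unique(pmax(c(mn * 1.000001, mn * 3, mn * 10, 1e-3, 1e-2, 0.05,
                        0.2), mn * 1.000001))
  out <- list()
  sizes <- integer(0)
  for (cut in cuts) {
    g <- close_groups(cut)
    if (max(g) < K && !(max(g) %in% sizes)) {
      sizes <- c(sizes, max(g))
      out <- c(out, list(merge_words(enc, g)))
    }
  }
  out
}

# candidate encoders that jump across mass-death transitions: dropping one
# of the lowest-marginal words (words die extremely slowly under plain
# iteration -- mass decay rates within 1e-4 of 1 are common)
prune_candidates <- function(enc, prior, mass_cut = 0.02, max_cands = 3L) {
  pw <- as.numeric(crossprod(enc, prior))
  ord <- order(pw)
  ord <- ord[pw[ord] < mass_cut]
  ord <- utils::head(ord, max_cands)
  out <- lapply(ord, function(j) {
    e2 <- enc[, -j, drop = FALSE]
    rs <- rowSums(e2)
    if (any(rs < 1e-12)) return(NULL)  # some chip relied on this word
    e2 / rs
  })
  out[!vapply(out, is.null, logical(1))]
}

# iterate ib_step at fixed beta until the encoder stops moving. Plain
# iteration suffers critical slowing near merge transitions and in bands
# of quasi-degenerate chips: contraction factors approach 1 and thousands
# of iterations crawl along a broad spectrum of slow eigenmodes. Two
# validated accelerators fix this:
#   * Anderson acceleration (depth `anderson_m`): the next iterate
#     extrapolates from the recent residual history by a small least
#     squares, which collapses many slow modes at once; a safeguard
#     rejects any extrapolated step whose residual grows and restarts
#     from the plain iteration.
#   * Agglomerative shortcut: the closest words (by total variation of
#     their listener meanings, at several cuts) are test-merged and the
#     merged encoder is kept only if its relaxed IB objective is at least
#     as good -- jumping directly to the endpoint of a merge drift.
# Both are accelerators, not approximations: every jump is validated, and
# convergence is always declared on the plain-map residual.
ib_converge <- function(enc, meanings, palette, beta, tol = 1e-9,
                        max_iter = 30000L, anderson_m = 10L,
                        check_every = 30L, relax_iter = 15L,
                        max_merge_tries = 5L) {
  step <- function(x) ib_step(x, meanings, palette, beta)
  nr <- nrow(enc)
  x <- enc
  g <- step(x)
  f <- g - x
  it <- 1L
  merge_tries <- 0L
  Xh <- list(); Fh <- list()
  res_at_last_check <- Inf
  flat_checks <- 0L
  while (it < max_iter) {
    res <- max(abs(f))
    if (res < tol) return(list(enc = g, iter = it, converged = TRUE))

    # --- Anderson extrapolation from the residual history ---
    Xh <- c(Xh, list(as.vector(x)))
    Fh <- c(Fh, list(as.vector(f)))
    if (length(Xh) > anderson_m) {
      Xh <- Xh[-1]; Fh <- Fh[-1]
    }
    xn <- NULL
    if (length(Xh) >= 2) {
      k <- length(Xh)
      dF <- vapply(2:k, function(i) Fh[[i]] - Fh[[i - 1]],
                   numeric(length(Fh[[1]])))
      dX <- vapply(2:k, function(i) Xh[[i]] - Xh[[i - 1]],
                   numeric(length(Xh[[1]])))
      gamma <- tryCatch(qr.coef(qr(dF), Fh[[k]]),
                        error = function(e) NULL)
      if (!is.null(gamma) && !any(is.na(gamma))) {
        v <- Xh[[k]] + Fh[[k]] - (dX + dF) %*% gamma
        v[v < 0] <- 0
        cand <- matrix(v, nr)
        rs <- rowSums(cand)
        if (all(rs > 0)) xn <- cand / rs
      }
    }
    if (is.null(xn)) xn <- g  # plain step
    gn <- step(xn)
    fn <- gn - xn
    it <- it + 1L
    if (max(abs(fn)) > 2 * res) {
      # safeguarded fallback: discard history, take the plain step
      Xh <- list(); Fh <- list()
      xn <- g
      gn <- step(xn)
      fn <- gn - xn
      it <- it + 1L
    }
    x <- xn; g <- gn; f <- fn

    # --- agglomerative shortcut across merge transitions (rationed:
    # in soft phases merges are consistently rejected, so stop trying
    # after a couple of failures at this beta) ---
    if (it %% check_every < 2L) {
      # Two asymptotic shortcuts, both jumps to an inevitable endpoint:
      # (1) exact duplicates (identical listener meanings) are objective-
      #     neutral flat directions; merge them unconditionally -- they
      #     otherwise make the residual history numerically singular;
      # (2) words whose marginal is tiny *and* strictly decaying under
      #     the map are dying (words never revive as beta decreases);
      #     pruning them skips thousands of iterations of exponential
      #     mass decay.
      pw_x <- as.numeric(crossprod(x, palette$prior))
      pw_g <- as.numeric(crossprod(g, palette$prior))
      dying <- pw_g < 1e-6 & pw_g < 0.999 * pw_x
      cleaned <- if (any(dying)) {
        gg <- g[, !dying, drop = FALSE]
        ib_cleanup(gg / rowSums(gg), meanings, palette,
                   prune_tol = 1e-14, merge_tol = 1e-8)
      } else {
        ib_cleanup(g, meanings, palette, prune_tol = 1e-14,
                   merge_tol = 1e-8)
      }
      if (ncol(cleaned) < ncol(g)) {
        x <- cleaned
        g <- step(x)
        f <- g - x
        it <- it + 1L
        Xh <- list(); Fh <- list()
      }
      res_now <- max(abs(f))
      slow <- res_now > 0.05 * res_at_last_check
      # give up early on a hopeless stall (residual flat, far from tol,
      # all shortcuts exhausted): the caller skips this beta
      flat_checks <- if (res_now > 0.9 * res_at_last_check &&
                         res_now > 100 * tol &&
                         merge_tries >= max_merge_tries) {
        flat_checks + 1L
      } else 0L
      res_at_last_check <- res_now
      if (flat_checks >= 4L) {
        return(list(enc = g, iter = it, converged = FALSE))
      }
      if (slow && merge_tries < max_merge_tries) {
        # escalate the validation depth on consecutive rejections: slow
        # drifts with distant endpoints need a longer relaxation before
        # the jump's superiority shows in the objective
        depth <- min(100L, relax_iter * 4L^merge_tries)
        merge_tries <- merge_tries + 1L
        cands <- c(merge_candidates(g, meanings, palette),
                   if (ncol(g) > 1) prune_candidates(g, palette$prior))
        if (length(cands)) {
          base <- g
          for (j in seq_len(relax_iter)) base <- step(base)
          obj_quick <- vapply(cands, function(cand) {
            for (j in seq_len(relax_iter)) cand <- step(cand)
            ib_objective(cand, meanings, palette, beta)
          }, numeric(1))
          it <- it + relax_iter * (length(cands) + 1L)
          # deep-relax the most promising candidate against the base
          pick <- which.min(obj_quick)
          cand <- cands[[pick]]
          for (j in seq_len(depth)) {
            cand <- step(cand)
            base <- step(base)
          }
          it <- it + 2L * depth
          obj_cand <- ib_objective(cand, meanings, palette, beta)
          obj_base <- ib_objective(base, meanings, palette, beta)
          # strict acceptance: the jump already beats the slow path. A
          # word in mid mass-death (or mid-merge) can keep the base ahead
          # by a hair for thousands of iterations, so when the candidate
          # has strictly fewer words and the base carries a near-dead
          # word, a bounded concession (1e-5 bits) is allowed: the
          # iterate then converges to the post-transition fixed point,
          # which is where the slow path was headed anyway
          accepted <- obj_cand <= obj_base + 1e-9
          if (!accepted && ncol(cand) < ncol(base) &&
              min(as.numeric(crossprod(base, palette$prior))) < 1e-3 &&
              obj_cand <= obj_base + 1e-5) {
            accepted <- TRUE
          }
          if (accepted) {
            merge_tries <- 0L  # cascades may follow
            x <- cand
          } else {
            x <- base  # the relaxation itself is progress
          }
          Xh <- list(); Fh <- list()
          g <- step(x)
          f <- g - x
          it <- it + 1L
          nr <- nrow(x)
        }
      }
    }
  }
  list(enc = g, iter = it, converged = FALSE)
}

# drop words with marginal < prune_tol; merge words whose listener meanings
# coincide (total variation < merge_tol). Returns the cleaned encoder.
ib_cleanup <- function(enc, meanings, palette, prune_tol = 1e-12,
                       merge_tol = 1e-9) {
  prior <- palette$prior
  pw <- as.numeric(crossprod(enc, prior))
  keep <- pw >= prune_tol
  enc <- enc[, keep, drop = FALSE]
  pw <- pw[keep]
  K <- ncol(enc)
  if (K > 1) {
    Mhat <- crossprod(enc * prior, meanings$M) / pw
    tv <- as.matrix(stats::dist(Mhat, method = "manhattan")) / 2
    group <- integer(K)
    g <- 0L
    for (j in seq_len(K)) {
      if (group[j] == 0L) {
        g <- g + 1L
        dup <- which(group == 0L & tv[j, ] < merge_tol)
        group[dup] <- g
      }
    }
    if (max(group) < K) {
      enc <- do.call(cbind, lapply(seq_len(max(group)), function(gg) {
        rowSums(enc[, group == gg, drop = FALSE])
      }))
    }
  }
  enc / rowSums(enc)
}

#' Compute the IB theoretical-limit curve by reverse deterministic annealing
#'
#' Sweeps the trade-off parameter beta down from `beta_init` to 1, solving
#' the IB problem at each beta by iterating [ib_step()] to a fixed point,
#' warm-started from the solution at the previous (larger) beta. At the
#' high-beta end the optimal encoder is near-deterministic (maximal
#' complexity); at beta = 1 the trivial one-word encoder is optimal and
#' complexity collapses to 0. The recorded (complexity, accuracy) points
#' trace the theoretical limit: no naming system can have accuracy above
#' the curve at its complexity.
#'
#' The default annealing schedule is adaptive in the information plane:
#' the multiplicative beta step shrinks whenever a step moves the solution
#' by more than `move_max` bits (in complexity or accuracy) and grows when
#' it moves less than `move_min`, so samples concentrate around the merge
#' transitions where the curve actually bends and skip the long flat
#' stretches. A fixed geometric schedule with `n_beta` values is available
#' with `schedule = "geometric"`.
#'
#' @param meanings a `meaning_model`.
#' @param palette a `color_palette`.
#' @param beta_init top of the annealing schedule (default 2^13).
#' @param schedule `"adaptive"` (default) or `"geometric"`.
#' @param n_beta number of beta values for the geometric schedule.
#' @param move_max,move_min adaptive-schedule movement band, in bits.
#' @param tol per-beta fixed-point tolerance (max absolute encoder change).
#' @param coarse_tol,coarse_above looser fixed-point tolerance used while
#'   the recorded complexity is still above `coarse_above` bits. The
#'   high-complexity stretch of the sweep is the most expensive (hundreds
#'   of live words) and the least informative -- scored systems live far
#'   below it -- and a partially converged iterate there lies along the
#'   annealing path, i.e. along the frontier itself, so the envelope is
#'   not degraded.
#' @param max_iter per-beta iteration cap.
#' @param init_jitter magnitude of the multiplicative perturbation applied
#'   to the near-identity initial encoder (breaks exact symmetry).
#' @param keep_encoders retain the encoder at every beta (memory-heavy for
#'   large palettes; the curve itself never needs them).
#' @param verbose print progress.
#' @return object of class `ib_curve`: list with `points` (data.frame
#'   `beta`, `complexity`, `accuracy`, `n_words`, ordered by decreasing
#'   beta), `envelope` (data.frame `complexity`, `accuracy`, `beta` after
#'   upper-envelope cleanup, ordered by increasing complexity), and
#'   optionally `encoders`.
#' @export
compute_ib_curve <- function(meanings, palette, beta_init = 2^13,
                             schedule = c("adaptive", "geometric"),
                             n_beta = 400, move_max = 0.2, move_min = 0.015,
                             tol = 1e-8, coarse_tol = 1e-6, coarse_above = 6,
                             max_iter = 2000L,
                             init_jitter = 1e-3, keep_encoders = FALSE,
                             verbose = FALSE) {
  stopifnot_palette(palette)
  schedule <- match.arg(schedule)
  n <- n_chips(palette)
  # near-identity start: each chip its own word, slightly smoothed
  enc <- diag(n) * (1 - init_jitter * n) + init_jitter
  enc <- enc / rowSums(enc)

  solve_at <- function(enc, beta, tol_here = tol) {
    t0 <- proc.time()[3]
    res <- ib_converge(enc, meanings, palette, beta, tol = tol_here,
                       max_iter = max_iter)
    enc <- ib_cleanup(res$enc, meanings, palette)
    ns <- naming_system(enc, tol = 1e-6)
    list(enc = enc, iter = res$iter, secs = proc.time()[3] - t0,
         converged = res$converged,
         point = data.frame(beta = beta,
                            complexity = complexity(ns, palette),
                            accuracy = accuracy(ns, meanings, palette),
                            n_words = ncol(enc)))
  }

  pts <- list()
  encs <- list()
  record <- function(sol) {
    pts[[length(pts) + 1]] <<- sol$point
    if (keep_encoders) encs[[length(encs) + 1]] <<- sol$enc
    if (verbose) {
      message(sprintf(
        "beta %.4f: %d words, complexity %.4f bits (%d iter, %.1fs)",
        sol$point$beta, sol$point$n_words, sol$point$complexity,
        sol$iter, sol$secs))
    }
  }

  if (schedule == "geometric") {
    for (beta in exp(seq(log(beta_init), log(1), length.out = n_beta))) {
      sol <- solve_at(enc, beta)
      enc <- sol$enc
      if (sol$converged) record(sol)
    }
  } else {
    f_max <- 2; f_min <- 2^(1 / 256)
    f <- 2^(1 / 8)
    sol <- solve_at(enc, beta_init)
    enc <- sol$enc
    record(sol)
    beta <- beta_init
    prev <- sol$point
    skips <- 0L
    while (beta > 1) {
      beta_next <- max(1, beta / f)
      cand <- solve_at(enc, beta_next,
                       tol_here = if (prev$complexity > coarse_above)
                         max(tol, coarse_tol) else tol)
      move <- max(abs(cand$point$complexity - prev$complexity),
                  abs(cand$point$accuracy - prev$accuracy))
      # sample finely where the curve bends (low complexity), coarsely on
      # the long gentle high-complexity stretch; overshooting solves are
      # kept (they are converged frontier points) and only the step size
      # reacts
      allowed <- max(2 * move_min, move_max * min(1, prev$complexity / 4))
      beta <- beta_next
      enc <- cand$enc
      if (cand$converged) {
        record(cand)
        prev <- cand$point
        skips <- 0L
        if (move > allowed) {
          f <- max(f_min, sqrt(f))
        } else if (move < 0.8 * allowed) {
          f <- min(f_max, f^1.5)
        }
      } else {
        # stalled just below a transition: the drift's endpoint is
        # reached quickly at a slightly lower beta, so skip recording
        # here and continue annealing from the current iterate
        skips <- skips + 1L
        if (verbose) {
          message(sprintf("beta %.4f: stalled (%d words), skipping",
                          beta_next, ncol(enc)))
        }
        if (skips > 6L) {
          stop(sprintf("iterative IB stalled at beta = %.4f", beta_next))
        }
      }
    }
  }
  points <- do.call(rbind, pts)
  structure(list(points = points, envelope = upper_envelope(points),
                 encoders = if (keep_encoders) encs else NULL),
            class = "ib_curve")
}

# keep only points forming the concave, nondecreasing upper-left frontier
# in the (complexity, accuracy) plane
upper_envelope <- function(points) {
  p <- points[order(points$complexity, -points$accuracy), , drop = FALSE]
  # drop points dominated by one with lower complexity and >= accuracy
  keep <- cummax(p$accuracy) <= p$accuracy
  p <- p[keep, , drop = FALSE]
  # monotone-chain upper hull in (complexity, accuracy)
  hull <- list()
  for (i in seq_len(nrow(p))) {
    while (length(hull) >= 2) {
      a <- hull[[length(hull) - 1]]; b <- hull[[length(hull)]]
      cross <- (b$complexity - a$complexity) * (p$accuracy[i] - a$accuracy) -
        (b$accuracy - a$accuracy) * (p$complexity[i] - a$complexity)
      if (cross >= 0) hull[[length(hull)]] <- NULL else break
    }
    hull[[length(hull) + 1]] <- p[i, ]
  }
  env <- do.call(rbind, hull)
  rownames(env) <- NULL
  env[, c("complexity", "accuracy", "beta")]
}

#' @export
print.ib_curve <- function(x, ...) {
  cat(sprintf(
    "<ib_curve> %d beta values in [%.3g, %.3g]; complexity range [%.4g, %.4g] bits\n",
    nrow(x$points), min(x$points$beta), max(x$points$beta),
    min(x$points$complexity), max(x$points$complexity)))
  invisible(x)
}

#' Evaluate the IB curve at given complexities
#'
#' Piecewise-linear interpolation of the curve's upper envelope; constant
#' extrapolation at the maximal accuracy beyond the computed complexity
#' range.
#'
#' @param curve an `ib_curve`.
#' @param complexity_bits numeric vector of complexities (bits).
#' @return accuracies (bits) at those complexities.
#' @export
curve_accuracy_at <- function(curve, complexity_bits) {
  env <- curve$envelope
  if (nrow(env) == 1) return(rep(env$accuracy, length(complexity_bits)))
  stats::approx(env$complexity, env$accuracy, xout = complexity_bits,
                rule = 2, ties = max)$y
}

# squared distance from point (x0, y0) to segment (x1,y1)-(x2,y2),
# plus the parameter t in [0,1] of the nearest location
point_segment_dist2 <- function(x0, y0, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((x0 - x1) * dx + (y0 - y1) * dy) / len2))
  list(d2 = (x1 + t * dx - x0)^2 + (y1 + t * dy - y0)^2, t = t)
}

curve_nearest <- function(curve, point) {
  env <- curve$envelope
  x0 <- point[1]; y0 <- point[2]
  if (nrow(env) == 1) {
    return(list(dist = sqrt((env$complexity - x0)^2 + (env$accuracy - y0)^2),
                beta = env$beta, segment = 1L, t = 0))
  }
  best <- list(d2 = Inf)
  for (i in seq_len(nrow(env) - 1)) {
    s <- point_segment_dist2(x0, y0, env$complexity[i], env$accuracy[i],
                             env$complexity[i + 1], env$accuracy[i + 1])
    if (s$d2 < best$d2) best <- list(d2 = s$d2, i = i, t = s$t)
  }
  # beta interpolated log-linearly along the nearest segment
  lb <- (1 - best$t) * log(env$beta[best$i]) + best$t * log(env$beta[best$i + 1])
  list(dist = sqrt(best$d2), beta = exp(lb), segment = best$i, t = best$t)
}

#' Inefficiency of a naming system
#'
#' The Euclidean distance, in the (complexity, accuracy) plane with both
#' axes in bits, from the system's point to the nearest point of the
#' piecewise-linear theoretical-limit curve. Zero means the system sits on
#' the curve, i.e. is optimally efficient at its complexity.
#'
#' @param point either a `naming_system`-derived point given as
#'   `c(complexity, accuracy)` in bits, or a `naming_system` itself (then
#'   `meanings` and `palette` are required to score it).
#' @param curve an `ib_curve`.
#' @param meanings,palette needed only when `point` is a `naming_system`.
#' @return nonnegative inefficiency score (bits).
#' @export
inefficiency <- function(point, curve, meanings = NULL, palette = NULL) {
  if (inherits(point, "naming_system")) {
    point <- c(complexity(point, palette), accuracy(point, meanings, palette))
  }
  curve_nearest(curve, point)$dist
}

#' Best-fit trade-off parameter of a naming system
#'
#' The beta of the curve location nearest to the system's point (the beta a
#' perfectly efficient system with this trade-off would have used), with
#' log-linear interpolation of beta between curve samples.
#'
#' @inheritParams inefficiency
#' @return the fitted beta (>= 1).
#' @export
fit_beta <- function(point, curve, meanings = NULL, palette = NULL) {
  if (inherits(point, "naming_system")) {
    point <- c(complexity(point, palette), accuracy(point, meanings, palette))
  }
  curve_nearest(curve, point)$beta
}

#' Write / read an IB curve as CSV
#'
#' Columns beta, complexity_bits, accuracy_bits, n_words (the full annealing
#' path; the envelope is recomputed on read).
#'
#' @param curve an `ib_curve`.
#' @param path file path.
#' @return `write_ib_curve_csv` returns `path` invisibly; `read_ib_curve_csv`
#'   an `ib_curve` (without encoders).
#' @export
write_ib_curve_csv <- function(curve, path) {
  # full double precision: hull decisions on read are bit-stable
  df <- data.frame(beta = sprintf("%.17g", curve$points$beta),
                   complexity_bits = sprintf("%.17g", curve$points$complexity),
                   accuracy_bits = sprintf("%.17g", curve$points$accuracy),
                   n_words = curve$points$n_words)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ib_curve_csv
#' @export
read_ib_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  points <- data.frame(beta = df$beta, complexity = df$complexity_bits,
                       accuracy = df$accuracy_bits, n_words = df$n_words)
  structure(list(points = points, envelope = upper_envelope(points),
                 encoders = NULL), class = "ib_curve")
}
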