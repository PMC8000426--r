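#' Game and training configuration
#'
#' `game_config()` fixes the discrimination-game parameters: the
#' discriminative-need percentile (minimum target-distractor distance as a
#' percentile of all pairwise chip distances), the vocabulary size (1,024 by
#' default, larger than the chip count so a one-word-per-chip code is always
#' possible in principle), and whether isolated targets are dropped.
#'
#' @param percentile discriminative-need percentile in \[0, 100\].
#' @param vocab_size Speaker vocabulary size |V|.
#' @param drop_isolated_targets drop targets with no valid distractor
#'   instead of erroring.
#' @return a list of class `game_config`.
#' @export
game_config <- function(percentile = 50, vocab_size = 1024L,
                        drop_isolated_targets = FALSE) {
  if (percentile < 0 || percentile > 100) stop("percentile must be in [0, 100]")
  if (vocab_size < 1) stop("vocab_size must be >= 1")
  structure(list(percentile = percentile, vocab_size = as.integer(vocab_size),
                 drop_isolated_targets = drop_isolated_targets),
            class = "game_config")
}

#' @rdname game_config
#' @param method `"gs"` (Gumbel-Softmax relaxation of the channel during
#'   training) or `"reinforce"` (fully discrete channel, score-function
#'   gradients with a running-mean baseline and entropy bonus).
#' @param tau Gumbel-Softmax temperature (> 0); low tau means near-one-hot
#'   (discrete-like) messages, high tau near-uniform (smooth) ones.
#' @param batch_size game rounds per gradient step.
#' @param learning_rate Adam step size.
#' @param entropy_coeff weight of the Speaker entropy bonus (REINFORCE only).
#' @param max_interactions training budget in game rounds.
#' @param eval_every evaluation interval in batches.
#' @param success_threshold argmax-decoded success rate at which a run
#'   counts as converged (default 0.95).
#' @param plateau_evals,plateau_delta training stops when performance has
#'   converged: the mean training loss of the best evaluation window
#'   improved by less than `plateau_delta` (nats) over the last
#'   `plateau_evals` evaluations. The run then counts as converged iff the
#'   argmax-decoded success rate is at least `success_threshold`.
#' @param grad_clip global gradient-norm clip applied to each agent's
#'   gradient before the Adam update (guards against the runaway logit
#'   sharpening that can destabilize long runs); `Inf` disables.
#' @param speaker_hidden integer vector of Speaker hidden-layer widths
#'   (default three layers of 1,000, leaky-ReLU).
#' @param listener_embed Listener word-embedding dimension (default 5).
#' @param seed RNG seed; a run is fully determined by its configs + seed.
#' @export
train_config <- function(method = c("gs", "reinforce"), tau = 1,
                         batch_size = 1024L, learning_rate = 1e-3,
                         entropy_coeff = 0.01, max_interactions = 1e7,
                         eval_every = 50L, success_threshold = 0.95,
                         plateau_evals = 5L, plateau_delta = 2e-3,
                         grad_clip = 5,
                         speaker_hidden = c(1000L, 1000L, 1000L),
                         listener_embed = 5L, seed = 1L) {
  method <- match.arg(method)
  if (method == "gs" && tau <= 0) stop("tau must be > 0 for gs")
  if (entropy_coeff < 0) stop("entropy_coeff must be >= 0")
  structure(list(method = method, tau = tau,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, entropy_coeff = entropy_coeff,
                 max_interactions = max_interactions,
                 eval_every = as.integer(eval_every),
                 success_threshold = success_threshold,
                 plateau_evals = as.integer(plateau_evals),
                 plateau_delta = plateau_delta,
                 grad_clip = grad_clip,
                 speaker_hidden = as.integer(speaker_hidden),
                 listener_embed = as.integer(listener_embed),
                 seed = as.integer(seed)),
            class = "train_config")
}

# CIELAB inputs are divided by 100 to keep activations O(1)
scale_coords <- function(coords) coords / 100

#' Initialize Speaker parameters
#'
#' The Speaker is a feed-forward network from a (scaled) 3-D CIELAB
#' coordinate to `vocab_size` logits through leaky-ReLU hidden layers
#' (He-style Gaussian initialization).
#'
#' @param vocab_size output vocabulary size.
#' @param hidden integer vector of hidden widths.
#' @param seed RNG seed for the initialization.
#' @param input_dim input dimension (3 for CIELAB).
#' @return object of class `speaker_params`.
#' @export
init_speaker <- function(vocab_size, hidden = c(1000L, 1000L, 1000L),
                         seed = 1L, input_dim = 3L) {
  dims <- c(input_dim, hidden, vocab_size)
  with_seed(seed, {
    W <- lapply(seq_len(length(dims) - 1), function(i) {
      matrix(stats::rnorm(dims[i] * dims[i + 1], sd = sqrt(2 / dims[i])),
             dims[i], dims[i + 1])
    })
    b <- lapply(dims[-1], function(d) numeric(d))
    structure(list(W = W, b = b, alpha = 0.01, vocab_size = vocab_size),
              class = "speaker_params")
  })
}

#' Initialize Listener parameters
#'
#' The Listener holds a word-embedding table (`vocab_size` x `embed_dim`)
#' and a linear map from (scaled) chip coordinates to the same embedding
#' space; a candidate's score is the inner product of the message embedding
#' with the candidate's projection, and the position guess is the softmax
#' over the two candidate scores.
#'
#' @param vocab_size vocabulary size.
#' @param embed_dim embedding dimension (default 5).
#' @param seed RNG seed.
#' @param input_dim chip-coordinate dimension.
#' @return object of class `listener_params`.
#' @export
init_listener <- function(vocab_size, embed_dim = 5L, seed = 1L,
                          input_dim = 3L) {
  with_seed(seed, {
    structure(list(
      E = matrix(stats::rnorm(vocab_size * embed_dim, sd = 0.1),
                 vocab_size, embed_dim),
      P = matrix(stats::rnorm(input_dim * embed_dim, sd = 0.5),
                 input_dim, embed_dim),
      b = numeric(embed_dim),
      vocab_size = vocab_size, embed_dim = embed_dim),
      class = "listener_params")
  })
}

# leaky ReLU: for 0 < alpha < 1 this is just the pointwise max
leaky_relu <- function(x, alpha) pmax(x, alpha * x)

row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

# forward pass keeping intermediates for backprop; X is B x 3 (already scaled)
speaker_forward <- function(sp, X) {
  L <- length(sp$W)
  pre <- vector("list", L)
  act <- vector("list", L + 1)
  act[[1]] <- X
  for (i in seq_len(L)) {
    z <- act[[i]] %*% sp$W[[i]]
    z <- sweep(z, 2, sp$b[[i]], "+")
    pre[[i]] <- z
    act[[i + 1]] <- if (i < L) leaky_relu(z, sp$alpha) else z
  }
  logits <- act[[L + 1]]
  m <- row_max(logits)
  el <- exp(logits - m)
  p <- el / rowSums(el)
  if (any(!is.finite(p))) stop("non-finite Speaker activations")
  list(pre = pre, act = act, logits = logits, p = p,
       logp = (logits - m) - log(rowSums(el)))
}

# backprop dlogits through the MLP; returns gradients shaped like sp$W / sp$b
speaker_backward <- function(sp, fwd, dlogits) {
  L <- length(sp$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dh <- dlogits
  for (i in rev(seq_len(L))) {
    gW[[i]] <- crossprod(fwd$act[[i]], dh)
    gb[[i]] <- colSums(dh)
    if (i > 1) {
      dh <- dh %*% t(sp$W[[i]])
      dh <- dh * (sp$alpha + (1 - sp$alpha) * (fwd$pre[[i - 1]] > 0))
    }
  }
  list(W = gW, b = gb)
}

#' Speaker word distribution for chips
#'
#' @param speaker a `speaker_params`.
#' @param coords chip coordinates, one row per chip (raw CIELAB units; the
#'   fixed /100 input scaling is applied internally).
#' @return matrix of categorical probabilities, chips x vocab (rows sum to 1).
#' @export
speaker_probs <- function(speaker, coords) {
  coords <- rbind(coords)  # accept a single coordinate vector
  speaker_forward(speaker, scale_coords(coords))$p
}

#' Sample from the Gumbel-Softmax relaxation
#'
#' Draws relaxed one-hot vectors y = softmax((g + log p) / tau) with
#' g ~ Gumbel(0, 1) i.i.d. As tau -> 0 the samples approach exact one-hot
#' draws from p (by the Gumbel-max construction, argmax frequencies equal p
#' at any tau); as tau -> Inf they flatten toward uniform. Exact zeros in p
#' are handled by clamping log p at log(1e-20).
#'
#' @param p a probability vector, or a matrix of row distributions.
#' @param tau temperature, > 0.
#' @param n number of samples when `p` is a single distribution.
#' @param logp optional exact log-probabilities matching `p`. When the
#'   caller has the log-softmax available (as during training) it should
#'   be passed: the clamp applied to `log(p)` otherwise (needed for exact
#'   zeros) would put a floor of `log(1e-20)` under dead words, which at
#'   high temperature leaks a visible fraction of the relaxed sample's
#'   mass onto words the speaker never uses.
#' @return matrix of relaxed samples (rows on the simplex).
#' @export
gs_sample <- function(p, tau, n = 1L, logp = NULL) {
  if (tau <= 0) stop("tau must be > 0")
  if (is.vector(p)) {
    p <- matrix(p, n, length(p), byrow = TRUE)
    if (!is.null(logp)) logp <- matrix(logp, n, ncol(p), byrow = TRUE)
  }
  if (is.null(logp)) logp <- log(pmax(p, 1e-20))
  g <- -log(-log(matrix(stats::runif(length(p)), nrow(p), ncol(p))))
  u <- (g + logp) / tau
  u <- u - row_max(u)
  eu <- exp(u)
  eu / rowSums(eu)
}

# listener internals: project candidate coords into embedding space
listener_project <- function(lp, coords) {
  sweep(scale_coords(rbind(coords)) %*% lp$P, 2, lp$b, "+")
}

#' Listener distribution over the two candidate positions
#'
#' The message (a one-hot or relaxed vector over the vocabulary) is turned
#' into an embedding by multiplying with the embedding table; each
#' candidate chip is linearly projected into the same space; the position
#' probabilities are the softmax of the two inner products. Swapping the
#' candidates swaps the probabilities.
#'
#' @param listener a `listener_params`.
#' @param message numeric vector of length `vocab_size` (one-hot at
#'   evaluation time, relaxed during Gumbel-Softmax training), or a word
#'   index.
#' @param candidates 2 x 3 matrix of candidate chip coordinates (raw CIELAB).
#' @return numeric length-2 probability vector over positions.
#' @export
listener_position_dist <- function(listener, message, candidates) {
  if (length(message) == 1) {
    e <- listener$E[as.integer(message), ]
  } else {
    e <- as.numeric(message %*% listener$E)
  }
  v <- listener_project(listener, candidates)
  s <- as.numeric(v %*% e)
  q <- exp(s - max(s))
  q / sum(q)
}

#' Cross-entropy game loss
#'
#' @param position_dist length-2 probability vector from
#'   [listener_position_dist()].
#' @param true_position 1 or 2.
#' @return the negative log probability of the true position.
#' @export
game_loss <- function(position_dist, true_position) {
  -log(position_dist[true_position])
}

#' REINFORCE surrogate objective and its Speaker logit gradient
#'
#' Computes the per-batch surrogate mean(L + sg(L - b) log P(w)) minus an
#' entropy bonus, together with its exact gradient with respect to the
#' Speaker logits: (L - b)(onehot(w) - p) / B for the score-function part
#' plus the entropy-maximization term. Differentiating the surrogate in the
#' loss argument reproduces the Listener's ordinary backprop gradient;
#' in the log-probability argument it gives the Speaker's REINFORCE
#' gradient, unbiased for the gradient of the expected loss.
#'
#' @param p matrix of Speaker categorical distributions (batch x vocab).
#' @param words sampled word index per batch row.
#' @param losses per-round cross-entropy losses.
#' @param baseline running-mean baseline b.
#' @param entropy_coeff entropy-bonus weight.
#' @return list with `value` (scalar surrogate) and `dlogits`
#'   (batch x vocab gradient of the surrogate w.r.t. Speaker logits).
#' @export
reinforce_surrogate <- function(p, words, losses, baseline,
                                entropy_coeff = 0) {
  B <- nrow(p)
  logp <- log(pmax(p, 1e-20))
  lp_w <- logp[cbind(seq_len(B), words)]
  H <- -rowSums(p * logp)
  adv <- losses - baseline
  value <- mean(losses + adv * lp_w) - entropy_coeff * mean(H)
  dlogits <- -p * adv / B
  dlogits[cbind(seq_len(B), words)] <-
    dlogits[cbind(seq_len(B), words)] + adv / B
  if (entropy_coeff > 0) {
    dlogits <- dlogits + entropy_coeff * p * (logp + H) / B
  }
  list(value = value, dlogits = dlogits)
}

# global-norm gradient clipping over a nested parameter list
clip_grads <- function(grads, clip) {
  if (!is.finite(clip)) return(grads)
  total <- sqrt(sum(unlist(rapply(grads, function(g) sum(g^2),
                                  how = "list"))))
  if (total <= clip) return(grads)
  rapply(grads, function(g) g * (clip / total), how = "replace")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "list", classes = c("matrix", "numeric"))
}

# params/grads: nested lists of matrices/vectors with identical shape
adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk <- function(p, g, s) {
    if (is.list(p) && !is.matrix(p)) {
      out_p <- p; out_s <- s
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], s[[k]])
        out_p[[k]] <- r$p; out_s[[k]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      upd(p, g, s)
    }
  }
  walk(params, grads, state)
}

# ---- evaluation ------------------------------------------------------------

#' Argmax-decoded success rate of a Speaker/Listener pair
#'
#' Success rates are computed with the most likely word deterministically
#' chosen from the Speaker distribution (ties broken by lowest index) and
#' the Listener picking the higher-scoring candidate; an exact score tie is
#' scored as failure. `mode = "exact"` averages over every valid
#' (target, distractor) pair with its sampling weight; `mode = "sampled"`
#' Monte-Carlo estimates the same quantity.
#'
#' @param speaker,listener trained parameter objects.
#' @param palette a `color_palette`.
#' @param threshold minimum target-distractor distance.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_rounds Monte-Carlo rounds for `mode = "sampled"`.
#' @param drop_isolated_targets as in [enumerate_valid_rounds()].
#' @return success rate in \[0, 1\].
#' @export
success_rate <- function(speaker, listener, palette, threshold,
                         mode = c("exact", "sampled"), n_rounds = 10000L,
                         drop_isolated_targets = FALSE) {
  mode <- match.arg(mode)
  p <- speaker_probs(speaker, palette$coords)
  w <- max.col(p, ties.method = "first")
  proj <- listener_project(listener, palette$coords)       # chips x embed
  S <- listener$E[w, , drop = FALSE] %*% t(proj)           # target-chip x cand
  if (mode == "exact") {
    rounds <- enumerate_valid_rounds(palette, threshold,
                                     drop_isolated_targets = drop_isolated_targets)
    st <- S[cbind(rounds$target, rounds$target)]
    sd <- S[cbind(rounds$target, rounds$distractor)]
    sum(rounds$weight * (st > sd))
  } else {
    rounds <- sample_rounds(palette, threshold, n_rounds,
                            drop_isolated_targets = drop_isolated_targets)
    st <- S[cbind(rounds$target, rounds$target)]
    sd <- S[cbind(rounds$target, rounds$distractor)]
    mean(st > sd)
  }
}

# ---- training --------------------------------------------------------------

#' Train a Speaker/Listener pair on the discrimination game
#'
#' Runs minibatch training with Adam until the argmax-decoded success rate
#' reaches the convergence threshold, the success trajectory plateaus, or
#' the interaction budget is exhausted. With `method = "gs"` the Speaker's
#' message is a Gumbel-Softmax relaxed sample during training (making the
#' whole pipeline differentiable) and a discrete one-hot at evaluation;
#' with `method = "reinforce"` the channel is discrete throughout and the
#' Speaker receives score-function gradients with a running-mean baseline
#' and an entropy bonus. A run is fully reproducible from its configs and
#' seed.
#'
#' @param palette a `color_palette`.
#' @param game a `game_config`.
#' @param config a `train_config`.
#' @param verbose print evaluation progress.
#' @return object of class `train_run`: list with `speaker`, `listener`,
#'   `trajectory` (data.frame `interactions`, `success`), `converged`,
#'   `interactions`, `final_success`, `game`, `config`.
#' @export
train_agents <- function(palette, game = game_config(),
                         config = train_config(), verbose = FALSE) {
  stopifnot_palette(palette)
  threshold <- distance_threshold(palette, game$percentile)
  sets <- valid_distractor_sets(palette, threshold)
  if (length(sets$empty_targets) && !game$drop_isolated_targets) {
    stop("some targets have no valid distractor at this percentile")
  }
  with_seed(config$seed, {
    sp <- init_speaker(game$vocab_size, hidden = config$speaker_hidden,
                       seed = sample.int(2^31 - 1, 1))
    lp <- init_listener(game$vocab_size, embed_dim = config$listener_embed,
                        seed = sample.int(2^31 - 1, 1))
    sp_state <- adam_init(list(W = sp$W, b = sp$b))
    lp_state <- adam_init(list(E = lp$E, P = lp$P, b = lp$b))
    baseline <- 0
    baseline_n <- 0
    n_batches <- ceiling(config$max_interactions / config$batch_size)
    traj <- list()
    converged <- FALSE
    best_loss_hist <- numeric(0)
    window_losses <- numeric(0)
    interactions <- 0
    eval_success <- function() {
      success_rate(sp, lp, palette, threshold, mode = "exact",
                   drop_isolated_targets = game$drop_isolated_targets)
    }
    for (bi in seq_len(n_batches)) {
      rounds <- sample_rounds(palette, threshold, config$batch_size,
                              sets = sets,
                              drop_isolated_targets = game$drop_isolated_targets)
      B <- nrow(rounds)
      Xt <- scale_coords(palette$coords[rounds$target, , drop = FALSE])
      # candidate in slot 1 / slot 2 according to the target's position
      at1 <- rounds$position == 1L
      c1 <- rounds$distractor; c1[at1] <- rounds$target[at1]
      c2 <- rounds$target; c2[at1] <- rounds$distractor[at1]
      X1 <- scale_coords(palette$coords[c1, , drop = FALSE])
      X2 <- scale_coords(palette$coords[c2, , drop = FALSE])
      fwd <- speaker_forward(sp, Xt)
      v1 <- sweep(X1 %*% lp$P, 2, lp$b, "+")
      v2 <- sweep(X2 %*% lp$P, 2, lp$b, "+")

      if (config$method == "gs") {
        y <- gs_sample(fwd$p, config$tau, logp = fwd$logp)
        e <- y %*% lp$E
      } else {
        # vectorized categorical sampling via the Gumbel-max trick
        gn <- -log(-log(matrix(stats::runif(B * ncol(fwd$p)), B)))
        words <- max.col(fwd$logp + gn, ties.method = "first")
        e <- lp$E[words, , drop = FALSE]
      }
      s1 <- rowSums(e * v1)
      s2 <- rowSums(e * v2)
      mx <- pmax(s1, s2)
      z1 <- exp(s1 - mx); z2 <- exp(s2 - mx)
      q1 <- z1 / (z1 + z2)
      qt <- 1 - q1; qt[at1] <- q1[at1]
      losses <- -log(pmax(qt, 1e-30))
      if (any(!is.finite(losses))) {
        stop(sprintf("training diverged at batch %d (non-finite loss)", bi))
      }
      # listener backward (common to both methods)
      t1 <- as.numeric(rounds$position == 1L)
      ds1 <- (q1 - t1) / B
      ds2 <- -ds1
      de <- ds1 * v1 + ds2 * v2
      dv1 <- ds1 * e
      dv2 <- ds2 * e
      gP <- crossprod(X1, dv1) + crossprod(X2, dv2)
      gb <- colSums(dv1) + colSums(dv2)

      if (config$method == "gs") {
        gE <- crossprod(y, de)
        dy <- de %*% t(lp$E)
        du <- y * (dy - rowSums(dy * y))
        dlogp <- du / config$tau
        dlogits <- dlogp - fwd$p * rowSums(dlogp)
      } else {
        gE <- matrix(0, nrow(lp$E), ncol(lp$E))
        agg <- rowsum(de, group = words)
        gE[as.integer(rownames(agg)), ] <- agg
        rs <- reinforce_surrogate(fwd$p, words, losses, baseline,
                                  entropy_coeff = config$entropy_coeff)
        dlogits <- rs$dlogits
        baseline_n <- baseline_n + 1
        baseline <- baseline + (mean(losses) - baseline) / baseline_n
      }
      sp_grads <- clip_grads(speaker_backward(sp, fwd, dlogits),
                             config$grad_clip)
      r <- adam_update(list(W = sp$W, b = sp$b), sp_grads, sp_state,
                       config$learning_rate, bi)
      sp$W <- r$p$W; sp$b <- r$p$b; sp_state <- r$s
      r <- adam_update(list(E = lp$E, P = lp$P, b = lp$b),
                       clip_grads(list(E = gE, P = gP, b = gb),
                                  config$grad_clip), lp_state,
                       config$learning_rate, bi)
      lp$E <- r$p$E; lp$P <- r$p$P; lp$b <- r$p$b; lp_state <- r$s
      interactions <- interactions + B

      window_losses <- c(window_losses, mean(losses))

      if (bi %% config$eval_every == 0 || bi == n_batches) {
        succ <- eval_success()
        mean_loss <- mean(window_losses)
        window_losses <- numeric(0)
        traj[[length(traj) + 1]] <- data.frame(interactions = interactions,
                                               success = succ,
                                               mean_loss = mean_loss)
        if (verbose) {
          message(sprintf("batch %d (%d interactions): success %.3f loss %.4f",
                          bi, interactions, succ, mean_loss))
        }
        # performance has converged when the (best-so-far) training loss
        # stops improving; the run is successful iff success is also high
        best_loss_hist <- c(best_loss_hist,
                            min(mean_loss, if (length(best_loss_hist))
                              min(best_loss_hist) else Inf))
        k <- config$plateau_evals
        nb <- length(best_loss_hist)
        if (nb > k &&
            best_loss_hist[nb - k] - best_loss_hist[nb] < config$plateau_delta) {
          converged <- succ >= config$success_threshold
          break
        }
        if (succ >= config$success_threshold && bi == n_batches) {
          converged <- TRUE
        }
      }
    }
    trajectory <- do.call(rbind, traj)
    final_success <- trajectory$success[nrow(trajectory)]
    structure(list(speaker = sp, listener = lp, trajectory = trajectory,
                   converged = converged, interactions = interactions,
                   final_success = final_success, threshold = threshold,
                   game = game, config = config),
              class = "train_run")
  })
}

#' @export
print.train_run <- function(x, ...) {
  cat(sprintf(
    "<train_run> %s%s: %s after %d interactions (success %.3f)\n",
    x$config$method,
    if (x$config$method == "gs") sprintf("(tau=%g)", x$config$tau) else "",
    if (x$converged) "converged" else "not converged",
    x$interactions, x$final_success))
  invisible(x)
}
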