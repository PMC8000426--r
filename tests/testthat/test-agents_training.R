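# Speaker/Listener networks, gradient estimators, and scaled-down training.

test_that("speaker outputs are categorical distributions", {
  sp <- init_speaker(32, hidden = c(16, 16), seed = 1)
  pal <- toy_palette4()
  p <- speaker_probs(sp, pal$coords)
  expect_equal(dim(p), c(4L, 32L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-12)
  # zero weights -> uniform over the vocabulary
  sp0 <- sp
  sp0$W <- lapply(sp0$W, function(w) w * 0)
  expect_equal(speaker_probs(sp0, pal$coords)[1, ], rep(1 / 32, 32),
               tolerance = 1e-12)
  # deterministic given the init seed
  sp2 <- init_speaker(32, hidden = c(16, 16), seed = 1)
  expect_identical(speaker_probs(sp2, pal$coords), p)
})

test_that("Gumbel-Softmax samples obey the temperature limits and frequency law", {
  p <- c(0.5, 0.3, 0.15, 0.05)
  set.seed(11)
  # Gumbel-max property: argmax frequencies equal p within MC error
  y <- gs_sample(p, tau = 1, n = 1e5)
  expect_true(all(abs(rowSums(y) - 1) < 1e-12))
  freq <- tabulate(max.col(y), nbins = 4) / 1e5
  se <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(freq - p) <= 4 * se))
  # tau -> 0: essentially one-hot (at tau = 0.001 the probability of an
  # unresolvable near-tie between the top two Gumbel scores is ~0.5%)
  y0 <- gs_sample(p, tau = 0.001, n = 1e4)
  expect_gte(mean(apply(y0, 1, max) >= 0.999), 0.99)
  # tau -> Inf: essentially uniform
  yI <- gs_sample(p, tau = 1e6, n = 100)
  expect_lt(max(abs(yI - 0.25)), 1e-3)
  # zero probabilities are log-clamped, not an error
  expect_silent(gs_sample(c(1, 0, 0), tau = 1, n = 10))
  expect_error(gs_sample(p, tau = 0), "tau")
})

test_that("listener position distribution is a symmetric softmax score", {
  lp <- init_listener(16, seed = 3)
  msg <- as.numeric(stats::rmultinom(1, 1, rep(1 / 16, 16)))
  cand <- rbind(c(10, 20, 30), c(50, -10, 5))
  q <- listener_position_dist(lp, msg, cand)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  expect_equal(listener_position_dist(lp, msg, cand[2:1, ]), rev(q),
               tolerance = 1e-12)
  # zero embedding: indifferent listener
  lp0 <- lp
  lp0$E <- lp0$E * 0
  expect_equal(listener_position_dist(lp0, msg, cand), c(0.5, 0.5))
  # word-index message equals one-hot message
  expect_equal(listener_position_dist(lp, which(msg == 1), cand), q)
})

test_that("game loss is the cross-entropy of the true position", {
  expect_equal(game_loss(c(1, 0), 1), 0)
  expect_equal(game_loss(c(0.5, 0.5), 2), log(2))
  expect_equal(game_loss(c(0.8, 0.2), 2), -log(0.2))
})

test_that("REINFORCE surrogate has centered score and zero entropy gradient at uniform", {
  set.seed(21)
  p <- random_row_stochastic(6, 5)
  words <- max.col(p)
  # constant loss equal to the baseline: zero speaker gradient
  rs <- reinforce_surrogate(p, words, losses = rep(0.7, 6), baseline = 0.7)
  expect_equal(max(abs(rs$dlogits)), 0)
  # entropy term alone vanishes at the uniform distribution
  pu <- matrix(1 / 5, 6, 5)
  rs2 <- reinforce_surrogate(pu, words, losses = rep(0.7, 6), baseline = 0.7,
                             entropy_coeff = 0.5)
  expect_equal(max(abs(rs2$dlogits)), 0, tolerance = 1e-12)
})

test_that("REINFORCE speaker gradient is unbiased on an enumerable toy game", {
  # single chip, 2 words, frozen listener: loss depends only on the word
  losses_by_word <- c(0.9, 0.1)
  logits <- c(0.3, -0.2)
  p <- exp(logits) / sum(exp(logits))
  # analytic policy gradient of E_w[L(w)] wrt logits: p * (L - E[L])
  analytic <- p * (losses_by_word - sum(p * losses_by_word))
  set.seed(99)
  n <- 1e5
  words <- sample(1:2, n, replace = TRUE, prob = p)
  P <- matrix(p, n, 2, byrow = TRUE)
  rs <- reinforce_surrogate(P, words, losses = losses_by_word[words],
                            baseline = 0)
  est <- colSums(rs$dlogits)  # sum of per-sample contributions = MC mean
  per_sample <- (losses_by_word[words]) *
    (cbind(words == 1, words == 2) - P)
  se <- apply(per_sample, 2, sd) / sqrt(n)
  expect_true(all(abs(est - analytic) <= 3 * se))
})

test_that("the Gumbel-Softmax training gradient matches finite differences", {
  set.seed(31)
  V <- 4; B <- 3; tau <- 7
  sp <- init_speaker(V, hidden = c(5), seed = 1)
  lp <- init_listener(V, embed_dim = 2, seed = 2)
  Xt <- matrix(rnorm(B * 3), B, 3)
  X1 <- matrix(rnorm(B * 3), B, 3)
  X2 <- matrix(rnorm(B * 3), B, 3)
  pos <- c(1L, 2L, 1L)
  G <- -log(-log(matrix(runif(B * V), B, V)))  # fixed relaxation noise

  loss_fn <- function(sp, lp) {
    fwd <- ibcolor:::speaker_forward(sp, Xt)
    u <- (G + fwd$logp) / tau
    u <- u - apply(u, 1, max)
    y <- exp(u) / rowSums(exp(u))
    e <- y %*% lp$E
    v1 <- sweep(X1 %*% lp$P, 2, lp$b, "+")
    v2 <- sweep(X2 %*% lp$P, 2, lp$b, "+")
    q1 <- 1 / (1 + exp(rowSums(e * v2) - rowSums(e * v1)))
    qt <- ifelse(pos == 1L, q1, 1 - q1)
    mean(-log(qt))
  }

  # analytic gradients via the same algebra the trainer uses
  fwd <- ibcolor:::speaker_forward(sp, Xt)
  u <- (G + fwd$logp) / tau
  u <- u - apply(u, 1, max)
  y <- exp(u) / rowSums(exp(u))
  e <- y %*% lp$E
  v1 <- sweep(X1 %*% lp$P, 2, lp$b, "+")
  v2 <- sweep(X2 %*% lp$P, 2, lp$b, "+")
  q1 <- 1 / (1 + exp(rowSums(e * v2) - rowSums(e * v1)))
  ds1 <- (q1 - as.numeric(pos == 1L)) / B
  de <- ds1 * v1 - ds1 * v2
  gE <- crossprod(y, de)
  dy <- de %*% t(lp$E)
  du <- y * (dy - rowSums(dy * y))
  dlogp <- du / tau
  dlogits <- dlogp - fwd$p * rowSums(dlogp)
  gsp <- ibcolor:::speaker_backward(sp, fwd, dlogits)
  gP <- crossprod(X1, ds1 * e) + crossprod(X2, -ds1 * e)

  eps <- 1e-6
  fd_vs_an <- function(an, bump) {
    hi <- bump(eps); lo <- bump(-eps)
    expect_equal(an, (hi - lo) / (2 * eps), tolerance = 1e-5)
  }
  fd_vs_an(gsp$W[[1]][1, 2], function(d) {
    s2 <- sp; s2$W[[1]][1, 2] <- s2$W[[1]][1, 2] + d; loss_fn(s2, lp)
  })
  fd_vs_an(gsp$W[[2]][3, 4], function(d) {
    s2 <- sp; s2$W[[2]][3, 4] <- s2$W[[2]][3, 4] + d; loss_fn(s2, lp)
  })
  fd_vs_an(gE[2, 1], function(d) {
    l2 <- lp; l2$E[2, 1] <- l2$E[2, 1] + d; loss_fn(sp, l2)
  })
  fd_vs_an(gP[3, 2], function(d) {
    l2 <- lp; l2$P[3, 2] <- l2$P[3, 2] + d; loss_fn(sp, l2)
  })
})

test_that("training converges on a separated blob palette and is reproducible", {
  pal <- make_blob_palette(2, 4, separation = 60, sd = 2, seed = 1)
  gm <- game_config(percentile = 50, vocab_size = 16)
  cfg <- train_config(method = "gs", tau = 1, batch_size = 128,
                      speaker_hidden = c(32, 32), eval_every = 10,
                      max_interactions = 2e5, seed = 5)
  run <- train_agents(pal, gm, cfg)
  expect_true(run$converged)
  expect_gte(run$final_success, 0.95)
  run2 <- train_agents(pal, gm, cfg)
  expect_identical(run$trajectory, run2$trajectory)
  expect_identical(run$speaker$W[[1]], run2$speaker$W[[1]])
  # extraction of the converged speaker yields a compact code
  ns <- extract_naming(run$speaker, pal, seed = 1)
  expect_lte(effective_vocab(ns), 16L)
})

test_that("REINFORCE training also converges on the blob game", {
  pal <- make_blob_palette(2, 4, separation = 60, sd = 2, seed = 2)
  gm <- game_config(percentile = 50, vocab_size = 16)
  cfg <- train_config(method = "reinforce", batch_size = 128,
                      speaker_hidden = c(32, 32), eval_every = 10,
                      max_interactions = 4e5, seed = 3)
  run <- train_agents(pal, gm, cfg)
  expect_gte(run$final_success, 0.95)
  expect_true(run$converged)
})

test_that("success rate of untrained agents is near chance; exact matches sampled", {
  pal <- make_blob_palette(2, 5, separation = 40, sd = 3, seed = 4)
  thr <- distance_threshold(pal, 50)
  sp <- init_speaker(16, hidden = c(8), seed = 2)
  lp <- init_listener(16, seed = 2)
  ex <- success_rate(sp, lp, pal, thr, mode = "exact")
  expect_lt(abs(ex - 0.5), 0.35)  # untrained: near chance, not degenerate
  set.seed(8)
  sm <- success_rate(sp, lp, pal, thr, mode = "sampled", n_rounds = 4e4)
  expect_lt(abs(sm - ex), 4 * sqrt(0.25 / 4e4) + 0.02)
})
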