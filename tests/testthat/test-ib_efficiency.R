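# Meaning model, mutual-information measures, annealed IB curve, Inef score.

test_that("meaning model is the normalized Gaussian kernel", {
  pal <- toy_palette4()
  me <- build_meanings(pal, sigma2 = 64)
  expect_equal(rowSums(me$M), rep(1, 4), tolerance = 1e-12)
  # mode at the center chip
  expect_equal(max.col(me$M), 1:4)
  # closed-form likelihood ratio between center and another chip
  d <- pal$dist[1, 2]
  expect_equal(me$M[1, 1] / me$M[1, 2], exp(d^2 / 128), tolerance = 1e-9)
  # full matrix equals direct evaluation
  direct <- exp(-pal$dist^2 / (2 * 64))
  direct <- direct / rowSums(direct)
  expect_equal(me$M, direct, tolerance = 1e-12)
  expect_error(build_meanings(pal, sigma2 = 0), "sigma2")
})

test_that("complexity and accuracy match brute-force sums on random systems", {
  set.seed(101)
  pal <- color_palette(matrix(rnorm(15, sd = 20), 5, 3))
  me <- build_meanings(pal)
  for (i in 1:50) {
    enc <- random_row_stochastic(5, 3)
    ns <- naming_system(enc, tol = 1e-9)
    expect_equal(complexity(ns, pal), complexity_brute(enc, pal$prior),
                 tolerance = 1e-10)
    expect_equal(accuracy(ns, me, pal),
                 accuracy_brute(enc, pal$prior, me$M),
                 tolerance = 1e-10)
  }
})

test_that("complexity/accuracy limits and the data-processing inequality hold", {
  pal <- std_palette()
  me <- std_meanings()
  one <- naming_system(matrix(1, 330, 1))
  expect_equal(complexity(one, pal), 0)
  expect_equal(accuracy(one, me, pal), 0, tolerance = 1e-12)
  id <- naming_system(diag(330))
  expect_equal(complexity(id, pal), log2(330), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    ns <- make_synthetic_naming(pal, sample(1:40, 1),
                                softness = runif(1, 0, 25), seed = i)
    cx <- complexity(ns, pal)
    ac <- accuracy(ns, me, pal)
    expect_gte(ac, 0)
    expect_lte(ac, cx + 1e-9)
    expect_lte(cx, min(log2(ncol(ns$enc)), log2(330)) + 1e-9)
  }
})

test_that("ib_step is a fixed-point iteration that decreases the objective", {
  pal <- toy_palette4()
  me <- build_meanings(pal, sigma2 = 30)
  beta <- 3
  set.seed(2)
  enc <- random_row_stochastic(4, 4)
  obj_prev <- Inf
  for (i in 1:400) {
    obj <- complexity(naming_system(enc, tol = 1e-6), pal) -
      beta * accuracy(naming_system(enc, tol = 1e-6), me, pal)
    expect_lte(obj, obj_prev + 1e-10)
    obj_prev <- obj
    enc <- ib_step(enc, me, pal, beta)
  }
  # converged solution is a fixed point
  expect_lt(max(abs(ib_step(enc, me, pal, beta) - enc)), 1e-10)

  # at beta = 1 the trivial solution is optimal: complexity collapses
  enc1 <- random_row_stochastic(4, 4)
  for (i in 1:2000) enc1 <- ib_step(enc1, me, pal, 1)
  expect_lt(complexity(naming_system(enc1, tol = 1e-6), pal), 1e-3)
})

test_that("annealed curve on a small palette dominates all deterministic encoders", {
  set.seed(33)
  pal <- color_palette(matrix(rnorm(15, sd = 12), 5, 3))
  me <- build_meanings(pal)
  # small palette: afford a dense, high-precision sweep
  cv <- compute_ib_curve(me, pal, move_max = 0.02, move_min = 0.002,
                         tol = 1e-11)
  # exhaustive frontier over the 5^5 deterministic encoders into <= 5 words
  grid <- expand.grid(rep(list(1:5), 5))
  worst <- -Inf
  for (r in seq_len(nrow(grid))) {
    enc <- matrix(0, 5, 5)
    enc[cbind(1:5, as.integer(grid[r, ]))] <- 1
    ns <- naming_system(enc)
    cx <- complexity(ns, pal)
    ac <- accuracy(ns, me, pal)
    worst <- max(worst, ac - curve_accuracy_at(cv, cx))
  }
  expect_lte(worst, 1e-6)
  # endpoints
  pts <- cv$points
  expect_lt(pts$complexity[nrow(pts)], 1e-3)
  expect_equal(pts$complexity[1], log2(pts$n_words[1]), tolerance = 1e-3)
})

test_that("complexity and accuracy are nondecreasing in beta along the path", {
  pal <- color_palette(matrix(rnorm(24, sd = 15), 8, 3))
  me <- build_meanings(pal)
  cv <- compute_ib_curve(me, pal, n_beta = 300)
  pts <- cv$points[order(cv$points$beta), ]
  expect_true(all(diff(pts$complexity) >= -1e-6))
  expect_true(all(diff(pts$accuracy) >= -1e-6))
})

test_that("inefficiency is planar distance to the interpolated curve", {
  toy <- structure(list(
    points = data.frame(beta = c(4, 1), complexity = c(2, 0),
                        accuracy = c(1, 0), n_words = c(4, 1)),
    envelope = data.frame(complexity = c(0, 2), accuracy = c(0, 1),
                          beta = c(1, 4))), class = "ib_curve")
  # hand-computed distance from (1, 0.2) to the segment (0,0)-(2,1):
  # projection t = (1*2 + 0.2*1)/5 = 0.44 -> nearest (0.88, 0.44)
  expect_equal(inefficiency(c(1, 0.2), toy),
               sqrt((1 - 0.88)^2 + (0.2 - 0.44)^2), tolerance = 1e-12)
  # a curve point has zero inefficiency and recovers its own beta
  expect_equal(inefficiency(c(2, 1), toy), 0)
  expect_equal(fit_beta(c(2, 1), toy), 4, tolerance = 1e-9)
  # fitted beta interpolates log-linearly along the segment
  b_mid <- fit_beta(c(0.88, 0.44), toy)
  expect_equal(b_mid, exp(0.44 * log(4)), tolerance = 1e-6)

  # label invariance: permuting words never changes the score
  pal <- toy_palette4()
  me <- build_meanings(pal)
  cv <- compute_ib_curve(me, pal, n_beta = 150)
  ns <- make_synthetic_naming(pal, 3, softness = 10)
  perm <- naming_system(ns$enc[, c(2, 3, 1)])
  expect_equal(inefficiency(perm, cv, me, pal), inefficiency(ns, cv, me, pal),
               tolerance = 1e-12)
})

test_that("fitted beta is monotone along a dense curve sweep", {
  pal <- color_palette(matrix(rnorm(18, sd = 14), 6, 3))
  me <- build_meanings(pal)
  cv <- compute_ib_curve(me, pal, n_beta = 200)
  env <- cv$envelope
  fitted <- vapply(seq_len(nrow(env)), function(i) {
    fit_beta(c(env$complexity[i], env$accuracy[i]), cv)
  }, numeric(1))
  expect_true(all(diff(fitted) >= -1e-6))
})

test_that("ib curve CSV round trip preserves points and envelope", {
  pal <- toy_palette4()
  me <- build_meanings(pal)
  cv <- compute_ib_curve(me, pal, n_beta = 100)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_ib_curve_csv(cv, tf)
  cv2 <- read_ib_curve_csv(tf)
  expect_equal(cv2$points$complexity, cv$points$complexity, tolerance = 1e-12)
  expect_equal(cv2$envelope, cv$envelope, tolerance = 1e-12)
})
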