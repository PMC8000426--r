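# Sweep orchestration, trend tests, discreteness comparison, plotting.

fake_table <- function(groups, values, method = "gs", tau = 1) {
  do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(percentile = groups[i], method = method, tau = tau,
               complexity = values[[i]],
               inefficiency = values[[i]] / 10,
               success = 0.99)
  }))
}

test_that("trend test calibration: null groups reject at about the nominal rate", {
  set.seed(71)
  n_sim <- 200
  rej <- 0
  pair_rej <- 0
  n_pairs <- 3
  for (s in 1:n_sim) {
    tab <- fake_table(c(20, 50, 80),
                      list(rnorm(8), rnorm(8), rnorm(8)))
    out <- complexity_trend_test(tab)
    if (out$omnibus$p.value < 0.05) rej <- rej + 1
    pair_rej <- pair_rej + sum(out$pairwise$significant)
  }
  # omnibus level: binomial 4-sigma band around 0.05
  expect_lt(rej / n_sim, 0.05 + 4 * sqrt(0.05 * 0.95 / n_sim))
  # Bonferroni-corrected family-wise rate stays at or below alpha
  expect_lt(pair_rej / n_sim, 0.05 + 4 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("trend test power: shifted groups are detected", {
  set.seed(72)
  tab <- fake_table(c(20, 50, 80),
                    list(rnorm(10, 3), rnorm(10, 2), rnorm(10, 1)))
  out <- complexity_trend_test(tab)
  expect_lt(out$omnibus$p.value, 0.05)
  expect_equal(out$groups$n, rep(10, 3))
  # medians follow the construction
  expect_true(all(diff(out$groups$median) < 0))
})

test_that("degenerate groupings are handled", {
  tab <- fake_table(20, list(rnorm(6)))
  expect_error(complexity_trend_test(tab), "at least 2 groups")
  tab2 <- rbind(fake_table(c(20, 50), list(rnorm(6), rnorm(6))),
                fake_table(80, list(rnorm(1))))
  expect_warning(out <- complexity_trend_test(tab2), "excluding")
  expect_equal(out$excluded_groups, "80")
})

test_that("discreteness comparison annotates star tiers correctly", {
  set.seed(73)
  # identical groups: no stars
  tab_same <- rbind(
    data.frame(method = "reinforce", tau = NA, complexity = rnorm(10, 2),
               inefficiency = abs(rnorm(10, 0.05, 0.01))),
    data.frame(method = "gs", tau = 1, complexity = rnorm(10, 2),
               inefficiency = abs(rnorm(10, 0.05, 0.01))))
  out_same <- discreteness_comparison(tab_same)
  expect_equal(out_same$pairwise$complexity$stars, "")
  # strongly shifted groups: the strongest star tier
  tab_diff <- rbind(
    data.frame(method = "reinforce", tau = NA, complexity = rnorm(30, 1, 0.1),
               inefficiency = abs(rnorm(30, 0.01, 0.002))),
    data.frame(method = "gs", tau = 10, complexity = rnorm(30, 5, 0.1),
               inefficiency = abs(rnorm(30, 0.5, 0.02))))
  out_diff <- discreteness_comparison(tab_diff)
  expect_equal(out_diff$pairwise$complexity$stars, "****")
  expect_equal(out_diff$summary$n, c(30, 30))
})

test_that("run_sweep produces scored rows and resumes identically", {
  pal <- make_blob_palette(2, 4, separation = 60, sd = 2, seed = 1)
  cfg <- train_config(batch_size = 128, speaker_hidden = c(16, 16),
                      eval_every = 10, max_interactions = 1e5)
  gm <- game_config(vocab_size = 16)
  out_dir <- withr::local_tempdir()
  tab <- run_sweep(pal, curve = NULL, percentiles = c(50, 60),
                   methods = data.frame(method = "gs", tau = 1),
                   n_seeds = 1, base_config = cfg, game_template = gm,
                   seed = 2, out_dir = out_dir)
  expect_equal(nrow(tab), 2L)  # grid cells x seeds
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$success > 0.5))
  expect_true(all(!is.na(tab$complexity)))
  # successful-run filter
  expect_true(all(successful_runs(tab)$success >= 0.95))
  # resuming from the persisted artifacts reproduces identical rows
  tab2 <- run_sweep(pal, curve = NULL, percentiles = c(50, 60),
                    methods = data.frame(method = "gs", tau = 1),
                    n_seeds = 1, base_config = cfg, game_template = gm,
                    seed = 2, out_dir = out_dir)
  expect_equal(tab2$complexity, tab$complexity, tolerance = 1e-12)
  expect_equal(tab2$success, tab$success, tolerance = 1e-12)
})

test_that("information plane plot writes a figure file", {
  pal <- toy_palette4()
  me <- build_meanings(pal)
  cv <- compute_ib_curve(me, pal, n_beta = 80)
  pts <- data.frame(complexity = c(0.5, 1), accuracy = c(0.2, 0.4),
                    group = c("nn", "human"))
  out <- withr::local_tempfile(fileext = ".pdf")
  information_plane_plot(pts, cv, out = out)
  expect_true(file.exists(out))
  expect_gt(file.info(out)$size, 0)
})
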