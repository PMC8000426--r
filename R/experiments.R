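#' Run a training sweep over game and method settings
#'
#' Trains one Speaker/Listener pair per grid cell (percentile x method x
#' tau x seed replicate), extracts the 25-sample naming system from each
#' converged Speaker, and scores it (success rate, complexity, accuracy,
#' inefficiency, best-fit beta, effective vocabulary). Each cell's RNG is
#' seeded from (global seed, cell index), so a sweep is fully reproducible
#' and resumable: with `out_dir` set, finished cells are persisted as JSON
#' and skipped on rerun.
#'
#' @param palette a `color_palette`.
#' @param curve an `ib_curve` for the palette's meaning model (used for
#'   inefficiency and fitted beta; may be NULL to skip those columns).
#' @param percentiles numeric vector of discriminative-need percentiles.
#' @param methods data.frame with columns `method` ("gs"/"reinforce") and
#'   `tau`; default GS at tau = 1.
#' @param n_seeds replicates per cell.
#' @param base_config a `train_config` supplying everything but method,
#'   tau and seed.
#' @param game_template a `game_config` supplying everything but the
#'   percentile.
#' @param sigma2 meaning-model variance for scoring.
#' @param n_samples word draws per chip for the naming-system extraction.
#' @param seed global seed.
#' @param out_dir optional directory for per-run JSON artifacts
#'   (incremental persistence / resume).
#' @param verbose print per-cell progress.
#' @return data.frame (the run table) with one row per cell: the cell
#'   settings plus `converged`, `success`, `complexity`, `accuracy`,
#'   `inefficiency`, `fit_beta`, `effective_vocab`, `interactions`. Failed
#'   cells are recorded with `error` set, never aborting the sweep.
#' @export
run_sweep <- function(palette, curve = NULL, percentiles = 50,
                      methods = data.frame(method = "gs", tau = 1),
                      n_seeds = 3, base_config = train_config(),
                      game_template = game_config(), sigma2 = 64,
                      n_samples = 25, seed = 1L, out_dir = NULL,
                      verbose = FALSE) {
  stopifnot_palette(palette)
  meanings <- build_meanings(palette, sigma2 = sigma2)
  grid <- expand.grid(percentile = percentiles,
                      mi = seq_len(nrow(methods)),
                      replicate = seq_len(n_seeds))
  grid$method <- methods$method[grid$mi]
  grid$tau <- methods$tau[grid$mi]
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cell_seed <- (seed * 10007L + i * 7919L) %% (2^31 - 1)
    tag <- sprintf("p%g_%s_tau%g_rep%d", g$percentile, g$method, g$tau,
                   g$replicate)
    cache <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".json"))
    if (!is.null(out_dir) && file.exists(cache)) {
      rows[[i]] <- as.data.frame(jsonlite::read_json(cache, simplifyVector = TRUE))
      next
    }
    row <- data.frame(percentile = g$percentile, method = g$method,
                      tau = g$tau, replicate = g$replicate, seed = cell_seed,
                      converged = NA, success = NA_real_,
                      complexity = NA_real_, accuracy = NA_real_,
                      inefficiency = NA_real_, fit_beta = NA_real_,
                      effective_vocab = NA_integer_,
                      interactions = NA_real_, error = NA_character_)
    res <- tryCatch({
      cfg <- base_config
      cfg$method <- g$method
      cfg$tau <- g$tau
      cfg$seed <- as.integer(cell_seed)
      gm <- game_template
      gm$percentile <- g$percentile
      run <- train_agents(palette, gm, cfg)
      ns <- extract_naming(run$speaker, palette, n_samples = n_samples,
                           seed = cell_seed)
      row$converged <- run$converged
      row$success <- run$final_success
      row$interactions <- run$interactions
      row$complexity <- complexity(ns, palette)
      row$accuracy <- accuracy(ns, meanings, palette)
      row$effective_vocab <- effective_vocab(ns, prior = palette$prior)
      if (!is.null(curve)) {
        pt <- c(row$complexity, row$accuracy)
        row$inefficiency <- inefficiency(pt, curve)
        row$fit_beta <- fit_beta(pt, curve)
      }
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
    if (!is.null(out_dir)) {
      jsonlite::write_json(res, cache, auto_unbox = TRUE, digits = NA)
    }
    if (verbose) {
      message(sprintf("[%d/%d] %s: success %.3f complexity %.3f",
                      i, nrow(grid), tag, res$success, res$complexity))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep only successful runs
#'
#' Applies the convergence filter used by every aggregate: a run enters the
#' analysis only if its argmax-decoded success rate is at least `threshold`
#' (default 0.95).
#'
#' @param table a run table from [run_sweep()].
#' @param threshold minimum success rate.
#' @return the filtered table.
#' @export
successful_runs <- function(table, threshold = 0.95) {
  table[!is.na(table$success) & table$success >= threshold, , drop = FALSE]
}

#' Test for a complexity trend across discriminative-need groups
#'
#' Omnibus Kruskal-Wallis rank test of naming-system complexity across the
#' grouping variable (percentile by default), plus all pairwise two-sided
#' Mann-Whitney-Wilcoxon tests with Bonferroni correction.
#'
#' @param table a run table (already filtered to successful runs if
#'   desired).
#' @param grouping column name to group by (default `"percentile"`).
#' @param value column name of the tested quantity (default
#'   `"complexity"`).
#' @param alpha significance level used for the reported star annotations.
#' @return list with `omnibus` (`htest` from [stats::kruskal.test()]),
#'   `pairwise` (data.frame group1/group2/statistic/p_raw/p_bonferroni/
#'   significant), `groups` (per-group n and median), `excluded_groups`.
#' @export
complexity_trend_test <- function(table, grouping = "percentile",
                                  value = "complexity", alpha = 0.05) {
  g <- table[[grouping]]
  v <- table[[value]]
  ok <- !is.na(g) & !is.na(v)
  g <- g[ok]; v <- v[ok]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 runs: ", paste(small, collapse = ", "))
    keep <- !(as.character(g) %in% small)
    g <- g[keep]; v <- v[keep]
  }
  lv <- unique(g)
  if (length(lv) < 2) stop("need at least 2 groups with >= 2 runs")
  omnibus <- stats::kruskal.test(v, factor(g))
  pairs <- utils::combn(sort(lv), 2)
  pw <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    wt <- suppressWarnings(stats::wilcox.test(v[g == a], v[g == b]))
    data.frame(group1 = a, group2 = b, statistic = unname(wt$statistic),
               p_raw = wt$p.value)
  })
  pw <- do.call(rbind, pw)
  pw$p_bonferroni <- stats::p.adjust(pw$p_raw, method = "bonferroni")
  pw$significant <- pw$p_bonferroni < alpha
  groups <- do.call(rbind, lapply(sort(lv), function(a) {
    data.frame(group = a, n = sum(g == a), median = stats::median(v[g == a]))
  }))
  list(omnibus = omnibus, pairwise = pw, groups = groups,
       excluded_groups = small)
}

# star tier used in figure annotations
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", ""), right = TRUE)
}

#' Compare complexity and inefficiency across channel-discreteness settings
#'
#' Groups runs by training method and Gumbel-Softmax temperature (the
#' smoothness of the channel), summarizes the complexity and inefficiency
#' distributions, and performs all pairwise Mann-Whitney-Wilcoxon tests
#' with Bonferroni correction, annotated with the conventional star tiers
#' (* < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001).
#'
#' @param table a run table.
#' @param values columns to compare (default complexity and inefficiency).
#' @return list with `summary` (per-setting n / median of each value) and
#'   `pairwise` (one data.frame per value with stars).
#' @export
discreteness_comparison <- function(table,
                                    values = c("complexity", "inefficiency")) {
  setting <- ifelse(table$method == "reinforce", "reinforce",
                    sprintf("gs_tau%g", table$tau))
  res <- list()
  for (val in values) {
    v <- table[[val]]
    ok <- !is.na(v)
    s <- setting[ok]; vv <- v[ok]
    lv <- sort(unique(s))
    if (length(lv) < 2) next
    pairs <- utils::combn(lv, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      wt <- suppressWarnings(stats::wilcox.test(vv[s == a], vv[s == b]))
      data.frame(group1 = a, group2 = b, p_raw = wt$p.value)
    }))
    pw$p_bonferroni <- stats::p.adjust(pw$p_raw, method = "bonferroni")
    pw$stars <- as.character(p_stars(pw$p_bonferroni))
    res[[val]] <- pw
  }
  summary <- do.call(rbind, lapply(sort(unique(setting)), function(a) {
    sel <- setting == a
    data.frame(setting = a, n = sum(sel),
               median_complexity = stats::median(table$complexity[sel],
                                                 na.rm = TRUE),
               median_inefficiency = stats::median(table$inefficiency[sel],
                                                   na.rm = TRUE))
  }))
  list(summary = summary, pairwise = res)
}

#' Information-plane figure
#'
#' Plots the theoretical-limit curve and scored naming systems on the
#' complexity/accuracy plane (purely presentational; all dominance claims
#' are asserted numerically elsewhere).
#'
#' @param points data.frame with columns `complexity`, `accuracy` and
#'   optionally `group` (colors the points).
#' @param curve an `ib_curve`.
#' @param out optional output file (any device [ggplot2::ggsave()]
#'   understands, e.g. pdf or svg).
#' @return the ggplot object, invisibly written to `out` when given.
#' @export
information_plane_plot <- function(points, curve, out = NULL) {
  env <- curve$envelope
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(data = env,
                       ggplot2::aes(x = complexity, y = accuracy)) +
    ggplot2::geom_point(
      data = points,
      if ("group" %in% names(points)) {
        ggplot2::aes(x = complexity, y = accuracy, color = group)
      } else {
        ggplot2::aes(x = complexity, y = accuracy)
      },
      alpha = 0.7) +
    ggplot2::labs(x = "Complexity, I(M;W) bits", y = "Accuracy, I(U;W) bits") +
    ggplot2::theme_minimal()
  if (!is.null(out)) ggplot2::ggsave(out, p, width = 6, height = 4)
  invisible(p)
}
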