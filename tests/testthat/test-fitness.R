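noiseless_counts <- function(ratios_per_interval, n_timepoints = 5,
                             base = 1000) {
  # counts where each lineage's ratio to "ref" changes by a fixed factor per
  # interval; ref held constant
  tp <- seq_len(n_timepoints) - 1
  rows <- lapply(names(ratios_per_interval), function(bc) {
    tibble::tibble(barcode_id = bc, timepoint = tp,
                   count = round(base * ratios_per_interval[[bc]]^tp))
  })
  dplyr::bind_rows(
    tibble::tibble(barcode_id = "ref", timepoint = tp, count = base),
    dplyr::bind_rows(rows)
  )
}

test_that("constant count ratios give zero fitness for every lineage", {
  counts <- noiseless_counts(list(a = 1, b = 1))
  fit <- infer_fitness_reference(counts, "ref", pseudocount = 0)
  expect_equal(tidy(fit)$s_hat, rep(0, 3), tolerance = 1e-12)
  expect_equal(tidy(fit)$std_error, rep(0, 3), tolerance = 1e-12)
})

test_that("a noiseless doubling ratio recovers s = ln 2 exactly", {
  counts <- noiseless_counts(list(mut = 2))
  fit <- infer_fitness_reference(counts, "ref", pseudocount = 0)
  est <- tidy(fit)
  expect_equal(est$s_hat[est$barcode_id == "mut"], log(2), tolerance = 1e-9)
  # two-point fold change agrees with the slope on noiseless data
  fc <- fitness_fold_change(counts, 0, 4, "ref", pseudocount = 0)
  expect_equal(fc$s_fc[fc$barcode_id == "mut"], log(2), tolerance = 1e-9)
})

test_that("row-wise OLS agrees with lm()", {
  withr::local_seed(1)
  counts <- sample_counts(
    simulate_competition(tiny_pool(), competition_design(bottleneck_size = 0,
                                                         n_replicates = 1),
                         seed = 2),
    reads_per_sample = 5e4, seed = 3
  ) |> dplyr::select(barcode_id, timepoint, count)
  pool <- tiny_pool()
  refs <- pool$barcode_id[pool$genotype_label == "reference"]
  fit <- infer_fitness_reference(counts, refs)
  est <- tidy(fit)

  # independent route: per-barcode lm on the same transformed response
  n_bc <- dplyr::n_distinct(counts$barcode_id)
  totals <- counts |>
    dplyr::group_by(timepoint) |>
    dplyr::summarise(total = sum(count),
                     ref = sum(count[barcode_id %in% refs]), .groups = "drop")
  one <- counts |>
    dplyr::filter(barcode_id == est$barcode_id[7]) |>
    dplyr::left_join(totals, by = "timepoint") |>
    dplyr::mutate(y = log((count + 0.5) / (total + 0.5 * n_bc)) -
                    log((ref + 0.5) / (total + 0.5 * n_bc)))
  m <- stats::lm(y ~ timepoint, data = one)
  expect_equal(est$s_hat[7], unname(stats::coef(m)[2]), tolerance = 1e-10)
  expect_equal(est$std_error[7],
               unname(sqrt(diag(stats::vcov(m)))[2]), tolerance = 1e-10)
})

test_that("mean-fitness mode: symmetric pools give zero, differences match reference mode", {
  # identical counts at all timepoints -> all zero
  counts <- noiseless_counts(list(a = 1, b = 1, c = 1))
  fit <- infer_fitness_meanfit(counts, pseudocount = 0)
  expect_equal(tidy(fit)$s_hat, rep(0, 4), tolerance = 1e-10)
  expect_true(all(abs(fit$mean_fitness$mean_fitness) < 1e-10))
  expect_true(fit$convergence$converged)

  # two lineages with known s-difference: both modes recover the difference
  counts2 <- noiseless_counts(list(fast = 2, slow = 1))
  ref_fit <- tidy(infer_fitness_reference(counts2, "ref", pseudocount = 0))
  mean_fit <- tidy(infer_fitness_meanfit(counts2, pseudocount = 0))
  d_ref <- ref_fit$s_hat[ref_fit$barcode_id == "fast"] -
    ref_fit$s_hat[ref_fit$barcode_id == "slow"]
  d_mean <- mean_fit$s_hat[mean_fit$barcode_id == "fast"] -
    mean_fit$s_hat[mean_fit$barcode_id == "slow"]
  expect_equal(d_ref, log(2), tolerance = 1e-9)
  expect_equal(d_mean, d_ref, tolerance = 1e-9)
})

test_that("mean-fitness and reference estimates differ by a lineage-independent shift", {
  pool <- lineage_pool(n_background = 50, n_reference = 30, seed = 4)
  sim <- simulate_competition(pool, competition_design(bottleneck_size = 0,
                                                       n_replicates = 1),
                              seed = 5)
  counts <- sample_counts(sim, 1e5, seed = 6) |>
    dplyr::select(barcode_id, timepoint, count)
  refs <- pool$barcode_id[pool$genotype_label == "reference"]
  a <- tidy(infer_fitness_reference(counts, refs))
  b <- tidy(infer_fitness_meanfit(counts))
  shift <- b$s_hat[match(a$barcode_id, b$barcode_id)] - a$s_hat
  expect_lt(diff(range(shift)), 1e-3)
  # self-consistency of the converged mean-fitness series
  fitb <- infer_fitness_meanfit(counts)
  cm <- dplyr::inner_join(
    counts |> dplyr::group_by(timepoint) |>
      dplyr::mutate(f = (count + 0.5) /
                      (sum(count) + 0.5 * dplyr::n())) |>
      dplyr::ungroup(),
    tidy(fitb)[, c("barcode_id", "s_hat")], by = "barcode_id")
  xbar_check <- cm |>
    dplyr::group_by(timepoint) |>
    dplyr::summarise(xbar = sum(f * s_hat), .groups = "drop")
  expect_equal(xbar_check$xbar, fitb$mean_fitness$mean_fitness,
               tolerance = 1e-8)
})

test_that("shift invariance: a constant added to all true fitnesses cancels", {
  base_pool <- lineage_pool(n_background = 40, seed = 7)
  shifted_pool <- base_pool
  nonref <- shifted_pool$genotype_label != "reference"
  shifted_pool$base_fitness[nonref] <- shifted_pool$base_fitness[nonref] + 0.3
  refs <- base_pool$barcode_id[base_pool$genotype_label == "reference"]
  des <- competition_design(bottleneck_size = 0, n_replicates = 1)
  est <- lapply(list(base_pool, shifted_pool), function(p) {
    sim <- simulate_competition(p, des, seed = 8)
    counts <- sample_counts(sim, 1e5, seed = 9) |>
      dplyr::select(barcode_id, timepoint, count)
    tidy(infer_fitness_reference(counts, refs))
  })
  # mutant-vs-reference contrasts shift by ~0.3; pairwise mutant differences
  # are preserved
  diffs <- dplyr::inner_join(est[[1]], est[[2]], by = "barcode_id",
                             suffix = c("_base", "_shift")) |>
    dplyr::inner_join(base_pool[, c("barcode_id", "genotype_label")],
                      by = "barcode_id") |>
    dplyr::filter(genotype_label != "reference") |>
    dplyr::mutate(d = s_hat_shift - s_hat_base)
  expect_equal(mean(diffs$d), 0.3, tolerance = 0.02)
  expect_lt(stats::sd(diffs$d), 0.02)
})

test_that("fold-change estimator is noisier than the multi-timepoint slope", {
  pool <- tiny_pool(n_background = 20)
  refs <- pool$barcode_id[pool$genotype_label == "reference"]
  des <- competition_design(bottleneck_size = 0, n_replicates = 1)
  sim <- simulate_competition(pool, des, seed = 10)
  ests <- lapply(1:40, function(k) {
    counts <- sample_counts(sim, 5000, seed = 100 + k) |>
      dplyr::select(barcode_id, timepoint, count)
    slope <- tidy(infer_fitness_reference(counts, refs))
    fc <- fitness_fold_change(counts, 0, 4, refs)
    dplyr::inner_join(slope[, c("barcode_id", "s_hat")], fc,
                      by = "barcode_id")
  })
  all_est <- dplyr::bind_rows(ests, .id = "seed")
  vars <- all_est |>
    dplyr::group_by(barcode_id) |>
    dplyr::summarise(v_slope = stats::var(s_hat), v_fc = stats::var(s_fc),
                     .groups = "drop")
  expect_gt(mean(vars$v_fc), mean(vars$v_slope))
  expect_gt(mean(vars$v_fc >= vars$v_slope), 0.7)
})

test_that("bias of the slope estimator shrinks monotonically with depth", {
  pool <- tiny_pool(n_background = 20)
  refs <- pool$barcode_id[pool$genotype_label == "reference"]
  sim <- simulate_competition(pool, competition_design(bottleneck_size = 0,
                                                       n_replicates = 1),
                              seed = 11)
  truth <- sim$fitness_truth
  bias <- vapply(c(1e3, 1e4, 1e5), function(depth) {
    est <- dplyr::bind_rows(lapply(1:10, function(k) {
      counts <- sample_counts(sim, depth, seed = 200 + k) |>
        dplyr::select(barcode_id, timepoint, count)
      tidy(infer_fitness_reference(counts, refs))
    }))
    m <- dplyr::inner_join(
      est |> dplyr::group_by(barcode_id) |>
        dplyr::summarise(s_mean = mean(s_hat), .groups = "drop"),
      truth, by = "barcode_id")
    mean(abs(m$s_mean - m$s_eff))
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("estimates on well-covered lineages are insensitive to the pseudocount", {
  pool <- tiny_pool(n_background = 10)
  refs <- pool$barcode_id[pool$genotype_label == "reference"]
  sim <- simulate_competition(pool, competition_design(bottleneck_size = 0,
                                                       n_replicates = 1),
                              seed = 12)
  counts <- sample_counts(sim, 1e5, seed = 13) |>
    dplyr::select(barcode_id, timepoint, count)
  stopifnot(all(counts$count >= 50))
  a <- tidy(infer_fitness_reference(counts, refs, pseudocount = 0.1))
  b <- tidy(infer_fitness_reference(counts, refs, pseudocount = 1))
  expect_lt(max(abs(a$s_hat - b$s_hat)), 1e-3)
})

test_that("degenerate inputs are rejected with instructive errors", {
  counts <- noiseless_counts(list(a = 2))
  expect_error(fitness_fold_change(counts, 2, 2, "ref"), "differ")
  expect_error(infer_fitness_reference(counts, "absent"), "reference")
  dead_ref <- counts
  dead_ref$count[dead_ref$barcode_id == "ref" & dead_ref$timepoint > 2] <- 0L
  expect_error(infer_fitness_reference(dead_ref, "ref"),
               "mean-fitness")
  one_tp <- dplyr::filter(counts, timepoint == 0)
  expect_error(infer_fitness_reference(one_tp, "ref"), "2 timepoints")
})

test_that("2SE intervals achieve their small-sample nominal coverage", {
  # with 5 timepoints the slope has 3 residual df, so the nominal coverage
  # of a +/- 2 SE interval is P(|t_3| <= 2), not 95%
  nominal <- stats::pt(2, df = 3) - stats::pt(-2, df = 3)
  pool <- lineage_pool(seed = 14)
  refs <- pool$barcode_id[pool$genotype_label == "reference"]
  sim <- simulate_competition(pool, competition_design(bottleneck_size = 0,
                                                       n_replicates = 1),
                              seed = 15)
  counts <- sample_counts(sim, 1e5, seed = 16) |>
    dplyr::select(barcode_id, timepoint, count)
  est <- tidy(infer_fitness_reference(counts, refs, min_coverage = 20)) |>
    dplyr::inner_join(sim$fitness_truth, by = "barcode_id") |>
    dplyr::filter(!low_coverage, !is_reference)
  cov <- mean(abs(est$s_hat - est$s_eff) <= 2 * est$std_error)
  mc_se <- sqrt(nominal * (1 - nominal) / nrow(est))
  expect_lt(abs(cov - nominal), 4 * mc_se)
})
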