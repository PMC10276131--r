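test_that("replicate R-squared is 1 for identical tables and near 0 under the null", {
  tab <- tibble::tibble(barcode_id = paste0("bc", 1:500),
                        count = rpois(500, 100))
  expect_equal(replicate_r2(tab, tab)$r_squared, 1, tolerance = 1e-12)

  withr::local_seed(2)
  hits <- vapply(1:100, function(k) {
    a <- tibble::tibble(barcode_id = paste0("bc", 1:500),
                        count = stats::rpois(500, 200))
    b <- tibble::tibble(barcode_id = paste0("bc", 1:500),
                        count = sample(stats::rpois(500, 200)))
    replicate_r2(a, b)$r_squared < 0.05
  }, logical(1))
  expect_gte(sum(hits), 99)

  expect_error(replicate_r2(tab[1:2, ], tab[1:2, ]), "3 shared barcodes")
})

test_that("split halves of a high-coverage sample reproduce with R-squared > 0.9", {
  pool <- lineage_pool(seed = 3)
  sim <- simulate_competition(pool,
                              competition_design(bottleneck_size = 0,
                                                 n_replicates = 1), seed = 3)
  last <- sim$trajectories |>
    dplyr::filter(timepoint == max(timepoint))
  hi <- vapply(1:20, function(k) {
    counts <- tibble::tibble(
      barcode_id = last$barcode_id,
      count = as.integer(stats::rmultinom(1, 7e5, last$frequency)[, 1])
    )
    halves <- split_sample(counts, 2, seed = 300 + k)
    a <- dplyr::filter(halves, split == 1)
    b <- dplyr::filter(halves, split == 2)
    replicate_r2(a, b)$r_squared > 0.9
  }, logical(1))
  expect_gte(mean(hi), 0.95)
})

test_that("replicate R-squared decreases with sequencing depth", {
  pool <- lineage_pool(seed = 4)
  sim <- simulate_competition(pool,
                              competition_design(bottleneck_size = 0,
                                                 n_replicates = 1), seed = 4)
  last <- dplyr::filter(sim$trajectories, timepoint == max(timepoint))
  mean_r2 <- vapply(c(1e2, 1e3, 1e4), function(depth) {
    mean(vapply(1:10, function(k) {
      withr::local_seed(400 + k + depth)
      a <- tibble::tibble(barcode_id = last$barcode_id,
                          count = as.integer(
                            stats::rmultinom(1, depth, last$frequency)[, 1]))
      b <- tibble::tibble(barcode_id = last$barcode_id,
                          count = as.integer(
                            stats::rmultinom(1, depth, last$frequency)[, 1]))
      replicate_r2(a, b)$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r2) > 0))
})

test_that("variance decomposition reproduces the study's observation bookkeeping", {
  fitness <- study_like_fitness(seed = 5)
  vd <- variance_decomposition(fitness, study_genotype_map())
  expect_equal(nrow(vd$within_experiment), 36L)
  expect_equal(nrow(vd$across_replicate), 306L)
  expect_equal(nrow(vd$across_batch), 34L)
  expect_true(all(tidy(vd)$sd >= 0))
  expect_true(all(tidy(vd)$n >= 2))
})

test_that("all-equal fitness values give zero SDs everywhere", {
  fitness <- study_like_fitness(seed = 6) |>
    dplyr::mutate(s_hat = 0.5)
  vd <- variance_decomposition(fitness, study_genotype_map())
  expect_true(all(tidy(vd)$sd == 0))
})

test_that("SD categories order within < across-replicate < across-batch under batch noise", {
  pool <- lineage_pool(n_background = 20, n_reference = 15, n_ira1 = 8,
                       n_gpb2 = 6, seed = 7)
  refs <- pool$barcode_id[pool$genotype_label == "reference"]
  # background lineages carry distinct mutations: no within-vessel grouping
  gmap <- pool |>
    dplyr::transmute(barcode_id, genotype_label = ifelse(
      genotype_label == "background",
      paste0("bg-", dplyr::row_number()), genotype_label))
  des <- competition_design(bottleneck_size = 0, n_replicates = 3,
                            n_batches = 4)
  ok <- vapply(1:10, function(k) {
    sim <- simulate_competition(pool, des, batch_effect_model(0.1, 0.03),
                                seed = 700 + k)
    counts <- sample_counts(sim, 3e4, seed = 800 + k)
    fitness <- fit_replicates(counts, refs) |>
      dplyr::filter(!is_reference)
    vd <- variance_decomposition(fitness, gmap)
    g <- glance(vd)
    g$median_sd_within < g$median_sd_across_replicate &&
      g$median_sd_across_replicate < g$median_sd_across_batch
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("with no environmental noise the three categories are comparable", {
  pool <- lineage_pool(n_background = 20, n_reference = 15, n_ira1 = 8,
                       n_gpb2 = 6, seed = 8)
  refs <- pool$barcode_id[pool$genotype_label == "reference"]
  des <- competition_design(bottleneck_size = 0, n_replicates = 3,
                            n_batches = 4)
  sim <- simulate_competition(pool, des, batch_effect_model(0, 0), seed = 9)
  counts <- sample_counts(sim, 3e4, seed = 10)
  fitness <- fit_replicates(counts, refs) |> dplyr::filter(!is_reference)
  gmap <- pool |>
    dplyr::transmute(barcode_id, genotype_label = ifelse(
      genotype_label == "background",
      paste0("bg-", dplyr::row_number()), genotype_label))
  vd <- variance_decomposition(fitness, gmap)
  g <- glance(vd)
  meds <- c(g$median_sd_within, g$median_sd_across_replicate,
            g$median_sd_across_batch)
  expect_lt(max(meds) / min(meds), 2)
})

test_that("genotype contrast arithmetic and invariances", {
  fitness <- tibble::tibble(
    barcode_id = rep(c("a1", "a2", "b1", "b2"), 2),
    genotype_label = rep(c("A", "A", "B", "B"), 2),
    replicate_id = rep(c("r1", "r2"), each = 4),
    batch_id = "batch01",
    s_hat = c(1, 1, 0.5, 0.5, 1, 1, 0.7, 0.7)
  )
  gc <- genotype_contrast(fitness, "A", "B")
  expect_equal(sort(gc$differences$difference), c(0.3, 0.5))

  # identical values in every replicate -> all differences 0, SD 0
  same <- dplyr::mutate(fitness, s_hat = 1)
  gc0 <- genotype_contrast(same, "A", "B")
  expect_true(all(gc0$differences$difference == 0))
  expect_equal(gc0$sd_contrast, 0)

  # invariance to any per-replicate constant
  shifted <- fitness |>
    dplyr::group_by(replicate_id) |>
    dplyr::mutate(s_hat = s_hat + dplyr::cur_group_id() * 3) |>
    dplyr::ungroup()
  expect_equal(genotype_contrast(shifted, "A", "B")$sd_contrast,
               gc$sd_contrast, tolerance = 1e-12)

  # replicates missing a genotype are excluded with a message
  partial <- dplyr::filter(fitness, !(replicate_id == "r2" &
                                        genotype_label == "B"))
  expect_message(gc1 <- genotype_contrast(partial, "A", "B"), "excluding")
  expect_equal(nrow(gc1$differences), 1L)
})

test_that("shared batch deviates cancel in the contrast but not in the medians", {
  pool <- lineage_pool(n_background = 10, n_reference = 15, n_ira1 = 8,
                       n_gpb2 = 6, seed = 11)
  refs <- pool$barcode_id[pool$genotype_label == "reference"]
  des <- competition_design(bottleneck_size = 0, n_replicates = 2,
                            n_batches = 5)
  ok <- vapply(1:20, function(k) {
    sim <- simulate_competition(pool, des, batch_effect_model(0.15, 0.05),
                                seed = 1100 + k)
    counts <- sample_counts(sim, 3e4, seed = 1200 + k)
    fitness <- fit_replicates(counts, refs) |>
      dplyr::inner_join(pool[, c("barcode_id", "genotype_label")],
                        by = "barcode_id")
    gc <- genotype_contrast(fitness, "IRA1", "GPB2")
    gc$sd_contrast < min(gc$median_sds$sd_of_medians)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("condition effects: balanced designs recover, confounded designs are flagged", {
  make_design <- function(confounded, effect, sigma_batch, seed) {
    withr::local_seed(seed)
    batches <- sprintf("batch%02d", 1:2)
    rows <- tidyr::expand_grid(batch_id = batches,
                               condition = c("control", "drug"),
                               rep = 1:3)
    if (confounded) {
      rows <- dplyr::filter(rows,
                            (batch_id == "batch01") == (condition == "drug"))
    }
    delta <- stats::setNames(stats::rnorm(2, 0, sigma_batch), batches)
    rows$s_hat <- 0.2 + effect * (rows$condition == "drug") +
      delta[rows$batch_id] + stats::rnorm(nrow(rows), 0, 0.01)
    rows
  }

  balanced <- make_design(FALSE, effect = 0.1, sigma_batch = 0, seed = 1)
  out <- estimate_condition_effect(balanced, "drug", "control")
  expect_false(out$confounded)
  expect_lt(abs(out$effect - 0.1), 0.03) # |noise| ~ N(0, 0.0058)

  miss <- vapply(1:40, function(k) {
    conf <- make_design(TRUE, effect = 0.1, sigma_batch = 0.15, seed = 10 + k)
    out <- estimate_condition_effect(conf, "drug", "control")
    expect_true(out$confounded)
    abs(out$effect - 0.1) > 2 * out$se_naive
  }, logical(1))
  expect_gte(mean(miss), 0.5)

  one <- dplyr::filter(balanced, condition == "control")
  expect_error(estimate_condition_effect(one), "two conditions")
  tiny <- balanced[c(1, 4), ]
  expect_error(estimate_condition_effect(tiny, "drug", "control"),
               "fewer than 2")
})

test_that("box statistics follow the hinge, whisker, and notch formulas", {
  b <- summarize_box(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3)
  expect_equal(b$lower_hinge, 2)
  expect_equal(b$upper_hinge, 4)
  expect_equal(b$iqr, 2)
  expect_equal(b$notch_halfwidth, 1.58 * 2 / sqrt(5))

  one <- summarize_box(7)
  expect_equal(one$median, 7)
  expect_equal(one$lower_hinge, 7)
  expect_equal(one$iqr, 0)
  expect_equal(one$notch_halfwidth, 0)

  # brute-force whisker rule: largest value within 1.5 IQR of the upper hinge
  v <- c(0, 0, 0, 100)
  bx <- summarize_box(v)
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(bx$whisker_high, max(v[v <= q[2] + 1.5 * (q[2] - q[1])]))
  expect_equal(bx$whisker_high, 0)

  expect_error(summarize_box(numeric(0)), "no values")
})
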