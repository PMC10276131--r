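#' Reproducibility of a technical replicate pair
#'
#' Compares barcode abundances between two halves of a split sample (PCR or
#' extraction technical replicates): pseudocount-regularised frequencies are
#' computed over the union of barcodes (a barcode absent from one member is
#' retained at pseudocount level — dropping it would bias the comparison
#' upward), transformed, and summarised as the squared Pearson correlation.
#'
#' @param table_a,table_b Count tibbles with columns `barcode_id`, `count`
#'   (one sample each).
#' @param pseudocount Reads added per barcode before forming frequencies.
#' @param transform `"log10"` (default) or `"raw"` frequencies.
#' @return One-row tibble: `r_squared`, `n_barcodes`, mean coverage and
#'   coverage class of each member, `transform`.
#' @export
replicate_r2 <- function(table_a, table_b, pseudocount = 0.5,
                         transform = c("log10", "raw")) {
  transform <- match.arg(transform)
  stopifnot(all(c("barcode_id", "count") %in% names(table_a)),
            all(c("barcode_id", "count") %in% names(table_b)))
  merged <- dplyr::full_join(
    dplyr::select(table_a, "barcode_id", count_a = "count"),
    dplyr::select(table_b, "barcode_id", count_b = "count"),
    by = "barcode_id"
  ) |>
    tidyr::replace_na(list(count_a = 0, count_b = 0))
  n <- nrow(merged)
  if (n < 3) {
    stop("need at least 3 shared barcodes to compare replicates",
         call. = FALSE)
  }
  fa <- (merged$count_a + pseudocount) / (sum(merged$count_a) + pseudocount * n)
  fb <- (merged$count_b + pseudocount) / (sum(merged$count_b) + pseudocount * n)
  if (transform == "log10") {
    fa <- log10(fa)
    fb <- log10(fb)
  }
  cov_class <- function(m) {
    if (m < 20) "low" else if (m <= 600) "moderate" else "high"
  }
  mean_a <- sum(merged$count_a) / n
  mean_b <- sum(merged$count_b) / n
  tibble::tibble(
    r_squared = stats::cor(fa, fb)^2,
    n_barcodes = n,
    mean_reads_a = mean_a,
    mean_reads_b = mean_b,
    coverage_class_a = cov_class(mean_a),
    coverage_class_b = cov_class(mean_b),
    transform = transform
  )
}

#' Decompose fitness variation into within/between-replicate/between-batch
#'
#' Descriptive decomposition of fitness variation. Three categories of
#' standard deviations (sample SD, `n - 1` denominator) are collected:
#'
#' * `within_experiment` — across the lineages of one genotype group
#'   competing in the same vessel, one SD per (experiment, genotype group)
#'   with at least 2 member lineages: sampling noise only, no environmental
#'   differences.
#' * `across_replicate` — for one barcode across the replicate experiments of
#'   one batch (at least 2 replicates): adds replicate-level environmental
#'   variation.
#' * `across_batch` — for one barcode across all replicates of all batches:
#'   adds batch-level environmental variation.
#'
#' The two lineage-wise categories are restricted to barcodes observed in at
#' least 2 batches (pool lineages tracked across the whole study);
#' batch-specific spike-ins, such as engineered genotype sets present in a
#' single batch, contribute to the within-experiment category only. Groups
#' with fewer than 2 members are skipped and counted in `skipped`.
#'
#' @param fitness Tibble with columns `barcode_id`, `replicate_id`,
#'   `batch_id`, `s_hat` (one fitness estimate per barcode and replicate
#'   experiment).
#' @param genotype_map Optional tibble (`barcode_id`, `genotype_label`);
#'   required for the within-experiment category unless `fitness` already
#'   carries `genotype_label`.
#' @return An object of class `variance_decomposition` with the three
#'   observation tibbles, per-category [summarize_box()] statistics, and skip
#'   counts. `tidy()` returns all observations in long form.
#' @export
variance_decomposition <- function(fitness, genotype_map = NULL) {
  req <- c("barcode_id", "replicate_id", "batch_id", "s_hat")
  missing <- setdiff(req, names(fitness))
  if (length(missing) > 0) {
    stop("fitness table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(genotype_map)) {
    fitness <- dplyr::left_join(
      dplyr::select(fitness, -dplyr::any_of("genotype_label")),
      genotype_map, by = "barcode_id"
    )
  }
  if (!"genotype_label" %in% names(fitness)) {
    stop("supply genotype_map or a genotype_label column", call. = FALSE)
  }

  fitness <- dplyr::mutate(
    fitness,
    experiment_id = paste(.data$batch_id, .data$replicate_id, sep = "/")
  )

  within_all <- fitness |>
    dplyr::filter(!is.na(.data$genotype_label)) |>
    dplyr::group_by(.data$experiment_id, .data$genotype_label) |>
    dplyr::summarise(sd = stats::sd(.data$s_hat), n = dplyr::n(),
                     .groups = "drop")
  within <- dplyr::filter(within_all, .data$n >= 2)

  n_batches_per_bc <- fitness |>
    dplyr::distinct(.data$barcode_id, .data$batch_id) |>
    dplyr::count(.data$barcode_id, name = "n_batches")
  multi_batch <- n_batches_per_bc$barcode_id[n_batches_per_bc$n_batches >= 2]
  lineage_tbl <- dplyr::filter(fitness, .data$barcode_id %in% multi_batch)

  across_rep_all <- lineage_tbl |>
    dplyr::group_by(.data$barcode_id, .data$batch_id) |>
    dplyr::summarise(sd = stats::sd(.data$s_hat), n = dplyr::n(),
                     .groups = "drop")
  across_rep <- dplyr::filter(across_rep_all, .data$n >= 2)

  across_batch_all <- lineage_tbl |>
    dplyr::group_by(.data$barcode_id) |>
    dplyr::summarise(sd = stats::sd(.data$s_hat), n = dplyr::n(),
                     .groups = "drop")
  across_batch <- dplyr::filter(across_batch_all, .data$n >= 2)

  box_or_empty <- function(v, category) {
    if (length(v[!is.na(v)]) == 0) {
      return(tibble::tibble(category = category, n = 0L))
    }
    dplyr::mutate(summarize_box(v), category = category)
  }
  summary <- dplyr::bind_rows(
    box_or_empty(within$sd, "within_experiment"),
    box_or_empty(across_rep$sd, "across_replicate"),
    box_or_empty(across_batch$sd, "across_batch")
  ) |>
    dplyr::relocate("category")

  structure(
    list(
      within_experiment = within,
      across_replicate = across_rep,
      across_batch = across_batch,
      summary = summary,
      skipped = c(
        within_experiment = nrow(within_all) - nrow(within),
        across_replicate = nrow(across_rep_all) - nrow(across_rep),
        across_batch = nrow(across_batch_all) - nrow(across_batch)
      )
    ),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Fitness variance decomposition (SD observations per category):\n")
  cat(sprintf("  within experiment: %4d obs, median SD %.4g\n",
              nrow(x$within_experiment),
              stats::median(x$within_experiment$sd)))
  cat(sprintf("  across replicates: %4d obs, median SD %.4g\n",
              nrow(x$across_replicate),
              stats::median(x$across_replicate$sd)))
  cat(sprintf("  across batches:    %4d obs, median SD %.4g\n",
              nrow(x$across_batch), stats::median(x$across_batch$sd)))
  if (sum(x$skipped) > 0) {
    cat("  skipped groups with < 2 members:", sum(x$skipped), "\n")
  }
  invisible(x)
}

#' @method tidy variance_decomposition
#' @export
tidy.variance_decomposition <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$within_experiment, category = "within_experiment",
                     group = paste(.data$experiment_id, .data$genotype_label),
                     sd = .data$sd, n = .data$n),
    dplyr::transmute(x$across_replicate, category = "across_replicate",
                     group = paste(.data$barcode_id, .data$batch_id),
                     sd = .data$sd, n = .data$n),
    dplyr::transmute(x$across_batch, category = "across_batch",
                     group = .data$barcode_id, sd = .data$sd, n = .data$n)
  )
}

#' @method glance variance_decomposition
#' @export
glance.variance_decomposition <- function(x, ...) {
  tibble::tibble(
    n_within = nrow(x$within_experiment),
    n_across_replicate = nrow(x$across_replicate),
    n_across_batch = nrow(x$across_batch),
    median_sd_within = stats::median(x$within_experiment$sd),
    median_sd_across_replicate = stats::median(x$across_replicate$sd),
    median_sd_across_batch = stats::median(x$across_batch$sd)
  )
}

#' Per-replicate fitness contrast between two genotype classes
#'
#' For every replicate experiment containing both genotypes, the mean fitness
#' of genotype A minus the mean of genotype B. Because replicate- and
#' batch-level environmental shifts move lineages of both genotypes together
#' (when they share environmental sensitivity), the shift cancels in the
#' contrast: its SD across replicates is typically far smaller than the SD of
#' either genotype's per-replicate medians.
#'
#' @param fitness Tibble with `barcode_id`, `replicate_id`, `batch_id`,
#'   `s_hat`, and `genotype_label` (or supply `genotype_map`).
#' @param genotype_a,genotype_b Genotype labels to contrast (A minus B).
#' @param genotype_map Optional (`barcode_id`, `genotype_label`) tibble.
#' @return An object of class `genotype_contrast`: the per-replicate
#'   differences tibble, the SD across them, and the per-genotype
#'   per-replicate medians with their SDs for comparison.
#' @export
genotype_contrast <- function(fitness, genotype_a, genotype_b,
                              genotype_map = NULL) {
  if (!is.null(genotype_map)) {
    fitness <- dplyr::left_join(
      dplyr::select(fitness, -dplyr::any_of("genotype_label")),
      genotype_map, by = "barcode_id"
    )
  }
  stopifnot("genotype_label" %in% names(fitness))
  fitness <- dplyr::mutate(
    fitness,
    experiment_id = paste(.data$batch_id, .data$replicate_id, sep = "/")
  )
  per_rep <- fitness |>
    dplyr::filter(.data$genotype_label %in% c(genotype_a, genotype_b)) |>
    dplyr::group_by(.data$experiment_id, .data$genotype_label) |>
    dplyr::summarise(
      mean_s = mean(.data$s_hat),
      median_s = stats::median(.data$s_hat),
      .groups = "drop"
    )
  wide <- per_rep |>
    dplyr::select("experiment_id", "genotype_label", "mean_s") |>
    tidyr::pivot_wider(names_from = "genotype_label",
                       values_from = "mean_s")
  keep <- stats::complete.cases(wide[, c(genotype_a, genotype_b)])
  excluded <- wide$experiment_id[!keep]
  if (length(excluded) > 0) {
    message("excluding replicate(s) missing a genotype: ",
            paste(excluded, collapse = ", "))
  }
  wide <- wide[keep, ]
  differences <- tibble::tibble(
    experiment_id = wide$experiment_id,
    difference = wide[[genotype_a]] - wide[[genotype_b]]
  )
  median_sds <- per_rep |>
    dplyr::filter(.data$experiment_id %in% wide$experiment_id) |>
    dplyr::group_by(.data$genotype_label) |>
    dplyr::summarise(sd_of_medians = stats::sd(.data$median_s),
                     .groups = "drop")

  structure(
    list(
      genotype_a = genotype_a,
      genotype_b = genotype_b,
      differences = differences,
      sd_contrast = stats::sd(differences$difference),
      median_sds = median_sds,
      excluded = excluded
    ),
    class = "genotype_contrast"
  )
}

#' @export
print.genotype_contrast <- function(x, ...) {
  cat(sprintf(
    "Genotype contrast %s - %s over %d replicate(s): SD of contrast = %.4g\n",
    x$genotype_a, x$genotype_b, nrow(x$differences), x$sd_contrast
  ))
  for (i in seq_len(nrow(x$median_sds))) {
    cat(sprintf("  SD of %s per-replicate medians: %.4g\n",
                x$median_sds$genotype_label[i], x$median_sds$sd_of_medians[i]))
  }
  invisible(x)
}

#' @method tidy genotype_contrast
#' @export
tidy.genotype_contrast <- function(x, ...) x$differences

#' @method glance genotype_contrast
#' @export
glance.genotype_contrast <- function(x, ...) {
  tibble::tibble(
    genotype_a = x$genotype_a,
    genotype_b = x$genotype_b,
    n_replicates = nrow(x$differences),
    mean_difference = mean(x$differences$difference),
    sd_contrast = x$sd_contrast
  )
}

#' Estimate a condition effect with a batch-confounding diagnostic
#'
#' The difference of condition means with its naive standard error (the
#' per-condition `sigma / sqrt(n)` terms combined) — the precision a study
#' reports when it treats replicates from different batches as independent.
#' The diagnostic compares that naive SE to the spread of per-batch condition
#' means and flags the fully confounded design where each batch contains only
#' one condition: there the batch effect is inseparable from the condition
#' effect and the naive SE overstates precision.
#'
#' @param fitness Tibble with columns `condition`, `batch_id`, and `s_hat`
#'   (one row per replicate measurement).
#' @param condition_a,condition_b The two condition labels (A minus B);
#'   defaults to the sorted unique conditions, which must number exactly 2.
#' @return One-row tibble: `effect`, `se_naive`, per-condition ns, the number
#'   of batches containing both conditions, the batch-aware SE of the effect
#'   (SD of per-batch differences / sqrt(#batches), `NA` when fewer than 2
#'   batches have both conditions), the SD of condition-centred per-batch
#'   means, and the `confounded` flag.
#' @export
estimate_condition_effect <- function(fitness, condition_a = NULL,
                                      condition_b = NULL) {
  stopifnot(all(c("condition", "batch_id", "s_hat") %in% names(fitness)))
  conds <- sort(unique(fitness$condition))
  if (length(conds) < 2) {
    stop("need two conditions to estimate an effect", call. = FALSE)
  }
  if (is.null(condition_a)) condition_a <- conds[1]
  if (is.null(condition_b)) condition_b <- conds[2]
  a <- fitness$s_hat[fitness$condition == condition_a]
  b <- fitness$s_hat[fitness$condition == condition_b]
  if (length(a) < 2 || length(b) < 2) {
    stop("standard error undefined with fewer than 2 replicates per condition",
         call. = FALSE)
  }
  se_naive <- sqrt(stats::sd(a)^2 / length(a) + stats::sd(b)^2 / length(b))

  batch_means <- fitness |>
    dplyr::filter(.data$condition %in% c(condition_a, condition_b)) |>
    dplyr::group_by(.data$batch_id, .data$condition) |>
    dplyr::summarise(mean_s = mean(.data$s_hat), .groups = "drop")
  both <- batch_means |>
    dplyr::count(.data$batch_id) |>
    dplyr::filter(.data$n == 2)
  confounded <- nrow(both) == 0

  batch_diffs <- batch_means |>
    dplyr::filter(.data$batch_id %in% both$batch_id) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_s")
  se_batch_aware <- if (nrow(batch_diffs) >= 2) {
    stats::sd(batch_diffs[[condition_a]] - batch_diffs[[condition_b]]) /
      sqrt(nrow(batch_diffs))
  } else {
    NA_real_
  }
  centred <- batch_means |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(centred = .data$mean_s - mean(.data$mean_s)) |>
    dplyr::ungroup()

  tibble::tibble(
    condition_a = condition_a,
    condition_b = condition_b,
    effect = mean(a) - mean(b),
    se_naive = se_naive,
    n_a = length(a),
    n_b = length(b),
    n_batches_with_both = nrow(both),
    se_batch_aware = se_batch_aware,
    sd_batch_means = stats::sd(centred$centred),
    confounded = confounded
  )
}

#' Boxplot summary statistics
#'
#' Hinges at the 25th/75th percentiles (linear interpolation, the continuous
#' type-7 convention), whiskers at the most extreme values within 1.5 x IQR
#' of the hinges, and a notch half-width of `1.58 * IQR / sqrt(n)` — a
#' roughly 95% confidence interval around the median.
#'
#' @param values Numeric vector (length >= 1; NAs dropped).
#' @return One-row tibble: `n`, `median`, `lower_hinge`, `upper_hinge`,
#'   `iqr`, `whisker_low`, `whisker_high`, `notch_halfwidth`.
#' @examples
#' summarize_box(c(1, 2, 3, 4, 5))
#' @export
summarize_box <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to summarise", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  tibble::tibble(
    n = length(values),
    median = q[2],
    lower_hinge = q[1],
    upper_hinge = q[3],
    iqr = iqr,
    whisker_low = min(values[values >= q[1] - 1.5 * iqr]),
    whisker_high = max(values[values <= q[3] + 1.5 * iqr]),
    notch_halfwidth = 1.58 * iqr / sqrt(length(values))
  )
}
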