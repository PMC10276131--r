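#' @title Log-linear fitness inference from barcode count trajectories
#' @description Fitness here is the log-linear rate of change of a lineage's
#'   frequency per unit competition time, estimated by ordinary least squares
#'   on log frequencies, benchmarked either against the aggregated counts of
#'   spiked-in neutral reference lineages or against an iteratively
#'   re-estimated population mean fitness.
#' @name fitness-inference
NULL

# counts tibble (barcode_id, timepoint, count) -> complete wide matrix
count_matrix <- function(counts) {
  stopifnot(all(c("barcode_id", "timepoint", "count") %in% names(counts)))
  wide <- counts |>
    dplyr::group_by(.data$barcode_id, .data$timepoint) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::complete(.data$barcode_id, .data$timepoint,
                    fill = list(count = 0)) |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "count")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  tp <- as.numeric(colnames(mat))
  ord <- order(tp)
  list(counts = mat[, ord, drop = FALSE], barcodes = wide$barcode_id,
       timepoints = tp[ord])
}

# pseudocount-regularised frequencies: (c + pc) / (total + pc * n_barcodes)
pseudo_freq <- function(count_mat, pseudocount) {
  totals <- colSums(count_mat) + pseudocount * nrow(count_mat)
  sweep(count_mat + pseudocount, 2, totals, "/")
}

# row-wise OLS of y (matrix) on t: slope and residual standard error
ols_slopes <- function(y, t) {
  n <- length(t)
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- as.vector(y %*% tc) / sxx
  intercept <- rowMeans(y) - slope * mean(t)
  fitted <- outer(slope, t) + intercept
  rss <- rowSums((y - fitted)^2)
  se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else rep(NA_real_, nrow(y))
  list(slope = slope, se = se)
}

#' Infer fitness relative to spiked-in reference lineages
#'
#' Aggregates the raw counts of the reference barcodes into a single
#' reference frequency per timepoint (pooling maximises effective depth as
#' the references are diluted out by adaptive mutants), forms
#' `y_i(t) = ln f_i(t) - ln f_ref(t)`, and fits an ordinary least-squares
#' slope per barcode. Reference lineages themselves are regressed against the
#' same aggregate, so their estimates scatter around zero.
#'
#' @param counts Tibble with columns `barcode_id`, `timepoint`, `count` for a
#'   single replicate competition.
#' @param reference_barcodes Character vector of reference barcode ids.
#' @param pseudocount Added per (barcode, timepoint) before taking logs
#'   (default 0.5), so zero-count timepoints stay usable; affected lineages
#'   are flagged.
#' @param min_coverage Mean reads/timepoint below which a lineage is flagged
#'   `low_coverage` (estimates are still returned).
#' @return An object of class `fitness_fit`; see [tidy.fitness_fit()] for the
#'   per-barcode estimates.
#' @examples
#' counts <- tibble::tibble(
#'   barcode_id = rep(c("ref", "mut"), each = 3),
#'   timepoint = rep(0:2, 2),
#'   count = c(100, 100, 100, 100, 200, 400)
#' )
#' fit <- infer_fitness_reference(counts, "ref", pseudocount = 0)
#' tidy(fit) # mutant slope = ln 2
#' @export
infer_fitness_reference <- function(counts, reference_barcodes,
                                    pseudocount = 0.5, min_coverage = 10) {
  cm <- count_matrix(counts)
  if (length(cm$timepoints) < 2) {
    stop("need at least 2 timepoints to fit a slope", call. = FALSE)
  }
  refs <- intersect(reference_barcodes, cm$barcodes)
  if (length(refs) == 0) {
    stop("no reference barcodes present in the count table", call. = FALSE)
  }
  ref_counts <- colSums(cm$counts[cm$barcodes %in% refs, , drop = FALSE])
  if (any(ref_counts == 0)) {
    stop("reference lineages have zero aggregate count at timepoint(s) ",
         paste(cm$timepoints[ref_counts == 0], collapse = ", "),
         "; consider mean-fitness benchmarking (infer_fitness_meanfit)",
         call. = FALSE)
  }

  freq <- pseudo_freq(cm$counts, pseudocount)
  totals <- colSums(cm$counts) + pseudocount * nrow(cm$counts)
  f_ref <- (ref_counts + pseudocount) / totals
  y <- log(freq) - matrix(log(f_ref), nrow = nrow(freq), ncol = ncol(freq),
                          byrow = TRUE)
  fit <- ols_slopes(y, cm$timepoints)

  estimates <- tibble::tibble(
    barcode_id = cm$barcodes,
    s_hat = fit$slope,
    std_error = fit$se,
    mode = "reference",
    n_timepoints_used = length(cm$timepoints),
    is_reference = cm$barcodes %in% refs,
    low_coverage = rowMeans(cm$counts) < min_coverage,
    zero_timepoints = rowSums(cm$counts == 0)
  )
  new_fitness_fit(estimates, mode = "reference", pseudocount = pseudocount,
                  timepoints = cm$timepoints,
                  reference_barcodes = refs)
}

#' Infer fitness against an iterated population mean-fitness benchmark
#'
#' Implements the mean-fitness normalisation commonly used when no reference
#' is spiked in: initial slopes of `ln f_i(t)` seed lineage fitnesses `s_i`;
#' the population mean fitness `xbar(t) = sum_i f_i(t) s_i` is then computed,
#' its trapezoidal cumulative integral `X(t)` added back
#' (`s_i <- slope of ln f_i(t) + X(t)`), and the two steps iterated to a
#' fixed point. At convergence the estimates satisfy the self-consistency
#' `sum_i f_i(t) s_i = xbar(t)`.
#'
#' Because lineage frequencies sum to one, only fitness *differences* are
#' identifiable from a closed pool: adding a constant to every `s_i` and to
#' `xbar` leaves the trajectories unchanged. The gauge is fixed by reporting
#' fitness relative to the population: the frequency-weighted mean of the
#' estimates (weights: each lineage's mean frequency over the timepoints) is
#' zero. Pairwise differences, and hence comparisons with reference-mode
#' estimates up to a common shift, are unaffected by this convention.
#'
#' @inheritParams infer_fitness_reference
#' @param tol Convergence tolerance on `max |delta s_i|` (default 1e-6).
#' @param max_iter Iteration cap; non-convergence returns estimates with a
#'   warning flag and the final residual.
#' @return A `fitness_fit` whose `mean_fitness` element holds the converged
#'   `xbar(t)` series and convergence metadata.
#' @export
infer_fitness_meanfit <- function(counts, pseudocount = 0.5, tol = 1e-6,
                                  max_iter = 100, min_coverage = 10) {
  cm <- count_matrix(counts)
  if (nrow(cm$counts) == 0) stop("empty count table", call. = FALSE)
  if (length(cm$timepoints) < 2) {
    stop("need at least 2 timepoints to fit a slope", call. = FALSE)
  }
  t <- cm$timepoints
  freq <- pseudo_freq(cm$counts, pseudocount)
  logf <- log(freq)

  w <- rowMeans(freq)
  w <- w / sum(w)
  recentre <- function(s) s - sum(w * s)

  s <- recentre(ols_slopes(logf, t)$slope)
  final_change <- Inf
  iter <- 0L
  se <- rep(NA_real_, length(s))
  while (iter < max_iter) {
    iter <- iter + 1L
    xbar <- as.vector(s %*% freq)
    X <- as.vector(pracma::cumtrapz(t, xbar))
    fit <- ols_slopes(logf + matrix(X, nrow = nrow(logf), ncol = ncol(logf),
                                    byrow = TRUE), t)
    s_new <- recentre(fit$slope)
    final_change <- max(abs(s_new - s))
    s <- s_new
    se <- fit$se
    if (final_change < tol) break
  }
  xbar <- as.vector(s %*% freq)
  converged <- final_change < tol
  if (!converged) {
    warning("mean-fitness iteration did not converge: final max |delta s| = ",
            format(final_change), call. = FALSE)
  }

  estimates <- tibble::tibble(
    barcode_id = cm$barcodes,
    s_hat = s,
    std_error = se,
    mode = "mean_fitness",
    n_timepoints_used = length(t),
    is_reference = FALSE,
    low_coverage = rowMeans(cm$counts) < min_coverage,
    zero_timepoints = rowSums(cm$counts == 0)
  )
  new_fitness_fit(
    estimates, mode = "mean_fitness", pseudocount = pseudocount,
    timepoints = t,
    mean_fitness = tibble::tibble(timepoint = t, mean_fitness = xbar),
    convergence = list(iterations = iter, final_change = final_change,
                       converged = converged)
  )
}

#' Two-timepoint fold-change fitness
#'
#' The simpler estimator used by deep mutational scans: the change in
#' `ln(f_i / f_ref)` between two timepoints divided by the elapsed time.
#' Identical to the slope estimator when only two timepoints exist, but
#' noisier than a multi-timepoint slope on the same data.
#'
#' @inheritParams infer_fitness_reference
#' @param t_first,t_last The two timepoints to contrast (must differ and be
#'   present in `counts`).
#' @return Tibble with `barcode_id`, `s_fc`, and a `zero_endpoint` flag for
#'   lineages with a zero raw count at either endpoint.
#' @export
fitness_fold_change <- function(counts, t_first, t_last, reference_barcodes,
                                pseudocount = 0.5) {
  if (t_last == t_first) {
    stop("t_first and t_last must differ", call. = FALSE)
  }
  cm <- count_matrix(counts)
  miss <- setdiff(c(t_first, t_last), cm$timepoints)
  if (length(miss) > 0) {
    stop("timepoint(s) not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  refs <- intersect(reference_barcodes, cm$barcodes)
  if (length(refs) == 0) {
    stop("no reference barcodes present in the count table", call. = FALSE)
  }
  j <- match(c(t_first, t_last), cm$timepoints)
  sub <- cm$counts[, j, drop = FALSE]
  ref_counts <- colSums(sub[cm$barcodes %in% refs, , drop = FALSE])
  totals <- colSums(sub) + pseudocount * nrow(sub)
  f <- sweep(sub + pseudocount, 2, totals, "/")
  f_ref <- (ref_counts + pseudocount) / totals
  y <- log(f) - matrix(log(f_ref), nrow = nrow(f), ncol = 2, byrow = TRUE)
  tibble::tibble(
    barcode_id = cm$barcodes,
    s_fc = (y[, 2] - y[, 1]) / (t_last - t_first),
    zero_endpoint = sub[, 1] == 0 | sub[, 2] == 0
  )
}

new_fitness_fit <- function(estimates, mode, pseudocount, timepoints,
                            reference_barcodes = NULL, mean_fitness = NULL,
                            convergence = NULL) {
  structure(
    list(
      estimates = estimates,
      mode = mode,
      pseudocount = pseudocount,
      timepoints = timepoints,
      reference_barcodes = reference_barcodes,
      mean_fitness = mean_fitness,
      convergence = convergence
    ),
    class = "fitness_fit"
  )
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat("Fitness fit (", x$mode, " benchmark): ", nrow(x$estimates),
      " lineages over ", length(x$timepoints), " timepoints\n", sep = "")
  if (!is.null(x$convergence)) {
    cat("  mean-fitness iteration: ", x$convergence$iterations,
        " iteration(s), converged = ", x$convergence$converged, "\n", sep = "")
  }
  cat("  flagged low coverage: ", sum(x$estimates$low_coverage), "\n", sep = "")
  invisible(x)
}

#' Per-barcode fitness estimates from a `fitness_fit`
#'
#' @param x A `fitness_fit`.
#' @param ... Unused.
#' @return The estimates tibble: `barcode_id`, `s_hat`, `std_error`, `mode`,
#'   `n_timepoints_used`, `is_reference`, `low_coverage`, `zero_timepoints`.
#' @method tidy fitness_fit
#' @export
tidy.fitness_fit <- function(x, ...) x$estimates

#' One-row summary of a `fitness_fit`
#'
#' @param x A `fitness_fit`.
#' @param ... Unused.
#' @method glance fitness_fit
#' @export
glance.fitness_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_barcodes = nrow(x$estimates),
    n_timepoints = length(x$timepoints),
    pseudocount = x$pseudocount,
    median_std_error = stats::median(x$estimates$std_error, na.rm = TRUE),
    n_low_coverage = sum(x$estimates$low_coverage),
    converged = if (is.null(x$convergence)) NA else x$convergence$converged
  )
}

#' Join a demultiplexed count table to timepoints via the sample sheet
#'
#' @param table Barcode count table (`sample_id`, `barcode_id`, `count`).
#' @param sheet Sample sheet tibble with `sample_id`, `timepoint` (and
#'   optionally `experiment_id`, `replicate_id`, `batch_id`, carried
#'   through).
#' @return Tibble suitable for the inference functions, one row per
#'   (sample, barcode).
#' @export
counts_to_trajectory <- function(table, sheet) {
  stopifnot(all(c("sample_id", "timepoint") %in% names(sheet)))
  missing <- setdiff(unique(table$sample_id), sheet$sample_id)
  if (length(missing) > 0) {
    stop("samples missing from sheet: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  dplyr::inner_join(table, sheet, by = "sample_id")
}
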