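#' Classify reads by index-misassignment mechanism
#'
#' Given each read's observed index tuple `(F, N, R, S)` and the scheme's
#' sample sheet, assigns one swap class per read by the following precedence:
#'
#' 1. any index absent from the scheme's pools -> `unmatched`;
#' 2. the tuple equals a sample's tuple -> `correct`;
#' 3. `(F, N)` matches some sample's left half and `(R, S)` matches some
#'    sample's right half, but the combination is not itself a sample ->
#'    `template_switch` (a cross-end chimera);
#' 4. the tuple differs from some sample's tuple in exactly one position ->
#'    `single_illumina_swap` if that position is N or S, else
#'    `single_inline_swap`;
#' 5. the tuple differs from some sample's tuple in exactly two positions ->
#'    `double_swap`;
#' 6. otherwise `unmatched`.
#'
#' On a nested unique-dual scheme with once-used indices these categories are
#' disjoint, and a flank-breakpoint template switch presents as a
#' `single_illumina_swap` — indistinguishable from an index hop.
#'
#' @param reads Tibble with columns `f_idx`, `n_idx`, `r_idx`, `s_idx` (other
#'   columns pass through).
#' @param scheme An `index_scheme` from [build_scheme()].
#' @return `reads` with columns `swap_class` and `assigned_sample`
#'   (the sample id for `correct` reads; `NA` otherwise — the class of a
#'   swapped read is well defined, its origin generally is not).
#' @export
classify_reads <- function(reads, scheme) {
  validate_scheme(scheme)
  s <- scheme$samples
  n <- nrow(reads)
  cls <- rep(NA_character_, n)
  assigned <- rep(NA_character_, n)

  in_pools <- reads$f_idx %in% scheme$inline_f &
    reads$n_idx %in% scheme$illumina_n &
    reads$r_idx %in% scheme$inline_r &
    reads$s_idx %in% scheme$illumina_s
  cls[!in_pools] <- "unmatched"

  keys <- tuple_key(reads$f_idx, reads$n_idx, reads$r_idx, reads$s_idx)
  skeys <- tuple_key(s$f_idx, s$n_idx, s$r_idx, s$s_idx)
  hit <- match(keys, skeys)
  correct <- is.na(cls) & !is.na(hit)
  cls[correct] <- "correct"
  assigned[correct] <- s$sample_id[hit[correct]]

  todo <- is.na(cls)
  if (any(todo)) {
    left_ok <- paste(reads$f_idx, reads$n_idx) %in% paste(s$f_idx, s$n_idx)
    right_ok <- paste(reads$r_idx, reads$s_idx) %in% paste(s$r_idx, s$s_idx)
    cls[todo & left_ok & right_ok] <- "template_switch"
  }

  # distance-1 candidates: wildcard one slot at a time; checking the
  # Illumina slots first fixes the class when both an Illumina and an inline
  # single-mismatch explanation exist
  slots <- c("n_idx", "s_idx", "f_idx", "r_idx")
  slot_class <- c(n_idx = "single_illumina_swap", s_idx = "single_illumina_swap",
                  f_idx = "single_inline_swap", r_idx = "single_inline_swap")
  for (slot in slots) {
    todo <- is.na(cls)
    if (!any(todo)) break
    rk <- wildcard_key(reads, slot)
    sk <- wildcard_key(s, slot)
    cls[todo & rk %in% sk] <- slot_class[[slot]]
  }

  todo <- is.na(cls)
  if (any(todo)) {
    pairs <- utils::combn(c("f_idx", "n_idx", "r_idx", "s_idx"), 2,
                          simplify = FALSE)
    dbl <- rep(FALSE, n)
    for (p in pairs) {
      rk <- wildcard_key(reads, p)
      sk <- wildcard_key(s, p)
      dbl <- dbl | rk %in% sk
    }
    cls[todo & dbl] <- "double_swap"
  }
  cls[is.na(cls)] <- "unmatched"

  reads$swap_class <- cls
  reads$assigned_sample <- assigned
  reads
}

wildcard_key <- function(df, drop_slots) {
  keep <- setdiff(c("f_idx", "n_idx", "r_idx", "s_idx"), drop_slots)
  do.call(paste, c(unname(as.list(df[keep])), sep = "\r"))
}

#' Collapse PCR duplicates by UMI
#'
#' Counts, per (sample, barcode), the number of distinct UMIs observed —
#' exact string match, no edit-distance collapsing — so reads amplified from
#' the same template molecule contribute a single count.
#'
#' @param reads Tibble carrying `umi`, `barcode_id`, and a sample column.
#' @param sample_col Column naming each read's sample; defaults to
#'   `assigned_sample` (from [classify_reads()]) when present, else
#'   `origin_sample`. Reads with `NA` in that column are dropped.
#' @return A barcode count table: tibble with `sample_id`, `barcode_id`,
#'   `count`.
#' @export
umi_deduplicate <- function(reads, sample_col = NULL) {
  if (!"umi" %in% names(reads)) {
    stop("reads carry no 'umi' column; cannot deduplicate", call. = FALSE)
  }
  if (is.null(sample_col)) {
    sample_col <- if ("assigned_sample" %in% names(reads)) "assigned_sample"
                  else "origin_sample"
  }
  if (!sample_col %in% names(reads)) {
    stop("no such sample column: ", sample_col, call. = FALSE)
  }
  reads |>
    dplyr::filter(!is.na(.data[[sample_col]])) |>
    dplyr::distinct(sample_id = .data[[sample_col]], .data$barcode_id,
                    .data$umi) |>
    dplyr::count(.data$sample_id, .data$barcode_id, name = "count") |>
    dplyr::arrange(.data$sample_id, .data$barcode_id)
}

#' Summarise index misassignment in a classified read set
#'
#' Reports, over mapped reads (everything but `unmatched`, which is reported
#' separately), the fraction with correct indices and the breakdown of
#' misassigned reads by mechanism, both as a share of misassigned reads and
#' of all mapped reads.
#'
#' @param classified Output of [classify_reads()].
#' @return An object of class `misassignment_report`.
#' @export
misassignment_report <- function(classified) {
  if (!"swap_class" %in% names(classified)) {
    stop("reads are not classified; run classify_reads() first", call. = FALSE)
  }
  mapped <- classified$swap_class != "unmatched"
  n_mapped <- sum(mapped)
  if (n_mapped == 0) stop("no mapped reads to report on", call. = FALSE)
  n_correct <- sum(classified$swap_class == "correct")
  n_mis <- n_mapped - n_correct

  swap_levels <- c("template_switch", "single_illumina_swap",
                   "single_inline_swap", "double_swap")
  counts <- table(factor(classified$swap_class[mapped & classified$swap_class
                                               != "correct"],
                         levels = swap_levels))
  breakdown <- tibble::tibble(
    swap_class = swap_levels,
    n = as.integer(counts),
    fraction_of_misassigned = if (n_mis > 0) as.integer(counts) / n_mis
                              else rep(0, length(swap_levels)),
    fraction_of_total = as.integer(counts) / n_mapped
  )

  structure(
    list(
      total_mapped = n_mapped,
      n_unmatched = sum(!mapped),
      correct_fraction = n_correct / n_mapped,
      misassigned_fraction = n_mis / n_mapped,
      breakdown = breakdown
    ),
    class = "misassignment_report"
  )
}

#' @export
print.misassignment_report <- function(x, ...) {
  cat(sprintf(
    "Misassignment report: %d mapped reads (%d unmatched excluded)\n",
    x$total_mapped, x$n_unmatched
  ))
  cat(sprintf("  correct: %.1f%%   misassigned: %.1f%%\n",
              100 * x$correct_fraction, 100 * x$misassigned_fraction))
  b <- x$breakdown
  for (i in seq_len(nrow(b))) {
    cat(sprintf("    %-22s %6.1f%% of misassigned  (%.1f%% of total)\n",
                b$swap_class[i], 100 * b$fraction_of_misassigned[i],
                100 * b$fraction_of_total[i]))
  }
  invisible(x)
}

#' @method tidy misassignment_report
#' @export
tidy.misassignment_report <- function(x, ...) x$breakdown

#' @method glance misassignment_report
#' @export
glance.misassignment_report <- function(x, ...) {
  tibble::tibble(
    total_mapped = x$total_mapped,
    n_unmatched = x$n_unmatched,
    correct_fraction = x$correct_fraction,
    misassigned_fraction = x$misassigned_fraction
  )
}

#' Demultiplex by Illumina indices alone (combinatorial collapse)
#'
#' Re-assigns every read by its `(N, S)` Illumina pair only, ignoring the
#' inline indices — what a combinatorial indexing scheme would see. All swaps
#' that nested unique-dual indexing detects are silently accepted, so reads
#' from a high-frequency lineage at a late timepoint can contaminate an
#' early-timepoint sample and flatten its frequency trajectory.
#'
#' @param reads Read-set tibble (with `umi`).
#' @param scheme An `index_scheme` whose `(N, S)` pairs map uniquely to
#'   samples (true for nested and unique-dual kinds).
#' @return A UMI-deduplicated barcode count table.
#' @export
collapse_to_combinatorial <- function(reads, scheme) {
  validate_scheme(scheme)
  s <- scheme$samples
  ns_key <- paste(s$n_idx, s$s_idx)
  if (anyDuplicated(ns_key)) {
    stop("(N, S) pairs do not map uniquely to samples under this scheme; ",
         "cannot collapse to combinatorial demultiplexing", call. = FALSE)
  }
  hit <- match(paste(reads$n_idx, reads$s_idx), ns_key)
  reads$assigned_sample <- s$sample_id[hit]
  umi_deduplicate(reads, sample_col = "assigned_sample")
}

#' Classify per-sample sequencing coverage
#'
#' Mean reads per barcode below 20 is low coverage, between 20 and 600
#' (inclusive) moderate, above 600 high. The denominator is the number of
#' distinct barcodes in the table (the pool size as observed).
#'
#' @param table Barcode count table (`sample_id`, `barcode_id`, `count`).
#' @return Tibble with `sample_id`, `mean_reads_per_barcode`,
#'   `coverage_class`.
#' @export
coverage_class <- function(table) {
  if (nrow(table) == 0) stop("empty count table", call. = FALSE)
  n_barcodes <- dplyr::n_distinct(table$barcode_id)
  table |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      mean_reads_per_barcode = sum(.data$count) / n_barcodes,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      coverage_class = dplyr::case_when(
        .data$mean_reads_per_barcode < 20 ~ "low",
        .data$mean_reads_per_barcode <= 600 ~ "moderate",
        TRUE ~ "high"
      )
    )
}
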