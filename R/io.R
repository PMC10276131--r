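#' Read and write barcode count tables
#'
#' Plain TSV with columns `sample_id`, `barcode_id`, `count`.
#'
#' @param table Count table tibble.
#' @param path File path (`.tsv`).
#' @return `read_count_table()` returns the tibble; the writer returns `path`
#'   invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(all(c("sample_id", "barcode_id", "count") %in% names(table)))
  readr::write_tsv(table[, c("sample_id", "barcode_id", "count")], path)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    barcode_id = readr::col_character(),
    count = readr::col_integer()
  ))
}

#' Read and write sample sheets
#'
#' CSV dialect with columns `sample_id`, `f_idx`, `n_idx`, `r_idx`, `s_idx`,
#' `experiment_id`, `timepoint`, `replicate_id`, `batch_id`. Identifiers are
#' opaque strings; metadata columns absent from the input tibble are written
#' as `NA`.
#'
#' @param sheet Tibble with at least `sample_id` and the four index columns.
#' @param path File path (`.csv`).
#' @export
write_sample_sheet <- function(sheet, path) {
  cols <- c("sample_id", "f_idx", "n_idx", "r_idx", "s_idx",
            "experiment_id", "timepoint", "replicate_id", "batch_id")
  stopifnot(all(c("sample_id", "f_idx", "n_idx", "r_idx", "s_idx") %in%
                  names(sheet)))
  for (col in setdiff(cols, names(sheet))) sheet[[col]] <- NA
  readr::write_csv(sheet[, cols], path)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    timepoint = readr::col_double(),
    .default = readr::col_character()
  ))
}

#' Read and write read sets as plain TSV
#'
#' The analysis-facing reads table has columns `f_idx`, `n_idx`, `r_idx`,
#' `s_idx`, `barcode_id`, `umi`; simulation truth fields are never written
#' here. `write_truth_tsv()` writes the truth sidecar (`origin_sample`,
#' `event`, `partner_sample`, `breakpoint_region`, `hidden`, row-aligned with
#' the reads table).
#'
#' @param reads Read-set tibble.
#' @param path File path (`.tsv`, optionally `.gz`).
#' @export
write_reads_tsv <- function(reads, path) {
  cols <- c("f_idx", "n_idx", "r_idx", "s_idx", "barcode_id", "umi")
  stopifnot(all(cols %in% names(reads)))
  readr::write_tsv(reads[, cols], path)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
}

#' @rdname write_reads_tsv
#' @export
write_truth_tsv <- function(reads, path) {
  cols <- c("origin_sample", "molecule_id", "event", "partner_sample",
            "breakpoint_region", "hidden")
  cols <- intersect(cols, names(reads))
  readr::write_tsv(reads[, cols], path)
  invisible(path)
}

#' Serialise an index scheme to JSON
#'
#' @param scheme An `index_scheme`.
#' @param path File path (`.json`).
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "index_scheme"))
  obj <- list(
    kind = scheme$kind,
    inline_f = scheme$inline_f, inline_r = scheme$inline_r,
    illumina_n = scheme$illumina_n, illumina_s = scheme$illumina_s,
    samples = scheme$samples,
    pairings = scheme$pairings
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scheme <- structure(
    list(
      kind = obj$kind,
      inline_f = obj$inline_f, inline_r = obj$inline_r,
      illumina_n = obj$illumina_n, illumina_s = obj$illumina_s,
      samples = tibble::as_tibble(obj$samples),
      pairings = if (is.null(obj$pairings)) NULL else
        lapply(obj$pairings, unlist)
    ),
    class = "index_scheme"
  )
  validate_scheme(scheme)
  scheme
}

#' Write a misassignment report as JSON
#'
#' @param report A `misassignment_report`.
#' @param path File path (`.json`).
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "misassignment_report"))
  jsonlite::write_json(
    list(
      total_mapped = report$total_mapped,
      n_unmatched = report$n_unmatched,
      correct_fraction = report$correct_fraction,
      misassigned_fraction = report$misassigned_fraction,
      breakdown = report$breakdown
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

# deterministic index-identifier -> nucleotide encoding: the i-th member of
# a pool maps to the base-4 expansion of i over ACGT, padded to `len`
encode_index_seq <- function(ids, pool, len = 8L) {
  i <- match(ids, pool) - 1L
  if (anyNA(i)) stop("index identifier outside its pool", call. = FALSE)
  vapply(i, function(x) {
    digits <- integer(len)
    for (p in seq_len(len)) {
      digits[p] <- x %% 4L
      x <- x %/% 4L
    }
    paste(c("A", "C", "G", "T")[rev(digits) + 1L], collapse = "")
  }, character(1))
}

decode_index_seq <- function(seqs, pool, len = 8L) {
  lookup <- encode_index_seq(pool, pool, len)
  pool[match(seqs, lookup)]
}

#' Write a read set as gzipped paired FASTQ
#'
#' Synthetic-dialect FASTQ: read 1 carries the forward inline index sequence,
#' the UMI, and the barcode; read 2 carries the reverse inline index
#' sequence. The Illumina indices ride the header comment in the
#' conventional `1:N:0:<i7>+<i5>` slot. Index identifiers are encoded as
#' deterministic 8-nt sequences derived from their position in the scheme's
#' pools, so reading the pair back with the same scheme recovers the
#' identifier tuples exactly. Base qualities are uniform and carry no
#' information.
#'
#' @param reads Read-set tibble.
#' @param scheme The `index_scheme` (supplies the identifier pools).
#' @param prefix Output prefix; writes `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz`.
#' @param index_seq_len Encoded index sequence length (nt).
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_reads <- function(reads, scheme, prefix, index_seq_len = 8L) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTQ output", call. = FALSE)
  }
  f_seq <- encode_index_seq(reads$f_idx, scheme$inline_f, index_seq_len)
  r_seq <- encode_index_seq(reads$r_idx, scheme$inline_r, index_seq_len)
  n_seq <- encode_index_seq(reads$n_idx, scheme$illumina_n, index_seq_len)
  s_seq <- encode_index_seq(reads$s_idx, scheme$illumina_s, index_seq_len)

  headers <- sprintf("read%06d 1:N:0:%s+%s", seq_len(nrow(reads)),
                     n_seq, s_seq)
  r1 <- Biostrings::DNAStringSet(paste0(f_seq, reads$umi, reads$barcode_id))
  r2 <- Biostrings::DNAStringSet(r_seq)
  names(r1) <- headers
  names(r2) <- headers

  p1 <- paste0(prefix, "_R1.fastq.gz")
  p2 <- paste0(prefix, "_R2.fastq.gz")
  Biostrings::writeXStringSet(r1, p1, format = "fastq", compress = TRUE)
  Biostrings::writeXStringSet(r2, p2, format = "fastq", compress = TRUE)
  invisible(c(p1, p2))
}

#' Read a synthetic-dialect paired FASTQ back into a read-set tibble
#'
#' @param prefix Prefix used by [write_fastq_reads()].
#' @param scheme The `index_scheme` used when writing.
#' @param umi_length UMI length in nt.
#' @param index_seq_len Encoded index sequence length (nt).
#' @return Tibble with `f_idx`, `n_idx`, `r_idx`, `s_idx`, `barcode_id`,
#'   `umi`.
#' @export
read_fastq_reads <- function(prefix, scheme, umi_length = 8L,
                             index_seq_len = 8L) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTQ input", call. = FALSE)
  }
  r1 <- Biostrings::readDNAStringSet(paste0(prefix, "_R1.fastq.gz"),
                                     format = "fastq")
  r2 <- Biostrings::readDNAStringSet(paste0(prefix, "_R2.fastq.gz"),
                                     format = "fastq")
  headers <- names(r1)
  illumina <- sub(".*:", "", headers)
  n_seq <- sub("\\+.*", "", illumina)
  s_seq <- sub(".*\\+", "", illumina)
  seq1 <- unname(as.character(r1))
  seq2 <- unname(as.character(r2))

  tibble::tibble(
    f_idx = decode_index_seq(substr(seq1, 1, index_seq_len),
                             scheme$inline_f, index_seq_len),
    n_idx = decode_index_seq(n_seq, scheme$illumina_n, index_seq_len),
    r_idx = decode_index_seq(substr(seq2, 1, index_seq_len),
                             scheme$inline_r, index_seq_len),
    s_idx = decode_index_seq(s_seq, scheme$illumina_s, index_seq_len),
    barcode_id = substr(seq1, index_seq_len + umi_length + 1L,
                        nchar(seq1)),
    umi = substr(seq1, index_seq_len + 1L, index_seq_len + umi_length)
  )
}
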