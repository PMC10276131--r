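#' Build a multiplexing index scheme
#'
#' Constructs one of three schemes for labelling samples pooled on a
#' sequencing lane, each a combination of inline indices (F forward, R
#' reverse, read as part of the amplicon) and Illumina adapter indices (N =
#' i7, S = i5, read separately):
#'
#' * `"combinatorial"` — samples are assigned freely over the product of the
#'   four index pools; cheap in primers but index misassignment is
#'   undetectable.
#' * `"unique_dual"` — every sample gets indices used by no other sample
#'   (two physical primers per sample), so any single swap is detectable.
#' * `"nested_unique_dual"` — each inline F index is exclusively paired with
#'   one Illumina N index, and each R with one S, and samples take all
#'   combinations of the F/N pairings with the R/S pairings. This keeps the
#'   single-swap detection power of unique dual indexing while the primer
#'   count grows with the pool sizes, not the sample count: 12 F/N x 8 R/S
#'   pairings label up to 96 samples with 40 primers, where plain unique dual
#'   indexing needs 192.
#'
#' Samples are assigned tuples in row-major (F-major) order.
#'
#' @param kind One of `"combinatorial"`, `"unique_dual"`,
#'   `"nested_unique_dual"`.
#' @param n_samples Number of samples to label.
#' @param n_f_pairs,n_r_pairs Pool sizes on the forward (F/N) and reverse
#'   (R/S) sides. Defaults: 12 and 8 for the nested scheme; ignored for
#'   `unique_dual` (pools are sized to `n_samples`).
#' @return An object of class `index_scheme`: the four index pools, the
#'   sample sheet tibble (`sample_id`, `f_idx`, `n_idx`, `r_idx`, `s_idx`),
#'   and, for the nested kind, the F->N and R->S pairings.
#' @examples
#' sch <- build_scheme("nested_unique_dual", 96, 12, 8)
#' primer_count(sch)
#' @export
build_scheme <- function(kind = c("nested_unique_dual", "unique_dual",
                                  "combinatorial"),
                         n_samples, n_f_pairs = NULL, n_r_pairs = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_samples >= 1)

  if (kind == "nested_unique_dual") {
    if (is.null(n_f_pairs)) n_f_pairs <- 12L
    if (is.null(n_r_pairs)) n_r_pairs <- 8L
  }
  if (kind == "combinatorial") {
    if (is.null(n_f_pairs)) n_f_pairs <- max(1L, ceiling(n_samples^0.25))
    if (is.null(n_r_pairs)) n_r_pairs <- n_f_pairs
  }
  if (kind == "unique_dual") {
    n_f_pairs <- n_samples
    n_r_pairs <- n_samples
  }

  cap <- scheme_capacity(kind, n_f_pairs, n_r_pairs)
  if (cap < n_samples) {
    stop(sprintf(
      "scheme capacity %d < %d samples; a %s scheme needs larger pools (have %d F/N and %d R/S)",
      cap, n_samples, kind, n_f_pairs, n_r_pairs
    ), call. = FALSE)
  }

  inline_f <- sprintf("F%02d", seq_len(n_f_pairs))
  illumina_n <- sprintf("N%02d", seq_len(n_f_pairs))
  inline_r <- sprintf("R%02d", seq_len(n_r_pairs))
  illumina_s <- sprintf("S%02d", seq_len(n_r_pairs))

  k <- seq_len(n_samples)
  sample_id <- sprintf("sample%03d", k)

  if (kind == "nested_unique_dual") {
    i_f <- (k - 1L) %/% n_r_pairs + 1L
    i_r <- (k - 1L) %% n_r_pairs + 1L
    samples <- tibble::tibble(
      sample_id = sample_id,
      f_idx = inline_f[i_f], n_idx = illumina_n[i_f],
      r_idx = inline_r[i_r], s_idx = illumina_s[i_r]
    )
    pairings <- list(
      f_n = stats::setNames(illumina_n, inline_f),
      r_s = stats::setNames(illumina_s, inline_r)
    )
  } else if (kind == "unique_dual") {
    samples <- tibble::tibble(
      sample_id = sample_id,
      f_idx = inline_f[k], n_idx = illumina_n[k],
      r_idx = inline_r[k], s_idx = illumina_s[k]
    )
    pairings <- NULL
  } else {
    # row-major over F x N x R x S, F slowest
    per_f <- n_f_pairs * n_r_pairs * n_r_pairs
    per_n <- n_r_pairs * n_r_pairs
    i_f <- (k - 1L) %/% per_f + 1L
    i_n <- ((k - 1L) %/% per_n) %% n_f_pairs + 1L
    i_r <- ((k - 1L) %/% n_r_pairs) %% n_r_pairs + 1L
    i_s <- (k - 1L) %% n_r_pairs + 1L
    samples <- tibble::tibble(
      sample_id = sample_id,
      f_idx = inline_f[i_f], n_idx = illumina_n[i_n],
      r_idx = inline_r[i_r], s_idx = illumina_s[i_s]
    )
    pairings <- NULL
  }

  scheme <- structure(
    list(
      kind = kind,
      inline_f = inline_f, inline_r = inline_r,
      illumina_n = illumina_n, illumina_s = illumina_s,
      samples = samples,
      pairings = pairings
    ),
    class = "index_scheme"
  )
  validate_scheme(scheme)
  scheme
}

#' Count the physical primers a scheme requires
#'
#' One distinct oligo per distinct index identifier per side; Illumina i7/i5
#' primers are counted individually. Under plain unique dual indexing each
#' sample needs its own forward and reverse oligo (2 per sample: 192 primers
#' for 96 samples); a nested scheme only needs one oligo per pool member
#' (12 + 8 + 12 + 8 = 40 for the default pools); a combinatorial scheme needs
#' one per distinct index actually used.
#'
#' @param scheme An `index_scheme`.
#' @return Integer primer count.
#' @export
primer_count <- function(scheme) {
  stopifnot(inherits(scheme, "index_scheme"))
  switch(scheme$kind,
    unique_dual = 2L * nrow(scheme$samples),
    nested_unique_dual = length(scheme$inline_f) + length(scheme$inline_r) +
      length(scheme$illumina_n) + length(scheme$illumina_s),
    combinatorial = length(unique(scheme$samples$f_idx)) +
      length(unique(scheme$samples$n_idx)) +
      length(unique(scheme$samples$r_idx)) +
      length(unique(scheme$samples$s_idx))
  )
}

#' Sample capacity of an index scheme kind
#'
#' @param kind Scheme kind, see [build_scheme()].
#' @param n_f_pairs,n_r_pairs Pool sizes per side. For `unique_dual` these
#'   are the numbers of available disjoint forward and reverse primer pairs.
#' @return Integer: combinatorial and nested kinds give the product of
#'   side-combination counts; unique dual gives the number of disjoint index
#'   pairs.
#' @export
scheme_capacity <- function(kind, n_f_pairs, n_r_pairs) {
  stopifnot(n_f_pairs >= 1, n_r_pairs >= 1)
  kind <- match.arg(kind, c("nested_unique_dual", "unique_dual",
                            "combinatorial"))
  as.integer(switch(kind,
    nested_unique_dual = n_f_pairs * n_r_pairs,
    combinatorial = n_f_pairs^2 * n_r_pairs^2,
    unique_dual = min(n_f_pairs, n_r_pairs)
  ))
}

#' List invariant violations of an index scheme
#'
#' @param scheme An `index_scheme`.
#' @return Character vector of problems; empty when the scheme is valid.
#' @export
scheme_problems <- function(scheme) {
  problems <- character(0)
  s <- scheme$samples
  if (anyDuplicated(s$sample_id)) {
    problems <- c(problems, "duplicate sample_ids")
  }
  if (anyDuplicated(tuple_key(s$f_idx, s$n_idx, s$r_idx, s$s_idx))) {
    problems <- c(problems, "sample index tuples are not all distinct")
  }
  if (!all(s$f_idx %in% scheme$inline_f) ||
      !all(s$n_idx %in% scheme$illumina_n) ||
      !all(s$r_idx %in% scheme$inline_r) ||
      !all(s$s_idx %in% scheme$illumina_s)) {
    problems <- c(problems, "sample uses an index outside the declared pools")
  }
  if (scheme$kind == "nested_unique_dual") {
    fn <- unique(s[, c("f_idx", "n_idx")])
    rs <- unique(s[, c("r_idx", "s_idx")])
    if (anyDuplicated(fn$f_idx) || anyDuplicated(fn$n_idx)) {
      problems <- c(problems,
                    "nested pairing violated: an F or N index pairs with more than one partner")
    }
    if (anyDuplicated(rs$r_idx) || anyDuplicated(rs$s_idx)) {
      problems <- c(problems,
                    "nested pairing violated: an R or S index pairs with more than one partner")
    }
  }
  if (scheme$kind == "unique_dual") {
    if (anyDuplicated(s$f_idx) || anyDuplicated(s$n_idx) ||
        anyDuplicated(s$r_idx) || anyDuplicated(s$s_idx)) {
      problems <- c(problems,
                    "unique dual scheme reuses an index across samples")
    }
  }
  problems
}

#' Validate an index scheme, erroring on the first problem
#'
#' @param scheme An `index_scheme`.
#' @return `scheme`, invisibly.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "index_scheme"))
  problems <- scheme_problems(scheme)
  if (length(problems) > 0) {
    stop("invalid index scheme: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  invisible(scheme)
}

#' @export
print.index_scheme <- function(x, ...) {
  cat("Index scheme (", x$kind, "): ", nrow(x$samples), " samples, ",
      primer_count(x), " primers\n", sep = "")
  cat("  pools: ", length(x$inline_f), " F, ", length(x$illumina_n), " N, ",
      length(x$inline_r), " R, ", length(x$illumina_s), " S\n", sep = "")
  invisible(x)
}
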