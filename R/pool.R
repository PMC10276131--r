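#' Construct a pool of barcoded lineages
#'
#' A lineage pool is a tibble with one row per uniquely barcoded lineage in a
#' pooled competition: its barcode sequence, genotype label, true fitness
#' (log-linear rate of frequency change per transfer interval, `s`), its
#' sensitivity to shared environmental shifts, and its starting frequency.
#'
#' Defaults emulate a competition of roughly 500 lineages: a set of neutral
#' reference (ancestor) lineages spiked in at elevated frequency, a class of
#' strongly adaptive mutants ("IRA1", roughly doubling in relative frequency
#' per interval), an intermediate class ("GPB2"), and a background of
#' near-neutral mutants.
#'
#' @param n_background Number of near-neutral background lineages.
#' @param n_reference Number of neutral reference lineages (`base_fitness = 0`,
#'   `env_sensitivity = 0`).
#' @param n_ira1 Number of strongly adaptive lineages (genotype `"IRA1"`).
#' @param n_gpb2 Number of intermediate adaptive lineages (genotype `"GPB2"`).
#' @param s_ira1,s_gpb2 True fitness of the two adaptive classes, log units per
#'   transfer interval.
#' @param sd_background Standard deviation of background lineage fitness.
#' @param reference_frequency Total initial frequency of the reference class
#'   (spiking references in high keeps their coverage up as adaptive mutants
#'   sweep).
#' @param barcode_length Barcode length in nucleotides.
#' @param seed Optional integer; fixes barcode draws and background fitness.
#' @return A tibble with columns `barcode_id`, `genotype_label`,
#'   `base_fitness`, `env_sensitivity`, `initial_frequency`.
#' @examples
#' pool <- lineage_pool(n_background = 20, seed = 1)
#' sum(pool$initial_frequency)
#' @export
lineage_pool <- function(n_background = 426, n_reference = 40, n_ira1 = 21,
                         n_gpb2 = 13, s_ira1 = 0.7, s_gpb2 = 0.4,
                         sd_background = 0.05, reference_frequency = 0.1,
                         barcode_length = 26L, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(n_reference >= 0, n_background >= 0, n_ira1 >= 0, n_gpb2 >= 0)
  n <- n_background + n_reference + n_ira1 + n_gpb2
  if (n < 1L) stop("pool must contain at least one lineage", call. = FALSE)

  genotype <- c(
    rep("reference", n_reference),
    rep("IRA1", n_ira1),
    rep("GPB2", n_gpb2),
    rep("background", n_background)
  )
  s <- c(
    rep(0, n_reference),
    rep(s_ira1, n_ira1),
    rep(s_gpb2, n_gpb2),
    stats::rnorm(n_background, 0, sd_background)
  )
  g <- c(rep(0, n_reference), rep(1, n - n_reference))

  n_other <- n - n_reference
  freq <- if (n_reference > 0 && n_other > 0) {
    c(
      rep(reference_frequency / n_reference, n_reference),
      rep((1 - reference_frequency) / n_other, n_other)
    )
  } else {
    rep(1 / n, n)
  }

  pool <- tibble::tibble(
    barcode_id = random_barcodes(n, barcode_length),
    genotype_label = genotype,
    base_fitness = s,
    env_sensitivity = g,
    initial_frequency = freq
  )
  validate_pool(pool)
  pool
}

#' Validate a lineage pool
#'
#' Checks the pool invariants: unique barcodes, initial frequencies summing to
#' one, and reference lineages pinned at zero fitness and zero environmental
#' sensitivity.
#'
#' @param pool A tibble as returned by [lineage_pool()].
#' @return `pool`, invisibly; errors describe the first violated invariant.
#' @export
validate_pool <- function(pool) {
  req <- c("barcode_id", "genotype_label", "base_fitness", "env_sensitivity",
           "initial_frequency")
  missing <- setdiff(req, names(pool))
  if (length(missing) > 0) {
    stop("pool is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pool$barcode_id)) {
    stop("barcode_ids must be unique within a pool", call. = FALSE)
  }
  if (abs(sum(pool$initial_frequency) - 1) > 1e-9) {
    stop("initial frequencies must sum to 1 (got ",
         format(sum(pool$initial_frequency)), ")", call. = FALSE)
  }
  if (any(pool$initial_frequency <= 0)) {
    stop("initial frequencies must be in (0, 1]", call. = FALSE)
  }
  ref <- pool$genotype_label == "reference"
  if (any(pool$base_fitness[ref] != 0) || any(pool$env_sensitivity[ref] != 0)) {
    stop("reference lineages must have base_fitness = 0 and env_sensitivity = 0",
         call. = FALSE)
  }
  invisible(pool)
}

#' Batch/replicate environmental effect model
#'
#' Environmental fitness shifts shared across lineages: every batch `b` draws a
#' deviate `delta_b ~ N(0, sigma_batch)` and every replicate `r` within it a
#' deviate `eps_r ~ N(0, sigma_rep)`. A lineage's effective fitness in that
#' replicate is `s_eff = base_fitness + env_sensitivity * (delta_b + eps_r)`,
#' so lineages with nonzero sensitivity move up or down together — the
#' signature of a batch effect. Setting both SDs to 0 recovers
#' `s_eff = base_fitness`.
#'
#' @param sigma_batch SD of the batch-level deviate (>= 0).
#' @param sigma_rep SD of the replicate-level deviate (>= 0).
#' @return An object of class `batch_effect_model`.
#' @export
batch_effect_model <- function(sigma_batch = 0.1, sigma_rep = 0.03) {
  stopifnot(is.numeric(sigma_batch), sigma_batch >= 0,
            is.numeric(sigma_rep), sigma_rep >= 0)
  structure(
    list(sigma_batch = sigma_batch, sigma_rep = sigma_rep),
    class = "batch_effect_model"
  )
}

#' Competition and sequencing design
#'
#' Bundles the experimental design of a pooled competition: when the
#' population is sampled, how many cells survive each transfer bottleneck, and
#' how deeply each sample is sequenced.
#'
#' @param timepoints Strictly increasing sampling times, in transfer-interval
#'   units (length >= 3 recommended for slope-based fitness inference).
#' @param bottleneck_size Cells carried through each transfer; the sentinel `0`
#'   selects a deterministic, infinite-population mode with no resampling.
#' @param reads_per_sample Sequencing reads emitted per sample.
#' @param n_replicates,n_batches Replicate competitions per batch (a scalar,
#'   or a vector with one entry per batch for unbalanced designs) and number
#'   of batches.
#' @param pcr_molecules_per_sample Number of template molecules drawn from each
#'   sample before amplification; if `NULL`, derived as
#'   `round(reads_per_sample / duplication_rate)`.
#' @param duplication_rate Mean sequencing reads per template molecule.
#' @param generations_per_interval Scaling of fitness units per transfer
#'   interval (default 1: fitness is per interval).
#' @return An object of class `competition_design`.
#' @export
competition_design <- function(timepoints = 0:4, bottleneck_size = 1e6,
                               reads_per_sample = 1e5, n_replicates = 3,
                               n_batches = 1, pcr_molecules_per_sample = NULL,
                               duplication_rate = 2,
                               generations_per_interval = 1) {
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 2 || any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing with length >= 2",
         call. = FALSE)
  }
  if (is.null(pcr_molecules_per_sample)) {
    pcr_molecules_per_sample <- max(1, round(reads_per_sample / duplication_rate))
  }
  if (!length(n_replicates) %in% c(1L, n_batches)) {
    stop("n_replicates must be a scalar or have one entry per batch",
         call. = FALSE)
  }
  n_replicates <- rep(as.integer(n_replicates), length.out = n_batches)
  stopifnot(
    bottleneck_size >= 0, reads_per_sample >= 1, all(n_replicates >= 1),
    n_batches >= 1, pcr_molecules_per_sample >= 1, duplication_rate > 0,
    generations_per_interval > 0
  )
  structure(
    list(
      timepoints = timepoints,
      bottleneck_size = bottleneck_size,
      reads_per_sample = as.integer(reads_per_sample),
      n_replicates = n_replicates,
      n_batches = as.integer(n_batches),
      pcr_molecules_per_sample = as.integer(pcr_molecules_per_sample),
      duplication_rate = duplication_rate,
      generations_per_interval = generations_per_interval
    ),
    class = "competition_design"
  )
}

#' Amplicon geometry for the template-switching breakpoint model
#'
#' The barcode amplicon consists of a homologous middle region carrying the
#' barcode, bounded by the two inline indices, plus two constant flanks
#' between the inline and Illumina indices. A template switch with a
#' breakpoint in the middle region joins the two index pairs of different
#' molecules (a detectable cross-end chimera under nested unique dual
#' indexing); a breakpoint in a flank only exchanges the outer Illumina index
#' on that side, and presents exactly like an index hop.
#'
#' @param left_flank_len,middle_len,right_flank_len Region lengths in bp
#'   (defaults 40/167/40).
#' @param barcode_offset 0-based offset of the barcode start within the middle
#'   region; `NULL` centres a 26-nt barcode.
#' @param barcode_length Barcode length in nt, used to centre the barcode.
#' @return An object of class `amplicon_geometry`.
#' @export
amplicon_geometry <- function(left_flank_len = 40, middle_len = 167,
                              right_flank_len = 40, barcode_offset = NULL,
                              barcode_length = 26) {
  stopifnot(left_flank_len > 0, middle_len > 0, right_flank_len > 0)
  if (is.null(barcode_offset)) {
    barcode_offset <- floor((middle_len - barcode_length) / 2)
  }
  if (barcode_offset < 0 || barcode_offset + barcode_length > middle_len) {
    stop("barcode must be fully contained in the middle region", call. = FALSE)
  }
  structure(
    list(
      left_flank_len = left_flank_len,
      middle_len = middle_len,
      right_flank_len = right_flank_len,
      barcode_offset = barcode_offset,
      barcode_length = barcode_length
    ),
    class = "amplicon_geometry"
  )
}

#' @export
print.batch_effect_model <- function(x, ...) {
  cat("Batch effect model: sigma_batch =", x$sigma_batch,
      ", sigma_rep =", x$sigma_rep, "\n")
  invisible(x)
}

#' @export
print.competition_design <- function(x, ...) {
  cat("Competition design:\n")
  cat("  timepoints:", paste(x$timepoints, collapse = ", "), "\n")
  cat("  bottleneck:", if (x$bottleneck_size == 0) "deterministic (infinite)"
      else format(x$bottleneck_size, scientific = FALSE), "\n")
  cat("  replicates per batch:", paste(x$n_replicates, collapse = ", "),
      "(", x$n_batches, "batch(es) )\n")
  cat("  reads/sample:", x$reads_per_sample,
      " molecules/sample:", x$pcr_molecules_per_sample, "\n")
  invisible(x)
}

#' @export
print.amplicon_geometry <- function(x, ...) {
  cat("Amplicon geometry:", x$left_flank_len, "/", x$middle_len, "/",
      x$right_flank_len, "bp; barcode at offset", x$barcode_offset, "\n")
  invisible(x)
}

# n unique random barcodes over {A,C,G,T}; redraws on (vanishingly rare)
# collision so pool invariants hold at any n used in practice.
random_barcodes <- function(n, len = 26L) {
  out <- random_dna(n, len)
  while (anyDuplicated(out)) {
    dup <- duplicated(out)
    out[dup] <- random_dna(sum(dup), len)
  }
  out
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  cols <- lapply(seq_len(len), function(i) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
  })
  do.call(paste0, cols)
}
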