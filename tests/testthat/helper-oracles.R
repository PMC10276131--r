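# Independent oracles and small fixtures shared across test files.

# Brute-force swap classifier: enumerates all samples and all chimera pairs
# and applies the category definitions literally, one read at a time.
# Deliberately loop-based and independent of the package's vectorised
# key-matching implementation.
brute_classify <- function(reads, scheme) {
  s <- scheme$samples
  slots <- c("f_idx", "n_idx", "r_idx", "s_idx")
  vapply(seq_len(nrow(reads)), function(i) {
    tup <- c(reads$f_idx[i], reads$n_idx[i], reads$r_idx[i], reads$s_idx[i])
    pools <- list(scheme$inline_f, scheme$illumina_n, scheme$inline_r,
                  scheme$illumina_s)
    if (!all(mapply(function(x, p) x %in% p, tup, pools))) return("unmatched")

    dists <- integer(nrow(s))
    mism <- vector("list", nrow(s))
    for (j in seq_len(nrow(s))) {
      stup <- c(s$f_idx[j], s$n_idx[j], s$r_idx[j], s$s_idx[j])
      diffpos <- which(tup != stup)
      dists[j] <- length(diffpos)
      mism[[j]] <- diffpos
    }
    if (any(dists == 0)) return("correct")

    # chimera: left half of one sample joined to right half of another
    for (a in seq_len(nrow(s))) {
      for (b in seq_len(nrow(s))) {
        if (tup[1] == s$f_idx[a] && tup[2] == s$n_idx[a] &&
            tup[3] == s$r_idx[b] && tup[4] == s$s_idx[b]) {
          return("template_switch")
        }
      }
    }

    ones <- which(dists == 1)
    if (length(ones) > 0) {
      pos <- vapply(mism[ones], identity, integer(1))
      if (any(pos %in% c(2, 4))) return("single_illumina_swap")
      return("single_inline_swap")
    }
    if (any(dists == 2)) return("double_swap")
    "unmatched"
  }, character(1))
}

# Deterministic relative-exponential recursion: frequency trajectory oracle
# for the infinite-bottleneck growth model.
deterministic_trajectory <- function(init_freq, s, timepoints) {
  f <- init_freq
  out <- matrix(NA_real_, nrow = length(init_freq), ncol = length(timepoints))
  out[, 1] <- f
  for (j in seq_along(timepoints)[-1]) {
    dt <- timepoints[j] - timepoints[j - 1]
    f <- f * exp(s * dt)
    f <- f / sum(f)
    out[, j] <- f
  }
  out
}

# tiny pool with known structure for fast tests
tiny_pool <- function(n_background = 10, seed = 1, ...) {
  lineage_pool(n_background = n_background, n_reference = 4, n_ira1 = 3,
               n_gpb2 = 2, seed = seed, ...)
}

# reads tibble straight from tuples, with the truth columns the simulator
# would attach
reads_from_tuples <- function(f, n, r, s, barcode = "B1", umi = NULL,
                              origin = NA_character_) {
  k <- length(f)
  tibble::tibble(
    f_idx = f, n_idx = n, r_idx = r, s_idx = s,
    barcode_id = rep_len(barcode, k),
    umi = if (is.null(umi)) sprintf("U%04d", seq_len(k)) else umi,
    origin_sample = rep_len(origin, k),
    molecule_id = sprintf("m%04d", seq_len(k)),
    event = "none",
    partner_sample = NA_character_,
    breakpoint_region = NA_character_,
    hidden = FALSE
  )
}

# uniform read set over a scheme's samples (one barcode per sample by default)
uniform_reads <- function(scheme, reads_per_sample = 50,
                          barcodes = NULL, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  s <- scheme$samples
  if (is.null(barcodes)) barcodes <- paste0("BC", seq_len(nrow(s)))
  out <- lapply(seq_len(nrow(s)), function(i) {
    reads_from_tuples(
      rep(s$f_idx[i], reads_per_sample), rep(s$n_idx[i], reads_per_sample),
      rep(s$r_idx[i], reads_per_sample), rep(s$s_idx[i], reads_per_sample),
      barcode = barcodes[i],
      umi = random_umis(reads_per_sample),
      origin = s$sample_id[i]
    )
  })
  dplyr::bind_rows(out)
}

random_umis <- function(n, len = 8) {
  do.call(paste0, lapply(seq_len(len), function(i) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
  }))
}

# per-replicate reference-mode fitness over a sample_counts() table
fit_replicates <- function(counts, refs, ...) {
  counts |>
    dplyr::group_by(batch_id, replicate_id) |>
    dplyr::group_modify(function(df, key) {
      tidy(infer_fitness_reference(df, refs, ...))
    }) |>
    dplyr::ungroup()
}

study_like_fitness <- function(seed = 1) {
  # 28 replicate experiments over 9 batches (3 per batch, 4 in the last);
  # 21 IRA1 + 13 GPB2 pool lineages everywhere; engineered IRA1non (6) and
  # IRA1mis (8) sets only in the 4-replicate batch
  withr::local_seed(seed)
  reps_per_batch <- c(rep(3, 8), 4)
  pool_bcs <- c(paste0("ira1_", 1:21), paste0("gpb2_", 1:13))
  eng_bcs <- c(paste0("non_", 1:6), paste0("mis_", 1:8))
  rows <- list()
  for (b in seq_len(9)) {
    for (r in seq_len(reps_per_batch[b])) {
      bcs <- if (b == 9) c(pool_bcs, eng_bcs) else pool_bcs
      rows[[length(rows) + 1]] <- tibble::tibble(
        barcode_id = bcs,
        replicate_id = sprintf("rep%02d", r),
        batch_id = sprintf("batch%02d", b),
        s_hat = stats::rnorm(length(bcs), 0.5, 0.05)
      )
    }
  }
  dplyr::bind_rows(rows)
}

study_genotype_map <- function() {
  tibble::tibble(
    barcode_id = c(paste0("ira1_", 1:21), paste0("gpb2_", 1:13),
                   paste0("non_", 1:6), paste0("mis_", 1:8)),
    # evolved IRA1 lineages carry distinct mutations: no within-vessel group
    genotype_label = c(paste0("IRA1-lineage-", 1:21), rep("GPB2", 13),
                       rep("IRA1non", 6), rep("IRA1mis", 8))
  )
}

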