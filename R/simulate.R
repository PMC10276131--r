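#' Simulate a pooled barcode competition
#'
#' Propagates lineage frequencies through serial transfers. Per transfer
#' interval the update is the deterministic relative-exponential step
#' `f_i <- f_i * exp(s_eff_i) / sum_j f_j * exp(s_eff_j)` followed by
#' multinomial resampling of `bottleneck_size` cells (skipped in the
#' deterministic mode, `bottleneck_size = 0`). Effective fitness combines each
#' lineage's base fitness with the shared batch and replicate environmental
#' deviates of `batch_model`, so the log-frequency-ratio slope of a lineage
#' against the references equals its `s_eff` by construction.
#'
#' @param pool Lineage pool tibble, see [lineage_pool()].
#' @param design A [competition_design()]. With a finite bottleneck the gaps
#'   between recorded timepoints must be whole numbers of transfers.
#' @param batch_model A [batch_effect_model()].
#' @param seed Optional integer seed; identical seeds reproduce identical
#'   output.
#' @return An object of class `competition_sim` with elements
#'   `trajectories` (tibble: `batch_id`, `replicate_id`, `timepoint`,
#'   `barcode_id`, `frequency`), `fitness_truth` (tibble: per
#'   batch/replicate/barcode `s_eff` and the environmental deviates), and the
#'   inputs. `has_reference` flags whether the pool contains reference
#'   lineages.
#' @examples
#' sim <- simulate_competition(
#'   lineage_pool(n_background = 30, seed = 1),
#'   competition_design(bottleneck_size = 0, n_replicates = 1),
#'   batch_effect_model(0, 0), seed = 1
#' )
#' head(sim$trajectories)
#' @export
simulate_competition <- function(pool, design,
                                 batch_model = batch_effect_model(0, 0),
                                 seed = NULL) {
  validate_pool(pool)
  stopifnot(inherits(design, "competition_design"),
            inherits(batch_model, "batch_effect_model"))
  if (!is.null(seed)) withr::local_seed(seed)

  tp <- design$timepoints
  steps <- diff(tp)
  finite_bn <- design$bottleneck_size > 0
  if (finite_bn && any(abs(steps - round(steps)) > 1e-8)) {
    stop("with a finite bottleneck, timepoint gaps must be whole numbers ",
         "of transfer intervals", call. = FALSE)
  }
  gen <- design$generations_per_interval

  trajs <- list()
  truth <- list()
  k <- 1L
  for (b in seq_len(design$n_batches)) {
    batch_id <- sprintf("batch%02d", b)
    delta_b <- stats::rnorm(1, 0, batch_model$sigma_batch)
    for (r in seq_len(design$n_replicates[b])) {
      replicate_id <- sprintf("rep%02d", r)
      eps_r <- stats::rnorm(1, 0, batch_model$sigma_rep)
      s_eff <- pool$base_fitness + pool$env_sensitivity * (delta_b + eps_r)

      f <- pool$initial_frequency
      freq_mat <- matrix(NA_real_, nrow = nrow(pool), ncol = length(tp))
      freq_mat[, 1] <- f
      for (j in seq_along(steps)) {
        if (finite_bn) {
          for (step in seq_len(round(steps[j]))) {
            f <- f * exp(s_eff * gen)
            f <- f / sum(f)
            cells <- stats::rmultinom(1, design$bottleneck_size, f)[, 1]
            f <- cells / design$bottleneck_size
          }
        } else {
          f <- f * exp(s_eff * gen * steps[j])
          f <- f / sum(f)
        }
        freq_mat[, j + 1] <- f
      }

      trajs[[k]] <- tibble::tibble(
        batch_id = batch_id,
        replicate_id = replicate_id,
        timepoint = rep(tp, each = nrow(pool)),
        barcode_id = rep(pool$barcode_id, times = length(tp)),
        frequency = as.vector(freq_mat)
      )
      truth[[k]] <- tibble::tibble(
        batch_id = batch_id,
        replicate_id = replicate_id,
        barcode_id = pool$barcode_id,
        genotype_label = pool$genotype_label,
        s_eff = s_eff,
        delta_batch = delta_b,
        eps_replicate = eps_r
      )
      k <- k + 1L
    }
  }

  structure(
    list(
      trajectories = dplyr::bind_rows(trajs),
      fitness_truth = dplyr::bind_rows(truth),
      pool = pool,
      design = design,
      batch_model = batch_model,
      has_reference = any(pool$genotype_label == "reference"),
      seed = seed
    ),
    class = "competition_sim"
  )
}

#' @export
print.competition_sim <- function(x, ...) {
  cat("Pooled competition simulation:\n")
  cat("  ", nrow(x$pool), "lineages,",
      length(x$design$timepoints), "timepoints,",
      sum(x$design$n_replicates), "replicate(s) over", x$design$n_batches,
      "batch(es)\n")
  if (!x$has_reference) cat("  note: pool contains no reference lineages\n")
  invisible(x)
}

#' Split a sample into technical replicates
#'
#' Mimics dividing a frozen cell sample (or an extracted DNA sample) into
#' technical replicates before downstream processing: each barcode's count is
#' thinned symmetrically across splits by multinomial draws, so per-barcode
#' totals across splits equal the input exactly.
#'
#' @param counts A data frame with columns `barcode_id` and `count`
#'   (non-negative integers), or a named numeric vector.
#' @param n_splits Number of technical replicates (>= 2).
#' @param seed Optional integer seed.
#' @return A tibble with columns `barcode_id`, `split` (1..n_splits),
#'   `count`.
#' @examples
#' split_sample(c(bc1 = 10, bc2 = 0), n_splits = 2, seed = 1)
#' @export
split_sample <- function(counts, n_splits = 2, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.numeric(counts)) {
    counts <- tibble::tibble(barcode_id = names(counts), count = as.vector(counts))
  }
  stopifnot(all(c("barcode_id", "count") %in% names(counts)))
  if (n_splits < 2) stop("n_splits must be >= 2", call. = FALSE)
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  split_mat <- vapply(counts$count, function(ct) {
    stats::rmultinom(1, ct, rep(1 / n_splits, n_splits))[, 1]
  }, integer(n_splits))
  # split_mat: n_splits x n_barcodes
  tibble::tibble(
    barcode_id = rep(counts$barcode_id, each = n_splits),
    split = rep(seq_len(n_splits), times = nrow(counts)),
    count = as.integer(split_mat)
  )
}

#' Multinomial read counts straight from simulated trajectories
#'
#' Samples a barcode count table directly from the true frequencies of a
#' simulation — the sequencing sampling step without the molecule/UMI/index
#' layer. Useful when only count-level behaviour is under study; use
#' [simulate_sequencing()] for the full library-preparation model.
#'
#' @param sim A `competition_sim` (or its `trajectories` tibble).
#' @param reads_per_sample Reads drawn per (batch, replicate, timepoint).
#' @param seed Optional integer seed.
#' @return Tibble with `batch_id`, `replicate_id`, `timepoint`, `barcode_id`,
#'   `count`; counts per sample sum to `reads_per_sample` exactly.
#' @export
sample_counts <- function(sim, reads_per_sample, seed = NULL) {
  traj <- if (inherits(sim, "competition_sim")) sim$trajectories else sim
  if (!is.null(seed)) withr::local_seed(seed)
  traj |>
    dplyr::group_by(.data$batch_id, .data$replicate_id, .data$timepoint) |>
    dplyr::mutate(
      count = as.integer(stats::rmultinom(1, reads_per_sample,
                                          .data$frequency)[, 1])
    ) |>
    dplyr::ungroup() |>
    dplyr::select("batch_id", "replicate_id", "timepoint", "barcode_id",
                  "count")
}

#' Emit UMI-tagged indexed reads from sample frequencies
#'
#' Models the library preparation and sequencing sampling chain: for each
#' sample, `pcr_molecules_per_sample` template molecules are drawn
#' multinomially from the barcode frequencies and tagged with random 8-nt
#' UMIs; then `reads_per_sample` reads are drawn uniformly over those
#' molecules, so PCR duplicates share a UMI. Each read carries the sample's
#' index tuple from `scheme` plus simulation truth fields.
#'
#' @param frequencies Tibble with columns `sample_id`, `barcode_id`,
#'   `frequency` (normalised within each sample).
#' @param design A [competition_design()] (supplies molecule and read
#'   depths).
#' @param scheme An index scheme from [build_scheme()] whose sample sheet
#'   covers every `sample_id`.
#' @param seed Optional integer seed.
#' @param umi_length UMI length in nt.
#' @return A read-set tibble with columns `f_idx`, `n_idx`, `r_idx`, `s_idx`,
#'   `barcode_id`, `umi` and truth columns `origin_sample`, `molecule_id`,
#'   `event`, `partner_sample`, `breakpoint_region`, `hidden`.
#' @export
simulate_sequencing <- function(frequencies, design, scheme, seed = NULL,
                                umi_length = 8L) {
  stopifnot(all(c("sample_id", "barcode_id", "frequency") %in% names(frequencies)))
  if (!is.null(seed)) withr::local_seed(seed)
  samples <- unique(frequencies$sample_id)
  missing <- setdiff(samples, scheme$samples$sample_id)
  if (length(missing) > 0) {
    stop("samples missing from the index scheme: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  tuples <- scheme$samples

  out <- lapply(samples, function(sid) {
    sub <- frequencies[frequencies$sample_id == sid, ]
    freq <- sub$frequency / sum(sub$frequency)
    m_total <- design$pcr_molecules_per_sample
    n_reads <- design$reads_per_sample

    mol_per_bc <- stats::rmultinom(1, m_total, freq)[, 1]
    mol_barcode <- rep(sub$barcode_id, times = mol_per_bc)
    mol_umi <- random_dna(m_total, umi_length)
    draws <- sample.int(m_total, n_reads, replace = TRUE)

    tup <- tuples[tuples$sample_id == sid, ]
    tibble::tibble(
      f_idx = tup$f_idx, n_idx = tup$n_idx,
      r_idx = tup$r_idx, s_idx = tup$s_idx,
      barcode_id = mol_barcode[draws],
      umi = mol_umi[draws],
      origin_sample = sid,
      molecule_id = paste0(sid, ":", draws),
      event = "none",
      partner_sample = NA_character_,
      breakpoint_region = NA_character_,
      hidden = FALSE
    )
  })
  dplyr::bind_rows(out)
}

#' Apply index misassignment to a read set
#'
#' Independently corrupts each read on the simulated flow cell. With
#' probability `p_template_switch` the read becomes a chimera with a partner
#' drawn uniformly from the pooled read set (so partner choice is
#' frequency-weighted) and a breakpoint uniform over the amplicon:
#' a middle-region breakpoint joins the focal read's left-end indices
#' (`f_idx`, `n_idx`) to the partner's right-end indices (`r_idx`, `s_idx`),
#' the barcode coming from whichever parent owns the barcode side of the
#' breakpoint; a flank breakpoint exchanges only the outer Illumina index on
#' that side, which is indistinguishable from an index hop. With probability
#' `p_hop` one Illumina index (N or S, uniform choice) is replaced by a
#' uniform draw from the scheme's corresponding pool.
#'
#' Truth columns record the event, partner sample, breakpoint region, and
#' whether the event is hidden (the resulting tuple is still a valid sample
#' tuple, so no index check can flag it).
#'
#' @param reads Read-set tibble from [simulate_sequencing()].
#' @param scheme Index scheme (supplies the Illumina index pools and the set
#'   of valid tuples).
#' @param p_template_switch,p_hop Per-read event probabilities;
#'   `p_template_switch + p_hop <= 1`.
#' @param geometry An [amplicon_geometry()].
#' @param seed Optional integer seed.
#' @return The read set with modified index/barcode/UMI fields and truth
#'   columns filled in.
#' @export
apply_misassignment <- function(reads, scheme, p_template_switch = 0,
                                p_hop = 0, geometry = amplicon_geometry(),
                                seed = NULL) {
  stopifnot(p_template_switch >= 0, p_hop >= 0,
            p_template_switch + p_hop <= 1)
  if (nrow(reads) == 0) {
    if (p_template_switch + p_hop > 0) {
      stop("cannot apply misassignment to an empty read set", call. = FALSE)
    }
    return(reads)
  }
  if (!is.null(seed)) withr::local_seed(seed)

  n <- nrow(reads)
  event <- sample(c("none", "template_switch", "index_hop"), n, replace = TRUE,
                  prob = c(1 - p_template_switch - p_hop,
                           p_template_switch, p_hop))

  out <- reads
  valid_keys <- tuple_key(scheme$samples$f_idx, scheme$samples$n_idx,
                          scheme$samples$r_idx, scheme$samples$s_idx)

  ts <- which(event == "template_switch")
  if (length(ts) > 0) {
    partner <- sample.int(n, length(ts), replace = TRUE)
    total_len <- geometry$left_flank_len + geometry$middle_len +
      geometry$right_flank_len
    bp <- stats::runif(length(ts), 0, total_len)
    region <- ifelse(
      bp < geometry$left_flank_len, "left_flank",
      ifelse(bp < geometry$left_flank_len + geometry$middle_len,
             "middle", "right_flank")
    )

    pf <- reads$f_idx[partner]; pn <- reads$n_idx[partner]
    pr <- reads$r_idx[partner]; ps <- reads$s_idx[partner]
    pbc <- reads$barcode_id[partner]; pumi <- reads$umi[partner]
    pmol <- reads$molecule_id[partner]

    mid <- region == "middle"
    lf <- region == "left_flank"
    rf <- region == "right_flank"

    # middle: focal contributes the left end (F, N), partner the right (R, S)
    out$r_idx[ts[mid]] <- pr[mid]
    out$s_idx[ts[mid]] <- ps[mid]
    bp_in_middle <- bp[mid] - geometry$left_flank_len
    from_partner <- bp_in_middle < geometry$barcode_offset
    out$barcode_id[ts[mid][from_partner]] <- pbc[mid][from_partner]
    out$molecule_id[ts[mid][from_partner]] <- pmol[mid][from_partner]

    # left flank: everything right of the breakpoint (F, barcode, R, S) is
    # the partner's; only the focal read's outer N survives. The UMI rides
    # the forward inline primer and travels with F.
    out$f_idx[ts[lf]] <- pf[lf]
    out$r_idx[ts[lf]] <- pr[lf]
    out$s_idx[ts[lf]] <- ps[lf]
    out$barcode_id[ts[lf]] <- pbc[lf]
    out$umi[ts[lf]] <- pumi[lf]
    out$molecule_id[ts[lf]] <- pmol[lf]

    # right flank: only the outer S comes from the partner
    out$s_idx[ts[rf]] <- ps[rf]

    out$event[ts] <- "template_switch"
    out$partner_sample[ts] <- reads$origin_sample[partner]
    out$breakpoint_region[ts] <- region
  }

  hop <- which(event == "index_hop")
  if (length(hop) > 0) {
    side <- sample(c("n", "s"), length(hop), replace = TRUE)
    hop_n <- hop[side == "n"]
    hop_s <- hop[side == "s"]
    if (length(hop_n) > 0) {
      out$n_idx[hop_n] <- sample(scheme$illumina_n, length(hop_n),
                                 replace = TRUE)
    }
    if (length(hop_s) > 0) {
      out$s_idx[hop_s] <- sample(scheme$illumina_s, length(hop_s),
                                 replace = TRUE)
    }
    out$event[hop] <- "index_hop"
  }

  changed <- c(ts, hop)
  if (length(changed) > 0) {
    keys <- tuple_key(out$f_idx[changed], out$n_idx[changed],
                      out$r_idx[changed], out$s_idx[changed])
    out$hidden[changed] <- keys %in% valid_keys
  }
  out
}

tuple_key <- function(f, n, r, s) paste(f, n, r, s, sep = "\r")
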