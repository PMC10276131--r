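#' Build a pipeline run configuration
#'
#' A run configuration is a plain, fully serialisable list with one section
#' per pipeline stage; absent fields take the documented defaults of the
#' underlying constructors. Its hash (recorded in every output's metadata)
#' identifies the run: the pipeline is deterministic given (config, seed).
#'
#' @param seed Integer master seed; every stochastic stage derives its own
#'   seed from it.
#' @param pool Named list of [lineage_pool()] arguments.
#' @param design Named list of [competition_design()] arguments.
#' @param batch_model Named list of [batch_effect_model()] arguments.
#' @param geometry Named list of [amplicon_geometry()] arguments.
#' @param misassignment List with `p_template_switch` and `p_hop`.
#' @param scheme List with `kind` (and optionally `n_f_pairs`,
#'   `n_r_pairs`).
#' @param inference List with `mode` (`"reference"` or `"mean_fitness"`) and
#'   `pseudocount`.
#' @param out_dir Output directory for [run_pipeline()] artifacts (`NULL`:
#'   keep results in memory only).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       pool = list(),
                       design = list(),
                       batch_model = list(),
                       geometry = list(),
                       misassignment = list(p_template_switch = 0, p_hop = 0),
                       scheme = list(kind = "nested_unique_dual"),
                       inference = list(mode = "reference", pseudocount = 0.5),
                       out_dir = NULL) {
  config <- list(
    seed = as.integer(seed),
    pool = pool,
    design = design,
    batch_model = batch_model,
    geometry = geometry,
    misassignment = utils::modifyList(
      list(p_template_switch = 0, p_hop = 0), misassignment),
    scheme = utils::modifyList(list(kind = "nested_unique_dual"), scheme),
    inference = utils::modifyList(
      list(mode = "reference", pseudocount = 0.5), inference),
    out_dir = out_dir
  )
  structure(config, class = "run_config")
}

#' Hash of a run configuration
#'
#' @param config A `run_config`.
#' @return Character hash identifying the configuration.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Check a run configuration against every stage's preconditions
#'
#' @param config A `run_config`.
#' @return A tibble with columns `severity` (`"error"` or `"warning"`) and
#'   `problem`; zero rows when the configuration is valid.
#' @examples
#' validate_config(run_config()) # zero rows
#' @export
validate_config <- function(config) {
  problems <- list()
  note <- function(severity, problem) {
    problems[[length(problems) + 1L]] <<- tibble::tibble(
      severity = severity, problem = problem)
  }

  design <- tryCatch(do.call(competition_design, config$design),
                     error = function(e) {
                       note("error", paste("design:", conditionMessage(e)))
                       NULL
                     })
  tryCatch(do.call(batch_effect_model, config$batch_model),
           error = function(e) note("error",
                                    paste("batch_model:", conditionMessage(e))))
  tryCatch(do.call(amplicon_geometry, config$geometry),
           error = function(e) note("error",
                                    paste("geometry:", conditionMessage(e))))

  p_ts <- config$misassignment$p_template_switch
  p_hop <- config$misassignment$p_hop
  if (p_ts < 0 || p_hop < 0 || p_ts + p_hop > 1) {
    note("error",
         "misassignment: p_template_switch + p_hop must lie in [0, 1]")
  }
  if (!config$scheme$kind %in%
        c("combinatorial", "unique_dual", "nested_unique_dual")) {
    note("error", paste("scheme: unknown kind", config$scheme$kind))
  }
  if (!config$inference$mode %in% c("reference", "mean_fitness")) {
    note("error", paste("inference: unknown mode", config$inference$mode))
  }
  if (!is.null(design)) {
    if (length(design$timepoints) < 3) {
      note("warning", paste(
        "fitness_inference precondition: slope-based inference needs >= 3",
        "timepoints; only", length(design$timepoints), "configured"))
    }
    n_lane <- max(design$n_replicates) * length(design$timepoints)
    cap <- tryCatch(
      scheme_capacity(config$scheme$kind,
                      config$scheme$n_f_pairs %||%
                        if (config$scheme$kind == "nested_unique_dual") 12L
                        else n_lane,
                      config$scheme$n_r_pairs %||%
                        if (config$scheme$kind == "nested_unique_dual") 8L
                        else n_lane),
      error = function(e) NA_integer_)
    if (!is.na(cap) && cap < n_lane) {
      note("error", sprintf(
        "scheme: capacity %d < %d samples per lane (replicates x timepoints)",
        cap, n_lane))
    }
  }
  if (length(problems) == 0) {
    tibble::tibble(severity = character(0), problem = character(0))
  } else {
    dplyr::bind_rows(problems)
  }
}

#' Run the full simulate -> demultiplex -> fit -> decompose pipeline
#'
#' Executes, in order: pooled-competition simulation, per-batch read
#' emission with index misassignment, classification and UMI deduplication,
#' per-replicate fitness inference, and variance decomposition plus a
#' genotype contrast. Each batch is treated as one sequencing lane: its
#' replicate x timepoint samples share an index scheme and misassignment
#' mixes reads within the lane. When `out_dir` is set, every stage's outputs
#' are written (count tables, fitness TSV, truth sidecar, report JSON,
#' config YAML) with the config hash and seed in the run metadata; rerunning
#' the same configuration reproduces identical outputs.
#'
#' @param config A `run_config`.
#' @param out_dir Overrides `config$out_dir`.
#' @return A list with elements `sim`, `scheme`, `counts` (nested demux
#'   count table with batch/replicate/timepoint metadata), `fitness`
#'   (combined per-replicate estimates), `misassignment` (per-batch
#'   reports), `decomposition`, `contrast`, `config`, `hash`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  problems <- validate_config(config)
  if (any(problems$severity == "error")) {
    stop("invalid config:\n  ",
         paste(problems$problem[problems$severity == "error"],
               collapse = "\n  "), call. = FALSE)
  }
  out_dir <- out_dir %||% config$out_dir
  hash <- config_hash(config)

  pool <- do.call(lineage_pool,
                  utils::modifyList(config$pool,
                                    list(seed = config$seed)))
  design <- do.call(competition_design, config$design)
  bmodel <- do.call(batch_effect_model, config$batch_model)
  geometry <- do.call(amplicon_geometry, config$geometry)

  sim <- simulate_competition(pool, design, bmodel, seed = config$seed + 1L)

  tp <- design$timepoints
  scheme_args <- config$scheme
  n_lane_max <- max(design$n_replicates) * length(tp)
  scheme <- build_scheme(scheme_args$kind, n_lane_max,
                         scheme_args$n_f_pairs, scheme_args$n_r_pairs)

  refs <- pool$barcode_id[pool$genotype_label == "reference"]
  counts_all <- list()
  reports <- list()
  fits <- list()
  reads_truth <- list()

  for (b in seq_len(design$n_batches)) {
    batch_id <- sprintf("batch%02d", b)
    n_rep <- design$n_replicates[b]
    lane_sheet <- tidyr::expand_grid(
      replicate_id = sprintf("rep%02d", seq_len(n_rep)),
      timepoint = tp
    )
    lane_sheet$sample_id <-
      scheme$samples$sample_id[seq_len(nrow(lane_sheet))]
    lane_sheet$batch_id <- batch_id

    freqs <- sim$trajectories |>
      dplyr::filter(.data$batch_id == !!batch_id) |>
      dplyr::inner_join(lane_sheet,
                        by = c("replicate_id", "timepoint", "batch_id")) |>
      dplyr::select("sample_id", "barcode_id", "frequency")

    reads <- simulate_sequencing(freqs, design, scheme,
                                 seed = config$seed + 100L + b)
    reads <- apply_misassignment(
      reads, scheme,
      p_template_switch = config$misassignment$p_template_switch,
      p_hop = config$misassignment$p_hop,
      geometry = geometry,
      seed = config$seed + 200L + b
    )
    classified <- classify_reads(reads, scheme)
    reports[[batch_id]] <- misassignment_report(classified)
    table <- umi_deduplicate(
      dplyr::filter(classified, .data$swap_class == "correct"))
    counts_all[[batch_id]] <- dplyr::inner_join(table, lane_sheet,
                                                by = "sample_id")
    reads_truth[[batch_id]] <- classified

    for (r in unique(lane_sheet$replicate_id)) {
      traj <- counts_all[[batch_id]] |>
        dplyr::filter(.data$replicate_id == r) |>
        dplyr::select("barcode_id", "timepoint", "count")
      fit <- if (config$inference$mode == "reference") {
        infer_fitness_reference(traj, refs,
                                pseudocount = config$inference$pseudocount)
      } else {
        infer_fitness_meanfit(traj,
                              pseudocount = config$inference$pseudocount)
      }
      est <- tidy(fit)
      est$replicate_id <- r
      est$batch_id <- batch_id
      fits[[paste(batch_id, r)]] <- est
    }
  }

  counts <- dplyr::bind_rows(counts_all)
  fitness <- dplyr::bind_rows(fits)
  genotype_map <- pool[, c("barcode_id", "genotype_label")]

  mutants <- dplyr::filter(fitness, !.data$is_reference)
  decomposition <- variance_decomposition(mutants, genotype_map)
  contrast <- tryCatch(
    suppressMessages(
      genotype_contrast(fitness, "IRA1", "GPB2", genotype_map)),
    error = function(e) NULL
  )

  result <- list(
    sim = sim,
    scheme = scheme,
    counts = counts,
    fitness = fitness,
    misassignment = reports,
    decomposition = decomposition,
    contrast = contrast,
    config = config,
    hash = hash
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(counts, file.path(out_dir, "counts.tsv"))
    readr::write_tsv(fitness, file.path(out_dir, "fitness.tsv"))
    readr::write_tsv(dplyr::bind_rows(reads_truth, .id = "batch_id") |>
                       dplyr::select(dplyr::any_of(c(
                         "batch_id", "origin_sample", "molecule_id", "event",
                         "partner_sample", "breakpoint_region", "hidden",
                         "swap_class"))),
                     file.path(out_dir, "truth.tsv"))
    for (batch_id in names(reports)) {
      write_report_json(reports[[batch_id]],
                        file.path(out_dir,
                                  paste0("misassignment_", batch_id, ".json")))
    }
    readr::write_tsv(tidy(decomposition),
                     file.path(out_dir, "decomposition.tsv"))
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    jsonlite::write_json(
      list(seed = config$seed, config_hash = hash,
           n_lineages = nrow(pool),
           n_experiments = sum(design$n_replicates)),
      file.path(out_dir, "run_metadata.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  result
}

#' Scenario presets
#'
#' `preset_one_big_batch()`: 4 replicate competitions in a single batch —
#' replicate effects only. `preset_nine_batches()`: 28 replicate experiments
#' spread over 9 batches (3 per batch, 4 in the last), with batch-level
#' environmental shifts dominating replicate-level ones; mirrors the
#' structure of a multi-year pooled-competition study. Both use scaled-down
#' pools and depths so a full pipeline run stays interactive.
#'
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
preset_one_big_batch <- function(seed = 1L) {
  run_config(
    seed = seed,
    pool = list(n_background = 60, n_reference = 20, n_ira1 = 8, n_gpb2 = 6),
    design = list(timepoints = 0:4, bottleneck_size = 1e5,
                  reads_per_sample = 5000, n_replicates = 4, n_batches = 1,
                  duplication_rate = 1.5),
    batch_model = list(sigma_batch = 0, sigma_rep = 0.03)
  )
}

#' @rdname preset_one_big_batch
#' @export
preset_nine_batches <- function(seed = 1L) {
  run_config(
    seed = seed,
    pool = list(n_background = 60, n_reference = 20, n_ira1 = 8, n_gpb2 = 6),
    design = list(timepoints = 0:4, bottleneck_size = 1e5,
                  reads_per_sample = 5000,
                  n_replicates = c(3, 3, 3, 3, 3, 3, 3, 3, 4), n_batches = 9,
                  duplication_rate = 1.5),
    batch_model = list(sigma_batch = 0.1, sigma_rep = 0.03)
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("Pipeline run config (seed ", x$seed, ", hash ",
      substr(config_hash(x), 1, 8), "...)\n", sep = "")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
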