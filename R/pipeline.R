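# End-to-end orchestration: simulate (optional) -> count -> call ->
# compare, with a deterministic run manifest.
#
# All randomness flows from one top-level seed, expanded per stage by a
# fixed rule (seed + stage offset) so that stages are individually
# reproducible and a full rerun with the same config is byte-identical.

STAGE_SEED_OFFSETS <- c(genome = 1L, catalog = 2L, control = 3L,
                        experiment = 4L, truth = 5L)

#' Build and validate a pipeline configuration
#'
#' A configuration is a plain named list (usually read from a YAML file)
#' with the top-level fields `seed`, `out_dir`, `overhang`, `alpha`,
#' `threshold`, `min_coverage`, and either a `simulate` block (genome /
#' catalog / library parameters) or an `inputs` block (paths to `mac`,
#' `ies_gff`, and reads or counts for experiment and control). Every seed
#' is explicit -- there are no wall-clock defaults.
#'
#' @param config A named list or a path to a YAML file.
#' @return The validated config list (class `ies_pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "iescall_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("config must be a named list or YAML path",
          class = "iescall_config_error")
  }
  defaults <- list(overhang = 5L, alpha = 0.95, threshold = 0.05,
                   min_coverage = 1L)
  for (nm in names(defaults)) config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    abort("config needs an explicit integer `seed`",
          class = "iescall_config_error")
  }
  if (is.null(config$out_dir)) {
    abort("config needs `out_dir`", class = "iescall_config_error")
  }
  if (config$alpha <= 0 || config$alpha >= 1) {
    abort("`alpha` must lie in (0, 1)", class = "iescall_config_error")
  }
  if (config$threshold <= 0 || config$threshold > 1) {
    abort("`threshold` must lie in (0, 1]", class = "iescall_config_error")
  }
  if (config$overhang < 1) {
    abort("`overhang` must be >= 1", class = "iescall_config_error")
  }
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    abort("config needs exactly one of `simulate` / `inputs`",
          class = "iescall_config_error")
  }
  if (has_sim) {
    sim_defaults <- list(n_scaffolds = 1L, scaffold_length = 100000L,
                         at_fraction = 0.72, n_ies = 200L, coverage = 100,
                         read_length = 101L, background_fraction = 0.3,
                         min_spacing = 300L, edge_margin = 150L,
                         retained_fraction = 0.5, retention_min = 0.1,
                         retention_max = 0.7)
    for (nm in names(sim_defaults)) {
      config$simulate[[nm]] <- config$simulate[[nm]] %||% sim_defaults[[nm]]
    }
  } else {
    inp <- config$inputs
    need_counts <- !is.null(inp$counts_experiment)
    required <- if (need_counts) {
      c("counts_experiment", "counts_control")
    } else {
      c("mac", "ies_gff", "reads_experiment", "reads_control")
    }
    missing_fields <- required[vapply(required, function(f) is.null(inp[[f]]),
                                      logical(1))]
    if (length(missing_fields) > 0L) {
      abort(sprintf("config `inputs` missing: %s",
                    paste(missing_fields, collapse = ", ")),
            class = "iescall_config_error")
    }
    paths <- unlist(inp[required])
    absent <- paths[!file.exists(paths)]
    if (length(absent) > 0L) {
      abort(sprintf("input file(s) not found: %s",
                    paste(absent, collapse = ", ")),
            class = "iescall_config_error")
    }
  }
  structure(config, class = "ies_pipeline_config")
}

#' Run the retention pipeline end to end
#'
#' Executes simulate (optional) -> count -> call -> compare and writes
#' the result files plus a manifest (`manifest.json`: config hash,
#' package version, input checksums, per-stage row counts and seeds) to
#' the output directory. Rerunning with the same config reproduces
#' byte-identical result tables.
#'
#' @param config A config list, `ies_pipeline_config`, or YAML path (see
#'   [pipeline_config()]).
#' @return Invisibly, a list with the retention `call`, both counts
#'   tables, the `annotations`, and the output `paths`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  k <- as.integer(config$overhang)
  manifest <- list(
    package = "iescall",
    version = as.character(utils::packageVersion("iescall")),
    config_hash = hash(unclass(config)),
    seed = seed,
    stages = list()
  )
  input_files <- character(0)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    mac0 <- simulate_genome(sim$n_scaffolds, sim$scaffold_length,
                            sim$at_fraction,
                            seed = seed + STAGE_SEED_OFFSETS[["genome"]])
    cat_res <- simulate_ies_catalog(
      mac0, sim$n_ies, min_spacing = sim$min_spacing,
      edge_margin = max(sim$edge_margin, sim$read_length),
      seed = seed + STAGE_SEED_OFFSETS[["catalog"]]
    )
    mac <- cat_res$mac
    annotations <- cat_res$annotations
    mac_plus_ies <- cat_res$mac_plus_ies
    n_ies <- nrow(annotations)
    n_ret <- round(sim$retained_fraction * n_ies)
    r <- with_seed(seed + STAGE_SEED_OFFSETS[["truth"]], {
      r <- numeric(n_ies)
      which_ret <- sample.int(n_ies, n_ret)
      r[which_ret] <- runif(n_ret, sim$retention_min, sim$retention_max)
      r
    })
    truth_exp <- retention_truth(annotations, r = r, coverage = sim$coverage)
    truth_ctrl <- retention_truth(annotations, r = 0, coverage = sim$coverage)
    exp_fastq <- file.path(out_dir, "reads_experiment.fastq")
    ctrl_fastq <- file.path(out_dir, "reads_control.fastq")
    sim_exp <- simulate_excision_reads(
      mac, mac_plus_ies, annotations, truth_exp,
      read_length = sim$read_length, overhang = k,
      background_fraction = sim$background_fraction,
      seed = seed + STAGE_SEED_OFFSETS[["experiment"]], fastq = exp_fastq,
      truth_path = file.path(out_dir, "truth_experiment.tsv")
    )
    sim_ctrl <- simulate_excision_reads(
      mac, mac_plus_ies, annotations, truth_ctrl,
      read_length = sim$read_length, overhang = k,
      background_fraction = sim$background_fraction,
      seed = seed + STAGE_SEED_OFFSETS[["control"]], fastq = ctrl_fastq,
      truth_path = file.path(out_dir, "truth_control.tsv")
    )
    write_genome(mac, file.path(out_dir, "mac.fasta"))
    write_genome(mac_plus_ies, file.path(out_dir, "mac_plus_ies.fasta"))
    write_ies_annotations(annotations, file.path(out_dir, "ies.gff3"))
    reads_exp <- sim_exp$reads
    reads_ctrl <- sim_ctrl$reads
    manifest$stages$simulate <- list(
      n_ies = n_ies, reads_experiment = nrow(reads_exp),
      reads_control = nrow(reads_ctrl),
      seeds = as.list(seed + STAGE_SEED_OFFSETS)
    )
    index <- build_probe_index(annotations, mac, mac_plus_ies, k = k)
    counts_exp <- count_reads(reads_exp, index)
    counts_ctrl <- count_reads(reads_ctrl, index)
  } else if (!is.null(config$inputs$counts_experiment)) {
    input_files <- unlist(config$inputs[c("counts_experiment",
                                          "counts_control")])
    counts_exp <- read_counts(config$inputs$counts_experiment)
    counts_ctrl <- read_counts(config$inputs$counts_control)
    annotations <- NULL
  } else {
    inp <- config$inputs
    input_files <- unlist(inp[c("mac", "ies_gff", "reads_experiment",
                                "reads_control")])
    mac <- read_genome(inp$mac)
    annotations <- read_ies_annotations(inp$ies_gff, mac)
    mac_plus_ies <- if (!is.null(inp$mac_plus_ies)) {
      read_genome(inp$mac_plus_ies)
    } else {
      insert_ies(mac, annotations)
    }
    index <- build_probe_index(annotations, mac, mac_plus_ies, k = k)
    counts_exp <- count_reads(read_sequencing_reads(inp$reads_experiment),
                              index)
    counts_ctrl <- count_reads(read_sequencing_reads(inp$reads_control),
                               index)
  }
  manifest$stages$count <- list(
    n_ies = nrow(counts_exp),
    experiment = list(n_plus = sum(counts_exp$n_plus),
                      n_minus = sum(counts_exp$n_minus)),
    control = list(n_plus = sum(counts_ctrl$n_plus),
                   n_minus = sum(counts_ctrl$n_minus)),
    overhang = k
  )
  write_counts(counts_exp, file.path(out_dir, "counts_experiment.tsv"))
  write_counts(counts_ctrl, file.path(out_dir, "counts_control.tsv"))

  call <- call_retention(counts_exp, counts_ctrl, alpha = config$alpha,
                         threshold = config$threshold,
                         min_coverage = config$min_coverage)
  write_retention_results(call, file.path(out_dir, "retention_results.tsv"))
  g <- glance(call)
  manifest$stages$call <- list(n_tested = g$n_tested,
                               n_retained = g$n_retained,
                               retained_fraction = g$retained_fraction)

  if (!is.null(annotations)) {
    compare_df <- left_join(call$results,
                            select(annotations, "ies_id", "length"),
                            by = "ies_id") |>
      filter(!is.na(.data$rs_experiment))
    quartiles <- size_bin_stats(compare_df, "rs_experiment", "length",
                                breaks = "quartiles")
    utils::write.table(quartiles,
                       file.path(out_dir, "size_by_rs_quartile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$compare <- list(n_bins = nrow(quartiles))
  }
  if (length(input_files) > 0L) {
    manifest$inputs <- as.list(tools::md5sum(input_files))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(call = call, counts_experiment = counts_exp,
                 counts_control = counts_ctrl, annotations = annotations,
                 paths = list(out_dir = out_dir,
                              results = file.path(out_dir,
                                                  "retention_results.tsv"),
                              manifest = file.path(out_dir, "manifest.json"))))
}
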