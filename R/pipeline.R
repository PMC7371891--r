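#' Read a run configuration file
#'
#' Plain-text `key: value` lines (blank lines and `#` comments ignored).
#' Recognized keys, with defaults in parentheses: `cds_fasta`, `flank_fasta`,
#' `catalog`, `dialect` (generic), `out_dir` (.), `max_samples` (5),
#' `zero_policy` (undefined), `pseudocount` (0.5), `wt_max` (700), `lof_min`
#' (900), `percentile` (95), `min_samples` (100), `n_genomes` (derived from
#' the catalog's distinct samples when absent), `type_samples`
#' (`type=count,...`, likewise derived when absent), `seed` (1), and the
#' simulation keys `n_genes` (20), `gene_length` (1500), `gc` (0.52),
#' `baseline_rate` (3e-5).
#'
#' @param path Config file; `overrides` (a named list, e.g. from command-line
#'   flags) win over file values.
#' @param overrides Named list of values overriding the file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(cds_fasta = NULL, flank_fasta = NULL, catalog = NULL,
              dialect = "generic", out_dir = ".", max_samples = 5,
              zero_policy = "undefined", pseudocount = 0.5,
              wt_max = 700, lof_min = 900, percentile = 95,
              min_samples = 100, n_genomes = NA, type_samples = NULL,
              seed = 1, n_genes = 20, gene_length = 1500, gc = 0.52,
              baseline_rate = 3e-5)
  numeric_keys <- c("max_samples", "pseudocount", "wt_max", "lof_min",
                    "percentile", "min_samples", "n_genomes", "seed",
                    "n_genes", "gene_length", "gc", "baseline_rate")
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
      if (length(m) != 3L) stop("cannot parse config line: ", ln)
      cfg[[m[2L]]] <- if (m[2L] %in% numeric_keys) as.numeric(m[3L]) else m[3L]
    }
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  if (cfg$wt_max > cfg$lof_min) stop("wt_max must not exceed lof_min")
  structure(cfg, class = "run_config")
}

parse_type_samples <- function(x) {
  if (is.null(x) || !nzchar(x)) return(NULL)
  parts <- strsplit(strsplit(x, ",")[[1]], "=")
  stats::setNames(as.integer(vapply(parts, `[`, "", 2L)),
                  trimws(vapply(parts, `[`, "", 1L)))
}

load_pipeline_inputs <- function(config) {
  for (key in c("cds_fasta", "catalog"))
    if (is.null(config[[key]]) || !file.exists(config[[key]]))
      stop("config must point at an existing ", key)
  genome <- read_cds_fasta(config$cds_fasta, flank_path = config$flank_fasta)
  records <- read_mutation_table(config$catalog, config$dialect)
  samples_per_type <- parse_type_samples(config$type_samples)
  if (is.null(samples_per_type)) {
    u <- unique(records[c("sample", "cancer_type")])
    samples_per_type <- vapply(split(u$sample, u$cancer_type),
                               function(s) length(unique(s)), integer(1))
  }
  n_genomes <- config$n_genomes
  if (is.na(n_genomes)) n_genomes <- sum(samples_per_type)
  list(genome = genome, records = records,
       samples_per_type = samples_per_type, n_genomes = n_genomes)
}

#' Build pan-cancer and cancer-type difficulty tables
#'
#' Reads the CDS FASTA and the mutation catalog, aggregates events, applies
#' the recurrence filter, estimates tendencies and writes one difficulty
#' table per scope under `out_dir` (`difficulty_pan-cancer.tsv` and
#' `difficulty_<type>.tsv`), the context site table, and a run log recording
#' the excluded-recurrent fraction and undefined-class count.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the pan-cancer table, per-type tables and
#'   log lines.
#' @export
run_build_difficulty <- function(config) {
  inp <- load_pipeline_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- aggregate_events(inp$records, inp$genome)
  filtered <- filter_recurrent(inp$records, events, config$max_samples)
  tt <- estimate_tendencies(filtered, inp$genome, inp$n_genomes)
  pan <- build_difficulty(tt, zero_policy = config$zero_policy,
                          pseudocount = config$pseudocount)
  type_tables <- cancer_type_difficulty(
    filtered, inp$genome, inp$samples_per_type,
    pan_reference_rate = attr(pan, "reference_rate"),
    min_samples = config$min_samples, zero_policy = config$zero_policy,
    pseudocount = config$pseudocount)

  write_difficulty_table(pan, file.path(config$out_dir,
                                        "difficulty_pan-cancer.tsv"))
  for (ty in names(type_tables))
    write_difficulty_table(type_tables[[ty]],
                           file.path(config$out_dir,
                                     paste0("difficulty_", ty, ".tsv")))
  write_context_sites(attr(tt, "sites"),
                      file.path(config$out_dir, "context_sites.tsv"))
  log <- c(sprintf("n_records: %d", nrow(inp$records)),
           sprintf("n_events: %d", nrow(events)),
           sprintf("n_genomes: %d", inp$n_genomes),
           sprintf("excluded_recurrent_fraction: %.6f",
                   attr(filtered, "excluded_fraction")),
           sprintf("n_unclassified: %d", attr(tt, "n_unclassified")),
           sprintf("n_undefined_classes: %d", sum(pan$flag == "undefined")),
           sprintf("fallback_types: %s",
                   paste(attr(type_tables, "fallback_types"),
                         collapse = ",")))
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(list(pan = pan, type_tables = type_tables, events = events,
                 log = log))
}

read_built_tables <- function(out_dir) {
  pan_path <- file.path(out_dir, "difficulty_pan-cancer.tsv")
  if (!file.exists(pan_path))
    stop("no difficulty tables under ", out_dir,
         "; run run_build_difficulty() first")
  pan <- read_difficulty_table(pan_path)
  files <- setdiff(list.files(out_dir, pattern = "^difficulty_.*\\.tsv$"),
                   "difficulty_pan-cancer.tsv")
  type_tables <- lapply(file.path(out_dir, files), read_difficulty_table)
  names(type_tables) <- sub("^difficulty_(.*)\\.tsv$", "\\1", files)
  list(pan = pan, type_tables = type_tables)
}

#' Assess all mutations of one gene
#'
#' Uses the difficulty tables previously written by
#' [run_build_difficulty()], computes per-event revised counts and labels,
#' calibrates the wild-type threshold from the gene's synonymous mutations
#' when at least 20 are available (otherwise the configured thresholds are
#' kept), and writes `assessment_<gene>.tsv` plus a calibration report.
#'
#' @param config A `run_config`.
#' @param gene Gene to assess.
#' @return Invisibly, a list with the assessment table and the calibration
#'   result (NULL when defaults were kept).
#' @export
run_assess <- function(config, gene) {
  inp <- load_pipeline_inputs(config)
  if (!gene %in% names(inp$genome$cds)) stop("unknown gene: ", gene)
  tabs <- read_built_tables(config$out_dir)
  events <- aggregate_events(inp$records, inp$genome)
  assessment <- annotate_gene(events, gene, inp$genome, tabs$pan,
                              tabs$type_tables,
                              wt_max = config$wt_max,
                              lof_min = config$lof_min)
  if (nrow(assessment) == 0L)
    warning("gene ", gene, " has no assessable mutations")

  calibration <- NULL
  syn <- assessment[assessment$consequence == "synonymous", , drop = FALSE]
  if (nrow(syn) >= 20L) {
    calibration <- calibrate_thresholds(syn, percentile = config$percentile)
    assessment$label <- classify_functional(
      assessment$revised_count,
      assessment$flags == "mnv_support",
      wt_max = calibration$wt_max, lof_min = config$lof_min)
  }
  utils::write.table(assessment,
                     file.path(config$out_dir,
                               paste0("assessment_", gene, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cal_lines <- if (is.null(calibration))
    sprintf("calibration: defaults kept (wt_max=%g, lof_min=%g); %d synonymous events",
            config$wt_max, config$lof_min, nrow(syn))
  else
    sprintf("calibration: wt_max=%g at percentile %g from %d synonymous events (%d outliers)",
            calibration$wt_max, calibration$percentile, calibration$n,
            nrow(calibration$outliers))
  writeLines(cal_lines, file.path(config$out_dir,
                                  paste0("calibration_", gene, ".txt")))
  invisible(list(assessment = assessment, calibration = calibration))
}

#' Shielding analysis of a hotspot codon
#'
#' Reconstructs the pan-cancer tendency table from the built difficulty
#' files and writes the ranked candidate report for synonymous recoding of
#' the given codon.
#'
#' @param config A `run_config`.
#' @param gene Gene id.
#' @param codon_index 1-based residue index.
#' @param lof_changes Deleterious target amino acids at the residue (single
#'   letters, `"*"` for stop).
#' @param include_self Include the identity recoding row.
#' @return Invisibly, the `shield_report`.
#' @export
run_shield <- function(config, gene, codon_index, lof_changes,
                       include_self = FALSE) {
  inp <- load_pipeline_inputs(config)
  tabs <- read_built_tables(config$out_dir)
  tend <- tendency_table(tabs$pan$pentamer, tabs$pan$alt,
                         ifelse(is.na(tabs$pan$tendency), 0,
                                tabs$pan$tendency),
                         tabs$pan$sites_per_genome, tabs$pan$count,
                         attr(tabs$pan, "n_genomes"))
  report <- shield_report(inp$genome, gene, codon_index, lof_changes, tend,
                          include_self = include_self)
  write_shield_report(report,
                      file.path(config$out_dir,
                                sprintf("shield_%s_codon%d.tsv", gene,
                                        codon_index)))
  invisible(report)
}

#' Generate a synthetic genome and catalog fixture
#'
#' Writes `genome.fa` and `catalog.tsv` under `out_dir` using the simulation
#' keys of the config; the files are in exactly the dialects the readers
#' consume.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the spec, genome and records.
#' @export
run_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- synthetic_spec(n_genes = config$n_genes,
                         gene_lengths = config$gene_length, gc = config$gc,
                         baseline_rate = config$baseline_rate,
                         seed = config$seed)
  genome <- make_genome(spec)
  records <- simulate_catalog(spec, genome)
  write_cds_fasta(genome, file.path(config$out_dir, "genome.fa"))
  write_catalog(records, file.path(config$out_dir, "catalog.tsv"))
  invisible(list(spec = spec, genome = genome, records = records))
}
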