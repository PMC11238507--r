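#' Run the full constraint pipeline in memory
#'
#' Convenience wrapper chaining the stages: enumerate possible SNVs, join
#' domain meta-positions, annotate mutability, flag rare observed variants,
#' calibrate expected counts on synonymous variation, aggregate constraint
#' per meta-position and score every missense variant.
#'
#' @param transcripts Transcript tibble ([read_transcripts()]).
#' @param alignments List of `hmc_alignment` objects (or one).
#' @param observed Observed-variant tibble ([read_observed_variants()]).
#' @param rate_table Rate table ([load_rate_table()]).
#' @param coverage,methylation Optional coverage / methylation tables.
#' @param maf_threshold Rarity threshold (default 0.001).
#' @param alpha Significance level (default 0.05).
#' @param quantile Posterior quantile of the score (default 0.95).
#' @param bins Score bin edges.
#' @param min_copies Minimum domain copies per assessable position.
#' @param cov_model A [coverage_model()].
#' @return List with `variants` (fully annotated possible-variant table),
#'   `calibration`, `records` (`hmc_constraint`), `scores` (score table).
#' @export
hmc_pipeline <- function(transcripts, alignments, observed, rate_table,
                         coverage = NULL, methylation = NULL,
                         maf_threshold = 0.001, alpha = 0.05,
                         quantile = 0.95, bins = c(0.5, 0.6, 0.8, 1),
                         min_copies = 2, cov_model = coverage_model()) {
  meta <- build_meta_positions(alignments)
  variants <- enumerate_snvs(transcripts) |>
    join_meta_positions(meta) |>
    annotate_mutability(rate_table, coverage = coverage,
                        methylation = methylation, cov_model = cov_model) |>
    apply_rarity_filter(observed, maf_threshold = maf_threshold)
  calibration <- calibrate_expected(variants)
  variants <- expected_counts(variants, calibration)
  records <- aggregate_constraint(variants, alpha = alpha,
                                  quantile = quantile, bins = bins,
                                  min_copies = min_copies)
  scores <- score_variants(records, variants)
  list(variants = variants, calibration = calibration, records = records,
       scores = scores)
}

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Recognised numeric keys are coerced; everything else stays character.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("no such config file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2)
  if (length(bad) > 0) {
    abort_config(sprintf("cannot parse config line %d: '%s'",
                         bad[1], lines[bad[1]]))
  }
  cfg <- setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, character(1), 1))
  numeric_keys <- c("maf_threshold", "alpha", "quantile", "min_copies",
                    "seed", "cohort_scale", "n_families")
  for (k in intersect(names(cfg), numeric_keys)) {
    cfg[[k]] <- as.numeric(cfg[[k]])
  }
  if ("bins" %in% names(cfg)) {
    cfg$bins <- as.numeric(strsplit(cfg$bins, ",")[[1]])
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  defaults <- list(maf_threshold = 0.001, alpha = 0.05, quantile = 0.95,
                   bins = c(0.5, 0.6, 0.8, 1), min_copies = 2, seed = 1)
  cfg <- modifyList(defaults, cfg)
  for (k in c("maf_threshold", "alpha", "quantile")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] >= 1) {
      abort_config(sprintf("config field '%s' must lie in (0, 1)", k))
    }
  }
  if (is.unsorted(cfg$bins, strictly = TRUE)) {
    abort_config("config field 'bins' must be sorted ascending")
  }
  cfg
}

#' Run one pipeline verb against files on disk
#'
#' File-based orchestration: each verb reads its declared inputs, writes TSV
#' artifacts into `out_dir`, and drops a JSON run manifest (resolved config,
#' input checksums, package version, seed). Verbs compose: `score` consumes
#' the outputs of `annotate` + `expect`.
#'
#' Verbs and their artifacts:
#' * `simulate`: synthetic universe via [sim_reference()]/[sim_write()].
#' * `annotate`: possible-variant TSV with meta-positions and rarity flags
#'   (`annotated.tsv`).
#' * `expect`: adds mutability and calibrated expected counts
#'   (`expected.tsv`, `calibration.json`).
#' * `score`: constraint records and the per-variant score table
#'   (`records.tsv`, `scores.tsv`).
#' * `evaluate`: per-bin risk-ratio report and precision-sensitivity curve
#'   from a label table (`bin_report.tsv`, `pr_curve.tsv`).
#'
#' @param verb One of `simulate`, `annotate`, `expect`, `score`, `evaluate`.
#' @param config Path to a flat key=value config file, or a named list.
#'   Recognised keys include `out_dir`, `alignments` (directory of Stockholm
#'   files), `cds_fasta`, `exons`, `flanks`, `observed`, `rate_table`,
#'   `coverage`, `methylation`, `labels`, plus the thresholds of
#'   [read_run_config()].
#' @return Named list of written artifact paths, invisibly.
#' @export
hmc_run <- function(verb = c("simulate", "annotate", "expect", "score",
                             "evaluate"),
                    config) {
  verb <- match.arg(verb)
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(verb,
                  simulate = run_simulate(cfg, out_dir),
                  annotate = run_annotate(cfg, out_dir),
                  expect = run_expect(cfg, out_dir),
                  score = run_score(cfg, out_dir),
                  evaluate = run_evaluate(cfg, out_dir))
  write_manifest(verb, cfg, paths, out_dir)
  invisible(paths)
}

require_inputs <- function(cfg, keys) {
  for (k in keys) {
    if (is.null(cfg[[k]])) {
      abort_config(sprintf("config field '%s' is required for this verb", k))
    }
    if (!file.exists(cfg[[k]])) {
      abort_data(sprintf("input '%s' not found: %s", k, cfg[[k]]))
    }
  }
}

run_simulate <- function(cfg, out_dir) {
  sc <- sim_config(seed = as.integer(cfg$seed %||% 1),
                   n_families = as.integer(cfg$n_families %||% 6),
                   cohort_scale = cfg$cohort_scale %||% 20)
  ref <- sim_reference(sc)
  sim_write(ref, out_dir)
}

load_annotation_inputs <- function(cfg) {
  require_inputs(cfg, c("cds_fasta", "exons", "alignments", "observed"))
  tx <- read_transcripts(cfg$cds_fasta, cfg$exons)
  if (!is.null(cfg$flanks) && file.exists(cfg$flanks)) {
    fl <- readr::read_tsv(cfg$flanks, show_col_types = FALSE,
                          progress = FALSE)
    tx <- tx |> left_join(fl, by = "transcript_id")
  }
  aln_files <- list.files(cfg$alignments, pattern = "\\.(sto|stk|fa|fasta)$",
                          full.names = TRUE)
  if (length(aln_files) == 0) {
    abort_data(paste0("no alignment files under ", cfg$alignments))
  }
  list(transcripts = tx,
       alignments = lapply(sort(aln_files), read_alignment),
       observed = read_observed_variants(cfg$observed))
}

run_annotate <- function(cfg, out_dir) {
  inp <- load_annotation_inputs(cfg)
  meta <- build_meta_positions(inp$alignments)
  ann <- enumerate_snvs(inp$transcripts) |>
    join_meta_positions(meta) |>
    apply_rarity_filter(inp$observed,
                        maf_threshold = cfg$maf_threshold)
  paths <- list(annotated = file.path(out_dir, "annotated.tsv"),
                meta_positions = file.path(out_dir, "meta_positions.tsv"))
  readr::write_tsv(ann, paths$annotated)
  write_meta_positions(meta, paths$meta_positions)
  paths
}

run_expect <- function(cfg, out_dir) {
  require_inputs(cfg, c("annotated", "rate_table"))
  ann <- readr::read_tsv(cfg$annotated, show_col_types = FALSE,
                         progress = FALSE)
  ann <- annotate_mutability(ann, cfg$rate_table,
                             coverage = cfg$coverage,
                             methylation = cfg$methylation)
  calibration <- calibrate_expected(ann)
  ann <- expected_counts(ann, calibration)
  paths <- list(expected = file.path(out_dir, "expected.tsv"),
                calibration = file.path(out_dir, "calibration.json"))
  readr::write_tsv(ann, paths$expected)
  jsonlite::write_json(unclass(calibration), paths$calibration,
                       auto_unbox = TRUE, digits = NA)
  paths
}

run_score <- function(cfg, out_dir) {
  require_inputs(cfg, "expected")
  ann <- readr::read_tsv(cfg$expected, show_col_types = FALSE,
                         progress = FALSE)
  records <- aggregate_constraint(ann, alpha = cfg$alpha,
                                  quantile = cfg$quantile, bins = cfg$bins,
                                  min_copies = cfg$min_copies)
  scores <- score_variants(records, ann)
  if (sum(records$powered) == 0) {
    warn("no powered meta-positions; score table is empty of assessments")
  }
  paths <- list(records = file.path(out_dir, "records.tsv"),
                scores = file.path(out_dir, "scores.tsv"))
  readr::write_tsv(tidy(records), paths$records)
  readr::write_tsv(scores, paths$scores)
  paths
}

run_evaluate <- function(cfg, out_dir) {
  require_inputs(cfg, c("scores", "labels"))
  scores <- readr::read_tsv(cfg$scores, show_col_types = FALSE,
                            progress = FALSE)
  labeled <- readr::read_tsv(cfg$labels, show_col_types = FALSE,
                             progress = FALSE)
  report <- bin_report(scores, labeled, bins = cfg$bins)
  joined <- labeled |>
    inner_join(scores |> select("chrom", "pos", "ref", "alt", "hmc"),
               by = c("chrom", "pos", "ref", "alt")) |>
    filter(!is.na(.data$hmc))
  paths <- list(bin_report = file.path(out_dir, "bin_report.tsv"))
  readr::write_tsv(report, paths$bin_report)
  if (nrow(joined) > 0 && length(unique(joined$label)) == 2) {
    pr <- precision_sensitivity(joined, "hmc", "label")
    paths$pr_curve <- file.path(out_dir, "pr_curve.tsv")
    readr::write_tsv(tidy(pr), paths$pr_curve)
  }
  paths
}

write_manifest <- function(verb, cfg, paths, out_dir) {
  inputs <- cfg[vapply(cfg, function(x)
    is.character(x) && length(x) == 1 && file.exists(x) &&
      !dir.exists(x), logical(1))]
  manifest <- list(
    verb = verb,
    version = as.character(packageVersion("hmcscore")),
    seed = cfg$seed,
    config = cfg[vapply(cfg, function(x) !is.function(x), logical(1))],
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))),
    artifacts = lapply(paths, as.character),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir,
                                           paste0("manifest_", verb, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
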