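# Pipeline assembly: one validated configuration object, a runner that
# chains the stages with per-stage accounting, and tabular report
# rendering (the figures of the study exist here as tables).

#' Pipeline configuration
#'
#' Defaults are the analysis' stated thresholds: 100 bp minimum read
#' length, Q20 quality, 100-read minimum abundance, 95% identity across at
#' least 100 bp for hits.
#'
#' @param min_len minimum read length (bp).
#' @param min_q Phred threshold for windowed quality trimming.
#' @param window quality window as a fraction of read length.
#' @param min_reads minimum reads per unique sequence.
#' @param min_identity,min_hit_len hit filter thresholds.
#' @param max_mismatch primer mismatch tolerance.
#' @param gap_comparison comparison universe for gap tests (`"parent"` or
#'   `"all"`).
#' @param abundance_before_assignment apply the 100-read filter before
#'   (`TRUE`, default) or after taxonomic assignment.
#' @param max_gap_days snow-lookup tolerance (days).
#' @param override_col optional expert-override column name.
#' @param seed seed recorded for simulation-driven runs.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_len = 100, min_q = 20, window = 0.1,
                            min_reads = 100, min_identity = 95,
                            min_hit_len = 100, max_mismatch = 2,
                            gap_comparison = "parent",
                            abundance_before_assignment = TRUE,
                            max_gap_days = 3, override_col = NULL, seed = 1) {
  for (f in c("min_len", "min_q", "min_reads", "min_identity", "min_hit_len")) {
    v <- get(f)
    if (!is.numeric(v) || v <= 0) abort(paste0("invalid '", f, "': must be positive"))
  }
  if (window <= 0 || window > 1) abort("invalid 'window': must be in (0, 1]")
  structure(list(
    min_len = min_len, min_q = min_q, window = window, min_reads = min_reads,
    min_identity = min_identity, min_hit_len = min_hit_len,
    max_mismatch = max_mismatch, gap_comparison = gap_comparison,
    abundance_before_assignment = abundance_before_assignment,
    max_gap_days = max_gap_days, override_col = override_col, seed = seed
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Sequencing side (when `reads` and `refs` are given): read QC
#' (primer/length/quality/dereplication), minimum-abundance filtering
#' (before or after assignment per the config), and gap-calibrated
#' taxonomic assignment. Observation side (when `observations` and
#' `traits` are given): cached-versus-fresh classification and cohort
#' tallies. Either side may be run alone.
#'
#' @param config a [pipeline_config()].
#' @param reads read tibble (optional).
#' @param refs aligned reference tibble (required with `reads`).
#' @param primer_fwd,primer_rev primer pair used for trimming.
#' @param marker marker of the sequencing data.
#' @param observations,traits,snow observation-side inputs (optional).
#' @return list with `log` (per-stage accounting), and whichever of
#'   `uniques`, `assignments`, `classified`, `summary`, `sac_presence`
#'   apply.
#' @export
run_pipeline <- function(config, reads = NULL, refs = NULL,
                         primer_fwd = NULL, primer_rev = NULL,
                         marker = "COI-5P",
                         observations = NULL, traits = NULL, snow = NULL) {
  if (!inherits(config, "pipeline_config")) abort("config must be a pipeline_config")
  out <- list()
  logs <- list()
  if (!is.null(reads)) {
    if (is.null(refs)) abort("refs are required when reads are supplied")
    if (is.null(primer_fwd) || is.null(primer_rev)) {
      abort("primer_fwd/primer_rev are required when reads are supplied")
    }
    qc <- run_read_qc(reads, primer_fwd, primer_rev,
                      max_mismatch = config$max_mismatch,
                      min_len = config$min_len, q_threshold = config$min_q,
                      window = config$window, min_reads = config$min_reads,
                      abundance_filter = config$abundance_before_assignment)
    logs <- c(logs, list(qc$log))
    uniques <- qc$uniques
    if (nrow(uniques) > 0) {
      uniques$query_id <- sprintf("u%04d", seq_len(nrow(uniques)))
    } else {
      uniques$query_id <- character(0)
    }
    asn <- assign_taxa(uniques, refs, marker = marker,
                       min_identity = config$min_identity,
                       min_hit_len = config$min_hit_len,
                       comparison = config$gap_comparison)
    logs <- c(logs, list(tibble(stage = "assign_taxa", n_in = nrow(uniques),
                                n_out = sum(asn$assigned_rank != "unassigned"))))
    if (!config$abundance_before_assignment) {
      uniques <- filter_min_reads(uniques, config$min_reads)
      logs <- c(logs, list(qc_log(uniques)))
      asn <- asn[asn$query_id %in% uniques$query_id, , drop = FALSE]
    }
    out$uniques <- uniques
    out$assignments <- asn
  }
  if (!is.null(observations)) {
    if (is.null(traits)) abort("traits are required when observations are supplied")
    cl <- classify_dataset(observations, traits, snow,
                           max_gap_days = config$max_gap_days,
                           override_col = config$override_col)
    logs <- c(logs, list(tibble(stage = "classify", n_in = nrow(observations),
                                n_out = nrow(cl))))
    out$classified <- cl
    out$summary <- attr(cl, "summary")
    out$sac_presence <- sac_level_cached_presence(cl)
  }
  out$log <- dplyr::bind_rows(logs)
  out
}

#' Render a tally table as TSV and JSON
#'
#' Emits both raw counts and percentages with a stable column order; the
#' two files hold identical cell values.
#'
#' @param tallies a tibble (e.g. from [designation_summary()] or
#'   [tally_diet()]).
#' @param path_prefix output path without extension.
#' @return named vector with the `tsv` and `json` paths, invisibly.
#' @export
render_report <- function(tallies, path_prefix) {
  stopifnot(is.data.frame(tallies))
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  readr::write_tsv(tallies, tsv)
  jsonlite::write_json(tallies, json, dataframe = "rows", digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}
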