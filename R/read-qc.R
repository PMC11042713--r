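# Amplicon read processing: primer trimming, length filter, windowed
# quality trimming, exact dereplication, and minimum-abundance filter.
#
# Reads travel as tibbles with columns read_id, sample_id, marker,
# sequence, quality (Phred+33 string). Every filter returns the retained
# tibble; rejected reads and stage accounting are exposed via attributes
# ("rejects", "qc_log") so the pipeline can keep records_in =
# records_out + records_dropped at every stage.

qc_result <- function(reads, stage, n_in, rejects = NULL) {
  attr(reads, "qc_log") <- tibble(stage = stage, n_in = n_in, n_out = nrow(reads))
  attr(reads, "rejects") <- rejects %||% tibble(read_id = character(0), reason = character(0))
  reads
}

#' Stage accounting attached to a QC result
#' @param x result of a QC step.
#' @return tibble with `stage`, `n_in`, `n_out`.
#' @export
qc_log <- function(x) attr(x, "qc_log")

#' Rejected reads attached to a QC result
#' @param x result of a QC step.
#' @return tibble with `read_id`, `reason`.
#' @export
qc_rejects <- function(x) attr(x, "rejects")

# mismatches of an anchored primer against a same-length read chunk;
# a read base matches if it lies in the IUPAC expansion of the primer code
iupac_mismatches <- function(chunk, primer) {
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  cc <- strsplit(toupper(chunk), "", fixed = TRUE)[[1]]
  sum(!mapply(function(p, b) b %in% IUPAC_MAP[[p]], pc, cc))
}

#' Trim primer flanks off reads
#'
#' Anchored, IUPAC-aware matching: the forward primer must sit at the 5'
#' end and the reverse-complemented reverse primer at the 3' end, each with
#' at most `max_mismatch` mismatches. Matching flanks and their qualities
#' are excised; non-matching reads are rejected with a reason.
#'
#' @param reads read tibble.
#' @param primer_fwd,primer_rev primer sequences (IUPAC codes allowed).
#' @param max_mismatch mismatches tolerated per primer (default 2).
#' @return retained, trimmed read tibble; see [qc_rejects()] for rejects.
#' @export
trim_primers <- function(reads, primer_fwd, primer_rev, max_mismatch = 2) {
  if (!nzchar(primer_fwd) || !nzchar(primer_rev)) abort("primers must be non-empty")
  primer_fwd <- toupper(primer_fwd); primer_rev <- toupper(primer_rev)
  if (!is_iupac(primer_fwd) || !is_iupac(primer_rev)) {
    abort("primers contain non-IUPAC characters")
  }
  rc_rev <- revcomp(primer_rev)
  nf <- nchar(primer_fwd); nr <- nchar(rc_rev)
  n_in <- nrow(reads)
  if (n_in == 0) return(qc_result(reads, "trim_primers", 0))

  reason <- rep(NA_character_, n_in)
  len <- nchar(reads$sequence)
  for (i in seq_len(n_in)) {
    if (len[i] < nf + nr) { reason[i] <- "too_short_for_primers"; next }
    if (iupac_mismatches(substr(reads$sequence[i], 1, nf), primer_fwd) > max_mismatch) {
      reason[i] <- "no_forward_primer"; next
    }
    if (iupac_mismatches(substr(reads$sequence[i], len[i] - nr + 1, len[i]), rc_rev) > max_mismatch) {
      reason[i] <- "no_reverse_primer"
    }
  }
  keep <- is.na(reason)
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substr(out$sequence, nf + 1, len[keep] - nr)
  out$quality <- substr(out$quality, nf + 1, len[keep] - nr)
  qc_result(out, "trim_primers", n_in,
            tibble(read_id = reads$read_id[!keep], reason = reason[!keep]))
}

#' Remove reads shorter than a minimum length
#'
#' Reads of exactly `min_len` bases are retained; only strictly shorter
#' reads are removed.
#'
#' @param reads read tibble.
#' @param min_len minimum length in bases (default 100).
#' @return retained read tibble.
#' @export
filter_length <- function(reads, min_len = 100) {
  if (min_len < 1) abort("min_len must be >= 1")
  keep <- nchar(reads$sequence) >= min_len
  qc_result(reads[keep, , drop = FALSE], "filter_length", nrow(reads),
            tibble(read_id = reads$read_id[!keep],
                   reason = rep("short_read", sum(!keep))))
}

# 1-based position before which the read is kept: first window whose mean
# Phred drops below the threshold truncates the read at the window start
quality_trim_point <- function(q, q_threshold, window) {
  L <- length(q)
  if (L == 0) return(0L)
  w <- max(1L, as.integer(floor(window * L)))
  cs <- cumsum(c(0, q))
  means <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
  bad <- which(means < q_threshold)
  if (length(bad) == 0) L else bad[1] - 1L
}

#' Quality-trim reads by windowed mean Phred score
#'
#' Sliding-window trimming in the style of read-trimming tools: with a
#' window of `window * read length` bases, the read is truncated at the
#' start of the first window whose mean quality falls below `q_threshold`.
#' Reads trimmed to zero length are removed here; shorter survivors are
#' expected to be removed by a downstream [filter_length()].
#'
#' @param reads read tibble.
#' @param q_threshold Phred threshold (default 20).
#' @param window window size as a fraction of read length in `(0, 1]`.
#' @return retained (possibly truncated) read tibble.
#' @export
filter_quality <- function(reads, q_threshold = 20, window = 0.1) {
  if (window <= 0 || window > 1) abort("window must be in (0, 1]")
  n_in <- nrow(reads)
  if (n_in == 0) return(qc_result(reads, "filter_quality", 0))
  qints <- phred_to_int(reads$quality)
  cut <- vapply(qints, quality_trim_point, integer(1),
                q_threshold = q_threshold, window = window)
  out <- reads
  out$sequence <- substr(out$sequence, 1, cut)
  out$quality <- substr(out$quality, 1, cut)
  keep <- cut > 0
  qc_result(out[keep, , drop = FALSE], "filter_quality", n_in,
            tibble(read_id = reads$read_id[!keep],
                   reason = rep("all_low_quality", sum(!keep))))
}

#' Collapse identical reads into unique sequences with counts
#'
#' Exact (100% identity) dereplication within each (sample, marker) pair.
#' Output is canonically ordered (sample, marker, decreasing count, then
#' sequence), so it does not depend on input read order.
#'
#' @param reads read tibble (already trimmed/filtered).
#' @return tibble of unique sequences: `sample_id`, `marker`, `sequence`,
#'   `read_count`.
#' @export
dereplicate <- function(reads) {
  reads |>
    dplyr::count(.data$sample_id, .data$marker, .data$sequence, name = "read_count") |>
    dplyr::arrange(.data$sample_id, .data$marker,
                   dplyr::desc(.data$read_count), .data$sequence) |>
    dplyr::select("sample_id", "marker", "sequence", "read_count")
}

#' Remove unique sequences below a minimum read count
#'
#' Sequences with exactly `min_reads` reads are retained; only those with
#' fewer are excluded.
#'
#' @param uniques unique-sequence tibble from [dereplicate()].
#' @param min_reads minimum read count (default 100).
#' @return retained unique-sequence tibble.
#' @export
filter_min_reads <- function(uniques, min_reads = 100) {
  if (min_reads < 1) abort("min_reads must be >= 1")
  keep <- uniques$read_count >= min_reads
  out <- uniques[keep, , drop = FALSE]
  attr(out, "qc_log") <- tibble(stage = "filter_min_reads",
                                n_in = nrow(uniques), n_out = nrow(out))
  out
}

#' Run the full read-QC chain
#'
#' Primer trimming, length filter, windowed quality trimming, the length
#' filter again (quality trimming can shorten reads), dereplication, and
#' optionally the minimum-abundance filter.
#'
#' @param reads read tibble.
#' @param primer_fwd,primer_rev primer pair.
#' @param max_mismatch primer mismatch tolerance.
#' @param min_len length filter (bp).
#' @param q_threshold,window quality-trimming parameters.
#' @param min_reads abundance filter threshold.
#' @param abundance_filter apply the abundance filter here (`TRUE`) or defer
#'   it to after taxonomic assignment (`FALSE`).
#' @return list with `uniques`, `reads` (filtered reads), and `log` (per-
#'   stage accounting tibble).
#' @export
run_read_qc <- function(reads, primer_fwd, primer_rev, max_mismatch = 2,
                        min_len = 100, q_threshold = 20, window = 0.1,
                        min_reads = 100, abundance_filter = TRUE) {
  logs <- list()
  r <- trim_primers(reads, primer_fwd, primer_rev, max_mismatch)
  logs <- c(logs, list(qc_log(r)))
  r <- filter_length(r, min_len); logs <- c(logs, list(qc_log(r)))
  r <- filter_quality(r, q_threshold, window); logs <- c(logs, list(qc_log(r)))
  r <- filter_length(r, min_len); logs <- c(logs, list(qc_log(r)))
  uniques <- dereplicate(r)
  logs <- c(logs, list(tibble(stage = "dereplicate", n_in = nrow(r), n_out = nrow(uniques))))
  if (abundance_filter) {
    uniques <- filter_min_reads(uniques, min_reads)
    logs <- c(logs, list(qc_log(uniques)))
  }
  list(uniques = uniques, reads = r, log = dplyr::bind_rows(logs))
}
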