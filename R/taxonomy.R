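# Taxonomic assignment of unique sequences: identity-filtered hits against
# an aligned reference library, with assignment rank calibrated by a
# barcode-gap analysis (maximum within-taxon p-distance versus minimum
# distance to the nearest neighbouring taxon).

#' Pairwise p-distance between two aligned sequences
#'
#' Proportion of differing sites among sites where neither sequence has a
#' gap (`-`) or an ambiguous base (pairwise deletion). Symmetric by
#' construction.
#'
#' @param a,b aligned sequences of equal length.
#' @return distance in `[0, 1]`; `NA` if no comparable sites remain.
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("p_distance: sequences must have equal length")
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  ok <- ca %in% acgt & cb %in% acgt
  if (!any(ok)) return(NA_real_)
  mean(ca[ok] != cb[ok])
}

#' Full pairwise p-distance matrix for an aligned set
#'
#' @param seqs character vector of aligned sequences (equal length).
#' @param labels row/column labels (default names or indices).
#' @return square symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(seqs, labels = NULL) {
  n <- length(seqs)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  if (length(unique(nchar(seqs))) != 1) {
    abort("p_distance_matrix: sequences must be aligned to equal length")
  }
  labels <- labels %||% names(seqs) %||% as.character(seq_len(n))
  chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  ok <- matrix(chars %in% c("A", "C", "G", "T"), nrow = n)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq((i + 1), n)) {
      comp <- ok[i, ] & ok[j, ]
      d[i, j] <- d[j, i] <- if (any(comp)) mean(chars[i, comp] != chars[j, comp]) else NA_real_
    }
  }
  d
}

#' Quality-control an aligned reference library
#'
#' Removes records with more than `max_ambiguity` unknown nucleotides
#' (characters other than A/C/G/T or `-`, as a fraction of non-gap sites)
#' or with more than `max_terminal_gaps` consecutive `-` characters at
#' either end of the alignment.
#'
#' @param refs reference tibble with `aligned_sequence`.
#' @param max_ambiguity maximum tolerated ambiguous fraction (default 0.02).
#' @param max_terminal_gaps maximum tolerated terminal gap run (default 12).
#' @return retained reference tibble; removed records with reasons in
#'   `attr(, "removed")`.
#' @export
reference_qc <- function(refs, max_ambiguity = 0.02, max_terminal_gaps = 12) {
  if (nrow(refs) == 0) return(refs)
  if (length(unique(nchar(refs$aligned_sequence))) != 1) {
    abort("reference_qc: sequences are not aligned (unequal lengths)")
  }
  stats_of <- function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    gap <- chars == "-"
    n_nongap <- sum(!gap)
    amb <- sum(!gap & !(chars %in% c("A", "C", "G", "T")))
    lead <- if (gap[1]) rle(gap)$lengths[1] else 0L
    rg <- rev(gap)
    trail <- if (rg[1]) rle(rg)$lengths[1] else 0L
    c(amb_frac = if (n_nongap > 0) amb / n_nongap else 1, lead = lead, trail = trail)
  }
  st <- t(vapply(refs$aligned_sequence, stats_of,
                 c(amb_frac = 0, lead = 0, trail = 0)))
  too_amb <- st[, "amb_frac"] > max_ambiguity
  too_gappy <- st[, "lead"] > max_terminal_gaps | st[, "trail"] > max_terminal_gaps
  keep <- !(too_amb | too_gappy)
  out <- refs[keep, , drop = FALSE]
  attr(out, "removed") <- tibble(
    record_id = refs$record_id[!keep],
    reason = ifelse(too_amb[!keep], "excess_ambiguity", "terminal_gap_run")
  )
  out
}

#' Barcode-gap analysis for one focal taxon
#'
#' Compares the maximum p-distance within the focal group against the
#' minimum p-distance from any focal member to any member of the
#' comparison set. A barcode gap exists when the smallest between-group
#' distance strictly exceeds the largest within-group distance; equality
#' counts as no gap. With a species-rank test the comparison set is the
#' focal species' congeners; with a genus-rank test, its confamilial
#' genera (`comparison = "parent"`), or all non-focal records
#' (`comparison = "all"`).
#'
#' @param refs QC-passed aligned reference tibble (`species`, `genus`,
#'   `family`, `aligned_sequence`).
#' @param focal_taxon focal species or genus label.
#' @param rank `"species"` or `"genus"`.
#' @param comparison `"parent"` (default) or `"all"`.
#' @return one-row tibble: `focal_taxon`, `rank_tested`, `max_intra`,
#'   `min_inter`, `n_intra_pairs`, `n_inter_pairs`, `has_gap` (`NA` when
#'   undetermined), `verdict` (`"gap"`, `"no_gap"`, `"undetermined"`).
#' @export
gap_analysis <- function(refs, focal_taxon, rank = c("species", "genus"),
                         comparison = c("parent", "all")) {
  rank <- match.arg(rank)
  comparison <- match.arg(comparison)
  focal <- refs[[rank]] == focal_taxon
  if (!any(focal)) abort(paste0("focal taxon '", focal_taxon, "' absent from references"))
  if (comparison == "parent") {
    parent_rank <- if (rank == "species") "genus" else "family"
    parent <- refs[[parent_rank]][focal][1]
    comp <- !focal & refs[[parent_rank]] == parent
  } else {
    comp <- !focal
  }
  fseq <- refs$aligned_sequence[focal]
  cseq <- refs$aligned_sequence[comp]

  n_f <- length(fseq)
  n_intra <- n_f * (n_f - 1) / 2
  max_intra <- NA_real_
  if (n_intra >= 1) {
    dmax <- -Inf
    for (i in seq_len(n_f - 1)) for (j in seq(i + 1, n_f)) {
      dij <- p_distance(fseq[i], fseq[j])
      if (!is.na(dij) && dij > dmax) dmax <- dij
    }
    if (is.finite(dmax)) max_intra <- dmax
  }
  n_inter <- n_f * length(cseq)
  min_inter <- NA_real_
  if (n_inter >= 1) {
    dmin <- Inf
    for (i in seq_len(n_f)) for (j in seq_along(cseq)) {
      dij <- p_distance(fseq[i], cseq[j])
      if (!is.na(dij) && dij < dmin) dmin <- dij
    }
    if (is.finite(dmin)) min_inter <- dmin
  }
  has_gap <- if (n_intra >= 1 && n_inter >= 1 && !is.na(max_intra) && !is.na(min_inter)) {
    min_inter > max_intra
  } else NA
  tibble(
    focal_taxon = focal_taxon, rank_tested = rank,
    max_intra = max_intra, min_inter = min_inter,
    n_intra_pairs = as.integer(n_intra), n_inter_pairs = as.integer(n_inter),
    has_gap = has_gap,
    verdict = if (is.na(has_gap)) "undetermined" else if (has_gap) "gap" else "no_gap"
  )
}

#' Barcode-gap analysis for every taxon in a library
#'
#' @param refs QC-passed reference tibble.
#' @param rank `"species"` or `"genus"`.
#' @param comparison passed to [gap_analysis()].
#' @return tibble with one [gap_analysis()] row per distinct taxon at
#'   `rank`.
#' @export
library_gap_analysis <- function(refs, rank = c("species", "genus"),
                                 comparison = "parent") {
  rank <- match.arg(rank)
  taxa <- unique(refs[[rank]])
  dplyr::bind_rows(lapply(taxa, function(t) {
    gap_analysis(refs, t, rank = rank, comparison = comparison)
  }))
}

# ---- similarity search -----------------------------------------------------

#' Local-alignment search of a query against a reference library
#'
#' A deterministic stand-in for an external similarity search: each
#' reference is aligned to the query with Smith-Waterman local alignment
#' (match +1, mismatch -1, linear gap cost 2) and reported as a hit with
#' percent identity (matches / alignment columns) and alignment length.
#'
#' @param query query sequence (character) or one-row unique-sequence
#'   tibble with `sequence` (and optionally `marker`).
#' @param refs reference tibble (`record_id`, taxonomy, `aligned_sequence`,
#'   `marker`); alignment gaps are stripped before searching.
#' @param query_id id recorded for the query.
#' @return hit tibble sorted by decreasing (identity, length, score):
#'   `query_id`, `subject_id`, `species`, `genus`, `family`,
#'   `percent_identity`, `alignment_length`, `score`.
#' @export
naive_search <- function(query, refs, query_id = "query") {
  if (nrow(refs) == 0) abort("naive_search: reference set is empty")
  if (is.data.frame(query)) {
    if ("marker" %in% names(query) && "marker" %in% names(refs) &&
        !all(refs$marker == query$marker[1])) {
      abort("naive_search: query and reference markers differ")
    }
    if ("query_id" %in% names(query)) query_id <- query$query_id[1]
    query <- query$sequence[1]
  }
  subj <- gsub("-", "", refs$aligned_sequence, fixed = TRUE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(subj),
    subject = Biostrings::DNAString(query),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
  alen <- Biostrings::nchar(aln)
  nmatch <- Biostrings::nmatch(aln)
  hits <- tibble(
    query_id = query_id,
    subject_id = refs$record_id,
    species = refs$species, genus = refs$genus, family = refs$family,
    percent_identity = ifelse(alen > 0, 100 * nmatch / alen, 0),
    alignment_length = as.integer(alen),
    score = BiocGenerics::score(aln)
  )
  dplyr::arrange(hits, dplyr::desc(.data$percent_identity),
                 dplyr::desc(.data$alignment_length), dplyr::desc(.data$score),
                 .data$subject_id)
}

#' Filter hits on identity and alignment length
#'
#' Retains hits with at least `min_identity` percent identity across at
#' least `min_length` aligned bases (both thresholds inclusive).
#'
#' @param hits hit tibble.
#' @param min_identity minimum percent identity (default 95).
#' @param min_length minimum alignment length in bp (default 100).
#' @return retained hit tibble.
#' @export
filter_hits <- function(hits, min_identity = 95, min_length = 100) {
  hits[hits$percent_identity >= min_identity &
         hits$alignment_length >= min_length, , drop = FALSE]
}

#' Candidate taxon from filtered hits
#'
#' Takes the best surviving hit by lexicographic (identity, length, score).
#' If several hits tie exactly at the top but name distinct species, the
#' candidate is promoted to the lowest taxonomic rank they share (genus,
#' then family); if they share no rank the query is left unassigned.
#'
#' @param query_id query to resolve.
#' @param hits filtered hit tibble (may contain other queries).
#' @return one-row tibble: `query_id`, `rank` (`"species"`, `"genus"`,
#'   `"family"`, `"none"`), `species`, `genus`, `family`.
#' @export
candidate_species <- function(query_id, hits) {
  h <- hits[hits$query_id == query_id, , drop = FALSE]
  none <- tibble(query_id = query_id, rank = "none",
                 species = NA_character_, genus = NA_character_,
                 family = NA_character_)
  if (nrow(h) == 0) return(none)
  h <- dplyr::arrange(h, dplyr::desc(.data$percent_identity),
                      dplyr::desc(.data$alignment_length),
                      dplyr::desc(.data$score), .data$subject_id)
  top <- h[h$percent_identity == h$percent_identity[1] &
             h$alignment_length == h$alignment_length[1] &
             h$score == h$score[1], , drop = FALSE]
  if (length(unique(top$species)) == 1) {
    return(tibble(query_id = query_id, rank = "species",
                  species = top$species[1], genus = top$genus[1],
                  family = top$family[1]))
  }
  if (length(unique(top$genus)) == 1) {
    return(tibble(query_id = query_id, rank = "genus",
                  species = NA_character_, genus = top$genus[1],
                  family = top$family[1]))
  }
  if (length(unique(top$family)) == 1) {
    return(tibble(query_id = query_id, rank = "family",
                  species = NA_character_, genus = NA_character_,
                  family = top$family[1]))
  }
  none
}

rank_order <- c(species = 1L, genus = 2L, family = 3L, none = 4L, unassigned = 4L)

lookup_verdict <- function(gap_results, taxon, rank) {
  row <- gap_results[gap_results$focal_taxon == taxon &
                       gap_results$rank_tested == rank, , drop = FALSE]
  if (nrow(row) == 0) NA_character_ else row$verdict[1]
}

#' Pull an assignment back to a reliable rank using gap results
#'
#' Animal markers (COI-5P, and ITS2 by the same scheme) report at species
#' rank only when the candidate species shows a barcode gap, otherwise at
#' genus. The plant marker (rbcLa) additionally tests the genus: no
#' species gap and no genus gap pulls the identification back to family.
#' An undetermined gap test (singleton group, no comparison set) is
#' treated as no gap — conservative pullback. A *missing* gap result for a
#' needed rank yields an unassigned record with a flag.
#'
#' @param candidate one-row tibble from [candidate_species()].
#' @param gap_results tibble from [library_gap_analysis()] (species rows;
#'   plus genus rows for rbcLa).
#' @param marker `"COI-5P"`, `"ITS2"`, or `"rbcLa"`.
#' @return one-row assignment tibble: `query_id`, `assigned_rank`,
#'   `assigned_taxon`, `fallback_reason`.
#' @export
apply_rank_fallback <- function(candidate, gap_results,
                                marker = c("COI-5P", "ITS2", "rbcLa")) {
  marker <- match.arg(marker)
  out <- function(rank, taxon, reason = NA_character_) {
    tibble(query_id = candidate$query_id, assigned_rank = rank,
           assigned_taxon = taxon, fallback_reason = reason)
  }
  if (candidate$rank == "none") {
    return(out("unassigned", NA_character_, "no_surviving_hits"))
  }
  if (candidate$rank == "family") {
    # animal markers cap at genus, so a family-level tie is unresolvable
    if (marker != "rbcLa") return(out("unassigned", NA_character_, "tie_beyond_genus"))
    return(out("family", candidate$family, "hit_tie_at_family"))
  }
  if (candidate$rank == "species") {
    v <- lookup_verdict(gap_results, candidate$species, "species")
    if (is.na(v)) return(out("unassigned", NA_character_, "missing_gap_result:species"))
    if (v == "gap") return(out("species", candidate$species))
  }
  # at (or pulled back to) genus
  reason_sp <- if (candidate$rank == "genus") "hit_tie_at_genus" else "no_species_gap"
  if (marker != "rbcLa") return(out("genus", candidate$genus, reason_sp))
  vg <- lookup_verdict(gap_results, candidate$genus, "genus")
  if (is.na(vg)) return(out("unassigned", NA_character_, "missing_gap_result:genus"))
  if (vg == "gap") return(out("genus", candidate$genus, reason_sp))
  out("family", candidate$family, paste0(reason_sp, ";no_genus_gap"))
}

#' Assign taxa to unique sequences against a reference library
#'
#' Runs reference QC, the local-alignment search, hit filtering, candidate
#' selection, per-library gap analyses, and rank fallback for every unique
#' sequence.
#'
#' @param uniques unique-sequence tibble ([dereplicate()] output) with a
#'   `query_id` column (added from row order if absent).
#' @param refs aligned reference tibble.
#' @param marker marker of the analysis.
#' @param min_identity,min_hit_len hit filter thresholds.
#' @param comparison gap-analysis comparison universe.
#' @return assignment tibble: one row per query with candidate fields,
#'   `assigned_rank`, `assigned_taxon`, `fallback_reason`.
#' @export
assign_taxa <- function(uniques, refs, marker = "COI-5P",
                        min_identity = 95, min_hit_len = 100,
                        comparison = "parent") {
  if (!"query_id" %in% names(uniques)) {
    uniques$query_id <- sprintf("u%04d", seq_len(nrow(uniques)))
  }
  if (nrow(uniques) == 0) {
    return(tibble(query_id = character(0), candidate_rank = character(0),
                  species = character(0), genus = character(0),
                  family = character(0), assigned_rank = character(0),
                  assigned_taxon = character(0), fallback_reason = character(0)))
  }
  refs <- reference_qc(refs)
  gaps <- library_gap_analysis(refs, "species", comparison)
  if (marker == "rbcLa") {
    gaps <- dplyr::bind_rows(gaps, library_gap_analysis(refs, "genus", comparison))
  }
  rows <- lapply(seq_len(nrow(uniques)), function(i) {
    hits <- naive_search(uniques$sequence[i], refs, query_id = uniques$query_id[i])
    hits <- filter_hits(hits, min_identity, min_hit_len)
    cand <- candidate_species(uniques$query_id[i], hits)
    asn <- apply_rank_fallback(cand, gaps, marker)
    dplyr::bind_cols(
      dplyr::select(cand, candidate_rank = "rank", "species", "genus", "family"),
      dplyr::select(asn, "query_id", "assigned_rank", "assigned_taxon", "fallback_reason")
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "query_id", "candidate_rank", "species", "genus", "family",
                "assigned_rank", "assigned_taxon", "fallback_reason")
}

#' Read a 12-column tabular hit file (outfmt-6 dialect)
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore. Subject ids carrying
#' `record|species|genus|family` labels are unpacked into taxonomy
#' columns.
#'
#' @param path tab-separated hit file without header.
#' @return hit tibble compatible with [filter_hits()].
#' @export
read_hit_table <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "score")
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE)
  parts <- strsplit(x$subject_id, "|", fixed = TRUE)
  if (all(lengths(parts) == 4)) {
    x$species <- vapply(parts, `[`, character(1), 2)
    x$genus <- vapply(parts, `[`, character(1), 3)
    x$family <- vapply(parts, `[`, character(1), 4)
    x$subject_id <- vapply(parts, `[`, character(1), 1)
  }
  x
}
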