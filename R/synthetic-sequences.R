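# Synthetic reference libraries and error-bearing amplicon reads.
#
# The generator emulates the shape of curated barcode reference sets
# (aligned marker sequences carrying species/genus/family labels) and of
# unidirectional amplicon sequencing: substitution errors only, per-base
# Phred qualities, primer flanks. No chimeras, indels, or
# homopolymer-specific errors are simulated.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0("invalid '", field, "': must be a single number in [0, 1]"))
  }
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(paste0("invalid '", field, "': must be an integer >= ", min))
  }
}

#' Specification for a synthetic aligned reference library
#'
#' Describes a library of `n_taxa` species, each with `seqs_per_taxon`
#' aligned sequences. Sequences are generated on a three-level hierarchy
#' (family root -> genus ancestor -> species ancestor -> individual) under
#' uniform random substitutions. Individuals diverge from their species
#' ancestor at `intra_divergence` per site; ancestors accrue an extra
#' `max(0, inter_divergence - intra_divergence)` per site at each ancestral
#' step, so `inter_divergence <= intra_divergence` collapses the between-
#' taxon signal and the library has no barcode gap.
#'
#' @param n_taxa number of species.
#' @param seqs_per_taxon sequences per species.
#' @param seq_length sites per sequence.
#' @param intra_divergence per-site substitution probability within species.
#' @param inter_divergence per-site divergence target between species.
#' @param ambiguity_rate fraction of sites replaced by `N` per sequence.
#' @param terminal_gap_run number of `-` characters overwriting each end of
#'   every sequence (to exercise reference QC); default 0.
#' @param species_per_genus,genera_per_family shape of the default taxonomy.
#' @param rank_labels optional data frame (`species`, `genus`, `family`) with
#'   one row per taxon, overriding the default labels.
#' @param marker marker name attached to all records.
#' @param seed RNG seed.
#' @return a validated list of class `ref_library_spec`.
#' @export
ref_library_spec <- function(n_taxa, seqs_per_taxon, seq_length = 300,
                             intra_divergence = 0.01, inter_divergence = 0.10,
                             ambiguity_rate = 0, terminal_gap_run = 0,
                             species_per_genus = 2, genera_per_family = 2,
                             rank_labels = NULL, marker = "COI-5P", seed = 1) {
  check_count(n_taxa, "n_taxa")
  check_count(seqs_per_taxon, "seqs_per_taxon")
  check_count(seq_length, "seq_length", min = 10)
  check_fraction(intra_divergence, "intra_divergence")
  check_fraction(inter_divergence, "inter_divergence")
  check_fraction(ambiguity_rate, "ambiguity_rate")
  check_count(terminal_gap_run + 1, "terminal_gap_run") # allows 0
  check_count(species_per_genus, "species_per_genus")
  check_count(genera_per_family, "genera_per_family")
  if (!is.null(rank_labels)) {
    need <- c("species", "genus", "family")
    if (!all(need %in% names(rank_labels)) || nrow(rank_labels) != n_taxa) {
      abort("invalid 'rank_labels': need species/genus/family columns, one row per taxon")
    }
  }
  structure(list(
    n_taxa = as.integer(n_taxa), seqs_per_taxon = as.integer(seqs_per_taxon),
    seq_length = as.integer(seq_length),
    intra_divergence = intra_divergence, inter_divergence = inter_divergence,
    ambiguity_rate = ambiguity_rate, terminal_gap_run = as.integer(terminal_gap_run),
    species_per_genus = as.integer(species_per_genus),
    genera_per_family = as.integer(genera_per_family),
    rank_labels = rank_labels, marker = marker, seed = seed
  ), class = "ref_library_spec")
}

default_rank_labels <- function(n_taxa, species_per_genus, genera_per_family) {
  genus_idx <- ceiling(seq_len(n_taxa) / species_per_genus)
  family_idx <- ceiling(genus_idx / genera_per_family)
  data.frame(
    species = sprintf("Species_%02d", seq_len(n_taxa)),
    genus = sprintf("Genus_%02d", genus_idx),
    family = sprintf("Family_%02d", family_idx),
    stringsAsFactors = FALSE
  )
}

#' Expected p-distance between two lineages at per-lineage rate `d`
#'
#' Under uniform substitutions to one of the three alternative bases with
#' probability `d` per lineage, a site differs with probability
#' `2 d (1 - d) + (2/3) d^2`.
#'
#' @param d per-lineage substitution probability.
#' @return expected proportion of differing sites.
#' @export
expected_pairwise_p <- function(d) 2 * d * (1 - d) + (2 / 3) * d^2

#' Generate a synthetic aligned reference library
#'
#' @param spec a [ref_library_spec()].
#' @return tibble with `record_id`, `species`, `genus`, `family`, `marker`,
#'   `aligned_sequence`; `n_taxa * seqs_per_taxon` rows.
#' @export
gen_reference_library <- function(spec) {
  if (!inherits(spec, "ref_library_spec")) abort("spec must be a ref_library_spec")
  labels <- spec$rank_labels %||%
    default_rank_labels(spec$n_taxa, spec$species_per_genus, spec$genera_per_family)
  e <- max(0, spec$inter_divergence - spec$intra_divergence)
  with_seed(spec$seed, {
    families <- unique(labels$family)
    roots <- stats::setNames(random_dna(length(families), spec$seq_length), families)
    genera <- unique(labels[, c("genus", "family")])
    genus_anc <- stats::setNames(
      vapply(seq_len(nrow(genera)),
             function(i) mutate_seq(roots[[genera$family[i]]], e), character(1)),
      genera$genus
    )
    species_anc <- vapply(seq_len(spec$n_taxa), function(i) {
      mutate_seq(genus_anc[[labels$genus[i]]], e)
    }, character(1))
    rows <- lapply(seq_len(spec$n_taxa), function(i) {
      seqs <- vapply(seq_len(spec$seqs_per_taxon), function(j) {
        s <- mutate_seq(species_anc[i], spec$intra_divergence)
        if (spec$ambiguity_rate > 0) {
          chars <- strsplit(s, "", fixed = TRUE)[[1]]
          amb <- stats::runif(length(chars)) < spec$ambiguity_rate
          chars[amb] <- "N"
          s <- paste(chars, collapse = "")
        }
        if (spec$terminal_gap_run > 0) {
          k <- min(spec$terminal_gap_run, floor(nchar(s) / 2))
          substr(s, 1, k) <- strrep("-", k)
          substr(s, nchar(s) - k + 1, nchar(s)) <- strrep("-", k)
        }
        s
      }, character(1))
      tibble(
        record_id = sprintf("%s_r%02d", gsub(" ", "_", labels$species[i]),
                            seq_len(spec$seqs_per_taxon)),
        species = labels$species[i], genus = labels$genus[i],
        family = labels$family[i], marker = spec$marker,
        aligned_sequence = seqs
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Specification for simulated amplicon reads
#'
#' @param reads_per_template reads generated from each template (recycled
#'   across templates).
#' @param error_rate per-base substitution probability in `[0, 1]`.
#' @param q_mean,q_sd mean and spread of per-base Phred scores (drawn from a
#'   normal truncated to `[0, 60]` and rounded).
#' @param primer_fwd,primer_rev forward/reverse primer sequences (the
#'   reverse primer is appended reverse-complemented, as it appears on an
#'   unidirectional read).
#' @param min_abundance_spike optional read count forced for the *first*
#'   template (to place a sequence just above/below an abundance filter).
#' @param sample_id sample label attached to all reads.
#' @param seed RNG seed.
#' @return a validated list of class `read_sim_spec`.
#' @export
read_sim_spec <- function(reads_per_template = 10, error_rate = 0,
                          q_mean = 35, q_sd = 4,
                          primer_fwd = "ACGTACGTAC", primer_rev = "TGCATGCATG",
                          min_abundance_spike = NULL, sample_id = "S01",
                          seed = 1) {
  check_fraction(error_rate, "error_rate")
  if (any(reads_per_template < 1)) abort("invalid 'reads_per_template': must be >= 1")
  if (q_mean < 0 || q_mean > 60) abort("invalid 'q_mean': Phred scores lie in [0, 60]")
  if (!is_iupac(primer_fwd) || !is_iupac(primer_rev)) {
    abort("invalid 'primer_fwd'/'primer_rev': non-IUPAC characters")
  }
  if (!is.null(min_abundance_spike)) check_count(min_abundance_spike, "min_abundance_spike")
  structure(list(
    reads_per_template = as.integer(reads_per_template), error_rate = error_rate,
    q_mean = q_mean, q_sd = q_sd,
    primer_fwd = toupper(primer_fwd), primer_rev = toupper(primer_rev),
    min_abundance_spike = min_abundance_spike, sample_id = sample_id, seed = seed
  ), class = "read_sim_spec")
}

sim_quality <- function(n, q_mean, q_sd) {
  q <- round(stats::rnorm(n, q_mean, q_sd))
  pmin(pmax(q, 0), 60)
}

#' Simulate reads from reference templates
#'
#' Each read is `primer_fwd + mutated(template) + revcomp(primer_rev)` with
#' a Phred quality string over the whole read. Alignment gaps in templates
#' are removed before mutation.
#'
#' @param templates tibble with `record_id` and `aligned_sequence` (or
#'   `sequence`) columns, e.g. from [gen_reference_library()].
#' @param spec a [read_sim_spec()].
#' @return tibble of reads: `read_id`, `sample_id`, `marker`, `template_id`,
#'   `sequence`, `quality` (Phred+33 string).
#' @export
gen_reads <- function(templates, spec) {
  if (!inherits(spec, "read_sim_spec")) abort("spec must be a read_sim_spec")
  if (is.null(templates) || nrow(templates) == 0) abort("templates must be non-empty")
  seq_col <- if ("aligned_sequence" %in% names(templates)) "aligned_sequence" else "sequence"
  marker <- if ("marker" %in% names(templates)) templates$marker else "COI-5P"
  n_reads <- rep_len(spec$reads_per_template, nrow(templates))
  if (!is.null(spec$min_abundance_spike)) n_reads[1] <- spec$min_abundance_spike
  rc_rev <- revcomp(spec$primer_rev)
  with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(templates)), function(i) {
      body <- gsub("-", "", templates[[seq_col]][i], fixed = TRUE)
      seqs <- vapply(seq_len(n_reads[i]), function(j) {
        paste0(spec$primer_fwd, mutate_seq(body, spec$error_rate), rc_rev)
      }, character(1))
      quals <- vapply(seqs, function(s) {
        int_to_phred(sim_quality(nchar(s), spec$q_mean, spec$q_sd))
      }, character(1), USE.NAMES = FALSE)
      tibble(
        read_id = sprintf("%s_read%04d", templates$record_id[i], seq_len(n_reads[i])),
        sample_id = spec$sample_id, marker = marker[min(i, length(marker))],
        template_id = templates$record_id[i], sequence = seqs, quality = quals
      )
    })
    dplyr::bind_rows(rows)
  })
}

# ---- FASTA / FASTQ I/O (Biostrings) ---------------------------------------

#' Write an aligned reference library to FASTA
#'
#' Headers encode the taxonomy as `record_id|species|genus|family`.
#' @param refs reference tibble from [gen_reference_library()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  ss <- Biostrings::BStringSet(refs$aligned_sequence)
  names(ss) <- paste(refs$record_id, refs$species, refs$genus, refs$family, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an aligned reference library from FASTA
#'
#' @param path FASTA file with `record_id|species|genus|family` headers.
#' @param marker marker label to attach.
#' @return reference tibble as produced by [gen_reference_library()].
#' @export
read_reference_fasta <- function(path, marker = "COI-5P") {
  ss <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  if (any(lengths(parts) != 4)) {
    abort("reference FASTA headers must be 'record_id|species|genus|family'")
  }
  tibble(
    record_id = vapply(parts, `[`, character(1), 1),
    species = vapply(parts, `[`, character(1), 2),
    genus = vapply(parts, `[`, character(1), 3),
    family = vapply(parts, `[`, character(1), 4),
    marker = marker,
    aligned_sequence = unname(as.character(ss))
  )
}

#' Write reads to FASTQ (Sanger Phred+33)
#' @param reads read tibble from [gen_reads()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  qs <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qs)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#' @param path FASTQ file (Phred+33).
#' @param sample_id,marker labels to attach to every read.
#' @return read tibble (`read_id`, `sample_id`, `marker`, `sequence`,
#'   `quality`).
#' @export
read_reads_fastq <- function(path, sample_id = "S01", marker = "COI-5P") {
  # Biostrings warns that it drops its own internal metadata columns here
  ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(
    read_id = sub(" .*$", "", names(ss)),
    sample_id = sample_id, marker = marker,
    sequence = unname(as.character(ss)),
    quality = unname(as.character(Biostrings::quality(ss)))
  )
}
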