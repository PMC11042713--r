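# Taxonomic assignment: p-distances, reference QC, hit filtering, local
# alignment search, candidate selection, gap analysis, rank fallback.

test_that("p-distance handles identity, substitutions, and gap sites", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  # gap column excluded: 4 comparable sites, 1 differing
  expect_equal(p_distance("AC-GT", "ACAGA"), 0.25)
  expect_error(p_distance("ACG", "ACGT"), "equal length")
})

test_that("p-distance matrix is symmetric, zero-diagonal, and matches ape", {
  skip_if_not_installed("ape")
  set.seed(2)
  seqs <- vapply(1:8, function(i) {
    paste(sample(c("A", "C", "G", "T", "-"), 50, TRUE,
                 prob = c(.23, .23, .23, .23, .08)), collapse = "")
  }, "")
  d <- p_distance_matrix(seqs)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 8), ignore_attr = TRUE)
  m <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  da <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "raw",
                                pairwise.deletion = TRUE))
  expect_equal(unname(d), unname(da))
})

test_that("reference QC enforces ambiguity and terminal-gap thresholds", {
  L <- 100
  mk <- function(seq) tibble::tibble(record_id = "x", species = "s",
                                     genus = "g", family = "f",
                                     marker = "COI-5P", aligned_sequence = seq)
  clean <- strrep("ACGT", 25)
  too_amb <- paste0(strrep("N", 3), substr(clean, 4, L))       # 3% N
  gap13 <- paste0(strrep("-", 13), substr(clean, 14, L))       # 13 leading gaps
  edge <- paste0(strrep("-", 12), "N", substr(clean, 14, L))   # 12 gaps + ~1% N
  refs <- dplyr::bind_rows(mk(clean), mk(too_amb), mk(gap13), mk(edge))
  refs$record_id <- c("clean", "amb", "gap13", "edge")
  out <- reference_qc(refs)
  expect_setequal(out$record_id, c("clean", "edge"))
  expect_setequal(attr(out, "removed")$record_id, c("amb", "gap13"))
  refs$aligned_sequence[1] <- "ACGT"
  expect_error(reference_qc(refs), "aligned")
})

test_that("hit filter boundaries are inclusive at 95% and 100 bp", {
  hits <- tibble::tibble(
    query_id = "q", subject_id = sprintf("s%d", 1:4),
    species = "sp", genus = "ge", family = "fa",
    percent_identity = c(94.9, 95.0, 98, 98),
    alignment_length = c(120L, 100L, 99L, 100L), score = 1
  )
  out <- filter_hits(hits)
  expect_setequal(out$subject_id, c("s2", "s4"))

  set.seed(10)
  rnd <- tibble::tibble(
    query_id = "q", subject_id = sprintf("s%d", 1:200),
    species = "sp", genus = "ge", family = "fa",
    percent_identity = stats::runif(200, 80, 100),
    alignment_length = sample(50:150, 200, TRUE), score = 1
  )
  out <- filter_hits(rnd, 95, 100)
  brute <- rnd[rnd$percent_identity >= 95 & rnd$alignment_length >= 100, ]
  expect_equal(out$subject_id, brute$subject_id)
})

test_that("naive_search reports identity and length as defined", {
  refs <- gen_reference_library(ref_library_spec(n_taxa = 2, seqs_per_taxon = 1,
                                                 seq_length = 100, seed = 20))
  q <- gsub("-", "", refs$aligned_sequence[1])
  hits <- naive_search(q, refs)
  top <- hits[1, ]
  expect_equal(top$subject_id, refs$record_id[1])
  expect_equal(top$percent_identity, 100)
  expect_equal(top$alignment_length, nchar(q))

  q5 <- q
  for (p in c(10, 30, 50, 70, 90)) {
    substr(q5, p, p) <- setdiff(c("A", "C", "G", "T"), substr(q, p, p))[1]
  }
  h5 <- naive_search(q5, refs)
  expect_equal(h5$percent_identity[h5$subject_id == refs$record_id[1]], 95)

  qq <- tibble::tibble(query_id = "u1", sequence = q, marker = "rbcLa")
  expect_error(naive_search(qq, refs), "marker")
})

test_that("naive_search top hit matches a Smith-Waterman oracle", {
  set.seed(33)
  for (i in 1:10) {
    refs <- gen_reference_library(ref_library_spec(
      n_taxa = 5, seqs_per_taxon = 2, seq_length = 70,
      intra_divergence = 0.05, inter_divergence = 0.2, seed = 100 + i))
    q <- gsub("-", "", refs$aligned_sequence[sample(nrow(refs), 1)])
    hits <- naive_search(q, refs)
    oracle <- vapply(gsub("-", "", refs$aligned_sequence), sw_score_oracle,
                     numeric(1), b = q, USE.NAMES = FALSE)
    expect_equal(sort(hits$score), sort(oracle))
    best <- refs$record_id[oracle == max(oracle)]
    expect_true(hits$subject_id[which.max(hits$score)] %in% best)
  }
})

test_that("candidate selection resolves ties to the lowest common rank", {
  expect_equal(candidate_species("q", tibble::tibble(
    query_id = character(0), subject_id = character(0), species = character(0),
    genus = character(0), family = character(0), percent_identity = numeric(0),
    alignment_length = integer(0), score = numeric(0)))$rank, "none")

  one <- tibble::tibble(query_id = "q", subject_id = "s1", species = "Aus bus",
                        genus = "Aus", family = "Aidae",
                        percent_identity = 99, alignment_length = 120L, score = 100)
  expect_equal(candidate_species("q", one)$species, "Aus bus")

  tie <- dplyr::bind_rows(one, dplyr::mutate(one, subject_id = "s2",
                                             species = "Aus cus"))
  cand <- candidate_species("q", tie)
  expect_equal(cand$rank, "genus")
  expect_equal(cand$genus, "Aus")

  cross <- dplyr::bind_rows(one, dplyr::mutate(one, subject_id = "s3",
                                               species = "Bus dus", genus = "Bus"))
  expect_equal(candidate_species("q", cross)$rank, "family")

  # a strictly better hit wins regardless of later rows
  better <- dplyr::bind_rows(dplyr::mutate(one, percent_identity = 97),
                             dplyr::mutate(one, subject_id = "s2",
                                           species = "Aus cus",
                                           percent_identity = 99.5))
  expect_equal(candidate_species("q", better)$species, "Aus cus")
})

test_that("gap analysis agrees with the exhaustive oracle on edge shapes", {
  # clean gap: two species, small intra, large inter
  lib <- gen_reference_library(ref_library_spec(
    n_taxa = 2, seqs_per_taxon = 3, seq_length = 200,
    intra_divergence = 0.01, inter_divergence = 0.05, seed = 51))
  g <- gap_analysis(lib, lib$species[1], "species")
  o <- gap_oracle(lib, lib$species[1], "species")
  expect_equal(g$max_intra, o$max_intra)
  expect_equal(g$min_inter, o$min_inter)
  expect_true(g$has_gap)

  # singleton focal group: undetermined
  single <- lib[c(1, 4:6), ]
  gs <- gap_analysis(single, single$species[1], "species")
  expect_equal(gs$n_intra_pairs, 0L)
  expect_equal(gs$verdict, "undetermined")

  # overlapping clusters: no gap
  over <- gen_reference_library(ref_library_spec(
    n_taxa = 2, seqs_per_taxon = 4, seq_length = 300,
    intra_divergence = 0.06, inter_divergence = 0.04, seed = 52))
  go <- gap_analysis(over, over$species[1], "species")
  oo <- gap_oracle(over, over$species[1], "species")
  expect_equal(go$max_intra, oo$max_intra)
  expect_equal(go$min_inter, oo$min_inter)
  expect_false(go$has_gap)

  expect_error(gap_analysis(lib, "Nope", "species"), "absent")
})

test_that("gap analysis equals the oracle across random small libraries", {
  for (seed in 1:30) {
    lib <- random_library(seed)
    for (rank in c("species", "genus")) {
      for (focal in unique(lib[[rank]])) {
        g <- gap_analysis(lib, focal, rank)
        o <- gap_oracle(lib, focal, rank)
        expect_equal(g$max_intra, o$max_intra)
        expect_equal(g$min_inter, o$min_inter)
        expect_equal(g$n_intra_pairs, as.integer(o$n_intra_pairs))
        expect_equal(g$n_inter_pairs, as.integer(o$n_inter_pairs))
        if (!is.na(o$has_gap)) expect_equal(g$has_gap, o$has_gap)
      }
    }
  }
})

test_that("rank fallback follows the per-marker pullback scheme", {
  cand <- tibble::tibble(query_id = "q", rank = "species", species = "Aus bus",
                         genus = "Aus", family = "Aidae")
  gaps <- tibble::tibble(
    focal_taxon = c("Aus bus", "Aus"), rank_tested = c("species", "genus"),
    verdict = c("gap", "gap")
  )
  expect_equal(apply_rank_fallback(cand, gaps, "COI-5P")$assigned_rank, "species")

  gaps$verdict <- c("no_gap", "gap")
  a <- apply_rank_fallback(cand, gaps, "COI-5P")
  expect_equal(a$assigned_rank, "genus")
  expect_equal(a$assigned_taxon, "Aus")
  expect_match(a$fallback_reason, "no_species_gap")
  expect_equal(apply_rank_fallback(cand, gaps, "rbcLa")$assigned_rank, "genus")

  gaps$verdict <- c("no_gap", "no_gap")
  r <- apply_rank_fallback(cand, gaps, "rbcLa")
  expect_equal(r$assigned_rank, "family")
  expect_equal(r$assigned_taxon, "Aidae")
  # animal marker never reports family
  expect_equal(apply_rank_fallback(cand, gaps, "COI-5P")$assigned_rank, "genus")

  # undetermined species test is treated as no gap (conservative)
  gaps$verdict <- c("undetermined", "gap")
  expect_equal(apply_rank_fallback(cand, gaps, "COI-5P")$assigned_rank, "genus")

  # missing gap rows flag the assignment
  miss <- apply_rank_fallback(cand, gaps[0, ], "COI-5P")
  expect_equal(miss$assigned_rank, "unassigned")
  expect_match(miss$fallback_reason, "missing_gap_result")
})

test_that("fallback never returns a more specific rank than the candidate", {
  rank_num <- c(species = 1, genus = 2, family = 3, unassigned = 4, none = 4)
  set.seed(44)
  for (i in 1:60) {
    crank <- sample(c("species", "genus", "family", "none"), 1)
    cand <- tibble::tibble(
      query_id = "q", rank = crank,
      species = if (crank == "species") "Aus bus" else NA_character_,
      genus = if (crank %in% c("species", "genus")) "Aus" else NA_character_,
      family = if (crank != "none") "Aidae" else NA_character_
    )
    gaps <- tibble::tibble(
      focal_taxon = c("Aus bus", "Aus"), rank_tested = c("species", "genus"),
      verdict = sample(c("gap", "no_gap", "undetermined"), 2, TRUE)
    )
    marker <- sample(c("COI-5P", "rbcLa"), 1)
    a <- apply_rank_fallback(cand, gaps, marker)
    expect_gte(rank_num[[a$assigned_rank]], rank_num[[crank]])
    if (marker != "rbcLa") expect_true(a$assigned_rank != "family")
  }
})

test_that("hit tables in tabular outfmt round-trip through the reader", {
  tsv <- tempfile(fileext = ".tsv")
  lines <- c(
    "q1\tr1|Aus bus|Aus|Aidae\t99.0\t120\t1\t0\t1\t120\t1\t120\t1e-50\t222",
    "q1\tr2|Bus cus|Bus|Bidae\t94.0\t110\t6\t0\t1\t110\t1\t110\t1e-40\t180"
  )
  writeLines(lines, tsv)
  h <- read_hit_table(tsv)
  expect_equal(h$species, c("Aus bus", "Bus cus"))
  expect_equal(h$percent_identity, c(99, 94))
  expect_equal(nrow(filter_hits(h)), 1)
})
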