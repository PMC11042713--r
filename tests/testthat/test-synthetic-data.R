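# Synthetic reference libraries, reads, snow series, and observations:
# degenerate cases, divergence/error-rate calibration, and determinism.

test_that("degenerate library specs behave as forced", {
  one <- gen_reference_library(ref_library_spec(n_taxa = 1, seqs_per_taxon = 1))
  expect_equal(nrow(one), 1)
  expect_setequal(c("record_id", "species", "genus", "family", "marker",
                    "aligned_sequence"), names(one))

  lib <- gen_reference_library(ref_library_spec(
    n_taxa = 3, seqs_per_taxon = 4, intra_divergence = 0, seed = 5))
  for (sp in unique(lib$species)) {
    expect_length(unique(lib$aligned_sequence[lib$species == sp]), 1)
    g <- gap_analysis(lib, sp, "species")
    expect_equal(g$max_intra, 0)
  }
})

test_that("library spec validation names the offending field", {
  expect_error(ref_library_spec(n_taxa = 0, seqs_per_taxon = 1), "n_taxa")
  expect_error(ref_library_spec(2, 2, intra_divergence = 1.5), "intra_divergence")
  expect_error(ref_library_spec(2, 2, ambiguity_rate = -0.1), "ambiguity_rate")
})

test_that("realised intra/inter divergence matches the generative model", {
  # pairwise distances inside one library share ancestral mutations, so
  # Monte-Carlo error is estimated across replicate libraries
  lib_means <- function(seed) {
    lib <- gen_reference_library(ref_library_spec(
      n_taxa = 5, seqs_per_taxon = 4, seq_length = 400,
      intra_divergence = 0.01, inter_divergence = 0.10, seed = seed))
    intra <- c(); inter <- c()
    for (i in seq_len(nrow(lib) - 1)) for (j in seq(i + 1, nrow(lib))) {
      d <- p_dist_oracle(lib$aligned_sequence[i], lib$aligned_sequence[j])
      if (lib$species[i] == lib$species[j]) {
        intra <- c(intra, d)
      } else if (lib$genus[i] == lib$genus[j]) {
        inter <- c(inter, d)
      }
    }
    c(intra = mean(intra), inter = mean(inter))
  }
  reps <- vapply(1:12, lib_means, c(intra = 0, inter = 0))
  t_intra <- expected_pair_diff(0.01)
  e <- 0.10 - 0.01 # extra ancestral divergence step per lineage
  t_inter <- expected_pair_diff(c(e, 0.01))
  se <- apply(reps, 1, stats::sd) / sqrt(ncol(reps))
  expect_lt(abs(mean(reps["intra", ]) - t_intra), 3 * se[["intra"]])
  expect_lt(abs(mean(reps["inter", ]) - t_inter), 3 * se[["inter"]])
})

test_that("library generation is seed-reproducible, byte for byte", {
  spec <- ref_library_spec(n_taxa = 3, seqs_per_taxon = 2, seed = 99,
                           ambiguity_rate = 0.01)
  a <- gen_reference_library(spec)
  b <- gen_reference_library(spec)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_reference_fasta(a, f1); write_reference_fasta(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(read_reference_fasta(f1)$aligned_sequence, a$aligned_sequence)
})

test_that("read counts are conserved and error-free reads match templates", {
  lib <- gen_reference_library(ref_library_spec(n_taxa = 2, seqs_per_taxon = 1, seed = 3))
  rs <- read_sim_spec(reads_per_template = 3, error_rate = 0, seed = 4)
  reads <- gen_reads(lib, rs)
  expect_equal(nrow(reads), 2 * 3)
  body <- substr(reads$sequence, nchar(rs$primer_fwd) + 1,
                 nchar(reads$sequence) - nchar(rs$primer_rev))
  expect_equal(body, gsub("-", "", lib$aligned_sequence)[rep(1:2, each = 3)],
               ignore_attr = TRUE)
  expect_equal(nchar(reads$sequence), nchar(reads$quality))
  expect_error(gen_reads(lib[0, ], rs), "non-empty")
})

test_that("observed per-base error rate is within 3 SE of the spec", {
  lib <- gen_reference_library(ref_library_spec(n_taxa = 1, seqs_per_taxon = 1,
                                                seq_length = 150, seed = 2))
  rs <- read_sim_spec(reads_per_template = 1000, error_rate = 0.01, seed = 7)
  reads <- gen_reads(lib, rs)
  tmpl <- strsplit(gsub("-", "", lib$aligned_sequence[1]), "")[[1]]
  body <- substr(reads$sequence, nchar(rs$primer_fwd) + 1,
                 nchar(reads$sequence) - nchar(rs$primer_rev))
  mm <- vapply(strsplit(body, ""), function(x) sum(x != tmpl), numeric(1))
  p_hat <- sum(mm) / (1000 * 150)
  se <- sqrt(0.01 * 0.99 / (1000 * 150))
  expect_lt(abs(p_hat - 0.01), 3 * se)
  q <- unlist(phred_to_int(reads$quality[1:20]))
  expect_true(all(q >= 0 & q <= 60))
})

test_that("FASTQ round-trips and is byte-identical under the same seed", {
  lib <- gen_reference_library(ref_library_spec(n_taxa = 2, seqs_per_taxon = 1, seed = 3))
  rs <- read_sim_spec(reads_per_template = 5, error_rate = 0.02, seed = 12)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_reads_fastq(gen_reads(lib, rs), f1)
  write_reads_fastq(gen_reads(lib, rs), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_reads_fastq(f1)
  fwd <- gen_reads(lib, rs)
  expect_equal(back$sequence, fwd$sequence)
  expect_equal(back$quality, fwd$quality)
})

test_that("snow series follows the depth profile day by day", {
  expect_equal(unique(gen_snow_series("2016-12-01", "2016-12-31",
                                      c("05-01:10-31" = 10))$depth_cm), 0)
  s <- gen_snow_series("2016-11-01", "2017-03-31", c("11-01:03-31" = 50))
  expect_equal(nrow(s), as.numeric(as.Date("2017-03-31") - as.Date("2016-11-01")) + 1)
  expect_equal(s$depth_cm[s$date == as.Date("2017-01-15")], 50)
  expect_true(all(s$depth_cm >= 0))
  expect_error(gen_snow_series("2017-01-02", "2017-01-01"), "start")
})

test_that("nearest-day snow lookup agrees with a linear scan over gaps", {
  s <- gen_snow_series("2017-01-01", "2017-01-31", c("01-01:01-31" = 30),
                       drop_dates = c("2017-01-10", "2017-01-11", "2017-01-12"))
  s$depth_cm <- seq_len(nrow(s)) # distinct values to identify the day chosen
  for (target in as.Date(c("2017-01-10", "2017-01-11", "2017-01-13"))) {
    got <- snow_depth_at(s, "SYN", target, max_gap_days = 3)
    gaps <- abs(as.numeric(s$date - target))
    expect_equal(got, s$depth_cm[which.min(gaps)])
  }
  expect_true(is.na(snow_depth_at(s[s$date < as.Date("2017-01-05"), ], "SYN",
                                  "2017-01-20", max_gap_days = 3)))
})

test_that("generated observations honour group probabilities and ground truth", {
  expect_equal(nrow(gen_observations(obs_sim_spec(n_items = 0))), 0)
  expect_error(obs_sim_spec(10, cached_fraction = 1.2), "cached_fraction")
  expect_error(obs_sim_spec(10, group_probs = c(0.5, 0.2, 0.2)), "group_probs")

  g <- gen_observations(obs_sim_spec(n_items = 200, group_probs = c(1, 0, 0), seed = 3))
  expect_true(all(g$food_group == "A"))

  obs <- gen_observations(obs_sim_spec(n_items = 120, cached_fraction = 0.4, seed = 21))
  expect_identical(obs, gen_observations(obs_sim_spec(n_items = 120,
                                                      cached_fraction = 0.4, seed = 21)))
  cl <- classify_dataset(obs, attr(obs, "traits"), attr(obs, "snow"))
  # ground-truth consistency, checked exhaustively
  expect_true(all(cl$designation[obs$truth_cached] == "likely_cached"))
  expect_true(all(!nzchar(cl$criteria_fired[!obs$truth_cached])))
})

test_that("an all-cached generation is recovered in full by the classifier", {
  obs <- gen_observations(obs_sim_spec(n_items = 50, cached_fraction = 1, seed = 6))
  cl <- classify_dataset(obs, attr(obs, "traits"), attr(obs, "snow"))
  expect_equal(sum(cl$designation == "likely_cached"), 50)
})
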