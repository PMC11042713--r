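# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with the functions
# they verify.

# Smith-Waterman local alignment score, linear gap cost, plain DP
sw_score_oracle <- function(a, b, match = 1, mismatch = -1, gapcost = 2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] - gapcost,
                             H[i + 1, j] - gapcost)
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# proportion of differing sites, pairwise deletion — independent of
# jaydiet::p_distance (vector comparison written from scratch)
p_dist_oracle <- function(a, b) {
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (sum(keep) == 0) return(NA_real_)
  sum(av[keep] != bv[keep]) / sum(keep)
}

# exhaustive all-pairs barcode-gap statistics for a focal taxon
gap_oracle <- function(refs, focal_taxon, rank = "species", comparison = "parent") {
  focal <- which(refs[[rank]] == focal_taxon)
  if (comparison == "parent") {
    parent_rank <- if (rank == "species") "genus" else "family"
    others <- which(refs[[rank]] != focal_taxon &
                      refs[[parent_rank]] == refs[[parent_rank]][focal[1]])
  } else {
    others <- which(refs[[rank]] != focal_taxon)
  }
  intra <- c()
  if (length(focal) >= 2) {
    for (i in seq_along(focal)) for (j in seq_along(focal)) {
      if (i < j) intra <- c(intra, p_dist_oracle(refs$aligned_sequence[focal[i]],
                                                 refs$aligned_sequence[focal[j]]))
    }
  }
  inter <- c()
  for (i in focal) for (j in others) {
    inter <- c(inter, p_dist_oracle(refs$aligned_sequence[i],
                                    refs$aligned_sequence[j]))
  }
  list(
    max_intra = if (length(intra) > 0) max(intra, na.rm = TRUE) else NA_real_,
    min_inter = if (length(inter) > 0) min(inter, na.rm = TRUE) else NA_real_,
    n_intra_pairs = length(focal) * (length(focal) - 1) / 2,
    n_inter_pairs = length(focal) * length(others),
    has_gap = if (length(intra) > 0 && length(inter) > 0) {
      min(inter, na.rm = TRUE) > max(intra, na.rm = TRUE)
    } else NA
  )
}

# windowed quality trimming re-implemented as an explicit scan
trim_point_oracle <- function(q, threshold, window) {
  L <- length(q)
  if (L == 0) return(0L)
  w <- max(1L, as.integer(floor(window * L)))
  for (i in seq_len(L - w + 1)) {
    if (mean(q[i:(i + w - 1)]) < threshold) return(i - 1L)
  }
  L
}

# exhaustive sliding-window Hamming search for a primer inside a read;
# returns every start position matching within max_mm mismatches
hamming_locate <- function(read, primer, max_mm) {
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  pv <- strsplit(primer, "", fixed = TRUE)[[1]]
  np <- length(pv)
  hits <- integer(0)
  for (s in seq_len(length(rv) - np + 1)) {
    if (sum(rv[s:(s + np - 1)] != pv) <= max_mm) hits <- c(hits, s)
  }
  hits
}

# Expected proportion of differing sites between two lineages, each a
# chain of independent uniform-substitution steps from a common ancestor.
# One step at rate d has eigenvalue 1 - (4/3) d on the non-identity
# component of the 4-state chain; for independent lineages with step
# rates in `steps_a` and `steps_b`, P(differ) = 3/4 (1 - prod(lambda)).
expected_pair_diff <- function(steps_a, steps_b = steps_a) {
  lam <- prod(1 - (4 / 3) * c(steps_a, steps_b))
  3 / 4 * (1 - lam)
}

# a small random aligned library with known labels, for gap-oracle sweeps
random_library <- function(seed) {
  set.seed(seed)
  ref_library_spec(
    n_taxa = sample(2:6, 1), seqs_per_taxon = sample(1:4, 1),
    seq_length = 60,
    intra_divergence = stats::runif(1, 0, 0.12),
    inter_divergence = stats::runif(1, 0, 0.15),
    species_per_genus = sample(2:3, 1),
    seed = seed
  ) |> gen_reference_library()
}
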