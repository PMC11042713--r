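#!/usr/bin/env Rscript
# Step 2 — read QC and gap-calibrated taxonomic assignment.
#
# Runs the full sequence side of the pipeline on both simulated regimes
# from step 1: primer trimming, 100 bp length filter, Q20 windowed
# quality trimming, exact dereplication, 100-read abundance filter, then
# local-alignment search with the 95%/100 bp hit filter and barcode-gap
# rank fallback. Finding: with a clean gap every unique sequence lands on
# its true species; without one, nothing is reported below genus (animal
# marker) or family (plant marker).

suppressMessages(library(jaydiet))
suppressMessages(library(readr))

simdir <- "results/sim"
out <- "results/assign"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
primers <- readLines(file.path(simdir, "primers.txt"))
cfg <- pipeline_config()

for (regime in c("gap", "nogap")) {
  marker <- if (regime == "gap") "COI-5P" else "rbcLa"
  refs <- read_reference_fasta(file.path(simdir, paste0("refs_", regime, ".fasta")),
                               marker = marker)
  reads <- read_reads_fastq(file.path(simdir, paste0("reads_", regime, ".fastq")),
                            marker = marker)
  res <- run_pipeline(cfg, reads = reads, refs = refs,
                      primer_fwd = primers[1], primer_rev = primers[2],
                      marker = marker)
  write_tsv(res$log, file.path(out, paste0("qc_log_", regime, ".tsv")))
  write_tsv(res$assignments, file.path(out, paste0("assignments_", regime, ".tsv")))
  gaps <- library_gap_analysis(reference_qc(refs), "species")
  write_tsv(gaps, file.path(out, paste0("gap_results_", regime, ".tsv")))
  message(regime, ": ", nrow(res$uniques), " unique sequences above the ",
          cfg$min_reads, "-read bar; assigned ranks: ",
          paste(names(table(res$assignments$assigned_rank)),
                table(res$assignments$assigned_rank), collapse = ", "),
          "; species-level gaps found for ",
          sum(gaps$verdict == "gap"), "/", nrow(gaps), " taxa")
}
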