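---
title: "Methods: diet metabarcoding QC, barcode-gap assignment, and the cached-versus-fresh classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet metabarcoding QC, barcode-gap assignment, and the cached-versus-fresh classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jaydiet)
```

`jaydiet` chains four analyses: amplicon read quality control,
identity-filtered taxonomic assignment with barcode-gap-driven rank
fallback, compilation of a multi-method diet dataset, and a rule-based
cached-versus-fresh classifier. This vignette explains the models and
procedures behind each stage, the parameters that matter, the synthetic
data that the tests rely on, and the design choices made where more than
one reasonable reading existed.

## Read quality control

Reads arrive demultiplexed (each carries a `sample_id` and a `marker`
among COI-5P, ITS2, and rbcLa) as sequence plus per-base Phred scores.
The stages, in order:

* **Primer trimming** (`trim_primers()`). Anchored matching: the forward
  primer must sit at the 5' end, the reverse-complemented reverse primer
  at the 3' end. Matching is IUPAC-aware (a read base matches a primer
  code if it lies in the code's expansion) with a per-primer mismatch
  tolerance (default 2). Reads failing either flank are rejected with a
  recorded reason rather than passed through untrimmed, because an
  untrimmed flank would corrupt downstream identity percentages.
* **Length filter** (`filter_length()`, default 100 bp). The boundary is
  inclusive: a 100 bp read survives; only strictly shorter reads are
  removed.
* **Quality trimming** (`filter_quality()`). The upstream tool cited for
  this step is a windowed trimmer, so we implement windowed mean-quality
  trimming: with a window of 0.1 × read length (the trimmer's default
  proportion), the read is truncated at the start of the first window
  whose mean Phred drops below the threshold (default Q20). The length
  filter is then re-applied, since truncation can push a read below
  100 bp. A read whose very first window fails is removed outright.
* **Dereplication** (`dereplicate()`). Exact string identity within each
  (sample, marker) pair; read counts are conserved exactly, and output
  order is canonical (decreasing count, then sequence), so the result is
  independent of input order.
* **Abundance filter** (`filter_min_reads()`, default 100 reads,
  inclusive at the boundary). Applied per (sample, marker), not
  globally, because the sample is the unit of diet inference. Whether
  the filter runs before or after taxonomic assignment is configurable
  (`abundance_before_assignment`, default before); the original order is
  not documented, and the choice only affects how much work the
  assignment stage does, not which sequences survive.

Every stage reports `n_in`/`n_out` plus per-read rejection reasons, so
`records_in = records_out + records_dropped` holds at each step.

## Taxonomic assignment

### Search and hit filtering

`naive_search()` stands in for an external similarity search so the
pipeline runs without network databases: each reference is aligned to
the query by Smith–Waterman local alignment (match +1, mismatch −1,
linear gap cost 2, via `Biostrings::pairwiseAlignment`), and reported
with percent identity (matches / alignment columns) and alignment
length. Hits are filtered at ≥95% identity across ≥100 aligned bases,
both inclusive. The search is deterministic and is checked in the tests
against a hand-written dynamic-programming oracle.

### Candidate selection

With several surviving hits, the candidate is the lexicographic best by
(identity, alignment length, score). If distinct species tie *exactly*
at the top, the candidate is promoted to their lowest common rank
(genus, then family): a tie between congeners is genuine ambiguity below
genus and should not be broken arbitrarily. A family-level tie under an
animal marker is unresolvable (those markers never report at family
rank) and yields an unassigned record.

### p-distance and the barcode gap

Distances are proportions of differing sites among sites where neither
aligned sequence has a gap or ambiguity (pairwise deletion) — the "raw"
distance of standard phylogenetic practice; the count variant differs
only by the constant alignment length when no sites are deleted.
Reference libraries are QC'd first: records with more than 2% unknown
nucleotides, or more than 12 consecutive `-` characters at either end of
the alignment, are removed (both thresholds inclusive on the keep side).

For a focal taxon, `gap_analysis()` computes `max_intra`, the largest
within-taxon distance, and `min_inter`, the smallest distance from any
focal member to the comparison set. The comparison universe is the
focal taxon's congeners for species-rank tests and its confamilial
genera for genus-rank tests (configurable to "all non-focal records").
A barcode gap exists iff `min_inter > max_intra` — strictly: equality
means within-group variation reaches between-group divergence, which is
exactly the situation the gap is supposed to exclude. A singleton focal
group (no intra pairs) or an empty comparison set yields an
`undetermined` verdict rather than a silent pass.

### Rank fallback

`apply_rank_fallback()` maps gap verdicts to reporting ranks. COI-5P
(and ITS2, by the same scheme — the original fungal marker produced no
usable identifications, so the choice is ours): species if the species
gap holds, else genus. rbcLa: species, else genus if the genus gap
holds, else family. An `undetermined` verdict is treated as *no gap* —
the conservative direction, since an unverifiable gap should not license
a fine-rank claim. A missing gap result for a needed rank flags the
assignment `unassigned` instead of guessing.

## Diet compilation

Observations are validated on load (`load_observations()`): unknown
method, food-group, or age-class codes become row-level error reports,
never silent drops. Dates that are not full `YYYY-MM-DD` values are
kept with a `partial_date` flag; they count in food-group tallies but
are excluded from seasonal ones. Seasons are year-agnostic month/day
windows: winter Nov 1–Mar 31, non-winter May 1–Oct 31. April falls in
neither window; we make that explicit (`"neither"`) rather than
silently attaching April — when most nestling samples are collected —
to either season. Percentages round half away from zero to whole
percent, matching the printed convention (121/662 → 18%).

## The cached-versus-fresh classifier

Each diet item identified to species is assigned one of four
designations. The decision procedure, in order:

1. **unknown** — the item is not identified to species, is flagged as
   misidentified (an input flag, not something the classifier infers),
   or its taxon has no known natural history.
2. **likely_cached** — at least one of four criteria fires. All four
   are always evaluated and the fired subset is recorded:
   * **C1** the observation date falls in the taxon's migratory-absence
     window (month/day windows, possibly wrapping the year end);
   * **C2** the observed life stage (when recorded) is outside its
     presence window;
   * **C3** the date falls in the taxon's underground window
     (hibernation/diapause);
   * **C4** snow depth on the date exceeds the item's height above the
     substrate. The criterion needs both numbers: no snow record within
     the lookup tolerance, or no substrate height, means C4 cannot
     fire. The original analysis states the principle (snow "would have
     precluded access") without a numeric rule; strict `snow > height`
     with both values known is our operationalisation.
3. **either_possible** — the taxon is present and accessible year-round.
4. **likely_fresh** — the date lies in a declared fresh-availability
   window; unavailability in the preceding summer/fall storage season is
   recorded as a strengthening note, not a separate category.
5. **either_possible** otherwise.

Criteria dominate the availability flags by construction (step 2
precedes 3–4), and a profile declaring both year-round accessibility
and an absence/underground window is rejected as contradictory. An
optional per-item expert-override column takes precedence over the
rules and is logged — published designations partly reflect expert
judgment and must be representable. Snow lookups use the station named
by the observation's location, exact date first, then the nearest day
within `max_gap_days` (default 3, earlier day wins ties).

Cohort summaries follow the study's denominators: "winter adults" are
adult stomach-contents items dated Nov 1–Mar 31; "nestlings" are all
nestling items regardless of season (their April dates fall in neither
season window). Percentages use the identified-to-species denominator
(all designations except `unknown`), reported alongside the full item
count.

## Synthetic data: what it emulates and what it does not

### Reference libraries and reads

`gen_reference_library()` generates aligned libraries on a three-level
hierarchy (family root → genus ancestor → species ancestor →
individual) under uniform random substitutions, the simplest model
consistent with p-distance analysis. Individuals diverge from their
species ancestor at `intra_divergence` per site; each ancestral step
adds `e = max(0, inter_divergence − intra_divergence)`. Two lineages
whose steps have rates \(d_1, \dots, d_k\) differ per site with
probability \(\tfrac34\bigl(1 - \prod_i (1 - \tfrac43 d_i)\bigr)\); the
tests check realised mean distances against this closed form, with
Monte-Carlo error estimated across replicate libraries because pairs
within one library share ancestral mutations. The `e = max(0, \cdot)`
construction is deliberate: when `intra ≥ inter` the between-taxon
signal collapses entirely and intra- and inter-taxon distances become
identically distributed, which is the no-barcode-gap regime the rank
fallback must handle. (A hierarchy with independent positive rates can
never make between-taxon distances stochastically smaller than
within-taxon ones.)

`gen_reads()` adds primer flanks, substitution errors at a uniform
per-base rate, and Phred scores from a normal truncated to [0, 60].
There are no indels, chimeras, or platform-specific homopolymer errors,
and no length variation beyond the primers — so passing tests show the
pipeline's logic is correct under substitution noise, not that it is
robust to every artefact of real sequencing runs.

### Observations with known ground truth

`gen_observations()` builds cached items criterion-first: pick a
criterion, then a taxon/date combination (and, for C4, snow conditions)
under which it provably holds; fresh items come from taxa with no
criterion windows, no substrate height, not year-round, dated inside
their fresh window. Ground-truth recovery is therefore guaranteed by
construction, which is the point: the tests verify that the classifier
implements its stated rules exactly, not that the rules are true of any
real ecosystem. The default observation window is a boreal winter
(Nov 1–Mar 31) with a 45 cm snowpack from mid-November.

### The packaged compiled-dataset reconstruction

The published supplementary tables behind the 662-item compiled dataset
are not redistributable, so `inst/extdata` carries a synthetic
reconstruction (built in code by `build_synthetic_jay_data()`, flagged
`_synthetic` in the filenames) whose margins match every count and
percentage printed in the study's text: the 121/147/394 method split,
the direct-observation food groups (20/23/78), the vertebrate
subcategories (6/34/35 of 75 — three directly observed vertebrate items
carry no subcategory, which reconciles the text's 78 and 75), the
winter-adult designation split (34/48/5 of 87 identified to species out
of 194), the nestling split (35/42/48 of 125 out of 212), plant cached
fractions (32/56 and 22/33), overall cohort food-group proportions
(49/36/15% and 80/18/2%), and the 10-of-15 sac-level cached presence.
Where an abstract-versus-results discrepancy exists for the nestling
cached percentage (29% vs 28%), the reconstruction follows the results
figure (35/125 → 28%). Taxon identities, exact dates, trait windows,
and snow profiles in the reconstruction are plausible inventions chosen
so the classifier *derives* those designations from the rules rather
than reading them from a column; individual rows are not the study's
rows, and only the printed margins are faithful.

## Numerical choices and degenerate inputs

* Thresholds at boundaries are inclusive on the keep side throughout
  (100 bp, 100 reads, 95%, 2% ambiguity, 12 terminal gaps); the gap
  verdict alone is strict (`>`).
* p-distance of two sequences with no comparable sites is `NA`, and gap
  statistics propagate it into an `undetermined` verdict.
* `tally_diet()` of an empty table is an empty table; percentages of a
  zero denominator are `NA`, never `NaN`.
* Classification is pure: identical inputs give identical outputs, and
  the whole pipeline is seed-reproducible byte for byte, including
  FASTQ/CSV writers.
* Problem sizes in the tests and the acceptance script are desk-scale
  by design — libraries of ≤50 sequences for oracle comparisons, 8-taxon
  libraries at 300 bp with ~100 reads per template for recovery runs,
  400 observations for classifier recovery — enough for the exact
  oracles and 3-SE calibration checks to be meaningful on one CPU.

## Known limitations

* The search is a stand-in: scores are Smith–Waterman with a fixed
  simple scoring scheme, not BLAST statistics; there are no E-values,
  and results against curated external databases will differ.
* ITS2 is plumbed through but untested against real fungal data (the
  original marker failed at amplification), and its fallback scheme is
  an assumption.
* Snow support is nearest-station/nearest-day only; no spatial
  interpolation.
* The classifier encodes phenology as sharp month/day windows; real
  phenology varies between years and sites, which is precisely why the
  original analysis kept an expert-override path — represented here,
  but no override data ship with the package.
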