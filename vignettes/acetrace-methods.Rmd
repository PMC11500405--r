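---
title: "Methods: raw-read gene-signature screening and SEC correlation profiling"
author: "acetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: raw-read gene-signature screening and SEC correlation profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetrace)
```

## Background

Functional genes that are rare in a habitat are routinely lost during
metagenome assembly: low-coverage regions are discarded by assemblers, so a
gene can be genuinely present in a sample yet absent from every
metagenome-assembled genome derived from it. The degradation pathway of the
artificial sweetener acesulfame is a case in point — the sulfatase gene that
initiates the pathway, and the acetoacetamide-*N*-sulfonate (ANSA) amidase
gene that completes it, occur at abundances where assembly-based surveys
miss them. `acetrace` implements the alternative: screen the *raw*
sequencing reads of shotgun metagenome and metatranscriptome datasets for
near-identical matches to the query genes, aggregate detections by sampling
site and year, and quantify how often such gene signatures appear per base
pair of data searched.

The package's second component supports the biochemical side of the same
question: given size-exclusion chromatography (SEC) fractions assayed for
substrate hydrolysis and profiled by shotgun proteomics, it identifies the
proteins whose abundance across fractions tracks the activity, calibrates
the column's mass scale, and ranks the oligomeric states consistent with
the apparent native mass of the active complex.

Everything is testable without external data: the `simulate_*` generators
fabricate genes, homolog decoys, error-bearing reads with truth labels,
multi-site surveys, and SEC experiments with planted activity-correlated
proteins.

## The significant-match definition

A dataset (one sequencing run) counts as containing a query-gene signature
when, at an identity of at least 97% (matches divided by alignment columns,
gaps counting as non-matches):

1. a single read aligns over **≥ 150 bp** of the query gene, or
2. shorter reads — each aligning over **≥ 30 bp** — jointly cover
   **≥ 140 bp** of the query (union of aligned query positions; overlap is
   counted once), or
3. a read that matches only a gene terminus (**≥ 30 bp** at the identity
   floor, alignment abutting query position 0 or the gene end) is *rescued*:
   realigned against the gene plus its genomic flanks, it produces one
   contiguous alignment of ≥ 150 bp at ≥ 97% identity that still overlaps
   the gene by ≥ 30 bp.

These thresholds live in a single configurable record,
`detection_criteria()`, and every output table records the values in force.
Two readings of rule 1 are possible: that the *read* must be ≥ 150 bp long,
or that the *alignment* must span ≥ 150 bp of the query. We measure the
aligned query span, since the evidence for presence of the gene is the
alignment, not unaligned read bases; a 160-bp read whose terminal 20 bp are
sequencing adapter should still count.

For rule 2 we apply the 97% floor per contributing read (not as an average
across reads), reuse the 30-bp floor as the minimum contribution, and take
the *union* of query positions — the conservative reading of "combined
coverage". A rescued read alone establishes significance (rule 3 is not
merely a contributor to rule 2), and rescued reads additionally contribute
their in-gene overlap to the coverage union.

## Alignment engine

Reads are aligned to the query with affine-gap local alignment
(`Biostrings::pairwiseAlignment`) under +1 match, −2 mismatch, gap open −2,
gap extend −1 (a gap of width *w* costs 2 + *w*), on both strands. The
scheme is recorded in `align_scoring()` so it is auditable; any scheme
stringent enough to recover ≥ 97%-identity alignments at the 30-bp floor
would serve.

Two semantics matter for faithfulness to HSP-style (blastn-like) evidence:

* **Only locally optimal alignments are classified.** A 150-bp read with
  five spread substitutions has one locally optimal alignment at 96.7%
  identity, which fails the floor. Sub-windows of it would pass 97% in
  isolation, but extending them increases the score, so they are not
  locally optimal and are not reported. This is what makes the identity
  floor sharp: 5 substitutions in 150 bp fail, 4 pass.
* **Masked re-search.** After a read's best alignment is recorded, the
  aligned read segment is masked and the remainder re-searched (up to 4
  rounds), so one read contributing two disjoint query segments yields two
  alignment records — required for the coverage-union rule.

**Seed prefilter.** Before dynamic programming, reads are screened for an
exact shared *k*-mer with the query (either strand). The word length is
derived from the criteria, not fixed: an alignment of *c* columns at
identity ≥ *m* contains at most `floor((1-m)·c)` non-match columns, which
split the matched columns into at most that many + 1 runs, so its longest
exact run is at least `ceil((c - floor((1-m)c)) / (floor((1-m)c) + 1))`.
Minimising over all alignment lengths ≥ 30 at *m* = 0.97 gives 17, so a
16-mer screen cannot discard any reportable alignment — the prefilter is
lossless, and it removes essentially all background reads (a random 150-mer
shares a 16-mer with a 1.5-kb gene with probability ≪ 1). If a user lowers
the identity floor far enough that no useful safe word exists (< 8), the
prefilter disables itself.

## Survey aggregation and detection-rate statistics

`aggregate_site_years()` reduces per-dataset detections to the survey's
counting unit: a (site, year, gene) triple is positive when at least one of
its datasets is significant, *regardless of how many reads or datasets*
support it; a site sampled in several years counts once per year. Regions
are free-form labels attached to sites (a continent partition is one
choice, not hardcoded logic); the function refuses metadata in which one
site maps to two regions.

`detection_rate()` is total base pairs searched divided by the number of
positive site-years — the "one detection every *N* Gbp" statistic. Because
published summaries do not always say whether such a rate pools several
query genes or averages per gene, both modes are exposed (`by_gene`).
`size_detection_correlation()` quantifies the companion observation that
positive-site counts track data volume: a least-squares slope through the
origin plus the Pearson correlation of the unconstrained (volume, count)
pairs per region or year. Zero-variance counts are reported as r = 0 with
`r_defined = FALSE` rather than `NA`, so downstream tables stay numeric.

## SEC correlation profiling

`endpoint_activity()` converts end-point substrate concentrations to
activity per fraction: `activity = c0 − remaining` (defaults: c0 = 2.25 mM
substrate, 40 min incubation; dividing by the incubation time is optional).
Values above c0 — assay noise — are clipped with a warning; negative
concentrations are an error. Profiles correlate against substrate
*removed*, not remaining: the measured elution trace (remaining substrate)
anti-correlates with the abundance of the responsible protein, and the
removed-substrate transform restores the natural orientation.

`sec_calibrate()` fits the standard SEC calibration, least squares of
log10(mass, kDa) on elution volume (mL) over a protein standard mix
(15–600 kDa range); `apparent_mass()` inverts it, warning when asked to
extrapolate more than 10% beyond the calibrated range. On noise-free
standards the round-trip is exact to numerical precision, which the suite
asserts at 1e-9 relative error.

`correlation_cluster()` takes the `top_n = 200` most abundant proteins
(ranked by abundance summed across fractions — the ranking statistic is a
design choice, as "most abundant across the fractions" admits several),
excludes zero-variance profiles with a warning, and clusters the activity
profile together with the protein profiles. Similarity between profiles is
100 × Pearson correlation and the distance is 100 − similarity; linkage is
average (UPGMA). Neither metric nor linkage is uniquely dictated by the
phrase "similarity value" that such analyses report, so both are recorded
in `clustering_params()` and configurable; Pearson + average linkage is the
standard pairing for elution-profile clustering. Cutting the tree at height
100 − threshold returns exactly the proteins joined with the activity leaf
at similarity above the threshold (default 75%).

`oligomer_candidates()` enumerates subunit counts n = 1..`n_max` whose
predicted mass n × monomer lies within a relative `tolerance` of the
apparent mass, ranked by absolute deviation. The defaults `n_max = 8`,
`tolerance = 0.2` cover the common situation where an apparent mass of
about 200 kDa with a 57-kDa monomer is consistent with both a trimer
(171 kDa) and a tetramer (228 kDa). `stoichiometry_check()` is the small
companion test that substrate removal and product formation agree within a
relative tolerance (two zeroes — the no-enzyme control — pass).

## What the generators emulate, and what they do not

* `make_gene()` draws i.i.d. bases at a target GC; a 1509-bp gene stands in
  for a 502-codon coding sequence plus stop.
* `mutate_to_identity()` plants a homolog decoy: edits uniformly along the
  sequence (substitutions, optionally 10% single-base indels) sized so that
  independent global realignment recovers the target identity within about
  one point. The 0.85 default emulates the closest known relative of the
  sulfatase query at 85% nucleotide identity. Mutations are uniform because
  only the overall identity of the relative is known, not its mutation
  clustering.
* `simulate_reads()` draws substitution-only reads uniformly from
  flank + gene + flank, either strand, with truth labels (origin
  coordinates, error counts). Substitution-only is deliberate: the match
  criteria are identity/coverage-based and the emulated read data are
  short-read; quality-score realism, GC bias, paired ends and chimeras are
  out of scope. Read-length distributions vary across real archives, so
  the length sampler is an argument rather than a fixed law.
* `simulate_sec()` builds a Gaussian activity peak over fraction index
  (peak at fraction 10, sd 1.5 fractions, 80% of c0 removed at the peak;
  30 fractions of 0.5 mL between 7 and 22 mL), planted proteins as scaled
  activity plus Gaussian noise (sd = `noise_sd` × peak), and background
  proteins as independent unimodal profiles. Background peak centres are
  drawn at least 4 fractions from the activity peak with widths of 1–3
  fractions: what background proteins must provide is *lack of correlation
  with activity*, and the Gaussian-overlap correlation
  `sqrt(2·s1·s2/(s1²+s2²)) · exp(−Δ²/(2(s1²+s2²)))` shows that this
  separation caps their similarity near 55%, safely below the 75%
  threshold, by construction rather than by luck. Real SEC data contain
  co-eluting complexes at the activity peak's position; recovering exactly
  the planted set here therefore demonstrates the clustering machinery,
  not that real data would yield an equally clean subcluster.

All generators take a seed and reproduce byte-identical output; randomness
never leaks into or out of the caller's RNG state.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open throughout, so interval arithmetic for
the coverage union is unambiguous (`IRanges::reduce` does the merging).
Identity is matches/columns including gap columns. Empty read collections
are not errors — they are negative detections. Zero detections make the
detection rate infinite, with a warning, rather than an error. Ties in
choosing a read's "best" alignment break by larger span, then smaller query
start. The classifier evaluates each (read, gene) pair independently; a
read may in principle support two homologous queries if it passes both
genes' thresholds.

## Problem sizes used by the test suite

The suite runs everything at desk scale, chosen so the full run stays
within a couple of minutes: oracle-equivalence fuzzing uses 1,000 random
alignment tables on a 300-bp gene plus sequence-level collections of ≤ 20
reads on a 400-bp gene with 200-bp flanks; the specificity check screens
10,000 error-free 150-bp reads simulated from an 85%-identity decoy of a
1,509-bp gene; SEC recovery uses 20 seeded experiments at the full
30 × 200 size with 5 planted proteins and 5% noise; the detection-rate
recovery uses 400 simulated site-years. Tera-base-scale survey statistics
(continental site counts, Gbp-per-detection magnitudes, the published
22% median query coverage) depend on archives that cannot be bundled, so
the suite checks the *properties* of those statistics on synthetic surveys
with known truth instead.

## Known limitations

* The alignment search reports locally optimal alignments under one fixed
  scoring scheme; it does not reproduce blastn's word-seeding heuristics,
  E-values, or protein-level searches.
* Identity targets of `mutate_to_identity()` are approximate (±1 point)
  once indels are requested, because indel placement interacts with the
  realignment.
* `correlation_cluster()` with defaults will not necessarily reproduce a
  published subcluster obtained with an unstated similarity metric and
  linkage; the parameters exist precisely so users can match their own
  conventions.
* The pipeline's YAML config (`pipeline_config()`) round-trips losslessly,
  but it intentionally stores only scalars — paths to external FASTQ
  archives and download logic are out of scope.
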