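---
title: "Detecting segmental duplications: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting segmental duplications: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sdscape)
```

## The problem

Segmental duplications (SDs) are genomic segments of at least 1 kb present
in two or more locations at 90% or higher sequence identity. They mediate
non-allelic homologous recombination, seed copy-number variation, and
harbour rapidly evolving gene families (immunity, xenobiotic metabolism,
olfaction). Two complementary signals reveal them:

* **Self-alignment (WGAC)**: aligning an assembly against itself finds
  pairs of loci whose sequences still resemble each other. This sees both
  ancient (low-identity) and recent duplications, but it also reports
  *artifacts*: loci duplicated in the assembly that are single-copy in the
  organism (mis-assembly).
* **Read depth (WSSD)**: mapping whole-genome shotgun reads back to the
  assembly. Genuinely duplicated sequence attracts reads from all its
  copies and shows proportionally elevated depth; an assembly artifact
  splits the reads of one true locus across two assembled loci and shows
  *depleted* depth.

The combination rule exploits this asymmetry. Old duplications (identity
below 94%) are safe: mis-assembly produces near-identical copies, not
diverged ones. Recent-looking alignments (identity at or above 94%,
boundary inclusive on the high side) are kept only where read depth
corroborates them; the remainder are discarded as artifactual. The final
SD map is the base-level union of the low-identity loci and the
depth-validated high-identity loci. Depth-only intervals with no
alignment evidence are reported in a separate track and not counted in
the map, since the map is defined as alignment-derived with depth used as
a filter.

## The self-alignment stage

`self_align()` is a gap-free seed-merge-extend aligner:

1. known repeats are excised (`mask_repeats()`) so common interspersed
   elements cannot seed alignments; reported loci are lifted back to
   assembly coordinates, re-spanning any excised repeat that falls inside
   an alignment;
2. exact k-mer seeds (k = 14 by default, valid range 12-20) shared by two
   loci on the same diagonal, in either orientation, are merged when
   separated by at most 100 bp;
3. merged runs are extended without gaps under an X-drop rule (match +1,
   mismatch -3, drop 20), and
4. trimmed to the maximal segment whose running identity stays at or
   above the identity floor (implemented as the maximum-scoring
   subsegment under the score `match: 1 - t`, `mismatch: -t`, whose sum
   is non-negative exactly when identity is at least `t`).

Alignments shorter than 1 kb or below 90% identity are discarded; pairs
are reported once, in canonical order (locus A lexicographically before
locus B), with identity to four decimals. Substitution-only modelling is
deliberate: percent identity is the only similarity measure used
downstream, and planted divergence then maps one-to-one to expected
identity. The aligner is gap-free; a planted copy with indels would be
reported as split alignments.

**Cleaning.** Duplicated loci are merged into blocks; blocks linked by
any alignment form duplicon families (single-linkage). A family with 50
or more copies, or with members on 3 or more distinct chromosomes, is
removed together with all its alignments -- such hyper-dispersed families
behave like unannotated high-copy repeats, not SDs. `filter_high_copy()`
is idempotent, and alignment counts are reported per stage (initial
versus cleaned) as canonical deduplicated pairs.

## The read-depth stage

`place_reads()` maps fixed-length reads (36 bp by default) to every locus
within 2 mismatches, both strands, via a pigeonhole seed index (a read
with at most 2 mismatches must match one of its three 12-mer thirds
exactly, so the search is exhaustive). Two mismatches on 36 bp
corresponds to ~94% identity, aligning the mapping stringency with the
94% identity boundary of the combination rule. A multi-mapped read's
depth contribution is split equally among its equal-best loci -- a
deterministic, seed-free alternative to random best-hit assignment. A
consequence worth stating: a *balanced*, correctly assembled two-copy
duplication shows no depth excess under equal splitting; excess depth at
a locus comes from copies absent from the assembly (donor-only copies in
the simulator, collapsed or polymorphic copies in real data).

`profile_depth()` summarizes weighted per-base coverage in 5 kb windows
sliding by 1 kb. Repeat bases are excluded from window denominators;
windows under 50% non-repeat bases are uncallable. The diploid background
is the 5%-per-tail trimmed mean/SD of callable windows outside known
duplication loci (the WGAC loci in the pipeline); trimming keeps the
calibration stable when a few percent of the genome is duplicated.

`call_wssd_intervals()` flags callable windows above
`background_mean + z * background_sd` (z = 3), merges overlapping and
adjacent flagged windows, trims each merged candidate to the span of its
elevated slide-length tiles, and keeps intervals of at least 10 kb. The
trimming step exists because a 5 kb window overlapping an excess region
by only a fraction still exceeds the window threshold, so untrimmed
candidates overstate a region by up to a window width per side -- enough
to push a 6 kb excess region over the 10 kb floor. The tile threshold
rescales the window SD by `sqrt(window / slide)`.

Absolute copy number is the diploid-scaled depth ratio
`2 * mean_depth / background_mean`, to one decimal. The window geometry,
z and the 10 kb floor are exposed in the configuration; the defaults
follow established read-depth practice, and only the 10 kb interval floor
is fixed by the method definition itself.

## The combination stage

`split_by_identity()` partitions cleaned alignments at 94% (inclusive on
the high side). `validate_high_identity()` keeps a high-identity
alignment when at least `min_support = 0.5` of either locus is covered by
WSSD intervals; the supported-fraction threshold is a package choice
(config-exposed), as the method definition names no fraction.
`build_final_map()` merges the surviving loci into disjoint SD regions
with support class, maximum contributing identity and (where available)
copy number, plus an SD-content summary. `verification_proportion()`
reports, over merged high-identity loci strictly longer than 10 kb, the
length fraction belonging to loci whose depth support reaches the
threshold -- a per-assembly quality indicator (low values flag assemblies
whose recent duplications are suspect).

## Permutation enrichment

Association between an SD map and landmark interval sets (CNVRs,
pericentromeric and subtelomeric regions, gene families) is tested by
re-placing the query regions uniformly at random -- chromosome drawn
proportional to length, start uniform over the feasible range, mutual
overlaps rejected -- and recomputing the overlap statistic (count of
landmarks hit, or total overlapping bases) for each of `n_replicates`
placements (10,000 by default). Fold enrichment is observed over null
mean; the empirical p-value uses the add-one convention
`(1 + #[null >= observed]) / (1 + n_replicates)`, so it is never zero and
the smallest reportable value at 10,000 replicates is just below 1e-4.
The test is upper-tail (enrichment); depletion shows up as p near 1 and
is left to the user to report two-sidedly if wanted. Queries are
shuffled, not landmarks, and placement is genome-wide (regions may change
chromosome); chromosomes without defined landmarks simply contribute
placement space. Pericentromeric and subtelomeric landmarks are built as
2 Mb flanks around centromeres and chromosome ends, 300 kb for designated
short (micro)chromosomes; on the packaged 1 Mb-chromosome fixtures the
run configuration scales the flank to 50 kb, because a 2 Mb flank sized
for real mammalian chromosomes would cover such a genome entirely and
degenerate the test. Gene-family enrichment re-places the family's gene
intervals against the SD map as landmarks, in both statistic modes; no
multiple-testing correction is applied across landmark sets.

## Gene content

`genes_in_sd()` intersects a gene annotation with the merged map (any
overlap of at least 1 bp by default; config-exposed, as no stricter
fraction is defined). Per-gene copy number is taken from the WSSD
interval with the largest overlap -- the assignment rule is a package
choice -- with genes touching no interval reported as Null.
`bin_gene_cn()` uses right-closed bins with edges 1.5, 2.5, 10.5, ...,
100.5 plus the Null bin, and a 1-decimal average over non-null genes.
`common_genes()` maps per-species SD gene sets into a shared reference
namespace through user-supplied ortholog tables (no live database
queries; a species gene mapping to two reference ids is an error) and
reports genes present in at least `min_species` species with full
Venn-style combination counts.

## The simulator and what passing tests mean

`make_fixture()` builds the canonical synthetic datasets. The standard
scale is 5 chromosomes of 1 Mb at GC 0.41 carrying:

* 30 regular duplication events, lengths log-spaced 1-50 kb, one
  reference copy each (tandem / intrachromosomal / interchromosomal in
  rotation), divergences 0-10% assigned inversely to length (the largest
  events are the most identical, so boundary-identity events are small
  and cannot dominate the recovery metric);
* donor-only extra copies (2-4) on every event at or above 94% identity,
  so genuine recent duplications carry the depth excess the validation
  step demands, and 0-1 extras on older events for copy-number variety;
* a 60-copy family on two chromosomes (removed by the 50-copy rule) and a
  3-chromosome family (removed by the chromosome rule);
* two assembly-artifact events (copies present in the reference, absent
  from the donor individual) that the 94% + depth rule must reject;
* a 200-copy, 300 bp interspersed repeat family, supplied as the repeat
  mask.

The donor individual is modelled as two haplotypes: hap A is the
reference minus artifact copies; hap B additionally carries the
donor-only copies. Reads are drawn uniformly over both haplotypes (36 bp,
0.5% uniform substitution errors, diploid 20x), which makes the
diploid-scaled copy-number estimate equal the total copy count across the
individual's two haplotypes -- including odd values. Events planted to
exercise the filters carry `expect_in_map = FALSE` in the ground truth
and are excluded from the recovery denominator (they are still planted
duplications, so they are also not counted as false-positive bases).

What the synthetic data does *not* emulate: GC-biased and
insert-size-structured coverage, quality-dependent sequencing error,
indels and rearrangements within duplications, satellite/heterochromatic
sequence, and polymorphism segregating in the reference individual beyond
the planted events. Passing the end-to-end tests therefore demonstrates
the correctness of the machinery under its stated model, not calibrated
performance on real assemblies.

Problem sizes in the packaged tests were chosen as the smallest that
exercise every rule meaningfully: the 5 Mb standard fixture for
end-to-end recovery and determinism, 0.4-1 Mb genomes for stage-level
properties, 200 tests of 500 replicates for null calibration of the
permutation machinery, and a brute-force alignment oracle on a 15 kb
genome (the all-diagonal scan is quadratic, and 15 kb already separates
seeded detection from exhaustive scanning).

## Numerical and design choices

* Coordinates are 0-based half-open everywhere in memory and on disk
  (BED); FASTA headers carry bare chromosome names.
* All randomness flows from one global seed; stages derive 31-bit seeds
  from `hash(seed, stage_name)` (`derive_seed()`), so any stage can be
  reproduced in isolation. C++ kernels draw from R's RNG.
* Identity ties in chaining are broken by (chromosome, start) order;
  identity is reported to 4 decimals; copy numbers to 1 decimal.
* Equal-length alignment counting: reciprocal pairs are counted once
  (canonical order). Counts of "initial" versus "cleaned" alignments are
  reported on that basis.
* The empirical p-value's add-one convention and upper-tail default are
  stated above; `empirical_p` is monotone non-increasing in the observed
  statistic for a fixed null.
* Degenerate inputs: an empty alignment set cleans to an empty set; an
  empty read set yields empty placements with a warning; a fully masked
  genome is a calibration error; a verification proportion with no
  qualifying loci is NA with a warning, not a crash; an empty gene family
  is an undefined-result error.
* The run manifest records the configuration snapshot (with input file
  basenames and checksums), per-stage record counts and output checksums;
  wall time is recorded but is the one field two otherwise identical runs
  may differ in.

## Known limitations

* The aligner is gap-free; duplications that accumulated indels are
  reported piecewise rather than as one alignment.
* Equal-split mapping means balanced assembled duplications carry no
  depth signal; validation of high-identity duplications therefore
  relies on copy-number polymorphism or collapse relative to the
  sequenced individual, exactly as in the underlying method.
* WSSD cannot call excess regions shorter than 10 kb, so genuine small
  recent duplications (< ~10 kb at >= 94% identity) are filtered out of
  the final map. This is visible in the end-to-end recovery metric,
  which remains above 90% but below 100% for exactly this reason.
* Copy-number estimates assume a diploid baseline everywhere, including
  sex chromosomes; single-copy chromosomes are the user's responsibility.
* Permutation placement is uniform and unaware of mappability or
  segmentation structure; no multiple-testing correction is applied
  across landmark sets.
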