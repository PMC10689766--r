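---
title: "Methods: virion induction profiling with vipseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virion induction profiling with vipseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vipseq)
```

## The measurement model

A lysogen culture sheds virions from whichever of its prophages induce
spontaneously. After DNase digestion of the supernatant only encapsidated
DNA survives, so sequencing that DNA and mapping reads back to the host
assembly yields a signal that is almost entirely prophage-derived, with a
thin uniform background from residual (undigested) host chromosome.
`vipseq` works entirely on this mapped representation; trimming and
alignment are upstream concerns.

Three observations drive the method:

1. **Coverage islands.** An active prophage produces a contiguous
   high-coverage region over its integrated locus; everything else sits at
   a low background depth.
2. **Junction reads.** The packaged genome is the excised circle, so
   fragments spanning the re-joined att site map discordantly on the
   linear reference: mate pairs anchored near attL and attR facing away
   from the prophage interior, and reads split across the junction,
   soft-clipped at one boundary with the clipped bases matching the
   sequence just inside the other. A handful of such reads identifies the
   exact boundaries — this is what makes the approach workable at very low
   titres.
3. **Mass-to-copies conversion.** Read fractions partition the measured
   eluted DNA mass between prophages; dividing a prophage's mass share by
   the mass of one genome copy (`M_nt · L / N_A`) gives an absolute titre
   in genome copies per mL.

## Detection: segmentation and boundary refinement

`compute_coverage()` counts alignments per base (overlapping mates count
twice; the simulator's oracles use the identical convention).
`segment_islands()` thresholds at `min_fold` (default 5) times the robust
background estimate — the median depth outside islands — merging runs
separated by at most `merge_gap_bp` (default 2000) and keeping merged
runs of at least `min_len_bp` (default 5000, comfortably below the
smallest active prophages seen in practice, ~16 kbp) whose mean depth
still clears the threshold. Background and islands are re-estimated
alternately until stable (at most 5 rounds). If the background median
reaches zero while islands exist, iteration stops with the current set;
if the library has no chromosomal background at all, every covered run
becomes a candidate and the profile is flagged.

A practical stability note, visible in simulation: the median background
estimate is only reliable when residual host coverage has median depth of
a few reads. At a background mean depth near 1–2× the median oscillates
between small integers and the 5× threshold can admit merged noise runs.
The package's simulations therefore run at background depths of roughly
4–6×; with sparser background the island edges (not the junction-refined
boundaries) become less reproducible.

`collect_junction_evidence()` gathers, per island, outward-facing mate
pairs whose anchors fall within `search_window_bp` (default 2000) of the
two island edges, and soft-clipped reads (clip at least `min_clip = 20`
bases) at one edge whose clipped sequence exactly matches the genome near
the other edge. Orientation-inconsistent pairs are recorded but never
counted. `refine_boundaries()` then scores candidate (attL, attR) pairs:
a mate pair supports a hypothesis when both mates lie inside it and the
implied circular insert — the distance from the right-edge mate to attR
plus the distance from attL to the left-edge mate's end — is at most
`max_insert_bp` (default 1500, about three times a typical short-insert
library); a split read supports exactly the boundary pair its clip and
anchor coordinates name. Ties are resolved by more split support, then
the shorter interval, then the leftmost start. Because the score only
changes at evidence-derived coordinates, searching those coordinates is
equivalent to exhaustive per-base enumeration; the test suite verifies
this equivalence directly on small instances.

Calls with fewer than `min_support = 2` junction observations keep their
island edges and are tiered `coverage_only` — mirroring the situation
where read coverage is too low to fix boundaries directly — rather than
being dropped. Two independent observations guard against chimeric
artefacts. Per-call GC is reported relative to the whole-genome GC (both
over A/C/G/T only); note the reference includes the prophages themselves.

`flanking_enrichment()` quantifies the lateral-transduction signature:
mean depth, enrichment over background, and the slope of `log(depth + 1)`
against distance from the prophage edge over a window each side. Strong
one-sided enrichment with a negative decay slope indicates host DNA
packaged in successive capsid headfuls. A caveat found in simulation:
when the near-edge gradient exceeds the island fold-threshold, the
transduced flank merges into the coverage island, the affected edge loses
its junction evidence and the call drops to `coverage_only`; flank
statistics are then best computed against junction-refined or known
boundaries.

## Quantification

`vip_titre()` implements

$$\mathrm{virions/mL} = \frac{m_\mathrm{DNA}\,N_A}{M_\mathrm{nt}\,L}\cdot\frac{r_{pp}}{r_\mathrm{tot}}$$

with `m_DNA` in ng per mL of original culture (converted to grams
internally), `N_A = 6.02214076e23` and `M_nt = 617.96` g/mol/bp. Reads
are assigned to calls by leftmost mapped position, which keeps per-call
counts exactly multinomial and makes the mass identity exact: summing
`titre · L · M_nt / N_A` over calls plus the residual read share
reconstructs `m_DNA` to machine precision. Reads are not fractionally
split across a boundary; a boundary-straddling read counts where it
starts. Background reads overlapping a prophage locus inflate its count
slightly (by about `b · L / G` of the read pool for background fraction
`b`); at realistic background levels (a few percent) this is well inside
counting noise.

`detection_limit()` converts the fluorometer's minimal detectable mass in
the assayed aliquot into a titre: minimum total eluted mass is
`qubit_limit_ng · elution_volume / assay_volume` (the aliquot measures
concentration, it does not consume mass), scaled per mL of supernatant,
converted at read fraction 1 and the mean prophage length, and divided by
`1 − concentration_loss_fraction` so the limit refers to the
unconcentrated supernatant. Loss is applied only here — reported titres
are deliberately unadjusted. With the standard parameters (0.1 ng, 24 µL,
5 µL, 30 mL, 41 kbp, 47% loss) the limit is ~7.2×10⁵ virions/mL;
`induction_rate()` divides a titre by CFU/mL times burst size (default
150, lambda-like).

## Prediction benchmarking

Per prediction/active pair: nucleotide precision `|pred ∩ active|/|pred|`
and recall `|pred ∩ active|/|active|`. An active prophage counts as
predicted only if a *single* prediction has recall strictly greater than
the threshold (default 0.75); recall is never summed across predictions,
though one long merged prediction may legitimately match several adjacent
active prophages. Active-prophage recall is the matched fraction.
`category_rates()` cross-tabulates predictions by structural-gene and
IS-element annotation (flags are consumed from an annotation table, never
computed here) and reports per-cell activity fractions, leaving empty
cells missing rather than zero.

## Phagotypes and protection

Prophage clustering takes a pairwise intergenomic-similarity matrix as
input (its computation is out of scope) and applies single-linkage
connected components at the chosen threshold — 95% for species-level,
70% for genus-level, 50% for a broader grouping; the published grouping
procedure is not algorithmically specified, and single linkage is the
deterministic choice consistent with threshold graphs. Cluster ids are
the lexicographically smallest member, so results are order-invariant.
Strains with identical genus-level cluster combinations share a
phagotype; the empty combination is a valid phagotype.

`protection_statistic()` counts plaquing among ordered donor→recipient
supernatant interactions whose cluster sets satisfy a relation. The
default `subset_either` (either set contains the other) reflects that
"same or subset phagotype" has no stated direction; `equal` and
`donor_subset_of_recipient` are available, and the exact interaction
denominators depend on this choice and on whether prophage-free strains
are included, so both are surfaced as options. A seeded permutation test
(default 1000 shuffles of which strain carries which cluster set) gives a
one-sided p-value for the within-group plaquing deficit; it is reported
separately and does not alter the counts.

Genome dereplication groups genomes with identical predicted-prophage
cluster sets (representative: smallest id; prophage-free genomes share
the empty group unless explicitly distinguished). Accessory genes are
attributed to active-prophage regions by midpoint containment, which is
robust to genes straddling att sites.

## The simulator

`make_lysogen()` draws a host backbone at a configured GC and inserts
prophages drawn at their own GC at fixed backbone positions, recording
truth intervals in final coordinates. `simulate_virion_reads()`
apportions read pairs multinomially: a background fraction (default 0.02,
residual undigested host DNA — the empirical value for real libraries is
not well characterised, so it is exposed in the config) uniform over the
chromosome, the rest split across prophages by DNA mass share
(`titre · L`). Prophage fragments start uniformly on the *circular*
excised genome with Normal(500, 60) lengths truncated at the 150 bp read
length, so a fragment wraps the junction with probability `length/L`,
reproducing the expected yields of outward-facing pairs and split reads.
Reads are error-free by default — the method consumes mapping positions,
not base identities — and are emitted pre-aligned in a truth SAM
(split reads carry their correct soft clips) so detection is testable
without bundling an aligner; FASTQ is also written for end-to-end runs
through a real mapper. The recorded `m_DNA` is derived from genome-copy
masses and inflated by `1/(1 − b)` so that read fractions and mass
fractions agree — i.e. it is the *total* encapsidated-plus-residual DNA
mass the assay would measure, which is what makes titre estimates
unbiased; at `b = 0` it equals the plain sum of per-prophage copy masses.

`apply_lateral_transduction()` adds host-derived pairs on one flank with
expected depth stepping down once per `headful_bp`, decaying
geometrically from `edge_enrichment ×` background to background across
`extent_bp` — a multiplicative loss per packaging step is the natural
model for successive capsid headfuls, and it yields the observed
log-linear decay. Defaults emulate the reported scale of the phenomenon
(~200 kbp extent).

What the simulator does *not* model: sequencing errors and mapping
ambiguity (all simulated reads are uniquely placed at MAPQ 60), repeats
and multi-copy elements, non-excising encapsidated elements (gene
transfer agents, generalized transduction), origin-spanning prophages
(unsupported and flagged by the coordinate conventions), uneven
background, or GC-dependent coverage bias. Passing tests therefore
demonstrate correctness of the algorithmic chain under clean mapping, not
robustness to alignment artefacts in real libraries.

## Problem sizes and numerical choices

The test suite and the acceptance script run the recovery properties on
60–80 kb lysogens with one or two prophages, 3,000–6,000 read pairs and
background depth ~4–6× across 100 seeded replicates each; boundary
recovery is exact in all replicates and mean titre bias is below 1%,
within three standard errors of the multinomial sampling noise. The
brute-force boundary enumeration is checked on ≤50 kb instances with a
150 bp search window. All randomness flows from a single integer seed;
identical configurations reproduce byte-identical outputs. Internal
coordinates are 0-based half-open everywhere, BED output is 0-based,
human-readable reports are 1-based inclusive with labelled columns.

## Known limitations

* Island segmentation needs a measurable background median; virion-only
  libraries fall back to covered-run candidates and are flagged.
* Strong lateral-transduction gradients can merge the flank into the
  island and demote the call to `coverage_only` (see above).
* Titres are not adjusted for concentration loss (only the detection
  limit is), matching the convention the assay reports.
* Interaction denominators in protection statistics depend on the chosen
  subset relation and strain inclusion rules; compare like with like.
* Multi-contig assemblies are accepted, but prophages must not span
  contig ends, and origin-spanning prophages are unsupported.
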