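---
title: "Single-molecule footprinting and methylation analysis of LINE-1 antisense promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule footprinting and methylation analysis of LINE-1 antisense promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspa)
```

## The biological question

A full-length LINE-1 (L1) retrotransposon carries a bidirectional CpG-island
promoter: a sense promoter driving the element's own open reading frames and
an antisense promoter (ASP) that can fire into the flanking host gene and
produce chimeric, potentially oncogenic transcripts. In normal somatic
tissue the promoter is densely CpG-methylated and silent; hypomethylation —
frequent in tumors and, strikingly, across histologically normal tissue of
tumor-bearing organs — activates it. At the chromatin level the silent
promoter sits in a compact *tetranucleosomal* configuration (a −1 and a +1
nucleosome at each of the two facing start sites), while the active promoter
loses both −1 nucleosomes, leaving a *dinucleosomal* state with
nucleosome-free regions (NFRs) upstream of both TSSs.

This package implements the complete analytical chain needed to study that
switch from single-molecule bisulfite data: GpC-methyltransferase
footprinting (M-SPA), locus-specific methylation quantification, strand-level
mixture statistics, cohort comparison, and a genome-annotation scan for
candidate ASPs — together with a generative simulator that produces every
input with known ground truth.

## Site contexts and the GpCpG exclusion

M-SPA treats intact chromatin with the GpC methyltransferase M.CviPI:
accessible GpC cytosines acquire methylation, nucleosome-protected ones do
not, and bisulfite sequencing of cloned single molecules reads the marks
out. The assay works at endogenously methylated loci because human DNA
carries no endogenous GpC methylation — except where GpC and CpG overlap in
a GpCpG trinucleotide. At such sites enzymatic and endogenous methylation
are indistinguishable, so `classify_sites()` removes **both** overlapping
dinucleotide calls and reports the position as excluded. Every analysis
downstream operates only on informative CpG (endogenous) and GpC
(accessibility) columns; an adjacent `N` voids a context entirely, since the
ambiguity cannot be resolved conservatively in either direction. All
coordinates are 1-based and inclusive, the style in which locus spans are
conventionally printed; any half-open arithmetic is private.

## The generative model

`simulate_clone_set()` draws molecules from a mixture over three occupancy
states and pushes them through enzyme treatment and bisulfite conversion:

* **Geometry.** Nucleosome cores protect 147 bp (the canonical core
  particle). In the tetra state a +1 nucleosome begins at each TSS (the two
  +1 cores face each other between the start sites, separated by a 20 bp
  linker) and a −1 core sits 20 bp upstream of each TSS. The di state keeps
  only the +1 cores; the open state has none. The default amplicon
  (`l1_promoter_locus()`) is a deterministic 780 bp tiling with a GpC
  roughly every 15 bp (at least 8 informative GpCs per 147 bp window), a
  CpG and an excluded GpCpG every 30 bp, and a plain-context C every 30 bp
  as the conversion-QC readout. The TSSs (249 and 562) are placed so each
  of the three internal linkers contains at least one informative GpC —
  otherwise abutting protection patches could never be separated even by a
  perfect assay.
* **Enzyme marking.** Each accessible GpC is marked with probability
  `enzyme_efficiency` (default 0.85, typical of a 15-minute in-nuclei
  reaction); GpCs under a footprint are never marked (a hard zero the tests
  assert). One uniform draw is spent per GpC regardless of accessibility,
  so runs sharing a seed are coupled across efficiency values (common
  random numbers), which makes mark sets nested along an efficiency grid.
* **Endogenous methylation.** By default CpG methylation follows the
  chromatin state (tetra molecules fully methylated, di/open fully
  unmethylated), reflecting the observed coupling of methylation and
  occupancy. Setting `endogenous_mixture = w` instead draws each strand
  fully methylated with probability `w`, the biphasic strand mixture seen
  in patient clones; intermediate per-site noise is deliberately not
  modelled, so the mixture stays identifiable.
* **Bisulfite conversion.** Unmethylated cytosines convert to T with
  probability `conversion_rate` (default 0.99). A failed conversion is
  indistinguishable from methylation — the single noise channel. Sequencing
  error is not modelled separately: the clones this emulates are
  Sanger-quality. One draw is again spent per cytosine, preserving the
  coupling. Reads keep the reference length (no indels).

Everything is reproducible: the same `sim_config(seed =)` yields
byte-identical molecules, reads, cohorts, and fragment populations.

## Calling methylation and accessibility

`call_methylation()` requires an ungapped full-length read (locus-specific
amplicons are fixed-length; indel-bearing or foreign clones — more than 10%
of non-site positions disagreeing with the converted reference — are
rejected by name). `qc_clones()` estimates per-clone conversion efficiency
from plain-context cytosines and drops clones below 0.95, the standard
bisulfite QC; no per-cell correction of conversion failure is attempted,
matching clone-sequencing practice. At the defaults this removes about 3%
of clones.

## Footprint inference

`call_footprints()` segments each molecule's accessibility vector into
maximal runs of protected GpCs. Missing calls are neutral — absence of
evidence neither extends nor breaks a run. A patch's span extends to the
midpoints between its terminal protected sites and the flanking accessible
sites (or to the amplicon edge): the data constrain a footprint edge only
to the interval between two informative sites, and the midpoint treats that
uncertainty symmetrically. Spans of 120–200 bp are classified `nucleosome`
(147 bp core ± linker/resolution slack); shorter patches are
`sub-nucleosomal`, longer ones `super-nucleosomal`.

The smoothing parameter `k` absorbs up to `k` isolated accessible calls
per patch. Its default is 0 (report exactly what the molecule shows), but
the package's own analyses run `k = 1`: at a conversion rate of 0.99 each
protected site has a ~1% chance of reading as a false accessible call, and
a single such call otherwise fragments a genuine nucleosome patch. Raising
`k` further trades those false fragmentations for false merges and measured
accuracy drops again, so `k = 1` is the matched setting for this noise
model.

## Promoter-state classification

`classify_promoter_state()` applies a fixed rule set over four 147 bp
windows: one directly up- and one directly downstream of each TSS, in its
own transcription direction.

* **Tetranucleosomal**: at least 90% of informative GpCs over the promoter
  span protected, *or* all four windows substantially covered by
  nucleosome/super-nucleosomal footprints. The global-protection rule is
  primary because internal linkers may carry no marked GpC on a given
  molecule, merging the four cores into fewer patches.
* **Dinucleosomal**: a nucleosome-sized *or larger* footprint over both +1
  windows, while both −1 windows contain at least one accessible site and
  no substantial footprint — the upstream NFRs that define the active
  state. Super-nucleosomal patches are accepted over the +1 windows because
  the two +1 cores abut across a 20 bp linker whose single GpC is unmarked
  on ~15% of molecules, fusing them into one long patch; the NFR
  requirement still separates this from the tetra configuration.
* **Open**: at most 10% of informative sites protected.
* **Other**: everything else, including any window without informative
  sites (reported as explicit "uninformative window" evidence).

Two overlap thresholds deliberately differ. *Claiming* occupancy requires
40 bp of footprint/window overlap, enough to ignore the 10–30 bp
sub-nucleosomal specks left by isolated unmarked GpCs. *Vetoing* an NFR
requires a footprint to cover at least half the −1 window
(`veto_cover = 0.5`): midpoint extension and `k`-absorption can push a
genuine +1 patch 50–70 bp past the TSS, and treating that jut as a −1
nucleosome would misclassify true dinucleosomal molecules. With these
settings the classifier recovers the true state of ~98–99% of molecules at
the default noise levels (enzyme efficiency 0.85, conversion 0.99) and the
mixture fractions to within about one percentage point; accuracy is
monotone in enzyme efficiency when conversion noise is absent, which is how
the monotonicity property is stated and tested — with conversion noise the
two channels interact at the margin and single molecules can flip either
way.

## Methylation statistics

`percent_methylation()` implements the standard per-site quantification,
100 × methylated / (methylated + unmethylated), with the subset summary as
the unweighted mean over sites — the convention of small-panel quantitative
assays, which average two to four CpGs. Calibration is measured at
`conversion_rate = 1`: the estimator itself is unbiased to well under one
percentage point at 500 clones, while at conversion 0.99 the chemistry adds
a known +((1 − rate) · (1 − w) · 100) offset that the pipeline reports
uncorrected, as the assay does.

`fully_unmethylated_fraction()` is the PUR statistic — the percentage of
strands unmethylated at every site of a panel — reported alongside the
fully-methylated and intermediate percentages (the three always sum to 100
on complete data). PUR is computed over a 2-CpG panel in the package's
analyses, mirroring the small panels such strand-specific assays probe;
over large panels conversion-failure attrition (a factor of rate^sites on
the fully-unmethylated class) would dominate. `strand_distribution()` bins
per-strand percent methylation in 10% bins with the exact-0 and exact-100
masses reported separately, because the biphasic claim concerns exactly
those endpoints; over a 10-CpG panel a 50/50 mixture puts ≥ 90% of strands
at the endpoints. `assay_concordance()` models two quantitative assays as
percent methylation over two disjoint panels of the same molecules and
reports their Pearson correlation.

## Cohort statistics

`mann_whitney_u()` uses mid-rank ties and reports a two-sided p (the
conventional default; sidedness is never implied by the figure-star
notation): exact by full enumeration of labellings when n₁ + n₂ ≤ 16 with
no ties — a cutoff balancing fidelity and the combinatorial cost — and a
tie- and continuity-corrected normal approximation otherwise; both paths
are cross-checked against each other and an independent implementation in
the overlap zone. `roc_auc()` requires an explicit positive-class
direction, with *low* methylation the positive (disease) signal by
default: a silently flipped sign is the main failure mode of ROC analyses
on methylation data. The threshold-sweep construction credits ties 0.5, so
AUC = U/(n₁·n₂) holds exactly and is asserted as a property.
`group_summary()` stars pairwise contrasts at p < 0.05/0.01/0.001 without
multiple-testing correction (a Bonferroni option exists, default off,
matching how such panels are conventionally annotated).

The cohort generator uses three groups sized 19/24/26 — 19 matching the
normal-donor count of the motivating study design, the others typical
cohort sizes — with methylation means 85/50/30% (sd 7/18/15): high and
tight in normal tissue, hypomethylated and dispersed in the field-defect
and tumor groups. Expression rises as methylation falls (means 1/3.5/6
relative units) and is coupled within groups at correlation −0.8. These
values are the package's standing definition of a "realistic" cohort; they
are not fitted to any dataset, and the real study's patient-level values
are not deposited, so printed clinical AUCs and correlations are structural
templates rather than reproduction targets.

## MNase fragmentation and the ASP scan

`simulate_mnase()` cuts each inter-nucleosome linker independently with
probability `p_cut`; a fragment's class is the number of cores it spans.
For tetranucleosomal molecules the three linkers give eight equiprobable
cut patterns at `p_cut = 0.5`, and the fragment-class frequencies
(0.60/0.25/0.10/0.05 for mono/di/tri/tetra) are checked against that
exhaustive enumeration. Nucleosome counts are conserved exactly.

`scan_candidate_asps()` returns the L1 repeats that satisfy all three
candidacy criteria: full length (≥ 6000 bp, the size of an intact element),
entirely intronic (no exon overlap, fully between two consecutive exons),
and antisense to the host gene — so the ASP fires in the host's sense
direction and can splice into its downstream exons. The scanner is verified
against a brute-force filter on genomes with planted candidates and decoys
(`make_synthetic_genome()`). It performs interval/strand logic over
*provided* annotations only; repeat discovery is out of scope.

## Problem sizes, determinism, and limitations

The shipped analyses use 200–1000 molecules per experiment, 10,000
replicates for null calibration, and 5000–10,000 molecules for
fragment-population checks — sizes at which every binomial acceptance band
is decisive while a full run completes in minutes on one core. All
randomness flows from explicit seeds.

What the simulator does **not** model bounds what passing tests show about
real data: no PCR bias or clonal duplicates, no bottom-strand reads, no
indels or sequencing error beyond the conversion channel, no intermediate
(partially methylated) strands, no H2A.Z/histone-mark layer, and fixed
nucleosome positions per state rather than thermodynamic positioning. The
classifier's rule set is likewise tied to the two-TSS geometry: loci whose
windows lack informative GpCs are honestly reported as `other`
("uninformative window") rather than guessed. Clone counts per sample in
the motivating assay are unknown, so `n_molecules` stays fully
configurable rather than asserting a study value; likewise whether a small
quantitative panel averages sites before or after technical replicates is
ambiguous in the source assays — the package averages sites of one
measurement and leaves replicate averaging to the caller.
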