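---
title: "Methods: trio binning, switch detection, scaffolding and QC in triokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio binning, switch detection, scaffolding and QC in triokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A diploid individual carries two haplotypes. Standard assembly collapses
or arbitrarily mixes them; *trio binning* instead uses short reads from
the two parents to partition the offspring's long reads by haplotype
before (or during) assembly, yielding two fully phased genomes. This is
especially clean when the parents are double haploids, so that each
contributes exactly one haplotype to the F1. `triokit` implements the
computational stages around such a project: hap-mer extraction and read
binning, phasing assessment of the resulting assemblies, iterative
reference-guided scaffolding with gap patching, and assembly QC — plus a
synthetic trio simulator so every stage is testable without external
data.

# Hap-mers and read binning

K-mers are counted canonically: each window of length $k$ is represented
by the lexicographic minimum of itself and its reverse complement over
$A<C<G<T$, which makes counting strand-independent. $k$ must be odd (an
even $k$ admits reverse-complement palindromes, which have no
unambiguous canonical form) and at most 31, the range representable in
two bits per base within a 64-bit word. The default $k = 21$ is the
standard trio-binning choice. Any non-ACGT base invalidates every
k-mer window that spans it.

A k-mer is a *hap-mer* (parent-specific) when its count in one parent's
reads passes a noise floor (`min_count`, default 5) and its count in the
other parent is *below* that floor. At 45x parental coverage a true
genomic k-mer is seen ~45 times while a k-mer created by a sequencing
error is usually seen once or twice, so a floor of 5 separates the two
regimes; it is configurable, as is an optional repeat ceiling
(`max_count`) to exclude high-copy repeats. The two specific sets are
disjoint by construction.

Each long read is scored by the number of its canonical k-mers found in
the A- and B-specific sets; the bin is the argmax, with ties — including
0–0 — going to `unknown`. The unknown bin is not waste: those reads come
from regions where the haplotypes are locally identical, and the
documented downstream convention is to assemble each parent from its own
bin *plus* the unknown bin. An optional normalization mode divides each
score by the size of its hap-mer set (computed by exact integer
cross-multiplication) to compensate for asymmetric set sizes; it is off
by default because the reference tools do not document such a
correction.

Why this works at low heterozygosity: at a genome-wide heterozygous
variant rate of ~0.117% a 15 kb read is expected to span ~17 variants,
each contributing up to $k$ hap-mers, so the probability that a read
carries no haplotype evidence at all is vanishingly small
($e^{-17}$ under a Poisson model). That is why error-free simulations
recover essentially every read.

# Phasing assessment and switch detection

Binned reads are aligned back to an assembly and, per fixed-width window
(default 1 Mb), the percentage of window bases covered by each bin's
placements is computed. "Coverage" here is *breadth* — the fraction of
bases covered by the union of intervals, never exceeding 100 regardless
of depth — matching the fraction semantics of `bedtools coverage`; a
mean-depth mode is available behind `mode = "depth"`. The signed
difference `pct_a - pct_b` classifies each window to the parent with the
higher rate (a dead zone `min_abs_diff`, default 0, makes near-zero
differences ties). For an assembly expected to be one parent's
haplotype, *concordance* is the percentage of non-tie windows classified
to that parent; ties are excluded from the denominator, a choice the
reference work leaves unstated and which we therefore make explicit.
*Switch blocks* — runs of windows assigned to the unexpected parent —
are reported at window resolution as BED intervals.

One placement is kept per read: the record with the most residue matches
(PAF column 10), ties broken by the earliest record; reads from the
unknown bin are excluded, since only the parental bins carry phasing
information.

# Reference-guided scaffolding and gap patching

Contigs are placed *whole* — no breaking on conflicting alignments. This
mirrors the deliberate workflow choice to preserve contig integrity
rather than accept the cuts that optical-map conflict resolution
introduces. After filtering alignments (block length ≥ 1 kb, mapq ≥ 10,
the scaffolder defaults), each contig is assigned to the chromosome with
the largest merged query-interval coverage; the ordering key along the
chromosome is the coverage-weighted mean of target starts, which is
deterministic and robust to split alignments; orientation is the sign of
the match-weighted strand sum. Confidence values (best/total coverage;
winning/total strand mass) are reported, with lexicographic tie-breaks
flagged low-confidence and a zero strand sum defaulting to "+" at
confidence 0.5. Scaffolds join contigs with 100 N gaps (AGP gap type
"scaffold", linkage "yes", evidence "align_genus") and adopt the
reference chromosome names; unplaced contigs pass through unchanged.

Gap patching fills an N-run when one donor sequence anchors both flanks
(within 50 kb by default) on the same strand in collinear order. Anchors
are the longest flank alignments; the donor coordinates of the gap edges
are obtained by linear interpolation through the anchor records, and the
gap — plus any flank overlap the anchors imply — is replaced by the
spanning donor sequence. Conflicting donors leave the gap untouched and
are logged. `run_workflow()` chains scaffold and patch steps (each step
against any reference, including externally produced hybrid assemblies)
and records contiguity statistics after each step.

# Assembly QC

N-statistics use the standard minimal-cover definition: N50 is the
length of the shortest sequence in the smallest set of longest sequences
reaching half the total; L50 is that set's size (N90/L90 analogous).
Contig statistics split scaffolds at N-runs of at least 10 bases (a
common convention; the threshold is a parameter). Gap discovery reports
maximal N-runs in BED coordinates.

Telomere exploration counts tandem-repeated units (two or more exact
consecutive copies) of each length 5–12 within the terminal 50 kb of
each sequence. Units are pooled over rotations and strand by the
*canonical rotation* — the lexicographic minimum over all rotations of
the unit and of its reverse complement — because a tandem array has no
distinguished phase or strand; non-primitive units (multiples of a
shorter unit) are skipped so that a hexamer array is not also reported
as its dodecamer double. The per-window search counts overlapping
occurrences of a unit and its reverse complement in 1 kb windows.

Heterozygosity is estimated as SNP positions plus indel positions (an
indel counts as one position whatever its length, matching the
position-count convention of `show-snps`-style callers) over a
denominator that is either the summed aligned length (default) or a
supplied genome size — the reference value's denominator is ambiguous,
so both modes are provided. Inputs are per-alignment-block counts, from
a TSV or parsed directly from minimap2 `cs:Z:` difference tags.

# The simulator: what it emulates and what it does not

`sim_config()` defaults are the study conditions at desk scale: two
2.5 Mb chromosomes (5 Mb genome) with 35% GC, telomere arrays
(`TTAGGG` ×300, reverse-complemented at the 5' end), heterozygosity
0.1168% split ~85/15 between SNPs and short indels (geometric lengths,
mean 3 bp), double-haploid parents sequenced at 45x with error-prone
(0.1%) 150 bp paired-end reads, and an F1 sequenced at 58x with ~15 kb
lognormal long reads. Variant positions are drawn over the ancestor at
the configured rates and each variant is applied to one haplotype chosen
at random, so realized heterozygosity equals the configured total
directly; drawing variants independently per haplotype would instead
realize roughly twice the per-haplotype rate and make the target
opaque. Overlapping indels are resolved left-to-right.

The truth PAF emulates *idealized haplotype-aware alignment*: a read is
placed, full length at its truth coordinates, only where the assembly
block under its midpoint derives from the read's own haplotype. With a
real aligner, cross-haplotype reads would still align (at ~99.9%
identity) and the observed coverage differences would be smaller in
magnitude; the emulation preserves the *sign* structure that switch
detection consumes while removing aligner noise, which is exactly what
aligner-free tests need. Consequences for interpretation: passing
switch-detection tests demonstrates correct window arithmetic,
classification and block recovery — not robustness to aligner-specific
mapping artifacts.

Other deliberate idealizations: the ancestor is i.i.d. sequence with GC
bias and no repeat families (real pepper-scale genomes are 75–80%
repetitive, which is not emulated at desk scale and makes real binning
and scaffolding harder than the simulation); long-read errors are
substitutions only (no HiFi chimeras or adapters); mosaic assemblies
require indel-free haplotypes so that the two coordinate systems agree.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere except AGP (1-based
  inclusive, per the standard); BED and TSV tracks mirror the internal
  convention.
* K-mer codes are 2-bit packed into 64-bit words and shuttled to R as
  raw vectors (8 bytes per k-mer) so that $k$ up to 31 stays exact;
  counting uses an open-addressing hash table, several-fold faster than
  node-based maps at the hundreds of millions of inserts a 45x
  short-read set produces. Code order is sorted, so all outputs are
  reproducible.
* Placement ties (equal chromosome coverage) break to the
  lexicographically smaller name and are flagged; equal best-match
  alignment records break to the earliest record.
* The windowed switch fixture uses 100 kb windows on the 5 Mb genome,
  preserving roughly the window-count-to-genome ratio of 1 Mb windows
  on a gigabase genome.
* Telomere search background: in i.i.d. sequence a specific hexamer
  occurs by chance at rate $4^{-6}$ per position, i.e. a Poisson mean
  of ~0.4 per kb window and strand, so isolated single-digit counts in
  interior windows are expected at any realistic genome size. Validation
  therefore checks array-level signal — windows with ≥ 5 occurrences
  (background probability ~3×10⁻⁵ per window under the Poisson model,
  fixed a priori) must lie inside planted arrays, and fully
  array-covered windows (~166 occurrences) must all be detected — rather
  than demanding literally zero interior counts.
* Heterozygosity recovery is validated on 1 Mb parent pairs across
  target rates 0.01–1%; at the lowest rate the binomial sampling error
  itself is ~10% relative, which bounds what any estimator can achieve
  at that scale.
* Problem sizes used in validation (5 Mb trio at full 45x/58x coverage
  for binning; 1 Mb pairs for heterozygosity; 300 kb trios for
  determinism checks) were chosen so the full suite runs on a single
  desktop core in a few minutes.

# Known limitations

* Exact canonical matching only — no inexact k-mer matching, mirroring
  the described method; highly divergent or error-rich reads therefore
  lose hap-mer evidence faster than a fuzzy matcher would.
* The scaffolder does not break chimeric contigs; a genuinely chimeric
  contig is placed (whole) by majority coverage and flagged only through
  its low location confidence.
* Gap patching interpolates donor coordinates linearly through anchor
  records, which is exact for gapless anchor alignments and approximate
  when anchors themselves contain indels.
* No optical-map processing, BUSCO/LAI scoring, or de novo contig
  assembly: the workflow consumes externally produced assemblies and
  alignments at those steps.
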