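---
title: "Methods: multi-caller somatic consensus, filtering and benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-caller somatic consensus, filtering and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticEnsemble)
```

# Scope

`somaticEnsemble` implements the post-calling half of a tumor-normal
whole-genome somatic pipeline: it consumes the outputs of several variant
callers (SNV/indel callers tagged `strelka2`, `mutect2`, `lancet`,
`svaba`; SV callers tagged `manta`, `lumpy`, `svaba`; a read-depth
segmenter for CNVs) and produces merged, filtered, confidence-tiered
callsets. Running the callers themselves, alignment, and annotation
database lookups are out of scope; annotations (population allele
frequencies, validation-call sets, split-read counts, CNV changepoints)
are consumed as data.

Filtering is *annotating*, never deleting: every merged record is kept,
and membership in the final callsets is derived from tags. A record with
no disqualifying tags belongs to the **AllSomatic** callset; the
**HighConfidence** callset is the subset whose `hc` flag is set. This
preserves the audit trail and guarantees HighConfidence ⊆ AllSomatic by
construction.

# Cross-caller consensus for small variants

Callers disagree on representation before they disagree on biology, so
merging operates on a normalized identity key `(chrom, pos, ref, alt)`:

* multi-allelic records are split at ingest, one record per alt allele;
* alleles are parsimony-trimmed (shared suffix, then shared prefix) and,
  when a reference sequence is supplied, simple indels are left-aligned
  through repeat tracts. Without this, identical indels from two callers
  can fail to share a key. Inputs from modern callers are usually already
  left-aligned, so the reference is optional.

Some callers phase adjacent substitutions into MNVs and some do not.
`decomposeMnvs()` splits every MNV into one SNV per altered base
(positions ascending; unchanged middle bases are emitted nowhere), each
carrying an origin identifier. After the key-based merge unions caller
support, `reconstituteMnvs()` replaces the constituents of an origin MNV
by a single MNV record *iff* every constituent is present with an
identical caller-support set; otherwise the SNVs stand individually.
Reconstitution is attempted longest origin first and each SNV is consumed
at most once, which makes the resolution of overlapping MNVs from
different callers deterministic. Indels merge on the exact normalized key
only — no positional slop — because nothing in the design justifies fuzzy
matching for small variants. An MNV and an unrelated overlapping indel do
not interact during reconstitution.

# Structural-variant merging

SVs are represented as breakend pairs in BEDPE convention (0-based
half-open intervals, intrachromosomal events stored left-to-right).
Events with a defined linear span (everything except translocations and
insertions) shorter than `sv_min_size = 500` bp are removed before
merging; the bound is strict (`span < 500` is removed, 500 survives).

Two events match when (i) their svtype agrees — a DUP never merges with a
DEL even at identical coordinates, the explicit type check being safer
than relying on strand orientation across heterogeneous caller notation —
(ii) strands agree at both breakends, (iii) the breakend intervals, each
padded by `sv_slop = 300` bp, overlap at both ends, and (iv) the spans
overlap reciprocally by at least `sv_reciprocal = 0.5` of *both* spans.
The reciprocal condition is interpreted on event spans in both directions
(the `-rf` semantics of interval tools) and waived for TRA/INS, whose
span is undefined. Merged records are connected components of this match
relation; representative coordinates come from the highest-priority
caller present (`manta > lumpy > svaba`), mirroring the count-selection
priority used for small variants.

# Panel of normals and common germline filtering

The small-variant PON is *location-keyed*: sites (chrom, pos) called in
two or more unrelated normal individuals, applied to the merged callset
regardless of the alt allele. This deliberately also removes
same-position different-allele calls — recurrent artifacts cluster by
position — and an allele-aware mode is the obvious refinement for future
work. An individual contributes a site once, however many alleles were
called there.

The SV PON clusters normal-sample SV calls that share type and strand
orientation with both breakends within 300 bp (maximum distance), with
*no* minimum-size requirement, and counts distinct individuals per
cluster. Somatic SVs matching (same criteria as the merge: slop 300,
same strands, 50% reciprocal) a cluster seen in ≥ 2 individuals are
tagged.

Small variants with an annotated population minor-allele frequency of 1%
*or higher* in any database are tagged `COMMON_GERMLINE`; the bound is
inclusive (`>= 0.01`), following the wording of the rule it implements.
SVs are tagged when they match a supplied germline SV catalog. CNV
segments are annotated but never filtered.

# Allele counts and the count-based filters

Because each caller reports different counts, final counts are chosen per
variant:

* SNVs, MNVs and simple indels with net length change `< 10` nt: a
  pileup over read evidence — unique fragments (a read pair counts once;
  pairs whose mates disagree on the allele are dropped), mapping and base
  quality ≥ 10, duplicate/supplementary/QC-fail/unmapped reads excluded.
  Depth is the number of surviving fragments, so the depth filter below
  operates on the post-filter pileup depth (the only depth this stage
  computes).
* Larger indels and complex substitutions (both alleles > 1 nt, unequal
  length): the first available caller report among `strelka2`,
  `mutect2`, `lancet`, in that order.
* Large indels called only by `svaba`: no final counts (source `NONE`) —
  that caller reports no reference allele count, so no VAF can be formed.
  Such records are tagged `NO_COUNTS` but *remain* in AllSomatic; they
  cannot be judged by count filters.

The filters then tag records with tumor VAF `< 0.0001`
(`LOW_TUMOR_VAF`), normal VAF `> 0.2` (`HIGH_NORMAL_VAF`), depth `< 2`
in either sample (`LOW_DEPTH`), or normal VAF strictly greater than
tumor VAF (`NORMAL_GT_TUMOR`). Boundary semantics are exactly as
written: a tumor VAF of exactly 0.0001, a normal VAF of exactly 0.2 and
a depth of exactly 2 all pass. The tags are recomputed from the stored
counts on every run, so re-filtering is idempotent.

# High-confidence tiers

A small variant is high confidence when called by ≥ 2 callers, or by one
caller and present in the targeted-validation call set or the
small-SV-derived call set. An SV is high confidence when called by ≥ 2
callers — literally any two, with no extra requirement for particular
pairs — or by `manta` or `lumpy` alone with either a CNV changepoint
within 1000 bp (inclusive, matching the distance conventions of
`bedtools closest`) of a breakend, or split-read support of at least 3
reads in the tumor and exactly 0 in the normal ("tumor only" read
literally; both constants are configurable). Orthogonal evidence is
consumed as data; the ±250 nt regional logic that produces targeted
validation calls lives in the simulator, since no external caller is
executed here.

# CNV categorization and purity/ploidy adjustment

Segments with log2 ratio `> 0.2` are amplifications and `< -0.235`
deletions, strict inequalities, so the thresholds themselves are neutral.
The deletion constant corresponds to a single-copy loss at 30% purity in
a diploid genome (`log2(0.85) = -0.2345`); the package adopts the
conventional printed constant `-0.235` as its bit-exact default rather
than the longer decimal, and the acceptance checks treat the two as
agreeing at the printed precision.

For an in-silico mixture in which a fraction $T_{frac}$ of reads comes
from the tumor library, the DNA-weighted purity is

$$T_{purity} = \frac{T_{frac}\,N_{ploidy}}
  {(1-T_{frac})\,T_{ploidy} + T_{frac}\,N_{ploidy}}$$

— a tetraploid tumor contributes twice the DNA per cell of a diploid
normal, so read fractions overstate cell fractions. Observed log2 ratios
are inverted to absolute tumor copy numbers and re-expressed as adjusted
ratios:

$$T_{CN} = \frac{T_{ploidy}\,N_{CN}\,(2^{Obs_{log2}} - (1-T_{purity}))}
  {N_{ploidy}\,T_{purity}}, \qquad
Adj_{log2} = \log_2\!\left(\frac{T_{CN}}{T_{ploidy}}
  \cdot \frac{N_{ploidy}}{N_{CN}}\right)$$

At purity 1 the adjustment is the identity. When the observed ratio
falls below what normal contamination alone allows
($2^{Obs} \le 1 - T_{purity}$), the inferred copy number is non-positive;
such segments are *flagged* (`neg_cn`, category DEL, missing adjusted
value) rather than clamped, so downstream evaluation can count them
explicitly. $N_{CN}$ defaults to 2 on autosomes; 1 on X/Y for males and
2 on X for females, supplied through the segment table.

# The synthetic-data generator

The simulator is the package's fixture source and defines its study
conditions; it is tested, first-class code.

`simulateTruth()` tiles two 1-Mb contigs with copy-number segments drawn
from integer states centred on 4 — emulating a heavily rearranged,
near-tetraploid tumor line — and scatters ~130 somatic variants (100
SNVs, 6 MNVs, 24 indels of 1-15 nt) and 10 SVs over them. A variant's
pure-tumor VAF reflects clone fraction × copy state: with `m` effective
mutant copies of `c_tot` tumor copies, VAF $= m/c_{tot}$. The clonal
structure defaults to 80% fully clonal, 20% at clone fraction 0.4 —
cell lines are mostly clonal, with some subclonality retained so that
low-VAF behaviour is exercised.

`simulateSampleCounts()` mixes at the *fragment-count* level: the
expected mixture VAF is
$v_{mix} = T_{frac}\, m / (T_{frac}\,c_{tot} + (1-T_{frac})\,N_{CN})$ and
alt fragments are Binomial at the drawn depth. Count-level mixing
preserves the first- and second-order statistics of read mixing at desk
scale without manipulating reads. The normal sample draws only a small
error-rate background at somatic loci. Fragment flags and qualities
(duplicates 2%, sub-threshold MQ/BQ 3% each) exercise the pileup
exclusions.

`simulateCallerOutputs()` gives each mock caller a saturating (Hill)
sensitivity curve in the alt read count, a per-Mb false-positive rate
with substitution types drawn from 96-channel context-bias weights (the
knob that emulates instrument-specific artifact spectra such as elevated
T>G in NTT contexts), and Gaussian count-reporting noise. The
non-phasing caller emits MNVs as constituent SNVs; the assembly-based
caller is restricted to indels for small variants. SV detections jitter
breakend coordinates (sd 20 bp) so cross-caller merging is non-trivial.

`simulateReads()` tiles a reference with error-profiled reads: a base
with reference context 5'-x[r]y-3' is mis-read as `a` with probability
`rate * 64 * w(x[r>a]y)`, so a uniform 192-channel profile reproduces the
requested overall rate exactly, and a `g_run_extend` knob extends G runs
to emulate the no-signal-G artifact of 2-colour sequencing chemistry.

What the simulator does **not** model: insert-size and GC structure,
alignment and mapping artifacts, base-caller internals, caller-specific
systematic errors beyond the profile knobs. Passing the simulation-based
tests therefore demonstrates the correctness and internal consistency of
the post-calling logic under controlled conditions — not the performance
of the stack on real sequencing data.

# Evaluation conventions

Cross-run comparisons classify a test callset against a reference run's
two tiers: TP = in the reference HighConfidence set, FP = absent from
the reference AllSomatic set, FN = reference HighConfidence calls
missed, and calls present in AllSomatic but not HighConfidence are
*ignored* — they cannot be confidently assigned either way — so
`tp + fp + ignored = |test|`. Precision, recall and F1 use the standard
formulas with missing values on zero denominators. MNVs are decomposed
to SNV keys before set comparison, matching how non-phasing callsets are
compared. SV set membership uses the merge criteria rather than exact
keys, since breakend coordinates differ across runs. CNVs are compared
at the base level per category with interval arithmetic (verified
against a dense per-base oracle in the tests).

# The mismatch profiler

Mismatch spectra are tallied in *read-strand* orientation over 192
channels (12 substitution types × 16 flanking contexts): for a
reverse-strand alignment, reference base, read base and both flanks are
reverse-complemented. Eligible bases — the rate denominator — are
aligned match positions on reads that survive the flag filters with
MQ ≥ 10, base quality ≥ 10, whose immediate neighbours are aligned to
adjacent reference positions (excluding read ends and indel-adjacent
bases), with no N in base or context; the denominator thus matches the
filtered numerator exactly. `collapseToSix()` folds purine-reference
channels onto their pyrimidine reverse complements, conserving the
total. Homopolymer statistics (`longestRuns()`) are computed on the full
read sequence, alignment-independent, because they characterize the
sequencer rather than the alignment.

# Numerical and design choices

* Strict vs inclusive bounds, in one place: CNV thresholds strict;
  SV minimum size inclusive at 500; germline MAF inclusive at 0.01;
  tumor-VAF floor inclusive at 0.0001; normal-VAF ceiling inclusive at
  0.2; depth inclusive at 2; changepoint distance inclusive at 1000 bp;
  split-read minimum inclusive at 3; pileup/caller indel switch
  exclusive at 10 nt (a 10 nt indel uses caller counts).
* Per-caller inputs default to PASS records only (configurable): the
  downstream comparisons are defined over PASS-filtered callsets, and
  feeding rejected records into the merge would conflate caller-internal
  filtering with consensus.
* All generators are pure functions of `(params, seed)`; pipeline reruns
  with identical seeds produce byte-identical output files.
* Ties in SV merging resolve by caller priority then leftmost
  coordinate; MNV reconstitution resolves longest origin first.

# Problem sizes

The test and acceptance workloads use two 1-Mb contigs with ~130 small
variants and 10 SVs per replicate; the purity-ladder reproduction runs
the full seven-point mixing grid (tumor 10-70X against normal 70-10X,
read fractions 0.125-0.875) with 10 seeded replicates per point; the
profiler recovery uses a 100-kb reference at 11X (≈10^6 eligible bases).
These sizes give stable statistics for every property tested while
keeping a full run in minutes on one core.

# Known limitations

* The PON is location-keyed for small variants; allele-aware filtering
  is deliberately left as a flagged extension.
* Segmentation and purity/ploidy *inference* are out of scope: only the
  mixture-truth purity equation and the adjustment algebra are
  implemented, so adjusted categories are only as good as the supplied
  purity and ploidy.
* The evidence-based pileup does not realign reads; indel allele
  assignment is taken from the evidence table.
* Insertions face no size filter, and their spans are undefined
  throughout; callsets dominated by insertions would exercise little of
  the SV merge logic.
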