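---
title: "Methods: event calling, psi statistics and flanking-motif enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event calling, psi statistics and flanking-motif enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceflank)
```

# Scope and model

`spliceflank` analyses the downstream products of a two-genotype RNA-seq
experiment (a wild type and a splicing-factor null mutant) together with a
RIP-seq binding experiment: isoform abundance tables, gene-level
differential-expression tables from several pipelines, and
immunoprecipitation fold-change tables from two transgenic lines and two
quantification methods. Nothing upstream of quantification (trimming,
alignment, the quantifier itself) is in scope.

## Event catalogue

Events are generated pairwise from same-gene transcript models and merged
on identical (type, chromosome, strand, anchors). The pairwise semantics
mirror the ioe-style event frameworks used in the field:

* **RI** — transcript A splices an intron that lies strictly inside an
  exon of transcript B. The inclusion form is the intron-retaining side.
* **SE** — transcript B carries two adjacent introns around an internal
  exon whose outer splice sites exactly match a single intron of
  transcript A. Inclusion is the exon-including side.
* **A5/A3** — two introns share one boundary and differ at the other;
  the shorter-intron transcript's exon must cover the span between the
  two alternative sites. Inclusion is the shorter-intron side, i.e. the
  transcripts whose exon extends to the alternative site nearer the
  opposite end of the intron.

With these conventions a positive Δψ always reads "the alternative
sequence (retained intron, skipped exon, alternative span) is included at
a higher rate in the mutant". Whether a shared-boundary intron pair is an
A5 or an A3 event depends on strand: an intron's genomic-left boundary is
its 5′ splice site only on the plus strand.

Multi-way alternative sites produce one event per distinct site pair, and
transcripts with identical local structure merge into the same event's
transcript sets. Events are regenerated from whatever GTF is supplied
rather than read from a pre-built release, so the catalogue always matches
the annotation in hand.

Internally all coordinates are 0-based half-open; GTF input/output is
1-based inclusive and BED output 0-based half-open.

## ψ, Δψ and SAS calling

For one event in one sample,
ψ = ΣTPM(inclusion) / ΣTPM(inclusion ∪ exclusion). A 0/0 ratio is
*missing*, not zero: an unexpressed event carries no inclusion
information. Δψ is the mean of non-missing mutant-replicate ψ minus the
mean of non-missing control-replicate ψ; replicates with missing ψ are
dropped rather than imputed. The abundance filter statistic is the sum
over event transcripts of their mean TPM across **all** samples (sum of
means; identical to the mean of per-sample sums). An event is called SAS
when *p* < 0.05 (strict) and total mean TPM ≥ 10 (inclusive), with no
multiple-testing correction — the filter is reported as a raw-p selection
rule and audited in the pipeline log.

### The significance test: why the default is a Welch t-test

The package ships a replicate-label permutation test on |Δψ|
(`permutation_test()`): exact enumeration of all `choose(n, n1)`
equal-size relabelings when that number is within the permutation budget,
Monte-Carlo with p = (1 + exceedances)/(1 + n_perm) otherwise. The exact
branch has a hard granularity floor: with equal group sizes every
relabeling has a group-swapped complement with the same |Δψ*|, so the
smallest attainable p at 3 vs 3 replicates is 2/20 = 0.1. A strict
α = 0.05 filter can therefore never fire on a 3v3 design under label
permutation — the selection stage would be vacuous at exactly the
replicate design this kind of study uses.

For that reason `call_sas()` defaults to a Welch t-test on the
per-replicate ψ values (`test = "welch"`), which has the small-sample
resolution the 3v3 design needs, and falls back to the exact permutation
p when the t statistic is undefined (both groups constant). The
permutation test remains available (`test = "permutation"`) and is the
recommended choice at ≥ 5 replicates per group, where its granularity is
no longer limiting; its null calibration is verified in the test suite at
8v8. Assumption to keep in mind: the t-test treats ψ as approximately
normal within groups, which is reasonable away from the 0/1 boundaries
(the simulator's logit-normal noise model is mildly heavier-tailed on the
raw scale near the boundaries).

## The twenty flanking regions

Each event contributes fixed 50-nt windows and one event-defined
(variable-length) alternative region, labeled in transcript orientation:
UE/DE abut the outer splice sites on the exon side, UI5/DI5 start at and
UI3/DI3 end at their splice sites inside the introns, and ASE is the
event-defined span (A5/A3 alternative span, retained intron, skipped
exon). Per type: A5 → UE, ASE, DI5, DI3, DE; A3 → UE, UI5, UI3, ASE, DE;
RI → UE, ASE, DE; SE → all seven. "Upstream" and "downstream" are
transcript-orientation terms — on the minus strand all windows reflect —
because splice-site identity (5′ vs 3′) only exists in transcript
orientation.

Numerical choices:

* **Short introns.** When an intron is shorter than twice the window, its
  two end windows would overlap; each is truncated at the intron midpoint
  (integer floor), so region sets within an intron stay disjoint and no
  nucleotide is double-counted in density denominators.
* **Gene bounds.** Windows are clipped at the annotated gene span, never
  padded with flanking genome; clipped regions keep their label, are
  flagged, and enter density denominators with their true length.
* **Deduplication.** Regions identical in (chromosome, interval, strand,
  label) — which arise when merged events share structure — collapse to
  one row before any statistic.

## Motif statistics

Motifs are fixed-length IUPAC-degenerate strings; `N` in a motif matches
any base, `N` in a *sequence* matches nothing. All start positions are
counted, overlapping occurrences included — for periodic degenerate
motifs (GGNGGNGG contains GGNGG at two offsets) any non-overlapping
convention would make the motif family mutually inconsistent. Scanning is
single-stranded on the sense sequence.

Density is per kilobase of region sequence (count/length × 1000), matching
how such tables are reported; the chi-squared test instead uses scan
positions Σ(Lᵢ − m + 1) so the opportunity count is correct for each motif
length. Enrichment is the plain density ratio of a Δψ-sign stratum against
the same region class over **all** events of the catalogue (both strata
included) — the all-events control-set convention. For variable-length
ASE regions the published arithmetic is not internally consistent between
the density columns and the enrichment column; this package defines
enrichment as the density ratio everywhere and surfaces raw counts,
lengths and scan positions so any alternative normalization can be
recomputed from the output.

The chi-squared test is Pearson's on the 2×2 hit/non-hit table, 1 df, no
continuity correction; degenerate tables (zero row or column) return
stat 0, p 1, flagged, rather than erroring. No multiple-testing
correction is applied to motif tests. The k-mer over-representation
screen — a deliberately simple stand-in for de novo motif discovery —
scores every test-set k-mer with a one-sided binomial tail at the
background per-position rate, with a +1 pseudocount on background counts
for k-mers unseen in the background. The W-box promoter scan counts exact
occurrences of the TTGAC(C/T)-core motifs in upstream sense sequences and
tests each motif's total count against a user-supplied genome background
frequency with the same binomial tail.

## Consensus set logic

Differential-expression tables are filtered at fold change ≥ 2
(inclusive, mutant/control orientation) and significance < 0.1 (strict);
the down-in-mutant side uses the symmetric fc ≤ 1/2 boundary. The
significance column is treated generically because real studies mix FDR
and p across pipelines. Direction-wise intersection across ≥ 2 sources
gives the consensus sets; intersection is monotone, so adding a source can
only shrink them. RIP selection keeps genes passing fc ≥ 2 and sig < 0.1
in *both* transgenic lines within a method (genes missing a line are
excluded from that method) and intersects across methods. Overlap of two
gene sets in an explicit universe is tested two-sided by Fisher's exact
test — the universe is always a required argument, never guessed. Term
enrichment reports actual, expected = |set|·K/|U|, fold = actual/expected
and the hypergeometric upper tail. When synthetic tables need an FDR,
Benjamini–Hochberg (`p.adjust`) is used.

# The synthetic-data generator

The generator emulates the study design at toy scale, and its defaults are
the package's declared study conditions: 200 two-isoform genes (50 planted
events per class) on one synthetic chromosome with alternating strands,
three biological replicates per condition, control ψ uniform on
(0.2, 0.8), half the events shifted by |Δψ| = 0.4 with random sign
(flipped when the mutant mean would leave (0.05, 0.95)), logit-normal
replicate noise with SD 0.2, log-normal gene expression (meanlog 3,
sdlog 1, i.e. median ≈ 20 TPM against the TPM ≥ 10 filter), exon lengths
120–300 nt, intron lengths 150–400 nt, alternative spans 30–80 nt, and a
600-nt intergenic pad sized for −500 promoter scans. Support tables use
three expression pipelines and two RIP methods × two lines with planted
fold 4, small log-normal fold noise (SD 0.15), planted significance
uniform on (0, 0.05) and null significance uniform on (0, 1); a
concordance parameter thins each source's planted hits independently.

Motif planting rewrites region sequence at random non-overlapping starts
until the overlap-counted total equals round(density × length/1000);
chance occurrences count toward the target and each candidate write is
accepted only if it changes the total by exactly one, so planted
densities are exact rather than additive. One practical consequence of a
uniform-base genome: short degenerate motifs have a non-trivial chance
density (GGNGG ≈ 3.9/kb), so density targets below chance are infeasible
for them; fold-recovery checks therefore use a sparser family member
(GGNNNNGGNGG, chance ≈ 0.015/kb) whose planted density dominates chance.

What the simulator does **not** emulate: read-level noise and coverage
bias, quantifier uncertainty (isoform TPMs are exact shares of the gene
total), correlated replicates, multi-isoform genes with more than one
event, GC/repeat structure of real genomes, and annotation error. Tests
passing on this generator therefore validate the event/ψ/region/motif
*logic* and its calibration under the declared noise model — they do not
certify performance on real libraries.

# Problem sizes and determinism

Every generator is a pure function of (config, seed); the RNG state of the
caller is saved and restored. The test suite and the acceptance script run
at deliberately modest sizes chosen as the smallest scales at which the
statistical checks are stable: 200-gene catalogues for parameter recovery,
500–600 draws for null-calibration fractions (binomial SE ≈ 0.009 around
0.05), 2000 Monte-Carlo permutations at 8v8 for permutation calibration,
and ~55 kb of region sequence (≥ 50 expected occurrences per stratum) for
planted-fold recovery within 20%. Exact-arithmetic checks (coordinates,
planted counts, intersections) use no tolerance; floating-point
comparisons use equality tolerances of 1e-10…1e-12.

# Known limitations

* Alternative first/last exons, mutually exclusive exons and complex
  events are out of scope; single-isoform genes contribute no events.
* The Welch default for 3v3 designs trades the permutation test's
  exactness for resolution; at ≥ 5 replicates per group the permutation
  test is preferable.
* The chi-squared motif test treats scan positions as independent
  Bernoulli trials; overlap counting makes hits weakly dependent for
  self-overlapping motifs, which slightly inflates the statistic at very
  high densities.
* Consensus intersections at published set sizes are verified against
  constructed synthetic tables; reproducing the published gene lists
  themselves requires the original supplementary data.
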