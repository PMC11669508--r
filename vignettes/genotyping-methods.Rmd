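---
title: "Methods: multi-assay quantification of CRISPR edits in polyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-assay quantification of CRISPR edits in polyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscreen)
```

# The problem

In a highly polyploid genome a CRISPR target locus is present in many
hom(e)ologous copies, and a loss-of-function phenotype requires editing
most of them. The quantity of interest is therefore not a genotype call
but a **co-editing frequency**: the fraction of the amplified allele pool
carrying an indel at the target site. `editscreen` implements four
independent estimators of that fraction, a melt-curve screen, and the
machinery to compare them per line, because each estimator measures a
different physical proxy (read counts, fragment-peak fluorescence, band
densitometry, duplex melting) with different failure modes.

Throughout, an *indel class* is a signed size delta in bp (never 0) with a
frequency over the method's own denominator.

# Read-based callers

## Conserved-sequence (CS) analysis

Each forward read is searched for an exact occurrence of the assay primer
and then for an exact occurrence of a conserved sequence downstream.  With
start-to-start wild-type distance $d_{WT}$ and observed distance $d$, the
read's call is $\Delta = d - d_{WT}$; $\Delta = 0$ is wild type, a missing
anchor makes the read uncallable (this is how deletions that remove the
conserved sequence vanish from the denominator).  Frequencies are counts
over **callable** reads.

*Filter.* Classes below `min_report_freq` (default 0.01, i.e. 1 %) are
noise-suppressed: they are removed from the breakdown but their reads stay
in the overall non-WT fraction.  Whether the overall figure should include
sub-threshold deviations is genuinely open; we include them because the
published per-line tables this mirrors show overall figures exceeding the
breakdown sum, which is only arithmetically possible if sub-threshold
reads are retained.  The consequence — `overall_non_wt_frequency >=
sum(calls$frequency)` — is asserted in the test suite.

*Tie-breaks.* Exact matching only (mismatch tolerance deliberately not
implemented as a default; the method is defined by exact anchors).  If an
anchor occurs more than once, the first occurrence wins (for the conserved
sequence, the first occurrence downstream of the primer), with a warning.
Reverse-strand assays are handled by reverse-complementing the read stream
(`reverse_reads = TRUE`), a convention the read-out itself leaves
implicit.

## Indicator-window analysis

Two 12-nt indicators bracket the cut site.  We derive them from the
wild-type amplicon as a function of the comparison range $R$: the left
indicator ends $R$ bp before the cut, the right one starts $R$ bp after
it.  This single parameter reproduces the method's two large-deletion
blind spots: a deletion can physically remove an indicator, and a
deviation with $|\Delta| > R$ is not representable inside the window; both
yield "unmatched".  Published per-target indicator placements live in
supplementary material that is not machine-readable, so placement-by-$R$
is the package's configuration convention (default $R$ = 35 bp, rerun at
70 bp).

The inter-indicator segment is compared with its wild-type counterpart.
Equal length and equal sequence is wild type; a length deviation is an
indel whose sequence is extracted by trimming the longest common prefix,
then the longest common suffix (prefix wins when they could overlap), and
reported lower-case.  Equal length with mismatches is a
**substitution-only** call: it is counted as non-WT in the overall figure
(the read is demonstrably not wild type) but never as an indel class,
because the downstream per-indel tables are defined over indels.  Callers
that need pure-indel concordance with CS should compare on synthetic data
with `substitution_rate = 0`, where the two overall figures agree exactly
(tested).

*Rerun merge.* `window_spectrum_with_rerun()` reruns only the reads the
primary pass could not call, so the two spectra have disjoint denominators
and `merge_rerun()` can renormalize over their union: counts are appended
(same-delta classes summed with a warning), the reporting filter is
re-applied at the primary floor, and the overall frequency can only grow.

*Spanning deletions.* When an amplicon carries two sgRNA sites
(`paired_site`), a deletion whose reconstructed interval covers both cut
positions is flagged `spans_both_sites`; the concordance layer uses the
flag to reconcile a single large CS class with per-site window calls.

# Capillary-electrophoresis quantification

The wild-type sample defines the WT peak set: every WT peak at or above
`min_rel_height` (default 0.1) of the tallest peak becomes a WT size, and
the tallest is the main size.  In mutant samples any peak within
`match_tolerance` of **any** WT size is wild type.  The formula

$$\text{co-editing \%} = 100\,\frac{\sum h - \sum h_{WT}}{\sum h}$$

uses all WT-size peaks in the numerator subtraction; the alternative
(subtracting only the main peak) is inconsistent with multi-length WT
pools, where satellite WT lengths would otherwise inflate every mutant
estimate.

Numerical choices:

* `match_tolerance` = 0.5 bp.  CE sizing scatter is sub-bp; 0.5 bp is the
  largest tolerance that cannot confuse adjacent integer size classes.
* Indel sizes are `round(size - main_wt_size)` — nearest integer, so a
  7.56 bp deviation reports as 8 — and always referenced to the **main**
  WT size, because published deltas are referenced to the expected
  amplicon, not to the nearest WT satellite.
* Peaks below `min_height_frac` (default 0.01) of total height are
  baseline noise, mirroring the NGS reporting floor; CE has no published
  floor, so the value is configurable.

This design *deliberately reproduces* the method's known bias: a true
−1 bp allele whose peak coincides with a WT satellite one bp below the
main peak is absorbed as wild type, and the co-editing estimate can
undercall by the allele's full frequency.  The bias is pinned by a test
(planted −1 at 20 % with WT sizes {226, 227}: estimate 0 %) rather than
corrected, since correcting it would require information CE does not
provide.

# RNP cleavage-assay scoring

The scorer takes band mean grey values as produced by image densitometry.
$\Delta GV = \overline{GV}_{cleaved} - GV_{uncleaved}$ (mean over the two
cleaved bands when the assay yields two products; an absent band
contributes 0, since a lane with only a cleaved product must still be
scorable).  The categorical mapping for a single cleaved product is

| $\Delta GV$ | score | band |
|---|---|---|
| < −90 | 0 | 0 % |
| −90 … −31 | 1 | < 40 % |
| −30 … 30 | 2 | ~50 % |
| 31 … 90 | 3 | > 60 % |
| > 90 | 4 | 100 % |

with all cut points scaled by 2/3 for dual-product assays (two cleaved
bands each carry roughly half the signal).  The tables are printed over
integers; real-valued input is floored first, which lands every gap value
(e.g. −30.5) on the lower score — the only reading that keeps the score
monotone in $\Delta GV$, a property the tests enforce across a dense grid.
Score 5 (100 % mutated with a large indel) is triggered by a band that
matches neither expected size within ±5 %, or by a lane with no band at
any expected size.

The sign convention — *more negative means more cleaved, i.e. less
mutated* — is implemented exactly as published even though it implies an
inverted-intensity gel image; flipping it silently would make the package
disagree with every printed score.

# Melt curves and HRMA

Each trace is normalized by a two-point linear map sending the mean
fluorescence in a pre-melt window to 100 and in a post-melt window to 0.
The map is affine-invariant (per-well gain and offset cancel) and
idempotent; both properties are tested.  Windows default to the first and
last 1 °C of the acquisition range — published per-target windows are in
unavailable supplementary material, so they are exposed as arguments.

The wild-type baseline is the mean of the normalized WT replicates
(typically two WT samples in triplicate); a sample's difference curve is
its mean normalized trace minus the baseline, and `max_fluor_diff` is the
maximum **absolute** difference over the grid (the published statistic
does not state a sign; absolute is the conservative reading).

Melt peaks are maxima of −dF/dT after a centred 5-point moving average of
the fluorescence and a second 5-point pass over the derivative, reported
to 0.1 °C.  Two numerical choices deserve note:

* The peak-prominence floor defaults to 0.10 of the maximum derivative.
  At the replicate noise level the generator emulates (0.5 normalized
  units per point), a 0.05 floor sits exactly at the smoothed derivative
  noise and admits spurious peaks on unremarkable traces; 0.10 clears the
  noise floor while keeping a 10 % allele mixture component detectable
  (its derivative peak is ~10 % of the major component's).
* Peak finding tolerates flat tops.  Symmetric smoothing of a symmetric
  transition yields exact two-point plateaus at the apex, which
  strict-inequality peak finders skip entirely; runs of equal value are
  therefore compressed and a run flanked by lower runs reports its
  midpoint.

# Concordance, chimerism, cost

The per-line table reports each method's overall frequency plus an
agreement matrix over the union of called indel classes, with a ±1 bp
size-agreement tolerance (CE/CS/window sizings of one event drift by
1–2 bp for longer deletions).  Two flags encode the known method-specific
misses: `ce_undercall` (CE overall more than 5 points below the best NGS
estimate) and `spanning_deletion` (reconciliation of single spanning CS
classes with per-site window calls).

Chimerism over vegetative progenies is class disagreement: each progeny
is mutant when its overall frequency reaches `mutant_threshold` (default
0.05 — the published classification is qualitative, so the threshold is
exposed), and an event is chimeric iff its progenies disagree.  The
verdict is order-invariant and a single progeny yields "insufficient
replicates" rather than a verdict.

Cost per sample sums `pack_price / reactions_per_pack` over a method's
components, with `per_replicate` rows multiplied by the replicate count
(3 for triplicate HRMA).  Published dollar figures are not reproduced
(their component prices are not available); the model is the arithmetic.

# The synthetic-data generator

The generator is the package's ground-truth source, not a fixture.  It
emulates: a polyploid allele pool with planted indel spectra (sizes and
frequencies free; deletions abut the cut site by default, offsets
configurable); per-base substitution error (default 0.001) and a per-read
1–2 bp background indel at `read_indel_rate` (default 0.002) — chosen so
spurious size classes appear at the sub-1 % level and genuinely exercise
the CS reporting filter; multi-length WT amplicon pools; CE peaks with
height proportional to summed allele frequency (multiplicative CV noise)
and Gaussian size jitter; gel lanes whose noiseless $\Delta GV$ is
$K(1-2f)$ in the cleaved fraction $f$ ($K$ = 120 single, 80 dual), which
places $f$ = 1/0.8/0.5/0.2/0 in score bands 0–4 by construction; and melt
curves as frequency-weighted mixtures of two-state sigmoids with
replicate noise.

It does **not** emulate: realistic Illumina error profiles or quality
scores, paired-end structure, PCR amplification bias between alleles, CE
stutter or dye artefacts, gel background gradients, or SNP-driven melt
heterogeneity between wild-type gene copies.  Passing tests therefore
demonstrate correctness of the estimators under their own model
assumptions, not robustness to every artefact of real instruments — most
importantly, real polyploid WT pools are themselves sequence-heterogeneous,
which is exactly why the HRMA baseline uses replicated WT samples.

Every generator is seeded from `sim_config(seed=)` and a fixed seed gives
byte-identical FASTQ/CSV output; read identifiers carry the allele of
origin and its true delta, so callers can be scored against exact truth.

# Problem sizes and validation battery

The test suite validates each stage at sizes chosen to make binomial
bounds meaningful while keeping the whole battery interactive:
planted-spectrum recovery uses 10,000–20,000 reads (3-binomial-SD bounds),
oracle equivalence uses 200 reads against naive string-scan
re-implementations that share no code with the vectorised callers,
Monte-Carlo checks of peak-size jitter use 1,000 draws, and CE noise
recovery uses 100 seeded replicates at 5 % CV.  `scripts/acceptance.R`
recomputes the categorical RNP threshold outcomes (single product at
$\Delta GV$ = +50 and 0; dual product at −40) by constructing the lanes
and running the scorer.

# Known limitations

* CS and window callers use exact anchor matching; highly degenerate
  amplicon pools with SNPs inside the anchors lose those copies from the
  denominator (the same way the laboratory methods do).
* The window caller's indicator placement is tied to $R$; assays whose
  published indicators were placed asymmetrically will need explicit
  configuration.
* CE quantification assumes peak height is proportional to allele
  abundance; saturated peaks violate this upstream of the package.
* The RNP score is categorical and cannot distinguish frequencies within
  a band; the concordance layer reports it as-is.
* HRMA's `max_fluor_diff` saturates for large Tm shifts: beyond
  saturation it no longer orders samples by mutant fraction, which can be
  reproduced by pushing the simulated shift large.
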