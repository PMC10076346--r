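---
title: "circseam: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circseam: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circseam)
```

This vignette explains the statistical models behind `circseam`, the
parameters a user may want to change, the numerical decisions taken where
the design was genuinely open, and what the synthetic validation scenarios
do and do not demonstrate about real data.

## The quantification model

A back-splicing junction (BSJ) is identified by its genomic coordinates and
strand; the package-wide identifier is `chrom:start-end:strand` with a
1-based start for readability, while every coordinate field in package
objects is 0-based half-open. Each BSJ contributes two count features: the
reads spanning the back-splicing junction itself (`|circ`) and the reads
mapping linearly over the same two splice junctions (`|linear`). Both are
junction-level counts, so circular and linear isoforms of the same locus
are measured on the same footing — the central requirement for asking
whether a change is biogenesis-level (discordant) rather than
transcriptional (concordant).

Detection tools only report linear-junction coverage where the BSJ itself
was seen, so a naive merge across samples would contain missing cells.
`complete_counts()` therefore takes an optional *linear supplement* — the
linear-junction coverage re-counted at those splice sites in the samples
lacking the BSJ — and fills circular counts with zero there. The resulting
matrix is dense over the union of BSJs.

Library size is the per-sample sum of counts over the whole junction
universe (circular plus linear features), not a whole-transcriptome total.
This keeps CPM values self-consistent within the object being analyzed and
requires no alignment files; it means CPMs are comparable within a
contrast, not across studies.

## Differential testing

Counts are modeled as negative binomial. Normalization is the trimmed mean
of M-values (TMM): the reference sample is the one whose upper-quartile
count rate is closest to the mean; features zero in either sample are
excluded; 30% of log-ratios and 5% of log-abundances are trimmed from each
tail; the factor is the precision-weighted mean of the remaining
log-ratios, and factors are rescaled to geometric mean 1. The test suite
cross-checks this implementation against the independent `edgeR`
implementation to 10⁻⁶. TMM assumes most junction features are not
differentially expressed between the conditions — the same assumption the
contrast designs here satisfy (tens of thousands of junctions, few hundred
deregulated).

Testing is a per-feature likelihood-ratio test: with dispersion φ fixed,
the NB likelihood with mean μᵢⱼ = mᵢ·Lⱼ (Lⱼ the effective library size) is
maximized under a common scale mᵢ (null) and one scale per group
(alternative), by Newton iteration on log m. The statistic 2(ℓ₁ − ℓ₀) is
referred to χ²(1). At φ = 0 the fit is the closed-form Poisson limit, and
the test equals the Poisson deviance LRT (checked against an independently
coded oracle).

Dispersion handling is deliberately simple: either a user-supplied value or
a *common* dispersion estimated by profile likelihood over a log-spaced
grid (10⁻⁴…4, 200 points). Tagwise/trended shrinkage is out of scope; the
testing contract (NB likelihood ratio against χ²(1)) is what the rest of
the pipeline depends on, and a dispersion computed elsewhere can always be
injected. With only three replicates per group the χ²(1) reference is an
asymptotic approximation; the null simulation in the acceptance suite
(2000 features, μ = 50, φ = 0.1, 3 vs 3) verifies that the realized type-I
error stays within [0.035, 0.065] at α = 0.05.

Two further conventions: significance uses the **raw** p-value at α = 0.05
(junction counts are low, and a false-discovery-rate criterion would be
dominated by the many weakly covered features; a BH-FDR column is emitted
but unused), and the reported log2 fold change is computed from
effective-library-normalized group mean counts with a 0.5 pseudo-count so
that groups with all-zero counts yield large but finite fold changes.

## Concordance classes, CLR and set statistics

For each circular/linear pair tested for both isoforms, `classify_pairs()`
assigns exactly one of four categories from the two (log2FC, p) pairs at
α = 0.05: *Concordant* (both significant, same sign), *DiscordantCirc*
(circular significant; linear unaltered or opposite), *DiscordantLin*
(linear significant, circular not), *Unaltered*. The partition is
exhaustive by construction and tested by enumeration.

The circular-to-linear ratio (CLR) is computed on mean CPM per condition —
one value per circRNA and condition, matching the one-distribution-per-cell
-line comparison it feeds — excluding pairs whose linear CPM is zero
(undefined ratio) rather than imputing. CLR distributions are compared with
the two-sided Kolmogorov–Smirnov test using the asymptotic p-value by
default (sample sizes in practice are hundreds to thousands; the exact
small-sample p is available via `exact = TRUE`).

All 2×2 comparisons (up/down proportions, set overlaps, window and region
enrichment, balance checks) use the two-tailed Fisher exact test. Reported
odds ratios are sample odds ratios with a Haldane–Anscombe 0.5 correction
when any cell is zero — a reporting convention only; p-values always come
from the exact test on the uncorrected table. For two-set overlaps the
percentage is |A∩B|/|A∪B| by default, because a single printed percentage
for a two-set Venn does not determine its denominator; `denominator =
"setA"`/`"setB"` give the other readings.

## Meta-BSJ binding enrichment

The question is whether a protein's RIP-seq peaks concentrate at fixed
positions relative to back-splicing junctions of the circRNAs it
downregulates. Geometry: for each BSJ extremity (5' donor and 3' acceptor
splice site) windows of 100 nt slide in 10-nt steps from 1000 nt upstream
to 1000 nt downstream, in the orientation of the circRNA's strand —
(2·1000 − 100)/10 + 1 = 191 windows per extremity. Offsets are
strand-relative: negative means upstream in transcript orientation.

Because exonic sequence, UTRs and biotype all correlate with RIP coverage,
raw target-versus-background comparisons would confound position with
composition. Each target window is therefore matched to `k = 2` control
windows from *invariant* circRNAs (raw p ≥ α in the same contrast, after
the expression filter) at the same extremity and offset, restricted to the
same host-gene biotype and exon-number class and nearest in Euclidean
distance on the window's (% exon, % 5'UTR, % CDS, % 3'UTR) overlap with the
representative transcript. When the restricted pool has fewer than `k`
windows the exon-class and then the biotype constraint are relaxed (the
pool-exhaustion order is this package's choice); a target with an empty
pool is excluded and logged. Controls may be reused across targets but not
within one. `balance_check()` verifies post hoc that the matched sets are
balanced on all matching properties.

Windows against peaks is a containment test (≥ 1 nt overlap), one 2×2
Fisher test per (extremity, offset) bin and per peak replicate — replicates
are never pooled, so reproducibility is visible as agreement across
replicate rows. Within each replicate, overlapping peaks are first reduced
to the longest peak of each overlap component.

The representative transcript of a circRNA — needed for region labels and
window properties — is chosen by lexicographic priority: (1) transcript
biotype equals gene biotype, (2) both BSJ boundaries coincide with
annotated exon junctions, (3) fewest exons inside the circularized span,
(4) lowest number of the first included exon, ties broken by transcript id.
Exons/introns inside the span are labeled in transcript order Ex_A, Intr_A,
(Ex_M, Intr_M)…, Intr_Z, Ex_Z. A bi-exonic circRNA has a single intron
proximal to both extremities; it is labeled `Intr_A` (the 5'-proximal name)
and documented as such, since the proximity-based scheme is ambiguous for
that case. Region-level enrichment is computed per exon-number group
(2, 3, 4+) and region label, again down-versus-invariant per replicate.

Interactor calling is deliberately coarse, as appropriate for RIP-seq
resolution: a circRNA is an interactor when its genomic span overlaps at
least one peak in at least two replicates.

## Summit structure profiles

For each merged peak, a 500-nt window centers the summit at offset 0
(offsets −250…+249; the even length puts the summit at the start of the
second half). For every offset the 151-nt subsequence centered on that
position (75 nt each side, center included — the "75 up / 75 down"
specification is read as inclusive of the center base) is extracted on the
strand of the associated circRNA, and its GC fraction and minimum folding
free energy are averaged over windows. Offsets whose 151-nt extent leaves
the chromosome are skipped, not padded.

Two folding backends are provided. The *external* backend shells out to the
thermodynamic `RNAfold` engine when it is on the `PATH` and uses its MFE.
The *builtin* backend is a self-contained nested-structure dynamic program
with pair energies GC = −3, AU = −2, GU = −1 kcal/mol, a minimum hairpin
loop of 3 nt and no pseudoknots, implemented in C++ and verified against
exhaustive structure enumeration for sequences up to 18 nt. The builtin
model is not a thermodynamic parameterization; absolute energies differ
from `RNAfold`, but the scientific claim carried by the profile is its
*shape* — a ΔG minimum and GC maximum at the summit — which both backends
reproduce. T and U are treated as equivalent; N cannot pair and is excluded
from GC numerator and denominator.

## The synthetic scenario: what it emulates, and what it does not

`scenario_config()` fixes the study conditions the pipeline is validated
under; its defaults are chosen once to mirror the target experimental
design and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| samples per group | 3 | typical knock-down RNA-seq design |
| BSJ mean / linear mean | 100 / 300 | junction-level counts; linear several-fold higher |
| NB dispersion | 0.1 | bulk RNA-seq biological variability |
| planted \|log2FC\| | 2 | clear effects at these depths |
| category mix | 15/35/10/40% (Conc/DiscCirc/DiscLin/Unalt) | discordant-circ-dominated deregulation |
| down-fraction among deregulated | 0.8 | helicase-knock-down situation (downregulation dominates) |
| dropout fraction | 0.1 | BSJs detected in only one group, to exercise completion |
| peak width / placement | 200 nt within ±100 nt of the 5' donor, in ≥ 2 of 3 replicates | BSJ-proximal binding, guaranteed span overlap |
| summit motif | GC 0.9 tapering linearly to background over ±75 nt | a graded GC/structure peak, not a plateau, so the metaprofile maximum is identified at offset 0 |

Detection dropout is applied only to deregulated circRNAs, in their
low-expression group — dropout of a highly expressed invariant circRNA is
not a failure mode of junction detection. Linear counts of
`DiscordantCirc` circRNAs are drawn at log2FC 0 ("unaltered"); the
opposite-direction discordant variant is available through the category
fractions and sign options. Every output file has its own RNG stream
derived from the master seed, so regenerating one file never shifts the
others, and generation is byte-deterministic given `(cfg, seed)`.

What passing the synthetic suite shows: the estimators are unbiased enough
and the tests calibrated enough to recover planted effects of the stated
size under NB sampling, the window machinery localizes planted binding,
and the profile machinery finds planted structure. What it does not show:
robustness to misannotation, multi-isoform hosts with unannotated
junctions, coverage-correlated RIP background, mapping artifacts at repetitive
BSJs, or dispersion heterogeneity across features — real-data phenomena the
generator intentionally does not model.

## Problem sizes and numerical details

The default scenario uses 48 circRNA-producing genes plus 8 extra genes on
a single synthetic chromosome of a few hundred kilobases; the acceptance
computations use a 2000-feature null simulation for test calibration,
three seeds of the uniform-placement scenario for enrichment calibration,
and stride-thinned metaprofiles (every 50th offset, offset 0 always
included) — sizes chosen so the whole validation runs in minutes on one
core while leaving Monte-Carlo margins well clear of the thresholds.

Numerical conventions worth knowing: Newton iteration on log m is capped
at 50 steps with step clamping at ±5 (all-zero features short-circuit to
scale 0); features with zero counts in both groups are excluded before
testing; `top_expressed()` breaks mean-CPM ties lexicographically by id;
`merge_longest()` breaks equal-length ties by lowest start;
`match_controls()` breaks distance ties by circRNA id, making the whole
enrichment path deterministic given its inputs. narrowPeak summit offsets
of −1 fall back to the interval midpoint. The high-confidence
three-detector intersection matches ids exactly by default, with an
optional ±1–2 nt coordinate slack because detectors can disagree on the
junction base.

## Known limitations

* The NB test uses a single common dispersion; with very few replicates
  and feature-specific dispersion the type-I error can drift from nominal.
* The CLR is undefined for pairs with zero linear CPM and such pairs are
  dropped, which can bias CLR comparisons for loci whose linear isoform is
  silenced in one condition.
* Window matching balances annotated composition, not sequence content;
  GC-driven RIP biases shared by target and control windows cancel, but
  target-specific sequence biases do not.
* Control windows may be reused across targets (each target window gets its
  own two nearest controls). With a small invariant pool a single
  peak-bearing control window can be counted many times, which
  pseudo-replicates the control side of the 2×2 table and can produce
  scattered *depletion*-direction significance at arbitrary offsets. The
  positional claim of the meta-BSJ analysis is carried by the
  enrichment-direction bins (odds ratio above 1), which require target-side
  coverage and cannot arise from control reuse.
* The builtin folding model ignores stacking, loop entropies and
  pseudoknots; use the external backend for absolute energies.
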