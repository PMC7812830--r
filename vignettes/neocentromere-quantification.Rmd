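---
title: "Quantifying an induced neocentromere: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying an induced neocentromere: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neocent)
```

This vignette is the package's own account of the models it implements,
the assumptions behind them, and the design decisions taken where the
underlying procedures were open. The setting is chromosome engineering in
human cells: the endogenous centromere of one chromosome 4 homolog is
deleted, survivors are screened, and a spontaneously formed neocentromere
— a new CENP-A domain at a naive locus — is characterised against its
parental line by calibrated ChIP-seq, long-read structural-variant
analysis and mitotic-spread cytology.

## Spike-in calibration

ChIP-seq read counts are not comparable across libraries: sequencing
depth, immunoprecipitation efficiency and, in spike-in designs, the
chromatin mixing ratio all differ sample to sample. The package models a
library's expected spike-in reads as

$$E[Ns_{IP}] \propto \text{mix} \times \text{depth} \times
  \text{efficiency}, \qquad
  E[Ns_{input}]/E[Nh_{input}] \approx \text{mix},$$

because the input library is sequenced without IP and therefore estimates
the mixing ratio alone. The calibration factor

$$F = C \cdot \frac{Ns_{input}/Nh_{input}}{Ns_{IP}}, \qquad C = 10^6$$

then satisfies $F \propto 1/(\text{depth}\times\text{efficiency})$, so
multiplying raw IP bin counts (which scale with depth × efficiency) by
$F$ cancels both, and the input correction removes run-to-run variation
in spike mixing. The contract that matters — and that the test suite
verifies by simulation — is at the *track* level: two samples with equal
underlying chromatin state produce calibrated tracks whose mean per-bin
log-ratio is within ±0.02 across 2× perturbations of depth and mixing.
Note that the factor *value* itself is not invariant under uniform
rescaling of all four read totals (doubling everything halves $F$); it is
the product of factor and raw counts that is invariant, which is the
quantity with physical meaning. $C$ is cosmetic.

Bins are 10 kb. Coverage is handled as `CoverageTrack` objects with an
explicit `unitState` (`raw`, `rpkm`, `calibrated`, `minmax`) so that unit
errors (e.g. calibrating an already-calibrated track) fail loudly rather
than silently compounding. Min–max rescaling of a constant track is
undefined and raises an error instead of returning zeros.

## Allele-specific deconvolution

ChIP signal at a diploid locus aggregates both homologs. Two assumptions
make the engineered allele estimable:

1. the parental line's signal originates equally from both alleles, and
2. the non-engineered homolog in the derived line is equivalent to a
   parental allele.

Writing $r_b$ for the calibrated derived:parent ratio in bin $b$, the
derived signal is $(1 + a_b)/2$ parental units, so

$$a_b = 2 r_b - 1$$

is the fraction of one-parental-allele signal remaining on the
engineered homolog, and the domain summary is
$100\,(1 - \overline{a})$ percent reduction, using the arithmetic mean
over the bins fully inside the domain (a median is available; the mean
matches the single-number character of the summary). A complete loss on
one allele gives $r = 0.5$; noise can push $r$ below 0.5, so $a$ is
clipped at 0 for reporting while the unclipped values are kept for
diagnostics. Ratios use a pseudocount (default 1 raw-count-equivalent)
so empty bins are defined.

The per-run precision of this estimator is set by Poisson counting: by
the delta method, with $B$ domain bins and around $\mu$ reads per bin,
$\mathrm{sd}(\widehat{\text{reduction}}) \approx
200\,r\sqrt{(1/\mu_D + 1/\mu_P)/B}$ percentage points. At the default
operating point (500 reads/bin, 10 bins) this is roughly 3–4 points —
the recovery distributions computed in the test suite sit on this floor.
Consequently the estimator is unbiased to within ~1 point in expectation,
while individual runs scatter by several points; no estimator of this
contrast can do better without more reads or more bins, since the bound
matches the idealized statistic that knows the true calibration factors.

## Structural-variant subtraction

Derived-line SV calls are screened against the parental callset to find
variants present only after neocentromere formation. Two calls are the
same variant when they are of the same type and their start positions
*and* lengths both agree within

$$x = \begin{cases} 5\ \text{bp} & \text{parental length} < 250\\
\text{parental length}/50 & \text{otherwise,}\end{cases}$$

a rule that is continuous at the branch (250/50 = 5), non-decreasing in
length, and computed from the *parental* call's length (the tolerance
scales with the size of the variant being matched against; the asymmetry
is by construction). Design choices taken where the procedure was open:

* **Any-match semantics.** A parental call may eliminate any number of
  derived calls; subtraction is set subtraction, not bipartite matching.
  Whether the original screen consumed a parental call after one match
  is not specified; any-match is the conservative choice for calling
  *novel* variants (it never lets a derived call survive because its
  best parental partner was "used up").
* **Inclusive thresholds.** Length ≥ 10 and support ≥ 5, matching
  minimum-length/minimum-support caller semantics.
* **Breakends.** BND records carry no meaningful length; they match on
  type and start position within the small tolerance (5 bp) only.
* **Intervals.** VCF positions are 1-based; spanning types (DEL, DUP,
  INV) cover `[start, start + length − 1]` for region overlap, while
  insertions and breakends are points.

The implementation groups candidates by chromosome and type; the test
suite checks it against a brute-force all-pairs oracle that re-evaluates
the rule independently, over a thousand simulated callset pairs.

## Domain detection and formation frequency

No peak-calling procedure is prescribed for a single strong CENP-A
domain, so the package uses the simplest reproducible detector, fully
parameterised: bins above `mean + zThreshold × SD` (default z = 3) are
seeds; background mean and SD are re-estimated once excluding candidate
regions so a strong domain does not inflate its own threshold; seed runs
separated by at most `mergeGapBins` (default 2) merge; and regions with
fewer than `minWidthBins` (default 3) above-threshold bins are dropped.
That last rule deliberately counts *seed bins* rather than the merged
span: on a chromosome-scale track (~19,000 bins) two isolated noise
exceedances a couple of bins apart would otherwise merge into a
3-bin-wide "domain", and the detector's false-positive behaviour on
pure-noise tracks would degrade. The primary domain is the widest, not
the highest — the biology of interest is the span of the CENP-A domain,
not its summit. A constant track yields no domains (not an error).

Domain metrics are `width = end − start` and the edge-to-point distance
to a reference position (0 inside the domain), both translation
invariant. Formation frequency is plain arithmetic,
`events / challenged cells`, with the challenged-cell count
back-calculated as `round(total × positive fraction)`; because observed
events are recovered isolates rather than all formation events, the
estimate is flagged as an upper limit.

## Spread quantification

Spot intensity is the ROI box sum minus `area × background`, with the
box defaulting to 10 px wide × 18 px tall (orientation configurable,
since only the two dimensions are conventional) and background estimated
as the median of a 2-pixel frame surrounding the box — robust to the
spot's own tails leaking into the frame; corner-mean and
lowest-quartile-mean estimators are provided as alternatives. Whether
the original measure was a sum or a mean is immaterial after
within-spread normalization (target / mean of reference spots), which
cancels any per-spread scale. Negative corrected intensities are floored
at 0 and flagged.

Intercentromere distance uses a line profile through both dots of a
pair: the two most prominent local maxima (a proper prominence
computation, not a simple height cutoff) are refined by three-point
parabolic interpolation and the peak-to-peak distance converted by the
pixel size. Refinement can be switched off for literal integer-pixel
behaviour. Profiles are sampled at exactly one-pixel spacing — sampling
at `length/⌈length⌉` spacing would silently rescale every distance by up
to a few percent. Fewer than two qualifying maxima is an explicit error
("single dot / no pair"), and dot-pattern classification
(`two-dots` / `one-dot` / `undetermined`) uses a resolution threshold of
3 px by default: two refined maxima closer than that are reported as one
dot, matching the cytological reading of unresolved foci.

## The synthetic-data generator

`simulationConfig()` fixes the study conditions as defaults: a
chromosome-4-sized track (190,214,555 bp) in 10-kb bins; a 100-kb
planted domain at 43.08–43.18 Mb (4p13); a planted allele-loss fraction
of 0.78; 500 reads per bin; a 1% spike-in chromatin admixture (the
spike-in fraction actually obtained in the experiments is not published;
1% mirrors the mixing protocol and is a modelling choice); unit depth
multipliers and IP efficiencies; 50 shared background SV calls with ≤2 bp
jitter plus 5 derived-only novel calls; and 8 Gaussian dot pairs of
amplitude 1000 on background 100 with noise SD 50 (5% of amplitude),
σ = 2 px, 1.0 µm separation at 0.1 µm/px.

Counts are Poisson per bin — the minimal sequencing-noise model — with
the engineered allele modelled as exactly one of two equal-copy alleles.
Seeds are explicit; the same seed gives bit-identical output and the
caller's RNG stream is left untouched. What the generator deliberately
does *not* emulate: read-level artefacts (no FASTQ), alignment and
mappability bias, GC effects, copy-number variation, overdispersion
beyond Poisson, chromatin-structure autocorrelation along the genome,
and optical effects beyond additive Gaussian noise (no PSF, no uneven
illumination). Passing tests therefore demonstrate correctness of the
estimators under the stated statistical model, not robustness to every
artefact of real data; on real libraries the user remains responsible
for the equal-allele assumption and for upstream alignment quality.

## Problem sizes and test design

The test suite runs every estimator at the default operating point:
full-length chromosome-4 tracks for calibration and domain recovery
(50 seeds each for the enriched and pure-noise conditions), 50 seeds per
planted reduction fraction (0.30 / 0.50 / 0.78), 1,000 simulated callset
pairs (each up to ~170 calls) for the subtraction oracle, and 20
simulated spreads (160 dot pairs) for distance recovery — sizes chosen
so the whole suite completes in about a minute while keeping Monte-Carlo
standard errors well below the asserted bounds. Unit tests use a 2-Mb
chromosome where genome length is irrelevant.

## Known limitations

* The allele estimator propagates no uncertainty; a bootstrap over bins
  would be straightforward but is not built in.
* The domain caller is a threshold detector, adequate for a single
  strong domain; segmented or HMM approaches are out of scope.
* Strand/orientation of INV/BND pairs is ignored in matching.
* Spot centers are supplied by the user (matching the manual
  measurement workflow); there is no automatic spot detection.
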