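# neocent

Quantitative analysis of induced neocentromere formation.

When the endogenous centromere of a human chromosome is deleted, a
neocentromere can arise spontaneously at a naive locus: a new CENP-A
chromatin domain that assembles a functional kinetochore without any
underlying α-satellite DNA. Characterising such an event quantitatively
requires a small set of recurring computations that this package
implements as tested, reusable functions:

* **Spike-in calibrated ChIP-seq** — binned coverage tracks are made
  comparable across samples that differ in sequencing depth, spike-in
  chromatin mixing and IP efficiency. For a sample with IP and input read
  totals split by target (`Nh`) and spike-in (`Ns`) genome, the scaling
  factor is

  ```
  F = C · (Ns_input / Nh_input) / Ns_IP ,   C = 10^6
  ```

  and calibrated coverage is `F ×` raw bin counts. RPKM and min–max
  (`[0, 1]`) unit transforms are included.

* **Allele-specific deconvolution** — ChIP signal at a diploid locus is
  the sum of two alleles. With the parental line contributing equally from
  both alleles and the non-engineered homolog unchanged, the calibrated
  derived:parent ratio `r` per bin gives the fraction of
  one-parental-allele signal remaining on the engineered homolog:

  ```
  a = 2r − 1 ,   percent reduction = 100 · (1 − mean a over the domain)
  ```

  So `r = 0.61` across a domain means the mark was reduced by 78% on the
  neocentromere-bearing chromosome.

* **SV callset subtraction** — long-read structural-variant calls from
  the derived line are screened against the parental callset. Two calls
  are the same variant when they share the SV type and both start
  positions and lengths agree within the adaptive tolerance

  ```
  x = 5 bp                      if parental SV length < 250 bp
  x = parental SV length / 50   otherwise
  ```

  with length ≥ 10 / read-support ≥ 5 filters and region selection.

* **Domain analysis** — a parameterised threshold detector
  (mean + 3 SD with one background re-estimation pass) recovers the
  enriched CENP-A domain, reports width and edge-to-point distances, and
  the formation frequency is `events / challenged cells`.

* **Spread quantification** — background-corrected spot intensities from
  a 10 × 18 px ROI with a surrounding 2-px frame, within-spread
  normalization, peak-to-peak intercentromere distances from line
  profiles with sub-pixel parabolic refinement, and one-dot/two-dots
  classification.

* **Synthetic data** — `simulationConfig()` drives generators for all of
  the above with known ground truth (Poisson binned counts with planted
  allele loss, jittered SV callsets with planted novel calls, Gaussian
  dot pairs on noisy background), so every stage is testable end to end
  without external data.

## Worked example

Simulate the full quantitative ChIP design at its default operating point
(chromosome-4-sized track, 10-kb bins, a 100-kb domain losing 78% of the
mark on the engineered allele, 1% spike-in), then recover the planted
truth:

```r
library(neocent)

cfg <- simulationConfig(seed = 4)
sim <- simulateChipExperiment(cfg)
res <- estimateAlleleReduction(sim$parentIp, sim$derivedIp, sim$counts,
                               sim$truth$domain)
res$factors$derived
#> ScalingFactor for derived: 0.105241
round(as.numeric(res$reduction), 1)
#> [1] 78.8

es <- simulateEnrichmentTrack(cfg, enrichment = 10)
doms <- callEnrichedDomain(rpkmNormalize(es$track, sum(binValues(es$track))))
doms[[1]]
#> Domain chr4:43,080,000-43,180,000 (100,000 bp, 10 bins, 10.03x enriched)
domainMetrics(doms[[1]], referencePoint = 49180000)
#>    width distance
#>    1e+05    6e+06

formationFrequency(1, challengedCells(2.5e8, 5e-4))
#> Formation frequency: 1 event / 125,000 challenged cells = 8e-06 (upper-limit estimate)
```

The recovered reduction (78.8%) is the planted 78% up to Poisson counting
noise; the domain caller returns the planted 100-kb domain at bin
resolution; and one isolate among 125,000 challenged cells corresponds to
a formation frequency of 8 × 10⁻⁶.

A thin command-line wrapper over the same functions lives in
`inst/scripts/neocent.R`:

```sh
Rscript inst/scripts/neocent.R simulate chip --seed 4 --outdir out
Rscript inst/scripts/neocent.R frequency --events 1 --cells 125000
```

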