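---
title: "Profiling heterochromatin enrichment: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling heterochromatin enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetprofile)
```

## The measurement model

A two-channel ChIP tiling array reports, per probe, a ChIP intensity
$c$ and an input intensity $i$. The enrichment statistic carried
through the whole package is the M value,

$$M = \log_2(c / i),$$

computed per probe, median-centered per sample, and averaged into
fixed-width genomic bins. Everything downstream — class profiles,
family summaries, differential reports — is arithmetic on bin means.
The package assumes intensities are strictly positive (zero or missing
intensities are rejected with an error rather than imputed with a
pseudocount; a user with such data must filter or impute explicitly
upstream, where the choice is visible).

**Normalization.** The array protocol literature usually states
normalization only by reference to external pipelines, so the package
commits to one deterministic, robust convention: subtract the median M
of the *uniquely mapping* probes, putting the typical background probe
at $M = 0$. Two properties follow. First, normalization is idempotent
in effect (re-centering a centered track changes nothing), and the
package treats a second `normalizeTrack()` call as an error because it
almost always indicates a pipeline bug. Second — and this matters for
interpretation — when a non-negligible fraction of the genome is
genuinely enriched, the median of the noise-convolved M distribution is
slightly positive, so centering subtracts a small constant from every
probe, enriched or not. Percentage changes of class means are therefore
statements about *centered* means. The synthetic-truth machinery
accounts for this exactly (see below).

**Binning.** Bins are half-open, $[kw, (k+1)w)$ with $w = 500$ bp by
default, aligned to multiples of $w$ from arm coordinate 0, with probe
positions taken as 0-based midpoints. A probe at exactly $kw$ belongs
to the upper bin. Bins with no retained probes are omitted, never
zero-filled: an absent bin means "not measured", not "no enrichment".
Non-unique probes stay in the M track (for completeness) but are
excluded from bins by default, mirroring the restriction of repeat
analyses to uniquely mappable probes.

**Class assignment.** A bin belongs to a feature interval exactly when
its midpoint ($\mathrm{start} + w/2$) lies inside it. The midpoint rule
was chosen over fractional-overlap thresholds because it is symmetric,
unambiguous for 500-bp bins against kb-scale features, and makes the
brute-force oracle trivial to state. Class labels are *sets*, not a
partition: TEs sit inside pericentric blocks and piRNA clusters, and
each class statistic is computed independently over its own bin set.
`euchromatin` is defined negatively, as the bins carrying no
heterochromatic label; subtelomeric windows coexist with either.
Chromosome-4-like arms are wholly heterochromatic by annotation
(`chromosome4` on every bin) and do not additionally receive the
pericentric label. Moving a bin across a pericentric border flips
exactly that one label.

**Differential summaries.** For each class,
$\Delta = \bar M_{mut} - \bar M_{wt}$ always, and
$\mathrm{percent\ decrease} = 100\,(\bar M_{wt}-\bar M_{mut})/\bar M_{wt}$
only where $\bar M_{wt}$ exceeds a floor (`mFloor`, default 0.1 on the
M scale). The floor exists because families with essentially no
enrichment (roo-like, $M \approx 0$) would otherwise produce absurd
percentages from a denominator that is pure noise; flagged entries
report $\Delta$ only. Direction is the strict sign of $\Delta$, with
exact ties counted as unchanged so the counts are reproducible.
Families and clusters enter the comparison only when covered by at
least `minBins` bins (default 5) in both conditions; the threshold is
configurable because the underlying choice — how much coverage makes a
family mean meaningful — is a judgement call, not a derivation.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `binWidth` | 500 | bp | the standard averaging window for heatmap-style TE/cluster summaries |
| `subtelWindow` | 50 000 | bp | the window adjacent to each assembly end used for arm-tip profiles |
| `mFloor` | 0.1 | log2 units | guards percent decreases against near-zero reference means |
| `minBins` | 5 | bins | minimum per-condition coverage for family comparisons |
| `probeSpacing` | 300 | bp | tiling-array-like density, ≥1 probe per 500-bp bin on average |
| `probeNoiseSd` | 0.3 | log2 units | per-probe Gaussian M noise typical of two-color arrays |
| `nonuniqueFraction` | 0.15 | — | fraction of probes flagged non-unique |

## What the synthetic generator emulates — and what it does not

`defaultSimConfig()` encodes the study conditions the package targets:
a mostly euchromatic genome (two 5-Mb major arms with 350-kb
pericentric blocks, one 350-kb chromosome-4-like arm), 83 TE families
of which 69 are sensitive (their class mean drops by 13.4% in the
mutant) and 14 are roo-like (near-zero baseline enrichment, no shift),
96 piRNA clusters of which 80 decrease by 8.7% and 16 (42AB-like)
increase, pericentric background decreasing by 6.7%, chromosome-4
background by 5.7%, and a +0.2 log2 gain across the subtelomeric 50-kb
windows of the major arms in the mutant. True M at a position is the
baseline of the most specific containing feature — TE family over piRNA
cluster over pericentric/chromosome-4 background over euchromatin at 0
— because TE signal is empirically distinct from the surrounding
heterochromatin. Input intensities are lognormal; ChIP equals input
times $2^{M_{true} + \varepsilon}$ with Gaussian $\varepsilon$; qPCR Ct
noise is Gaussian; assay replicate noise is mean-one lognormal. All
randomness in a call flows from one integer seed, and identical
configuration plus seed reproduces byte-identical output.

Condition shifts can be applied on two scales. The *percent* scale
(`shiftScale = "percent"`, the shipped default) multiplies the true
mean by $1 - s/100$, which is the natural encoding when the quantities
being emulated are reported as percent decreases of class means; the
*additive* scale adds $s$ on log2 units and is the natural encoding for
fold-change-style effects. Both are first-class; the default follows
the semantics of the planted effects rather than the mechanically
simpler additive rule.

The generator deliberately omits: nucleotide sequence (no mappability
is computed — uniqueness is a planted flag), array platform artifacts
(spatial effects, dye bias, saturation), biological replicate
structure for the arrays, and any piRNA biogenesis mechanism. Passing
recovery tests on this generator therefore demonstrates that the
*estimators* are correct and calibrated under a clean noise model; it
does not validate dye-bias correction, replicate merging, or any claim
about real hybridization chemistry.

## Planted truth under median centering

The subtle numerical choice in the package is what "the planted truth"
means for class means. With, say, a quarter of probes genuinely
enriched, the sample median that `normalizeTrack()` subtracts does not
converge to zero but to the solution $t^\*$ of

$$\tfrac{1}{n}\sum_j \Phi\!\big((t - M_j)/\sigma\big) = \tfrac12,$$

where $M_j$ are the noise-free true M values and $\sigma$ the probe
noise sd. `simTruth()` therefore defines the true class mean as the
noise-free class mean *minus $t^\**$ — the large-sample expectation of
the pipeline's own estimator — computed by root-finding on the mixture
CDF (plain median when $\sigma = 0$). Comparing estimates against naive
uncentered baselines would build a deterministic offset into every
recovery test and misattribute an estimator property to estimation
error. With all baselines and shifts zero, $t^\* = 0$ and the entire
pipeline propagates exact zeros, which the test suite asserts
literally.

Two related statistical points, both reflected in the tests:

* The two conditions are profiled on the same bin layout, so layout
  heterogeneity (TE insertions inside clusters, edge bins) cancels in
  paired per-bin differences. Detection-probability calculations for
  direction counts use the sd of paired differences; treating the
  conditions as independent overstates the noise.
* A qPCR standard curve's fitting error is shared by every IP well
  inverted through it, so the within-plate replicate SEM cannot bound
  the accuracy of a single plate's enrichment estimate. Recovery of
  planted enrichment is assessed across replicate plates. The reported
  `enrichment_sem` is the first-order propagation across IP replicates
  and explicitly excludes curve uncertainty.

## Assay computations

The standard curve is an ordinary least-squares fit of Ct against
$\log_{10}$ (dilution fraction); a valid curve needs at least three
distinct dilutions and a negative slope, and the amplification base
$b = 10^{-1/\mathrm{slope}}$ must fall in $(1, 2.5]$. Pull-down
efficacy inverts the fitted line exactly, so the Ct of the 1% input
well maps back to 0.01 by construction; IP Ct values outside the
dilution-calibrated range are flagged as extrapolated rather than
rejected. Replicate efficacies are combined on the linear scale
(efficacy, not Ct, is the normalized quantity). ΔΔCt folds use base 2
per the classic method; an efficiency-corrected base from the fitted
curve can be supplied instead via the `base` argument but is not the
default. β-galactosidase activity uses the full 2-hour read window by
default; a linear-range ceiling (`odCeiling`, e.g. 1.5 OD) optionally
drops saturated readings. Negative fitted slopes are clamped to zero
with a flag — a reporter cannot have negative activity, but silently
returning a negative slope would corrupt downstream fold changes.
Ratio SEMs (relative enrichment, genotype folds) use the first-order
delta method, and a class's fold against itself is exactly 1 with SEM
0. SEMs are undefined for fewer than two replicates and the package
refuses to compute them.

## Problem sizes

The shipped study sizes are chosen so that the full test suite and the
acceptance script each run in well under two minutes on a single core:
the default genome is 10.35 Mb (about 34 500 probes per condition), the
planted-shift recovery study uses a ~4.9-Mb genome with 30 TE families
and 20 clusters over 10 seeds, qPCR recovery uses 100 simulated plates,
and reporter recovery uses 200 simulated replicate tables. These are
deliberate scale-downs of a 120-Mb genome; every estimator is
scale-free (means, medians, least squares), so nothing in the method
depends on the genome size beyond statistical power.

## Known limitations

* Peak or region significance calling is out of scope; all summaries
  are class averages.
* No dye-bias, quantile or lowess normalization — median centering
  only. Real two-color data may need preprocessing before entering the
  pipeline.
* Replicate arrays are not merged; each condition is one track.
* Percent decreases are computed over bins on the centered M scale;
  with few bins or near-floor reference means they are noisy, and the
  package flags rather than extrapolates those cases.
* The annotation is trusted input: pericentric borders, TE instances
  and cluster coordinates are never inferred from signal.
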