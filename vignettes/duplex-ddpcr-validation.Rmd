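---
title: "Duplex ddPCR quantification and analytical validation with DuplexDrops"
author: "DuplexDrops authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex ddPCR quantification and analytical validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DuplexDrops)
```

## The measurement problem

A duplex droplet digital PCR (ddPCR) assay quantifies a rare somatic point
mutation against its wild-type background in a single reaction. The reaction
is partitioned into roughly 20,000 nanolitre-scale droplets; a mutant-specific
probe reports on the FAM channel (channel 1) and a wild-type probe on the VIC
channel (channel 2). After thermal cycling each droplet is read as a pair of
fluorescence amplitudes, and the droplets fall into four clusters:
double-negative, mutant-only (FAM+), wild-type-only (VIC+), and
double-positive. Because template molecules distribute over droplets
essentially at random, the number of templates in a droplet is Poisson, and
counting *positive droplets* gives absolute quantification without a standard
curve.

`DuplexDrops` implements this whole desk-side analysis: droplet
classification, Poisson quantification, variant-allele-fraction (VAF)
estimation with uncertainty, and the analytical-validation cascade used to
characterise such an assay (linearity, repeatability, limit of blank, probit
limit of detection, Total-Error limit of quantification), plus fragment-size
and purity QC for ctDNA-mimicking reference materials. A droplet-level
simulator generates every input the pipeline consumes, so all stages are
testable without instrument exports.

## The quantification model

With $n$ droplets and a fraction $p$ positive for a target, the
maximum-likelihood estimate of the mean template copies per droplet is

$$\hat\lambda = -\ln(1 - p),$$

and the concentration in the reaction is $\hat\lambda / V_d$ for droplet
volume $V_d$ (times any pre-partition dilution factor). Positives for the
mutant target are the mutant-only plus double-positive droplets; for the
wild-type target, wild-type-only plus double-positive. No collision
correction beyond the Poisson model is applied — double occupancy is exactly
what the model accounts for.

The variant allele fraction is the concentration ratio

$$\mathrm{VAF} = \frac{c_\mathrm{mu}}{c_\mathrm{mu} + c_\mathrm{wt}},$$

stored as a fraction and reported as a percent to two decimals. Confidence
intervals on concentration use a Wilson score interval on the positive
fraction pushed through $-\ln(1-p)$ (the Wilson interval stays stable when
positives are very few, which is exactly the blank/low-VAF regime this assay
cares about); the VAF interval uses the delta method on the two estimated
$\lambda$s, whose binomial variance is $p/((1-p)n)$.

```{r quant-example}
well <- simulateDroplets(SimConfig(seed = 1), muCopies = 3000,
                         wtCopies = 3000)
res <- quantifyWell(well)
res$counts
res$vaf
```

## Classification choices

Thresholds are set per channel at the minimum-density point between the two
largest modes of a kernel density estimate of the amplitudes
(`estimateThresholds()`). This valley heuristic is reproducible and
parameter-light; when a channel is unimodal (no template, or saturated) no
valley exists, and the midpoint of the amplitude range is used with an
explicit flag and warning. Manual thresholds always override
(`manualThresholds()`).

Two deliberate conventions:

* A droplet **exactly at** a threshold is negative on that channel. Ties are
  vanishingly rare with continuous amplitudes, but the strict inequality is
  the conservative direction for blank counting.
* "Rain" droplets (intermediate amplitudes) are classified purely by which
  side of the threshold they land on; no droplet-exclusion filter is
  applied. Instrument software sometimes offers such filters, but none is
  modelled here, and the validation cascade is designed to absorb rain as
  measurement noise.

## The analytical-validation cascade

**Linearity.** `assessLinearity()` is ordinary least squares of measured VAF
(percent) on the nominal VAF of a gravimetric dilution series (50%, 20%, 5%,
1%, 0.2%, 0.1% is the canonical ladder). $R^2$ is carried at full precision
and displayed to four decimals.

**Repeatability.** `repeatabilityRsd()` is the sample relative standard
deviation, $100\,\mathrm{SD}/\mathrm{mean}$, over replicate VAFs. At fixed
total template, counting noise makes the RSD grow as the VAF shrinks — the
property tests assert this trend on simulated ladders.

**Limit of blank.** `estimateLob()` is the EP17-style non-parametric
estimator: pool the blank measurements (canonically 30 wild-type plasmid +
30 wild-type genomic DNA wells, 60 in all), sort, and read the value at rank
$N \times \text{percentile} + 0.5$, interpolating between the bracketing
order statistics — with $N = 60$ at the 95th percentile the rank is 57.5 and
the LOB is the mean of the 57th and 58th values. Ranks beyond the observed
range clamp to the extreme order statistics. A replicate is then *positive*
when its measured VAF is strictly greater than the LOB (`callPositive()`).

**Limit of detection.** `fitProbit()` fits a maximum-likelihood binomial
probit of the per-level hit rate on $\log_{10}$ VAF,
$P(\text{detect}) = \Phi(a + b \log_{10} v)$, and solves for the level
detected with 95% probability. The log scale is the standard choice for
concentration-type dose–response spanning decades (the canonical design is
five levels, 0.2% down to 0.01%, with 12 replicates each); a linear-scale
option is provided. The CI on the LOD comes from the delta method on the
coefficient covariance. Complete separation (no level with an intermediate
hit rate) makes the likelihood degenerate: the fit is flagged non-converged
and a bracketing estimate (midpoint between the highest all-negative and
lowest all-positive levels) is reported with a warning rather than a
spuriously precise number.

**Limit of quantification.** `computeLoq()` applies the Total-Error rule,
$\mathrm{TE} = |\mathrm{bias}| + 2\,\mathrm{SD}$ per level. Bias enters as an
absolute value (a sign convention has to be chosen; quantification error is
what matters, not its direction). If the tested level at (or nearest above)
the LOD meets the preset goal, LOQ = LOD. Otherwise the LOQ is the lowest
tested level *at or above the LOD* that meets the goal: an LOQ below the LOD
would assert quantification where detection itself is unreliable, and
restricting the fallback this way also keeps the LOQ monotone in the goal
(raising the goal can never raise the LOQ). When no level meets the goal the
result is an explicit no-LOQ outcome, not an error. The Total-Error goal has
no universal default and is a required argument.

```{r cascade-example}
lin <- assessLinearity(c(50, 20, 5, 1, 0.2, 0.1),
                       c(50.76, 20.39, 5.22, 0.98, 0.25, 0.10))
lin
lobRes <- estimateLob(0.001 * (1:60))
lobRes
pf <- fitProbit(data.frame(vaf = c(0.2, 0.1, 0.05, 0.02, 0.01),
                           nPos = c(12, 11, 9, 6, 3), nTotal = 12))
pf
computeLoq(data.frame(vaf = c(0.1, 0.2), bias = c(0.01, 0.01),
                      sd = c(0.02, 0.01)), teGoal = 0.2, lod = lod95(pf))
```

## Fragment-size and purity QC

ctDNA is characterised by fragments of roughly 90–150 bp (mono-nucleosome
protection; micrococcal nuclease digestion of chromatin leaves ~147 bp
cores). `findMainPeak()` reports the size of the global abundance maximum of
an electrophoretic profile and judges single-peakedness by *topographic
prominence*: a secondary peak counts only if its prominence exceeds 10% of
the main-peak height (configurable). Prominence, rather than raw local
maxima, makes the call robust to bin-level jitter on the flank of the main
peak while still catching a genuine secondary population. The ctDNA window
check is the closed interval 90–150 bp. `purityCheck()` passes a sample when
A260/A280 lies in [1.8, 2.0] (endpoints included) and A260/A230 strictly
exceeds 2.0.

## What the simulator emulates — and what it does not

`simulateDroplets()` draws per-droplet mutant and wild-type template counts
independently as Poisson with means `copies / nDroplets`; occupied droplets
emit that channel's positive-cluster mean, unoccupied the negative mean, and
Gaussian noise is added per channel. Double occupancy lights both channels
independently, matching the four-quadrant readout. Optional *rain* replaces
a positive droplet's amplitude with a uniform draw between the cluster
means — any smear model suffices for exercising the classifier, and the
uniform is the least structured choice. Optional per-droplet false-positive
rates model chemistry artefacts on either channel and are what give blank
wells a non-zero measured VAF. All randomness flows from the single seed in
`SimConfig`; the caller's RNG state is saved and restored, and the same
configuration is bit-reproducible.

Defaults are chosen once as instrument-nominal figures: 20,000 droplets of
0.85 nL; negative/positive amplitude means 1000/8000 (FAM) and 1000/6000
(VIC) with noise SD 200, i.e. clusters separated by many noise SDs, as a
well-optimised assay shows; rain and false-positive rates default to 0 (the
clean plasmid baseline) and are switched on explicitly for ctDNA-like wells
(rain 0.02) and blank panels (mutant-channel false-positive rate around
1e-4, giving a realistic sub-0.1% blank VAF distribution).

The simulator does **not** model fluorescence physics (channel crosstalk,
droplet-volume variation), droplet-QC filtering, MNase digestion kinetics,
or sequence-context effects. Passing tests therefore demonstrate that the
*statistical pipeline* is correct under the Poisson partition model with
well-separated clusters — not that any particular instrument's raw data will
be this clean. Real amplitude exports can be fed in directly through
`readAmplitudeCsv()`.

`simulateFragments()` draws fragment lengths from a Gaussian truncated at
1 bp (optional second component for contaminant testing) and bins them on a
1-bp grid — a deliberately minimal stand-in for a chip-electrophoresis
trace, synthetic by construction and labelled as such.

## Numerical choices and degenerate inputs

* Saturated wells (every droplet positive) raise an explicit error:
  $-\ln(1-p)$ is undefined at $p = 1$ and the well needs dilution, not a
  number.
* Zero positives give concentration 0 with a valid one-sided interval.
* `estimateLob()` requires at least 20 blanks and warns below 60.
* Probit fitting requires at least 3 positive levels and errors on a
  non-increasing detection curve (slope $\le 0$).
* Problem sizes in the test-suite simulations (wells of 20,000 droplets, 6–8
  replicates per condition, 150–200 resamples for the probit sampling
  distribution) are chosen so the whole property suite runs in seconds while
  keeping Monte-Carlo intervals tight enough to be meaningful.

## Known limitations

* Thresholding is per-well and per-channel; no information is shared across
  wells of a plate, and no 2-D (joint-channel) clustering is attempted.
* The probit LOD and the delta-method CIs are asymptotic; with 12 replicates
  per level the CI is indicative rather than exact.
* The Total-Error LOQ rule evaluates only tested levels; it does not
  interpolate between levels.
* Gravimetric mixture plans work in copy space; pipetting and weighing
  errors of a real dilution series are not modelled.
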