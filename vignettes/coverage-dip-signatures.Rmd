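---
title: "Quantifying cfDNA coverage-dip signatures: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cfDNA coverage-dip signatures: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

Cell-free DNA is released into plasma mostly as mononucleosomal fragments
(about 167 bp): nucleosome-bound DNA survives digestion, open chromatin does
not.  At a region of open chromatin in the contributing cells, WGS coverage
of plasma DNA therefore dips, and the average of that dip over a set of
regions sharing an annotation (for example tumor-specific DNase I
hypersensitivity sites) is a per-sample signature of the chromatin state of
the cells shedding the DNA.

`cfdip` treats the *fragment* — reconstructed from a properly paired
template's leftmost position and TLEN — as the unit of observation, because
the fragment, not the read, is the footprint of what was protected.  Coverage
at a position is the number of fragments overlapping it.

## Binning and normalization

Regions of a set differ in length, so profiles are made comparable by
reducing each region to its center `c = floor((start + end) / 2)` and binning
a fixed window around it: `n_bins` (odd, default 41) bins of `bin_size`
(default 500 bp), i.e. about +/-10 kb.  Bin `j` of every region covers the
same signed offset from the center, which is what makes the column mean
across regions meaningful.  The defaults are a compromise: the dip itself has
a scale of one to a few kb, and several kb of flank on both sides are needed
to anchor the baseline and to train the bias model; 500 bp per bin keeps the
per-bin Poisson noise manageable at typical 1-15x depths.  `bin_size` must be
even so that bin edges `[c + offset - w/2, c + offset + w/2)` stay integral.

Raw per-bin coverage is divided by a genome-background factor: the mean
per-base fragment coverage over `n_norm_windows` (default 200) random 1 kb
windows placed uniformly over the genome (seeded, away from chromosome
edges).  Normalizing against the genome background rather than against the
region set itself means a genuine dip is not normalized away; after division,
1.0 means "average genome coverage" for every sample regardless of
sequencing depth.  Regions whose window would cross a chromosome end are
dropped with a warning, never padded: padded sequence would fabricate bias
features.

Strand is ignored throughout (fragments are double-stranded, coverage is
strand-symmetric), and overlapping regions within a set are processed
independently.

## Bias correction

Coverage varies technically with sequence composition and alignability.  Per
(region, bin) cell we compute 82 covariates: GC fraction, the 16 dinucleotide
and 64 trinucleotide frequencies on the forward strand (k-mers containing N
are excluded from numerator and denominator; bins over 10% N are masked out
entirely), and mean per-base mappability from the supplied bigWig.  K-mers
are deliberately not reverse-complement-collapsed: the collapse saves columns
but discards strand-composition information, and the regressor is free to
ignore redundant columns.

The bias model regresses observed normalized coverage on these covariates,
with two safeguards:

* **Leakage control.**  Only bins whose center offset satisfies
  `|offset| > exclude_center_halfwidth` (default 2000 bp) enter training, so
  the biological dip cannot be learned as "bias".  The full grid is predicted
  at correction time.  When the dip is expected to be wider than 2 kb the
  exclusion should be at least its full support (about three times the dip
  scale); the signal-preservation checks in the test suite use 4500 bp for a
  1500 bp dip for exactly this reason.
* **Additive correction.**  `corrected = observed - predicted + train_mean`.
  A ratio correction explodes at low-coverage bins; the additive form is
  stable everywhere, preserves the training mean by construction, and may
  legitimately produce small negative values, which are kept (flooring would
  bias the aggregate).

The default regressor is gradient-boosted regression trees (xgboost,
`nthread = 1`, seeded, hence bit-reproducible) with deliberately conservative
settings: depth-2 trees, learning rate 0.05, 100 rounds, minimum child weight
50, L2 regularization 5, and 50% column subsampling.  Per-bin coverage is
noisy and the technical signal is weak; an aggressive booster (or even OLS on
82 columns and a few hundred rows) memorizes noise and shows *negative*
cross-validated R^2.  The model's out-of-sample explanatory power is always
reported (`holdout_r2`, seeded 3-fold CV on the training rows) together with
before/after correlations of coverage with GC and mappability; an
intercept-only degenerate case reports correlation 0 with a flag.  Ordinary
least squares is available (`method = "lm"`) as an exact, fast alternative
used widely in the test suite.

## The dip model and signature metrics

The aggregated profile (column mean and SE over retained regions; optionally
a 10% trimmed mean to resist outlier regions) is summarized by bounded
nonlinear least squares of

    y(x) = b0 + b1 x + b2 x^2 - d exp(-x^2 / (2 sigma^2))

over the bin-center offsets `x` in bp.  The quadratic baseline absorbs a
sloping or curved background; the Gaussian carries the dip.  No biological
derivation fixes this functional form — it is the minimal shape with
interpretable depth (`d`, coverage units), width (`sigma`, bp) and
background, and the model-free nonparametric area is always reported
alongside as a fallback.

Numerical choices, all visible in the code:

* fitting runs in kb units internally for conditioning, coefficients are
  reported per bp;
* initialization: `b0` = mean of the outer 25% of bins, `b1 = b2 = 0`,
  `d = b0 - min(profile)`, `sigma = 1000` bp;
* bounds: `d >= 0`; `sigma` in `[bin_size, half_span]`, which keeps the
  Gaussian resolvable on the grid;
* the Levenberg-Marquardt fit (minpack.lm) is declared converged only when
  its own status is clean *and* its RSS does not exceed the baseline-only
  quadratic fit; otherwise parametric metrics are reported missing and only
  the nonparametric area is used;
* the standard error of `d` comes from the LM Jacobian; when `d` sits on the
  zero bound the information matrix is singular and a pseudoinverse fallback
  (with a residual-scale floor) is used, so "no dip" fits still carry an
  uncertainty.

Signature strength defaults to the analytic dip area
`d * sigma * sqrt(2*pi)` (coverage x bp), which integrates depth and width
and agrees with numeric integration of the fitted Gaussian to better than 1%
whenever the grid spans at least 4 sigma.  `dip_depth` and the nonparametric
area are selectable alternatives.  The nonparametric area is the flank
baseline (mean over bins with `|offset| > 3/4 half_span`) minus the profile,
summed over central bins (`|offset| <= half_span/2`) times bin size; negative
values are reported as-is and flag an inverted signature.

## Group testing

Each case sample's metric is tested against the control cohort by a normal
z-score (`(score - control_mean) / control_sd`, two-sided p, at least 3
controls, degenerate SD flagged), BH-adjusted across region sets within a
sample.  A subtlety governs the metric choice: `d` is bounded at zero, so for
a control group with *no* dip the fitted `dip_area` piles up on the bound and
its "control distribution" is half point mass — no z-score is meaningful.
Where the control group is expected to be null on the tested set, the
continuous nonparametric area is the appropriate metric; where controls share
a genuine baseline signature (the common case for tissue signatures in
healthy plasma), `dip_area` is fine and the leave-one-out calibration checks
in the test suite use exactly that configuration (controls with a modest 0.15
dip).

# The synthetic-data generator

`simulate_bundle()` is not a fixture dump but a model of the measurement:

* a toy multi-chromosome genome of i.i.d. bases at configurable GC (default
  0.41, human-like);
* regions of fixed length (default 1 kb) in non-overlapping slots spaced so
  analysis windows never collide, kept clear of chromosome ends;
* fragments with lengths from a truncated normal (mean 167, sd 20, range
  70-400 bp — mononucleosomal cfDNA), midpoints sampled by thinning a uniform
  candidate stream with per-position rate
  `1 - dip_depth * exp(-D^2 / (2 dip_sigma^2))` (`D` = distance to the
  nearest region center) and, optionally, an exponential GC tilt
  `exp(gc_bias * (GC_frag - 0.5))`, normalized to a proper acceptance
  probability; sampling stops when the accepted bases reach
  `mean_coverage * genome_length`, so realized depth lands on the target;
* each fragment is emitted as one proper read pair that reproduces it
  exactly (perfect reference match, uniform qualities — base-level fidelity
  is irrelevant to coverage math), converted to a coordinate-sorted, indexed
  BAM;
* mappability 1.0 everywhere except configured intervals, written as bigWig;
* a truth JSON recording every parameter and the emitted fragment count.

Defaults mirror the regime the method is built for: hundreds of ~1 kb
regions and about 5x depth, with dips of a few tens of percent at a 1-2 kb
scale.  What the generator does *not* emulate — and what passing tests
therefore cannot certify — includes mapping errors and alignability structure
(reads are placed, not aligned), copy-number variation, chromatin-dependent
fragment-length shifts, fragment-end sequence preferences, and correlated
(non-i.i.d.) genome composition.  Conclusions about real plasma WGS still
require real validation cohorts.

# Study conditions used by the automated checks

The test suite and `scripts/acceptance.R` run the pipeline at the sizes the
package targets, scaled so the full suite completes in a few minutes: exact
per-base oracle equivalence on dozens of randomized small instances;
parameter recovery and signal-preservation on a 500-region, 5x simulation;
GC-bias removal on a 150-region, 4x simulation with `gc_bias = 4`; null
calibration and leave-one-out z-scores on 20+ replicates of 60-region, 4x
simulations; and a 5-vs-5 case/control cohort.  All randomness is seeded and
every simulated condition is recorded in the truth JSON next to the outputs.

# Known limitations

* The bias model corrects composition and mappability, not copy number; a
  focal amplification overlapping a region set will masquerade as signal.
* Fragment-length-stratified analysis (e.g. separate short/long-fragment
  signatures) is not implemented.
* The Gaussian-plus-quadratic dip model under-fits profiles with shoulders
  (e.g. phased nucleosome peaks flanking the dip); the nonparametric area is
  the intended fallback there.
* Group testing assumes an approximately normal control distribution of the
  chosen metric; with very few controls the z-test is indicative, not
  calibrated.
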