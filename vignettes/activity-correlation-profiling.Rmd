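---
title: "Activity correlation profiling: models, assumptions and design choices"
author: "acprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity correlation profiling: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acprofiler)
```

## The problem

Some biochemical activities — the ER's dolichol-linked oligosaccharide
scramblase is the motivating example — resist classical purification: the
activity survives detergent solubilisation and reconstitutes robustly into
proteoliposomes, yet every column step loses it or dilutes it beyond
recognition. Activity correlation profiling sidesteps purification. A crude
detergent extract of membrane proteins is resolved into fractions by
velocity gradient sedimentation; each fraction is split, one half assayed
for the activity in reconstituted vesicles and the other half quantified by
multiplexed (TMT) mass spectrometry. A protein that *is* the activity must
co-sediment with it, so its abundance profile across fractions should match
the activity profile. Candidates are the proteins whose Pearson correlation
with the activity profile clears a stringent threshold, further filtered by
biological priors (essentiality, membrane topology, localization).

`acprofiler` implements this method end to end over synthetic data: a
gradient/TMT simulator supplying ground truth, the Poisson occupancy model
of the end-point reconstitution assay, the correlation and curation steps,
and scenario experiments that quantify when the method succeeds and — just
as importantly — when it fails.

## The gradient simulator

Each sedimenting species (a monomer or a complex) is described by a mass,
a sedimentation coefficient, an abundance and an activity flag. When no S
value is given it is derived from the globular-protein scaling
$s = k\,M^{2/3}$, with $k$ anchored so a 29 kDa globular protein sediments
at 2.8 S (`K_SVEDBERG`). The S-to-fraction map is a straight line
`position = slope * S + intercept` fitted by least squares to sedimentation
standards (2.8, 3.6, 4.2 and 8.9 S). A linear map is adequate over this
range; no attempt is made to solve gradient transport equations. Because
the standards' numeric peak positions are a free choice, the package's
default calibration places them on `position = 0.82 S + 2.2`, which spreads
the standards over the middle of a 12-fraction gradient and puts a 6–7 S
species at fractions 7–8, where the activity peak is expected.

A species' band is a Gaussian in fraction coordinates, width
`band_sigma = 0.8` fractions by default (band spread is visible in real
gradients but never parameterised; 0.8 reproduces bands occupying roughly
three fractions). The discretised band is renormalised to sum to the
species' abundance — mass conservation is the testable contract; tails
clipped at the gradient ends are folded back rather than reflected. Note a
discretisation subtlety: the centroid of a discretised Gaussian recovers
the band centre with error on the order of $e^{-2\pi^2\sigma^2}$, which is
negligible at $\sigma = 0.8$ but grows as $\sigma \to 0$ (all mass
collapses onto one fraction). Calibration round-trip accuracy is therefore
best at moderate band widths, and the round-trip test uses the default
width.

Oligomeric states of one protein are linked by `pool_of`: MS reports a
protein, not its quaternary state, so pooled rows are summed under the
parent id in the observed matrix.

TMT-style measurement error is multiplicative log-normal per cell:
`value = truth * exp(eps)`, `eps ~ N(0, sigma)` with
`sigma = sqrt(log(1 + cv^2))` so the per-cell coefficient of variation is
exactly `cv`. This is the standard error model for isobaric-label relative
quantification: errors scale with signal and the noise is unbiased in the
median (the mean carries the usual log-normal factor
$e^{\sigma^2/2} \approx 1.005$ at `cv = 0.1`). The generator's default
conditions mirror the study design: ~3000 species, two technical
replicates, `cv = 0.1`, six MS fractions (5–10), activity assayed over
fractions 5–11. Decoy masses are drawn log-uniformly over 20–300 kDa —
a simple, realistic span for ER membrane proteins and complexes that
yields a bulk-protein peak early in the gradient and a mean peaking mass
that grows monotonically down the gradient, as observed in real data.
What the simulator does **not** emulate: peptide-level effects (missing
proteins, shared peptides), ratio compression, detergent micelle effects
on sedimentation, and non-Gaussian band shapes. Passing tests therefore
demonstrate the statistical logic of the method, not robustness to every
real-data artefact.

## The reconstitution assay model

The assay readout is an end point. Reporter glycolipid is distributed
between the leaflets of large unilamellar vesicles; the lectin probe
captures only outer-leaflet reporter. In protein-free vesicles that is the
outer pool, `f_out = 0.5` for symmetric reconstitution, giving ~50%
capture. If a vesicle carries at least one functional scramblase, the
inner pool is scrambled to the surface faster than it is captured (the
model treats scrambling as infinitely fast — no kinetics), so occupied
vesicles report 100%. Copies distribute over vesicles by Poisson statistics
with mean $\lambda$, and vesicles are treated as identical in size (a
single $\lambda$; size dispersity would mix Poisson means and is noted as
an extension). The expected capture is

$$E[\text{capture}] = 100\left[f_{out} + (1 - f_{out})(1 - e^{-\lambda})\right],$$

which runs from 50% at $\lambda = 0$ to 100% at saturation. The flipping
statistic normalises the raw triplet of conditions (buffer / lectin /
lectin + detergent), `100 (R_ConA - R_buffer) / (R_ConA-TX - R_buffer)`,
and in the ideal model equals the occupied-vesicle fraction
$100(1 - e^{-\lambda})$ — the analytic cross-check used in the tests.

`occupancy_scale` links simulated protein amounts to $\lambda$. It is a
free constant (vesicle number and diameter are not modelled), calibrated
by the assay's own design rule: reconstitute just enough protein — half of
each fraction by default (`reconstituted_share = 0.5`) — that the peak
fraction reports ~70% capture, i.e. 40% of vesicles occupied,
$\lambda_{peak} = \ln(5/3) \approx 0.51$. This keeps the readout inside
its quasi-linear range while leaving headroom.

Two consequences of the saturating transform are worth stating plainly.
First, the assay is insensitive to changes of less than about twofold near
saturation; the in-silico immunodepletion model reproduces this — removing
one of three equally expressed redundant active proteins lowers the
readout by exactly one third only in the small-$\lambda$ limit, and by
less at saturation. (Depletion is modelled with equivalent total protein
reconstituted, the surviving active amount scaling $\lambda$ by $1 - q$
exactly.) Second, even at the 70% design point the activity profile is a
slightly compressed image of the active species' band, so the Pearson
score of the active species itself is ~0.997 rather than 1 at zero noise;
it reaches 1 only in the fully linear regime (e.g. a 55% design point).
The package correlates against the readout as measured — that is what the
experiment does — and the tests assert the corresponding bounds.

## Correlation and curation

Per technical replicate, duplicate activity measurements are first
averaged per fraction, both profiles are restricted to their common
fractions (the six MS channels by default; the activity value at fraction
11 is measured but unused), and a Pearson score is computed per protein.
At least three common fractions are required. Flat (zero-variance)
profiles yield a *missing* score, never 0, and missingness propagates to
curation as "fails the threshold". Scores are aggregated across replicates
as mean ± sample SD (a single defined replicate reports SD 0 by
convention); the mean is the filtered quantity.

Curation intersects the high-correlation set (default threshold 0.9,
inclusive comparison by default with a flag for strict inequality) with
annotation-derived sets: essential proteins, membrane proteins with at
least `min_tm` predicted transmembrane spans (default 3), and a
localization label (default "ER"; multi-localized proteins pass if any
label matches). Annotations are inputs — the package never queries
topology predictors or organism databases. Unannotated proteins are
excluded with an explicit machine-readable reason rather than silently
dropped, every exclusion carries its failed filters, and the full Venn
accounting (all intersection and exclusive-region sizes) is reported. A
near-threshold report lists proteins just under the cut-off for manual
rescue review, reproducing the judgement call of admitting a biologically
compelling near-miss.

## Scenario experiments and known limitations

The `X + XY` scenario models activity regulated at the level of quaternary
structure: protein X is active as a monomer but inactive in a heterodimer
with Y. MS merges both states under X's id, so X's observed profile is the
sum of two bands (a discrete two-band mixture, not a widened Gaussian —
pools are distinct sedimenting species), while the activity tracks only
the monomer band. With half of X complexed and the complex band well
separated (the defaults, 60 + 80 kDa, put the bands ~2.8 fractions apart),
X's score collapses below the threshold and curation discards the true
protein. The sweep over the complexed share is monotone at zero noise and
reports the smallest share at which X fails. Controls: an *active* complex
restores the correlation, and with no band separation the pools are
indistinguishable and X keeps scoring highly. The inverse scenario — two
individually inactive monomers whose complex is active — is expressible by
flagging only the complex active; each monomer then scores below the
complex profile.

The recovery benchmark runs the whole pipeline across seeded simulations
and records the rank of the true species by mean score. Its headline
result is a limitation worth understanding: at the study scale (3000
species whose S values span ~2.2–13.3 S, 10% TMT noise, two replicates),
the true species virtually always clears the 0.9 threshold (median score
~0.997) but almost never ranks exactly first. Tens of decoys co-sediment
within the noise-limited profile resolution (roughly ±0.1 fraction) of the
active species; species with indistinguishable expected profiles cannot be
separated by any profile-correlation statistic, so the top rank among the
near-ties is a lottery. Correlation profiling on a single separation
dimension delivers a *candidate set*, not a unique hit — which is exactly
how the method behaves on real data, and why orthogonal separations or
downstream depletion experiments are needed to resolve the set.

## Numerical conventions

- Fractions are indexed 1-based from the top of the gradient.
- Peak-fraction ties break toward the earliest fraction.
- All randomness flows through one integer seed per simulation call; the
  caller's RNG state is restored afterwards.
- The calibration fit requires at least two distinct standards and a
  positive slope; degenerate assay windows (`R_ConA-TX = R_buffer`),
  zero-variance correlations and `P + S = 0` measurements raise errors or
  missing values rather than silently producing numbers.
- Problem sizes used in the shipped tests: mixtures of 50–3000 species,
  100-simulation benchmarks, 10000-replicate noise checks — small enough
  to run in under a minute yet at the scale the study conditions specify.

## A worked example

```{r example, eval = FALSE}
library(acprofiler)

# simulate the study conditions
sim <- simulate_experiment(list(seed = 1))

# correlate each replicate with the activity profile and aggregate
records <- aggregate_replicates(
  lapply(sim$replicates, correlate_profiles, activity = sim$activity))

# curate with an annotation table (here: built alongside the truth)
head(records[order(-records$r_mean), ])

# the X + XY failure mode
xxy <- xxy_experiment(xxy_config(complex_fraction = 0.5))
xxy$r_x  # ~0.35: the true scramblase is discarded at a 0.9 threshold
```
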