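---
title: "Quantifying hypertrophic olivary degeneration from medullary asymmetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hypertrophic olivary degeneration from medullary asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hodasym)
```

## The detection problem

Hypertrophic olivary degeneration (HOD) is a delayed, transsynaptic
degeneration of the inferior olivary nucleus (ION) after lesions of the
Guillain–Mollaret triangle. Radiologically it is a unilateral
hyperintensity — and transiently an enlargement — of one olive on
T2-weighted, proton-density (PD) and FLAIR images, with decreased
fractional anisotropy (FA) and increased mean diffusivity (MD) on
diffusion imaging. The finding is subtle: expert readers disagree
appreciably, and a healthy ION is itself mildly hyperintense on PD. This
package implements a quantitative alternative: measure the left/right
intensity asymmetry of the anterior medullary quadrants that contain the
IONs, calibrate what "normal" asymmetry looks like on disease controls,
and call HOD where a patient's asymmetry exceeds that norm.

Because no clinical images ship with the package, every component is
exercised end-to-end on synthetic brainstem phantoms with known ground
truth. The phantoms are first-class, tested code, not a fixture: the
package's claims are claims about the pipeline's behaviour under this
generative model.

## Segmentation model

The medulla cross-section is divided using two surface landmarks that
are easy to identify on axial slices: the anterior median fissure and
the two posterolateral sulci. The line joining the sulci separates
anterior from posterior; its perpendicular through the fissure separates
left from right. Using the perpendicular rather than the image column
axis makes the split robust to in-plane head rotation. Voxels exactly on
the midsagittal divider go to the left quadrant (a deterministic,
measure-zero tie-break); voxels exactly on the sulcus line count as
anterior.

The ROI is the pair of anterior quadrants pooled over an 8-mm axial
slab: 4 consecutive slices on 2-mm grids (PD/T2/DTI) and 2 on the 4-mm
FLAIR grid. Where the slab cannot be centred exactly on the olive it is
biased inferiorly — the centring rule is a package choice, made once for
reproducibility, since a manual protocol does not need one. Pooling
voxels across slices (rather than averaging per-slice means) is likewise
a declared choice; with near-constant slice cross-sections the two
differ negligibly. When no medulla outline is available the package
substitutes a declared disc of configurable radius around the landmark
centroid; the phantom generator always supplies the true cylinder mask.

ROI means use the quadrant mean intensity; all downstream statistics are
ratios of such means, so intensity units cancel.

## Asymmetry indices

For the structural contrasts the index is unsigned: with quadrant means
$a \ge b$,
$$\mathrm{diff}\% = 100\,(a - b)/b,$$
normalized by the *lower* mean so the statistic is always positive, with
the higher side carried separately. Exactly equal means return side
"none" and 0 — a measure-zero case handled deterministically. For FA/MD
the expected HOD side (known per patient from the causative lesion) is
the reference:
$$100\,(m_\mathrm{expected} - m_\mathrm{contralateral})/m_\mathrm{expected},$$
signed, so FA effects come out negative and MD effects positive.
Percentages are carried as percentages throughout (1.21 means 1.21%).

## Threshold calibration

Controls show a genuine physiological asymmetry of order 1–2%, so zero
is the wrong null. The detection threshold per modality is
$$\mathrm{threshold} = \bar{x}_\mathrm{ctrl} + 2.576\, s_\mathrm{ctrl},$$
with the sample SD ($n-1$ denominator). The multiplier 2.576 is the
two-sided 99% normal quantile; applied one-sidedly to a nonnegative
statistic its nominal coverage is ~99.5%. The package keeps the formula
as stated and labels it the "99% threshold (convention)" — the
`z` argument of `calibrate_threshold()` exposes the multiplier for
anyone preferring 2.326. Exceedance is strict (`>`); a zero-SD control
sample degrades the threshold to the mean and warns. For exceeding calls
the higher-intensity side is checked against the expected side: a
contralateral hit is reported as a quantitative false positive rather
than a detection.

## The phantom generator

The phantom is deliberately minimal: a cylindrical medulla (radius 9 mm)
in a 96×96×24 grid at 0.625×0.625×2 mm (matching a 240-mm field of view
at matrix 384 cropped to the brainstem), containing two ellipsoidal
olives with semi-axes 3×2×6 mm centred 4.5 mm lateral and 2.5 mm
anterior of the medullary axis — proportions consistent with the true
ION's ~6-mm width and ~12-mm craniocaudal extent, and placed so that
even a 20%-enlarged olive stays clear of the midsagittal divider. FLAIR
is produced by averaging pairs of 2-mm slices into a 4-mm grid, honestly
reproducing the two-slice FLAIR segmentation; FA/MD maps are generated
directly on a 2-mm isotropic grid (baseline FA 0.45, MD 8×10⁻⁴ mm²/s) —
simulating the diffusion acquisition itself is out of scope.

A planted HOD on side $s$ multiplies that olive's structural intensity
by $1+e$, its semi-axes by $1+\mathrm{enlargement}$, its FA by $1-0.35$
and its MD by $1+0.10$. Because the olive occupies only part of the
quadrant, the measured index is the *diluted* effect: for olive voxel
count $K$ (within the slab), quadrant count $N$ and olive contrast $c$,
$$\mathrm{diff}\% = 100\,\frac{K (1+c)\, e}{N + K c},$$
which the noiseless phantom reproduces to machine precision — this
closed form, evaluated from the ground-truth masks, is the oracle for
the recovery tests. At the default geometry the dilution factor is
roughly 0.25–0.3, so intensity effects of 0.1–0.3 map to measured
asymmetries of ~3–10%. The same dilution applies to the DTI effects: the
default FA effect of 0.35 yields a measured expected-side FA difference
around −10 to −15%, and the subgroup contrast is therefore asserted as
sign and ordering (PD+ strongly negative FA / positive MD, PD− near
zero), not as equality to any particular magnitude.

Control-like residual asymmetry cannot come from the HOD mechanism
(controls have none), so it is modelled separately: a signed draw
$r \sim N(0, \sigma_m)$ per structural modality scales one half of the
medulla by $1+|r|/100$, making the noiseless measured index exactly
$|r|$. The unsigned index over a cohort is then folded-normal with mean
$\sigma_m\sqrt{2/\pi}$; the default $\sigma_m$ are chosen by inverting
that relation for target control means of 1.21% (PD), 1.37% (T2) and
2.14% (FLAIR) — the order observed in healthy-control data, with FLAIR
noticeably wider. The true shape of the physiological asymmetry
distribution is unknown (per-subject control values are not published
anywhere we know of), so the folded-normal is a declared modelling
choice, exposed via `control_asymmetry_sd`.

Noise is additive Gaussian per voxel (default SD 2% of background for
structural, 3% of baseline for DTI). Rician noise is intentionally
omitted: the analysis consumes ROI means over hundreds of voxels, where
the Gaussian approximation is adequate and the mean's noise
(≈ 0.1% of background) is an order of magnitude below the physiological
asymmetry.

Cohorts draw each patient's expected side (left/right, ½ each) and, with
probability `hod_prevalence_in_patients` (default 0.6 — not every
triangle lesion produces HOD), an intensity effect from a log-normal
(median 0.15, log-SD 0.5) truncated to [0, 0.5]: strictly positive and
right-skewed, with a minority of sub-threshold effects so that
quantitative sensitivity is high but not trivially 100%. Raters are
Bernoulli machines: sensitivity per true HOD, 1−specificity per
HOD-free subject (with a uniform random side), and a laterality error
rate for flipping the side of a correct positive. Every generator output
is a pure function of its spec including the seed, and restores the
caller's RNG state.

What the phantoms do *not* model: coil bias fields, susceptibility and
motion artifacts, partial-volume anatomy, inter-modality misregistration
(phantoms are generated pre-aligned; the registration question is
thereby sidestepped, not answered), bilateral HOD, and rater behaviour
beyond independent Bernoulli errors (no difficulty-dependent or
correlated disagreement). Passing tests therefore demonstrate the
pipeline's arithmetic, calibration behaviour and statistical routing —
not clinical performance.

## Statistical machinery

The normality screen is the Lilliefors variant of the
Kolmogorov–Smirnov test: the KS distance is computed against a normal
with sample-estimated mean/SD, and since that composite-null
distribution is not the classical KS law, the p-value is obtained by
seeded Monte-Carlo (default 10,000 standard-normal replicates of the
same n, each standardized by its own estimates;
$p = (1 + \#\{D^\ast \ge D\})/(R+1)$). This trades a lookup-table
dialect for a reproducible, self-contained null.

Routing follows the study design the package emulates: normal data →
paired t within a group, Welch t between groups; otherwise
Wilcoxon–Mann–Whitney (signed-rank for paired data). All tests are
two-sided — sidedness is never assumed — and significance is α = 0.05
with no multiplicity correction (none is part of the emulated design;
the report carries raw p-values). The WMW p-value is exact for
min(n₁,n₂) ≤ 8 without ties and a tie-corrected normal approximation
with continuity correction otherwise; the exact branch is verified in
the tests against full enumeration of $\binom{n_1+n_2}{n_1}$
arrangements. Welch's test on two zero-variance samples is reported as a
flagged degenerate result (t = 0/∞) rather than an error, so cohort
loops never die on a pathological subgroup.

Fleiss' kappa uses three categories by default — none / HOD-left /
HOD-right — because raters report presence *and* side; a binary
`mode = "presence"` is available since either convention is defensible.
Agreement is computed over patients only by default (controls can be
included via `roles`). The all-one-category table has chance agreement 1
and is returned as an explicit undefined state. Consensus requires
agreement on side, not merely on presence.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen as the
package's own working sizes: 15+15 subjects for pipeline runs (the scale
of the emulated study), 200 patients for the subgroup contrast, 30
phantoms for noisy-recovery checks, 10,000+10,000 draws for threshold
coverage, and 4,000 replicates for type-I calibration of the two-sample
tests. Key tolerances: noiseless recovery at 10⁻¹², stochastic checks at
3–4 SDs of their own sampling distribution. Seeds are fixed in specs;
child seeds are drawn below 2³¹.

## Known limitations

- The quadrant ROI includes non-olivary tissue by design (direct ION
  segmentation is avoided as poorly reproducible), so all effects are
  diluted; the dilution factor depends on the declared geometry.
- Bilateral HOD is invisible to a left/right asymmetry index and is out
  of scope.
- The threshold model assumes an approximately normal control
  distribution; heavy-tailed controls would inflate false-positive
  rates, which is why the coverage property is asserted under the normal
  model only.
- Simulated raters bound what the reliability analysis can show: kappa
  values reflect the Bernoulli error model, not the texture of real
  reader disagreement.
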