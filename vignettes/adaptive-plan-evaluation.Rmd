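---
title: "Evaluating daily plan adaptation for prostate SBRT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating daily plan adaptation for prostate SBRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Ultra-hypofractionated prostate SBRT (40 Gy in 5 fractions, PACE-C-style
constraints) leaves little room for interfractional anatomical change: daily
bladder and rectal filling moves organ walls relative to the target, and the
prostate itself shifts and deforms between fractions. Image-guided
radiotherapy (IGRT) corrects position only; adaptive radiotherapy (ART)
strategies modify the plan itself, at increasing computational cost —
re-weighting of existing segments (ART1), additional segment re-shaping
(ART2), or full re-optimization (ART3).

`adaptrt` provides a reusable, fully synthetic pipeline for comparing such
strategies: a pelvic cohort generator with per-fraction deformation, a
parametric dose engine producing archetypal dose distributions for each
strategy, a voxel-exact DVH/constraint engine with the PACE-C criterion
table, the relative penalty score

$$S = \sum_n \begin{cases} \left|\frac{M_n - C_n}{C_n}\right| \times 100 &
\text{if criterion } n \text{ is exceeded} \\ 0 & \text{else} \end{cases}$$

and the cohort statistics built on it (penalty aggregation per criterion and
per patient, paired t-tests, overlap–penalty correlation, overlap-volume
adaptation triggers). It also ships a plain-text transcription of the
published cohort penalty table and recomputes its totals, cohort means and
reduction percentages exactly (`verify_printed_table()`); the underlying
patient images are not public, so patient-level dosimetry is emulated, never
reproduced.

## The synthetic cohort

Each patient is a parametric phantom: the prostate an ellipsoid with volume
drawn lognormally to reproduce a 65.3 ± 26.3 cc spread; two
posterior-superior seminal-vesicle lobes whose proximal 1 cm joins the CTV;
the bladder a sphere superior-anterior of the prostate (its neck overlapping
the prostatic base); the rectum a capsule (cylinder with hemispheric caps)
posterior of it. The PTV adds an isotropic 4 mm margin via an exact
Euclidean-distance expansion. Masks use the voxel-centre-inside rule on a
2 mm isotropic lattice — simple and checkable against closed-form volumes
(ellipsoid voxelization agrees with $\tfrac{4}{3}\pi abc$ to < 3% at 2 mm).

Per fraction, three things change:

* **rigid prostate shift**, Gaussian with SD (1.5, 3.5, 3) mm (L-R, A-P,
  I-S), capped at 10 mm;
* **organ filling**: bladder and rectum radii scale with the cube root of a
  lognormal fill factor clamped to [0.6, 1.6] (so bladder volume scales
  linearly with the factor);
* **target deformation**: the prostate semi-axes scale per-axis lognormally
  (sdlog 0.06/0.08/0.06, clamped to [0.78, 1.3]), giving daily surface
  excursions of up to ~6 mm, the magnitude reported clinically.

The third item extends the minimal "rigid shift + filling" deformation
model. It is necessary: with a rigid target and exact centroid registration,
an unadapted (IGRT) dose distribution is geometrically indistinguishable
from a freshly conformed one, and no ordering between strategies can emerge.
Daily target deformation is precisely what plan adaptation responds to.

Registration between planning and daily CTV is translation-only by default
(centroid match); a principal-axes rotation estimate exists behind a flag
but is off because ellipsoidal phantoms under-constrain rotation (the
clinical workflow used 6 degrees of freedom — a documented simplification).

The whole cohort is a pure function of `(master_seed, cohort_params())`;
per-patient and per-fraction seeds are hashed from the master seed and the
indices.

## The dose engine

The clinical study used a commercial Monte Carlo treatment planning system;
`adaptrt` substitutes an explicit archetype:

$$D(x) = P \exp\!\left(-\frac{\max(0, d(x) - c)^2}{2\sigma^2}\right)
\cdot N(x)$$

with $d(x)$ the exact Euclidean distance to the PTV (0 inside), $\sigma$ the
penumbra scale, $c$ a conformity-degradation offset (how far the
prescription plateau leaks beyond the PTV), and $N$ a smooth multiplicative
noise field (white Gaussian noise smoothed at 5 mm correlation length,
standardized, exponentiated; mean 1, amplitude 2% — emulating Monte Carlo
statistical noise). The plateau $P$ equals the CTV prescription, 40 Gy.

Strategy differences are *entirely* parameter ordering:

| approach | $\sigma$ (mm) | $c$ (mm) | OAR sparing | rescaled |
|---|---|---|---|---|
| REFERENCE / IGRT | 4 | 2 | — | no |
| ART1 | 4 | 1 | — | yes |
| ART2 | 3.5 | 0.5 | — | yes |
| ART3 | 3 | 0 | depth 0.3 beyond a 3 mm interface shell | yes |

The penumbra ordering (reference = ART1 ≥ ART2 ≥ ART3) encodes that
re-optimization sharpens dose gradients. The conformity ordering encodes
that a plan copied unaltered onto a *deformed* daily anatomy has degraded
effective conformity around the daily target, which segment morphing
restores progressively. ART3's interface sparing multiplies the dose inside
each OAR by $1 - 0.3\,w(d)$ with $w = \mathrm{clamp}((d - m)/m, 0, 1)$,
$m = 3$ mm: untouched within the interface shell (where target coverage
forbids carving), saturating at $2m$. IGRT transforms the reference dose
rigidly (trilinear interpolation, 0 Gy outside); ART plans are rescaled so
that $D_{95\%}(\mathrm{CTV}) = 40$ Gy exactly (to $10^{-6}$ Gy), as the
protocol prescribes; REFERENCE and IGRT are never rescaled.

Setting $P$ to 40 Gy exactly makes all archetypes produce identical CTV
DVHs under zero noise and zero deformation (rescale factor 1) — a designed
invariant. Its knife-edge consequence: with noise on, an unrescaled plan
has $V_{40\,\mathrm{Gy}}(\mathrm{CTV}) \approx 50\%$. This is the same
knife-edge that led the clinical analysis to exclude
$V_{40\,\mathrm{Gy}}(\mathrm{CTV})$ from all statistics and from $S$, and
this package excludes it identically.

## Metrics and scoring

$V_{x\,\mathrm{Gy}}$ and $D_{x\%}$ are computed voxel-exactly from the dose
array (the binned DVH exists only for curves and point-wise mean ± SD
statistics), removing bin-width sensitivity from the penalty score. Default
bins are 0.05 Gy up to 50 Gy (0.25 Gy for the accumulated cohort curves).
$D_{x\%}$ uses the $(100-x)\%$ quantile with linear interpolation between
order statistics (the clinical system's convention is unpublished; exact
numeric parity with it is not a goal). A constraint value exactly equal to
its bound is "not exceeded" — the formula's "if exceeded" is read strictly.
Minor-variation tiers exist only where the protocol defines them (target
coverage 90–94.9%); minor variations are penalized like any other
exceedance, they only tier differently.

The criterion table is configuration (`pace_criteria()`, a CSV shipped with
the package): the full constraint set including bowel, femoral heads and
penile bulb for tier reporting, with `in_penalty = TRUE` for the four
scored criteria ($V_{36.25}$(PTV), $D_{98\%}$(PTV), $V_{37}$(bladder),
$V_{36}$(rectum)).

Statistics follow the clinical analysis: paired Student t-tests on the
per-plan metric values (raw p-values, no multiplicity correction;
zero-variance differences report p = 1 with a flag), Pearson correlation
between PTV–OAR overlap volumes and the per-plan total $S$, and the trigger
ratio: among plans with $V_{37}$(bladder) > 9 cc or $V_{36}$(rectum)
> 1.5 cc, the fraction whose overlap exceeds the cohort-mean overlap
(pooled over all fraction anatomies — overlaps are anatomy properties,
identical across strategies). Where a single "overlap vs S" number is
needed, the package uses the summed bladder + rectum overlap; per-organ
correlations are always reported alongside.

## What the defaults were calibrated to — and what a green test means

The generator's free magnitudes (organ gaps, fill spread, deformation
spread) were fixed once against three stated design goals: (i) reference
plans meet the scored constraints on their own planning anatomy (typically
— about 80% of synthetic patients have a perfectly compliant reference
plan, the rest carry small penalties, as in the published reference
column); (ii) daily filling and deformation produce occasional constraint
violations, not wholesale failure; (iii) the cohort-level ordering
S(IGRT) > S(ART1), S(IGRT) > S(ART2), min(ART1, ART2) > S(ART3) emerges
from the archetype parameter ordering at the default 32 × 5 cohort.

A green cohort test therefore establishes that the *pipeline* reproduces
the qualitative structure of the clinical result under the stated model —
not that the synthetic numbers match patient data. Known divergences from
the clinical cohort, left as is:

* Synthetic IGRT degradation is OAR-dominated; PTV-coverage violations are
  rare because a 4 mm margin plus a 4 mm penumbra forgives the deformations
  the phantom produces. The clinical IGRT arm showed substantial coverage
  penalties, driven by registration residuals and anatomy this phantom does
  not model (no fiducial-free soft-tissue matching errors, no rotations).
* Mean overlap volumes (≈ 4.9 cc bladder, ≈ 0.3 cc rectum at defaults) are
  smaller than the clinical 7.2/2.6 cc: with a plateau archetype, any
  PTV–rectum overlap receives full prescription, so a clinically-sized
  overlap would make even perfect plans violate $V_{36}$(rectum) < 2 cc.
  Real optimizers under-dose inside the overlap; the archetype cannot.
* Exact penalty magnitudes and reduction percentages of the synthetic run
  (≈ 21/46/76% at seed 1) are smaller than the printed 79.2/75.7/93.2%.
  The printed values are verified exactly — but from the shipped printed
  table, the only faithful source.

## Numerical choices

Distance maps use an exact Euclidean distance transform (Felzenszwalb's
separable parabolic algorithm, anisotropic spacing, C++). Dose resampling
is trilinear with zero-padding. Margin expansion thresholds the distance
map, so `expand_margin(mask, 0)` is the identity and the expansion is
monotone. The per-fraction sub-seeds stay below 2^31. Degenerate inputs
fail loudly: empty masks, non-positive constraint bounds, ragged evaluation
grids, organs escaping the lattice.

## Scope

No DICOM-RT, no image synthesis, no deformable registration, no MLC/fluence
modelling, no delivery-time results. Volumes are exchanged as NRRD
(raw/ascii) plus JSON manifests; tables as CSV.
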