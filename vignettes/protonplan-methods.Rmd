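---
title: "Methods: proton plan uncertainty analysis on synthetic base-of-skull phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proton plan uncertainty analysis on synthetic base-of-skull phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonplan)
```

## Scope and intent

`protonplan` models the two uncertainty axes that dominate intensity
modulated proton therapy (IMPT) of base-of-skull tumors and pediatric
craniopharyngioma: *physical* setup/range errors, analyzed with a
twelve-scenario worst-case recomputation, and *biological* uncertainty in
the proton relative biological effectiveness (RBE), analyzed by replacing
the clinical constant RBE of 1.1 with the McNamara phenomenological model
driven by dose-averaged linear energy transfer (LET~d~). A rotational
photon-arc surrogate provides the modality comparator, and a seeded
synthetic phantom generator stands in for a patient cohort, so every
analysis in the package is reproducible from a single integer seed.

Real clinical plans for this site are produced by inverse "minimax"
robust optimization inside a commercial treatment planning system and are
not reproducible from published information. The package instead
forward-computes plans with analytic spread-out Bragg peak (SOBP) weights.
All comparisons it produces are therefore *orderings and trends* on
synthetic geometry, not clinical dosimetry.

## Synthetic phantoms

Each phantom is a voxel grid (water-equivalent density, 1.0 inside the
external contour) carrying seven structure masks: `CTV`, `brainstem`,
`optic_chiasm`, `optic_nerve_L/R`, `brain`, `external`. The topology
mirrors the treatment site: the clinical target volume (CTV) sits at the
base of the skull, the optic chiasm overlaps the CTV (default 70% of its
volume inside the target, reflecting that the majority of the chiasm
typically lies within the target for these cases), and the brainstem sits
directly posterior, abutting the CTV by default.

Structures are analytic solids — ellipsoids for CTV, chiasm, brain and
external; a vertical elliptic cylinder for the brainstem; capsule segments
for the optic nerves — rasterized by the voxel-center-inside rule. The
CTV and chiasm are rasterized to an *exact voxel count* (the `n` voxels
with smallest ellipsoid norm), which pins their volumes to the request
within half a voxel at any resolution. The chiasm center is found by
bisection along an anterosuperior axis until the requested CTV overlap
holds to within one voxel.

Cohort generation jitters the base geometry per phantom: CTV volume is
log-normal around 30 cm^3 (adult) / 18 cm^3 (pediatric) with sd 0.15 on
the log scale; chiasm overlap is normal (mean 0.7, sd 0.08, clamped to
[0.45, 0.95]); half the cohort has the brainstem abutting the CTV and the
rest a uniform 0–1.5 mm gap; the head scale varies ±4%. No published CTV
volumes exist for the cohort, so these jitter ranges are a modelling
choice of this package — plausible for the site, but not cohort-matched.
The default cohort is 6 adult + 4 pediatric phantoms on a 4 mm grid; a
2 mm default is used when building single phantoms.

What the generator deliberately does *not* emulate: tissue heterogeneity
(a bone-shell toggle exists but defaults to off, consistent with beam
directions chosen to avoid heterogeneous regions), anatomical shape
realism, and inter-patient variation in OAR topology. Passing tests on
this cohort therefore demonstrate correctness of the analysis machinery
and reproduction of directional claims, not performance on real anatomy.

## Proton dose and LET engine

Protons in water follow the power-law range–energy relation
$R = \alpha E^p$ with $\alpha = 0.0022$ cm·MeV^−p^ and $p = 1.77$, giving
the stopping power $S(r) = r^{1/p-1} / (p\,\alpha^{1/p})$ at residual
range $r$. End-of-range straggling is Gaussian with
$\sigma = 1.2\%$ of the range. The pristine depth-dose is
$D(z) = \mathrm{E}[S(R'-z)]$ and the dose-averaged LET is
$\mathrm{LET_d}(z) = \mathrm{E}[S^2]/\mathrm{E}[S]$, both expectations
over $R' \sim N(R, \sigma)$. The integrable singularities at $r = 0$ are
removed exactly by the substitutions $r = t^{p}$ and $r = t^{p/(2-p)}$,
so plain midpoint quadrature (400 nodes) is accurate; both curves depend
on depth only through the residual range, so one profile per field serves
all pullback peaks. LET~d~ is capped at 20 keV/µm in the falloff tail
where the dose vanishes and the ratio of expectations becomes
numerically extreme. Because the blurred depth-dose peaks about one
straggling width proximal to the *mean* range, the curve is
re-parameterized so that its dose maximum sits exactly at the requested
range — the quantity the rest of the engine reasons about.

SOBP weights are fitted by non-negative least squares against a unit
plateau on a fine depth grid. Pulled-back peaks share the absolute
straggling width of the deepest peak (energy degradation preserves the
field's spread); the default peak spacing is one straggling width, which
keeps the plateau ripple below 2% across the supported geometries. A
plateau that cannot reach 2% flatness raises an explicit warning rather
than passing silently.

Fields are parallel beams. Water-equivalent depth is the density-weighted
path from the external surface: closed-form for the uniform-density
analytic phantoms (ray–ellipsoid intersection), ray-stepping at
half-voxel resolution otherwise. The lateral fluence is a conformal
aperture: the CTV projection in the beam's eye view, dilated by the
aperture margin (default 6 mm) plus a half-voxel rasterization allowance,
then blurred with a Gaussian penumbra (default sigma 5 mm). The SOBP
range and modulation of each field are auto-fitted to the CTV depth
interval with distal/proximal margins of 3.5% of range + 1 mm, the
standard clinical range-uncertainty recipe. The total dose is normalized
so that the median CTV dose times 1.1 equals the prescription — plans are
"optimized" under the constant clinical RBE, with variable RBE applied
strictly post hoc, as in clinical practice.

The default beam arrangement is a 4-field star (two superior-lateral
fields at gantry 100°/260°, elevation +35°; two inferior-anterior-lateral
fields at 40°/320°, elevation −15°). The clinical angles for this site
are center-specific and not published in a reusable form; these defaults
reproduce the star *topology* — opposed oblique pairs crossing in the
target, with distal edges distributed around it — rather than any
specific machine configuration.

Per-voxel LET~d~ accumulates $\sum_i d_i L_i / \sum_i d_i$ over all
fields and pullback peaks. Voxels whose total dose falls below 0.5% of
the plan maximum are excluded from the LET map (set to zero and flagged),
matching the dose threshold used by the analytical LET script the
clinical workflow relies on.

## RBE models and fractionation conversion

The constant model multiplies physical dose by 1.1. The McNamara model
computes, per voxel,

$$\mathrm{RBE} = \frac{1}{2D_p}\left(\sqrt{(\alpha/\beta)_x^2 +
 4D_p(\alpha/\beta)_x\,\mathrm{RBE}_{max} +
 4D_p^2\,\mathrm{RBE}_{min}^2} - (\alpha/\beta)_x\right)$$

with $\mathrm{RBE}_{max} = p_0 + p_1\,\mathrm{LET_d}/(\alpha/\beta)_x$,
$\mathrm{RBE}_{min} = p_2 + p_3\sqrt{(\alpha/\beta)_x}\,\mathrm{LET_d}$
and the published fit constants $p_0 = 0.99064$, $p_1 = 0.35605$,
$p_2 = 1.1012$, $p_3 = -0.0038703$. Three numerical choices are ours and
documented here: $D_p$ is the physical dose per fraction, taken as total
voxel dose divided by the number of fractions (uniform fractionation
assumed); at $D_p = 0$ the analytic limit $\mathrm{RBE}_{max}$ is
returned; and $\mathrm{RBE}_{min}$ is floored at zero where the linear
LET term would drive it negative (at the 20 keV/µm LET cap this floor is
never reached for the tissues considered). Voxels excluded from the LET
map fall back to RBE 1.1. The default analysis uses matched
$(\alpha/\beta)_x$ for tumor and normal tissue at 2, 3 and 4 Gy, plus a
variant with a tumor $(\alpha/\beta)_x$ of 10 Gy for CTV-coverage
sensitivity.

Constraint transfer between fractionation schemes uses the isoeffective
biologically effective dose relation
$D_1 = D_2\,(1 + d_2/(\alpha/\beta)_x)/(1 + d_1/(\alpha/\beta)_x)$,
applied at load time to the shipped EQD2-style constraint table. That
table (`inst/extdata/eqd2_constraints_synthetic.csv`) is a *synthetic,
user-editable stand-in*: representative consensus-style limits for the
intracranial organs at risk, not a published table.

## Robustness analysis

The twelve scenarios are the full cross of the six single-axis 3 mm
isocenter shifts with ±3.5% water-equivalent range scaling. The exact
shift/range pairing used clinically is not published; any twelve-element
cross-pairing consistent with the stated counts is acceptable, and the
full cross is the natural choice. Each scenario is recomputed, never
interpolated: the beam geometry is rigidly translated and every field's
pullback ranges, modulation and straggling width are scaled together,
while SOBP weights and the dose normalization stay frozen at nominal so
errors change the delivered dose rather than being renormalized away.
Worst-case extraction is per metric (highest scenario value for OAR
metrics, lowest for CTV coverage), so different metrics may select
different scenarios. Scenario breach counting reports
breaches/(12 × phantoms).

## Photon-arc surrogate

The comparator is a single coplanar arc of 72 equispaced parallel beams
with apertures conformal to the PTV (CTV + 3 mm), exponential attenuation
at 0.05 cm^−1^ (6 MV-like; build-up ignored at phantom scale) and a 4 mm
penumbra, normalized to the median PTV dose. It generates the
characteristic rotational low-dose bath; it does not model multi-leaf
collimation, arc optimization, or the physician trade-offs of clinical
arc plans — any report comparing against it is surrogate-based by
construction, and the package labels it as such in grid metadata.

## Metrics

Cumulative DVHs use 0.05 Gy bins with linear interpolation; D~V~ and
V~D~ statistics are validated against voxel-sorting oracles to within one
bin width. Whether clinical D95 values derive from interpolated DVHs or
raw quantiles is generally unstated in the literature; this package
documents and tests linear interpolation. A D~0.1cc~ exactly at its limit
counts as a breach ("irradiated at or above the constraint");
maximum-dose rules breach at the limit, mean-dose rules strictly above
it. The brain-minus-CTV mask is formed by set difference at evaluation
time.

## Worked example

```{r example, eval = FALSE}
ph <- build_phantom(phantom_spec("adult", voxel_mm = 4, random_seed = 7))
plan <- plan_proton(ph)
rob <- robustness_analysis(plan, ph)
rob$worst

g2 <- rbe_weighted_dose(plan$dose, plan$letd, "mcnamara",
                        alpha_beta_x = 2, n_fractions = 39)
volume_at_dose(compute_dvh(g2, "brainstem", ph), 58)

st <- run_study(study_config(seed = 1))
glance(st)
plot_constraint_volume(st, "brainstem")
```

## Problem sizes and determinism

The default cohort analysis (10 phantoms, 4 mm grid, 4 fields, 12
scenarios each, three variable-RBE maps plus the photon arc) completes in
a couple of minutes on a single core; single-phantom engine tests use a
5 mm grid. These sizes were chosen as the smallest grids on which the
structure topology (a sub-cubic-centimeter chiasm, 0.1 cm^3 DVH
statistics) remains resolvable. All randomness — phantom jitter, cohort
composition — flows from explicit integer seeds; planning, scenario
recomputation and metric evaluation are fully deterministic, and the test
suite asserts bit-identical reruns.

## Known limitations

* Forward-computed plans cannot trade target coverage against OAR
  constraints the way inverse robust optimization does; in particular the
  in-target part of the chiasm receives the full target dose rather than
  being capped at its constraint.
* Parallel beams (no divergence), no nuclear halo, no heterogeneity
  corrections, no range shifters, no spot-by-spot scanning structure.
* The LET~d~ model is analytic; Monte Carlo LET distributions differ in
  the halo and at material interfaces.
* Systematic errors only: no random per-fraction error sampling, no
  intra-fraction motion, no anatomical change over the course.
* The photon surrogate is fixed-form; it under-represents what an
  optimized clinical arc plan can achieve for organ sparing.
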