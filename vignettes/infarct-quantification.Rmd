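---
title: "Quantifying myocardial infarct size on LGE images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myocardial infarct size on LGE images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Late gadolinium enhancement (LGE) cardiovascular MRI shows infarcted
myocardium as bright tissue against viable ("remote") wall. Infarct size —
usually expressed as a percentage of left-ventricular (LV) mass — is a
primary endpoint in cardioprotection trials, and a family of semi-automated
algorithms exists to delineate the enhanced region from LV contours alone or
with modest user input. These algorithms differ in how they pick an intensity
threshold, whether they model partial-volume effects, and whether they handle
microvascular obstruction (MVO, a hypointense core inside the infarct that
must be counted as infarct). Different choices yield systematically different
infarct sizes on identical images, so the quantification method is itself a
study variable.

`lgequant` implements nine quantifiers behind one interface, a synthetic
short-axis phantom with analytic ground truth to exercise them, and the
agreement statistics (modified Bland–Altman, limits of agreement, Lin's
concordance correlation coefficient) used to compare methods against a
reference.

## The quantifiers

All methods operate on a `SliceStack` (voxel intensities, in-plane spacing,
slice thickness, IR or PSIR signal convention) and a myocardial mask
rasterized from endocardial/epicardial polygons (voxel-center, even-odd
rule). Intensity comparisons are inclusive (`>=`), which makes
uniform-plateau inputs deterministic. Results are per-voxel weights in
$[0,1]$; infarct volume is $\sum_i w_i \, v_{\text{vox}}$, mass is volume
times density (1.05 g/mL by default), and the reported fraction is
$100 \times \text{mass}/\text{LV mass}$.

**n-SD from remote.** A user-drawn remote region of interest (ROI) gives
mean $\mu_r$ and sample SD $s_r$ (the $n-1$ denominator; configurable);
voxels inside the infarct ROI at or above $\mu_r + n\,s_r$ are infarct, with
$n \in \{2, 3, 5, 6\}$ as presets. If no infarct ROI was identified on any
slice, infarct size is zero by contract.

**FWHM.** The full-width-at-half-maximum threshold in the zero-anchored
(original) form is $\max/2$: it presumes a magnitude (IR) image whose viable
myocardium is nulled near zero, and the package refuses PSIR input on this
path. The remote-anchored form is $\mu_r + (\max - \mu_r)/2$, the midpoint
between the remote level and the maximum. Two variants locate the maximum:
`roi_max` (inside the infarct ROI — the variant used for comparisons here)
and `seed_grow` (multi-pass region growing from user seeds, re-thresholding
at half the current region maximum until stable).

Note a sign subtlety: with a *positive* remote mean (imperfect nulling), the
zero anchor $\max/2$ sits *below* the midpoint $(\max+\mu_r)/2$, so zero
anchoring over-segments. With a *negative* remote mean (PSIR), the
relationship reverses — $\max/2 > (\max+\mu_r)/2$ — so zero anchoring
*under*-segments relative to remote anchoring. The package exposes both
anchors (plus a `force_psir` override for studying the failure mode), and a
property test pins down this ordering.

**Otsu.** The threshold maximizing between-class variance over cuts placed
between sorted distinct values, ties resolved to the lowest threshold. It is
applied to pooled myocardial intensities and, by construction, always finds
a "bright class" — so it reports non-zero infarct even on infarct-free
myocardium. That failure mode is asserted in the tests.

**Manual.** A fixed threshold over the myocardium.

**FACT.** Fully automatic from LV contours (IR and PSIR): candidates at
$\mu_r + 2 s_r$ above the automatically detected remote; feature filters on
connected components — mass $\ge$ 0.1 g (strictly smaller removed), minimum
endocardial distance $\le$ 2 mm, component mean $\ge$ 50 % of the pooled
candidate mean; a remote-anchored FWHM threshold inside the survivors; the
filters re-applied (the pooled mean is recomputed on the post-FWHM
candidates); and MVO inclusion. Binary weights.

**Heiberg-08.** IR only. Each slice is split into five equal angular sectors
around the mask centroid (anchored at the +x image axis, counter-clockwise;
offset configurable); the midmural half (transmural depth in $[0.25,
0.75]$) of the lowest-mean sector is the remote sample, pooled over slices.
Support at $\mu_r + 1.8\,s_r$, artifact cleanup, removal of isolated
volumes below 1.5 cm³, MVO inclusion, then linear weights
$w = \mathrm{clip}\!\left((I - \mu_r)/(I_{\max} - \mu_r),\, 0, 1\right)$
with $I_{\max}$ the per-stack myocardial maximum. Because the anchor is the
*maximum*, measurement noise inflates $I_{\max}$ and deflates every weight:
the method is intrinsically noise-sensitive in its weighted size even when
its support is stable. MVO voxels get weight 1.

**EWA.** Fully automatic, IR and PSIR: surface coil intensity correction, a
two-component Gaussian mixture fitted to the myocardial intensities by EM,
posterior classification (infarct if posterior > 0.5), the same cleanup and
small-component removal (0.1 g), MVO inclusion, and linear weights between
the two fitted class means. If the fitted classes are not separated the
method reports zero with a warning ("no infarct evidence").

### Shared machinery

*Connected components* are 6-connected (4-connected in-plane plus face
adjacency across slices) — conservative against diagonal noise chains; the
rule is centralizable because the original implementations do not document
theirs.

*Artifact cleanup* stands in for the level-set artifact-exclusion step of
the published pipelines, which is not described in enough detail to
reproduce: retain the largest component plus components above a mass floor,
then one in-plane morphological opening–closing pass (4-neighbor
structuring element), constrained to the mask. It preserves the function —
discard discontiguous specks, smooth ragged borders — with a deterministic,
testable substitute.

*MVO inclusion* fills non-infarct myocardial components whose in-plane
boundary touches only infarct voxels and/or the endocardial border; anything
reaching the epicardial border is left alone. The probe uses the *enhanced*
support (voxels that will carry positive weight): at zero remote SD a
threshold of $\mu_r$ admits weight-zero remote voxels into the raw support,
and probing with those would "fill" the dark partial-volume rim at the
endocardium.

*Coil correction* estimates a smooth multiplicative gain field as a
low-order polynomial (default linear in-plane plus a linear slice term) fit
to the log-intensities over the mask. Robustness matters more than
flexibility here: the enhanced wedge is a large, spatially coherent outlier,
and two safeguards keep it out of the field. First, initial residuals are
taken against a flat median field and the robust scale is *frozen* at that
point — re-estimating the scale after each fit lets the field creep into the
infarct sector, absorbing true enhancement as gain. Second, the scale is
estimated from the non-positive residual side only (enhancement contaminates
only the positive side; the negative side is remote noise plus the thin dark
partial-volume rim), with Tukey bisquare weights cut at $3 s_0$. Degrees
above 1 re-enable sector extrapolation and are deliberately not the default.
The corrected stack preserves the myocardial median; PSIR input is shifted
positive before the log fit and the shift removed afterwards.

## The phantom

`phantom_spec()` / `generate_phantom()` build an annular LV wall over
parallel short-axis slices with a bright infarct wedge:

| parameter | default | meaning |
|---|---|---|
| grid, spacing | 64 px, 1.5×1.5 mm | in-plane sampling |
| slices, thickness | 8, 8 mm | no slice gap |
| endo/epi radius | 20 / 30 mm | may taper per slice |
| extent, transmurality | 72°, 1.0 | wedge angle and depth from endocardium |
| morphology | solid | or patchy: seeded insular disks inside the wedge |
| remote / infarct mean | 20 / 100 (IR) | PSIR remote defaults to −0.2 × infarct mean |
| remote / infarct SD | 0 / 0 | measurement-noise scales per class |
| MVO fraction | 0 | subendocardial hypointense core inside the wedge |
| edema width | 0 mm | intermediate-intensity halo around the wedge |
| coil amplitude | 0 | total relative span of a linear multiplicative ramp |

Sub-voxel structure is handled by 4× in-plane supersampling: each voxel's
intensity is the area-weighted mixture of the class means it straddles, the
noise scale mixes the same way, and the same subsamples give the
ground-truth weights. Noise is Rician for IR (magnitude of a complex
Gaussian perturbation, so intensities stay non-negative) and Gaussian for
PSIR. The intensity defaults encode TI nulling: remote myocardium sits near
zero relative to the enhanced infarct (5:1 contrast), which is the
assumption the zero-anchored FWHM exploits.

**Truth-weight convention.** LV mass counts a voxel fully when its center is
inside the wall, so the ground-truth weight of a voxel is defined as the
infarct share of its *wall* content (infarct subpoints / wall subpoints),
not of its whole area. With whole-area weights, voxels straddling the
endo/epicardial arcs would lose infarct area that the binary LV-mass
denominator still counts, biasing the noise-free 72° wedge to ~19.2 %
instead of the analytic 20 %. With the wall-share convention the noise-free
truth lands within 0.5 %-pts of the analytic value on a 64×64 grid, and is
exactly linear in the wedge extent.

The generator also draws the ROIs a human would provide: the infarct ROI as
the truth support (optionally dilated by a margin in mm, cropped to the
mask; slices without support emit no ROI, which exercises the zero-infarct
contract), and the remote ROI as a semi-lunar annular sector diametrically
opposite the wedge with a 20° safety margin (refused if the infarct spans
more than 300°). The blood pool defaults to background intensity — the
phantom models wall classes; a bright cavity can be switched on to study
partial-volume effects at the endocardial border, but it is not part of the
reference conditions.

Determinism: one seed drives patch placement and noise; identical seeds give
bit-identical cases (asserted down to report bytes in the tests).

**What the phantom does not emulate.** No MRI physics (TI/relaxation,
surface-coil geometry beyond a linear ramp), no motion or ghosting, no
through-plane partial volume, no trabeculation or papillary anatomy, no
registration error between in-vivo and reference geometry, and its noise is
stationary per class. Passing tests on phantoms therefore validate the
*algorithmic* contracts — thresholds, filters, weighting, bookkeeping — not
clinical accuracy on real data, where contours are uncertain and enhancement
is heterogeneous.

## Agreement statistics

`bland_altman(method, reference)` reports the bias (mean of method −
reference), SD of differences ($n-1$), limits of agreement bias ± 1.96 SD,
a two-sided one-sample t-test of the differences (a zero-variance
difference vector short-circuits to p = 1 when the bias is 0, else p = 0),
Lin's concordance
$\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ with
population-denominator moments (Lin's original; $n-1$ by option), and the
least-squares line of method on reference. The "modified" Bland–Altman plot
puts the reference (not the pair mean) on the x-axis, appropriate when one
axis is a gold standard. `compare_all()` runs a method panel over phantom
cases and tabulates one row per method, flagging method/convention
mismatches (Heiberg-08 and zero-anchored FWHM on PSIR) as "not designed"
rather than running them.

## Numerical choices and edge cases

- Polygon inclusion: even-odd rule at voxel centers; contour coordinates in
  mm with pixel (0,0) centered at the slice-plane origin. Simplicity and
  endo-inside-epi nesting are validated (vertices exactly on the epicardial
  boundary are tolerated so a zero-width wall rasterizes to an empty mask).
- Midmural band: transmural depth $d_\text{endo}/(d_\text{endo} +
  d_\text{epi})$ from exact point-to-polygon distances; walls too thin for
  the $[0.25, 0.75]$ window fall back to the mid-most voxel layer so the
  band is never empty on a non-empty slice.
- EM: log-space E-step with underflow fallback to the nearer mean, SD floor
  $10^{-3}$ of the value range, ordering enforced by relabeling, convergence
  on log-likelihood gain < $10^{-8}$ (monotonicity is asserted per
  iteration in the tests).
- EWA separation rule: classes count as separated when the mean gap exceeds
  4 × the *smaller* class SD. The smaller SD is the informative one — the
  infarct-class SD is routinely inflated by partial-volume voxels, and a
  sum-based rule wrongly zeroes genuine infarcts.
- Thresholds pool remote/ROI statistics over the whole stack by default
  (per-slice mode by option); the FWHM maximum is likewise per stack or per
  slice.
- Small-component cutoffs are strict: a component exactly at 0.1 g (or
  1.5 cm³) is retained.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
default 64×64 phantoms with 8 slices for accuracy checks, 2–4 slices for
replicated studies (20 noisy cases for the bias-ordering and agreement
runs), 100 samples of up to 2000 values for the Otsu/exhaustive-search
comparison, and 20 seeded draws of n = 10 000 for EM parameter recovery.
These sizes were chosen so each property is measured well away from its
tolerance while a full run stays interactive.

## Known limitations

- The level-set artifact exclusion of the published FACT/Heiberg-08/EWA
  pipelines is approximated by the component/morphology cleanup described
  above; exact reproduction would require details not in the public record.
- FACT's remote region is not defined in its public description when only
  LV contours are given; the package reuses the sector-based automatic
  remote (the Heiberg-08 rule) for it.
- Heiberg-08's weighted size inherits the noise sensitivity of its
  maximum-intensity anchor (see above).
- The EWA weighting is linear between fitted class means; a
  posterior-probability weighting is an equally defensible reading of the
  published description and would differ on wide rims.
- 2D contours only; no DICOM; no long-axis or cine data.
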