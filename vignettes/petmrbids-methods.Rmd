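---
title: "Curation and quality control of preclinical hybrid PET/MR data with petmrbids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and quality control of preclinical hybrid PET/MR data with petmrbids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Retrospective and preclinical PET/MR studies — nonhuman-primate imaging in
particular — are hard to share. Raw data arrive as DICOM trees whose folder
organization differs between sites, whose headers are frequently incomplete
(echo times stripped by anonymizers, missing dose information, absent
gradient tables), and whose quality varies across acquisition campaigns and
scanner software versions. `petmrbids` addresses the two halves of that
problem:

1. **Curation**: a config-driven DICOM-to-BIDS converter that assembles
   multi-dimensional volumes (multi-echo, dynamic), reorients them to a
   uniform axis code, and resolves every required sidecar key through an
   auditable precedence chain that can compensate missing tags.
2. **Quality control**: an automated metric battery — Otsu-VOI SNR, CNR and
   median intensity for images, the pseudo noise-equivalent count rate
   (PNECR) for dynamic PET counting statistics — plus cohort-level
   availability and distribution reports and a robust outlier flag.

Because real preclinical cohorts cannot ship inside a package, a third
component generates fully synthetic DICOM cohorts with known ground truth, so
that every stage of the pipeline is testable end to end.

## Volume assembly and orientation

DICOM slices are grouped into series by folder and SeriesInstanceUID, then
ordered by the projection of `ImagePositionPatient` onto the slice normal
(`InstanceNumber` is the fallback; ties are an error, never a guess). The
echo axis is keyed on distinct `EchoTime` values and the frame axis on
temporal position (or one multi-slice file per frame); a series with both
gets a five-dimensional stack. The voxel-to-world affine is built in the
NIfTI RAS+ convention from the orientation, position and spacing tags.

Reorientation is a pure permutation/flip of the spatial axes: the target is a
three-letter axis code (`RPI`, `RSA`, ...), each letter naming the anatomical
direction along which the voxel index grows. The affine is updated so the
world coordinates of every voxel are preserved, which makes the operation
exactly invertible and compositional — properties the test suite checks by
voxel-level equality. Oblique acquisitions are common in large-animal
imaging; an affine whose worst axis deviation is at or below 20° is snapped
to the nearest code silently, beyond that a warning flags the volume for
manual review. The 20° default errs on the side of converting (preclinical
head coils rarely exceed it), and the snap never resamples — voxels are only
permuted, never interpolated.

## Sidecar resolution

Every sequence the overview config selects declares its required sidecar
keys. Each key resolves through a fixed precedence:

1. **dose config** for the PET dose keys (`TracerName`,
   `InjectedRadioactivity` in MBq, `InjectedMass` in nmol,
   `SpecificRadioactivity` in GBq/µmol) — these are measured at the bench,
   not by the scanner, so they outrank header values;
2. **DICOM via the tag map**, with millisecond-to-second conversion for
   `EchoTime` and `RepetitionTime` (sidecars store seconds);
3. **overview fallback values** for tags the headers lost.

The source of every key is recorded (`dose_config` / `dicom` / `fallback`),
so a converted dataset is fully auditable. An unresolvable required key stops
the conversion with a named error; silence is never an option. Dynamic PET
frame timing comes from a frame-schedule config string such as
`"8x4;4x6;6x10;8x20"` (8 frames of 4 s, then 4 of 6 s, 6 of 10 s, 8 of
20 s): starts are cumulative from zero, and when a declared frame count
disagrees with the block arithmetic the expansion trusts the arithmetic and
emits a validation warning rather than guessing which number was intended.

## The quality metrics

All image metrics derive from a single segmentation of each acquisition.
The *reference volume* is the 3-D (echo, frame) sub-volume with the highest
mean intensity — "highest mean" rather than "highest maximum" because a
single hot voxel should not select the reference. An Otsu threshold computed
on that volume splits the stack into a volume of interest (VOI, tissue) and
background (noise); the same mask pair is then applied to every volume of the
stack, while the noise statistic is recomputed per volume.

$$\mathrm{SNR} = \frac{\mu_\mathrm{VOI}}{\sigma_\mathrm{noise}}, \qquad
  \mathrm{CNR} = \frac{\max_\mathrm{VOI} - \min_\mathrm{VOI}}{\sigma_\mathrm{noise}}, \qquad
  \text{median intensity} = \mathrm{median}_\mathrm{VOI}$$

with $\sigma_\mathrm{noise}$ the sample standard deviation (n − 1) of the
background voxels. CNR uses the literal max and min — no percentile
clipping — so it is sensitive to single extreme voxels by design; robust
variants are deliberately out of scope. A noiseless background raises an
error instead of returning infinity.

Composite acquisitions reduce to scalars by fixed rules: dynamic series
average the per-frame metrics over frames; multi-echo series average the
median intensity across echoes but take SNR and CNR from the first echo
only, where SNR is maximal; a static volume is the degenerate case of both
(the suite checks the 1-frame, 1-echo path equals the static path exactly).

The Otsu implementation works on a 256-bin equal-width histogram between the
observed minimum and maximum, maximizing the between-class variance
$w_0 w_1 (\mu_0 - \mu_1)^2$ over all cut points; ties resolve to the lowest
threshold. The returned threshold is the upper edge of the last background
bin, so `x >= threshold` is the foreground rule. Note that when the two
intensity classes are separated by a run of empty bins the maximizer is a
plateau and any cut inside the valley is equally valid — the lowest-threshold
tie-break makes the choice deterministic, but comparisons with other
implementations are only meaningful up to the plateau width.

For dynamic PET counting statistics, each frame's total prompts $P$ and
randoms $D$ give

$$\mathrm{PNECR} = \frac{(P - D)^2}{P}$$

with $P = 0$ defined as 0 and $D > P$ an error. Because the totals scale
with frame duration, the per-frame value divided by the duration (a rate in
counts/s) is what the curve and its maximum report — that makes curves
comparable across schedules with 4 s and 300 s frames; the undivided total is
kept alongside since the formula is defined on totals. Log-scale exports drop
non-positive frames and report how many were dropped.

## Outlier flagging

Within each sequence group, an acquisition is flagged when its metric
deviates from the group median by more than 3 scaled median absolute
deviations (consistency constant 1.4826) *and* by at least 5% of the group
median. The MAD criterion alone degenerates on near-constant groups: when a
sequence is acquired identically across a cohort, the MAD shrinks to the
sampling noise of the metric estimate and a 0.5% fluctuation can exceed
three of them. The relative floor encodes that a deviation must also be
practically relevant before it is worth a reviewer's attention; 5% is well
below any acquisition-parameter change worth catching (the scenarios this
rule targets shift SNR by tens of percent) and well above estimator noise at
the VOI sizes involved. Both cut-offs are parameters; setting the floor to 0
restores the pure MAD rule. This flagging rule is a deliberate
formalization of what is usually done by visual inspection, and flags are a
review queue, not a verdict. Groups smaller than 4 are not flagged at all.

## The synthetic cohort generator

`make_cohort()` emulates a multi-session preclinical study: per session a
T1w, a T2w, a three-echo T2*w, a 7-volume diffusion series and a dynamic PET
acquisition with a per-frame prompts/randoms table, written as classic
DICOM, plus the three conversion configs, a participants table and a
manifest of everything planted. Defaults follow the study conditions the
toolkit targets: 20 subjects, two test-retest subjects, a 26-frame
water-tracer schedule (8×4 s, 4×6 s, 6×10 s, 8×20 s), injected
radioactivity drawn around 255 ± 15 MBq, acquisition years cycling
2016–2019, and an age composition of 5/6/7 years in 4/12/4 proportion.

The phantom is an ellipsoid of tissue mean µ over a zero-mean background,
with additive Gaussian noise of SD σ everywhere and intensities quantized to
integers — the quantized array is the ground truth, so DICOM and NIfTI round
trips can be checked bit-exactly (signed values ride on a rescale intercept
in the unsigned 16-bit pixel payload). The default grid is 64×64×32 at 2 mm
isotropic: a desk-scale stand-in for a clinical 256×256×127 matrix that
keeps a full 20-subject loop within a few minutes on one CPU while still
providing the ≥10⁴ background voxels the SNR-recovery tolerance assumes.
Multi-echo tissue decays as $e^{-TE/T_2^*}$; dynamic PET follows a
gamma-variate time–activity curve (peak amplitude at $t_0 + \alpha\beta$),
frame intensities are the curve averaged over each frame, prompts are
Poisson on the true-coincidence integral plus a randoms floor, and randoms
Poisson on the floor alone.

What the generator does *not* emulate — and what green tests therefore do
not show about real data: anatomy (no atlas rendering), Rician magnitude
statistics at low SNR (the additive-Gaussian approximation is documented and
only holds at the SNR levels generated), scanner physics (no scatter,
attenuation, dead time or decay correction), and oblique acquisitions beyond
the synthetic rotation used in tests. Cohort-level quality distributions of
a real animal cohort (scanner software effects, injection-timing
variability) are represented only by the planted-outlier mechanism.

## Numerical and design choices

* σ of the noise is always the sample SD (n − 1); the participants summary
  uses the same convention, which is what reproduces the reference age SD of
  0.65 from counts 4/12/4 at ages 5/6/7 (population SD does not).
* Slice ordering prefers geometry over instance numbers; two slices at the
  same spatial position abort assembly.
* Whether background noise should be measured on the reference volume only
  or per volume is underdetermined; it is computed per volume (masks fixed,
  statistics per volume), so a frame with genuinely higher noise shows it.
* PET dose values outrank DICOM headers because they are external bench
  measurements; this also means a wrong doses file wins silently — the
  provenance record is the audit trail for that risk.
* Determinism: sidecar keys are serialized in sorted order, generator trees
  are byte-identical for identical seeds, and every stochastic test fixes
  its seed.
* Problem sizes in the shipped tests (16×16×8 unit-test phantoms, 64×64×32
  acceptance phantoms, one 20-subject full loop) were chosen as the smallest
  sizes at which the statistical tolerances are comfortably met.

## Known limitations

Only the explicit-VR little-endian transfer syntax is read (anything else is
rejected loudly, never mis-parsed); enhanced multi-frame DICOM is supported
read-only and per-frame private functional groups are not parsed. The BIDS
writer targets the common anat/dwi/perf/pet layouts; it does not cover
events, physiological recordings or derivatives. The structural validator is
a rule-based checker of naming, placement and required files — it is not a
replacement for the full BIDS validator.
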