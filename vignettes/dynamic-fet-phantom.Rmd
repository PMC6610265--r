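---
title: "Methods: dynamic FET-PET evaluation and the attenuation-bias phantom"
author: "dynFET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic FET-PET evaluation and the attenuation-bias phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: the model each
module implements, the assumptions behind it, the parameters that matter,
and the places where the design was genuinely open and a choice had to be
made. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The evaluation pipeline

A dynamic [18F]FET acquisition is reconstructed into eight frames (2 x 2,
4 x 4, 2 x 10 minutes; `standardSchedule()`), with injection at
acquisition start. All voxel values are standardised uptake values (SUV),
treated as dimensionless intensities. The pipeline is:

1. **Late summed image.** A duration-weighted mean over the last 20
   minutes. Two numerical choices matter. First, the clinical convention
   quotes the window as "21–40 min", which is not a frame boundary;
   windows are therefore *snapped to the nearest frame boundary* (21 to
   20, 31 to 30) and the decision is logged — frames are the atomic unit
   of reconstructed data and sub-frame windows have no data behind them.
   Second, the "summed" image is computed as a duration-weighted *mean*
   rather than a raw sum: SUV is an intensive quantity, the mean keeps
   SUV units, and every relative threshold (90% of maximum) is invariant
   to the distinction anyway.

2. **Delineation.** Five region definitions, all on the summed image:

   | definition | rule | dimensionality |
   |---|---|---|
   | ROI90 | grow at >= 0.90 x in-tumour max | single axial slice |
   | VOI90 | same, 3D | volume |
   | ROI_TBR | grow at >= 1.6 x contralateral background | single slice |
   | VOI_TBR | same, 3D | volume |
   | VOI_FIX | sphere, 15.6 mm diameter (~2 mL), on the max | volume |

   plus reader-style 1-cm spheres placed at a fixed world position
   (`SPHERE_MANUAL`). The background is the mean over a 2-cm-diameter
   sphere on unaffected contralateral brain. Thresholds are inclusive
   (">= "), matching the "equal or greater" convention. Region growing
   uses 26-connectivity in 3D and 8-connectivity in-slice — the common
   clinical choice — and both are configurable
   (`segmentationConfig()`). The maximum search is restricted to a
   user-supplied tumour hint when one is given (readers select lesions
   visually); ties are broken by the lexicographically smallest (i, j, k)
   index so results are deterministic. Sphere membership is by voxel
   *centre* inclusion with no partial volumes: deterministic, and
   consistent with binary mask semantics.

3. **Plausibility.** A threshold that is too low floods the region into
   extracerebral tissue. "Too low for a meaningful segmentation" is
   operationalised as: volume above 50 mL, or more than 20% of the
   region's voxels outside a supplied brain mask. Both numbers are
   package choices (the clinical literature gives only the qualitative
   rule), are configurable, and every exclusion is logged with the lesion
   id.

4. **Kinetics.** The TAC pairs each frame's mean regional SUV with the
   frame's end time. TTP is the end time of the *earliest* frame
   attaining the maximum. TBR is the regional mean in the frame covering
   30–40 min divided by the background.

5. **Categorisation.** Two published schemes. The two-class scheme:
   DECREASING iff the peak is early (TTP <= 20 min, inclusive — "within
   20 min") *and* the curve then falls by more than a descent fraction
   from peak to last frame; everything else is INCREASING, since the
   early-peak-with-descent shape is that scheme's only non-increasing
   class. The three-class scheme adds PLATEAU between them; INCREASING
   requires the maximum in the final frame, or a late (> 20 min) maximum
   with the last value within a small tolerance of it and a rising tail.

   The verbal rules ("constantly increasing", "slight descent",
   "continuous descent") are not quantified in the clinical literature,
   so the package fixes: `descentFraction = 0.10` (a >= 10% peak-to-end
   drop counts as a true descent, consistent with common FET-PET
   practice) and `increaseTolerance = 0.025`. Both live in
   `classifierConfig()` and are logged when they matter. One shape has
   no class in the published three-class list — a late peak followed by
   a *strong* descent. It is reported as PLATEAU with a `lateDescent`
   flag raised on the metrics record, rather than silently absorbed.

### A frame-resolution limit of the three-class scheme

With 10-minute late frames, a curve peaking after ~29 minutes has its
frame-averaged maximum in the *final* frame: at TAC level it is
indistinguishable from a constantly increasing curve, and the scheme's own
definition then makes it INCREASING. This is a property of the frame
schedule, not of any particular classifier, and it bounds the plateau
peak times the package's recovery experiments sample (`tp` in [22, 29]
minutes). Peaks later than that are recoverable only with finer late
framing.

## The phantom

`phantomSpec()` declares a scene: an ellipsoidal brain, spherical lesions,
a z-aligned vessel cylinder, a scalp shell. Each structure carries one
analytic kinetic model:

- increasing: $C(t) = A\,(1 - e^{-t/\tau})$;
- gamma variate: $C(t) = A\,(t/t_p)^{\alpha} e^{\alpha (1 - t/t_p)}$,
  maximal at $t_p$ — early $t_p$ gives the early-peak class, late $t_p$
  the plateau class, and a *small* $\alpha$ a blood-like curve with
  near-instant rise and slow washout;
- constant: background tissue.

A voxel's clean value in frame $i$ is the model's *frame average*
$\frac{1}{\Delta t_i}\int C(t)\,dt$, computed by adaptive quadrature
(`stats::integrate`, relative tolerance 1e-8) — what a frame-wise
reconstruction reports. Noise is additive zero-mean Gaussian on SUV with
per-frame standard deviation $\sigma_0 / \sqrt{\Delta t_f / 10}$:
`noiseSigma0` is the SUV noise of a 10-minute frame and shorter frames
are noisier as $1/\sqrt{\Delta t}$, emulating the count statistics of
frame-wise reconstruction without modelling the sinogram domain
(reconstruction is out of scope). The seed fully determines the
realisation. Consequently a "simulated lesion's" TAC noise is the voxel
noise divided by $\sqrt{n_\text{voxels}}$ of its region; the classifier
recovery experiment applies noise at this lesion level (a 10-mm-radius
lesion on the phantom grid), which is the level at which the pipeline
actually operates.

Structure overlaps are an error unless an explicit priority order is
given, which resolves ownership voxelwise and enables deliberate
partial-volume scenes (e.g. a vessel hugging a lesion). Lesions may carry
*compartments* — sub-spheres painted inside the parent — to model
heterogeneous tumours; these override the parent without counting as
overlaps.

The default scene (`defaultPhantomSpec()`) is 96 x 96 x 64 voxels at 2 mm
isotropic — brain-scale but desk-fast — with constant brain background at
SUV 1.2, one lesion per canonical pattern (amplitudes ~3–4, i.e. late
tumour-to-brain contrast ~1.7–2.7), a carotid-like vessel (peak SUV 8 at
2.5 min, slow washout so it remains above the 1.6 x background threshold
in the late window — the precondition of the vessel-inclusion failure
mode), and a scalp shell at SUV 1.8. The early-peaking lesion uses a
small $\alpha$ so its tail stays above background, as real early-peak
lesions do; a sharply decaying gamma would leave the lesion invisible in
the summed image and no threshold method could delineate it. Lesions are
placed off the mid-sagittal plane because synthetic-mode background
placement mirrors the lesion across that plane; a midline lesion would
mirror onto itself (with real data the background centre must be supplied,
as clinical placement is manual).

## Attenuation-correction bias

In dynamic PET every frame is corrected with the same attenuation map, so
an imperfect map produces one strictly positive 3D multiplicative field
applied identically to all frames (`applyBias`). Three field models stand
in for the CT/Dixon/UTE/model-based spectrum: `uniform` (pure global
scale), `radial` (centre-to-edge gradient, the signature of neglected
skull attenuation), and `smooth_random` (Gaussian-filtered white noise
rescaled so the largest deviation equals the requested amplitude —
spatially structured local bias with a chosen correlation length).
Magnitudes default to <= 10%, the scale reported for MRI-based attenuation
error in the brain; no quantitative per-method bias maps exist to
calibrate against, so these are explicit stand-ins, configurable per run.

Two consequences drive everything downstream, and both are exact
pre-noise: (i) for any *fixed* voxel set, the biased TAC is voxelwise
proportional to the reference TAC across frames, so pattern class and TTP
cannot change when the region itself is fixed; (ii) re-delineated
threshold regions *can* change, because the bias moves the apparent
maximum and the thresholded set.

## The comparison harness

`analyzeLesion` evaluates one lesion on one image under every definition;
`runAnalyze` applies it across attenuation variants with the reader-style
1-cm sphere placed once on the reference and copied verbatim (isolating
the pure attenuation effect), while VOI_FIX follows each reconstruction's
own maximum (its clinical definition). `compareToReference` emits one
change record per definition — pattern flags, TTP shift in frame units
(test − ref), relative TBR and volume differences ((test − ref)/ref) —
and `aggregateChanges` produces the summary grid: whole-percent change
rates (raw fractions are kept alongside), TTP summaries formatted as
`"changed/evaluated (shifts...)"` with the multiset of absolute frame
shifts, and exclusion tallies. The reference method is a labelled input,
never inferred.

## Validation experiments and problem sizes

The experiments in `R/experiments.R` back every claim above and are the
substance of the acceptance script and `test-acceptance.R`. Problem sizes
are the package's choices for desk-scale runs:

- *Fixed-sphere invariance*: 50 homogeneous-lesion phantoms
  (40 x 40 x 24 at 4 mm) x 3 bias models, pre-noise; identical ~2 mL and
  1-cm spheres inside the lesion. Exactness is expected, not approximate
  agreement: the masks are fixed and homogeneous, so proportionality is
  algebraic.
- *Region-growing correctness*: 100 random binary 9^3 volumes, 2D and 3D,
  against two independent oracles (a loop-based minimum-neighbour
  labelling in the test suite; a vectorised label-propagation reference
  in the package for the acceptance script).
- *Classifier recovery*: 150 noise-free curves and 500 noisy simulated
  lesions at `noiseSigma0 = 0.05` SUV, families sampled from
  family-typical ranges (increasing tau in [5, 25] min; plateau tp in
  [22, 29] min — see the frame-resolution limit; decreasing tp in
  [3, 15] min).
- *Vessel contamination*: a constructed scene (increasing lesion abutting
  a slow-washout vessel) in which the background-relative region spills
  into the vessel and the mixed TAC flips to DECREASING while the
  vessel-free tumour region stays INCREASING; the flip fraction is also
  located analytically by sweeping the mixing fraction
  (`vesselFlipFraction`).
- *End-to-end*: 50 heterogeneous lesions (two separated hot compartments
  of different pattern class, late summed contrast within a few percent)
  under a smooth bias field whose correlation length (15 mm) is chosen
  on the order of the compartment separation so that local bias can
  reorder the apparent maxima; threshold-based definitions re-delineate
  per image, fixed spheres are copied. This scene is designed to *expose*
  the delineation mechanism at a realistic bias magnitude, not to
  calibrate its clinical frequency.

## What the phantom does and does not emulate

It emulates: frame-averaged analytic kinetics, duration-dependent noise,
physiological confounders adjacent to lesions, lesion heterogeneity, and
the one property of attenuation error that drives the analysis — a
time-independent multiplicative field. It does **not** emulate: the
reconstruction chain (OP-OSEM, scatter, randoms, point-spread blur),
real attenuation-map anatomy, patient motion (explicitly absent in the
emulated protocol), partial-volume averaging at structure boundaries
beyond voxelisation, or reader variability in manual placement. Passing
tests therefore demonstrate the internal consistency of the evaluation
logic and the bias mechanism, not clinical performance on patient data:
in particular, the pattern-change *rates* the end-to-end experiment
reports are properties of the synthetic scene, comparable in kind but not
in value to rates observed in any patient cohort.

## Other limitations

- Orientation handling in NIfTI I/O is limited to axis-aligned grids with
  positive spacings (diagonal affine plus origin); oblique acquisitions
  are out of scope.
- The contralateral-mirror background placement assumes approximate
  left-right symmetry of the scene, which holds for the synthetic brain
  but must be replaced by manual placement on real data.
- Gaussian noise can produce (rare, small) negative SUVs at short frames;
  values are deliberately not clamped, to keep the noise model exact.
- The two- and three-class rules are threshold rules on eight numbers;
  near class boundaries their output is sensitive to the configured
  fractions, which is precisely why both are explicit, logged
  configuration rather than constants buried in code.
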