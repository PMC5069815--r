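---
title: "Methods: co-culture phenotypic screening analysis"
author: "hcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-culture phenotypic screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscreen)
```

## The assay being modelled

A co-culture screen plates two hepatic cell populations in the same
384-well wells: Huh7 (hepatocellular carcinoma) and Fa2N-4 (immortalized
normal hepatocyte). Because the malignant population alone expresses high
CHALV1 and AFP, immunofluorescence imaging lets a single well report two
readouts at once: how strongly a compound suppresses the HCC population
(anticancer activity) and how strongly it suppresses hepatocytes
(hepatotoxicity). A compound is a selective hit when the mean HCC
inhibition exceeds 50 % while the mean hepatocyte inhibition stays below
20 % — both strict inequalities, applied after averaging replicate wells.

The package implements the full analysis chain — segmentation,
classification, inhibition, Z′-gated hit calling, dose-response
confirmation, organelle-level mode-of-action readouts — plus a synthetic
screen generator that stands in for the instrument. Every analysis stage is
validated against the generator's per-cell ground truth.

## The growth and seeding model

Both populations grow exponentially, \(N(t) = N_0\,2^{t/T_d}\), with
doubling times of 23.8 h (Huh7) and 43.5 h (Fa2N-4). Over the 88 h from
seeding to fixation (16 h pre-incubation + 72 h treatment) the faster HCC
population overtakes: a 1500:800 hepatocyte:HCC seeding (the 65:35 premix)
ends near 42:58. The pure exponential form (no lag, no carrying capacity)
is justified by the short assay window; `estimate_doubling_time()` fits
\(\log_2\) counts by least squares and refuses non-growing series.
`design_seeding_ratio()` is the closed-form inverse of the composition
prediction and round-trips to \(10^{-6}\).

Compound effect is an endpoint multiplier: each compound carries a
four-parameter-logistic survival curve per population,
\(V(c) = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1+(c/\mathrm{IC50})^h)\),
applied once to the grown population. No time-resolved kill kinetics are
modelled — the assay itself is an endpoint assay.

## What the synthetic generator emulates (and what it does not)

`simulate_well()` draws grown counts (Poisson), surviving counts
(binomial at the 4PL survival times a baseline 3 % death fraction, with a
2 % log-normal well-to-well technical CV), then renders four 512×512
16-bit fields per well. Nuclei are Gaussian blobs (radius ~6±1 px,
log-normal Hoechst amplitude); CHALV1/AFP are uniform cytoplasm disks
(nucleus + ring) whose value is the cell's sampled log-normal marker
intensity — HCC medians 10× the hepatocyte medians, geometric SD 1.35;
overlapping cytoplasm is resolved by nearest-centre compositing. Additive
Gaussian read noise (SD 5) sits on a constant background (100). Cell
placement is rejection sampling with a minimum centroid separation of
1.2× the mean nucleus diameter; an overfull field raises an error naming
the capacity.

Three generator choices are worth calling out:

* **Imaged fraction (0.05).** Four microscope fields cover only part of a
  physical well, so the generator renders a binomial subsample of the
  surviving cells. The default makes a DMSO well yield roughly 700–800
  analysed cells (comfortably above the >100-cell QC floor) and puts the
  control window near the Z′ ≈ 0.7 operating point such an assay is
  expected to reach. No field-to-well area ratio is published for the
  instrument; this is a fixture parameter, not a claim about the optics.
* **Positive-control potency.** The sorafenib control uses top 100,
  bottom 0, IC50 4 μM, hill 1.3 — about 77 % kill of both populations at
  the 10 μM control dose — strong enough for a wide Z′ window while
  keeping positive-control wells above the cell-count QC.
* **Hepatocyte arm of the selective hits.** The three planted selective
  compounds use the published Huh7 resazurin IC50s (4.074 nM, 2.764 μM,
  0.5194 nM) on the HCC side, and a high `bottom` (80–85 % viability,
  i.e. partial maximal kill) on the hepatocyte side so that hepatocyte
  inhibition at 10 μM stays under 20 %. Applying the published
  single-culture hepatocyte IC50s unchanged would put the pyrimethamine
  analogue's hepatocyte inhibition near 30 % at 10 μM — inconsistent with
  its selective-hit status in the co-culture imaging screen, which is a
  different readout from single-culture resazurin viability. The
  generator therefore treats the co-culture hit behaviour as the ground
  truth to emulate.

Not modelled: point-spread optics, z-blur, photobleaching, cell-shape
realism beyond disks and rings, spatial plate effects, or edge artefacts.
Passing tests therefore demonstrate correctness of the *analysis* under a
known generative model — not robustness to uneven illumination, debris,
or segmentation-hostile morphologies of real images.

## Segmentation and classification

`detect_nuclei()` smooths with a Gaussian (σ = 1.5 px), thresholds with
global Otsu, splits touching nuclei by a watershed on the distance
transform (tolerance 1), and removes regions smaller than a disk of half
the mean nucleus radius (~28 px). Surviving labels are renumbered in
increasing original-label order so repeated runs are identical; two hard
disks overlapping by 30 % of a radius are split into two labels.

`measure_markers()` reports, per label, the mean intensity over the
nucleus mask and over a 4-px dilation ring per channel. Both markers are
cytoplasmic/secreted, so the ring (cytoplasm proxy) is the classification
signal; nuclear-channel statistics (Hoechst, γ-H2AX) use the nucleus
mask. Ring pixels contested by neighbouring cells go to the lowest
adjacent label (deterministic). Coordinates in all CSV output are 0-based
(row, col), origin top-left.

Classification cutoffs come from the pooled negative-control wells: an
exhaustive Otsu split of each marker's log10 ring-intensity histogram
(256 bins). A split is only trusted when it sits in a genuine valley —
the density at the cut must be below 0.8× the smaller flanking peak —
otherwise the distribution is treated as unimodal and a config-fixed
cutoff is required. At least 50 pooled control cells are demanded. The
log-scale split makes the derived cutoffs scale-equivariant, which in
turn makes classification invariant under common intensity rescaling.
The HCC call requires *both* markers above cutoff; single-positive cells
are AMBIGUOUS and excluded from both population counts, so boundary
cells can never inflate either denominator. On generator fixtures with
10× marker separation this classifies >99 % of matched cells correctly
with <2 % ambiguous.

## Screening statistics

The per-well readout is the classified HCC (and hepatocyte) cell count.
Percent inhibition is normalised per plate against the mean of QC-passing
negative controls and is deliberately not clipped below zero. The plate
window is the Z′-factor on HCC counts of positive vs negative controls,
\(Z' = 1 - 3(\sigma_p+\sigma_n)/|\mu_p-\mu_n|\); a plate below the 0.5
gate aborts hit calling but still writes its report. Equal control means
raise a "no assay window" error. Wells with ≤100 cells fail QC and are
excluded from all statistics (strict inequality: 101 passes). Replicate
disagreement beyond 30 percentage points of HCC inhibition is flagged in
the compound table.

## Dose-response fitting

`fit_dose_response()` fits the variable-slope 4PL by bounded
Levenberg–Marquardt least squares on the log10-dose axis. Numerical
choices:

* The zero-dose (DMSO) control anchors the top plateau and is placed 3
  decades below the lowest nonzero dose on the log axis (a log axis has
  no zero); moving that anchor to 4 decades changes recovered IC50s by
  well under 0.5 %, and the offset is exposed as `anchor_decades`.
* Initialisation: top/bottom from the response extremes, the log-IC50
  start at the dose bracketing 50 % of the range, hill 1; five
  multistarts jitter the log-IC50 start by ±1 decade; lowest residual sum
  of squares wins, ties going to the smaller hill slope.
* Bounds: 0 ≤ bottom ≤ top ≤ 120 (slight stimulation allowed), hill in
  (0, 10], log-IC50 within 3 decades of the ladder.
* A response range under 10 percentage points is declared non-converged —
  no IC50 is reported for flat data, and non-converged fits are refused
  by every downstream ratio.
* IC50s outside [lowest nonzero dose / 100, highest dose × 100] are
  flagged `extrapolated`.

On the standard 10-point ladder (DMSO + 1 pM–100 μM, decade steps), the
fitter recovers noise-free curves to ~10⁻¹⁰ relative error and, across
100 random curves (hill 0.5–3, 5 % noise), keeps the median
|log10(fitted/true)| under 0.1.

Selectivity is `IC50ER = IC50(hepatocyte)/IC50(HCC)`; it is unitless and
reciprocal-consistent. Condition comparisons (`compare_fits()`) fit each
replicate separately and report the fold-shift from mean log10 IC50s plus
a two-sample t-test (p < 0.05); with fewer than three replicates per arm
the t-test is skipped. One caveat the package quantifies rather than
hides: at 3 % response noise a *single* triplicate experiment estimates a
2.6-fold IC50 shift with a standard deviation of ~0.34 fold-units, so
recovery claims at the 10 % level are made on means over several
independent experiments, and the per-experiment scatter is what the
t-test is for.

## Mode-of-action readouts

* **Lysosomal puncta.** A difference-of-Gaussians band-pass (σ and 1.6σ,
  σ = 1.2 px) thresholded at an absolute response floor; connected
  components above 2 px become puncta, assigned to the footprint
  containing their centroid; orphans are dropped and counted. Lowering
  the floor can only grow the detected set. Condition summaries report
  n, mean, SD.
* **Cathepsin-B translocation.** Per cell,
  `1 − (signal inside puncta)/(signal over footprint)` after subtracting
  the per-image median background outside all footprints, clipped to
  [0, 1]; 0 is fully lysosomal, 1 fully cytosolic. Cells without signal
  above background are excluded with a warning. The index is invariant to
  positive rescaling of the channel.
* **Nuclear channels.** γ-H2AX is quantified as mean nuclear intensity —
  matching its diffuse (non-focal) appearance in this system — and the
  same operator serves EdU, ROS and TMRM (the latter two over the whole
  footprint, as cytosolic/mitochondrial signals). Positive fractions
  (EdU) use an Otsu cut on per-cell means, guarded so a signal-free
  channel scores zero positives.
* **Spheroids.** A 50-slice stack's mid-plane (0-based index
  `floor(n/2)`) is segmented like a 2-D field; the apoptotic fraction is
  decided in three stages anchored on the image background: no bright
  pixels → 0; Otsu split of per-cell means; if even the dimmer class sits
  far above background, every cell is positive. This keeps the 0 %, 60 %
  and 100 % fixtures all exact.

## Problem sizes used in validation

The packaged pilot-screen fixture is one full plate: 43 compounds in
duplicate at 10 μM plus 8 DMSO and 8 sorafenib control wells, 4 rendered
512×512 fields per well (~75 000 rendered cells), which the end-to-end
test processes in a few minutes on a single core. Organelle fixtures use
220 cells per arm; spheroid fixtures use 9–15 slices at 170 mid-plane
cells (the mid-plane operator only ever reads one slice, so slice count
does not affect the statistics). These sizes were chosen to keep every
statistical check's sampling error well inside its asserted tolerance.

## Known limitations

* The generator's realism budget is spent on statistical structure
  (count distributions, intensity separations, dose-response shapes), not
  optics; segmentation performance on real Operetta images will be worse
  and should be re-validated against hand-annotated fields.
* Hit calling assumes a single plate; no cross-plate normalisation or
  spatial (edge/row) correction is implemented.
* IC50 confidence comes from replicate refits (t-tests), not bootstrap or
  profile-likelihood intervals.
* The classification rule is a hard two-marker AND; partially stained or
  dying cells land in AMBIGUOUS and are simply excluded rather than
  modelled.
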