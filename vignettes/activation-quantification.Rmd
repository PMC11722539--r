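---
title: "Quantifying GTPase activation and filopodia from ratiometric FRET imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GTPase activation and filopodia from ratiometric FRET imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofret)
```

## The measurement model

An intramolecular FRET biosensor for an activated Rho GTPase emits more
acceptor (YFP) light relative to donor (CFP) light where the GTPase is
GTP-loaded. The per-voxel acceptor/donor emission ratio $R$ is therefore the
raw activation readout, and everything downstream is a way of turning a
noisy two-channel z-stack of one neuron into a single comparable activation
score:

1. **Background subtraction.** Each channel has an additive acquisition
   offset plus autofluorescence. We subtract the per-channel median over a
   cell-free region (a border band by default, or an explicit ROI) and clamp
   at zero. The median is robust to stray bright pixels in the background
   region.
2. **Segmentation.** Object voxels are separated from background on the
   summed donor+acceptor intensity. The default is an Otsu threshold
   computed once from the whole-stack histogram and applied voxelwise; a
   fixed "predefined" threshold is available. We compute Otsu on
   `log1p`-transformed intensities: fluorescence stacks are dominated by a
   large zero-mode background and often contain a cell body several times
   brighter than the neurites, and in the linear domain the between-class
   criterion then prefers the soma/neurite split over the
   background/object split. The log transform is monotone, so clean
   two-level images are still split exactly; the threshold is reported in
   intensity units.
3. **Ratio with a donor floor.** $R = I_A / I_D$ is undefined (NA), not
   infinite, wherever the corrected donor falls below a floor, by default 1%
   of the in-mask donor median. Without the floor, dim mask-edge voxels
   produce arbitrarily large ratios that dominate column sums.
4. **Density map.** For each $(x, y)$ column the masked, defined ratios are
   summed over $z$ and divided by the imaged object volume in that column
   (masked voxel count × z-step): a depth-normalized mean ratio per micron.
   The divisor is deliberately *per column*: a whole-neuron-volume divisor
   would make every map value depend on total neuron size, so two neurons
   with identical local activation but different somata would get different
   maps. The whole-neuron alternative remains available
   (`divisor = "neuron"`).
5. **Line profile.** Sampling lines run perpendicular to the midline at
   one-pixel spacing, from the midline 30 µm toward the ipsilateral side,
   sampled bilinearly at pixel resolution. Lines with under 50% defined
   samples are dropped (a choice: the alternative, keeping all lines, lets
   a handful of spurious mask columns dominate sparse distances); the rest
   are averaged per distance, ignoring undefined samples. Because the cell
   body sits adjacent to the midline, distance from the midline and
   distance from the cell body are the same coordinate, which is how the
   5–30 µm measurement window and the 20–25 µm baseline window live on one
   axis.
6. **Two-reference normalization.** Probe expression varies between
   neurons; the profile is anchored so the cell-body window (default
   0–3 µm; the reference is stated only as "at the cell body", so the
   window length is a configurable choice) maps to 1 and the axon-shaft
   baseline window (20–25 µm) to 0. The raw window means are retained.
7. **Gaussian fit and AUC.** The normalized profile is fitted with
   $f(d) = A e^{-(d-\mu)^2/2\sigma^2} + c$. The offset $c$ is included
   deliberately even though the model is described just as "a Gaussian":
   without it the score could not vanish for flat profiles. The activation
   score is the integral of the Gaussian *component only* over 0–30 µm.

## Why the score is rescaled to ratio units

The two-reference normalization divides by the peak–baseline span. Any
profile of the form $\text{baseline} + A g(d)$ with $g$ fixed normalizes to
the *same* curve for every $A$: normalized profiles are
amplitude-invariant by construction. An AUC computed purely on the
normalized scale therefore cannot distinguish strong from weak activation —
it would report fold changes of ≈1 between genotypes whose true activation
differs tenfold. The pipeline therefore multiplies the dimensionless
Gaussian integral by the raw normalization span re-expressed in plain ratio
units, $(\bar v_{peak} - \bar v_{base}) \cdot \Delta z$ (the $\Delta z$
factor undoes the density map's per-micron-of-depth division, an
acquisition artifact). On noise-free synthetic input the resulting score
equals the planted $A \sigma \sqrt{2\pi}\,[\Phi(\frac{30-\mu}{\sigma}) -
\Phi(\frac{-\mu}{\sigma})]$ exactly, it scales linearly with planted
amplitude, and it stays invariant to probe expression (scaling both
channels) and to the z-step. `compute_auc(..., scale = 1)` returns the
dimensionless score when the normalized-scale convention is wanted.

## The synthetic world

The generator renders the simplest scene for which all ground truth is
analytic: a spherical cell body (radius 3 µm, three times the axon's
brightness) touching a planar midline, and a straight cylindrical axon
(30 µm long, 2 µm wide) running perpendicular to it, imaged as sixteen
0.5-µm optical sections spanning 8 µm at 0.1 µm/pixel. Inside the neuron
the planted ratio is $\text{baseline} + A e^{-(d-c)^2/2\sigma^2}$ along the
lateral axis, with the bump defaulting to the proximal axon
($c = 8$ µm, $\sigma = 3$ µm, $A = 1$ ratio unit) — a localized activation
inside the 5–30 µm measurement window. The acceptor channel is synthesized
as donor signal × target ratio, so the planted ratio is exact before noise;
photon noise is independent Poisson per channel after brightness scaling
(donor 200 photons/axon voxel over a 100-count offset — placeholders for an
uncalibrated detector, since no SNR or camera calibration is stated for
this kind of acquisition; both are scene parameters). Morphologies plant
straight filopodia of known Euclidean length and laterality on a 1-µm-node
shaft; when lengths are supplied explicitly they are laid axis-aligned so
the strict 1-µm boundary is exact in floating point.

What a green test does establish: the pipeline's arithmetic, its oracle
equivalences, and parameter recovery under Poisson noise at stated
brightness. What it does not: robustness to irregular neuron geometry,
point-spread blur, spectral bleed-through, photobleaching, or segmentation
on dim real tissue — none of which the generator emulates (deliberately;
the geometry is stylized precisely so ground truth stays analytic).

## Morphometry conventions

A filopodium is a maximal protrusion subtree attached to the shaft; its
length is the *path* length along the longest attachment-to-tip path
(protrusions "extend" along their own arc, so a curved 1.2-µm filopodium
counts even if its tip is under 1 µm from the shaft), multi-tip subtrees
count once with their longest path, and the counting filter is strictly
greater than 1 µm. Laterality is operationalized as the sign of the tip
displacement along the frame's lateral axis relative to the attachment
point, since no formal definition is stated in the field. The 5–30 µm
region restriction is exposed but off by default — it is stated for the
FRET measurement window, and whether published counts were so restricted
is not stated. All length thresholds are in microns.

## Statistics

All tests are computed from their defining formulas, with base R supplying
only distribution tails (`pt`, `pf`, `ptukey`); base R's own test functions
appear exclusively as independent cross-checks in the test suite.
Summary-statistics *t* tests take (mean, SEM, n) triples — the exact form
figures print — and reproduce the raw-data tests whenever the summaries
come from the raw data. SEM is the sample SD over $\sqrt{n}$ throughout
(the figure-legend convention; a worked two-point example elsewhere that
implies the population SD is not followed). Mann–Whitney enumerates all
labelings exactly for $\min(n) \le 8$, with two-sided
$p = P(|U - n_1 n_2/2| \ge |u - n_1 n_2/2|)$, and otherwise uses the
tie-corrected normal approximation with continuity correction. Tukey HSD
uses the Tukey–Kramer per-pair standard error for unbalanced groups.
Sample-size analysis inverts the noncentral-*t* power of the two-sided
two-sample test, refined from the normal-approximation closed form; the
published n = 10/11 determinations used unreported preliminary-data effect
sizes and so are not reproduction targets.

For the intensity timecourse, the negative control (null mutant at 15:00 h)
maps to 0 and wild type at 15:00 h to 1: the two source statements of this
convention disagree on the assignment, and the figure-legend version is
adopted because a null mutant is the natural zero; `flip_references`
swaps it. References are group means, not per-embryo values.

## Numerical choices

* Gaussian fitting initializes at $A = \max - \min$ (sign flipped when the
  minimum departs further from the offset estimate), $\mu$ at the extremum,
  $\sigma = 3$ µm, $c$ at the baseline-window mean; a port-algorithm `nls`
  fit is polished by bounded L-BFGS-B on failure, $\sigma$ bounded below by
  $10^{-6}$, and non-convergence is a flag on the result, never an error.
  Constant profiles short-circuit to the exact $A = 0$ fit.
* The AUC quadrature (`integrate`, rel.tol $10^{-10}$) is tested against
  the error-function closed form to $10^{-8}$.
* Map coordinates are continuous with pixel centers at
  $(i - \tfrac12) \cdot \text{pixel}$; interpolation is bilinear, and a
  sample is undefined if any neighbor with nonzero weight is undefined.
* Type-I calibration runs 10,000 null simulations per test with an
  independent seeded stream per test, so one unlucky shared draw sequence
  cannot push several tests over the bound at once.
* Determinism: every generator and the config-driven pipeline are seeded;
  identical config + seed reproduces result bundles bitwise (checked by
  hash in the tests).

## Known limitations

Stacks are held in memory as dense double arrays (fine for single-neuron
fields; not for large mosaics). TIFF support is a minimal self-contained
baseline implementation (uncompressed grayscale multi-page, uint8/16/32 and
float32), written because no TIFF reader exists in the target R stack; it
is cross-checked against an independent reader but does not aim at tiled,
compressed or OME flavors. The midline frame must be supplied (or comes
from the generator): there is no automatic neuron or midline detection. No
spectral unmixing, bleed-through or photobleaching correction is applied.
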