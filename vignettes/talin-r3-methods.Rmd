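---
title: "Models and methods behind talinR3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind talinR3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(talinR3)
```

talinR3 quantifies the mechanical stability of the talin rod R3 subdomain,
a four-helix bundle that unfolds at the lowest force of all talin rod
subdomains and thereby exposes cryptic vinculin binding sites. The package
covers five measurement families: steered-MD (SMD) trajectory metrics,
constant-force pull-plan construction, FRAP recovery fitting, micropattern
colocalization imaging, and two-state thermal melts. Each family has a
paired synthetic generator with recorded ground truth; generate-analyze-
recover round trips are the backbone of the test suite.

## Bundle model and pulling geometry

A `helix_bundle` is a residue-indexed heavy-atom table plus four inclusive
helix ranges. The default ranges (H1 796–815, H2 824–849, H3 856–880,
H4 886–909) are a design choice: published structural figures draw the
helix boundaries without printing numbers, so we chose ranges that contain
every textually fixed residue — the pull anchors (Q800, T804, V808, S815 in
H1; Q888, G896, A900, A904 in H4) and the four mutated core positions
(805, 812, 890, 897) — and made them configurable everywhere they are
consumed. Author (mouse talin-1) numbering is kept throughout; file
readers never renumber.

`build_pull_plan()` emits a declarative description of the constant-force
experiment: the four H1 anchor α-carbons fixed, the four H4 anchor
α-carbons pulled along +z, after `orient_to_axis()` applies the *minimal*
rotation taking the Val808→Gly896 α-carbon vector (d3) onto +z. Minimal
rotation (Rodrigues, with explicit handling of the parallel and
antiparallel degeneracies) is one of several valid conventions; any
rotation with the same image works, and tests only require parallelism to
1e-6 rad with all pairwise distances preserved to 1e-9 nm. The centroid is
placed at the centre of a 10 × 10 × 30 nm box. Running the MD engine is
deliberately out of scope, as are force fields, solvation and
minimization.

The mutation builder applies the serine substitution series cumulatively
(1S = I805S, 2S adds I812S, 3S adds L890S, 4S adds L897S); the labels are
validated against exactly that ordering. No deposited accession exists for
the fragment, so `r3_synthetic_sequence()` provides a clearly-labelled
synthetic 117-residue stand-in that honours only the residue identities
fixed by the design (anchors and mutated positions); it is for exercising
the machinery, not a database sequence.

Conservation is scored per alignment column as the fraction of non-gap
rows matching the column's modal residue, with gaps excluded from the
denominator, ties broken alphabetically, and all-gap columns scored 0 and
flagged. Fraction-identity was chosen over entropy-based scores because it
is the simplest auditable measure for "is this core residue invariant
across species"; the profile maps columns onto reference numbering so core
positions can be read off directly.

## Water penetration and displacement metrics

The penetration criterion: a water oxygen has entered the hydrophobic core
when its minimum distance to the heavy atoms of **every** one of the four
helices is at or below the cutoff (default 0.5 nm). Conjunction over
helices is what isolates *core* water — proximity to a single helix is just
solvation. Water hydrogens are excluded because water-model hydrogen
placement varies; protein hydrogens are excluded for the same reason.
Waters beyond the bundle ends that still meet the criterion are counted:
end-clipping in visualizations is cosmetic, not part of the definition.

The counter prunes waters outside each helix's cutoff-expanded bounding box
before exact distance evaluation; it is exact, and the test suite holds it
equal to a naive all-pairs oracle on hundreds of random configurations,
along with rigid-motion invariance, water-permutation invariance,
increment-by-one behaviour, and monotonicity in the cutoff.

Counts are smoothed with a 10-frame sliding average. Two conventions are
implemented because reasonable readers of a "sliding average of 10 frames"
differ: the default `trailing` window averages the last `min(i, 10)`
frames (matches progressive traces); `centered` uses a full-length window
clamped at the array bounds. Both are fixed points on constant series and
never leave the input range. Replicate averaging is an element-wise mean,
with linear interpolation onto the first replicate's grid restricted to
the common time range when grids differ. All operations take explicit
per-frame timestamps; no frame rate is ever assumed.

Displacement is tracked on the four antiparallel anchor pairs
(800–904, 804–900, 808–896, 815–888) as per-frame Euclidean α-carbon
distances in nm. `refold_time()` returns the earliest time after which d3
*stays* within a tolerance band (default 0.05 nm) of its baseline to the
end of the series — a stays-in-band criterion rather than first touch, so
a transient crossing does not count as refolding. A series ending outside
the band returns `NA` ("not refolded").

## FRAP normalization and fitting

Normalization follows the double ratio
`F = [B(t)/B(t<0)] / [Cell(t)/Cell(t<0)]`, with the pre-bleach references
taken as the mean over *all* pre-bleach frames (more robust to shot noise
than the last frame alone). Dividing by the whole-cell ratio cancels
acquisition fading algebraically — the generator includes a fading factor
on both channels precisely so the tests can assert this cancellation.
"Normalization to zero" is implemented as full-scale normalization (first
post-bleach value → 0, pre-bleach level → 1), so the fitted plateau reads
directly as the mobile fraction; a subtract-only mode is available.

The recovery model is the single exponential `F(t) = M (1 − e^{−kt})` on
post-bleach times, fitted by Levenberg–Marquardt (minpack.lm) with
M₀ = mean of the last decile of F, k₀ = ln 2 / (time to half of M₀),
bounds M ∈ [0, 1.5] and k > 0. A bi-exponential or diffusion-vs-binding
model is deliberately excluded. Non-convergence and a rate pinned at its
bound are flagged in the returned object, never silent. The plateau is
fitted unconstrained within its bounds even though acquisition stops at
90 s; for half-times much longer than the window the mobile fraction is
extrapolated and the fit flag should be inspected.

## Imaging quantification

Adhesion/cytosol ratios are mean-intensity quotients: invariant to global
multiplicative gain (hence robust to expression differences) but *not* to
additive offsets — a property asserted by test, and the reason a
background-subtraction step belongs before ratio computation. Adhesion
segmentation defaults (blur σ 0.2 µm, background subtraction at σ 2 µm,
Otsu threshold, minimum object area 0.25 µm², cytosol = cell minus
0.5-µm-dilated adhesions) are unexceptional and fully configurable, since
the upstream experiments did not publish a segmentation recipe.

The paxillin mask is a Gaussian extension (default σ 0.3 µm) of the
paxillin channel followed by a threshold (manual, Otsu fallback). The
colocalization measure is Mander's *split* coefficient M1 — the fraction
of channel-a intensity on pixels where channel b exceeds a manual
threshold, evaluated inside the mask — because a manual gate on the
fibronectin channel pairs naturally with the split form. It is bounded in
[0, 1], equals 1 on identical channels, and is invariant to uniform
scaling of channel a.

Micropatterns are square lattices rasterized with the pixel-centre
convention; coverage equals (square/pitch)² up to discretization when the
field holds whole lattice periods (a field cutting a partial period biases
coverage at any resolution — a windowing effect, not a rasterization one).
The fibronectin fraction of adhesions is area-weighted (pixels, not
adhesion counts), and the on- plus off-pattern fractions sum to one
exactly. Migration speed is path length over duration (net displacement
speed is also reported); zero-duration tracks are dropped with a warning.

## Melt fitting

Single-wavelength melts are fitted with the standard two-state van 't Hoff
model with linear folded/unfolded baselines. Temperatures are converted to
kelvin internally and reported in Celsius. Initialization: Tm₀ at the
maximum absolute finite-difference slope, baselines from straight-line
fits to the first and last temperature quartiles, ΔH₀ = 250 kJ/mol; Tm is
bounded to the scanned range and ΔH to [1, 5000] kJ/mol. Degenerate inputs
are flagged, not fitted silently: a signal span (or fitted transition
amplitude) below 5× the baseline-residual noise flags "no clear
transition", and a midpoint pinned at the scan boundary flags "unresolved
Tm". The fit is invariant to affine rescaling of the signal axis, and the
fitted Tm is exactly the temperature where the unfolded fraction crosses
one half — both asserted by test. The original analyses used a proprietary
fitting package; the van 't Hoff two-state model is the universally
accepted equivalent for single-wavelength melts. Spectral deconvolution
(helical content) is excluded because it requires an external basis-set
library.

## Synthetic generators: what they emulate, and what they do not

All generators take a seed, are bit-reproducible given one, and record
every ground-truth parameter in metadata exportable as a JSON sidecar
(`write_ground_truth()`).

* `gen_bundle_trajectory()` builds four straight dummy-atom chains at the
  corners of a square prism (side 0.6 nm), residue-numbered to contain all
  anchors, with adjacent chains antiparallel so the four displacement
  anchor pairs sit at matched heights and d3 equals the H1–H4 separation
  exactly. The separation grows linearly at the requested rate; exactly
  the scheduled number of waters satisfy the penetration criterion per
  frame (verified internally by an all-pairs check before emission), with
  far-field background waters that never do. It emulates geometry only —
  no forces, thermostats, secondary structure, or realistic solvent.
  Passing round trips therefore validate the *metrics*, not any MD
  physics.
* `gen_frap()` constructs raw ROI/whole-cell traces whose double ratio is
  exactly `M (1 − e^{−kt})` at zero noise (default sampling 0.5 s, 5 s
  pre-bleach, 90 s post-bleach, bleach floor 0.3 of the pre-bleach level),
  with optional multiplicative noise and shared acquisition fading. It
  does not model diffusion during bleach, reversible photoswitching, or
  whole-cell depletion by the bleach pulse (the depletion correction is
  exactly what the double ratio cannot cancel; the generator keeps it at
  zero so recovery is exact by construction).
* `gen_scene()` draws a 512×512 lattice at the requested coverage (default
  0.5625 = (0.75)², the 56 %-fibronectin layout) and places elliptical
  adhesions (semi-axes 1.5–5 px) wholly on or wholly off the squares,
  assigning each to the class that moves the running *area* fraction
  towards the target; the realized fraction lands within about one
  adhesion footprint (~0.2 pp) of it. Channels are flat enrichments plus
  Gaussian noise — no PSF beyond Gaussian blur, no adhesion substructure,
  no cytosolic gradients.
* `gen_melt()` evaluates the two-state model exactly (default flat
  baselines −15/−4, ΔH 200 kJ/mol, 20–90 °C in 2 °C steps) plus optional
  additive noise. `gen_tracks()` produces persistent random walks with
  Gaussian turning (SD = (1 − persistence)·π) and optional lognormal step-
  speed noise; persistence 1 with zero noise gives exact straight lines.

## Problem sizes and tolerances used by the test suite

Noiseless round trips assert recovery to 1e-6 (FRAP mobile fractions) or
0.1 °C (melts). Noisy-recovery checks use 100 FRAP curves (σ = 0.02,
median mobile-fraction error < 0.02, median relative half-time error
< 10 %) and 50 melt fits (noise 2 % of span, median Tm error < 0.5 °C).
The water counter is held exactly equal to the all-pairs oracle on 200
random configurations of up to 500 waters; scene recovery uses 500
adhesions at 512². These sizes keep the full suite comfortably fast on a
laptop while leaving the statistical assertions well-powered.

## Known limitations

* Trajectory input is PDB (multi-model), GRO, or the plain CSV frame
  table; compressed binary trajectory formats (XTC) have no reader in the
  R ecosystem used here, so convert externally or export frame tables.
* The helix boundaries, paxillin-mask threshold/blur, and adhesion
  segmentation recipe are configurable defaults, not published values.
* The refolding metric summarizes a single distance (d3); it does not
  assess secondary-structure recovery.
* Mander's M1 depends on the manual threshold for channel b; no automatic
  threshold search (e.g. Costes) is provided.
* The FRAP model assumes a single kinetic class; curves with clear
  bi-exponential character will show structured residuals (inspect `rms`).
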