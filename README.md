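# talinR3

Quantification toolkit for studies of the mechanical stability of the talin
rod R3 subdomain — the four-helix bundle (mouse talin-1 residues ~795–911)
that unfolds first under cytoskeletal force and thereby acts as a cellular
mechanosensor. Experiments probing R3 stability combine steered molecular
dynamics (SMD), FRAP of adhesion proteins, micropatterned-substrate
colocalization imaging, migration tracking, and CD thermal melts. This
package implements the bespoke quantifications those experiments need, plus
synthetic-data generators with recorded ground truth so every analysis can
be validated by parameter recovery. It is aimed at structural
biologists and mechanobiologists who have the raw measurements (trajectory
coordinates, ROI intensity traces, channel images, tracks, melt curves) and
need the downstream numbers.

## What it computes

**SMD trajectory metrics.** A water molecule counts as having penetrated
the hydrophobic core when its oxygen lies within 5 Å of the heavy atoms of
*every* one of the four helices; the per-frame count, its 10-frame sliding
average, and replicate averaging give the mechanostability readout
(`count_penetrating_waters()`, `penetration_series()`). Helix separation is
tracked on four α-carbon vectors, d1 = Gln800–Ala904, d2 = Thr804–Ala900,
d3 = Val808–Gly896, d4 = Ser815–Gln888 (`displacement_series()`), and
refolding is scored as the earliest time the relaxation-phase d3 stays
within a tolerance band of its baseline (`refold_time()`).

**Pull-plan construction.** `build_pull_plan()` encodes the constant-force
geometry: α-carbons of H1 residues 800/804/808/815 fixed, H4 residues
888/896/900/904 pulled at constant force (150 pN in the reference
protocol) along +z after rigidly orienting the bundle so the d3 vector is
parallel to the z axis (`orient_to_axis()`), in a 10 × 10 × 30 nm box.
Mutant construction (`apply_mutations()`, the I805S/I812S/L890S/L897S
serine series 1S–4S) and alignment conservation profiling
(`conservation_profile()`) cover the design side.

**FRAP.** `normalize_frap()` applies the double-ratio normalization
F = [B(t)/B(t<0)] / [Cell(t)/Cell(t<0)] followed by full-scale
zero-normalization; `fit_frap()` fits F(t) = M·(1 − e^(−kt)) so the mobile
fraction is the plateau M and the half-recovery time is ln 2 / k.

**Imaging.** Adhesion/cytosol intensity ratios and vinculin/talin ratios,
Gaussian-extended paxillin masking, Mander's split coefficient M1 under a
manual threshold, square-lattice micropattern masks (coverage =
(square/pitch)²), fibronectin area fractions of adhesions, and
migration-track path/net speeds.

**Melts.** `fit_melt()` fits a two-state van 't Hoff model with linear
baselines, S(T) = (b_f(T) + b_u(T)·K(T)) / (1 + K(T)) with
K = exp[−ΔH/R·(1/T − 1/Tm)], returning Tm as the transition midpoint.

## Worked example

```r
library(talinR3)

# FRAP: noisy synthetic record at mobile fraction 0.33, t1/2 = 10 s
rec <- gen_frap(mobile_fraction = 0.33, half_time_s = 10,
                noise_sigma = 0.02, seed = 7)
fit_frap(normalize_frap(rec))
#> <frap_fit> mobile fraction = 0.3343, half time = 9.671 s

# CD melt at the wild-type midpoint
fit_melt(gen_melt(tm_C = 66.9, noise_sigma = 0.2, seed = 7))
#> <melt_fit> Tm = 66.65 C, dH = 215.9 kJ/mol

# Micropatterned scene: 500 adhesions at a 26 % fibronectin area fraction
sc <- gen_scene(fn_adhesion_fraction = 0.26, n_adhesions = 500, seed = 7)
100 * fn_fraction(sc$masks$adhesion, sc$masks$pattern)
#> 26.1

# Water penetration on a synthetic bundle trajectory with 3 core waters
tr <- gen_bundle_trajectory(n_frames = 30, open_rate_nm_per_ns = 0,
                            n_core_waters = 3, seed = 7)
penetration_series(tr)$count[1:10]
#> 3 3 3 3 3 3 3 3 3 3

# Constant-force pull plan
build_pull_plan(helix_bundle(tr[[1]]$protein_atoms), 150)
#> <pull_plan> 150 pN along (0, 0, 1)
#>   fixed CA (H1):   800, 804, 808, 815
#>   pulled CA (H4):  888, 896, 900, 904
#>   box: 10 x 10 x 30 nm
```

The FRAP fit recovers the generating mobile fraction to within the noise
floor (0.334 vs 0.33), the melt fit recovers the midpoint to 0.25 °C under
2 % noise (exactly, when noiseless), and the scene quantification returns
the generating fibronectin fraction to a tenth of a percentage point.

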