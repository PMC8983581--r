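---
title: "Quantifying nuclear condensate puncta: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear condensate puncta: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

punctakit quantifies liquid-liquid phase separation (LLPS) of
fusion oncoproteins in cell nuclei from two-channel confocal stacks, and
the companion in vitro readouts (FRAP, dilution-series condensate
imaging, turbidity). This vignette is the package's methodological
account: what is computed, under which model assumptions, which
parameters matter, and what the validation on synthetic ground truth
does and does not demonstrate.

## The quantities

A nucleus expressing an LLPS-prone protein partitions it between a
dilute nucleoplasmic *light phase* and condensed *dense-phase* puncta.
Per nucleus the package reports:

* **puncta number density** — puncta per 10^3 µm^3 of nuclear volume.
  Density rather than raw count is reported because a fraction of nuclei
  is never fully inside the imaged stack; such nuclei are kept and
  flagged (`touches_stack_boundary`), and density remains comparable.
* **V_p** — mean punctum volume (µm^3).
* **[LP]**, **[DP]** — calibrated mean protein intensity in the
  nucleoplasm outside puncta, and pooled over all punctum voxels of the
  nucleus. The intensity-to-concentration map is linear
  (`calibration_model(slope, offset)`), identity by default; with
  `offset = 0` all ratio metrics are calibration-independent.
* **K_p = [DP]/[LP]** — the partition coefficient, and
  **ΔG_Tr = −RT ln K_p** (kcal/mol, R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹,
  T = 310.15 K by default — live-cell imaging at 37 °C), negative when
  partitioning into the dense phase is favourable.
* **PCC** — Pearson correlation between the protein and DNA channels
  over the nuclear mask, the colocalization readout that separates
  chromatin-associated from chromatin-independent condensates.
* **periphery fraction** — the fraction of puncta closer than 0.5 µm to
  the nuclear boundary (the conventional periphery-exclusion distance).

Zero-punctum nuclei have a defined density (0), [LP], total
concentration, and PCC, but *undefined* (`NA`, never 0) V_p, [DP], K_p
and ΔG_Tr; summaries list density-type metrics over all cells and
distribution-type metrics only over cells with puncta. `write_tables()`
encodes undefined metrics as empty CSV fields.

## Nucleus segmentation

Nuclei are found in the DNA-stain channel. The final algorithm is:

1. light 3-D Gaussian smoothing (0.3 µm lateral and axial — just enough
   to regularize the edge);
2. a rough global Otsu threshold refined by isodata iteration;
3. morphological consolidation of the rough mask: per-layer despeckling
   (min 1 µm²), closing (0.6 µm), convex-hull filling of each in-layer
   component, the same hull filling on the two orthogonal slice
   families, and filling of 3-D enclosed background pockets;
4. estimation of the *local* interior DNA level by normalized
   convolution (0.8 µm lateral window) over the consolidated mask;
5. the final mask: voxels brighter than **half the local level** — a
   blurred step edge crosses half its own height at the true boundary,
   so the contour stays calibrated even when chromatin texture modulates
   local brightness several-fold;
6. consolidation again, 3-D connected components, and a minimum-volume
   filter (50 µm³) against debris.

Two design points deserve emphasis. First, a single global threshold is
*not* sufficient: wherever the local DNA level is darker than average,
a global cut places the boundary inward, and the losses do not cancel
(dark rim patches can be carved arbitrarily deep, bright ones bulge at
most a fraction of the smoothing width outward). The adaptive local
level removes this bias. Second, the convex-hull filling encodes the
assumption that nucleus cross-sections are convex to good
approximation; it restores DNA-poor interior voids (nucleolus-like
regions) and rim bays that intensity alone would carve out. Because
every planar section of a convex body is convex, hull-filling the three
slice families never overshoots a convex nucleus; for markedly
non-convex nuclei set `convex_fill = FALSE` (topological hole filling
only). All thresholds are relative, so segmentation is invariant to
positive intensity rescaling.

## Puncta detection and measurement

Puncta are detected in the protein channel with a scale-adapted
Laplacian-of-Gaussian (LoG) filter: for each scale σ in a ladder
(default 0.1–0.5 µm, the submicron-blob range) the channel is smoothed
with per-axis voxel sigmas derived from the physical voxel size, the
3-D Laplacian is taken with physical spacings, and the response is
multiplied by −σ² (scale normalization; bright blobs give positive
response). The per-voxel maximum across scales is the detection grid.
Scales below one voxel on any axis are clamped with a warning.

Detection then proceeds:

* **foreground** — response above a threshold; by default Otsu on the
  positive response within nuclear voxels (scale-invariant; quantile
  and absolute policies are available);
* **seeds** — 26-neighbourhood local maxima of the response inside the
  foreground, at least 0.3 µm inside the nucleus (the LoG filter
  responds to the bright nucleus/background edge itself; the margin
  keeps that ring from seeding phantom puncta), greedily filtered to a
  minimum separation of 0.3 µm (≈ the lateral resolution limit;
  candidates ranked by response with exact ties broken by lexicographic
  voxel order for determinism). A ridge-connectivity rule (1 %
  prominence) merges plateau and shoulder maxima of the same blob —
  noiseless symmetric blobs otherwise produce exact-tie twin maxima
  farther apart than the separation limit and split in two;
* **watershed** — each seed grows into one region by priority flooding
  of the response within the foreground (6-connectivity, deterministic
  tie-breaks);
* **contrast filter** — regions whose intensity peak does not rise at
  least 10 % above the nucleoplasm level are discarded (they carry no
  dense phase; residual rim responses in punctum-free nuclei fail this
  test);
* **half-maximum refinement** — each region is restricted to voxels
  above the nucleoplasm level plus half the punctum's peak rise. For a
  blurred sphere the half-height contour sits at the true boundary, so
  refined regions track true punctum volume; raw LoG-foreground regions
  over-fill blobs substantially.

Per punctum the package reports volume, mean and integrated intensity
(the sum over member voxels), centroid, the parent nucleus (majority
vote of member voxels, falling back to the centroid), and the distance
from the centroid to the nuclear boundary via an anisotropy-aware
Euclidean distance transform. Cytoplasmic condensates are excluded by
default (with a logged count) and kept with `nucleus_id = 0` when
`nuclear_only = FALSE`, for constructs that condense in both
compartments.

[LP] is measured over nuclear voxels at least 0.3 µm inside the
segmented boundary (partial-volume rim voxels otherwise dilute it),
excluding the detection foreground plus an anisotropic halo margin
(0.45 µm axial / 0.25 µm lateral) around puncta — phase-boundary voxels
belong to neither phase cleanly.

## FRAP

Traces carry ROI, background and unbleached-reference channels plus a
prebleach level. Normalization is double: background-subtracted ROI
over background-subtracted reference (cancelling acquisition
photobleaching exactly for multiplicative drift), rescaled so prebleach
maps to 1. The recovery model is the single exponential

I(t) = I₀ + M_f (1 − I₀)(1 − 2^(−t/T½)),

with I₀ the post-bleach floor, M_f the mobile fraction, and T½ the
half-time (the fitted curve reaches half its plateau rise at t = T½).
Fitting is bounded Levenberg–Marquardt (M_f ∈ (0, 1.05] as a soft cap
for noise, T½ ∈ (0, 10 t_max]), initialized by exact profiling: for
fixed T½ the model is linear in (I₀, amplitude), so a coarse log-spaced
T½ grid with closed-form linear fits locates the global least-squares
basin before the optimizer polishes it. A log-linear rate guess alone
strands the optimizer in local optima on noisy traces at roughly twice
the attainable error. Flat traces (immobile limit) are flagged
`converged = FALSE` rather than silently fitted.

A single noisy trace carries limited information about T½: at noise
sd 0.05 on the normalized scale with 50 points, the Cramér–Rao bound
for the three-parameter fit corresponds to a median relative error
around 10 % — no estimator can do better per trace. Replicate traces
are therefore averaged first (`frap_group_curve()`, the mean ± SD
presentation with n ≈ 20) and the mean curve is fitted; the validation
suite demonstrates recovery of T½ and M_f to a few percent under that
protocol, and to better than 1 % on noiseless traces.

## In vitro dilution series and turbidity

Dilution-series stacks (13 planes over 6 µm at 0.5 µm steps by default)
are reduced to maximum-intensity projections; condensates are counted
as connected bright components above a robust threshold
(median + 6 MAD by default — a bimodal split such as Otsu hallucinates
foreground on condensate-free fields) with a minimum area of 0.05 µm².
A sample is called phase-separated when at least 3 objects are found
(single specks are not trusted). The saturation concentration is
reported as a bracket: `lower` = highest condensate-free concentration
(0 when every concentration is positive, read "C_sat < upper"),
`upper` = lowest positive one (+∞ when none is). Non-monotone detection
patterns are flagged and bracketed from the first positive with a
warning. Turbidity series are summarized as per-concentration
mean ± SD of buffer-subtracted A340 over replicates (≥ 3 by
convention; fewer than 2 leaves the SD undefined and flags the row).

## FG-motif valence

FG valence is the number of FG dipeptides in a sequence or region
(1-based inclusive coordinates); every GLFG contains exactly one FG and
is counted once. GLFG occurrences are scanned with overlap-tolerant
lookahead. Mutation specs name the F of each targeted motif explicitly
(`F>A` or `FG>AA`) and are validated residue-by-residue against the
parent — positions are never inferred, since the exact mutated
positions in published constructs live in plasmid maps rather than in
sequence databases. `generate_construct_sequence()` emits a synthetic
two-region FG architecture with exact per-region FG/GLFG counts;
spacers avoid phenylalanine and leucine (no accidental FG or GLFG, and
no spacer-created GLFG upgrade of a plain FG) and are compositionally
biased toward N/Q/S/T to mimic the disordered-region composition that
favours LLPS.

## The synthetic-data generator: what it emulates, and what not

`generate_cell_stack()` builds the validation scenes: an ellipsoidal
nucleus (default semi-axes 2.8 × 4.5 × 4.5 µm) on the default
acquisition grid of 62 planes at 0.2 µm z-spacing (a 12.2 µm axial
span) with 0.1 µm lateral pixels; uniform light-phase protein intensity
(default 100 a.u.) with spherical puncta (default 150 per nucleus,
radius 0.35 ± 0.05 µm) painted at `kp_true` × the light phase
(`kp_true` from ~2 to ~50 spans the contrast between constructs);
a DNA channel built as smoothed random texture (0.5 µm correlation
length, ~50 % relative contrast — deliberately harsh, with deep
chromatin-poor voids) whose `dna_overlap` parameter steers puncta onto
DNA-dense or DNA-poor voxels to span the PCC contrast between
chromatin-binding and non-binding constructs; optional cytoplasmic
puncta; Gaussian PSF-like blur; and Poisson + Gaussian noise with
configurable scales (the acquisition's photon and camera parameters are
not published, so these are exposed knobs rather than fixed truths).
Every scene records its ground truth (centres, radii, analytic volumes
(4/3)πr³, nucleus volume, `kp_true`), and generation is bit-identical
under a fixed seed.

Two generator choices matter for interpretation:

* **PSF width.** The default blur is mild and sub-voxel
  (σ = 0.05 µm axial / 0.04 µm lateral): it softens sphere edges
  without destroying identifiability. A realistic spinning-disk PSF
  (σ ≈ 0.08 µm lateral, ≈ 0.25 µm axial) retains only ~54–75 % of the
  dense-phase contrast inside the true sphere of a 0.35 µm punctum, so
  *any* region-mean [DP] estimator — this package's and the standard
  field practice alike — underestimates K_p several-fold-compressed
  under real optics. Passing parameter-recovery tests therefore
  validates the pipeline's bookkeeping and segmentation, not immunity
  to PSF bias; absolute K_p values from real submicron puncta should be
  read as lower bounds, and comparisons between constructs imaged
  identically remain meaningful.
* **Texture harshness.** The DNA texture's deep voids are harder than
  typical live Hoechst staining; they are what forced the adaptive
  thresholding and convex-fill machinery above, and they define the
  robustness envelope the tests demonstrate.

## Numerical choices and degenerate inputs

* All geometry is anisotropy-aware through the physical voxel size;
  axis order is channel-z-y-x, coordinates voxel-centred and 0-based
  internally, distances in µm.
* Axis convolutions are dense banded-kernel matrix products with
  border-renormalized kernels; the distance transform is the
  Felzenszwalb separable algorithm with per-axis spacings (a large
  finite sentinel replaces +∞ in the envelope arithmetic, which
  otherwise produces Inf − Inf = NaN) and treats out-of-volume space as
  background.
* Watershed flooding and seed ranking break exact ties by insertion and
  lexicographic voxel order, so all detection outputs are deterministic.
* Degenerate inputs degrade softly: blank stacks give empty label
  volumes with a warning; zero-punctum nuclei give defined densities
  and undefined distribution metrics; constant channels give `NA` PCC
  with a warning; placement that cannot satisfy the non-overlap
  constraint within the retry budget is an error.
* Validation problem sizes: the standard scene is one nucleus with 50
  puncta on a 32 × 96 × 96 grid; ellipsoid-volume checks run four
  geometries spanning semi-axes 2–6 µm; the FRAP recovery study uses
  100 seeds × 20 traces; the bracketing study 20 ladder/threshold
  combinations.

## Known limitations

* Volume accuracy on the smallest nuclei (semi-axes ~2–3 µm) can reach
  ~8 % error on adverse chromatin-texture realizations; across
  realizations the error is within a few percent.
* The convexity assumption is wrong for lobed or indented nuclei;
  disable `convex_fill` there and expect chromatin voids to need manual
  handling.
* Region-mean partitioning metrics compress under realistic PSFs (see
  above); no deconvolution or model-based PSF correction is attempted.
* Touching nuclei are not split (no nucleus-level watershed); the
  minimum-volume filter and boundary flags are the only guards.
* FRAP fitting assumes a single well-mixed recovering species; no
  reaction–diffusion modelling or bleach-geometry correction.
* The condensate/no-condensate call on dilution fields replaces a
  visual judgement with fixed count/area thresholds; the bracket is
  only as fine as the concentration ladder.
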