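# punctakit

Quantitative analysis of nuclear biomolecular condensates ("puncta")
formed by phase-separating fusion oncoproteins, from two-channel 3-D
confocal stacks, plus the companion biophysical readouts: FRAP recovery
fitting, in vitro saturation-concentration bracketing, turbidity
summaries, and FG-motif valence accounting for nucleoporin-derived
constructs. It is written for groups studying liquid–liquid phase
separation (LLPS) of chromatin-binding oncofusions — e.g. NUP98 fusion
proteins in leukemia models — who need per-cell, per-punctum numbers
rather than qualitative images.

## What it computes

For each nucleus (segmented from the DNA-stain channel) and its puncta
(scale-normalized Laplacian-of-Gaussian detection with seeded 3-D
watershed in the protein channel):

* puncta number density (count per 10³ µm³ nuclear volume) and mean
  punctum volume *V*<sub>p</sub> (µm³);
* light- and dense-phase concentrations [LP] and [DP] (calibrated mean
  intensity outside vs. inside puncta);
* the partition coefficient *K*<sub>p</sub> = [DP]/[LP] and the Gibbs
  free energy of transfer ΔG<sub>Tr</sub> = −*RT* ln *K*<sub>p</sub>
  (kcal/mol; negative = partitioning into puncta is favourable);
* Pearson colocalization (PCC) of protein with DNA over the nuclear
  mask, and the fraction of puncta within 0.5 µm of the nuclear
  periphery.

FRAP traces are double-normalized (background-subtracted, referenced to
an unbleached structure, prebleach = 1) and fitted with the
single-exponential recovery
*I*(t) = *I*₀ + *M*<sub>f</sub>(1 − *I*₀)(1 − 2^(−t/T<sub>½</sub>)),
yielding the half-time *T*<sub>½</sub> and mobile fraction
*M*<sub>f</sub>. Dilution-series images are reduced to
maximum-intensity projections, condensates counted per field, and the
saturation concentration *C*<sub>sat</sub> reported as a bracket
between the highest condensate-free and lowest condensate-positive
concentrations. FG/GLFG motif valence is counted per region, with
validated F→A and FG→AA mutation application.

A first-class synthetic-data generator produces ground-truthed scenes
(ellipsoidal nuclei, spherical puncta of known *K*<sub>p</sub>, DNA
texture with controllable punctum overlap, PSF-like blur, Poisson +
Gaussian noise), FRAP traces, dilution ladders, turbidity series and
FG-repeat sequences, so every pipeline stage is verifiable by parameter
recovery. See `vignettes/condensate-quantification.Rmd` for the methods
account.

## Worked example

```r
library(punctakit)

# a ground-truthed scene: one nucleus, 50 puncta, true Kp = 8
params <- scene_params(grid_shape = c(32L, 96L, 96L),
                       nucleus_semi_axes = c(2.2, 3.8, 3.8),
                       puncta_count = 50L, kp_true = 8, seed = 2L)
scene <- generate_cell_stack(params)

res <- quantify_stack(scene$stack)
round(res$cells[, c("n_puncta", "puncta_density", "v_p", "lp", "dp",
                    "k_p", "delta_g_tr", "pcc")], 3)
#>   n_puncta puncta_density   v_p      lp      dp   k_p delta_g_tr   pcc
#> 1       49        361.282 0.184 100.048 780.509 7.801     -1.266 0.103
```

49 of the 50 generated puncta are recovered; the measured light phase
(100.0 a.u.) matches the generated nucleoplasm level, and the measured
*K*<sub>p</sub> of 7.80 recovers the true ratio of 8 within a few
percent (ΔG<sub>Tr</sub> = −1.27 kcal/mol at 310 K: partitioning is
favourable). With the identity calibration, [LP] and [DP] are in a.u.;
supply `calibration_model(slope, offset)` for µmol/L.

```r
fit <- fit_recovery(normalize_trace(
  generate_frap_trace(t_half = 12, m_f = 0.7, noise_sd = 0.02,
                      n_points = 60, seed = 5)))
fit
#> <frap_fit> T_1/2 = 12.19 s, M_f = 0.7097, rss = 0.0241, converged = TRUE

csat_bracket(generate_dilution_series(csat_true = 50,
                                      concentrations = c(10, 20, 40, 80, 160),
                                      seed = 1))
#> <csat_bracket> C_sat between 40 and 80
```

## Analysis workflow

`analysis/` holds numbered driver scripts over the package functions —
a simulated two-construct imaging experiment end to end:

1. `01_simulate_scenes.R` — two constructs (strongly vs. weakly
   partitioning), six cells each, written as OME-style TIFFs under
   `scratch/` with manifests and ground truth under `results/`;
2. `02_quantify_cells.R` — segmentation, per-cell metrics,
   per-construct summaries, Mann–Whitney construct comparisons, trend
   and periphery statistics;
3. `03_frap_recovery.R` — group-mean FRAP fits for a liquid-like and a
   gel-like condition;
4. `04_invitro_csat.R` — *C*<sub>sat</sub> brackets across a
   construct ladder and a turbidity summary;
5. `05_fg_valence.R` — FG/GLFG valence and composition table for the
   wild-type, 8FA, 21FGAA and Midi-style constructs.

Each writes its tables under `results/`.

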