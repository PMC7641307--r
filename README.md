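# xsijunction

Conformational-ensemble analysis of a DNA four-way (Holliday) junction from
X-ray scattering interferometry (XSI) and single-molecule FRET, for
structural biologists working on nucleic-acid junctions and for anyone who
needs a tested, self-contained implementation of the XSI molecular-ruler
pipeline.

The Holliday junction — the central intermediate of genetic recombination —
stacks into two X-shaped conformers (isoI/isoII) at high ionic strength and
opens up at low ionic strength. XSI resolves this directly: two 7 Å gold
nanocrystals attached to specific arms scatter X-rays whose interference
term encodes the distribution of their separation,

    B(q, d) = F(q, R)^2 · sin(qd)/(qd),

with `F` the sphere form amplitude of the gold label. From six measured
profiles per condition (double-labeled AB, single-labeled A and B, unlabeled
U, free gold Au, buffer Buf) the combination `AB + U − A − B` isolates the
gold–gold interference, which a maximum-entropy fit over the basis curves
`B(q, d)` inverts into an absolute distance distribution
P(d) (entropy `−Σ p ln(p/m)` maximized subject to `χ²/N ≤ 1`). Peak areas
give conformer populations and `ΔΔG = RT ln(p_major/p_minor)`; parametric
arm-geometry models (stacked-X, planar cross, square pyramid, tetrahedral)
are fitted to measured distances for model discrimination; and a two-state
dwell-time analysis extracts interconversion rates from smFRET traces.

The package includes a full synthetic-data module (bead-model Debye
simulation of all six profiles with counting noise; telegraph-process FRET
traces), so every stage of the pipeline is testable without beamline data.

## Worked example

Simulate the high-Mg²⁺ BH-label condition (isoII 84% at 54 Å, isoI 16% at
89 Å), extract the interference pattern, invert it, and summarize:

```r
library(xsijunction)

bundle  <- generate_xsi_bundle(scenario_preset("high_Mg_BH"), seed = 42)
sub     <- lapply(bundle$profiles[c("AB", "A", "B", "U")],
                  subtract_buffer, buffer = bundle$profiles$Buf)
pattern <- extract_interference(sub$AB, sub$A, sub$B, sub$U)
basis   <- build_basis_matrix(pattern$q_grid, default_d_grid())
dist    <- fit_distribution(pattern, basis)

ensemble_summary(dist, q_max = max(pattern$q_grid), min_height = 0.5,
                 label_pair = bundle$label_pair,
                 condition = bundle$condition)
#> Ensemble summary [BH] @ 10 mM MgCl2
#>   peak 1: mode 54.0 A (5.0-73.0 A), area 78.8%
#>   peak 2: mode 88.0 A (73.0-117.0 A), area 16.5%
#>   major/minor = 83%/17%, ddG = 0.925 kcal/mol at 298.15 K
```

The inversion recovers the stacked-state mixture: the major population at
54 Å (the short BH distance of isoII), the minor one near 89 Å (isoI), a
population split close to the generating 84/16, and a free-energy
preference for isoII of ~1 kcal/mol.

Kinetics from simulated smFRET traces (77 traces × 10 s at 306 fps, states
E = 0.58/0.14 interconverting at 45.6 and 7.9 s⁻¹):

```r
set.seed(42)
traces <- lapply(1:77, function(i)
  generate_fret_trace(fret_state_model(), duration = 10))
res <- analyze_fret_traces(traces)
res$rates
#> <dwell_summary> 7975 transitions, 3973 + 3925 complete dwells
#>   k(low->high) = 47.4 +/- 0.75 1/s, k(high->low) = 6.4 +/- 0.1 1/s
#>   occupancy low/high = 0.143/0.857
round(res$E_high, 3)
#> [1] 0.578
```

Geometric model predictions for the open state:

```r
pair_distance(junction_preset("planar"), "BR")   # opposite arms, planar cross
#> [1] 109.3
compare_geometry_models(c(BR = 93, HR = 90, RX = 87))
#>        family         rmsd overparameterized
#> 1      planar 1.318665e+01             FALSE
#> 2     pyramid 1.318541e+01             FALSE
#> 3 tetrahedral 2.563773e+00             FALSE
#> 4        free 1.854422e-06             FALSE
```

The planar cross misses the measured low-salt distances by ~13 Å RMSD
(its opposite-pair prediction of 109.3 Å overshoots the measured 93 Å),
while an out-of-plane (tetrahedral-like) arrangement fits within ~2.6 Å —
the geometric signature of an open, non-planar junction.

An end-to-end run over named conditions, with all intermediates written to
disk, is available through `run_pipeline()` (see `?run_pipeline` and the
thin CLI wrapper in `inst/scripts/xsi_pipeline.R`), and the methods
vignette (`vignettes/xsi-junction-methods.Rmd`) documents the model,
parameter choices and limitations.

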