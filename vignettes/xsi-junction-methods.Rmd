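---
title: "Methods: XSI distance distributions and smFRET kinetics for a DNA four-way junction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: XSI distance distributions and smFRET kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xsijunction)
```

## The measurement being modeled

X-ray scattering interferometry (XSI) attaches two small gold nanocrystals
(radius 7 &Aring;) to specific arms of a macromolecule and measures the
interference between their scattered waves. For an isotropic solution the
interference contribution of a label pair at distance $d$ is

$$B(q, d) = F(q, R)^2 \,\frac{\sin(qd)}{qd},
\qquad F(q,R) = 3\,\frac{\sin(qR) - qR\cos(qR)}{(qR)^3},$$

where $F$ is the sphere form amplitude of the gold label. A measured
interference pattern is therefore a weighted superposition of these basis
curves over the distribution $P(d)$ of label separations in the ensemble —
which is exactly what makes the technique a *molecular ruler*: inverting the
pattern returns an absolute distance distribution, not a single average.

The experiment records six profiles per condition: the doubly labeled
construct (AB), two singly labeled constructs (A, B), the unlabeled molecule
(U), free gold (Au) and buffer (Buf). After buffer subtraction, the
combination

$$I_{\mathrm{Au-Au}}(q) = I_{AB} + I_U - I_A - I_B$$

cancels the molecule term and both molecule–gold cross terms exactly when
the four constructs share one conformational ensemble, leaving only the
gold–gold interference. The package implements this subtraction literally
(`subtract_buffer()`, `extract_interference()`) and verifies the exact
cancellation property on synthetic data, where all four constructs are built
from the same conformer sample.

The system under study is a four-way (Holliday) DNA junction assembled from
four 22-mer strands, i.e. four 11-bp arms named X, B, H and R in cyclic
order. At high ionic strength it stacks into two conformers (isoI, isoII)
that exchange on the tens-of-milliseconds timescale; at low ionic strength
electrostatic repulsion holds it in an open state. Label pairs on different
arms (BH, HR, BR, RX) triangulate the arm geometry.

## Forward model

`debye_intensity()` evaluates the orientation-averaged Debye sum

$$I(q) = \sum_{i}\sum_{j} f_i(q) f_j(q)\,
\mathrm{sinc}(q\,r_{ij})$$

over a coarse bead model: one unit-weight point bead per base pair placed on
the helix axis, plus gold labels with weight 25 modulated by the sphere form
amplitude. Radial helical detail is far below the resolution of the
technique, and the 25:1 contrast reflects the electron-density dominance of
a 7 &Aring; gold particle over a base pair that the method relies on. The
default momentum-transfer grid is 256 linear points on
0.01–0.35 &Aring;⁻¹, a typical small-angle range for these
detector geometries; the distance grid for inversions is 5–150 &Aring; in
1 &Aring; steps, spanning every distance an 11-bp-arm junction can produce.

## Synthetic data generator

Because no public scattering data accompany this system, the generator is a
first-class module rather than a test fixture. A scenario is a mixture of
junction states, each with a characteristic gold–gold distance, a
population weight, and a central gap (0 for stacked states, 16.3 &Aring;
for open ones). Per state it samples 200 conformers: the labeled-arm
opening angle and an axial breathing factor are jittered so the label
distance is Gaussian with s.d. 5 &Aring; (the ensemble width; split evenly
in variance between the angular and axial modes). All four constructs are
built from the *same* conformer sample, so the interference extraction
cancels exactly up to noise — the property the real experiment relies on
approximately.

Counting noise is added per exposure as
$\sigma(q) = \epsilon\sqrt{I(q)\,I(q_1)}$ with $\epsilon = 1\%$ at the
low-$q$ anchor, and 10 exposures are averaged, mirroring the 10 × 3 s
exposure protocol; the reported uncertainty is the standard error of that
average. The buffer is a flat baseline (10% of the unlabeled construct's
forward intensity) added to every sample profile; free gold is two
uncorrelated spheres.

Shipped presets encode the reported ensembles: `high_Mg_BH` (54 Å at 84%,
89 Å at 16%), `high_Mg_HR` (89 Å at 84%, 57 Å at 16%), `intermediate_Mg_BH`
(61/84 Å), and single-state open presets `low_salt_BR` (93 Å),
`low_salt_HR` (90 Å), `low_salt_RX` (87 Å). For `high_Mg_BR` the two
stacked states are nearly symmetric and the measured peaks overlap; no
separate distances are published, so the preset uses 86/90 Å — a separation
below the ensemble width, reproducing the observed single broadened
feature. The generator does **not** emulate detector artifacts, radiation
damage, inter-particle interference at finite concentration, label
flexibility beyond the effective axial offset, or gold-size polydispersity;
passing tests demonstrate correct inversion of the stated physics, not
robustness to those real-data effects.

The smFRET generator simulates a continuous-time two-state telegraph
process with exponential dwells (defaults: $k_{I\to II}=45.6$ s⁻¹,
$k_{II\to I}=7.9$ s⁻¹), integrates state occupancy across each camera frame
at 306 fps, and emits donor/acceptor intensities with fixed total
(1000 a.u.) and per-channel Gaussian noise (80 a.u.), which makes the
0.58/0.14 efficiency states clearly resolvable, as in the published traces.
Photophysics (blinking, bleaching) is out of scope.

## Maximum-entropy inversion

`fit_distribution()` recovers $P(d)$ by maximizing the relative entropy
$S = -\sum_i p_i \ln(p_i/m_i)$ (uniform prior $m$ by default) subject to
$\chi^2/N \le 1$, with an overall amplitude refit in closed form at every
evaluation (weighted least squares; the basis normalization absorbs
concentration and exposure scale). Numerical choices:

* **Feasibility first.** The least-$\chi^2$ solution over non-negative
  weights is computed exactly by non-negative least squares (the amplitude
  is absorbed into unnormalized weights, making $\chi^2$ quadratic). If even
  that cannot reach the target, the NNLS solution is returned with an
  `infeasible` flag — the constraint is never silently relaxed.
* **Multiplicative positivity.** For a fixed trade-off multiplier
  $\lambda$, the inner problem $\min_p \lambda\chi^2 - S$ is solved in
  softmax coordinates $p_i = e^{z_i}/\sum_j e^{z_j}$ with the analytic
  gradient (the amplitude term drops by the envelope theorem) under BFGS.
  This is a multiplicative update scheme — weights stay positive without
  explicit bounds — and is validated against a brute-force constrained
  optimizer on small grids.
* **Constraint matching.** $\lambda$ is bracketed geometrically and then
  bisected on $\log\lambda$ until $\chi^2/N$ lands within $\pm 0.05$ of the
  target, warm-starting each solve; a final full-budget polish runs at the
  selected multiplier. Weights below $10^{-12}$ are reported as zero.
* **Degenerate input.** If the prior already satisfies the constraint
  (e.g. uncertainties so large the data carry no information), the prior is
  returned unchanged — the entropy maximum.

## Resolution matching and peak analysis

A pattern measured on $q \le q_{\max}$ determines Fourier components of
$P(d)$ only up to $q_{\max}$. At the $\chi^2/N = 1$ stopping point the
entropy term fills the unconstrained band with low-amplitude structure:
broad peaks acquire ripple of period $\approx 2\pi/q_{\max}$
(~18 &Aring; here), and data-free stretches of the grid relax toward the
prior as flat plateaus. Both are well-understood artifacts of
entropy-regularized inversion, and both are handled in the analysis layer,
not by additional regularization (the inversion itself stays entropy-only):

* `resolution_smooth()` convolves the recovered weights with a Gaussian of
  s.d. $\pi/(2 q_{\max})$ (~4.5 &Aring; at the default range) — enough to
  suppress band-edge ripple, while blurring genuine features by less than
  the instrumental resolution $\pi/q_{\max}$. Peak *modes* are unbiased by
  the symmetric kernel; well-separated peaks keep their areas.
* `find_peaks()` partitions the grid at the minima between local maxima,
  merges peaks with area below `min_area = 0.02` into their nearest
  neighbor (ripple-scale fragments), and, when `min_height` is set,
  excludes segments whose maximum never rises above that fraction of the
  uniform level $1/n$ (default 0.5 in the pipeline): a "peak" that stays
  below half the prior floor is entropy backfill, not a detected
  population. Peak modes are reported at grid resolution — 1 &Aring; —
  without sub-grid interpolation.

Populations are renormalized areas of the retained peaks, and the conformer
preference is $\Delta\Delta G = RT\ln(p_{major}/p_{minor})$ at 298.15 K by
default. The measurements themselves were done at 5–15 °C; the standard
state is used because the published ~1 kcal/mol figure is consistent with
it, and the temperature is an explicit argument.

## Geometry models

`junction_geometry()` places a gold label at
$\tfrac{gap}{2} + n_{bp}\,rise + offset$ along each arm direction. The
constants are anchored as follows: 11 bp per arm (22-mer strands), B-form
rise 3.3 &Aring;, central gap 16.3 &Aring; for open states (from a
protein-bound planar crystal structure), and an effective axial gold offset
of 10.2 &Aring; per label, calibrated so a continuous 22-bp helix with
terminal labels predicts 93.0 &Aring; — the published B-form ruler value
for this construct. The separately published rotational offset is folded
into this effective axial value; a +2 &Aring; `salt_offset_shift`
reproduces the reported label displacement at intermediate salt.

The planar cross predicts $2 \times 54.65 = 109.3$ &Aring; for opposite
pairs and $\sqrt{2} \times 54.65 = 77.3$ &Aring; for adjacent ones; the
tetrahedral arrangement puts all six pairs at
$2 \times 54.65\sqrt{2/3} = 89.2$ &Aring;. `fit_arm_directions()`
least-squares fits a family's free parameters to measured distances —
none for planar/tetrahedral, the apex half-angle for a regular square
pyramid, and all four directions (8 spherical angles, deterministic
multi-start BFGS seeded from the structured families plus 24 fixed random
starts) for the free family. Because each family is seeded from its nested
predecessors, RMSD is non-increasing along planar ⊂ pyramid ⊂ free. With
fewer than three measured distances the free fit is flagged
over-parameterized. The inter-duplex angle of a stacked form inverts
$d = 2L'\sin(\mathrm{IDA}/2)$ with $L' = n_{bp}\,rise + offset$; with the
default offsets a 54 &Aring; short pair gives ~71°, somewhat above the
canonical ~60°, which suggests the stacked short-pair geometry also
involves a radial label offset this parameterization folds into the axial
term — a known limitation.

## smFRET kinetics

Efficiency is the proximity ratio $E = I_A/(I_A + I_D)$ (no gamma
correction). Idealization is a transparent threshold classifier at the
midpoint of the state efficiencies (0.36 for 0.58/0.14) followed by
iterative removal of runs shorter than 2 frames; it is validated by ≥95%
frame-wise agreement with the latent simulated path under the default
noise. Rates are reciprocal mean dwells with the censored first and last
dwells discarded. Because the idealizer cannot observe dwells shorter than
its minimum-dwell filter, observed dwells follow a truncated exponential
with mean $t_{dead} + 1/k$; `estimate_rates()` therefore *subtracts* the
dead time (`min_dwell_frames/fps` in the pipeline) from the mean dwell
before inverting. At 306 fps and $k_{I \to II} = 45.6$ s⁻¹ the mean isoI
dwell is only ~6.7 frames, so this correction is what keeps the recovered
forward rate within a few percent; the uncorrected estimator is ~20% low.
Standard errors are $k/\sqrt{n_{dwells}}$, and equilibrium populations
follow detailed balance, $p_{II} = k_{I\to II}/(k_{I\to II} + k_{II\to I})$.

## Problem sizes and determinism

Analyses in the tests and in `scripts/acceptance.R` use the package
defaults throughout: 200 conformers per state on the 256-point q grid for
scattering, and 77 traces × 10 s at 306 fps (several thousand transitions)
for kinetics — sizes at which the stochastic targets sit comfortably inside
their tolerances. Every random operation takes an explicit seed, and a
fixed seed reproduces bundles, traces, fits and pipeline output files
byte-for-byte; `run_pipeline()` stamps each output with a hash of its
configuration.

## Known limitations

* The basis normalization (overall amplitude as a free scale) follows the
  $F^2 \mathrm{sinc}$ convention; absolute intensities are not modeled.
* No solvent-excluded-volume or hydration-layer corrections; DNA beads are
  point scatterers on the axis.
* The entropy-only inversion plus resolution matching recovers peak
  positions and areas, but peak *widths* inherit both the 5 &Aring;
  generator jitter and the smoothing kernel and should not be read as
  ensemble widths.
* The two-state threshold kinetics deliberately replaces likelihood-based
  trace modeling; it requires resolvable states and a frame rate well above
  the fastest rate.
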