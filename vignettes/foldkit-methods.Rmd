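---
title: "Models and methods behind foldkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foldkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldkit)
```

foldkit implements the quantitative analysis used in *in vitro* studies of
outer-membrane-protein (OMP) folding: kinetic folding assays in liposomes,
chaperone binding titrations, gel and CD controls, and coarse-grained (CG)
membrane simulations around a β-barrel protein. This vignette describes
each model, the defaults and why they were chosen, the numerical details,
and what the synthetic-data generators do and do not emulate.

## Kinetic folding transients

A folding transient is a time series of tryptophan fluorescence recorded
after diluting an unfolded OMP into liposomes. Two regimes occur in
practice:

- **Exponential transients.** Fluorescence relaxes as
  $y(t) = A_1 e^{-k_1 t} + c$ or
  $y(t) = A_1 e^{-k_1 t} + A_2 e^{-k_2 t} + c$. Replicates of the same
  condition are fitted *globally*: they share the rate constant(s) while
  keeping independent amplitudes and offsets, because replicate traces
  report the same kinetics but different absolute intensities.
- **Lag-phase transients.** In some lipids folding shows a lag before a
  rapid rise, which no small sum of exponentials fits well. These are
  summarized model-free by the half-time $t_{50}$ (below); a
  four-parameter logistic (`fit_sigmoid()`) is available for display only.

### Global fitting

`fit_exponential_global()` uses variable projection: for a candidate rate
vector the per-transient amplitudes and offsets are the exact linear
least-squares solution, so the numerical search runs only over one or two
log-rates. The search is initialized from a deterministic log-spaced grid
spanning $[1/(10\,t_{\max}),\ 10/\Delta t_{\min}]$ — slower than anything
observable up to faster than the sampling — which removes the need for
manual starting values and makes the fit reproducible: the same data give
the same fit. One-exponential fits use golden-section refinement around
the best grid point; two-exponential fits refine the best three grid pairs
by Nelder–Mead. Rates are reported in descending order ($k_1 > k_2$), with
amplitudes permuted to match. Standard errors come from the linearized
covariance $\hat\sigma^2 (J^\top J)^{-1}$ using the full analytic Jacobian
over rates, amplitudes, and offsets.

Replicates are equally weighted. When batch identifiers are present,
`summarize_values()` averages within batches first and computes the
s.e.m. across batch means, matching the convention of reporting errors
across independent liposome batches.

### Model selection

Whether a transient needs a second exponential is traditionally judged by
inspecting residuals. `select_exponential_model()` replaces that with a
reproducible rule: the two-exponential fit is kept only if it improves the
corrected AIC by more than 10 **and** the two rates are positive and
separated by more than a factor of 3. Both thresholds are arguments. An
AICc margin of 10 is decisive evidence under the usual information-
criterion calibration, and the separation requirement discards
two-exponential "fits" that split one phase into two nearly identical
rates. Constant signals are rejected outright ("no decay component").

### The half-time t50

`extract_t50()` follows the standard recipe: locate the global minimum of
the signal; fit a horizontal baseline to the trailing fraction of samples
(default `baseline_fraction = 0.1`, since published transients plateau
well before the end of acquisition — the trailing tenth is flat); the
$t_{50}$ is the first time at or after the minimum where the signal
crosses the midpoint of those two levels, located by linear interpolation
between the bracketing samples. Taking the *first* crossing after the
minimum makes the estimator well defined under noise, where the half level
can be crossed repeatedly. The estimator is invariant under affine signal
transforms and scales linearly with the time axis; for rising
single-exponential data it equals $\ln 2 / k$ to within one sampling
interval (both properties are tested).

Failure states are explicit: a signal that never reaches the half level
("no folding detected") or a baseline at or below the minimum
(monotonically decreasing signal) raise classed errors rather than
returning numbers.

### Fold changes

Catalysis is summarized as a ratio $R = X/Y$ of two means (rates or
$t_{50}$ values) with the error propagated in quadrature:
$\delta R = |R| \sqrt{(\delta X/X)^2 + (\delta Y/Y)^2}$, where
$\delta X, \delta Y$ are s.e.m. values. `fold_change()` rejects zero
denominators and satisfies $R_{XY} \cdot R_{YX} = 1$.

### Sigmoid form

The sigmoidal function used for display of lag-phase transients is the
four-parameter logistic
$y(t) = L + (U - L)/(1 + e^{-s(t - t_m)})$ — the minimal sigmoid with two
asymptotes, a midpoint, and a steepness. Published figures do not pin down
the functional form, so the simplest standard choice was made; no
quantitative conclusions are drawn from this fit ($t_{50}$ values always
come from `extract_t50()`).

## Hill-equation binding analysis

MST titrations are modelled as
$$S_{obs} = S_U + (S_B - S_U)\,\frac{[L]^n}{K_D + [L]^n}.$$
In this algebraic form $K_D$ has units of concentration$^n$, which makes
values incomparable across different $n$. `fit_hill()` therefore fits and
reports the apparent dissociation constant
$K_{d,app} = K_D^{1/n}$ — the ligand concentration at half saturation —
and emits the raw $K_D$ as a derived quantity; both are in the output
because published values do not always say which convention they use.

Fitting is Levenberg–Marquardt (`minpack.lm::nlsLM`) with data-driven
initialization: $S_U$, $S_B$ from the signals at the lowest/highest
concentrations, $K_{d,app}$ from the concentration nearest half signal
change, $n = 1$. Zero-concentration points are valid data (the model
predicts $S_U$ there) but play no role in the log-scale initialization.
The Hill coefficient can be held fixed (`fix_hill_n = 1`) to reproduce the
standard cooperativity comparison: the residual sum of squares of the
constrained fit is reported so free-$n$ and $n = 1$ fits can be compared
directly. A warning is raised when the fitted $S_B$ lies far outside the
observed signal range (saturation not approached).

`simulate_titration()` reproduces the serial-dilution design: sixteen
two-fold dilutions from 100 µM reach $100/2^{15}$ µM ≈ 3 nM, the ladder of
the SurA-vs-labeled-tOmpA experiment. Default generating parameters are
the reported ones ($K_{d,app} = 1.8$ µM, $n = 1.5$), with Gaussian noise
whose default SD is 1% of the dynamic range.

## Gel and CD observables

`fraction_folded()` implements
$\text{fraction folded} = F/(F + U)$ with $F$, $U$ the folded/unfolded
band intensities of the unboiled lane. The alternative convention that
divides by the boiled-lane band is available via
`denominator = "boiled"`, but the unboiled-lane ratio is the default
(dividing by the boiled band can exceed 1 when the unboiled bands are not
depleted).

`mean_residue_ellipticity()` computes $MRW = M/(N-1)$ (Daltons per peptide
bond) and $[\theta]_{MRE} = MRW\,\theta_\lambda/(10\,d\,c)$ with $d$ in cm
and $c$ in g/mL. The concentration unit in the printed formula is
ambiguous in parts of the literature, so a `conc_units = "mg_ml"` flag is
provided; the default follows the g/mL definition. Spectra are expected
blank-subtracted upstream.

## Coarse-grained membrane analysis

The membrane module contrasts the lipid environment at a designated
protein residue (for a β-barrel, typically the strand-seam residue and an
equivalent residue on the opposite face) with bulk membrane:

- **Selections.** *Annular*: lipids whose PO4 bead lies within 12 Å
  (inclusive) of any bead of the anchor residue. *Bulk*: lipids whose PO4
  bead is strictly more than 30 Å from every protein bead. Distances use
  the xy-periodic minimum image; z is non-periodic (planar bilayer with
  solvent slabs). Selections are recomputed every frame. A
  `lipid_reference = "any_bead"` switch measures the annular distance from
  whole lipids instead of phosphates; the PO4 default keeps the annular
  and bulk criteria consistent.
- **Thickness.** Mean PO4 z of the selected upper-leaflet lipids minus the
  selected lower-leaflet lipids. Leaflets are assigned by PO4 position
  relative to the midplane (mean PO4 z). Published work does not define a
  local thickness estimator; this selection-restricted leaflet-mean is the
  simplest phosphate-based one. Each leaflet must contribute at least
  `min_per_leaflet = 3` lipids, otherwise the frame contributes a missing
  value (excluded from time averages) — three lipids is the minimum for a
  mean that is not dominated by a single molecule.
- **Order parameters.** For each bond along each acyl chain,
  $S = \tfrac12(3\cos^2\theta - 1)$ with $\theta$ the angle to the z axis
  (the bilayer normal is fixed to z; all systems are planar, so no
  local-normal estimation is attempted). Bonds are labelled G-1 (glycerol
  bead to first chain bead: GL1–C1A and GL2–C1B), then 1-2, 2-3, 3-4 as
  the chain length allows — two-bead chains have only G-1 and 1-2. The two
  chains are pooled into one value per bond label.
- **Aggregation.** `profile_trajectories()` discards the first
  `burn_in_fraction` of frames per replica (default 1/6: a trajectory
  spanning 3 µs is analysed over its final 2.5 µs), time-averages each
  metric per replica with equal frame weights, then reports mean ±
  sample SD (n−1) across replicas. Replicas must expose identical bond
  sets.

## The synthetic bilayer generator

`generate_bilayer_trajectory()` builds planar two-leaflet MARTINI-style
bilayers (one PO4, two glycerol beads, 2/3/4 acyl beads per chain — thin
to thick lipids) around a cylindrical "barrel" of protein beads, with
sizes chosen to match typical CG systems: ~360 lipids, 30 frames, 5
replicas, at lattice spacing 7.5 Å (~56 Å² per lipid). One protein residue
per azimuthal column of beads gives the barrel author-numberable residues;
the ground-truth record names the seam and opposite anchors.

Two design points matter for how the generator is used in tests:

- **Plateau perturbation profile.** The imposed thinning (and extra chain
  disorder) around the seam anchor follows a plateau-Gaussian radial
  profile: full depth $\Delta$ within `thinning_plateau` (default 13 Å) of
  the anchor point, Gaussian decay (width 4 Å) beyond. The plateau covers
  the whole 12 Å annular shell, so the expected annular thickness is
  *exactly* `bulk_thickness − thinning_depth`, while the opposite face and
  the bulk are unperturbed to well below the jitter level. A plain
  Gaussian centred on the seam cannot do this: averaged over the shell it
  delivers only part of $\Delta$, and its tail reaches the opposite face.
  The plateau profile keeps the recovery tests sharp.
- **Deterministic cone-angle chains.** Acyl chains are built bead by bead
  with a fixed polar angle $\theta_c$ from the normal and a uniform random
  azimuth per bond, so every bond has exactly
  $S = \tfrac12(3\cos^2\theta_c - 1)$ — the order-parameter ground truth
  is analytic, not sampled, and recovery tests need no stochastic oracle.
  Defaults are $\theta_c = 20°$ in bulk ($S = 0.82$) and $40°$ at the seam
  ($S = 0.38$), i.e. a disordered seam.

Lipids are placed on a jittered square lattice plus two concentric rings
packed against the barrel wall. The rings emulate annular-shell packing
and guarantee that the 12 Å selection is populated in both leaflets; a
bare lattice at bilayer density leaves the shell underpopulated.

What the generator does **not** emulate: physical dynamics. Frames are
i.i.d. redraws of jitter and azimuths, not time-correlated MD; there is no
lipid diffusion, no elastic response, no headgroup chemistry, and the
protein is a rigid cylinder. Passing recovery tests therefore demonstrates
that the *estimators* are correct and unbiased at realistic geometry and
noise, not that any particular simulation result is reproduced. The same
holds for the kinetic and titration generators: multiplicative Gaussian
noise emulates photomultiplier noise levels but not instrument drift,
photobleaching, or mixing artifacts.

## Numerical choices and degenerate inputs

- All lengths are Å, kinetic times seconds, trajectory times µs,
  concentrations molar; GRO files (nm) are converted on read/write.
- Rate ordering ties are broken as $k_1 \ge k_2$ with amplitudes permuted
  accordingly.
- Zero-length bonds are skipped in order-parameter computation; lipids at
  exactly the annular cutoff are included (≤), lipids at exactly the bulk
  cutoff are excluded (strict >).
- Burn-in uses `floor(fraction × n + 1e-9)` so that, e.g., 30 frames at
  1/6 discard exactly 5 frames despite floating-point representation.
- A single replica yields SD 0 rather than NA, flagged by
  `n_replicas = 1` in the profile.
- Malformed inputs (non-monotone time, fewer samples than parameters,
  monolayers, unknown anchor residues, invalid GRO records) raise classed
  errors (`foldkit_input_error` / `foldkit_fit_error`) with informative
  messages rather than propagating NaN.

## Problem sizes used in the test suite

The suite validates parameter recovery with 100-seed kinetic and
200-seed titration simulations, and membrane recovery on 5 replicas × 30
frames × ~360 lipids (with smaller configurations in unit tests). These
sizes keep every estimate's Monte-Carlo error well below the tolerances
being checked.

## Known limitations

- The global fitter assumes homoscedastic noise within a transient; with
  strongly multiplicative noise the reported rate standard errors are
  approximate (coverage is verified empirically in the tests).
- The local thickness estimator does not pair leaflets within an annulus;
  for strongly curved or deformed bilayers a surface-fitting estimator
  would be preferable.
- No support for binary trajectory formats (XTC/TRR); multi-frame GRO is
  the interchange format.
- The Hill fit treats the MST signal as a generic binding readout; no
  thermophoresis physics is modelled.
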