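# foldkit

Tidy analysis tools for *in vitro* outer-membrane-protein (OMP) folding
studies. The package covers the quantitative pipeline of a typical
BamA-catalysis experiment end to end:

- **Folding kinetics.** Fluorescence folding transients are fitted with
  single- or double-exponential models, *globally*: replicate transients
  share the rate constant(s) `k1` (and `k2`) while keeping independent
  amplitudes `A1`, `A2` and offsets `c`, the standard treatment for
  replicate folding traces. Lag-phase (sigmoidal) transients are compared
  model-free via the half-time `t50`: the time to reach halfway between the
  minimum fluorescence and a horizontal baseline fitted to the trailing
  part of the trace.
- **Fold-change statistics.** Ratios `R = X/Y` of rates or `t50` values
  carry errors propagated in quadrature,
  `δR = |R|·sqrt((δX/X)² + (δY/Y)²)`, with `s.e.m. = σ/√n` computed across
  liposome batches when batch identifiers are present.
- **Binding.** MST titrations are fitted with the Hill equation
  `S_obs = S_U + (S_B − S_U)·[L]ⁿ/(K_D + [L]ⁿ)`; the apparent dissociation
  constant `K_d,app = K_D^(1/n)` (the half-saturation concentration) is
  reported alongside the raw `K_D`.
- **Gel and CD observables.** Fraction folded from semi-native SDS-PAGE
  band intensities, and mean residue ellipticity
  `[θ]_MRE = MRW·θ_λ/(10·d·c)` with `MRW = M/(N−1)` for CD spectra.
- **Membrane analysis.** Coarse-grained bilayer snapshots (GRO format or
  generated) are profiled for local vs bulk properties: phosphate-based
  membrane thickness and acyl-chain order parameters
  `S = ½(3cos²θ − 1)` per bond (G-1, 1-2, 2-3, 3-4), for lipids within
  12 Å of designated protein residues (e.g. the β-barrel seam) and for
  bulk lipid (> 30 Å from the protein), averaged over post-burn-in frames
  and replicate trajectories.
- **Synthetic data.** Seeded generators produce folding transients,
  serial-dilution titrations, and planar CG bilayer trajectories with an
  imposed seam thinning/disorder profile and *exact* ground truth, so the
  whole pipeline is testable without external data.

All user-facing functions take a data frame first and return tibbles;
fitted objects support `tidy()`, `glance()`, `augment()`, and
`autoplot()`.

## Worked example

```r
library(foldkit)

# three replicate folding transients at k = 0.0149 /s with 2% noise
tr  <- generate_transients(rates = 0.0149, amplitudes = -5, offset = 6,
                           noise_fraction = 0.02, n_replicates = 3, seed = 7)
fit <- fit_exponential_global(tr, n_exponentials = 1)
fit
#> Global 1-exponential fit: 3 transient(s), 1803 observations
#>   k1 = 0.0149 +/- 7.8e-05 s^-1
#>   RSS = 22.65, AICc = -7878

# catalysis comparison from two summarized rates (units 1e-3 /s)
fold_change(c(mean = 14.9, sem = 0.3), c(mean = 1.2, sem = 0.1))
#> # A tibble: 1 × 6
#>   ratio ratio_error numerator_mean numerator_sem denominator_mean denominator_sem
#>   <dbl>       <dbl>          <dbl>         <dbl>            <dbl>           <dbl>
#> 1  12.4        1.06           14.9           0.3              1.2             0.1

# Hill fit of a simulated 16-point MST titration
tt <- simulate_titration(kd_app = 1.8e-6, hill_n = 1.5, seed = 1)
fit_hill(tt)
#> Hill fit (16 points): K_d,app = 1.78e-06 M, n = 1.48, RSS = 13.98
```

The first fit recovers the shared rate (0.0149 ± 0.00008 s⁻¹, matching
the generating 0.0149 s⁻¹). The fold change says the numerator condition is
12.4 ± 1.1 times faster than the denominator. The Hill fit recovers the
generating affinity (1.78 vs 1.8 µM) and cooperativity (1.48 vs 1.5).

For the membrane side:

```r
traj <- generate_bilayer_trajectory(chain_beads = 4, thinning_depth = 12,
                                    n_frames = 30, n_replicas = 5, seed = 1)
gt   <- attr(traj, "ground_truth")
prof <- profile_trajectories(traj,
          anchors = c(seam = gt$seam_residue, opposite = gt$opposite_residue))
tidy(prof)
```

reports seam thickness ≈ 32 Å vs bulk ≈ 44 Å (the imposed 12 Å thinning)
and seam order parameters ≈ 0.38 vs bulk ≈ 0.82 on every bond (the
imposed disorder).

A thin command-line wrapper over these functions is installed at
`inst/scripts/foldkit.R` (subcommands `fit-kinetics`, `t50`, `fold-change`,
`fit-hill`, `mre`, `fraction-folded`, `membrane-profile`,
`simulate-transients`, `simulate-titration`).

## Vignette

`vignettes/foldkit-methods.Rmd` documents the models, estimators, default
parameters, numerical choices, and the scope and limitations of the
synthetic generators.
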