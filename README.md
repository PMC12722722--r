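# poregate

Free-energy, kinetic and titration analysis of gated membrane channels.

`poregate` is an R toolkit for the quantitative layer of molecular
dynamics studies of pH-gated channels such as the aquaglyceroporins
(water/glycerol/H2O2 channels whose extracellular loop collapses at
acidic pH). It is aimed at simulation scientists who already have
trajectory-derived tables (umbrella-window samples, solute traces,
protonation time series, nonequilibrium work values, distance series)
or deposited coordinate models, and need the downstream statistics:

- **WHAM free-energy profiles** from umbrella-sampling windows:
  self-consistent solution of
  `rho(z) = sum_i h_i(z) / sum_j N_j exp((f_j - w_j(z))/kT)`,
  `f_j = -kT ln sum_z rho(z) exp(-w_j(z)/kT)`, with harmonic biases
  `w_j(z) = k/2 (z - c_j)^2`, bootstrap SEM bands over monomers and
  replicates, and barrier/well extraction.
- **Kramers-style permeation rates**, `k = (D/delta^2) exp(-dG/kT)`,
  per-monomer traversal counting with a chatter-proof state machine,
  and solute rate ratios in which the pore length cancels.
- **Constant-pH titration**: protonated fractions, per-group
  Henderson-Hasselbalch fits `f(pH) = 1/(1 + 10^(pH - pKa))`, apparent
  pKa with bootstrap SEM, and pKa-shift free energies
  `ddG = ln(10) kT dpKa`.
- **Bennett acceptance ratio** estimates of free-energy differences
  from forward/reverse work values (Crooks-consistent maximum
  likelihood), work-distribution overlap diagnostics, and combination
  of per-method estimates with error propagation.
- **Contact statistics**: propensities with group bootstrap,
  protonation-conditioned and cooperative contacts, ring-stacking vs
  pH, and 26-connected 3-D solute density clusters.
- **Structure geometry**: sphere-squeezing pore-radius profiles with
  closure detection, atom-selection distances, Kabsch superposition
  RMSD with outlier trimming, and residue-wise backbone RMSD.

A first-class synthetic-data module generates every input the pipeline
consumes — overdamped Langevin traces in analytic sum-of-Gaussians
potentials, exact-Metropolis umbrella windows, two-state protonation
chains with Henderson-Hasselbalch equilibria, Crooks-consistent
Gaussian work distributions, and toy pore structures — with known
ground truth, so the whole pipeline is validated end to end without an
MD engine.

## Worked example

Recover a 23 kJ/mol permeation barrier from synthetic umbrella windows
at the usual protocol settings (1 A spacing, 2000 kJ/mol/nm^2 spring,
1e5 samples per window), then convert barriers to a rate ratio:

```r
library(poregate)

pot <- potential_spec(heights = 23, centers = 0, widths = 2,
                      domain = c(-15, 15))
windows <- generate_umbrella_dataset(pot, centers = seq(-14, 14, 1),
                                     seed = 42)
pmf <- solve_wham(windows)
pmf
#> pmf_profile: 294 bins on [-14.65, 14.65] A, reference bulk_zero
#>   barrier 22.97 kJ/mol at z = 0.05 A; deepest well -0.10 kJ/mol at z = -14.25 A

solute_rate_ratio(10, 23, diffusion_ratio = 3)
#> [1] 550.26
```

The recovered barrier (22.97 kJ/mol) sits within statistical error of
the planted 23 kJ/mol; the rate ratio says a solute facing a 23 kJ/mol
barrier and 3x slower diffusion permeates ~550x slower than one facing
10 kJ/mol — the water-vs-glycerol regime of an aquaglyceroporin.

Estimate a deprotonation free-energy difference from Crooks-consistent
work values, and a protonation level from an apparent pKa:

```r
ws <- generate_work_samples(dG_true = -8.46, sigma = 2, seed = 7)
bar_estimate(ws, n_boot = 200, seed = 8)
#> free_energy_estimate [bar]: dG = -8.467 +/- 0.014 kJ/mol

100 * henderson_hasselbalch(pH = 7.4, pKa = 7.8)
#> [1] 71.5
```

A residue with apparent pKa 7.8 is ~71% protonated at physiological pH
— the regime in which a buried gating aspartate keeps a channel
population partly closed in vivo.

A command-line interface wraps the same functions for shell pipelines
(`exec/poregate`): subcommands `simulate`, `wham`, `rate`, `titrate`,
`bar`, `contacts`, `cluster`, `pore`, `rmsd`, `measure`, each reading
TSV inputs and writing a JSON summary that embeds the resolved
configuration and seed.

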