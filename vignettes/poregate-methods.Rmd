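---
title: "Methods: free-energy, kinetic and titration analysis of gated channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy, kinetic and titration analysis of gated channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poregate)
```

`poregate` implements the quantitative analysis layer of a molecular
dynamics study of a pH-gated membrane channel (an aquaglyceroporin-type
water/glycerol/H2O2 channel whose extracellular loop collapses at acidic
pH): free-energy profiles along the pore axis, permeation kinetics,
constant-pH titration, alchemical free-energy differences, contact
statistics, and pore geometry. Every estimator is exercised end-to-end
on synthetic data with known ground truth, so the package is testable
without running an MD engine. This vignette records the models, the
defaults and why they were chosen, and what the synthetic tests do and
do not demonstrate about real simulation data.

All energies are kJ/mol, lengths Angstrom, times ns. Thermal energy
defaults to `kT_at(300)` = 2.494 kJ/mol. Umbrella spring constants are
accepted in kJ/mol/nm^2, the unit MD protocols print, and converted
once, centrally (`spring_nm2_to_A2()`). The channel coordinate z
increases from the intracellular to the extracellular side; since
deposited structures carry no canonical origin, the package treats z as
relative to whatever frame the input tables use, and "bulk" defaults to
the outer 10% of the covered range at each end.

## Synthetic data with closed-form ground truth

The free-energy landscape is modelled as a sum of Gaussian terms
(`potential_spec()`): smooth, analytically differentiable, and able to
mimic the printed barrier shapes (a single 10, 23 or 28 kJ/mol barrier
at a selectivity filter, or a -5 kJ/mol binding well). Closed forms for
the energy and force make every downstream estimator checkable against
an exact oracle.

`simulate_langevin_1d()` propagates overdamped (Brownian) dynamics,
`z <- z - (D dt / kT) dU/dz + sqrt(2 D dt) xi`, with reflecting domain
walls. The default diffusion coefficient D = 230 A^2/ns is the bulk
self-diffusion of water at 300 K; the true in-pore value for any given
channel is unknown and the choice is deliberately labelled arbitrary —
all rate *ratios* are independent of it, and the Kramers conversion
takes D explicitly. The default step dt = 2e-5 ns keeps the drift per
step below ~10% of the thermal displacement under the default umbrella
spring, where the integrator's discretization error is negligible for
the moments the tests check.

`generate_umbrella_dataset()` produces umbrella windows at the study's
protocol settings (1 A spacing, 2000 kJ/mol/nm^2 restraint, first 10%
of each window discarded as equilibration). By default it samples each
window with an independence-Metropolis sampler — proposals from the
bias Gaussian `N(c, kT/k)`, accepted with the Boltzmann factor of the
unbiased potential — rather than the Langevin integrator. The reason is
statistical efficiency: the integrator's autocorrelation time under the
stiff default spring is tens of steps, so 1e5 integrator steps carry
only a few thousand independent samples per window, which is too noisy
to resolve a flat profile to a fraction of kT across a 29-window
ladder. The Metropolis sampler draws from the biased distribution
exactly (on a flat potential every proposal is accepted and the samples
are iid), so the WHAM oracle tests probe the estimator, not the
sampler. `method = "langevin"` is retained for studying the realistic
correlated regime, and the Langevin path is the engine behind the
kinetics fixtures.

`generate_permeation_trace()` builds a piecewise path with an exact
number of complete slab traversals plus non-crossing excursions; the
base path dwells half a slab-width outside the boundaries and crosses
between consecutive samples, and the additive jitter is clipped at 2.5
standard deviations (with `noise_sd` capped below one eighth of the
slab width), so the constructed count is exact under any amount of
permitted jitter.

`generate_lambda_traces()` emulates constant-pH MD protonation traces
as two-state Markov chains sampled with the exact discrete-time
propagator, with stationary protonated fraction given by
Henderson-Hasselbalch and total exchange rate `k_exchange`. Neither the
exchange rate nor the trace length is printed for the real system; the
package defaults (20 exchanges/ns, 1 microsecond — within the 0.5-1.5
microsecond production range typical of such studies) were chosen once
so that every entry on a pH 5-10 grid around pKa 7.8 shows at least the
~200 transitions needed for a per-group titration fit, and are not
revisited. The sampling interval must resolve exchange
(`k_exchange * dt` well below 1), otherwise observed transition counts
undercount the underlying chain.

`generate_work_samples()` draws forward/reverse work values from the
equal-variance Gaussian pair that satisfies the Crooks fluctuation
theorem exactly (means `dG + sigma^2/2kT` and `-dG + sigma^2/2kT`); a
logistic regression of direction on work recovers slope `1/kT` and
intercept `-dG/kT`, which the tests verify.

## WHAM

`solve_wham()` iterates the standard weighted-histogram equations to
self-consistency on the window offsets f_j (tolerance 1e-4 kJ/mol, cap
1e5 iterations, both package choices). Two numerical points matter and
were found the hard way, by running the estimator on *exact* expected
counts:

- **Bin-averaged bias factors.** The harmonic bias Boltzmann factor has
  standard deviation `sqrt(kT/k)` = 0.35 A at the default spring —
  comparable to the bin. Evaluating it at bin midpoints misstates
  expected counts by a few percent per bin with a systematic sign
  pattern, which accumulates across the window ladder into a spurious
  bow of order 0.5 kT. The bias factor is therefore integrated over
  each bin in closed form (normal CDF differences).
- **Consistent window totals.** The per-window counts N_j entering the
  denominators must be the counts actually binned on the retained grid.
  Using raw sample counts overstates the edge windows, whose tails fall
  off the grid, and the maximum-likelihood solution absorbs the
  mismatch as a ~kT dome across the entire profile.

The default bin width is 0.1 A: at 0.2 A the residual within-bin
factorization error on steep barrier flanks still biases a 28 kJ/mol
barrier low by ~0.9 kJ/mol, while at 0.1 A the bias drops to ~0.3
kJ/mol (the profile is insensitive to further halving, which a test
checks). The profile is computed over the span of window centers plus
~2 bias standard deviations; beyond that the density rests on a single
window's exponential tail. Leading/trailing bins with fewer than 25
pooled counts are trimmed; interior empty bins are a coverage gap and
raise an error.

Profiles are referenced either to a zero bulk mean (`bulk_zero`,
default) or to a zero minimum (`min_zero`); `profile_features()`
extracts the barrier (max minus bulk mean) and deepest well with ties
broken toward smaller z. Per-monomer profiles are solved independently
and combined as mean with a bootstrap SEM band over (monomer,
replicate) groups (`pmf_by_group()`), treating each monomer channel as
an independent replicate. The group bootstrap (`bootstrap_band()`,
resample whole groups, SD of resampled means) is the single error
engine shared by rates, pKa values and propensities. Plain WHAM with a
group bootstrap is the package's documented choice; no Bayesian
bootstrap or autocorrelation-based inefficiency weighting is applied.

## Kinetics

`count_crossings()` registers a permeation event when a particle that
last entered the slab through one boundary exits through the opposite
one; same-side re-exits reset without counting, so boundary chatter
never increments. Both directions count toward the rate (equilibrium
flux); per-direction rates are reported alongside, since printed
per-monomer rates do not state the convention. Slab boundaries default
to the caller's choice — typically the PMF bulk-region edges.

`kramers_rate()` evaluates `k = (D/delta^2) exp(-dG/kT)` with pore
length delta defaulting to 50 A (5 nm). `solute_rate_ratio()` evaluates
the delta-free ratio; with barriers of 10 and 23 kJ/mol and glycerol
diffusing 3x slower than water it returns ~550, the "roughly 500 times
slower" regime. A property test checks that *counted* Langevin
crossing-rate ratios between two barrier heights agree with the Kramers
form within a factor of two — in conditions where transit is
barrier-limited; for low barriers and wide slabs the diffusive stretch
dominates the mean first-passage time and the exponential form
deliberately does not apply.

## Titration

`protonation_fractions()` time-averages the binary protonation state
after a 100 ns equilibration cut (the printed discard).
`fit_henderson_hasselbalch()` fits `f(pH) = 1/(1+10^(pH-pKa))` with the
Hill coefficient fixed at 1 (a free-Hill variant exists behind a flag
but the apparent pKa remains the half-protonation point), fitting each
(monomer, replicate) group separately and averaging — matching the
fit-then-average convention of pKa values averaged over monomers and
replicates — with a bootstrap SEM over groups. Physiological pH is
taken as 7.4 where a number is needed: at pKa 7.8 that gives 71.5%
protonation, the "about 70%" regime. `deprotonation_delta_g()` converts
a pKa shift to `ln(10) kT (pKa2 - pKa1)`; the sign convention (negative
means deprotonation is cheaper in state 2, i.e. protonation favours
state 1) is attached to the value, because printed per-state pKa pairs
are rarely available and only the magnitude scale (~8.5 kJ/mol for the
gating aspartate) can be compared.

## Bennett acceptance ratio

`bar_estimate()` solves the Bennett self-consistency condition with
Fermi weights and offset `M = kT ln(nF/nR)` by bracketed root finding
on `[min(W) - 10 kT, max(W) + 10 kT]` to 1e-8 kJ/mol. Two failure modes
are distinguished: no sign change over the bracket, and a root at which
the effective number of overlap samples (the summed Fermi weights)
falls below one — both abort with a pointer to `work_overlap()`, the
histogram overlap coefficient between forward and negated reverse
works. Uncertainty comes from a bootstrap over work values, with the
Bennett asymptotic variance reported alongside (they agree within ~30%
on Gaussian fixtures, which a test checks). On Crooks-Gaussian fixtures
the estimate must fall between the two one-sided Jarzynski
exponential-average estimates and converge to truth as n grows; both
are property tests.

`combine_state_estimates()` merges independent estimates of the same
quantity (e.g. a constant-pH pKa-shift value and an alchemical BAR
value) as an unweighted mean with `se = sqrt(sum se_i^2)/n` — the
propagation matching simple bar-height averaging of per-method points;
inverse-variance weighting is available behind a flag. The propagation
divides by n (not n-1); both variants were checked and the unweighted
/n form is the documented default.

## Contacts and density clusters

Contacts default to a minimum heavy-atom distance of 3.5 A (the usual
hydrogen-bond donor-acceptor criterion; the analysis the package
mirrors prints no cutoff, so every result carries its criterion).
Ring stacking requires centroid distance <= 5.5 A and interplanar angle
<= 30 degrees. Conditioned propensities report P(contact | state) for a
synchronized binary state — a protonation trace or a second pair's
contact state (cooperativity) — with absent condition states reported
as undefined (NA), never zero, and sub-5% occupancy flagged.
`solute_density_clusters()` voxelizes positions (1 A default), keeps
voxels above an occupancy threshold (default 10x the mean occupancy
over the bounding box — for strongly localized or degenerate point sets
an explicit threshold is more meaningful), and groups them by
26-connectivity; clusters are ranked by summed occupancy and their
occupancy-weighted centroids are reported for comparison with modelled
ligand sites.

## Structure geometry

`profile_pore()` is a sphere-squeezing profiler: at each axial station
it maximizes the clearance `min_i(|c - x_i| - r_i)` over the in-plane
sphere center, with 64 stochastic restarts around the previous center
(the most promising few polished by Nelder-Mead), marching both
directions from a seed point and terminating a direction when the
radius reaches the 5 A end radius (exit to bulk). The in-plane drift
per station is capped (1 A default) so the probe cannot escape sideways
through a wall gap; every reported radius is a non-overlap certificate,
verified in tests to 1e-6 A. A profile whose minimum radius falls below
0.5 A is flagged closed — the "near-zero pore radius" observable of a
collapsed-loop channel. vdW radii come from the Bondi table by default,
with the simple AMBER-like set used by classic pore profilers available
as `vdw_table("hole")`. `generate_toy_pore()` builds wall-atom rings
whose accessible radius is known by construction, providing the
profiler's oracle (cylinder, hourglass, blocked).

`superpose_rmsd()` is a Kabsch least-squares fit over atoms paired by
(chain, residue number, atom name), followed by up to 5 cycles of
rejecting pairs deviating by more than twice the current RMSD —
emulating the trimming behaviour of common viewers' align commands,
since printed inter-structure RMSD values rarely state their
convention. `residuewise_rmsd()` superposes once globally on backbone
atoms and then reports per-residue backbone RMSD and its argmax — the
loop that moves most between open and closed conformations.
`atom_distance()` reports the minimum heavy-atom distance by default
and a specific-atom distance on request, because the atom pair behind a
printed filter separation (e.g. the ~7 A arginine-tyrosine gap of an
aromatic/arginine filter) is usually unstated.

The structure-metric checks against the deposited open/closed models
require coordinate files that cannot be redistributed with the package;
with the files placed under `inst/extdata/deposited/` the acceptance
test exercises them, and without them it reports the absence rather
than silently passing.

## Problem sizes and what the tests show

The oracle suites run at: 29 umbrella windows x 1e5 samples per
dataset; 1e4 work values per direction; 144 lambda entries x 4.4e5
steps; 1e6-step Langevin traces; toy pores of ~10^3 wall atoms. These
sizes make every tolerance a small multiple of the estimator's
statistical error and keep the full suite in minutes on one CPU.

Passing them shows the estimators are correct and calibrated on data
that exactly satisfies the generating models — Markovian protonation,
Gaussian work distributions, memoryless 1-D diffusion, rigid pore
walls. Real MD data violate all of these mildly (correlated noise,
non-Gaussian work tails, position-dependent diffusion, conformational
heterogeneity between monomers), so synthetic SEMs are much smaller
than the published error bars, and agreement here does not certify
force-field or sampling adequacy of any particular simulation. What it
does certify is that, given data of the stated form, the pipeline
returns the right numbers.

## Known limitations

No MBAR generalization or 2-D profiles; no autocorrelation-aware
weighting inside WHAM (group-level bootstrap only); no collective
p_f/p_d permeability formalism; no lambda-dynamics propagation or
charge-coupling corrections; no D-H-A angle hydrogen-bond criterion;
pore profiling assumes a single connected lumen along the supplied
axis.
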