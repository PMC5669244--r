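# toygold

Analysis chain for metadynamics simulations of peptide adsorption at
solid–liquid interfaces, validated end to end on a synthetic Langevin/slab
system with analytically known ground truth.

## What it is for

Quantifying how strongly a peptide binds a crystal facet from an
enhanced-sampling trajectory takes a chain of post-processing steps, each
with its own conventions and pitfalls. This package implements that chain
for the common one-CV setup — the collective variable *s* is the peptide
centre-of-mass height above the surface in a slab geometry — aimed at
simulators who want tested, reusable building blocks rather than one-off
scripts:

* **Bias reconstruction** — rebuild the metadynamics bias
  `V(s) = Σ w·exp(−(s−s₀)²/2σ²)` from deposited Gaussian hills and form the
  end-of-run free-energy estimate `G(s) = −V(s, t_f)` (with the
  `γ/(γ−1)` factor for well-tempered runs).
* **Symmetrised profiles** — average `G` with its mirror image about the
  midplane between the slab and its periodic image,
  `G_sym(s) = ½[G(s) + G(2m−s)]`, keeping `½|G(s) − G(2m−s)|` as a per-point
  asymmetry error bar.
* **Equilibration assignment** — histogram the biased CV over increasing
  time intervals and start the analysis once successive histograms agree in
  L1 distance.
* **Re-weighting** — three schemes for per-frame unbiased weights:
  equal weights per CV bin, `W(t) = exp(−G(s(t),t_f)/kT)/N(s(t))`
  ("average weight"); the time-dependent-bias scheme
  `W(t) ∝ exp([V(s(t),t) − c(t)]/kT)` ("Bonomi"); and block-frozen static-bias
  weights ("time period") — plus block-bootstrap errors and effective sample
  sizes.
* **Adsorption free energy** — `ΔG = −kT ln(∫_bound e^(−G/kT) / ∫_bulk
  e^(−G/kT))` over equal-width windows (or the well depth), facet ranking
  with error-bar significance flags, and area-fraction mixing for
  polycrystalline estimates.
* **Structure at the interface** — re-weighted residue–surface contact
  probabilities with strength classes (moderate/significant/strong at
  26–50/51–75/75–100 %), mean simultaneous contacts, vertical and lateral
  interfacial water densities, the first-layer boundary at the first trough,
  and peptide-displaced first-layer water counts.
* **Synthetic ground truth** — a Langevin toy system (analytic adsorption
  landscape, planted conformer statistics, slab fixtures with planted
  contact probabilities and water layers) that exercises every stage with
  known answers.

File formats are the plain-text dialects of the enhanced-sampling
ecosystem: `#! FIELDS`-headed column files for hills and CV series, GRO-style
coordinate frames for slab snapshots, flat `key = value` configs.

## Worked example

Simulate a biased trajectory on a square-well landscape (depth 10 kJ/mol,
well at 0.5 nm, walls at 0 and 4 nm), rebuild the profile, and extract the
adsorption free energy:

```r
library(toygold)

landscape <- toy_landscape("square_well", depth = 10, well_center = 0.5,
                           well_width = 0.5, wall_z = 0, image_wall_z = 4)
spec <- langevin_spec(dt = 0.005, friction = 20, temperature = 300,
                      n_steps = 1e6, seed = 42, out_stride = 10,
                      metad = list(height = 0.3, sigma = 0.05, stride = 250))
sim <- run_langevin(landscape, spec)

cfg <- run_config(bound_region = c(0.3, 0.7), bulk_region = c(1.8, 2.2))
bias <- sum_hills(sim$hills, cv_grid(cfg))
profile <- symmetrise(free_energy_estimate(bias, bulk_region = cfg$bulk_region),
                      midplane = 2)
profile
#> free_energy_profile: 801 points on [0, 4] nm, bulk-zeroed, symmetrised
#>   min G = -9.500 kJ/mol at s = 3.655 nm

extract_dG(profile, cfg)
#> adsorption_result (partition_ratio): dG = -9.08 +/- 0.85 kJ/mol
```

The recovered well depth and ΔG sit within the asymmetry error of the exact
values for this landscape (`extract_dG` on `landscape_free_energy()` gives
−9.85 kJ/mol for these windows; the −10 kJ/mol plateau depth is recovered
exactly only with hard-edged wells and windows inside the flat regions).

The full campaign — three synthetic "facets" as three well depths, each with
planted contact and water-structure fixtures — runs the whole chain and
ranks the facets:

```r
report <- run_campaign(campaign_config(seed = 1))
report
#> campaign_report
#> ranking (strongest binder first):
#>    facet         dG       err significant_vs_next
#> 1 facetA -16.296302 1.0306725                TRUE
#> 2 facetB -10.384559 0.5462935                TRUE
#> 3 facetC  -5.490643 0.9703850                  NA
#> facetA: dG = -16.30 +/- 1.03 kJ/mol, mean contacts 3.50, displaced waters 35.0
#> facetB: dG = -10.38 +/- 0.55 kJ/mol, mean contacts 2.62, displaced waters 20.0
#> facetC: dG = -5.49 +/- 0.97 kJ/mol, mean contacts 1.49, displaced waters 5.0
```

The recovered ΔG values track the planted depths (16/10/6 kJ/mol), the
contact and displaced-water statistics track their planted fixtures
(Σp = 3.5/2.7/1.45 expected contacts; 35/20/5 planted water deficits), and
the ranking is significance-flagged by the summed error bars.

A thin shell wrapper for the campaign, profile reconstruction and
equilibration lives in `inst/scripts/toygold`.

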