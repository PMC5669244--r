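---
title: "Metadynamics re-weighting and adsorption analysis on a toy slab system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metadynamics re-weighting and adsorption analysis on a toy slab system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toygold)
```

## The problem this package addresses

Enhanced-sampling simulations of a peptide adsorbing at a solid--liquid
interface commonly bias a single collective variable (CV): the height *s* of
the peptide's centre of mass above the surface, in a slab geometry that is
periodic along the surface normal. Metadynamics deposits repulsive Gaussian
"hills" along *s*, so that at the end of the run the accumulated bias
approximates the negative free-energy profile, $G(s) \approx -V(s, t_f)$.
From that profile one reads the adsorption free energy; from the re-weighted
trajectory one reads unbiased structural statistics (which residues anchor
the peptide, how much first-layer water it displaces).

`toygold` implements that full analysis chain — bias reconstruction,
equilibration assignment, three re-weighting schemes, symmetrised profiles
with asymmetry error bars, adsorption free-energy extraction with facet
ranking, residue-contact statistics, and interfacial water-structure
metrics — together with a synthetic Langevin/slab system whose ground truth
is known analytically, so every stage can be validated end to end.

## The toy system

`toy_landscape()` defines an analytic free-energy landscape on
$s \in [\text{wall}, \text{image wall}]$: a binding well of depth $D$ near
the wall, a flat bulk plateau at zero, and an exact mirror image of the well
near the image wall. The mirroring reproduces the slab geometry in which the
peptide sees two equivalent interfaces — the top of the slab and the
underside of its periodic image — which is what makes profile symmetrisation
meaningful.

The square well uses tanh-smoothed edges of width `edge` (default 0.05 nm):
overdamped dynamics needs a finite force, and because
`landscape_free_energy()` returns the *same* smoothed form, the recovery
tests compare the estimate against the exact stationary law of the dynamics,
not an idealisation of it. `edge = 0` gives the hard-edged profile, used
only for closed-form checks of the static estimators (a partition-ratio
extraction over equal-width windows inside the flat parts returns $-D$
exactly).

An orthogonal two-state "conformation" coordinate is attached to each frame:
its energy gap interpolates between `gap_bulk` (default 0 kJ/mol) and
`gap_well` (default 2 kJ/mol) with the well occupancy, and the label is
drawn from the exact conditional law
$p_1(s) = 1/(1 + e^{-\Delta\varepsilon(s)/kT})$. Re-weighted averages of
this observable therefore have a planted truth, which is how the three
re-weighting schemes are cross-validated.

`make_slab_fixture()` generates the structural side: snapshots with a gold
lattice, per-residue reference atoms at Gaussian heights above the top gold
layer, and water oxygens in planted vertical layers with uniform in-plane
positions. Its manifest records the planted contact probabilities
($P(\text{height} \le \text{cutoff})$ under the sampling law) and per-layer
counts, giving the contact and water modules binomial-level oracles.

## Integrator and metadynamics parameters

The CV follows overdamped (position) Langevin dynamics via Euler--Maruyama,

$$ s_{n+1} = s_n - \frac{\Delta t}{\gamma} U'(s_n) +
   \sqrt{2 kT \Delta t / \gamma}\, \xi_n, $$

with reflecting walls. Function defaults are $\Delta t = 0.01$ ps and
$\gamma = 1$ ps$^{-1}$, the simplest scheme with a known stationary law
(validated against the closed-form variance $kT/\kappa$ on the harmonic
landscape). The shipped campaign instead uses $\Delta t = 0.005$ ps and
$\gamma = 20$ ps$^{-1}$: with tanh edges of width 0.05 nm the maximum force
is $\sim D/2\,\text{edge} \approx 100$ kJ mol$^{-1}$ nm$^{-1}$, and these
settings keep the per-step drift ($\le 0.025$ nm) and noise
($\approx 0.035$ nm) below the edge width, while a box crossing still takes
only $\sim 10^4$ steps so a $10^6$-step run re-crosses the box dozens of
times.

Hill deposition defaults for the campaign are height 0.3 kJ/mol
($\approx 0.12\,kT$), width $\sigma = 0.05$ nm, stride 250 steps — small
frequent hills in the usual enhanced-sampling style, giving 4000 hills over
$10^6$ steps and a residual ripple well under $kT$. Standard (non-tempered)
deposition is the default; well-tempered deposition is supported (recorded
hill heights are the deposited, already-scaled heights, and
`free_energy_estimate()` applies the $\gamma/(\gamma-1)$ factor when a bias
factor is present).

## Bias reconstruction and the symmetrised profile

`sum_hills()` evaluates $V(s) = \sum_h w_h e^{-(s - s_h)^2 / 2\sigma_h^2}$
on a grid (default spacing 0.005 nm, finer than $\sigma/4$), truncating each
Gaussian at $6\sigma$; the truncation error is below $1.6\times10^{-8}$ of a
hill height and is tested against an untruncated brute-force oracle. The
end-of-run estimate is $G(s) = -V(s, t_f)$, shifted to a declared reference.
The default reference zeroes the mean of $G$ over the bulk window, so the
adsorption free energy reads directly off the well.

`symmetrise()` averages the profile with its mirror image about the
midplane, $G_\mathrm{sym}(s) = \tfrac12[G(s) + G(2m - s)]$, and keeps
$\tfrac12|G(s) - G(2m - s)|$ as a per-point asymmetry error — the two halves
of the profile are independent estimates of the same physics, so their
disagreement is an honest error bar. Whether such averaging should happen in
$G$ or in $e^{-G/kT}$ is a genuinely open choice; averaging in $G$ is the
default here (it keeps the asymmetry error interpretable as an energy and is
idempotent exactly), with `average = "boltzmann"` available for comparison.

## Equilibration assignment

`assign_equilibration()` splits the trajectory into equal *time* intervals,
histograms the biased CV in each, and takes the analysis start as the first
interval from which all successive L1 distances between normalised
histograms stay below a threshold (default 0.1). The visual procedure this
automates has no published metric, so the L1 threshold is a package choice;
it is calibrated so that stationary i.i.d. sampling at $10^5$ frames
equilibrates immediately while a mid-trajectory distribution change is
flagged into the second half (tested across 20 seeds). On the toy campaign
with standard metadynamics the biased distribution keeps evolving slowly,
so the detector legitimately reports non-equilibration and falls back to the
final interval — the report carries an explicit flag either way. Lowering
the threshold can only postpone the assigned time (tested), and the detector
is invariant to affine rescaling of the CV when the bin width is rescaled
alongside.

## The three re-weighting schemes

All schemes produce normalised per-frame weights with an effective sample
size $1/\sum W^2$ as a degeneracy diagnostic.

* **Average weight** (the scheme used for headline numbers): all frames in a
  CV bin are weighted equally, $W(t) = e^{-G(s(t), t_f)/kT} / N(s(t))$, with
  $G$ the symmetrised end-of-run profile and $N(s)$ the frame count of the
  bin (default width 0.02 nm, half-open $[lo, hi)$ bins). Bins with no
  frames contribute nothing; whether the raw or symmetrised profile enters
  here is unstated in the workflow this implements, and the symmetrised one
  is used because it is the better estimate of the same $G$.
* **Bonomi**: the time-*dependent* bias enters,
  $W(t) \propto e^{[V(s(t), t) - c(t)]/kT}$, with the running offset
  $c(t) = kT \ln \langle e^{V(s, t)/kT}\rangle$ re-evaluated by trapezoid
  over the CV grid at each hill deposition (a 1-D CV makes the quadrature
  exact and cheap). Frames before the first hill see zero bias. For a bias
  that is static over the analysis window this reduces exactly to umbrella
  unbiasing, $W \propto e^{V(s)/kT}$.
* **Time period**: the analysis window is cut into equal time blocks; within
  each block the bias is frozen at its block-end value and static-bias
  weights are used, and blocks are combined with equal mass. The underlying
  scheme is described only qualitatively in the sources this package draws
  on; this block construction is one reasonable reading and is labelled as
  an interpretation in the documentation.

On the toy campaign all three recover the planted conformer population in
the bound state within the combined bootstrap/binomial errors of a
$10^6$-step unbiased reference run, and the average-weight scheme flattens
the sampled CV histogram exactly (a self-consistency identity of the
equal-weight construction).

Ensemble averages use a weighted moving-block bootstrap (default 200
resamples of 100-frame blocks, seeded) for standard errors, since the
workflow being reproduced states no error recipe for observables; estimates
with effective sample size below 10 carry a warning.

## Adsorption free energy and facet comparison

`extract_dG()` supports two estimators over declared bound and bulk CV
windows. The default, `partition_ratio`, is
$\Delta G = -kT \ln \left(\int_\mathrm{bound} e^{-G/kT} ds \, / \,
\int_\mathrm{bulk} e^{-G/kT} ds\right)$ over equal-width windows (the
standard-state length cancels); it is continuous in $G$ and invariant to
constant shifts. `well_depth` (the minimum of $G$ over the bound window) is
kept for comparison with depth-reading conventions. The quoted uncertainty
is the maximum asymmetry error over the bound window, combined in quadrature
with any supplied bootstrap spread. `rank_facets()` orders facets by
$\Delta G$ and flags adjacent gaps as significant when they exceed the sum
of the two error bars; `polycrystalline_mix()` forms the area-fraction
weighted combination with quadrature errors, with fractions as caller
inputs.

## Contacts and interfacial water

A residue is in contact when the minimum height of its reference atoms above
the surface plane is at or below a per-residue cutoff (van der Waals extent
of the reference atom + gold radius + 0.05 nm tolerance; `vdw_cutoff()`).
The boundary itself counts as contact. Contact probabilities are classified
with upper-closed bins — none $\le 0.25$, moderate $(0.25, 0.5]$,
significant $(0.5, 0.75]$, strong $(0.75, 1]$ — a continuous rendering of
the integer-percent bands (26--50 %, 51--75 %, 75--100 %) used in the field.
The mean number of simultaneous contacts equals $\sum_r p_r$ exactly (an
identity of expectations, asserted to $10^{-12}$). Distance is measured
vertically to the mean top-layer plane by default, which suits flat
fixtures; a nearest-atom mode would be the right extension for strongly
rumpled reconstructions where a single plane is ill-defined.

`vertical_profile()` converts (optionally frame-weighted) water-oxygen
height histograms to mass density (water mass assigned wholly to the oxygen
bin; bin width 0.01 nm). The first interfacial layer ends at the first
trough: extrema are strict sign changes of the discrete first difference
with plateau ties resolved to the smaller height, and a peak must reach at
least 25 % of the profile maximum — without that floor a single stray
molecule in an otherwise empty bin would register as the first "layer" in an
empirical histogram. The trough is the minimum between the first two such
peaks; if no second peak exists the trough is undefined and flagged.
`lateral_map()` histograms first-layer waters in-plane (default 0.025 nm
cells, periodic wrapping); its cell masses recover the layer mass to
$10^{-9}$ relative, and the vertical profile conserves total water mass to
the same tolerance. `displaced_waters()` differences the bare-surface
first-layer count against the weighted bound-state count, using the bare
trough for both; the whole surface is counted, with no restriction to the
peptide's in-plane footprint, matching the "waters released" reading of the
quantity.

## The campaign and its conditions

`run_campaign()` chains all stages for three synthetic "facets", modelled as
three well depths (16, 10, 6 kJ/mol) with facet-specific fixtures: planted
contact probabilities decreasing from facet A to C and planted bound-state
first-layer deficits of 35, 20 and 5 waters. The campaign therefore
exercises the comparative logic of a facet study — a significance-flagged
$\Delta G$ ranking, contact-class counts and displaced-water ordering that
co-vary with binding strength — without claiming to reproduce any published
system. Stage outputs are pure functions of (config, seed); reports are
reproducible bit for bit, carry a config hash, and validate against the JSON
schema shipped in `inst/schema/`.

## Problem sizes and what the tests show

The validation suite runs the campaign conditions at $10^6$ Langevin steps
($10^5$ frames, 4000 hills) for profile recovery and re-weighting checks,
$10^5$ steps for the end-to-end pipeline tests, 300--500-frame fixtures for
contact and water statistics, and $5 \times 10^4$-sample series for the
equilibration detector; everything completes in well under a minute on one
CPU. Passing these tests shows that the estimators are correct against
analytic and brute-force oracles *under the toy model's assumptions*: a 1-D
overdamped CV, uncorrelated conformer labels, Gaussian water layers,
uncorrelated fixture frames. Real REST-metadynamics trajectories violate all
of these to some degree — slow orthogonal degrees of freedom, correlated
frames, rugged landscapes — so agreement here validates the *analysis
chain*, not any force field or sampling protocol.

## Known limitations

* One collective variable only; no 2-D bias grids or adaptive hill widths.
* The time-period scheme is an interpretation of a qualitatively described
  procedure (see above).
* The equilibration criterion is a quantitative stand-in for a visual
  procedure; its threshold is a tunable, not a derived, quantity.
* Facet area fractions for polycrystalline mixing are inputs, not derived
  from surface energetics.
* GRO snapshot ingestion covers the minimal dialect the fixtures use, not
  the full trajectory-format zoo.
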