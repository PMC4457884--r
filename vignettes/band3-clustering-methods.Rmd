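---
title: "Modelling oxidation-induced band 3 clustering: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxidation-induced band 3 clustering: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`band3sim` simulates, at single-molecule resolution, how oxidative stress
reorganises the anion exchanger band 3 (AE1) on the red-blood-cell
membrane: thiol oxidation by diamide, phosphorylation and release from the
cytoskeleton, diffusion-limited aggregation into clusters, and the
irreversible stabilisation of those clusters by hemichrome, all coupled to
the cell's antioxidant metabolism. This vignette documents the model, its
numerical machinery, the tunable parameters, and the design decisions that
were genuinely open.

## The membrane as a hexagonal voxel lattice

The membrane patch is a flat rectangular sheet of hexagonally packed
voxels of radius $r_v = 3.62$ nm with periodic boundaries; each voxel has
six equidistant neighbours at spacing $2 r_v$ and holds at most one
molecule (excluded volume). The sheet's area, about $2.62\ \mu m^2$,
equals the total surface of the reference cuboid compartment
($1.06 \times 1.06 \times 0.089\ \mu m$, roughly one-thousandth of a red
cell) and carries 4800 band 3 dimers — one particle per dimer — at the
physiological surface density. We use a flat periodic sheet rather than a
closed cuboid because every measured quantity (cluster statistics,
diffusion coefficients, residency times) is local and curvature plays no
role at this scale; diffusion is measured "on a membrane with periodic
boundary conditions" in either picture.

A molecule with diffusion coefficient $D$ attempts a walk to a uniformly
chosen neighbour every

$$\tau = \alpha\,(2 r_v)^2 / (4 D), \qquad \alpha = 0.91675,$$

where $\alpha$ is the two-dimensional hexagonal-lattice correction. This
constant is fixed by the two anchored step intervals of the model — 1.2 ms
for unphosphorylated band 3 ($D = 10^{-14}\ m^2 s^{-1}$) and 12 µs for
phosphorylated band 3 ($D = 10^{-12}\ m^2 s^{-1}$) — and it implies that
the realised long-time coefficient of a free lattice walker is
$D/\alpha \approx 1.09 \times 10^{-14}\ m^2 s^{-1}$ for nominal
$D = 10^{-14}$, the "sampling excess" the diffusion measurements are
anchored to. Blocked moves (target occupied) consume the time step without
displacement, which is what produces the excluded-volume slow-down at
4800 molecules per sheet.

The phosphorylated-state coefficient $D = 10^{-12}\ m^2 s^{-1}$ is not
printed as such anywhere; it is implied by the 100-fold ratio of the two
printed step intervals and is adopted as the package default.
Hemichrome-bound mobile species inherit the coefficients of their unbound
counterparts; the supplementary parameter tables that might refine this
are not available, and the choice only affects how quickly a few dozen
hemichrome-tagged molecules find clusters.

## Reactions

The reaction set couples three mechanisms:

* **Collision reactions** (cluster nucleation and growth). When a walk
  attempt lands on an occupied voxel and the (unordered) species pair
  matches a rule, both molecules convert in place with probability $p$.
  Probabilities derive from bimolecular rate constants through
  $p = k/\kappa$ with $\kappa = 3.45\times10^{-12}\ m^3 s^{-1}$, the
  unique scale consistent with all printed rate/probability pairs
  (nucleation $3.45\times10^{-13} \to 0.1$, growth
  $3.45\times10^{-12} \to 1$, mixed hemichrome clustering
  $1.03\times10^{-12} \to 0.3$). Nucleation being ten times less probable
  than growth is what makes phosphorylated molecules attach to existing
  clusters rather than founding new ones.
* **First-order events** (phosphorylation $5\times10^{-4}\ s^{-1}$,
  dephosphorylation $5\times10^{-3}\ s^{-1}$, and their hemichrome
  counterparts) and **neighbour-dependent dissociation**: a
  cluster-state molecule with $n$ occupied neighbour sites leaves the
  cluster at $4^{6-n}\ s^{-1}$ (hemichrome-stabilised: $2^{6-n}$), so
  interior molecules (n = 6) dissociate at 1/s while exposed molecules
  leave orders of magnitude faster. These are scheduled by an exact
  event-driven sampler: all propensities are piecewise constant between
  conversion events, so resampling one exponential waiting time from the
  current total propensity after every conversion (a direct-method
  scheduler, equivalent in law to the next-reaction method) is exact. The
  bound-site count $n$ is maintained incrementally from current lattice
  adjacency, never cached across configuration changes.
* **Hybrid pool-particle reactions** (oxidation of band 3 by the diamide
  pool, re-reduction by GSH, hemichrome attachment). A well-mixed pool
  drives per-molecule conversion propensities, e.g.
  $\lambda_{ox} = k_1 c_{diamide}$ with $c$ in molecules/m³ and
  $k_1 = 10^{-23}$; when an event fires, one uniformly chosen particle
  converts in place and the pool decrements by the stoichiometric amount.
  The dimensional reading of the printed constants for these rules
  ($10^{-23}$ m s⁻¹, $10^{-50}$ m³ s⁻¹) is not defined in the main text;
  we adopt the per-concentration interpretation above (reduction:
  $\lambda_{red} = k_3 c_{GSH}^2$), which makes the printed constants
  dimensionally productive and yields seconds-scale oxidation at 0.25 mM
  diamide together with the minutes-scale clustering transient. Hemichrome
  attachment targets free oxidised band 3 (the reaction-table form); a
  configuration switch (`hemichrome_target = "cluster"`) implements the
  alternative cluster-associated reading.

Because the exposure integrals $\int c\,dt$ are integrated analytically
inside the ODE layer, hybrid conversion counts over a coupling step are
binomial draws with $P = 1 - e^{-k \int c\,dt}$ — exact even when the
diamide transient is much faster than the coupling step.

## Antioxidant metabolism

The deterministic subsystem is deliberately minimal: hexokinase supply of
G6P, G6PDH (the pentose-phosphate entry step and the G6PD-deficiency
lesion), glutathione reductase, direct GSH oxidation by diamide
(300 M⁻¹s⁻¹, consuming 2 GSH), S-glutathionylation of protein thiols, a
basal glutathione redox turnover, and diamide-driven hemichrome formation
$v = K_{cF} [diamide] [HbO_2]/(K_{mS} + [HbO_2])$. The full whole-cell
metabolic network this subsystem was distilled from is out of scope; its
role here is to shape two trajectories — the GSH transient and the
hemichrome supply — that the particle layer consumes.

G6PDH uses a two-substrate Michaelis–Menten law with competitive
inhibition of the G6P site by ATP and 2,3-BPG and of the NADP site by
NADPH; this uses every published patient-specific constant (healthy:
$V_{max}$ 64, $K_{mG6P}$ 67 µM, $K_{mNADP}$ 3.7 µM, $K_{iNADPH}$ 3.1 µM,
$K_{iATP}$ 749 µM, $K_{i2,3BPG}$ 2289 µM; deficient: 1.1, 152, 3.8, 0.62,
180, 520) in its conventional role. The exact upstream rate law is not
reproducible from the main text, so the published $V_{max}$ values are
treated as relative activities bridged to flux by one calibrated scale
(`g6pdh_scale`, M/s per activity unit).

Initial concentrations and the remaining kinetic constants are
**calibrated, not printed**: they were chosen once so that (i) the
diamide-free state is an exact fixed point (enforced constructively at
initialisation by solving for the NADPH partition and back-computing the
turnover and hexokinase capacities), (ii) a 0.25 mM dose at 30%
hematocrit (per-cell 0.833 mM) depletes GSH sharply with recovery over
tens of minutes in the healthy cell, and (iii) the deficient cell stays
depleted for hours. Baseline GSH is 1.8 mM — the low end of the
physiological range — because the depletion depth per dose is
stoichiometrically bounded at 2 GSH per diamide and the deep depletion
seen experimentally is only reachable from a modest baseline. The 30%
hematocrit dose scaling (nominal concentration divided by 0.3) reflects
that the extracellular dose partitions into the cell volume fraction.

Integration uses lsoda (relative tolerance $10^{-6}$) over coupling steps
of 1 s during the dose transient and 2 s afterwards, with event-driven
operator splitting: pools advance first, then hybrid conversions fire,
then the particle layer advances. Exchanging the split order moves pools
by less than the solver tolerance on the scales involved (verified in the
test suite).

## Scenarios and the desk-scale preset

`build_scenario()` exposes the named presets: `control`, `g6pd`
(identical except the published deficient enzyme parameters),
`reversible_only` (hemichrome rules removed), `uniform_dissociation`
(single-rate cluster dissociation for the scheme comparison),
`repeated_dose` (0.125 mM pulses) and `spectrin`. The uniform
dissociation rate is the mean of $4^{6-n}$ over the bound-site scheme's
neighbour distribution at peak clustering, since no printed value exists
for that comparison.

Reproducing the published clustering percentages at full scale
(4800 molecules, 100 seeds, 120 min) is a long-running computation. The
desk-scale surrogate used throughout the tests is the quarter-area sheet
(1200 molecules at the same surface density, quarter cytosol volume so
all concentrations are unchanged). On it, the control scenario peaks near
$t \approx 20$–$30$ min and then declines with a small hemichrome-stabilised
residual at 120 min, and the G6PD scenario rises to a sustained plateau —
the qualitative fingerprints of the published curves. Shape checks in the
acceptance suite run 3 seeds per scenario for 60 min of model time;
problem sizes were chosen so the whole suite completes on a desktop in
well under half an hour. Full-scale multi-seed reproduction is available
through `run_scenarios(build_scenario("control"), seeds = 1:100)` for
long-running use.

What the desk-scale runs do *not* show: absolute percentages at the
printed precision (a 1200-molecule sheet has ~0.9-point ensemble SD and
the hemichrome capacity scales with compartment volume), the flatness of
the G6PD plateau beyond ~90 min (our minimal metabolism lets a slow GSH
trickle re-reduce a few percent of the oxidised pool), and any feature of
real membranes absent from the model: lipid heterogeneity, curvature,
membrane deformation and vesiculation, and the downstream
opsonization biology.

## Spectrin mesh and hop diffusion

The cytoskeleton extension tiles the sheet with an equilateral triangular
mesh of spectrin filaments (target edge 100 nm, snapped to the periodic
sheet). Filament voxels are impenetrable; a walk attempt into a filament
voxel succeeds only with the fence **gap probability**, in which case the
molecule jumps across the filament to the voxel beyond (a transient gap
in the fence), landing in the neighbouring triangular compartment.
Spectrin-bound band 3 (`BoundBand3`) occupies every filament
intersection; it is immobile, oxidisable in place, and released as mobile
phosphorylated band 3 upon phosphorylation. One anchor sits at each of
the ~$12\times12$ intersections per full sheet — the mesh geometry admits
no more — so the bound fraction is set by the mesh, not by a target
fraction. Deficiency scenarios remove a uniform random fraction of
filaments (and orphaned anchors) without ever adding fences.

The gap probability is the single free parameter of the mesh. It was
calibrated once, to 0.0297, so that a single free band 3 tracked for
200 s hops to an adjacent compartment every ≈347 ms on average, and is
stored with that provenance. Hops are detected as debounced triangle
reassignments: a compartment change must persist for at least two
consecutive walk-interval samples, suppressing boundary jitter against
the tracking protocol's granularity. With the mesh intact the long-time
effective diffusion of free band 3 drops by more than an order of
magnitude below the unconfined value, the cage effect that motivates the
extension.

## Measurements

* `effective_D()` fits the ensemble time-averaged MSD against lag time by
  ordinary least squares over a 10–50% window of the trace span (short
  lags are contaminated by lattice discreteness, long lags by statistics
  starvation) and divides by 4.
* `identify_clusters()` takes connected components of cluster-state
  molecules under the same 6-neighbour adjacency the dissociation
  kinetics use, so measurement and dynamics cannot drift apart.
* `hop_residency()` returns debounced compartment dwell times with the
  censored final dwell flagged rather than pooled.
* `reaction_interval_stats()` reports per-rule mean inter-event times
  over a window; rules without events are absent, not zero.

## Numerical and design notes

* One deterministic RNG stream (xoshiro256**) drives each engine,
  seed-derived; R-side hybrid draws use R's RNG seeded per run, so a
  (configuration, seed) pair replays bit-identically.
* Collision products occupy the two reactant voxels (every bimolecular
  rule is a 2→2 conversion), so no product placement search exists.
* The uniform-rate dissociation variant and the hemichrome-target switch
  are configuration flags, keeping the scheme comparisons within one code
  path.
* Walk phases reset when a mobility class empties and repopulates; walk
  scheduling is synchronous per class, which is the lattice method's
  standard semantics.
* Degenerate inputs are rejected loudly: non-positive dimensions, fences
  finer than the voxel resolution, collision probabilities outside
  [0, 1], over-filled placement.

## Known limitations

* The crowded-sheet effective diffusion coefficient measured here
  (~$9.6\times10^{-15}\ m^2 s^{-1}$ at 4800 molecules) sits above the
  published $8.1\times10^{-15}$: simple blocking plus tracer correlation
  on a 6-neighbour sheet at 8.3% occupancy cannot reproduce a 26%
  slow-down, suggesting the original surface walk semantics (a
  three-dimensional hexagonal close-packed surface with edge and corner
  voxels) obstruct slightly more than a flat periodic sheet. The
  discrepancy does not propagate: clustering kinetics are anchored to
  collision probabilities, not to the crowded diffusion coefficient.
* The minimal metabolism reproduces trajectory shapes, not the full
  metabolic state; quantities like the G6P pool are placeholders with
  calibrated kinetics.
* Long-time G6PD behaviour declines slowly where the published curve
  stays flat (see above).
* The biconcave whole-cell geometry, membrane mechanics, and opsonization
  downstream of clustering are out of scope.
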