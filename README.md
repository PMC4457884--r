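# band3sim

Single-molecule simulation of oxidation-induced clustering of band 3
(anion exchanger 1) on the human red-blood-cell membrane.

Oxidative stress drives the clustering of band 3, the event that marks
damaged and senescent red cells for removal from circulation: diamide (or
in vivo oxidants) oxidises band 3 thiols, oxidised band 3 is
phosphorylated and released from the spectrin cytoskeleton, the now-mobile
molecules aggregate into immobile clusters, and denatured haemoglobin
(hemichrome) binds the clusters irreversibly. `band3sim` models this
cascade at single-molecule resolution and couples it to the cell's
antioxidant metabolism, for in-silico experiments on healthy,
G6PD-deficient and spectrin-deficient cells under arbitrary dosing
schedules.

The model has three coupled layers:

* **Particle layer** — a periodic sheet of hexagonally packed voxels
  (radius $r_v = 3.62$ nm, one molecule per voxel) carrying 4800 band 3
  dimers on 2.62 µm². A molecule with diffusion coefficient $D$ walks to a
  random neighbour every $\tau = \alpha (2r_v)^2/(4D)$ seconds
  ($\alpha = 0.91675$): 1.2 ms for unphosphorylated ($10^{-14}$ m²/s),
  12 µs for phosphorylated band 3 ($10^{-12}$ m²/s). Collisions convert
  reactive pairs with probability $p = k/\kappa$,
  $\kappa = 3.45\times10^{-12}$ m³/s: cluster nucleation has $p = 0.1$,
  growth $p = 1$. Cluster members with $n$ occupied neighbour sites
  dissociate at $4^{6-n}$ /s ($2^{6-n}$ when hemichrome-stabilised),
  scheduled by an exact event-driven sampler.
* **Metabolism layer** — a minimal deterministic antioxidant subsystem
  (GSH/GSSG, NADPH, G6PDH with the published healthy and G6PD-deficient
  kinetic constants, glutathione reductase, hemichrome formation)
  integrated with lsoda and coupled to the particles through well-mixed
  pools.
* **Spectrin extension** — a 100-nm triangular filament mesh whose fences
  band 3 crosses only through transient gaps (hop diffusion), with
  spectrin-bound band 3 anchored at the intersections.

## Worked example

```r
library(band3sim)

# healthy cell, 0.25 mM diamide at t = 0, desk-scale quarter sheet
spec <- build_scenario("control", scale = 0.25, t_end = 1800)
run  <- run_scenario(spec, seed = 1)
tail(run$series[, c("time", "Band3oxi", "Band3cluster", "percent_clustered", "GSH")], 1)
#>     time Band3oxi Band3cluster percent_clustered          GSH
#> 181 1800       79          169          15.83333 0.0008423509
```

Thirty model minutes after the dose, 79 of the 1200 dimers are still
oxidised, 169 sit in plain clusters (15.8% clustered including the
hemichrome-stabilised ones), and glutathione — 1.8 mM before the dose —
is at 0.84 mM on its way back up: the control cell is past its clustering
peak (about 20% at t ≈ 20 min) and will decay to a small irreversible
hemichrome residual by two hours. Swapping one argument
(`build_scenario("g6pd")`) replaces the G6PDH kinetics with the deficient
patient set; glutathione then stays depleted and the clustered fraction
climbs monotonically to a ~38% plateau instead.

Diffusion-side measurements use the same engine:

```r
# effective diffusion of 100 free band 3 dimers (nominal D = 1e-14 m2/s)
effective_D(simulate_free_diffusion(100, 30, seed = 1, sample_dt = 0.25))
#> [1] 1.043431e-14

# mean fence-hop residency in the intact spectrin mesh
mean_hop_residency(seeds = 1:10, duration = 200)$mean_ms
#> [1] 346.604
```

A thin command-line interface wraps the same functions
(`inst/cli/band3sim.R run|sweep|aggregate|analyze`), writing CSV time
series, snapshot frames and a JSON manifest that replays a run
bit-identically.

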