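# Reference diffusion experiments: free and crowded walkers for effective
# diffusion measurements, and single-molecule tracking in the spectrin
# mesh for hop-diffusion residency analysis.

#' Simulate non-reacting band 3 diffusion and record trajectories
#'
#' Places `n` unphosphorylated band 3 molecules on a periodic sheet
#' (optionally under an intact spectrin mesh) with no reactions enabled,
#' and records unwrapped trajectories for [effective_D()].
#'
#' @param n Number of molecules.
#' @param duration Simulated time (s).
#' @param seed Engine seed.
#' @param scale Sheet area scale (1 = full 2.62 um^2 sheet).
#' @param D Diffusion coefficient (m^2 s^-1).
#' @param sample_dt Trace sampling interval (s).
#' @param mesh `NULL`, or a [build_mesh()] object whose filaments fence the
#'   walkers; spectrin-bound band 3 is anchored at the mesh vertices.
#' @param track Number of molecules to track (default all).
#' @return An [engine_traces()] list.
#' @export
simulate_free_diffusion <- function(n, duration, seed = 1L, scale = 1,
                                    D = 1.0e-14, sample_dt = 0.5,
                                    mesh = NULL, track = n) {
  surf <- if (is.null(mesh)) default_surface(scale) else mesh$surface
  sp <- species_catalogue(D_band3 = D)
  eng <- particle_engine(surf, sp, rules = NULL, seed = seed)
  if (!is.null(mesh)) {
    .eng_set_mesh(eng$ptr, mesh$filament_voxels, mesh$gap_probability)
    if (length(mesh$vertex_voxels) > 0)
      place_at(eng, "BoundBand3", mesh$vertex_voxels)
  }
  ids <- .eng_place_random(eng$ptr, 0L, as.integer(n))
  track_molecules(eng, ids[seq_len(min(track, n))], sample_dt)
  run_engine(eng, duration)
  engine_traces(eng)
}

#' Track a single free band 3 in a spectrin mesh
#'
#' Runs a single unphosphorylated band 3 dimer under an intact (or
#' deficient) spectrin mesh and returns its trajectory sampled at every
#' walk interval, together with the mesh, for [hop_residency()] analysis.
#'
#' @param duration Tracking time (s).
#' @param seed Engine seed.
#' @param scale Sheet area scale (0.25 is ample for a local measurement).
#' @param deficiency Fraction of filaments removed.
#' @param gap_probability Fence gap probability (calibrated default).
#' @param D Diffusion coefficient of the tracked molecule.
#' @return A list with `traces` (single-column [engine_traces()]) and
#'   `mesh`.
#' @export
simulate_hop_tracking <- function(duration = 200, seed = 1L, scale = 0.25,
                                  deficiency = 0,
                                  gap_probability = spectrin_gap_probability(),
                                  D = 1.0e-14) {
  surf <- default_surface(scale)
  set.seed(seed)
  mesh <- build_mesh(surf, deficiency = deficiency,
                     gap_probability = gap_probability)
  sp <- species_catalogue(D_band3 = D)
  eng <- particle_engine(surf, sp, rules = NULL, seed = seed)
  .eng_set_mesh(eng$ptr, mesh$filament_voxels, mesh$gap_probability)
  if (length(mesh$vertex_voxels) > 0)
    place_at(eng, "BoundBand3", mesh$vertex_voxels)
  id <- .eng_place_random(eng$ptr, 0L, 1L)
  track_molecules(eng, id, walk_interval(D))
  run_engine(eng, duration)
  list(traces = engine_traces(eng), mesh = mesh)
}

#' Mean fence-hop residency time over several seeds
#'
#' Convenience driver for the hop-diffusion measurement: tracks one free
#' band 3 per seed in the intact mesh and pools the debounced dwell times.
#'
#' @param seeds Integer seeds (one tracked molecule each).
#' @param duration Tracking time per seed (s).
#' @param ... Passed to [simulate_hop_tracking()].
#' @return A list: `mean_ms` (pooled mean dwell, ms), `per_seed_ms`,
#'   `n_hops` (total), `se_ms` (standard error of the per-seed means).
#' @export
mean_hop_residency <- function(seeds = 1:10, duration = 200, ...) {
  per <- vapply(seeds, function(s) {
    hr <- simulate_hop_tracking(duration = duration, seed = s, ...)
    res <- hop_residency(hr$traces$t, hr$traces$x[, 1], hr$traces$y[, 1],
                         hr$mesh)
    c(mean(res$dwells) * 1e3, length(res$dwells))
  }, numeric(2))
  list(mean_ms = sum(per[1, ] * per[2, ]) / sum(per[2, ]),
       per_seed_ms = per[1, ],
       n_hops = sum(per[2, ]),
       se_ms = stats::sd(per[1, ]) / sqrt(length(seeds)))
}
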