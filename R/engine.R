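# Thin R wrapper around the compiled particle engine. A `particle_engine`
# couples one lattice surface with a species catalogue, the reaction rule
# set and one deterministic RNG stream.

#' Create a particle engine
#'
#' Instantiates the compiled lattice engine for a surface, registers the
#' species catalogue and (optionally) the reaction rule set. Rules of kind
#' `"hybrid"` and `"ode"` involve well-mixed pools and are driven by the
#' scenario layer (see [run_scenario()]); all other kinds are executed
#' inside the engine.
#'
#' @param surface A [build_surface()] lattice.
#' @param species A [species_catalogue()] data frame.
#' @param rules A [reaction_rules()] data frame, or `NULL` for a pure
#'   diffusion engine.
#' @param seed Integer seed of the engine's RNG stream.
#' @return An object of class `particle_engine`.
#' @export
particle_engine <- function(surface, species = species_catalogue(),
                            rules = NULL, seed = 1L) {
  ptr <- .eng_create(surface$W, surface$H, surface$voxel_radius, as.double(seed))
  for (i in seq_len(nrow(species))) {
    tau <- species$walk_interval[i]
    .eng_add_species(ptr, species$name[i], if (is.finite(tau)) tau else 0,
                     species$cluster_state[i])
  }
  eng <- structure(list(ptr = ptr, surface = surface, species = species,
                        rules = rules, seed = seed),
                   class = "particle_engine")
  if (!is.null(rules)) configure_rules(eng, rules)
  eng
}

species_index <- function(eng, name) {
  i <- match(name, eng$species$name)
  if (any(is.na(i))) stop("unknown species: ", paste(name[is.na(i)], collapse = ", "))
  eng$species$index[i]
}

split_pair <- function(s) strsplit(s, "+", fixed = TRUE)[[1]]

configure_rules <- function(eng, rules) {
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    tag <- r$rule
    if (r$kind == "collision") {
      re <- split_pair(r$reactants); pr <- split_pair(r$products)
      .eng_set_collision(eng$ptr,
                         species_index(eng, re[1]), species_index(eng, re[2]),
                         species_index(eng, pr[1]), species_index(eng, pr[2]),
                         r$p, tag)
    } else if (r$kind == "unimolecular") {
      .eng_add_first_order(eng$ptr, species_index(eng, r$reactants),
                           species_index(eng, r$products), r$k, tag)
    } else if (r$kind == "dissociation") {
      .eng_add_dissociation(eng$ptr, species_index(eng, r$reactants),
                            species_index(eng, r$products), FALSE, r$base, tag)
    } else if (r$kind == "dissociation_uniform") {
      .eng_add_dissociation(eng$ptr, species_index(eng, r$reactants),
                            species_index(eng, r$products), TRUE, r$k, tag)
    }
    # hybrid / ode rules are handled by the scenario coupling layer
  }
  invisible(eng)
}

#' Place molecules uniformly at random on free voxels
#'
#' @param eng A [particle_engine()].
#' @param species Species name.
#' @param count Number of molecules; placement fails if fewer free voxels
#'   remain.
#' @return Invisibly, the molecule ids.
#' @export
place_random <- function(eng, species, count) {
  stopifnot(count >= 0)
  if (count == 0) return(invisible(integer(0)))
  invisible(.eng_place_random(eng$ptr, species_index(eng, species), as.integer(count)))
}

#' Place molecules at specific voxels
#'
#' @inheritParams place_random
#' @param voxels Zero-based voxel indices.
#' @export
place_at <- function(eng, species, voxels) {
  invisible(.eng_place_at(eng$ptr, species_index(eng, species), as.integer(voxels)))
}

#' Advance the particle engine
#'
#' Runs diffusion, collision reactions and scheduled stochastic events for
#' `duration` seconds of model time.
#'
#' @param eng A [particle_engine()].
#' @param duration Model time to advance (s).
#' @export
run_engine <- function(eng, duration) {
  .eng_run(eng$ptr, duration)
  invisible(eng)
}

#' Species counts of a particle engine
#'
#' @param eng A [particle_engine()].
#' @return Named integer vector of molecule counts per species.
#' @export
engine_counts <- function(eng) .eng_counts(eng$ptr)

#' Molecule table of a particle engine
#'
#' @param eng A [particle_engine()].
#' @return A data frame with one row per molecule: id, species name, voxel,
#'   wrapped coordinates `x`/`y` (m), unwrapped coordinates `ux`/`uy` (m)
#'   and `bound_neighbors` (adjacent cluster-state molecules).
#' @export
engine_occupancy <- function(eng) {
  df <- .eng_occupancy(eng$ptr)
  df$species <- eng$species$name[df$species + 1L]
  df
}

#' Record trajectories of selected molecules
#'
#' Enables periodic sampling of unwrapped molecule coordinates; retrieve
#' with [engine_traces()].
#'
#' @param eng A [particle_engine()].
#' @param ids Molecule ids to track.
#' @param sample_dt Sampling interval (s).
#' @export
track_molecules <- function(eng, ids, sample_dt) {
  .eng_track(eng$ptr, as.integer(ids), sample_dt)
  invisible(eng)
}

#' Retrieve recorded trajectories
#'
#' @param eng A [particle_engine()].
#' @return A list with `t` (sample times, s) and matrices `x`, `y`
#'   (samples x molecules, unwrapped metres).
#' @export
engine_traces <- function(eng) .eng_traces(eng$ptr)

#' Per-rule event counts
#'
#' @param eng A [particle_engine()].
#' @return Named numeric vector of cumulative event counts keyed by rule
#'   number.
#' @export
engine_event_counts <- function(eng) {
  ec <- .eng_event_counts(eng$ptr)
  names(ec) <- seq_along(ec) - 1L
  ec[ec > 0]
}

#' Enable the reaction event log
#'
#' Records `(time, rule)` for every reaction event in a window, for use
#' with [reaction_interval_stats()].
#'
#' @param eng A [particle_engine()].
#' @param t0,t1 Window of model time to log (s).
#' @param max_events Cap on stored events.
#' @export
log_events <- function(eng, t0, t1, max_events = 2e6) {
  .eng_log_events(eng$ptr, t0, t1, max_events)
  invisible(eng)
}

#' Retrieve the reaction event log
#'
#' @param eng A [particle_engine()].
#' @return Data frame with `time` (s) and `rule`.
#' @export
event_log <- function(eng) .eng_event_log(eng$ptr)

#' Bound-neighbour histogram of cluster-state molecules
#'
#' @param eng A [particle_engine()].
#' @param species Cluster-state species names.
#' @return Integer vector of counts for n = 0..6 bound neighbour sites.
#' @export
bound_neighbor_histogram <- function(eng,
                                     species = c("Band3cluster", "hemiBand3cluster")) {
  species <- intersect(species, eng$species$name)
  h <- .eng_bound_histogram(eng$ptr, species_index(eng, species))
  names(h) <- 0:6
  h
}

#' Convert randomly chosen molecules between species
#'
#' Used by the hybrid pool-particle coupling: a uniformly chosen particle
#' of the reactant species changes species in place.
#'
#' @param eng A [particle_engine()].
#' @param from,to Species names.
#' @param count Number of conversions requested.
#' @return The number actually performed (limited by availability).
#' @export
convert_random <- function(eng, from, to, count) {
  if (count <= 0) return(0L)
  .eng_convert_random(eng$ptr, species_index(eng, from), species_index(eng, to),
                      as.integer(count))
}
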