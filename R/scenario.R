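# Scenario presets and the hybrid simulation driver.
#
# A scenario couples three layers over a shared clock: the particle engine
# (diffusion, collisions, first-order and dissociation events), the
# deterministic metabolite pools, and the hybrid pool-particle reactions
# (band 3 oxidation by diamide, re-reduction by GSH, hemichrome
# attachment). The layers are synchronised by operator splitting: each
# coupling step first advances the ODE pools, then converts particles with
# probabilities derived from the step's exposure integrals, then advances
# the particle engine.

#' Diamide dose schedules
#'
#' `dose_schedule()` builds an explicit schedule from vectors of times and
#' nominal extracellular concentrations; `pulse_train()` builds a regular
#' train of equal doses. Doses are translated into per-cell diamide through
#' the suspension hematocrit when applied.
#'
#' @param time_s Application times (s), non-decreasing.
#' @param conc_M Added extracellular diamide concentration (M) per
#'   application, non-negative.
#' @return A data frame with columns `time_s`, `conc_M`.
#' @export
dose_schedule <- function(time_s = 0, conc_M = 0.25e-3) {
  if (length(conc_M) == 1) conc_M <- rep(conc_M, length(time_s))
  stopifnot(length(time_s) == length(conc_M), !is.unsorted(time_s),
            all(conc_M >= 0))
  data.frame(time_s = as.numeric(time_s), conc_M = as.numeric(conc_M))
}

#' @rdname dose_schedule
#' @param interval_s Interval between pulses (s).
#' @param n Number of pulses.
#' @param start_s Time of the first pulse (s).
#' @export
pulse_train <- function(interval_s, conc_M, n, start_s = 0) {
  dose_schedule(start_s + interval_s * (seq_len(n) - 1), conc_M)
}

#' Build a simulation scenario
#'
#' Assembles a fully resolved scenario specification from a named preset.
#' Presets: `"control"` (healthy cell, 0.25 mM diamide at t = 0, bound-site
#' dissociation, hemichrome reactions on), `"g6pd"` (identical except the
#' G6PD-deficient enzyme parameters), `"reversible_only"` (hemichrome
#' reactions removed), `"uniform_dissociation"` (single-rate cluster
#' dissociation), `"repeated_dose"` (0.125 mM pulses at 30-min intervals),
#' and `"spectrin"` (intact spectrin mesh with spectrin-bound band 3).
#'
#' @param name Preset name.
#' @param scale Area scale of the membrane sheet; 1 is the full 2.62 um^2
#'   sheet with 4800 band 3 dimers, 0.25 the desk-scale quarter-area preset
#'   with 1200.
#' @param t_end Simulated time (s).
#' @param dose A [dose_schedule()]; `NULL` keeps the preset default. Use
#'   `dose_schedule(numeric(0), numeric(0))` for an undosed null scenario.
#' @param record_dt Time-series cadence (s).
#' @param overrides Named list of fields to replace in the assembled spec
#'   (advanced use).
#' @return An object of class `scenario_spec`.
#' @export
build_scenario <- function(name = c("control", "g6pd", "reversible_only",
                                    "uniform_dissociation", "repeated_dose",
                                    "spectrin"),
                           scale = 1, t_end = 7200, dose = NULL,
                           record_dt = 10, overrides = list()) {
  name <- match.arg(name)
  variant <- if (name == "g6pd") "g6pd" else "control"
  scheme <- if (name == "uniform_dissociation") "uniform" else "bound_site"
  hemi <- name != "reversible_only"
  spectrin <- name == "spectrin"
  if (is.null(dose)) {
    dose <- if (name == "repeated_dose")
      pulse_train(1800, 0.125e-3, n = ceiling(t_end / 1800))
    else dose_schedule(0, 0.25e-3)
  }
  spec <- list(
    name = name,
    scale = scale,
    surface = default_surface(scale),
    n_band3 = as.integer(round(4800 * scale)),
    species = species_catalogue(),
    rules = reaction_rules(scheme = scheme, hemichrome = hemi,
                           spectrin = spectrin),
    scheme = scheme,
    hemichrome = hemi,
    hemichrome_target = "band3oxi",
    metabolism = metabolism_params(variant, volume_L = 1e-16 * scale),
    dose = dose,
    spectrin = spectrin,
    spectrin_deficiency = 0,
    gap_probability = spectrin_gap_probability(),
    t_end = t_end,
    record_dt = record_dt
  )
  for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
  class(spec) <- "scenario_spec"
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: %d band 3 dimers on %.3g um^2 (scale %.3g), t_end %g s\n",
              x$name, x$n_band3, x$surface$area * 1e12, x$scale, x$t_end))
  cat(sprintf("  scheme %s, hemichrome %s, spectrin %s, %d dose(s)\n",
              x$scheme, x$hemichrome, x$spectrin, nrow(x$dose)))
  invisible(x)
}

#' Apply a scheduled diamide dose to the metabolite pools
#'
#' Adds the hematocrit-scaled per-cell diamide amount of every schedule
#' entry in `(t_from, t_to]` to the diamide pool.
#'
#' @param state Metabolism state vector.
#' @param schedule A [dose_schedule()].
#' @param t_from,t_to Window of model time covered (s).
#' @param hematocrit Suspension hematocrit.
#' @return The updated state vector.
#' @export
apply_dose <- function(state, schedule, t_from, t_to, hematocrit = 0.3) {
  hit <- schedule$time_s >= t_from & schedule$time_s < t_to
  if (any(hit))
    state[["diamide"]] <- state[["diamide"]] + sum(schedule$conc_M[hit]) / hematocrit
  state
}

band3_species <- function() c("Band3", "Band3oxi", "Band3phos", "Band3cluster",
                              "hemiBand3oxi", "hemiBand3phos", "hemiBand3cluster",
                              "BoundBand3", "BoundBand3oxi")

#' Percentage of clustered band 3 from species counts
#'
#' @param counts Named species counts (as from [engine_counts()]).
#' @return `100 * (Band3cluster + hemiBand3cluster) / total band 3`.
#' @export
percent_clustered_counts <- function(counts) {
  tot <- sum(counts[intersect(band3_species(), names(counts))])
  if (tot == 0) return(0)
  100 * (counts[["Band3cluster"]] + counts[["hemiBand3cluster"]]) / tot
}

#' Run a scenario
#'
#' Executes the coupled particle/ODE/hybrid simulation defined by a
#' [build_scenario()] specification and returns the recorded time series.
#'
#' @param spec A `scenario_spec`.
#' @param seed Integer seed; drives both the engine RNG stream and the
#'   hybrid-event draws, making runs bit-reproducible.
#' @param log_window Optional `c(t0, t1)` to record the reaction event log
#'   (for [reaction_interval_stats()]).
#' @param snapshot_dt Optional cadence (s) for occupancy snapshots.
#' @param keep_engine Return the live engine (for post-run inspection such
#'   as [bound_neighbor_histogram()]).
#' @return A list of class `scenario_run`: `series` (data frame of time,
#'   species counts, percent clustered and pool concentrations), `spec`,
#'   `seed`, plus optional `snapshots`, `event_log`, `engine`, `mesh`.
#' @export
run_scenario <- function(spec, seed = 1L, log_window = NULL,
                         snapshot_dt = NULL, keep_engine = FALSE) {
  set.seed(seed)
  eng <- particle_engine(spec$surface, spec$species, spec$rules, seed = seed)

  mesh <- NULL
  n_bound <- 0L
  if (isTRUE(spec$spectrin)) {
    mesh <- build_mesh(spec$surface, deficiency = spec$spectrin_deficiency,
                       gap_probability = spec$gap_probability)
    .eng_set_mesh(eng$ptr, mesh$filament_voxels, mesh$gap_probability)
    vv <- mesh$vertex_voxels
    n_bound <- min(length(vv), spec$n_band3)
    if (n_bound > 0) place_at(eng, "BoundBand3", vv[seq_len(n_bound)])
  }
  place_random(eng, "Band3", spec$n_band3 - n_bound)

  mi <- metabolism_init(spec$metabolism)
  state <- mi$state
  mp <- mi$params
  vol <- mp$volume_L
  per_mol <- 1 / (AVOGADRO * vol) # concentration change per molecule event

  if (!is.null(log_window)) log_events(eng, log_window[1], log_window[2])

  rec_t <- seq(0, spec$t_end, by = spec$record_dt)
  snap_t <- if (!is.null(snapshot_dt)) seq(0, spec$t_end, by = snapshot_dt) else numeric(0)
  snapshots <- list()

  sp_names <- spec$species$name
  series <- matrix(0, nrow = length(rec_t), ncol = length(sp_names) + 7)
  colnames(series) <- c("time", sp_names, "percent_clustered", "GSH", "GSSG",
                        "NADPH", "diamide", "hemichrome")
  ri <- 1L

  record <- function(tnow) {
    cts <- engine_counts(eng)
    series[ri, ] <<- c(tnow, cts, percent_clustered_counts(cts),
                       state[["GSH"]], state[["GSSG"]], state[["NADPH"]],
                       state[["diamide"]], state[["hemichrome"]])
    ri <<- ri + 1L
  }
  record(0)
  if (length(snap_t) > 0) snapshots[["0"]] <- engine_occupancy(eng)

  tnow <- 0
  while (tnow < spec$t_end) {
    dt <- if (tnow < 60) 1 else 2
    dt <- min(dt, spec$t_end - tnow)
    # keep record times on the step grid
    nxt <- rec_t[rec_t > tnow + 1e-9]
    if (length(nxt) > 0) dt <- min(dt, nxt[1] - tnow)

    state <- apply_dose(state, spec$dose, tnow, tnow + dt, mp$hematocrit)
    im <- integrate_metabolism(state, mp, dt)
    state <- im$state
    pr <- hybrid_probabilities(im$increments, mp)

    cts <- engine_counts(eng)
    # oxidation of band 3 by the diamide pool (rule 1)
    dia_pool <- floor(pool_molecules(state[["diamide"]], vol))
    n_ox <- min(stats::rbinom(1, cts[["Band3"]], pr[["oxidation"]]), dia_pool)
    n_ox <- convert_random(eng, "Band3", "Band3oxi", n_ox)
    if (isTRUE(spec$spectrin) && cts[["BoundBand3"]] > 0) {
      n_oxb <- min(stats::rbinom(1, cts[["BoundBand3"]], pr[["oxidation"]]),
                   dia_pool - n_ox)
      n_oxb <- convert_random(eng, "BoundBand3", "BoundBand3oxi", n_oxb)
      n_ox <- n_ox + n_oxb
    }
    state[["diamide"]] <- max(0, state[["diamide"]] - n_ox * per_mol)

    # re-reduction of oxidised band 3 by GSH (rule 3): consumes 2 GSH
    n_red <- stats::rbinom(1, cts[["Band3oxi"]], pr[["reduction"]])
    n_red <- convert_random(eng, "Band3oxi", "Band3", n_red)
    if (isTRUE(spec$spectrin) && cts[["BoundBand3oxi"]] > 0) {
      n_redb <- stats::rbinom(1, cts[["BoundBand3oxi"]], pr[["reduction"]])
      n_redb <- convert_random(eng, "BoundBand3oxi", "BoundBand3", n_redb)
      n_red <- n_red + n_redb
    }
    if (n_red > 0) {
      state[["GSH"]] <- max(0, state[["GSH"]] - 2 * n_red * per_mol)
      state[["GSSG"]] <- state[["GSSG"]] + n_red * per_mol
    }

    # hemichrome attachment (rule 10), limited by the hemichrome pool
    if (spec$hemichrome) {
      hemi_pool <- floor(pool_molecules(state[["hemichrome"]], vol))
      from <- if (identical(spec$hemichrome_target, "cluster")) "Band3cluster" else "Band3oxi"
      to <- if (identical(spec$hemichrome_target, "cluster")) "hemiBand3cluster" else "hemiBand3oxi"
      n_h <- min(stats::rbinom(1, cts[[from]], pr[["hemi"]]), hemi_pool)
      n_h <- convert_random(eng, from, to, n_h)
      state[["hemichrome"]] <- max(0, state[["hemichrome"]] - n_h * per_mol)
    }

    run_engine(eng, dt)
    tnow <- tnow + dt

    if (ri <= length(rec_t) && abs(tnow - rec_t[ri]) < 1e-6) record(tnow)
    if (length(snap_t) > 0 && any(abs(tnow - snap_t) < 1e-6))
      snapshots[[sprintf("%g", tnow)]] <- engine_occupancy(eng)
  }

  out <- list(series = as.data.frame(series), spec = spec, seed = seed)
  if (length(snap_t) > 0) out$snapshots <- snapshots
  if (!is.null(log_window)) out$event_log <- event_log(eng)
  if (keep_engine) { out$engine <- eng; out$mesh <- mesh }
  class(out) <- "scenario_run"
  out
}

#' Run a scenario over several seeds and aggregate
#'
#' @param spec A `scenario_spec`.
#' @param seeds Integer vector of seeds.
#' @return A list of class `scenario_ensemble` with `runs` (list of
#'   [run_scenario()] results) and `summary` (data frame of per-time mean
#'   and SD of the clustered percentage).
#' @export
run_scenarios <- function(spec, seeds = 1:10) {
  runs <- lapply(seeds, function(s) run_scenario(spec, seed = s))
  pc <- sapply(runs, function(r) r$series$percent_clustered)
  summary <- data.frame(
    time = runs[[1]]$series$time,
    mean_percent_clustered = rowMeans(pc),
    sd_percent_clustered = apply(pc, 1, stats::sd)
  )
  structure(list(runs = runs, summary = summary, seeds = seeds,
                 spec = spec), class = "scenario_ensemble")
}
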