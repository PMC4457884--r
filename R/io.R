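# Configuration files, run outputs and reproducibility plumbing.
#
# Scenario configurations are YAML with SI units (concentrations in M,
# times in s, lengths in m). Outputs are CSV (time series, snapshots,
# heatmaps) plus a JSON run manifest that suffices to replay a run
# bit-identically.

config_keys <- c("scenario", "scale", "t_end", "seed", "record_dt",
                 "dose", "pulse", "scheme", "hemichrome",
                 "hemichrome_target", "spectrin_deficiency",
                 "gap_probability", "metabolism", "collision_rates")

#' Load a scenario configuration file
#'
#' Reads a YAML scenario description, validates it (unknown keys,
#' out-of-range collision probabilities and malformed dose schedules are
#' rejected with informative messages) and resolves it against the named
#' preset's defaults. An empty file yields the packaged control scenario.
#'
#' @param path Path to a YAML file; see
#'   `system.file("extdata", "control.yaml", package = "band3sim")` for the
#'   packaged control configuration.
#' @return A list with the resolved `scenario_spec` and the `seed`.
#' @export
load_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$collision_rates)) {
    for (nm in names(cfg$collision_rates)) {
      k <- cfg$collision_rates[[nm]]
      p <- tryCatch(collision_probability(k), error = function(e)
        stop("collision rule ", nm, ": ", conditionMessage(e), call. = FALSE))
    }
  }
  dose <- NULL
  if (!is.null(cfg$pulse)) {
    pu <- cfg$pulse
    for (f in c("interval_s", "conc_M", "n"))
      if (is.null(pu[[f]])) stop("pulse schedule needs field ", f)
    dose <- pulse_train(pu$interval_s, pu$conc_M, pu$n)
  } else if (!is.null(cfg$dose)) {
    tt <- vapply(cfg$dose, function(d) d$time_s, numeric(1))
    cc <- vapply(cfg$dose, function(d) d$conc_M, numeric(1))
    if (is.unsorted(tt)) stop("dose times must be non-decreasing")
    if (any(cc < 0)) stop("dose concentrations must be non-negative")
    dose <- dose_schedule(tt, cc)
  }
  name <- if (is.null(cfg$scenario)) "control" else cfg$scenario
  overrides <- list()
  for (f in c("scheme", "hemichrome", "hemichrome_target",
              "spectrin_deficiency", "gap_probability"))
    if (!is.null(cfg[[f]])) overrides[[f]] <- cfg[[f]]
  spec <- build_scenario(
    name,
    scale = if (is.null(cfg$scale)) 1 else cfg$scale,
    t_end = if (is.null(cfg$t_end)) 7200 else cfg$t_end,
    dose = dose,
    record_dt = if (is.null(cfg$record_dt)) 10 else cfg$record_dt,
    overrides = overrides
  )
  if (!is.null(cfg$metabolism))
    for (nm in names(cfg$metabolism)) spec$metabolism[[nm]] <- cfg$metabolism[[nm]]
  list(spec = spec, seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

config_hash <- function(spec, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  slim <- spec
  slim$surface <- unclass(slim$surface)
  slim$species <- NULL # derived from the catalogue defaults
  writeLines(jsonlite::toJSON(list(spec = slim, seed = seed),
                              auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write run outputs and a reproducibility manifest
#'
#' Writes the recorded time series (tidy CSV), any occupancy snapshots
#' (one CSV per frame, coordinates in nm) and a JSON manifest recording
#' the configuration hash, seed, package version, model time span and
#' file inventory. Re-running the same configuration and seed reproduces
#' identical files.
#'
#' @param run A [run_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  ts <- file.path(dir, "timeseries.csv")
  utils::write.csv(run$series, ts, row.names = FALSE)
  files <- c(files, basename(ts))
  if (!is.null(run$snapshots)) {
    for (nm in names(run$snapshots)) {
      sn <- run$snapshots[[nm]]
      out <- data.frame(id = sn$id, species = sn$species,
                        x_nm = sn$x * 1e9, y_nm = sn$y * 1e9)
      f <- file.path(dir, sprintf("snapshot_t%s.csv", nm))
      utils::write.csv(out, f, row.names = FALSE)
      files <- c(files, basename(f))
    }
  }
  manifest <- list(
    package = "band3sim",
    version = as.character(utils::packageVersion("band3sim")),
    scenario = run$spec$name,
    config_hash = config_hash(run$spec, run$seed),
    seed = run$seed,
    t_start = 0,
    t_end = run$spec$t_end,
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Export a spectrin mesh for overlay rendering
#'
#' @param mesh A [build_mesh()] object.
#' @param path Output CSV path.
#' @return Invisibly, the exported data frame of filament segments
#'   (endpoint coordinates in nm) and vertex positions.
#' @export
write_mesh_csv <- function(mesh, path) {
  seg <- data.frame(kind = "filament",
                    x1_nm = mesh$segments$x * 1e9,
                    y1_nm = mesh$segments$y * 1e9,
                    x2_nm = (mesh$segments$x + mesh$segments$dx) * 1e9,
                    y2_nm = (mesh$segments$y + mesh$segments$dy) * 1e9)
  ver <- data.frame(kind = "vertex",
                    x1_nm = mesh$vertices$x * 1e9,
                    y1_nm = mesh$vertices$y * 1e9,
                    x2_nm = NA_real_, y2_nm = NA_real_)
  out <- rbind(seg, ver)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Dose-interval sweep of clustered band 3 levels
#'
#' Runs the control scenario under a grid of pulse intervals and diamide
#' concentrations and reports the clustered percentage at the end time
#' (heatmap format: one row per grid cell).
#'
#' @param intervals_s Pulse intervals (s).
#' @param doses_M Diamide concentrations per pulse (M).
#' @param t_end Simulated time per cell (s).
#' @param scale Sheet area scale.
#' @param seeds Seeds averaged per cell.
#' @return A data frame: `interval_s`, `dose_M`, `percent_clustered`
#'   (mean over seeds at `t_end`).
#' @export
run_dose_sweep <- function(intervals_s, doses_M, t_end = 7200, scale = 0.25,
                           seeds = 1L) {
  grid <- expand.grid(interval_s = intervals_s, dose_M = doses_M)
  grid$percent_clustered <- mapply(function(iv, dm) {
    spec <- build_scenario("control", scale = scale, t_end = t_end,
                           dose = pulse_train(iv, dm, n = ceiling(t_end / iv)))
    mean(vapply(seeds, function(s)
      percent_clustered(run_scenario(spec, seed = s)), numeric(1)))
  }, grid$interval_s, grid$dose_M)
  grid
}
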