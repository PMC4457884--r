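# Measurement procedures: cluster identification, clustered percentage,
# effective diffusion from mean squared displacement, fence-hop residency
# times, and reaction interval statistics.

#' Identify band 3 clusters from an occupancy table
#'
#' Clusters are the connected components of cluster-state molecules under
#' the 6-neighbour lattice adjacency (the same relation that defines the
#' bound-site count of the dissociation kinetics); an isolated
#' cluster-state molecule is a size-1 component.
#'
#' @param occupancy An [engine_occupancy()] data frame (or any data frame
#'   with `id`, `species`, `voxel`, `bound_neighbors` columns).
#' @param surface The [build_surface()] lattice the occupancy lives on.
#' @param cluster_species Species names treated as cluster-state.
#' @return A list of class `cluster_report`: `membership` (data frame of
#'   molecule id, voxel and cluster label), `sizes` (per-cluster sizes),
#'   `n_clusters`, and `histogram` (bound-neighbour counts for n = 0..6).
#' @export
identify_clusters <- function(occupancy, surface,
                              cluster_species = c("Band3cluster", "hemiBand3cluster")) {
  cl <- occupancy[occupancy$species %in% cluster_species, , drop = FALSE]
  hist <- tabulate(factor(cl$bound_neighbors, levels = 0:6), nbins = 7)
  names(hist) <- 0:6
  if (nrow(cl) == 0) {
    return(structure(list(membership = data.frame(id = integer(0), voxel = integer(0),
                                                  cluster = integer(0)),
                          sizes = integer(0), n_clusters = 0L, histogram = hist),
                     class = "cluster_report"))
  }
  nb <- surface_neighbors(surface)
  inset <- integer(surface$n_voxels)
  inset[cl$voxel + 1L] <- seq_len(nrow(cl))
  nbv <- nb[cl$voxel + 1L, , drop = FALSE]
  from <- rep(seq_len(nrow(cl)), 6)
  to <- inset[nbv + 1L]
  ok <- to > 0
  g <- igraph::graph_from_edgelist(cbind(from[ok], to[ok]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(cl) - igraph::vcount(g)))
  comp <- igraph::components(g)
  structure(list(
    membership = data.frame(id = cl$id, voxel = cl$voxel,
                            cluster = comp$membership[seq_len(nrow(cl))]),
    sizes = as.integer(comp$csize),
    n_clusters = comp$no,
    histogram = hist
  ), class = "cluster_report")
}

#' Percentage of clustered band 3 molecules
#'
#' @param x A `scenario_run`, an [engine_counts()] vector, or an
#'   [engine_occupancy()] data frame.
#' @param ... Unused.
#' @return Percentage of band 3 in cluster states (at the final recorded
#'   time for a `scenario_run`).
#' @export
percent_clustered <- function(x, ...) UseMethod("percent_clustered")

#' @export
percent_clustered.default <- function(x, ...) percent_clustered_counts(x)

#' @export
percent_clustered.scenario_run <- function(x, ...) {
  utils::tail(x$series$percent_clustered, 1)
}

#' @export
percent_clustered.data.frame <- function(x, ...) {
  tab <- table(factor(x$species, levels = band3_species()))
  percent_clustered_counts(as.vector(tab) |> stats::setNames(band3_species()))
}

#' Time-averaged ensemble mean squared displacement
#'
#' Computes MSD over lag times using all available time origins (the
#' standard single-particle-tracking estimator), averaged over molecules.
#'
#' @param traces An [engine_traces()] list (`t`, `x`, `y` with one column
#'   per molecule, unwrapped coordinates).
#' @param n_lags Number of lag values to evaluate.
#' @param max_lag_frac Largest lag as a fraction of the trace span.
#' @return A data frame with `lag` (s) and `msd` (m^2).
#' @export
compute_msd <- function(traces, n_lags = 40, max_lag_frac = 0.5) {
  nt <- length(traces$t)
  stopifnot(nt >= 4)
  dt <- traces$t[2] - traces$t[1]
  lags <- unique(pmax(1L, as.integer(round(seq(1, max_lag_frac * (nt - 1),
                                               length.out = n_lags)))))
  x <- as.matrix(traces$x); y <- as.matrix(traces$y)
  msd <- vapply(lags, function(L) {
    dx <- x[(1 + L):nt, , drop = FALSE] - x[1:(nt - L), , drop = FALSE]
    dy <- y[(1 + L):nt, , drop = FALSE] - y[1:(nt - L), , drop = FALSE]
    mean(dx * dx + dy * dy)
  }, numeric(1))
  data.frame(lag = lags * dt, msd = msd)
}

#' Effective diffusion coefficient from trajectories
#'
#' Ordinary-least-squares slope of the ensemble MSD against lag time over
#' a fit window, divided by 4 (two dimensions). The default window of
#' 10-50% of the trace span avoids short-time lattice discreteness and
#' long-time statistics starvation.
#'
#' @param traces An [engine_traces()] list; at least 2 samples per
#'   molecule.
#' @param fit_window Fractions `c(lo, hi)` of the maximum lag to fit over.
#' @return Effective diffusion coefficient (m^2 s^-1).
#' @export
effective_D <- function(traces, fit_window = c(0.1, 0.5)) {
  stopifnot(length(fit_window) == 2, fit_window[1] < fit_window[2])
  msd <- compute_msd(traces, max_lag_frac = fit_window[2])
  span <- max(msd$lag)
  w <- msd$lag >= fit_window[1] / fit_window[2] * span
  if (sum(w) < 2) stop("degenerate fit window")
  fit <- stats::lm(msd ~ lag, data = msd[w, ])
  unname(stats::coef(fit)[2] / 4)
}

#' Fence-hop residency times from a trajectory
#'
#' Assigns every sample of a trajectory to its mesh triangle
#' (compartment), detects debounced compartment changes (a change must
#' persist for at least `debounce` consecutive samples to count as a hop,
#' suppressing boundary jitter), and returns the dwell durations between
#' hops. The final dwell is censored by the end of the trace.
#'
#' @param t Sample times (s), strictly increasing, regular.
#' @param x,y Coordinates (m; unwrapped values allowed).
#' @param mesh A [build_mesh()] object.
#' @param debounce Minimum persistence (samples) of a compartment change.
#' @return A list with `dwells` (completed dwell durations, s), `censored`
#'   (the final, incomplete dwell, s) and `n_hops`.
#' @export
hop_residency <- function(t, x, y, mesh, debounce = 2) {
  stopifnot(length(t) >= 2, length(x) == length(t), length(y) == length(t))
  ids <- triangle_of(mesh, x, y)
  r <- rle(ids)
  # keep only runs long enough to count as a genuine compartment change;
  # short excursions are folded back into the surrounding dwell
  keep <- r$lengths >= debounce
  keep[1] <- TRUE
  vals <- r$values[keep]
  ends <- cumsum(r$lengths)[keep]
  # merge consecutive equal assignments after the filtering, keeping the
  # last end of each merged group
  last <- c(vals[-1] != vals[-length(vals)], TRUE)
  ends <- ends[last]
  starts <- c(1, utils::head(ends, -1) + 1)
  dt <- t[2] - t[1]
  dur <- (ends - starts + 1) * dt
  n <- length(dur)
  list(dwells = if (n > 1) dur[-n] else numeric(0),
       censored = dur[n],
       n_hops = n - 1L)
}

#' Per-rule mean reaction intervals from an event log
#'
#' @param log A data frame with `time` and `rule` (from [event_log()]).
#' @param window `c(t0, t1)` analysis window (s).
#' @return A data frame with one row per rule observed at least twice in
#'   the window: `rule`, `n_events`, `mean_interval` (s). Rules without
#'   events are absent (not reported as zero).
#' @export
reaction_interval_stats <- function(log, window = range(log$time)) {
  stopifnot(all(c("time", "rule") %in% names(log)))
  lg <- log[log$time >= window[1] & log$time <= window[2], ]
  if (nrow(lg) == 0)
    return(data.frame(rule = integer(0), n_events = integer(0),
                      mean_interval = numeric(0)))
  out <- do.call(rbind, lapply(split(lg$time, lg$rule), function(tt) {
    tt <- sort(tt)
    data.frame(n_events = length(tt),
               mean_interval = if (length(tt) > 1) mean(diff(tt)) else NA_real_)
  }))
  out$rule <- as.integer(rownames(out))
  rownames(out) <- NULL
  out[!is.na(out$mean_interval), c("rule", "n_events", "mean_interval")]
}
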