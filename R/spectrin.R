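# Triangular spectrin cytoskeleton: filaments rasterised onto the voxel
# lattice act as impenetrable fences that band 3 can only cross when a
# transient gap opens (with a fixed gap probability per attempted
# crossing); spectrin-bound band 3 sits at the filament intersections.

#' Calibrated fence gap probability
#'
#' Probability that an attempted crossing of a spectrin filament succeeds
#' (a transient gap in the fence). A single free parameter of the mesh
#' model, calibrated once so that the mean compartment residency time of a
#' free band 3 dimer in the intact 100-nm mesh is about 347 ms; stored here
#' with that provenance and not tuned per scenario.
#'
#' @return Numeric scalar.
#' @export
spectrin_gap_probability <- function() 0.0297

#' Build a triangular spectrin mesh on a surface lattice
#'
#' Lays out spectrin filaments as the edges of an equilateral triangular
#' tiling (target edge length 100 nm, snapped to the periodic sheet), marks
#' every voxel under a filament as impenetrable, and records the filament
#' intersections where spectrin-bound band 3 (`BoundBand3`) is anchored.
#' Deficiency removes a uniform random fraction of the filaments (edges);
#' vertices that lose all their filaments lose their anchor too.
#'
#' @param surface A [build_surface()] lattice.
#' @param edge_length Target filament length between intersections (m).
#' @param deficiency Fraction of filaments removed, in `[0, 1]`.
#' @param gap_probability Fence crossing probability; defaults to the
#'   calibrated [spectrin_gap_probability()].
#' @param seed Optional integer seed for the deficiency sampling (uses the
#'   current R RNG state when `NULL`).
#' @return An object of class `spectrin_mesh`: mesh spacing (`Lx`, `hy`),
#'   grid size (`ncx`, `nry`), `vertices` (data frame), `segments` (data
#'   frame of kept filaments with endpoint coordinates), `filament_voxels`,
#'   `vertex_voxels` and `gap_probability`.
#' @export
build_mesh <- function(surface, edge_length = 100e-9, deficiency = 0,
                       gap_probability = spectrin_gap_probability(),
                       seed = NULL) {
  stopifnot(deficiency >= 0, deficiency <= 1)
  r <- surface$voxel_radius
  if (edge_length < 8 * r) stop("mesh edge length below voxel resolution")
  if (!is.null(seed)) set.seed(seed)
  ncx <- max(1L, as.integer(round(surface$width / edge_length)))
  nry <- max(2L, as.integer(round(surface$height / (edge_length * sqrt(3) / 2))))
  if (nry %% 2L == 1L) nry <- nry + 1L
  Lx <- surface$width / ncx
  hy <- surface$height / nry

  # vertex grid (odd rows shifted by Lx/2)
  vg <- expand.grid(i = 0:(ncx - 1), j = 0:(nry - 1))
  vx <- (vg$i + 0.5 * (vg$j %% 2)) * Lx
  vy <- vg$j * hy

  # edges: east, up-right, up-left from every vertex (periodic)
  ei <- rep(vg$i, 3); ej <- rep(vg$j, 3)
  dxs <- c(rep(Lx, nrow(vg)), rep(Lx / 2, nrow(vg)), rep(-Lx / 2, nrow(vg)))
  dys <- c(rep(0, nrow(vg)), rep(hy, nrow(vg)), rep(hy, nrow(vg)))
  x1 <- (ei + 0.5 * (ej %% 2)) * Lx
  y1 <- ej * hy
  nedge <- length(x1)
  keep <- rep(TRUE, nedge)
  nrem <- round(deficiency * nedge)
  if (nrem > 0) keep[sample.int(nedge, nrem)] <- FALSE

  # voxel under a continuous point
  pt_voxel <- function(x, y) {
    j <- as.integer(round(y / (sqrt(3) * r))) %% surface$H
    i <- as.integer(round((x - (j %% 2) * r) / (2 * r))) %% surface$W
    j * surface$W + i
  }
  vertex_voxels <- pt_voxel(vx, vy)

  fil <- integer(0)
  if (any(keep)) {
    ns <- ceiling(edge_length / (r / 2))
    frac <- (0:ns) / ns
    for (e in which(keep)) {
      px <- (x1[e] + frac * dxs[e]) %% surface$width
      py <- (y1[e] + frac * dys[e]) %% surface$height
      fil <- c(fil, pt_voxel(px, py))
    }
    fil <- setdiff(unique(fil), vertex_voxels)
  }

  # anchors survive only with at least one incident filament
  if (nrem > 0) {
    inc <- integer(0)
    for (e in which(keep)) {
      v1 <- pt_voxel(x1[e], y1[e])
      v2 <- pt_voxel((x1[e] + dxs[e]) %% surface$width,
                     (y1[e] + dys[e]) %% surface$height)
      inc <- c(inc, v1, v2)
    }
    vertex_voxels <- vertex_voxels[vertex_voxels %in% unique(inc)]
  }

  structure(list(
    surface = surface, edge_length = edge_length,
    Lx = Lx, hy = hy, ncx = ncx, nry = nry,
    deficiency = deficiency,
    vertices = data.frame(x = vx, y = vy),
    segments = data.frame(x = x1[keep], y = y1[keep],
                          dx = dxs[keep], dy = dys[keep]),
    n_edges_intact = nedge,
    filament_voxels = fil,
    vertex_voxels = vertex_voxels,
    gap_probability = gap_probability
  ), class = "spectrin_mesh")
}

#' @export
print.spectrin_mesh <- function(x, ...) {
  cat(sprintf("<spectrin_mesh> %d x %d cells (edge %.3g nm), %d/%d filaments, %d anchors, gap p = %g\n",
              x$ncx, x$nry, x$Lx * 1e9, nrow(x$segments), x$n_edges_intact,
              length(x$vertex_voxels), x$gap_probability))
  invisible(x)
}

#' Triangle (compartment) assignment of points in a spectrin mesh
#'
#' Maps x/y coordinates (wrapped onto the sheet) to the index of the mesh
#' triangle containing them; used for hop detection and residency analysis.
#'
#' @param mesh A [build_mesh()] object.
#' @param x,y Coordinates in metres (unwrapped values are wrapped
#'   periodically).
#' @return Integer triangle ids.
#' @export
triangle_of <- function(mesh, x, y) {
  x <- x %% mesh$surface$width
  y <- y %% mesh$surface$height
  band <- pmin(floor(y / mesh$hy), mesh$nry - 1)
  # local coordinate with the band's bottom-row offset removed
  u <- x / mesh$Lx - 0.5 * (band %% 2)
  fy <- y / mesh$hy - band
  s1 <- floor(u - fy / 2)
  s2 <- floor(u + fy / 2)
  up <- s1 == s2
  cell <- ((ifelse(up, s1, pmin(s1, s2)) %% mesh$ncx) + mesh$ncx) %% mesh$ncx
  as.integer(band * 2 * mesh$ncx + 2 * cell + !up)
}
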