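#' @useDynLib band3sim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Lattice/geometry constants used throughout the model.
#
# The membrane patch is a flat rectangular sheet of hexagonally packed voxels
# with periodic boundaries. Its area equals the total surface area of the
# reference cuboid compartment (1.06 um x 1.06 um x 89 nm), i.e. about
# 2.62 um^2, which holds the full complement of 4800 band 3 dimers.

#' Hexagonal-lattice constants
#'
#' `hex_walk_alpha()` returns the dimensionless 2-D hexagonal-lattice
#' correction used in [walk_interval()]. `collision_kappa()` returns the
#' rate-to-probability scale for surface bimolecular reactions (m^3 s^-1),
#' see [collision_probability()]. `default_voxel_radius()` returns the voxel
#' radius in metres.
#'
#' @return A numeric scalar.
#' @export
hex_walk_alpha <- function() 0.91675

#' @rdname hex_walk_alpha
#' @export
collision_kappa <- function() 3.45e-12

#' @rdname hex_walk_alpha
#' @export
default_voxel_radius <- function() 3.62e-9

# total surface area of the reference cuboid membrane compartment (m^2)
default_sheet_area <- function() 2 * 1.06e-6^2 + 4 * 1.06e-6 * 8.9e-8

#' Build a periodic hexagonal surface lattice
#'
#' Discretises a rectangular membrane patch into a sheet of hexagonally
#' packed voxels (6 neighbours each) with periodic boundaries on all edges.
#' Voxel columns are spaced `2 * voxel_radius` apart and rows
#' `sqrt(3) * voxel_radius`; the realised dimensions are the requested ones
#' rounded to whole voxels (the row count is forced even so the periodic
#' wrap is seamless).
#'
#' @param width,height Sheet dimensions in metres. Must be positive and at
#'   least 4 voxel diameters.
#' @param voxel_radius Voxel radius in metres (default 3.62 nm).
#' @return An object of class `lattice_surface` with elements `W` (columns),
#'   `H` (rows), `n_voxels`, `voxel_radius`, `width`, `height` (realised,
#'   metres) and `area` (m^2).
#' @examples
#' surf <- build_surface(1e-7, 1e-7)
#' surf$n_voxels
#' @export
build_surface <- function(width, height, voxel_radius = default_voxel_radius()) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("surface dimensions must be positive")
  if (voxel_radius <= 0) stop("voxel_radius must be positive")
  if (width < 8 * voxel_radius || height < 4 * sqrt(3) * voxel_radius)
    stop("surface dimensions must be at least 4 voxel diameters")
  W <- max(4L, as.integer(round(width / (2 * voxel_radius))))
  H <- max(4L, as.integer(round(height / (sqrt(3) * voxel_radius))))
  if (H %% 2L == 1L) H <- H + 1L
  structure(list(
    W = W, H = H, n_voxels = W * H,
    voxel_radius = voxel_radius,
    width = W * 2 * voxel_radius,
    height = H * sqrt(3) * voxel_radius,
    area = W * H * 2 * sqrt(3) * voxel_radius^2
  ), class = "lattice_surface")
}

#' @export
print.lattice_surface <- function(x, ...) {
  cat(sprintf(
    "<lattice_surface> %d x %d voxels (n = %d), r_v = %.3g nm, %.3g x %.3g um, area %.3g um^2\n",
    x$W, x$H, x$n_voxels, x$voxel_radius * 1e9,
    x$width * 1e6, x$height * 1e6, x$area * 1e12))
  invisible(x)
}

#' Default full-scale membrane sheet
#'
#' A square periodic sheet whose area equals the total surface of the
#' reference cuboid compartment (about 2.62 um^2), holding 4800 band 3
#' dimers at the physiological surface density. `scale` shrinks the area
#' (and with it the molecule complement chosen by the scenario presets)
#' proportionally; `scale = 0.25` is the desk-scale quarter-area preset.
#'
#' @param scale Area scale factor in (0, 1].
#' @param voxel_radius Voxel radius in metres.
#' @return A `lattice_surface`.
#' @export
default_surface <- function(scale = 1, voxel_radius = default_voxel_radius()) {
  stopifnot(scale > 0, scale <= 1)
  side <- sqrt(default_sheet_area() * scale)
  build_surface(side, side, voxel_radius)
}

#' Diffusion step interval on the hexagonal lattice
#'
#' Time a molecule with diffusion coefficient `D` waits between successive
#' voxel-to-voxel walk attempts: `alpha * (2 r)^2 / (4 D)`, where `alpha`
#' is the 2-D hexagonal-lattice correction. With the default voxel radius
#' this gives 1.2 ms for unphosphorylated band 3 (D = 1e-14 m^2/s) and
#' 12 us for phosphorylated band 3 (D = 1e-12 m^2/s).
#'
#' @param D Diffusion coefficient (m^2 s^-1). Non-positive values denote an
#'   immobile species and return `Inf`.
#' @param voxel_radius Voxel radius (m).
#' @param alpha Lattice correction factor.
#' @return Walk interval in seconds.
#' @examples
#' walk_interval(1e-14) # ~1.2e-3 s
#' @export
walk_interval <- function(D, voxel_radius = default_voxel_radius(),
                          alpha = hex_walk_alpha()) {
  ifelse(D <= 0, Inf, alpha * (2 * voxel_radius)^2 / (4 * D))
}

#' Voxel centre coordinates
#'
#' @param surface A `lattice_surface`.
#' @param voxel Zero-based voxel indices (`row * W + col`).
#' @return A two-column matrix of x/y coordinates in metres.
#' @export
voxel_xy <- function(surface, voxel) {
  r <- surface$voxel_radius
  j <- voxel %/% surface$W
  i <- voxel %% surface$W
  cbind(x = 2 * r * i + (j %% 2) * r, y = sqrt(3) * r * j)
}

#' Neighbour table of a surface lattice
#'
#' Returns the 6 neighbours of every voxel (zero-based indices) under the
#' periodic hexagonal topology used by the simulation engine.
#'
#' @param surface A `lattice_surface`.
#' @return An `n_voxels` x 6 integer matrix.
#' @export
surface_neighbors <- function(surface) {
  eng <- .eng_create(surface$W, surface$H, surface$voxel_radius, 1)
  .eng_neighbors(eng)
}
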