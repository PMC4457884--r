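# Species catalogue and the band 3 reaction rule set.
#
# One particle represents one band 3 dimer. The oxidation cascade is
# Band3 -> Band3oxi -> Band3phos -> Band3cluster, with hemichrome-bound
# counterparts (hemiBand3*) once denatured haemoglobin attaches, and
# spectrin-bound species (BoundBand3*) in the cytoskeleton extension.
# Cluster-state species are immobile; phosphorylated species diffuse two
# orders of magnitude faster than unphosphorylated ones, reflecting release
# from cytoskeletal attachment upon phosphorylation.

#' Species catalogue of the band 3 clustering model
#'
#' @param D_band3 Diffusion coefficient of unphosphorylated band 3
#'   (m^2 s^-1).
#' @param D_phos Diffusion coefficient of phosphorylated band 3 (m^2 s^-1);
#'   the default reproduces the 100-fold walk-interval ratio between the
#'   phosphorylated (12 us) and unphosphorylated (1.2 ms) states.
#' @param voxel_radius Voxel radius (m), used to derive walk intervals.
#' @return A data frame with one row per species: `name`, `D`, `mobile`,
#'   `cluster_state`, `hemichrome_bound`, `walk_interval` (s) and `index`
#'   (zero-based engine index).
#' @export
species_catalogue <- function(D_band3 = 1.0e-14, D_phos = 1.0e-12,
                              voxel_radius = default_voxel_radius()) {
  # hemichrome-bound mobile species inherit the coefficients of their
  # unbound counterparts
  sp <- data.frame(
    name = c("Band3", "Band3oxi", "Band3phos", "Band3cluster",
             "hemiBand3oxi", "hemiBand3phos", "hemiBand3cluster",
             "BoundBand3", "BoundBand3oxi"),
    D = c(D_band3, D_band3, D_phos, 0, D_band3, D_phos, 0, 0, 0),
    cluster_state = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE,
                      FALSE, FALSE),
    hemichrome_bound = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                         FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  sp$mobile <- sp$D > 0
  sp$walk_interval <- walk_interval(sp$D, voxel_radius)
  sp$index <- seq_len(nrow(sp)) - 1L
  sp
}

#' Convert a bimolecular rate constant into a collision probability
#'
#' Surface bimolecular reactions fire upon collision of two reactants on
#' adjacent voxels with probability `p = k / kappa`, where
#' `kappa = 3.45e-12 m^3 s^-1` is the diffusion-limited collision scale of
#' the lattice (the unique constant consistent with all printed rate /
#' probability pairs of the rule set: 3.45e-13 -> 0.1, 1.03e-12 -> 0.3,
#' 3.45e-12 -> 1).
#'
#' @param k Intrinsic bimolecular rate constant (m^3 s^-1), positive.
#' @param kappa Rate-to-probability scale (m^3 s^-1).
#' @return Collision probability in (0, 1].
#' @examples
#' collision_probability(3.45e-13) # 0.1
#' @export
collision_probability <- function(k, kappa = collision_kappa()) {
  if (any(k <= 0)) stop("rate constant must be positive")
  p <- k / kappa
  if (any(p > 1 + 1e-12))
    stop("rate constant ", format(max(k)), " m^3/s exceeds the diffusion limit: ",
         "collision probability would be ", format(max(p)), " > 1")
  pmin(p, 1)
}

#' Neighbour-dependent cluster dissociation rate
#'
#' A cluster-associated molecule with `n_bound` occupied neighbouring sites
#' dissociates at rate `base^(6 - n_bound)` per second, so interior
#' molecules (n = 6) leave at the minimum rate of 1/s while exposed edge
#' molecules leave orders of magnitude faster.
#'
#' @param n_bound Number of bound (cluster-occupied) neighbour sites,
#'   integer in 0..6.
#' @param base Dissociation base (> 1); 4 for plain clusters, 2 for
#'   hemichrome-stabilised clusters.
#' @return Dissociation rate (s^-1).
#' @examples
#' dissociation_rate(6, 4) # 1
#' dissociation_rate(1, 4) # 1024
#' @export
dissociation_rate <- function(n_bound, base) {
  if (any(n_bound < 0 | n_bound > 6 | n_bound != round(n_bound)))
    stop("n_bound must be an integer in [0, 6]")
  if (any(base <= 1)) stop("dissociation base must exceed 1")
  base^(6 - n_bound)
}

#' The band 3 reaction rule set
#'
#' Returns the full reaction table of the clustering model: hybrid
#' pool-particle reactions (oxidation by diamide, reduction by glutathione,
#' hemichrome attachment), first-order phosphorylation state changes,
#' collision-driven cluster nucleation/growth, and neighbour-dependent
#' cluster dissociation. `rule` numbers the reaction rows; collision rows
#' carry both the intrinsic rate `k` (m^3 s^-1) and the collision
#' probability `p = k / kappa`.
#'
#' @param scheme `"bound_site"` (neighbour-dependent dissociation,
#'   the developed model) or `"uniform"` (a single first-order dissociation
#'   rate, the comparison scheme).
#' @param hemichrome Logical; include the irreversible hemichrome reactions
#'   (rules 9-15). With `FALSE` the model is the fully reversible scheme.
#' @param uniform_rate Dissociation rate used by the `"uniform"` scheme
#'   (s^-1). The default is the mean bound-site rate over the neighbour
#'   distribution observed at peak clustering in the reference run (see
#'   [uniform_dissociation_rate()]).
#' @param spectrin Logical; add the spectrin-extension rule that releases
#'   spectrin-bound oxidised band 3 into the mobile phosphorylated state
#'   (band 3 detaches from spectrin upon phosphorylation).
#' @return A data frame describing every rule.
#' @export
reaction_rules <- function(scheme = c("bound_site", "uniform"),
                           hemichrome = TRUE,
                           uniform_rate = default_uniform_rate(),
                           spectrin = FALSE) {
  scheme <- match.arg(scheme)
  rules <- list(
    # rule, kind, reactants, products, k, p, base
    list(1L, "hybrid", "Diamide+Band3", "Band3oxi", 1.0e-23, NA, NA),
    list(2L, "ode", "Diamide+2GSH", "GSSG", 300, NA, NA),
    list(3L, "hybrid", "Band3oxi+2GSH", "Band3+GSSG", 1.0e-50, NA, NA),
    list(4L, "unimolecular", "Band3oxi", "Band3phos", 5.0e-4, NA, NA),
    list(5L, "unimolecular", "Band3phos", "Band3oxi", 5.0e-3, NA, NA),
    list(6L, "collision", "Band3phos+Band3phos", "Band3cluster+Band3cluster",
         3.45e-13, 0.1, NA),
    list(7L, "collision", "Band3phos+Band3cluster", "Band3cluster+Band3cluster",
         3.45e-12, 1, NA),
    list(8L, "dissociation", "Band3cluster", "Band3phos", NA, NA, 4),
    list(9L, "ode", "HbO2+Diamide", "hemichrome", NA, NA, NA),
    list(10L, "hybrid", "Band3oxi+hemichrome", "hemiBand3oxi", 1.0e-23, NA, NA),
    list(11L, "unimolecular", "hemiBand3oxi", "hemiBand3phos", 5.0e-4, NA, NA),
    list(12L, "collision", "hemiBand3phos+hemiBand3phos",
         "hemiBand3cluster+hemiBand3cluster", 1.03e-12, 0.3, NA),
    list(12L, "collision", "Band3phos+hemiBand3phos",
         "Band3cluster+hemiBand3cluster", 1.03e-12, 0.3, NA),
    list(13L, "collision", "hemiBand3phos+hemiBand3cluster",
         "hemiBand3cluster+hemiBand3cluster", 3.45e-12, 1, NA),
    list(13L, "collision", "Band3phos+hemiBand3cluster",
         "Band3cluster+hemiBand3cluster", 3.45e-12, 1, NA),
    list(13L, "collision", "hemiBand3phos+Band3cluster",
         "hemiBand3cluster+Band3cluster", 3.45e-12, 1, NA),
    list(14L, "dissociation", "hemiBand3cluster", "hemiBand3phos", NA, NA, 2),
    list(15L, "unimolecular", "hemiBand3phos", "hemiBand3oxi", 5.0e-3, NA, NA)
  )
  if (spectrin) # phosphorylation releases spectrin-bound band 3
    rules <- c(rules, list(list(4L, "unimolecular", "BoundBand3oxi",
                                "Band3phos", 5.0e-4, NA, NA)))
  df <- do.call(rbind, lapply(rules, function(r)
    data.frame(rule = r[[1]], kind = r[[2]], reactants = r[[3]],
               products = r[[4]], k = r[[5]], p = r[[6]], base = r[[7]],
               stringsAsFactors = FALSE)))
  if (!hemichrome) df <- df[df$rule < 9L, ]
  if (scheme == "uniform") {
    i <- df$kind == "dissociation" & df$reactants == "Band3cluster"
    df$kind[i] <- "dissociation_uniform"
    df$base[i] <- NA
    df$k[i] <- uniform_rate
  }
  # cross-check printed collision probabilities against the collision scale
  ci <- df$kind == "collision"
  pc <- collision_probability(df$k[ci])
  bad <- abs(pc - df$p[ci]) > 0.005
  if (any(bad))
    warning("collision probability inconsistent with k/kappa for rule(s) ",
            paste(df$rule[ci][bad], collapse = ", "))
  df
}

#' Mean bound-site dissociation rate over an observed neighbour histogram
#'
#' Used to parameterise the uniform-rate dissociation comparison scheme:
#' the single first-order rate equals the mean of `base^(6-n)` over the
#' neighbour-count distribution of cluster-associated molecules.
#'
#' @param histogram Integer vector of length 7 (counts for n = 0..6).
#' @param base Dissociation base of the reference scheme.
#' @return Rate in s^-1.
#' @export
uniform_dissociation_rate <- function(histogram, base = 4) {
  stopifnot(length(histogram) == 7)
  if (sum(histogram) == 0) return(base^3) # arbitrary midpoint for empty input
  sum(histogram * dissociation_rate(0:6, base)) / sum(histogram)
}

# Frozen default for the uniform-rate comparison scheme, computed once with
# uniform_dissociation_rate() from the neighbour histogram of the bound-site
# control run at peak clustering (t = 30 min, desk-scale preset, seed 1:
# counts 0,3,5,18,23,23,145 for n = 0..6, mean rate 28.2 /s).
default_uniform_rate <- function() 28.2
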