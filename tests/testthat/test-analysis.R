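test_that("cluster identification matches a breadth-first-search oracle", {
  surf <- build_surface(30 * 2 * 3.62e-9, 30 * sqrt(3) * 3.62e-9)
  set.seed(77)
  voxels <- sample.int(surf$n_voxels, 500) - 1L
  occ <- data.frame(id = seq_along(voxels) - 1L, species = "Band3cluster",
                    voxel = voxels, bound_neighbors = 0L)
  rep <- identify_clusters(occ, surf)
  ora_nb <- oracle_neighbors(surf$W, surf$H, surf$voxel_radius)
  lab_ora <- oracle_bfs_components(voxels, ora_nb)
  # identical partitions (up to label permutation)
  expect_equal(rep$n_clusters, max(lab_ora))
  split_imp <- split(occ$id, rep$membership$cluster)
  split_ora <- split(occ$id, lab_ora)
  canon <- function(s) unname(lapply(s[order(sapply(s, min))], sort))
  expect_equal(canon(split_imp), canon(split_ora))
  expect_equal(sum(rep$sizes), nrow(occ))

  # permutation invariance and idempotence
  perm <- sample.int(nrow(occ))
  rep2 <- identify_clusters(occ[perm, ], surf)
  expect_equal(sort(rep2$sizes), sort(rep$sizes))
  rep3 <- identify_clusters(occ, surf)
  expect_identical(rep3$membership$cluster, rep$membership$cluster)
})

test_that("two adjacent cluster molecules form one size-2 cluster with n = 1 each", {
  surf <- build_surface(1.5e-7, 1.5e-7)
  eng <- particle_engine(surf, species_catalogue(), seed = 1)
  nb <- surface_neighbors(surf)
  v <- 4L * surf$W + 4L
  place_at(eng, "Band3cluster", c(v, nb[v + 1L, 3]))
  occ <- engine_occupancy(eng)
  expect_equal(occ$bound_neighbors, c(1L, 1L))
  rep <- identify_clusters(occ, surf)
  expect_equal(rep$n_clusters, 1L)
  expect_equal(rep$sizes, 2L)
  # empty state -> zero clusters
  rep0 <- identify_clusters(occ[0, ], surf)
  expect_equal(rep0$n_clusters, 0L)
})

test_that("clustered percentage counts cluster states over total band 3", {
  cts <- c(Band3 = 0L, Band3oxi = 0L, Band3phos = 0L, Band3cluster = 4800L,
           hemiBand3oxi = 0L, hemiBand3phos = 0L, hemiBand3cluster = 0L,
           BoundBand3 = 0L, BoundBand3oxi = 0L)
  expect_equal(percent_clustered(cts), 100)
  cts["Band3cluster"] <- 0L; cts["Band3"] <- 4800L
  expect_equal(percent_clustered(cts), 0)
  cts["Band3cluster"] <- 300L; cts["hemiBand3cluster"] <- 180L
  cts["Band3"] <- 4320L
  expect_equal(percent_clustered(cts), 100 * 480 / 4800)
})

test_that("effective_D is zero for immobile molecules and rejects bad windows", {
  tr <- list(t = seq(0, 10, by = 0.5),
             x = matrix(1e-7, nrow = 21, ncol = 5),
             y = matrix(2e-7, nrow = 21, ncol = 5))
  expect_equal(effective_D(tr), 0)
  expect_error(effective_D(tr, fit_window = c(0.5, 0.1)))
})

test_that("hop residency recovers scripted compartment dwells exactly", {
  surf <- default_surface(0.25)
  mesh <- build_mesh(surf)
  # centroids of three triangles sharing a band
  cent <- function(id) {
    band <- id %/% (2 * mesh$ncx); rest <- id %% (2 * mesh$ncx)
    cell <- rest %/% 2; up <- rest %% 2 == 0
    x <- (cell + (if (up) 0.5 else 1) + 0.5 * (band %% 2)) * mesh$Lx
    y <- (band + if (up) 1 / 3 else 2 / 3) * mesh$hy
    c(x, y)
  }
  ids <- c(0L, 1L, 2L)
  stopifnot(length(unique(triangle_of(mesh, sapply(ids, function(i) cent(i)[1]),
                                      sapply(ids, function(i) cent(i)[2]))) ) == 3)
  dt <- 0.01
  dwell_samples <- c(40, 25, 60) # scripted dwells in samples
  seqids <- rep(ids, times = dwell_samples)
  xy <- t(sapply(seqids, cent))
  res <- hop_residency(seq_along(seqids) * dt, xy[, 1], xy[, 2], mesh)
  expect_equal(res$n_hops, 2L)
  expect_equal(res$dwells, c(40, 25) * dt, tolerance = 1e-9)
  expect_equal(res$censored, 60 * dt, tolerance = 1e-9)

  # single compartment -> one censored dwell, no hops
  res0 <- hop_residency(seq_len(100) * dt, rep(xy[1, 1], 100), rep(xy[1, 2], 100),
                        mesh)
  expect_equal(res0$n_hops, 0L)
  expect_equal(length(res0$dwells), 0L)
})

test_that("debounce suppresses single-sample boundary jitter", {
  surf <- default_surface(0.25)
  mesh <- build_mesh(surf)
  dt <- 0.01
  base <- c(rep(0L, 50), 1L, rep(0L, 49), rep(2L, 50)) # 1-sample excursion
  cent <- function(id) {
    band <- id %/% (2 * mesh$ncx); rest <- id %% (2 * mesh$ncx)
    cell <- rest %/% 2; up <- rest %% 2 == 0
    c((cell + (if (up) 0.5 else 1) + 0.5 * (band %% 2)) * mesh$Lx,
      (band + if (up) 1 / 3 else 2 / 3) * mesh$hy)
  }
  xy <- t(sapply(base, cent))
  res <- hop_residency(seq_along(base) * dt, xy[, 1], xy[, 2], mesh)
  expect_equal(res$n_hops, 1L) # only the genuine change to compartment 2
  expect_equal(res$dwells, 100 * dt, tolerance = 1e-9)
})

test_that("reaction interval statistics handle scripted and Poisson streams", {
  lg <- data.frame(time = seq(2, 40, by = 2), rule = 7L)
  st <- reaction_interval_stats(lg)
  expect_equal(st$mean_interval, 2)
  expect_equal(st$n_events, 20L)

  set.seed(5)
  lam <- 50
  tt <- cumsum(stats::rexp(4000, lam))
  stp <- reaction_interval_stats(data.frame(time = tt, rule = 1L))
  expect_lt(abs(stp$mean_interval - 1 / lam), 4 / (lam * sqrt(4000)))

  # a rule without events is absent, not zero
  st2 <- reaction_interval_stats(data.frame(time = c(1, 2), rule = c(3L, 3L)),
                                 window = c(0, 10))
  expect_false(5L %in% st2$rule)
})
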