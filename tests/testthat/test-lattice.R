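test_that("walk interval reproduces the anchored step times and scales with D", {
  expect_lt(abs(walk_interval(1.0e-14) * 1e3 - 1.2), 0.05)  # ms
  expect_lt(abs(walk_interval(1.0e-12) * 1e6 - 12), 0.5)    # us
  expect_equal(walk_interval(2e-14), walk_interval(1e-14) / 2)
  expect_identical(walk_interval(0), Inf)
  expect_identical(walk_interval(-1), Inf)
})

test_that("surface construction validates dimensions and holds the full complement", {
  expect_error(build_surface(-1e-7, 1e-7), "positive")
  expect_error(build_surface(1e-8, 1e-7), "4 voxel diameters")
  surf <- default_surface()
  expect_gte(surf$n_voxels, 4800)
  expect_lt(abs(surf$area - 2.62e-12) / 2.62e-12, 0.01)
  # realised area is consistent to within one voxel row
  expect_lt(abs(surf$area - surf$width * surf$height), surf$width * 2 * surf$voxel_radius)
})

test_that("every voxel has 6 distinct neighbours and the relation is symmetric", {
  surf <- build_surface(4 * 2 * 3.62e-9, 4 * sqrt(3) * 3.62e-9)
  expect_equal(surf$W, 4L); expect_equal(surf$H, 4L)
  nb <- surface_neighbors(surf)
  expect_true(all(apply(nb, 1, function(z) length(unique(z)) == 6)))

  surf10 <- build_surface(10 * 2 * 3.62e-9, 10 * sqrt(3) * 3.62e-9)
  nb10 <- surface_neighbors(surf10)
  # exhaustive symmetry scan
  for (v in seq_len(nrow(nb10))) {
    for (u in nb10[v, ]) expect_true((v - 1L) %in% nb10[u + 1L, ])
  }
  # brute-force geometric oracle: neighbours are the voxels at distance 2r
  ora <- oracle_neighbors(surf10$W, surf10$H, surf10$voxel_radius)
  for (v in seq_len(nrow(nb10))) {
    expect_equal(sort(nb10[v, ]), ora[[v]])
  }
})

test_that("random placement is exclusive, exhaustive and seed-reproducible", {
  surf <- default_surface()
  sp <- species_catalogue()
  eng <- particle_engine(surf, sp, seed = 7)
  place_random(eng, "Band3", 4800)
  occ <- engine_occupancy(eng)
  expect_equal(nrow(occ), 4800)
  expect_equal(length(unique(occ$voxel)), 4800)

  # zero-count placement leaves occupancy unchanged
  place_random(eng, "Band3", 0)
  expect_equal(nrow(engine_occupancy(eng)), 4800)

  # over-filling is rejected
  small <- build_surface(8e-8, 8e-8)
  eng2 <- particle_engine(small, sp, seed = 1)
  expect_error(place_random(eng2, "Band3", small$n_voxels + 1), "free voxels")

  # same seed -> identical placement; different seed -> different
  engA <- particle_engine(surf, sp, seed = 3); place_random(engA, "Band3", 500)
  engB <- particle_engine(surf, sp, seed = 3); place_random(engB, "Band3", 500)
  engC <- particle_engine(surf, sp, seed = 4); place_random(engC, "Band3", 500)
  expect_identical(engine_occupancy(engA)$voxel, engine_occupancy(engB)$voxel)
  expect_false(identical(engine_occupancy(engA)$voxel, engine_occupancy(engC)$voxel))
})

test_that("excluded volume holds throughout a crowded simulation", {
  surf <- default_surface(0.1)
  eng <- particle_engine(surf, species_catalogue(), seed = 2)
  place_random(eng, "Band3", floor(surf$n_voxels * 0.3))
  run_engine(eng, 5)
  occ <- engine_occupancy(eng)
  expect_equal(length(unique(occ$voxel)), nrow(occ))
})

test_that("a fully surrounded molecule never moves", {
  surf <- build_surface(1e-7, 1e-7)
  sp <- species_catalogue()
  eng <- particle_engine(surf, sp, seed = 5)
  nb <- surface_neighbors(surf)
  centre <- 3L * surf$W + 3L
  place_at(eng, "Band3", centre)
  place_at(eng, "BoundBand3", nb[centre + 1L, ]) # immobile cage
  run_engine(eng, 2)
  occ <- engine_occupancy(eng)
  expect_equal(occ$voxel[occ$species == "Band3"], centre)
})

test_that("free walkers recover the lattice diffusion coefficient within 5%", {
  # the hexagonal walk realises an effective coefficient D/alpha (the
  # sampling excess over the nominal D that the model is anchored to)
  tr <- simulate_free_diffusion(n = 200, duration = 25, seed = 11,
                                scale = 0.25, sample_dt = 0.25)
  dhat <- effective_D(tr)
  target <- 1.0e-14 / hex_walk_alpha()
  expect_lt(abs(dhat - target) / target, 0.05)
})

test_that("crowding reduces the effective diffusion coefficient", {
  d_dilute <- effective_D(simulate_free_diffusion(100, 20, seed = 21, scale = 0.25,
                                                  sample_dt = 0.25))
  d_crowd <- effective_D(simulate_free_diffusion(1200, 20, seed = 21, scale = 0.25,
                                                 sample_dt = 0.25))
  expect_lt(d_crowd, d_dilute)
})

test_that("identical seeds give bit-identical trajectories", {
  run1 <- simulate_free_diffusion(50, 5, seed = 42, scale = 0.1, sample_dt = 0.5)
  run2 <- simulate_free_diffusion(50, 5, seed = 42, scale = 0.1, sample_dt = 0.5)
  expect_identical(run1$x, run2$x)
  expect_identical(run1$y, run2$y)
  run3 <- simulate_free_diffusion(50, 5, seed = 43, scale = 0.1, sample_dt = 0.5)
  expect_false(identical(run1$x, run3$x))
})
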