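test_that("climate world has the configured geometry, range and determinism", {
  cfg <- world_config(fine_shape = c(120L, 120L), aggregation_factor = 6L,
                      seed = 3L)
  w1 <- generate_climate_world(cfg)
  expect_equal(dim(w1$energy_fine), c(120L, 120L))
  expect_equal(w1$coarse_dim, c(20L, 20L))

  w2 <- generate_climate_world(cfg)
  expect_identical(w1$energy_fine, w2$energy_fine)
  expect_identical(w1$land_mask, w2$land_mask)

  land_vals <- w1$energy_fine[w1$land_mask]
  expect_true(all(land_vals >= cfg$energy_range[1] &
                    land_vals <= cfg$energy_range[2]))
  water_vals <- w1$water_fine[w1$land_mask]
  expect_true(all(water_vals >= cfg$water_range[1] &
                    water_vals <= cfg$water_range[2]))
  expect_equal(mean(w1$land_mask), cfg$land_fraction, tolerance = 0.05)
  # climate defined exactly on land
  expect_true(all(is.na(w1$energy_fine[!w1$land_mask])))
  expect_false(anyNA(w1$energy_fine[w1$land_mask]))
})

test_that("invalid world configurations are rejected", {
  expect_error(world_config(fine_shape = c(121L, 120L)), "divisible")
  expect_error(world_config(aggregation_factor = 1L), ">= 2")
  expect_error(world_config(energy_range = c(5, 5)), "max > min")
})

test_that("species pools concentrate around their archetypes", {
  world <- generate_climate_world(world_config(seed = 5L))
  archs <- default_archetypes(breadth = 0.06, n_species = 12L)
  pool <- suppressWarnings(generate_species_pool(world, archs, seed = 5L))
  expect_equal(length(pool$planted_labels), n_species(pool$presence))
  expect_true(all(lengths(pool$presence$cells) >= 5L))

  # all occupied cells lie on coarse land with defined climate
  coarse <- aggregate_world(world)
  cells <- unique(unlist(pool$presence$cells))
  expect_true(all(coarse$land[cells]))
  expect_false(anyNA(coarse$energy[cells]))

  # block structure: within-archetype profile cosine similarity exceeds
  # between-archetype similarity (computed directly from emitted profiles)
  assignment <- assign_bins(coarse, bin_grid(coarse, 10L))
  prof <- niche_profiles(pool$presence, assignment)
  w <- as.matrix(prof$w)
  w <- sweep(w, 2, sqrt(colSums(w^2)), "/")
  cosine <- crossprod(w)
  lab <- pool$planted_labels[colnames(w)]
  same <- outer(lab, lab, "==") & upper.tri(cosine)
  diff <- outer(lab, lab, "!=") & upper.tri(cosine)
  expect_gt(mean(cosine[same]), mean(cosine[diff]))

  # pool determinism
  pool2 <- suppressWarnings(generate_species_pool(world, archs, seed = 5L))
  expect_identical(pool$presence$cells, pool2$presence$cells)
})

test_that("an archetype with no suitable climate is reported by index", {
  world <- generate_climate_world(world_config(seed = 5L))
  bad <- archetype_spec(c(1e6, 1e6), c(1, 1), 3L)
  expect_error(generate_species_pool(world, list(bad)),
               "archetype 1 has zero")
})

test_that("geographic restriction keeps ~rho of each range, contiguously", {
  run <- small_run()
  presence <- run$presence
  land <- run$coarse$land

  ident <- apply_geographic_restriction(presence, 1, land, seed = 2L)
  expect_identical(ident$cells, presence$cells)

  half <- apply_geographic_restriction(presence, 0.5, land, seed = 2L)
  n0 <- lengths(presence$cells)[names(half$cells)]
  n1 <- lengths(half$cells)
  expect_true(all(abs(n1 - pmax(5L, round(0.5 * n0))) <= 1L))

  # retained cells are a subset of the original range
  for (s in names(half$cells)) {
    expect_true(all(half$cells[[s]] %in% presence$cells[[s]]))
  }
})
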