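test_that("bootstrap networks preserve profile normalization", {
  run <- small_run()
  boots <- bootstrap_networks(run$presence, run$coarse, run$assignment,
                              B = 3L, seed = 9L)
  expect_length(boots, 3L)
  for (b in boots) {
    per_sp <- rowsum(b$edges$weight, b$edges$species)
    expect_true(all(abs(per_sp - 1) < 1e-9))
  }
  # determinism
  boots2 <- bootstrap_networks(run$presence, run$coarse, run$assignment,
                               B = 3L, seed = 9L)
  expect_identical(boots[[2]]$edges, boots2[[2]]$edges)
})

test_that("a single-pixel cell resamples to itself", {
  # coarse world with factor 2 and exactly one land pixel in a block
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- TRUE          # block (1,1): single pixel
  mask[3:4, 3:4] <- TRUE      # block (2,2): four pixels
  energy <- matrix(NA_real_, 4, 4)
  water <- matrix(NA_real_, 4, 4)
  energy[mask] <- c(10, 20, 22, 24, 26)
  water[mask] <- c(5, 6, 7, 8, 9)
  world <- structure(list(
    energy_fine = energy, water_fine = water, land_mask = mask,
    coarse_dim = c(2L, 2L),
    config = world_config(fine_shape = c(4L, 4L), aggregation_factor = 2L)
  ), class = "climate_world")
  coarse <- aggregate_world(world)
  expect_equal(coarse$energy[1, 1], 10)
  expect_equal(nrow(coarse$cell_pixels[[1]]), 1L)

  pres <- presence_matrix(list(spA = c(1L, 4L), spB = 4L), c(2L, 2L))
  assignment <- assign_bins(coarse, bin_grid(coarse, 2L))
  boots <- bootstrap_networks(pres, coarse, assignment, B = 5L, seed = 1L)
  # spA's single-pixel cell always lands in the same bin: its weight on the
  # bin of cell 1 never drops below the deterministic share
  for (b in boots) {
    wA <- b$edges$weight[b$edges$species == "spA"]
    expect_true(abs(sum(wA) - 1) < 1e-12)
  }
})

test_that("resampled cell means have the analytic bootstrap variance", {
  set.seed(42)
  pix <- rnorm(30, sd = 3)
  n <- length(pix)
  means <- replicate(4000, mean(sample(pix, n, replace = TRUE)))
  # bootstrap variance of the mean = population (1/n) variance / n
  expected <- (stats::var(pix) * (n - 1) / n) / n
  expect_equal(stats::var(means), expected, tolerance = 0.1)
})

test_that("support counts matching bootstrap modules above the threshold", {
  net <- micro_network()
  obs <- flat_partition(
    net, stats::setNames(c(1, 2, 2, 1, 1, 2), c("b1", "b2", "b3", "s1", "s2", "s3")))

  # identical partitions: support 1 everywhere
  sup <- domain_support(obs, rep(list(obs), 10))
  expect_equal(sup$support, c(1, 1))
  expect_equal(attr(sup, "B"), 10L)

  # 7 of 10 partitions keep domain 1 intact; 3 scramble it
  scram <- flat_partition(
    net, stats::setNames(c(1, 1, 2, 2, 1, 2), c("b1", "b2", "b3", "s1", "s2", "s3")))
  sup <- domain_support(obs, c(rep(list(obs), 7), rep(list(scram), 3)))
  expect_equal(sup$support[1], 0.7)

  # Jaccard matching is strict by default: similarity exactly 0.5 misses.
  # one-module bootstrap partition {all six nodes} vs domain {b1,s1,s2}
  # has J = 3/6 = 0.5 exactly
  allin <- flat_partition(
    net, stats::setNames(rep(1, 6), c("b1", "b2", "b3", "s1", "s2", "s3")))
  expect_equal(domain_support(obs, list(allin))$support[1], 0)
  expect_equal(domain_support(obs, list(allin), strict = FALSE)$support[1], 1)

  expect_error(domain_support(obs, list()), "at least one")
})
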