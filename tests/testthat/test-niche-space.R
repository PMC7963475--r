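test_that("block aggregation takes masked means and flags empty blocks", {
  fine <- matrix(2, 12, 6)
  mask <- matrix(TRUE, 12, 6)
  expect_equal(aggregate_to_coarse(fine, mask, 6L), matrix(2, 2, 1))

  # one block: land values 1, 2, 3 among 33 sea pixels -> mean 2
  fine <- matrix(99, 6, 6)
  mask <- matrix(FALSE, 6, 6)
  fine[1, 1] <- 1; fine[2, 1] <- 2; fine[3, 1] <- 3
  mask[1:3, 1] <- TRUE
  expect_equal(aggregate_to_coarse(fine, mask, 6L), matrix(2, 1, 1))

  # all-sea block -> NA
  expect_true(is.na(aggregate_to_coarse(matrix(1, 6, 6),
                                        matrix(FALSE, 6, 6), 6L)[1, 1]))
  expect_error(aggregate_to_coarse(matrix(1, 7, 6), matrix(TRUE, 7, 6), 6L),
               "divisible")
})

test_that("aggregation is mean-preserving over land", {
  run <- small_run()
  world <- run$world
  coarse <- run$coarse
  n <- coarse$n_land_pixels
  expect_equal(
    sum(coarse$energy[coarse$land] * n[coarse$land]) / sum(n),
    mean(world$energy_fine[world$land_mask]),
    tolerance = 1e-9
  )
})

test_that("quantile edges follow the linear-interpolation convention", {
  expect_equal(as.numeric(quantile_edges(1:100, 2L)), c(1, 50.5, 100))

  # skewed values: every interval still holds n/d +- 1 cells
  set.seed(1)
  vals <- rexp(400)^2
  for (d in c(4L, 7L, 10L)) {
    e <- quantile_edges(vals, d)
    counts <- table(findInterval(vals, e, rightmost.closed = TRUE,
                                 all.inside = TRUE))
    expect_true(all(abs(counts - length(vals) / d) <= 1))
  }

  # duplicate edges collapse
  e <- quantile_edges(c(5, 5, 5, 7), 4L)
  expect_lt(attr(e, "effective_d"), 4L)
  expect_true(all(diff(e) > 0))

  expect_error(quantile_edges(1:10, 1L), ">= 2")
  expect_error(quantile_edges(rep(3, 10), 4L), "degenerate")
})

test_that("bin assignment is half-open, exhaustive and disjoint", {
  run <- small_run()
  coarse <- run$coarse
  grid <- bin_grid(coarse, 8L)
  assignment <- assign_bins(coarse, grid)

  # exact lower edge of an interior interval maps into that interval
  e3 <- grid$energy_edges[3]
  idx <- findInterval(e3, grid$energy_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  expect_equal(idx, 3L)
  # maximum value falls in the last (closed) interval, not overflow
  mx <- max(coarse$energy[coarse$land])
  expect_equal(findInterval(mx, grid$energy_edges, rightmost.closed = TRUE,
                            all.inside = TRUE),
               length(grid$energy_edges) - 1L)

  # partition property: bin sizes sum to land cells; every land cell binned
  expect_equal(sum(assignment$bins$n_cells), sum(coarse$land))
  expect_false(anyNA(assignment$bin_id[coarse$land]))
  expect_true(all(is.na(assignment$bin_id[!coarse$land])))
})

test_that("out-of-range values clamp to the end bins and are counted", {
  x <- c(-5, 0.5, 1.5, 99)
  idx <- nichedomains:::interval_index(x, c(0, 1, 2))
  expect_equal(as.integer(idx), c(1L, 1L, 2L, 2L))
  expect_equal(attr(idx, "n_clamped"), 2L)
})

test_that("small ranges are filtered at the configured threshold", {
  cells <- lapply(1:10, function(k) seq_len(k))
  names(cells) <- sprintf("sp%02d", 1:10)
  pres <- presence_matrix(cells, c(10L, 10L))

  filt <- filter_small_ranges(pres, 5L)
  expect_equal(n_species(filt), 6L)           # counts 1..4 removed
  expect_equal(nrow(attr(filt, "removed")), 4L)
  expect_true(all(lengths(filt$cells) >= 5L))
  # 4-cell species removed, 5-cell species kept
  expect_false("sp04" %in% names(filt$cells))
  expect_true("sp05" %in% names(filt$cells))

  expect_identical(filter_small_ranges(pres, 1L)$cells, pres$cells)
  expect_error(filter_small_ranges(pres, 99L), "no species survive filter")
})

test_that("niche profiles are occurrence proportions summing to one", {
  bin_id <- matrix(c(1L, 1L, 2L, 3L), 2, 2)
  assignment <- micro_assignment(bin_id, c("A", "B", "C"))
  pres <- presence_matrix(list(sp1 = c(1L, 2L, 3L, 4L), sp2 = c(1L, 2L)),
                          c(2L, 2L))
  prof <- niche_profiles(pres, assignment)
  expect_equal(as.numeric(prof$w[, "sp1"]), c(0.5, 0.25, 0.25))
  expect_equal(as.numeric(prof$w[, "sp2"]), c(1, 0, 0))
  expect_equal(unname(Matrix::colSums(prof$w)), c(1, 1))

  run <- small_run()
  expect_true(all(abs(Matrix::colSums(run$profiles$w) - 1) < 1e-9))
  # profile conservation: total weight equals number of species
  expect_equal(sum(run$profiles$w), n_species(run$presence), tolerance = 1e-9)
})

test_that("the division elbow rule picks the first saturated candidate", {
  expect_equal(division_elbow(c(5L, 10L, 15L, 20L, 25L),
                              c(1.0, 2.0, 2.9, 2.95, 2.96)), 15L)
  expect_equal(division_elbow(12L, 3.2), 12L)
  expect_error(division_elbow(integer(0), numeric(0)), "empty")
})

test_that("division selection recovers the planted domain count", {
  run <- small_run()
  sel <- select_divisions(run$presence, run$coarse, d_candidates = c(6L, 12L, 18L),
                          n_runs = 10L, seed = 3L)
  expect_true(sel$d_star %in% c(6L, 12L, 18L))
  expect_equal(nrow(sel$curve), 3L)
  expect_true(all(sel$curve$gain > 0))
  part <- sel$partitions[[as.character(sel$d_star)]]
  expect_equal(max(part$module), 4L)
})
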