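test_that("bin specificity matches the hand-worked micro-network", {
  net <- micro_network()
  part <- micro_partition()
  s <- bin_specificity(net, part)
  expect_equal(unname(s["b1"]), 1, tolerance = 1e-12)
  expect_equal(unname(s["b2"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(s["b3"]), 1, tolerance = 1e-12)

  # Eq. 1 conservation: own-domain share + cross-domain share = 1 per bin
  e <- net$edges
  dom <- stats::setNames(part$module, part$nodes)
  for (b in unique(e$bin)) {
    sel <- e$bin == b
    own <- sum(e$weight[sel][dom[e$species[sel]] == dom[b]])
    cross <- sum(e$weight[sel][dom[e$species[sel]] != dom[b]])
    expect_equal(own / sum(e$weight[sel]) + cross / sum(e$weight[sel]), 1,
                 tolerance = 1e-12)
  }
})

test_that("projected specificity is constant within a bin, no smoothing", {
  # 2x3 coarse grid: bins 1 (A), 2 (B), 3 (C) laid out with a boundary
  bin_id <- matrix(c(1L, 1L, 2L, 2L, 3L, NA), 2, 3)
  assignment <- micro_assignment(bin_id, c("b1", "b2", "b3"))
  s <- c(b1 = 1, b2 = 1 / 3, b3 = 0.75)
  sp <- project_specificity(assignment, s)
  expect_equal(sp[1:2, 1], c(1, 1))
  expect_equal(sp[1:2, 2], c(1 / 3, 1 / 3))
  expect_equal(sp[1, 3], 0.75)
  expect_true(is.na(sp[2, 3]))
  # histogram bookkeeping: value counts equal bin cell counts
  counts <- table(sp)
  expect_equal(as.integer(counts[as.character(c(1 / 3, 0.75, 1))]),
               c(2L, 1L, 2L))
})

test_that("actual specificity follows Eq. 2 on the micro-network", {
  net <- micro_network()
  part <- micro_partition()
  # one-cell-per-bin geography; the b2 cell holds species s2 and s3
  bin_id <- matrix(c(1L, 2L, 3L), 1, 3)
  assignment <- micro_assignment(bin_id, c("b1", "b2", "b3"))
  pres <- presence_matrix(list(s1 = 1L, s2 = c(1L, 2L), s3 = c(2L, 3L)),
                          c(1L, 3L))
  sa <- actual_specificity(net, part, pres, assignment)
  # b2 in domain 2; present species s2 (w=0.5, domain 1), s3 (w=0.25, domain 2)
  expect_equal(sa[1, 2], 0.25 / 0.75, tolerance = 1e-12)
  expect_equal(sa[1, 1], 1)    # b1 cell holds s1, s2, both domain 1
  expect_equal(sa[1, 3], 1)    # b3 cell holds only s3

  # cell holding only the same-domain species
  pres2 <- presence_matrix(list(s1 = 1L, s2 = 1L, s3 = c(2L, 3L)), c(1L, 3L))
  sa2 <- actual_specificity(net, part, pres2, assignment)
  expect_equal(sa2[1, 2], 1)

  # no species anywhere in a cell -> excluded
  expect_equal(attr(sa2, "n_excluded"), 0L)
})

test_that("G is the mean absolute difference and its anchors hold", {
  s_p <- matrix(c(0.5, 0.9), 1, 2)
  s_a <- matrix(c(0.7, 0.5), 1, 2)
  expect_equal(geographical_signal(s_a, s_p)$G, 0.3, tolerance = 1e-12)

  # S_A == S_P -> G = 0
  expect_equal(geographical_signal(s_p, s_p)$G, 0)

  # when every cell's species pool reproduces its bin's weights, Eq. 2
  # reduces to Eq. 1 cell-wise and G vanishes
  net <- micro_network()
  part <- micro_partition()
  bin_id <- matrix(c(1L, 2L, 3L), 1, 3)
  assignment <- micro_assignment(bin_id, c("b1", "b2", "b3"))
  pres_full <- presence_matrix(
    list(s1 = 1L, s2 = c(1L, 2L), s3 = c(2L, 3L)), c(1L, 3L))
  # s2 and s3 together reproduce b2's full weight set; s1, s2 reproduce b1's
  sa <- actual_specificity(net, part, pres_full, assignment)
  sp <- project_specificity(assignment, bin_specificity(net, part))
  expect_equal(geographical_signal(sa, sp)$G, 0, tolerance = 1e-12)

  expect_error(geographical_signal(matrix(NA_real_, 1, 1),
                                   matrix(NA_real_, 1, 1)), "no usable")
})

test_that("region maps conserve bin cell counts and label by domain", {
  run <- small_run()
  regions <- region_map(run$assignment, run$partition)
  # every land cell labelled
  expect_false(anyNA(regions$labels[run$coarse$land]))
  # conservation: cells per region = sum of its bins' cell counts
  dom_of_bin <- stats::setNames(
    run$partition$module[run$partition$kind == "bin"],
    run$partition$nodes[run$partition$kind == "bin"])
  for (d in regions$legend$domain) {
    if (d == 0) next
    bins_d <- names(dom_of_bin)[dom_of_bin == d]
    n_from_bins <- sum(run$assignment$bins$n_cells[
      run$assignment$bins$label %in% bins_d])
    expect_equal(regions$legend$n_cells[regions$legend$domain == d],
                 n_from_bins)
  }
  # geographic recovery: region labels align with the planted archetype
  # footprints (majority vote per planted domain, mismatch only at edges)
  sp_cells <- run$presence$cells
  planted <- run$planted_labels
  mismatch <- 0; total <- 0
  for (a in sort(unique(planted))) {
    cells_a <- unlist(sp_cells[names(planted)[planted == a]])
    lab <- regions$labels[unique(cells_a)]
    best <- as.integer(names(which.max(table(lab))))
    mismatch <- mismatch + sum(lab != best)
    total <- total + length(lab)
  }
  expect_lt(mismatch / total, 0.25)
})

test_that("all specificity values and G stay within [0, 1]", {
  run <- small_run()
  spec <- bin_specificity(run$network, run$partition)
  expect_true(all(spec > 0 & spec <= 1))
  expect_true(all(run$S_P[!is.na(run$S_P)] >= 0 & run$S_P[!is.na(run$S_P)] <= 1))
  expect_true(all(run$S_A[!is.na(run$S_A)] >= 0 & run$S_A[!is.na(run$S_A)] <= 1))
  expect_gte(run$signal$G, 0)
  expect_lte(run$signal$G, 1)
})
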