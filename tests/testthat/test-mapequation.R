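test_that("one-module code length equals the visit-rate entropy", {
  # 4 nodes with uniform flow in one module: L = log2(4) = 2 bits
  net4 <- niche_network_from_edges(data.frame(
    bin = c("b1", "b1", "b2", "b2"),
    species = c("s1", "s2", "s1", "s2"), weight = 0.5
  ))
  one <- stats::setNames(rep("1", 4), c("b1", "b2", "s1", "s2"))
  expect_equal(map_equation_code_length(net4, one), 2, tolerance = 1e-12)
  expect_equal(one_level_codelength(net4), 2, tolerance = 1e-12)
})

test_that("disconnected components have no exit term and never merge for free", {
  # two equal bicliques, disconnected
  net <- niche_network_from_edges(data.frame(
    bin = c("b1", "b1", "b2", "b2"),
    species = c("s1", "s2", "s3", "s4"),
    weight = c(0.7, 0.3, 0.5, 0.5)
  ))
  g <- nichedomains:::as_graph(net)
  p <- g$strength / (2 * g$total)
  split_mod <- stats::setNames(c("1", "2", "1", "1", "2", "2"), g$node_ids)
  # closed form: L = sum over modules of p_module * H(within visit rates)
  L_manual <- 0
  for (m in c("1", "2")) {
    pm <- p[split_mod == m]
    L_manual <- L_manual + sum(pm) *
      (-sum((pm / sum(pm)) * log2(pm / sum(pm))))
  }
  expect_equal(map_equation_code_length(net, split_mod), L_manual,
               tolerance = 1e-12)

  # merging the two components into one module never decreases L
  merged <- stats::setNames(rep("1", 6), g$node_ids)
  expect_gte(map_equation_code_length(net, merged),
             map_equation_code_length(net, split_mod))
})

test_that("hierarchical partitions refuse mixed module/leaf levels", {
  net <- micro_network()
  bad <- stats::setNames(c("1", "1:1", "1:1", "1", "1:2", "1:2"),
                         c("b1", "b2", "b3", "s1", "s2", "s3"))
  expect_error(map_equation_code_length(net, bad), "mixes nodes")
})

test_that("a nested path and its flat equivalent differ by the index term", {
  net <- make_random_bipartite(4, 6, seed = 9)
  found <- detect_domains(net, n_runs = 50, seed = 1, hierarchical = FALSE)
  flat <- stats::setNames(as.character(found$module), found$nodes)
  nested <- stats::setNames(paste0("1:", found$module), found$nodes)
  L_flat <- map_equation_code_length(net, flat)
  L_nested <- map_equation_code_length(net, nested)
  # wrapping everything under one super-module adds a (possibly zero)
  # index codebook; it can never compress better
  expect_gte(L_nested + 1e-12, L_flat)
})

test_that("the optimizer attains the exhaustive-search minimum", {
  sizes <- list(c(3L, 5L), c(4L, 4L), c(3L, 7L), c(4L, 6L), c(5L, 5L))
  for (k in seq_along(sizes)) {
    net <- make_random_bipartite(sizes[[k]][1], sizes[[k]][2], seed = 20 + k)
    oracle <- exhaustive_min_codelength(net)
    found <- detect_domains(net, n_runs = 100, seed = k, hierarchical = FALSE)
    expect_equal(found$codelength, oracle$codelength, tolerance = 1e-9)
    # C++ and R evaluations of the found partition agree
    L_r <- map_equation_code_length(
      net, stats::setNames(as.character(found$module), found$nodes))
    expect_equal(L_r, found$codelength, tolerance = 1e-9)
  }
})

test_that("the partition-count iterator enumerates Bell numbers", {
  bell <- function(n) {
    k <- 0L
    nichedomains:::iterate_partitions(n, function(m) k <<- k + 1L)
    k
  }
  expect_equal(vapply(1:6, bell, 0L), c(1L, 2L, 5L, 15L, 52L, 203L))
})
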