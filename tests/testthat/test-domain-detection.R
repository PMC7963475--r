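test_that("disconnected bicliques are split into their components", {
  net <- niche_network_from_edges(data.frame(
    bin = c("b1", "b1", "b2", "b2"),
    species = c("s1", "s2", "s3", "s4"),
    weight = c(0.6, 0.4, 0.5, 0.5)
  ))
  part <- detect_domains(net, n_runs = 20, seed = 1)
  expect_equal(max(part$module), 2L)
  sets <- domain_node_sets(part)
  sets <- lapply(sets, sort)
  expect_true(list(c("b1", "s1", "s2")) %in% sets ||
                identical(sets[[1]], c("b1", "s1", "s2")) ||
                identical(sets[[2]], c("b1", "s1", "s2")))
})

test_that("detection is deterministic given seed and n_runs", {
  net <- make_random_bipartite(6, 14, seed = 33)
  p1 <- detect_domains(net, n_runs = 30, seed = 5)
  p2 <- detect_domains(net, n_runs = 30, seed = 5)
  expect_identical(p1$path, p2$path)
  expect_identical(p1$codelength, p2$codelength)
  expect_error(detect_domains(net, n_runs = 0, seed = 1), "n_runs")
})

test_that("planted archetypes are recovered and beat their own code length", {
  run <- small_run()
  part <- run$partition
  sp <- names(run$presence$cells)
  found <- part$module[match(sp, part$nodes)]
  planted <- run$planted_labels[sp]
  expect_gte(adjusted_mutual_information(found, planted), 0.9)

  # search result is at least as compressed as the planted partition
  # (bins labelled by their majority planted domain)
  g <- nichedomains:::as_graph(run$network)
  planted_paths <- character(g$n)
  names(planted_paths) <- g$node_ids
  planted_paths[sp] <- as.character(planted)
  for (b in g$node_ids[g$kind == "bin"]) {
    e <- run$network$edges[run$network$edges$bin == b, ]
    by_dom <- rowsum(e$weight, planted[e$species])
    planted_paths[b] <- rownames(by_dom)[which.max(by_dom)]
  }
  L_planted <- map_equation_code_length(run$network, planted_paths)
  expect_lte(part$codelength, L_planted + 1e-9)

  # and never worse than the trivial one-module solution
  expect_lte(part$codelength, one_level_codelength(run$network) + 1e-9)
})

test_that("a custom backend can replace the built-in optimizer", {
  net <- make_random_bipartite(4, 6, seed = 2)
  # trivial backend: everything in one module
  one_mod <- function(graph, n_trials) {
    g_mod <- rep(1L, graph$n)
    list(modules = g_mod,
         codelength = nichedomains:::codelength_flat(graph, g_mod))
  }
  part <- detect_domains(net, n_runs = 5, seed = 1, hierarchical = FALSE,
                         backend = one_mod)
  expect_equal(max(part$module), 1L)
  expect_equal(part$codelength, one_level_codelength(net), tolerance = 1e-12)
})

test_that("major domains are flagged at the species threshold", {
  net <- micro_network()
  part <- flat_partition(
    net, stats::setNames(c(1, 2, 2, 1, 1, 2), c("b1", "b2", "b3", "s1", "s2", "s3")))
  md <- major_domains(part, min_species = 2L)
  expect_equal(md$major, c(TRUE, FALSE))
  expect_equal(sum(md$n_species), 3L)   # partition property

  md_all <- major_domains(part, min_species = 1L)
  expect_true(all(md_all$major))

  # threshold boundary: 49 species minor, 50 major
  mods <- c(rep(1L, 49L), rep(2L, 50L))
  fake <- structure(list(
    nodes = c(sprintf("x%03d", 1:99), "bA", "bB"),
    kind = c(rep("species", 99), "bin", "bin"),
    path = as.character(c(mods, 1L, 2L)),
    module = c(mods, 1L, 2L),
    top = c(mods, 1L, 2L),
    codelength = 1, n_levels = 1L
  ), class = "niche_partition")
  md <- major_domains(fake, min_species = 50L)
  expect_equal(md$major, c(FALSE, TRUE))
})
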