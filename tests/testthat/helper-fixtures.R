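# Shared fixtures: all built in code at test time.

# Random bipartite niche network with nb bins and ns species; every species
# row sums to 1 and every bin has at least one link.
make_random_bipartite <- function(nb, ns, seed) {
  set.seed(seed)
  repeat {
    w <- matrix(stats::rbinom(nb * ns, 1, 0.5) * stats::runif(nb * ns), nb, ns)
    if (all(colSums(w) > 0) && all(rowSums(w) > 0)) break
  }
  w <- sweep(w, 2, colSums(w), "/")
  idx <- which(w > 0, arr.ind = TRUE)
  niche_network_from_edges(data.frame(
    bin = sprintf("b%02d", idx[, 1]),
    species = sprintf("s%02d", idx[, 2]),
    weight = w[idx]
  ))
}

# The 3-species / 3-bin micro-network used throughout the hand-worked
# examples: s1 entirely in b1; s2 split evenly over b1, b2; s3 over b2 (1/4)
# and b3 (3/4).
micro_network <- function() {
  niche_network_from_edges(data.frame(
    bin = c("b1", "b1", "b2", "b2", "b3"),
    species = c("s1", "s2", "s2", "s3", "s3"),
    weight = c(1, 0.5, 0.5, 0.25, 0.75)
  ))
}

# Its reference partition: D1 = {b1, s1, s2}, D2 = {b2, b3, s3}.
micro_partition <- function() {
  nodes <- c("b1", "b2", "b3", "s1", "s2", "s3")
  structure(list(
    nodes = nodes,
    kind = c("bin", "bin", "bin", "species", "species", "species"),
    path = c("1", "2", "2", "1", "1", "2"),
    module = c(1L, 2L, 2L, 1L, 1L, 2L),
    top = c(1L, 2L, 2L, 1L, 1L, 2L),
    codelength = NA_real_,
    n_levels = 1L
  ), class = "niche_partition")
}

# Hand-built bin assignment on a tiny coarse grid: a matrix of bin ids and
# matching metadata, enough for the geography operations.
micro_assignment <- function(bin_id, labels) {
  occ <- sort(unique(as.vector(bin_id[!is.na(bin_id)])))
  bins <- data.frame(
    bin_id = occ,
    label = labels[occ],
    n_cells = as.integer(table(factor(bin_id[!is.na(bin_id)], levels = occ))),
    stringsAsFactors = FALSE
  )
  structure(list(bin_id = bin_id, bins = bins, grid = NULL, n_clamped = 0L),
            class = "bin_assignment")
}

# A small synthetic world pipeline run shared by several tests (built once
# per test process).
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- run_config(
        world = world_config(fine_shape = c(120L, 120L), seed = 7L),
        archetypes = default_archetypes(breadth = 0.06),
        d = 12L, n_runs = 30L, n_runs_boot = 20L, B = 0L, seed = 7L
      )
      cache <<- run_pipeline(cfg, verbose = FALSE)
    }
    cache
  }
})

# flat niche_partition from a named module vector (for hand tests)
flat_partition <- function(network, modules) {
  g <- nichedomains:::as_graph(network)
  m <- modules[g$node_ids]
  structure(list(
    nodes = g$node_ids, kind = g$kind,
    path = as.character(m),
    module = match(m, sort(unique(m))),
    top = as.integer(m),
    codelength = NA_real_, n_levels = 1L
  ), class = "niche_partition")
}

# all permutations of a vector (tiny n only), for the AMI oracle
all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
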