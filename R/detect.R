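# Niche-domain detection: multi-restart map-equation search plus an
# optional hierarchical pass (grouping of domains into super-domains and
# recursive splitting), each accepted only when it lowers the hierarchical
# code length.

new_niche_partition <- function(g, paths, codelength) {
  upaths <- sort(unique(paths))
  finest <- match(paths, upaths)
  top <- as.integer(vapply(strsplit(paths, ":", fixed = TRUE), `[`, "", 1L))
  structure(list(
    nodes = g$node_ids,
    kind = g$kind,
    path = paths,
    module = finest,
    top = top,
    codelength = codelength,
    n_levels = max(lengths(strsplit(paths, ":", fixed = TRUE)))
  ), class = "niche_partition")
}

#' @export
print.niche_partition <- function(x, ...) {
  cat("niche_partition:", max(x$module), "domains over", length(x$nodes),
      "nodes (", sum(x$kind == "bin"), "bins,", sum(x$kind == "species"),
      "species ), code length", format(x$codelength, digits = 6), "bits,",
      x$n_levels, "level(s)\n")
  invisible(x)
}

#' Node sets of the finest-level domains
#'
#' @param partition A `niche_partition`.
#' @param node_kind `"union"` (bins and species, the default), `"species"`,
#'   or `"bin"`.
#' @return Named list of character node-id vectors, one per finest domain.
#' @export
domain_node_sets <- function(partition, node_kind = c("union", "species", "bin")) {
  node_kind <- match.arg(node_kind)
  keep <- switch(node_kind,
                 union = rep(TRUE, length(partition$nodes)),
                 species = partition$kind == "species",
                 bin = partition$kind == "bin")
  split(partition$nodes[keep], partition$module[keep])
}

# run the optimizer backend on an internal graph
run_backend <- function(g, n_trials, backend) {
  if (is.null(backend)) {
    infomap_core(g$n, g$from, g$to, g$w, as.integer(n_trials))
  } else {
    backend(g, n_trials)
  }
}

# aggregate an internal graph by a flat module vector
aggregate_graph <- function(g, modules) {
  m_from <- modules[g$from]
  m_to <- modules[g$to]
  cross <- m_from != m_to
  nm <- max(modules)
  strength <- as.numeric(rowsum(g$strength, modules))
  if (!any(cross)) {
    return(list(n = nm, from = integer(0), to = integer(0), w = numeric(0),
                strength = strength, total = g$total))
  }
  a <- pmin(m_from[cross], m_to[cross])
  b <- pmax(m_from[cross], m_to[cross])
  key <- paste(a, b)
  w <- as.numeric(rowsum(g$w[cross], key))
  ab <- do.call(rbind, strsplit(rownames(rowsum(g$w[cross], key)), " "))
  list(n = nm, from = as.integer(ab[, 1]), to = as.integer(ab[, 2]), w = w,
       strength = strength, total = g$total)
}

induced_subgraph <- function(g, nodes) {
  sel <- g$from %in% nodes & g$to %in% nodes
  idx <- match(seq_len(g$n), nodes)
  from <- idx[g$from[sel]]
  to <- idx[g$to[sel]]
  w <- g$w[sel]
  strength <- numeric(length(nodes))
  for (k in seq_along(from)) {
    strength[from[k]] <- strength[from[k]] + w[k]
    strength[to[k]] <- strength[to[k]] + w[k]
  }
  list(n = length(nodes), from = from, to = to, w = w, strength = strength,
       total = sum(w))
}

#' Detect niche domains by minimizing the map equation
#'
#' Runs a multi-restart stochastic search (random node order, greedy local
#' moves with module aggregation repeated to convergence) for the partition
#' of the bipartite species-bin network with the minimum map-equation code
#' length, keeping the best of `n_runs` restarts. With
#' `hierarchical = TRUE`, two refinements are then attempted and accepted
#' only when they lower the hierarchical code length: grouping the found
#' domains into super-domains (the top hierarchical level), and recursively
#' splitting domains into sub-domains. Domains reported downstream are
#' always the finest-level modules.
#'
#' @param network A `niche_network`.
#' @param n_runs Number of restarts (the reference analysis scale is 1000).
#' @param seed Integer RNG seed; results are deterministic given
#'   `(seed, n_runs)`.
#' @param hierarchical Attempt the hierarchical refinements?
#' @param backend `NULL` for the built-in optimizer, or a function
#'   `(graph, n_trials)` returning `list(modules = <integer>, codelength =
#'   <bits>)` over the same node ordering, to substitute an external
#'   map-equation optimizer.
#' @return A `niche_partition`.
#' @export
detect_domains <- function(network, n_runs = 1000L, seed = 1L,
                           hierarchical = TRUE, backend = NULL) {
  stopifnot(inherits(network, "niche_network"))
  if (n_runs < 1L) stop_config("n_runs must be >= 1")
  g <- as_graph(network)
  if (g$n < 2L) stop_config("network must have at least 2 nodes")

  with_seed(seed, {
    res <- run_backend(g, n_runs, backend)
    modules <- match(res$modules, unique(res$modules))
    paths <- as.character(modules)
    L <- res$codelength

    if (hierarchical) {
      # super-domain grouping (top level of the hierarchy)
      nm <- max(modules)
      if (nm >= 3L) {
        ag <- aggregate_graph(g, modules)
        if (length(ag$w) > 0) {
          sup <- run_backend(ag, min(n_runs, 100L), backend)
          smod <- match(sup$modules, unique(sup$modules))
          if (max(smod) > 1L && max(smod) < nm) {
            cand <- paste(smod[modules], modules, sep = ":")
            Lc <- map_equation_code_length(network,
                                           stats::setNames(cand, g$node_ids))
            if (Lc < L - 1e-12) {
              paths <- cand
              L <- Lc
            }
          }
        }
      }
      # recursive sub-domain splitting
      for (depth in 1:3) {
        improved <- FALSE
        for (mp in unique(paths)) {
          members <- which(paths == mp)
          if (length(members) < 4L) next
          sg <- induced_subgraph(g, members)
          if (length(sg$w) == 0L) next
          sub <- run_backend(sg, min(n_runs, 50L), backend)
          sm <- match(sub$modules, unique(sub$modules))
          if (max(sm) < 2L) next
          cand <- paths
          cand[members] <- paste(mp, sm, sep = ":")
          Lc <- map_equation_code_length(network,
                                         stats::setNames(cand, g$node_ids))
          if (Lc < L - 1e-12) {
            paths <- cand
            L <- Lc
            improved <- TRUE
          }
        }
        if (!improved) break
      }
    }
  })
  new_niche_partition(g, paths, L)
}
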