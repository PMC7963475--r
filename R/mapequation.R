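# The map equation for undirected weighted networks with link-weight
# proportional flow: node visit rates are strengths normalized by twice the
# total link weight, module exit rates are boundary link weight over twice
# the total. Code lengths are in bits.

# Module exit rates q_m (flow units) for a flat partition given as an
# integer module vector over graph nodes.
module_exits <- function(g, modules) {
  cross <- modules[g$from] != modules[g$to]
  q <- numeric(max(modules))
  if (any(cross)) {
    cf <- rowsum(g$w[cross], modules[g$from][cross])
    ct <- rowsum(g$w[cross], modules[g$to][cross])
    q[as.integer(rownames(cf))] <- q[as.integer(rownames(cf))] + cf[, 1]
    q[as.integer(rownames(ct))] <- q[as.integer(rownames(ct))] + ct[, 1]
  }
  q / (2 * g$total)
}

# Two-level map-equation code length for a flat partition (integer labels
# 1..M, no gaps required).
codelength_flat <- function(g, modules) {
  modules <- match(modules, sort(unique(modules)))
  p <- g$strength / (2 * g$total)
  q <- module_exits(g, modules)
  S <- as.numeric(rowsum(p, modules))
  sum(plogp(sum(q))) - 2 * sum(plogp(q)) + sum(plogp(q + S)) - sum(plogp(p))
}

#' One-level (single module) map-equation code length
#'
#' The entropy of the node visit rates: the description length of a random
#' walk when the whole network is a single module. The compression gain of a
#' partition is this value minus its optimized code length.
#'
#' @param network A `niche_network`.
#' @return Code length in bits.
#' @export
one_level_codelength <- function(network) {
  g <- as_graph(network)
  p <- g$strength / (2 * g$total)
  -sum(plogp(p))
}

# Normalize a partition argument into a named character vector of module
# paths ("1", "2:1", ...) over the graph's node ids.
partition_paths <- function(partition, node_ids) {
  if (inherits(partition, "niche_partition")) {
    paths <- stats::setNames(partition$path, partition$nodes)
  } else if (is.character(partition)) {
    paths <- partition
  } else if (is.numeric(partition)) {
    paths <- stats::setNames(as.character(as.integer(partition)),
                             names(partition))
  } else {
    stop_config("unsupported partition representation")
  }
  missing <- setdiff(node_ids, names(paths))
  if (length(missing)) {
    stop_config("partition is missing nodes: ", paste(utils::head(missing, 3),
                                                      collapse = ", "))
  }
  paths[node_ids]
}

#' Map-equation code length of a (possibly hierarchical) partition
#'
#' Evaluates the description length, in bits, of a random walk on the
#' undirected weighted species-bin network under a given nested module
#' structure. For a flat partition this is the two-level map equation; for
#' nested module paths the index-level term recurses: every internal module
#' contributes a codebook over its children's enter rates plus its own exit
#' rate, and every finest module a codebook over its nodes' visit rates plus
#' its exit rate.
#'
#' @param network A `niche_network`.
#' @param partition A `niche_partition`, or a named vector mapping every
#'   node id to a module path such as `"2"` or `"2:1"` (colon-nested,
#'   finest last), or a named integer module vector.
#' @return Code length in bits.
#' @export
map_equation_code_length <- function(network, partition) {
  g <- as_graph(network)
  paths <- partition_paths(partition, g$node_ids)
  split_paths <- strsplit(unname(paths), ":", fixed = TRUE)
  depth <- lengths(split_paths)
  p <- g$strength / (2 * g$total)

  # exit rate of the node set labelled by a path prefix
  prefix_of <- function(k) {
    vapply(split_paths, function(pp) {
      if (length(pp) >= k) paste(pp[seq_len(k)], collapse = ":") else NA_character_
    }, "")
  }
  max_depth <- max(depth)
  prefix_levels <- lapply(seq_len(max_depth), prefix_of)

  exit_of <- function(member) {
    cross <- xor(member[g$from], member[g$to])
    sum(g$w[cross]) / (2 * g$total)
  }

  # collect every distinct prefix with its members, children, leaf status
  terms <- 0
  all_prefixes <- character(0)
  for (k in seq_len(max_depth)) {
    lv <- prefix_levels[[k]]
    for (pref in unique(stats::na.omit(lv))) {
      member <- !is.na(lv) & lv == pref
      is_leaf_here <- depth[member] == k
      if (any(is_leaf_here) && !all(is_leaf_here)) {
        stop_config("invalid partition: module '", pref,
                    "' mixes nodes and submodules")
      }
      q_pref <- exit_of(member)
      if (all(is_leaf_here)) {
        total <- q_pref + sum(p[member])
        terms <- terms + plogp(total) - plogp(q_pref) - sum(plogp(p[member]))
      } else {
        kids <- unique(prefix_levels[[k + 1L]][member])
        q_kids <- vapply(kids, function(kp) {
          exit_of(!is.na(prefix_levels[[k + 1L]]) &
                    prefix_levels[[k + 1L]] == kp)
        }, 0)
        total <- q_pref + sum(q_kids)
        terms <- terms + plogp(total) - plogp(q_pref) - sum(plogp(q_kids))
      }
      all_prefixes <- c(all_prefixes, pref)
    }
  }
  # root codebook over top-level module enter (= exit) rates
  top <- unique(prefix_levels[[1L]])
  q_top <- vapply(top, function(tp) {
    exit_of(prefix_levels[[1L]] == tp)
  }, 0)
  terms + plogp(sum(q_top)) - sum(plogp(q_top))
}

# --- exhaustive-search oracle (tiny networks only) ------------------------

# Iterate all set partitions of n items as restricted growth strings,
# calling fn(modules) for each. Bell(10) = 115975, so n <= 10 stays cheap.
iterate_partitions <- function(n, fn) {
  a <- integer(n)      # 0-based growth string
  b <- integer(n)      # b[i] = max(a[1..i-1])
  repeat {
    fn(a + 1L)
    # next restricted growth string
    i <- n
    while (i > 1L && a[i] == b[i] + 1L) i <- i - 1L
    if (i == 1L) break
    a[i] <- a[i] + 1L
    if (i < n) {
      for (j in (i + 1L):n) {
        b[j] <- max(b[j - 1L], a[j - 1L])
        a[j] <- 0L
      }
    }
  }
  invisible(NULL)
}

#' Exhaustively minimize the two-level map equation (oracle)
#'
#' Evaluates every set partition of the network's nodes and returns the
#' global minimum two-level code length. Only feasible for very small
#' networks; used as an independent check of the stochastic search.
#'
#' @param network A `niche_network` with at most `max_n` nodes.
#' @param max_n Safety cap on node count (default 10).
#' @return A list: `codelength`, `modules` (named integer vector).
#' @export
exhaustive_min_codelength <- function(network, max_n = 10L) {
  g <- as_graph(network)
  if (g$n > max_n) stop_config("exhaustive search capped at ", max_n, " nodes")
  best <- Inf
  best_mod <- NULL
  iterate_partitions(g$n, function(m) {
    L <- codelength_flat(g, m)
    if (L < best - 1e-12) {
      best <<- L
      best_mod <<- m
    }
  })
  list(codelength = best,
       modules = stats::setNames(best_mod, g$node_ids))
}
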