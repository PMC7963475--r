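# Bootstrap significance clustering: resample fine-pixel climates within
# each occupied coarse cell, rebuild the species-bin network, re-cluster,
# and score each observed domain by Jaccard module matching.

#' Bootstrap replicate networks from within-cell climate resampling
#'
#' For every replicate, every species, and every coarse cell the species
#' occupies, the cell's `n` fine land pixels are resampled with replacement
#' (`n` draws, jointly for the energy and water axes so within-cell
#' covariance is preserved), averaged, and the cell re-assigned to a climate
#' bin using the original bin edges. Profiles and the bipartite network are
#' then rebuilt. This propagates within-cell climatic variability -- the
#' dominant range-map uncertainty -- into the domain structure.
#'
#' @param presence A filtered `presence_matrix`.
#' @param coarse A `coarse_climate` (holds the per-cell fine pixel values).
#' @param assignment The observed `bin_assignment` (its edges are reused,
#'   never re-estimated, across replicates).
#' @param B Number of bootstrap networks (the reference analysis scale is
#'   100).
#' @param seed Integer RNG seed.
#' @return List of `B` `niche_network` objects.
#' @export
bootstrap_networks <- function(presence, coarse, assignment, B = 100L,
                               seed = 1L) {
  stopifnot(inherits(presence, "presence_matrix"),
            inherits(coarse, "coarse_climate"),
            inherits(assignment, "bin_assignment"))
  if (B < 1L) stop_config("B must be >= 1")
  grid <- assignment$grid
  sp_names <- names(presence$cells)
  cells_flat <- unlist(presence$cells, use.names = FALSE)
  sp_rep <- rep(seq_along(sp_names), lengths(presence$cells))
  if (any(vapply(coarse$cell_pixels[unique(cells_flat)], is.null, TRUE))) {
    stop_config("missing fine pixel values for an occupied cell")
  }
  by_cell <- split(seq_along(cells_flat), cells_flat)

  with_seed(seed, {
    lapply(seq_len(B), function(b) {
      e_mean <- numeric(length(cells_flat))
      w_mean <- numeric(length(cells_flat))
      for (cell_chr in names(by_cell)) {
        rows <- by_cell[[cell_chr]]
        pix <- coarse$cell_pixels[[as.integer(cell_chr)]]
        n <- nrow(pix)
        draw <- matrix(sample.int(n, n * length(rows), replace = TRUE),
                       nrow = n)
        e_mean[rows] <- colMeans(matrix(pix[draw, 1L], nrow = n))
        w_mean[rows] <- colMeans(matrix(pix[draw, 2L], nrow = n))
      }
      e_idx <- interval_index(e_mean, grid$energy_edges)
      w_idx <- interval_index(w_mean, grid$water_edges)
      bin <- (e_idx - 1L) * grid$d_w + w_idx

      bin_levels <- sort(unique(bin))
      counts <- Matrix::sparseMatrix(
        i = match(bin, bin_levels), j = sp_rep, x = 1,
        dims = c(length(bin_levels), length(sp_names))
      )
      w <- counts %*% Matrix::Diagonal(x = 1 / Matrix::colSums(counts))
      w <- methods::as(w, "CsparseMatrix")
      e_of <- (bin_levels - 1L) %/% grid$d_w + 1L
      w_of <- (bin_levels - 1L) %% grid$d_w + 1L
      bins <- data.frame(
        bin_id = bin_levels,
        label = sprintf("e%02d_w%02d", e_of, w_of),
        e_idx = e_of, w_idx = w_of,
        n_cells = NA_integer_,
        stringsAsFactors = FALSE
      )
      dimnames(w) <- list(bins$label, sp_names)
      build_network(structure(list(w = w, bins = bins, species = sp_names),
                              class = "niche_profiles"))
    })
  })
}

# Jaccard similarity between two character sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Bootstrap support of the observed niche domains
#'
#' For each observed finest-level domain (node set: its bins and species,
#' or species only), the support is the proportion of bootstrap partitions
#' that contain at least one module with Jaccard similarity strictly above
#' `jaccard_threshold` to it. Nodes absent from a bootstrap network count
#' as absent from all its modules.
#'
#' @param observed The observed `niche_partition`.
#' @param bootstrap_partitions List of `niche_partition` objects fitted to
#'   bootstrap networks.
#' @param jaccard_threshold Matching threshold (default 0.5).
#' @param node_kind Node set defining a domain: `"union"` (default) or
#'   `"species"`.
#' @param strict Use strictly-greater matching (default `TRUE`).
#' @return A `support_table` data.frame: `domain`, `n_bins`, `n_species`,
#'   `support`; attributes `B` and `jaccard_threshold`.
#' @export
domain_support <- function(observed, bootstrap_partitions,
                           jaccard_threshold = 0.5,
                           node_kind = c("union", "species"),
                           strict = TRUE) {
  node_kind <- match.arg(node_kind)
  if (length(bootstrap_partitions) < 1L) {
    stop_config("need at least one bootstrap partition")
  }
  obs_sets <- domain_node_sets(observed, node_kind)
  if (any(lengths(obs_sets) == 0L)) stop_config("empty observed domain")
  boot_sets <- lapply(bootstrap_partitions, domain_node_sets, node_kind)

  support <- vapply(obs_sets, function(dom) {
    hits <- vapply(boot_sets, function(bs) {
      best <- max(vapply(bs, jaccard, 0, a = dom))
      if (strict) best > jaccard_threshold else best >= jaccard_threshold
    }, TRUE)
    mean(hits)
  }, 0)

  kinds <- split(observed$kind, observed$module)
  out <- data.frame(
    domain = as.integer(names(obs_sets)),
    n_bins = vapply(kinds, function(k) sum(k == "bin"), 0L),
    n_species = vapply(kinds, function(k) sum(k == "species"), 0L),
    support = unname(support)
  )
  attr(out, "B") <- length(bootstrap_partitions)
  attr(out, "jaccard_threshold") <- jaccard_threshold
  class(out) <- c("support_table", "data.frame")
  out
}

#' Flag major niche domains
#'
#' A domain is "major" when it holds at least `min_species` species nodes;
#' smaller domains are typically left uninterpreted in regional summaries.
#'
#' @param partition A `niche_partition`.
#' @param min_species Species-count threshold (default 50).
#' @return data.frame: `domain`, `n_species`, `n_bins`, `major`.
#' @export
major_domains <- function(partition, min_species = 50L) {
  kinds <- split(partition$kind, partition$module)
  n_sp <- vapply(kinds, function(k) sum(k == "species"), 0L)
  n_bin <- vapply(kinds, function(k) sum(k == "bin"), 0L)
  data.frame(
    domain = as.integer(names(kinds)),
    n_species = unname(n_sp),
    n_bins = unname(n_bin),
    major = unname(n_sp >= min_species)
  )
}
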