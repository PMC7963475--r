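# Coarse aggregation of the climate fields, the quantile-binned climate
# space, and species niche profiles (the bipartite link weights).

# Per-coarse-block count of TRUE fine pixels.
block_counts <- function(mask, factor) {
  nr <- nrow(mask) %/% factor
  nc <- ncol(mask) %/% factor
  out <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx)) {
    fr <- ((idx - 1L) %% nrow(mask)) %/% factor + 1L
    fc <- ((idx - 1L) %/% nrow(mask)) %/% factor + 1L
    tab <- table(factor(cell_index(fr, fc, nr), levels = seq_len(nr * nc)))
    out[] <- as.integer(tab)
  }
  out
}

#' Aggregate a fine raster to the coarse grid by masked block means
#'
#' Each coarse cell is the arithmetic mean of its fine land pixels;
#' coarse cells whose block holds no land pixel are `NA`. Non-integer
#' aggregation factors are not supported: real rasters whose resolutions are
#' not integer multiples must be resampled upstream.
#'
#' @param fine_raster Numeric matrix (may contain `NA` over sea).
#' @param land_mask Logical matrix, same shape.
#' @param factor Integer block side; must divide both dimensions.
#' @return Numeric coarse matrix with `NA` for all-sea blocks.
#' @export
aggregate_to_coarse <- function(fine_raster, land_mask, factor) {
  if (any(dim(fine_raster) %% factor != 0)) {
    stop_config("raster dimensions must be divisible by the aggregation factor")
  }
  stopifnot(all(dim(fine_raster) == dim(land_mask)))
  nr <- nrow(fine_raster) %/% factor
  nc <- ncol(fine_raster) %/% factor
  idx <- which(land_mask & !is.na(fine_raster))
  sums <- matrix(0, nr, nc)
  counts <- matrix(0L, nr, nc)
  if (length(idx)) {
    fr <- ((idx - 1L) %% nrow(fine_raster)) %/% factor + 1L
    fc <- ((idx - 1L) %/% nrow(fine_raster)) %/% factor + 1L
    g <- cell_index(fr, fc, nr)
    rs <- rowsum(fine_raster[idx], g)
    sums[as.integer(rownames(rs))] <- as.numeric(rs)
    counts[] <- as.integer(table(factor(g, levels = seq_len(nr * nc))))
  }
  out <- sums / counts
  out[counts == 0L] <- NA_real_
  out
}

#' Aggregate a climate world to its coarse analysis grid
#'
#' Computes coarse energy and water rasters (masked block means), the coarse
#' land mask (>= 1 fine land pixel), and stores each coarse land cell's fine
#' (energy, water) pixel values, which the bootstrap resampler draws from.
#'
#' @param world A `climate_world`.
#' @return A `coarse_climate` list: `energy`, `water` (coarse matrices),
#'   `land` (logical), `n_land_pixels`, `cell_pixels` (list indexed by
#'   coarse cell id -> 2-column matrix of fine energy/water values),
#'   `dim`, `factor`.
#' @export
aggregate_world <- function(world) {
  stopifnot(inherits(world, "climate_world"))
  f <- world$config$aggregation_factor
  energy <- aggregate_to_coarse(world$energy_fine, world$land_mask, f)
  water <- aggregate_to_coarse(world$water_fine, world$land_mask, f)
  counts <- block_counts(world$land_mask, f)
  land <- counts > 0L

  nrf <- nrow(world$land_mask)
  nrc <- nrow(land)
  idx <- which(world$land_mask)
  fr <- ((idx - 1L) %% nrf) %/% f + 1L
  fc <- ((idx - 1L) %/% nrf) %/% f + 1L
  coarse_of_fine <- cell_index(fr, fc, nrc)
  ord <- order(coarse_of_fine)
  pix <- cbind(energy = world$energy_fine[idx][ord],
               water = world$water_fine[idx][ord])
  groups <- coarse_of_fine[ord]
  cell_pixels <- vector("list", nrc * ncol(land))
  split_idx <- split(seq_along(groups), groups)
  for (k in names(split_idx)) {
    cell_pixels[[as.integer(k)]] <- pix[split_idx[[k]], , drop = FALSE]
  }

  structure(list(
    energy = energy, water = water, land = land,
    n_land_pixels = counts, cell_pixels = cell_pixels,
    dim = dim(land), factor = f
  ), class = "coarse_climate")
}

#' Quantile break points for one climate axis
#'
#' Breaks are placed at the k/d quantiles (k = 0..d, linear-interpolation
#' quantiles) of the land-cell values, so each interval holds an
#' approximately equal number of cells regardless of how skewed the axis is.
#' Consecutive duplicate breaks (heavy ties) are collapsed; the effective
#' number of divisions may then be below `d`.
#'
#' @param values Numeric vector of coarse land-cell values of the axis.
#' @param d Number of divisions (>= 2).
#' @return Strictly increasing numeric vector of at most `d + 1` edges;
#'   attribute `"effective_d"` is `length(edges) - 1`.
#' @export
quantile_edges <- function(values, d) {
  if (d < 2L) stop_config("d must be >= 2")
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop_config("no values to bin")
  if (max(values) - min(values) < .Machine$double.eps) {
    stop_config("degenerate axis: all values identical")
  }
  edges <- unname(stats::quantile(values, probs = seq(0, 1, length.out = d + 1L),
                                  type = 7))
  edges <- edges[c(TRUE, diff(edges) > 0)]
  attr(edges, "effective_d") <- length(edges) - 1L
  edges
}

#' Build the two-dimensional climate-space bin grid
#'
#' @param coarse A `coarse_climate`.
#' @param d Number of quantile divisions for both axes, or `c(d_energy,
#'   d_water)`.
#' @return A `bin_grid` list: `energy_edges`, `water_edges`, `d_e`, `d_w`.
#' @export
bin_grid <- function(coarse, d) {
  stopifnot(inherits(coarse, "coarse_climate"))
  d <- rep_len(as.integer(d), 2L)
  ee <- quantile_edges(coarse$energy[coarse$land], d[1])
  we <- quantile_edges(coarse$water[coarse$land], d[2])
  structure(list(
    energy_edges = as.numeric(ee), water_edges = as.numeric(we),
    d_e = attr(ee, "effective_d"), d_w = attr(we, "effective_d")
  ), class = "bin_grid")
}

# Interval index with the half-open convention [e_k, e_{k+1}), last closed;
# out-of-range values (edges from another dataset) clamp to the end bins.
interval_index <- function(x, edges) {
  n_clamped <- sum(x < edges[1] | x > edges[length(edges)], na.rm = TRUE)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  attr(idx, "n_clamped") <- n_clamped
  idx
}

#' Assign every coarse land cell to a climate bin
#'
#' Intervals are half-open (left closed) with the last interval closed, so
#' the assignment is exhaustive and disjoint. Values outside the outer edges
#' (possible when edges come from another dataset) are clamped to the end
#' bins and counted.
#'
#' @param coarse A `coarse_climate`.
#' @param grid A `bin_grid`.
#' @return A `bin_assignment` list: `bin_id` (integer coarse matrix, `NA`
#'   over sea), `bins` (data.frame bin_id/label/e_idx/w_idx/intervals/
#'   n_cells for non-empty bins), `grid`, `n_clamped`.
#' @export
assign_bins <- function(coarse, grid) {
  stopifnot(inherits(coarse, "coarse_climate"), inherits(grid, "bin_grid"))
  land_idx <- which(coarse$land)
  e_idx <- interval_index(coarse$energy[land_idx], grid$energy_edges)
  w_idx <- interval_index(coarse$water[land_idx], grid$water_edges)
  n_clamped <- attr(e_idx, "n_clamped") + attr(w_idx, "n_clamped")
  bin <- (e_idx - 1L) * grid$d_w + w_idx
  bin_id <- matrix(NA_integer_, coarse$dim[1], coarse$dim[2])
  bin_id[land_idx] <- bin

  occ <- sort(unique(bin))
  e_of <- (occ - 1L) %/% grid$d_w + 1L
  w_of <- (occ - 1L) %% grid$d_w + 1L
  bins <- data.frame(
    bin_id = occ,
    label = sprintf("e%02d_w%02d", e_of, w_of),
    e_idx = e_of, w_idx = w_of,
    energy_lo = grid$energy_edges[e_of], energy_hi = grid$energy_edges[e_of + 1L],
    water_lo = grid$water_edges[w_of], water_hi = grid$water_edges[w_of + 1L],
    n_cells = as.integer(table(factor(bin, levels = occ))),
    stringsAsFactors = FALSE
  )
  structure(list(bin_id = bin_id, bins = bins, grid = grid,
                 n_clamped = n_clamped),
            class = "bin_assignment")
}

#' Species niche profiles: occurrence proportions over climate bins
#'
#' The link weights of the bipartite species-bin network: `w[i, j]` is the
#' proportion of species `j`'s occupied coarse cells whose climate falls in
#' bin `i`. Every species row sums to one (an "occurrence" is one occupied
#' coarse cell). Bins no species occupies are dropped.
#'
#' @param presence A filtered `presence_matrix`.
#' @param assignment A `bin_assignment`.
#' @return A `niche_profiles` list: `w` (sparse bins x species
#'   `dgCMatrix` with bin labels and species ids as dimnames),
#'   `bins` (metadata for the retained bins), `species`.
#' @export
niche_profiles <- function(presence, assignment) {
  stopifnot(inherits(presence, "presence_matrix"),
            inherits(assignment, "bin_assignment"))
  if (any(lengths(presence$cells) == 0L)) {
    stop_config("species with zero cells must be filtered upstream")
  }
  sp_names <- names(presence$cells)
  cells <- unlist(presence$cells, use.names = FALSE)
  sp_rep <- rep(seq_along(sp_names), lengths(presence$cells))
  bin_of_cell <- assignment$bin_id[cells]
  if (anyNA(bin_of_cell)) {
    stop_config("presence includes cells with no climate (sea cells)")
  }
  bin_levels <- sort(unique(bin_of_cell))
  counts <- Matrix::sparseMatrix(
    i = match(bin_of_cell, bin_levels), j = sp_rep, x = 1,
    dims = c(length(bin_levels), length(sp_names))
  )
  w <- counts %*% Matrix::Diagonal(x = 1 / Matrix::colSums(counts))
  w <- methods::as(w, "CsparseMatrix")
  bins <- assignment$bins[match(bin_levels, assignment$bins$bin_id), ]
  rownames(bins) <- NULL
  dimnames(w) <- list(bins$label, sp_names)
  structure(list(w = w, bins = bins, species = sp_names),
            class = "niche_profiles")
}

#' Select the number of climate-space divisions
#'
#' For each candidate division count `d`, the climate space is binned, the
#' bipartite network built and clustered, and the compression gain recorded:
#' the one-module map-equation code length minus the optimized code length,
#' in bits. The selected `d*` is the smallest candidate whose forward
#' marginal gain (gain at the next candidate minus gain at `d`) falls below
#' `tol` times the cumulative gain at `d` -- the smallest number of
#' divisions that has essentially exhausted the information gain. The full
#' curve is returned for inspection.
#'
#' @param presence Filtered `presence_matrix`.
#' @param coarse A `coarse_climate`.
#' @param d_candidates Increasing integer sequence (default `5:30`).
#' @param tol Relative tolerance on the marginal gain (default 0.02).
#' @param n_runs Restarts of the partition search per candidate.
#' @param seed Integer RNG seed for the searches.
#' @return A list: `d_star`, `curve` (data.frame d/code_length/one_level/
#'   gain), `partitions` (the fitted partition per candidate).
#' @export
select_divisions <- function(presence, coarse, d_candidates = 5:30,
                             tol = 0.02, n_runs = 20L, seed = 1L) {
  if (length(d_candidates) == 0L) stop_config("empty candidate list")
  if (is.unsorted(d_candidates, strictly = TRUE)) {
    stop_config("d_candidates must be strictly increasing")
  }
  gains <- numeric(length(d_candidates))
  L <- numeric(length(d_candidates))
  L0 <- numeric(length(d_candidates))
  parts <- vector("list", length(d_candidates))
  for (k in seq_along(d_candidates)) {
    grid <- bin_grid(coarse, d_candidates[k])
    assignment <- assign_bins(coarse, grid)
    net <- build_network(niche_profiles(presence, assignment))
    part <- detect_domains(net, n_runs = n_runs, seed = seed + k,
                           hierarchical = FALSE)
    L[k] <- part$codelength
    L0[k] <- one_level_codelength(net)
    gains[k] <- L0[k] - L[k]
    parts[[k]] <- part
  }
  curve <- data.frame(d = d_candidates, code_length = L, one_level = L0,
                      gain = gains)
  list(d_star = division_elbow(d_candidates, gains, tol), curve = curve,
       partitions = stats::setNames(parts, d_candidates))
}

#' Elbow rule on a compression-gain curve
#'
#' Given cumulative compression gains over increasing division counts,
#' returns the smallest `d` whose forward marginal gain falls below `tol`
#' times the cumulative gain at `d` (the largest candidate if none does;
#' a single candidate is returned unchanged).
#'
#' @param d_candidates Increasing integer division counts.
#' @param gains Compression gain (bits) at each candidate.
#' @param tol Relative marginal-gain tolerance.
#' @return The selected division count.
#' @export
division_elbow <- function(d_candidates, gains, tol = 0.02) {
  if (length(d_candidates) == 0L) stop_config("empty candidate list")
  stopifnot(length(gains) == length(d_candidates))
  if (length(d_candidates) > 1L) {
    for (k in seq_len(length(d_candidates) - 1L)) {
      if (gains[k + 1L] - gains[k] < tol * gains[k]) {
        return(d_candidates[k])
      }
    }
  }
  d_candidates[length(d_candidates)]
}
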