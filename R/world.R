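#' Configure a synthetic climate world
#'
#' A synthetic world stands in for the global climate rasters and range-map
#' derived occupancy grids used in empirical climate regionalizations: two
#' spatially autocorrelated climate fields (an energy surrogate such as
#' potential evapotranspiration and a water surrogate such as annual
#' precipitation) on a fine grid, a land mask, and a coarse analysis grid
#' obtained by integer block aggregation.
#'
#' @param fine_shape Integer vector `c(rows, cols)` of the fine grid.
#' @param aggregation_factor Integer >= 2; fine pixels per coarse-cell side.
#'   `fine_shape` must be divisible by it in both dimensions.
#' @param land_fraction Fraction of fine pixels that are land, in (0, 1].
#' @param energy_range,water_range Numeric `c(min, max)` value ranges of the
#'   two climate axes, in the units of the axes (e.g. mm/yr for both PET and
#'   AP). Must be non-degenerate.
#' @param autocorr_scale Gaussian smoothing length of the random fields, in
#'   fine pixels.
#' @param gradient_weight Relative weight in (0, 1) of the linear
#'   north--south gradient added to the energy axis.
#' @param seed Integer RNG seed; the world is a pure function of the config.
#'
#' @return A `world_config` list.
#' @seealso [generate_climate_world()]
#' @export
world_config <- function(fine_shape = c(120L, 120L),
                         aggregation_factor = 6L,
                         land_fraction = 0.7,
                         energy_range = c(0, 2000),
                         water_range = c(0, 3000),
                         autocorr_scale = 8,
                         gradient_weight = 0.5,
                         seed = 1L) {
  fine_shape <- as.integer(fine_shape)
  aggregation_factor <- as.integer(aggregation_factor)
  if (length(fine_shape) != 2L || any(fine_shape <= 0L)) {
    stop_config("fine_shape must be two positive integers")
  }
  if (aggregation_factor < 2L) {
    stop_config("aggregation_factor must be an integer >= 2")
  }
  if (any(fine_shape %% aggregation_factor != 0L)) {
    stop_config("fine_shape must be divisible by aggregation_factor in both dimensions")
  }
  if (!(land_fraction > 0 && land_fraction <= 1)) {
    stop_config("land_fraction must be in (0, 1]")
  }
  for (rg in list(energy_range, water_range)) {
    if (length(rg) != 2L || !(rg[2] > rg[1])) {
      stop_config("climate ranges must be c(min, max) with max > min")
    }
  }
  if (!(gradient_weight >= 0 && gradient_weight < 1)) {
    stop_config("gradient_weight must be in [0, 1)")
  }
  structure(list(
    fine_shape = fine_shape,
    aggregation_factor = aggregation_factor,
    land_fraction = land_fraction,
    energy_range = as.numeric(energy_range),
    water_range = as.numeric(water_range),
    autocorr_scale = autocorr_scale,
    gradient_weight = gradient_weight,
    seed = as.integer(seed)
  ), class = "world_config")
}

# Separable Gaussian blur with edge renormalization (kernel rows re-sum to 1
# near the borders, so the blur is mean-preserving for constant fields).
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  smoother <- function(n) {
    h <- ceiling(3 * sigma)
    idx <- seq_len(n)
    d <- outer(idx, idx, "-")
    k <- exp(-0.5 * (d / sigma)^2)
    k[abs(d) > h] <- 0
    k / rowSums(k)
  }
  sr <- smoother(nrow(x))
  sc <- smoother(ncol(x))
  sr %*% x %*% t(sc)
}

rescale_to <- function(x, range) {
  rg <- range(x)
  if (rg[2] - rg[1] < .Machine$double.eps) {
    return(matrix(mean(range), nrow(x), ncol(x)))
  }
  range[1] + (x - rg[1]) / (rg[2] - rg[1]) * (range[2] - range[1])
}

#' Generate a synthetic climate world
#'
#' Builds the climate part of a synthetic world: two fine-resolution,
#' spatially autocorrelated climate rasters (energy and water) and a land
#' mask. Each field is white noise convolved with a Gaussian of
#' `autocorr_scale`, affinely rescaled to its configured range; the energy
#' field additionally carries a linear north--south gradient (mixed in with
#' `gradient_weight`) mimicking the latitudinal energy gradient. The land
#' mask thresholds a third, more smoothed field at the `land_fraction`
#' quantile, which yields one or more contiguous land blocks.
#'
#' @param config A [world_config()].
#' @return A `climate_world` list with `energy_fine`, `water_fine` (matrices,
#'   `NA` over sea), `land_mask` (logical matrix), `coarse_dim`, and the
#'   `config`. Deterministic given `config$seed`.
#' @export
generate_climate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  nr <- config$fine_shape[1]
  nc <- config$fine_shape[2]
  f <- config$aggregation_factor

  with_seed(config$seed, {
    noise_e <- matrix(stats::rnorm(nr * nc), nr, nc)
    noise_w <- matrix(stats::rnorm(nr * nc), nr, nc)
    noise_m <- matrix(stats::rnorm(nr * nc), nr, nc)
  })

  field_e <- gaussian_smooth(noise_e, config$autocorr_scale)
  field_w <- gaussian_smooth(noise_w, config$autocorr_scale)
  # larger blobs for the mask so land forms contiguous blocks
  field_m <- gaussian_smooth(noise_m, 2 * config$autocorr_scale)

  std <- function(x) (x - mean(x)) / stats::sd(x)
  gradient <- matrix(rep(seq(-1, 1, length.out = nr), nc), nr, nc)
  gw <- config$gradient_weight
  energy_raw <- gw * gradient + (1 - gw) * std(field_e)

  energy <- rescale_to(energy_raw, config$energy_range)
  water <- rescale_to(std(field_w), config$water_range)

  if (config$land_fraction >= 1) {
    land <- matrix(TRUE, nr, nc)
  } else {
    thr <- stats::quantile(field_m, 1 - config$land_fraction, names = FALSE)
    land <- field_m >= thr
  }
  energy[!land] <- NA_real_
  water[!land] <- NA_real_

  coarse_dim <- config$fine_shape %/% f
  n_land_coarse <- sum(block_counts(land, f) > 0L)
  if (n_land_coarse == 0L) {
    stop_config("land_fraction yields zero coarse land cells")
  }

  structure(list(
    energy_fine = energy,
    water_fine = water,
    land_mask = land,
    coarse_dim = coarse_dim,
    config = config
  ), class = "climate_world")
}

#' Specify a planted climate archetype
#'
#' An archetype is a point in climate space around which a pool of synthetic
#' species concentrates: species occupy coarse cells with probability
#' proportional to a Gaussian kernel centred on (a jittered copy of) the
#' archetype centre. `breadth` is the kernel standard deviation per axis and
#' controls niche overlap between archetypes; `occupancy_rho` is the fraction
#' of climatically suitable cells each species actually occupies.
#'
#' @param center Numeric `c(energy, water)` in climate units.
#' @param breadth Kernel standard deviation per axis, `c(energy, water)`
#'   (a scalar is recycled). Must be positive.
#' @param n_species Number of species in the pool.
#' @param occupancy_rho Fraction in (0, 1] of suitable cells occupied.
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(center, breadth, n_species, occupancy_rho = 0.6) {
  breadth <- rep_len(as.numeric(breadth), 2L)
  if (any(breadth <= 0)) stop_config("breadth must be > 0")
  if (n_species < 1L) stop_config("n_species must be >= 1")
  if (!(occupancy_rho > 0 && occupancy_rho <= 1)) {
    stop_config("occupancy_rho must be in (0, 1]")
  }
  structure(list(
    center = as.numeric(center),
    breadth = breadth,
    n_species = as.integer(n_species),
    occupancy_rho = occupancy_rho
  ), class = "archetype_spec")
}

#' Generate a synthetic species pool with planted niche domains
#'
#' Samples, for every species of every archetype, a set of occupied coarse
#' land cells: cells are drawn without replacement with probability
#' proportional to a Gaussian kernel of the species' niche centre evaluated
#' at the cell's (energy, water). Each species' centre is jittered around its
#' archetype centre (s.d. = breadth / 2 per axis) so conspecifics of a pool
#' differ. The number of cells drawn is `occupancy_rho` times the number of
#' suitable cells (Mahalanobis distance <= 3 from the centre), floored at
#' `min_range_cells`. Species that cannot reach `min_range_cells` suitable
#' cells are dropped with a warning.
#'
#' @param world A `climate_world`.
#' @param archetypes List of [archetype_spec()] objects.
#' @param min_range_cells Minimum occupied coarse cells per emitted species.
#' @param seed Integer RNG seed.
#' @return A list with `presence` (a `presence_matrix`) and `planted_labels`
#'   (named integer vector, species -> archetype index).
#' @export
generate_species_pool <- function(world, archetypes, min_range_cells = 5L,
                                  seed = 1L) {
  stopifnot(inherits(world, "climate_world"))
  if (length(archetypes) < 1L) stop_config("need at least one archetype")
  coarse <- aggregate_world(world)
  land_cells <- which(coarse$land)           # linear indices, column-major
  e_vals <- coarse$energy[land_cells]
  w_vals <- coarse$water[land_cells]

  species_cells <- list()
  labels <- integer(0)
  n_dropped <- 0L

  with_seed(seed, {
    for (a in seq_along(archetypes)) {
      arch <- archetypes[[a]]
      z2_arch <- ((e_vals - arch$center[1]) / arch$breadth[1])^2 +
        ((w_vals - arch$center[2]) / arch$breadth[2])^2
      if (!any(z2_arch <= 9)) {
        stop_config("archetype ", a, " has zero climatically suitable cells")
      }
      for (s in seq_len(arch$n_species)) {
        center <- arch$center + stats::rnorm(2L, 0, arch$breadth / 2)
        z2 <- ((e_vals - center[1]) / arch$breadth[1])^2 +
          ((w_vals - center[2]) / arch$breadth[2])^2
        suitable <- z2 <= 9
        if (sum(suitable) < min_range_cells) {
          n_dropped <- n_dropped + 1L
          next
        }
        n_target <- max(min_range_cells,
                        as.integer(round(arch$occupancy_rho * sum(suitable))))
        n_target <- min(n_target, sum(suitable))
        kernel <- exp(-0.5 * z2[suitable])
        picked <- sample(which(suitable), n_target, prob = kernel)
        sp_id <- sprintf("sp%04d", length(species_cells) + 1L)
        species_cells[[sp_id]] <- sort(land_cells[picked])
        labels[sp_id] <- a
      }
    }
  })
  if (n_dropped > 0L) {
    warning(n_dropped, " species dropped: fewer than ", min_range_cells,
            " suitable cells", call. = FALSE)
  }
  if (length(species_cells) == 0L) stop_config("no species generated")
  presence <- presence_matrix(species_cells, world$coarse_dim)
  list(presence = presence, planted_labels = labels)
}

#' Restrict species to contiguous geographic patches
#'
#' Emulates a geographical signal: a species is retained only within one
#' contiguous patch of the coarse grid containing approximately
#' `rho` times its occupied cells, so that species of the same niche domain
#' co-occur in only part of the domain's geographic footprint. The patch is
#' grown by breadth-first search (rook adjacency) over land cells from a
#' randomly chosen occupied seed cell until the target count of occupied
#' cells is reached. `rho = 1` is the identity.
#'
#' @param presence A `presence_matrix`.
#' @param rho Retention fraction(s) in (0, 1]; a scalar or a vector named by
#'   species.
#' @param land Logical coarse land matrix (patches may cross unoccupied land).
#' @param min_range_cells Species falling below this after restriction are
#'   dropped with a warning.
#' @param seed Integer RNG seed.
#' @return A restricted `presence_matrix`.
#' @export
apply_geographic_restriction <- function(presence, rho, land,
                                         min_range_cells = 5L, seed = 1L) {
  stopifnot(inherits(presence, "presence_matrix"))
  sp <- names(presence$cells)
  rho_vec <- if (length(rho) == 1L) stats::setNames(rep(rho, length(sp)), sp) else rho
  if (!all(sp %in% names(rho_vec))) stop_config("rho must cover every species")
  if (any(rho_vec <= 0 | rho_vec > 1)) stop_config("rho values must be in (0, 1]")

  nr <- nrow(land)
  nc <- ncol(land)
  out <- presence$cells
  dropped <- character(0)

  with_seed(seed, {
    for (s in sp) {
      r <- rho_vec[[s]]
      if (r >= 1) next
      cells <- presence$cells[[s]]
      target <- max(min_range_cells, as.integer(round(r * length(cells))))
      if (target >= length(cells)) next
      occupied <- logical(nr * nc)
      occupied[cells] <- TRUE
      seed_cell <- cells[sample.int(length(cells), 1L)]
      # BFS over land; collect occupied cells in visit order
      visited <- logical(nr * nc)
      queue <- seed_cell
      visited[seed_cell] <- TRUE
      kept <- integer(0)
      while (length(queue) > 0L && length(kept) < target) {
        cur <- queue[1L]
        queue <- queue[-1L]
        if (occupied[cur]) kept <- c(kept, cur)
        rr <- cell_row(cur, nr)
        cc <- cell_col(cur, nr)
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          r2 <- rr + d[1L]
          c2 <- cc + d[2L]
          if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
            nxt <- cell_index(r2, c2, nr)
            if (!visited[nxt] && land[nxt]) {
              visited[nxt] <- TRUE
              queue <- c(queue, nxt)
            }
          }
        }
      }
      if (length(kept) < min_range_cells) {
        dropped <- c(dropped, s)
      } else {
        out[[s]] <- sort(kept)
      }
    }
  })
  if (length(dropped) > 0L) {
    warning(length(dropped), " species dropped by geographic restriction: ",
            "patch below ", min_range_cells, " cells", call. = FALSE)
    out <- out[setdiff(sp, dropped)]
  }
  presence_matrix(out, presence$coarse_dim)
}
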