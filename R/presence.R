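#' Species presence on the coarse grid
#'
#' Sparse species-by-cell occupancy: a named list of sorted coarse-cell
#' linear indices (column-major) per species, plus the coarse grid shape.
#' Range maps carry no abundance, so a cell is simply occupied or not.
#'
#' @param cells Named list, species id -> integer vector of occupied coarse
#'   cell indices (column-major linear indices, deduplicated).
#' @param coarse_dim Integer `c(rows, cols)` of the coarse grid.
#' @return A `presence_matrix` object.
#' @export
presence_matrix <- function(cells, coarse_dim) {
  if (is.null(names(cells)) || anyDuplicated(names(cells))) {
    stop_config("cells must be a uniquely named list (one entry per species)")
  }
  cells <- lapply(cells, function(x) sort(unique(as.integer(x))))
  structure(list(
    cells = cells,
    coarse_dim = as.integer(coarse_dim)
  ), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  n_cells <- lengths(x$cells)
  cat("presence_matrix:", length(x$cells), "species on a",
      x$coarse_dim[1], "x", x$coarse_dim[2], "coarse grid\n")
  if (length(n_cells)) {
    cat("  occupied cells per species: median", stats::median(n_cells),
        "range [", min(n_cells), ",", max(n_cells), "]\n")
  }
  invisible(x)
}

#' Number of species in a presence matrix
#' @param presence A `presence_matrix`.
#' @return Integer count.
#' @export
n_species <- function(presence) length(presence$cells)

#' Remove species with small ranges
#'
#' Species occupying fewer than `min_cells` coarse cells are removed; the
#' realized niche of very narrow-ranging species is too uncertain to place
#' in climate space. The default mirrors the usual five-cell cut at half
#' degree resolution.
#'
#' @param presence A `presence_matrix`.
#' @param min_cells Minimum occupied coarse cells to keep a species.
#' @return The filtered `presence_matrix`; attribute `"removed"` holds a
#'   data.frame of removed species and their cell counts.
#' @export
filter_small_ranges <- function(presence, min_cells = 5L) {
  stopifnot(inherits(presence, "presence_matrix"))
  n <- lengths(presence$cells)
  keep <- n >= min_cells
  if (!any(keep)) stop_config("no species survive filter")
  out <- presence_matrix(presence$cells[keep], presence$coarse_dim)
  attr(out, "removed") <- data.frame(
    species = names(presence$cells)[!keep],
    n_cells = unname(n[!keep]),
    stringsAsFactors = FALSE
  )
  out
}

# data.frame view (species_id, cell, row, col) used by the CSV writers.
presence_to_df <- function(presence) {
  nr <- presence$coarse_dim[1]
  sp <- rep(names(presence$cells), lengths(presence$cells))
  cell <- unlist(presence$cells, use.names = FALSE)
  data.frame(species_id = sp,
             cell_row = cell_row(cell, nr),
             cell_col = cell_col(cell, nr),
             stringsAsFactors = FALSE)
}

presence_from_df <- function(df, coarse_dim) {
  nr <- coarse_dim[1]
  idx <- cell_index(as.integer(df$cell_row), as.integer(df$cell_col), nr)
  presence_matrix(split(idx, df$species_id), coarse_dim)
}
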