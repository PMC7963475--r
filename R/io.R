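# Plain-text artifact I/O. Rasters use the ESRI ASCII grid format (.asc), a
# standard plain-text raster interchange format readable by GDAL-based GIS
# tools; tabular artifacts are CSV; partitions are also exported as JSON.

#' Write a raster matrix as an ESRI ASCII grid
#'
#' @param x Numeric or integer matrix; `NA` written as the nodata value.
#' @param path Output path (conventionally `.asc`).
#' @param cellsize Cell size recorded in the header (grid units).
#' @param nodata Nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, cellsize = 1, nodata = -9999) {
  hdr <- c(
    sprintf("ncols %d", ncol(x)),
    sprintf("nrows %d", nrow(x)),
    "xllcorner 0", "yllcorner 0",
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  x[is.na(x)] <- nodata
  rows <- apply(x, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid into a matrix
#'
#' @param path Path to an `.asc` file written by [write_ascii_grid()] or a
#'   GIS tool.
#' @return Numeric matrix with nodata as `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  x <- do.call(rbind, vals)
  stopifnot(nrow(x) == hdr$nrows, ncol(x) == hdr$ncols)
  if (!is.null(hdr$nodata_value)) x[x == hdr$nodata_value] <- NA_real_
  x
}

#' Write presence as a sparse CSV (species_id, cell_row, cell_col)
#' @param presence A `presence_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_presence_csv <- function(presence, path) {
  utils::write.csv(presence_to_df(presence), path, row.names = FALSE)
  invisible(path)
}

#' Read presence from a sparse CSV
#' @param path CSV with columns species_id, cell_row, cell_col.
#' @param coarse_dim Integer `c(rows, cols)` of the coarse grid.
#' @return A `presence_matrix`.
#' @export
read_presence_csv <- function(path, coarse_dim) {
  presence_from_df(utils::read.csv(path, stringsAsFactors = FALSE),
                   coarse_dim)
}

#' Write niche profiles as a sparse CSV (bin_label, species_id, weight)
#' @param profiles A `niche_profiles`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  tw <- Matrix::summary(profiles$w)
  df <- data.frame(bin_label = rownames(profiles$w)[tw$i],
                   species_id = colnames(profiles$w)[tw$j],
                   weight = tw$x)
  utils::write.csv(df[df$weight > 0, ], path, row.names = FALSE)
  invisible(path)
}

#' Write bin edges as CSV (axis, k, edge)
#' @param grid A `bin_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(grid, path) {
  df <- rbind(
    data.frame(axis = "energy", k = seq_along(grid$energy_edges) - 1L,
               edge = grid$energy_edges),
    data.frame(axis = "water", k = seq_along(grid$water_edges) - 1L,
               edge = grid$water_edges)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a partition as flat CSV and nested JSON
#'
#' The CSV has one row per node (`node_id`, `kind`, `level1`, `level2`,
#' ...); the JSON maps node id to its module path.
#'
#' @param partition A `niche_partition`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_partition <- function(partition, csv_path = NULL, json_path = NULL) {
  parts <- strsplit(partition$path, ":", fixed = TRUE)
  depth <- max(lengths(parts))
  lv <- vapply(seq_len(depth), function(k) {
    vapply(parts, function(p) if (length(p) >= k) p[k] else "", "")
  }, character(length(parts)))
  lv <- matrix(lv, nrow = length(parts))
  colnames(lv) <- paste0("level", seq_len(depth))
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(node_id = partition$nodes, kind = partition$kind, lv,
                 stringsAsFactors = FALSE),
      csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(codelength = partition$codelength,
           n_levels = partition$n_levels,
           paths = as.list(stats::setNames(partition$path, partition$nodes))),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}

#' Per-domain summary table
#'
#' One row per finest domain: species and bin counts, geographic cell
#' count, mean projected specificity over its cells, and bootstrap support
#' when available. This is the table a downstream regression of support on
#' specificity would consume.
#'
#' @param partition A `niche_partition`.
#' @param regions A `region_map`.
#' @param s_p Projected-specificity raster.
#' @param support Optional `support_table`.
#' @return data.frame.
#' @export
domain_summary <- function(partition, regions, s_p, support = NULL) {
  md <- major_domains(partition, min_species = 50L)
  lab <- regions$labels
  md$n_cells <- vapply(md$domain, function(d) {
    sum(lab == d, na.rm = TRUE)
  }, 0L)
  md$mean_S_P <- vapply(md$domain, function(d) {
    sel <- !is.na(lab) & lab == d
    if (any(sel)) mean(s_p[sel]) else NA_real_
  }, 0)
  if (!is.null(support)) {
    md$bootstrap_support <- support$support[match(md$domain, support$domain)]
  }
  md
}
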