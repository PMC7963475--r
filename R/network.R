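#' Build the weighted bipartite species-bin network
#'
#' Climatic bins and species form the two disjoint node sets; each positive
#' niche-profile weight `w[i, j]` becomes one link. Because every species
#' row sums to one, the total link weight `W` equals the number of species.
#' Bins or species without any positive link are dropped (with a message
#' when any are).
#'
#' @param profiles A `niche_profiles`.
#' @return A `niche_network` list: `edges` (data.frame bin/species/weight),
#'   `bins` (bin metadata), `species`, `W`.
#' @export
build_network <- function(profiles) {
  stopifnot(inherits(profiles, "niche_profiles"))
  w <- methods::as(methods::as(profiles$w, "generalMatrix"), "CsparseMatrix")
  if (length(w@x) == 0L) stop_config("empty profiles: no links")
  tw <- Matrix::summary(w)
  edges <- data.frame(
    bin = rownames(w)[tw$i],
    species = colnames(w)[tw$j],
    weight = tw$x,
    stringsAsFactors = FALSE
  )
  edges <- edges[edges$weight > 0, ]
  keep_bins <- sort(unique(edges$bin))
  keep_sp <- sort(unique(edges$species))
  n_iso <- (nrow(w) - length(keep_bins)) + (ncol(w) - length(keep_sp))
  if (n_iso > 0L) message(n_iso, " isolated nodes dropped")
  edges <- edges[order(edges$bin, edges$species), ]
  rownames(edges) <- NULL
  bins <- profiles$bins[match(keep_bins, profiles$bins$label), ]
  rownames(bins) <- NULL
  structure(list(edges = edges, bins = bins, species = keep_sp,
                 W = sum(edges$weight)),
            class = "niche_network")
}

#' Build a bipartite network directly from an edge list
#'
#' Convenience constructor for small hand-specified networks: one row per
#' link (`bin`, `species`, `weight`). Bin and species namespaces must be
#' disjoint.
#'
#' @param edges data.frame with columns `bin`, `species`, `weight` (> 0).
#' @return A `niche_network`.
#' @export
niche_network_from_edges <- function(edges) {
  stopifnot(all(c("bin", "species", "weight") %in% names(edges)))
  if (any(edges$weight <= 0)) stop_config("all weights must be positive")
  if (length(intersect(edges$bin, edges$species)) > 0L) {
    stop_config("bin and species node names must be disjoint")
  }
  edges <- edges[order(edges$bin, edges$species), c("bin", "species", "weight")]
  rownames(edges) <- NULL
  bins <- data.frame(bin_id = seq_along(sort(unique(edges$bin))),
                     label = sort(unique(edges$bin)),
                     stringsAsFactors = FALSE)
  structure(list(edges = edges, bins = bins,
                 species = sort(unique(edges$species)),
                 W = sum(edges$weight)),
            class = "niche_network")
}

#' @export
print.niche_network <- function(x, ...) {
  cat("niche_network:", nrow(x$bins), "bins,", length(x$species),
      "species,", nrow(x$edges), "links, W =", format(x$W), "\n")
  invisible(x)
}

#' Write a bipartite network in Pajek format
#'
#' Two-mode Pajek: the vertex header declares the first-mode size
#' (`*Vertices N NB`), bin nodes are listed first (sorted by label), species
#' second (sorted by id), and `*Edges` carries the weighted links with 17
#' significant digits so round trips are bit-stable.
#'
#' @param network A `niche_network`.
#' @param path Output path (conventionally `.net`).
#' @return `path`, invisibly.
#' @export
write_pajek <- function(network, path) {
  stopifnot(inherits(network, "niche_network"))
  bins <- sort(network$bins$label)
  sp <- sort(network$species)
  ids <- stats::setNames(seq_len(length(bins) + length(sp)), c(bins, sp))
  lines <- c(
    sprintf("*Vertices %d %d", length(ids), length(bins)),
    sprintf('%d "%s"', ids, names(ids)),
    "*Edges",
    sprintf("%d %d %.17g", ids[network$edges$bin],
            ids[network$edges$species], network$edges$weight)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a bipartite network from Pajek format
#'
#' Parses the two-mode Pajek layout written by [write_pajek()], validating
#' rather than assuming bipartiteness: every edge must join a first-mode
#' (bin) vertex to a second-mode (species) vertex, every edge endpoint must
#' be a declared vertex, and weights must be positive. Errors cite the
#' offending line number.
#'
#' @param path Path to a `.net` file.
#' @param bins Optional bin metadata data.frame to reattach (matched on
#'   label); otherwise minimal metadata is reconstructed.
#' @return A `niche_network`.
#' @export
read_pajek <- function(path, bins = NULL) {
  lines <- readLines(path)
  parse_err <- function(i, msg) {
    stop_config("Pajek parse error at line ", i, ": ", msg)
  }
  hdr <- grep("^\\*Vertices", lines, ignore.case = TRUE)
  if (length(hdr) != 1L) stop_config("Pajek parse error: need one *Vertices header")
  hv <- strsplit(trimws(lines[hdr]), "\\s+")[[1]]
  if (length(hv) < 3L) parse_err(hdr, "two-mode header '*Vertices N NB' required")
  n_total <- as.integer(hv[2])
  n_bins <- as.integer(hv[3])
  edge_hdr <- grep("^\\*Edges", lines, ignore.case = TRUE)
  if (length(edge_hdr) != 1L) stop_config("Pajek parse error: need one *Edges header")

  vlines <- lines[(hdr + 1L):(edge_hdr - 1L)]
  vlines <- vlines[nzchar(trimws(vlines))]
  if (length(vlines) != n_total) {
    parse_err(hdr, sprintf("declared %d vertices, found %d", n_total, length(vlines)))
  }
  vm <- regmatches(vlines, regexec('^\\s*(\\d+)\\s+"([^"]*)"', vlines))
  bad <- which(lengths(vm) != 3L)
  if (length(bad)) parse_err(hdr + bad[1], "malformed vertex line")
  vid <- as.integer(vapply(vm, `[`, "", 2L))
  vlabel <- vapply(vm, `[`, "", 3L)
  if (!identical(vid, seq_len(n_total))) {
    parse_err(hdr + 1L, "vertex ids must be 1..N in order")
  }

  elines_idx <- which(seq_along(lines) > edge_hdr & nzchar(trimws(lines)))
  ef <- strsplit(trimws(lines[elines_idx]), "\\s+")
  bad <- which(lengths(ef) != 3L)
  if (length(bad)) parse_err(elines_idx[bad[1]], "edge line must be 'i j w'")
  from <- as.integer(vapply(ef, `[`, "", 1L))
  to <- as.integer(vapply(ef, `[`, "", 2L))
  wt <- as.numeric(vapply(ef, `[`, "", 3L))
  for (k in seq_along(from)) {
    i <- elines_idx[k]
    if (is.na(from[k]) || is.na(to[k]) || from[k] < 1L || from[k] > n_total ||
        to[k] < 1L || to[k] > n_total) {
      parse_err(i, "edge names an undeclared vertex")
    }
    if ((from[k] <= n_bins) == (to[k] <= n_bins)) {
      parse_err(i, "edge violates bipartiteness")
    }
    if (is.na(wt[k]) || wt[k] <= 0) parse_err(i, "edge weight must be positive")
  }
  swap <- from > n_bins
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp

  edges <- data.frame(bin = vlabel[from], species = vlabel[to], weight = wt,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$bin, edges$species), ]
  rownames(edges) <- NULL
  bin_labels <- vlabel[seq_len(n_bins)]
  if (is.null(bins)) {
    bins <- data.frame(bin_id = seq_len(n_bins), label = bin_labels,
                       stringsAsFactors = FALSE)
  } else {
    bins <- bins[match(bin_labels, bins$label), ]
    rownames(bins) <- NULL
  }
  structure(list(edges = edges, bins = bins,
                 species = vlabel[(n_bins + 1L):n_total],
                 W = sum(wt)),
            class = "niche_network")
}

# Internal dense-index graph view used by the map-equation code. Nodes are
# ordered bins first (sorted by label) then species (sorted by id).
as_graph <- function(network) {
  bins <- sort(network$bins$label)
  sp <- sort(network$species)
  ids <- c(bins, sp)
  from <- match(network$edges$bin, ids)
  to <- match(network$edges$species, ids)
  w <- network$edges$weight
  strength <- numeric(length(ids))
  for (k in seq_along(from)) {
    strength[from[k]] <- strength[from[k]] + w[k]
    strength[to[k]] <- strength[to[k]] + w[k]
  }
  list(n = length(ids), node_ids = ids,
       kind = rep(c("bin", "species"), c(length(bins), length(sp))),
       from = from, to = to, w = w,
       strength = strength, total = sum(w))
}
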