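# Projection of niche domains back to geography, and the specificity /
# geographical-signal statistics quantifying transition zones and the
# geographic mismatch between a domain's climate and its species.

#' Project niche domains to a geographic region map
#'
#' Every coarse land cell is labelled with the finest-level domain of its
#' climatic bin: the climate regions are the geographic footprints of the
#' niche domains. Bins absent from the partition (dropped as isolated when
#' the network was built) get the label 0, "unclassified".
#'
#' @param assignment A `bin_assignment`.
#' @param partition A `niche_partition` over the network built from the
#'   same assignment.
#' @return A `region_map` list: `labels` (integer coarse matrix, `NA` over
#'   sea, 0 for unclassified), `legend` (data.frame domain/n_bins/n_cells).
#' @export
region_map <- function(assignment, partition) {
  stopifnot(inherits(assignment, "bin_assignment"),
            inherits(partition, "niche_partition"))
  bin_domain <- stats::setNames(partition$module[partition$kind == "bin"],
                                partition$nodes[partition$kind == "bin"])
  lab_of_bin <- bin_domain[assignment$bins$label]
  lab_of_bin[is.na(lab_of_bin)] <- 0L
  labels <- assignment$bin_id
  land_idx <- which(!is.na(assignment$bin_id))
  labels[land_idx] <- lab_of_bin[match(assignment$bin_id[land_idx],
                                       assignment$bins$bin_id)]
  used <- sort(unique(labels[land_idx]))
  legend <- data.frame(
    domain = used,
    n_bins = vapply(used, function(d) sum(lab_of_bin == d), 0L),
    n_cells = vapply(used, function(d) sum(labels[land_idx] == d), 0L)
  )
  structure(list(labels = labels, legend = legend), class = "region_map")
}

#' Bin specificity to its niche domain
#'
#' The specificity of climatic bin `i` in domain `D` is the fraction of its
#' link weight going to species of its own domain:
#' `S_i = sum_{j in D} w[i, j] / sum_j w[i, j]`. It is 1 when the bin
#' connects only to species of its own domain; low values mark climatic
#' transition zones whose species pool mixes domains.
#'
#' @param network A `niche_network`.
#' @param partition A `niche_partition` covering all its nodes.
#' @return Named numeric vector, one value in (0, 1] per bin label.
#' @export
bin_specificity <- function(network, partition) {
  stopifnot(inherits(network, "niche_network"),
            inherits(partition, "niche_partition"))
  dom <- stats::setNames(partition$module, partition$nodes)
  miss <- setdiff(c(network$edges$bin, network$edges$species),
                  partition$nodes)
  if (length(miss)) stop_config("partition does not cover node(s): ",
                                paste(utils::head(miss, 3), collapse = ", "))
  e <- network$edges
  same <- dom[e$bin] == dom[e$species]
  tot <- rowsum(e$weight, e$bin)
  own <- rowsum(e$weight * same, e$bin)
  stats::setNames(as.numeric(own / tot), rownames(tot))
}

#' Project bin specificity to geography
#'
#' Every coarse cell with the climate of bin `i` receives bin `i`'s
#' specificity, with no smoothing or interpolation.
#'
#' @param assignment A `bin_assignment`.
#' @param specificity Named vector from [bin_specificity()].
#' @return Numeric coarse matrix `S_P` (`NA` where no specificity applies).
#' @export
project_specificity <- function(assignment, specificity) {
  stopifnot(inherits(assignment, "bin_assignment"))
  out <- matrix(NA_real_, nrow(assignment$bin_id), ncol(assignment$bin_id))
  land_idx <- which(!is.na(assignment$bin_id))
  lab <- assignment$bins$label[match(assignment$bin_id[land_idx],
                                     assignment$bins$bin_id)]
  out[land_idx] <- specificity[lab]
  out
}

#' Actual specificity from the locally present species pool
#'
#' For a cell `q` in bin `i` of domain `D`, the actual specificity is the
#' same ratio as the bin specificity but restricted to the species present
#' in `q`: `S_A(q) = sum_{j in D present in q} w[i, j] /
#' sum_{j present in q} w[i, j]`. Cells where no (network) species is
#' present are `NA` and counted as excluded.
#'
#' @param network A `niche_network`.
#' @param partition A `niche_partition`.
#' @param presence The `presence_matrix` the network was built from.
#' @param assignment The matching `bin_assignment`.
#' @return Numeric coarse matrix `S_A`; attribute `"n_excluded"` counts
#'   land cells with no species present.
#' @export
actual_specificity <- function(network, partition, presence, assignment) {
  stopifnot(inherits(presence, "presence_matrix"))
  dom <- stats::setNames(partition$module, partition$nodes)
  w_lookup <- Matrix::sparseMatrix(
    i = match(network$edges$bin, sort(unique(network$edges$bin))),
    j = match(network$edges$species, sort(unique(network$edges$species))),
    x = network$edges$weight,
    dimnames = list(sort(unique(network$edges$bin)),
                    sort(unique(network$edges$species)))
  )
  sp_in_net <- colnames(w_lookup)

  nr <- nrow(assignment$bin_id)
  inc_sp <- rep(names(presence$cells), lengths(presence$cells))
  inc_cell <- unlist(presence$cells, use.names = FALSE)
  keep <- inc_sp %in% sp_in_net
  inc_sp <- inc_sp[keep]
  inc_cell <- inc_cell[keep]

  bin_of_cell <- assignment$bin_id[inc_cell]
  bin_lab <- assignment$bins$label[match(bin_of_cell, assignment$bins$bin_id)]
  w_ij <- w_lookup[cbind(match(bin_lab, rownames(w_lookup)),
                         match(inc_sp, colnames(w_lookup)))]
  if (any(w_ij <= 0)) {
    stop_config("species present in a cell with zero weight in its bin: ",
                "presence and network are inconsistent")
  }
  same <- dom[bin_lab] == dom[inc_sp]
  den <- rowsum(w_ij, inc_cell)
  num <- rowsum(w_ij * same, inc_cell)

  out <- matrix(NA_real_, nrow(assignment$bin_id), ncol(assignment$bin_id))
  out[as.integer(rownames(den))] <- as.numeric(num / den)
  n_land <- sum(!is.na(assignment$bin_id))
  attr(out, "n_excluded") <- n_land - nrow(den)
  out
}

#' Geographical signal
#'
#' The mean absolute cell-wise difference between the actual and projected
#' specificity over the `N` cells where both are defined:
#' `G = (1/N) * sum_q |S_A(q) - S_P(q)|`. G is 0 when the species actually
#' present in every cell reproduce the bin-level weights (no geographical
#' signal) and tends to 1 when domains are defined by species occurring
#' elsewhere in the domain's climate.
#'
#' @param s_a,s_p Aligned `S_A` and `S_P` coarse matrices.
#' @return A `signal_report` list: `G`, `n_cells_used`, `n_cells_excluded`,
#'   and the two rasters.
#' @export
geographical_signal <- function(s_a, s_p) {
  stopifnot(all(dim(s_a) == dim(s_p)))
  used <- !is.na(s_a) & !is.na(s_p)
  if (!any(used)) stop_config("no usable cells: S_A and S_P never co-defined")
  G <- mean(abs(s_a[used] - s_p[used]))
  structure(list(
    G = G,
    n_cells_used = sum(used),
    n_cells_excluded = sum(!is.na(s_p) & is.na(s_a)),
    S_A = s_a, S_P = s_p
  ), class = "signal_report")
}

#' @export
print.signal_report <- function(x, ...) {
  cat("geographical signal G =", format(x$G, digits = 4), "over",
      x$n_cells_used, "cells (", x$n_cells_excluded, "excluded )\n")
  invisible(x)
}
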