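# Adjusted mutual information between two labelings (regionalizations),
# chance-corrected under the permutation (hypergeometric) model. Entropies
# and information are computed in nats; AMI is scale-free.

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Expected mutual information under the permutation model
#'
#' The expectation of the mutual information between two labelings with
#' fixed marginal counts, over all assignments of labels to items
#' (hypergeometric model). Computed exactly from the marginals.
#'
#' @param a_counts,b_counts Integer label counts of the two partitions
#'   (same total).
#' @return Expected MI in nats.
#' @export
expected_mutual_information <- function(a_counts, b_counts) {
  n <- sum(a_counts)
  if (sum(b_counts) != n) stop_config("marginals must share the same total")
  emi <- 0
  for (ai in a_counts) {
    for (bj in b_counts) {
      nij_min <- max(1L, ai + bj - n)
      nij_max <- min(ai, bj)
      if (nij_max < nij_min) next
      for (nij in nij_min:nij_max) {
        term <- (nij / n) * log(n * nij / (ai * bj))
        lp <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
        emi <- emi + term * exp(lp)
      }
    }
  }
  emi
}

#' Adjusted mutual information between two regionalizations
#'
#' Compares two labelings of the same cell set (for example two climate
#' region rasters, or detected vs planted species labels):
#' `AMI = (MI - E[MI]) / (mean(H_a, H_b) - E[MI])`, with the expected MI
#' under the permutation model. The index is 1 when the partitions are
#' equal (up to label renaming) and is close to 0 for independent ones.
#' `NA` cells are excluded pairwise. Degenerate single-label partitions:
#' AMI is 1 if both labelings are identical single-label partitions, else 0.
#'
#' @param labels_a,labels_b Vectors, matrices or factors of equal length.
#' @param normalization `"mean"` (default) or `"max"` of the two entropies.
#' @return AMI, a scalar.
#' @export
adjusted_mutual_information <- function(labels_a, labels_b,
                                        normalization = c("mean", "max")) {
  normalization <- match.arg(normalization)
  a <- as.vector(labels_a)
  b <- as.vector(labels_b)
  if (length(a) != length(b)) stop_config("labelings must have equal length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 2L) stop_config("need at least two shared cells")

  tab <- table(a, b)
  n <- sum(tab)
  a_counts <- rowSums(tab)
  b_counts <- colSums(tab)
  ha <- entropy_counts(a_counts)
  hb <- entropy_counts(b_counts)
  if (ha == 0 && hb == 0) return(1)   # both single-label: identical
  if (ha == 0 || hb == 0) return(0)

  nz <- tab[tab > 0]
  outer_ab <- outer(a_counts, b_counts)[tab > 0]
  mi <- sum((nz / n) * log(n * nz / outer_ab))
  emi <- expected_mutual_information(a_counts, b_counts)
  denom <- switch(normalization, mean = mean(c(ha, hb)), max = max(ha, hb))
  (mi - emi) / (denom - emi)
}
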