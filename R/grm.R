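#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum p (1 - p))` with `Z` the genotype matrix centered at
#' twice the reference allele frequencies. Frequencies are meant to be fixed
#' at their founder-generation values so that the base of the relationship
#' matrix does not drift across evaluation years. Loci whose reference
#' frequency is not strictly inside (0, 1) are dropped.
#'
#' @param M `n x m` dosage matrix (0/1/2), one row per genotyped animal.
#' @param p length-`m` reference allele frequencies.
#' @return an `n x n` symmetric matrix with attributes `freq` (frequencies
#'   used) and `scale` (the `2 sum p(1-p)` denominator).
#' @examples
#' compute_grm(matrix(c(2, 0), 2, 1), p = 0.5)
#' @export
compute_grm <- function(M, p) {
  M <- as.matrix(M)
  if (ncol(M) != length(p)) stop("one frequency per locus required")
  keep <- which(p > 0 & p < 1)
  if (!length(keep)) stop("no usable loci: all frequencies at the boundary")
  p <- p[keep]
  Z <- sweep(M[, keep, drop = FALSE], 2L, 2 * p)
  sc <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / sc
  attr(G, "freq") <- p
  attr(G, "scale") <- sc
  G
}

# Centered marker rows for incremental GRM building inside the breeding loop.
# Returns list(Z = centered matrix over usable loci, scale).
center_markers <- function(M, p) {
  keep <- which(p > 0 & p < 1)
  if (!length(keep)) stop("no usable marker loci")
  list(Z = sweep(M[, keep, drop = FALSE], 2L, 2 * p[keep]),
       scale = 2 * sum(p[keep] * (1 - p[keep])),
       keep = keep)
}
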