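#' Generate a synthetic founder population
#'
#' Creates founder haplotypes standing in for a genotyped base population of
#' a commercial strain. Per-locus allele frequencies are drawn uniformly from
#' `[maf_low, maf_high]` and haplotypes are sampled independently per locus
#' in a mixing pool of `n_mixing_pop` individuals; `n_mixing_generations`
#' rounds of random mating with recombination then let drift build up
#' within-chromosome linkage disequilibrium, after which the pool is expanded
#' to `n_founders` individuals by one further round of random mating.
#'
#' The defaults (pool of 50, 30 generations) emulate the long, narrow
#' bottleneck of a closed hatchery strain and yield the short-range LD levels
#' reported for dense SNP panels in farmed rainbow trout (mean r-squared
#' roughly 0.2 between loci under 1 cM apart, decaying towards baseline
#' beyond ~20 cM). Loci that drift to fixation are redrawn (independently at
#' their original frequency) so every locus segregates.
#'
#' @param n_founders number of founder individuals (>= 2).
#' @param map a [build_genetic_map()] object.
#' @param maf_low,maf_high bounds of the allele-1 frequency draw,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param n_mixing_generations rounds of random mating used to create LD
#'   (0 = none; founders are then drawn directly at the sampled frequencies).
#' @param seed optional integer seed.
#' @param n_mixing_pop size of the mixing pool the drift acts on.
#' @return an object of class `founder_pop`: list with `haps` (an
#'   `n_loci x 2 n_founders` 0/1 integer matrix; individual `i` owns columns
#'   `2i-1` and `2i`), `n`, `map` and `freq` (realized allele-1 frequencies).
#' @examples
#' map <- build_genetic_map(1, 100, 50, seed = 1)
#' fp <- generate_founder_population(20, map, seed = 1,
#'                                   n_mixing_generations = 2)
#' range(fp$freq)
#' @export
generate_founder_population <- function(n_founders, map, maf_low = 0.05,
                                        maf_high = 0.5,
                                        n_mixing_generations = 30,
                                        seed = NULL, n_mixing_pop = 50) {
  if (n_founders < 2) stop("need at least 2 founders")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5")
  if (!is.null(seed)) set.seed(seed)
  L <- map$n_loci
  Nm <- if (n_mixing_generations > 0) max(2L, as.integer(n_mixing_pop))
        else n_founders
  H <- 2L * Nm
  p <- runif(L, maf_low, maf_high)
  haps <- matrix((runif(L * H) < p) * 1L, nrow = L, ncol = H)
  haps <- resample_monomorphic(haps, p)
  random_generation <- function(haps, n_par, n_off) {
    sire <- sample.int(n_par, n_off, replace = TRUE)
    dam <- sample.int(n_par, n_off, replace = TRUE)
    clash <- which(dam == sire)
    while (length(clash)) {
      dam[clash] <- sample.int(n_par, length(clash), replace = TRUE)
      clash <- clash[dam[clash] == sire[clash]]
    }
    g1 <- drop_gametes(haps, 2L * sire - 1L, 2L * sire, map$pos,
                       map$chr_first, map$chr_last, map$chr_len)
    g2 <- drop_gametes(haps, 2L * dam - 1L, 2L * dam, map$pos,
                       map$chr_first, map$chr_last, map$chr_len)
    out <- matrix(0L, nrow = L, ncol = 2L * n_off)
    out[, seq(1L, 2L * n_off, by = 2L)] <- g1
    out[, seq(2L, 2L * n_off, by = 2L)] <- g2
    out
  }
  if (n_mixing_generations > 0) {
    for (g in seq_len(n_mixing_generations))
      haps <- random_generation(haps, Nm, Nm)
    haps <- random_generation(haps, Nm, n_founders)
  }
  haps <- resample_monomorphic(haps, p)
  structure(list(haps = haps, n = as.integer(n_founders), map = map,
                 freq = rowMeans(haps)),
            class = "founder_pop")
}

# Redraw loci fixed for either allele; drift-fixed loci are replaced by an
# independent draw at the original frequency (no LD for those rare loci).
resample_monomorphic <- function(haps, p) {
  H <- ncol(haps)
  repeat {
    s <- .rowSums(haps, nrow(haps), H)
    bad <- which(s == 0L | s == H)
    if (!length(bad)) return(haps)
    haps[bad, ] <- (matrix(runif(length(bad) * H), length(bad), H) <
                      p[bad]) * 1L
  }
}

#' @export
print.founder_pop <- function(x, ...) {
  cat("founder_pop:", x$n, "founders,", x$map$n_loci, "loci; allele-1 freq in [",
      sprintf("%.3f, %.3f", min(x$freq), max(x$freq)), "]\n")
  invisible(x)
}

#' Extract genotype dosages
#'
#' Sums haplotype pairs into 0/1/2 allele counts.
#'
#' @param haps `n_loci x 2k` haplotype matrix (consecutive column pairs are
#'   individuals).
#' @return an `n_loci x k` integer dosage matrix.
#' @export
dosage_from_haps <- function(haps) {
  k <- ncol(haps) / 2L
  haps[, seq(1L, 2L * k, by = 2L), drop = FALSE] +
    haps[, seq(2L, 2L * k, by = 2L), drop = FALSE]
}
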