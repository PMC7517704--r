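#' Simulate one meiosis
#'
#' Draws a single recombinant gamete from a parent's haplotype pair under the
#' Haldane model: the crossover count per chromosome is Poisson with mean
#' chromosome length / 100 (no interference), crossover positions are uniform,
#' and the starting haplotype of each chromosome is chosen with probability
#' 1/2.
#'
#' @param parent an `n_loci x 2` 0/1 haplotype matrix.
#' @param map the [build_genetic_map()] the haplotypes live on.
#' @return an integer vector of length `n_loci` (the gamete).
#' @examples
#' map <- build_genetic_map(1, 100, 10, seed = 1)
#' parent <- cbind(rep(0L, 10), rep(1L, 10))
#' g <- meiosis(parent, map)
#' @export
meiosis <- function(parent, map) {
  parent <- as.matrix(parent)
  if (nrow(parent) != map$n_loci || ncol(parent) != 2L)
    stop("parent must be an n_loci x 2 haplotype matrix over the map")
  storage.mode(parent) <- "integer"
  drop_gametes(parent, 1L, 2L, map$pos, map$chr_first, map$chr_last,
               map$chr_len)[, 1L]
}

#' Create one offspring from two parents
#'
#' One meiosis from each parent, pedigree links recorded, and true breeding
#' values computed when a trait architecture is supplied. Selfing (identical
#' sire and dam ids) is rejected: the mating design never selfs.
#'
#' @param sire,dam lists with elements `id` and `haps` (`n_loci x 2` matrix).
#' @param map the shared [build_genetic_map()].
#' @param sex `"M"` or `"F"`.
#' @param birth_year integer birth year.
#' @param arch optional [assign_trait_architecture()] object; when given, the
#'   offspring's `tbv_B`/`tbv_C` are filled in.
#' @return a list with `haps`, `sire_id`, `dam_id`, `sex`, `birth_year` and
#'   (optionally) `tbv_B`, `tbv_C`.
#' @export
make_offspring <- function(sire, dam, map, sex = "M", birth_year = 1L,
                           arch = NULL) {
  if (identical(sire$id, dam$id)) stop("selfing is not part of the design")
  haps <- cbind(meiosis(sire$haps, map), meiosis(dam$haps, map))
  out <- list(haps = haps, sire_id = sire$id, dam_id = dam$id, sex = sex,
              birth_year = as.integer(birth_year))
  if (!is.null(arch)) {
    tbv <- true_breeding_values(haps, arch)
    out$tbv_B <- tbv[["tbv_B"]]
    out$tbv_C <- tbv[["tbv_C"]]
  }
  out
}
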