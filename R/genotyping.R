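#' Phenotype-based selection for genotyping
#'
#' Implements the five genotyping strategies under a fixed budget. Screening
#' never ranks the whole population: fish are randomly partitioned into
#' disjoint groups of `group_size` (each fish has one chance of being
#' screened; fish left over after forming the required groups are not
#' screened), and the best/worst fish of each group are taken by phenotype:
#'
#' * `Random`: a uniform sample of `budget` fish, no groups.
#' * `Top1_1`: `budget` groups; the best fish of each group.
#' * `T1_1B1_1`: `budget / 2` groups; the best and the worst of each group.
#' * `T1_2B1_2`: `budget` groups; best and worst of each group, then the
#'   better fish of each disjoint random pair of tops and the worse fish of
#'   each disjoint random pair of bottoms (half tops, half bottoms).
#' * `T3_4B1_4`: `budget` groups; tops and bottoms as above, then the best 3
#'   of each random four tops and the worst 1 of each random four bottoms
#'   (3/4 tops, 1/4 bottoms).
#'
#' Ties in phenotype are broken towards the lowest id for determinism.
#'
#' @param phenotype numeric vector, the phenotype of each candidate measured
#'   in its own environment.
#' @param strategy one of `"Random"`, `"Top1_1"`, `"T1_1B1_1"`,
#'   `"T1_2B1_2"`, `"T3_4B1_4"`.
#' @param budget number of fish to genotype.
#' @param group_size screening group size (default 20).
#' @param ids optional ids used for tie-breaking (defaults to position).
#' @return sorted integer vector of positions selected for genotyping.
#' @examples
#' set.seed(1)
#' sel <- select_for_genotyping(rnorm(400), "Top1_1", budget = 20)
#' length(sel)
#' @export
select_for_genotyping <- function(phenotype, strategy, budget,
                                  group_size = 20L,
                                  ids = seq_along(phenotype)) {
  n <- length(phenotype)
  strategy <- match.arg(strategy,
                        c("Random", "Top1_1", "T1_1B1_1", "T1_2B1_2",
                          "T3_4B1_4"))
  if (budget < 1 || budget > n) stop("budget must be in [1, n]")
  if (strategy == "Random") return(sort(sample.int(n, budget)))
  n_groups <- switch(strategy,
                     Top1_1 = budget,
                     T1_1B1_1 = {
                       if (budget %% 2L) stop("T1_1B1_1 needs an even budget")
                       budget %/% 2L
                     },
                     T1_2B1_2 = {
                       if (budget %% 2L) stop("T1_2B1_2 needs an even budget")
                       budget
                     },
                     T3_4B1_4 = {
                       if (budget %% 4L) stop("T3_4B1_4 needs a budget divisible by 4")
                       budget
                     })
  if (n_groups * group_size > n)
    stop(sprintf("insufficient fish: %d groups of %d needed, %d available",
                 n_groups, group_size, n))
  perm <- sample.int(n, n_groups * group_size)
  gm <- matrix(perm, nrow = group_size)
  # order group members by id so that which.max/min resolve ties to lowest id
  gm <- apply(gm, 2L, function(g) g[order(ids[g])])
  ph <- matrix(phenotype[gm], nrow = group_size)
  tops <- gm[cbind(apply(ph, 2L, which.max), seq_len(n_groups))]
  if (strategy == "Top1_1") return(sort(tops))
  bots <- gm[cbind(apply(ph, 2L, which.min), seq_len(n_groups))]
  if (strategy == "T1_1B1_1") return(sort(c(tops, bots)))
  pick_of <- function(pool, k, take_best, n_take) {
    pm <- matrix(sample(pool), nrow = k)
    pp <- matrix(phenotype[pm], nrow = k)
    unlist(lapply(seq_len(ncol(pm)), function(j) {
      o <- if (take_best) order(-pp[, j], pm[, j])  # ties to lowest id
           else order(pp[, j], pm[, j])
      pm[o[seq_len(n_take)], j]
    }))
  }
  if (strategy == "T1_2B1_2")
    return(sort(c(pick_of(tops, 2L, TRUE, 1L), pick_of(bots, 2L, FALSE, 1L))))
  sort(c(pick_of(tops, 4L, TRUE, 3L), pick_of(bots, 4L, FALSE, 1L)))
}
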