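make_het_parent <- function(L) cbind(rep(0L, L), rep(1L, L))

test_that("a homozygous parent transmits its haplotype unchanged", {
  map <- build_genetic_map(2, 180, 100, seed = 2)
  parent <- cbind(rep(1L, 100), rep(1L, 100))
  set.seed(5)
  g <- meiosis(parent, map)
  expect_identical(g, rep(1L, 100))
})

test_that("crossover count matches the Haldane expectation of length/100", {
  # fully heterozygous parent: strand switches along the gamete reveal the
  # crossovers falling between adjacent loci
  L <- 200L
  map <- build_genetic_map(1, 100, L, seed = 3)
  parent <- make_het_parent(L)
  set.seed(6)
  n <- 10000L
  switches <- vapply(seq_len(n), function(i) {
    g <- meiosis(parent, map)
    sum(diff(g) != 0L)
  }, 0L)
  se <- sd(switches) / sqrt(n)
  expect_lt(abs(mean(switches) - 1.0), 3 * se + 0.01)
})

test_that("heterozygous loci are transmitted half-half (chi-square, a = 0.01)", {
  L <- 20L
  map <- build_genetic_map(1, 50, L, seed = 4)
  parent <- make_het_parent(L)
  set.seed(7)
  n <- 10000L
  first_allele <- vapply(seq_len(n), function(i) meiosis(parent, map)[1L], 0L)
  k <- sum(first_allele)
  chi2 <- (k - n / 2)^2 / (n / 4)
  expect_lt(chi2, qchisq(0.99, df = 1))
})

test_that("make_offspring records pedigree, computes TBV, rejects selfing", {
  map <- tiny_map(80, 2, 120)
  fp <- generate_founder_population(30, map, seed = 12,
                                    n_mixing_generations = 2)
  arch <- assign_trait_architecture(map, fp, 20, 0.5, 0.3, seed = 13)
  sire <- list(id = 1L, haps = fp$haps[, 1:2])
  dam <- list(id = 2L, haps = fp$haps[, 3:4])
  set.seed(14)
  off <- make_offspring(sire, dam, map, sex = "F", birth_year = 5, arch = arch)
  expect_equal(off$sire_id, 1L)
  expect_equal(off$dam_id, 2L)
  expect_equal(off$birth_year, 5L)
  expect_equal(unname(true_breeding_values(off$haps, arch)),
               unname(c(off$tbv_B, off$tbv_C)))
  expect_error(make_offspring(sire, sire, map), "selfing")
})

test_that("identical fully inbred parents breed offspring with their TBV", {
  map <- tiny_map(60, 1, 90)
  fp <- generate_founder_population(10, map, seed = 15,
                                    n_mixing_generations = 0)
  arch <- assign_trait_architecture(map, fp, 15, 0.2, 0.3, seed = 16)
  hom <- cbind(fp$haps[, 1], fp$haps[, 1])  # doubled haploid
  p1 <- list(id = 1L, haps = hom)
  p2 <- list(id = 2L, haps = hom)
  off <- make_offspring(p1, p2, map, arch = arch)
  expect_equal(unname(c(off$tbv_B, off$tbv_C)),
               unname(true_breeding_values(hom, arch)))
})

test_that("mean offspring TBV matches the parent average within MC error", {
  map <- tiny_map(120, 2, 150)
  fp <- generate_founder_population(40, map, seed = 17,
                                    n_mixing_generations = 3)
  arch <- assign_trait_architecture(map, fp, 30, 0.5, 0.3, seed = 18)
  sire <- list(id = 1L, haps = fp$haps[, 1:2])
  dam <- list(id = 2L, haps = fp$haps[, 3:4])
  mid <- (true_breeding_values(sire$haps, arch) +
            true_breeding_values(dam$haps, arch)) / 2
  set.seed(19)
  tb <- t(vapply(seq_len(400),
                 function(i) make_offspring(sire, dam, map,
                                            arch = arch)[c("tbv_B", "tbv_C")] |>
                   unlist(), numeric(2)))
  for (j in 1:2) {
    se <- sd(tb[, j]) / sqrt(nrow(tb))
    expect_lt(abs(mean(tb[, j]) - mid[j]), 4 * se)
  }
})
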