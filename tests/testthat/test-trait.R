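make_arch_fixture <- function(r_g = 0.5, h2 = 0.3, n_founders = 150,
                              n_loci = 200, n_qtl = 40, seed = 21) {
  map <- tiny_map(n_loci, 2, 180, seed = seed)
  fp <- generate_founder_population(n_founders, map, seed = seed + 1,
                                    n_mixing_generations = 3)
  list(map = map, fp = fp,
       arch = assign_trait_architecture(map, fp, n_qtl, r_g, h2,
                                        seed = seed + 2))
}

test_that("QTL and marker sets partition the loci", {
  fx <- make_arch_fixture()
  arch <- fx$arch
  expect_length(arch$qtl, 40)
  expect_length(arch$markers, 160)
  expect_length(intersect(arch$qtl, arch$markers), 0)
  expect_setequal(c(arch$qtl, arch$markers), seq_len(200))
  expect_error(assign_trait_architecture(fx$map, fx$fp, 200, 0.5, 0.3),
               "n_qtl")
  expect_error(assign_trait_architecture(fx$map, fx$fp, 10, 1.2, 0.3), "r_g")
  expect_error(assign_trait_architecture(fx$map, fx$fp, 10, 0.5, 0), "h2")
})

test_that("residual variance follows (1 - h2) / h2", {
  fx <- make_arch_fixture(h2 = 0.3)
  expect_equal(fx$arch$sigma_e2, 7 / 3)
  expect_equal(make_arch_fixture(h2 = 0.1, seed = 31)$arch$sigma_e2, 9)
})

test_that("founder genetic variance is 1 and TBV correlation equals r_g", {
  for (rg in c(0.2, 0.8)) {
    fx <- make_arch_fixture(r_g = rg, seed = 40 + round(10 * rg))
    tbv <- sibGenoSim:::tbv_batch(fx$fp$haps, fx$arch)
    expect_equal(var(tbv[, 1]), 1, tolerance = 1e-8)
    expect_equal(var(tbv[, 2]), 1, tolerance = 1e-8)
    expect_equal(cor(tbv[, 1], tbv[, 2]), rg, tolerance = 1e-8)
    expect_equal(mean(tbv[, 1]), 0, tolerance = 1e-10)
  }
})

test_that("TBV equals a per-locus brute-force loop exactly", {
  fx <- make_arch_fixture()
  arch <- fx$arch
  for (i in c(1L, 7L, 42L)) {
    haps <- fx$fp$haps[, (2 * i - 1):(2 * i)]
    brute <- c(0, 0)
    for (k in seq_along(arch$qtl)) {
      dose <- haps[arch$qtl[k], 1] + haps[arch$qtl[k], 2]
      brute <- brute + dose * arch$effects[k, ]
    }
    brute <- brute - arch$founder_mean
    expect_equal(unname(true_breeding_values(haps, arch)), unname(brute))
    expect_equal(unname(sibGenoSim:::tbv_batch(haps, arch)[1, ]),
                 unname(brute))
  }
})

test_that("an all-zero genotype scores minus the founder mean", {
  fx <- make_arch_fixture()
  zero <- matrix(0L, fx$map$n_loci, 2)
  expect_equal(unname(true_breeding_values(zero, fx$arch)),
               unname(-fx$arch$founder_mean))
})

test_that("phenotype equals TBV in the noise-free limit", {
  fx <- make_arch_fixture()
  arch <- fx$arch
  arch$sigma_e2 <- 0
  tbv <- sibGenoSim:::tbv_batch(fx$fp$haps, arch)
  ph <- simulate_phenotype(tbv[, 1], tbv[, 2], rep(c("B", "C"), 75), arch)
  expect_equal(ph, ifelse(rep(c(TRUE, FALSE), 75), tbv[, 1], tbv[, 2]))
  expect_error(simulate_phenotype(1, 1, "none", arch), "placed")
})

test_that("phenotypic variance and regression on TBV match the h2 model", {
  fx <- make_arch_fixture(h2 = 0.3, n_founders = 600, seed = 60)
  arch <- fx$arch
  tbv <- sibGenoSim:::tbv_batch(fx$fp$haps, arch)
  set.seed(61)
  ph <- simulate_phenotype(tbv[, 1], tbv[, 2], rep("B", 600), arch)
  expect_equal(var(ph), 1 + 7 / 3, tolerance = 0.35)
  slope <- coef(lm(ph ~ tbv[, 1]))[2]
  expect_equal(unname(slope), 1, tolerance = 0.2)
})
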