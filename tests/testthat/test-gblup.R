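test_that("GRM matches the VanRaden single-locus cases", {
  expect_equal(compute_grm(matrix(2, 1, 1), 0.5)[1, 1], 2)
  expect_equal(compute_grm(matrix(1, 1, 1), 0.5)[1, 1], 0)
  expect_error(compute_grm(matrix(1, 1, 1), 1), "usable")
})

test_that("founder GRM diagonal centers near 1 under base frequencies", {
  map <- tiny_map(500, 2, 200, seed = 80)
  fp <- generate_founder_population(200, map, seed = 81,
                                    n_mixing_generations = 4)
  G <- compute_grm(t(dosage_from_haps(fp$haps)), fp$freq)
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  expect_equal(G, t(G))
})

test_that("bivariate GBLUP equals the dense MME oracle to 1e-8", {
  toy <- toy_bivar()
  sol <- solve_bivariate_gblup(toy$rec, toy$G, toy$vc)
  oracle <- mme_oracle(toy$rec, toy$G, toy$vc)
  expect_equal(sol$gebv_B, unname(oracle$gebv_B), tolerance = 1e-8)
  expect_equal(sol$gebv_C, unname(oracle$gebv_C), tolerance = 1e-8)
})

test_that("animals without records in one trait get GEBVs through G and the
           genetic covariance", {
  toy <- toy_bivar()
  sol <- solve_bivariate_gblup(toy$rec, toy$G, toy$vc)
  # animals 1..7 have only B records, yet carry non-trivial C-trait GEBVs
  expect_true(all(abs(sol$gebv_C[1:7]) > 0))
})

test_that("univariate GBLUP equals the dense oracle and its closed form", {
  set.seed(90)
  n <- 9
  G <- random_pd_matrix(n)
  rec <- data.frame(animal = 1:n, year = rep(c(1, 2, 3), 3),
                    value = rnorm(n))
  vc <- list(sigma2_g = 1.5, sigma2_e = 2.5)
  sol <- solve_univariate_gblup(rec, G, vc)
  expect_equal(sol$gebv, unname(mme_oracle(rec, G, vc)$gebv),
               tolerance = 1e-8)
  # with G = I and one year class, GEBV is the centered record shrunk by
  # s2g / (s2g + s2e)
  rec2 <- data.frame(animal = 1:2, year = c(1, 1), value = c(3, 7))
  sol2 <- solve_univariate_gblup(rec2, diag(2), vc)
  expect_equal(sol2$gebv, 1.5 / 4 * c(-2, 2), tolerance = 1e-8)
})

test_that("flat phenotypes within year classes give zero GEBV", {
  toy <- toy_bivar()
  toy$rec$value <- ave(toy$rec$value, paste(toy$rec$env, toy$rec$year))
  sol <- solve_bivariate_gblup(toy$rec, toy$G, toy$vc)
  expect_equal(sol$gebv_B, rep(0, 12), tolerance = 1e-8)
  expect_equal(sol$gebv_C, rep(0, 12), tolerance = 1e-8)
})

test_that("GEBVs are invariant to shifting a year class (fixed-effect
           absorption)", {
  toy <- toy_bivar()
  sol1 <- solve_bivariate_gblup(toy$rec, toy$G, toy$vc)
  toy$rec$value[toy$rec$env == "B" & toy$rec$year == 10] <-
    toy$rec$value[toy$rec$env == "B" & toy$rec$year == 10] + 100
  sol2 <- solve_bivariate_gblup(toy$rec, toy$G, toy$vc)
  expect_equal(sol1$gebv_B, sol2$gebv_B, tolerance = 1e-8)
  expect_equal(sol1$gebv_C, sol2$gebv_C, tolerance = 1e-8)
})

test_that("noise-free limit returns within-class centered phenotypes", {
  set.seed(91)
  rec <- data.frame(animal = 1:6, year = rep(1, 6), value = rnorm(6))
  sol <- solve_univariate_gblup(rec, diag(6),
                                list(sigma2_g = 1, sigma2_e = 1e-10))
  expect_equal(sol$gebv, rec$value - mean(rec$value), tolerance = 1e-4)
})

test_that("expected dispersion bias follows the covariance algebra", {
  vc_eq <- variance_components(1, 1, 0.5, 2, 2)
  expect_equal(expected_bias(0.5, vc_eq, has_C_records = FALSE), 0.5)
  expect_equal(expected_bias(0.5, vc_eq, has_C_records = TRUE), 1)
  vc_4 <- variance_components(1, 4, 0.8, 2, 2)
  expect_equal(expected_bias(0.8, vc_4, has_C_records = FALSE), 1.6)
})
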