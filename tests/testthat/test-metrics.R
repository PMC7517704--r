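test_that("rate of genetic gain recovers trends and ignores level shifts", {
  lin <- setNames(0.3 * (1:21), 1:21)
  expect_equal(rate_of_genetic_gain(lin), 0.3)
  expect_equal(rate_of_genetic_gain(lin + 5), 0.3)
  expect_equal(rate_of_genetic_gain(setNames(rep(2, 21), 1:21)), 0)
  # full-scale windows imply the divisor 42
  expect_equal(sum(19:21) - sum(5:7), 42)
  expect_error(rate_of_genetic_gain(lin[1:10]), "cover")
})

test_that("pedigree inbreeding reproduces textbook values", {
  full_sib <- data.frame(id = 1:5, sire = c(NA, NA, 1, 1, 3),
                         dam = c(NA, NA, 2, 2, 4))
  expect_equal(unname(pedigree_inbreeding(full_sib)), c(0, 0, 0, 0, 0.25))
  half_sib <- data.frame(id = 1:6, sire = c(NA, NA, NA, 1, 1, 4),
                         dam = c(NA, NA, NA, 2, 3, 5))
  expect_equal(unname(pedigree_inbreeding(half_sib)[6]), 0.125)
  # selfed grandparents / ordering violations are rejected
  bad <- data.frame(id = 1:2, sire = c(2, NA), dam = c(NA, NA))
  expect_error(pedigree_inbreeding(bad), "parents before offspring")
})

test_that("inbreeding matches the recursive kinship oracle on random
           pedigrees", {
  set.seed(130)
  for (rep in 1:40) {
    n <- sample(6:10, 1)
    sire <- dam <- integer(n)
    for (i in 3:n) {
      if (runif(1) < 0.75) {
        pair <- sample(i - 1L, 2L)
        sire[i] <- pair[1]
        dam[i] <- pair[2]
      }
    }
    ped <- data.frame(id = 1:n, sire = ifelse(sire == 0, NA, sire),
                      dam = ifelse(dam == 0, NA, dam))
    expect_equal(unname(pedigree_inbreeding(ped)),
                 kinship_oracle(sire, dam))
  }
})

test_that("rate of inbreeding recovers a constructed constant rate", {
  f <- 1 - (1 - 0.01)^((5:21) / 3)
  expect_equal(rate_of_inbreeding(setNames(f, 5:21)), 1, tolerance = 1e-10)
  expect_equal(rate_of_inbreeding(setNames(rep(0.1, 17), 5:21)), 0)
  expect_error(rate_of_inbreeding(setNames(c(0.5, 1), 5:6)), "below 1")
})

test_that("drift-only inbreeding matches the Wright-Fisher expectation", {
  # random mating, no selection: delta-F ~ 100 / (2N) percent per generation
  N <- 20
  set.seed(131)
  rates <- vapply(1:6, function(rep) {
    gens <- 14
    ids <- 1:N
    ped <- data.frame(id = ids, sire = NA_integer_, dam = NA_integer_,
                      gen = 0)
    nxt <- N + 1
    for (g in 1:gens) {
      prev <- ped$id[ped$gen == g - 1]
      kids <- t(replicate(N, sample(prev, 2)))
      ped <- rbind(ped, data.frame(id = nxt:(nxt + N - 1),
                                   sire = kids[, 1], dam = kids[, 2],
                                   gen = g))
      nxt <- nxt + N
    }
    F <- pedigree_inbreeding(ped[c("id", "sire", "dam")])
    Fg <- tapply(F, ped$gen, mean)[as.character(4:gens)]
    rate_of_inbreeding(setNames(Fg, 4:gens), generation_interval = 1)
  }, 0)
  mc_se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 100 / (2 * N)), 2 * mc_se + 0.3)
})

test_that("accuracy and bias behave under scaling and shifting", {
  set.seed(132)
  tbv <- rnorm(200)
  gebv <- tbv + rnorm(200, 0, 0.5)
  ab <- accuracy_and_bias(gebv, tbv)
  expect_equal(accuracy_and_bias(tbv, tbv)$bias_slope, 1)
  expect_equal(accuracy_and_bias(2 * tbv, tbv)$bias_slope, 0.5)
  expect_equal(accuracy_and_bias(2 * tbv, tbv)$accuracy, 1)
  shifted <- accuracy_and_bias(gebv + 7, tbv)
  expect_equal(shifted$accuracy, ab$accuracy)
  expect_equal(shifted$bias_slope, ab$bias_slope)
  scaled <- accuracy_and_bias(3 * gebv, tbv)
  expect_equal(scaled$bias_slope, ab$bias_slope / 3)
  expect_warning(accuracy_and_bias(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("replicate summaries report mean, SE and the gain/inbreeding
           ratio", {
  r <- data.frame(delta_G = c(1, 3), delta_F_percent = c(2, 2))
  s <- summarize_replicates(r)
  expect_equal(s$mean[s$metric == "delta_G"], 2)
  expect_equal(s$se[s$metric == "delta_G"], 1)
  expect_equal(attr(s, "gain_per_F"), 1)
  same <- summarize_replicates(data.frame(x = rep(4, 5)))
  expect_equal(same$se, 0)
  # SE of 100 replicates of N(mu, sigma^2) is close to sigma / 10
  set.seed(133)
  s100 <- summarize_replicates(data.frame(x = rnorm(100, 0, 2)))
  expect_lt(abs(s100$se - 0.2), 0.06)
  expect_error(summarize_replicates(data.frame(x = 1)), "2 replicates")
})

test_that("repeat-dam expectation matches its Monte Carlo and drives the
           cross-year relationship", {
  expect_equal(expected_repeat_dams(50, 400, 200), 3.125)
  set.seed(134)
  mc <- repeat_dams_mc(50, 400, 200, n_sims = 4000)
  expect_equal(mc, 3.125, tolerance = 0.1)
  expect_equal(cross_year_relationship(50, 400, 200), 0.015625)
})
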