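# micro-profile end-to-end checks of the yearly cycle bookkeeping
micro_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_config("micro", c_strategy = "T1_1B1_1",
                             b_strategy = "Top1_1", r_g = 0.5, h2 = 0.3,
                             years = 8)
      cache <<- simulate_scheme(cfg, master_seed = 3, replicate = 1,
                                keep_state = TRUE)
    }
    cache
  }
})

test_that("the yearly cycle conserves the genotyping budget and its B/C
           split", {
  st <- micro_run()$state
  cfg <- st$cfg
  rows <- seq_len(st$geno$n)
  by_year <- table(st$geno$rec_year[rows])
  expect_true(all(by_year == cfg$budget))
  for (t in 4:8) {
    sel <- rows[st$geno$rec_year[rows] == t]
    expect_equal(sum(st$geno$env[sel] == "C"), cfg$budget_C)
    expect_equal(sum(st$geno$env[sel] == "B"), cfg$budget_B)
  }
})

test_that("no fish is genotyped twice and GEBVs exist only for genotyped
           fish", {
  st <- micro_run()$state
  rows <- seq_len(st$geno$n)
  expect_false(anyDuplicated(st$geno$id[rows]) > 0)
  expect_true(all(st$ped$genotyped[st$geno$id[rows]]))
  expect_equal(sum(st$ped$genotyped), st$geno$n)
  expect_true(all(is.finite(st$gebv_B[rows])))
})

test_that("cohorts, female pool and parent ages follow the design", {
  res <- micro_run()
  st <- res$state
  cfg <- st$cfg
  expect_equal(as.integer(table(st$ped$birth_year[st$ped$birth_year > 0])),
               rep(cfg$n_offspring, cfg$years))
  expect_equal(nrow(st$pool), cfg$n_pool)
  # parents of the year-8 cohort: sires born in year 5 (3-year-olds), dams
  # born in years 5 (3-yo) or 4 (retained 4-yo)
  coh8 <- which(st$ped$birth_year == 8)
  sires <- unique(st$ped$sire[coh8])
  dams <- unique(st$ped$dam[coh8])
  expect_true(all(st$ped$birth_year[sires] == 5))
  expect_true(all(st$ped$birth_year[dams] %in% c(4, 5)))
  expect_length(sires, cfg$n_sires)
  expect_length(dams, cfg$n_dams)
  # each parent mated exactly twice (two families of family_size offspring)
  expect_true(all(table(st$ped$sire[coh8]) == 2 * cfg$family_size))
  expect_true(all(table(st$ped$dam[coh8]) == 2 * cfg$family_size))
  # sires are genotyped B males
  expect_true(all(st$ped$genotyped[sires]))
  expect_true(all(st$ped$env[sires] == "B"))
  expect_true(all(st$ped$sex[sires] == "M"))
})

test_that("years 1-3 use founder parents and no genotyping", {
  st <- micro_run()$state
  for (t in 1:3) {
    coh <- which(st$ped$birth_year == t)
    parents <- unique(c(st$ped$sire[coh], st$ped$dam[coh]))
    expect_true(all(st$ped$birth_year[parents] == 0))
  }
  expect_true(all(st$geno$rec_year[seq_len(st$geno$n)] >= 4))
})

test_that("a replicate is deterministic given its seeds", {
  cfg <- scenario_config("micro", years = 6)
  a <- simulate_scheme(cfg, master_seed = 11, replicate = 2)
  b <- simulate_scheme(cfg, master_seed = 11, replicate = 2)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$series, b$series)
  c <- simulate_scheme(cfg, master_seed = 11, replicate = 3)
  expect_false(identical(a$series$G_t, c$series$G_t))
})

test_that("scenarios sharing a replicate index share founder genomes", {
  cfg1 <- scenario_config("micro", c_strategy = "Random")
  cfg2 <- scenario_config("micro", c_strategy = "Top1_1")
  s1 <- new_population_state(cfg1, master_seed = 5, replicate = 1)
  s2 <- new_population_state(cfg2, master_seed = 5, replicate = 1)
  expect_identical(s1$founders$haps, s2$founders$haps)
  expect_identical(s1$arch$qtl, s2$arch$qtl)
})

test_that("infeasible scenarios are rejected, not degraded", {
  # desk scale cannot screen 72 new females in groups of 20 (11% retention)
  expect_error(scenario_config("desk", prop_females_kept = 0.11),
               "infeasible")
  # too small a male share of the B budget
  expect_error(scenario_config("desk", b_strategy = "Top1_1",
                               genotyped_male_fraction = 0.05),
               "sires|infeasible")
  # full scale keeps the study arithmetic: 1,000 genotyped per year
  cfg <- scenario_config("full")
  expect_equal(cfg$budget, 1000L)
  expect_equal(cfg$n_offspring, 20000L)
  expect_equal(cfg$n_pairs, 100L)
  expect_equal(cfg$family_size, 200L)
  expect_equal(cfg$n_new_females, 200L)
  f11 <- scenario_config("full", prop_females_kept = 0.11)
  expect_equal(f11$n_new_females, 360L)
  expect_equal(f11$n_kept_females, 40L)
})
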