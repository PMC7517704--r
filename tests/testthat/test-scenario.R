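test_that("the scenario grid mirrors the base-plus-alternatives design", {
  g <- build_scenario_grid(list(profile = "micro"))
  expect_false(any(duplicated(g$scenario_id)))
  # C-strategy sweep: 4 strategies x 3 r_g x 2 h2
  expect_equal(sum(g$sweep == "C_strategy"), 24)
  # B sweep loses the cells duplicating the C sweep's Random/Top1_1 column
  expect_equal(sum(g$b_strategy == "T3_4B1_4"), 6)
  # allocation sweep only at h2 = 0.3
  expect_true(all(g$h2[g$sweep == "allocation"] == 0.3))
  expect_setequal(unique(g$prop_C[g$sweep == "allocation"]),
                  c(0, 0.2, 0.4, 0.6))
  # base cell present: bracketed factor levels with 20% to C
  expect_true(any(g$c_strategy == "Random" & g$b_strategy == "Top1_1" &
                    g$prop_C == 0.2 & g$prop_females_kept == 1))
  # cells the scale cannot support are flagged, not dropped or degraded
  expect_true(all(vapply(g$config[g$feasible], inherits, TRUE,
                         "scenario_config")))
  expect_true(all(vapply(g$config[!g$feasible], is.null, TRUE)))
  expect_error(build_scenario_grid(list(nonsense = 1)), "unknown")
})

test_that("run_scenario is deterministic and its replicates exchangeable", {
  cfg <- scenario_config("micro", years = 6)
  a <- run_scenario(cfg, n_replicates = 2, master_seed = 9)
  b <- run_scenario(cfg, n_replicates = 2, master_seed = 9)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$bias, b$bias)
  # permuting replicate rows leaves the summary unchanged
  sh <- a[c(2, 1), ]
  cols <- c("accuracy", "bias")
  expect_equal(summarize_replicates(a[cols]), summarize_replicates(sh[cols]))
})

test_that("summary report has the strategy-table layout", {
  cfg1 <- scenario_config("micro", years = 6, c_strategy = "Random")
  cfg2 <- scenario_config("micro", years = 6, c_strategy = "Top1_1")
  res <- list(C_Random = run_scenario(cfg1, 2, 1),
              C_Top = run_scenario(cfg2, 2, 1))
  long <- report(res)
  expect_true(all(c("scenario", "metric", "mean", "se") %in% names(long)))
  wide <- report(res, layout = "wide")
  expect_true(all(c("C_Random", "C_Top") %in% names(wide)))
  expect_true("accuracy" %in% wide$metric)
})

test_that("YAML scenario configs round-trip through validation", {
  cfg <- scenario_config("micro", c_strategy = "T1_2B1_2", r_g = 0.8,
                         h2 = 0.1, years = 12, reml_year = 10)
  f <- tempfile(fileext = ".yaml")
  write_scenario_config(cfg, f)
  back <- read_scenario_config(f)
  for (field in c("scenario_id", "c_strategy", "b_strategy", "r_g", "h2",
                  "prop_C", "years", "reml_year", "n_offspring",
                  "male_fraction_B", "female_geno_budget"))
    expect_identical(back[[field]], cfg[[field]])
  unlink(f)
})

test_that("sex-ratio optimization returns a grid member", {
  expect_equal(optimize_sex_ratio(scenario_config("micro"), grid = 1), 1)
  cfg <- scenario_config("micro", b_strategy = "Top1_1", years = 8,
                         gain_first = 4L, gain_last = 8L)
  best <- optimize_sex_ratio(cfg, grid = c(0.5, 1), pilot_replicates = 2,
                             master_seed = 3)
  expect_true(best %in% c(0.5, 1))
})

test_that("plain-text exports round-trip", {
  map <- tiny_map(30, 2, 100)
  f <- tempfile()
  write_genetic_map(map, f)
  back <- read.table(f, header = TRUE)
  expect_equal(nrow(back), 30)
  expect_equal(back$pos_cM, map$pos)
  fp <- generate_founder_population(5, map, seed = 2,
                                    n_mixing_generations = 0)
  f2 <- tempfile()
  export_genotypes_text(fp$haps, map, f2)
  expect_equal(nrow(read.table(f2, header = TRUE)), 30)
  f3 <- tempfile()
  save_founder_genome(fp, f3)
  expect_identical(load_founder_genome(f3)$haps, fp$haps)
  unlink(c(f, f2, f3))
})
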