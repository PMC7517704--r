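#' Scenario configuration
#'
#' One cell of the factor grid plus scale parameters. The six investigated
#' factors are the genotyping strategy for fish in the commercial environment
#' (C), the strategy for selection candidates in the breeding environment
#' (B), the genetic correlation `r_g` between the trait measured in B and in
#' C, the heritability `h2`, the proportion of genotyping (and of offspring)
#' allocated to C, and the proportion of selected females kept in two
#' consecutive years.
#'
#' Two built-in scale profiles preserve the structural ratios that drive
#' selection intensities and genotyping distortions (screening groups of 20,
#' one genotyping slot per 20 offspring, degree-2 partly factorial mating, a
#' 3-year lag from birth to selection, 21 years):
#'
#' * `"full"`: 20,000 offspring/year from 50 sires x 50 dams (100 families of
#'   200), 1,000 genotyped/year, 400-female pool, 36,451 loci (3,742 QTL).
#' * `"desk"`: 2,000 offspring/year from 10 x 10 parents (20 families of
#'   100), 100 genotyped/year, 80-female pool, 3,400 loci (400 QTL). Runs in
#'   minutes on one CPU.
#' * `"micro"`: 400 offspring/year, 20 genotyped/year; for smoke tests.
#'
#' Sex structure. Screening for genotyping happens within sex, and
#' `budget_B * group_size` always equals the number of B fish, so the design
#' must tile exactly: with `b_strategy = "Random"` no females are genotyped
#' (`genotyped_male_fraction = 1`), females are selected phenotypically
#' (best of each random group of 20 by B phenotype) and the B sex ratio is
#' 1:1; with a group-based `b_strategy` the yearly female intake is genotyped
#' (budget = number of new females, same screening strategy), the male budget
#' is the remainder, and the B sex ratio equals the male budget share so both
#' screenings use every B fish. `genotyped_male_fraction` can be overridden;
#' infeasible settings are rejected, never silently degraded.
#'
#' @param profile `"desk"`, `"full"` or `"micro"`.
#' @param c_strategy genotyping strategy in C: `"Random"`, `"Top1_1"`,
#'   `"T1_1B1_1"` or `"T1_2B1_2"`.
#' @param b_strategy genotyping strategy in B: `"Random"`, `"Top1_1"`,
#'   `"T1_2B1_2"` or `"T3_4B1_4"`.
#' @param r_g genetic correlation between the B- and C-measured trait.
#' @param h2 heritability of the trait (both environments).
#' @param prop_C proportion of genotyping (= proportion of offspring)
#'   allocated to fish in C: 0, 0.2, 0.4 or 0.6 in the study design.
#' @param prop_females_kept proportion of selected females used in two
#'   consecutive years (1.00 or 0.11 in the study design).
#' @param years number of simulated years.
#' @param eval_years years in which GEBV accuracy/bias of the 3-year-old
#'   genotyped B fish are recorded.
#' @param gain_first,gain_last birth-year windows of the genetic-gain rate.
#' @param reml_year year of the optional REML variance-component snapshot
#'   (`NA` = none; the snapshot never feeds back into selection).
#' @param genotyped_male_fraction optional override of the male share of the
#'   B genotyping budget (`NULL` = derived as described above).
#' @param ... scale-parameter overrides (`n_offspring`, `budget`, `n_sires`,
#'   `n_dams`, `n_pool`, `n_founders`, `n_loci`, `n_qtl`, `n_chromosomes`,
#'   `map_length_cM`, `group_size`, `maf_low`, `maf_high`,
#'   `n_mixing_generations`, `generation_interval`).
#' @return an object of class `scenario_config` (validated).
#' @examples
#' cfg <- scenario_config("micro", r_g = 0.5, h2 = 0.3)
#' cfg$family_size
#' @export
scenario_config <- function(profile = c("desk", "full", "micro"),
                            c_strategy = "Random", b_strategy = "Top1_1",
                            r_g = 0.5, h2 = 0.3, prop_C = 0.2,
                            prop_females_kept = 1.0, years = 21L,
                            eval_years = 10:12, gain_first = 5:7,
                            gain_last = 19:21, reml_year = NA_integer_,
                            genotyped_male_fraction = NULL, ...) {
  profile <- match.arg(profile)
  scale <- switch(profile,
    full = list(n_offspring = 20000L, budget = 1000L, n_sires = 50L,
                n_dams = 50L, n_pool = 400L, n_founders = 958L,
                n_loci = 36451L, n_qtl = 3742L),
    desk = list(n_offspring = 2000L, budget = 100L, n_sires = 10L,
                n_dams = 10L, n_pool = 80L, n_founders = 958L,
                n_loci = 3400L, n_qtl = 400L),
    micro = list(n_offspring = 400L, budget = 20L, n_sires = 2L,
                 n_dams = 2L, n_pool = 16L, n_founders = 120L,
                 n_loci = 600L, n_qtl = 100L))
  base <- c(scale, list(n_chromosomes = 29L, map_length_cM = 2927.1,
                        group_size = 20L, maf_low = 0.05, maf_high = 0.5,
                        n_mixing_generations = 30L, n_mixing_pop = 50L,
                        generation_interval = 3))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown)) stop("unknown scale parameter(s): ",
                            paste(unknown, collapse = ", "))
  base[names(dots)] <- dots
  cfg <- c(base,
           list(profile = profile,
                c_strategy = match.arg(c_strategy,
                                       c("Random", "Top1_1", "T1_1B1_1",
                                         "T1_2B1_2")),
                b_strategy = match.arg(b_strategy,
                                       c("Random", "Top1_1", "T1_2B1_2",
                                         "T3_4B1_4")),
                r_g = r_g, h2 = h2, prop_C = prop_C,
                prop_females_kept = prop_females_kept,
                years = as.integer(years), eval_years = as.integer(eval_years),
                gain_first = as.integer(gain_first),
                gain_last = as.integer(gain_last),
                reml_year = as.integer(reml_year),
                genotyped_male_fraction = genotyped_male_fraction))
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

#' Validate and derive a scenario configuration
#'
#' Checks the structural invariants of a scenario (integer genotyping split,
#' exact family sizes, divisibility required by the group strategies, enough
#' fish for every screening, enough genotyped males for the sire selection)
#' and fills in the derived quantities: family structure, B/C budgets, female
#' intake and retention numbers, male/female genotyping budgets and the B sex
#' ratio. Infeasible scenarios raise an error.
#'
#' @param cfg a [scenario_config()] object (possibly edited).
#' @return the validated config with derived fields added.
#' @export
validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (n_offspring %% (2L * n_sires) != 0)
      stop("n_offspring must be a multiple of the 2 * n_sires matings")
    if (n_sires != n_dams)
      stop("partly factorial design uses equal sire and dam numbers")
    bc <- budget * prop_C
    if (abs(bc - round(bc)) > 1e-9)
      stop("budget * prop_C must be an integer")
  })
  cfg$n_pairs <- 2L * cfg$n_sires
  cfg$family_size <- cfg$n_offspring %/% cfg$n_pairs
  cfg$budget_C <- as.integer(round(cfg$budget * cfg$prop_C))
  cfg$budget_B <- cfg$budget - cfg$budget_C
  cfg$n_C <- as.integer(round(cfg$n_offspring * cfg$prop_C))
  cfg$n_B <- cfg$n_offspring - cfg$n_C
  # female intake and retention: n_new + round(kept-prop * n_new) = pool
  cfg$n_new_females <- as.integer(round(cfg$n_pool /
                                          (1 + cfg$prop_females_kept)))
  cfg$n_kept_females <- cfg$n_pool - cfg$n_new_females

  groups_needed <- function(strategy, budget) {
    switch(strategy,
           Random = 0L,
           Top1_1 = budget,
           T1_1B1_1 = { if (budget %% 2L) stop(strategy, " needs an even budget")
                        budget %/% 2L },
           T1_2B1_2 = { if (budget %% 2L) stop(strategy, " needs an even budget")
                        budget },
           T3_4B1_4 = { if (budget %% 4L)
                          stop(strategy, " needs a budget divisible by 4")
                        budget })
  }

  # Sex structure of the B genotyping. Returns the derived fields or a
  # character explaining why this female budget cannot work.
  check_structure <- function(female_geno) {
    male_geno <- cfg$budget_B - female_geno
    if (male_geno < cfg$n_sires)
      return("fewer genotyped B males than sires needed")
    if (female_geno > 0L && female_geno < cfg$n_new_females)
      return("genotyped females fewer than the yearly female intake")
    gs <- cfg$group_size
    male_fish <- if (cfg$b_strategy == "Random") male_geno
                 else groups_needed(cfg$b_strategy, male_geno) * gs
    female_fish <- if (female_geno > 0L) {
      if (cfg$b_strategy == "Random") female_geno
      else groups_needed(cfg$b_strategy, female_geno) * gs
    } else cfg$n_new_females * gs      # phenotypic Top1_1 selection
    if (male_fish + female_fish > cfg$n_B)
      return(sprintf("B cohort too small: %d male + %d female screening slots for %d fish",
                     male_fish, female_fish, cfg$n_B))
    m <- if (cfg$b_strategy == "Random") 0.5 else male_fish / cfg$n_B
    if (round(m * cfg$n_B) < male_fish ||
        cfg$n_B - round(m * cfg$n_B) < female_fish)
      return("B sex ratio cannot accommodate both screenings")
    list(female_geno_budget = as.integer(female_geno),
         male_geno_budget = as.integer(male_geno),
         male_fraction_B = m)
  }

  if (is.null(cfg$genotyped_male_fraction)) {
    # preferred: genotype the female intake (same screening strategy);
    # fall back to phenotypic female selection with an all-male budget
    candidates <- if (cfg$b_strategy == "Random") 0L
                  else c(cfg$n_new_females, 0L)
  } else {
    f <- cfg$genotyped_male_fraction
    if (f < 0 || f > 1) stop("genotyped_male_fraction must be in [0, 1]")
    candidates <- cfg$budget_B - as.integer(round(f * cfg$budget_B))
  }
  derived <- NULL
  reasons <- character(0)
  for (fg in candidates) {
    d <- check_structure(fg)
    if (is.list(d)) { derived <- d; break }
    reasons <- c(reasons, sprintf("female budget %d: %s", fg, d))
  }
  if (is.null(derived))
    stop("scenario infeasible under the screening design: ",
         paste(reasons, collapse = "; "))
  cfg[names(derived)] <- derived
  cfg$females_genotyped <- cfg$female_geno_budget > 0L

  if (cfg$prop_C > 0) {
    gc <- groups_needed(cfg$c_strategy, cfg$budget_C)
    if (gc * cfg$group_size > cfg$n_C)
      stop(sprintf("C screening infeasible: %d groups of %d needed, %d C fish",
                   gc, cfg$group_size, cfg$n_C))
    if (cfg$budget_C > cfg$n_C) stop("C genotyping budget exceeds C fish")
  }
  if (cfg$n_dams > cfg$n_pool) stop("more dams than available females")
  if (cfg$n_founders < 2 * (3L * cfg$n_sires + cfg$n_dams))
    stop("not enough founders to seed three start-up years")
  cfg$scenario_id <- with(cfg, sprintf(
    "C-%s_B-%s_rg%g_h2%g_pC%g_pF%g_%s",
    c_strategy, b_strategy, r_g, h2, 100 * prop_C,
    100 * prop_females_kept, profile))
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config:", x$scenario_id, "\n")
  cat(sprintf("  %d offspring/yr (%d families of %d), %d genotyped/yr (B %d / C %d)\n",
              x$n_offspring, x$n_pairs, x$family_size, x$budget, x$budget_B,
              x$budget_C))
  cat(sprintf("  females: pool %d = %d new + %d kept, %s\n", x$n_pool,
              x$n_new_females, x$n_kept_females,
              if (x$females_genotyped)
                sprintf("genotyped (budget %d)", x$female_geno_budget)
              else "phenotypically selected"))
  invisible(x)
}
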