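# The yearly sib-testing breeding cycle with overlapping generations.
#
# Timeline: fish born in year t are placed in B or C at birth, phenotyped /
# genotyped / evaluated at year t + 3 (when 3 years old), and the selected
# ones mate in that same year. Years 1-3 are seeded with founder parents;
# from year 4 on, sires are the top genotyped 3-year-old B males, the female
# pool holds this year's selected 3-year-olds plus the retained share of last
# year's, and 50 dams (full scale) are drawn from it at random. Neo-males
# spawn once, so sires are never reused across years.

#' Initialize a population state
#'
#' Builds the genetic map, synthetic founder population and trait
#' architecture for one replicate and sets up the bookkeeping (pedigree,
#' genotype store, relationship matrix) for a scenario run. Randomness is
#' split into named substreams derived from `(master_seed, replicate)`:
#' founder genomes and raw trait draws are shared by all scenarios that share
#' a replicate index, while the breeding stream is scenario-specific.
#'
#' @param cfg a [scenario_config()] object.
#' @param master_seed integer master seed.
#' @param replicate replicate index.
#' @return an environment of class `population_state`.
#' @export
new_population_state <- function(cfg, master_seed = 1L, replicate = 1L) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  set.seed(substream_seed(master_seed, replicate, "founders",
                          cfg$n_loci, cfg$n_founders))
  st$map <- build_genetic_map(cfg$n_chromosomes, cfg$map_length_cM,
                              cfg$n_loci)
  st$founders <- generate_founder_population(cfg$n_founders, st$map,
                                             cfg$maf_low, cfg$maf_high,
                                             cfg$n_mixing_generations,
                                             n_mixing_pop = cfg$n_mixing_pop)
  set.seed(substream_seed(master_seed, replicate, "architecture", cfg$n_qtl))
  st$arch <- assign_trait_architecture(st$map, st$founders, cfg$n_qtl,
                                       cfg$r_g, cfg$h2)
  set.seed(substream_seed(master_seed, replicate, "breeding",
                          cfg$scenario_id))

  n_total <- cfg$n_founders + cfg$years * cfg$n_offspring
  st$n_total <- n_total
  st$ped <- list(sire = integer(n_total), dam = integer(n_total),
                 birth_year = integer(n_total), sex = character(n_total),
                 env = character(n_total), pheno = rep(NA_real_, n_total),
                 rec_year = integer(n_total), tbv_B = rep(NA_real_, n_total),
                 tbv_C = rep(NA_real_, n_total),
                 genotyped = logical(n_total))
  nf <- cfg$n_founders
  st$ped$birth_year[seq_len(nf)] <- 0L
  st$ped$env[seq_len(nf)] <- "none"
  sexes <- rep("F", nf)
  sexes[sample.int(nf, nf %/% 2L)] <- "M"
  st$ped$sex[seq_len(nf)] <- sexes
  st$founder_males <- sample(which(sexes == "M"))   # consumed year 1-3 sires
  st$founder_females <- which(sexes == "F")
  st$cohort_start <- c("0" = 1L)
  st$cohort_haps <- list("0" = st$founders$haps)
  st$kept_haps <- list()
  st$next_id <- nf + 1L

  # marker centering fixed at founder frequencies (VanRaden method 1)
  mk <- st$arch$markers
  p <- st$founders$freq[mk]
  use <- which(p > 0 & p < 1)
  st$marker_rows <- mk[use]
  st$marker_p <- p[use]
  st$grm_scale <- 2 * sum(st$marker_p * (1 - st$marker_p))

  max_geno <- cfg$budget * max(cfg$years - 3L, 0L)
  st$max_geno <- max_geno
  st$geno <- list(n = 0L, id = integer(max_geno), env = character(max_geno),
                  rec_year = integer(max_geno), value = numeric(max_geno),
                  birth_year = integer(max_geno), sex = character(max_geno))
  st$Z <- matrix(0, max_geno, length(st$marker_rows))
  st$G <- matrix(0, max_geno, max_geno)
  st$geno_row <- integer(n_total)          # id -> genotype-store row (0 = none)
  st$gebv_B <- rep(NA_real_, max_geno)
  st$gebv_C <- rep(NA_real_, max_geno)
  st$pool <- NULL
  st$prev_new_females <- integer(0)
  st$series_G <- rep(NA_real_, cfg$years)
  st$acc_bias <- list()
  st$reml <- NULL
  st$year <- 0L
  class(st) <- c("population_state", "environment")
  st
}

#' @export
print.population_state <- function(x, ...) {
  cat("population_state:", x$cfg$scenario_id, "- year", x$year, "of",
      x$cfg$years, ";", x$geno$n, "fish genotyped\n")
  invisible(x)
}

# assemble an n_loci x 2k haplotype matrix for the given ids
get_haps <- function(st, ids) {
  starts <- st$cohort_start
  out <- matrix(0L, st$map$n_loci, 2L * length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    k <- findInterval(id, starts)
    key <- names(starts)[k]
    hm <- st$cohort_haps[[key]]
    if (!is.null(hm)) {
      col <- id - starts[[k]] + 1L
      out[, 2L * j - 1L] <- hm[, 2L * col - 1L]
      out[, 2L * j] <- hm[, 2L * col]
    } else {
      hk <- st$kept_haps[[as.character(id)]]
      if (is.null(hk)) stop("haplotypes of id ", id, " no longer available")
      out[, (2L * j - 1L):(2L * j)] <- hk
    }
  }
  out
}

# --- yearly steps -----------------------------------------------------------

genotype_cohort <- function(st, t) {
  cfg <- st$cfg
  u <- t - 3L
  coh <- cohort_ids(st, u)
  ped <- st$ped
  sel <- integer(0)
  bm <- coh[ped$env[coh] == "B" & ped$sex[coh] == "M"]
  bf <- coh[ped$env[coh] == "B" & ped$sex[coh] == "F"]
  if (cfg$b_strategy == "Random") {
    sel <- c(sel, sort(sample(bm, cfg$male_geno_budget)))
  } else {
    sel <- c(sel, bm[select_for_genotyping(ped$pheno[bm], cfg$b_strategy,
                                           cfg$male_geno_budget,
                                           cfg$group_size, ids = bm)])
    if (cfg$female_geno_budget > 0L)
      sel <- c(sel, bf[select_for_genotyping(ped$pheno[bf], cfg$b_strategy,
                                             cfg$female_geno_budget,
                                             cfg$group_size, ids = bf)])
  }
  if (cfg$budget_C > 0L) {
    cc <- coh[ped$env[coh] == "C"]
    sel <- c(sel, if (cfg$c_strategy == "Random")
      sort(sample(cc, cfg$budget_C))
      else cc[select_for_genotyping(ped$pheno[cc], cfg$c_strategy,
                                    cfg$budget_C, cfg$group_size, ids = cc)])
  }
  stopifnot(length(sel) == cfg$budget, !any(ped$genotyped[sel]))
  st$ped$genotyped[sel] <- TRUE

  # genotype store, records and incremental GRM block
  n0 <- st$geno$n
  rows <- n0 + seq_along(sel)
  st$geno$n <- n0 + length(sel)
  st$geno$id[rows] <- sel
  st$geno$env[rows] <- st$ped$env[sel]
  st$geno$rec_year[rows] <- t
  st$geno$value[rows] <- st$ped$pheno[sel]
  st$geno$birth_year[rows] <- u
  st$geno$sex[rows] <- st$ped$sex[sel]
  st$geno_row[sel] <- rows
  dos <- dosage_from_haps(get_haps(st, sel))[st$marker_rows, , drop = FALSE]
  Znew <- t(dos) - rep(2 * st$marker_p, each = length(sel))
  st$Z[rows, ] <- Znew
  ntot <- st$geno$n
  blk <- tcrossprod(Znew, st$Z[seq_len(ntot), , drop = FALSE]) / st$grm_scale
  st$G[rows, seq_len(ntot)] <- blk
  st$G[seq_len(ntot), rows] <- t(blk)
  invisible(sel)
}

evaluate_population <- function(st) {
  cfg <- st$cfg
  n <- st$geno$n
  G <- st$G[seq_len(n), seq_len(n), drop = FALSE]
  if (cfg$prop_C > 0) {
    rec <- data.frame(animal = seq_len(n), env = st$geno$env[seq_len(n)],
                      year = st$geno$rec_year[seq_len(n)],
                      value = st$geno$value[seq_len(n)])
    sol <- solve_bivariate_gblup(rec, G, st$arch$varcomp_true)
    st$gebv_B[seq_len(n)] <- sol$gebv_B
    st$gebv_C[seq_len(n)] <- sol$gebv_C
  } else {
    rec <- data.frame(animal = seq_len(n),
                      year = st$geno$rec_year[seq_len(n)],
                      value = st$geno$value[seq_len(n)])
    sol <- solve_univariate_gblup(rec, G,
                                  list(sigma2_g = 1,
                                       sigma2_e = st$arch$sigma_e2))
    st$gebv_B[seq_len(n)] <- sol$gebv
    st$gebv_C[seq_len(n)] <- NA_real_
  }
  invisible(NULL)
}

# selection criterion per genotype-store row: C-trait GEBV when C records
# exist (breeding-goal weight 1 on C, 0 on B), else B-trait GEBV
selection_criterion <- function(st) {
  n <- st$geno$n
  if (st$cfg$prop_C > 0) st$gebv_C[seq_len(n)] else st$gebv_B[seq_len(n)]
}

cohort_ids <- function(st, birth_year) {
  key <- as.character(birth_year)
  start <- st$cohort_start[[key]]
  if (is.null(start)) stop("no cohort born in year ", birth_year)
  n <- if (birth_year == 0L) st$cfg$n_founders else st$cfg$n_offspring
  seq.int(start, start + n - 1L)
}

#' Select parents for the current year
#'
#' From the genotyped 3-year-olds of the current year: the top sires by the
#' selection criterion (C-trait GEBV when C records exist, otherwise B-trait
#' GEBV), the new female intake (by GEBV among genotyped females, or the best
#' of each random group of 20 by B phenotype when females are not genotyped),
#' the females retained from last year's intake (by GEBV if genotyped, at
#' random otherwise), and the dams: a uniform draw without replacement from
#' the pooled females.
#'
#' @param st a `population_state` (year >= 4, evaluation done).
#' @param t current year.
#' @return list with `sires`, `new_females`, `retained_females`, `dams`
#'   (vectors of ids) and `pool` (data.frame of the female pool).
#' @export
select_parents <- function(st, t) {
  cfg <- st$cfg
  ped <- st$ped
  u <- t - 3L
  coh <- cohort_ids(st, u)
  crit <- selection_criterion(st)
  rows <- seq_len(st$geno$n)
  cand <- rows[st$geno$birth_year[rows] == u & st$geno$sex[rows] == "M" &
                 st$geno$env[rows] == "B"]
  if (length(cand) < cfg$n_sires)
    stop("fewer genotyped 3-year-old males than sires required")
  o <- cand[order(-crit[cand], st$geno$id[cand])]
  sires <- st$geno$id[o[seq_len(cfg$n_sires)]]

  if (cfg$females_genotyped) {
    fr <- rows[st$geno$birth_year[rows] == u & st$geno$sex[rows] == "F" &
                 st$geno$env[rows] == "B"]
    if (length(fr) < cfg$n_new_females)
      stop("fewer genotyped females than the yearly intake")
    of <- fr[order(-crit[fr], st$geno$id[fr])]
    new_females <- st$geno$id[of[seq_len(cfg$n_new_females)]]
  } else {
    bf <- coh[ped$env[coh] == "B" & ped$sex[coh] == "F"]
    pick <- select_for_genotyping(ped$pheno[bf], "Top1_1",
                                  cfg$n_new_females, cfg$group_size,
                                  ids = bf)
    new_females <- bf[pick]
  }

  if (t == 4L) {
    # bootstrap: no previously selected females exist; fill the retained
    # slots at random from the same cohort's unselected B females
    bf_rest <- setdiff(coh[ped$env[coh] == "B" & ped$sex[coh] == "F"],
                       new_females)
    retained <- sort(sample(bf_rest, cfg$n_kept_females))
  } else if (cfg$n_kept_females > 0L) {
    prev <- st$prev_new_females
    if (cfg$females_genotyped) {
      pr <- st$geno_row[prev]
      op <- prev[order(-crit[pr], prev)]
      retained <- op[seq_len(cfg$n_kept_females)]
    } else {
      retained <- sort(sample(prev, cfg$n_kept_females))
    }
  } else retained <- integer(0)

  pool <- data.frame(id = c(new_females, retained),
                     status = rep(c("new", "held"),
                                  c(length(new_females), length(retained))))
  stopifnot(nrow(pool) == cfg$n_pool)
  dams <- sort(sample(pool$id, cfg$n_dams))
  st$prev_new_females <- new_females
  st$pool <- pool
  list(sires = sires, new_females = new_females,
       retained_females = retained, dams = dams, pool = pool)
}

make_births <- function(st, t, sires, dams) {
  cfg <- st$cfg
  pairs <- partly_factorial_matings(sires, dams)
  fs <- cfg$family_size
  sire_of <- rep(pairs$sire, each = fs)
  dam_of <- rep(pairs$dam, each = fs)
  parents <- unique(c(pairs$sire, pairs$dam))
  P <- get_haps(st, parents)
  pidx <- match(sire_of, parents)
  midx <- match(dam_of, parents)
  gs <- drop_gametes(P, 2L * pidx - 1L, 2L * pidx, st$map$pos,
                     st$map$chr_first, st$map$chr_last, st$map$chr_len)
  gd <- drop_gametes(P, 2L * midx - 1L, 2L * midx, st$map$pos,
                     st$map$chr_first, st$map$chr_last, st$map$chr_len)
  N <- length(sire_of)
  haps <- matrix(0L, st$map$n_loci, 2L * N)
  haps[, seq(1L, 2L * N, by = 2L)] <- gs
  haps[, seq(2L, 2L * N, by = 2L)] <- gd
  alloc <- allocate_offspring(N, cfg$prop_C, cfg$male_fraction_B, 0.5)
  tbv <- tbv_batch(haps, st$arch)
  pheno <- simulate_phenotype(tbv[, 1L], tbv[, 2L], alloc$env, st$arch)
  ids <- seq.int(st$next_id, st$next_id + N - 1L)
  st$next_id <- st$next_id + N
  st$cohort_start[[as.character(t)]] <- ids[1L]
  st$cohort_haps[[as.character(t)]] <- haps
  st$ped$sire[ids] <- sire_of
  st$ped$dam[ids] <- dam_of
  st$ped$birth_year[ids] <- t
  st$ped$sex[ids] <- alloc$sex
  st$ped$env[ids] <- alloc$env
  st$ped$pheno[ids] <- pheno
  st$ped$rec_year[ids] <- t + 3L
  st$ped$tbv_B[ids] <- tbv[, 1L]
  st$ped$tbv_C[ids] <- tbv[, 2L]
  st$series_G[t] <- mean(tbv[, 2L])
  invisible(ids)
}

prune_haplotypes <- function(st, t) {
  pool_ids <- if (is.null(st$pool)) integer(0) else st$pool$id
  drop_year <- t - 3L
  if (t == 3L) drop_year <- 0L   # founders no longer needed after year 3
  key <- as.character(drop_year)
  if (drop_year >= 0L && !is.null(st$cohort_haps[[key]])) {
    keep <- pool_ids[pool_ids %in% cohort_ids(st, drop_year)]
    for (id in keep)
      st$kept_haps[[as.character(id)]] <-
        get_haps(st, id)
    st$cohort_haps[[key]] <- NULL
  }
  st$kept_haps <- st$kept_haps[names(st$kept_haps) %in%
                                 as.character(pool_ids)]
  invisible(NULL)
}

record_accuracy_bias <- function(st, t) {
  u <- t - 3L
  rows <- seq_len(st$geno$n)
  sel <- rows[st$geno$birth_year[rows] == u & st$geno$env[rows] == "B"]
  gebv <- if (st$cfg$prop_C > 0) st$gebv_C[sel] else st$gebv_B[sel]
  tbv <- st$ped$tbv_C[st$geno$id[sel]]
  ab <- accuracy_and_bias(gebv, tbv)
  st$acc_bias[[as.character(t)]] <- c(accuracy = ab$accuracy,
                                      bias = ab$bias_slope)
  invisible(NULL)
}

#' Advance the breeding scheme by one year
#'
#' Runs one yearly cycle: in years 1-3 founder parents are drawn at random
#' (no genotyping, no GEBV); from year 4 on, the cohort born three years ago
#' is genotyped according to the scenario's strategies, all genotyped fish
#' are (re-)evaluated with GBLUP using the true variance components and all
#' records accumulated to date, accuracy/bias and the REML snapshot are
#' recorded when due, parents are selected, and the new cohort is born,
#' allocated to B/C and phenotyped on its placement schedule.
#'
#' @param st a `population_state` from [new_population_state()].
#' @param year the year to simulate (must be `st$year + 1`).
#' @return the state, invisibly.
#' @export
run_breeding_cycle <- function(st, year) {
  cfg <- st$cfg
  if (year != st$year + 1L) stop("years must be simulated in order")
  if (year <= 3L) {
    sires <- st$founder_males[seq.int((year - 1L) * cfg$n_sires + 1L,
                                      year * cfg$n_sires)]
    dams <- sample(st$founder_females, cfg$n_dams)
  } else {
    genotype_cohort(st, year)
    evaluate_population(st)
    if (year %in% cfg$eval_years) record_accuracy_bias(st, year)
    if (!is.na(cfg$reml_year) && year == cfg$reml_year) {
      n <- st$geno$n
      rec <- data.frame(animal = seq_len(n), env = st$geno$env[seq_len(n)],
                        year = st$geno$rec_year[seq_len(n)],
                        value = st$geno$value[seq_len(n)])
      st$reml <- estimate_varcomp_reml(rec,
                                       st$G[seq_len(n), seq_len(n),
                                            drop = FALSE])
    }
    sel <- select_parents(st, year)
    sires <- sel$sires
    dams <- sel$dams
  }
  make_births(st, year, sires, dams)
  prune_haplotypes(st, year)
  st$year <- year
  invisible(st)
}

#' Simulate a complete breeding scheme
#'
#' Runs one replicate of a scenario for `cfg$years` years and computes the
#' outcome measures: the yearly rate of genetic gain in the C trait, the
#' per-generation rate of pedigree inbreeding, the GEBV accuracy and
#' dispersion bias of the 3-year-old genotyped B fish averaged over the
#' evaluation years, and (when configured) the REML variance-component
#' snapshot.
#'
#' @param cfg a [scenario_config()] object.
#' @param master_seed integer master seed.
#' @param replicate replicate index.
#' @param keep_state return the final `population_state` as `$state`
#'   (memory-heavy; for inspection and tests).
#' @return list with `metrics` (one-row data.frame: `delta_G`,
#'   `delta_F_percent`, `accuracy`, `bias`), `series` (per-year mean C-trait
#'   TBV and mean inbreeding of the fish born that year), `acc_by_year`,
#'   `reml` and optionally `state`.
#' @export
simulate_scheme <- function(cfg, master_seed = 1L, replicate = 1L,
                            keep_state = FALSE) {
  st <- new_population_state(cfg, master_seed, replicate)
  for (t in seq_len(cfg$years)) run_breeding_cycle(st, t)

  ids <- seq_len(st$next_id - 1L)
  ped <- data.frame(id = ids, sire = st$ped$sire[ids], dam = st$ped$dam[ids],
                    birth_year = st$ped$birth_year[ids])
  ped$sire[ped$sire == 0L] <- NA_integer_
  ped$dam[ped$dam == 0L] <- NA_integer_
  F <- pedigree_inbreeding(ped)
  years <- seq_len(cfg$years)
  F_t <- vapply(years, function(t) mean(F[st$ped$birth_year[ids] == t]), 0)
  G_t <- st$series_G[years]

  delta_G <- if (all(c(cfg$gain_first, cfg$gain_last) <= cfg$years))
    rate_of_genetic_gain(setNames(G_t, years), cfg$gain_first, cfg$gain_last)
  else NA_real_
  f_years <- 5:min(21L, cfg$years)
  delta_F <- if (length(f_years) >= 2 && cfg$years >= 6)
    rate_of_inbreeding(setNames(F_t, years)[as.character(f_years)],
                       cfg$generation_interval)
  else NA_real_
  ab <- do.call(rbind, st$acc_bias)
  accuracy <- if (!is.null(ab)) mean(ab[, "accuracy"]) else NA_real_
  bias <- if (!is.null(ab)) mean(ab[, "bias"]) else NA_real_

  out <- list(metrics = data.frame(delta_G = delta_G,
                                   delta_F_percent = delta_F,
                                   accuracy = accuracy, bias = bias),
              series = data.frame(year = years, G_t = G_t, F_t = F_t),
              acc_by_year = ab, reml = st$reml)
  if (keep_state) out$state <- st
  out
}
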