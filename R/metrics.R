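#' Yearly rate of genetic gain
#'
#' Contrasts the mean C-trait TBV of the cohorts born in a late window
#' against an early window: `delta_G = (sum(G[last]) - sum(G[first])) /
#' (sum(last) - sum(first))`. With the default windows (years 5-7 vs 19-21)
#' the divisor is 42, and a linear trend `G_t = b * t` is recovered exactly
#' as `b`.
#'
#' @param series numeric vector of per-birth-year cohort means, named by
#'   year.
#' @param first_years,last_years the two year windows.
#' @return the rate of gain per year.
#' @examples
#' rate_of_genetic_gain(setNames(0.3 * (1:21), 1:21))  # 0.3
#' @export
rate_of_genetic_gain <- function(series, first_years = 5:7,
                                 last_years = 19:21) {
  yrs <- as.character(c(first_years, last_years))
  if (any(!yrs %in% names(series)))
    stop("series must cover both year windows")
  (sum(series[as.character(last_years)]) -
      sum(series[as.character(first_years)])) /
    (sum(last_years) - sum(first_years))
}

#' Pedigree inbreeding coefficients
#'
#' Wright's inbreeding coefficient of every individual from the full true
#' pedigree, via the Meuwissen-Luo tabular algorithm (compiled). Founders
#' (unknown parents) are treated as non-inbred and unrelated.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (NA or 0 =
#'   unknown) and optionally `birth_year` used for ordering checks.
#' @return numeric vector of inbreeding coefficients, named by id, in the
#'   input row order.
#' @examples
#' ped <- data.frame(id = 1:5, sire = c(NA, NA, 1, 1, 3),
#'                   dam = c(NA, NA, 2, 2, 4))
#' pedigree_inbreeding(ped)[["5"]]  # full-sib mating: 0.25
#' @export
pedigree_inbreeding <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  if (anyDuplicated(ped$id)) stop("duplicated ids in pedigree")
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  known_s <- !is.na(ped$sire) & !(ped$sire %in% c(0L))
  known_d <- !is.na(ped$dam) & !(ped$dam %in% c(0L))
  if (any(known_s & is.na(s)) || any(known_d & is.na(d)))
    stop("parent id missing from the pedigree")
  s[!known_s] <- 0L
  d[!known_d] <- 0L
  row <- seq_len(n)
  if (any(s >= row, na.rm = TRUE) || any(d >= row, na.rm = TRUE))
    stop("pedigree must list parents before offspring (no cycles)")
  setNames(inbreeding_ml(as.integer(s), as.integer(d)), ped$id)
}

#' Per-generation rate of inbreeding
#'
#' Regresses `log(1 - F_t)` on generation number (`t / generation_interval`)
#' and returns `delta_F (%) = (1 - exp(beta)) * 100` where `beta` is the
#' regression slope. A constant series gives 0.
#'
#' @param F_series mean inbreeding per birth year, named by year (the study
#'   design regresses over years 5-21).
#' @param generation_interval years per generation (3 in this design: the
#'   candidate age at selection).
#' @return rate of inbreeding in percent per generation.
#' @examples
#' f <- 1 - (1 - 0.01)^((5:21) / 3)
#' rate_of_inbreeding(setNames(f, 5:21))  # 1
#' @export
rate_of_inbreeding <- function(F_series, generation_interval = 3) {
  if (any(F_series >= 1)) stop("inbreeding coefficients must be below 1")
  gen <- as.numeric(names(F_series)) / generation_interval
  y <- log(1 - F_series)
  if (var(y) == 0) return(0)
  beta <- coef(lm(y ~ gen))[["gen"]]
  (1 - exp(beta)) * 100
}

#' GEBV accuracy and dispersion bias
#'
#' Accuracy is the Pearson correlation between GEBV and the C-trait TBV;
#' dispersion bias is the slope of the regression of TBV on GEBV (slope < 1:
#' inflated/over-dispersed predictions; > 1: deflated). With C records in the
#' model both have expectation 1; without, selection uses the B-trait GEBV
#' and accuracy has expectation `r_g` (see [expected_bias()] for the slope).
#'
#' @param gebv,tbv numeric vectors (the same fish).
#' @param year optional grouping vector; statistics are computed per year
#'   and averaged, as in the study design (years 10-12).
#' @return list with `accuracy` and `bias_slope` (NA with a warning if the
#'   GEBV have zero variance).
#' @examples
#' accuracy_and_bias(gebv = c(1, 2, 3), tbv = c(2, 4, 6))  # acc 1, slope 2
#' @export
accuracy_and_bias <- function(gebv, tbv, year = NULL) {
  one <- function(g, v) {
    if (length(g) < 2 || sd(g) == 0 || sd(v) == 0) {
      warning("zero-variance GEBV or TBV: accuracy/bias undefined")
      return(c(NA_real_, NA_real_))
    }
    c(cor(g, v), sum((g - mean(g)) * (v - mean(v))) / sum((g - mean(g))^2))
  }
  if (is.null(year)) {
    r <- one(gebv, tbv)
  } else {
    r <- rowMeans(vapply(unique(year),
                         function(t) one(gebv[year == t], tbv[year == t]),
                         numeric(2)))
  }
  list(accuracy = r[1], bias_slope = r[2])
}

#' Aggregate per-replicate metrics
#'
#' Means and standard errors over replicates (`SE = sd / sqrt(n)`), plus the
#' ratio of the mean rate of gain to the mean rate of inbreeding when both
#' are present.
#'
#' @param reps data.frame with one row per replicate and one column per
#'   metric.
#' @return data.frame with columns `metric`, `mean`, `se`, `n`; the
#'   `delta_G / delta_F` ratio of means is attached as attribute `gain_per_F`
#'   when computable.
#' @export
summarize_replicates <- function(reps) {
  if (nrow(reps) < 2) stop("need at least 2 replicates to summarize")
  num <- reps[vapply(reps, is.numeric, TRUE)]
  out <- data.frame(metric = names(num),
                    mean = vapply(num, mean, 0, na.rm = TRUE),
                    se = vapply(num, function(x)
                      sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))), 0),
                    n = vapply(num, function(x) sum(!is.na(x)), 0L),
                    row.names = NULL)
  if (all(c("delta_G", "delta_F_percent") %in% out$metric)) {
    dG <- out$mean[out$metric == "delta_G"]
    dF <- out$mean[out$metric == "delta_F_percent"]
    if (is.finite(dG) && is.finite(dF) && dF != 0)
      attr(out, "gain_per_F") <- dG / dF
  }
  out
}

#' Expected number of repeat dams in consecutive years
#'
#' When `n_dams` dams are drawn uniformly each year from a pool of `n_pool`
#' females of which the `n_new` current-year intake is retained to the next
#' year, a year-t dam reappears as a dam in year t+1 with probability
#' (intake share) x (redraw probability), giving
#' `n_dams * (n_new / n_pool) * (n_dams / n_pool)` repeat dams in
#' expectation — 3.125 at the full scale of the design (50 dams, 400-female
#' pool, 200 retained).
#'
#' @param n_dams dams drawn per year.
#' @param n_pool females available per year.
#' @param n_new newly selected females per year (all retained under 100%
#'   retention).
#' @return expected number of females serving as dams in both years.
#' @examples
#' expected_repeat_dams(50, 400, 200)  # 3.125
#' @export
expected_repeat_dams <- function(n_dams = 50, n_pool = 400, n_new = 200) {
  n_dams * (n_new / n_pool) * (n_dams / n_pool)
}

#' Monte Carlo check of the repeat-dam expectation
#'
#' Simulates the retention/dam-draw scheme: year-t dams drawn from a pool in
#' which `n_new` females are new (and retained), year-t+1 dams drawn from the
#' retained females plus a fresh intake.
#'
#' @inheritParams expected_repeat_dams
#' @param n_sims number of simulated year pairs.
#' @return mean number of repeat dams over the simulations.
#' @export
repeat_dams_mc <- function(n_dams = 50, n_pool = 400, n_new = 200,
                           n_sims = 10000) {
  mean(vapply(seq_len(n_sims), function(i) {
    dams1 <- sample.int(n_pool, n_dams)          # pool: 1..n_new are new
    retained <- seq_len(n_new)                   # kept to next year
    dams2 <- sample.int(n_pool, n_dams)          # next pool: 1..n_new = kept
    length(intersect(intersect(dams1, retained), dams2))
  }, 0))
}

#' Expected cross-year relationship through repeat dams
#'
#' The additive relationship between a current-year offspring and the
#' previous-year offspring of its dam is 0.25 (maternal half sibs, non-inbred
#' unrelated parents). Weighting by the probability that a random
#' current-year offspring's dam also served the previous year
#' (`expected_repeat_dams / n_dams`) gives the expected relationship tying
#' consecutive year classes together — 0.015625 at full scale.
#'
#' @inheritParams expected_repeat_dams
#' @return the expected additive relationship.
#' @examples
#' cross_year_relationship(50, 400, 200)  # 0.015625
#' @export
cross_year_relationship <- function(n_dams = 50, n_pool = 400, n_new = 200) {
  (expected_repeat_dams(n_dams, n_pool, n_new) / n_dams) * 0.25
}
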