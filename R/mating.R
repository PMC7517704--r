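#' Partly factorial mating design
#'
#' Pairs equal numbers of sires and dams so that every sire is mated to two
#' different dams and every dam to two different sires, with the pairing
#' otherwise random. Relative to pair mating this doubles the number of
#' families connecting the parents (2n full-sib families from n + n parents).
#'
#' @param sires,dams vectors of parent ids (equal length, >= 2, no overlap
#'   between the two sets is checked by the caller).
#' @return data.frame with columns `sire`, `dam`; `2 n` rows, each parent id
#'   appearing exactly twice, the two mates of each parent distinct.
#' @examples
#' m <- partly_factorial_matings(1:3, 4:6)
#' table(m$sire); table(m$dam)
#' @export
partly_factorial_matings <- function(sires, dams) {
  n <- length(sires)
  if (length(dams) != n) stop("equal numbers of sires and dams required")
  if (n < 2) stop("the two-partner constraint needs at least 2 sires and 2 dams")
  if (anyDuplicated(sires) || anyDuplicated(dams))
    stop("parent ids must be unique within sex")
  round1 <- sample(dams)
  # second round: a random derangement of the first, so each sire's two dams
  # (and symmetrically each dam's two sires) are distinct
  repeat {
    s <- sample.int(n)
    if (!any(s == seq_len(n))) break
  }
  data.frame(sire = c(sires, sires), dam = c(round1, round1[s]))
}

#' Allocate offspring to environments and sexes
#'
#' Splits a cohort between the breeding environment (B) and the commercial
#' environment (C): `round(prop_C * n)` fish go to C, chosen at random across
#' the cohort (so family-wise C fractions match `prop_C` on average), the
#' rest stay in B. Sexes are then assigned with exact counts per environment;
#' sex-reversal technology makes any B sex ratio feasible in practice.
#'
#' @param n cohort size.
#' @param prop_C proportion of offspring (and of genotyping) allocated to C,
#'   `0 <= prop_C < 1`.
#' @param male_fraction_B fraction of B fish that are male.
#' @param male_fraction_C fraction of C fish that are male.
#' @return data.frame with columns `env` (`"B"`/`"C"`) and `sex`
#'   (`"M"`/`"F"`), one row per fish in cohort order.
#' @export
allocate_offspring <- function(n, prop_C, male_fraction_B = 0.5,
                               male_fraction_C = 0.5) {
  if (prop_C < 0 || prop_C >= 1) stop("prop_C must be in [0, 1)")
  n_C <- round(prop_C * n)
  env <- rep("B", n)
  if (n_C > 0) env[sample.int(n, n_C)] <- "C"
  sex <- rep("F", n)
  iB <- which(env == "B"); iC <- which(env == "C")
  nmB <- round(male_fraction_B * length(iB))
  nmC <- round(male_fraction_C * length(iC))
  if (nmB > 0) sex[sample(iB, nmB)] <- "M"
  if (nmC > 0) sex[sample(iC, nmC)] <- "M"
  data.frame(env = env, sex = sex)
}
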