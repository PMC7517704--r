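#' Assign a two-environment trait architecture
#'
#' Splits the loci of a map into a QTL set (chosen uniformly without
#' replacement) and the complementary marker set, and gives each QTL an
#' additive effect pair — one effect for the trait expressed in the breeding
#' environment (B), one for the commercial environment (C). The trait in B and
#' the trait in C are modelled as two genetically correlated traits fully
#' controlled by the shared QTL; the genetic correlation `r_g` parameterizes
#' the strength of genotype-by-environment re-ranking.
#'
#' Effects are drawn as independent normals and then linearly recombined so
#' that, in the supplied founder population, the realized genetic variance of
#' each trait is exactly 1 and the realized correlation between the two
#' founder true-breeding-value vectors is exactly `r_g`. The residual variance
#' per environment is `(1 - h2) / h2`, so founder phenotypic variance is
#' `1/h2` and heritability is `h2` in both environments.
#'
#' @param map a [build_genetic_map()] object.
#' @param founders a [generate_founder_population()] object on the same map.
#' @param n_qtl number of QTL (< number of loci).
#' @param r_g genetic correlation between the B- and C-expressed trait,
#'   `|r_g| <= 1`.
#' @param h2 heritability of the trait in both environments, in (0, 1).
#' @param seed optional integer seed.
#' @return an object of class `trait_architecture`: list with `qtl` and
#'   `markers` (locus indices), `effects` (`n_qtl x 2`, columns B and C),
#'   `founder_mean` (length-2 centering constants), `r_g`, `h2`, `sigma_e2`
#'   and `varcomp_true` (the simulated variance components, see
#'   [variance_components()]).
#' @examples
#' map <- build_genetic_map(1, 100, 60, seed = 1)
#' fp <- generate_founder_population(100, map, seed = 2)
#' arch <- assign_trait_architecture(map, fp, 10, r_g = 0.5, h2 = 0.3, seed = 3)
#' length(arch$markers)  # 50
#' @export
assign_trait_architecture <- function(map, founders, n_qtl, r_g, h2,
                                      seed = NULL) {
  L <- map$n_loci
  if (n_qtl >= L || n_qtl < 1) stop("need 1 <= n_qtl < n_loci")
  if (abs(r_g) > 1) stop("|r_g| must not exceed 1")
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  qtl <- sort(sample.int(L, n_qtl))
  markers <- setdiff(seq_len(L), qtl)
  a_raw <- matrix(rnorm(2L * n_qtl), n_qtl, 2L)
  D <- t(dosage_from_haps(founders$haps)[qtl, , drop = FALSE])  # founders x QTL
  t_raw <- D %*% a_raw
  # recombine the two effect columns so the founder TBVs realize var = 1 for
  # both traits and correlation exactly r_g (TBVs are linear in the effects,
  # so the same recombination applies to the effect columns)
  t1 <- t_raw[, 1L] - mean(t_raw[, 1L])
  s1 <- sd(t1)
  if (s1 == 0) stop("degenerate founder variation at the sampled QTL")
  b1 <- a_raw[, 1L] / s1
  beta <- sum(t1 * (t_raw[, 2L] - mean(t_raw[, 2L]))) / sum(t1 * t1)
  e <- (t_raw[, 2L] - mean(t_raw[, 2L])) - beta * t1
  se <- sd(e)
  if (se == 0) stop("founder TBVs for the two traits are collinear; cannot realize r_g")
  be <- (a_raw[, 2L] - beta * a_raw[, 1L]) / se
  effects <- cbind(B = b1, C = r_g * b1 + sqrt(1 - r_g^2) * be)
  founder_mean <- colMeans(D %*% effects)
  structure(list(qtl = qtl, markers = markers, effects = effects,
                 founder_mean = setNames(founder_mean, c("B", "C")),
                 r_g = r_g, h2 = h2, sigma_e2 = (1 - h2) / h2,
                 varcomp_true = variance_components(1, 1, r_g,
                                                   (1 - h2) / h2,
                                                   (1 - h2) / h2)),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("trait_architecture:", length(x$qtl), "QTL /", length(x$markers),
      sprintf("markers; r_g = %.2f, h2 = %.2f, sigma_e2 = %.3f\n",
              x$r_g, x$h2, x$sigma_e2))
  invisible(x)
}

#' Variance components of the bivariate model
#'
#' Container for the five (co)variance components of the two-environment
#' animal model: additive genetic variances in B and C, their covariance and
#' the residual variances. Used both for the simulated ("true") values that
#' drive GBLUP prediction and for REML estimates.
#'
#' @param sigma2_gB,sigma2_gC additive genetic variances.
#' @param sigma_gBgC additive genetic covariance.
#' @param sigma2_eB,sigma2_eC residual variances (must be positive).
#' @return an object of class `variance_components` (a named list).
#' @export
variance_components <- function(sigma2_gB, sigma2_gC, sigma_gBgC,
                                sigma2_eB, sigma2_eC) {
  if (sigma2_eB <= 0 || sigma2_eC <= 0) stop("residual variances must be positive")
  S <- matrix(c(sigma2_gB, sigma_gBgC, sigma_gBgC, sigma2_gC), 2L, 2L)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("genetic covariance matrix must be positive semi-definite")
  structure(list(sigma2_gB = sigma2_gB, sigma2_gC = sigma2_gC,
                 sigma_gBgC = sigma_gBgC, sigma2_eB = sigma2_eB,
                 sigma2_eC = sigma2_eC),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components: gB %.3f gC %.3f gBgC %.3f eB %.3f eC %.3f\n",
              x$sigma2_gB, x$sigma2_gC, x$sigma_gBgC, x$sigma2_eB, x$sigma2_eC))
  invisible(x)
}

#' True breeding values of one individual
#'
#' The TBV of each trait is the sum over QTL of the allele count times that
#' trait's effect, centered on the founder mean.
#'
#' @param haps `n_loci x 2` haplotype matrix of the individual.
#' @param arch an [assign_trait_architecture()] object.
#' @return named numeric vector `c(tbv_B, tbv_C)`.
#' @export
true_breeding_values <- function(haps, arch) {
  dos <- haps[arch$qtl, 1L] + haps[arch$qtl, 2L]
  tbv <- drop(crossprod(arch$effects, dos)) - arch$founder_mean
  setNames(as.numeric(tbv), c("tbv_B", "tbv_C"))
}

# Vectorized TBV for a cohort: haps is n_loci x 2N (column pairs = fish).
tbv_batch <- function(haps, arch) {
  dosQ <- dosage_from_haps(haps[arch$qtl, , drop = FALSE])
  tbv <- crossprod(dosQ, arch$effects)
  sweep(tbv, 2L, arch$founder_mean)
}

#' Simulate phenotypes
#'
#' Each fish expresses the trait of the environment it was placed in:
#' phenotype = TBV of that trait + Normal(0, sigma_e2) residual. Fixed year
#' effects are simulated as zero (the evaluation model still fits them).
#' Unplaced fish cannot be phenotyped.
#'
#' @param tbv_B,tbv_C numeric vectors of true breeding values.
#' @param env character vector, `"B"` or `"C"` per fish.
#' @param arch an [assign_trait_architecture()] object (supplies `sigma_e2`).
#' @return numeric vector of phenotypes.
#' @export
simulate_phenotype <- function(tbv_B, tbv_C, env, arch) {
  if (any(!env %in% c("B", "C")))
    stop("every phenotyped fish must be placed in B or C")
  n <- length(env)
  tbv <- ifelse(env == "B", tbv_B, tbv_C)
  tbv + rnorm(n, 0, sqrt(arch$sigma_e2))
}
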