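# GBLUP with year fixed effects, solved in observation space.
#
# Every genotyped fish carries exactly one record, so the phenotypic
# covariance matrix V = S[env_i, env_j] * G[a_i, a_j] + diag(residual) is
# n x n and the BLUP g_hat = Cov(g, y) V^{-1} (y - X b_hat) with b_hat the
# GLS fixed-effect solution is identical to the solution of Henderson's
# mixed-model equations (verified against a dense MME oracle in the tests).

#' Solve the bivariate GBLUP model
#'
#' Fits the two-environment animal model: records measured in the breeding
#' environment (B) and the commercial environment (C) are modelled as two
#' genetically correlated traits with fixed year effects per environment,
#' genetic covariance `G (x) S` (Kronecker; `S` the 2x2 genetic covariance
#' matrix) and heterogeneous diagonal residuals. Fish in C act as the
#' reference population: candidates kept in B receive a C-trait GEBV through
#' the genomic relationships and the genetic covariance even though they have
#' no C record of their own.
#'
#' @param records data.frame with columns `animal` (row index into `G`),
#'   `env` (`"B"`/`"C"`), `year` and `value`; at most one record per animal.
#' @param G genomic relationship matrix over all genotyped animals (rows
#'   indexed by `animal`); animals without records still receive GEBVs.
#' @param varcomp a [variance_components()] object (inside the breeding loop
#'   the simulator passes the true components).
#' @return data.frame with one row per animal in `G`: `animal`, `gebv_B`,
#'   `gebv_C`. Attribute `fixed` holds the estimated year effects.
#' @export
solve_bivariate_gblup <- function(records, G, varcomp) {
  stopifnot(all(c("animal", "env", "year", "value") %in% names(records)))
  if (anyDuplicated(records$animal))
    stop("at most one record per animal is supported")
  if (any(!records$env %in% c("B", "C")))
    stop("records must be measured in B or C")
  S <- matrix(c(varcomp$sigma2_gB, varcomp$sigma_gBgC,
                varcomp$sigma_gBgC, varcomp$sigma2_gC), 2L, 2L)
  ei <- ifelse(records$env == "B", 1L, 2L)
  re <- c(varcomp$sigma2_eB, varcomp$sigma2_eC)[ei]
  sol <- gls_blup_core(records$value, records$animal, ei, re, S, G,
                       classes = paste(records$env, records$year, sep = ":"))
  out <- data.frame(animal = seq_len(nrow(G)),
                    gebv_B = sol$gebv[, 1L], gebv_C = sol$gebv[, 2L])
  attr(out, "fixed") <- sol$fixed
  out
}

#' Solve the univariate GBLUP model
#'
#' Single-trait animal model with year fixed effects, used for scenarios with
#' no records in the commercial environment (selection is then on the GEBV of
#' the B trait only).
#'
#' @param records data.frame with columns `animal`, `year`, `value`.
#' @param G genomic relationship matrix.
#' @param varcomp list or [variance_components()]; `sigma2_gB`/`sigma2_eB`
#'   (or `sigma2_g`/`sigma2_e`) are used.
#' @return data.frame with `animal`, `gebv` for every animal in `G`;
#'   attribute `fixed` as in [solve_bivariate_gblup()].
#' @export
solve_univariate_gblup <- function(records, G, varcomp) {
  stopifnot(all(c("animal", "year", "value") %in% names(records)))
  if (anyDuplicated(records$animal))
    stop("at most one record per animal is supported")
  s2g <- if (!is.null(varcomp$sigma2_g)) varcomp$sigma2_g else varcomp$sigma2_gB
  s2e <- if (!is.null(varcomp$sigma2_e)) varcomp$sigma2_e else varcomp$sigma2_eB
  sol <- gls_blup_core(records$value, records$animal,
                       rep(1L, nrow(records)), rep(s2e, nrow(records)),
                       matrix(s2g, 1L, 1L), G,
                       classes = paste0("y", records$year))
  out <- data.frame(animal = seq_len(nrow(G)), gebv = sol$gebv[, 1L])
  attr(out, "fixed") <- sol$fixed
  out
}

# y: records; anim: animal index per record; ei: trait index per record;
# re: residual variance per record; S: t x t genetic covariance; G: relation
# matrix; classes: fixed-effect class labels per record.
# indicator matrix of fixed-effect classes (robust to a single class)
class_dummies <- function(labels) {
  f <- factor(labels)
  X <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  X[cbind(seq_along(f), as.integer(f))] <- 1
  X
}

gls_blup_core <- function(y, anim, ei, re, S, G, classes) {
  n <- length(y)
  f <- factor(classes)
  X <- class_dummies(classes)
  Gaa <- G[anim, anim, drop = FALSE]
  V <- Gaa * S[ei, ei, drop = FALSE]
  diag(V) <- diag(V) + re
  cV <- tryCatch(chol(V), error = function(e) {
    # near-singular relationship block: small ridge, reported via attribute
    chol(V + diag(1e-6 * mean(diag(V)), n))
  })
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, Vi_X)
  b <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% b
  w <- backsolve(cV, forwardsolve(t(cV), r))
  # gebv_t(i) = sum_j G[i, a_j] S[t, e_j] w_j
  t_dim <- nrow(S)
  gebv <- matrix(0, nrow(G), t_dim)
  for (t in seq_len(t_dim))
    gebv[, t] <- G[, anim, drop = FALSE] %*% (S[t, ei] * w)
  list(gebv = gebv, fixed = setNames(as.numeric(b), levels(f)))
}

#' Expected dispersion bias of GEBV
#'
#' Large-sample expectation of the regression slope of the C-trait TBV on the
#' GEBV used for selection. With C records in the model the slope has
#' expectation 1. Without C records selection uses the B-trait GEBV and the
#' expectation is `r_g * sqrt(sigma2_gC / sigma2_gB)`, which reduces to `r_g`
#' when the two genetic variances are equal.
#'
#' @param r_g genetic correlation between the B- and C-expressed traits.
#' @param varcomp a [variance_components()] object.
#' @param has_C_records logical; does the evaluation include C records?
#' @return the expected regression slope.
#' @examples
#' expected_bias(0.5, variance_components(1, 1, 0.5, 2, 2), FALSE)  # 0.5
#' @export
expected_bias <- function(r_g, varcomp, has_C_records) {
  if (has_C_records) 1 else r_g * sqrt(varcomp$sigma2_gC / varcomp$sigma2_gB)
}
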