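# Restricted maximum likelihood for the one- and two-environment animal
# model, using average-information (AI) updates computed in observation
# space. With one record per genotyped animal the phenotypic covariance is
#   V = S[env_i, env_j] * G[a_i, a_j] + diag(residual),
# and the REML log-likelihood, score and AI matrix only need V^{-1} and the
# projection P = V^{-1} - V^{-1} X (X'V^{-1}X)^{-1} X'V^{-1}.

#' Estimate variance components by REML
#'
#' AI-REML for the bivariate (records in both environments) or univariate
#' model with year fixed effects. Updates are guarded: the 2x2 genetic
#' covariance matrix is bent to the nearest positive semi-definite matrix
#' when an update leaves the parameter space, residual variances are kept
#' positive, and steps are halved when the restricted likelihood would
#' decrease. Convergence is declared when the largest relative parameter
#' change drops below `tol`.
#'
#' @param records data.frame with columns `animal`, `env` (`"B"`/`"C"`),
#'   `year`, `value`; one record per animal. A single-environment data.frame
#'   triggers the univariate model.
#' @param G genomic relationship matrix covering all record animals.
#' @param init optional numeric vector of starting values
#'   (`sigma2_gB, sigma2_gC, sigma_gBgC, sigma2_eB, sigma2_eC`, or
#'   `sigma2_g, sigma2_e` for the univariate model).
#' @param tol relative-change convergence tolerance.
#' @param max_iter maximum AI iterations; non-convergence is reported, not an
#'   error.
#' @return list with `varcomp` (a [variance_components()] object, or a list
#'   `sigma2_g`/`sigma2_e` for the univariate model), `h2_B`/`h2_C`
#'   (heritability estimates), `loglik`, `iterations`, `converged` and
#'   `bent` (number of PSD bends applied).
#' @export
estimate_varcomp_reml <- function(records, G, init = NULL, tol = 1e-6,
                                  max_iter = 200L) {
  stopifnot(all(c("animal", "year", "value") %in% names(records)))
  if (is.null(records$env)) records$env <- "B"
  envs <- sort(unique(records$env))
  bivar <- length(envs) == 2L
  y <- records$value
  n <- length(y)
  anim <- records$animal
  ei <- if (bivar) ifelse(records$env == "B", 1L, 2L) else rep(1L, n)
  X <- class_dummies(paste(records$env, records$year))
  Gaa <- G[anim, anim, drop = FALSE]
  i1 <- which(ei == 1L); i2 <- which(ei == 2L)
  G11 <- Gaa[i1, i1, drop = FALSE]
  G22 <- Gaa[i2, i2, drop = FALSE]
  G12 <- Gaa[i1, i2, drop = FALSE]

  # starting values: split the within-class variance half genetic, half residual
  cls <- as.integer(factor(paste(records$env, records$year)))
  r0 <- y - ave(y, cls)
  vW <- vapply(seq_along(envs), function(k) {
    v <- var(r0[ei == k]); if (!is.finite(v) || v <= 0) 1 else v
  }, 0)
  theta <- if (!is.null(init)) as.numeric(init)
  else if (bivar) c(vW[1] / 2, vW[2] / 2, 0, vW[1] / 2, vW[2] / 2)
  else c(vW[1] / 2, vW[1] / 2)
  p_gen <- if (bivar) 3L else 1L   # leading genetic parameters
  floor_e <- 1e-8 * max(vW)
  bent <- 0L

  sanitize <- function(th) {
    if (bivar) {
      Sg <- matrix(c(th[1], th[3], th[3], th[2]), 2L, 2L)
      es <- eigen(Sg, symmetric = TRUE)
      if (min(es$values) < 1e-8 * max(abs(es$values), 1)) {
        bent <<- bent + 1L
        ev <- pmax(es$values, 1e-6 * max(abs(es$values), 1e-3))
        Sg <- es$vectors %*% (ev * t(es$vectors))
        th[1:3] <- c(Sg[1, 1], Sg[2, 2], Sg[1, 2])
      }
      th[4:5] <- pmax(th[4:5], floor_e)
    } else {
      th[1] <- max(th[1], 0)
      th[2] <- max(th[2], floor_e)
    }
    th
  }

  build_V <- function(th) {
    if (bivar) {
      S <- matrix(c(th[1], th[3], th[3], th[2]), 2L, 2L)
      V <- Gaa * S[ei, ei]
      diag(V) <- diag(V) + c(th[4], th[5])[ei]
    } else {
      V <- Gaa * th[1]
      diag(V) <- diag(V) + th[2]
    }
    V
  }

  eval_point <- function(th) {
    V <- build_V(th)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vi <- chol2inv(cV)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    cX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cX)) return(NULL)
    P <- Vi - ViX %*% chol2inv(cX) %*% t(ViX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
                    sum(y * Py))
    list(P = P, Py = Py, loglik = ll)
  }

  # A_k %*% v for each variance parameter's derivative matrix
  Amul <- function(k, v) {
    u <- numeric(n)
    if (bivar) {
      switch(k,
             u[i1] <- G11 %*% v[i1],
             u[i2] <- G22 %*% v[i2],
             { u[i1] <- G12 %*% v[i2]; u[i2] <- crossprod(G12, v[i1]) },
             u[i1] <- v[i1],
             u[i2] <- v[i2])
    } else {
      if (k == 1L) u <- drop(Gaa %*% v) else u <- v
    }
    u
  }
  traces <- function(P) {
    if (bivar) c(sum(P[i1, i1] * G11), sum(P[i2, i2] * G22),
                 2 * sum(P[i1, i2] * G12), sum(diag(P)[i1]),
                 sum(diag(P)[i2]))
    else c(sum(P * Gaa), sum(diag(P)))
  }

  theta <- sanitize(theta)
  cur <- eval_point(theta)
  if (is.null(cur)) stop("REML could not evaluate the starting point")
  npar <- length(theta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    q <- vapply(seq_len(npar), function(k) Amul(k, cur$Py), numeric(n))
    score <- -0.5 * (traces(cur$P) - colSums(cur$Py * q))
    Pq <- cur$P %*% q
    AI <- 0.5 * crossprod(q, Pq)
    delta_ai <- drop(tryCatch(solve(AI, score),
                              error = function(e) MASS::ginv(AI) %*% score))
    # guard against boundary overshoot: cap the relative step
    cap <- max(abs(delta_ai) / (abs(theta) + 1e-2))
    if (is.finite(cap) && cap > 5) delta_ai <- delta_ai * (5 / cap)
    # fallback: scaled gradient ascent when the AI direction is unusable
    delta_gr <- score / (abs(diag(AI)) + 1e-8)
    capg <- max(abs(delta_gr) / (abs(theta) + 1e-2))
    if (is.finite(capg) && capg > 1) delta_gr <- delta_gr / capg
    accepted <- FALSE
    for (delta in list(delta_ai, delta_gr)) {
      step <- 1
      for (h in seq_len(12L)) {
        cand <- sanitize(theta + step * delta)
        ev <- eval_point(cand)
        if (!is.null(ev) && ev$loglik > cur$loglik + 1e-10) {
          rel <- max(abs(cand - theta) / (abs(theta) + 1e-3))
          theta <- cand
          cur <- ev
          accepted <- TRUE
          if (rel < tol) converged <- TRUE
          break
        }
        step <- step / 2
      }
      if (accepted) break
    }
    if (!accepted || converged) {
      if (!accepted) converged <- TRUE  # no uphill step left: at the optimum
      break
    }
  }

  if (bivar) {
    vc <- variance_components(theta[1], theta[2], theta[3], theta[4], theta[5])
    list(varcomp = vc,
         h2_B = theta[1] / (theta[1] + theta[4]),
         h2_C = theta[2] / (theta[2] + theta[5]),
         loglik = cur$loglik, iterations = iter, converged = converged,
         bent = bent)
  } else {
    list(varcomp = list(sigma2_g = theta[1], sigma2_e = theta[2]),
         h2_B = theta[1] / (theta[1] + theta[2]), h2_C = NA_real_,
         loglik = cur$loglik, iterations = iter, converged = converged,
         bent = bent)
  }
}

#' Restricted log-likelihood of a variance-component setting
#'
#' Evaluates the REML log-likelihood of the (bi)variate model at fixed
#' variance components; useful for checking that the fitted maximum dominates
#' perturbed settings.
#'
#' @inheritParams estimate_varcomp_reml
#' @param varcomp a [variance_components()] object or univariate list.
#' @return the restricted log-likelihood (a scalar).
#' @export
reml_loglik <- function(records, G, varcomp) {
  if (is.null(records$env)) records$env <- "B"
  bivar <- length(unique(records$env)) == 2L
  th <- if (bivar) c(varcomp$sigma2_gB, varcomp$sigma2_gC,
                     varcomp$sigma_gBgC, varcomp$sigma2_eB,
                     varcomp$sigma2_eC)
  else c(if (!is.null(varcomp$sigma2_g)) varcomp$sigma2_g else varcomp$sigma2_gB,
         if (!is.null(varcomp$sigma2_e)) varcomp$sigma2_e else varcomp$sigma2_eB)
  y <- records$value
  anim <- records$animal
  ei <- if (bivar) ifelse(records$env == "B", 1L, 2L) else rep(1L, length(y))
  X <- class_dummies(paste(records$env, records$year))
  Gaa <- G[anim, anim, drop = FALSE]
  if (bivar) {
    S <- matrix(c(th[1], th[3], th[3], th[2]), 2L, 2L)
    V <- Gaa * S[ei, ei]
    diag(V) <- diag(V) + c(th[4], th[5])[ei]
  } else {
    V <- Gaa * th[1]
    diag(V) <- diag(V) + th[2]
  }
  cV <- chol(V)
  Vi <- chol2inv(cV)
  ViX <- Vi %*% X
  cX <- chol(crossprod(X, ViX))
  P <- Vi - ViX %*% chol2inv(cX) %*% t(ViX)
  -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
            sum(y * drop(P %*% y)))
}
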