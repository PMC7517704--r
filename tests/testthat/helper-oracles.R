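# Independent oracles used across the suite. These deliberately re-derive
# results by a different route than the package code.

# Dense mixed-model-equation oracle for GBLUP. Builds Henderson's MME with an
# explicit G-inverse and solves by dense inversion. Supports one record per
# animal, bivariate (env "B"/"C") or univariate input.
mme_oracle <- function(records, G, varcomp) {
  n_anim <- nrow(G)
  bivar <- !is.null(records$env) && length(unique(records$env)) > 1
  if (is.null(records$env)) records$env <- "B"
  cls <- factor(paste(records$env, records$year))
  X <- matrix(0, nrow(records), nlevels(cls))
  X[cbind(seq_len(nrow(records)), as.integer(cls))] <- 1
  nrec <- nrow(records)
  if (bivar) {
    Tg <- matrix(c(varcomp$sigma2_gB, varcomp$sigma_gBgC,
                   varcomp$sigma_gBgC, varcomp$sigma2_gC), 2, 2)
    Z <- matrix(0, nrec, 2 * n_anim)
    for (r in seq_len(nrec)) {
      off <- if (records$env[r] == "B") 0 else n_anim
      Z[r, off + records$animal[r]] <- 1
    }
    Rinv <- diag(1 / ifelse(records$env == "B", varcomp$sigma2_eB,
                            varcomp$sigma2_eC))
    Ginv_big <- kronecker(solve(Tg), solve(G))
  } else {
    s2g <- if (!is.null(varcomp$sigma2_g)) varcomp$sigma2_g else varcomp$sigma2_gB
    s2e <- if (!is.null(varcomp$sigma2_e)) varcomp$sigma2_e else varcomp$sigma2_eB
    Z <- matrix(0, nrec, n_anim)
    Z[cbind(seq_len(nrec), records$animal)] <- 1
    Rinv <- diag(rep(1 / s2e, nrec))
    Ginv_big <- solve(G) / s2g
  }
  C11 <- t(X) %*% Rinv %*% X
  C12 <- t(X) %*% Rinv %*% Z
  C22 <- t(Z) %*% Rinv %*% Z + Ginv_big
  C <- rbind(cbind(C11, C12), cbind(t(C12), C22))
  rhs <- rbind(t(X) %*% Rinv %*% records$value,
               t(Z) %*% Rinv %*% records$value)
  sol <- solve(C, rhs)
  u <- sol[-(seq_len(ncol(X))), 1]
  if (bivar) list(gebv_B = u[seq_len(n_anim)],
                  gebv_C = u[n_anim + seq_len(n_anim)])
  else list(gebv = u)
}

# Recursive kinship oracle (tabular-free): f(i, j) by the classic recursion,
# F_i = f(sire_i, dam_i). Pedigree as vectors with 0 = unknown; parents must
# have smaller indices.
kinship_oracle <- function(sire, dam) {
  f <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i == j) return(0.5 * (1 + f(sire[i], dam[i])))
    if (i > j) { k <- i; i <- j; j <- k }
    0.5 * (f(i, sire[j]) + f(i, dam[j]))
  }
  vapply(seq_along(sire), function(i) f(sire[i], dam[i]), 0)
}

# random positive-definite relationship-like matrix
random_pd_matrix <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(rnorm(n * 3 * n), n)
  G <- tcrossprod(M) / (3 * n)
  G + diag(0.05, n)
}

tiny_map <- function(n_loci = 60, n_chr = 2, len = 200, seed = 11) {
  build_genetic_map(n_chr, len, n_loci, seed = seed)
}

# toy record set for the bivariate mixed-model checks
toy_bivar <- function(n_anim = 12, n_B = 7, seed = 71) {
  set.seed(seed)
  G <- random_pd_matrix(n_anim)
  rec <- data.frame(animal = seq_len(n_anim),
                    env = rep(c("B", "C"), c(n_B, n_anim - n_B)),
                    year = rep(c(10, 11), length.out = n_anim),
                    value = rnorm(n_anim, 5))
  vc <- variance_components(1.2, 0.8, 0.4, 2.0, 1.5)
  list(rec = rec, G = G, vc = vc)
}

# simulate one-record-per-animal data under the bivariate animal model
simulate_model_data <- function(G, vc, n_B, seed) {
  set.seed(seed)
  n <- nrow(G)
  Tg <- matrix(c(vc$sigma2_gB, vc$sigma_gBgC, vc$sigma_gBgC, vc$sigma2_gC),
               2, 2)
  cG <- chol(G)
  g <- t(cG) %*% matrix(rnorm(2 * n), n, 2) %*% chol(Tg)
  env <- rep(c("B", "C"), c(n_B, n - n_B))
  year <- rep(c(1, 2), length.out = n)
  e <- rnorm(n, 0, sqrt(ifelse(env == "B", vc$sigma2_eB, vc$sigma2_eC)))
  mu <- ifelse(env == "B", 1, -2) + 0.5 * year
  data.frame(animal = seq_len(n), env = env, year = year,
             value = mu + ifelse(env == "B", g[, 1], g[, 2]) + e)
}
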