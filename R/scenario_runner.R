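#' Build the scenario grid
#'
#' Reproduces the base-plus-alternatives structure of the study design (not
#' the full factor cross): a base scenario — random genotyping in C, top-fish
#' genotyping in B, 20% of genotyping allocated to C, 100% of selected
#' females kept — crossed with `r_g` in {0.2, 0.5, 0.8} and `h2` in
#' {0.1, 0.3}; a C-strategy sweep and a B-strategy sweep over the same
#' `r_g` x `h2` cells; and an allocation x retention sweep
#' (`prop_C` in {0, 20, 40, 60}%, females kept in {100, 11}%) at `h2 = 0.3`
#' only.
#'
#' @param base_overrides named list of [scenario_config()] arguments applied
#'   to every cell (e.g. `list(profile = "desk", years = 12)`).
#' @return data.frame of factor levels with one row per unique scenario and
#'   a list-column `config` of validated [scenario_config()] objects.
#' @export
build_scenario_grid <- function(base_overrides = list()) {
  known <- c(names(formals(scenario_config)),
             c("n_offspring", "budget", "n_sires", "n_dams", "n_pool",
               "n_founders", "n_loci", "n_qtl", "n_chromosomes",
               "map_length_cM", "group_size", "maf_low", "maf_high",
               "n_mixing_generations", "n_mixing_pop",
               "generation_interval"))
  bad <- setdiff(names(base_overrides), setdiff(known, "..."))
  if (length(bad)) stop("unknown factor(s): ", paste(bad, collapse = ", "))
  rg <- c(0.2, 0.5, 0.8)
  h2 <- c(0.1, 0.3)
  cells <- rbind(
    expand.grid(c_strategy = c("Random", "Top1_1", "T1_1B1_1", "T1_2B1_2"),
                b_strategy = "Top1_1", r_g = rg, h2 = h2, prop_C = 0.2,
                prop_females_kept = 1, sweep = "C_strategy",
                stringsAsFactors = FALSE),
    expand.grid(c_strategy = "Random",
                b_strategy = c("Random", "Top1_1", "T1_2B1_2", "T3_4B1_4"),
                r_g = rg, h2 = h2, prop_C = 0.2, prop_females_kept = 1,
                sweep = "B_strategy", stringsAsFactors = FALSE),
    expand.grid(c_strategy = "Random", b_strategy = "Top1_1", r_g = rg,
                h2 = 0.3, prop_C = c(0, 0.2, 0.4, 0.6),
                prop_females_kept = c(1, 0.11), sweep = "allocation",
                stringsAsFactors = FALSE))
  configs <- vector("list", nrow(cells))
  ids <- character(nrow(cells))
  feasible <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    args <- c(as.list(cells[i, setdiff(names(cells), "sweep")]),
              base_overrides)
    cf <- tryCatch(do.call(scenario_config, args), error = function(e) e)
    if (inherits(cf, "error")) {
      # the design cell exists but cannot be run at this scale / screening
      # structure; keep the row, flag it
      configs[i] <- list(NULL)
      ids[i] <- do.call(paste, c(as.list(vapply(
        cells[i, setdiff(names(cells), "sweep")], as.character, "")),
        sep = "_"))
      feasible[i] <- FALSE
    } else {
      configs[[i]] <- cf
      ids[i] <- cf$scenario_id
      feasible[i] <- TRUE
    }
  }
  keep <- !duplicated(ids)
  out <- cells[keep, , drop = FALSE]
  out$scenario_id <- ids[keep]
  out$feasible <- feasible[keep]
  out$config <- configs[keep]
  rownames(out) <- NULL
  out
}

#' Run replicates of one scenario
#'
#' Simulates `n_replicates` independent replicates of a scenario (the study
#' design uses 100 at full scale) with substream-derived seeds, collects the
#' per-replicate outcome metrics and, when the config requests a REML
#' snapshot year, the estimated variance components.
#'
#' @param cfg a [scenario_config()] object.
#' @param n_replicates number of replicates.
#' @param master_seed integer master seed.
#' @return data.frame with one row per replicate (`replicate`, `delta_G`,
#'   `delta_F_percent`, `accuracy`, `bias`, and REML columns when
#'   snapshotted, including `failed` for replicates whose REML did not
#'   converge). Failed replicates are recorded, not fatal.
#' @export
run_scenario <- function(cfg, n_replicates = 20L, master_seed = 1L) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch(simulate_scheme(cfg, master_seed, r),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("replicate ", r, " failed: ", conditionMessage(res))
      rows[[r]] <- data.frame(replicate = r, delta_G = NA_real_,
                              delta_F_percent = NA_real_,
                              accuracy = NA_real_, bias = NA_real_,
                              failed = TRUE)
      next
    }
    row <- cbind(data.frame(replicate = r), res$metrics,
                 data.frame(failed = FALSE))
    if (!is.null(res$reml)) {
      vc <- res$reml$varcomp
      row <- cbind(row, data.frame(
        sigma2_gB = vc$sigma2_gB %||% vc$sigma2_g,
        sigma2_gC = vc$sigma2_gC %||% NA_real_,
        sigma_gBgC = vc$sigma_gBgC %||% NA_real_,
        sigma2_eB = vc$sigma2_eB %||% vc$sigma2_e,
        sigma2_eC = vc$sigma2_eC %||% NA_real_,
        h2_B = res$reml$h2_B, h2_C = res$reml$h2_C,
        reml_converged = res$reml$converged))
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  attr(out, "scenario_id") <- cfg$scenario_id
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary tables across scenarios
#'
#' Aggregates a list of [run_scenario()] results into a long table (one row
#' per scenario x metric with mean and SE) or a wide layout with scenarios as
#' columns, mirroring the strategy-comparison tables of the study design.
#'
#' @param results named list of per-replicate data.frames from
#'   [run_scenario()] (names = scenario labels).
#' @param layout `"long"` or `"wide"`.
#' @return a data.frame.
#' @export
report <- function(results, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  long <- do.call(rbind, lapply(names(results), function(nm) {
    s <- summarize_replicates(results[[nm]][
      setdiff(names(results[[nm]]), c("replicate", "failed",
                                      "reml_converged"))])
    cbind(data.frame(scenario = nm), s)
  }))
  rownames(long) <- NULL
  if (layout == "long") return(long)
  wide <- reshape(long[c("scenario", "metric", "mean")],
                  idvar = "metric", timevar = "scenario",
                  direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Grid search for the genotyped sex ratio in B
#'
#' Short pilot runs over a grid of candidate male shares of the B genotyping
#' budget, returning the grid member with the highest mean rate of genetic
#' gain. Scenarios may equally fix the fraction in the config; when females
#' are selected phenotypically (not genotyped), spending the whole budget on
#' males dominates, since female selection needs no genotypes.
#'
#' @param cfg a [scenario_config()] object.
#' @param grid candidate fractions in (0, 1].
#' @param pilot_replicates replicates per candidate.
#' @param master_seed integer master seed.
#' @return the selected fraction (a grid member).
#' @export
optimize_sex_ratio <- function(cfg, grid = c(0.5, 0.75, 1),
                               pilot_replicates = 2L, master_seed = 1L) {
  if (!length(grid)) stop("empty grid")
  if (length(grid) == 1L) return(grid)
  gains <- vapply(grid, function(f) {
    cand <- cfg
    cand$genotyped_male_fraction <- f
    cand <- tryCatch(validate_scenario_config(cand),
                     error = function(e) NULL)
    if (is.null(cand)) return(-Inf)
    mean(run_scenario(cand, pilot_replicates, master_seed)$delta_G,
         na.rm = TRUE)
  }, 0)
  if (all(!is.finite(gains))) stop("no feasible fraction in the grid")
  grid[which.max(gains)]
}
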