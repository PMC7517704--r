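# Plain-text and serialized exchange formats.

#' Write a genetic map as tab-separated text
#'
#' Columns: chromosome, locus id, position in cM.
#'
#' @param map a [build_genetic_map()] object.
#' @param file output path.
#' @export
write_genetic_map <- function(map, file) {
  write.table(data.frame(chromosome = map$chr,
                         locus = seq_len(map$n_loci),
                         pos_cM = map$pos),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Export haplotypes as PLINK-style transposed text
#'
#' Loci as rows, two allele columns (0/1) per individual, preceded by
#' chromosome, locus id and position.
#'
#' @param haps `n_loci x 2k` haplotype matrix.
#' @param map the matching [build_genetic_map()].
#' @param file output path.
#' @export
export_genotypes_text <- function(haps, map, file) {
  write.table(cbind(data.frame(chromosome = map$chr,
                               locus = seq_len(map$n_loci),
                               pos_cM = map$pos),
                    as.data.frame(haps)),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Save / load a founder genome container
#'
#' Serializes a [generate_founder_population()] object (haplotypes stored per
#' chromosome) to an RDS container.
#'
#' @param founders a `founder_pop` object.
#' @param file path.
#' @export
save_founder_genome <- function(founders, file) {
  map <- founders$map
  by_chr <- lapply(seq_len(map$n_chromosomes), function(c)
    founders$haps[map$chr_first[c]:map$chr_last[c], , drop = FALSE])
  saveRDS(list(by_chr = by_chr, map = map, n = founders$n,
               freq = founders$freq), file)
}

#' @rdname save_founder_genome
#' @return `load_founder_genome()` returns the restored `founder_pop`.
#' @export
load_founder_genome <- function(file) {
  x <- readRDS(file)
  structure(list(haps = do.call(rbind, x$by_chr), n = x$n, map = x$map,
                 freq = x$freq),
            class = "founder_pop")
}

#' Write a pedigree as tab-separated text
#'
#' Columns: id, sire, dam, birth_year, sex, environment, genotyped flag
#' (those present in `ped`).
#'
#' @param ped pedigree data.frame.
#' @param file output path.
#' @export
write_pedigree <- function(ped, file) {
  write.table(ped, file, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "0")
}

#' Write GEBVs as tab-separated text
#'
#' @param gebv data.frame from [solve_bivariate_gblup()] or
#'   [solve_univariate_gblup()].
#' @param file output path.
#' @export
write_gebv <- function(gebv, file) {
  write.table(gebv, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a scenario configuration in YAML
#'
#' The YAML file holds any subset of [scenario_config()] arguments (factor
#' levels, scale overrides, seeds); missing fields take the profile
#' defaults. Derived fields are recomputed on read, so a round trip
#' revalidates the scenario.
#'
#' @param file path to a YAML config.
#' @return a validated [scenario_config()].
#' @export
read_scenario_config <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(scenario_config, vals)
}

#' @rdname read_scenario_config
#' @param cfg a [scenario_config()] to write.
#' @export
write_scenario_config <- function(cfg, file) {
  keep <- c("profile", "c_strategy", "b_strategy", "r_g", "h2", "prop_C",
            "prop_females_kept", "years", "eval_years", "gain_first",
            "gain_last", "reml_year", "genotyped_male_fraction",
            "n_offspring", "budget", "n_sires", "n_dams", "n_pool",
            "n_founders", "n_loci", "n_qtl", "n_chromosomes",
            "map_length_cM", "group_size", "maf_low", "maf_high",
            "n_mixing_generations", "n_mixing_pop", "generation_interval")
  x <- cfg[intersect(keep, names(cfg))]
  x <- x[!vapply(x, function(v) is.null(v) || all(is.na(v)), TRUE)]
  yaml::write_yaml(x, file)
}
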