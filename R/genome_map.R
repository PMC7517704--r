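#' Build a genetic map
#'
#' Constructs a multi-chromosome genetic map with loci allocated to
#' chromosomes in near-equal numbers and positions drawn uniformly within each
#' chromosome. Chromosomes have equal lengths summing to `total_length_cM`;
#' the default dimensions emulate the rainbow trout genome used throughout the
#' simulator (29 chromosome pairs, 2927.1 cM).
#'
#' @param n_chromosomes number of chromosome pairs.
#' @param total_length_cM total map length in centimorgans.
#' @param n_loci total number of biallelic loci; must be at least
#'   `n_chromosomes`.
#' @param seed optional integer seed for the position draws.
#' @return an object of class `genome_map`: a list with `n_chromosomes`,
#'   `n_loci`, `total_length_cM`, `chr_len` (per-chromosome lengths, cM),
#'   `chr_first`/`chr_last` (1-based locus index bounds per chromosome),
#'   `chr` (chromosome of each locus) and `pos` (position of each locus in cM
#'   relative to its chromosome start, non-decreasing within chromosome).
#' @examples
#' map <- build_genetic_map(2, 200, 100, seed = 1)
#' sum(map$chr_len)
#' @export
build_genetic_map <- function(n_chromosomes = 29, total_length_cM = 2927.1,
                              n_loci = 36451, seed = NULL) {
  if (n_chromosomes < 1 || n_loci < n_chromosomes || total_length_cM <= 0)
    stop("invalid map configuration: need n_loci >= n_chromosomes >= 1 and a positive length")
  if (!is.null(seed)) set.seed(seed)
  per <- rep(n_loci %/% n_chromosomes, n_chromosomes)
  extra <- n_loci %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  chr_len <- rep(total_length_cM / n_chromosomes, n_chromosomes)
  pos <- unlist(lapply(seq_len(n_chromosomes),
                       function(c) sort(runif(per[c], 0, chr_len[c]))))
  chr_last <- cumsum(per)
  chr_first <- c(1L, head(chr_last, -1L) + 1L)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 n_loci = as.integer(n_loci),
                 total_length_cM = total_length_cM,
                 chr_len = chr_len,
                 chr_first = as.integer(chr_first),
                 chr_last = as.integer(chr_last),
                 chr = rep(seq_len(n_chromosomes), per),
                 pos = pos),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", x$n_chromosomes, "chromosomes,", x$n_loci, "loci,",
      sprintf("%.1f cM total\n", x$total_length_cM))
  invisible(x)
}
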