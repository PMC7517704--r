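#' Derive a deterministic substream seed
#'
#' Folds a master seed and an arbitrary list of labels (replicate index,
#' stream name, scenario id, ...) into a 31-bit integer seed. Substreams keep
#' the sources of randomness separable: scenarios sharing a master seed and a
#' replicate index share founder genomes, and adding scenarios never perturbs
#' the draws of existing ones.
#'
#' @param master integer master seed.
#' @param ... further labels (coerced to character) identifying the stream.
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' substream_seed(1, 3, "founders")
#' @export
substream_seed <- function(master, ...) {
  parts <- paste(c(as.character(master), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 17
  for (b in utf8ToInt(parts)) {
    # multiplier kept small enough that h * 69069 + b stays exact in doubles
    h <- (h * 69069 + b) %% 2147483629
  }
  as.integer(h + 1)
}
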