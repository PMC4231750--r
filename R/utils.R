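#' @useDynLib pingpongr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom setNames
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA character vectors
#'
#' DNA is handled in the DNA alphabet throughout (T stands for U); N is
#' preserved.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 5'/3' base coordinates of 0-based half-open stranded intervals
five_prime <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

three_prime <- function(start, end, strand) {
  ifelse(strand == "+", end - 1L, start)
}

# All randomness in a run is derived from one user seed; genotype streams
# get distinct sub-seeds so WT and KO libraries are independent draws.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% (2^31 - 1))
}

# condition constructors used for the CLI exit-code mapping
ppr_config_error <- function(msg) {
  stop(structure(class = c("ppr_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

ppr_input_error <- function(msg) {
  stop(structure(class = c("ppr_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# deterministic hash of an R object (config provenance in manifests)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
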