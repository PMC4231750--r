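#' Clip the 3' adapter from read sequences
#'
#' Finds the leftmost position at which the remainder of the read matches a
#' prefix of the adapter: a suffix of at least `min_overlap` bases must
#' equal the adapter prefix of the same length (a read running through the
#' whole adapter matches on the full adapter), and a terminal suffix
#' shorter than `min_overlap` may still match an adapter prefix. Matching
#' is exact (0 mismatches). Returns the insert (possibly empty) or
#' `NA_character_` when no adapter is found; policy for unclipped reads is
#' applied by [preprocess_reads()].
#'
#' The default adapter is the Illumina TruSeq small-RNA 3' adapter.
#'
#' @param sequences character vector of read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum internal adapter overlap (>= 1).
#' @return character vector of clipped inserts, `NA` where no match.
#' @export
clip_adapter <- function(sequences, adapter = "TGGAATTCTCGGGTGCCAAGG",
                         min_overlap = 5L) {
  if (min_overlap < 1L) ppr_config_error("min_overlap must be >= 1")
  if (nchar(adapter) < min_overlap)
    ppr_config_error("adapter shorter than min_overlap")
  pos <- cpp_clip_adapter(sequences, adapter, as.integer(min_overlap))
  out <- substr(sequences, 1L, pmax(pos, 0L))
  out[pos < 0L] <- NA_character_
  out
}

#' Length-filter clipped reads
#'
#' Keeps reads of more than 10 bp, i.e. length >= 11 nt, the minimum the
#' mapping hierarchy accepts. Idempotent; the number of discarded reads is
#' attached as `attr(, "n_dropped")`.
#'
#' @param reads data.frame with a `length` column (clean-read table).
#' @param min_len minimum retained length (default 11).
#' @return filtered data.frame.
#' @export
length_filter <- function(reads, min_len = 11L) {
  keep <- reads$length >= min_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Preprocess raw reads: clip, apply the unclipped-read policy, filter
#'
#' Reads without an adapter hit are dropped by default: with 50-bp
#' chemistry any insert of piRNA size runs into the adapter, so an
#' unclipped read is longer than any small RNA of interest. Set
#' `keep_unclipped = TRUE` to retain them whole instead.
#'
#' @param raw data.frame from [read_fastq()].
#' @param library library label (e.g. `"WT"`, `"KO"`).
#' @param adapter,min_overlap see [clip_adapter()].
#' @param keep_unclipped retain reads with no adapter match?
#' @param min_len see [length_filter()].
#' @return clean-read data.frame (`id`, `sequence`, `length`, `library`)
#'   with `attr(, "stage_counts")`: `input`, `clipped`, `dropped_unclipped`,
#'   `dropped_short`, `kept`.
#' @export
preprocess_reads <- function(raw, library = "library",
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             min_overlap = 5L, keep_unclipped = FALSE,
                             min_len = 11L) {
  ins <- clip_adapter(raw$sequence, adapter, min_overlap)
  unclipped <- is.na(ins)
  if (keep_unclipped) {
    ins[unclipped] <- raw$sequence[unclipped]
    dropped_unclipped <- 0L
    keep <- rep(TRUE, length(ins))
  } else {
    dropped_unclipped <- sum(unclipped)
    keep <- !unclipped
  }
  clean <- data.frame(id = raw$id[keep], sequence = ins[keep],
                      length = nchar(ins[keep]), library = library,
                      stringsAsFactors = FALSE)
  out <- length_filter(clean, min_len)
  attr(out, "stage_counts") <- c(
    input = nrow(raw), clipped = sum(!unclipped),
    dropped_unclipped = dropped_unclipped,
    dropped_short = attr(out, "n_dropped"), kept = nrow(out))
  out
}
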