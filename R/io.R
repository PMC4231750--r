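#' Read a 4-line FASTQ file
#'
#' Strict 4-line-per-record parser (Phred+33). Malformed input — a record
#' count not divisible by four, a header not starting with `@`, a missing
#' `+` separator, or sequence/quality length disagreement — raises a parse
#' error naming the offending line.
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) ppr_input_error(paste0("FASTQ not found: ", path))
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0)
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  if (n %% 4 != 0)
    ppr_input_error(sprintf(
      "truncated FASTQ record at line %d (%d lines, not a multiple of 4)",
      4L * (n %/% 4L) + 1L, n))
  h <- lines[seq(1, n, 4)]
  s <- toupper(lines[seq(2, n, 4)])
  p <- lines[seq(3, n, 4)]
  q <- lines[seq(4, n, 4)]
  bad <- which(!startsWith(h, "@"))
  if (length(bad))
    ppr_input_error(sprintf("FASTQ header missing '@' at line %d",
                            (bad[1] - 1L) * 4L + 1L))
  bad <- which(!startsWith(p, "+"))
  if (length(bad))
    ppr_input_error(sprintf("FASTQ separator missing '+' at line %d",
                            (bad[1] - 1L) * 4L + 3L))
  bad <- which(nchar(s) != nchar(q))
  if (length(bad))
    ppr_input_error(sprintf(
      "sequence/quality length mismatch for record at line %d",
      (bad[1] - 1L) * 4L + 1L))
  bad <- which(grepl("[^ACGTN]", s))
  if (length(bad))
    ppr_input_error(sprintf("non-ACGTN base in sequence at line %d",
                            (bad[1] - 1L) * 4L + 2L))
  data.frame(id = sub("^@", "", sub("\\s.*$", "", h)), sequence = s,
             quality = q, stringsAsFactors = FALSE)
}

#' Write a 4-line FASTQ file
#'
#' Quality defaults to a constant `I` (Phred 40): the downstream analysis
#' never consumes quality values.
#'
#' @param ids,sequences character vectors of equal length.
#' @param path output path.
#' @param quality optional quality strings (recycled per-read constant `I`).
#' @export
write_fastq <- function(ids, sequences, path, quality = NULL) {
  if (is.null(quality)) quality <- strrep("I", nchar(sequences))
  out <- character(4L * length(ids))
  out[seq(1, length(out), 4)] <- paste0("@", ids)
  out[seq(2, length(out), 4)] <- sequences
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- quality
  writeLines(out, path)
  invisible(path)
}

#' Read/write FASTA (70-column wrap)
#'
#' Thin wrappers over Biostrings.
#' @param path FASTA file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) ppr_input_error(paste0("FASTA not found: ", path))
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 70L)
  invisible(path)
}

#' Read a BED6 file of genomic intervals
#'
#' Coordinates are 0-based half-open and preserved verbatim, in file order
#' (no implicit sort). `start >= end` or a strand outside `+`/`-` is a
#' validation error.
#'
#' @param path BED6 file path.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) ppr_input_error(paste0("BED not found: ", path))
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  x <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "name", "score",
                                "strand"),
                  colClasses = c("character", "integer", "integer",
                                 "character", "integer", "character"),
                  stringsAsFactors = FALSE)
  if (any(x$start < 0) || any(x$start >= x$end))
    ppr_input_error("BED validation: need 0 <= start < end")
  if (!all(x$strand %in% c("+", "-")))
    ppr_input_error("BED validation: strand must be '+' or '-'")
  x
}

#' @rdname read_bed
#' @param intervals data.frame in [read_bed()] shape.
#' @export
write_bed <- function(intervals, path) {
  write.table(intervals[, c("chrom", "start", "end", "name", "score",
                            "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) ppr_input_error(paste0("TSV not found: ", path))
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a simulated library and its references to disk
#'
#' Emits `<label>.fastq` (Phred+33, constant quality), `<label>_truth.tsv`,
#' and — once per output directory — `genome.fa`, `consensus.fa`,
#' `mirnas.fa`, `clusters.bed` and `insertions.bed`. With
#' `adapter = TRUE` the configured 3' adapter is appended to every read and
#' the result truncated to the configured read length, emulating raw
#' sequencer output so that adapter clipping is exercised downstream.
#'
#' @param lib result of [simulate_library()].
#' @param ref the [build_reference()] object.
#' @param outdir output directory (created if missing).
#' @param adapter logical: append the 3' adapter (raw-read mode)?
#' @return invisible character vector of written paths.
#' @export
write_library <- function(lib, ref, outdir, adapter = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir))
    ppr_input_error(paste0("cannot create output directory: ", outdir))
  label <- lib$reads$library[1] %||% "library"
  cfg <- ref$config
  seqs <- lib$reads$sequence
  if (isTRUE(adapter))
    seqs <- substr(paste0(seqs, cfg$adapter), 1L, cfg$read_length)
  paths <- c(
    fastq = file.path(outdir, paste0(label, ".fastq")),
    truth = file.path(outdir, paste0(label, "_truth.tsv")),
    genome = file.path(outdir, "genome.fa"),
    consensus = file.path(outdir, "consensus.fa"),
    mirnas = file.path(outdir, "mirnas.fa"),
    clusters = file.path(outdir, "clusters.bed"),
    insertions = file.path(outdir, "insertions.bed"))
  write_fastq(lib$reads$id, seqs, paths["fastq"])
  write_tsv(lib$truth, paths["truth"])
  write_fasta(ref$genome, paths["genome"])
  write_fasta(ref$consensus, paths["consensus"])
  write_fasta(ref$mirnas, paths["mirnas"])
  write_bed(ref$clusters, paths["clusters"])
  ins <- ref$insertions
  write_bed(data.frame(chrom = rep("genome", nrow(ins)), start = ins$start,
                       end = ins$end, name = ins$family,
                       score = rep(0L, nrow(ins)), strand = ins$strand,
                       stringsAsFactors = FALSE), paths["insertions"])
  invisible(paths)
}
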