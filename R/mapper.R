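#' Build a k-mer seed index over reference forward strands
#'
#' Every k-mer position on the forward strand of each reference is stored;
#' the reverse strand is served at query time by looking up the read's
#' reverse complement. Positions are 0-based.
#'
#' @param refs named character vector of reference sequences.
#' @param k seed length (>= 8; default 11, the minimum read length).
#' @return object of class `kmer_index`.
#' @export
build_index <- function(refs, k = 11L) {
  k <- as.integer(k)
  if (k < 8L) ppr_config_error("k must be >= 8")
  if (length(refs) > 0 && k > min(nchar(refs)))
    ppr_config_error("k larger than shortest reference")
  env <- new.env(parent = emptyenv(), hash = TRUE)
  n_pos <- 0L
  for (i in seq_along(refs)) {
    L <- nchar(refs[[i]])
    kmers <- substring(refs[[i]], 1:(L - k + 1L), k:L)
    pos <- 0:(L - k)
    n_pos <- n_pos + length(pos)
    byk <- split(pos, kmers)
    for (km in names(byk)) {
      prev <- if (exists(km, envir = env, inherits = FALSE))
        get(km, envir = env) else NULL
      assign(km, rbind(prev, cbind(i, byk[[km]])), envir = env)
    }
  }
  structure(list(k = k, refs = refs, env = env, n_positions = n_pos),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index: k=%d, %d reference(s), %d positions\n",
              x$k, length(x$refs), x$n_positions))
  invisible(x)
}

#' Exact alignment of one read against an indexed reference set
#'
#' Reports all exact occurrences on both strands (strand `-` means the
#' read's reverse complement matches the forward reference at `offset`),
#' each with 0 mismatches. A read containing N matches nothing. Hits are
#' ordered by (reference input order, offset, `+` before `-`).
#'
#' @param read a single read sequence.
#' @param index a [build_index()] object.
#' @return data.frame with `ref`, `offset` (0-based), `strand`,
#'   `mismatches`.
#' @export
align_exact <- function(read, index) {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  if (nchar(read) < k) ppr_config_error("read shorter than index k")
  empty <- data.frame(ref = character(0), offset = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (grepl("[^ACGT]", read)) return(empty)
  len <- nchar(read)
  probe <- function(query, strand) {
    km <- substr(query, 1L, k)
    if (!exists(km, envir = index$env, inherits = FALSE)) return(NULL)
    cand <- get(km, envir = index$env)
    hits <- NULL
    for (j in seq_len(nrow(cand))) {
      i <- cand[j, 1]; p <- cand[j, 2]
      if (p + len <= nchar(index$refs[[i]]) &&
          substr(index$refs[[i]], p + 1L, p + len) == query)
        hits <- rbind(hits, data.frame(
          ref = names(index$refs)[i], ref_i = i, offset = p, strand = strand,
          mismatches = 0L, stringsAsFactors = FALSE))
    }
    hits
  }
  out <- rbind(probe(read, "+"), probe(revcomp(read), "-"))
  if (is.null(out)) return(empty)
  out <- out[order(out$ref_i, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$ref_i <- NULL
  out
}

#' Best gapless hit of one read against consensus sequences
#'
#' Substitution-only (Hamming) comparison of the read and its reverse
#' complement at every offset of every consensus, keeping at most `max_mm`
#' mismatches. Returns the single best hit — fewest mismatches, ties broken
#' by consensus input order, then smaller offset, then `+` before `-` — or
#' `NULL` when nothing is within `max_mm`. N counts as a mismatch.
#'
#' @param read a single read sequence.
#' @param consensus named character vector of consensus sequences.
#' @param max_mm maximum mismatches (default 2).
#' @return one-row data.frame (`family`, `offset`, `strand`, `mismatches`)
#'   or `NULL`.
#' @export
align_hamming <- function(read, consensus, max_mm = 2L) {
  if (max_mm < 0L) ppr_config_error("max_mm must be >= 0")
  hit <- cpp_hamming_best(read, unname(consensus), as.integer(max_mm))
  if (is.na(hit$ref[1])) return(NULL)
  data.frame(family = names(consensus)[hit$ref[1]], offset = hit$offset[1],
             strand = hit$strand[1], mismatches = hit$mismatches[1],
             stringsAsFactors = FALSE)
}

# unique genome hit entirely inside exactly one cluster interval?
assign_cluster <- function(chrom, start, end, clusters) {
  out <- rep(NA_character_, length(chrom))
  for (i in seq_len(nrow(clusters))) {
    hit <- !is.na(chrom) & chrom == clusters$chrom[i] &
      start >= clusters$start[i] & end <= clusters$end[i]
    out[hit] <- clusters$name[i]
  }
  out
}

#' Hierarchically classify a library of clean reads
#'
#' The mapping hierarchy: (1) reads exactly matching a mature miRNA or
#' other cellular ncRNA (either orientation, full length) are classed
#' `mirna_ncrna` and go no further; (2) remaining reads are mapped to the
#' genome allowing no mismatch — a read with exactly one genome hit lying
#' entirely within one piRNA cluster is assigned that cluster — and,
#' independently, to the transposon consensus set allowing `max_mm`
#' mismatches (best hit only). Reporting precedence:
#' `cluster` > `transposon_only` > `genome_other` > `unmapped`.
#'
#' @param reads clean-read data.frame (`id`, `sequence`, `length`,
#'   `library`).
#' @param mirnas named character vector of mature miRNA sequences (the
#'   normalization denominator counts these only).
#' @param genome named character vector of chromosome sequences.
#' @param clusters cluster intervals in [read_bed()] shape.
#' @param consensus named character vector of transposon consensus
#'   sequences.
#' @param ncrnas optional additional cellular ncRNA sequences (classed
#'   `mirna_ncrna` but not counted as miRNA).
#' @param max_mm transposon mismatch allowance (default 2).
#' @param k seed length for the exact genome mapper.
#' @return assignment data.frame: `read_id`, `library`, `length`,
#'   `sequence`, `is_mirna`, `final_class`, `genome_hits`, `cluster_id`,
#'   `g_strand`, `g_offset`, `family`, `strand`, `offset`, `mismatches`.
#' @export
classify_reads <- function(reads, mirnas, genome, clusters, consensus,
                           ncrnas = NULL, max_mm = 2L, k = 11L) {
  n <- nrow(reads)
  seqs <- reads$sequence
  mir_set <- unique(c(mirnas, revcomp(mirnas)))
  ncr_set <- if (length(ncrnas)) unique(c(ncrnas, revcomp(ncrnas))) else
    character(0)
  is_mirna <- seqs %in% mir_set
  is_ncrna <- is_mirna | seqs %in% ncr_set

  out <- data.frame(read_id = reads$id, library = reads$library,
                    length = reads$length, sequence = seqs,
                    is_mirna = is_mirna,
                    final_class = NA_character_,
                    genome_hits = 0L, cluster_id = NA_character_,
                    g_strand = NA_character_, g_offset = NA_integer_,
                    family = NA_character_, strand = NA_character_,
                    offset = NA_integer_, mismatches = NA_integer_,
                    stringsAsFactors = FALSE)
  out$final_class[is_ncrna] <- "mirna_ncrna"

  todo <- which(!is_ncrna)
  if (length(todo)) {
    useq <- unique(seqs[todo])
    uidx <- match(seqs[todo], useq)

    # exact genome hits (all occurrences, both strands)
    gh <- cpp_exact_all(useq, unname(genome), as.integer(k))
    hits_per_seq <- tabulate(gh$read, nbins = length(useq))
    out$genome_hits[todo] <- hits_per_seq[uidx]
    single <- gh[gh$read %in% which(hits_per_seq == 1L), , drop = FALSE]
    u_chrom <- rep(NA_character_, length(useq))
    u_off <- rep(NA_integer_, length(useq))
    u_str <- rep(NA_character_, length(useq))
    u_chrom[single$read] <- names(genome)[single$ref]
    u_off[single$read] <- single$offset
    u_str[single$read] <- single$strand
    out$g_offset[todo] <- u_off[uidx]
    out$g_strand[todo] <- u_str[uidx]
    u_len <- nchar(useq)
    u_cluster <- assign_cluster(u_chrom, u_off, u_off + u_len, clusters)
    out$cluster_id[todo] <- u_cluster[uidx]

    # best transposon hit for every non-miRNA read
    if (length(consensus)) {
      th <- cpp_hamming_best(useq, unname(consensus), as.integer(max_mm))
      out$family[todo] <- names(consensus)[th$ref][uidx]
      out$offset[todo] <- th$offset[uidx]
      out$strand[todo] <- th$strand[uidx]
      out$mismatches[todo] <- th$mismatches[uidx]
    }

    fc <- rep("unmapped", length(todo))
    fc[out$genome_hits[todo] > 0L] <- "genome_other"
    fc[!is.na(out$family[todo])] <- "transposon_only"
    fc[!is.na(out$cluster_id[todo])] <- "cluster"
    out$final_class[todo] <- fc
  }
  out
}
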