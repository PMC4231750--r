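# Brute-force oracles, deliberately independent of the package's seeded /
# vectorized implementations: plain double loops over every offset.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGTN", "TGCAN",
                     strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# every exact occurrence of `read` in named refs, both strands
oracle_exact <- function(read, refs) {
  out <- NULL
  rc <- oracle_revcomp(read)
  for (i in seq_along(refs)) {
    L <- nchar(refs[[i]])
    len <- nchar(read)
    for (p in 0:(L - len)) {
      win <- substr(refs[[i]], p + 1, p + len)
      if (win == read)
        out <- rbind(out, data.frame(ref = names(refs)[i], offset = p,
                                     strand = "+", mismatches = 0L,
                                     stringsAsFactors = FALSE))
      if (win == rc)
        out <- rbind(out, data.frame(ref = names(refs)[i], offset = p,
                                     strand = "-", mismatches = 0L,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    return(data.frame(ref = character(0), offset = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  # '-' rows for an offset must follow the '+' row at the same offset
  out <- out[order(match(out$ref, names(refs)), out$offset, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

hamming_dist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# best gapless hit with the documented tie-break: fewest mismatches, then
# reference input order, then offset, then '+' before '-'
oracle_hamming <- function(read, refs, max_mm = 2L) {
  best <- NULL
  best_mm <- max_mm + 1L
  rc <- oracle_revcomp(read)
  len <- nchar(read)
  for (i in seq_along(refs)) {
    L <- nchar(refs[[i]])
    if (L < len) next
    for (p in 0:(L - len)) {
      win <- substr(refs[[i]], p + 1, p + len)
      for (strand in c("+", "-")) {
        mm <- hamming_dist(win, if (strand == "+") read else rc)
        if (mm < best_mm) {
          best_mm <- mm
          best <- data.frame(family = names(refs)[i], offset = p,
                             strand = strand, mismatches = mm,
                             stringsAsFactors = FALSE)
        }
      }
    }
  }
  best
}

# direct transcription of the leftmost-adapter-prefix clipping rule
oracle_clip <- function(read, adapter, min_overlap) {
  n <- nchar(read)
  alen <- nchar(adapter)
  for (i in 0:(n - 1)) {
    tail <- substr(read, i + 1, n)
    tlen <- nchar(tail)
    cmp <- min(tlen, alen)
    if (substr(tail, 1, cmp) == substr(adapter, 1, cmp))
      return(substr(read, 1, i))
  }
  NA_character_
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small, fast generator settings shared across tests
small_config <- function(...) {
  args <- list(...)
  defaults <- list(seed = 42L, genome_length = 60000L, n_clusters = 3L,
                   cluster_length_range = c(2000L, 4000L),
                   n_transposon_families = 2L,
                   consensus_length_range = c(2500L, 3500L),
                   copies_per_family = 2L, n_mirnas = 20L, depth = 20000L,
                   sites_per_family = 20L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
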