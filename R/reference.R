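#' Build a synthetic reference set
#'
#' Generates a random genome and embeds, mutually disjoint: transposon
#' consensus insertions (forward or reverse-complement according to the
#' insertion strand), stranded piRNA cluster intervals, and mature miRNA
#' sequences. Each consensus occurs verbatim at each of its insertions, so
#' transposon-derived reads are genome-mappable (multi-mapping across
#' copies) while cluster reads are genome-unique.
#'
#' @param config a [sim_config()] object.
#' @return list of class `pirna_reference` with elements `genome` (named
#'   character, one chromosome `"genome"`), `clusters` (BED-like data.frame,
#'   0-based half-open, stranded), `consensus` (named character),
#'   `insertions` (data.frame with `start`, `end`, `family`, `strand`),
#'   `mirnas` (named character), `mirna_loci` (data.frame), and `config`.
#' @export
build_reference <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 0L))
  G <- config$genome_length

  # feature sizing: everything must fit with room to spare for placement
  cons_len <- if (config$n_transposon_families > 0)
    sample(config$consensus_length_range[1]:config$consensus_length_range[2],
           config$n_transposon_families, replace = TRUE) else integer(0)
  clus_len <- if (config$n_clusters > 0)
    sample(config$cluster_length_range[1]:config$cluster_length_range[2],
           config$n_clusters, replace = TRUE) else integer(0)
  mirna_len <- if (config$n_mirnas > 0)
    sample(config$mirna_length_range[1]:config$mirna_length_range[2],
           config$n_mirnas, replace = TRUE) else integer(0)
  total <- sum(cons_len) * config$copies_per_family + sum(clus_len) +
    sum(mirna_len)
  if (total > G)
    ppr_config_error(sprintf(
      "total feature length (%d) exceeds genome_length (%d)", total, G))

  genome <- random_dna(G)
  occupied <- matrix(integer(0), ncol = 2)  # rows: start, end (half-open)

  place <- function(len) {
    for (try in 1:5000) {
      s <- sample.int(G - len + 1L, 1L) - 1L
      e <- s + len
      if (nrow(occupied) == 0 ||
          all(e <= occupied[, 1] | s >= occupied[, 2])) {
        occupied <<- rbind(occupied, c(s, e))
        return(c(s, e))
      }
    }
    ppr_config_error("could not place features; genome too crowded (sizing error)")
  }

  # transposon consensus sequences and their genomic insertions
  fam_names <- c("L1A_like", "L1Gf_like", "IAP_like",
                 paste0("TE", seq_len(max(0, config$n_transposon_families - 3))))
  fam_names <- fam_names[seq_len(config$n_transposon_families)]
  consensus <- setNames(vapply(cons_len, random_dna, character(1)), fam_names)
  ins <- data.frame(start = integer(0), end = integer(0),
                    family = character(0), strand = character(0),
                    stringsAsFactors = FALSE)
  for (i in seq_along(consensus)) {
    for (cp in seq_len(config$copies_per_family)) {
      iv <- place(cons_len[i])
      strand <- sample(c("+", "-"), 1L)
      seqi <- if (strand == "+") consensus[[i]] else revcomp(consensus[[i]])
      substr(genome, iv[1] + 1L, iv[2]) <- seqi
      ins <- rbind(ins, data.frame(start = iv[1], end = iv[2],
                                   family = fam_names[i], strand = strand,
                                   stringsAsFactors = FALSE))
    }
  }

  # stranded piRNA clusters (left as random genome: unique sequence)
  clusters <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), name = character(0),
                         score = integer(0), strand = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_len(config$n_clusters)) {
    iv <- place(clus_len[i])
    clusters <- rbind(clusters, data.frame(
      chrom = "genome", start = iv[1], end = iv[2],
      name = paste0("cluster_", i), score = 0L,
      strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE))
  }

  # mature miRNAs, embedded outside clusters and insertions
  mirnas <- character(0)
  mirna_loci <- data.frame(start = integer(0), end = integer(0),
                           name = character(0), strand = character(0),
                           stringsAsFactors = FALSE)
  for (i in seq_len(config$n_mirnas)) {
    iv <- place(mirna_len[i])
    seqi <- random_dna(mirna_len[i])
    substr(genome, iv[1] + 1L, iv[2]) <- seqi
    nm <- sprintf("mir_%03d", i)
    mirnas[nm] <- seqi
    mirna_loci <- rbind(mirna_loci, data.frame(
      start = iv[1], end = iv[2], name = nm, strand = "+",
      stringsAsFactors = FALSE))
  }

  structure(list(genome = c(genome = genome), clusters = clusters,
                 consensus = consensus, insertions = ins, mirnas = mirnas,
                 mirna_loci = mirna_loci, config = config),
            class = "pirna_reference")
}

#' @export
print.pirna_reference <- function(x, ...) {
  cat("Synthetic piRNA reference set\n")
  cat(sprintf("  genome: %d bp\n", nchar(x$genome[[1]])))
  cat(sprintf("  clusters: %d (total %d bp)\n", nrow(x$clusters),
              sum(x$clusters$end - x$clusters$start)))
  cat(sprintf("  transposon families: %d (%d insertions)\n",
              length(x$consensus), nrow(x$insertions)))
  cat(sprintf("  miRNAs: %d\n", length(x$mirnas)))
  invisible(x)
}
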