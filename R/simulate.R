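# sample from a candidate vector (safe for length-1 candidates)
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

# Choose n 5'-end positions among `candidates` such that the read's first
# base is T with probability u1_bias. `is_t` flags candidates whose base,
# in read orientation, is T.
biased_positions <- function(candidates, is_t, n, u1_bias) {
  t_pos <- candidates[is_t]
  o_pos <- candidates[!is_t]
  if (length(t_pos) == 0) return(resample(o_pos, n))
  if (length(o_pos) == 0) return(resample(t_pos, n))
  want_t <- runif(n) < u1_bias
  out <- integer(n)
  out[want_t] <- resample(t_pos, sum(want_t))
  out[!want_t] <- resample(o_pos, sum(!want_t))
  out
}

# Ping-pong cleavage sites: for each consensus, positions where a guide
# piRNA (1U-biased first base) directs slicing of the opposite strand.
# Geometry per site, guide 5' at g on '+' (mirror for '-'):
#   guide      [g, g+L)            strand +
#   responder  5' at g+9, strand -, so the 5'-5' overlap is exactly 10
#   byproduct  [g+10, g+L) strand -, length L-10, abutting the responder
make_pingpong_sites <- function(ref, config) {
  margin <- 40L
  sites <- NULL
  for (fam in names(ref$consensus)) {
    cons <- ref$consensus[[fam]]
    chars <- strsplit(cons, "")[[1]]
    L <- length(chars)
    for (j in seq_len(config$sites_per_family)) {
      strand <- sample(c("+", "-"), 1L)
      glen <- resample(config$guide_lengths, 1L)
      if (strand == "+") {
        cand <- (margin):(L - glen - margin)          # 0-based guide 5'
        is_t <- chars[cand + 1L] == "T"
      } else {
        cand <- (glen + margin):(L - 1L - margin)     # 0-based guide 5' (= end-1)
        is_t <- chars[cand + 1L] == "A"               # complement is T
      }
      g5 <- biased_positions(cand, is_t, 1L, config$u1_bias)
      sites <- rbind(sites, data.frame(
        family = fam, strand = strand, g5 = g5, glen = glen,
        stringsAsFactors = FALSE))
    }
  }
  sites
}

extract_seq <- function(seqstr, start, end, strand) {
  s <- substring(seqstr, start + 1L, end)
  neg <- strand == "-"
  if (any(neg)) s[neg] <- revcomp(s[neg])
  s
}

#' Simulate one small-RNA library with ground truth
#'
#' Draws `depth` reads from the configured class mixture: exact mature
#' miRNAs; cluster-derived primary piRNAs (1U-biased, on the cluster
#' strand); transposon ping-pong guides and responders whose 5' ends
#' overlap by exactly 10 bp, so that the responder's 10th base is the
#' complement of the guide's first base (mechanistic 10A); captured
#' cleavage byproducts of length guide - 10 abutting the responder; and
#' uniform degradation fragments (11-35 nt). For the KO genotype, classes
#' inside the configured depletion windows are thinned by the profile's
#' scale factors, so expected class counts equal
#' depth x class_mix x depletion.
#'
#' All reads are substrings of the reference (reverse-complemented for the
#' minus strand); transposon-class coordinates are reported in consensus
#' space under the family name, all others in genome space.
#'
#' @param ref a [build_reference()] object.
#' @param config the [sim_config()] used to build `ref`.
#' @param genotype `"WT"` or `"KO"`.
#' @return list with `reads` (data.frame: `id`, `sequence`, `length`,
#'   `library`) and `truth` (data.frame: `read_id`, `true_class`, `ref`,
#'   `start`, `end`, `strand`, `feature`, `guide_length`).
#' @export
simulate_library <- function(ref, config, genotype) {
  validate_sim_config(config)
  if (!genotype %in% c("WT", "KO"))
    ppr_input_error(paste0("unknown genotype label: ", genotype))
  set.seed(derive_seed(config$seed, if (genotype == "WT") 1L else 2L))

  genome <- ref$genome[[1]]
  mix <- config$class_mix[c("mirna", "cluster_primary", "pingpong",
                            "degradation")]
  n_class <- as.vector(stats::rmultinom(1, config$depth, mix))
  names(n_class) <- names(mix)
  rows <- list()

  ## miRNA reads: exact mature sequences
  if (n_class["mirna"] > 0 && length(ref$mirnas) > 0) {
    i <- sample.int(length(ref$mirnas), n_class["mirna"], replace = TRUE)
    rows$mirna <- data.frame(
      true_class = "mirna", ref = "genome",
      start = ref$mirna_loci$start[i], end = ref$mirna_loci$end[i],
      strand = "+", feature = ref$mirna_loci$name[i],
      guide_length = NA_integer_, sequence = unname(ref$mirnas[i]),
      stringsAsFactors = FALSE)
  }

  ## cluster-derived primary piRNAs
  n_cp <- n_class["cluster_primary"]
  if (n_cp > 0 && nrow(ref$clusters) > 0) {
    lens24 <- as.integer(names(config$primary_length_dist))
    cl <- sample.int(nrow(ref$clusters), n_cp, replace = TRUE)
    len <- lens24[sample.int(length(lens24), n_cp, replace = TRUE,
                             prob = config$primary_length_dist)]
    fp <- integer(n_cp)
    for (ci in unique(cl)) {
      cstart <- ref$clusters$start[ci]; cend <- ref$clusters$end[ci]
      cstrand <- ref$clusters$strand[ci]
      chars <- strsplit(substr(genome, cstart + 1L, cend), "")[[1]]
      tbase <- if (cstrand == "+") "T" else "A"
      for (li in unique(len[cl == ci])) {
        sel <- which(cl == ci & len == li)
        cand <- if (cstrand == "+") cstart + 0:(cend - cstart - li) else
          (cstart + li - 1L):(cend - 1L)
        is_t <- chars[cand - cstart + 1L] == tbase
        fp[sel] <- biased_positions(cand, is_t, length(sel), config$u1_bias)
      }
    }
    cstrand <- ref$clusters$strand[cl]
    start <- ifelse(cstrand == "+", fp, fp - len + 1L)
    end <- ifelse(cstrand == "+", fp + len, fp + 1L)
    rows$cluster <- data.frame(
      true_class = "cluster_primary", ref = "genome",
      start = start, end = end, strand = cstrand,
      feature = ref$clusters$name[cl], guide_length = NA_integer_,
      sequence = extract_seq(genome, start, end, cstrand),
      stringsAsFactors = FALSE)
  }

  ## transposon ping-pong guides, responders, and captured byproducts
  n_pp <- n_class["pingpong"]
  if (n_pp > 0 && length(ref$consensus) > 0) {
    sites <- make_pingpong_sites(ref, config)
    si <- sample.int(nrow(sites), n_pp, replace = TRUE)
    is_guide <- runif(n_pp) < 0.5
    fam <- sites$family[si]; gstr <- sites$strand[si]
    g5 <- sites$g5[si]; glen <- sites$glen[si]

    gi <- which(is_guide)
    if (length(gi)) {
      start <- ifelse(gstr[gi] == "+", g5[gi], g5[gi] - glen[gi] + 1L)
      end <- ifelse(gstr[gi] == "+", g5[gi] + glen[gi], g5[gi] + 1L)
      seqs <- character(length(gi))
      for (f in unique(fam[gi])) {
        k <- fam[gi] == f
        seqs[k] <- extract_seq(ref$consensus[[f]], start[k], end[k],
                               gstr[gi][k])
      }
      rows$guide <- data.frame(
        true_class = "pingpong_guide", ref = fam[gi],
        start = start, end = end, strand = gstr[gi], feature = fam[gi],
        guide_length = glen[gi], sequence = seqs, stringsAsFactors = FALSE)
    }

    ri <- which(!is_guide)
    if (length(ri)) {
      lens24 <- as.integer(names(config$responder_length_dist))
      rlen <- lens24[sample.int(length(lens24), length(ri), replace = TRUE,
                                prob = config$responder_length_dist)]
      rstr <- ifelse(gstr[ri] == "+", "-", "+")
      r5 <- ifelse(gstr[ri] == "+", g5[ri] + 9L, g5[ri] - 9L)
      start <- ifelse(rstr == "+", r5, r5 - rlen + 1L)
      end <- ifelse(rstr == "+", r5 + rlen, r5 + 1L)
      seqs <- character(length(ri))
      for (f in unique(fam[ri])) {
        k <- fam[ri] == f
        seqs[k] <- extract_seq(ref$consensus[[f]], start[k], end[k], rstr[k])
      }
      rows$responder <- data.frame(
        true_class = "pingpong_responder", ref = fam[ri],
        start = start, end = end, strand = rstr, feature = fam[ri],
        guide_length = glen[ri], sequence = seqs, stringsAsFactors = FALSE)

      # byproducts are captured at cleavage, before any stability effect
      cap <- which(runif(length(ri)) < config$p_byproduct)
      if (length(cap)) {
        bg5 <- g5[ri][cap]; bglen <- glen[ri][cap]
        bstr <- rstr[cap]; bfam <- fam[ri][cap]
        bstart <- ifelse(bstr == "-", bg5 + 10L, bg5 - bglen + 1L)
        bend <- ifelse(bstr == "-", bg5 + bglen, bg5 - 9L)
        bseq <- character(length(cap))
        for (f in unique(bfam)) {
          k <- bfam == f
          bseq[k] <- extract_seq(ref$consensus[[f]], bstart[k], bend[k],
                                 bstr[k])
        }
        rows$byproduct <- data.frame(
          true_class = "byproduct", ref = bfam,
          start = bstart, end = bend, strand = bstr, feature = bfam,
          guide_length = bglen, sequence = bseq, stringsAsFactors = FALSE)
      }
    }
  }

  ## degradation: uniform random genomic fragments, 11-35 nt
  n_dg <- n_class["degradation"]
  if (n_dg > 0) {
    len <- sample(11:35, n_dg, replace = TRUE)
    start <- vapply(len, function(l)
      sample.int(config$genome_length - l + 1L, 1L) - 1L, integer(1))
    strand <- sample(c("+", "-"), n_dg, replace = TRUE)
    end <- start + len
    rows$degradation <- data.frame(
      true_class = "degradation", ref = "genome",
      start = start, end = end, strand = strand, feature = NA_character_,
      guide_length = NA_integer_,
      sequence = extract_seq(genome, start, end, strand),
      stringsAsFactors = FALSE)
  }

  all <- do.call(rbind, rows)
  rownames(all) <- NULL
  all$length <- all$end - all$start

  # genotype-specific depletion: thin classes inside their length windows
  if (genotype == "KO" && nrow(config$depletion) > 0) {
    factor <- rep(1, nrow(all))
    for (i in seq_len(nrow(config$depletion))) {
      d <- config$depletion[i, ]
      hit <- all$true_class == d$class & all$length >= d$min_len &
        all$length <= d$max_len
      factor[hit] <- factor[hit] * d$factor
    }
    all <- all[runif(nrow(all)) < factor, , drop = FALSE]
  }

  reads <- data.frame(id = sprintf("%s_%07d", genotype, seq_len(nrow(all))),
                      sequence = all$sequence, length = all$length,
                      library = genotype, stringsAsFactors = FALSE)
  truth <- data.frame(read_id = reads$id, true_class = all$true_class,
                      ref = all$ref, start = all$start, end = all$end,
                      strand = all$strand, feature = all$feature,
                      guide_length = all$guide_length,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}
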