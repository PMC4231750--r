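#' Length distributions by group
#'
#' One histogram per combination of the grouping columns, zero-filled over
#' the full length support (empty groups and unobserved lengths are
#' emitted, not omitted). For strand-resolved histograms pass the relevant
#' strand column (`strand` for consensus coordinates, `g_strand` for
#' genome/cluster coordinates) in `group_by`.
#'
#' @param assignments assignment data.frame (needs `length` plus the
#'   grouping columns).
#' @param group_by character vector of grouping column names.
#' @param lengths integer support of the histogram (default 11:35).
#' @return long data.frame: grouping columns, `length`, `count`.
#' @export
length_distribution <- function(assignments,
                                group_by = c("library", "final_class"),
                                lengths = 11:35) {
  missing_keys <- setdiff(group_by, names(assignments))
  if (length(missing_keys))
    ppr_config_error(paste0("unknown grouping key(s): ",
                            paste(missing_keys, collapse = ", ")))
  keys <- assignments[, group_by, drop = FALSE]
  groups <- unique(keys)
  rownames(groups) <- NULL
  if (nrow(assignments) == 0) {
    # an empty input still yields the zero-filled support
    out <- data.frame(length = lengths, count = 0L)
    for (cn in rev(group_by)) out <- cbind(setNames(list(NA), cn), out)
    return(out)
  }
  out <- NULL
  for (g in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(assignments))
    for (cn in group_by) {
      v <- groups[[cn]][g]
      sel <- sel & (if (is.na(v)) is.na(keys[[cn]]) else
        !is.na(keys[[cn]]) & keys[[cn]] == v)
    }
    cnt <- tabulate(factor(assignments$length[sel], levels = lengths),
                    nbins = length(lengths))
    block <- groups[rep(g, length(lengths)), , drop = FALSE]
    block$length <- lengths
    block$count <- cnt
    out <- rbind(out, block)
  }
  if (is.null(out)) {
    out <- groups[integer(0), , drop = FALSE]
    out$length <- integer(0)
    out$count <- integer(0)
  }
  rownames(out) <- NULL
  out
}

#' Nucleotide bias at read positions 1 and 10
#'
#' Base fractions among the supplied reads at the 1st and 10th positions
#' of the read's own sequence (1-based; mismatched positions follow the
#' read, not the reference). Reads with N at the queried position are
#' excluded from that position's denominator and reported in the
#' `n_excluded` column. Callers restrict input to the 24-33-nt window of a
#' class of interest.
#'
#' @param sequences character vector of read sequences (all >= 10 nt).
#' @return data.frame: `position` (1, 10), fractions `A`, `C`, `G`, `T`,
#'   `n`, `n_excluded`.
#' @export
first_tenth_bias <- function(sequences) {
  if (length(sequences) == 0)
    ppr_input_error("no reads: nucleotide bias has no denominator")
  if (any(nchar(sequences) < 10))
    ppr_input_error("all reads must be at least 10 nt")
  one_pos <- function(p) {
    b <- substr(sequences, p, p)
    keep <- b %in% c("A", "C", "G", "T")
    fr <- if (sum(keep) > 0)
      as.numeric(table(factor(b[keep], levels = c("A", "C", "G", "T")))) /
        sum(keep)
    else rep(0, 4)
    data.frame(position = p, A = fr[1], C = fr[2], G = fr[3], T = fr[4],
               n = sum(keep), n_excluded = sum(!keep))
  }
  rbind(one_pos(1L), one_pos(10L))
}

#' Per-million-miRNA normalization
#'
#' Scales a raw read count to reads per million miRNA-mapped reads of the
#' same library, the normalization used for all cross-library comparisons.
#'
#' @param raw raw read count(s).
#' @param mirna_total total miRNA-mapped reads of the library (> 0).
#' @return `raw * 1e6 / mirna_total`.
#' @export
normalize_per_million_mirna <- function(raw, mirna_total) {
  if (is.na(mirna_total) || mirna_total <= 0)
    ppr_input_error("miRNA total is zero: library cannot be normalized")
  raw * 1e6 / mirna_total
}

mirna_total_of <- function(assignments) {
  sum(assignments$is_mirna)
}

count_cluster <- function(a, id, window) {
  sum(!is.na(a$cluster_id) & a$cluster_id == id &
        a$length >= window[1] & a$length <= window[2])
}

count_family <- function(a, fam, window) {
  sum(!is.na(a$family) & a$family == fam & !a$is_mirna &
        a$length >= window[1] & a$length <= window[2])
}

#' Per-feature WT/KO count table with fold changes
#'
#' One row per piRNA cluster (reads uniquely mapped within the cluster)
#' and per transposon family (reads whose best consensus hit is that
#' family), restricted to the piRNA size window. Counts are normalized per
#' million miRNA reads of their own library; `fold = wt_norm / ko_norm`
#' (NA when the KO count is zero) and folds >= 3 are flagged — the
#' "3-fold reduction" line of the WT-vs-KO scatter.
#'
#' @param wt,ko assignment data.frames of the two libraries.
#' @param clusters cluster intervals ([read_bed()] shape).
#' @param families character vector of transposon family names.
#' @param window piRNA length window (default 24-33 nt).
#' @return data.frame: `feature_type`, `feature_id`, `wt_raw`, `ko_raw`,
#'   `wt_norm`, `ko_norm`, `fold`, `fold3`.
#' @export
feature_counts <- function(wt, ko, clusters, families,
                           window = c(24L, 33L)) {
  wt_m <- mirna_total_of(wt)
  ko_m <- mirna_total_of(ko)
  rows <- rbind(
    if (nrow(clusters)) data.frame(feature_type = "cluster",
                                   feature_id = clusters$name,
                                   stringsAsFactors = FALSE),
    if (length(families)) data.frame(feature_type = "transposon",
                                     feature_id = families,
                                     stringsAsFactors = FALSE))
  if (is.null(rows))
    return(data.frame(feature_type = character(0), feature_id = character(0),
                      wt_raw = integer(0), ko_raw = integer(0),
                      wt_norm = numeric(0), ko_norm = numeric(0),
                      fold = numeric(0), fold3 = logical(0)))
  cnt <- function(a, type, id) {
    if (type == "cluster") count_cluster(a, id, window) else
      count_family(a, id, window)
  }
  rows$wt_raw <- mapply(cnt, rows$feature_type, rows$feature_id,
                        MoreArgs = list(a = wt))
  rows$ko_raw <- mapply(cnt, rows$feature_type, rows$feature_id,
                        MoreArgs = list(a = ko))
  rows$wt_norm <- normalize_per_million_mirna(rows$wt_raw, wt_m)
  rows$ko_norm <- normalize_per_million_mirna(rows$ko_raw, ko_m)
  rows$fold <- ifelse(rows$ko_norm == 0, NA_real_,
                      rows$wt_norm / rows$ko_norm)
  rows$fold3 <- !is.na(rows$fold) & rows$fold >= 3
  rownames(rows) <- NULL
  rows
}

#' 5'-5' overlap-distance histogram (ping-pong signature)
#'
#' For every pair of opposite-strand reads in the piRNA size window on one
#' transposon consensus, the overlap distance is
#' `d = five_prime(minus) - five_prime(plus) + 1`, so a 10-bp 5'-5'
#' overlap gives d = 10 — the ping-pong hallmark. Pairs are counted
#' all-vs-all with read multiplicity, over d in `1..dmax`.
#'
#' @param assignments assignment data.frame (consensus coordinates in
#'   `family`, `strand`, `offset`).
#' @param family transposon family name (must be present in the table's
#'   reference set).
#' @param window piRNA length window (default 24-33).
#' @param dmax largest distance tabulated (default 30).
#' @return object of class `overlap_histogram`: list with `d`, `count`,
#'   `mode`, `family`, `n_pairs`.
#' @export
overlap_histogram <- function(assignments, family, window = c(24L, 33L),
                              dmax = 30L) {
  known <- unique(assignments$family[!is.na(assignments$family)])
  if (!family %in% known)
    ppr_input_error(paste0("family absent from assignments: ", family))
  a <- assignments[!is.na(assignments$family) &
                     assignments$family == family &
                     !assignments$is_mirna &
                     assignments$length >= window[1] &
                     assignments$length <= window[2], , drop = FALSE]
  fp <- five_prime(a$offset, a$offset + a$length, a$strand)
  maxp <- if (nrow(a)) max(fp) + 1L else 1L
  cp <- tabulate(fp[a$strand == "+"] + 1L, nbins = maxp + dmax)
  cm <- tabulate(fp[a$strand == "-"] + 1L, nbins = maxp + dmax)
  count <- vapply(1:dmax, function(d) {
    idx <- seq_len(maxp)
    sum(as.numeric(cp[idx]) * cm[idx + d - 1L])
  }, numeric(1))
  mode <- if (sum(count) > 0) which.max(count) else NA_integer_
  structure(list(d = 1:dmax, count = count, mode = mode, family = family,
                 n_pairs = sum(count)), class = "overlap_histogram")
}

#' @export
print.overlap_histogram <- function(x, ...) {
  cat(sprintf("5'-5' overlap histogram for %s: %g pairs, mode at d=%s\n",
              x$family, x$n_pairs, x$mode))
  invisible(x)
}

#' @export
plot.overlap_histogram <- function(x, ...) {
  graphics::barplot(x$count, names.arg = x$d, xlab = "5'-5' distance (bp)",
                    ylab = "pairs", main = x$family, ...)
  invisible(x)
}

# unique (strand, offset, length) tuples with multiplicities and a
# representative position-10 base, for one family in consensus space
position_tuples <- function(assignments, family, window) {
  a <- assignments[!is.na(assignments$family) &
                     assignments$family == family & !assignments$is_mirna &
                     assignments$length >= window[1] &
                     assignments$length <= window[2], , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(strand = character(0), offset = integer(0),
                      length = integer(0), count = integer(0),
                      base10 = character(0), stringsAsFactors = FALSE))
  key <- paste(a$strand, a$offset, a$length)
  first <- !duplicated(key)
  t <- data.frame(strand = a$strand[first], offset = a$offset[first],
                  length = a$length[first],
                  count = as.integer(table(key)[key[first]]),
                  base10 = substr(a$sequence[first], 10L, 10L),
                  stringsAsFactors = FALSE)
  rownames(t) <- NULL
  t
}

#' Slicer-byproduct adjacency scan
#'
#' Searches one transposon family's consensus coordinates for short RNAs
#' (11-23 nt) in the byproduct configuration:
#' \describe{
#'   \item{rule A (required)}{a same-strand 24-33-nt piRNA starts
#'     immediately downstream — the short RNA's 3' end is 1 bp upstream of
#'     the piRNA's 5' start.}
#'   \item{rule B (recorded when present)}{an opposite-strand 24-33-nt
#'     piRNA (the guide) whose 3'-end coordinate equals the short RNA's 5'
#'     coordinate.}
#' }
#' When both rules hold and the (downstream, guide) pair has a 5'-5'
#' overlap of 10, the short RNA's length is exactly guide length - 10
#' (19 nt for 29-nt guides, 16 nt for 26-nt guides). Reads are counted
#' with multiplicity; the A10 flag is the downstream piRNA's own 10th
#' base.
#'
#' @param assignments assignment data.frame.
#' @param family transposon family name.
#' @param short_window short-RNA length window (default 11-23).
#' @param pirna_window piRNA length window (default 24-33).
#' @return list of class `byproduct_scan`: `links` (one row per
#'   short/downstream/guide position combination, with `d` and
#'   `both_rules`), `summary` (dual-rule link weight per short length x
#'   guide length), `a10_rule_a` and `a10_dual` (weighted fractions of
#'   downstream piRNAs with A at position 10), `family`.
#' @export
byproduct_scan <- function(assignments, family, short_window = c(11L, 23L),
                           pirna_window = c(24L, 33L)) {
  shorts <- position_tuples(assignments, family, short_window)
  pirnas <- position_tuples(assignments, family, pirna_window)
  links <- NULL
  for (i in seq_len(nrow(shorts))) {
    s <- shorts[i, ]
    down <- if (s$strand == "+")
      pirnas[pirnas$strand == "+" & pirnas$offset == s$offset + s$length, ,
             drop = FALSE]
    else
      pirnas[pirnas$strand == "-" &
               pirnas$offset + pirnas$length == s$offset, , drop = FALSE]
    if (nrow(down) == 0) next  # rule A is required
    s_fp <- five_prime(s$offset, s$offset + s$length, s$strand)
    opp <- pirnas[pirnas$strand != s$strand, , drop = FALSE]
    g_tp <- three_prime(opp$offset, opp$offset + opp$length, opp$strand)
    guides <- opp[g_tp == s_fp, , drop = FALSE]
    for (j in seq_len(nrow(down))) {
      dn <- down[j, ]
      base <- data.frame(
        family = family, strand = s$strand, short_offset = s$offset,
        short_length = s$length, short_count = s$count,
        down_offset = dn$offset, down_length = dn$length,
        down_count = dn$count, down_a10 = dn$base10 == "A",
        stringsAsFactors = FALSE)
      if (nrow(guides) == 0) {
        base$guide_offset <- NA_integer_
        base$guide_length <- NA_integer_
        base$guide_count <- NA_integer_
        base$d <- NA_integer_
        base$both_rules <- FALSE
        links <- rbind(links, base)
      } else {
        for (gj in seq_len(nrow(guides))) {
          g <- guides[gj, ]
          row <- base
          row$guide_offset <- g$offset
          row$guide_length <- g$length
          row$guide_count <- g$count
          fp_dn <- five_prime(dn$offset, dn$offset + dn$length, s$strand)
          fp_g <- five_prime(g$offset, g$offset + g$length, g$strand)
          row$d <- if (s$strand == "+") fp_g - fp_dn + 1L else
            fp_dn - fp_g + 1L
          row$both_rules <- TRUE
          links <- rbind(links, row)
        }
      }
    }
  }
  if (is.null(links))
    links <- data.frame(family = character(0), strand = character(0),
                        short_offset = integer(0), short_length = integer(0),
                        short_count = integer(0), down_offset = integer(0),
                        down_length = integer(0), down_count = integer(0),
                        down_a10 = logical(0), guide_offset = integer(0),
                        guide_length = integer(0), guide_count = integer(0),
                        d = integer(0), both_rules = logical(0),
                        stringsAsFactors = FALSE)
  rownames(links) <- NULL
  dual <- links[links$both_rules, , drop = FALSE]
  summary <- if (nrow(dual)) {
    agg <- stats::aggregate(short_count ~ short_length + guide_length,
                            data = dual, FUN = sum)
    names(agg)[3] <- "weight"
    agg[order(agg$short_length, agg$guide_length), , drop = FALSE]
  } else data.frame(short_length = integer(0), guide_length = integer(0),
                    weight = integer(0))
  wfrac <- function(df) {
    w <- df$short_count * df$down_count
    if (sum(w) == 0) NA_real_ else sum(w * df$down_a10) / sum(w)
  }
  structure(list(links = links, summary = summary,
                 a10_rule_a = wfrac(links), a10_dual = wfrac(dual),
                 family = family),
            class = "byproduct_scan")
}

#' @export
print.byproduct_scan <- function(x, ...) {
  cat(sprintf("byproduct scan (%s): %d link rows, %d dual-rule\n",
              x$family, nrow(x$links), sum(x$links$both_rules)))
  if (nrow(x$summary)) {
    cat("dual-rule weight by (short length, guide length):\n")
    print(x$summary, row.names = FALSE)
  }
  cat(sprintf("A10 fraction of downstream piRNAs: rule A %.3f, dual %.3f\n",
              x$a10_rule_a, x$a10_dual))
  invisible(x)
}

#' KO/WT depletion ratios by size window
#'
#' Normalized (per-million-miRNA) KO/WT count ratios for the cluster and
#' transposon read classes inside each length window — the comparison that
#' separates a MILI-size (24-27 nt) effect from a MIWI2-size (28-32 nt)
#' effect. The ratio is NA when the WT window count is zero.
#'
#' @param wt,ko assignment data.frames.
#' @param windows named list of `c(min, max)` length windows.
#' @return data.frame: `class`, `window`, `min_len`, `max_len`, `wt_norm`,
#'   `ko_norm`, `ratio`.
#' @export
depletion_by_window <- function(wt, ko,
                                windows = list(mili = c(24L, 27L),
                                               miwi2 = c(28L, 32L))) {
  wt_m <- mirna_total_of(wt)
  ko_m <- mirna_total_of(ko)
  cnt <- function(a, cls, w) {
    if (cls == "cluster")
      sum(!is.na(a$cluster_id) & a$length >= w[1] & a$length <= w[2])
    else
      sum(!is.na(a$family) & !a$is_mirna & a$length >= w[1] &
            a$length <= w[2])
  }
  out <- NULL
  for (cls in c("cluster", "transposon")) {
    for (wn in names(windows)) {
      w <- windows[[wn]]
      wr <- cnt(wt, cls, w)
      kr <- cnt(ko, cls, w)
      wt_norm <- normalize_per_million_mirna(wr, wt_m)
      ko_norm <- normalize_per_million_mirna(kr, ko_m)
      out <- rbind(out, data.frame(
        class = cls, window = wn, min_len = w[1], max_len = w[2],
        wt_norm = wt_norm, ko_norm = ko_norm,
        ratio = if (wr == 0) NA_real_ else ko_norm / wt_norm,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
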