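mk_assign <- function(length, family = NA_character_, strand = NA_character_,
                      offset = NA_integer_, sequence = strrep("A", length),
                      library = "WT", cluster_id = NA_character_,
                      is_mirna = FALSE, final_class = "transposon_only") {
  data.frame(read_id = sprintf("r%03d", seq_along(length)), library = library,
             length = length, sequence = sequence, is_mirna = is_mirna,
             final_class = final_class, genome_hits = 0L,
             cluster_id = cluster_id, g_strand = NA_character_,
             g_offset = NA_integer_, family = family, strand = strand,
             offset = offset, mismatches = 0L, stringsAsFactors = FALSE)
}

test_that("length distributions count per group and zero-fill", {
  a <- mk_assign(c(rep(26L, 5), rep(29L, 3)))
  ld <- length_distribution(a, group_by = "library")
  expect_equal(ld$count[ld$length == 26], 5)
  expect_equal(ld$count[ld$length == 29], 3)
  expect_equal(sum(ld$count), 8)
  expect_equal(nrow(ld), length(11:35))  # unobserved lengths emitted as 0
  expect_error(length_distribution(a, group_by = "nonsense"),
               class = "ppr_config_error")
  # empty input still yields the zero-filled support
  ld0 <- length_distribution(a[0, ], group_by = "library")
  expect_equal(nrow(ld0), length(11:35))
  expect_true(all(ld0$count == 0))
})

test_that("synthetic libraries show the configured bimodal length profile", {
  cfg <- small_config()
  ref <- build_reference(cfg)
  lib <- simulate_library(ref, cfg, "WT")
  a <- classify_reads(lib$reads, ref$mirnas, ref$genome, ref$clusters,
                      ref$consensus)
  ld <- length_distribution(a[a$final_class == "cluster", ],
                            group_by = "library")
  top2 <- ld$length[order(-ld$count)][1:2]
  expect_setequal(top2, c(26L, 29L))
})

test_that("positional nucleotide fractions are exact on constructed reads", {
  seqs <- c(rep(strrep("T", 26), 7), rep(strrep("G", 26), 3))
  b <- first_tenth_bias(seqs)
  expect_equal(b$T[b$position == 1], 0.7)
  expect_equal(b$G[b$position == 1], 0.3)
  expect_equal(rowSums(b[, c("A", "C", "G", "T")]), c(1, 1))
  all_a10 <- vapply(1:5, function(i)
    paste0(strrep("C", 9), "A", strrep("C", 16)), character(1))
  b2 <- first_tenth_bias(all_a10)
  expect_equal(b2$A[b2$position == 10], 1.0)
  expect_error(first_tenth_bias(character(0)), class = "ppr_input_error")
})

test_that("reads with N at the queried position leave the denominator", {
  seqs <- c(strrep("T", 26), paste0("N", strrep("T", 25)))
  b <- first_tenth_bias(seqs)
  expect_equal(b$n[b$position == 1], 1L)
  expect_equal(b$n_excluded[b$position == 1], 1L)
  expect_equal(b$T[b$position == 1], 1.0)
  expect_equal(b$n[b$position == 10], 2L)
})

test_that("per-million-miRNA normalization is exact and scale-invariant", {
  expect_equal(normalize_per_million_mirna(12, 3e6), 4.0)
  expect_equal(normalize_per_million_mirna(0, 1000), 0.0)
  expect_equal(normalize_per_million_mirna(24, 6e6),
               normalize_per_million_mirna(12, 3e6))
  expect_error(normalize_per_million_mirna(5, 0), class = "ppr_input_error")
})

test_that("feature table computes folds, flags and undefined ratios", {
  clusters <- data.frame(chrom = "g", start = 0L, end = 1000L, name = "cl1",
                         score = 0L, strand = "+", stringsAsFactors = FALSE)
  wt <- rbind(mk_assign(rep(26L, 30), cluster_id = "cl1",
                        final_class = "cluster"),
              mk_assign(rep(26L, 1000), is_mirna = TRUE,
                        final_class = "mirna_ncrna"))
  ko10 <- rbind(mk_assign(rep(26L, 10), cluster_id = "cl1",
                          final_class = "cluster", library = "KO"),
                mk_assign(rep(26L, 1000), is_mirna = TRUE,
                          final_class = "mirna_ncrna", library = "KO"))
  ft <- feature_counts(wt, ko10, clusters, character(0))
  expect_equal(ft$fold, 3.0)
  expect_true(ft$fold3)
  # identical libraries: fold exactly 1, not flagged
  ft1 <- feature_counts(wt, wt, clusters, character(0))
  expect_equal(ft1$fold, 1.0)
  expect_false(ft1$fold3)
  # empty KO feature: fold undefined, reported as NA
  ko0 <- mk_assign(rep(26L, 1000), is_mirna = TRUE,
                   final_class = "mirna_ncrna", library = "KO")
  ft0 <- feature_counts(wt, ko0, clusters, character(0))
  expect_true(is.na(ft0$fold))
  expect_false(ft0$fold3)
})

test_that("overlap distance follows the 5'-5' geometry", {
  # + read with 5' at 100, - read with 5' at 109: d = 10
  a <- mk_assign(c(26L, 26L), family = "te1", strand = c("+", "-"),
                 offset = c(100L, 84L))
  h <- overlap_histogram(a, "te1")
  expect_equal(h$count[h$d == 10], 1)
  expect_equal(sum(h$count), 1)
  expect_equal(h$mode, 10L)
  # sense-only reads: empty histogram, no mode
  h0 <- overlap_histogram(mk_assign(26L, family = "te1", strand = "+",
                                    offset = 100L), "te1")
  expect_equal(sum(h0$count), 0)
  expect_true(is.na(h0$mode))
  expect_error(overlap_histogram(a, "absent"), class = "ppr_input_error")
})

test_that("pair counting respects read multiplicity and the size window", {
  a <- mk_assign(c(26L, 26L, 26L, 20L), family = "te1",
                 strand = c("+", "+", "-", "-"),
                 offset = c(100L, 100L, 84L, 90L))
  h <- overlap_histogram(a, "te1")
  expect_equal(h$count[h$d == 10], 2)  # 2 identical + reads x 1 - read
  expect_equal(sum(h$count), 2)        # the 20-nt read is outside 24-33
})

test_that("the overlap histogram is invariant under reference flip", {
  cfg <- small_config()
  ref <- build_reference(cfg)
  lib <- simulate_library(ref, cfg, "WT")
  a <- classify_reads(lib$reads, ref$mirnas, ref$genome, ref$clusters,
                      ref$consensus)
  fam <- names(ref$consensus)[1]
  h <- overlap_histogram(a, fam)
  L <- nchar(ref$consensus[[fam]])
  b <- a
  sel <- !is.na(b$family) & b$family == fam
  b$offset[sel] <- L - (b$offset[sel] + b$length[sel])
  b$strand[sel] <- ifelse(b$strand[sel] == "+", "-", "+")
  h2 <- overlap_histogram(b, fam)
  expect_equal(h2$count, h$count)
  expect_equal(h2$mode, h$mode)
})

test_that("depletion ratios are 1 for identical libraries", {
  clusters <- data.frame(chrom = "g", start = 0L, end = 1000L, name = "cl1",
                         score = 0L, strand = "+", stringsAsFactors = FALSE)
  a <- rbind(mk_assign(rep(26L, 50), cluster_id = "cl1",
                       final_class = "cluster"),
             mk_assign(rep(30L, 40), family = "te1", strand = "+",
                       offset = 5L),
             mk_assign(rep(22L, 500), is_mirna = TRUE,
                       final_class = "mirna_ncrna"))
  d <- depletion_by_window(a, a)
  expect_true(all(d$ratio[!is.na(d$ratio)] == 1.0))
  # zero WT count -> undefined ratio
  expect_true(is.na(d$ratio[d$class == "cluster" & d$window == "miwi2"]))
})
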