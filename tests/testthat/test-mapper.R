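test_that("k-mer index stores every position, duplicates included", {
  idx <- build_index(c(r = "ACGTACGTACGT"), k = 8L)
  expect_equal(idx$n_positions, 5L)            # 12 - 8 + 1
  idx2 <- build_index(c(r = strrep("A", 12)), k = 8L)
  expect_equal(idx2$n_positions, 5L)           # all the same 8-mer
  expect_equal(nrow(get("AAAAAAAA", envir = idx2$env)), 5L)
  empty <- build_index(character(0), k = 11L)
  expect_equal(empty$n_positions, 0L)
})

test_that("index construction validates k", {
  expect_error(build_index(c(r = "ACGTACGT"), k = 7L),
               class = "ppr_config_error")
  expect_error(build_index(c(r = "ACGTACGT"), k = 11L),
               "shortest reference")
})

test_that("align_exact finds constructed occurrences on both strands", {
  set.seed(7)
  read <- random_seq(25)
  genome <- c(g = paste0(random_seq(100), read, random_seq(80),
                         revcomp(read), random_seq(60)))
  idx <- build_index(genome, k = 11L)
  hits <- align_exact(read, idx)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$offset, c(100L, 205L))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$mismatches, c(0L, 0L))
})

test_that("align_exact agrees with a brute-force scan oracle", {
  set.seed(11)
  refs <- c(a = random_seq(800), b = random_seq(500))
  idx <- build_index(refs, k = 11L)
  for (i in 1:40) {
    read <- if (i %% 2 == 0) {
      l <- sample(15:30, 1)
      p <- sample(400, 1)
      s <- substr(refs[[sample(2, 1)]], p, p + l - 1)
      if (runif(1) < 0.5) revcomp(s) else s
    } else random_seq(30)  # almost surely absent
    expect_equal(align_exact(read, idx), oracle_exact(read, refs))
  }
})

test_that("batch exact mapper matches the per-read path", {
  set.seed(12)
  refs <- c(a = random_seq(600))
  idx <- build_index(refs, k = 11L)
  reads <- vapply(1:30, function(i) {
    if (i %% 2 == 0) substr(refs[[1]], sample(500, 1), 600) else
      random_seq(20)
  }, character(1))
  reads <- substr(reads, 1, 25)
  gh <- pingpongr:::cpp_exact_all(reads, unname(refs), 11L)
  for (i in seq_along(reads)) {
    mine <- gh[gh$read == i, c("offset", "strand"), drop = FALSE]
    rownames(mine) <- NULL
    ora <- align_exact(reads[i], idx)[, c("offset", "strand"), drop = FALSE]
    expect_equal(mine, ora)
  }
})

test_that("align_hamming recovers planted hits and applies best-hit rules", {
  set.seed(21)
  cons <- c(famA = random_seq(300), famB = random_seq(300))
  # read = famA[51..80] with one substitution
  s <- strsplit(substr(cons[["famA"]], 51, 80), "")[[1]]
  s[15] <- setdiff(c("A", "C", "G", "T"), s[15])[1]
  hit <- align_hamming(paste(s, collapse = ""), cons, max_mm = 2L)
  expect_equal(hit$family, "famA")
  expect_equal(hit$offset, 50L)
  expect_equal(hit$mismatches, 1L)
  # a read matching famB exactly and famA with 2 mismatches -> famB
  r <- substr(cons[["famB"]], 101, 128)
  cons2 <- c(mut = cons[["famA"]], famB = cons[["famB"]])
  substr(cons2[["mut"]], 101, 128) <- r
  substr(cons2[["mut"]], 101, 102) <- chartr("ACGT", "CATG",
                                             substr(cons2[["mut"]], 101, 102))
  hit2 <- align_hamming(r, cons2, max_mm = 2L)
  expect_equal(hit2$family, "famB")
  expect_equal(hit2$mismatches, 0L)
  # nothing within 2 mismatches -> NULL
  expect_null(align_hamming(random_seq(30), cons, max_mm = 2L))
})

test_that("hamming mapper equals the exhaustive double-loop oracle", {
  set.seed(31)
  cons <- c(f1 = random_seq(250), f2 = random_seq(250))
  for (i in 1:60) {
    read <- if (i %% 3 == 0) {
      l <- sample(c(12, 18, 24:33), 1)
      p <- sample(200 - l, 1)
      s <- strsplit(substr(cons[[sample(2, 1)]], p, p + l - 1), "")[[1]]
      for (j in sample(l, sample(0:3, 1))) s[j] <- sample(c("A", "C", "G", "T"), 1)
      s <- paste(s, collapse = "")
      if (runif(1) < 0.5) revcomp(s) else s
    } else random_seq(sample(11:35, 1))
    mine <- align_hamming(read, cons, max_mm = 2L)
    ora <- oracle_hamming(read, cons, max_mm = 2L)
    if (is.null(ora)) expect_null(mine) else expect_equal(mine, ora)
  }
})

make_tiny_refset <- function() {
  set.seed(41)
  mir <- c(mirX = random_seq(22))
  cons <- c(te1 = random_seq(400))
  cluster_seq <- random_seq(300)
  genome <- c(g = paste0(random_seq(100), cluster_seq, random_seq(50),
                         cons[[1]], random_seq(50), mir[[1]],
                         random_seq(50)))
  clusters <- data.frame(chrom = "g", start = 100L, end = 400L,
                         name = "cl1", score = 0L, strand = "+",
                         stringsAsFactors = FALSE)
  list(mir = mir, cons = cons, genome = genome, clusters = clusters)
}

test_that("classification follows the miRNA-first hierarchy", {
  rs <- make_tiny_refset()
  # plant the miRNA inside the consensus too: hierarchy must still win
  cons <- rs$cons
  substr(cons[["te1"]], 51, 72) <- rs$mir[[1]]
  genome <- c(g = paste0(substr(rs$genome[[1]], 1, 450), cons[[1]],
                         substr(rs$genome[[1]], 851, nchar(rs$genome[[1]]))))
  reads <- data.frame(id = "m1", sequence = rs$mir[[1]], length = 22L,
                      library = "WT", stringsAsFactors = FALSE)
  a <- classify_reads(reads, rs$mir, genome, rs$clusters, cons)
  expect_equal(a$final_class, "mirna_ncrna")
  expect_true(a$is_mirna)
  expect_true(is.na(a$cluster_id) && is.na(a$family))
})

test_that("cluster assignment requires a unique genome hit", {
  rs <- make_tiny_refset()
  in_cluster <- substr(rs$genome[[1]], 151, 178)       # inside cl1
  # duplicate that sequence elsewhere: two genome hits, no cluster
  genome2 <- c(g = paste0(rs$genome[[1]], in_cluster))
  reads <- data.frame(id = c("u", "d"),
                      sequence = c(in_cluster, in_cluster),
                      length = 28L, library = "WT", stringsAsFactors = FALSE)
  a1 <- classify_reads(reads[1, ], rs$mir, rs$genome, rs$clusters, rs$cons)
  expect_equal(a1$genome_hits, 1L)
  expect_equal(a1$cluster_id, "cl1")
  expect_equal(a1$final_class, "cluster")
  a2 <- classify_reads(reads[2, ], rs$mir, genome2, rs$clusters, rs$cons)
  expect_equal(a2$genome_hits, 2L)
  expect_true(is.na(a2$cluster_id))
  expect_equal(a2$final_class, "genome_other")
})

test_that("a consensus-only hit with mismatches is transposon_only", {
  rs <- make_tiny_refset()
  s <- strsplit(substr(rs$cons[[1]], 101, 128), "")[[1]]
  s[5] <- setdiff(c("A", "C", "G", "T"), s[5])[1]
  s[20] <- setdiff(c("A", "C", "G", "T"), s[20])[1]
  reads <- data.frame(id = "t", sequence = paste(s, collapse = ""),
                      length = 28L, library = "WT", stringsAsFactors = FALSE)
  a <- classify_reads(reads, rs$mir, rs$genome, rs$clusters, rs$cons)
  expect_equal(a$genome_hits, 0L)
  expect_equal(a$family, "te1")
  expect_equal(a$mismatches, 2L)
  expect_equal(a$final_class, "transposon_only")
})

test_that("every read receives exactly one final class", {
  cfg <- small_config(depth = 5000L)
  ref <- build_reference(cfg)
  lib <- simulate_library(ref, cfg, "WT")
  a <- classify_reads(lib$reads, ref$mirnas, ref$genome, ref$clusters,
                      ref$consensus)
  expect_equal(nrow(a), nrow(lib$reads))
  expect_false(any(is.na(a$final_class)))
  cls <- table(a$final_class)
  expect_equal(sum(cls), nrow(lib$reads))
  # hierarchy invariants
  expect_true(all(is.na(a$cluster_id[a$genome_hits != 1L])))
  expect_true(all(is.na(a$family[a$is_mirna])))
})

test_that("classification is strand-symmetric", {
  cfg <- small_config(depth = 800L)
  ref <- build_reference(cfg)
  lib <- simulate_library(ref, cfg, "WT")
  G <- nchar(ref$genome[[1]])
  a <- classify_reads(lib$reads, ref$mirnas, ref$genome, ref$clusters,
                      ref$consensus)
  # mirror world: reverse-complement genome, clusters and consensus,
  # reverse-complement every read
  rc_clusters <- ref$clusters
  rc_clusters$start <- G - ref$clusters$end
  rc_clusters$end <- G - ref$clusters$start
  rc_clusters$strand <- ifelse(ref$clusters$strand == "+", "-", "+")
  mirror <- lib$reads
  mirror$sequence <- revcomp(mirror$sequence)
  b <- classify_reads(mirror, ref$mirnas,
                      c(genome = revcomp(ref$genome[[1]])), rc_clusters,
                      setNames(revcomp(ref$consensus), names(ref$consensus)))
  expect_equal(b$final_class, a$final_class)
  expect_equal(b$genome_hits, a$genome_hits)
  expect_equal(b$cluster_id, a$cluster_id)
  expect_equal(b$family, a$family)
})

test_that("truth classes are recovered for >= 99% of non-degradation reads", {
  cfg <- small_config()
  ref <- build_reference(cfg)
  lib <- simulate_library(ref, cfg, "WT")
  a <- classify_reads(lib$reads, ref$mirnas, ref$genome, ref$clusters,
                      ref$consensus)
  m <- merge(a, lib$truth, by = "read_id")
  m <- m[m$true_class != "degradation", ]
  expected <- c(mirna = "mirna_ncrna", cluster_primary = "cluster",
                pingpong_guide = "transposon_only",
                pingpong_responder = "transposon_only",
                byproduct = "transposon_only")
  ok <- m$final_class == expected[m$true_class]
  expect_gte(mean(ok), 0.99)
})
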