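log_msg <- function(...) message(sprintf(...))

#' Simulate a paired WT/KO library set to disk
#'
#' Builds the synthetic reference, simulates both genotype libraries,
#' writes raw (adapter-carrying) FASTQ plus references, annotations and
#' truth tables, and records a manifest with the seed and a config hash so
#' runs are reproducible byte for byte.
#'
#' @param out output directory.
#' @param config a [sim_config()]; its `depletion` is replaced when
#'   `preset` is given.
#' @param preset optional depletion preset name (see [depletion_preset()]).
#' @param force overwrite a non-empty output directory?
#' @param adapter write raw reads with the 3' adapter appended (default
#'   TRUE; the processing step clips it back off).
#' @return invisible list with `paths`, `manifest`, `ref`, `wt`, `ko`.
#' @export
cmd_simulate <- function(out, config = sim_config(), preset = NULL,
                         force = FALSE, adapter = TRUE) {
  if (!is.null(preset)) config$depletion <- depletion_preset(preset)
  validate_sim_config(config)
  if (dir.exists(out) && length(dir(out)) > 0 && !force)
    ppr_input_error(paste0("output directory not empty (use force): ", out))
  ref <- build_reference(config)
  wt <- simulate_library(ref, config, "WT")
  ko <- simulate_library(ref, config, "KO")
  p1 <- write_library(wt, ref, out, adapter = adapter)
  p2 <- write_library(ko, ref, out, adapter = adapter)
  manifest <- list(seed = config$seed, config_hash = object_hash(config),
                   preset = preset %||% "config",
                   n_reads = list(WT = nrow(wt$reads), KO = nrow(ko$reads)),
                   files = as.list(c(p1, ko_fastq = unname(p2["fastq"]),
                                     ko_truth = unname(p2["truth"]))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("simulated WT (%d reads) and KO (%d reads) into %s",
          nrow(wt$reads), nrow(ko$reads), out)
  invisible(list(paths = c(p1, ko_fastq = unname(p2["fastq"])),
                 manifest = manifest, ref = ref, wt = wt, ko = ko))
}

read_reference_dir <- function(ref_dir) {
  need <- c(genome = "genome.fa", consensus = "consensus.fa",
            mirnas = "mirnas.fa", clusters = "clusters.bed")
  paths <- file.path(ref_dir, need)
  missing <- !file.exists(paths)
  if (any(missing))
    ppr_input_error(paste0("missing reference file(s): ",
                           paste(paths[missing], collapse = ", ")))
  list(genome = read_fasta(paths[1]), consensus = read_fasta(paths[2]),
       mirnas = read_fasta(paths[3]), clusters = read_bed(paths[4]))
}

#' Process one library: clip, filter, classify
#'
#' Runs the preprocessing and mapping hierarchy over a FASTQ file against
#' the references in `ref_dir` and writes the per-read assignment TSV.
#' Stage counts (input, clipped, kept after the length filter, and the
#' final class breakdown) are logged and attached to the result.
#'
#' @param fastq FASTQ path.
#' @param label library label (`"WT"` or `"KO"`).
#' @param ref_dir directory holding `genome.fa`, `consensus.fa`,
#'   `mirnas.fa`, `clusters.bed` (as written by [cmd_simulate()]).
#' @param out output directory.
#' @param adapter,min_overlap,keep_unclipped see [preprocess_reads()].
#' @param max_mm transposon mismatch allowance.
#' @return invisible assignment data.frame with `attr(, "stage_counts")`;
#'   written to `<out>/<label>_assignments.tsv` together with
#'   `<label>_stage_counts.tsv`.
#' @export
cmd_process <- function(fastq, label, ref_dir, out,
                        adapter = "TGGAATTCTCGGGTGCCAAGG", min_overlap = 5L,
                        keep_unclipped = FALSE, max_mm = 2L) {
  refs <- read_reference_dir(ref_dir)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  raw <- read_fastq(fastq)
  clean <- preprocess_reads(raw, library = label, adapter = adapter,
                            min_overlap = min_overlap,
                            keep_unclipped = keep_unclipped)
  sc <- attr(clean, "stage_counts")
  assign <- classify_reads(clean, refs$mirnas, refs$genome, refs$clusters,
                           refs$consensus, max_mm = max_mm)
  cls <- table(factor(assign$final_class,
                      levels = c("mirna_ncrna", "cluster", "transposon_only",
                                 "genome_other", "unmapped")))
  counts <- data.frame(stage = c(names(sc), names(cls)),
                       count = c(unname(sc), as.integer(cls)),
                       stringsAsFactors = FALSE)
  write_tsv(assign, file.path(out, paste0(label, "_assignments.tsv")))
  write_tsv(counts, file.path(out, paste0(label, "_stage_counts.tsv")))
  log_msg("processed %s: %s", label,
          paste(counts$stage, counts$count, sep = "=", collapse = " "))
  attr(assign, "stage_counts") <- counts
  invisible(assign)
}

#' Compare a processed WT/KO pair
#'
#' Emits the full Figure-2/3-style report bundle: the per-feature
#' normalized count table with fold changes, length distributions, 1U/10A
#' bias tables, per-family 5'-5' overlap histograms and byproduct
#' summaries for both libraries, and the per-size-window depletion
#' profile.
#'
#' @param wt_tsv,ko_tsv assignment TSVs written by [cmd_process()].
#' @param ref_dir reference directory (as in [cmd_process()]).
#' @param out output directory for the report bundle.
#' @param pirna_window,short_window length windows (nt).
#' @param windows named list of depletion size windows.
#' @return invisible list with all computed tables.
#' @export
cmd_compare <- function(wt_tsv, ko_tsv, ref_dir, out,
                        pirna_window = c(24L, 33L),
                        short_window = c(11L, 23L),
                        windows = list(mili = c(24L, 27L),
                                       miwi2 = c(28L, 32L))) {
  refs <- read_reference_dir(ref_dir)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  wt <- read_tsv(wt_tsv)
  ko <- read_tsv(ko_tsv)
  for (a in list(wt, ko)) {
    bad_cl <- setdiff(stats::na.omit(unique(a$cluster_id)),
                      refs$clusters$name)
    bad_fam <- setdiff(stats::na.omit(unique(a$family)),
                       names(refs$consensus))
    if (length(bad_cl) || length(bad_fam))
      ppr_input_error("assignment TSVs do not match the reference set")
  }
  fams <- names(refs$consensus)

  ft <- feature_counts(wt, ko, refs$clusters, fams, window = pirna_window)
  dep <- depletion_by_window(wt, ko, windows = windows)
  ld <- rbind(length_distribution(wt), length_distribution(ko))

  bias <- NULL
  for (a in list(wt, ko)) {
    lib <- a$library[1]
    for (cls in c("cluster", "transposon")) {
      sel <- if (cls == "cluster") !is.na(a$cluster_id) else
        !is.na(a$family) & !a$is_mirna
      sel <- sel & a$length >= pirna_window[1] & a$length <= pirna_window[2]
      if (any(sel)) {
        b <- first_tenth_bias(a$sequence[sel])
        b$library <- lib
        b$class <- cls
        bias <- rbind(bias, b)
      }
    }
  }

  oh <- NULL
  bp_summary <- NULL
  scans <- list()
  for (a in list(wt, ko)) {
    lib <- a$library[1]
    present <- intersect(fams, unique(a$family[!is.na(a$family)]))
    for (fam in present) {
      h <- overlap_histogram(a, fam, window = pirna_window)
      oh <- rbind(oh, data.frame(library = lib, family = fam, d = h$d,
                                 count = h$count, stringsAsFactors = FALSE))
      s <- byproduct_scan(a, fam, short_window = short_window,
                          pirna_window = pirna_window)
      scans[[paste(lib, fam)]] <- s
      if (nrow(s$summary)) {
        sm <- s$summary
        sm$library <- lib
        sm$family <- fam
        bp_summary <- rbind(bp_summary, sm)
      }
    }
  }

  write_tsv(ft, file.path(out, "feature_counts.tsv"))
  write_tsv(dep, file.path(out, "depletion_by_window.tsv"))
  write_tsv(ld, file.path(out, "length_distributions.tsv"))
  if (!is.null(bias)) write_tsv(bias, file.path(out, "nucleotide_bias.tsv"))
  if (!is.null(oh)) write_tsv(oh, file.path(out, "overlap_histograms.tsv"))
  if (!is.null(bp_summary))
    write_tsv(bp_summary, file.path(out, "byproduct_summary.tsv"))
  log_msg("compared %s vs %s: %d features, report in %s",
          basename(wt_tsv), basename(ko_tsv), nrow(ft), out)
  invisible(list(feature_counts = ft, depletion = dep,
                 length_distributions = ld, bias = bias,
                 overlap_histograms = oh, byproduct_summary = bp_summary,
                 byproduct_scans = scans))
}
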