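#' Default piRNA length distributions
#'
#' Primary piRNAs in fetal testis libraries show a bimodal length profile
#' with peaks at 26 nt (MILI-bound sizes) and 29 nt (MIWI2-bound sizes);
#' ping-pong responders peak at 29 nt. Both distributions live on 24-33 nt.
#'
#' @name length_dists
#' @keywords internal
NULL

default_primary_length_dist <- function() {
  setNames(c(0.05, 0.10, 0.25, 0.10, 0.10, 0.25, 0.05, 0.04, 0.03, 0.03),
           24:33)
}

default_responder_length_dist <- function() {
  setNames(c(0.03, 0.04, 0.08, 0.10, 0.15, 0.30, 0.12, 0.08, 0.06, 0.04),
           24:33)
}

#' Depletion profile presets
#'
#' A depletion profile scales the expected count of a read class inside a
#' length window in the knockout library. Two presets mirror the two mutant
#' phenotypes the analysis distinguishes:
#' \describe{
#'   \item{hsp90a}{uniform 1/3 depletion of all 24-33-nt piRNA classes
#'     (cluster primaries, ping-pong guides and responders); miRNAs
#'     untouched.}
#'   \item{fkbp6}{1/3 depletion confined to 28-32-nt piRNAs (the MIWI2-bound
#'     size range); 24-27-nt piRNAs untouched.}
#'   \item{none}{no depletion (a control pair).}
#' }
#' Because the 16/19-nt cleavage byproducts fall outside the 24-33-nt
#' window, neither preset touches them.
#'
#' @param preset one of `"hsp90a"`, `"fkbp6"`, `"none"`.
#' @return data.frame with columns `class`, `min_len`, `max_len`, `factor`.
#' @export
depletion_preset <- function(preset = c("hsp90a", "fkbp6", "none")) {
  preset <- match.arg(preset)
  pirna_classes <- c("cluster_primary", "pingpong_guide", "pingpong_responder")
  switch(preset,
    hsp90a = data.frame(class = pirna_classes, min_len = 24L, max_len = 33L,
                        factor = 1 / 3, stringsAsFactors = FALSE),
    fkbp6 = data.frame(class = pirna_classes, min_len = 28L, max_len = 32L,
                       factor = 1 / 3, stringsAsFactors = FALSE),
    none = data.frame(class = character(0), min_len = integer(0),
                      max_len = integer(0), factor = numeric(0),
                      stringsAsFactors = FALSE)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic paired WT/KO small-RNA library generator.
#' Defaults describe an E16.5-testis-like library: a strong miRNA
#' background, cluster-derived primary piRNAs with a 1U bias, transposon
#' ping-pong pairs with the 10-bp 5'-5' overlap, and captured cleavage
#' byproducts.
#'
#' @param seed integer seed; every random draw derives from it.
#' @param genome_length synthetic genome size in bases.
#' @param n_clusters number of piRNA clusters.
#' @param cluster_length_range min/max cluster length (uniform).
#' @param n_transposon_families number of transposon consensus sequences.
#' @param consensus_length_range min/max consensus length (uniform).
#' @param copies_per_family genomic insertions per family.
#' @param n_mirnas number of mature miRNA species.
#' @param mirna_length_range min/max miRNA length.
#' @param depth total reads drawn per library before depletion.
#' @param class_mix named fractions for classes `mirna`, `cluster_primary`,
#'   `pingpong`, `degradation`; must sum to 1.
#' @param u1_bias probability that a primary piRNA (cluster primary or
#'   ping-pong guide) starts with U (T in DNA space).
#' @param primary_length_dist named probability vector on 24:33 nt.
#' @param responder_length_dist named probability vector on 24:33 nt.
#' @param guide_lengths lengths used for ping-pong guides (subset of 24:33).
#' @param p_byproduct probability that a cleavage's upstream fragment is
#'   captured as a 16/19-nt-type read.
#' @param depletion a preset name (see [depletion_preset()]) or a
#'   data.frame in the same shape; applied to the KO genotype only.
#' @param sites_per_family number of ping-pong cleavage sites per consensus.
#' @param adapter 3' adapter sequence appended in adapter-mode FASTQ output.
#' @param read_length sequencer read length for adapter-mode output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 7L,
                       genome_length = 200000L,
                       n_clusters = 5L,
                       cluster_length_range = c(3000L, 8000L),
                       n_transposon_families = 3L,
                       consensus_length_range = c(5000L, 7000L),
                       copies_per_family = 4L,
                       n_mirnas = 50L,
                       mirna_length_range = c(20L, 23L),
                       depth = 200000L,
                       class_mix = c(mirna = 0.40, cluster_primary = 0.20,
                                     pingpong = 0.30, degradation = 0.10),
                       u1_bias = 0.85,
                       primary_length_dist = default_primary_length_dist(),
                       responder_length_dist = default_responder_length_dist(),
                       guide_lengths = c(26L, 29L),
                       p_byproduct = 0.15,
                       depletion = "hsp90a",
                       sites_per_family = 40L,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 50L) {
  if (is.character(depletion)) depletion <- depletion_preset(depletion)
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              n_clusters = as.integer(n_clusters),
              cluster_length_range = as.integer(cluster_length_range),
              n_transposon_families = as.integer(n_transposon_families),
              consensus_length_range = as.integer(consensus_length_range),
              copies_per_family = as.integer(copies_per_family),
              n_mirnas = as.integer(n_mirnas),
              mirna_length_range = as.integer(mirna_length_range),
              depth = as.integer(depth),
              class_mix = class_mix,
              u1_bias = u1_bias,
              primary_length_dist = primary_length_dist,
              responder_length_dist = responder_length_dist,
              guide_lengths = as.integer(guide_lengths),
              p_byproduct = p_byproduct,
              depletion = depletion,
              sites_per_family = as.integer(sites_per_family),
              adapter = adapter,
              read_length = as.integer(read_length))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  req <- c("mirna", "cluster_primary", "pingpong", "degradation")
  if (!all(req %in% names(cfg$class_mix)))
    ppr_config_error("class_mix must name mirna, cluster_primary, pingpong, degradation")
  if (abs(sum(cfg$class_mix) - 1) > 1e-9)
    ppr_config_error("class_mix must sum to 1")
  probs <- c(cfg$class_mix, cfg$u1_bias, cfg$p_byproduct,
             cfg$primary_length_dist, cfg$responder_length_dist,
             cfg$depletion$factor)
  if (any(probs < 0 | probs > 1))
    ppr_config_error("all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$primary_length_dist) - 1) > 1e-9 ||
      abs(sum(cfg$responder_length_dist) - 1) > 1e-9)
    ppr_config_error("length distributions must sum to 1")
  if (!all(names(cfg$primary_length_dist) == 24:33) ||
      !all(names(cfg$responder_length_dist) == 24:33))
    ppr_config_error("length distributions must be named over 24:33")
  if (length(cfg$guide_lengths) < 1 ||
      any(cfg$guide_lengths < 24L | cfg$guide_lengths > 33L))
    ppr_config_error("guide_lengths must be a non-empty subset of 24..33")
  if (cfg$depth <= 0) ppr_config_error("depth must be positive")
  if (cfg$genome_length <= 0) ppr_config_error("genome_length must be positive")
  invisible(cfg)
}

#' Read a run configuration file
#'
#' YAML key-value file whose keys mirror [sim_config()] argument names plus
#' the run-level keys `min_overlap`, `max_mismatches`, `pirna_window`,
#' `mili_window`, `miwi2_window`, `short_window`. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return named list of overrides.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) ppr_input_error(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  allowed <- c(names(formals(sim_config)), "min_overlap", "max_mismatches",
               "pirna_window", "mili_window", "miwi2_window", "short_window",
               "preset")
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    ppr_config_error(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  vals
}

# run-level analysis defaults (size windows from the paper's protein-size
# ranges: MILI-bound 24-27 nt, MIWI2-bound 28-32 nt)
run_defaults <- function() {
  list(min_overlap = 5L, max_mismatches = 2L,
       pirna_window = c(24L, 33L), mili_window = c(24L, 27L),
       miwi2_window = c(28L, 32L), short_window = c(11L, 23L),
       guide_lengths = c(26L, 29L), k = 11L)
}
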