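#' Simulation configuration
#'
#' Bundles every parameter of the ground-truthed simulator: genome geometry,
#' misjoin edits to inject into the Hi-C-style scaffold layout, the optical
#' label-map noise model, and the long-read model. Defaults describe a small
#' diploid-free genome at the scale used throughout the package's synthetic
#' experiments.
#'
#' @param seed integer seed controlling all randomness downstream.
#' @param genome_length total genome size in bp.
#' @param n_chromosomes number of chromosomes (one scaffold each).
#' @param n_contigs number of contigs the genome is fragmented into.
#' @param min_contig_length minimum contig size in bp.
#' @param misjoins named integer vector with any of the names
#'   `"TRANSLOCATION"`, `"INVERSION"`, `"FUSION"` giving the number of each
#'   edit type to inject into the observed layout.
#' @param hic_gap_fill fixed gap filler (bp) the Hi-C-style scaffolder writes
#'   between joined contigs; every observed gap gets this declared length.
#' @param true_gap_mean,true_gap_sd mean/SD (bp) of the true physical gap
#'   between adjacent contigs (normal, truncated at 100 bp).
#' @param enzymes list of labelling enzymes, each
#'   `list(name=, motif=, nick_offset=)`. Defaults to the two nicking
#'   endonucleases Nt.BspQI (GCTCTTC) and Nb.BssSI (CACGAG).
#' @param sizing_sd_coeff optical sizing noise scale: an interval of true
#'   length L bp gets additive noise with SD `sizing_sd_coeff * sqrt(L/1000)`.
#' @param label_miss_rate probability that a true label is not observed.
#' @param false_label_rate expected false labels per 100 kb.
#' @param read_length_median,read_length_sigma lognormal read-length model
#'   (median in bp, sdlog shape).
#' @param read_coverage fold coverage of simulated reads.
#' @param min_anchor_read minimum anchored bp on each side of a junction for
#'   a read alignment to count as spanning.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 5e6,
                       n_chromosomes = 2L,
                       n_contigs = 40L,
                       min_contig_length = 8e4,
                       misjoins = integer(0),
                       hic_gap_fill = 100L,
                       true_gap_mean = 2000,
                       true_gap_sd = 700,
                       enzymes = list(
                         list(name = "BSPQI", motif = "GCTCTTC", nick_offset = 8L),
                         list(name = "BSSSI", motif = "CACGAG", nick_offset = 1L)
                       ),
                       sizing_sd_coeff = 400,
                       label_miss_rate = 0.10,
                       false_label_rate = 0.5,
                       read_length_median = 15000,
                       read_length_sigma = 0.45,
                       read_coverage = 30,
                       min_anchor_read = 1000) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.numeric(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    n_contigs = as.integer(n_contigs),
    min_contig_length = as.numeric(min_contig_length),
    misjoins = misjoins,
    hic_gap_fill = as.integer(hic_gap_fill),
    true_gap_mean = as.numeric(true_gap_mean),
    true_gap_sd = as.numeric(true_gap_sd),
    enzymes = enzymes,
    sizing_sd_coeff = as.numeric(sizing_sd_coeff),
    label_miss_rate = as.numeric(label_miss_rate),
    false_label_rate = as.numeric(false_label_rate),
    read_length_median = as.numeric(read_length_median),
    read_length_sigma = as.numeric(read_length_sigma),
    read_coverage = as.numeric(read_coverage),
    min_anchor_read = as.numeric(min_anchor_read)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

misjoin_types <- c("TRANSLOCATION", "INVERSION", "FUSION")

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fail <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (cfg$genome_length < cfg$n_contigs * cfg$min_contig_length)
    fail("genome_length must be >= n_contigs * min_contig_length")
  if (cfg$hic_gap_fill <= 0) fail("hic_gap_fill must be > 0")
  for (p in c("label_miss_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) fail(paste(p, "must lie in [0, 1]"))
  }
  if (cfg$false_label_rate < 0) fail("false_label_rate must be >= 0")
  if (cfg$sizing_sd_coeff < 0) fail("sizing_sd_coeff must be >= 0")
  if (cfg$n_chromosomes < 1 || cfg$n_contigs < cfg$n_chromosomes)
    fail("need n_contigs >= n_chromosomes >= 1")
  mj <- cfg$misjoins
  if (length(mj)) {
    if (is.null(names(mj)) || !all(names(mj) %in% misjoin_types))
      fail("misjoins must be named with TRANSLOCATION/INVERSION/FUSION")
    if (any(mj < 0)) fail("misjoin counts must be >= 0")
    n_junctions <- cfg$n_contigs - cfg$n_chromosomes
    if (sum(mj) >= n_junctions)
      fail("total misjoin count must be < number of junctions (n_contigs - n_chromosomes)")
  }
  if (length(cfg$enzymes) < 1) fail("at least one enzyme is required")
  for (e in cfg$enzymes) {
    if (is.null(e$name) || is.null(e$motif)) fail("each enzyme needs name and motif")
  }
  if (cfg$read_coverage <= 0) fail("read_coverage must be > 0")
  invisible(cfg)
}

#' Alignment scoring parameters
#'
#' Parameters of the local dynamic-programming alignment of label maps.
#' Score units are arbitrary; the defaults were chosen so that, at the
#' simulator's default noise level, genuine structural discordance separates
#' cleanly from sizing noise.
#'
#' @param sigma sizing SD scale (bp per sqrt(kb)) used by the interval
#'   penalty; should match the expected measurement noise.
#' @param gap_prior score units per kb of implied gap charged when an
#'   interval crosses a declared gap (default 0: any non-negative physical
#'   gap is free). A small positive value makes the aligner prefer the
#'   smallest crossing consistent with the labels, at the cost of a
#'   downward pull on implied gap sizes.
#' @param penalty_weight multiplier applied to the sizing penalty inside the
#'   alignment recurrence. Values above 1 make the aligner stricter than the
#'   nominal noise model, sharpening discrimination at structural
#'   boundaries, while `sigma` itself keeps describing the physical noise
#'   (it is still used for stitching tolerances and gap slack).
#' @param match_bonus score gained per matched label pair.
#' @param miss_penalty score lost per skipped reference label.
#' @param false_penalty score lost per skipped query label.
#' @param lookback maximum extension step per side, i.e. at most
#'   `lookback - 1` consecutive labels can be skipped on either map.
#' @param min_matched_labels minimum matched pairs for an alignment to be
#'   reported.
#' @param min_score minimum local alignment score to be reported.
#' @param trailing_k number of unaligned labels beyond an alignment end (on
#'   both maps, same side) that defines an internal termination and hence a
#'   breakpoint.
#' @param max_drop X-drop threshold (score units): an alignment ends when its
#'   running score falls more than this below its running maximum, so a chain
#'   cannot drain through an extended discordant region and resume on the
#'   other side.
#' @param stitch_window collinear alignment segments of the same query, 
#'   reference, and orientation separated by less than this many bp on both
#'   maps are stitched back into one chain before breakpoint detection, so a
#'   transient scoring sag does not masquerade as a structural termination.
#' @param min_label_distance label condensation distance (bp) applied to
#'   in-silico digests before alignment, emulating instrument resolution.
#'
#' @return an object of class `align_params`.
#' @export
align_params <- function(sigma = 400,
                         gap_prior = 0,
                         penalty_weight = 1,
                         match_bonus = 3,
                         miss_penalty = 4,
                         false_penalty = 4,
                         lookback = 5L,
                         min_matched_labels = 9L,
                         min_score = 30,
                         trailing_k = 10L,
                         max_drop = 12,
                         stitch_window = 150000,
                         min_label_distance = 1000) {
  stopifnot(miss_penalty >= 0, false_penalty >= 0, lookback >= 1,
            trailing_k >= 1, sigma >= 0, max_drop > 0, penalty_weight > 0,
            min_label_distance >= 0)
  structure(list(
    sigma = sigma, gap_prior = gap_prior, penalty_weight = penalty_weight,
    match_bonus = match_bonus, miss_penalty = miss_penalty,
    false_penalty = false_penalty, lookback = as.integer(lookback),
    min_matched_labels = as.integer(min_matched_labels),
    min_score = min_score, trailing_k = as.integer(trailing_k),
    max_drop = max_drop, stitch_window = stitch_window,
    min_label_distance = min_label_distance
  ), class = "align_params")
}
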