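#' Validate a scaffold layout against optical label maps
#'
#' The full conflict-detection pass: in-silico digestion of the observed
#' scaffolds, per-channel alignment of every query map against every
#' scaffold map (with sizing slack at declared Hi-C gaps), breakpoint
#' extraction, cross-channel merging, classification relative to Hi-C gaps,
#' gap-size estimation, optional read-support assessment, scaffold cutting
#' at confirmed structural conflicts, and before/after statistics.
#'
#' @param layout the observed [scaffold_layout] to validate.
#' @param contigs named [Biostrings::DNAStringSet] of contig sequences.
#' @param query_maps list of [label_map]s (optical consensus maps), named
#'   `"<map_id>|<channel>"`.
#' @param enzymes list of `list(name=, motif=)` (channels to digest).
#' @param params an [align_params].
#' @param reads optional PAF tibble for junction read support.
#' @param merge_window,min_channels see [merge_channels()].
#' @param near_distance,gap_tol see [classify_conflicts()].
#' @param min_anchor,min_mapq,strong_min see [assess_junctions()].
#' @param classes_to_cut conflict classes that trigger scaffold cuts.
#' @return list of class `validation_result`: `ref_maps`, `alignments`,
#'   `breakpoints`, `conflicts` (classified), `gap_sizes`, `assessments`
#'   (or `NULL`), `support_summary` (or `NULL`), `layout_before`,
#'   `layout_after`, `stats_before`, `stats_after`.
#' @export
validate_scaffolds <- function(layout, contigs, query_maps, enzymes,
                               params = align_params(), reads = NULL,
                               merge_window = 50000, min_channels = 1,
                               near_distance = 50000, gap_tol = NULL,
                               min_anchor = 1000, min_mapq = 20, strong_min = 5,
                               classes_to_cut = "NEAR_GAP_STRUCTURAL") {
  scaf_seqs <- build_scaffold_seqs(layout, contigs)
  ref_maps <- in_silico_digest(scaf_seqs, enzymes, params$min_label_distance)
  hic_gaps <- gap_records(layout, source = "HIC")
  alignments <- list()
  for (qm in query_maps) {
    refs <- Filter(function(rm) rm$channel == qm$channel, ref_maps)
    alignments <- c(alignments,
                    align_to_reference_set(qm, refs, params, ref_gaps = hic_gaps,
                                           fragment_mode = TRUE))
  }
  alignments <- stitch_alignments(alignments, query_maps, ref_maps, params,
                                  ref_gaps = hic_gaps)
  ## reporting thresholds apply to the stitched chains
  alignments <- Filter(function(a)
    a$score >= params$min_score && nrow(a$pairs) >= params$min_matched_labels,
    alignments)
  breakpoints <- detect_breakpoints(alignments, ref_maps, params,
                                    query_maps = query_maps,
                                    require_continuation = TRUE)
  breakpoints <- suppress_collinear_terminations(breakpoints, alignments,
                                                 query_maps, ref_maps,
                                                 hic_gaps, params)
  conflicts <- merge_channels(breakpoints, merge_window, min_channels)
  conflicts <- classify_conflicts(conflicts, hic_gaps, alignments,
                                  query_maps, ref_maps,
                                  near_distance = near_distance,
                                  gap_tol = gap_tol)
  gap_sizes <- gap_size_report(hic_gaps, alignments, query_maps, ref_maps)
  assessments <- NULL
  support_summary <- NULL
  if (!is.null(reads) && nrow(hic_gaps)) {
    assessments <- assess_junctions(reads, hic_gaps, min_anchor = min_anchor,
                                    min_mapq = min_mapq, strong_min = strong_min)
    support_summary <- summarize_support(assessments)
  }
  layout_after <- cut_at_conflicts(layout, conflicts,
                                   classes_to_cut = classes_to_cut,
                                   near_distance = near_distance)
  structure(list(
    ref_maps = ref_maps, alignments = alignments, breakpoints = breakpoints,
    conflicts = conflicts, gap_sizes = gap_sizes,
    assessments = assessments, support_summary = support_summary,
    layout_before = layout, layout_after = layout_after,
    stats_before = assembly_stats(layout),
    stats_after = assembly_stats(layout_after)
  ), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  tab <- table(factor(x$conflicts$classification,
                      levels = c("NEAR_GAP_STRUCTURAL", "GAP_SIZE_ONLY", "INTERNAL")))
  cat(sprintf("<validation_result> %d breakpoints -> %d conflicts (%s)\n",
              nrow(x$breakpoints), nrow(x$conflicts),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  cat(sprintf("  scaffolds %d -> %d, N50 %s -> %s\n",
              x$stats_before$n_scaffolds, x$stats_after$n_scaffolds,
              format(x$stats_before$scaffold_n50, big.mark = ","),
              format(x$stats_after$scaffold_n50, big.mark = ",")))
  invisible(x)
}

#' Score conflict recall and precision against simulation ground truth
#'
#' @param result a `validation_result`.
#' @param truth the `ground_truth` the dataset was simulated from.
#' @param window maximum distance (bp) between a conflict and the recorded
#'   misjoin junction for a hit (default 50 kb).
#' @return list: `n_misjoins`, `n_detected` (misjoins with a
#'   `NEAR_GAP_STRUCTURAL` conflict within `window`), `false_at_correct`
#'   (conflicts within `window` of an intact junction but not of any
#'   misjoined one), `junctions` (the [junction_truth()] table).
#' @export
score_against_truth <- function(result, truth, window = 50000) {
  jt <- junction_truth(truth)
  mj <- truth$misjoin_records
  conf <- result$conflicts
  struct <- conf[conf$classification == "NEAR_GAP_STRUCTURAL", , drop = FALSE]
  detected <- vapply(seq_len(nrow(mj)), function(k) {
    any(struct$scaffold == mj$scaffold[k] &
          abs(struct$position - mj$position[k]) <= window)
  }, TRUE)
  bad <- jt[!jt$intact, , drop = FALSE]
  good <- jt[jt$intact, , drop = FALSE]
  near_any <- function(cf, tab) {
    if (!nrow(tab)) return(rep(FALSE, nrow(cf)))
    vapply(seq_len(nrow(cf)), function(k) {
      any(tab$scaffold == cf$scaffold[k] &
            pmax(0, pmax(tab$start - cf$position[k],
                         cf$position[k] - tab$end)) <= window)
    }, TRUE)
  }
  false_hits <- near_any(conf, good) & !near_any(conf, bad)
  list(n_misjoins = nrow(mj), n_detected = sum(detected),
       false_at_correct = sum(false_hits), junctions = jt)
}

#' Write a simulated dataset to disk
#'
#' Emits the generator's external formats: genome, contig and scaffold
#' FASTA, true and observed AGP, query-map CMAP, read PAF, ground-truth
#' misjoin BED, and a JSON echo of the configuration.
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(dataset$genome, p("genome.fasta"))
  Biostrings::writeXStringSet(dataset$truth$contigs, p("contigs.fasta"))
  scafs <- build_scaffold_seqs(dataset$truth$observed_layout, dataset$truth$contigs)
  Biostrings::writeXStringSet(scafs, p("scaffolds.fasta"))
  write_agp(dataset$truth$true_layout, p("true_layout.agp"))
  write_agp(dataset$truth$observed_layout, p("observed_layout.agp"))
  write_cmap(dataset$query_maps, p("query_maps.cmap"))
  if (!is.null(dataset$reads)) write_paf(dataset$reads, p("reads.paf"))
  mj <- dataset$truth$misjoin_records
  if (nrow(mj)) {
    bed <- data.frame(mj$scaffold, format(mj$position, scientific = FALSE),
                      format(mj$position + 1, scientific = FALSE),
                      paste0(mj$type, ":", mj$left_comp, "-", mj$right_comp))
    utils::write.table(bed, p("misjoins.bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- dataset$config
    cfg$misjoins <- as.list(cfg$misjoins)
    jsonlite::write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Write breakpoints as BED
#'
#' 0-based half-open single-base intervals, name `channel:query:side`,
#' score = alignment score.
#'
#' @param breakpoints tibble from [detect_breakpoints()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_breakpoints_bed <- function(breakpoints, path) {
  bed <- data.frame(
    breakpoints$scaffold,
    format(floor(breakpoints$position), scientific = FALSE),
    format(floor(breakpoints$position) + 1, scientific = FALSE),
    paste0(breakpoints$channel, ":", breakpoints$query_id, ":", breakpoints$side),
    round(breakpoints$score, 1))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
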