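#' Read / write PAF alignment records
#'
#' Minimal PAF (12 mandatory columns): query name/length/start/end, strand,
#' target name/length/start/end, matches, alignment length, mapping quality.
#' Coordinates 0-based half-open.
#'
#' @param path file path.
#' @return `read_paf`: tibble with columns `qname`, `qlen`, `qstart`,
#'   `qend`, `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`,
#'   `mapq`.
#' @export
read_paf <- function(path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq")
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = cols, fill = TRUE)[, cols]
  tibble::as_tibble(tab)
}

#' @rdname read_paf
#' @param records PAF tibble.
#' @export
write_paf <- function(records, path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Does a single read alignment span a junction?
#'
#' TRUE iff one primary record covers the whole window
#' `[gap.start - min_anchor, gap.end + min_anchor)` on the gap's scaffold
#' with mapping quality at least `min_mapq`. Split or supplementary
#' fragments of a read are never combined: a read broken across a junction
#' is evidence against the join, not for it.
#'
#' @param record one PAF row (or a tibble; vectorised over rows).
#' @param gap one row of [gap_records()].
#' @param min_anchor required anchored bp on each side of the gap.
#' @param min_mapq minimum mapping quality.
#' @return logical vector, one per record row.
#' @export
spans_junction <- function(record, gap, min_anchor = 1000, min_mapq = 20) {
  record$tname == gap$scaffold &
    record$tstart <= gap$start - min_anchor &
    record$tend >= gap$end + min_anchor &
    record$mapq >= min_mapq
}

#' Assess every Hi-C junction by spanning-read support
#'
#' Counts spanning reads per gap via [spans_junction()] and assigns the
#' support class: `UNSUPPORTED` (0 reads — the signature of a confirmed
#' misjoin), `WEAK` (fewer than `strong_min`), `SUPPORTED` (at least
#' `strong_min`). Junctions on scaffolds absent from the alignments are
#' counted 0 and flagged `no_data`.
#'
#' @param records PAF tibble.
#' @param gaps tibble from [gap_records()] (HIC gaps).
#' @param min_anchor,min_mapq see [spans_junction()].
#' @param strong_min minimum spanning reads for full support (default 5).
#' @return tibble: `junction_id`, `scaffold`, `gap_index`, `start`, `end`,
#'   `spanning_count`, `support_class`, `no_data`.
#' @export
assess_junctions <- function(records, gaps, min_anchor = 1000, min_mapq = 20,
                             strong_min = 5) {
  by_scaf <- split(seq_len(nrow(records)), records$tname)
  n <- nrow(gaps)
  count <- integer(n)
  nodata <- logical(n)
  for (k in seq_len(n)) {
    idx <- by_scaf[[gaps$scaffold[k]]]
    if (is.null(idx)) {
      nodata[k] <- TRUE
      next
    }
    count[k] <- sum(spans_junction(records[idx, ], gaps[k, ],
                                   min_anchor = min_anchor, min_mapq = min_mapq))
  }
  klass <- ifelse(count == 0, "UNSUPPORTED",
                  ifelse(count < strong_min, "WEAK", "SUPPORTED"))
  tibble::tibble(
    junction_id = paste0(gaps$scaffold, ":gap", gaps$gap_index),
    scaffold = gaps$scaffold, gap_index = gaps$gap_index,
    start = gaps$start, end = gaps$end,
    spanning_count = count, support_class = klass, no_data = nodata)
}

#' Summarise junction support classes
#'
#' @param assessments tibble from [assess_junctions()].
#' @return tibble with one row per class (`UNSUPPORTED`, `WEAK`,
#'   `SUPPORTED`): `count`, `total`, `percentage` (rounded to the nearest
#'   integer).
#' @export
summarize_support <- function(assessments) {
  if (is.null(assessments) || nrow(assessments) == 0)
    stop("cannot summarise empty junction assessments", call. = FALSE)
  classes <- c("UNSUPPORTED", "WEAK", "SUPPORTED")
  count <- vapply(classes, function(cl)
    sum(assessments$support_class == cl), 0L)
  total <- nrow(assessments)
  tibble::tibble(support_class = classes, count = unname(count), total = total,
                 percentage = unname(floor(100 * count / total + 0.5)))
}
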