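#' Nxx contiguity statistic
#'
#' Smallest length L such that pieces of length >= L together contain at
#' least `fraction` of the total (lengths sorted descending, cumulative-sum
#' rule). `fraction = 0.5` gives the familiar N50.
#'
#' @param lengths positive piece lengths.
#' @param fraction target fraction in (0, 1).
#' @return the Nxx value in bp.
#' @export
nxx <- function(lengths, fraction = 0.5) {
  if (length(lengths) == 0)
    stop("Nxx is undefined for an empty length set", call. = FALSE)
  stopifnot(all(lengths > 0), fraction > 0, fraction < 1)
  srt <- sort(lengths, decreasing = TRUE)
  srt[which(cumsum(srt) >= fraction * sum(srt))[1]]
}

#' Assembly statistics of a scaffold layout
#'
#' Computes the standard contiguity report: totals, scaffold count and
#' N50/mean/extremes, gap count and total gap bases, placed contig count,
#' and the same summary over the unplaced ("remaining") contigs. Scaffold
#' fields are `NA` when the layout has no scaffolds.
#'
#' @param layout a [scaffold_layout].
#' @return an object of class `assembly_stats` (a named list).
#' @export
assembly_stats <- function(layout) {
  slen <- as.numeric(scaffold_lengths(layout))
  gaps <- gap_records(layout)
  comp <- layout$components
  rem <- layout$unplaced$length
  has_sc <- length(slen) > 0
  out <- list(
    total_assembly_length = sum(slen) + sum(rem),
    total_scaffold_length = if (has_sc) sum(slen) else NA_real_,
    n_scaffolds = length(slen),
    scaffold_n50 = if (has_sc) nxx(slen, 0.5) else NA_real_,
    scaffold_mean = if (has_sc) mean(slen) else NA_real_,
    scaffold_longest = if (has_sc) max(slen) else NA_real_,
    scaffold_shortest = if (has_sc) min(slen) else NA_real_,
    n_gaps = nrow(gaps),
    gap_size = sum(gaps$declared_length),
    contigs_in_scaffolds = sum(comp$type == "W"),
    remaining_contigs = length(rem),
    remaining_total_length = sum(rem),
    remaining_n50 = if (length(rem)) nxx(rem, 0.5) else NA_real_,
    remaining_mean = if (length(rem)) mean(rem) else NA_real_,
    remaining_max = if (length(rem)) max(rem) else NA_real_,
    remaining_min = if (length(rem)) min(rem) else NA_real_
  )
  structure(out, class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  for (f in names(x)) cat(sprintf("%-24s %s\n", f, format(x[[f]], big.mark = ",")))
  invisible(x)
}

#' Misjoin involvement rate by contig-length bin
#'
#' Bins every contig (placed and unplaced) by length into
#' `[k*bin_width, (k+1)*bin_width)` and reports, per bin, how many contigs
#' were involved in a misjoin and the percentage `floor(100 * involved /
#' count)`. Bins with no contigs are reported with `NA` percentage.
#'
#' @param layout a [scaffold_layout].
#' @param involved_ids contig ids flanking misjoined junctions.
#' @param bin_width bin width in bp.
#' @return tibble: `bin_start`, `bin_end`, `n_contigs`, `n_involved`,
#'   `percentage`.
#' @export
error_rate_by_contig_length <- function(layout, involved_ids, bin_width = 50000) {
  stopifnot(bin_width > 0)
  comp <- layout$components
  w <- comp[comp$type == "W", , drop = FALSE]
  lens <- c(stats::setNames(w$comp_end - w$comp_beg, w$comp_id),
            stats::setNames(layout$unplaced$length, layout$unplaced$comp_id))
  bins <- floor(lens / bin_width)
  kmax <- max(bins)
  rows <- lapply(0:kmax, function(k) {
    ids <- names(lens)[bins == k]
    n <- length(ids)
    inv <- sum(ids %in% involved_ids)
    tibble::tibble(bin_start = k * bin_width, bin_end = (k + 1) * bin_width,
                   n_contigs = n, n_involved = inv,
                   percentage = if (n > 0) floor(100 * inv / n) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Integer percentage of a count ratio
#'
#' `100 * numerator / denominator` under an explicit rounding mode:
#' `"nearest"` (half away from zero) or `"floor"`. Published summaries mix
#' both conventions, so the mode is never implicit.
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @param rounding `"nearest"` or `"floor"`.
#' @return integer percent in `[0, 100]`.
#' @export
percentage_summary <- function(numerator, denominator,
                               rounding = c("nearest", "floor")) {
  rounding <- match.arg(rounding)
  if (denominator <= 0)
    stop("percentage undefined: denominator must be > 0", call. = FALSE)
  x <- 100 * numerator / denominator
  if (rounding == "floor") floor(x) else floor(x + 0.5)
}

#' Compare two assembly statistics reports
#'
#' @param stats_before,stats_after `assembly_stats` objects with matching
#'   fields.
#' @return tibble: `field`, `before`, `after`, `delta` (after - before),
#'   `fold` (after / before).
#' @export
compare_runs <- function(stats_before, stats_after) {
  stopifnot(identical(names(stats_before), names(stats_after)))
  b <- as.numeric(unlist(stats_before))
  a <- as.numeric(unlist(stats_after))
  tibble::tibble(field = names(stats_before), before = b, after = a,
                 delta = a - b, fold = a / b)
}
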