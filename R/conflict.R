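#' Merge breakpoints across enzyme channels into conflicts
#'
#' Breakpoints on the same scaffold within `merge_window` of each other are
#' clustered by single linkage; each cluster becomes one conflict at the
#' median breakpoint position with the union of supporting channels. Two
#' independent enzyme channels calling the same position is strong evidence
#' that the map reconstruction, not the labelling, contradicts the assembly.
#'
#' @param breakpoints tibble from [detect_breakpoints()].
#' @param merge_window single-linkage distance in bp (default 50 kb).
#' @param min_channels minimum distinct channels per retained conflict
#'   (default 1; 2 reproduces dual-enzyme confirmation).
#' @return tibble of unclassified conflicts: `scaffold`, `position`,
#'   `channels` (comma-collapsed), `n_channels`, `n_breakpoints`,
#'   `dual_channel`.
#' @export
merge_channels <- function(breakpoints, merge_window = 50000, min_channels = 1) {
  empty <- tibble::tibble(scaffold = character(0), position = numeric(0),
                          channels = character(0), n_channels = integer(0),
                          n_breakpoints = integer(0), dual_channel = logical(0))
  if (is.null(breakpoints) || nrow(breakpoints) == 0) return(empty)
  rows <- list()
  for (s in unique(breakpoints$scaffold)) {
    sub <- breakpoints[breakpoints$scaffold == s, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    cl <- cumsum(c(1, diff(sub$position) > merge_window))
    for (g in unique(cl)) {
      grp <- sub[cl == g, , drop = FALSE]
      ch <- sort(unique(grp$channel))
      rows[[length(rows) + 1]] <- tibble::tibble(
        scaffold = s, position = stats::median(grp$position),
        channels = paste(ch, collapse = ","), n_channels = length(ch),
        n_breakpoints = nrow(grp), dual_channel = length(ch) >= 2)
    }
  }
  out <- do.call(rbind, rows)
  out[out$n_channels >= min_channels, , drop = FALSE]
}

## matched ref-label counts of an alignment just left/right of a gap;
## only labels within `window` bp of the gap count, so an alignment whose
## nearest matches sit far away cannot pass as locally spanning
spanning_flanks <- function(aln, gap, ref_map, window = Inf) {
  rpos <- ref_map$positions[aln$pairs[, "ref"]]
  c(left = sum(rpos <= gap$start & rpos >= gap$start - window),
    right = sum(rpos >= gap$end & rpos <= gap$end + window))
}

#' Implied physical size of a declared gap
#'
#' Uses an alignment whose matched labels flank the gap: the optical map
#' measures the physical distance between the two labels; subtracting the
#' scaffold sequence distances from each label to its side of the gap leaves
#' the implied gap size. May be negative (the joined contigs overlap).
#'
#' @param aln a `map_alignment` spanning the gap.
#' @param gap one row of [gap_records()] (`start`, `end`, `declared_length`).
#' @param query_map,ref_map the aligned [label_map]s.
#' @param anchor_offset count this many matched pairs outward from the gap
#'   before anchoring the measurement (default 3): the pairs immediately at
#'   the crossing are the ones the aligner may have paired ambiguously,
#'   while pairs a couple of labels away are locked in by their context.
#' @return implied gap size in bp, or `NA` if the alignment has no matched
#'   label on one side.
#' @export
estimate_gap_size <- function(aln, gap, query_map, ref_map, anchor_offset = 3) {
  rpos <- ref_map$positions[aln$pairs[, "ref"]]
  qpos <- query_map$positions[aln$pairs[, "query_orig"]]
  li <- which(rpos <= gap$start)
  ri <- which(rpos >= gap$end)
  if (!length(li) || !length(ri)) return(NA_real_)
  li <- max(1, li[length(li)] - anchor_offset)
  ri <- min(length(rpos), ri[1] + anchor_offset)
  qd <- abs(qpos[ri] - qpos[li])
  qd - (gap$start - rpos[li]) - (rpos[ri] - gap$end)
}

#' Classify conflicts relative to Hi-C gaps
#'
#' For each conflict the distance to the nearest `"HIC"`-sourced gap is
#' computed. If some alignment cleanly spans that gap (at least
#' `span_flank_labels` matched labels on each side) yet the implied gap size
#' disagrees with the declared filler by more than `gap_tol`, the conflict is
#' `GAP_SIZE_ONLY` — the join is structurally fine, only the filler length is
#' wrong. Otherwise conflicts within `near_distance` of a gap are
#' `NEAR_GAP_STRUCTURAL` (candidate scaffolding errors at a Hi-C junction)
#' and the rest `INTERNAL`.
#'
#' @param conflicts tibble from [merge_channels()].
#' @param gaps tibble from [gap_records()] (HIC gaps of the layout).
#' @param alignments list of `map_alignment`s over the same reference maps.
#' @param query_maps,ref_maps label-map lists indexed `"<id>|<channel>"`.
#' @param near_distance bp radius defining "near a gap" (default 50 kb).
#' @param gap_tol tolerance on `|implied - declared|`; default
#'   `max(10000, declared_length)` per gap.
#' @param span_flank_labels matched labels required on each side of a gap,
#'   within `near_distance` of it, for an alignment to count as cleanly
#'   spanning it (default 3).
#' @param min_spanning minimum number of independent cleanly spanning
#'   alignments required before a conflict may be downgraded to
#'   `GAP_SIZE_ONLY` (default 2): a single spanning chain can be a
#'   coincidental crossing, while a genuine size-only discrepancy is seen by
#'   every channel covering the junction.
#' @return `conflicts` with added columns `nearest_gap_distance` (bp or
#'   `Inf`), `nearest_gap_index`, `implied_gap` (bp or `NA`),
#'   `classification`.
#' @export
classify_conflicts <- function(conflicts, gaps, alignments, query_maps, ref_maps,
                               near_distance = 50000, gap_tol = NULL,
                               span_flank_labels = 3, min_spanning = 2) {
  n <- nrow(conflicts)
  nearest_d <- rep(Inf, n)
  nearest_i <- rep(NA_integer_, n)
  implied <- rep(NA_real_, n)
  klass <- rep("INTERNAL", n)
  for (k in seq_len(n)) {
    g <- gaps[gaps$scaffold == conflicts$scaffold[k], , drop = FALSE]
    if (!nrow(g)) next
    pos <- conflicts$position[k]
    d <- pmax(0, pmax(g$start - pos, pos - g$end))
    j <- which.min(d)
    nearest_d[k] <- d[j]
    nearest_i[k] <- g$gap_index[j]
    gap <- g[j, ]
    ## implied size from alignments cleanly spanning the nearest gap
    est <- numeric(0)
    for (aln in alignments) {
      if (aln$ref_id != gap$scaffold) next
      rmap <- ref_maps[[paste0(aln$ref_id, "|", aln$channel)]]
      qmap <- query_maps[[paste0(aln$query_id, "|", aln$channel)]]
      if (is.null(rmap) || is.null(qmap)) next
      fl <- spanning_flanks(aln, gap, rmap, window = near_distance)
      if (fl["left"] >= span_flank_labels && fl["right"] >= span_flank_labels) {
        e <- estimate_gap_size(aln, gap, qmap, rmap)
        if (!is.na(e)) est <- c(est, e)
      }
    }
    tol <- if (is.null(gap_tol)) max(10000, gap$declared_length) else gap_tol
    if (length(est)) {
      implied[k] <- stats::median(est)
      if (length(est) >= min_spanning &&
          abs(implied[k] - gap$declared_length) > tol) {
        klass[k] <- "GAP_SIZE_ONLY"
        next
      }
    }
    if (nearest_d[k] <= near_distance) klass[k] <- "NEAR_GAP_STRUCTURAL"
  }
  conflicts$nearest_gap_distance <- nearest_d
  conflicts$nearest_gap_index <- nearest_i
  conflicts$implied_gap <- implied
  conflicts$classification <- klass
  conflicts
}

#' Declared vs implied size for every Hi-C gap
#'
#' @inheritParams classify_conflicts
#' @param span_window bp window around the gap within which flanking matched
#'   labels must lie (default 50 kb).
#' @return `gaps` with added `implied_gap` (median over cleanly spanning
#'   alignments, `NA` when none) and `n_spanning_alignments`.
#' @export
gap_size_report <- function(gaps, alignments, query_maps, ref_maps,
                            span_flank_labels = 3, span_window = 50000) {
  implied <- rep(NA_real_, nrow(gaps))
  nspan <- integer(nrow(gaps))
  for (k in seq_len(nrow(gaps))) {
    gap <- gaps[k, ]
    est <- numeric(0)
    for (aln in alignments) {
      if (aln$ref_id != gap$scaffold) next
      rmap <- ref_maps[[paste0(aln$ref_id, "|", aln$channel)]]
      qmap <- query_maps[[paste0(aln$query_id, "|", aln$channel)]]
      if (is.null(rmap) || is.null(qmap)) next
      fl <- spanning_flanks(aln, gap, rmap, window = span_window)
      if (fl["left"] >= span_flank_labels && fl["right"] >= span_flank_labels) {
        e <- estimate_gap_size(aln, gap, qmap, rmap)
        if (!is.na(e)) est <- c(est, e)
      }
    }
    nspan[k] <- length(est)
    if (length(est)) implied[k] <- stats::median(est)
  }
  gaps$implied_gap <- implied
  gaps$n_spanning_alignments <- nspan
  gaps
}

#' Cut scaffolds at confirmed conflicts
#'
#' Each conflict whose classification is in `classes_to_cut` splits its
#' scaffold. A conflict within `near_distance` of a gap removes that gap:
#' the scaffold separates into two and the filler bases are dropped. An
#' `INTERNAL` conflict splits the containing contig at the conflict position
#' into two components. Contig bases are conserved (minus nothing: only gap
#' filler bases are removed) and output scaffolds are re-numbered.
#'
#' @param layout a [scaffold_layout].
#' @param conflicts classified conflicts from [classify_conflicts()].
#' @param classes_to_cut classifications that trigger a cut.
#' @param near_distance bp radius used to snap a conflict to its gap.
#' @return a new [scaffold_layout].
#' @export
cut_at_conflicts <- function(layout, conflicts,
                             classes_to_cut = "NEAR_GAP_STRUCTURAL",
                             near_distance = 50000) {
  comp <- layout$components
  cuts <- conflicts[conflicts$classification %in% classes_to_cut, , drop = FALSE]
  if (nrow(cuts)) {
    slen <- scaffold_lengths(layout)
    bad <- !(cuts$scaffold %in% names(slen)) |
      cuts$position < 0 | cuts$position >= slen[cuts$scaffold]
    if (any(bad))
      stop("conflict coordinate outside scaffold: ",
           paste(cuts$scaffold[bad], round(cuts$position[bad]), collapse = "; "),
           call. = FALSE)
  }
  new_rows <- list()
  for (s in unique(comp$scaffold)) {
    sub <- comp[comp$scaffold == s, , drop = FALSE]
    sub <- sub[order(sub$part), , drop = FALSE]
    cs <- cuts[cuts$scaffold == s, , drop = FALSE]
    drop_gap <- rep(FALSE, nrow(sub))
    contig_cut <- list()
    for (k in seq_len(nrow(cs))) {
      pos <- cs$position[k]
      gidx <- which(sub$type != "W")
      if (length(gidx)) {
        d <- pmax(0, pmax(sub$start[gidx] - pos, pos - sub$end[gidx]))
        j <- gidx[which.min(d)]
        if (min(d) <= near_distance) {
          drop_gap[j] <- TRUE
          next
        }
      }
      widx <- which(sub$type == "W" & sub$start <= pos & sub$end > pos)
      if (length(widx) == 1) {
        contig_cut[[length(contig_cut) + 1]] <- c(row = widx, pos = pos)
      }
    }
    ## expand component rows into pieces, inserting breaks
    pieces <- list()   # list of rows; NULL marker = scaffold break
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, ]
      if (row$type != "W") {
        if (drop_gap[i]) pieces[[length(pieces) + 1]] <- "BREAK"
        else pieces[[length(pieces) + 1]] <- row
        next
      }
      at <- sort(unique(vapply(contig_cut, function(x)
        if (x["row"] == i) x["pos"] else NA_real_, 0)))
      at <- at[!is.na(at) & at > row$start & at < row$end]
      if (!length(at)) {
        pieces[[length(pieces) + 1]] <- row
      } else {
        bnds <- c(row$start, at, row$end)
        for (p in seq_len(length(bnds) - 1)) {
          piece <- row
          piece$start <- bnds[p]; piece$end <- bnds[p + 1]
          off1 <- bnds[p] - row$start; off2 <- bnds[p + 1] - row$start
          if (row$orientation == "+") {
            piece$comp_beg <- row$comp_beg + off1
            piece$comp_end <- row$comp_beg + off2
          } else {
            piece$comp_beg <- row$comp_end - off2
            piece$comp_end <- row$comp_end - off1
          }
          piece$comp_id <- paste0(row$comp_id, ".", p)
          pieces[[length(pieces) + 1]] <- piece
          if (p < length(bnds) - 1) pieces[[length(pieces) + 1]] <- "BREAK"
        }
      }
    }
    ## regroup into scaffolds, dropping dangling gaps at break boundaries
    groups <- list(list())
    for (p in pieces) {
      if (identical(p, "BREAK")) groups[[length(groups) + 1]] <- list()
      else groups[[length(groups)]][[length(groups[[length(groups)]]) + 1]] <- p
    }
    gi <- 0
    for (grp in groups) {
      while (length(grp) && grp[[1]]$type != "W") grp <- grp[-1]
      while (length(grp) && grp[[length(grp)]]$type != "W") grp <- grp[-length(grp)]
      if (!length(grp)) next
      gi <- gi + 1
      nm <- if (length(groups) == 1) s else paste0(s, "_", gi)
      pos <- 0; part <- 1L
      for (row in grp) {
        w <- row$end - row$start
        row$scaffold <- nm
        row$start <- pos; row$end <- pos + w
        row$part <- part
        new_rows[[length(new_rows) + 1]] <- row
        pos <- pos + w; part <- part + 1L
      }
    }
  }
  scaffold_layout(do.call(rbind, new_rows), layout$unplaced)
}
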