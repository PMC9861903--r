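#' Sizing-error penalty for a pair of intervals
#'
#' Chi-square-style penalty comparing a query (optical) interval with a
#' reference (in-silico) interval: `(q - r)^2 / (sigma^2 * max(r, 1000)/1000)`,
#' i.e. the squared sizing error in units of the expected measurement
#' variance for an interval of that size. Symmetric in the sign of the
#' difference; zero iff the intervals agree. With `sigma = 0` any mismatch is
#' a forbidden transition (`Inf`).
#'
#' @param q_len,r_len interval lengths in bp (vectorised).
#' @param sigma sizing SD scale in bp per sqrt(kb).
#' @return penalty in score units.
#' @export
interval_penalty <- function(q_len, r_len, sigma) {
  stopifnot(all(q_len >= 0), all(r_len >= 0))
  diff <- q_len - r_len
  if (sigma <= 0) return(ifelse(diff == 0, 0, Inf))
  diff^2 / (sigma^2 * pmax(r_len, 1000) / 1000)
}

orient_positions <- function(map, orientation) {
  if (orientation == "+") map$positions else rev(map$length - map$positions)
}

## cumulative declared-gap bp at each (oriented) reference label position
gap_cumsum_at <- function(positions, ref_gaps) {
  if (is.null(ref_gaps) || nrow(ref_gaps) == 0) return(numeric(length(positions)))
  vapply(positions, function(p)
    sum(ref_gaps$declared_length[ref_gaps$end <= p]), 0)
}

#' Align a label map against a set of reference maps
#'
#' Local alignment over label indices with the [interval_penalty()] sizing
#' model, skip penalties for unobserved reference labels (`miss_penalty`)
#' and spurious query labels (`false_penalty`), and a `lookback` bound on
#' consecutive skips. Both query orientations are evaluated against every
#' reference. All local optima with score >= `min_score` and >=
#' `min_matched_labels` matched pairs are reported greedily by score,
#' non-overlapping on the query across the whole reference set: each query
#' label is claimed by its best-scoring placement, so a region cannot also
#' align spuriously elsewhere. A reference region may still attract several
#' queries. Reference intervals containing declared Hi-C gap fillers
#' (`ref_gaps`) get sizing slack, since the filler length is a placeholder,
#' not a measurement. Chains are segmented with an X-drop (`max_drop`): an
#' alignment cannot sag through an extended discordant region and resume.
#'
#' @param query a [label_map].
#' @param refs list of reference [label_map]s (same channel as the query).
#' @param params an [align_params].
#' @param ref_gaps optional tibble of declared gaps on the references
#'   (columns `scaffold`, `start`, `end`, `declared_length`), as from
#'   [gap_records()].
#' @param fragment_mode keep small low-scoring fragments (>= 3 pairs) that
#'   would normally be discarded, so that [stitch_alignments()] can assemble
#'   them into chains; apply the reporting thresholds to the stitched chains
#'   instead (this is what the pipeline does).
#' @return list of `map_alignment` objects: `query_id`, `ref_id`, `channel`,
#'   `orientation`, `score`, `pairs` (matrix with columns `query` (oriented
#'   index), `query_orig` (original index), `ref`), and unaligned flank
#'   label counts `query_left`, `query_right`, `ref_left`, `ref_right`
#'   (query flanks in oriented coordinates, so "left" is always the
#'   low-reference side).
#' @export
align_to_reference_set <- function(query, refs, params = align_params(),
                                   ref_gaps = NULL, fragment_mode = FALSE) {
  min_pairs <- if (fragment_mode) 3L else params$min_matched_labels
  min_sc <- if (fragment_mode) min(9, params$min_score) else params$min_score
  nq <- length(query$positions)
  if (nq < min_pairs) return(list())
  dp <- list()
  cand <- list()
  for (ri in seq_along(refs)) {
    ref <- refs[[ri]]
    nr <- length(ref$positions)
    if (nr < params$min_matched_labels) next
    g <- ref_gaps
    if (!is.null(g) && "scaffold" %in% names(g))
      g <- g[g$scaffold == ref$map_id, , drop = FALSE]
    gcum <- gap_cumsum_at(ref$positions, g)
    for (orient in c("+", "-")) {
      qpos <- orient_positions(query, orient)
      res <- dp_fill_cpp(qpos, ref$positions, gcum, params$sigma,
                         params$match_bonus, params$miss_penalty,
                         params$false_penalty, params$lookback,
                         params$max_drop, params$penalty_weight,
                         params$gap_prior)
      key <- paste0(ri, orient)
      dp[[key]] <- res
      hits <- which(res$S >= min_sc, arr.ind = TRUE)
      if (nrow(hits)) {
        cand[[key]] <- data.frame(i = hits[, 1], j = hits[, 2],
                                  score = res$S[hits], ri = ri,
                                  orient = orient, stringsAsFactors = FALSE)
      }
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) return(list())
  cand <- cand[order(-cand$score), , drop = FALSE]
  to_orig <- function(i, orient) if (orient == "+") i else nq + 1L - i
  used <- logical(nq)
  out <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    orient <- cand$orient[k]; ri <- cand$ri[k]
    if (used[to_orig(i, orient)]) next
    key <- paste0(ri, orient)
    S <- dp[[key]]$S; Pa <- dp[[key]]$Pa; Pb <- dp[[key]]$Pb
    ref <- refs[[ri]]
    nr <- length(ref$positions)
    ## traceback; truncate where the chain reaches an already-claimed query
    ## label, so the unclaimed continuation of a shared chain is kept (its
    ## segment-local score is the score difference across the retained part)
    chain_i <- integer(0); chain_j <- integer(0)
    ci <- i; cj <- j
    base <- 0
    repeat {
      if (used[to_orig(ci, orient)]) { base <- S[ci, cj]; break }
      chain_i <- c(ci, chain_i); chain_j <- c(cj, chain_j)
      a <- Pa[ci, cj]; b <- Pb[ci, cj]
      if (a == 0L) break
      ci <- ci - a; cj <- cj - b
    }
    n <- length(chain_i)
    if (n < min_pairs) next
    score <- S[i, j] - base
    if (score < min_sc) next
    orig <- vapply(chain_i, to_orig, 0L, orient = orient)
    used[orig] <- TRUE
    out[[length(out) + 1]] <- structure(list(
      query_id = query$map_id, ref_id = ref$map_id, channel = query$channel,
      orientation = orient, score = score,
      pairs = cbind(query = chain_i, query_orig = orig, ref = chain_j),
      query_left = chain_i[1] - 1L,
      query_right = nq - chain_i[n],
      ref_left = chain_j[1] - 1L,
      ref_right = nr - chain_j[n]
    ), class = "map_alignment")
  }
  out
}

#' Align two label maps
#'
#' Convenience wrapper around [align_to_reference_set()] for a single
#' reference map.
#'
#' @param query,ref [label_map] objects.
#' @param params an [align_params].
#' @param ref_gaps optional tibble of declared gaps on the reference.
#' @return list of `map_alignment` objects (see [align_to_reference_set()]).
#' @export
align_maps <- function(query, ref, params = align_params(), ref_gaps = NULL) {
  align_to_reference_set(query, list(ref), params, ref_gaps)
}

#' @export
print.map_alignment <- function(x, ...) {
  cat(sprintf("<map_alignment> %s (%s) vs %s [%s] score=%.1f pairs=%d flanks q(%d,%d) r(%d,%d)\n",
              x$query_id, x$channel, x$ref_id, x$orientation, x$score,
              nrow(x$pairs), x$query_left, x$query_right, x$ref_left, x$ref_right))
  invisible(x)
}

#' Stitch collinear alignment segments into chains
#'
#' Local alignment ends a segment at any extended scoring sag (X-drop), but
#' a sag caused by a run of missed or false labels is not a structural
#' signal: the query resumes aligning right where it left off. Segments of
#' the same query, reference and orientation that are collinear on both maps
#' and separated by less than `stitch_window` bp on each are therefore
#' merged back into one chain. A genuinely discordant continuation — other
#' scaffold, flipped orientation, or a distant reference position — is never
#' stitched, and its terminations remain visible to breakpoint detection.
#'
#' @param alignments list of `map_alignment` from [align_maps()].
#' @param query_maps,ref_maps label-map lists indexed `"<id>|<channel>"`.
#' @param params an [align_params] (uses `stitch_window`).
#' @param ref_gaps optional tibble of declared gaps on the references (as
#'   from [gap_records()]): each declared gap inside the stitched stretch
#'   contributes `gap_allowance` of sizing slack, since its true physical
#'   size is unknown.
#' @param gap_allowance bp of slack per declared gap in the skipped stretch.
#' @param max_skipped_labels stitching is refused when the skipped stretch
#'   contains more than this many unaligned labels on either map: a scoring
#'   sag skips a handful of noisy labels, whereas a whole foreign region
#'   (a misplaced contig) contains dozens that simply do not align.

#' @return list of `map_alignment` chains (scores summed over stitched
#'   segments, flanks recomputed).
#' @export
stitch_alignments <- function(alignments, query_maps, ref_maps,
                              params = align_params(), ref_gaps = NULL,
                              gap_allowance = 20000, max_skipped_labels = 25) {
  if (length(alignments) < 2) return(alignments)
  key <- vapply(alignments, function(a)
    paste(a$query_id, a$ref_id, a$channel, a$orientation, sep = "\r"), "")
  out <- list()
  for (kk in unique(key)) {
    grp <- alignments[key == kk]
    if (length(grp) == 1) { out <- c(out, grp) ; next }
    qmap <- query_maps[[paste0(grp[[1]]$query_id, "|", grp[[1]]$channel)]]
    rmap <- ref_maps[[paste0(grp[[1]]$ref_id, "|", grp[[1]]$channel)]]
    rg <- ref_gaps
    if (!is.null(rg)) rg <- rg[rg$scaffold == grp[[1]]$ref_id, , drop = FALSE]
    ord <- order(vapply(grp, function(a) a$pairs[1, "query"], 0))
    grp <- grp[ord]
    cur <- grp[[1]]
    for (a_orig in grp[-1]) {
      last <- cur$pairs[nrow(cur$pairs), ]
      ## greedy label claims can interleave two chains slightly around a
      ## sag; speculatively trim the incoming chain's head back to strict
      ## collinearity (the trim only sticks if the stitch succeeds, so a
      ## non-collinear chain is never damaged)
      a <- a_orig
      trim <- 0L
      while (nrow(a$pairs) > 1 &&
             (a$pairs[1, "query"] <= last["query"] ||
              a$pairs[1, "ref"] <= last["ref"]) && trim < 20L) {
        a$pairs <- a$pairs[-1, , drop = FALSE]
        trim <- trim + 1L
      }
      if (trim > 0L) {
        a$query_left <- a$pairs[1, "query"] - 1L
        a$ref_left <- a$pairs[1, "ref"] - 1L
      }
      first <- a$pairs[1, ]
      q_gap <- abs(qmap$positions[first["query_orig"]] -
                     qmap$positions[last["query_orig"]])
      r_gap <- rmap$positions[first["ref"]] - rmap$positions[last["ref"]]
      ## the skipped stretch must also be size-consistent: a genuine scoring
      ## sag covers the same physical region on both maps, while a spurious
      ## bridge lands at an arbitrary offset; declared gaps inside the
      ## stretch have unknown true size and get gap_allowance of slack each
      lo <- rmap$positions[last["ref"]]; hi <- rmap$positions[first["ref"]]
      n_gaps <- 0; declared <- 0
      if (!is.null(rg) && nrow(rg)) {
        inside <- rg$start >= lo & rg$end <= hi
        n_gaps <- sum(inside)
        declared <- sum(rg$declared_length[inside])
      }
      r_net <- r_gap - declared
      tol <- 5 * params$sigma * sqrt(max(r_net, 1000) / 1000) + 0.05 * r_net
      consistent <- q_gap >= r_net - tol &
        q_gap <= r_net + tol + n_gaps * gap_allowance
      skipped <- max(first["ref"] - last["ref"], first["query"] - last["query"]) - 1
      if (first["query"] > last["query"] && first["ref"] > last["ref"] &&
          r_gap > 0 && r_gap < params$stitch_window && consistent &&
          skipped <= max_skipped_labels) {
        cur$pairs <- rbind(cur$pairs, a$pairs)
        cur$score <- cur$score + a$score
        cur$query_right <- a$query_right
        cur$ref_right <- a$ref_right
      } else {
        out[[length(out) + 1]] <- cur
        cur <- a_orig
      }
    }
    out[[length(out) + 1]] <- cur
  }
  out
}

#' Extract breakpoints from internally terminating alignments
#'
#' An alignment end is an internal termination when at least `trailing_k`
#' unaligned labels remain beyond it on *both* the query map and the
#' reference map on the same side: the two maps keep going but stop agreeing,
#' the signature of a structural conflict. Terminations at a map end emit
#' nothing. The breakpoint is placed at the reference position of the last
#' matched label on that side (conservative, always label-anchored).
#'
#' @param alignments list of `map_alignment` from [align_maps()].
#' @param ref_maps list of reference [label_map]s indexed by
#'   `"<map_id>|<channel>"` or by `map_id`.
#' @param params an [align_params] (uses `trailing_k`).
#' @param query_maps optional list of query [label_map]s (same indexing);
#'   needed for the physical end guard on the query side.
#' @param end_guard bp: alignment ends closer than this to a physical map
#'   end (on either map) are treated as map-end terminations — ragged
#'   unaligned label runs at map boundaries are instrument edge effects,
#'   not structural signals.
#' @param require_continuation when `TRUE`, a termination only counts as a
#'   breakpoint if some of the query labels beyond it (the next
#'   `continuation_window` labels) are aligned by another chain: at a real
#'   misjoin the query demonstrably continues somewhere else, whereas a
#'   ragged unalignable tail is claimed by nothing. The pipeline enables
#'   this; standalone calls default to the plain trailing-label rule.
#' @param continuation_window,min_continuation labels inspected beyond the
#'   termination and the minimum that must be aligned elsewhere.
#' @return tibble of breakpoints: `scaffold`, `position`, `channel`,
#'   `query_id`, `side` (`"left"`/`"right"`), `score`, `aln_id`.
#' @export
detect_breakpoints <- function(alignments, ref_maps, params = align_params(),
                               query_maps = NULL, end_guard = 30000,
                               require_continuation = FALSE,
                               continuation_window = 60, min_continuation = 3) {
  rows <- list()
  k <- params$trailing_k
  ## per (query, channel): which original query label indices are claimed
  claimed <- list()
  if (require_continuation) {
    for (aln in alignments) {
      kk <- paste0(aln$query_id, "|", aln$channel)
      claimed[[kk]] <- union(claimed[[kk]], aln$pairs[, "query_orig"])
    }
  }
  for (ai in seq_along(alignments)) {
    aln <- alignments[[ai]]
    rmap <- ref_maps[[paste0(aln$ref_id, "|", aln$channel)]]
    if (is.null(rmap)) rmap <- ref_maps[[aln$ref_id]]
    if (is.null(rmap)) stop("reference map not found for ", aln$ref_id, call. = FALSE)
    qmap <- NULL
    if (!is.null(query_maps)) {
      qmap <- query_maps[[paste0(aln$query_id, "|", aln$channel)]]
      if (is.null(qmap)) qmap <- query_maps[[aln$query_id]]
    }
    np <- nrow(aln$pairs)
    ## oriented query positions of the chain ends (for the end guard)
    q_end_dist <- function(row, side) {
      if (is.null(qmap)) return(Inf)
      pos <- qmap$positions[aln$pairs[row, "query_orig"]]
      if (aln$orientation == "-") pos <- qmap$length - pos
      if (side == "left") pos else qmap$length - pos
    }
    ## does the query continue aligned beyond this chain end?
    continues <- function(side) {
      if (!require_continuation) return(TRUE)
      nq_lab <- if (!is.null(qmap)) length(qmap$positions) else
        max(aln$pairs[, "query_orig"])
      o_end <- if (side == "left") aln$pairs[1, "query"] else aln$pairs[np, "query"]
      o_trail <- if (side == "left") seq_len(o_end - 1) else
        seq_len(nq_lab - o_end) + o_end
      if (length(o_trail) > continuation_window) {
        o_trail <- if (side == "left") utils::tail(o_trail, continuation_window)
                   else utils::head(o_trail, continuation_window)
      }
      orig <- if (aln$orientation == "+") o_trail else nq_lab + 1L - o_trail
      own <- aln$pairs[, "query_orig"]
      kk <- paste0(aln$query_id, "|", aln$channel)
      length(setdiff(intersect(orig, claimed[[kk]]), own)) >= min_continuation
    }
    if (aln$ref_left >= k && aln$query_left >= k) {
      rpos <- rmap$positions[aln$pairs[1, "ref"]]
      if (rpos >= end_guard && q_end_dist(1, "left") >= end_guard &&
          continues("left")) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          scaffold = aln$ref_id,
          position = rpos,
          channel = aln$channel, query_id = aln$query_id,
          side = "left", score = aln$score, aln_id = ai)
      }
    }
    if (aln$ref_right >= k && aln$query_right >= k) {
      rpos <- rmap$positions[aln$pairs[np, "ref"]]
      if (rmap$length - rpos >= end_guard &&
          q_end_dist(np, "right") >= end_guard &&
          continues("right")) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          scaffold = aln$ref_id,
          position = rpos,
          channel = aln$channel, query_id = aln$query_id,
          side = "right", score = aln$score, aln_id = ai)
      }
    }
  }
  if (!length(rows))
    return(tibble::tibble(scaffold = character(0), position = numeric(0),
                          channel = character(0), query_id = character(0),
                          side = character(0), score = numeric(0),
                          aln_id = integer(0)))
  do.call(rbind, rows)
}

#' Suppress termination pairs explained by collinear continuation
#'
#' A right-end breakpoint of chain A and a left-end breakpoint of chain B
#' (same query map, reference and orientation) are not structural evidence
#' when B resumes where A left off: the physical distance between interior
#' anchor pairs of A and B matches the reference distance (declared gaps get
#' `gap_allowance` slack each), meaning the query runs straight through and
#' the chains merely failed to align a noisy stretch between them. Interior
#' anchors (a few pairs in from the ends) make the test robust to ragged
#' chain boundaries. Suppression is additionally vetoed when any other
#' alignment occupies the intervening reference region: real misplaced
#' sequence between A and B attracts its own alignment, whereas a noisy
#' unalignable stretch stays empty. A genuinely misjoined junction therefore
#' keeps its terminations even when the foreign segment happens to have the
#' same size as the sequence it displaced.
#'
#' @param breakpoints tibble from [detect_breakpoints()] (needs `aln_id`).
#' @param alignments the chain list the breakpoints were derived from.
#' @param query_maps,ref_maps label-map lists indexed `"<id>|<channel>"`.
#' @param ref_gaps tibble of declared gaps (as from [gap_records()]).
#' @param params an [align_params].
#' @param max_span only consider continuations within this many bp on the
#'   reference (default 300 kb).
#' @param anchor use the anchor-th pair from each chain end (default 4).
#' @param gap_allowance bp of size slack per declared gap in the skipped
#'   stretch.
#' @return the breakpoint tibble with suppressed rows removed.
#' @export
suppress_collinear_terminations <- function(breakpoints, alignments,
                                            query_maps, ref_maps, ref_gaps,
                                            params = align_params(),
                                            max_span = 300000, anchor = 4,
                                            gap_allowance = 20000) {
  if (is.null(breakpoints) || nrow(breakpoints) == 0) return(breakpoints)
  drop <- logical(nrow(breakpoints))
  key <- vapply(alignments, function(a)
    paste(a$query_id, a$ref_id, a$channel, a$orientation, sep = "\r"), "")
  rights <- which(breakpoints$side == "right")
  lefts <- which(breakpoints$side == "left")
  for (ri in rights) {
    A <- alignments[[breakpoints$aln_id[ri]]]
    for (li in lefts) {
      B <- alignments[[breakpoints$aln_id[li]]]
      if (key[breakpoints$aln_id[li]] != key[breakpoints$aln_id[ri]]) next
      if (identical(breakpoints$aln_id[li], breakpoints$aln_id[ri])) next
      qmap <- query_maps[[paste0(A$query_id, "|", A$channel)]]
      rmap <- ref_maps[[paste0(A$ref_id, "|", A$channel)]]
      if (is.null(qmap) || is.null(rmap)) next
      na <- nrow(A$pairs); nb <- nrow(B$pairs)
      pa <- A$pairs[max(1, na - anchor + 1), ]
      pb <- B$pairs[min(anchor, nb), ]
      if (pb["query"] <= pa["query"] || pb["ref"] <= pa["ref"]) next
      r_dist <- rmap$positions[pb["ref"]] - rmap$positions[pa["ref"]]
      if (r_dist <= 0 || r_dist > max_span) next
      q_dist <- abs(qmap$positions[pb["query_orig"]] -
                      qmap$positions[pa["query_orig"]])
      gg <- ref_gaps[ref_gaps$scaffold == A$ref_id, , drop = FALSE]
      lo <- rmap$positions[pa["ref"]]; hi <- rmap$positions[pb["ref"]]
      inside <- gg$start >= lo & gg$end <= hi
      r_net <- r_dist - sum(gg$declared_length[inside])
      tol <- 5 * params$sigma * sqrt(max(r_net, 1000) / 1000) + 0.05 * r_net
      if (q_dist < r_net - tol ||
          q_dist > r_net + tol + sum(inside) * gap_allowance) next
      ## veto: another alignment occupying the skipped reference region
      ## means real (misplaced) sequence sits between A and B
      occupied <- FALSE
      a_end <- rmap$positions[A$pairs[na, "ref"]]
      b_start <- rmap$positions[B$pairs[1, "ref"]]
      for (di in seq_along(alignments)) {
        if (di == breakpoints$aln_id[ri] || di == breakpoints$aln_id[li]) next
        D <- alignments[[di]]
        if (D$ref_id != A$ref_id || D$channel != A$channel) next
        dmap <- ref_maps[[paste0(D$ref_id, "|", D$channel)]]
        dpos <- dmap$positions[D$pairs[, "ref"]]
        if (sum(dpos > a_end & dpos < b_start) >= 3) { occupied <- TRUE; break }
      }
      if (!occupied) {
        drop[ri] <- TRUE
        drop[li] <- TRUE
      }
    }
  }
  breakpoints[!drop, , drop = FALSE]
}
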